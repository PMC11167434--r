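# helper: tstat map from an array
tmap_of <- function(arr, df = 12) {
  stat_map(arr, kind = "tstat", df = df)
}

test_that("conjunction equals the intersection of thresholded maps", {
  set.seed(4)
  d <- c(8, 8, 6)
  tcrit <- stats::qt(0.999, 12)
  for (rep in 1:20) {
    maps <- lapply(1:3, function(i) {
      tmap_of(array(rnorm(prod(d), sd = 4), dim = d))
    })
    cj <- conjunction(maps, 0.001)
    inter <- Reduce(`&`, lapply(maps, function(m) m$data > tcrit))
    expect_equal(cj$data != 0, inter, ignore_attr = TRUE)
    # subset of every individually thresholded input
    for (m in maps) {
      expect_true(all(cj$data <= (m$data > tcrit)))
    }
  }
})

test_that("conjunction of identical maps reproduces each thresholded map", {
  set.seed(9)
  d <- c(8, 8, 6)
  m <- tmap_of(array(rnorm(prod(d), sd = 4), dim = d))
  cj <- conjunction(list(m, m), 0.001)
  single <- threshold_cluster(m, 0.001)
  expect_equal(cj$data, single$data)
})

test_that("disjoint suprathreshold sets give an empty conjunction", {
  d <- c(6, 6, 4)
  a <- array(-1, dim = d); a[1:3, , ] <- 10
  b <- array(-1, dim = d); b[4:6, , ] <- 10
  cj <- conjunction(list(tmap_of(a), tmap_of(b)), 0.001)
  expect_equal(sum(cj$data), 0)
  expect_error(conjunction(list(), 0.001), "at least")
  expect_error(conjunction(list(tmap_of(a)), 0.001), ">= 2")
})

test_that("8 planted-ROI t-maps sharing one ROI conjoin to that ROI", {
  d <- c(12, 12, 10)
  shared <- roi_sphere(c(6, 6, 5), 2, d)
  maps <- lapply(1:8, function(i) {
    a <- array(0, dim = d)
    own <- roi_sphere(c(3 + (i %% 3) * 3, 3 + (i %% 4) * 2, 3), 1.5, d)
    a[own] <- 8
    a[shared] <- 8
    tmap_of(a)
  })
  cj <- conjunction(maps, 0.001)
  expect_setequal(which(cj$data != 0), shared)
})

test_that("global-null conjunction is laxer than conjunction-null", {
  set.seed(2)
  d <- c(8, 8, 6)
  maps <- lapply(1:4, function(i) {
    tmap_of(array(rnorm(prod(d), mean = 1.5, sd = 1.5), dim = d))
  })
  strict <- conjunction(maps, 0.001)
  lax <- conjunction(maps, 0.001, conj_null = "global")
  expect_true(all(lax$data >= strict$data))
})

# build subject maps with planted per-condition amplitudes
planted_subject_maps <- function(n_subjects, amp, d = c(12, 12, 10),
                                 noise = 0.3, seed = 1) {
  conds <- names(amp)
  rois <- list(
    face = roi_sphere(c(3, 3, 3), 1.5, d),
    hands = roi_sphere(c(3, 9, 3), 1.5, d),
    trunk = roi_sphere(c(9, 3, 3), 1.5, d),
    feet = roi_sphere(c(9, 9, 3), 1.5, d))
  set.seed(seed)
  subj <- lapply(seq_len(n_subjects), function(i) {
    out <- lapply(conds, function(cn) {
      seg <- sub("_(motor|tactile)$", "", cn)
      a <- array(rnorm(prod(d), sd = noise), dim = d)
      a[rois[[seg]]] <- a[rois[[seg]]] + amp[[cn]]
      stat_map(a, kind = "beta")
    })
    names(out) <- conds
    out
  })
  attr(subj, "rois") <- rois
  subj
}

all_conds <- function() {
  as.vector(outer(c("face", "hands", "trunk", "feet"),
                  c("motor", "tactile"), paste, sep = "_"))
}

test_that("segment-specific map recovers a planted dominant segment", {
  amp <- stats::setNames(rep(1, 8), all_conds())
  amp[c("hands_motor", "hands_tactile")] <- 2
  subj <- planted_subject_maps(20, amp, seed = 31)
  rois <- attr(subj, "rois")
  m <- segment_specific_map(subj, "hands", voxel_p = 0.001)
  on <- which(m$data != 0)
  expect_true(all(on %in% rois$hands))
  expect_gte(length(intersect(on, rois$hands)),
             0.9 * length(rois$hands))
})

test_that("segment contrast cancels when all conditions share one map", {
  # all 8 contrast images identical within subject: the target-vs-others
  # contrast cancels exactly, leaving an empty (zero-variance) map
  set.seed(5)
  d <- c(12, 12, 10)
  subj <- lapply(1:12, function(i) {
    base <- array(rnorm(prod(d), mean = 2), dim = d)
    out <- lapply(all_conds(), function(cn) stat_map(base, kind = "beta"))
    stats::setNames(out, all_conds())
  })
  m <- segment_specific_map(subj, "face", voxel_p = 0.001)
  expect_equal(sum(m$data), 0)
  neg <- lapply(subj, function(sm) {
    lapply(sm, function(x) { x$data <- -x$data; x })
  })
  m2 <- segment_specific_map(neg, "face", voxel_p = 0.001)
  expect_equal(sum(m2$data), 0)
  expect_error(segment_specific_map(subj, "arms"), "face|%in%")
})

test_that("missing contrast maps are rejected", {
  amp <- stats::setNames(rep(1, 8), all_conds())
  subj <- planted_subject_maps(5, amp)
  subj <- lapply(subj, function(sm) sm[-1])
  expect_error(segment_specific_map(subj, "face"), "missing contrast")
})

test_that("motor/tactile partition matches the voxelwise sign oracle", {
  amp <- stats::setNames(c(3, 3, 3, 3, 1, 1, 1, 1), all_conds())
  subj <- planted_subject_maps(16, amp, seed = 17, noise = 0.2)
  d <- c(12, 12, 10)
  wb <- stat_map(array(1, dim = d), kind = "binary")
  part <- motor_tactile_partition(subj, wb, voxel_p = 1e-5)
  rois <- attr(subj, "rois")
  allroi <- sort(unlist(rois))
  # motor-dominant everywhere signal exists
  expect_gte(sum(part$motor$data[allroi] != 0), 0.9 * length(allroi))
  expect_equal(sum(part$tactile$data), 0)
  # outputs disjoint
  expect_equal(max(part$motor$data + part$tactile$data), 1)
  # motor == tactile imagewise: both outputs exactly empty
  set.seed(3)
  subj_eq <- lapply(1:12, function(i) {
    base <- array(rnorm(prod(d), mean = 1.5), dim = d)
    stats::setNames(lapply(all_conds(), function(cn) {
      stat_map(base, kind = "beta")
    }), all_conds())
  })
  part_eq <- motor_tactile_partition(subj_eq, wb, voxel_p = 0.001)
  expect_equal(sum(part_eq$motor$data) + sum(part_eq$tactile$data), 0)
  expect_error(motor_tactile_partition(subj, wb, voxel_p = NULL),
               "thresholds")
})

test_that("raising voxel_p never shrinks a thresholded mask", {
  set.seed(6)
  d <- c(8, 8, 6)
  m <- tmap_of(array(rnorm(prod(d), mean = 1, sd = 2), dim = d))
  sizes <- vapply(c(0.0005, 0.001, 0.01, 0.05, 0.2),
                  function(p) sum(threshold_cluster(m, p)$data),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("segment mask set is pairwise disjoint and well-formed", {
  amp <- stats::setNames(c(2, 1, 1, 1, 2, 1, 1, 1), all_conds())
  subj <- planted_subject_maps(14, amp, seed = 23, noise = 0.25)
  masks <- build_segment_masks(subj, voxel_p = 0.001)
  seg <- masks$segments
  stack <- Reduce(`+`, lapply(seg, function(m) m$data))
  expect_lte(max(stack), 1)  # no voxel claimed twice
  expect_equal(names(seg), c("face", "hands", "trunk", "feet"))
  # face dominates: its specific map covers most of its ROI
  rois <- attr(subj, "rois")
  expect_gte(sum(seg$face$data[rois$face] != 0),
             0.9 * length(rois$face))
})

test_that("mask sets write to NIfTI with a manifest and read back", {
  amp <- stats::setNames(c(2, 1, 1, 1, 2, 1, 1, 1), all_conds())
  subj <- planted_subject_maps(8, amp, seed = 2, noise = 0.25)
  masks <- build_segment_masks(subj, voxel_p = 0.001)
  dir <- withr::local_tempdir()
  manifest <- write_segment_masks(masks, dir)
  expect_true(file.exists(file.path(dir, "whole_body_conjunction.nii.gz")))
  meta <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  expect_equal(meta$provenance$voxel_p, 0.001)
  rt <- read_stat_map(file.path(dir, "face_specific.nii.gz"))
  expect_equal(rt$data, masks$segments$face$data, ignore_attr = TRUE)
  expect_equal(rt$kind, "binary")
})
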