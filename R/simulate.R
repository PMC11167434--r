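#' @importFrom stats rnorm
NULL

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards, so generators are pure functions of their seed.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Round half away from zero
#'
#' The rounding rule used for every planted fraction-times-count quantity
#' (voxels, pixels), so counting oracles are unambiguous: 0.5 rounds to
#' 1, -0.5 to -1.
#'
#' @param x numeric vector.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Voxel indices of a spherical ROI
#'
#' @param center voxel coordinate (3-vector, 1-based).
#' @param radius radius in voxels.
#' @param dim grid dimensions.
#' @return integer vector of linear voxel indices.
#' @export
roi_sphere <- function(center, radius, dim) {
  rng <- lapply(1:3, function(a) {
    seq(max(1L, floor(center[a] - radius)), min(dim[a], ceiling(center[a] + radius)))
  })
  g <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  g <- g[d2 <= radius^2, , drop = FALSE]
  as.integer(g$x + (g$y - 1L) * dim[1] + (g$z - 1L) * dim[1] * dim[2])
}

#' Planted ground truth for the synthetic study
#'
#' Defines where each localizer condition activates (one spherical ROI per
#' body segment and modality, plus an optional shared "whole-body" ROI
#' active in every localizer condition, emulating regions with broad
#' receptive fields), the planted effect sizes, the emotion-to-segment
#' overlap fractions, and the noise model.
#'
#' @param grid a [grid_spec()].
#' @param roi_centers named list mapping condition labels (e.g.
#'   `"face_motor"`) to voxel coordinates; default lays out 8 disjoint
#'   spheres on the default grid.
#' @param roi_radius_vox sphere radius in voxels (default 3).
#' @param shared_center voxel coordinate of the ROI shared by all
#'   localizer conditions, or `NULL` for none.
#' @param effect_size named vector of planted beta amplitudes per
#'   condition; unnamed scalar recycles to all conditions (default 2).
#' @param emotion_overlap_fraction emotions x segments matrix of planted
#'   overlap fractions in `[0, 1]`.
#' @param emotion_shared_fraction named per-emotion fraction of the shared
#'   whole-body ROI activated during recall (how strongly each emotion
#'   engages the conjunction map).
#' @param noise_sd i.i.d. Gaussian noise SD (default 1).
#' @param drift_amplitude amplitude of the low-frequency cosine drift
#'   (default 1).
#' @param baseline constant added to every voxel (default 0; set to e.g.
#'   100 when exercising proportional global scaling).
#' @param seed integer RNG seed.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(grid = grid_spec(),
                         roi_centers = default_roi_centers(grid),
                         roi_radius_vox = 3,
                         shared_center = default_shared_center(grid),
                         effect_size = 2,
                         emotion_overlap_fraction = default_overlap_fractions(),
                         emotion_shared_fraction = default_shared_fractions(),
                         noise_sd = 1,
                         drift_amplitude = 1,
                         baseline = 0,
                         seed = 1L) {
  stopifnot(noise_sd >= 0, drift_amplitude >= 0, roi_radius_vox >= 1)
  if (!is.null(emotion_overlap_fraction)) {
    stopifnot(all(emotion_overlap_fraction >= 0),
              all(emotion_overlap_fraction <= 1))
  }
  if (is.null(names(effect_size)) && length(effect_size) == 1L) {
    effect_size <- stats::setNames(rep(effect_size, length(roi_centers)),
                                   names(roi_centers))
  }
  truth <- structure(list(grid = grid, roi_centers = roi_centers,
                          roi_radius_vox = roi_radius_vox,
                          shared_center = shared_center,
                          effect_size = effect_size,
                          emotion_overlap_fraction = emotion_overlap_fraction,
                          emotion_shared_fraction = emotion_shared_fraction,
                          noise_sd = noise_sd,
                          drift_amplitude = drift_amplitude,
                          baseline = baseline, seed = as.integer(seed),
                          extra_voxels = list()),
                     class = "ground_truth")
  check_roi_disjoint(truth)
  if (!is.null(shared_center)) {
    if (any(shared_center - roi_radius_vox < 1) ||
        any(shared_center + roi_radius_vox > grid$dim)) {
      stop("shared ROI does not fit inside the grid")
    }
    sh <- roi_sphere(shared_center, roi_radius_vox, grid$dim)
    for (cn in names(roi_centers)) {
      if (length(intersect(sh, roi_sphere(roi_centers[[cn]],
                                          roi_radius_vox, grid$dim)))) {
        warning("shared ROI overlaps segment ROI ", cn)
      }
    }
  }
  truth
}

#' Body segments and emotions of the paradigm
#'
#' The four body districts used by the localizer tasks and silhouette
#' labeling, and the five recalled emotions, in canonical order.
#'
#' @return character vector.
#' @export
body_segments <- function() c("face", "hands", "trunk", "feet")

#' @rdname body_segments
#' @export
emotion_names <- function() {
  c("happiness", "sadness", "fear", "anger", "serenity")
}

#' @rdname ground_truth
#' @export
default_shared_center <- function(grid = grid_spec()) {
  round(grid$dim * c(0.5, 0.5, 0.8))
}

#' @rdname ground_truth
#' @export
default_roi_centers <- function(grid = grid_spec()) {
  d <- grid$dim
  q <- function(f) round(d * f)
  cs <- list(
    face_motor   = c(q(0.25)[1], q(0.25)[2], q(0.3)[3]),
    face_tactile = c(q(0.25)[1], q(0.25)[2], q(0.7)[3]),
    hands_motor   = c(q(0.25)[1], q(0.75)[2], q(0.3)[3]),
    hands_tactile = c(q(0.25)[1], q(0.75)[2], q(0.7)[3]),
    trunk_motor   = c(q(0.75)[1], q(0.25)[2], q(0.3)[3]),
    trunk_tactile = c(q(0.75)[1], q(0.25)[2], q(0.7)[3]),
    feet_motor   = c(q(0.75)[1], q(0.75)[2], q(0.3)[3]),
    feet_tactile = c(q(0.75)[1], q(0.75)[2], q(0.7)[3])
  )
  cs
}

# Default planted emotion-to-segment overlap fractions: every emotion
# touches every segment to a different degree, face generally strongest,
# mirroring the qualitative structure of group body-emotion tables.
default_overlap_fractions <- function() {
  m <- rbind(happiness = c(0.50, 0.25, 0.30, 0.10),
             sadness   = c(0.60, 0.20, 0.30, 0.05),
             fear      = c(0.20, 0.25, 0.35, 0.15),
             anger     = c(0.35, 0.25, 0.15, 0.05),
             serenity  = c(0.25, 0.20, 0.15, 0.10))
  colnames(m) <- body_segments()
  m
}

# Fraction of the shared whole-body ROI engaged per emotion: sadness
# strongest, anger weakest, echoing how unevenly recalled emotions cover
# a sensorimotor conjunction map.
default_shared_fractions <- function() {
  c(happiness = 0.10, sadness = 0.20, fear = 0.08, anger = 0.03,
    serenity = 0.05)
}

segment_of_condition <- function(cond) sub("_(motor|tactile)$", "", cond)

roi_voxels_for <- function(truth, cond, include_shared = TRUE) {
  v <- integer(0)
  if (cond %in% names(truth$roi_centers)) {
    v <- roi_sphere(truth$roi_centers[[cond]], truth$roi_radius_vox,
                    truth$grid$dim)
  }
  if (include_shared && !is.null(truth$shared_center) &&
      grepl("_(motor|tactile)$", cond)) {
    v <- union(v, roi_sphere(truth$shared_center, truth$roi_radius_vox,
                             truth$grid$dim))
  }
  if (cond %in% names(truth$extra_voxels)) {
    v <- union(v, truth$extra_voxels[[cond]])
  }
  sort(v)
}

check_roi_disjoint <- function(truth) {
  conds <- names(truth$roi_centers)
  segs <- segment_of_condition(conds)
  vox <- lapply(conds, function(cn) {
    roi_sphere(truth$roi_centers[[cn]], truth$roi_radius_vox, truth$grid$dim)
  })
  n <- length(conds)
  if (n < 2) return(invisible(TRUE))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (segs[i] != segs[j] && length(intersect(vox[[i]], vox[[j]]))) {
        stop(sprintf("ROIs for distinct segments overlap: %s vs %s",
                     conds[i], conds[j]))
      }
    }
  }
  invisible(TRUE)
}

#' Simulate one 4-D block-design run
#'
#' Inside each condition's ROI the time series is the planted beta times
#' the boxcar convolved with the canonical HRF; a low-frequency cosine
#' drift and i.i.d. Gaussian noise are added everywhere, on top of a
#' constant baseline.  Deterministic given the seed.
#'
#' @param design a [design_spec()] whose condition names match entries of
#'   `truth$roi_centers` (or `truth$extra_voxels`).
#' @param truth a [ground_truth()].
#' @param grid a [grid_spec()]; defaults to the grid in `truth`.
#' @param seed RNG seed; defaults to `truth$seed`.
#' @return 4-D array (x, y, z, time).
#' @export
simulate_run <- function(design, truth, grid = truth$grid,
                         seed = truth$seed) {
  stopifnot(inherits(design, "design_spec"), inherits(truth, "ground_truth"))
  if (truth$noise_sd < 0) stop("noise_sd must be >= 0")
  check_roi_disjoint(truth)
  d <- grid$dim
  for (cn in names(truth$roi_centers)) {
    ctr <- truth$roi_centers[[cn]]
    if (any(ctr - truth$roi_radius_vox < 1) ||
        any(ctr + truth$roi_radius_vox > d)) {
      stop("grid too small to contain ROI ", cn)
    }
  }
  nvox <- prod(d)
  nt <- design$n_volumes
  mat <- matrix(truth$baseline, nrow = nvox, ncol = nt)
  for (cn in design$condition_names) {
    beta <- truth$effect_size[cn]
    if (is.na(beta)) beta <- 0
    if (beta == 0) next
    vox <- roi_voxels_for(truth, cn)
    if (!length(vox)) next
    reg <- convolved_regressor(design, cn)
    mat[vox, ] <- mat[vox, , drop = FALSE] +
      beta * matrix(reg, nrow = length(vox), ncol = nt, byrow = TRUE)
  }
  if (truth$drift_amplitude > 0) {
    drift <- truth$drift_amplitude *
      cos(pi * (2 * seq_len(nt) - 1) / (2 * nt))
    mat <- mat + matrix(drift, nrow = nvox, ncol = nt, byrow = TRUE)
  }
  if (truth$noise_sd > 0) {
    mat <- mat + with_seed(seed, {
      matrix(rnorm(nvox * nt, sd = truth$noise_sd), nrow = nvox)
    })
  }
  array(mat, dim = c(d, nt))
}

#' Plant group-level emotion maps with controlled overlap
#'
#' For each emotion, builds a binary suprathreshold map whose intersection
#' with each segment mask has exactly `round(fraction * |mask|)` voxels
#' (round-half-away-from-zero), plus `n_outside` voxels outside all masks.
#'
#' @param truth a [ground_truth()] carrying `emotion_overlap_fraction`.
#' @param masks named list of binary segment [stat_map()]s (one per body
#'   segment).
#' @param n_outside number of suprathreshold voxels planted outside all
#'   masks (default 50).
#' @param seed RNG seed; defaults to `truth$seed`.
#' @return named list of binary [stat_map()]s, one per emotion.
#' @export
simulate_emotion_maps <- function(truth, masks, n_outside = 50,
                                  seed = truth$seed) {
  frac <- truth$emotion_overlap_fraction
  stopifnot(is.matrix(frac), !is.null(rownames(frac)))
  if (!length(masks)) stop("masks must be nonempty")
  segs <- colnames(frac)
  stopifnot(all(segs %in% names(masks)))
  dimg <- dim(masks[[1]]$data)
  mask_idx <- lapply(masks[segs], function(m) which(m$data != 0))
  if (any(!lengths(mask_idx))) stop("masks must be nonempty")
  all_in <- sort(unique(unlist(mask_idx)))
  outside <- setdiff(seq_len(prod(dimg)), all_in)
  with_seed(seed, {
    out <- lapply(rownames(frac), function(e) {
      chosen <- integer(0)
      for (s in segs) {
        f <- frac[e, s]
        k <- round_half_away(f * length(mask_idx[[s]]))
        if (f > 0 && k < 1) {
          warning(sprintf(
            "%s/%s: fraction %.3g of %d voxels rounds to 0", e, s, f,
            length(mask_idx[[s]])))
        }
        if (k >= 1) {
          chosen <- c(chosen, sample(mask_idx[[s]], k))
        }
      }
      if (n_outside > 0) {
        chosen <- c(chosen, sample(outside, min(n_outside, length(outside))))
      }
      m <- array(0, dim = dimg)
      m[chosen] <- 1
      stat_map(m, affine = masks[[1]]$affine, kind = "binary",
               threshold_meta = list(method = "planted"))
    })
    names(out) <- rownames(frac)
    out
  })
}

#' Plant subject-level emotion activation inside segment ROIs
#'
#' For GLM-backed synthetic recall runs: selects, per emotion and segment,
#' a deterministic subset of the segment's conjunction ROI voxels covering
#' the planted overlap fraction, and registers it in `truth$extra_voxels`
#' under the emotion's condition name so [simulate_run()] activates it.
#'
#' @param truth a [ground_truth()].
#' @param effect planted beta amplitude for each emotion condition
#'   (default 2); the neutral condition gets beta 0.
#' @param seed seed for subset selection; defaults to `truth$seed`.
#' @return the modified `ground_truth`, with an `extra_voxels` entry and
#'   an `effect_size` entry per emotion.
#' @export
plant_emotion_betas <- function(truth, effect = 2, seed = truth$seed) {
  frac <- truth$emotion_overlap_fraction
  segs <- colnames(frac)
  seg_vox <- lapply(segs, function(s) {
    sort(union(
      roi_sphere(truth$roi_centers[[paste0(s, "_motor")]],
                 truth$roi_radius_vox, truth$grid$dim),
      roi_sphere(truth$roi_centers[[paste0(s, "_tactile")]],
                 truth$roi_radius_vox, truth$grid$dim)))
  })
  names(seg_vox) <- segs
  shared_vox <- if (!is.null(truth$shared_center)) {
    roi_sphere(truth$shared_center, truth$roi_radius_vox, truth$grid$dim)
  } else integer(0)
  # activation is planted as a compact blob (voxels nearest a random
  # anchor within the ROI), emulating spatially contiguous activation
  blob <- function(vox, k) {
    if (k < 1) return(integer(0))
    anchor <- sample(vox, 1)
    co <- arrayInd(vox, truth$grid$dim)
    a <- arrayInd(anchor, truth$grid$dim)
    d2 <- rowSums(sweep(co, 2, as.numeric(a))^2)
    sort(vox[order(d2, vox)[seq_len(min(k, length(vox)))]])
  }
  with_seed(seed, {
    for (e in rownames(frac)) {
      chosen <- integer(0)
      for (s in segs) {
        k <- round_half_away(frac[e, s] * length(seg_vox[[s]]))
        chosen <- c(chosen, blob(seg_vox[[s]], k))
      }
      fs <- truth$emotion_shared_fraction[e]
      if (length(shared_vox) && !is.na(fs) && fs > 0) {
        chosen <- c(chosen, blob(shared_vox,
                                 round_half_away(fs * length(shared_vox))))
      }
      truth$extra_voxels[[e]] <- chosen
      truth$effect_size[e] <- effect
    }
    truth$effect_size["neutral"] <- 0
    truth
  })
}

#' Simulate per-episode intensity and vividness ratings
#'
#' Emotional episodes are drawn around `neutral_mean + effect`, neutral
#' episodes around `neutral_mean`; values are rounded to integers and
#' clipped to the 1-5 scale.
#'
#' @param n_emotional episodes per emotion (default 3).
#' @param n_neutral total neutral episodes (default one per emotional
#'   episode).
#' @param effect planted emotional-minus-neutral mean difference.
#' @param sd rating noise SD before rounding.
#' @param seed RNG seed.
#' @param emotions emotion labels.
#' @param neutral_mean mean of neutral ratings (default 2).
#' @param subject_id subject label.
#' @return data frame of class `ratings_table` with columns subject_id,
#'   episode_id, condition, emotion, intensity, vividness.
#' @export
simulate_ratings <- function(n_emotional = 3,
                             n_neutral = n_emotional * length(emotions),
                             effect = 1.5, sd = 0.8, seed = 1L,
                             emotions = emotion_names(),
                             neutral_mean = 2, subject_id = "s01") {
  stopifnot(n_emotional > 0, n_neutral > 0, sd >= 0)
  if (neutral_mean + effect > 5 || neutral_mean + effect < 1) {
    warning("planted emotional mean lies outside the 1-5 scale")
  }
  clip <- function(x) pmin(5L, pmax(1L, as.integer(round_half_away(x))))
  with_seed(seed, {
    emo <- expand.grid(rep = seq_len(n_emotional), emotion = emotions,
                       stringsAsFactors = FALSE)
    n_e <- nrow(emo)
    df <- data.frame(
      subject_id = subject_id,
      episode_id = c(sprintf("emo_%s_%d", emo$emotion, emo$rep),
                     sprintf("neutral_%d", seq_len(n_neutral))),
      condition = c(paste0("emotional:", emo$emotion),
                    rep("neutral", n_neutral)),
      emotion = c(emo$emotion, rep(NA_character_, n_neutral)),
      intensity = clip(c(rnorm(n_e, neutral_mean + effect, sd),
                         rnorm(n_neutral, neutral_mean, sd))),
      vividness = clip(c(rnorm(n_e, neutral_mean + effect, sd),
                         rnorm(n_neutral, neutral_mean, sd))),
      stringsAsFactors = FALSE)
    class(df) <- c("ratings_table", "data.frame")
    df
  })
}

#' Default localizer block design
#'
#' 20 s task blocks alternated with 20 s rest, cycling over the four body
#' segments.  Condition labels are `<segment>_<modality>`.
#'
#' @param modality `"motor"` or `"tactile"`.
#' @param n_cycles repetitions of the 4-segment cycle (default 4).
#' @param tr_seconds TR (default 2).
#' @param block_s,rest_s block and rest durations (default 20 s each).
#' @return a [design_spec()].
#' @export
localizer_design <- function(modality = c("motor", "tactile"), n_cycles = 4,
                             tr_seconds = 2, block_s = 20, rest_s = 20) {
  modality <- match.arg(modality)
  segs <- c("hands", "feet", "face", "trunk")  # fixed stimulation order
  conds <- paste0(segs, "_", modality)
  onsets <- seq(0, by = block_s + rest_s, length.out = n_cycles * 4)
  blocks <- data.frame(onset = onsets, duration = block_s,
                       condition = rep(conds, n_cycles))
  total <- max(onsets) + block_s + rest_s
  design_spec(tr_seconds, ceiling(total / tr_seconds), blocks,
              condition_names = paste0(body_segments(), "_", modality))
}

#' Default emotional-recall block design
#'
#' 14 s emotional episodes (n per emotion) alternated with 14 s neutral
#' episodes, with a gap after each episode for the rating period.
#'
#' @param n_per_emotion episodes per emotion (default 3).
#' @param tr_seconds TR (default 2).
#' @param episode_s episode duration (default 14 s).
#' @param gap_s gap between episodes (default 10 s).
#' @param emotions emotion labels.
#' @param seed seed for the episode-order shuffle.
#' @return a [design_spec()].
#' @export
recall_design <- function(n_per_emotion = 3, tr_seconds = 2, episode_s = 14,
                          gap_s = 10, emotions = emotion_names(), seed = 1L) {
  emo_eps <- rep(emotions, n_per_emotion)
  emo_eps <- with_seed(seed, sample(emo_eps))
  conds <- as.vector(rbind(emo_eps, "neutral"))  # alternate with neutral
  onsets <- seq(0, by = episode_s + gap_s, length.out = length(conds))
  blocks <- data.frame(onset = onsets, duration = episode_s,
                       condition = conds)
  total <- max(onsets) + episode_s + gap_s
  design_spec(tr_seconds, ceiling(total / tr_seconds), blocks,
              condition_names = c(emotions, "neutral"))
}
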