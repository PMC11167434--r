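test_that("null signal gives an all-zero volume", {
  truth <- tiny_truth()
  truth$effect_size["face_motor"] <- 0
  vol <- simulate_run(one_block_design(), truth)
  expect_true(all(vol == 0))
})

test_that("noiseless ROI time series equals boxcar convolved with HRF", {
  truth <- tiny_truth()
  ds <- one_block_design()
  vol <- simulate_run(ds, truth)
  reg <- emomap:::convolved_regressor(ds, "face_motor")
  roi <- roi_sphere(c(8, 8, 6), 3, tiny_grid()$dim)
  mat <- matrix(vol, nrow = prod(tiny_grid()$dim))
  expect_equal(unname(mat[roi[1], ]), reg, tolerance = 1e-12)
  expect_true(all(mat[-roi, ] == 0))
})

test_that("simulation is a pure function of its seed", {
  truth <- tiny_truth(noise_sd = 1, drift = 1, seed = 42)
  ds <- one_block_design()
  v1 <- simulate_run(ds, truth)
  v2 <- simulate_run(ds, truth)
  expect_identical(v1, v2)
  v3 <- simulate_run(ds, truth, seed = 43)
  expect_false(identical(v1, v3))
  # seeding does not disturb the caller's RNG stream
  set.seed(1); a <- rnorm(3)
  set.seed(1); invisible(simulate_run(ds, truth)); b <- rnorm(3)
  expect_identical(a, b)
})

test_that("overlapping ROIs for distinct segments are rejected", {
  expect_error(
    ground_truth(grid = tiny_grid(),
                 roi_centers = list(face_motor = c(8, 8, 6),
                                    hands_motor = c(9, 8, 6)),
                 shared_center = NULL, effect_size = 1),
    "overlap")
  # same segment, two modalities may overlap
  expect_silent(
    ground_truth(grid = tiny_grid(),
                 roi_centers = list(face_motor = c(8, 8, 6),
                                    face_tactile = c(9, 8, 6)),
                 shared_center = NULL, effect_size = 1))
})

test_that("negative noise is rejected", {
  expect_error(tiny_truth(noise_sd = -1), "noise_sd")
})

test_that("planted emotion maps hit exact per-segment counts", {
  masks <- tiny_segment_masks(dim = c(20, 20, 12), each = 1000)
  truth <- ground_truth(grid = grid_spec(c(20, 20, 12)),
                        roi_centers = list(), shared_center = NULL,
                        effect_size = numeric(0),
                        emotion_overlap_fraction = rbind(
                          happiness = c(face = 0.25, hands = 0.5,
                                        trunk = 1, feet = 0)),
                        seed = 5)
  maps <- simulate_emotion_maps(truth, masks, n_outside = 30)
  em <- maps$happiness
  counts <- vapply(masks, function(m) sum(em$data * m$data), numeric(1))
  expect_equal(unname(counts), c(250, 500, 1000, 0))
  all_in <- Reduce(`+`, lapply(masks, function(m) m$data))
  expect_equal(sum(em$data * (all_in == 0)), 30)
  # determinism
  maps2 <- simulate_emotion_maps(truth, masks, n_outside = 30)
  expect_identical(maps, maps2)
})

test_that("fraction rounding warns when a positive fraction rounds to 0", {
  masks <- tiny_segment_masks(each = 10)
  truth <- ground_truth(grid = grid_spec(c(10, 10, 8)),
                        roi_centers = list(), shared_center = NULL,
                        effect_size = numeric(0),
                        emotion_overlap_fraction = rbind(
                          happiness = c(face = 0.04, hands = 0, trunk = 0,
                                        feet = 0)),
                        seed = 5)
  expect_warning(maps <- simulate_emotion_maps(truth, masks,
                                               n_outside = 0),
                 "rounds to 0")
  expect_equal(sum(maps$happiness$data), 0)
})

test_that("silhouette generator plants exact per-segment pixel counts", {
  tpl <- body_template()
  fr <- c(face = 0.123, hands = 0.25, trunk = 0.5, feet = 0)
  sil <- simulate_silhouette(fr, 0, tpl, seed = 9)
  for (i in seq_along(fr)) {
    seg_px <- tpl$segment_labels == i
    expect_equal(sum(sil$activation[seg_px]),
                 emomap:::round_half_away(fr[i] * sum(seg_px)),
                 ignore_attr = TRUE)
  }
  expect_true(all(sil$activation[tpl$body_mask == 0] == 0))
})

test_that("silhouette channels are disjoint unless overlap is allowed", {
  tpl <- body_template()
  sil <- simulate_silhouette(0.4, 0.4, tpl, seed = 1)
  expect_equal(max(sil$activation + sil$deactivation), 1)
  expect_error(simulate_silhouette(0.7, 0.5, tpl, seed = 1),
               "disjoint")
  sil2 <- simulate_silhouette(0.7, 0.5, tpl, seed = 1,
                              allow_overlap = TRUE)
  expect_gt(max(sil2$activation + sil2$deactivation), 1)
})

test_that("all-zero and all-one silhouette fractions behave as planted", {
  tpl <- body_template()
  s0 <- simulate_silhouette(0, 0, tpl, seed = 1)
  expect_equal(sum(s0$activation) + sum(s0$deactivation), 0)
  s1 <- simulate_silhouette(c(face = 1, hands = 0, trunk = 0, feet = 0),
                            0, tpl, seed = 1)
  expect_equal(sum(s1$activation[tpl$segment_labels == 1]),
               tpl$segment_counts[["face"]])
})

test_that("ratings generator plants the emotional-neutral effect", {
  # effect 0, sd -> 0: constant identical columns
  r0 <- simulate_ratings(n_emotional = 3, effect = 0, sd = 1e-9,
                         seed = 1, neutral_mean = 3)
  expect_true(all(r0$intensity == 3))
  expect_true(all(r0$vividness == 3))
  # reproducible given seed
  expect_identical(simulate_ratings(seed = 7), simulate_ratings(seed = 7))
  # effect placing means off-scale warns
  expect_warning(simulate_ratings(effect = 4.5, seed = 1), "scale")
})

test_that("planted rating effect is detected by a paired t-test", {
  # effect 2, sd 0.3, 15 episodes per arm: p < 0.05 in >= 95% of seeds
  hits <- vapply(1:200, function(s) {
    r <- simulate_ratings(n_emotional = 3, n_neutral = 15, effect = 2,
                          sd = 0.3, seed = s, neutral_mean = 2)
    emo <- r$intensity[r$condition != "neutral"]
    neu <- r$intensity[r$condition == "neutral"]
    d <- emo - neu
    # integer rounding can make the paired differences constant; a
    # constant nonzero difference is a (perfectly) significant effect
    if (stats::sd(d) == 0) mean(d) != 0
    else stats::t.test(d)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
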