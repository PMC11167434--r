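tpl <- body_template()

test_that("template segments partition the body mask", {
  expect_equal(sum(tpl$segment_counts), tpl$pixel_count_inside)
  expect_true(all((tpl$segment_labels > 0) == (tpl$body_mask == 1)))
  expect_true(all(tpl$segment_counts > 100))
})

test_that("registering the template to itself is near-identity", {
  sil <- simulate_silhouette(0.3, 0.1, tpl, seed = 4)
  scan <- render_scan(sil, tpl)
  reg <- register_to_template(scan, tpl)
  expect_lt(abs(reg$transform$tx), 0.5)
  expect_lt(abs(reg$transform$ty), 0.5)
  expect_lt(abs(reg$transform$angle_deg), 0.5)
  expect_lt(abs(reg$transform$scale - 1), 0.01)
})

test_that("planted similarity transforms are recovered", {
  sil <- simulate_silhouette(c(face = 0.5, hands = 0.25, trunk = 0.3,
                               feet = 0.1), 0, tpl, seed = 2)
  cases <- list(list(tx = 5, ty = -3, angle_deg = 0, scale = 1),
                list(tx = -9, ty = 8, angle_deg = -4.5, scale = 1),
                list(tx = 2, ty = 6, angle_deg = 3, scale = 1.02))
  for (tr in cases) {
    scan <- render_scan(sil, tpl, tr)
    reg <- register_to_template(scan, tpl)
    expect_lt(abs(reg$transform$tx - tr$tx), 0.5)
    expect_lt(abs(reg$transform$ty - tr$ty), 0.5)
    expect_lt(abs(reg$transform$angle_deg - tr$angle_deg), 0.5)
  }
})

test_that("a blank page fails registration with a metric report", {
  blank <- matrix(1, tpl$dim[1], tpl$dim[2])
  expect_error(register_to_template(blank, tpl), "converge")
})

test_that("pixel coding matches a per-pixel hue-rule oracle", {
  sil <- simulate_silhouette(c(face = 1, hands = 0, trunk = 0.2,
                               feet = 0),
                             c(face = 0, hands = 0.3, trunk = 0.1,
                               feet = 0), tpl, seed = 6)
  rgb <- render_scan(sil, tpl)
  coded <- code_pixels(rgb, tpl)
  expect_equal(coded$activation, sil$activation)
  expect_equal(coded$deactivation, sil$deactivation)
  # all-white page codes to zero
  white <- array(1, dim = c(tpl$dim, 3))
  blank <- code_pixels(white, tpl)
  expect_equal(sum(blank$activation) + sum(blank$deactivation), 0)
  # pure red face region: activation counts the whole segment
  s_face <- simulate_silhouette(c(face = 1, hands = 0, trunk = 0,
                                  feet = 0), 0, tpl, seed = 1)
  cf <- code_pixels(render_scan(s_face, tpl), tpl)
  expect_equal(sum(cf$activation), tpl$segment_counts[["face"]])
  expect_equal(sum(cf$deactivation), 0)
})

test_that("pixels outside the body boundary are discarded", {
  rgb <- array(1, dim = c(tpl$dim, 3))
  rgb[, , 2] <- 0; rgb[, , 3] <- 0  # entire page red
  coded <- code_pixels(rgb, tpl)
  expect_equal(sum(coded$activation), tpl$pixel_count_inside)
  expect_true(all(coded$activation[tpl$body_mask == 0] == 0))
})

test_that("subtraction map is activation minus deactivation", {
  sil <- simulate_silhouette(0.3, 0.2, tpl, seed = 3)
  sub <- subtraction_map(sil)
  expect_true(all(sub %in% c(-1, 0, 1)))
  expect_equal(sub, sil$activation - sil$deactivation)
  # activation-only silhouette: map equals the activation channel
  a_only <- simulate_silhouette(0.4, 0, tpl, seed = 2)
  expect_equal(subtraction_map(a_only), a_only$activation)
  # identical channels cancel
  ident <- silhouette(tpl$body_mask, tpl$body_mask)
  expect_true(all(subtraction_map(ident) == 0))
})

test_that("segment percentages equal the planted counting oracle", {
  fr <- c(face = 0.25, hands = 0.5, trunk = 0.123, feet = 0)
  sil <- simulate_silhouette(fr, 0, tpl, seed = 11)
  pct <- segment_percentages(sil, tpl)
  for (s in names(fr)) {
    k <- emomap:::round_half_away(fr[[s]] * tpl$segment_counts[[s]])
    expect_equal(pct[[s]], 100 * k / tpl$segment_counts[[s]])
  }
  # fully colored trunk reads 100%; empty silhouette reads zeros
  full <- simulate_silhouette(c(face = 0, hands = 0, trunk = 1, feet = 0),
                              0, tpl, seed = 1)
  expect_equal(segment_percentages(full, tpl)[["trunk"]], 100)
  empty <- simulate_silhouette(0, 0, tpl, seed = 1)
  expect_equal(unname(segment_percentages(empty, tpl)), rep(0, 4))
  # conservation: segment counts sum to total colored pixels
  expect_equal(sum(segment_percentages(sil, tpl) *
                     tpl$segment_counts / 100),
               sum(sil$activation))
})

test_that("subtraction channel counts net-positive pixels only", {
  sil <- simulate_silhouette(c(face = 0.4, hands = 0, trunk = 0, feet = 0),
                             c(face = 0.3, hands = 0, trunk = 0, feet = 0),
                             tpl, seed = 8)
  pa <- segment_percentages(sil, tpl, channel = "activation")
  ps <- segment_percentages(sil, tpl, channel = "subtraction")
  expect_equal(pa[["face"]], ps[["face"]])  # channels disjoint here
  over <- simulate_silhouette(c(face = 0.4, hands = 0, trunk = 0,
                                feet = 0),
                              c(face = 0.4, hands = 0, trunk = 0,
                                feet = 0),
                              tpl, seed = 8, allow_overlap = TRUE)
  ps2 <- segment_percentages(over, tpl, channel = "subtraction")
  expect_lte(ps2[["face"]], pa[["face"]])
})

test_that("group pixel t-map matches analytic expectation and flags ties", {
  set.seed(14)
  n <- 26
  d <- tpl$dim
  rasters <- lapply(1:n, function(i) {
    matrix(stats::rbinom(prod(d), 1, 0.5), d[1], d[2])  # mean .5, sd .5
  })
  gt <- group_pixel_tmap(rasters)
  expect_equal(gt$df, n - 1)
  ok <- !gt$zero_variance
  expect_equal(mean(gt$t[ok]), 0.5 / (0.5 / sqrt(26)), tolerance = 0.05)
  # sign-flipped inputs negate the t raster
  gt_neg <- group_pixel_tmap(lapply(rasters, function(r) -r))
  expect_equal(gt_neg$t, -gt$t)
  # identical nonzero pixels across subjects are flagged and zeroed
  same <- lapply(1:5, function(i) matrix(1, 4, 4))
  gs <- group_pixel_tmap(same)
  expect_true(all(gs$zero_variance))
  expect_true(all(gs$t == 0))
  expect_error(group_pixel_tmap(same[1:2]), ">= 3")
})

test_that("pre/post reliability behaves at its extremes", {
  set.seed(21)
  mats <- lapply(1:26, function(i) matrix(runif(20, 0, 60), 5, 4))
  same <- prepost_reliability(mats, mats)
  expect_equal(same$r, 1)
  expect_equal(same$n, 26 * 20)
  # independent noise: negligible correlation
  indep <- lapply(1:26, function(i) matrix(runif(20, 0, 60), 5, 4))
  expect_lt(abs(prepost_reliability(mats, indep)$r), 0.2)
  # small perturbation: attenuation stays high
  jit <- lapply(mats, function(m) m + rnorm(20, 0, 0.1 * sd(m)))
  expect_gt(prepost_reliability(mats, jit)$r, 0.95)
  expect_error(prepost_reliability(list(matrix(1, 2, 2)),
                                   list(matrix(1, 2, 2))), "variance")
})

test_that("silhouettes and templates round-trip through PNG", {
  sil <- simulate_silhouette(0.3, 0.1, tpl, seed = 5,
                             subject_id = "s01", phase = "pre",
                             emotion = "fear")
  path <- withr::local_tempfile(fileext = ".png")
  write_silhouette_png(sil, path)
  back <- read_silhouette_png(path)
  expect_equal(back$activation, sil$activation)
  expect_equal(back$deactivation, sil$deactivation)
  expect_equal(back$emotion, "fear")
  tpath <- withr::local_tempfile(fileext = ".png")
  write_template_png(tpl, tpath)
  lab <- round(png::readPNG(tpath) * 4)
  expect_equal(lab, tpl$segment_labels, ignore_attr = TRUE)
})
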