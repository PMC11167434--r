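test_that("proportional scaling equalizes in-mask frame means", {
  set.seed(2)
  vol <- array(100 + rnorm(8 * 8 * 6 * 10), dim = c(8, 8, 6, 10))
  sc <- scale_global(vol)
  mat <- matrix(sc, nrow = 8 * 8 * 6)
  means <- colMeans(mat)
  expect_lt(max(abs(means - 100)), 1e-10)
  # frame means (50, 200) -> (100, 100)
  v2 <- array(rep(c(50, 200), each = 4), dim = c(2, 2, 1, 2))
  m2 <- scale_global(v2, mask = array(1, dim = c(2, 2, 1)))
  expect_equal(unique(as.vector(m2)), 100)
  # zero-mean frame rejected
  v3 <- array(0, dim = c(2, 2, 1, 2))
  expect_error(scale_global(v3, mask = array(1, dim = c(2, 2, 1)))
               , "frame mean|empty mask")
})

test_that("Gaussian smoothing reproduces the analytic kernel on a delta", {
  d <- c(21, 21, 15)
  img <- array(0, dim = d)
  img[11, 11, 8] <- 1
  fwhm <- 6  # mm at 2 mm voxels -> sigma ~ 1.274 vox
  sm <- smooth_gaussian(img, fwhm, voxel_mm = 2)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / 2
  # center value of the separable normalized kernel
  g1 <- function(k) {
    r <- ceiling(4 * sigma)
    w <- exp(-(-r:r)^2 / (2 * sigma^2))
    (w / sum(w))[r + 1 + k]
  }
  expect_equal(sm[11, 11, 8], g1(0)^3, tolerance = 1e-12)
  expect_equal(sm[12, 11, 8], g1(1) * g1(0)^2, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-8)  # mass conserved
  # fwhm 0 is the identity; constant stays constant in the interior
  expect_identical(smooth_gaussian(img, 0), img)
  cst <- array(3, dim = d)
  smc <- smooth_gaussian(cst, fwhm, voxel_mm = 2)
  expect_equal(smc[11, 11, 8], 3, tolerance = 1e-12)
})

test_that("smoothing a stat_map with a sheared affine is rejected", {
  aff <- diag(c(2, 2, 2, 1)); aff[1, 2] <- 0.5
  m <- stat_map(array(0, dim = c(4, 4, 4)), affine = aff, kind = "beta")
  expect_error(smooth_gaussian(m, 6), "shear")
})

test_that("noiseless first-level fit recovers planted betas exactly", {
  truth <- tiny_truth(drift = 1)
  truth$effect_size["face_motor"] <- 1.7
  ds <- one_block_design()
  X <- build_design(ds, highpass_s = 128)
  fit <- fit_first_level(simulate_run(ds, truth), X)
  beta <- contrast_tmap(fit, c(face_motor = 1), what = "beta")
  roi <- roi_sphere(c(8, 8, 6), 3, tiny_grid()$dim)
  expect_lt(max(abs(beta$data[roi] - 1.7)), 1e-8)
  expect_lt(max(abs(beta$data[-roi])), 1e-8)
})

test_that("first-level fit equals the direct pseudo-inverse solution", {
  set.seed(11)
  n <- 25; d <- c(4, 4, 3)
  X <- cbind(a = rnorm(n), b = rnorm(n), intercept = 1)
  vol <- array(rnorm(prod(d) * n), dim = c(d, n))
  fit <- fit_first_level(vol, X)
  Y <- t(matrix(vol, nrow = prod(d)))
  B <- solve(t(X) %*% X) %*% t(X) %*% Y
  expect_lt(max(abs(fit$beta - t(B))), 1e-10)
  rv <- colSums((Y - X %*% B)^2) / (n - 3)
  expect_lt(max(abs(fit$resvar - rv)), 1e-10)
})

test_that("duplicated design columns are rejected with names", {
  set.seed(1)
  X <- cbind(a = rnorm(10), b = rnorm(10))
  X <- cbind(X, a_copy = X[, "a"])
  vol <- array(rnorm(2 * 2 * 2 * 10), dim = c(2, 2, 2, 10))
  expect_error(fit_first_level(vol, X), "rank deficient.*a")
})

test_that("contrast t-map matches the scalar OLS formula on a tiny case", {
  # 6 timepoints, 2 regressors, 1 voxel: hand-computable oracle
  X <- cbind(x = c(0, 1, 0, 1, 0, 1), intercept = 1)
  y <- c(1.2, 3.1, 0.8, 2.9, 1.1, 3.4)
  vol <- array(y, dim = c(1, 1, 1, 6))
  fit <- fit_first_level(vol, X)
  b <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% b
  s2 <- sum(res^2) / (6 - 2)
  cvec <- c(1, 0)
  t_oracle <- (t(cvec) %*% b) /
    sqrt(s2 * t(cvec) %*% solve(t(X) %*% X) %*% cvec)
  tm <- contrast_tmap(fit, c(x = 1))
  expect_equal(as.numeric(tm$data), as.numeric(t_oracle),
               tolerance = 1e-12)
  expect_equal(tm$df, 4)
  # sign flip of the weights negates the t-map
  tneg <- contrast_tmap(fit, c(x = -1))
  expect_equal(tneg$data, -tm$data)
})

test_that("pure-noise t-maps are calibrated at the nominal voxel level", {
  set.seed(33)
  n <- 40
  X <- cbind(x = rnorm(n), intercept = 1)
  d <- c(40, 40, 30)  # 48k voxels
  vol <- array(rnorm(prod(d) * n), dim = c(d, n))
  tm <- contrast_tmap(fit_first_level(vol, X), c(x = 1))
  frac <- mean(abs(tm$data) > stats::qt(0.999, tm$df))
  se <- sqrt(0.002 * 0.998 / prod(d))
  expect_lt(abs(frac - 0.002), 3 * se)
})

test_that("zero-variance voxels get t = 0 and a flag", {
  X <- cbind(x = c(0, 1, 0, 1), intercept = 1)
  vol <- array(5, dim = c(2, 2, 1, 4))  # constant: zero residual variance
  tm <- contrast_tmap(fit_first_level(vol, X), c(x = 1))
  expect_true(all(tm$data == 0))
  expect_true(all(tm$zero_variance))
})

test_that("second-level t matches the analytic expectation", {
  set.seed(5)
  d <- c(12, 12, 10)
  n <- 20
  maps <- lapply(1:n, function(i) {
    stat_map(array(rnorm(prod(d), mean = 0.5, sd = 1), dim = d),
             kind = "beta")
  })
  tm <- second_level_ttest(maps)
  expect_equal(tm$df, n - 1)
  # E[t] ~ mu * sqrt(n): 0.5 * sqrt(20) = 2.236; sd of mean t ~ 1/sqrt(V)
  expect_lt(abs(mean(tm$data) - 0.5 * sqrt(20)), 0.05)
  # identical maps across subjects: zero variance flagged, capped to 0
  same <- lapply(1:5, function(i) {
    stat_map(array(1, dim = c(3, 3, 3)), kind = "beta")
  })
  tms <- second_level_ttest(same)
  expect_true(all(tms$zero_variance))
  expect_true(all(tms$data == 0))
  expect_error(second_level_ttest(maps[1:2]), "3 subjects")
})

test_that("scaling a run by k > 0 leaves t-maps unchanged after scaling", {
  truth <- tiny_truth(noise_sd = 0.5, seed = 8)
  truth$baseline <- 100
  ds <- one_block_design()
  vol <- simulate_run(ds, truth)
  X <- build_design(ds, highpass_s = 128)
  msk <- array(1, dim = tiny_grid()$dim)
  t1 <- contrast_tmap(fit_first_level(scale_global(vol, mask = msk), X),
                      c(face_motor = 1))
  t2 <- contrast_tmap(fit_first_level(scale_global(3 * vol, mask = msk),
                                      X), c(face_motor = 1))
  expect_equal(t1$data, t2$data, tolerance = 1e-9)
})

test_that("voxel thresholding behaves at the extremes", {
  d <- c(6, 6, 4)
  zero <- stat_map(array(0, dim = d), kind = "tstat", df = 10)
  expect_equal(sum(threshold_cluster(zero, 0.001)$data), 0)
  set.seed(3)
  any_map <- stat_map(array(rnorm(prod(d)), dim = d), kind = "tstat",
                      df = 10)
  full <- threshold_cluster(any_map, 1)  # voxel_p = 1 keeps everything
  expect_equal(sum(full$data), prod(d))
})

test_that("cluster correction requires enough permutations", {
  d <- c(6, 6, 4)
  m <- stat_map(array(1, dim = d), kind = "tstat", df = 10)
  nulls <- matrix(rnorm(50 * prod(d)), nrow = 50)
  expect_error(threshold_cluster(m, 0.001, cluster_p = 0.05,
                                 null_maps = nulls),
               "100 permutations")
  expect_error(threshold_cluster(m, 0.001, cluster_p = 0.05),
               "null_maps")
})

test_that("connected components labeling matches hand-built cases", {
  a <- array(0, dim = c(5, 5, 5))
  a[1:2, 1, 1] <- 1           # 2-voxel cluster
  a[5, 5, 5] <- 1             # singleton
  a[4, 4, 4] <- 1             # diagonal neighbor of (5,5,5): 26-conn only
  cl26 <- cluster_label(a, 26)
  expect_setequal(cl26$sizes, c(2, 2))
  cl6 <- cluster_label(a, 6)
  expect_setequal(cl6$sizes, c(2, 1, 1))
  expect_equal(length(cluster_label(array(0, dim = c(3, 3, 3)))$sizes), 0)
})

test_that("a strong planted cluster survives permutation correction", {
  set.seed(21)
  d <- c(14, 14, 10)
  roi <- roi_sphere(c(7, 7, 5), 2.2, d)  # ~50 voxels
  n <- 15
  maps <- lapply(1:n, function(i) {
    x <- array(rnorm(prod(d)), dim = d)
    x[roi] <- x[roi] + 10 / sqrt(n)  # group t ~ 10 inside
    stat_map(x, kind = "beta")
  })
  tm <- second_level_ttest(maps)
  nulls <- signflip_null_tmaps(maps, n_perm = 500, seed = 77)
  out <- threshold_cluster(tm, 0.001, cluster_p = 0.05, null_maps = nulls)
  expect_gte(sum(out$data[roi]), 0.9 * length(roi))
  expect_equal(out$threshold_meta$method,
               "signflip-max-cluster-permutation")
})
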