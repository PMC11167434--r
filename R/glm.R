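#' Proportional global scaling
#'
#' Rescales every frame of a 4-D run so its in-mask mean equals a fixed
#' grand value, removing global signal differences between frames.
#'
#' @param volume 4-D array (x, y, z, time).
#' @param target grand mean after scaling (default 100).
#' @param mask optional 3-D logical/0-1 array; by default an
#'   intensity-based mask keeps voxels whose time-averaged intensity
#'   exceeds one eighth of the global mean (the usual SPM convention).
#' @return 4-D array with all in-mask frame means equal to `target`.
#' @export
scale_global <- function(volume, target = 100, mask = NULL) {
  stopifnot(length(dim(volume)) == 4L)
  d <- dim(volume)
  mat <- matrix(volume, nrow = prod(d[1:3]), ncol = d[4])
  if (is.null(mask)) {
    vmean <- rowMeans(mat)
    mask_idx <- which(vmean > mean(vmean) / 8)
  } else {
    stopifnot(identical(dim(mask), d[1:3]))
    mask_idx <- which(mask != 0)
  }
  if (!length(mask_idx)) stop("empty mask in scale_global")
  fmeans <- colMeans(mat[mask_idx, , drop = FALSE])
  if (any(fmeans <= 0)) stop("non-positive in-mask frame mean")
  mat <- sweep(mat, 2, target / fmeans, `*`)
  array(mat, dim = d)
}

gaussian_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(4 * sigma)
  offs <- -r:r
  g <- exp(-offs^2 / (2 * sigma^2))
  g <- g / sum(g)
  K <- matrix(0, n, n)
  for (k in seq_along(offs)) {
    j <- seq_len(n) + offs[k]
    ok <- j >= 1 & j <= n
    K[cbind(which(ok), j[ok])] <- K[cbind(which(ok), j[ok])] + g[k]
  }
  K
}

#' Separable 3-D Gaussian smoothing
#'
#' Smooths a 3-D map with a separable Gaussian of the given full width at
#' half maximum, `sigma = fwhm / (2 * sqrt(2 * log(2)))` per axis in voxel
#' units, using a zero-padded boundary.  The kernel is normalized to unit
#' sum, so the total image sum is conserved for content away from the
#' edges (to within the truncation of the kernel at 4 sigma).
#'
#' @param x 3-D array or [stat_map()].
#' @param fwhm_mm FWHM in mm (scalar or 3-vector).
#' @param voxel_mm voxel size in mm (scalar or 3-vector); taken from the
#'   map affine when `x` is a `stat_map` (diagonal affines only).
#' @return same type as `x`.
#' @export
smooth_gaussian <- function(x, fwhm_mm, voxel_mm = 2) {
  is_map <- inherits(x, "stat_map")
  if (is_map) {
    A <- x$affine[1:3, 1:3]
    if (any(abs(A[row(A) != col(A)]) > 1e-9)) {
      stop("smooth_gaussian supports only shear-free diagonal affines")
    }
    voxel_mm <- abs(diag(A))
    arr <- x$data
  } else {
    arr <- x
  }
  stopifnot(length(dim(arr)) == 3L, all(fwhm_mm >= 0))
  fwhm_mm <- rep_len(fwhm_mm, 3L)
  voxel_mm <- rep_len(voxel_mm, 3L)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  d <- dim(arr)
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    K <- gaussian_kernel_matrix(d[ax], sigma_vox[ax])
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- K %*% matrix(a, nrow = da[1])
    arr <- aperm(array(a, dim = da), order(perm))
  }
  if (is_map) {
    x$data <- arr
    x
  } else {
    arr
  }
}

#' Fit a first-level fixed-effects GLM
#'
#' Ordinary least squares per voxel against the supplied design matrix.
#'
#' @param volume 4-D array (x, y, z, time).
#' @param design a [design_matrix()][build_design] (or plain matrix with
#'   column names).
#' @param affine voxel-to-mm affine stored with derived maps.
#' @return object of class `first_level_fit`: beta matrix (voxels x
#'   regressors), residual variance, residual df, `(X'X)^{-1}`, grid
#'   dimensions.
#' @export
fit_first_level <- function(volume, design, affine = diag(c(2, 2, 2, 1))) {
  X <- if (inherits(design, "design_matrix")) design$matrix else design
  stopifnot(length(dim(volume)) == 4L)
  d <- dim(volume)
  if (d[4] != nrow(X)) stop("number of volumes does not match design rows")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  Y <- t(matrix(volume, nrow = prod(d[1:3]), ncol = d[4]))  # time x voxels
  beta <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta
  df <- nrow(X) - qrX$rank
  resvar <- colSums(resid^2) / df
  y_scale <- colMeans(Y^2)
  xtxinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot),
                                drop = FALSE]
  structure(list(beta = t(beta), resvar = resvar, df = df,
                 xtx_inv = xtxinv, names = colnames(X), dim = d[1:3],
                 y_scale = y_scale, affine = affine),
            class = "first_level_fit")
}

#' @export
print.first_level_fit <- function(x, ...) {
  cat(sprintf("First-level fit: %d voxels, %d regressors, df = %d\n",
              nrow(x$beta), length(x$names), x$df))
  invisible(x)
}

#' Contrast specification
#'
#' @param weights named numeric vector of contrast weights over regressor
#'   names; unnamed regressors get weight 0.
#' @param label human-readable contrast label.
#' @return object of class `contrast_spec`.
#' @export
contrast_spec <- function(weights, label = paste(names(weights),
                                                 collapse = " ")) {
  if (all(weights == 0)) stop("contrast weights must not be all zero")
  structure(list(weights = weights, label = label), class = "contrast_spec")
}

expand_weights <- function(contrast, names) {
  w <- if (inherits(contrast, "contrast_spec")) contrast$weights else contrast
  if (is.null(names(w))) {
    if (length(w) != length(names)) stop("contrast length mismatch")
    return(as.numeric(w))
  }
  if (!all(names(w) %in% names)) {
    stop("unknown regressors in contrast: ",
         paste(setdiff(names(w), names), collapse = ", "))
  }
  full <- stats::setNames(numeric(length(names)), names)
  full[names(w)] <- w
  as.numeric(full)
}

#' Contrast beta and t maps from a first-level fit
#'
#' Computes `c'beta` and `t = c'beta / sqrt(sigma^2 c'(X'X)^{-1} c)` per
#' voxel.  Voxels with zero estimated residual variance are set to t = 0
#' and flagged in the returned map's `zero_variance` element.
#'
#' @param fit a [fit_first_level()] result.
#' @param contrast a [contrast_spec()] or numeric weight vector.
#' @param what `"tstat"` (default) or `"beta"` (contrast effect map).
#' @return a [stat_map()].
#' @export
contrast_tmap <- function(fit, contrast, what = c("tstat", "beta")) {
  what <- match.arg(what)
  cw <- expand_weights(contrast, fit$names)
  eff <- as.numeric(fit$beta %*% cw)
  if (what == "beta") {
    return(stat_map(array(eff, dim = fit$dim), affine = fit$affine,
                    kind = "beta"))
  }
  cvar <- as.numeric(t(cw) %*% fit$xtx_inv %*% cw)
  se <- sqrt(fit$resvar * cvar)
  # zero residual variance up to floating-point noise in the data scale
  zero <- se == 0 | fit$resvar < fit$y_scale * 1e-20
  tval <- numeric(length(eff))
  tval[!zero] <- eff[!zero] / se[!zero]
  m <- stat_map(array(tval, dim = fit$dim), affine = fit$affine,
                kind = "tstat", df = fit$df)
  m$zero_variance <- array(zero, dim = fit$dim)
  m
}

#' Second-level one-sample t-test across subjects
#'
#' Random-effects group inference: a one-sample t across subjects per
#' voxel, df = n - 1.  Voxels with zero between-subject variance are
#' masked to t = 0 and flagged.
#'
#' @param contrast_maps list of per-subject [stat_map()] beta maps on a
#'   common grid (>= 3 subjects).
#' @return a [stat_map()] of kind `tstat`.
#' @export
second_level_ttest <- function(contrast_maps) {
  n <- length(contrast_maps)
  if (n < 3) stop("second-level inference requires at least 3 subjects")
  for (m in contrast_maps[-1]) {
    if (!same_grid(contrast_maps[[1]], m)) stop("subject grids mismatch")
  }
  d <- dim(contrast_maps[[1]]$data)
  Y <- vapply(contrast_maps, function(m) as.numeric(m$data),
              numeric(prod(d)))
  tv <- group_tstat(Y)
  m <- stat_map(array(tv$t, dim = d), affine = contrast_maps[[1]]$affine,
                kind = "tstat", df = n - 1L)
  m$zero_variance <- array(tv$zero, dim = d)
  m
}

# One-sample t over columns of a units x tests matrix laid out as
# tests x units: Y is units-in-columns?  Here Y is (voxels x subjects).
group_tstat <- function(Y) {
  n <- ncol(Y)
  m <- rowMeans(Y)
  v <- (rowSums(Y^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0  # numerical guard
  se <- sqrt(v / n)
  zero <- se == 0 | v < rowMeans(Y^2) * 1e-20
  t <- numeric(length(m))
  t[!zero] <- m[!zero] / se[!zero]
  list(t = t, zero = zero)
}

#' Sign-flip permutation null t-maps for a second-level test
#'
#' Under the symmetric null, subject contrast maps can be sign-flipped;
#' each permutation yields a group t-map used to build the max-cluster-size
#' null distribution.
#'
#' @param contrast_maps list of per-subject beta [stat_map()]s.
#' @param n_perm number of sign-flip permutations (default 500).
#' @param seed RNG seed.
#' @return matrix (n_perm x n_voxels) of null t values, with the grid
#'   dimensions in attribute `grid_dim`.
#' @export
signflip_null_tmaps <- function(contrast_maps, n_perm = 500, seed = 1L) {
  n <- length(contrast_maps)
  d <- dim(contrast_maps[[1]]$data)
  Y <- vapply(contrast_maps, function(m) as.numeric(m$data),
              numeric(prod(d)))                       # voxels x subjects
  ssq <- rowSums(Y^2)
  S <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                              nrow = n_perm))
  M <- (S %*% t(Y)) / n                               # n_perm x voxels
  V <- sweep(-n * M^2, 2, ssq, `+`) / (n - 1)
  V[V < 0] <- 0
  SE <- sqrt(V / n)
  Tm <- M / SE
  Tm[SE == 0] <- 0
  attr(Tm, "grid_dim") <- d
  Tm
}

# --- connected components ------------------------------------------------

neighbor_offsets <- function(connectivity = 26) {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6) {
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  } else if (connectivity != 26) {
    stop("connectivity must be 6 or 26")
  }
  as.matrix(offs)
}

#' Label connected clusters of suprathreshold voxels
#'
#' @param supra 3-D logical (or 0/1) array.
#' @param connectivity 26 (default) or 6.
#' @return list with `labels` (3-D integer array, 0 = background),
#'   `sizes` (voxel count per cluster).
#' @export
cluster_label <- function(supra, connectivity = 26) {
  d <- dim(supra)
  idx <- which(supra != 0)
  labels <- array(0L, dim = d)
  if (!length(idx)) return(list(labels = labels, sizes = integer(0)))
  offs <- neighbor_offsets(connectivity)
  coord <- arrayInd(idx, d)
  rank_of <- integer(prod(d))       # 0 = not suprathreshold
  rank_of[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(offs))) {
    nb <- coord + matrix(offs[k, ], nrow = nrow(coord), ncol = 3,
                         byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
      (nb[ok, 3] - 1L) * d[1] * d[2]
    nb_rank <- rank_of[nb_lin]
    self_rank <- which(ok)
    hit <- nb_rank > 0
    for (m in which(hit)) {
      a <- find(self_rank[m])
      b <- find(nb_rank[m])
      if (a != b) parent[b] <- a
    }
  }
  root <- vapply(seq_along(idx), find, integer(1))
  comp <- match(root, unique(root))
  labels[idx] <- comp
  sizes <- tabulate(comp)
  list(labels = labels, sizes = sizes)
}

max_cluster_size <- function(supra, connectivity = 26) {
  s <- cluster_label(supra, connectivity)$sizes
  if (length(s)) max(s) else 0L
}

#' Voxelwise and cluster-extent thresholding of a t-map
#'
#' Retains voxels with p below `voxel_p` (one- or two-sided Student t),
#' then, when `cluster_p` is given, keeps only clusters whose extent is
#' significant against the max-cluster-size distribution of sign-flip
#' permutation null maps (familywise control).  With `cluster_p = NULL`
#' only the voxel threshold is applied (the single-subject p < 0.05 mode).
#'
#' @param map a [stat_map()] of kind `tstat` with known df.
#' @param voxel_p voxelwise uncorrected p threshold.
#' @param cluster_p cluster-level familywise alpha, or `NULL` to skip the
#'   cluster step.
#' @param null_maps matrix of permutation null t values (permutations x
#'   voxels) from [signflip_null_tmaps()], or a list of 3-D arrays;
#'   required when `cluster_p` is given (at least 100 permutations).
#' @param connectivity cluster connectivity, 26 (default) or 6.
#' @param one_sided if `TRUE` (default) threshold positive t only,
#'   matching directional contrasts; otherwise two-sided on |t|.
#' @return binary [stat_map()] with `threshold_meta` recording the
#'   thresholds and method.
#' @export
threshold_cluster <- function(map, voxel_p, cluster_p = NULL,
                              null_maps = NULL, connectivity = 26,
                              one_sided = TRUE) {
  stopifnot(inherits(map, "stat_map"), map$kind == "tstat")
  df <- map$df
  tcrit <- if (one_sided) {
    stats::qt(1 - voxel_p, df)
  } else {
    stats::qt(1 - voxel_p / 2, df)
  }
  exceeds <- function(tvals) {
    if (one_sided) tvals > tcrit else abs(tvals) > tcrit
  }
  supra <- exceeds(map$data)
  meta <- list(voxel_p = voxel_p, cluster_p = cluster_p,
               method = if (is.null(cluster_p)) "voxel-threshold"
                        else "signflip-max-cluster-permutation",
               one_sided = one_sided, connectivity = connectivity,
               df = df)
  if (!is.null(cluster_p)) {
    if (is.null(null_maps)) stop("cluster correction requires null_maps")
    if (is.list(null_maps)) {
      null_maps <- t(vapply(null_maps, as.numeric,
                            numeric(length(map$data))))
    }
    n_perm <- nrow(null_maps)
    if (n_perm < 100 && cluster_p <= 0.05) {
      stop("at least 100 permutations required for cluster_p <= 0.05")
    }
    d <- dim(map$data)
    null_max <- vapply(seq_len(n_perm), function(i) {
      s <- exceeds(null_maps[i, ])
      if (!any(s)) return(0L)
      max_cluster_size(array(s, dim = d), connectivity)
    }, integer(1))
    cl <- cluster_label(supra, connectivity)
    keep <- array(FALSE, dim = d)
    retained <- integer(0)
    for (ci in seq_along(cl$sizes)) {
      p_cl <- (1 + sum(null_max >= cl$sizes[ci])) / (1 + n_perm)
      if (p_cl <= cluster_p) {
        keep[cl$labels == ci] <- TRUE
        retained <- c(retained, cl$sizes[ci])
      }
    }
    supra <- keep
    meta$cluster_size_threshold <-
      if (length(null_max)) as.numeric(stats::quantile(null_max,
                                                       1 - cluster_p))
      else NA_real_
    meta$n_permutations <- n_perm
  }
  stat_map(array(as.numeric(supra), dim = dim(map$data)),
           affine = map$affine, kind = "binary", threshold_meta = meta)
}
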