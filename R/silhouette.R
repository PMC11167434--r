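#' Synthetic body template raster
#'
#' A front-facing body silhouette on a pixel grid: head (face segment),
#' arms (hands segment), torso (trunk segment) and legs (feet segment),
#' with generous page margins so that shifted/rotated scans stay on the
#' page.  Serves as the registration reference and the segment labeling.
#'
#' @param height,width raster size in pixels (default 160 x 110).
#' @return object of class `body_template`: `body_mask` (0/1 matrix),
#'   `segment_labels` (0 = outside, 1 = face, 2 = hands, 3 = trunk,
#'   4 = feet), `pixel_count_inside`, `segment_counts`.
#' @export
body_template <- function(height = 160, width = 110) {
  lab <- matrix(0L, nrow = height, ncol = width)
  cx <- round(width / 2)
  rr <- row(lab); cc <- col(lab)
  # head: circle, radius ~ height/16
  r_head <- round(height / 16)
  head_ctr <- c(round(height * 0.13), cx)
  lab[(rr - head_ctr[1])^2 + (cc - head_ctr[2])^2 <= r_head^2] <- 1L
  # torso: rectangle
  t0 <- round(height * 0.20); t1 <- round(height * 0.50)
  half_t <- round(width * 0.12)
  lab[rr >= t0 & rr <= t1 & abs(cc - cx) <= half_t] <- 3L
  # arms: two rectangles flanking the torso
  a0 <- round(height * 0.22); a1 <- round(height * 0.48)
  arm_in <- half_t + 3; arm_out <- half_t + 3 + round(width * 0.08)
  arm <- rr >= a0 & rr <= a1 & abs(cc - cx) >= arm_in &
    abs(cc - cx) <= arm_out
  lab[arm] <- 2L
  # legs: two rectangles below the torso
  l0 <- t1 + 1; l1 <- round(height * 0.88)
  leg <- rr >= l0 & rr <= l1 & abs(cc - cx) >= 2 & abs(cc - cx) <= half_t
  lab[leg] <- 4L
  mask <- (lab > 0) + 0L
  counts <- stats::setNames(tabulate(lab, nbins = 4L), body_segments())
  if (any(counts == 0)) stop("degenerate template: empty segment")
  structure(list(body_mask = mask, segment_labels = lab,
                 pixel_count_inside = sum(mask),
                 segment_counts = counts,
                 dim = c(height, width)),
            class = "body_template")
}

#' @export
print.body_template <- function(x, ...) {
  cat(sprintf("Body template %d x %d: %d pixels inside (%s)\n",
              x$dim[1], x$dim[2], x$pixel_count_inside,
              paste(sprintf("%s %d", names(x$segment_counts),
                            x$segment_counts), collapse = ", ")))
  invisible(x)
}

#' Silhouette container
#'
#' Paired binary activation/deactivation rasters over the body template.
#'
#' @param activation,deactivation 0/1 matrices of equal size.
#' @param registered whether the rasters are on the template grid.
#' @param subject_id,phase,emotion metadata (`phase` is `"pre"` or
#'   `"post"`).
#' @return object of class `silhouette`.
#' @export
silhouette <- function(activation, deactivation,
                       registered = TRUE, subject_id = NA_character_,
                       phase = NA_character_, emotion = NA_character_) {
  stopifnot(is.matrix(activation), identical(dim(activation),
                                             dim(deactivation)))
  if (!all(activation %in% c(0, 1)) || !all(deactivation %in% c(0, 1))) {
    stop("silhouette channels must be binary 0/1")
  }
  structure(list(activation = activation, deactivation = deactivation,
                 registered = registered, subject_id = subject_id,
                 phase = phase, emotion = emotion),
            class = "silhouette")
}

#' @export
print.silhouette <- function(x, ...) {
  cat(sprintf(
    "Silhouette %s/%s/%s: %d activated, %d deactivated pixels\n",
    x$subject_id, x$phase, x$emotion, sum(x$activation),
    sum(x$deactivation)))
  invisible(x)
}

#' Simulate a colored silhouette with planted per-segment fractions
#'
#' Within each body segment, `round(fraction * segment_pixel_count)`
#' pixels (round-half-away-from-zero) are set to 1 in the corresponding
#' channel.  By default the two channels are disjoint.
#'
#' @param frac_act,frac_deact activation/deactivation fractions in
#'   `[0, 1]`; scalars or named vectors over segments.
#' @param template a [body_template()].
#' @param seed RNG seed for pixel placement.
#' @param allow_overlap if `FALSE` (default) the channels are disjoint and
#'   `frac_act + frac_deact <= 1` is required per segment.
#' @param subject_id,phase,emotion metadata passed to [silhouette()].
#' @return a [silhouette()].
#' @export
simulate_silhouette <- function(frac_act, frac_deact = 0, template,
                                seed = 1L, allow_overlap = FALSE,
                                subject_id = NA_character_,
                                phase = NA_character_,
                                emotion = NA_character_) {
  segs <- body_segments()
  fa <- expand_fractions(frac_act, segs)
  fd <- expand_fractions(frac_deact, segs)
  stopifnot(all(fa >= 0 & fa <= 1), all(fd >= 0 & fd <= 1))
  if (!allow_overlap && any(fa + fd > 1 + 1e-12)) {
    stop("frac_act + frac_deact > 1 with disjoint channels")
  }
  act <- matrix(0, template$dim[1], template$dim[2])
  deact <- act
  with_seed(seed, {
    for (i in seq_along(segs)) {
      px <- which(template$segment_labels == i)
      ka <- round_half_away(fa[i] * length(px))
      kd <- round_half_away(fd[i] * length(px))
      sel_a <- if (ka >= 1) sample(px, ka) else integer(0)
      pool <- if (allow_overlap) px else setdiff(px, sel_a)
      sel_d <- if (kd >= 1) sample(pool, kd) else integer(0)
      act[sel_a] <- 1
      deact[sel_d] <- 1
    }
  })
  silhouette(act, deact, registered = TRUE, subject_id = subject_id,
             phase = phase, emotion = emotion)
}

expand_fractions <- function(f, segs) {
  if (length(f) == 1L && is.null(names(f))) {
    return(stats::setNames(rep(f, length(segs)), segs))
  }
  stopifnot(all(segs %in% names(f)))
  f[segs]
}

#' Render a silhouette as a colored scanned page
#'
#' Produces an RGB raster emulating a scanned pen-and-paper silhouette:
#' white page, light-gray printed body, red activation and blue
#' deactivation coloring, optionally moved by a similarity transform
#' (what a slightly misplaced scan looks like).
#'
#' @param sil a [silhouette()] on the template grid.
#' @param template a [body_template()].
#' @param transform similarity transform applied to the drawing, as
#'   `list(tx=, ty=, angle_deg=, scale=)` (pixels, degrees); identity by
#'   default.  `tx` shifts rows, `ty` columns.
#' @return array height x width x 3 of RGB values in `[0, 1]`.
#' @export
render_scan <- function(sil, template,
                        transform = list(tx = 0, ty = 0, angle_deg = 0,
                                         scale = 1)) {
  lab <- template$segment_labels
  composite <- matrix(0L, nrow(lab), ncol(lab))
  composite[lab > 0] <- 1L
  composite[sil$activation == 1] <- 2L
  composite[sil$deactivation == 1] <- 3L
  warped <- warp_nearest(composite, transform, inverse = FALSE)
  rgb <- array(1, dim = c(nrow(lab), ncol(lab), 3))
  body <- warped == 1L
  rgb[, , 1][body] <- 0.82; rgb[, , 2][body] <- 0.82
  rgb[, , 3][body] <- 0.82
  act <- warped == 2L
  rgb[, , 1][act] <- 0.93; rgb[, , 2][act] <- 0.08
  rgb[, , 3][act] <- 0.10
  de <- warped == 3L
  rgb[, , 1][de] <- 0.10; rgb[, , 2][de] <- 0.15
  rgb[, , 3][de] <- 0.90
  rgb
}

# similarity transform of pixel coordinates about the image center:
# forward maps template coords -> scan coords.
transform_points <- function(pts, par, center) {
  th <- par$angle_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  sweep(sweep(pts, 2, center) %*% t(R) * par$scale, 2,
        center + c(par$tx, par$ty), `+`)
}

invert_transform <- function(par) {
  th <- -par$angle_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  t_new <- -as.numeric(R %*% c(par$tx, par$ty)) / par$scale
  list(tx = t_new[1], ty = t_new[2], angle_deg = -par$angle_deg,
       scale = 1 / par$scale)
}

# Resample an image under the similarity transform (nearest neighbor).
# inverse = FALSE renders src through the forward map (output(q) =
# src(T^-1 q)); inverse = TRUE pulls a scan back onto the template grid.
warp_nearest <- function(src, par, inverse = FALSE) {
  if (inverse) par <- invert_transform(par)
  d <- dim(src)
  center <- (d + 1) / 2
  q <- cbind(as.vector(row(src)), as.vector(col(src)))
  inv <- invert_transform(par)
  p <- transform_points(q, inv, center)
  ri <- round(p[, 1]); ci <- round(p[, 2])
  ok <- ri >= 1 & ri <= d[1] & ci >= 1 & ci <= d[2]
  out <- array(0, dim = d)
  storage.mode(out) <- storage.mode(src)
  out[ok] <- src[cbind(ri[ok], ci[ok])]
  matrix(out, d[1], d[2])
}

bilinear_sample <- function(img, pts, fill = 0) {
  d <- dim(img)
  r <- pts[, 1]; c <- pts[, 2]
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- numeric(nrow(pts)); val[] <- fill
  gi <- function(ri, ci) {
    ok <- ri >= 1 & ri <= d[1] & ci >= 1 & ci <= d[2]
    v <- numeric(length(ri)); v[] <- fill
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  (1 - fr) * (1 - fc) * gi(r0, c0) + (1 - fr) * fc * gi(r0, c0 + 1) +
    fr * (1 - fc) * gi(r0 + 1, c0) + fr * fc * gi(r0 + 1, c0 + 1)
}

smooth2d <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  Kr <- gaussian_kernel_matrix(nrow(mat), sigma)
  Kc <- gaussian_kernel_matrix(ncol(mat), sigma)
  Kr %*% mat %*% t(Kc)
}

# Mutual information between fixed template intensities and the scan
# sampled through the candidate transform, with linear partial-volume
# binning (Mattes-style Parzen window of order 1).
mi_metric <- function(fixed_vals, fixed_bin, moving_img, pts, par, center,
                      n_bins = 24) {
  p <- transform_points(pts, par, center)
  mv <- bilinear_sample(moving_img, p, fill = 0)
  rng <- range(moving_img)
  if (diff(rng) <= 0) return(0)
  mb <- (mv - rng[1]) / diff(rng) * (n_bins - 1) + 1
  m0 <- floor(mb); fm <- mb - m0
  m0 <- pmin(pmax(m0, 1), n_bins)
  m1 <- pmin(m0 + 1, n_bins)
  idx <- c(fixed_bin + (m0 - 1) * n_bins, fixed_bin + (m1 - 1) * n_bins)
  w <- c(1 - fm, fm)
  H <- matrix(0, n_bins, n_bins)
  acc <- rowsum(w, idx)
  H[as.integer(rownames(acc))] <- acc
  H <- H / sum(H)
  pf <- rowSums(H); pm <- colSums(H)
  nz <- H > 0
  sum(H[nz] * log(H[nz] / (pf[row(H)[nz]] * pm[col(H)[nz]])))
}

#' Register a scanned silhouette page to the body template
#'
#' Estimates the 2-D similarity transform (translation, rotation,
#' isotropic scale) that maximizes the mutual information between the
#' template and the scan (linear partial-volume joint histogram), using a
#' coarse translation/rotation grid search followed by Nelder-Mead
#' refinement, then resamples the scan onto the template grid.
#'
#' @param scan grayscale matrix or RGB array (height x width x 3).
#' @param template a [body_template()].
#' @param n_bins histogram bins for the mutual-information metric.
#' @param sigma_px Gaussian pre-smoothing of both images (pixels).
#' @param max_shift_px,max_angle_deg coarse search ranges.
#' @return list with `registered` (same type as `scan`, on the template
#'   grid), `transform` (tx, ty, angle_deg, scale: template -> scan), and
#'   `metric` (final mutual information, nats).
#' @export
register_to_template <- function(scan, template, n_bins = 24,
                                 sigma_px = 1.5, max_shift_px = 12,
                                 max_angle_deg = 6) {
  gray <- if (length(dim(scan)) == 3L) {
    0.299 * scan[, , 1] + 0.587 * scan[, , 2] + 0.114 * scan[, , 3]
  } else scan
  stopifnot(identical(dim(gray), as.integer(template$dim)) ||
              identical(dim(gray), template$dim))
  fixed <- smooth2d(template$body_mask + 0, sigma_px)
  moving <- smooth2d(max(gray) - gray, sigma_px)  # ink density
  if (stats::sd(moving) < 1e-8) {
    stop("registration failed to converge: blank scan (metric 0)")
  }
  d <- dim(fixed)
  center <- (d + 1) / 2
  sub <- seq(1, length(fixed), by = 3)  # pixel subsample for the metric
  pts <- cbind(as.vector(row(fixed))[sub], as.vector(col(fixed))[sub])
  fv <- as.vector(fixed)[sub]
  frng <- range(fv)
  fb <- floor((fv - frng[1]) / diff(frng) * (n_bins - 1)) + 1
  obj <- function(p) {
    -mi_metric(fv, fb, moving, pts,
               list(tx = p[1], ty = p[2], angle_deg = p[3],
                    scale = exp(p[4])), center, n_bins)
  }
  # coarse grid over translations and rotations
  grid <- expand.grid(tx = seq(-max_shift_px, max_shift_px, by = 4),
                      ty = seq(-max_shift_px, max_shift_px, by = 4),
                      th = seq(-max_angle_deg, max_angle_deg, by = 3))
  vals <- apply(grid, 1, function(g) obj(c(g[1], g[2], g[3], 0)))
  best <- as.numeric(grid[which.min(vals), ])
  fit <- stats::optim(c(best, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-10,
                                     parscale = c(1, 1, 1, 0.01)))
  fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 200, reltol = 1e-12,
                                      parscale = c(0.2, 0.2, 0.2, 0.002)))
  if (fit2$value < fit$value) fit <- fit2
  mi <- -fit$value
  if (mi < 0.05) {
    stop(sprintf("registration failed to converge (final metric %.4f)",
                 mi))
  }
  par <- list(tx = fit$par[1], ty = fit$par[2], angle_deg = fit$par[3],
              scale = exp(fit$par[4]))
  registered <- if (length(dim(scan)) == 3L) {
    out <- scan
    for (k in 1:3) out[, , k] <- warp_nearest(scan[, , k], par,
                                              inverse = TRUE)
    out
  } else {
    warp_nearest(scan, par, inverse = TRUE)
  }
  list(registered = registered, transform = par, metric = mi)
}

#' Code a registered color scan into binary silhouette channels
#'
#' Red-dominant pixels (HSV hue below `red_hue[1]` or above `red_hue[2]`,
#' with saturation and value floors) become activation; blue-hue pixels
#' become deactivation; everything else, and everything outside the body
#' boundary, is 0.
#'
#' @param rgb registered RGB array (height x width x 3, values in 0-1).
#' @param template a [body_template()]; pixels outside its body mask are
#'   discarded.
#' @param red_hue,blue_hue hue windows in degrees.
#' @param min_sat,min_val saturation/value floors.
#' @param subject_id,phase,emotion metadata.
#' @return a [silhouette()].
#' @export
code_pixels <- function(rgb, template, red_hue = c(20, 340),
                        blue_hue = c(200, 260), min_sat = 0.35,
                        min_val = 0.15, subject_id = NA_character_,
                        phase = NA_character_, emotion = NA_character_) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  hsv <- grDevices::rgb2hsv(r = as.vector(rgb[, , 1]),
                            g = as.vector(rgb[, , 2]),
                            b = as.vector(rgb[, , 3]), maxColorValue = 1)
  hue <- hsv[1, ] * 360
  colored <- hsv[2, ] >= min_sat & hsv[3, ] >= min_val
  red <- colored & (hue < red_hue[1] | hue > red_hue[2])
  blue <- colored & hue >= blue_hue[1] & hue <= blue_hue[2]
  inside <- template$body_mask == 1
  act <- matrix(as.numeric(red), template$dim[1], template$dim[2]) * inside
  de <- matrix(as.numeric(blue), template$dim[1], template$dim[2]) * inside
  silhouette(act, de, registered = TRUE, subject_id = subject_id,
             phase = phase, emotion = emotion)
}

#' Activation-minus-deactivation subtraction map
#'
#' @param sil a [silhouette()].
#' @return integer matrix in `{-1, 0, 1}`.
#' @export
subtraction_map <- function(sil) {
  stopifnot(inherits(sil, "silhouette"))
  sil$activation - sil$deactivation
}

#' Percentage of colored pixels per body segment
#'
#' `100 * colored_pixels_in_segment / segment_pixel_count` per segment.
#'
#' @param x a [silhouette()] or a subtraction raster.
#' @param template a [body_template()].
#' @param channel `"activation"` (default; count activation pixels) or
#'   `"subtraction"` (count net-positive pixels of the subtraction map).
#' @return named numeric 4-vector (percent).
#' @export
segment_percentages <- function(x, template,
                                channel = c("activation", "subtraction")) {
  channel <- match.arg(channel)
  if (any(template$segment_counts == 0)) stop("template has empty segment")
  colored <- if (inherits(x, "silhouette")) {
    if (channel == "activation") x$activation == 1
    else subtraction_map(x) > 0
  } else {
    if (channel == "activation") x != 0 else x > 0
  }
  segs <- body_segments()
  out <- vapply(seq_along(segs), function(i) {
    100 * sum(colored[template$segment_labels == i]) /
      template$segment_counts[i]
  }, numeric(1))
  stats::setNames(out, segs)
}

#' Pixel-wise group t-map across subjects' subtraction maps
#'
#' One-sample t per pixel across subjects; pixels with zero
#' between-subject variance are masked to 0 and flagged.
#'
#' @param rasters list (>= 3) of subtraction matrices on one template.
#' @return list with `t` (matrix), `df`, `zero_variance` (logical
#'   matrix).
#' @export
group_pixel_tmap <- function(rasters) {
  n <- length(rasters)
  if (n < 3) stop("group pixel t-map requires >= 3 subjects")
  d <- dim(rasters[[1]])
  Y <- vapply(rasters, as.numeric, numeric(prod(d)))
  tv <- group_tstat(Y)
  list(t = matrix(tv$t, d[1], d[2]), df = n - 1L,
       zero_variance = matrix(tv$zero, d[1], d[2]))
}

#' Pre/post-scan silhouette reliability
#'
#' Pearson correlation over the concatenated per-subject, per-emotion,
#' per-segment percentage vectors of the pre- and post-scan silhouettes,
#' with the p-value from the t transform of r.
#'
#' @param pre_mats,post_mats lists (matched order) of emotions x segments
#'   percentage matrices, one per subject.
#' @return list with `r`, `p`, `n` (number of paired entries).
#' @export
prepost_reliability <- function(pre_mats, post_mats) {
  stopifnot(length(pre_mats) == length(post_mats),
            length(pre_mats) >= 1)
  pre <- unlist(lapply(pre_mats, as.numeric))
  post <- unlist(lapply(post_mats, as.numeric))
  stopifnot(length(pre) == length(post))
  if (stats::sd(pre) == 0 || stats::sd(post) == 0) {
    stop("zero variance in percentage vectors")
  }
  ct <- stats::cor.test(pre, post)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(pre))
}

#' Write a silhouette as an 8-bit PNG (activation/deactivation channels)
#'
#' Channel 1 holds the activation raster, channel 2 the deactivation
#' raster; a JSON sidecar records metadata and pixel counts.
#'
#' @param sil a [silhouette()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_silhouette_png <- function(sil, path) {
  arr <- array(0, dim = c(dim(sil$activation), 3))
  arr[, , 1] <- sil$activation
  arr[, , 2] <- sil$deactivation
  png::writePNG(arr, path)
  jsonlite::write_json(
    list(subject_id = sil$subject_id, phase = sil$phase,
         emotion = sil$emotion, registered = sil$registered,
         n_activation = sum(sil$activation),
         n_deactivation = sum(sil$deactivation)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a silhouette written by [write_silhouette_png()]
#'
#' @param path PNG path.
#' @return a [silhouette()].
#' @export
read_silhouette_png <- function(path) {
  arr <- png::readPNG(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  silhouette(round(arr[, , 1]), round(arr[, , 2]),
             registered = isTRUE(meta$registered),
             subject_id = meta$subject_id %||% NA_character_,
             phase = meta$phase %||% NA_character_,
             emotion = meta$emotion %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a segment-label raster as an 8-bit PNG
#'
#' @param template a [body_template()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_template_png <- function(template, path) {
  png::writePNG(template$segment_labels / 4, path)
  invisible(path)
}
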