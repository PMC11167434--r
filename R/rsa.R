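#' JZS Bayesian one-sample t-test
#'
#' Classical one-sample t-test plus the Jeffreys-Zellner-Siow Bayes
#' factor: a Cauchy prior with scale `prior_scale` on the standardized
#' effect size under the alternative, computed by numerical integration
#' of the Gaussian-scale-mixture (inverse-gamma on g) representation.
#'
#' @param values numeric vector (n >= 2, finite, non-constant).
#' @param mu0 null value (default 0).
#' @param prior_scale Cauchy prior scale on the effect size, default
#'   `sqrt(2)/2`.
#' @return list of class `bf_result`: `t`, `df`, `p` (two-sided),
#'   `bf10`, `prior_scale`, `n`.
#' @export
bayes_one_sample <- function(values, mu0 = 0, prior_scale = sqrt(2) / 2) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 observations")
  if (!all(is.finite(values))) stop("values must be finite")
  s <- stats::sd(values)
  if (s == 0) stop("zero variance: t statistic undefined")
  tt <- (mean(values) - mu0) / (s / sqrt(n))
  df <- n - 1
  p <- 2 * stats::pt(-abs(tt), df)
  bf10 <- jzs_bf10(tt, n, prior_scale)
  structure(list(t = tt, df = df, p = p, bf10 = bf10,
                 prior_scale = prior_scale, n = n),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g, BF10 = %.3f (Cauchy scale %.3f)\n",
              x$df, x$t, x$p, x$bf10, x$prior_scale))
  invisible(x)
}

#' JZS Bayes factor from a t statistic
#'
#' Marginal likelihood ratio (alternative over null) for a one-sample t
#' statistic under the JZS prior: effect size delta ~ Cauchy(0, r),
#' integrated via the equivalent inverse-gamma(1/2, r^2/2) mixture on g.
#'
#' @param t observed t statistic.
#' @param n sample size.
#' @param prior_scale Cauchy scale r.
#' @return BF10 (positive scalar).
#' @export
jzs_bf10 <- function(t, n, prior_scale = sqrt(2) / 2) {
  nu <- n - 1
  r <- prior_scale
  null_dens <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  integrand <- function(g) {
    (1 + n * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      r / (sqrt(2 * pi) * g^(3 / 2)) * exp(-r^2 / (2 * g))
  }
  alt <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10,
                          abs.tol = 0)$value
  alt / null_dens
}

#' Representational similarity between pixel and voxel matrices
#'
#' For each subject, the Pearson correlation between the flattened
#' pixel (self-report) and voxel (fMRI) body-emotion matrices (mode
#' `"direct"`), or between the lower triangles of the 5 x 5
#' emotion-dissimilarity matrices built within each modality (mode
#' `"rdm"`).  The coefficients are then tested against zero across
#' subjects with a one-sample t-test, by default after Fisher
#' z-transformation.
#'
#' @param pixel_mats,voxel_mats lists (matched subject order) of
#'   emotions x segments matrices.
#' @param mode `"direct"` (default) or `"rdm"`.
#' @param method correlation coefficient, `"pearson"` (default) or
#'   `"spearman"`.
#' @param fisher_z if `TRUE` (default) the group t-test is on Fisher
#'   z-transformed coefficients; `FALSE` tests raw r.
#' @return list of class `rsa_result`: `r` (per-subject), `excluded`
#'   (indices of constant-matrix subjects), `t`, `df`, `p`, `mean_r`,
#'   `mode`, `fisher_z`.
#' @export
rsa_voxel_pixel <- function(pixel_mats, voxel_mats,
                            mode = c("direct", "rdm"),
                            method = c("pearson", "spearman"),
                            fisher_z = TRUE) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  stopifnot(length(pixel_mats) == length(voxel_mats))
  feats <- function(m) {
    m <- unclass(m)
    m[is.na(m)] <- 0
    if (mode == "direct") return(as.numeric(m))
    dm <- as.matrix(stats::dist(m))       # emotion dissimilarity matrix
    dm[lower.tri(dm)]
  }
  rs <- rep(NA_real_, length(pixel_mats))
  for (i in seq_along(pixel_mats)) {
    a <- feats(pixel_mats[[i]])
    b <- feats(voxel_mats[[i]])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning(sprintf("subject %d excluded: constant matrix", i))
      next
    }
    rs[i] <- stats::cor(a, b, method = method)
  }
  usable <- which(!is.na(rs))
  if (length(usable) < 3) {
    stop("fewer than 3 subjects with usable matrices")
  }
  r_use <- rs[usable]
  vals <- if (fisher_z) atanh(pmin(pmax(r_use, -1 + 1e-12), 1 - 1e-12))
          else r_use
  if (stats::sd(vals) == 0) {
    # all coefficients identical (e.g. all exactly 1): degenerate t
    tt <- if (mean(vals) == 0) 0 else Inf
    p <- if (is.infinite(tt)) 0 else 1
    res <- list(t = tt, df = length(vals) - 1L, p = p)
  } else {
    ht <- stats::t.test(vals)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  structure(list(r = rs, excluded = setdiff(seq_along(rs), usable),
                 t = res$t, df = res$df, p = res$p,
                 mean_r = mean(r_use), mode = mode,
                 fisher_z = fisher_z, method = method),
            class = "rsa_result")
}

#' @export
print.rsa_result <- function(x, ...) {
  cat(sprintf(
    "RSA (%s, %s%s): mean r = %.3f over %d subjects; t(%g) = %.3f, p = %.4g\n",
    x$mode, x$method, if (x$fisher_z) ", Fisher z" else "",
    x$mean_r, sum(!is.na(x$r)), x$df, x$t, x$p))
  if (length(x$excluded)) {
    cat("  excluded subjects:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Paired emotional-vs-neutral ratings contrasts
#'
#' Per emotion: subject-level mean rating for that emotion's episodes
#' minus the subject's mean neutral rating, tested with a paired
#' (one-sample on differences) t-test and JZS Bayes factor.
#'
#' @param ratings a ratings table (rows: subject_id, condition,
#'   emotion, intensity, vividness), e.g. rbind of [simulate_ratings()]
#'   per subject.
#' @param measure `"intensity"` or `"vividness"`.
#' @param prior_scale Cauchy prior scale for the Bayes factor.
#' @return data frame with one row per emotion: emotion, n, mean_diff,
#'   t, df, p, bf10.
#' @export
ratings_contrast <- function(ratings, measure = c("intensity", "vividness"),
                             prior_scale = sqrt(2) / 2) {
  measure <- match.arg(measure)
  stopifnot(all(c("subject_id", "condition", "emotion", measure) %in%
                  names(ratings)))
  subjects <- unique(ratings$subject_id)
  if (length(subjects) < 2) stop("need at least 2 subjects")
  emos <- unique(ratings$emotion[!is.na(ratings$emotion)])
  out <- lapply(emos, function(e) {
    diffs <- vapply(subjects, function(s) {
      rs <- ratings[ratings$subject_id == s, ]
      emo_vals <- rs[[measure]][!is.na(rs$emotion) & rs$emotion == e]
      neu_vals <- rs[[measure]][rs$condition == "neutral"]
      if (!length(emo_vals) || !length(neu_vals)) return(NA_real_)
      mean(emo_vals) - mean(neu_vals)
    }, numeric(1))
    if (anyNA(diffs)) {
      warning(sprintf("%s: %d subject(s) dropped for missing pairs", e,
                      sum(is.na(diffs))))
      diffs <- diffs[!is.na(diffs)]
    }
    bf <- bayes_one_sample(diffs, prior_scale = prior_scale)
    data.frame(emotion = e, n = bf$n, mean_diff = mean(diffs), t = bf$t,
               df = bf$df, p = bf$p, bf10 = bf$bf10,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
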