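#' Block-design specification for one functional run
#'
#' Bundles the repetition time, run length and block timing table that
#' define a single block-design run (localizer or recall).
#'
#' @param tr_seconds repetition time in seconds (positive).
#' @param n_volumes number of volumes acquired (positive integer).
#' @param blocks data frame with columns `onset` (s), `duration` (s) and
#'   `condition` (character). May have zero rows.
#' @param condition_names ordered character vector of condition labels;
#'   defaults to the conditions present in `blocks`.
#'
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(tr_seconds, n_volumes, blocks,
                        condition_names = NULL) {
  stopifnot(is.numeric(tr_seconds), length(tr_seconds) == 1L, tr_seconds > 0)
  stopifnot(is.numeric(n_volumes), length(n_volumes) == 1L, n_volumes >= 1)
  if (missing(blocks) || is.null(blocks)) {
    blocks <- data.frame(onset = numeric(0), duration = numeric(0),
                         condition = character(0))
  }
  stopifnot(is.data.frame(blocks),
            all(c("onset", "duration", "condition") %in% names(blocks)))
  blocks$condition <- as.character(blocks$condition)
  if (nrow(blocks)) {
    if (any(blocks$onset < 0)) stop("block onsets must be >= 0")
    if (any(blocks$duration <= 0)) stop("block durations must be > 0")
    total <- n_volumes * tr_seconds
    if (any(blocks$onset + blocks$duration > total + 1e-9)) {
      stop("a block extends past the end of the run")
    }
    blocks <- blocks[order(blocks$onset), , drop = FALSE]
    rownames(blocks) <- NULL
  }
  if (is.null(condition_names)) condition_names <- unique(blocks$condition)
  if (!all(blocks$condition %in% condition_names)) {
    stop("every block condition must appear in condition_names")
  }
  structure(list(tr_seconds = tr_seconds,
                 n_volumes = as.integer(n_volumes),
                 blocks = blocks,
                 condition_names = condition_names),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("Block design: %d volumes, TR %.3g s, %d blocks, %d conditions\n",
              x$n_volumes, x$tr_seconds, nrow(x$blocks),
              length(x$condition_names)))
  invisible(x)
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard canonical HRF: a gamma density peaking at `peak_s` minus a
#' scaled gamma undershoot peaking at `undershoot_s`.  The same function is
#' used by the synthetic-data generator and by the GLM design builder, so
#' noiseless simulated runs are fit exactly.
#'
#' @param t time in seconds (vector; values < 0 return 0).
#' @param peak_s response peak delay (default 6 s).
#' @param undershoot_s undershoot delay (default 16 s).
#' @param ratio peak-to-undershoot amplitude ratio (default 6).
#'
#' @return numeric vector of HRF values (unit-integral response minus the
#'   scaled undershoot).
#' @export
canonical_hrf <- function(t, peak_s = 6, undershoot_s = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak_s, rate = 1) -
    stats::dgamma(t, shape = undershoot_s, rate = 1) / ratio
  h[t < 0] <- 0
  h
}

# Condition regressor: boxcar sampled on a fine grid, convolved with the
# canonical HRF, then sampled at volume-acquisition times.
convolved_regressor <- function(design, condition, dt = 0.1,
                                hrf = canonical_hrf) {
  total <- design$n_volumes * design$tr_seconds
  tgrid <- seq(0, total + 32, by = dt)
  box <- numeric(length(tgrid))
  b <- design$blocks[design$blocks$condition == condition, , drop = FALSE]
  for (i in seq_len(nrow(b))) {
    box[tgrid >= b$onset[i] & tgrid < b$onset[i] + b$duration[i]] <- 1
  }
  h <- hrf(seq(0, 32, by = dt))
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(tgrid)] * dt
  vol_t <- (seq_len(design$n_volumes) - 1L) * design$tr_seconds
  conv[findInterval(vol_t, tgrid)]
}

# Discrete cosine drift basis (unit-norm columns, constant excluded).
# K = floor(2 * run_length / cutoff) columns, the SPM high-pass convention.
dct_basis <- function(n_volumes, tr_seconds, highpass_s) {
  k_max <- floor(2 * n_volumes * tr_seconds / highpass_s)
  n <- n_volumes
  if (k_max < 1) return(matrix(numeric(0), nrow = n, ncol = 0))
  sapply(seq_len(k_max), function(k) {
    sqrt(2 / n) * cos(pi * (2 * seq_len(n) - 1) * k / (2 * n))
  })
}

#' Build a first-level design matrix
#'
#' One boxcar-convolved regressor per condition, a discrete-cosine drift
#' basis realizing the high-pass cutoff, and an intercept.
#'
#' @param design a [design_spec()].
#' @param highpass_s high-pass cutoff in seconds (default 128); drift
#'   columns model all cosines with period above the cutoff.  Must exceed
#'   twice the TR.
#' @param hrf HRF function of time in seconds, default [canonical_hrf()].
#' @param dt microtime resolution (s) for the boxcar convolution.
#'
#' @return An object of class `design_matrix`: list with `matrix`
#'   (n_volumes x n_regressors), `names`, `condition_names`, `hrf_id`,
#'   `highpass_s`.
#' @export
build_design <- function(design, highpass_s = 128, hrf = canonical_hrf,
                         dt = 0.1) {
  stopifnot(inherits(design, "design_spec"))
  if (highpass_s <= 2 * design$tr_seconds) {
    stop("highpass_s must exceed twice the TR")
  }
  conds <- design$condition_names
  cond_cols <- sapply(conds, function(cn) {
    convolved_regressor(design, cn, dt = dt, hrf = hrf)
  })
  if (length(conds) == 0L) {
    cond_cols <- matrix(numeric(0), nrow = design$n_volumes, ncol = 0)
  }
  if (length(conds) == 1L) cond_cols <- matrix(cond_cols, ncol = 1L)
  drift <- dct_basis(design$n_volumes, design$tr_seconds, highpass_s)
  X <- cbind(cond_cols, drift, 1)
  nm <- c(conds,
          if (ncol(drift)) paste0("dct", seq_len(ncol(drift))),
          "intercept")
  colnames(X) <- nm
  structure(list(matrix = X, names = nm, condition_names = conds,
                 hrf_id = "double-gamma", highpass_s = highpass_s),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d volumes x %d regressors (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Write block timings as a tab-delimited events file
#'
#' Three columns (onset, duration, condition), tab-separated, with header.
#'
#' @param design a [design_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(design, path) {
  utils::write.table(design$blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited events file into a design spec
#'
#' @param path events file written by [write_events()].
#' @param tr_seconds,n_volumes run geometry (not stored in the events file).
#' @param condition_names optional condition ordering.
#' @return a [design_spec()].
#' @export
read_events <- function(path, tr_seconds, n_volumes, condition_names = NULL) {
  blocks <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  design_spec(tr_seconds, n_volumes, blocks, condition_names)
}
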