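#' Mask an emotion map by a sensorimotor mask
#'
#' Voxelwise AND of two binary maps on a common grid.
#'
#' @param emotion_map,mask binary [stat_map()]s.
#' @return binary [stat_map()].
#' @export
mask_emotion <- function(emotion_map, mask) {
  stopifnot(inherits(emotion_map, "stat_map"), inherits(mask, "stat_map"))
  if (!same_grid(emotion_map, mask)) stop("grid mismatch")
  out <- emotion_map
  out$data <- (emotion_map$data != 0 & mask$data != 0) + 0
  out$kind <- "binary"
  out
}

#' Convergence percentage of an emotion map with a mask
#'
#' `mode = "mask"` (default): the percentage of the sensorimotor mask
#' reached by the emotion map, `100 * |emotion AND mask| / |mask|`.
#' `mode = "emotion"`: the percentage of the emotion map falling inside
#' the mask.  An empty denominator set yields `NA` (rendered as a dash in
#' reports, the convention for segments with no selective voxels).
#'
#' @param emotion_map,mask binary [stat_map()]s.
#' @param mode denominator convention.
#' @return scalar percentage, or `NA_real_` when undefined.
#' @export
convergence_percent <- function(emotion_map, mask,
                                mode = c("mask", "emotion")) {
  mode <- match.arg(mode)
  inter <- sum(mask_emotion(emotion_map, mask)$data)
  denom <- switch(mode,
                  mask = sum(mask$data != 0),
                  emotion = sum(emotion_map$data != 0))
  if (denom == 0) return(NA_real_)
  100 * inter / denom
}

#' Body-emotion matrix of per-segment voxel percentages
#'
#' For each emotion map, the percentage of each segment mask covered:
#' `100 * |emotion AND segment| / |segment|`.  This is the voxel-space
#' analogue of the silhouette pixel percentages (the "emotional
#' homunculus" in voxels).
#'
#' @param emotion_maps named list of binary [stat_map()]s (one per
#'   emotion), e.g. single-subject maps thresholded at the p < 0.05 mode.
#' @param masks a [build_segment_masks()] result or a named list of
#'   per-segment binary maps.
#' @return emotions x segments numeric matrix (percent) of class
#'   `body_emotion_matrix` with attribute `source = "voxels"`.
#' @export
voxel_homunculus <- function(emotion_maps, masks) {
  seg_masks <- if (inherits(masks, "segment_mask_set")) masks$segments
               else masks
  if (!all(body_segments() %in% names(seg_masks))) {
    stop("missing segment mask(s): ",
         paste(setdiff(body_segments(), names(seg_masks)), collapse = ", "))
  }
  m <- t(vapply(emotion_maps, function(em) {
    vapply(body_segments(), function(s) {
      denom <- sum(seg_masks[[s]]$data != 0)
      if (denom == 0) return(NA_real_)
      100 * sum(em$data != 0 & seg_masks[[s]]$data != 0) / denom
    }, numeric(1))
  }, numeric(length(body_segments()))))
  dimnames(m) <- list(names(emotion_maps), body_segments())
  body_emotion_matrix(m, source = "voxels")
}

#' Body-emotion matrix container
#'
#' A 5 emotions x 4 segments matrix of percentages, from pixels
#' (silhouettes) or voxels (brain maps).
#'
#' @param values emotions x segments numeric matrix, entries in
#'   `[0, 100]` (or `NA`).
#' @param source `"pixels"` or `"voxels"`.
#' @param subject_id subject label or `"group"`.
#' @return the matrix with class `body_emotion_matrix`.
#' @export
body_emotion_matrix <- function(values, source = c("pixels", "voxels"),
                                subject_id = "group") {
  source <- match.arg(source)
  stopifnot(is.matrix(values))
  ok <- is.na(values) | (values >= 0 & values <= 100 + 1e-9)
  if (!all(ok)) stop("percentages must lie in [0, 100]")
  structure(values, class = c("body_emotion_matrix", class(values)),
            source = source, subject_id = subject_id)
}

#' @export
print.body_emotion_matrix <- function(x, ...) {
  cat(sprintf("Body-emotion matrix (%s, %s):\n", attr(x, "source"),
              attr(x, "subject_id")))
  print(round(unclass(x), 2), ...)
  invisible(x)
}

#' Hotspot segments per emotion
#'
#' A segment is a hotspot for an emotion when its value is within a
#' fraction `tau` of the row maximum (`tau = 0`: the strict argmax set,
#' ties included).  All-zero (or all-`NA`) rows yield an empty set.
#'
#' @param matrix a [body_emotion_matrix()] or plain emotions x segments
#'   matrix.
#' @param tau tie tolerance in `[0, 1)` (default 0).
#' @return named list of character vectors of hotspot segments.
#' @export
hotspots <- function(matrix, tau = 0) {
  stopifnot(tau >= 0, tau < 1)
  segs <- colnames(matrix)
  out <- lapply(seq_len(nrow(matrix)), function(i) {
    row <- matrix[i, ]
    row[is.na(row)] <- 0
    mx <- max(row)
    if (mx <= 0) return(character(0))
    segs[row >= (1 - tau) * mx]
  })
  names(out) <- rownames(matrix)
  out
}

#' Hotspot congruence table between pixel and voxel matrices
#'
#' For each emotion and segment, flags whether the segment is a hotspot
#' in the self-report (pixel) matrix and in the fMRI (voxel) matrix, and
#' whether the two agree.
#'
#' @param pixel_mat,voxel_mat emotions x segments matrices on matched
#'   emotions.
#' @param tau hotspot tie tolerance (see [hotspots()]).
#' @return data frame with columns emotion, segment, self_report, fmri
#'   (logical), agree (logical), of class `hotspot_table`.
#' @export
congruence_table <- function(pixel_mat, voxel_mat, tau = 0) {
  if (!identical(rownames(pixel_mat), rownames(voxel_mat))) {
    stop("emotion rows of pixel and voxel matrices do not match")
  }
  hp <- hotspots(pixel_mat, tau)
  hv <- hotspots(voxel_mat, tau)
  segs <- colnames(pixel_mat)
  rows <- do.call(rbind, lapply(rownames(pixel_mat), function(e) {
    data.frame(emotion = e, segment = segs,
               self_report = segs %in% hp[[e]],
               fmri = segs %in% hv[[e]],
               stringsAsFactors = FALSE)
  }))
  rows$agree <- rows$self_report == rows$fmri
  class(rows) <- c("hotspot_table", "data.frame")
  rows
}

#' Format a hotspot table with +/- flags
#'
#' @param x a [congruence_table()] result.
#' @param ... unused.
#' @return data frame with one row per emotion and `+`/`-` flag columns
#'   per segment and modality.
#' @export
format.hotspot_table <- function(x, ...) {
  segs <- unique(x$segment)
  emos <- unique(x$emotion)
  out <- data.frame(emotion = emos, stringsAsFactors = FALSE)
  pm <- function(b) ifelse(b, "+", "-")
  for (s in segs) {
    sub <- x[x$segment == s, ]
    sub <- sub[match(emos, sub$emotion), ]
    out[[paste0(s, "_self")]] <- pm(sub$self_report)
    out[[paste0(s, "_fmri")]] <- pm(sub$fmri)
  }
  out
}

#' Build a convergence table over emotions and masks
#'
#' @param emotion_maps named list of binary emotion [stat_map()]s.
#' @param masks named list of binary [stat_map()]s (e.g. whole-body plus
#'   per-segment masks).
#' @param mode denominator convention (see [convergence_percent()]).
#' @return emotions x masks matrix of percentages of class
#'   `convergence_table` (entries `NA` where undefined).
#' @export
convergence_table <- function(emotion_maps, masks,
                              mode = c("mask", "emotion")) {
  mode <- match.arg(mode)
  m <- matrix(NA_real_, length(emotion_maps), length(masks),
              dimnames = list(names(emotion_maps), names(masks)))
  for (i in seq_along(emotion_maps)) {
    for (j in seq_along(masks)) {
      m[i, j] <- convergence_percent(emotion_maps[[i]], masks[[j]], mode)
    }
  }
  structure(m, class = c("convergence_table", class(m)), mode = mode)
}

#' @export
print.convergence_table <- function(x, ...) {
  cat(sprintf("Convergence table (%% of %s):\n", attr(x, "mode")))
  fmt <- format(round(unclass(x), 2), nsmall = 2)
  fmt[is.na(unclass(x))] <- "-"
  print(fmt, quote = FALSE)
  invisible(x)
}
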