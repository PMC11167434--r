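#' Voxel grid specification
#'
#' @param dim integer 3-vector of grid dimensions.
#' @param voxel_mm voxel size in mm (scalar or 3-vector), default 2 mm
#'   isotropic.
#' @return list with `dim`, `voxel_mm` and a RAS `affine` (4x4).
#' @export
grid_spec <- function(dim = c(32L, 32L, 24L), voxel_mm = 2) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  voxel_mm <- rep_len(voxel_mm, 3L)
  affine <- diag(c(voxel_mm, 1))
  structure(list(dim = dim, voxel_mm = voxel_mm, affine = affine),
            class = "grid_spec")
}

#' Statistical map on a voxel grid
#'
#' A 3-D scalar map with its affine and a `kind` tag.  Binary maps contain
#' only 0/1; t-maps carry degrees of freedom.
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 affine matrix (voxel -> mm).
#' @param kind one of `"beta"`, `"tstat"`, `"binary"`.
#' @param df degrees of freedom; required iff `kind == "tstat"`.
#' @param threshold_meta optional list recording thresholds applied
#'   (voxel_p, cluster_p, method).
#' @return object of class `stat_map`.
#' @export
stat_map <- function(data, affine = diag(c(2, 2, 2, 1)),
                     kind = c("beta", "tstat", "binary"),
                     df = NULL, threshold_meta = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (kind == "tstat") {
    if (is.null(df) || df < 1) stop("tstat maps require df >= 1")
  } else {
    df <- NULL
  }
  if (kind == "binary" && !all(data %in% c(0, 1))) {
    stop("binary maps may contain only 0 and 1")
  }
  structure(list(data = data, affine = affine, kind = kind, df = df,
                 threshold_meta = threshold_meta),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  d <- dim(x$data)
  extra <- switch(x$kind,
                  tstat = sprintf(", df = %g", x$df),
                  binary = sprintf(", %d suprathreshold voxels",
                                   sum(x$data != 0)),
                  "")
  cat(sprintf("stat_map [%s]: %d x %d x %d%s\n", x$kind, d[1], d[2], d[3],
              extra))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$affine, b$affine, tolerance = 1e-8))
}

#' Write a statistical map as NIfTI-1 with a JSON threshold sidecar
#'
#' @param map a [stat_map()].
#' @param path output path (`.nii` or `.nii.gz`); metadata sidecar written
#'   alongside as `<path>.json` when `threshold_meta` is present.
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, path) {
  img <- RNifti::asNifti(map$data)
  RNifti::qform(img) <- structure(map$affine, code = 2L)
  RNifti::writeNifti(img, path)
  meta <- list(kind = map$kind)
  if (!is.null(map$df)) meta$df <- map$df
  if (!is.null(map$threshold_meta)) meta$threshold <- map$threshold_meta
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a statistical map written by [write_stat_map()]
#'
#' @param path NIfTI path.
#' @param kind map kind if no sidecar is present.
#' @return a [stat_map()].
#' @export
read_stat_map <- function(path, kind = "beta") {
  img <- RNifti::readNifti(path)
  meta_path <- paste0(path, ".json")
  df <- NULL
  threshold_meta <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    kind <- meta$kind
    df <- meta$df
    threshold_meta <- meta$threshold
  }
  stat_map(array(as.numeric(img), dim = dim(img)),
           affine = unclass(RNifti::xform(img)), kind = kind, df = df,
           threshold_meta = threshold_meta)
}

#' Write a 4-D functional run as NIfTI-1
#'
#' @param volume 4-D numeric array (x, y, z, time).
#' @param grid a [grid_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_nifti <- function(volume, grid, path) {
  stopifnot(length(dim(volume)) == 4L)
  img <- RNifti::asNifti(volume)
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4-D functional run from NIfTI-1
#'
#' @param path NIfTI path.
#' @return 4-D numeric array.
#' @export
read_run_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}
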