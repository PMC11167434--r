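#' Minimum-statistic conjunction of t-maps
#'
#' Voxelwise minimum across the input t-maps, thresholded (and optionally
#' cluster-corrected) like a single t-map.  Under the conjunction null
#' (default) the minimum is compared against the single-map critical t, so
#' the result equals the intersection of the individually thresholded maps
#' when the cluster step is disabled.  The global-null variant compares the
#' minimum against the critical value for `voxel_p^(1/k)`.
#'
#' @param maps list of >= 2 [stat_map()]s of kind `tstat` on one grid with
#'   equal df.
#' @param voxel_p voxelwise p threshold.
#' @param cluster_p cluster familywise alpha or `NULL`.
#' @param null_maps permutation null minimum-maps (permutations x voxels),
#'   e.g. from [signflip_null_minmaps()]; required when `cluster_p` given.
#' @param conj_null `"conjunction"` (default, inference on all effects) or
#'   `"global"`.
#' @param connectivity,one_sided passed to [threshold_cluster()].
#' @return binary [stat_map()].
#' @export
conjunction <- function(maps, voxel_p, cluster_p = NULL, null_maps = NULL,
                        conj_null = c("conjunction", "global"),
                        connectivity = 26, one_sided = TRUE) {
  conj_null <- match.arg(conj_null)
  if (!length(maps)) stop("conjunction requires at least one t-map")
  if (length(maps) < 2) stop("conjunction requires >= 2 t-maps")
  for (m in maps) stopifnot(inherits(m, "stat_map"), m$kind == "tstat")
  for (m in maps[-1]) if (!same_grid(maps[[1]], m)) stop("grid mismatch")
  dfs <- vapply(maps, function(m) m$df, numeric(1))
  if (length(unique(dfs)) > 1) {
    warning("t-maps have different df; using the minimum")
  }
  df <- min(dfs)
  d <- dim(maps[[1]]$data)
  mn <- Reduce(pmin, lapply(maps, function(m) m$data))
  eff_p <- if (conj_null == "global") voxel_p^(1 / length(maps)) else voxel_p
  mmap <- stat_map(array(mn, dim = d), affine = maps[[1]]$affine,
                   kind = "tstat", df = df)
  out <- threshold_cluster(mmap, eff_p, cluster_p = cluster_p,
                           null_maps = null_maps,
                           connectivity = connectivity,
                           one_sided = one_sided)
  out$threshold_meta$method <- paste0("min-statistic-conjunction-",
                                      conj_null, "-null")
  out$threshold_meta$voxel_p <- voxel_p
  out$threshold_meta$n_maps <- length(maps)
  out
}

#' Permutation null minimum-maps for a conjunction
#'
#' Applies the same sign-flips jointly to every contrast's subject maps
#' (preserving the within-subject dependence between contrasts) and takes
#' the voxelwise minimum of the resulting group t-maps.
#'
#' @param maps_by_contrast list over contrasts; each element a list of
#'   per-subject beta [stat_map()]s (same subject order everywhere).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return matrix (n_perm x voxels) of null minimum-t values.
#' @export
signflip_null_minmaps <- function(maps_by_contrast, n_perm = 500,
                                  seed = 1L) {
  Ts <- lapply(seq_along(maps_by_contrast), function(i) {
    signflip_null_tmaps(maps_by_contrast[[i]], n_perm = n_perm, seed = seed)
  })
  out <- Reduce(pmin, Ts)
  attr(out, "grid_dim") <- attr(Ts[[1]], "grid_dim")
  out
}

subject_combined_maps <- function(subject_maps, weights) {
  lapply(subject_maps, function(sm) {
    d <- dim(sm[[1]]$data)
    acc <- array(0, dim = d)
    scale <- 0
    for (nm in names(weights)) {
      if (!nm %in% names(sm)) stop("missing contrast map: ", nm)
      acc <- acc + weights[nm] * sm[[nm]]$data
      scale <- scale + abs(weights[nm]) * mean(abs(sm[[nm]]$data))
    }
    # exact contrast cancellation leaves only floating-point residue;
    # snap it to zero so downstream variance estimates see true zeros
    acc[abs(acc) < scale * 1e-12] <- 0
    stat_map(acc, affine = sm[[1]]$affine, kind = "beta")
  })
}

segment_contrast_weights <- function(target,
                                     segments = body_segments(),
                                     modalities = c("motor", "tactile")) {
  all_conds <- as.vector(outer(segments, modalities, paste, sep = "_"))
  w <- stats::setNames(numeric(length(all_conds)), all_conds)
  tgt <- paste0(target, "_", modalities)
  oth <- setdiff(all_conds, tgt)
  w[tgt] <- 1 / length(tgt)
  w[oth] <- -1 / length(oth)
  w
}

#' Body-segment-specific group map
#'
#' Second-level contrast "target segment (motor + tactile) > mean of the
#' other segments (both modalities)", thresholded and optionally
#' cluster-corrected.
#'
#' @param subject_maps list over subjects; each a named list of
#'   per-condition beta [stat_map()]s with names `<segment>_<modality>`
#'   for all 4 segments x 2 modalities.
#' @param target target segment (`"face"`, `"hands"`, `"trunk"`,
#'   `"feet"`).
#' @param voxel_p,cluster_p thresholds (see [threshold_cluster()]).
#' @param n_perm sign-flip permutations used when `cluster_p` is given.
#' @param seed permutation seed.
#' @param connectivity,one_sided passed to [threshold_cluster()].
#' @return binary [stat_map()] with the group t-map attached as
#'   `$tmap`.
#' @export
segment_specific_map <- function(subject_maps, target, voxel_p = 0.001,
                                 cluster_p = NULL, n_perm = 500, seed = 1L,
                                 connectivity = 26, one_sided = TRUE) {
  stopifnot(target %in% body_segments())
  w <- segment_contrast_weights(target)
  combined <- subject_combined_maps(subject_maps, w)
  tmap <- second_level_ttest(combined)
  nulls <- if (!is.null(cluster_p)) {
    signflip_null_tmaps(combined, n_perm = n_perm, seed = seed)
  }
  out <- threshold_cluster(tmap, voxel_p, cluster_p = cluster_p,
                           null_maps = nulls, connectivity = connectivity,
                           one_sided = one_sided)
  out$threshold_meta$contrast <-
    sprintf("%s motor+tactile > other segments", target)
  out$tmap <- tmap
  out
}

#' Partition the whole-body map into motor- and tactile-dominant voxels
#'
#' Second-level contrast motor > tactile (summed over segments) and its
#' negation, thresholded and restricted to the whole-body map.  The two
#' outputs are disjoint by construction.
#'
#' @param subject_maps per-subject named lists of condition beta maps (as
#'   in [segment_specific_map()]).
#' @param whole_body binary [stat_map()] restricting the partition.
#' @param voxel_p voxelwise p threshold (default 0.001).
#' @param cluster_p,n_perm,seed optional cluster correction.
#' @param connectivity passed to [threshold_cluster()].
#' @return list with binary maps `motor` and `tactile`.
#' @export
motor_tactile_partition <- function(subject_maps, whole_body,
                                    voxel_p = 0.001, cluster_p = NULL,
                                    n_perm = 500, seed = 1L,
                                    connectivity = 26) {
  if (is.null(voxel_p)) stop("thresholds must be supplied")
  segs <- body_segments()
  w <- stats::setNames(
    rep(c(1, -1) / length(segs), each = length(segs)),
    c(paste0(segs, "_motor"), paste0(segs, "_tactile")))
  combined <- subject_combined_maps(subject_maps, w)
  tmap <- second_level_ttest(combined)
  nulls <- if (!is.null(cluster_p)) {
    signflip_null_tmaps(combined, n_perm = n_perm, seed = seed)
  }
  motor <- threshold_cluster(tmap, voxel_p, cluster_p, nulls,
                             connectivity = connectivity, one_sided = TRUE)
  neg <- tmap
  neg$data <- -neg$data
  tactile <- threshold_cluster(neg, voxel_p, cluster_p, nulls,
                               connectivity = connectivity,
                               one_sided = TRUE)
  restrict <- function(m) {
    m$data <- m$data * (whole_body$data != 0)
    m
  }
  list(motor = restrict(motor), tactile = restrict(tactile))
}

#' Build the full set of sensorimotor masks from localizer contrasts
#'
#' Produces the whole-body conjunction map (minimum statistic over all 8
#' localizer contrasts), one specific map per body segment (target
#' segment > others), and the motor/tactile partition.  Voxels claimed by
#' more than one segment-specific map are assigned to the segment with the
#' larger contrast t, so segment masks are pairwise disjoint.
#'
#' @param subject_maps per-subject named lists of condition beta
#'   [stat_map()]s (names `<segment>_<modality>`).
#' @param voxel_p voxelwise threshold (default 0.001).
#' @param cluster_p cluster familywise alpha or `NULL`.
#' @param n_perm permutations for the cluster null.
#' @param seed permutation seed.
#' @param connectivity cluster connectivity.
#' @return object of class `segment_mask_set`: list with `whole_body`,
#'   `segments` (named list of binary maps), `partition`
#'   (motor/tactile), and `provenance`.
#' @export
build_segment_masks <- function(subject_maps, voxel_p = 0.001,
                                cluster_p = NULL, n_perm = 500, seed = 1L,
                                connectivity = 26) {
  conds <- as.vector(outer(body_segments(), c("motor", "tactile"),
                           paste, sep = "_"))
  maps_by_contrast <- lapply(conds, function(cn) {
    lapply(subject_maps, function(sm) sm[[cn]])
  })
  names(maps_by_contrast) <- conds
  group_t <- lapply(maps_by_contrast, second_level_ttest)
  conj_nulls <- if (!is.null(cluster_p)) {
    signflip_null_minmaps(maps_by_contrast, n_perm = n_perm, seed = seed)
  }
  whole_body <- conjunction(group_t, voxel_p, cluster_p = cluster_p,
                            null_maps = conj_nulls,
                            connectivity = connectivity)
  seg_maps <- lapply(body_segments(), function(s) {
    segment_specific_map(subject_maps, s, voxel_p = voxel_p,
                         cluster_p = cluster_p, n_perm = n_perm,
                         seed = seed, connectivity = connectivity)
  })
  names(seg_maps) <- body_segments()
  # disjointness: competing voxels go to the segment with the larger t
  tstack <- vapply(seg_maps, function(m) as.numeric(m$tmap$data),
                   numeric(length(whole_body$data)))
  bstack <- vapply(seg_maps, function(m) as.numeric(m$data),
                   numeric(length(whole_body$data)))
  multi <- rowSums(bstack) > 1
  if (any(multi)) {
    winner <- max.col(tstack[multi, , drop = FALSE], ties.method = "first")
    for (j in seq_along(seg_maps)) {
      drop_j <- multi & bstack[, j] > 0
      drop_j[multi][winner == j] <- FALSE
      seg_maps[[j]]$data[array(drop_j, dim = dim(whole_body$data))] <- 0
    }
  }
  partition <- motor_tactile_partition(subject_maps, whole_body,
                                       voxel_p = voxel_p,
                                       cluster_p = cluster_p,
                                       n_perm = n_perm, seed = seed,
                                       connectivity = connectivity)
  structure(list(
    whole_body = whole_body,
    segments = seg_maps,
    partition = partition,
    provenance = list(voxel_p = voxel_p, cluster_p = cluster_p,
                      n_perm = if (!is.null(cluster_p)) n_perm else NULL,
                      connectivity = connectivity,
                      n_subjects = length(subject_maps))),
    class = "segment_mask_set")
}

#' @export
print.segment_mask_set <- function(x, ...) {
  cat("Segment mask set\n")
  cat(sprintf("  whole body: %d voxels\n", sum(x$whole_body$data != 0)))
  for (s in names(x$segments)) {
    cat(sprintf("  %-6s: %d voxels\n", s, sum(x$segments[[s]]$data != 0)))
  }
  invisible(x)
}

#' Write a segment mask set as NIfTI volumes plus a JSON manifest
#'
#' @param masks a [build_segment_masks()] result.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_segment_masks <- function(masks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  wb <- file.path(dir, "whole_body_conjunction.nii.gz")
  write_stat_map(masks$whole_body, wb)
  files$whole_body <- basename(wb)
  for (s in names(masks$segments)) {
    p <- file.path(dir, sprintf("%s_specific.nii.gz", s))
    m <- masks$segments[[s]]
    m$tmap <- NULL
    write_stat_map(m, p)
    files[[s]] <- basename(p)
  }
  for (m in names(masks$partition)) {
    p <- file.path(dir, sprintf("wholebody_%s.nii.gz", m))
    write_stat_map(masks$partition[[m]], p)
    files[[paste0("partition_", m)]] <- basename(p)
  }
  manifest <- file.path(dir, "masks_manifest.json")
  jsonlite::write_json(list(files = files, provenance = masks$provenance),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
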