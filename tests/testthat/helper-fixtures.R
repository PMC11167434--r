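# Shared small fixtures, built in code at test time.

tiny_grid <- function() grid_spec(c(16, 16, 12))

tiny_truth <- function(noise_sd = 0, drift = 0, seed = 1L, ...) {
  ground_truth(grid = tiny_grid(),
               roi_centers = list(face_motor = c(8, 8, 6)),
               shared_center = NULL,
               effect_size = c(face_motor = 1),
               noise_sd = noise_sd, drift_amplitude = drift,
               seed = seed, ...)
}

one_block_design <- function(n_volumes = 40, tr = 2,
                             condition = "face_motor") {
  design_spec(tr, n_volumes,
              data.frame(onset = 0, duration = 20, condition = condition))
}

# binary stat_map from a set of linear voxel indices
binary_map_from <- function(idx, dim, affine = diag(c(2, 2, 2, 1))) {
  a <- array(0, dim = dim)
  a[idx] <- 1
  stat_map(a, affine = affine, kind = "binary")
}

random_binary_map <- function(dim, p = 0.3) {
  stat_map(array(as.numeric(stats::runif(prod(dim)) < p), dim = dim),
           kind = "binary")
}

# segment masks: 4 disjoint blocks in a small grid
tiny_segment_masks <- function(dim = c(10, 10, 8), each = 50) {
  stopifnot(4 * each <= prod(dim))
  segs <- c("face", "hands", "trunk", "feet")
  idx <- split(seq_len(4 * each), rep(1:4, each = each))
  out <- lapply(1:4, function(i) binary_map_from(idx[[i]], dim))
  names(out) <- segs
  out
}
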