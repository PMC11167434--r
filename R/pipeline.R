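#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end synthetic pipeline with
#' defaults chosen to emulate the study design at desk scale: 2 s TR
#' block designs (20 s localizer blocks, 14 s recall episodes), four body
#' segments x two localizer modalities, five recalled emotions, pre/post
#' silhouettes and per-episode ratings.
#'
#' @param n_subjects number of simulated subjects (default 8).
#' @param grid_dim voxel grid (default 24 x 24 x 18 at 2 mm).
#' @param voxel_mm voxel size in mm.
#' @param voxel_p group voxelwise threshold (default 0.001).
#' @param cluster_p cluster familywise alpha (default 0.05; `NA` disables
#'   the cluster step).
#' @param single_subject_p single-subject voxel threshold (default 0.05,
#'   no cluster step).
#' @param n_permutations sign-flip permutations for cluster correction.
#' @param seed master seed; all per-subject seeds derive from it.
#' @param effect planted localizer/emotion beta amplitude.
#' @param noise_sd,drift_amplitude,baseline noise model of the simulator.
#' @param smooth_fwhm_mm Gaussian smoothing FWHM applied to contrast maps
#'   (default 0 = off, preserving planted voxel counts).
#' @param highpass_s high-pass cutoff (default 128 s).
#' @param n_localizer_cycles repetitions of the 4-segment localizer cycle.
#' @param n_per_emotion recall episodes per emotion.
#' @param denominator_mode convergence denominator (`"mask"` or
#'   `"emotion"`).
#' @param rsa_mode `"direct"` or `"rdm"`.
#' @param channel silhouette counting channel (`"activation"` or
#'   `"subtraction"`).
#' @param one_sided directional thresholding (default TRUE).
#' @param connectivity cluster connectivity (26 or 6).
#' @param pixel_fractions emotions x segments matrix of planted silhouette
#'   activation fractions (defaults to the emotion overlap fractions).
#' @param subject_jitter_sd between-subject SD of the planted fractions.
#' @param prepost_jitter_sd pre-to-post SD of the planted fractions.
#' @param ratings_effect,ratings_sd planted emotional-minus-neutral rating
#'   effect and noise.
#' @param register_scans `"check"` (default: register one scan per
#'   subject and record the recovered transform), `"all"`, or `"none"`.
#' @param write_maps write NIfTI masks/maps and silhouette PNGs.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_subjects = 8,
                       grid_dim = c(24, 24, 18),
                       voxel_mm = 2,
                       voxel_p = 0.001,
                       cluster_p = 0.05,
                       single_subject_p = 0.05,
                       n_permutations = 200,
                       seed = 1L,
                       effect = 2,
                       noise_sd = 1,
                       drift_amplitude = 1,
                       baseline = 100,
                       smooth_fwhm_mm = 0,
                       highpass_s = 128,
                       n_localizer_cycles = 4,
                       n_per_emotion = 3,
                       denominator_mode = c("mask", "emotion"),
                       rsa_mode = c("direct", "rdm"),
                       channel = c("activation", "subtraction"),
                       one_sided = TRUE,
                       connectivity = 26,
                       pixel_fractions = NULL,
                       subject_jitter_sd = 0.05,
                       prepost_jitter_sd = 0.03,
                       ratings_effect = 1.5,
                       ratings_sd = 0.8,
                       register_scans = c("check", "all", "none"),
                       write_maps = FALSE) {
  denominator_mode <- match.arg(denominator_mode)
  rsa_mode <- match.arg(rsa_mode)
  channel <- match.arg(channel)
  register_scans <- match.arg(register_scans)
  stopifnot(voxel_p > 0, voxel_p < 1, single_subject_p > 0,
            single_subject_p < 1)
  if (!is.null(cluster_p) && !is.na(cluster_p)) {
    stopifnot(cluster_p > 0, cluster_p < 1)
    if (n_permutations < 100) {
      stop("n_permutations must be >= 100 when cluster correction is on")
    }
  } else {
    cluster_p <- NULL
  }
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

subject_seed <- function(seed, i, salt = 0L) {
  (as.integer(seed) * 1009L + i * 7919L + salt * 104729L) %% 2147483647L
}

#' Simulate a full multi-subject study
#'
#' Generates, per subject: a motor and a tactile localizer run, an
#' emotional-recall run with subject-level emotion activation planted
#' inside the segment ROIs, pre- and post-scan silhouettes for each
#' emotion, and per-episode ratings.
#'
#' @param config a [run_config()].
#' @return list of class `study`: `subjects` (per-subject data),
#'   `truth`, `template`, `designs`, `config`.
#' @export
simulate_study <- function(config = run_config()) {
  grid <- grid_spec(config$grid_dim, config$voxel_mm)
  truth0 <- ground_truth(grid = grid,
                         effect_size = config$effect,
                         noise_sd = config$noise_sd,
                         drift_amplitude = config$drift_amplitude,
                         baseline = config$baseline,
                         seed = config$seed)
  # one shared group-level emotion activation pattern: the planted overlap
  # fractions are a property of the group, subjects differ by noise
  truth0 <- plant_emotion_betas(truth0, effect = config$effect,
                                seed = config$seed)
  template <- body_template()
  designs <- list(
    motor = localizer_design("motor", n_cycles = config$n_localizer_cycles),
    tactile = localizer_design("tactile",
                               n_cycles = config$n_localizer_cycles),
    recall = recall_design(config$n_per_emotion, seed = config$seed))
  frac0 <- if (is.null(config$pixel_fractions)) {
    truth0$emotion_overlap_fraction
  } else config$pixel_fractions
  emos <- rownames(frac0)
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    truth_i <- truth0
    truth_i$seed <- subject_seed(config$seed, i)
    runs <- list(
      motor = simulate_run(designs$motor, truth_i,
                           seed = subject_seed(config$seed, i, 2L)),
      tactile = simulate_run(designs$tactile, truth_i,
                             seed = subject_seed(config$seed, i, 3L)),
      recall = simulate_run(designs$recall, truth_i,
                            seed = subject_seed(config$seed, i, 4L)))
    jitter_frac <- function(f, sd, seed) {
      out <- with_seed(seed, f + stats::rnorm(length(f), 0, sd))
      out[out < 0] <- 0
      out[out > 1] <- 1
      out
    }
    frac_subj <- array(jitter_frac(frac0, config$subject_jitter_sd,
                                   subject_seed(config$seed, i, 5L)),
                       dim = dim(frac0), dimnames = dimnames(frac0))
    sil <- list(pre = list(), post = list())
    for (phase in c("pre", "post")) {
      for (e in emos) {
        f <- frac_subj[e, ]
        if (phase == "post") {
          f <- jitter_frac(f, config$prepost_jitter_sd,
                           subject_seed(config$seed, i,
                                        6L + match(e, emos)))
        }
        sil[[phase]][[e]] <- simulate_silhouette(
          f, 0, template,
          seed = subject_seed(config$seed, i,
                              10L + match(e, emos) +
                                ifelse(phase == "post", 100L, 0L)),
          subject_id = sprintf("s%02d", i), phase = phase, emotion = e)
      }
    }
    ratings <- simulate_ratings(
      n_emotional = config$n_per_emotion,
      effect = config$ratings_effect, sd = config$ratings_sd,
      seed = subject_seed(config$seed, i, 8L),
      subject_id = sprintf("s%02d", i))
    list(id = sprintf("s%02d", i), truth = truth_i, runs = runs,
         silhouettes = sil, ratings = ratings)
  })
  structure(list(subjects = subjects, truth = truth0, template = template,
                 designs = designs, config = config, grid = grid),
            class = "study")
}

#' @export
print.study <- function(x, ...) {
  cat(sprintf(
    "Synthetic study: %d subjects, grid %s, runs: %s\n",
    length(x$subjects), paste(x$grid$dim, collapse = "x"),
    paste(names(x$designs), collapse = ", ")))
  invisible(x)
}

first_level_contrasts <- function(subject, designs, config, grid) {
  affine <- grid$affine
  prep <- function(vol) {
    if (config$baseline > 0) vol <- scale_global(vol) else vol
  }
  out <- list()
  for (run in c("motor", "tactile")) {
    X <- build_design(designs[[run]], highpass_s = config$highpass_s)
    fit <- fit_first_level(prep(subject$runs[[run]]), X, affine = affine)
    for (cn in designs[[run]]$condition_names) {
      w <- stats::setNames(1, cn)
      out[[cn]] <- contrast_tmap(fit, w, what = "beta")
      if (config$smooth_fwhm_mm > 0) {
        out[[cn]] <- smooth_gaussian(out[[cn]], config$smooth_fwhm_mm)
      }
    }
  }
  Xr <- build_design(designs$recall, highpass_s = config$highpass_s)
  fit_r <- fit_first_level(prep(subject$runs$recall), Xr, affine = affine)
  emo <- setdiff(designs$recall$condition_names, "neutral")
  emo_beta <- list()
  emo_binary <- list()
  for (e in emo) {
    w <- stats::setNames(c(1, -1), c(e, "neutral"))
    emo_beta[[e]] <- contrast_tmap(fit_r, w, what = "beta")
    if (config$smooth_fwhm_mm > 0) {
      emo_beta[[e]] <- smooth_gaussian(emo_beta[[e]], config$smooth_fwhm_mm)
    }
    tm <- contrast_tmap(fit_r, w, what = "tstat")
    emo_binary[[e]] <- threshold_cluster(tm, config$single_subject_p,
                                         cluster_p = NULL,
                                         one_sided = config$one_sided)
  }
  list(localizer = out, emotion_beta = emo_beta,
       emotion_binary = emo_binary)
}

format_percent_table <- function(mat, digits = 2) {
  out <- format(round(unclass(mat), digits), nsmall = digits,
                trim = TRUE)
  out[is.na(unclass(mat))] <- "-"
  df <- data.frame(emotion = rownames(mat), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  basename(path)
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate, first- and second-level GLM, sensorimotor mask
#' construction, group and single-subject emotion mapping, silhouette
#' digitization, convergence tables, hotspot congruence and RSA/ratings
#' statistics, and writes the report bundle (CSV tables shaped like the
#' group body-emotion and convergence tables, plus a JSON provenance
#' manifest) to `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param study optionally a pre-simulated [simulate_study()] result.
#' @return list of class `pipeline_result` with all intermediate and
#'   final objects.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         study = NULL) {
  t_start <- Sys.time()
  if (is.null(study)) study <- simulate_study(config)
  template <- study$template
  grid <- study$grid
  emos <- rownames(study$truth$emotion_overlap_fraction)
  segs <- body_segments()

  # --- first level ---------------------------------------------------
  firsts <- lapply(study$subjects, first_level_contrasts,
                   designs = study$designs, config = config, grid = grid)
  localizer_maps <- lapply(firsts, `[[`, "localizer")

  # --- sensorimotor masks --------------------------------------------
  masks <- build_segment_masks(localizer_maps,
                               voxel_p = config$voxel_p,
                               cluster_p = config$cluster_p,
                               n_perm = config$n_permutations,
                               seed = subject_seed(config$seed, 0L, 20L),
                               connectivity = config$connectivity)

  # --- group emotion maps --------------------------------------------
  emotion_group <- list()
  for (e in emos) {
    betas <- lapply(firsts, function(f) f$emotion_beta[[e]])
    tmap <- second_level_ttest(betas)
    nulls <- if (!is.null(config$cluster_p)) {
      signflip_null_tmaps(betas, n_perm = config$n_permutations,
                          seed = subject_seed(config$seed, 0L,
                                              21L + match(e, emos)))
    }
    emotion_group[[e]] <- threshold_cluster(
      tmap, config$voxel_p, cluster_p = config$cluster_p,
      null_maps = nulls, connectivity = config$connectivity,
      one_sided = config$one_sided)
  }

  # --- convergence tables (group level) ------------------------------
  table2 <- convergence_table(emotion_group,
                              list(sensorimotor = masks$whole_body),
                              mode = config$denominator_mode)
  table3 <- convergence_table(emotion_group, masks$segments,
                              mode = config$denominator_mode)

  # --- single-subject voxel homunculi --------------------------------
  voxel_mats <- lapply(seq_along(firsts), function(i) {
    vh <- voxel_homunculus(firsts[[i]]$emotion_binary, masks)
    attr(vh, "subject_id") <- study$subjects[[i]]$id
    vh
  })
  table5 <- body_emotion_matrix(
    Reduce(`+`, lapply(voxel_mats, unclass)) / length(voxel_mats),
    source = "voxels", subject_id = "group")

  # --- silhouettes ----------------------------------------------------
  registration_checks <- list()
  pixel_mats <- list(pre = list(), post = list())
  subtraction_by_emotion <- stats::setNames(
    lapply(emos, function(e) list()), emos)
  for (i in seq_along(study$subjects)) {
    subj <- study$subjects[[i]]
    for (phase in c("pre", "post")) {
      mat <- matrix(NA_real_, length(emos), length(segs),
                    dimnames = list(emos, segs))
      for (e in emos) {
        sil <- subj$silhouettes[[phase]][[e]]
        do_register <- config$register_scans == "all" ||
          (config$register_scans == "check" && phase == "pre" &&
             e == emos[1])
        if (do_register) {
          scan <- render_scan(sil, template)
          reg <- register_to_template(scan, template)
          if (config$register_scans == "all") {
            sil <- code_pixels(reg$registered, template,
                               subject_id = subj$id, phase = phase,
                               emotion = e)
          }
          registration_checks[[paste(subj$id, phase, e, sep = "_")]] <-
            reg$transform
        }
        mat[e, ] <- segment_percentages(sil, template,
                                        channel = config$channel)
        if (phase == "post") {
          subtraction_by_emotion[[e]][[subj$id]] <- subtraction_map(sil)
        }
      }
      pixel_mats[[phase]][[subj$id]] <-
        body_emotion_matrix(mat, source = "pixels", subject_id = subj$id)
    }
  }
  table1 <- body_emotion_matrix(
    Reduce(`+`, lapply(pixel_mats$post, unclass)) /
      length(pixel_mats$post),
    source = "pixels", subject_id = "group")
  reliability <- prepost_reliability(pixel_mats$pre, pixel_mats$post)
  pixel_tmaps <- lapply(subtraction_by_emotion, group_pixel_tmap)

  # --- congruence and RSA --------------------------------------------
  table6 <- congruence_table(table1, table5)
  rsa <- rsa_voxel_pixel(pixel_mats$post, voxel_mats,
                         mode = config$rsa_mode)
  ratings_all <- do.call(rbind, lapply(study$subjects, `[[`, "ratings"))
  ratings_tests <- list(
    intensity = ratings_contrast(ratings_all, "intensity"),
    vividness = ratings_contrast(ratings_all, "vividness"))
  # Bayesian one-sample tests: does every emotion engage every segment?
  bf_cell <- function(mats) {
    grid_df <- expand.grid(emotion = emos, segment = segs,
                           stringsAsFactors = FALSE)
    grid_df$bf10 <- NA_real_
    grid_df$p <- NA_real_
    for (k in seq_len(nrow(grid_df))) {
      vals <- vapply(mats, function(m) {
        unclass(m)[grid_df$emotion[k], grid_df$segment[k]]
      }, numeric(1))
      vals[is.na(vals)] <- 0
      if (stats::sd(vals) > 0) {
        bf <- bayes_one_sample(vals)
        grid_df$bf10[k] <- bf$bf10
        grid_df$p[k] <- bf$p
      }
    }
    grid_df
  }
  bf_pixels <- bf_cell(pixel_mats$post)
  bf_voxels <- bf_cell(voxel_mats)

  result <- structure(list(
    config = config, study = study, masks = masks,
    emotion_group = emotion_group,
    table1 = table1, table2 = table2, table3 = table3,
    table5 = table5, table6 = table6,
    voxel_mats = voxel_mats, pixel_mats = pixel_mats,
    reliability = reliability, pixel_tmaps = pixel_tmaps,
    rsa = rsa, ratings = ratings_tests,
    bf_pixels = bf_pixels, bf_voxels = bf_voxels,
    registration_checks = registration_checks,
    elapsed_s = as.numeric(Sys.time() - t_start, units = "secs")),
    class = "pipeline_result")

  if (!is.null(out_dir)) write_report(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run: %d subjects, %.1f s\n",
              length(x$study$subjects), x$elapsed_s))
  cat(sprintf("  whole-body mask: %d voxels\n",
              sum(x$masks$whole_body$data != 0)))
  cat(sprintf("  pre/post silhouette reliability r = %.3f (p = %.3g)\n",
              x$reliability$r, x$reliability$p))
  cat(sprintf("  RSA mean r = %.3f, t(%g) = %.2f, p = %.3g\n",
              x$rsa$mean_r, x$rsa$df, x$rsa$t, x$rsa$p))
  invisible(x)
}

#' Write the pipeline report bundle
#'
#' CSV tables (group pixel percentages, convergence with the whole-body
#' and per-segment masks, group voxel percentages, hotspot congruence,
#' ratings and RSA statistics) plus a JSON provenance manifest; map
#' volumes and silhouette rasters when `config$write_maps` is set.
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  files <- list()
  files$table1_pixel_percentages <- write_table_csv(
    format_percent_table(result$table1),
    file.path(out_dir, "table1_pixel_percentages.csv"))
  files$table2_convergence_wholebody <- write_table_csv(
    format_percent_table(result$table2),
    file.path(out_dir, "table2_convergence_wholebody.csv"))
  files$table3_convergence_segments <- write_table_csv(
    format_percent_table(result$table3),
    file.path(out_dir, "table3_convergence_segments.csv"))
  files$table5_voxel_percentages <- write_table_csv(
    format_percent_table(result$table5),
    file.path(out_dir, "table5_voxel_percentages.csv"))
  files$table6_hotspot_congruence <- write_table_csv(
    format(result$table6),
    file.path(out_dir, "table6_hotspot_congruence.csv"))
  fmt_stats <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) round(x, 4))
    df
  }
  files$ratings_intensity <- write_table_csv(
    fmt_stats(result$ratings$intensity),
    file.path(out_dir, "ratings_intensity.csv"))
  files$ratings_vividness <- write_table_csv(
    fmt_stats(result$ratings$vividness),
    file.path(out_dir, "ratings_vividness.csv"))
  rsa_df <- data.frame(subject = seq_along(result$rsa$r),
                       r = round(result$rsa$r, 6))
  files$rsa_subject_r <- write_table_csv(
    rsa_df, file.path(out_dir, "rsa_subject_r.csv"))
  summary_df <- data.frame(
    quantity = c("prepost_reliability_r", "prepost_reliability_p",
                 "rsa_mean_r", "rsa_t", "rsa_p"),
    value = round(c(result$reliability$r, result$reliability$p,
                    result$rsa$mean_r, result$rsa$t, result$rsa$p), 6))
  files$summary_stats <- write_table_csv(
    summary_df, file.path(out_dir, "summary_stats.csv"))
  files$bf_pixels <- write_table_csv(
    fmt_stats(result$bf_pixels), file.path(out_dir, "bf_pixels.csv"))
  files$bf_voxels <- write_table_csv(
    fmt_stats(result$bf_voxels), file.path(out_dir, "bf_voxels.csv"))
  if (isTRUE(cfg$write_maps)) {
    write_segment_masks(result$masks, file.path(out_dir, "masks"))
    dir.create(file.path(out_dir, "emotion_maps"), showWarnings = FALSE)
    for (e in names(result$emotion_group)) {
      write_stat_map(result$emotion_group[[e]],
                     file.path(out_dir, "emotion_maps",
                               sprintf("%s_masked.nii.gz", e)))
    }
    dir.create(file.path(out_dir, "silhouettes"), showWarnings = FALSE)
    for (sid in names(result$pixel_mats$post)) {
      utils::write.csv(
        round(unclass(result$pixel_mats$post[[sid]]), 2),
        file.path(out_dir, "silhouettes",
                  sprintf("%s_post_percentages.csv", sid)))
    }
  }
  manifest <- list(
    package = "emomap",
    version = as.character(utils::packageVersion("emomap")),
    seed = cfg$seed,
    n_subjects = cfg$n_subjects,
    grid = cfg$grid_dim,
    thresholds = list(voxel_p = cfg$voxel_p, cluster_p = cfg$cluster_p,
                      single_subject_p = cfg$single_subject_p,
                      n_permutations = cfg$n_permutations,
                      one_sided = cfg$one_sided,
                      connectivity = cfg$connectivity),
    denominator_mode = cfg$denominator_mode,
    rsa_mode = cfg$rsa_mode,
    channel = cfg$channel,
    voxel_volume_mm3 = prod(rep_len(cfg$voxel_mm, 3)),
    registration_checks = result$registration_checks,
    files = files,
    elapsed_s = result$elapsed_s)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest_path)
}
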