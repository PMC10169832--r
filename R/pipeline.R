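#' Analysis configuration
#'
#' Collects every tunable of the per-subject pipeline in one validated,
#' serializable object. Input frames come either from files (`frame_files`
#' with a dialect of multi-page TIFF, PNG series, or raw + JSON sidecar)
#' or from a phantom specification (`phantom_seed` etc.), in which case the
#' subject is simulated.
#'
#' @param frame_files input frame path(s), or `NULL` to simulate a phantom.
#' @param dialect `"tiff"`, `"png"` or `"raw"`.
#' @param roi_masks list with `arteriole_files`, `venule_files`, `faz_file`
#'   and optionally `foveola_centre`, on the original (pre-upscaling) grid;
#'   `NULL` when a phantom provides ground-truth ROIs.
#' @param upscale_factor frame upscaling factor (2 by default).
#' @param registration `"rigid+nonlinear"`, `"rigid"` or `"none"`.
#' @param vessel_scales vesselness scales on the original grid (scaled by
#'   `upscale_factor` internally).
#' @param lo_frac,hi_frac hysteresis thresholds (fractions of the maximum
#'   vesselness).
#' @param min_segment_length minimum vessel-segment length, upscaled px.
#' @param mean_floor CoV validity floor (`NULL` = 1% of global mean).
#' @param fcp_width F-cp annulus width on the original grid, px.
#' @param phantom_shape,n_arterioles,n_venules,faz_radius,phantom_seed
#'   phantom geometry when simulating.
#' @param model a [temporal_model()] for simulation.
#' @param motion `NULL` for none, or list with `max_shift`, `max_rot_deg`
#'   for injected rigid inter-frame motion.
#' @param out_dir optional output directory; when set, all intermediates
#'   (CoV map TIFF, skeleton mask, segment table CSV, ROI summary CSV,
#'   transform records JSON) are written under it.
#' @param seed integer seed governing simulation randomness.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(frame_files = NULL, dialect = c("tiff", "png", "raw"),
                            roi_masks = NULL, upscale_factor = 2L,
                            registration = c("rigid+nonlinear", "rigid", "none"),
                            vessel_scales = c(0.6, 1.25, 2.5), lo_frac = 0.02,
                            hi_frac = 0.10, min_segment_length = 3,
                            mean_floor = NULL, fcp_width = 6,
                            phantom_shape = c(304, 304), n_arterioles = 8,
                            n_venules = 8, faz_radius = 30,
                            phantom_seed = 1, model = temporal_model(),
                            motion = NULL, out_dir = NULL, seed = 1) {
  dialect <- match.arg(dialect)
  registration <- match.arg(registration)
  if (!is.null(frame_files)) {
    missing <- frame_files[!file.exists(frame_files)]
    if (length(missing)) stop_octa("frame file not found: %s", missing[1])
    if (is.null(roi_masks)) stop_octa("file-based analysis needs roi_masks")
  }
  if (!is.null(roi_masks)) {
    paths <- c(roi_masks$arteriole_files, roi_masks$venule_files, roi_masks$faz_file)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stop_octa("ROI mask file not found: %s", missing[1])
  }
  structure(as.list(environment()), class = "analysis_config")
}

#' Write/read an analysis configuration (YAML)
#'
#' The configuration round-trips through serialization unchanged (the
#' temporal model is stored field by field).
#'
#' @param config an [analysis_config()].
#' @param path YAML file path.
#' @return the configuration (invisibly for the writer).
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$model <- unclass(x$model)
  x$schema <- "octacov-config-1"
  yaml::write_yaml(x, path)
  invisible(config)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!identical(x$schema, "octacov-config-1"))
    stop_octa("unrecognized config schema: %s", x$schema %||% "<missing>")
  x$schema <- NULL
  x$model <- structure(x$model, class = "temporal_model")
  for (f in c("phantom_shape", "vessel_scales"))
    if (!is.null(x[[f]])) x[[f]] <- as.numeric(unlist(x[[f]]))
  structure(x, class = "analysis_config")
}

#' Run the full per-subject analysis
#'
#' Executes the pipeline stages in order: obtain frames (read files or
#' simulate a phantom, optionally injecting inter-frame motion), upscale
#' and align, compute the pixel-wise CoV map, extract centrelines,
#' decompose into vessel segments with mean CoV, build the ROI categories
#' (ground truth for phantoms, mask files otherwise), assign segments and
#' summarize per ROI. Deterministic for a fixed config and seed. Any stage
#' failure aborts with the stage name.
#'
#' @param config an [analysis_config()].
#' @return list of class `subject_result`: `frames` (aligned), `cov`,
#'   `skeleton`, `segments`, `roi`, `assignments`, `summaries`,
#'   `phantom` (when simulated), `config`.
#' @export
run_subject <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_octa("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  phantom <- NULL
  if (is.null(config$frame_files)) {
    phantom <- stage("simulate", generate_phantom(
      shape = config$phantom_shape, n_arterioles = config$n_arterioles,
      n_venules = config$n_venules, faz_radius = config$faz_radius,
      seed = config$phantom_seed))
    sim <- stage("simulate", simulate_sequence(phantom, config$model, seed = config$seed))
    fs <- sim$frames
    if (!is.null(config$motion))
      fs <- stage("simulate", inject_motion(fs, config$motion$max_shift %||% 3,
                                            config$motion$max_rot_deg %||% 1,
                                            seed = config$seed + 1))
  } else {
    fs <- stage("load", switch(config$dialect,
      tiff = read_frames_tiff(config$frame_files[1]),
      png = read_frames_png(config$frame_files),
      raw = read_frames_raw(config$frame_files[1])))
  }

  f <- config$upscale_factor
  if (config$registration == "none") {
    frames_up <- lapply(seq_len(n_frames(fs)), function(t) upscale(fs$frames[, , t], f))
    aligned <- octa_frames(frames_up, px_per_mm = fs$px_per_mm * f, aligned = TRUE,
                           upscale_factor = f,
                           transforms = rep(list(list(rigid = c(dx = 0, dy = 0, theta = 0))),
                                            n_frames(fs)))
  } else {
    aligned <- stage("align", align_sequence(
      fs, upscale_factor = f,
      nonlinear = config$registration == "rigid+nonlinear"))
  }

  cov <- stage("covmap", compute_cov_map(aligned, mean_floor = config$mean_floor))
  sk <- stage("segment", segment_centrelines(aligned, scales = config$vessel_scales * f,
                                             lo_frac = config$lo_frac,
                                             hi_frac = config$hi_frac))
  segs <- stage("segment", segment_mean_cov(cov, decompose_segments(sk, config$min_segment_length)))

  rs <- stage("roi", {
    if (!is.null(phantom)) {
      base <- roi_set(
        arterioles = lapply(phantom$vessel_masks[grep("^a", names(phantom$vessel_masks))],
                            upscale_mask, factor = f),
        venules = lapply(phantom$vessel_masks[grep("^v", names(phantom$vessel_masks))],
                         upscale_mask, factor = f),
        faz = upscale_mask(phantom$faz_mask, f),
        foveola_centre = upscale_coord(phantom$fovea_centre, f))
    } else {
      rm_ <- config$roi_masks
      base <- load_roi_masks(rm_$arteriole_files, rm_$venule_files, rm_$faz_file,
                             foveola_centre = rm_$foveola_centre)
      base$arterioles <- lapply(base$arterioles, upscale_mask, factor = f)
      base$venules <- lapply(base$venules, upscale_mask, factor = f)
      base$faz <- upscale_mask(base$faz, f)
      base$shape <- base$shape * f
      if (!is.null(base$foveola_centre))
        base$foveola_centre <- upscale_coord(base$foveola_centre, f)
    }
    base <- build_influence_rois(base)
    base <- add_quadrants(base)
    add_fcp_band(base, width = config$fcp_width * f)
  })

  asg <- stage("roi", assign_segments(segs, rs))
  summ <- stage("summarize", summarize_roi(asg))

  res <- structure(list(frames = aligned, cov = cov, skeleton = sk,
                        segments = segs, roi = rs, assignments = asg,
                        summaries = summ, phantom = phantom, config = config),
                   class = "subject_result")
  if (!is.null(config$out_dir)) write_subject_outputs(res, config$out_dir)
  res
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result> %d segments in %d ROIs across %d categories\n",
              nrow(x$assignments), nrow(x$summaries),
              length(unique(x$summaries$category))))
  invisible(x)
}

write_subject_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  v <- res$cov$values
  v[!is.finite(v)] <- NaN
  tiff::writeTIFF(v / max(v, na.rm = TRUE), file.path(out_dir, "cov_map.tiff"),
                  bits.per.sample = 32L, compression = "none", reduce = FALSE)
  write_mask_tiff(res$skeleton$mask, file.path(out_dir, "skeleton.tiff"))
  write.csv(res$assignments, file.path(out_dir, "segments.csv"), row.names = FALSE)
  write.csv(res$summaries, file.path(out_dir, "roi_summaries.csv"), row.names = FALSE)
  write_transforms_json(res$frames, file.path(out_dir, "transforms.json"))
  invisible(out_dir)
}

#' Run a cohort analysis
#'
#' Runs (or accepts pre-computed) per-subject analyses, pools each
#' subject's segments into the subjects x categories tables of medians and
#' IQRs, and runs the full statistical battery on each: Shapiro-Wilk
#' per-category normality, Mauchly's test, Huynh-Feldt-corrected
#' repeated-measures ANOVA with generalized eta-squared, and
#' Bonferroni-corrected post-hoc paired comparisons. A failing subject is
#' reported and dropped; the cohort continues only while >= 2 subjects
#' remain.
#'
#' @param configs list of [analysis_config()]s, or of `subject_result`s.
#' @param out_dir optional directory for cohort CSV/JSON outputs.
#' @return list of class `cohort_result`: `subjects` (per-subject results),
#'   `medians_table`, `iqr_table`, `anova_medians`, `anova_iqr`,
#'   `posthoc_medians`, `posthoc_iqr`, `shapiro_medians`, `shapiro_iqr`.
#' @export
run_cohort <- function(configs, out_dir = NULL) {
  if (length(configs) < 2) stop_octa("a cohort needs at least 2 subjects")
  subjects <- vector("list", length(configs))
  names(subjects) <- names(configs) %||% paste0("S", seq_along(configs))
  for (i in seq_along(configs)) {
    subjects[[i]] <- if (inherits(configs[[i]], "subject_result")) configs[[i]] else {
      tryCatch(run_subject(configs[[i]]), error = function(e) {
        warn_octa("subject %s failed and was dropped: %s",
                  names(subjects)[i], conditionMessage(e))
        NULL
      })
    }
  }
  ok <- !vapply(subjects, is.null, TRUE)
  # a subject with an empty category cannot enter the complete-table design
  for (i in which(ok)) {
    a <- subjects[[i]]$assignments
    empty <- vapply(roi_categories(), function(cat) all(is.na(a[[cat]])), TRUE)
    if (any(empty)) {
      warn_octa("subject %s has no segments in %s and was dropped",
                names(subjects)[i], paste(roi_categories()[empty], collapse = ", "))
      ok[i] <- FALSE
    }
  }
  if (sum(ok) < 2) stop_octa("fewer than 2 subjects completed; cohort aborted")
  subjects <- subjects[ok]
  asg <- lapply(subjects, `[[`, "assignments")
  med <- pool_categories(asg, "median")
  iqr <- pool_categories(asg, "IQR")
  res <- structure(list(
    subjects = subjects,
    medians_table = med, iqr_table = iqr,
    shapiro_medians = shapiro_by_category(med),
    shapiro_iqr = shapiro_by_category(iqr),
    anova_medians = rm_anova(med), anova_iqr = rm_anova(iqr),
    posthoc_medians = posthoc_pairwise(med), posthoc_iqr = posthoc_pairwise(iqr)
  ), class = "cohort_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_category_table(med, file.path(out_dir, "medians_table.csv"))
    write_category_table(iqr, file.path(out_dir, "iqr_table.csv"))
    write.csv(as.data.frame(res$posthoc_medians), file.path(out_dir, "posthoc_medians.csv"), row.names = FALSE)
    write.csv(as.data.frame(res$posthoc_iqr), file.path(out_dir, "posthoc_iqr.csv"), row.names = FALSE)
    for (which_ in c("medians", "iqr")) {
      a <- res[[paste0("anova_", which_)]]
      jsonlite::write_json(unclass(a)[c("F", "df_effect_corr", "df_error_corr",
                                        "p_corrected", "epsilon_hf", "epsilon_gg",
                                        "mauchly_W", "mauchly_p", "ges")],
                           file.path(out_dir, paste0("anova_", which_, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  res
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects\n\nMedians (temporal variation):\n", length(x$subjects)))
  print(x$anova_medians)
  cat("\nIQRs (spatial variation):\n")
  print(x$anova_iqr)
  invisible(x)
}
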