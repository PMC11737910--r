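#' Configure an end-to-end ventilation imaging run
#'
#' Bundles every stage setting for a reproducible phantom-to-comparison run:
#' which body positions to simulate, the phantom and registration settings,
#' the percentile threshold, the section scheme, and the cohort size. Cohort
#' subjects are seed-offset phantom instances with mild subject-level jitter
#' on the expansion and gravity gradient, shared across positions so the
#' across-position comparison is paired.
#'
#' @param positions character vector of body positions to simulate.
#' @param out_dir output directory for the run.
#' @param seed base integer seed; subject s uses seed + 1000 * s offsets.
#' @param n_subjects cohort size (1 for a single-subject run; >= 5 enables
#'   the paired position comparison).
#' @param phantom named list of \code{\link{phantom_spec}} argument overrides
#'   applied to every position (e.g. grid_shape, noise_sd_hu).
#' @param registration a \code{\link{registration_config}}.
#' @param use_truth_dvf if TRUE skip registration and use the phantom's
#'   ground-truth field (fast; exercises all downstream stages exactly).
#' @param threshold highly-functional percentile threshold (default 75).
#' @param fractions,slab_thickness section scheme (see
#'   \code{\link{define_sections}}).
#' @param alpha,m significance settings (see \code{\link{compare_positions}}).
#' @param subject_sd named list of subject-jitter SDs:
#'   \code{global_expansion} (default 0.05) and \code{gravity_gradient}
#'   (default 0.02).
#' @param write_volumes if TRUE write NIfTI intermediates per position.
#' @return A \code{run_config} list (JSON-serialisable).
#' @export
run_config <- function(positions = c("supine", "prone", "right_lateral", "left_lateral"),
                       out_dir = tempfile("ctvi_run_"),
                       seed = 1L, n_subjects = 1L,
                       phantom = list(), registration = registration_config(),
                       use_truth_dvf = FALSE, threshold = 75,
                       fractions = c(0.15, 0.40, 0.65, 0.88), slab_thickness = 3L,
                       alpha = 0.05, m = 3L,
                       subject_sd = list(global_expansion = 0.04, gravity_gradient = 0.02),
                       write_volumes = TRUE) {
  positions <- match.arg(positions,
                         c("supine", "prone", "right_lateral", "left_lateral"),
                         several.ok = TRUE)
  structure(list(positions = positions, out_dir = out_dir, seed = as.integer(seed),
                 n_subjects = as.integer(n_subjects), phantom = phantom,
                 registration = registration, use_truth_dvf = isTRUE(use_truth_dvf),
                 threshold = threshold, fractions = fractions,
                 slab_thickness = as.integer(slab_thickness),
                 alpha = alpha, m = as.integer(m), subject_sd = subject_sd,
                 write_volumes = isTRUE(write_volumes)),
            class = "run_config")
}

run_stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  log$times[[name]] <- c(log$times[[name]], proc.time()[["elapsed"]] - t0)
  res
}

#' Run the full ventilation imaging pipeline
#'
#' For every subject and body position: generate the phantom pair, obtain the
#' exhale-to-inhale displacement field (B-spline registration, or the ground
#' truth when configured), compute the Jacobian ventilation map, convert to
#' percentiles over both lungs, flag highly functional voxels, segment the
#' lungs, define cranio-caudal sections and tabulate section ratios and lung
#' volumes; finally, with a cohort of 5 or more subjects, run the paired
#' position comparison. All outputs are written under the run directory
#' together with the exact configuration and a log of per-stage wall times.
#'
#' @param config a \code{\link{run_config}}.
#' @param verbose print progress.
#' @return Invisibly, a list with \code{report} (section ratios),
#'   \code{volumes} (per-phase lung volumes), \code{dvf_stats} (regional
#'   vector summaries), \code{comparison} (or NULL), and \code{dir}.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, "run_config.json")
  strip_classes <- function(x)
    if (is.list(x)) lapply(unclass(x), strip_classes) else x
  jsonlite::write_json(strip_classes(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  log <- new.env()
  log$times <- list()
  report <- list(); volumes <- list(); dvf_stats <- list()
  for (s in seq_len(config$n_subjects)) {
    sseed <- config$seed + 1000L * (s - 1L)
    jit <- with_local_seed(sseed, list(
      ge = stats::rnorm(1, 0, config$subject_sd$global_expansion),
      gg = stats::rnorm(1, 0, config$subject_sd$gravity_gradient)))
    for (p in seq_along(config$positions)) {
      pos <- config$positions[p]
      args <- config$phantom
      args$position <- pos
      args$seed <- sseed + p
      base_ge <- if (is.null(config$phantom$global_expansion)) 1.30
                 else config$phantom$global_expansion
      base_gg <- if (is.null(config$phantom$gravity_gradient)) 0.15
                 else config$phantom$gravity_gradient
      # clamp subject jitter to the deformation range every position supports
      args$global_expansion <- min(1.38, max(1.08, base_ge + jit$ge))
      args$gravity_gradient <- min(0.30, max(0.05, base_gg + jit$gg))
      spec <- do.call(phantom_spec, args)
      pair <- run_stage("phantom", log, generate_phantom(spec))
      dvf <- if (config$use_truth_dvf) pair$truth_dvf
             else run_stage("registration", log,
                            register_bspline(pair$exhale, pair$inhale,
                                             config$registration))
      lungs <- run_stage("segmentation", log, segment_lungs(pair$exhale))
      jac <- run_stage("ventilation", log, jacobian_map(dvf))
      pmap <- percentile_map(jac, lungs)
      hf <- functional_mask(pmap, config$threshold)
      sections <- run_stage("sections", log,
                            define_sections(lungs, config$fractions,
                                            config$slab_thickness))
      ratios <- run_stage("report", log, functional_ratio(hf, lungs, sections))
      ratios <- cbind(subject = s, position = pos, ratios)
      report[[length(report) + 1L]] <- ratios
      lungs_in <- segment_lungs(pair$inhale)
      for (ph in c("expiration", "inspiration")) {
        mk <- if (ph == "expiration") lungs else lungs_in
        for (lg in c("total", "left", "right"))
          volumes[[length(volumes) + 1L]] <- data.frame(
            subject = s, position = pos, phase = ph, lung = lg,
            volume_ml = lung_volume(mk, lg))
      }
      vs <- run_stage("dvf_stats", log, {
        out <- lapply(c(left = 1L, right = 2L), function(lab)
          region_vector_summary(dvf, lungs$data == lab, pair$gravity))
        cbind(subject = s, position = pos,
              region = names(out), do.call(rbind, out))
      })
      dvf_stats[[length(dvf_stats) + 1L]] <- vs
      if (config$write_volumes && s == 1L) {
        pdir <- file.path(config$out_dir, pos)
        dir.create(pdir, showWarnings = FALSE)
        write_phantom(pair, pdir)
        write_dvf(dvf, file.path(pdir, "dvf.nii.gz"))
        write_volume(jac, file.path(pdir, "jacobian.nii.gz"))
        write_volume(hf, file.path(pdir, "functional.nii.gz"))
        write_volume(lungs, file.path(pdir, "lungs.nii.gz"))
      }
      if (verbose) message(sprintf("subject %d %s done", s, pos))
    }
  }
  report <- do.call(rbind, report)
  volumes <- do.call(rbind, volumes)
  dvf_stats <- do.call(rbind, dvf_stats)
  utils::write.csv(report, file.path(config$out_dir, "section_report.csv"),
                   row.names = FALSE)
  utils::write.csv(volumes, file.path(config$out_dir, "lung_volumes.csv"),
                   row.names = FALSE)
  utils::write.csv(dvf_stats, file.path(config$out_dir, "dvf_stats.csv"),
                   row.names = FALSE)
  comparison <- NULL
  if (config$n_subjects >= 5L && length(config$positions) >= 2L &&
      "supine" %in% config$positions) {
    per_pos <- split(report, report$position)
    comparison <- run_stage("comparison", log,
                            compare_positions(per_pos, config$alpha, config$m))
    utils::write.csv(comparison, file.path(config$out_dir, "comparison.csv"),
                     row.names = FALSE)
  }
  log_df <- data.frame(stage = names(log$times),
                       total_seconds = vapply(log$times, sum, 0),
                       calls = vapply(log$times, length, 0L))
  info <- list(package_version = as.character(utils::packageVersion("bhctvi")),
               r_version = R.version.string,
               config_md5 = unname(tools::md5sum(cfg_path)),
               stage_seconds = as.list(stats::setNames(log_df$total_seconds,
                                                       log_df$stage)))
  jsonlite::write_json(info, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(report = report, volumes = volumes, dvf_stats = dvf_stats,
                 comparison = comparison, dir = config$out_dir))
}
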