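#' Reproducible end-to-end run configuration
#'
#' Collects every knob of a simulate-process-map-roi-stats run in one
#' plain list that round-trips losslessly through YAML. All randomness
#' (noise draws, subject-level streams) derives from the single `seed`.
#'
#' @param seed Master seed.
#' @param n_subjects Number of simulated subjects (independent noise
#'   streams over the same anatomy).
#' @param n_repeats Repeated acquisitions per session (averaged during
#'   processing).
#' @param grid List with `nx`, `ny`, `voxel_dims`.
#' @param noise_sigma Rician noise scale relative to the unsaturated
#'   signal.
#' @param b0_coef Polynomial B0-surface coefficients (see
#'   [b0_polynomial()]).
#' @param classes List of tissue-class descriptions (`name`, `ph`,
#'   `shape`, `center`, `radii`, optional `inner_radii`).
#' @param timepoints List of `list(time = <min>, ph = <named overrides>)`;
#'   scripted pH changes (e.g. a drug response) are expressed as per-class
#'   overrides at later timepoints.
#' @param cest,wassr Schedule descriptions (`start`, `stop`, `step`,
#'   `refs`, `b1`, `duration`).
#' @param smoothing Spline smoothing control for the CEST readout (see
#'   [fit_spline()]).
#' @param wassr_smoothing Spline smoothing control for the WASSR B0 fit.
#' @param calibration List with `slope` and `intercept` (see
#'   [aacid_calibration()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_subjects = 3L, n_repeats = 3L,
                       grid = list(nx = 32L, ny = 32L,
                                   voxel_dims = c(0.4, 0.4, 2)),
                       noise_sigma = 0.02,
                       b0_coef = c(0, 0.05, -0.04, 0.02, 0.03, -0.02),
                       classes = NULL, timepoints = NULL,
                       cest = list(start = 1.2, stop = 6.6, step = 0.1,
                                   refs = c(-1000, 1000), b1 = 1.5, duration = 4),
                       wassr = list(start = -0.6, stop = 0.6, step = 0.03,
                                    refs = c(-1000, 1000), b1 = 0.2, duration = 0.1),
                       smoothing = 0.4, wassr_smoothing = "gcv",
                       calibration = list(slope = -4, intercept = 12.8)) {
  if (is.null(classes)) {
    classes <- list(
      list(name = "contralateral", ph = 7.0, shape = "ellipse",
           center = c(0.30, 0.50), radii = c(0.16, 0.28)),
      list(name = "peritumoral", ph = 7.05, shape = "annulus",
           center = c(0.70, 0.45), radii = c(0.145, 0.17),
           inner_radii = c(0.10, 0.12)),
      list(name = "tumor", ph = 7.2, shape = "ellipse",
           center = c(0.70, 0.45), radii = c(0.10, 0.12)))
  }
  if (is.null(timepoints)) {
    # drug-challenge style script: transient intracellular acidification
    # at 20 min (tumor -0.31 pH, contralateral -0.22), recovery by 40 min
    timepoints <- list(
      list(time = 0, ph = list()),
      list(time = 20, ph = list(tumor = 6.89, contralateral = 6.78,
                                peritumoral = 6.85)),
      list(time = 40, ph = list()))
  }
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 n_repeats = as.integer(n_repeats), grid = grid,
                 noise_sigma = noise_sigma, b0_coef = b0_coef,
                 classes = classes, timepoints = timepoints,
                 cest = cest, wassr = wassr, smoothing = smoothing,
                 wassr_smoothing = wassr_smoothing, calibration = calibration),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config()` returns a [run_config()];
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

config_schedule <- function(s) {
  make_offset_schedule(s$start, s$stop, s$step,
                       reference_offsets = as.numeric(unlist(s$refs)),
                       b1 = s$b1, duration = s$duration)
}

config_classes <- function(classes, ph_override = list()) {
  lapply(classes, function(cl) {
    ph <- if (!is.null(ph_override[[cl$name]])) ph_override[[cl$name]] else cl$ph
    tissue_class(cl$name, ph, cl$shape,
                 center = as.numeric(unlist(cl$center)),
                 radii = as.numeric(unlist(cl$radii)),
                 inner_radii = if (is.null(cl$inner_radii)) NULL
                               else as.numeric(unlist(cl$inner_radii)))
  })
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Process one acquisition session to AACID/pH maps
#'
#' Normalizes each repeat by its reference frames, averages the repeats,
#' estimates the WASSR B0 map and computes AACID/pH maps — the standard
#' per-session processing chain.
#'
#' WASSR stacks without their own reference frames are normalized against
#' the reference image of the same-repeat CEST stack. Voxels whose
#' unsaturated signal falls below `signal_frac` times the median tissue
#' reference are masked out (air voxels carry positive pure-noise
#' magnitude signal and would otherwise pass a zero test).
#'
#' The two spectra get separate smoothing controls. The WASSR dip is deep
#' relative to the noise and benefits from generalized cross-validation
#' smoothing before locating its minimum. For the CEST readout, heavy
#' (GCV-selected) smoothing flattens the narrow amine/amide features and
#' biases AACID upward, while reading a pure interpolant pushes the full
#' per-offset noise through the nonlinear AACID ratio (whose small
#' denominator makes it upward-biased under noise); a fixed moderate
#' smoothing (spar 0.4, the per-voxel RMSE minimizer at the protocol
#' noise level) is the default.
#'
#' @param cest_stacks,wassr_stacks Lists of raw [zspec_stack()]s
#'   (repeats).
#' @param smoothing Spline smoothing control for the CEST readout.
#' @param wassr_smoothing Spline smoothing control for the WASSR B0 fit.
#' @param cal An [aacid_calibration()].
#' @param signal_frac Signal mask threshold as a fraction of the bright
#'   (99th-percentile) reference signal.
#' @return List with `maps` ([make_maps()] result), `b0` (the
#'   [estimate_b0_map()] result) and the averaged normalized stacks.
#' @export
process_session <- function(cest_stacks, wassr_stacks, smoothing = 0.4,
                            wassr_smoothing = "gcv",
                            cal = aacid_calibration(), signal_frac = 0.2) {
  ref1 <- reference_image(cest_stacks[[1]])
  # anchor on the bright (tissue) end: air can dominate the voxel count
  thr <- signal_frac * stats::quantile(ref1[ref1 > 0], 0.99, names = FALSE)
  cest <- average_repeats(lapply(cest_stacks, normalize_by_reference,
                                 min_reference = thr))
  wassr <- average_repeats(mapply(function(w, cst)
    normalize_by_reference(w, reference = if (length(w$reference_offsets_ppm))
                             NULL else reference_image(cst),
                           min_reference = thr),
    wassr_stacks, cest_stacks, SIMPLIFY = FALSE))
  b0 <- estimate_b0_map(wassr, smoothing = wassr_smoothing)
  maps <- make_maps(cest, b0map = b0, cal = cal, smoothing = smoothing)
  list(maps = maps, b0 = b0, cest = cest, wassr = wassr)
}

#' Run the full simulate-process-map-roi-stats pipeline
#'
#' Simulates `n_subjects` phantom sessions at each scripted timepoint,
#' processes them to AACID/pH maps, summarizes the truth-mask ROIs,
#' runs the statistical battery (Shapiro-Wilk on baseline values, two-way
#' RM ANOVA side-by-time with Greenhouse-Geisser correction, Tukey
#' post-hoc over timepoints) and writes all results plus a provenance
#' record to `out_dir`. Deterministic for a fixed config.
#'
#' @param config A [run_config()] (or path to its YAML file).
#' @param out_dir Output directory (created if needed).
#' @param write_maps Write subject-1 maps/truth as NIfTI (default TRUE).
#' @return Invisibly, a list with the ROI long table (`roi`), the
#'   per-ROI time-course summary (`timecourse`), the ANOVA table
#'   (`anova`), Tukey results (`tukey`) and output paths.
#' @export
run_pipeline <- function(config, out_dir, write_maps = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  run_stage("config", {
    stopifnot(inherits(config, "run_config"))
    required <- c("seed", "n_subjects", "n_repeats", "grid", "noise_sigma",
                  "classes", "timepoints", "cest", "wassr", "calibration")
    miss <- setdiff(required, names(config)[!vapply(config, is.null, TRUE)])
    if (length(miss)) stopf("missing field(s): %s", paste(miss, collapse = ", "))
    if (length(config$timepoints) < 1L) stopf("at least one timepoint required")
  })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cal <- aacid_calibration(config$calibration$slope, config$calibration$intercept)
  cest_sched <- run_stage("config", config_schedule(config$cest))
  wassr_sched <- run_stage("config", config_schedule(config$wassr))
  times <- vapply(config$timepoints, `[[`, 0, "time")
  subject_seeds <- derive_seeds(config$seed, config$n_subjects * length(times))

  roi_rows <- list()
  first_session <- NULL
  for (s in seq_len(config$n_subjects)) {
    for (ti in seq_along(times)) {
      tp <- config$timepoints[[ti]]
      phant <- run_stage("simulate", {
        spec <- phantom_spec(
          nx = config$grid$nx, ny = config$grid$ny,
          voxel_dims = as.numeric(unlist(config$grid$voxel_dims)),
          classes = config_classes(config$classes, tp$ph),
          b0 = b0_polynomial(as.numeric(unlist(config$b0_coef))),
          noise_sigma = config$noise_sigma,
          seed = subject_seeds[(s - 1L) * length(times) + ti])
        generate_phantom(spec, cest_sched, wassr_sched,
                         n_repeats = config$n_repeats)
      })
      sess <- run_stage("process",
        process_session(phant$cest, phant$wassr,
                        smoothing = config$smoothing,
                        wassr_smoothing = config$wassr_smoothing, cal = cal))
      n_inv <- sum(!sess$maps$aacid$valid & phant$truth$label > 0)
      message(sprintf("[map] subject %d t=%g min: %d tissue voxel(s) invalid",
                      s, times[ti], n_inv))
      if (is.null(first_session)) {
        first_session <- list(sess = sess, truth = phant$truth)
      }
      for (roi in names(phant$truth$masks$masks)) {
        st <- run_stage("roi",
          roi_stats(sess$maps$aacid, phant$truth$masks$masks[[roi]]))
        roi_rows[[length(roi_rows) + 1L]] <-
          cbind(data.frame(subject = s, roi = roi, time = times[ti]), st)
      }
    }
  }
  roi_tab <- do.call(rbind, roi_rows)

  # per-ROI time course: subject means summarized across subjects
  tc <- run_stage("roi", {
    agg <- aggregate(mean ~ roi + time, roi_tab, mean)
    names(agg)[3] <- "mean_aacid"
    sdv <- aggregate(mean ~ roi + time, roi_tab, sd)$mean
    agg$sd <- ifelse(is.na(sdv), 0, sdv)
    agg$n <- aggregate(mean ~ roi + time, roi_tab, length)$mean
    agg$sem <- agg$sd / sqrt(agg$n)
    agg <- agg[order(agg$roi, agg$time), ]
    base <- agg$mean_aacid[match(paste(agg$roi, min(times)),
                                 paste(agg$roi, agg$time))]
    agg$pct_change <- percent_change(base, agg$mean_aacid)
    agg$delta_ph <- delta_ph(base, agg$mean_aacid, cal)
    agg
  })

  stats_out <- run_stage("stats", {
    out <- list(anova = NULL, tukey = NULL, shapiro = NULL)
    base_vals <- roi_tab$mean[roi_tab$time == min(times)]
    if (length(base_vals) >= 3 && sd(base_vals) > 0)
      out$shapiro <- shapiro_wilk(base_vals)
    two_sided <- roi_tab[roi_tab$roi %in% c("tumor", "contralateral"), ]
    if (config$n_subjects >= 2 && length(times) >= 2 &&
        length(unique(two_sided$roi)) == 2) {
      names(two_sided)[names(two_sided) == "roi"] <- "side"
      names(two_sided)[names(two_sided) == "mean"] <- "value"
      out$anova <- rm_anova_gg(two_sided, value = "value",
                               subject = "subject", within = c("side", "time"))
      if (length(times) >= 2)
        out$tukey <- tukey_posthoc(two_sided, "time", value = "value",
                                   subject = "subject", error = "within")
    }
    out
  })

  run_stage("report", {
    write.csv(roi_tab, file.path(out_dir, "roi_values.csv"), row.names = FALSE)
    write.csv(tc, file.path(out_dir, "timecourse.csv"), row.names = FALSE)
    if (!is.null(stats_out$anova))
      write.csv(stats_out$anova, file.path(out_dir, "anova.csv"),
                row.names = FALSE)
    if (!is.null(stats_out$tukey))
      write.csv(stats_out$tukey, file.path(out_dir, "tukey.csv"),
                row.names = FALSE)
    rpt <- c("AACID CEST pH pipeline report", "")
    if (!is.null(stats_out$shapiro))
      rpt <- c(rpt, sprintf("Shapiro-Wilk (baseline ROI means): W = %.4f, p = %.4g",
                            stats_out$shapiro$statistic, stats_out$shapiro$p))
    if (!is.null(stats_out$anova)) {
      rpt <- c(rpt, "", "Two-way RM ANOVA (Greenhouse-Geisser corrected):")
      rpt <- c(rpt, sprintf("  %-12s F(%.2f, %.2f) = %8.3f  p = %.4g %s",
                            stats_out$anova$effect, stats_out$anova$df_num_gg,
                            stats_out$anova$df_den_gg, stats_out$anova$statistic,
                            stats_out$anova$p,
                            significance_stars(stats_out$anova$p)))
    }
    if (!is.null(stats_out$tukey)) {
      rpt <- c(rpt, "", "Tukey post-hoc (time):")
      rpt <- c(rpt, sprintf("  t=%s vs t=%s: diff = %+.4f, p = %.4g %s",
                            stats_out$tukey$level_1, stats_out$tukey$level_2,
                            stats_out$tukey$diff, stats_out$tukey$p,
                            stats_out$tukey$stars))
    }
    writeLines(rpt, file.path(out_dir, "report.txt"))

    cfg_path <- file.path(out_dir, "config.yaml")
    write_run_config(config, cfg_path)
    prov <- list(package = "cestpH",
                 version = as.character(packageVersion("cestpH")),
                 seed = config$seed,
                 config_md5 = unname(tools::md5sum(cfg_path)),
                 n_subjects = config$n_subjects,
                 timepoints = times)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  if (isTRUE(write_maps) && !is.null(first_session)) {
    run_stage("report", {
      map_dir <- file.path(out_dir, "maps")
      dir.create(map_dir, showWarnings = FALSE)
      write_map(first_session$sess$maps$aacid, file.path(map_dir, "aacid.nii.gz"))
      write_map(first_session$sess$maps$ph, file.path(map_dir, "ph.nii.gz"))
      write_map(first_session$sess$b0, file.path(map_dir, "b0.nii.gz"))
      write_roi_set(first_session$truth$masks, file.path(map_dir, "rois.nii.gz"))
      export_voxels(first_session$sess$maps, file.path(map_dir, "voxels.csv"))
    })
  }

  invisible(list(roi = roi_tab, timecourse = tc, anova = stats_out$anova,
                 tukey = stats_out$tukey, shapiro = stats_out$shapiro,
                 out_dir = out_dir))
}
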