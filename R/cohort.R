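#' Cohort experiment configuration
#'
#' Describes a reproducible phantom cohort experiment: each subject gets a
#' phantom with infarct extent and core fraction drawn uniformly from the
#' configured ranges, is rendered through the MRI pipeline (2SD segmentation
#' and transmurality polar map) and the voltage-mapping pipeline (point
#' sampling, polar-map interpolation, threshold classification), and the two
#' modalities are compared. A single master seed determines every random
#' draw; the same configuration always produces byte-identical outputs.
#'
#' @param n_subjects Number of subjects (default 60).
#' @param infarct_fraction Range (length-2) of the scar surface fraction
#'   (default `c(0.15, 0.45)`).
#' @param core_fraction Range of the transmural-core fraction of the scar
#'   (default `c(0.3, 0.6)`).
#' @param voltage_noise_sd_mV Gaussian noise SD on sampled voltages
#'   (default 0.1).
#' @param si_normal_mean,si_normal_sd,si_scar_mean MRI signal-intensity
#'   parameters (defaults 100, 10, 160).
#' @param voxel_mm MRI in-plane voxel size (default 1).
#' @param sampling `"points"` for sparse catheter-style sampling or
#'   `"dense"` for the one-point-per-cell idealised limit.
#' @param n_points,min_per_segment Sparse-sampling parameters (defaults 202
#'   and 4).
#' @param scheme SI classification scheme name (default `"25-50-75"`).
#' @param sweep List with `lo`, `hi`, `steps`, `levels` for the bipolar
#'   threshold calibration; `NULL` skips the sweep.
#' @param seed Master seed (default 1).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 60L,
                          infarct_fraction = c(0.15, 0.45),
                          core_fraction = c(0.3, 0.6),
                          voltage_noise_sd_mV = 0.1,
                          si_normal_mean = 100, si_normal_sd = 10,
                          si_scar_mean = 160, voxel_mm = 1,
                          sampling = c("points", "dense"),
                          n_points = 202L, min_per_segment = 4L,
                          scheme = "25-50-75",
                          sweep = list(lo = 0.5, hi = 1.5, steps = 100L,
                                       levels = c(25, 30, 50, 60, 75)),
                          seed = 1L) {
  sampling <- match.arg(sampling)
  infarct_fraction <- as.numeric(infarct_fraction)
  core_fraction <- as.numeric(core_fraction)
  stopifnot(length(infarct_fraction) == 2, length(core_fraction) == 2)
  if (any(infarct_fraction < 0) || any(infarct_fraction >= 1) ||
      diff(infarct_fraction) < 0 ||
      any(core_fraction < 0) || any(core_fraction > 1) ||
      diff(core_fraction) < 0) {
    stop("parameter ranges out of their valid domains", call. = FALSE)
  }
  if (voltage_noise_sd_mV < 0) stop("negative noise SD", call. = FALSE)
  structure(list(
    n_subjects = stop_if_not_scalar_count(n_subjects, "n_subjects"),
    infarct_fraction = infarct_fraction,
    core_fraction = core_fraction,
    voltage_noise_sd_mV = voltage_noise_sd_mV,
    si_normal_mean = si_normal_mean, si_normal_sd = si_normal_sd,
    si_scar_mean = si_scar_mean, voxel_mm = voxel_mm,
    sampling = sampling, n_points = as.integer(n_points),
    min_per_segment = as.integer(min_per_segment),
    scheme = scheme, sweep = sweep, seed = as.integer(seed)
  ), class = "cohort_config")
}

# run both pipelines for one subject; returns maps + per-subject area row
run_subject <- function(config, subject_seed, subject_id) {
  seeds <- derive_seeds(subject_seed, 4L)
  pars <- withr::with_seed(seeds[1], c(
    stats::runif(1, config$infarct_fraction[1], config$infarct_fraction[2]),
    stats::runif(1, config$core_fraction[1], config$core_fraction[2])
  ))
  phantom <- make_phantom(infarct_fraction = pars[1], core_fraction = pars[2],
                          seed = seeds[2])

  stack <- render_mri_stack(phantom, voxel_mm = config$voxel_mm,
                            si_normal_mean = config$si_normal_mean,
                            si_normal_sd = config$si_normal_sd,
                            si_scar_mean = config$si_scar_mean,
                            seed = seeds[3])
  seg <- segment_2sd(stack)
  vol <- infarct_volume(seg$scar_mask, stack)
  tmap <- transmurality_map(seg$scar_mask, stack,
                            n_sectors = phantom$n_sectors)
  mri_class <- classify_transmurality(tmap, si_scheme(config$scheme))

  model <- voltage_model(noise_sd_mV = config$voltage_noise_sd_mV)
  points <- if (config$sampling == "dense") {
    dense_mapping_points(phantom, model, seed = seeds[4])
  } else {
    sample_noga_points(phantom, model, n_points = config$n_points,
                       min_per_segment = config$min_per_segment,
                       seed = seeds[4])
  }
  upv_map <- build_polar_map(points, "upv")
  bipv_map <- build_polar_map(points, "bipv")
  upv_class <- classify_voltage(upv_map)
  bipv_class <- classify_voltage(bipv_map)

  upv_af <- area_fractions(upv_class)
  bipv_af <- area_fractions(bipv_class)
  mri_af <- area_fractions(mri_class)

  ov <- lapply(c("transmural", "non_transmural", "combined"), function(rg) {
    withCallingHandlers(overlap_ratio(mri_class, bipv_class, rg),
                        warning = function(w) invokeRestart("muffleWarning"))
  })

  mri_le_area <- 100 * sum(tmap$valid & tmap$values > 0) / sum(tmap$valid)
  row <- data.frame(
    subject = subject_id,
    infarct_fraction = pars[1], core_fraction = pars[2],
    mri_infarct_volume_ml = vol$volume_ml,
    mri_infarct_pct_volume = vol$percent_of_lv,
    mri_le_area_pct = mri_le_area,
    mri_transmural_pct = unname(mri_af["transmural"]),
    mri_nontransmural_pct =
      sum(mri_af[intersect(c("non_transmural", "border"), names(mri_af))]),
    noga_infarct_core_pct = unname(upv_af["infarct"]),
    noga_border_pct = unname(upv_af["border"]),
    noga_infarct_total_pct = unname(upv_af["infarct"] + upv_af["border"]),
    noga_transmural_pct = unname(bipv_af["transmural"]),
    noga_nontransmural_pct = unname(bipv_af["non_transmural"]),
    overlap_transmural = ov[[1]]$ratio,
    overlap_nontransmural = ov[[2]]$ratio,
    overlap_combined = ov[[3]]$ratio
  )
  list(row = row, phantom = phantom, trans_map = tmap,
       bipv_map = bipv_map, points = points)
}

#' Run a full cohort experiment
#'
#' Generates `config$n_subjects` phantoms, runs the MRI and voltage-mapping
#' pipelines on each, and assembles the cohort-level agreement statistics:
#' Pearson correlation (with grade), least-absolute-residual regression and
#' Bland-Altman analysis for infarct size, transmural and non-transmural
#' areas (always as NOGA minus cMRI); mean overlap ratios; the bipolar
#' threshold-sweep calibration; and pooled-point ROC analysis of the bipolar
#' cut-off. Subjects that fail are recorded and skipped; the remaining
#' cohort is still summarised.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional directory; when given, per-subject tables, maps
#'   and the summary are written as CSV/JSON.
#' @return An object of class `cohort_result`: list with `subjects` (data
#'   frame, one row per subject), `agreement` (list of per-measure
#'   comparison statistics), `overlap_summary`, `sweep`
#'   (a [threshold_sweep()] or `NULL`), `roc`, `failures`, `config`.
#' @export
run_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  subject_seeds <- derive_seeds(config$seed, config$n_subjects)

  rows <- vector("list", config$n_subjects)
  trans_maps <- list()
  bipv_maps <- list()
  all_points <- list()
  failures <- character()
  for (s in seq_len(config$n_subjects)) {
    res <- tryCatch(run_subject(config, subject_seeds[s], s),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("subject %d: %s", s, conditionMessage(res)))
      next
    }
    rows[[s]] <- res$row
    trans_maps[[length(trans_maps) + 1L]] <- res$trans_map
    bipv_maps[[length(bipv_maps) + 1L]] <- res$bipv_map
    all_points[[length(all_points) + 1L]] <- res$points
  }
  subjects <- do.call(rbind, rows)
  if (is.null(subjects) || nrow(subjects) == 0) {
    stop("every subject failed; first failure: ", failures[1], call. = FALSE)
  }

  compare_pair <- function(x, y) {
    out <- list(n = length(x))
    out$pearson <- tryCatch(pearson_with_grade(x, y), error = function(e) NULL)
    out$fit <- tryCatch(robust_linear_fit(y, x), error = function(e) NULL)
    out$bland_altman <- bland_altman(x, y)
    out
  }
  agreement <- list(
    infarct_size = compare_pair(subjects$noga_infarct_total_pct,
                                subjects$mri_le_area_pct),
    transmural = compare_pair(subjects$noga_transmural_pct,
                              subjects$mri_transmural_pct),
    non_transmural = compare_pair(subjects$noga_nontransmural_pct,
                                  subjects$mri_nontransmural_pct)
  )

  overlap_summary <- do.call(rbind, lapply(
    c("overlap_transmural", "overlap_nontransmural", "overlap_combined"),
    function(cn) {
      v <- subjects[[cn]]
      data.frame(region = sub("overlap_", "", cn),
                 mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
                 n_defined = sum(!is.na(v)))
    }))

  sweep <- NULL
  if (!is.null(config$sweep) && length(bipv_maps) >= 3 &&
      any(subjects$infarct_fraction > 0)) {
    sweep <- tryCatch(
      threshold_sweep(bipv_maps, trans_maps,
                      lo = config$sweep$lo, hi = config$sweep$hi,
                      steps = config$sweep$steps,
                      levels = config$sweep$levels),
      error = function(e) NULL)
  }

  roc <- tryCatch({
    pooled <- do.call(rbind, lapply(all_points, as.data.frame))
    class(pooled) <- c("mapping_points", "data.frame")
    roc_bipv_cutoff(pooled, seed = derive_seeds(config$seed, 1L))
  }, error = function(e) NULL)

  out <- structure(list(subjects = subjects, agreement = agreement,
                        overlap_summary = overlap_summary, sweep = sweep,
                        roc = roc, failures = failures, config = config,
                        subject_seeds = subject_seeds),
                   class = "cohort_result")
  if (!is.null(out_dir)) write_cohort_result(out, out_dir)
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects (%d failed)\n",
              nrow(x$subjects), length(x$failures)))
  for (nm in names(x$agreement)) {
    a <- x$agreement[[nm]]
    if (!is.null(a$pearson)) {
      cat(sprintf("  %s: r=%.3f (%s), mean diff %.2f%% of LV surface\n",
                  nm, a$pearson$r, a$pearson$grade,
                  a$bland_altman$mean_diff))
    }
  }
  print(x$overlap_summary, row.names = FALSE)
  invisible(x)
}

# persist a cohort result: summary CSVs + JSON report, one dir per run
write_cohort_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$subjects, file.path(out_dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(result$overlap_summary,
                   file.path(out_dir, "overlap_summary.csv"),
                   row.names = FALSE)
  if (!is.null(result$sweep)) {
    utils::write.csv(result$sweep$best, file.path(out_dir, "sweep_best.csv"),
                     row.names = FALSE)
  }
  report <- list(
    package_version = as.character(utils::packageVersion("cardiomap")),
    config = unclass(result$config),
    agreement = lapply(result$agreement, function(a) {
      list(r = a$pearson$r %||% NA, p = a$pearson$p %||% NA,
           grade = a$pearson$grade %||% NA,
           slope = a$fit$slope %||% NA, intercept = a$fit$intercept %||% NA,
           mean_diff = a$bland_altman$mean_diff,
           sd_diff = a$bland_altman$sd_diff,
           limits = unname(a$bland_altman$limits))
    }),
    auc = result$roc$auc %||% NA,
    subject_seeds = result$subject_seeds,
    failures = result$failures
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
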