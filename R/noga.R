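#' Build a voltage bull's-eye map from sparse mapping points
#'
#' Interpolates accepted (stable) mapping points onto the polar grid:
#' every cell whose centre lies within `connect_mm` of at least one point
#' (the automatic point-connection distance) receives an inverse-distance
#' weighted (power 2) average of the in-reach point voltages; a cell reached
#' by exactly one point takes that point's value (nearest-neighbour
#' fallback), and a point coinciding with the cell centre supplies its value
#' exactly. Cells beyond reach are invalid, as is the fibrous-ring annulus
#' at the disk rim.
#'
#' @param points A `mapping_points` data frame ([sample_noga_points()] /
#'   [dense_mapping_points()] or [read_mapping_points()]).
#' @param field `"upv"` or `"bipv"`.
#' @param connect_mm Interpolation reach in disk mm (default 15).
#' @param n_slices,n_sectors Polar grid dimensions (defaults 8 and 32).
#' @param idw_power Inverse-distance weighting exponent (default 2).
#' @return A [polar_map()] of kind `"unipolar_mV"` or `"bipolar_mV"`.
#' @export
build_polar_map <- function(points, field = c("upv", "bipv"),
                            connect_mm = 15, n_slices = 8L, n_sectors = 32L,
                            idw_power = 2) {
  field <- match.arg(field)
  if (connect_mm <= 0) stop("`connect_mm` must be positive", call. = FALSE)
  pts <- points[points$stable, , drop = FALSE]
  if (nrow(pts) == 0) stop("no stable mapping points: empty map", call. = FALSE)
  if (any(pts$upv_mV < 0) || any(pts$bipv_mV < 0)) {
    stop("mapping-point voltages must be non-negative", call. = FALSE)
  }
  vals <- if (field == "upv") pts$upv_mV else pts$bipv_mV
  disk_r <- attr(points, "disk_radius_mm") %||% 40
  ann <- attr(points, "annulus_fraction") %||% 0.08

  cc <- polar_cell_centres(n_slices, n_sectors, disk_r, ann)
  est <- matrix(NA_real_, n_slices, n_sectors)
  for (k in seq_len(nrow(cc))) {
    d <- sqrt((pts$u_map - cc$u[k])^2 + (pts$v_map - cc$v[k])^2)
    reach <- d <= connect_mm
    if (!any(reach)) next
    dk <- d[reach]
    vk <- vals[reach]
    if (any(dk < 1e-9)) {
      est[cc$slice[k], cc$sector[k]] <- mean(vk[dk < 1e-9])
    } else if (length(dk) == 1L) {
      est[cc$slice[k], cc$sector[k]] <- vk
    } else {
      w <- 1 / dk^idw_power
      est[cc$slice[k], cc$sector[k]] <- sum(w * vk) / sum(w)
    }
  }
  polar_map(est, if (field == "upv") "unipolar_mV" else "bipolar_mV",
            valid = !is.na(est), disk_radius_mm = disk_r,
            annulus_fraction = ann)
}

#' Voltage classification thresholds
#'
#' The standard discriminatory cut-offs of endocardial voltage mapping.
#' Unipolar: `<5` mV infarct core, `[5, 15]` mV border zone, `>15` mV normal
#' viability. Bipolar: `<0.8` mV transmural infarction, `[0.8, 1.9]` mV
#' non-transmural infarction, `>1.9` mV normal myocardium. The printed
#' strict inequalities are honoured, so boundary values land in the middle
#' band.
#'
#' @param upv_infarct,upv_normal Unipolar band edges (defaults 5 and 15 mV).
#' @param bipv_transmural,bipv_normal Bipolar band edges (defaults 0.8 and
#'   1.9 mV).
#' @return An object of class `voltage_thresholds`.
#' @export
voltage_thresholds <- function(upv_infarct = 5, upv_normal = 15,
                               bipv_transmural = 0.8, bipv_normal = 1.9) {
  if (!(upv_infarct < upv_normal) || !(bipv_transmural < bipv_normal)) {
    stop("thresholds must be strictly ordered within each modality",
         call. = FALSE)
  }
  structure(list(upv_infarct = upv_infarct, upv_normal = upv_normal,
                 bipv_transmural = bipv_transmural,
                 bipv_normal = bipv_normal),
            class = "voltage_thresholds")
}

#' Classify a voltage polar map into viability classes
#'
#' @param map A `polar_map` of kind `"unipolar_mV"` or `"bipolar_mV"`.
#' @param thresholds A [voltage_thresholds()] object.
#' @return A class-label [polar_map()]. Unipolar maps yield classes
#'   `infarct` / `border` / `normal`; bipolar maps yield `transmural` /
#'   `non_transmural` / `normal`. Per-class percentages of the valid mapped
#'   surface are available through [area_fractions()].
#' @export
classify_voltage <- function(map, thresholds = voltage_thresholds()) {
  stopifnot(inherits(map, "polar_map"))
  if (!map$kind %in% c("unipolar_mV", "bipolar_mV")) {
    stop("`map` must be a unipolar or bipolar voltage map", call. = FALSE)
  }
  if (!inherits(thresholds, "voltage_thresholds")) {
    stop("`thresholds` must be a voltage_thresholds object", call. = FALSE)
  }
  v <- map$values
  if (map$kind == "unipolar_mV") {
    codes <- ifelse(v < thresholds$upv_infarct, 1L,
                    ifelse(v <= thresholds$upv_normal, 2L, 3L))
    labels <- c("infarct", "border", "normal")
  } else {
    codes <- ifelse(v < thresholds$bipv_transmural, 1L,
                    ifelse(v <= thresholds$bipv_normal, 2L, 3L))
    labels <- c("transmural", "non_transmural", "normal")
  }
  make_class_map(map, matrix(codes, map$n_slices, map$n_sectors), labels)
}

#' Calibrate the bipolar threshold against MRI transmurality by iterative sweep
#'
#' For every threshold `t` in `steps` equal steps from `lo` to `hi` mV, the
#' low-voltage area of each subject's bipolar map (`bipv < t`, restricted to
#' the crop mask, as a percentage of the valid surface) is computed; for
#' every transmurality level the cohort vector of those areas is correlated
#' (Pearson) with the cohort vector of MRI areas above that level. The
#' threshold maximising the correlation is reported per level, flagged as
#' saturated when it falls on a sweep boundary (the true optimum then lies
#' at or beyond the swept range).
#'
#' @param bipolar_maps List of bipolar [polar_map()]s (one per subject).
#' @param trans_maps List of matching transmurality [polar_map()]s.
#' @param crop_masks Optional list of logical cell masks restricting the
#'   bipolar area to the MRI-defined infarct region; `NULL` crops each map to
#'   the cells with any MRI transmurality (> 0).
#' @param lo,hi,steps Sweep range and step count (defaults 0.5 mV to 1.5 mV
#'   in 100 steps, i.e. 0.01 mV resolution).
#' @param levels Transmurality percentage levels to calibrate against
#'   (default `c(25, 30, 50, 60, 75)`).
#' @return An object of class `threshold_sweep`: list with `thresholds`,
#'   `correlation` (threshold x level matrix), `noga_area` (subject x
#'   threshold), `mri_area` (subject x level), and `best` (data frame with
#'   per-level best cut-off, its correlation, and a saturation flag).
#' @export
threshold_sweep <- function(bipolar_maps, trans_maps, crop_masks = NULL,
                            lo = 0.5, hi = 1.5, steps = 100L,
                            levels = c(25, 30, 50, 60, 75)) {
  if (inherits(bipolar_maps, "polar_map")) bipolar_maps <- list(bipolar_maps)
  if (inherits(trans_maps, "polar_map")) trans_maps <- list(trans_maps)
  n_sub <- length(bipolar_maps)
  if (n_sub != length(trans_maps) || n_sub == 0) {
    stop("need matching non-empty lists of bipolar and transmurality maps",
         call. = FALSE)
  }
  if (n_sub < 3) {
    stop("cohort-level correlation needs at least 3 subjects", call. = FALSE)
  }
  thresholds <- seq(lo, hi, length.out = steps + 1L)

  noga_area <- matrix(NA_real_, n_sub, length(thresholds))
  mri_area <- matrix(NA_real_, n_sub, length(levels))
  for (s in seq_len(n_sub)) {
    bm <- bipolar_maps[[s]]
    tm <- trans_maps[[s]]
    if (!identical(dim(bm$values), dim(tm$values))) {
      stop("bipolar and transmurality maps must share one grid", call. = FALSE)
    }
    crop <- if (is.null(crop_masks)) {
      tm$valid & tm$values > 0
    } else {
      crop_masks[[s]]
    }
    if (!any(crop)) {
      stop(sprintf("empty crop mask for subject %d", s), call. = FALSE)
    }
    n_valid <- sum(bm$valid)
    v <- bm$values[bm$valid & crop]
    noga_area[s, ] <- vapply(thresholds, function(t) 100 * sum(v < t) / n_valid,
                             numeric(1))
    tv <- tm$values[tm$valid]
    mri_area[s, ] <- vapply(levels, function(L) {
      100 * sum(tv * 100 > L) / sum(tm$valid)
    }, numeric(1))
  }

  flat <- apply(noga_area, 1, function(r) max(r) == min(r))
  if (all(flat)) {
    stop("low-voltage area is constant across all thresholds: correlation undefined",
         call. = FALSE)
  }

  cor_mat <- matrix(NA_real_, length(thresholds), length(levels),
                    dimnames = list(NULL, paste0("level_", levels)))
  for (L in seq_along(levels)) {
    y <- mri_area[, L]
    if (stats::var(y) == 0) next
    for (t in seq_along(thresholds)) {
      x <- noga_area[, t]
      if (stats::var(x) > 0) cor_mat[t, L] <- stats::cor(x, y)
    }
  }

  best <- data.frame(level = levels, cutoff_mV = NA_real_, r = NA_real_,
                     saturated = NA)
  n_thr <- length(thresholds)
  for (L in seq_along(levels)) {
    r <- cor_mat[, L]
    if (all(is.na(r))) next
    k <- which.max(r)
    # a maximum on (or within one step of) a sweep boundary is not an
    # interior optimum: the true cut-off lies at or beyond the swept range
    sat <- k <= 2L || k >= n_thr - 1L
    best$cutoff_mV[L] <- if (sat) thresholds[if (k <= 2L) 1L else n_thr] else thresholds[k]
    best$r[L] <- r[k]
    best$saturated[L] <- sat
  }

  structure(list(thresholds = thresholds, levels = levels,
                 correlation = cor_mat, noga_area = noga_area,
                 mri_area = mri_area, best = best),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> %d subjects, %.2f-%.2f mV in %d steps\n",
              nrow(x$noga_area), min(x$thresholds), max(x$thresholds),
              length(x$thresholds) - 1L))
  print(x$best, row.names = FALSE)
  invisible(x)
}
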