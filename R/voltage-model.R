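#' Electrogram voltage model
#'
#' Maps local scar transmurality to unipolar (UPV) and bipolar (BiPV)
#' electrogram voltages. The bipolar map is piecewise linear in
#' transmurality, anchored exactly at the two conventional bipolar viability
#' cut-offs - 1.9 mV at 25% transmurality (upper edge of the non-transmural
#' band) and 0.8 mV at 75% transmurality (transmural cut-off) - extended
#' linearly beyond the anchors and clipped to `[bipv_floor_mV,
#' bipv_plateau_mV]`. With zero noise the standard cut-offs are therefore the
#' exact recoverable truth for calibration.
#'
#' Unipolar voltage summates the activity of the surrounding endocardium, so
#' it is driven by the *scar burden*: the transmurality averaged over a
#' neighbourhood of radius `upv_neighbourhood` cells (circular in sector,
#' clamped in slice). Healthy cells (zero transmurality) sit at a plateau of
#' `upv_normal_mV` (> 15 mV, i.e. normal viability); any scar involvement
#' drops the tissue out of the normal band, onto a line
#' `upv_scar_max_mV - upv_scar_slope_mV * burden` spanning the border-zone
#' and infarct-core ranges.
#'
#' @param upv_normal_mV Healthy unipolar plateau (default 17).
#' @param upv_scar_max_mV Unipolar voltage as scar burden approaches zero
#'   (default 13.5, inside the 5-15 mV border band).
#' @param upv_scar_slope_mV Unipolar decrease per unit scar burden
#'   (default 10; full burden gives 3.5 mV, inside the <5 mV infarct band).
#' @param upv_neighbourhood Neighbourhood radius, in cells, of the burden
#'   average (default 1).
#' @param bipv_anchors Matrix-like with two rows `(transmurality, mV)`;
#'   defaults to the `(0.25, 1.9)` and `(0.75, 0.8)` anchors.
#' @param bipv_floor_mV,bipv_plateau_mV Clipping range of the bipolar map
#'   (defaults 0.05 and 3).
#' @param noise_sd_mV SD of independent Gaussian noise added to each sampled
#'   voltage (default 0).
#' @return An object of class `voltage_model`.
#' @examples
#' m <- voltage_model()
#' bipv_from_transmurality(c(0.25, 0.75), m)  # the anchors: 1.9, 0.8
#' @export
voltage_model <- function(upv_normal_mV = 17, upv_scar_max_mV = 13.5,
                          upv_scar_slope_mV = 10, upv_neighbourhood = 1L,
                          bipv_anchors = rbind(c(0.25, 1.9), c(0.75, 0.8)),
                          bipv_floor_mV = 0.05, bipv_plateau_mV = 3,
                          noise_sd_mV = 0) {
  a <- as.matrix(bipv_anchors)
  if (!all(dim(a) == c(2, 2)) || a[1, 1] >= a[2, 1] || a[1, 2] <= a[2, 2]) {
    stop("`bipv_anchors` must be two (transmurality, mV) rows with the bipolar map strictly decreasing",
         call. = FALSE)
  }
  if (noise_sd_mV < 0) stop("`noise_sd_mV` must be >= 0", call. = FALSE)
  if (upv_normal_mV <= 15) {
    stop("`upv_normal_mV` must exceed the 15 mV normal-viability cut-off",
         call. = FALSE)
  }
  structure(list(
    upv_normal_mV = upv_normal_mV,
    upv_scar_max_mV = upv_scar_max_mV,
    upv_scar_slope_mV = upv_scar_slope_mV,
    upv_neighbourhood = as.integer(upv_neighbourhood),
    bipv_anchors = a,
    bipv_floor_mV = bipv_floor_mV,
    bipv_plateau_mV = bipv_plateau_mV,
    noise_sd_mV = noise_sd_mV
  ), class = "voltage_model")
}

#' Noise-free bipolar voltage at a given transmurality
#'
#' @param transmurality Numeric vector of transmurality fractions in `[0,1]`.
#' @param model A [voltage_model()].
#' @return Bipolar voltages in mV.
#' @export
bipv_from_transmurality <- function(transmurality, model = voltage_model()) {
  a <- model$bipv_anchors
  slope <- (a[2, 2] - a[1, 2]) / (a[2, 1] - a[1, 1])
  v <- a[1, 2] + slope * (transmurality - a[1, 1])
  clamp(v, model$bipv_floor_mV, model$bipv_plateau_mV)
}

# neighbourhood-averaged transmurality (scar burden) per grid cell;
# circular in the sector direction, clamped at apex/base
burden_field <- function(phantom, radius = 1L) {
  tf <- phantom$transmurality
  if (radius == 0L) return(tf)
  ns <- phantom$n_slices
  nk <- phantom$n_sectors
  acc <- matrix(0, ns, nk)
  cnt <- matrix(0, ns, nk)
  for (di in -radius:radius) {
    ii <- clamp(seq_len(ns) + di, 1L, ns)
    keep <- seq_len(ns) + di >= 1L & seq_len(ns) + di <= ns
    for (dj in -radius:radius) {
      jj <- ((seq_len(nk) - 1L + dj) %% nk) + 1L
      acc[keep, ] <- acc[keep, ] + tf[ii[keep], jj, drop = FALSE]
      cnt[keep, ] <- cnt[keep, ] + 1
    }
  }
  acc / cnt
}

#' Noise-free voltage fields of a phantom
#'
#' Evaluates the voltage model on every grid cell of a phantom, returning the
#' exact (noise-free) unipolar and bipolar fields that sparse mapping points
#' sample from.
#'
#' @param phantom An [make_phantom()] object.
#' @param model A [voltage_model()].
#' @return List of two `n_slices` x `n_sectors` matrices, `upv_mV` and
#'   `bipv_mV`.
#' @export
voltage_fields <- function(phantom, model = voltage_model()) {
  tf <- phantom$transmurality
  burden <- burden_field(phantom, model$upv_neighbourhood)
  upv <- ifelse(tf > 0,
                pmax(0.05, model$upv_scar_max_mV -
                       model$upv_scar_slope_mV * burden),
                model$upv_normal_mV)
  list(upv_mV = upv, bipv_mV = matrix(bipv_from_transmurality(tf, model),
                                      nrow(tf), ncol(tf)))
}

# shared by samplers: mm coordinates of a point at continuous grid position
# (slice_pos in [0, n_slices], angle in radians)
point_coordinates <- function(phantom, slice_pos, angle,
                              disk_radius_mm = 40, annulus_fraction = 0.08) {
  r_endo <- stats::approx(seq_len(phantom$n_slices) - 0.5, phantom$r_endo_mm,
                          xout = slice_pos, rule = 2)$y
  rho <- slice_pos / phantom$n_slices * disk_radius_mm * (1 - annulus_fraction)
  data.frame(
    x_mm = r_endo * cos(angle),
    y_mm = r_endo * sin(angle),
    z_mm = slice_pos * phantom$slice_thickness_mm,
    u_map = rho * cos(angle),
    v_map = rho * sin(angle)
  )
}

#' Sample sparse endocardial mapping points from a phantom
#'
#' Emulates point-by-point catheter mapping of the endocardium: `n_points`
#' stable points are placed on the endocardial surface with at least
#' `min_per_segment` points in each of the 12 myocardial segments, and each
#' point records the unipolar and bipolar voltage of its underlying grid cell
#' under the voltage model, plus independent Gaussian noise
#' (`model$noise_sd_mV`). Sampled voltages are truncated at zero. Positions
#' are reported both on the endocardial surface (`x_mm`, `y_mm`, `z_mm`) and
#' in bull's-eye polar-map coordinates (`u_map`, `v_map`; apex at the centre).
#'
#' @param phantom An [make_phantom()] object.
#' @param model A [voltage_model()].
#' @param n_points Total number of points (default 202, a typical complete
#'   endocardial map). Must be at least `12 * min_per_segment`.
#' @param min_per_segment Minimum points per 12-segment region (default 4).
#' @param seed Integer seed.
#' @param disk_radius_mm Bull's-eye disk radius used for `u_map`/`v_map`
#'   (default 40); the outer `annulus_fraction` of the disk is the fibrous
#'   ring and carries no mapping points.
#' @param annulus_fraction Fibrous-ring annulus width as a fraction of the
#'   disk radius (default 0.08).
#' @return A `data.frame` of class `mapping_points` with columns `slice_idx`,
#'   `sector_idx`, `x_mm`, `y_mm`, `z_mm`, `u_map`, `v_map`, `upv_mV`,
#'   `bipv_mV`, `stable`.
#' @export
sample_noga_points <- function(phantom, model = voltage_model(),
                               n_points = 202L, min_per_segment = 4L,
                               seed = 1L, disk_radius_mm = 40,
                               annulus_fraction = 0.08) {
  stopifnot(inherits(phantom, "lv_phantom"))
  n_points <- stop_if_not_scalar_count(n_points, "n_points")
  if (n_points < 12L * min_per_segment) {
    stop(sprintf("`n_points` must be at least 12 * min_per_segment = %d",
                 12L * min_per_segment), call. = FALSE)
  }
  seg <- phantom$segment12
  fields <- voltage_fields(phantom, model)

  withr::with_seed(seed, {
    cells <- unlist(lapply(1:12, function(s) {
      pool <- which(seg == s)
      sample(pool, min_per_segment, replace = length(pool) < min_per_segment)
    }))
    extra <- n_points - length(cells)
    if (extra > 0) {
      cells <- c(cells, sample.int(length(seg), extra, replace = TRUE))
    }
    i <- row(seg)[cells]
    j <- col(seg)[cells]
    slice_pos <- i - stats::runif(n_points)
    angle <- (j - stats::runif(n_points)) * 2 * pi / phantom$n_sectors
    upv <- fields$upv_mV[cells] + stats::rnorm(n_points, 0, model$noise_sd_mV)
    bipv <- fields$bipv_mV[cells] + stats::rnorm(n_points, 0, model$noise_sd_mV)
  })

  pos <- point_coordinates(phantom, slice_pos, angle,
                           disk_radius_mm, annulus_fraction)
  out <- data.frame(slice_idx = i, sector_idx = j, pos,
                    upv_mV = pmax(0, upv), bipv_mV = pmax(0, bipv),
                    stable = TRUE)
  class(out) <- c("mapping_points", "data.frame")
  attr(out, "disk_radius_mm") <- disk_radius_mm
  attr(out, "annulus_fraction") <- annulus_fraction
  out
}

#' Dense mapping points (one per grid cell)
#'
#' Places one mapping point at the centre of every (slice, sector) cell,
#' carrying the model voltages plus the model's Gaussian noise. With a
#' zero-noise model this is the idealised sampling limit used for
#' self-consistency checks of the polar-map builder: dense noise-free points
#' make the reconstructed map reproduce the model fields exactly.
#'
#' @inheritParams sample_noga_points
#' @return A `mapping_points` data frame, one row per cell.
#' @export
dense_mapping_points <- function(phantom, model = voltage_model(), seed = 1L,
                                 disk_radius_mm = 40,
                                 annulus_fraction = 0.08) {
  stopifnot(inherits(phantom, "lv_phantom"))
  fields <- voltage_fields(phantom, model)
  i <- as.vector(row(phantom$transmurality))
  j <- as.vector(col(phantom$transmurality))
  pos <- point_coordinates(phantom, i - 0.5,
                           (j - 0.5) * 2 * pi / phantom$n_sectors,
                           disk_radius_mm, annulus_fraction)
  n <- length(i)
  noise <- if (model$noise_sd_mV > 0) {
    withr::with_seed(seed, matrix(stats::rnorm(2 * n, 0, model$noise_sd_mV), n))
  } else {
    matrix(0, n, 2)
  }
  out <- data.frame(slice_idx = i, sector_idx = j, pos,
                    upv_mV = pmax(0, as.vector(fields$upv_mV) + noise[, 1]),
                    bipv_mV = pmax(0, as.vector(fields$bipv_mV) + noise[, 2]),
                    stable = TRUE)
  class(out) <- c("mapping_points", "data.frame")
  attr(out, "disk_radius_mm") <- disk_radius_mm
  attr(out, "annulus_fraction") <- annulus_fraction
  out
}
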