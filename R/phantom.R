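#' Ground-truth left-ventricle infarct phantom
#'
#' Builds a shell model of the left-ventricular myocardium on an
#' `n_slices` x `n_sectors` grid (slice 1 at the apex, sector 1 at the
#' right-ventricular insertion point) carrying a scar *transmurality* field:
#' for every (slice, sector) cell the fraction of the wall thickness, measured
#' from the endocardium outward, that is occupied by scar. The infarct is a
#' single smooth anteroapical region: cells are ranked by an elliptical
#' distance in (slice, sector) space from a seeded anteroapical centre, the
#' closest `infarct_fraction` of cells (largest-remainder rounding) form the
#' scar support, and transmurality decays piecewise-linearly from a peak at
#' the centre to `t_edge` at the rim. The decay is scaled so that exactly
#' `core_fraction` of the scar support (same rounding quantum) lies above 75%
#' transmurality, which is the conventional transmural-infarct cut-off.
#'
#' The phantom is the shared parent of both imaging modalities: it can be
#' rendered into an MRI-like signal-intensity slice stack
#' ([render_mri_stack()]) and sampled into NOGA-like sparse voltage mapping
#' points ([sample_noga_points()]).
#'
#' @param infarct_fraction Fraction of the LV surface (grid cells) covered by
#'   scar, in `[0, 1)`. Default 0.36, giving a large reperfused
#'   anterior/anteroseptal/apical infarct whose derived volume fraction and
#'   voltage-map areas sit in the range reported for chronic LAD-occlusion
#'   infarcts.
#' @param core_fraction Fraction of the scar support with transmurality
#'   above 0.75 (the transmural core), in `[0, 1]`. Default 0.5.
#' @param n_slices Number of apico-basal levels (default 8).
#' @param n_sectors Number of angular wall sectors per slice (default 32).
#' @param wall_thickness_mm Wall thickness in mm; a scalar or an
#'   `n_slices` x `n_sectors` matrix. Default 10.
#' @param seed Integer seed; the phantom is a pure function of its arguments
#'   and this seed.
#' @param t_peak Peak transmurality at the infarct centre (default 0.95).
#' @param t_edge Minimum transmurality of involved rim cells (default 0.12,
#'   i.e. about one voxel of scar depth at default geometry; thinner
#'   involvement is below imaging resolution and is not modelled).
#' @param centre_slice,centre_sector Nominal infarct centre in grid
#'   coordinates (defaults 2.5 and 9: anteroapical with apical involvement).
#' @param axis_ratio Sector-to-slice semi-axis ratio of the elliptical
#'   infarct shape (default 2.2: wider circumferentially than apico-basally).
#' @param jitter Relative seeded jitter applied to the centre and axis ratio,
#'   providing between-subject variability in cohorts (default 0.15).
#'
#' @return An object of class `lv_phantom`: a list with elements
#'   `n_slices`, `n_sectors`, `transmurality` (matrix, values in `[0,1]`),
#'   `wall_thickness_mm` (matrix), `segment12` (matrix of 12-segment labels),
#'   `r_endo_mm` (endocardial radius per slice, tapering from 25 mm at the
#'   base to 19 mm at the apex - together with the 10 mm wall and 8 mm slice
#'   thickness this gives a myocardial volume of about 105 mL, the scale of
#'   an adult-pig or human left ventricle), `slice_thickness_mm`, and `seed`.
#'
#' @examples
#' ph <- make_phantom(seed = 7)
#' range(ph$transmurality)
#' mean(ph$transmurality > 0)   # close to infarct_fraction
#' @export
make_phantom <- function(infarct_fraction = 0.36, core_fraction = 0.5,
                         n_slices = 8L, n_sectors = 32L,
                         wall_thickness_mm = 10, seed = 1L,
                         t_peak = 0.95, t_edge = 0.12,
                         centre_slice = 2.5, centre_sector = 9,
                         axis_ratio = 2.2, jitter = 0.15) {
  n_slices <- stop_if_not_scalar_count(n_slices, "n_slices")
  n_sectors <- stop_if_not_scalar_count(n_sectors, "n_sectors")
  if (infarct_fraction < 0 || infarct_fraction >= 1) {
    stop("`infarct_fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (core_fraction < 0 || core_fraction > 1) {
    stop("`core_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (t_edge <= 0 || t_peak <= 0.75 || t_peak > 1 || t_edge >= 0.75) {
    stop("need 0 < t_edge < 0.75 < t_peak <= 1", call. = FALSE)
  }

  wall <- wall_thickness_mm
  if (length(wall) == 1L) {
    wall <- matrix(wall, n_slices, n_sectors)
  }
  if (!all(dim(wall) == c(n_slices, n_sectors)) || any(wall <= 0)) {
    stop("`wall_thickness_mm` must be positive, scalar or n_slices x n_sectors",
         call. = FALSE)
  }

  n_cells <- n_slices * n_sectors
  tf <- matrix(0, n_slices, n_sectors)
  n_scar <- round(infarct_fraction * n_cells)

  if (n_scar > 0) {
    jit <- withr::with_seed(seed, stats::runif(3, -jitter, jitter))
    ci <- centre_slice * (1 + jit[1])
    cj <- centre_sector + jit[2] * n_sectors / 8
    ar <- axis_ratio * (1 + jit[3])

    ii <- row(tf)
    jj <- sector_diff(col(tf), cj, n_sectors)
    d <- sqrt((ii - ci)^2 + (jj / ar)^2)
    # deterministic tie-break so the rank ordering is unambiguous
    d <- d + (ii * n_sectors + col(tf)) * 1e-9

    ord <- order(d)
    support <- ord[seq_len(n_scar)]
    ds <- d[support]
    d_edge <- if (n_scar < n_cells) {
      mean(c(max(ds), min(d[ord[n_scar + 1L]])))
    } else {
      max(ds) * 1.001
    }

    n_core <- round(core_fraction * n_scar)
    # smooth power-law decay t_peak -> t_edge; the exponent is solved so that
    # exactly n_core cells lie above 75% transmurality. A single smooth
    # profile (no slope break at the diagnostic threshold) avoids piling cell
    # density onto the very cut-off the calibration operations estimate.
    tvals <- if (n_core >= n_scar) {
      0.76 + (t_peak - 0.76) * (1 - ds / d_edge)
    } else if (n_core == 0L) {
      t_edge + (0.74 - t_edge) * (1 - ds / d_edge)
    } else {
      d_core <- mean(d[support[order(ds)][n_core + c(0L, 1L)]])
      gamma <- log((t_peak - 0.75) / (t_peak - t_edge)) / log(d_core / d_edge)
      t_peak - (t_peak - t_edge) * (ds / d_edge)^gamma
    }
    tf[support] <- clamp(tvals, t_edge * 0.5, t_peak)
  }

  structure(list(
    n_slices = n_slices,
    n_sectors = n_sectors,
    transmurality = tf,
    wall_thickness_mm = wall,
    segment12 = segment12_labels(n_slices, n_sectors),
    r_endo_mm = seq(19, 25, length.out = n_slices),
    slice_thickness_mm = 8,
    seed = as.integer(seed)
  ), class = "lv_phantom")
}

#' 12-segment labels for a polar grid
#'
#' Partitions an `n_slices` x `n_sectors` grid into the 12-segment scheme used
#' during endocardial mapping: three apico-basal bands (apical, mid, basal)
#' crossed with four circumferential quadrants (anterior, lateral, inferior,
#' septal).
#'
#' @param n_slices,n_sectors Grid dimensions; each must be at least 3 and 4
#'   respectively so that every segment is non-empty.
#' @return Integer matrix with values 1..12.
#' @export
segment12_labels <- function(n_slices = 8L, n_sectors = 32L) {
  if (n_slices < 3L || n_sectors < 4L) {
    stop("need n_slices >= 3 and n_sectors >= 4 for 12 non-empty segments",
         call. = FALSE)
  }
  band <- as.integer(cut(seq_len(n_slices), 3))
  quad <- as.integer(cut(seq_len(n_sectors), 4))
  matrix(
    (rep(band, times = n_sectors) - 1L) * 4L + rep(quad, each = n_slices),
    n_slices, n_sectors
  )
}

#' @export
print.lv_phantom <- function(x, ...) {
  cat(sprintf("<lv_phantom> %d slices x %d sectors, seed %d\n",
              x$n_slices, x$n_sectors, x$seed))
  cat(sprintf("  scar support: %d / %d cells (%.1f%% of surface)\n",
              sum(x$transmurality > 0), length(x$transmurality),
              100 * mean(x$transmurality > 0)))
  if (any(x$transmurality > 0)) {
    cat(sprintf("  transmurality: peak %.2f, core (>0.75) %d cells\n",
                max(x$transmurality), sum(x$transmurality > 0.75)))
  }
  invisible(x)
}

#' Analytic scar and myocardial cross-section of a phantom
#'
#' Integrates the transmurality field over the shell geometry, giving the
#' exact scar volume fraction implied by the phantom (scar occupies the inner
#' `T` fraction of the wall, so its cross-section in a sector is the annulus
#' sector from the endocardial radius to `r_endo + T * wall`).
#'
#' @param phantom An [make_phantom()] object.
#' @return List with `scar_volume_ml`, `myo_volume_ml` and
#'   `scar_fraction_pct` (scar volume as a percentage of myocardial volume).
#' @export
analytic_scar_volume <- function(phantom) {
  stopifnot(inherits(phantom, "lv_phantom"))
  tf <- phantom$transmurality
  wall <- phantom$wall_thickness_mm
  r0 <- matrix(phantom$r_endo_mm, phantom$n_slices, phantom$n_sectors)
  dtheta <- 2 * pi / phantom$n_sectors
  a_scar <- dtheta / 2 * ((r0 + tf * wall)^2 - r0^2)
  a_myo <- dtheta / 2 * ((r0 + wall)^2 - r0^2)
  vol <- function(a) sum(a) * phantom$slice_thickness_mm / 1000
  list(scar_volume_ml = vol(a_scar),
       myo_volume_ml = vol(a_myo),
       scar_fraction_pct = 100 * sum(a_scar) / sum(a_myo))
}
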