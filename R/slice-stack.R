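#' Short-axis signal-intensity slice stack
#'
#' Container for a voxelised short-axis late-enhancement image: a 3D array of
#' signal intensities (slice x row x col) together with the per-slice
#' myocardial delineation (endocardial and epicardial masks) and a remote
#' region of normal-appearing myocardium that serves as the reference for 2SD
#' segmentation.
#'
#' @param voxels 3D numeric array, `c(n_slices, nrow, ncol)`.
#' @param voxel_mm In-plane voxel size in mm (isotropic).
#' @param slice_thickness_mm Slice thickness in mm.
#' @param endo_mask Logical array, same dimension: the LV cavity (inside the
#'   endocardial border).
#' @param epi_mask Logical array: everything inside the epicardial border
#'   (cavity plus myocardium). The myocardium is `epi_mask & !endo_mask`.
#' @param remote_mask Logical array marking normal-appearing remote
#'   myocardium; must be a subset of the myocardium.
#' @return An object of class `slice_stack` with derived element `myo_mask`.
#' @export
slice_stack <- function(voxels, voxel_mm, slice_thickness_mm,
                        endo_mask, epi_mask, remote_mask) {
  if (length(dim(voxels)) != 3L) stop("`voxels` must be a 3D array", call. = FALSE)
  if (voxel_mm <= 0 || slice_thickness_mm <= 0) {
    stop("voxel dimensions must be positive", call. = FALSE)
  }
  for (m in list(endo_mask, epi_mask, remote_mask)) {
    if (!identical(dim(m), dim(voxels))) {
      stop("masks must match the voxel array dimensions", call. = FALSE)
    }
  }
  myo <- epi_mask & !endo_mask
  if (any(remote_mask & !myo)) {
    stop("`remote_mask` must be a subset of the myocardium", call. = FALSE)
  }
  n_slices <- dim(voxels)[1]
  myo_per_slice <- apply(myo, 1, sum)
  if (any(myo_per_slice == 0)) {
    stop("myocardium mask is empty on at least one slice", call. = FALSE)
  }
  structure(list(
    voxels = voxels, voxel_mm = voxel_mm,
    slice_thickness_mm = slice_thickness_mm,
    endo_mask = endo_mask, epi_mask = epi_mask,
    myo_mask = myo, remote_mask = remote_mask,
    n_slices = n_slices
  ), class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<slice_stack> %d slices of %dx%d voxels (%.2g mm in-plane, %.2g mm thick)\n",
              d[1], d[2], d[3], x$voxel_mm, x$slice_thickness_mm))
  cat(sprintf("  myocardium %d voxels, remote reference %d voxels\n",
              sum(x$myo_mask), sum(x$remote_mask)))
  invisible(x)
}

#' Render a phantom into an MRI-like late-enhancement slice stack
#'
#' Voxelises the phantom shell on a regular in-plane grid, one image per
#' apico-basal slice. Myocardial voxels whose depth from the endocardium is
#' at most `transmurality * wall_thickness` of their (slice, sector) cell are
#' scar and draw their signal intensity from the hyperintense scar
#' distribution `N(si_scar_mean, si_scar_sd)`; all other myocardial voxels
#' draw from the normal distribution `N(si_normal_mean, si_normal_sd)`.
#' Voxels outside the myocardium are zero. The remote region is the
#' myocardium of cells whose 3x3 cell neighbourhood is scar-free, so the 2SD
#' reference never touches the infarct rim.
#'
#' @param phantom An [make_phantom()] object.
#' @param voxel_mm In-plane voxel size in mm (default 1).
#' @param si_normal_mean,si_normal_sd Signal intensity of normal myocardium
#'   (defaults 100 and 10, arbitrary units).
#' @param si_scar_mean Mean scar signal intensity (default 160); must exceed
#'   `si_normal_mean + 2 * si_normal_sd` so that the 2SD rule is satisfiable.
#' @param si_scar_sd Scar signal SD (defaults to `si_normal_sd`).
#' @param seed Integer seed for the intensity noise.
#' @return A [slice_stack()] with an extra element `scar_truth`: the logical
#'   ground-truth scar voxel mask (used for validation only, never by the
#'   segmentation).
#' @export
render_mri_stack <- function(phantom, voxel_mm = 1,
                             si_normal_mean = 100, si_normal_sd = 10,
                             si_scar_mean = 160, si_scar_sd = si_normal_sd,
                             seed = 1L) {
  stopifnot(inherits(phantom, "lv_phantom"))
  if (voxel_mm <= 0) stop("`voxel_mm` must be positive", call. = FALSE)
  if (si_normal_sd < 0 || si_scar_sd < 0) {
    stop("signal-intensity SDs must be non-negative", call. = FALSE)
  }
  if (si_scar_mean <= si_normal_mean + 2 * si_normal_sd) {
    stop("`si_scar_mean` must exceed si_normal_mean + 2*si_normal_sd for the 2SD rule to be satisfiable",
         call. = FALSE)
  }

  ns <- phantom$n_slices
  nk <- phantom$n_sectors
  r_epi_max <- max(phantom$r_endo_mm + apply(phantom$wall_thickness_mm, 1, max))
  half <- ceiling((r_epi_max + 3) / voxel_mm)
  w <- 2L * half + 1L
  centre <- half + 1L

  x <- ((1:w) - centre) * voxel_mm
  xx <- matrix(x, w, w)
  yy <- t(xx)
  rc <- sqrt(xx^2 + yy^2)
  theta <- atan2(yy, xx) %% (2 * pi)
  sector <- pmin(floor(theta / (2 * pi / nk)) + 1L, nk)

  dims <- c(ns, w, w)
  vox <- array(0, dims)
  endo <- array(FALSE, dims)
  epi <- array(FALSE, dims)
  scar <- array(FALSE, dims)
  remote <- array(FALSE, dims)

  # cells whose whole 3x3 neighbourhood is scar-free -> remote reference
  remote_cell <- burden_field(phantom, 1L) == 0

  noise_seeds <- derive_seeds(seed, ns)
  for (sl in seq_len(ns)) {
    r0 <- phantom$r_endo_mm[sl]
    wall_s <- phantom$wall_thickness_mm[sl, ][sector]
    t_s <- matrix(phantom$transmurality[sl, ][sector], w, w)
    myo_s <- rc >= r0 & rc < r0 + wall_s
    scar_s <- myo_s & t_s > 0 & (rc - r0) <= t_s * wall_s
    remote_s <- myo_s & matrix(remote_cell[sl, ][sector], w, w)

    si <- matrix(0, w, w)
    withr::with_seed(noise_seeds[sl], {
      si[myo_s] <- stats::rnorm(sum(myo_s), si_normal_mean, si_normal_sd)
      si[scar_s] <- stats::rnorm(sum(scar_s), si_scar_mean, si_scar_sd)
    })
    vox[sl, , ] <- si
    endo[sl, , ] <- rc < r0
    epi[sl, , ] <- rc < r0 + wall_s
    scar[sl, , ] <- scar_s
    remote[sl, , ] <- remote_s
  }

  out <- slice_stack(vox, voxel_mm, phantom$slice_thickness_mm,
                     endo, epi, remote)
  out$scar_truth <- scar
  out
}
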