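# Programmatic fixtures shared across test files.

# Annular toy stack: one slice, concentric endo/epi circles on a voxel-centre
# radius rule, optional per-region scar. `scar_rule` receives the voxel-centre
# radius matrix and angle matrix and returns a logical matrix.
annulus_stack <- function(width = 41L, r_endo = 9.5, r_epi = 19.5,
                          si = 100, scar_rule = NULL, voxel_mm = 1,
                          slice_mm = 8) {
  ctr <- (width + 1L) / 2L
  xx <- matrix(seq_len(width) - ctr, width, width)
  yy <- t(xx)
  rc <- sqrt(xx^2 + yy^2)
  th <- atan2(yy, xx) %% (2 * pi)
  myo <- rc >= r_endo & rc < r_epi
  endo <- rc < r_endo
  epi <- rc < r_epi
  arr <- function(m) array(m, c(1L, width, width))
  vox <- matrix(si, width, width)
  st <- slice_stack(arr(vox), voxel_mm, slice_mm, arr(endo), arr(epi), arr(myo))
  st$toy_scar <- if (is.null(scar_rule)) {
    array(FALSE, c(1L, width, width))
  } else {
    arr(scar_rule(rc, th) & myo)
  }
  st
}

# Dice coefficient computed directly from two logical masks (independent of
# the package's overlap machinery).
dice_direct <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# noise-free dense-sampled subject: phantom + both pipelines
noise_free_subject <- function(seed, infarct_fraction = 0.36,
                               core_fraction = 0.5) {
  phantom <- make_phantom(infarct_fraction = infarct_fraction,
                          core_fraction = core_fraction, seed = seed)
  stack <- render_mri_stack(phantom, si_normal_sd = 0, seed = seed + 1000L)
  seg <- segment_2sd(stack)
  tmap <- transmurality_map(seg$scar_mask, stack)
  model <- voltage_model(noise_sd_mV = 0)
  points <- dense_mapping_points(phantom, model)
  list(phantom = phantom, stack = stack, tmap = tmap, points = points,
       upv_map = build_polar_map(points, "upv"),
       bipv_map = build_polar_map(points, "bipv"))
}
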