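test_that("2SD segmentation applies the strict mean+2SD rule", {
  # remote voxels {90,100,110}: mean 100, sample sd 10 -> threshold 120
  w <- 5L
  vox <- array(100, c(1, w, w))
  endo <- array(FALSE, c(1, w, w))
  epi <- array(TRUE, c(1, w, w))
  remote <- array(FALSE, c(1, w, w))
  vox[1, 1, 1:3] <- c(90, 100, 110)
  remote[1, 1, 1:3] <- TRUE
  vox[1, 2, 1] <- 121
  vox[1, 2, 2] <- 119
  vox[1, 2, 3] <- 120          # boundary: not strictly greater
  st <- slice_stack(vox, 1, 8, endo, epi, remote)
  seg <- segment_2sd(st)
  expect_equal(seg$threshold, 120)
  expect_true(seg$scar_mask[1, 2, 1])
  expect_false(seg$scar_mask[1, 2, 2])
  expect_false(seg$scar_mask[1, 2, 3])
})

test_that("a uniform stack yields an empty scar mask", {
  st <- annulus_stack(si = 100)
  expect_identical(sum(segment_2sd(st)$scar_mask), 0L)
})

test_that("degenerate remote regions are rejected", {
  st <- annulus_stack()
  st$remote_mask[] <- FALSE
  expect_error(segment_2sd(st), "remote region")
})

test_that("voxels outside the myocardium are never tagged", {
  st <- annulus_stack()
  st$voxels[!st$myo_mask] <- 1e6
  seg <- segment_2sd(st)
  expect_true(all(st$myo_mask[seg$scar_mask]))
})

test_that("infarct volume is voxel count times voxel volume", {
  # 1000 scar voxels at 1 x 1 x 8 mm -> 8.0 mL
  w <- 64L
  vox <- array(100, c(1, w, w))
  endo <- array(FALSE, c(1, w, w))
  epi <- array(TRUE, c(1, w, w))
  remote <- array(FALSE, c(1, w, w)); remote[1, 1, 1:10] <- TRUE
  st <- slice_stack(vox, 1, 8, endo, epi, remote)
  scar <- array(FALSE, c(1, w, w))
  scar[1, 1:25, 1:40] <- TRUE  # 1000 voxels
  vol <- infarct_volume(scar, st)
  expect_equal(vol$volume_ml, 8.0)
  expect_equal(infarct_volume(array(FALSE, c(1, w, w)), st)$volume_ml, 0)
  expect_equal(infarct_volume(array(FALSE, c(1, w, w)), st)$percent_of_lv, 0)
  expect_error(infarct_volume(scar[, 1:10, , drop = FALSE], st), "dimensions")
})

test_that("recovered infarct percentage matches the analytic value to a point", {
  # phantom scaled so the analytic scar burden sits near 17% of LV mass
  ph <- make_phantom(infarct_fraction = 0.30, core_fraction = 0.45, seed = 31)
  av <- analytic_scar_volume(ph)
  expect_gt(av$scar_fraction_pct, 12)
  expect_lt(av$scar_fraction_pct, 22)
  st <- render_mri_stack(ph, voxel_mm = 1, seed = 32)
  vol <- infarct_volume(st$scar_truth, st)
  expect_lt(abs(vol$percent_of_lv - av$scar_fraction_pct), 1)
  # the strict 2SD mask adds a known false-positive floor (~2% of normal
  # myocardium at Gaussian noise), so the segmented volume sits slightly high
  vol2 <- infarct_volume(segment_2sd(st)$scar_mask, st)
  expect_gt(vol2$percent_of_lv, vol$percent_of_lv - 1)
  expect_lt(vol2$percent_of_lv, vol$percent_of_lv + 3)
})

test_that("midline ray projection is exact on analytic half/full-thickness sectors", {
  # two sectors with vertical midlines: scar over the inner half of the wall
  # (upper half-plane) and over the full wall (lower half-plane)
  st <- annulus_stack(scar_rule = function(rc, th) {
    (th < pi & rc < 14.5) | th >= pi
  })
  tm <- transmurality_map(st$toy_scar, st, n_sectors = 2L,
                          method = "ray", rays = 1L)
  expect_identical(tm$values[1, 1], 0.5)
  expect_identical(tm$values[1, 2], 1)
})

test_that("boundary and ray methods match a per-voxel radial oracle", {
  # three wedges with distinct analytic transmuralities, constant per wedge
  tvals <- c(0.3, 0.8, 0)
  st <- annulus_stack(width = 61L, r_endo = 14.5, r_epi = 24.5,
                      scar_rule = function(rc, th) {
    sec <- pmin(floor(th / (2 * pi / 3)) + 1L, 3L)
    rc < 14.5 + tvals[sec] * 10
  })
  # oracle: 1/r-weighted voxel counts per wedge (area -> radial measure)
  w <- dim(st$voxels)[2]
  ctr <- (w + 1) / 2
  xx <- matrix(seq_len(w) - ctr, w, w); yy <- t(xx)
  rc <- sqrt(xx^2 + yy^2)
  th <- atan2(yy, xx) %% (2 * pi)
  sec <- pmin(floor(th / (2 * pi / 3)) + 1L, 3L)
  myo <- st$myo_mask[1, , ]
  scar <- st$toy_scar[1, , ]
  oracle <- vapply(1:3, function(j) {
    wsel <- myo & sec == j
    sum((1 / rc)[wsel & scar]) / sum((1 / rc)[wsel])
  }, numeric(1))
  expect_equal(oracle, tvals, tolerance = 0.05)

  for (method in c("boundary", "ray")) {
    tm <- transmurality_map(st$toy_scar, st, n_sectors = 3L, method = method)
    expect_equal(as.vector(tm$values), oracle, tolerance = 0.03)
  }
})

test_that("scar boundary localisation resists isolated false positives", {
  # clean nested input: exact gap midpoint
  rb <- cardiomap:::robust_scar_boundary(c(10, 11, 12, 13, 14), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(rb$radius, 11.5)
  # one stray false positive deep in the wall must not drag the boundary out
  rb2 <- cardiomap:::robust_scar_boundary(10:19, c(TRUE, TRUE, rep(FALSE, 5), TRUE, FALSE, FALSE))
  expect_equal(rb2$radius, 11.5)
  # all scar -> full thickness
  rb3 <- cardiomap:::robust_scar_boundary(10:12, rep(TRUE, 3))
  expect_identical(rb3$k, rb3$n)
})

test_that("sectors without myocardium are invalid and excluded", {
  st <- annulus_stack()
  st$myo_mask[1, , 1:20] <- FALSE   # remove half the ring
  st$epi_mask[1, , 1:20] <- FALSE
  st$remote_mask <- st$myo_mask
  tm <- transmurality_map(st$toy_scar, st, n_sectors = 8L)
  expect_true(any(!tm$valid))
  expect_true(all(is.na(tm$values[!tm$valid])))
})

test_that("noise-free pipeline recovers the phantom transmurality field", {
  for (s in c(5, 23)) {
    ph <- make_phantom(seed = s)
    st <- render_mri_stack(ph, si_normal_sd = 0, seed = s + 1)
    tm <- transmurality_map(segment_2sd(st)$scar_mask, st)
    expect_lte(max(abs(tm$values - ph$transmurality)), 0.05)
    expect_identical(unname(tm$values > 0), unname(ph$transmurality > 0))
  }
})

test_that("SI schemes classify the printed band examples correctly", {
  grid <- polar_map(matrix(c(0.80, 0.55, 0.24, 0.25, 0.50, 0.75, 0.30, 0.60),
                           2, 4), "transmurality")
  cls <- classify_transmurality(grid, si_scheme("25-50-75"))
  lev <- attr(cls, "levels")
  expect_identical(lev[cls$values[1, 1]], "transmural")       # 80%
  expect_identical(lev[cls$values[1, 2]], "normal")           # 24%
  expect_identical(lev[cls$values[2, 2]], "non_transmural")   # 25% boundary
  expect_identical(lev[cls$values[1, 3]], "non_transmural")   # 50% boundary
  expect_identical(lev[cls$values[2, 3]], "border")           # 75% boundary

  cls2 <- classify_transmurality(grid, si_scheme("30-60"))
  lev2 <- attr(cls2, "levels")
  expect_identical(lev2[cls2$values[2, 1]], "non_transmural") # 55%
  expect_identical(lev2[cls2$values[1, 4]], "normal")         # 30% boundary
  expect_identical(lev2[cls2$values[2, 4]], "non_transmural") # 60% boundary
})

test_that("a map entirely below 25% is all normal", {
  m <- polar_map(matrix(runif(256, 0, 0.24), 8, 32), "transmurality")
  af <- area_fractions(classify_transmurality(m, si_scheme("25-50-75")))
  expect_equal(unname(af["normal"]), 100)
  expect_true(all(af[c("non_transmural", "border", "transmural")] == 0))
})

test_that("classification is monotone: raising values never shrinks the transmural area", {
  withr::with_seed(9, {
    for (i in 1:10) {
      v <- matrix(runif(256), 8, 32)
      up <- pmin(v + matrix(runif(256, 0, 0.3), 8, 32), 1)
      f1 <- area_fractions(classify_transmurality(polar_map(v, "transmurality")))
      f2 <- area_fractions(classify_transmurality(polar_map(up, "transmurality")))
      expect_gte(f2[["transmural"]], f1[["transmural"]])
    }
  })
})

test_that("unknown schemes are a configuration error", {
  m <- polar_map(matrix(0.5, 8, 32), "transmurality")
  expect_error(si_scheme("20-40"), "arg")
  expect_error(classify_transmurality(m, scheme = list(name = "x")), "scheme")
})
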