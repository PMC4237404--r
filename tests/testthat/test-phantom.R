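test_that("scar support honours the requested surface fraction to one cell", {
  ph <- make_phantom(infarct_fraction = 0.20, seed = 1)
  expect_true(sum(ph$transmurality > 0) %in% c(51L, 52L))

  for (f in c(0.1, 0.36, 0.6)) {
    ph <- make_phantom(infarct_fraction = f, seed = 2)
    expect_lte(abs(sum(ph$transmurality > 0) - f * 256), 1)
  }
})

test_that("empty-scar phantom has an all-zero field", {
  ph <- make_phantom(infarct_fraction = 0, seed = 5)
  expect_true(all(ph$transmurality == 0))
})

test_that("phantom generation is a pure function of arguments and seed", {
  a <- make_phantom(seed = 42)
  b <- make_phantom(seed = 42)
  expect_identical(a, b)
  c <- make_phantom(seed = 43)
  expect_false(identical(a$transmurality, c$transmurality))
})

test_that("transmurality values stay in [0,1] and the core count is exact", {
  for (s in 1:5) {
    set.seed(s)
    f <- runif(1, 0.1, 0.5)
    cf <- runif(1, 0.2, 0.7)
    ph <- make_phantom(infarct_fraction = f, core_fraction = cf, seed = s)
    expect_true(all(ph$transmurality >= 0 & ph$transmurality <= 1))
    n_scar <- sum(ph$transmurality > 0)
    expect_lte(abs(sum(ph$transmurality > 0.75) - cf * n_scar), 1)
  }
})

test_that("the scar support is a single 8-connected region", {
  connected_size <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0) return(0L)
    ns <- nrow(mask); nk <- ncol(mask)
    seen <- matrix(FALSE, ns, nk)
    queue <- list(idx[1, ])
    seen[idx[1, 1], idx[1, 2]] <- TRUE
    count <- 1L
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        i <- cur[1] + di
        j <- ((cur[2] + dj - 1) %% nk) + 1
        if (i >= 1 && i <= ns && mask[i, j] && !seen[i, j]) {
          seen[i, j] <- TRUE
          count <- count + 1L
          queue[[length(queue) + 1L]] <- c(i, j)
        }
      }
    }
    count
  }
  for (s in c(1, 7, 19)) {
    ph <- make_phantom(seed = s)
    supp <- ph$transmurality > 0
    expect_identical(connected_size(supp), sum(supp))
  }
})

test_that("the 12-segment labels partition the grid into non-empty groups", {
  seg <- segment12_labels(8, 32)
  expect_identical(sort(unique(as.vector(seg))), 1:12)
  expect_true(all(table(seg) > 0))
  expect_identical(sum(table(seg)), 256L)
  expect_error(segment12_labels(2, 32), "non-empty")
})

test_that("invalid phantom parameters are rejected", {
  expect_error(make_phantom(infarct_fraction = 1), "infarct_fraction")
  expect_error(make_phantom(infarct_fraction = -0.1), "infarct_fraction")
  expect_error(make_phantom(n_slices = 0), "positive integer")
  expect_error(make_phantom(n_sectors = -4), "positive integer")
  expect_error(make_phantom(wall_thickness_mm = 0), "wall_thickness_mm")
})

test_that("bipolar model hits its anchors exactly and decreases in transmurality", {
  m <- voltage_model()
  expect_identical(bipv_from_transmurality(0.75, m), 0.8)
  expect_identical(bipv_from_transmurality(0.25, m), 1.9)
  tt <- seq(0, 1, by = 0.01)
  v <- bipv_from_transmurality(tt, m)
  expect_true(all(diff(v) < 0))
  expect_gt(bipv_from_transmurality(0, m), 1.9)
  expect_error(voltage_model(bipv_anchors = rbind(c(0.25, 0.8), c(0.75, 1.9))),
               "strictly decreasing")
})

test_that("unipolar field separates healthy plateau from any scar involvement", {
  ph <- make_phantom(seed = 3)
  f <- voltage_fields(ph)
  supp <- ph$transmurality > 0
  expect_true(all(f$upv_mV[!supp] > 15))
  expect_true(all(f$upv_mV[supp] < 15))
  expect_true(all(f$upv_mV[supp] > 0))
})

test_that("rendered scar volume matches the analytic shell integral within 2%", {
  ph <- make_phantom(seed = 11)
  st <- render_mri_stack(ph, voxel_mm = 1, seed = 12)
  vol <- infarct_volume(st$scar_truth, st)
  av <- analytic_scar_volume(ph)
  expect_lt(abs(vol$percent_of_lv - av$scar_fraction_pct),
            0.02 * av$scar_fraction_pct)
})

test_that("zero-noise rendering separates scar from normal by the 2SD rule", {
  ph <- make_phantom(seed = 2)
  st <- render_mri_stack(ph, si_normal_sd = 0, seed = 3)
  remote <- st$voxels[st$remote_mask]
  thr <- mean(remote) + 2 * sd(remote)
  expect_true(all(st$voxels[st$scar_truth] > thr))

  empty <- make_phantom(infarct_fraction = 0, seed = 2)
  st0 <- render_mri_stack(empty, si_normal_sd = 0, seed = 3)
  expect_identical(sum(segment_2sd(st0)$scar_mask), 0L)
})

test_that("renderer rejects parameters that break the 2SD precondition", {
  ph <- make_phantom(seed = 1)
  expect_error(render_mri_stack(ph, voxel_mm = 0), "voxel_mm")
  expect_error(render_mri_stack(ph, si_normal_sd = -1), "non-negative")
  expect_error(render_mri_stack(ph, si_scar_mean = 115), "2SD")
})

test_that("rendering is seed-deterministic", {
  ph <- make_phantom(seed = 4)
  a <- render_mri_stack(ph, seed = 9)
  b <- render_mri_stack(ph, seed = 9)
  expect_identical(a$voxels, b$voxels)
})

test_that("sparse sampling covers every 12-segment region and is seeded", {
  ph <- make_phantom(seed = 6)
  pts <- sample_noga_points(ph, n_points = 202, min_per_segment = 4, seed = 8)
  expect_identical(nrow(pts), 202L)
  seg_of <- ph$segment12[cbind(pts$slice_idx, pts$sector_idx)]
  expect_true(all(table(factor(seg_of, levels = 1:12)) >= 4))
  expect_true(all(pts$upv_mV >= 0) && all(pts$bipv_mV >= 0))

  again <- sample_noga_points(ph, n_points = 202, min_per_segment = 4, seed = 8)
  expect_identical(pts, again)
  expect_error(sample_noga_points(ph, n_points = 40, min_per_segment = 4),
               "at least")
})

test_that("noise-free sampled voltages evaluate the model at the cell", {
  ph <- make_phantom(seed = 6)
  m <- voltage_model(noise_sd_mV = 0)
  pts <- sample_noga_points(ph, m, n_points = 202, seed = 3)
  fields <- voltage_fields(ph, m)
  idx <- cbind(pts$slice_idx, pts$sector_idx)
  expect_equal(pts$bipv_mV, fields$bipv_mV[idx])
  expect_equal(pts$upv_mV, fields$upv_mV[idx])
  # anchor cells: transmurality exactly at the cut-offs
  expect_equal(bipv_from_transmurality(ph$transmurality[idx], m), pts$bipv_mV)
})

test_that("noise-free modalities agree with the phantom ground truth", {
  sub <- noise_free_subject(21)
  # MRI side recovers the transmurality field within the voxelisation bound
  expect_lte(max(abs(sub$tmap$values - sub$phantom$transmurality)), 0.05)
  # voltage side: infarct extent (core + border) equals the scar support
  af <- area_fractions(classify_voltage(sub$upv_map))
  support_pct <- 100 * mean(sub$phantom$transmurality > 0)
  expect_lte(abs((af[["infarct"]] + af[["border"]]) - support_pct), 100 / 256)
})
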