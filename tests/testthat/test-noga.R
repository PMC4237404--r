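test_that("a single central point maps exactly the cells within reach", {
  pts <- data.frame(slice_idx = 1L, sector_idx = 1L, x_mm = 0, y_mm = 0,
                    z_mm = 0, u_map = 0, v_map = 0, upv_mV = 10,
                    bipv_mV = 1, stable = TRUE)
  class(pts) <- c("mapping_points", "data.frame")
  m <- build_polar_map(pts, "upv", connect_mm = 15)
  cc <- cardiomap:::polar_cell_centres(8, 32)
  within <- matrix(FALSE, 8, 32)
  within[cbind(cc$slice, cc$sector)] <- sqrt(cc$u^2 + cc$v^2) <= 15
  expect_identical(m$valid, within)
  expect_true(all(m$values[m$valid] == 10))
})

test_that("dense noise-free sampling reproduces the model voltage fields", {
  ph <- make_phantom(seed = 14)
  model <- voltage_model(noise_sd_mV = 0)
  pts <- dense_mapping_points(ph, model)
  fields <- voltage_fields(ph, model)
  for (f in c("upv", "bipv")) {
    m <- build_polar_map(pts, f)
    expect_true(all(m$valid))
    expect_lt(max(abs(m$values - fields[[paste0(f, "_mV")]])), 0.01)
  }
})

test_that("a default 202-point map leaves no cell out of interpolation reach", {
  ph <- make_phantom(seed = 15)
  pts <- sample_noga_points(ph, n_points = 202, seed = 16)
  m <- build_polar_map(pts, "bipv")
  expect_true(all(m$valid))
})

test_that("only stable points participate in map construction", {
  ph <- make_phantom(seed = 17)
  pts <- sample_noga_points(ph, n_points = 202, seed = 18)
  pts2 <- pts
  pts2$upv_mV[151:202] <- 999   # poison the tail...
  pts2$stable[151:202] <- FALSE # ...then reject it
  m_ref <- build_polar_map(pts[1:150, ], "upv")
  m <- build_polar_map(pts2, "upv")
  expect_identical(m$values, m_ref$values)
  pts$stable[] <- FALSE
  expect_error(build_polar_map(pts, "upv"), "empty map")
  pts3 <- pts[1:5, ]; pts3$stable <- TRUE; pts3$bipv_mV[1] <- -1
  expect_error(build_polar_map(pts3, "bipv"), "non-negative")
})

test_that("voltage classification follows the printed cut-off table", {
  thr <- voltage_thresholds()
  up <- polar_map(matrix(c(4.9, 5, 15, 20, 16, 10), 2, 3), "unipolar_mV")
  cls <- classify_voltage(up, thr)
  lev <- attr(cls, "levels")
  expect_identical(lev[cls$values[1, 1]], "infarct")   # 4.9 mV
  expect_identical(lev[cls$values[2, 1]], "border")    # 5 mV boundary
  expect_identical(lev[cls$values[1, 2]], "border")    # 15 mV boundary
  expect_identical(lev[cls$values[2, 2]], "normal")    # 20 mV

  bp <- polar_map(matrix(c(2.0, 0.8, 1.9, 0.79), 2, 2), "bipolar_mV")
  cls2 <- classify_voltage(bp, thr)
  lev2 <- attr(cls2, "levels")
  expect_identical(lev2[cls2$values[1, 1]], "normal")          # 2.0 mV
  expect_identical(lev2[cls2$values[2, 1]], "non_transmural")  # 0.8 boundary
  expect_identical(lev2[cls2$values[1, 2]], "non_transmural")  # 1.9 boundary
  expect_identical(lev2[cls2$values[2, 2]], "transmural")      # 0.79 mV
})

test_that("a uniformly normal unipolar map is 100% normal", {
  m <- polar_map(matrix(20, 8, 32), "unipolar_mV")
  af <- area_fractions(classify_voltage(m))
  expect_equal(unname(af), c(0, 0, 100))
})

test_that("widening the infarct band never shrinks the infarct fraction", {
  withr::with_seed(4, {
    m <- polar_map(matrix(runif(256, 0, 20), 8, 32), "unipolar_mV")
    f1 <- area_fractions(classify_voltage(m, voltage_thresholds(upv_infarct = 5)))
    f2 <- area_fractions(classify_voltage(m, voltage_thresholds(upv_infarct = 7)))
    expect_gte(f2[["infarct"]], f1[["infarct"]])
  })
})

test_that("mismatched map kind and thresholds are rejected", {
  m <- polar_map(matrix(0.5, 8, 32), "transmurality")
  expect_error(classify_voltage(m), "voltage map")
  expect_error(voltage_thresholds(upv_infarct = 20, upv_normal = 15),
               "strictly ordered")
})

test_that("low-voltage area is non-decreasing in the threshold", {
  ph <- make_phantom(seed = 19)
  sub <- noise_free_subject(19)
  sw <- threshold_sweep(list(sub$bipv_map, sub$bipv_map, sub$bipv_map),
                        list(sub$tmap, sub$tmap, sub$tmap),
                        crop_masks = rep(list(matrix(TRUE, 8, 32)), 3))
  expect_true(all(diff(sw$noga_area[1, ]) >= 0))
})

test_that("sweep areas at the standard cut-off reduce to classified areas", {
  sub <- noise_free_subject(20)
  full <- matrix(TRUE, 8, 32)
  sw <- threshold_sweep(rep(list(sub$bipv_map), 3), rep(list(sub$tmap), 3),
                        crop_masks = rep(list(full), 3))
  af <- area_fractions(classify_voltage(sub$bipv_map))
  k <- which(abs(sw$thresholds - 0.8) < 1e-9)
  expect_equal(sw$noga_area[1, k], unname(af["transmural"]))
})

test_that("sweep rejects degenerate inputs", {
  flat <- polar_map(matrix(5, 8, 32), "bipolar_mV")
  tm <- polar_map(matrix(0.5, 8, 32), "transmurality")
  expect_error(threshold_sweep(rep(list(flat), 3), rep(list(tm), 3)),
               "constant|undefined")
  sub <- noise_free_subject(22)
  expect_error(threshold_sweep(list(sub$bipv_map), list(sub$tmap)),
               "3 subjects")
})

test_that("colour-scale rendering round-trips voltages", {
  ph <- make_phantom(seed = 23)
  m <- build_polar_map(dense_mapping_points(ph), "bipv")
  sc <- noga_colour_scale("bipolar")
  img <- render_polar_png(m, sc)
  dec <- rgb_to_voltage(img, sc)
  ras <- polar_raster(m, raster_size = 200)
  ok <- dec$valid & ras$valid
  expect_gt(sum(ok), 1000)
  half_step <- max(diff(sc$voltage_mV)) / 2
  expect_lte(max(abs(dec$values[ok] - ras$values[ok])), half_step)
})

test_that("pure red decodes to the lowest voltage band; annotations are invalid", {
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- c(1, 0, 0)       # pure red
  img[1, 2, ] <- c(1, 1, 1)       # white annotation
  img[2, 1, ] <- c(0.5, 0.5, 0.5) # grey (invalid-cell marker)
  img[2, 2, ] <- c(1, 1, 0)       # pure yellow: the 0.8 mV control point
  dec <- rgb_to_voltage(img, noga_colour_scale("bipolar"))
  expect_lt(dec$values[1, 1], 0.8)
  expect_false(dec$valid[1, 2])
  expect_false(dec$valid[2, 1])
  expect_equal(dec$values[2, 2], 0.8)
})

test_that("the disk raster interpolates the cell grid", {
  ph <- make_phantom(seed = 24)
  m <- build_polar_map(dense_mapping_points(ph), "bipv")
  ras <- polar_raster(m, raster_size = 400)
  cc <- cardiomap:::polar_cell_centres(8, 32)
  px <- 2 * m$disk_radius_mm / 400
  ix <- round((cc$u / px) + (400 + 1) / 2)
  iy <- round((cc$v / px) + (400 + 1) / 2)
  got <- ras$values[cbind(ix, iy)]
  expect_lt(stats::median(abs(got - m$values[cbind(cc$slice, cc$sector)]),
                          na.rm = TRUE), 0.05)
})

test_that("ROC analysis reproduces a brute-force worked example", {
  pts <- data.frame(upv_mV = c(1, 1, 10, 10), bipv_mV = c(0.3, 0.9, 1.2, 2.5),
                    stable = TRUE)
  class(pts) <- c("mapping_points", "data.frame")
  roc <- roc_bipv_cutoff(pts, n_boot = 0)
  expect_identical(roc$auc, 1)
  ss <- sens_spec_at(roc, 1.0)
  expect_identical(unname(ss), c(1, 1))
  # brute force over all label/score pairs
  brute <- mean(outer(pts$bipv_mV[pts$upv_mV < 5], pts$bipv_mV[pts$upv_mV >= 5],
                      `<`))
  expect_identical(roc$auc, brute)
})

test_that("rank AUC equals the trapezoidal AUC", {
  withr::with_seed(31, {
    for (i in 1:5) {
      sc <- round(runif(60, 0, 3), 1)  # ties included
      lb <- runif(60) < 0.4
      curve <- cardiomap:::roc_points(lb, sc)
      expect_equal(cardiomap:::auc_trapezoid(curve),
                   cardiomap:::auc_rank(lb, sc))
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  withr::with_seed(8, {
    ph <- make_phantom(seed = 25)
    pts <- sample_noga_points(ph, voltage_model(noise_sd_mV = 0.3),
                              n_points = 202, seed = 26)
  })
  roc <- roc_bipv_cutoff(pts, n_boot = 200, seed = 5)
  ref <- pROC::roc(response = pts$upv_mV < 5, predictor = pts$bipv_mV,
                   direction = ">", quiet = TRUE)
  expect_equal(roc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_true(roc$auc_ci[1] <= roc$auc && roc$auc <= roc$auc_ci[2])
})

test_that("single-class labelling is an undefined ROC", {
  pts <- data.frame(upv_mV = c(10, 12), bipv_mV = c(1, 2), stable = TRUE)
  class(pts) <- c("mapping_points", "data.frame")
  expect_error(roc_bipv_cutoff(pts), "ROC undefined")
})
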