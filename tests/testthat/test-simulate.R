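test_that("forward model equals the direct summation oracle", {
  opt <- tiny_optics(16)
  obj <- make_point_scatterers(4, 16, 3, seed = 2)
  pi_ <- make_pupil_phase(opt, "speckle", list(n_modes = 10, rms = 1.2), seed = 5)
  po_ <- make_pupil_phase(opt, "speckle", list(n_modes = 10, rms = 1.2), seed = 6,
                          side = "output")
  st <- simulate_scan(obj, pi_, po_, opt, scan_step_px = 2, foi_px = 10,
                      fod_px = 16)
  expect_equal(nrow(st$scan_px), 25)
  direct <- oracle_scan(unclass(obj), pi_, po_, st$scan_px, 16)
  rel <- frob(st$frames - direct) / frob(direct)
  expect_lt(rel, 1e-10)
})

test_that("point object with flat pupils gives shifted PSF frames", {
  opt <- tiny_optics(32)
  o <- matrix(0, 32, 32); o[17, 15] <- 1
  obj <- structure(o + 0i, class = c("object_map", "matrix"), side_px = 32L)
  st <- simulate_scan(obj, flat_pupil(opt), flat_pupil(opt, side = "output"), opt)
  conf <- confocal_image(st)
  pk <- which(conf == max(conf), arr.ind = TRUE)[1, ]
  hit <- st$scan_px[(pk[2] - 1) * st$scan_dims[1] + pk[1], ]
  # confocal response maximal when the scan lands on the scatterer
  expect_equal(unname(hit), c(17, 15))
  # each frame is the product of two shifted PSFs sampled at the scatterer:
  # in the de-scanned frame the peak sits at r0 - r_i + centre
  s <- 5
  fr <- Mod(st$frames[, , s])
  pk_f <- which(fr == max(fr), arr.ind = TRUE)[1, ]
  cc <- floor(32 / 2) + 1
  expected <- c(17, 15) - st$scan_px[s, ] + cc
  expect_equal(unname(pk_f), unname((expected - 1) %% 32 + 1))
})

test_that("multiple-scattering noise is calibrated to the requested ssmr", {
  opt <- tiny_optics(32)
  obj <- make_siemens_star(8, 32)
  pi_ <- make_pupil_phase(opt, "speckle", list(n_modes = 30, rms = 1.3), seed = 1)
  po_ <- make_pupil_phase(opt, "speckle", list(n_modes = 30, rms = 1.3), seed = 2,
                          side = "output")
  st <- simulate_scan(obj, pi_, po_, opt, ssmr = 0.08, seed = 9)
  expect_gte(nrow(st$scan_px), 100)
  r <- ssmr_estimate(st)
  expect_lt(abs(r - 0.08) / 0.08, 0.2)
  # identical seed -> bit-identical speckle
  st2 <- simulate_scan(obj, pi_, po_, opt, ssmr = 0.08, seed = 9)
  expect_identical(st$frames, st2$frames)
})

test_that("simulation inputs are validated", {
  opt <- tiny_optics(16)
  obj <- make_siemens_star(4, 16)
  fp <- flat_pupil(opt); fpo <- flat_pupil(opt, side = "output")
  expect_error(simulate_scan(obj, fp, fpo, opt, foi_px = 20), "beyond|multiple")
  expect_error(simulate_scan(obj, fp, fpo, opt, foi_px = 9), "multiple")
  expect_error(simulate_scan(obj, fp, fpo, opt, ssmr = -1), "ssmr")
  expect_error(simulate_scan(obj, fp, fpo, optics_config(0.9, 1, grid_size = 32)),
               "grid")
  expect_error(simulate_scan(obj, NULL, NULL, opt), "phi_i")
})

test_that("flat-pupil confocal image localises the object at delta_d", {
  opt <- optics_config(0.9, 1.0, grid_size = 32)
  o <- matrix(0, 32, 32); o[17, 17] <- 1
  obj <- structure(o + 0i, class = c("object_map", "matrix"), side_px = 32L)
  st <- simulate_scan(obj, flat_pupil(opt), flat_pupil(opt, side = "output"), opt)
  conf <- confocal_image(st)
  pk <- which(conf == max(conf), arr.ind = TRUE)[1, ]
  # neighbours one scan step (= delta_d) away have dropped below half maximum
  expect_lt(conf[pk[1] + 1, pk[2]] / conf[pk[1], pk[2]], 0.5)
  expect_lt(conf[pk[1] - 1, pk[2]] / conf[pk[1], pk[2]], 0.5)
})
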