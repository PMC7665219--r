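test_that("de-scan / lab conversion shifts by the illumination position", {
  s <- tiny_stack(16, seed = 3)
  st <- s$stack
  lab <- descan_to_lab(st)
  expect_equal(lab$frame, "lab")
  expect_error(descan_to_lab(lab), "de-scanned")
  # a frame whose scan position coincides with the frame centre is unchanged
  cc <- floor(st$fod_px / 2) + 1
  j <- which(st$scan_px[, 1] == cc & st$scan_px[, 2] == cc)
  if (length(j) == 1)
    expect_equal(lab$frames[, , j], st$frames[, , j])
  # round trip on the common support
  back <- lab_to_descan(lab)
  expect_equal(back$frames, st$frames, tolerance = 1e-14)
})

test_that("windowed (non-periodic) lab frames zero-fill unmeasured pixels", {
  opt <- tiny_optics(32)
  obj <- make_siemens_star(8, 32)
  st <- simulate_scan(obj, flat_pupil(opt), flat_pupil(opt, side = "output"),
                      opt, foi_px = 16, fod_px = 8)
  expect_false(st$full_grid)
  lab <- descan_to_lab(st)
  # window = FOI bounding box dilated by the FOD margin
  expect_equal(lab$window_dim,
               c(diff(range(st$scan_px[, 1])) + 1 + 8 - 1,
                 diff(range(st$scan_px[, 2])) + 1 + 8 - 1))
  back <- lab_to_descan(lab)
  expect_equal(back$frames, st$frames, tolerance = 1e-14)
})

test_that("matrix assembly flattens frames column-wise with y fastest", {
  s <- tiny_stack(16, seed = 4)
  lab <- descan_to_lab(s$stack)
  R <- assemble_matrix(lab)
  expect_equal(dim(R$m), c(16 * 16, nrow(s$stack$scan_px)))
  j <- 7
  expect_equal(R$m[, j], as.vector(lab$frames[, , j]))
  # Frobenius norm equals the stack energy
  expect_equal(frob(R$m), sqrt(sum(Mod(lab$frames)^2)))
  expect_error(assemble_matrix(s$stack), "lab-frame")
})

test_that("spectral transform is unitary and matches the DFT-matrix oracle", {
  s <- tiny_stack(16, seed = 5)
  Rsq <- square_matrix(assemble_matrix(descan_to_lab(s$stack)))
  expect_error(to_spectral(assemble_matrix(descan_to_lab(s$stack))), "square")
  Rt <- to_spectral(Rsq)
  expect_equal(frob(Rt$m), frob(Rsq$m), tolerance = 1e-10)
  oracle <- oracle_spectral(Rsq$m, Rt$dims[1], Rt$dims[2])
  expect_lt(frob(Rt$m - oracle) / frob(oracle), 1e-10)
  back <- from_spectral(Rt)
  expect_lt(frob(back$m - Rsq$m) / frob(Rsq$m), 1e-10)
})

test_that("identity reflection matrix stays the identity in k space", {
  s <- tiny_stack(16, seed = 6)
  Rsq <- square_matrix(assemble_matrix(descan_to_lab(s$stack)))
  Rsq$m <- diag(nrow(Rsq$m)) + 0i
  Rt <- to_spectral(Rsq)
  expect_lt(max(Mod(Rt$m - diag(nrow(Rsq$m)))), 1e-10)
})

test_that("shift-invariant pupils give a diagonal spectral matrix on a mirror", {
  opt <- tiny_optics(16)
  obj <- structure(matrix(1 + 0i, 16, 16), class = c("object_map", "matrix"),
                   side_px = 16L)
  pi_ <- make_pupil_phase(opt, "speckle", list(n_modes = 8, rms = 1), seed = 1)
  po_ <- make_pupil_phase(opt, "speckle", list(n_modes = 8, rms = 1), seed = 2,
                          side = "output")
  st <- simulate_scan(obj, pi_, po_, opt)
  Rt <- to_spectral(square_matrix(assemble_matrix(descan_to_lab(st))))
  off <- Rt$m; diag(off) <- 0
  expect_lt(max(Mod(off)) / max(Mod(diag(Rt$m))), 1e-8)
})

test_that("OCM image implements the confocal pinhole", {
  opt <- optics_config(0.9, 1.0, grid_size = 32)
  o <- matrix(0, 32, 32); o[17, 17] <- 1
  obj <- structure(o + 0i, class = c("object_map", "matrix"), side_px = 32L)
  st <- simulate_scan(obj, flat_pupil(opt), flat_pupil(opt, side = "output"), opt)
  R <- assemble_matrix(descan_to_lab(st))
  expect_error(ocm_image(R, -0.2), ">= 0")
  img0 <- ocm_image(R, pinhole_radius_airy = 0)
  expect_equal(img0, confocal_image(st), tolerance = 1e-12)
  # 1-Airy pinhole sums the surrounding pixels: oracle by direct integration
  img1 <- ocm_image(R, pinhole_radius_airy = 1)
  r_px <- 0.61 * 0.9 / 1.0 / opt$pixel_pitch
  s_pk <- which.max(img0)
  ri <- st$scan_px[s_pk, ]
  lab <- descan_to_lab(st)
  acc <- 0
  for (dy in -3:3) for (dx in -3:3) {
    if (dy^2 + dx^2 <= r_px^2)
      acc <- acc + Mod(lab$frames[ri[1] + dy, ri[2] + dx, s_pk])^2
  }
  expect_equal(img1[arrayInd(s_pk, st$scan_dims)], acc, tolerance = 1e-12)
  # aberrations can only lose confocal peak intensity (Strehl <= 1)
  ab <- make_pupil_phase(opt, "speckle", list(n_modes = 30, rms = 1.5), seed = 3)
  st_ab <- simulate_scan(obj, ab, mirror_pupil(ab), opt)
  expect_lt(max(confocal_image(st_ab)), max(img0))
})
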