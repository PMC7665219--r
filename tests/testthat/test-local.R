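test_that("FOI tiling covers the scan grid with clipped margins", {
  s <- tiny_stack(16, seed = 1)
  step_um <- s$stack$scan_step_px * s$opt$pixel_pitch
  til1 <- tile_foi(s$stack, s$stack$scan_dims[1] * step_um, margin = 0)
  expect_equal(length(til1$tiles), 1L)

  til <- tile_foi(s$stack, 2 * step_um, margin = step_um)
  cover <- matrix(FALSE, s$stack$scan_dims[1], s$stack$scan_dims[2])
  for (t in til$tiles) {
    cover[t$core$y[1]:t$core$y[2], t$core$x[1]:t$core$x[2]] <- TRUE
    expect_true(all(t$full$y >= 1 & t$full$y <= s$stack$scan_dims[1]))
  }
  expect_true(all(cover))                       # cores tile the FOI exactly
  expect_error(tile_foi(s$stack, 1e4), "exceeds")
  expect_error(tile_foi(s$stack, 2, margin = -1), ">= 0")
})

test_that("a 150 um field at ~10 um subregions gives about 15x15 tiles", {
  # geometry-only check on a synthetic stack descriptor
  opt <- optics_config(0.9, 1.0, grid_size = 668)
  fake <- structure(list(scan_dims = c(333L, 333L), scan_step_px = 2L,
                         optics = opt), class = "field_stack")
  til <- tile_foi(fake, 10)
  expect_lte(abs(til$n_tiles[1] - 15), 1)
  expect_lte(abs(til$n_tiles[2] - 15), 1)
})

test_that("sub-matrix entries are the lab-frame stack samples", {
  s <- tiny_stack(16, seed = 2)
  lab <- descan_to_lab(s$stack)
  til <- tile_foi(s$stack, 4 * s$opt$pixel_pitch * 2, margin = 0)
  tile <- til$tiles[[1]]
  Rsub <- build_sub_matrix(lab, tile, fod_px = 8)
  # N_i equals the scan positions in the tile: (FOI_tile/delta_d)^2
  expect_equal(ncol(Rsub$m), length(tile$scan_idx))
  expect_equal(length(tile$scan_idx),
               (tile$core$y[2] - tile$core$y[1] + 1) *
                 (tile$core$x[2] - tile$core$x[1] + 1))
  # index bookkeeping oracle: random entries equal frame samples
  set.seed(5)
  for (k in 1:20) {
    j <- sample(ncol(Rsub$m), 1)
    iy <- sample(Rsub$row_dims[1], 1); ix <- sample(Rsub$row_dims[2], 1)
    pos <- c(Rsub$lattice$y[iy], Rsub$lattice$x[ix])
    val <- lab$frames[((pos[1] - 1) %% 16) + 1, ((pos[2] - 1) %% 16) + 1,
                      tile$scan_idx[j]]
    expect_equal(Rsub$m[(ix - 1) * Rsub$row_dims[1] + iy, j], val)
  }
})

test_that("pad_to_square inserts zero columns at the unscanned lattice sites", {
  s <- tiny_stack(16, seed = 3)
  lab <- descan_to_lab(s$stack)
  til <- tile_foi(s$stack, 4 * 0.45, margin = 0)
  Rsub <- build_sub_matrix(lab, til$tiles[[1]], fod_px = 8)
  Rsq <- pad_to_square(Rsub)
  expect_equal(nrow(Rsq$m), ncol(Rsq$m))
  expect_equal(frob(Rsq$m), frob(Rsub$m))       # zeros add nothing
  expect_equal(Rsq$m[, Rsq$real_cols], Rsub$m)
  zero_cols <- setdiff(seq_len(ncol(Rsq$m)), Rsq$real_cols)
  expect_true(all(Mod(Rsq$m[, zero_cols]) == 0))
  # N_o < N_i is impossible to square by padding columns
  bad <- Rsub; bad$m <- Rsub$m[1:2, , drop = FALSE]; bad$row_dims <- c(1L, 2L)
  expect_error(pad_to_square(bad), "N_o < N_i")
  # zero columns never contribute to the CLASS spectrum
  Rt <- to_spectral(Rsq)
  sp <- class_spectrum(Rt)
  manual <- Rsq
  manual$m[, zero_cols] <- 0   # already zero; spectrum must be unchanged
  expect_equal(class_spectrum(to_spectral(manual)), sp)
})

test_that("one full-field tile reduces the local solver to the global one", {
  s <- tiny_stack(16, seed = 4, rms = 1.0, modes = 15)
  fit_g <- suppressWarnings(run_class(s$stack, max_iter = 15))
  til <- tile_foi(s$stack, 8 * 0.45, margin = 0)
  fit_l <- suppressWarnings(run_local_class(s$stack, til, max_iter = 15,
                                            mode = "two_sided"))
  expect_equal(length(fit_l$tiles), 1L)
  d <- wrap_phase(fit_l$tiles[[1]]$phi_o$phase - fit_g$phi_o$phase)
  expect_lt(sqrt(mean(d[fit_g$phi_o$mask]^2)), 1e-6)
  expect_equal(fit_l$tiles[[1]]$image, fit_g$image, tolerance = 1e-9)
})

test_that("a globally uniform mild screen yields consistent per-tile maps", {
  # dense diffuse (tissue-like) reflectance isolates the medium property from
  # object structure: every tile sees statistically identical backscatter, so
  # the independently fitted maps must agree
  opt <- optics_config(0.9, 1.0, grid_size = 96)
  obj <- local({
    set.seed(314)
    amp <- pmin(0.5 * sqrt(-log(runif(96^2))), 1)
    structure(matrix(amp * exp(1i * runif(96^2, 0, 2 * pi)), 96, 96),
              class = c("object_map", "matrix"), side_px = 96L)
  })
  phi <- make_pupil_phase(opt, "speckle", list(n_modes = 60, rms = 0.8),
                          seed = 21)
  st <- simulate_scan(obj, phi, mirror_pupil(phi), opt, foi_px = 64)
  til <- tile_foi(st, 16 * 2 * 0.225, margin = 0)   # 2 x 2 tiles, 256 columns
  fit <- suppressWarnings(run_local_class(st, til, max_iter = 40, fod_px = 48))
  expect_equal(length(fit$tiles), 4L)
  maps <- lapply(fit$tiles, function(t) t$phi_o)
  for (a in 1:3) for (b in (a + 1):4) {
    ag <- phase_agreement(maps[[a]], maps[[b]])
    expect_lt(ag$rms_rad, 0.15)
  }
  # every tile map spans the FOD-supported mode count of the plan
  nc_plan <- plan_acquisition(opt, 48 * 0.225, 48 * 0.225, 1)$N_c
  expect_equal(fit$tiles[[1]]$n_modes, nc_plan)
})

test_that("stitching blends tiles into a partition of unity", {
  s <- tiny_stack(16, seed = 6)
  til <- tile_foi(s$stack, 4 * 0.45, margin = 0.9)
  fit <- suppressWarnings(run_local_class(s$stack, til, max_iter = 3,
                                          fod_px = 8))
  # constant tile images stitch to exactly that constant
  for (t in seq_along(fit$tiles))
    fit$tiles[[t]]$image <- matrix(3.25, nrow(fit$tiles[[t]]$image),
                                   ncol(fit$tiles[[t]]$image))
  out <- stitch(fit)
  expect_equal(max(abs(out - 3.25)), 0, tolerance = 1e-12)
  # single tile: identity
  til1 <- tile_foi(s$stack, 8 * 0.45, margin = 0)
  fit1 <- suppressWarnings(run_local_class(s$stack, til1, max_iter = 3,
                                           fod_px = 8))
  expect_equal(stitch(fit1), fit1$tiles[[1]]$image)
})

test_that("isoplanatic search handles the degenerate single candidate", {
  s <- tiny_stack(16, seed = 7)
  expect_warning(est <- estimate_isoplanatic_size(s$stack, 3.6), "single")
  expect_equal(est$side, 3.6)
})
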