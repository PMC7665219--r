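test_that("CLASS spectrum sums anti-diagonals over the unwrapped differences", {
  s <- tiny_stack(16, seed = 7)
  Rt <- to_spectral(square_matrix(assemble_matrix(descan_to_lab(s$stack))))
  n <- nrow(Rt$m)
  # identity matrix: N at zero momentum difference, 0 elsewhere
  Rt_id <- Rt; Rt_id$m <- diag(n) + 0i
  sp <- class_spectrum(Rt_id)
  ctr <- c(Rt$dims[1], Rt$dims[2])
  expect_equal(Mod(sp[ctr[1], ctr[2]]), n)
  sp[ctr[1], ctr[2]] <- 0
  expect_equal(max(Mod(sp)), 0)
  # random small matrix vs double-loop oracle
  set.seed(42)
  Rt_r <- Rt
  Rt_r$m <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  expect_equal(class_spectrum(Rt_r),
               oracle_class_spectrum(Rt_r$m, Rt$dims[1], Rt$dims[2]),
               tolerance = 1e-12)
})

test_that("phase steps vanish for flat pupils and match a brute-force sum", {
  opt <- tiny_optics(16)
  obj <- make_siemens_star(4, 16)
  st <- simulate_scan(obj, flat_pupil(opt), flat_pupil(opt, side = "output"), opt)
  Rt <- to_spectral(square_matrix(assemble_matrix(descan_to_lab(st))))
  expect_lt(max(abs(input_phase_step(Rt)[Rt$mask])), 1e-6)
  expect_lt(max(abs(output_phase_step(Rt)[Rt$mask])), 1e-6)

  # small random matrix: both steps against explicit loops
  s <- tiny_stack(16, seed = 8)
  Rt <- to_spectral(square_matrix(assemble_matrix(descan_to_lab(s$stack))))
  ny <- Rt$dims[1]; nx <- Rt$dims[2]; n <- ny * nx
  sp <- oracle_class_spectrum(Rt$m, ny, nx)
  fy <- c(0:floor((ny - 1) / 2), -ceiling((ny - 1) / 2):-1)
  fx <- c(0:floor((nx - 1) / 2), -ceiling((nx - 1) / 2):-1)
  fyv <- rep(fy, times = nx); fxv <- rep(fx, each = ny)
  phi_i_direct <- numeric(n); phi_o_direct <- numeric(n)
  for (j in seq_len(n)) {
    zc <- 0i; zr <- 0i
    for (i in seq_len(n)) {
      dsel <- c(fyv[i] - fyv[j] + ny, fxv[i] - fxv[j] + nx)
      zc <- zc + Conj(Rt$m[i, j]) * sp[dsel[1], dsel[2]]
      dsel_r <- c(fyv[j] - fyv[i] + ny, fxv[j] - fxv[i] + nx)
      zr <- zr + Conj(Rt$m[j, i]) * sp[dsel_r[1], dsel_r[2]]
    }
    phi_i_direct[j] <- Arg(zc)
    phi_o_direct[j] <- Arg(zr)
  }
  phi_i_direct[!Rt$mask] <- 0
  phi_o_direct[!Rt$mask] <- 0
  expect_equal(as.vector(input_phase_step(Rt)), phi_i_direct, tolerance = 1e-10)
  expect_equal(as.vector(output_phase_step(Rt)), phi_o_direct, tolerance = 1e-10)
})

test_that("injected input tilt is estimated with the correction sign", {
  opt <- tiny_optics(32)
  obj <- make_siemens_star(8, 32)
  ramp <- make_pupil_phase(opt, "zernike", list(coefficients = c(0, 1.2)))
  st <- simulate_scan(obj, ramp, flat_pupil(opt, side = "output"), opt)
  Rt <- to_spectral(square_matrix(assemble_matrix(descan_to_lab(st))))
  p1 <- input_phase_step(Rt)
  truth <- sample_pupil(ramp, Rt$ky, Rt$kx)
  expect_gt(stats::cor(p1[Rt$mask], -truth[Rt$mask]), 0.99)
})

test_that("apply_step is a pure phase correction", {
  s <- tiny_stack(16, seed = 9)
  Rt <- to_spectral(square_matrix(assemble_matrix(descan_to_lab(s$stack))))
  n <- prod(Rt$dims)
  expect_equal(apply_step(Rt, matrix(0, Rt$dims[1], Rt$dims[2]),
                          matrix(0, Rt$dims[1], Rt$dims[2]))$m, Rt$m)
  set.seed(1)
  p_i <- matrix(runif(n, -pi, pi), Rt$dims[1], Rt$dims[2])
  p_o <- matrix(runif(n, -pi, pi), Rt$dims[1], Rt$dims[2])
  stepped <- apply_step(Rt, p_i, p_o)
  expect_equal(Mod(stepped$m), Mod(Rt$m), tolerance = 1e-12)
  # two sequential steps equal one step with summed phases
  q_i <- matrix(runif(n, -pi, pi), Rt$dims[1], Rt$dims[2])
  q_o <- matrix(runif(n, -pi, pi), Rt$dims[1], Rt$dims[2])
  two <- apply_step(stepped, q_i, q_o)
  one <- apply_step(Rt, p_i + q_i, p_o + q_o)
  expect_lt(frob(two$m - one$m) / frob(one$m), 1e-12)
})

test_that("flat-pupil data converge immediately with CLASS = OCM", {
  opt <- tiny_optics(32)
  obj <- make_siemens_star(8, 32)
  st <- simulate_scan(obj, flat_pupil(opt), flat_pupil(opt, side = "output"), opt)
  fit <- run_class(st)
  expect_true(fit$converged)
  expect_equal(fit$iterations, 1L)
  expect_lt(max(abs(fit$phi_i$phase)), 1e-6)
  expect_lt(max(abs(fit$image - fit$ocm)) / max(fit$ocm), 1e-6)
})

test_that("CLASS recovers injected speckle screens on a small instance", {
  opt <- tiny_optics(32)
  obj <- make_siemens_star(8, 32)
  pi_ <- make_pupil_phase(opt, "speckle", list(n_modes = 40, rms = 1.2), seed = 1)
  po_ <- make_pupil_phase(opt, "speckle", list(n_modes = 40, rms = 1.2), seed = 2,
                          side = "output")
  st <- simulate_scan(obj, pi_, po_, opt)
  fit <- suppressWarnings(run_class(st, max_iter = 80))
  ti <- sample_pupil(pi_, fit$spectral$ky, fit$spectral$kx)
  to <- sample_pupil(po_, fit$spectral$ky, fit$spectral$kx)
  agi <- phase_agreement(fit$phi_i$phase, ti, fit$spectral$mask)
  ago <- phase_agreement(fit$phi_o$phase, to, fit$spectral$mask)
  expect_gt(agi$pearson, 0.85)
  expect_gt(ago$pearson, 0.85)
  expect_gt(agi$strehl_resid, 0.85)
  # phase-only correction: per-entry modulus of the matrix unchanged
  expect_equal(Mod(fit$spectral_corrected$m), Mod(fit$spectral$m),
               tolerance = 1e-10)
  # confocal gain consistent with the injected round-trip Strehl
  cons <- enhancement_consistency(fit, pi_, po_)
  expect_lt(abs(cons$ratio - 1), 0.3)
})

test_that("the confocal objective is non-decreasing over iterations", {
  for (i in 1:12) {
    s <- tiny_stack(16, seed = 20 + i, ssmr = if (i %% 2) Inf else 0.3,
                    rms = 0.8 + 0.08 * i, modes = 12 + i)
    fit <- suppressWarnings(run_class(s$stack, max_iter = 6))
    objs <- c(fit$log$objective, fit$objective)
    expect_gte(min(diff(objs)), -1e-9 * max(objs))
  }
})

test_that("retrieved maps are reported wrapped, piston-free, masked", {
  s <- tiny_stack(16, seed = 33)
  fit <- suppressWarnings(run_class(s$stack, max_iter = 30))
  p <- fit$phi_i$phase
  expect_true(all(p > -pi - 1e-12 & p <= pi + 1e-12))
  expect_lt(abs(Arg(mean(exp(1i * p[fit$phi_i$mask])))), 1e-6)
  expect_true(all(p[!fit$phi_i$mask] == 0))
})

test_that("class_fit methods expose images, coefficients and residuals", {
  s <- tiny_stack(16, seed = 12)
  fit <- suppressWarnings(run_class(s$stack, max_iter = 20))
  expect_identical(fitted(fit), fit$image)
  expect_identical(class_image(fit), fit$image)
  cf <- coef(fit)
  expect_named(cf, c("phi_i", "phi_o"))
  r <- residuals(fit)
  expect_equal(dim(r), unname(s$stack$scan_dims))
  expect_true(all(r >= -1e-12))
  out <- capture.output({ print(fit); print(summary(fit)) })
  expect_true(any(grepl("CLASS", out)))
})
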