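# Brute-force oracles and small shared builders, independent of the package's
# FFT-based implementation paths.

# Direct triple-sum evaluation of the double-pass forward model on the
# periodic grid: E_lab(r_o; r_i) = sum_r p_o(r_o - r) O(r) p_i(r - r_i).
oracle_scan <- function(object, phi_i, phi_o, scan_px, fod_px) {
  n <- nrow(object)
  a_i <- phi_i$mask * exp(1i * phi_i$phase)
  a_o <- phi_o$mask * exp(1i * phi_o$phase)
  # direct inverse DFT for the PSF kernels (double loop in k)
  kern <- function(a) {
    p <- matrix(0i, n, n)
    for (iy in 0:(n - 1)) for (ix in 0:(n - 1)) {
      ph <- outer(0:(n - 1) * iy, rep(1, n)) + outer(rep(1, n), 0:(n - 1) * ix)
      p <- p + a[iy + 1, ix + 1] * exp(2i * pi * ph / n)
    }
    p / n^2
  }
  p_i <- kern(a_i); p_o <- kern(a_o)
  cc <- floor(fod_px / 2) + 1
  out <- array(0i, dim = c(fod_px, fod_px, nrow(scan_px)))
  idx <- function(v) ((v - 1) %% n) + 1
  for (s in seq_len(nrow(scan_px))) {
    y_i <- scan_px[s, 1]; x_i <- scan_px[s, 2]
    p_i_s <- p_i[idx((1:n) - y_i + 1), idx((1:n) - x_i + 1)]  # p_i(r - r_i)
    for (oy in seq_len(fod_px)) for (ox in seq_len(fod_px)) {
      r_o <- c(y_i + oy - cc, x_i + ox - cc)     # lab position of this pixel
      p_o_ro <- p_o[idx(r_o[1] - (1:n) + 1), idx(r_o[2] - (1:n) + 1)]
      out[oy, ox, s] <- sum(p_o_ro * object * p_i_s)
    }
  }
  out
}

# Explicit DFT-matrix product for the basis change R~ = F R F^-1.
oracle_spectral <- function(m, ny, nx) {
  n <- ny * nx
  w1 <- function(nn) exp(-2i * pi * outer(0:(nn - 1), 0:(nn - 1)) / nn) / sqrt(nn)
  f2 <- kronecker(w1(nx), w1(ny))   # column-major flattening, y fastest
  f2 %*% m %*% Conj(t(f2))
}

# Double-loop CLASS spectrum over the unwrapped difference set.
oracle_class_spectrum <- function(m, ny, nx) {
  fy <- c(0:floor((ny - 1) / 2), -ceiling((ny - 1) / 2):-1)
  fx <- c(0:floor((nx - 1) / 2), -ceiling((nx - 1) / 2):-1)
  fyv <- rep(fy, times = nx); fxv <- rep(fx, each = ny)
  s <- matrix(0i, 2 * ny - 1, 2 * nx - 1)
  for (i in seq_len(ny * nx)) for (j in seq_len(ny * nx)) {
    dy <- fyv[i] - fyv[j]; dx <- fxv[i] - fxv[j]
    s[dy + ny, dx + nx] <- s[dy + ny, dx + nx] + m[i, j]
  }
  s
}

tiny_optics <- function(n = 16) optics_config(0.9, 1.0, grid_size = n)

tiny_stack <- function(n = 16, seed = 1, ssmr = Inf, rms = 1.2, modes = 20) {
  opt <- tiny_optics(n)
  obj <- make_point_scatterers(5, n, 3, seed = seed)
  pi_ <- make_pupil_phase(opt, "speckle", list(n_modes = modes, rms = rms),
                          seed = 100 + seed)
  po_ <- make_pupil_phase(opt, "speckle", list(n_modes = modes, rms = rms),
                          seed = 200 + seed, side = "output")
  list(opt = opt, obj = obj, phi_i = pi_, phi_o = po_,
       stack = simulate_scan(obj, pi_, po_, opt, ssmr = ssmr, seed = seed))
}

frob <- function(m) sqrt(sum(Mod(m)^2))
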