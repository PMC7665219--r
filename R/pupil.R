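#' Pupil aberration phase screens
#'
#' A `pupil_phase` is an angle-dependent phase retardation \eqn{\phi(k)}
#' sampled on a transverse-wavevector grid and supported on the NA disk
#' \eqn{|k| < k_{NA} = 2\pi\alpha/\lambda}. Separate screens describe the
#' illumination (input) and detection (output) pupils. Matrices are stored in
#' FFT (wrap-around) order with the zero-frequency mode at element `[1, 1]`;
#' use [fft_shift()] style re-centering only for display.
#'
#' Two generative models are provided:
#' \describe{
#'   \item{`zernike`}{a sum of Noll-indexed Zernike polynomials over the NA
#'     disk, `params$coefficients` being a numeric vector of coefficients in
#'     radians indexed by Noll `j` (element 1 = piston, 4 = defocus, ...).}
#'   \item{`speckle`}{a bandlimited Gaussian random screen whose correlation
#'     length over the pupil plane sets the effective number of independent
#'     aberration modes; this emulates the speckle-like pupil maps produced by
#'     strongly heterogeneous layers such as bone. Supply either
#'     `params$corr_length` (rad/um) or `params$n_modes` (the target mode
#'     count, converted as \eqn{\ell = 2 k_{NA}/\sqrt{N}}); `params$rms` sets
#'     the RMS phase in radians inside the mask (default 2).}
#' }
#'
#' @param optics an [optics_config()].
#' @param model `"zernike"` or `"speckle"`.
#' @param params list of model parameters, see Details.
#' @param seed integer seed making the speckle screen reproducible
#'   (bit-identical screens for identical seeds); ignored for `zernike`.
#' @param side `"input"` or `"output"`; a label carried for bookkeeping.
#' @param n grid side in pixels (default: the optics grid size).
#' @param pitch sample-plane pitch defining the k-grid spacing
#'   \eqn{\delta k = 2\pi/(n \cdot pitch)} (default: the optics pixel pitch).
#' @return object of class `pupil_phase`: fields `phase` (n x n matrix,
#'   radians, wrapped to (-pi, pi], zero outside the mask), `mask` (logical NA
#'   disk), `ky`, `kx` (rad/um, FFT order), `dk`, `k_na`, `side`, `optics`.
#' @examples
#' opt <- optics_config(0.9, 1.0, grid_size = 32)
#' p <- make_pupil_phase(opt, "zernike", list(coefficients = c(0, 0, 0, 1)))
#' sp <- make_pupil_phase(opt, "speckle", list(n_modes = 100, rms = 1.5),
#'                        seed = 1)
#' @export
make_pupil_phase <- function(optics, model = c("zernike", "speckle"),
                             params = list(), seed = NULL,
                             side = c("input", "output"),
                             n = optics$grid_size, pitch = optics$pixel_pitch) {
  stopifnot(inherits(optics, "optics_config"))
  model <- match.arg(model)
  side <- match.arg(side)
  kg <- k_grid(n, n, pitch)
  k_na <- k_cutoff(optics)
  kr <- sqrt(kg$kyy^2 + kg$kxx^2)
  mask <- kr < k_na * (1 - 1e-12)

  phase <- matrix(0, n, n)
  if (model == "zernike") {
    co <- params$coefficients
    if (!is.null(co) && length(co) > 0) {
      rho <- kr / k_na
      theta <- atan2(kg$kyy, kg$kxx)
      for (j in seq_along(co)) {
        if (co[j] != 0) phase <- phase + co[j] * zernike_noll(j, rho, theta)
      }
    }
  } else {
    dk <- 2 * pi / (n * pitch)
    ell <- params$corr_length
    if (is.null(ell)) {
      if (is.null(params$n_modes))
        stop_invalid("speckle model needs params$corr_length or params$n_modes")
      ell <- 2 * k_na / sqrt(params$n_modes)
    }
    if (!is.numeric(ell) || ell <= 0)
      stop_invalid("speckle correlation length must be positive")
    if (ell <= dk)
      warning("speckle correlation length at or below the k-grid spacing; ",
              "the screen is unresolved on this grid")
    rms <- if (is.null(params$rms)) 2 else params$rms
    phase <- with_seed(seed, speckle_screen(n, dk, ell, rms, mask))
    # zero circular mean on the mask (exact even after wrapping)
    phase <- phase - circ_mean(phase[mask])
  }
  phase[!mask] <- 0
  new_pupil_phase(wrap_phase(phase), mask, kg$ky, kg$kx, k_na, side, optics)
}

new_pupil_phase <- function(phase, mask, ky, kx, k_na, side, optics) {
  phase[!mask] <- 0
  structure(list(phase = phase, mask = mask, ky = ky, kx = kx,
                 dk = c(ky[2] - ky[1], kx[2] - kx[1]), k_na = k_na,
                 side = side, optics = optics),
            class = "pupil_phase")
}

#' Flat (aberration-free) pupil
#'
#' @inheritParams make_pupil_phase
#' @param ... passed to [make_pupil_phase()].
#' @return a `pupil_phase` with zero phase on the NA disk.
#' @export
flat_pupil <- function(optics, side = "input", ...) {
  make_pupil_phase(optics, "zernike", list(), side = side, ...)
}

# Gaussian-correlated random screen over the pupil plane: white noise smoothed
# by a Gaussian kernel of FWHM = ell (in rad/um), then standardised on mask.
speckle_screen <- function(n, dk, ell, rms, mask) {
  w <- matrix(stats::rnorm(n * n), n, n)
  sigma_px <- (ell / dk) / (2 * sqrt(2 * log(2)))   # FWHM -> sd, in k-pixels
  f <- fft_freq(n)                                  # cycles per pixel
  fyy <- matrix(f, n, n); fxx <- matrix(f, n, n, byrow = TRUE)
  transfer <- exp(-2 * pi^2 * sigma_px^2 * (fyy^2 + fxx^2))
  s <- Re(stats::fft(stats::fft(w) * transfer, inverse = TRUE)) / (n * n)
  v <- s[mask]
  s <- (s - mean(v)) / stats::sd(v) * rms
  s
}

# Noll-indexed Zernike polynomial Z_j on (rho, theta); Noll normalisation
# (unit RMS over the continuous unit disk).
zernike_noll <- function(j, rho, theta) {
  if (j < 1) stop_invalid("Noll index must be >= 1")
  nm <- noll_to_nm(j)
  n <- nm[1]; m <- nm[2]; am <- abs(m)
  r <- matrix(0, nrow(rho), ncol(rho))
  for (s in 0:((n - am) / 2)) {
    r <- r + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + am) / 2 - s) *
         factorial((n - am) / 2 - s)) * rho^(n - 2 * s)
  }
  norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  if (m > 0) norm * r * cos(am * theta)
  else if (m < 0) norm * r * sin(am * theta)
  else norm * r
}

noll_to_nm <- function(j) {
  n <- 0; j1 <- j - 1
  while (j1 > n) { n <- n + 1; j1 <- j1 - n }
  m <- (-1)^j * ((n %% 2) + 2 * floor((j1 + ((n + 1) %% 2)) / 2))
  c(n, m)
}

#' Mirror a pupil screen through the pupil centre
#'
#' Returns the screen \eqn{\phi(-k)} with the opposite side label. Under
#' optical reciprocity (detection kernel = transpose of the illumination
#' kernel) the output pupil is the mirrored input pupil, so
#' `mirror_pupil(phi_i)` is the reciprocity-consistent detection screen; the
#' locally varying solver's reciprocity mode assumes exactly this relation.
#'
#' @param pupil a `pupil_phase`.
#' @return a `pupil_phase` with mirrored phase (and mask), opposite side.
#' @export
mirror_pupil <- function(pupil) {
  stopifnot(inherits(pupil, "pupil_phase"))
  n <- nrow(pupil$phase)
  idx <- c(1L, n:2L)               # index of -k on the FFT-ordered grid
  out <- pupil
  out$phase <- pupil$phase[idx, idx]
  out$mask <- pupil$mask[idx, idx]
  out$phase[!out$mask] <- 0
  out$side <- if (pupil$side == "input") "output" else "input"
  out
}

#' Point-spread function of a pupil
#'
#' Centered inverse discrete Fourier transform of the complex pupil function
#' \eqn{\exp(i\phi(k))} on the NA disk, normalised so that the flat-phase PSF
#' has unit peak amplitude. The intensity FWHM of the flat-phase PSF equals
#' the diffraction limit \eqn{\delta_d} to within one pixel.
#'
#' @param pupil a [make_pupil_phase()] object.
#' @return complex matrix (same side as the pupil grid) with the zero-shift
#'   pixel at `floor(n/2)+1`; attributes `pitch` (um/pixel) and `optics`.
#' @export
psf_from_pupil <- function(pupil) {
  stopifnot(inherits(pupil, "pupil_phase"))
  a <- pupil$mask * exp(1i * pupil$phase)
  psf <- stats::fft(a, inverse = TRUE) / sum(pupil$mask)
  psf <- fft_shift(psf)
  n <- nrow(a)
  structure(psf, pitch = 2 * pi / (n * pupil$dk[1]), optics = pupil$optics)
}

#' @export
print.pupil_phase <- function(x, ...) {
  v <- x$phase[x$mask]
  cat("Pupil phase screen (", x$side, "): ", nrow(x$phase), "x",
      ncol(x$phase), " k-grid, ", sum(x$mask), " modes in NA disk\n", sep = "")
  cat("  dk =", signif(x$dk[1], 4), "rad/um, k_NA =", signif(x$k_na, 4),
      "rad/um, RMS =", signif(stats::sd(v), 3), "rad\n")
  invisible(x)
}

#' @export
plot.pupil_phase <- function(x, main = paste("pupil phase,", x$side), ...) {
  img <- fft_shift(x$phase * ifelse(x$mask, 1, NA))
  graphics::image(t(img)[, rev(seq_len(nrow(img)))], asp = 1, axes = FALSE,
                  col = grDevices::hcl.colors(64, "Spectral"), main = main, ...)
  invisible(x)
}
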