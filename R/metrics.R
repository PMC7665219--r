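# Quantitative evaluation: PSF statistics, Strehl ratios, phase-map
# agreement and signal-to-multiple-scattering ratios.

#' Strehl ratio of a pupil phase screen
#'
#' \eqn{S = |\langle e^{i\phi} \rangle|^2} averaged over the NA mask: the
#' peak-intensity ratio of the aberrated to the ideal PSF for a phase-only
#' pupil. `S = 1` iff the phase is constant on the mask.
#'
#' @param phi phase matrix (radians) or a `pupil_phase`.
#' @param mask logical mask (defaults to the pupil's NA mask).
#' @return Strehl ratio in `[0, 1]`.
#' @export
strehl_ratio <- function(phi, mask = NULL) {
  if (inherits(phi, "pupil_phase")) {
    if (is.null(mask)) mask <- phi$mask
    phi <- phi$phase
  }
  if (is.null(mask)) mask <- !is.na(phi)
  Mod(mean(exp(1i * phi[mask])))^2
}

#' PSF quality report
#'
#' Measures the peak intensity, Strehl ratio (peak relative to the
#' flat-pupil PSF simulated on the same grid, cancelling discretisation),
#' the intensity FWHM along a horizontal line through the peak (half-maximum
#' crossings located by linear interpolation) and the radius enclosing half
#' the total energy. Multi-lobed (speckled) PSFs are reported with
#' `multi_lobe = TRUE` and the FWHM refers to the dominant lobe.
#'
#' @param field complex or real 2-D field (e.g. from [psf_from_pupil()]);
#'   intensity is `Mod(field)^2`.
#' @param optics an [optics_config()].
#' @param pitch pixel pitch of `field` in um (default: attribute of `field`,
#'   else the optics pitch).
#' @return object of class `psf_report`: `peak`, `strehl`, `fwhm_um`,
#'   `ee50_radius_um`, `multi_lobe`.
#' @export
psf_report <- function(field, optics, pitch = NULL) {
  stopifnot(inherits(optics, "optics_config"))
  if (is.null(pitch)) pitch <- attr(field, "pitch")
  if (is.null(pitch)) pitch <- optics$pixel_pitch
  inten <- Mod(field)^2
  n <- nrow(inten)
  pk <- which(inten == max(inten), arr.ind = TRUE)[1, ]
  # reference: flat pupil on an identical grid (cancels discretisation)
  flat <- psf_from_pupil(flat_pupil(optics, n = n, pitch = pitch))
  strehl <- max(inten) / max(Mod(flat)^2)
  prof <- inten[pk[1], ]
  fwhm <- fwhm_interp(prof, pk[2]) * pitch
  # encircled energy
  yy <- matrix(seq_len(n) - pk[1], n, n)
  xx <- matrix(seq_len(n) - pk[2], n, n, byrow = TRUE)
  r <- sqrt(yy^2 + xx^2) * pitch
  o <- order(r)
  cum <- cumsum(inten[o]) / sum(inten)
  ee50 <- r[o][which(cum >= 0.5)[1]]
  # multi-lobe flag: a secondary local maximum above half the peak
  half <- inten > 0.5 * max(inten)
  multi <- count_components(half) > 1
  structure(list(peak = max(inten), strehl = strehl, fwhm_um = fwhm,
                 ee50_radius_um = ee50, multi_lobe = multi),
            class = "psf_report")
}

#' @export
print.psf_report <- function(x, ...) {
  cat("PSF report: peak ", signif(x$peak, 4), ", Strehl ",
      signif(x$strehl, 4), ", FWHM ", signif(x$fwhm_um, 4), " um, EE50 ",
      signif(x$ee50_radius_um, 4), " um",
      if (x$multi_lobe) " [multi-lobed]" else "", "\n", sep = "")
  invisible(x)
}

# FWHM of a 1-D profile around peak index, linear interpolation of the
# half-max crossings nearest the peak.
fwhm_interp <- function(prof, ipk) {
  h <- prof[ipk] / 2
  left <- NA_real_
  for (i in seq(ipk, 2)) {
    if (prof[i - 1] <= h) {
      left <- (i - 1) + (h - prof[i - 1]) / (prof[i] - prof[i - 1])
      break
    }
  }
  right <- NA_real_
  for (i in seq(ipk, length(prof) - 1)) {
    if (prof[i + 1] <= h) {
      right <- i + (prof[i] - h) / (prof[i] - prof[i + 1])
      break
    }
  }
  right - left
}

# 4-connected component count of a logical matrix (tiny flood fill).
count_components <- function(b) {
  lab <- matrix(0L, nrow(b), ncol(b))
  nc <- 0L
  for (j in seq_len(ncol(b))) for (i in seq_len(nrow(b))) {
    if (b[i, j] && lab[i, j] == 0L) {
      nc <- nc + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[2] < 1 || p[1] > nrow(b) || p[2] > ncol(b)) next
        if (!b[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- nc
        stack <- c(stack, list(p + c(1, 0)), list(p - c(1, 0)),
                   list(p + c(0, 1)), list(p - c(0, 1)))
      }
    }
  }
  nc
}

#' Agreement between two pupil phase maps
#'
#' Compares two phase screens modulo the intrinsic degeneracies of
#' reflection-matrix phase retrieval: piston (a global phase offset) and
#' linear tilt (a global image shift) are removed from the wrapped
#' difference before statistics. The tilt is estimated by locating the peak
#' of the inverse transform of `exp(i * difference)` (the cross-PSF shift)
#' and refined by local optimisation; RMS is circular-aware.
#'
#' @param phi_a,phi_b phase matrices (radians) or `pupil_phase` objects on a
#'   common grid.
#' @param mask logical mask (default: NA disk of the inputs).
#' @return list with `rms_rad` (circular RMS of the aligned difference),
#'   `pearson` (masked correlation after alignment, computed on
#'   sine-transformed circularly centred values so it is continuous through
#'   the +-pi branch), `strehl_resid` (Strehl ratio of the aligned residual:
#'   how well a correction with `phi_b` would undo `phi_a`), `tilt` (cycles
#'   per grid), `piston` (rad).
#' @export
phase_agreement <- function(phi_a, phi_b, mask = NULL) {
  if (inherits(phi_a, "pupil_phase")) { if (is.null(mask)) mask <- phi_a$mask; phi_a <- phi_a$phase }
  if (inherits(phi_b, "pupil_phase")) { if (is.null(mask)) mask <- phi_b$mask; phi_b <- phi_b$phase }
  stopifnot(all(dim(phi_a) == dim(phi_b)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(phi_a), ncol(phi_a))
  ny <- nrow(phi_a); nx <- ncol(phi_a)
  z <- mask * exp(1i * (phi_a - phi_b))
  # integer-pixel tilt from the correlation peak
  c_map <- stats::fft(z, inverse = TRUE)
  pk <- which(Mod(c_map) == max(Mod(c_map)), arr.ind = TRUE)[1, ]
  # peak at frequency f means the difference carries tilt -f
  ty0 <- -fft_freq(ny)[pk[1]] * ny   # integer cycles across the grid
  tx0 <- -fft_freq(nx)[pk[2]] * nx
  yy <- matrix(seq_len(ny) - 1, ny, nx)
  xx <- matrix(seq_len(nx) - 1, ny, nx, byrow = TRUE)
  score <- function(t) {
    ramp <- 2 * pi * (t[1] * yy / ny + t[2] * xx / nx)
    -Mod(sum(z * exp(-1i * ramp)))
  }
  opt <- stats::optim(c(ty0, tx0), score, method = "Nelder-Mead",
                      control = list(reltol = 1e-10))
  t_hat <- opt$par
  ramp <- 2 * pi * (t_hat[1] * yy / ny + t_hat[2] * xx / nx)
  d <- wrap_phase(phi_a - phi_b - ramp)
  piston <- circ_mean(d[mask])
  d <- wrap_phase(d - piston)
  # circular-aware correlation: Pearson on the sine-transformed, circularly
  # centred values (continuous through +-pi, ~Pearson for mild phases,
  # ~0 for independent screens)
  b_adj <- phi_b + ramp + piston        # phi_b aligned onto phi_a
  sa <- sin(phi_a[mask] - circ_mean(phi_a[mask]))
  sb <- sin(b_adj[mask] - circ_mean(b_adj[mask]))
  list(rms_rad = sqrt(mean(d[mask]^2)),
       pearson = stats::cor(sa, sb),
       strehl_resid = Mod(mean(exp(1i * d[mask])))^2,
       tilt = t_hat, piston = piston)
}

#' Estimate the single-to-multiple-scattering intensity ratio
#'
#' For synthetic stacks carrying ground truth, the realised ratio of the
#' mean confocal signal intensity to the mean multiple-scattering (noise)
#' intensity. Noise-free stacks return `Inf` with a message attribute.
#'
#' @param stack a `field_stack` produced by [simulate_scan()].
#' @return the realised ratio (scalar); `Inf` for noise-free data.
#' @export
ssmr_estimate <- function(stack) {
  stopifnot(inherits(stack, "field_stack"))
  tr <- stack$truth
  if (is.null(tr)) stop_invalid("ssmr_estimate() needs a stack with /truth")
  if (tr$mean_noise_intensity == 0) {
    out <- Inf
    attr(out, "note") <- "noise-free stack"
    return(out)
  }
  mean(Mod(tr$signal_confocal)^2) / tr$mean_noise_intensity
}

#' Confocal enhancement consistency check
#'
#' On synthetic data the intensity gain of the corrected confocal image over
#' the uncorrected one should approximate the inverse round-trip Strehl of
#' the injected aberrations, \eqn{1/(S_i S_o)}; this ties the measured image
#' enhancement to the injected pupil screens.
#'
#' @param fit a `class_fit`.
#' @param phi_i_true,phi_o_true injected `pupil_phase` screens (fine grid).
#' @return list with `enhancement` (measured mean confocal intensity ratio),
#'   `inverse_strehl` (predicted), `ratio` (measured / predicted).
#' @export
enhancement_consistency <- function(fit, phi_i_true, phi_o_true) {
  stopifnot(inherits(fit, "class_fit"))
  tm_i <- sample_pupil(phi_i_true, fit$spectral$ky, fit$spectral$kx)
  tm_o <- sample_pupil(phi_o_true, fit$spectral$ky, fit$spectral$kx)
  msk <- fit$spectral$mask
  s_round <- strehl_ratio(tm_i, msk) * strehl_ratio(tm_o, msk)
  enh <- sum(fit$image) / sum(fit$ocm)
  list(enhancement = enh, inverse_strehl = 1 / s_round,
       ratio = enh * s_round)
}
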