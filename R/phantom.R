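#' Test phantoms: Siemens star and filament fields
#'
#' `make_siemens_star()` builds the classical resolution target of alternating
#' binary-amplitude sectors; `make_filaments()` draws smooth random curves of
#' fixed width, a phantom for myelinated-fibre-like structures. Both return an
#' `object_map`: a complex amplitude reflectance \eqn{O(r)} with
#' \eqn{|O(r)| \le 1} on the sample-plane grid.
#'
#' @param n_spokes even number (>= 2) of alternating bright/dark sectors.
#' @param side_px pixels per side of the object grid.
#' @param radius_frac star radius as a fraction of the half-side.
#' @return an `object_map`: complex `side_px` x `side_px` matrix with
#'   attribute `side_px`.
#' @examples
#' star <- make_siemens_star(16, 64)
#' fil <- make_filaments(n = 4, width_px = 2, side_px = 64, seed = 7)
#' @export
make_siemens_star <- function(n_spokes = 16, side_px = 64, radius_frac = 0.95) {
  n_spokes <- as.integer(n_spokes)
  if (is.na(n_spokes) || n_spokes < 2 || n_spokes %% 2 != 0)
    stop_invalid("n_spokes must be an even integer >= 2")
  n <- as.integer(side_px)
  c0 <- (n + 1) / 2
  y <- matrix(seq_len(n) - c0, n, n)
  x <- t(y)
  theta <- atan2(y, x)
  r <- sqrt(x^2 + y^2)
  sector <- floor((theta + pi) / (2 * pi / n_spokes)) %% 2
  amp <- ifelse(sector == 0 & r <= radius_frac * n / 2, 1, 0)
  new_object_map(amp + 0i)
}

#' @rdname make_siemens_star
#' @param n number of filaments.
#' @param width_px filament width (Gaussian FWHM) in pixels.
#' @param seed integer seed; identical seeds give identical phantoms.
#' @export
make_filaments <- function(n = 6, width_px = 2, side_px = 64, seed = NULL) {
  ns <- as.integer(side_px)
  if (n < 1 || width_px <= 0) stop_invalid("need n >= 1 and width_px > 0")
  amp <- with_seed(seed, {
    a <- matrix(0, ns, ns)
    for (f in seq_len(n)) {
      # smooth random curve: random endpoint pair plus low-order sinusoidal wiggle
      t <- seq(0, 1, length.out = 4 * ns)
      p0 <- stats::runif(2, 0.1, 0.9) * ns
      p1 <- stats::runif(2, 0.1, 0.9) * ns
      nrm <- c(-(p1[2] - p0[2]), p1[1] - p0[1])
      nrm <- nrm / max(sqrt(sum(nrm^2)), 1e-9)
      amp_w <- stats::runif(1, 0.02, 0.12) * ns
      ph <- stats::runif(2, 0, 2 * pi)
      wig <- amp_w * (sin(2 * pi * t + ph[1]) + 0.5 * sin(4 * pi * t + ph[2]))
      cy <- p0[2] + t * (p1[2] - p0[2]) + nrm[2] * wig
      cx <- p0[1] + t * (p1[1] - p0[1]) + nrm[1] * wig
      iy <- round(cy); ix <- round(cx)
      ok <- iy >= 1 & iy <= ns & ix >= 1 & ix <= ns
      a[cbind(iy[ok], ix[ok])] <- 1
    }
    # dilate to the requested width with a Gaussian brush, then clip
    sd_px <- width_px / (2 * sqrt(2 * log(2)))
    f <- fft_freq(ns)
    fyy <- matrix(f, ns, ns); fxx <- matrix(f, ns, ns, byrow = TRUE)
    transfer <- exp(-2 * pi^2 * sd_px^2 * (fyy^2 + fxx^2))
    sm <- Re(stats::fft(stats::fft(a) * transfer, inverse = TRUE)) / (ns * ns)
    sm <- sm / max(sm, 1e-12)
    pmin(pmax(sm, 0), 1)
  })
  new_object_map(amp + 0i)
}

#' Sparse point-scatterer phantom
#'
#' Isolated unit-amplitude point reflectors on an otherwise dark field,
#' separated by at least `min_sep_px`. Useful for PSF and Strehl analyses
#' where the confocal response of each scatterer is an uncontaminated copy of
#' the system PSF.
#'
#' @param n_points number of scatterers.
#' @param side_px grid side in pixels.
#' @param min_sep_px minimum pairwise separation (pixels).
#' @param seed integer seed.
#' @return an `object_map`.
#' @export
make_point_scatterers <- function(n_points = 12, side_px = 64,
                                  min_sep_px = 8, seed = NULL) {
  ns <- as.integer(side_px)
  amp <- with_seed(seed, {
    a <- matrix(0, ns, ns)
    pts <- matrix(numeric(0), 0, 2)
    guard <- 0
    while (nrow(pts) < n_points && guard < 10000) {
      guard <- guard + 1
      p <- ceiling(stats::runif(2, 0.08, 0.92) * ns)
      if (nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_sep_px) {
        pts <- rbind(pts, p)
        a[p[1], p[2]] <- 1
      }
    }
    a
  })
  new_object_map(amp + 0i)
}

new_object_map <- function(m) {
  if (max(Mod(m)) > 1 + 1e-12)
    stop_invalid("object reflectance must satisfy |O(r)| <= 1")
  structure(m, class = c("object_map", class(m)), side_px = nrow(m))
}

#' @export
print.object_map <- function(x, ...) {
  cat("Object map:", nrow(x), "x", ncol(x), "px, lit fraction",
      signif(mean(Mod(x) > 0.5), 3), "\n")
  invisible(x)
}
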