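#' Simulate a scanned reflection-matrix acquisition
#'
#' Scalar-diffraction forward model of time-gated, focused-illumination
#' imaging through an aberrating layer. For every illumination position `r_i`
#' on the scan lattice the detected laboratory-frame field is the double-pass
#' response
#' \deqn{E_{lab}(r_o; r_i) = \sum_r P_o(r_o - r)\, O(r)\, P_i(r - r_i) + E_M,}
#' evaluated as a periodic convolution on the object grid, where `P_i`, `P_o`
#' are the illumination and detection amplitude PSFs generated from the input
#' and output pupil screens, `O` the complex amplitude reflectance, and `E_M`
#' a time-gated multiple-scattering speckle field, modelled as white circular
#' complex Gaussian noise per pixel and frame. Frames are returned de-scanned
#' (confocal pixel at the frame centre) and cropped to the field of detection.
#'
#' The noise variance is calibrated so that the mean confocal intensity of
#' the signal term divided by the mean noise intensity equals `ssmr`, the
#' single-scattering to multiple-scattering confocal intensity ratio
#' (`ssmr = Inf` disables noise).
#'
#' Spatially varying (anisoplanatic) media are simulated by piecewise-constant
#' pupil screens: `patch_map` assigns one entry of `screens` to every scan
#' position, and each frame is synthesised with its patch's screens, which
#' reproduces exactly the isoplanatic-patch structure assumed by local
#' correction.
#'
#' @param object an `object_map` (complex reflectance, `|O| <= 1`).
#' @param phi_i,phi_o input/output `pupil_phase` screens on the object grid
#'   (ignored when `patch_map` is given).
#' @param optics an [optics_config()]; `optics$grid_size` must match the
#'   object grid and the pixel pitch must divide the scan step exactly.
#' @param scan_step_px scan interval in pixels; the default is the
#'   diffraction limit \eqn{\delta_d} rounded to integer pixels.
#' @param foi_px side of the scanned field of illumination in pixels
#'   (centred on the grid; default: the full grid).
#' @param fod_px side of the recorded field of detection in pixels
#'   (default: the full grid, in which case frames are periodic).
#' @param ssmr target single-to-multiple-scattering confocal intensity
#'   ratio (> 0, `Inf` = noise free).
#' @param seed integer; identical seeds give bit-identical speckle noise.
#' @param patch_map optional integer matrix over the scan grid (dims
#'   `foi_px/scan_step_px` squared) assigning a patch id to each scan position.
#' @param screens optional list of `list(phi_i =, phi_o =)` per patch id.
#' @return a `field_stack`: complex array `frames` of dims
#'   `(fod_px, fod_px, N_s)` in de-scanned coordinates, the scan index maps,
#'   optics metadata and (for synthetic data) a `truth` group holding the
#'   screens, object, calibrated noise variance and realised signal/noise
#'   confocal statistics.
#' @export
simulate_scan <- function(object, phi_i = NULL, phi_o = NULL, optics,
                          scan_step_px = NULL, foi_px = NULL, fod_px = NULL,
                          ssmr = Inf, seed = NULL,
                          patch_map = NULL, screens = NULL) {
  stopifnot(inherits(object, "object_map"), inherits(optics, "optics_config"))
  n <- nrow(object)
  if (n != optics$grid_size)
    stop_invalid("object grid (%d) does not match optics grid_size (%d)",
                 n, optics$grid_size)
  dd <- diffraction_limit(optics)
  if (is.null(scan_step_px)) scan_step_px <- max(1L, as.integer(round(dd / optics$pixel_pitch)))
  scan_step_px <- as.integer(scan_step_px)
  if (abs(scan_step_px * optics$pixel_pitch / dd - 1) > 0.5)
    warning("scan step differs from the diffraction-limited interval by >50%")
  if (is.null(foi_px)) foi_px <- n
  if (is.null(fod_px)) fod_px <- n
  foi_px <- as.integer(foi_px); fod_px <- as.integer(fod_px)
  if (fod_px > n) stop_invalid("fod_px cannot exceed the simulation grid")
  if (foi_px %% scan_step_px != 0)
    stop_invalid("foi_px must be a multiple of the scan step (integer de-scan shifts)")
  nsy <- foi_px %/% scan_step_px
  start <- floor((n - foi_px) / 2) + 1L
  if (start < 1L || start + foi_px - 1L > n)
    stop_invalid("scan grid extends beyond the object support")
  scan_1d <- start + scan_step_px * (seq_len(nsy) - 1L)
  scan_px <- cbind(y = rep(scan_1d, times = nsy),
                   x = rep(scan_1d, each = nsy))

  if (is.null(patch_map)) {
    if (is.null(phi_i) || is.null(phi_o))
      stop_invalid("supply phi_i and phi_o (or patch_map + screens)")
    patch_map <- matrix(1L, nsy, nsy)
    screens <- list(list(phi_i = phi_i, phi_o = phi_o))
  } else {
    patch_map <- matrix(as.integer(patch_map), nsy, nsy)
    if (is.null(screens) || max(patch_map) > length(screens))
      stop_invalid("screens must provide one entry per patch id in patch_map")
  }
  # Per-patch pupil functions: illumination PSF field (zero shift at [1,1])
  # and detection pupil spectrum.
  pre <- lapply(screens, function(sc) {
    stopifnot(inherits(sc$phi_i, "pupil_phase"), inherits(sc$phi_o, "pupil_phase"))
    if (nrow(sc$phi_i$phase) != n || nrow(sc$phi_o$phase) != n)
      stop_invalid("pupil screens must live on the simulation grid")
    a_i <- sc$phi_i$mask * exp(1i * sc$phi_i$phase)
    a_o <- sc$phi_o$mask * exp(1i * sc$phi_o$phase)
    list(p_i = stats::fft(a_i, inverse = TRUE) / (n * n), a_o = a_o)
  })

  cc <- floor(fod_px / 2) + 1L
  crop <- function(m, y, x) {
    d <- circ_shift(m, cc - y, cc - x)           # confocal pixel -> (cc, cc)
    d[seq_len(fod_px), seq_len(fod_px), drop = FALSE]
  }
  ns <- nrow(scan_px)
  frames <- array(0i, dim = c(fod_px, fod_px, ns))
  obj <- unclass(object)
  for (s in seq_len(ns)) {
    y <- scan_px[s, 1]; x <- scan_px[s, 2]
    pp <- pre[[patch_map[((s - 1L) %% nsy) + 1L, ((s - 1L) %/% nsy) + 1L]]]
    illum <- obj * circ_shift(pp$p_i, y - 1L, x - 1L)
    e_lab <- stats::fft(pp$a_o * stats::fft(illum), inverse = TRUE) / (n * n)
    frames[, , s] <- crop(e_lab, y, x)
  }

  sig_conf <- frames[cc, cc, ]
  truth <- list(screens = screens, patch_map = patch_map, object = object,
                signal_confocal = sig_conf, sigma2 = 0,
                mean_noise_intensity = 0)
  if (is.finite(ssmr)) {
    if (ssmr <= 0) stop_invalid("ssmr must be positive (or Inf for noise free)")
    sigma2 <- mean(Mod(sig_conf)^2) / ssmr
    noise <- with_seed(seed, rcnorm(length(frames), sigma2))
    truth$sigma2 <- sigma2
    truth$mean_noise_intensity <- mean(Mod(noise)^2)
    frames <- frames + array(noise, dim = dim(frames))
  }

  structure(list(frames = frames, scan_px = scan_px,
                 scan_dims = c(nsy, nsy), scan_step_px = scan_step_px,
                 frame = "descanned", fod_px = fod_px, foi_px = foi_px,
                 grid_px = n, full_grid = fod_px == n,
                 optics = optics, ssmr = ssmr, seed = seed, truth = truth),
            class = "field_stack")
}

#' @export
print.field_stack <- function(x, ...) {
  cat("Field stack (", x$frame, "): ", nrow(x$scan_px), " scan positions (",
      x$scan_dims[1], " x ", x$scan_dims[2], ", step ", x$scan_step_px,
      " px), frames ", dim(x$frames)[1], " x ", dim(x$frames)[2], " px\n",
      sep = "")
  cat("  grid ", x$grid_px, " px, pitch ", signif(x$optics$pixel_pitch, 4),
      " um, ssmr = ", x$ssmr, "\n", sep = "")
  invisible(x)
}

#' Confocal image directly from a de-scanned stack
#'
#' Intensity of the centre (confocal) pixel of every de-scanned frame,
#' arranged on the scan grid. Equivalent to [ocm_image()] with pinhole
#' radius 0 but without assembling the matrix.
#'
#' @param stack a de-scanned `field_stack`.
#' @return numeric matrix over the scan grid.
#' @export
confocal_image <- function(stack) {
  stopifnot(inherits(stack, "field_stack"), stack$frame == "descanned")
  cc <- floor(stack$fod_px / 2) + 1L
  matrix(Mod(stack$frames[cc, cc, ])^2,
         stack$scan_dims[1], stack$scan_dims[2])
}
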