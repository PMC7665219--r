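#' Optical configuration of the scanning microscope
#'
#' Bundles the physical constants of the simulated instrument: illumination
#' wavelength, objective numerical aperture, sample-plane pixel pitch and the
#' simulation grid size. The diffraction-limited resolution
#' \eqn{\delta_d = \lambda / (2\alpha)} is always recomputed from wavelength
#' and NA, never stored.
#'
#' The default pixel pitch is \eqn{\delta_d / 2} (Nyquist sampling for a field
#' bandlimited by the NA), so the default scan step of one resolution element
#' is an exact integer number of pixels and de-scanning never interpolates.
#'
#' @param wavelength illumination wavelength in micrometres.
#' @param na numerical aperture \eqn{\alpha} of the objective (0, 1.33].
#' @param pixel_pitch sample-plane pixel pitch in micrometres; must divide the
#'   scan step exactly. Default \eqn{\delta_d/2}.
#' @param grid_size pixels per side of the simulation field.
#' @return an object of class `optics_config`.
#' @examples
#' opt <- optics_config(wavelength = 0.9, na = 1.0, grid_size = 64)
#' diffraction_limit(opt)  # 0.45 um
#' @export
optics_config <- function(wavelength, na, pixel_pitch = wavelength / (4 * na),
                          grid_size = 64) {
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop_invalid("wavelength must be a positive length in micrometres")
  if (!is.numeric(na) || na <= 0 || na > 1.33)
    stop_invalid("numerical aperture must lie in (0, 1.33]")
  if (!is.numeric(pixel_pitch) || pixel_pitch <= 0)
    stop_invalid("pixel_pitch must be positive")
  grid_size <- as.integer(grid_size)
  if (is.na(grid_size) || grid_size < 4)
    stop_invalid("grid_size must be an integer >= 4")
  structure(list(wavelength = wavelength, na = na,
                 pixel_pitch = pixel_pitch, grid_size = grid_size),
            class = "optics_config")
}

#' Diffraction-limited resolution
#'
#' @param optics an [optics_config()].
#' @return \eqn{\delta_d = \lambda/(2\alpha)} in micrometres.
#' @export
diffraction_limit <- function(optics) {
  stopifnot(inherits(optics, "optics_config"))
  optics$wavelength / (2 * optics$na)
}

# NA cutoff spatial frequency k_NA = 2*pi*alpha/lambda (rad/um).
k_cutoff <- function(optics) 2 * pi * optics$na / optics$wavelength

#' @export
print.optics_config <- function(x, ...) {
  cat("Optics: lambda =", x$wavelength, "um, NA =", x$na,
      ", pitch =", signif(x$pixel_pitch, 4), "um, grid",
      x$grid_size, "x", x$grid_size, "px\n")
  cat("  diffraction limit delta_d =", signif(diffraction_limit(x), 4), "um\n")
  invisible(x)
}

#' Analytic acquisition planner
#'
#' Closed-form planning of a reflection-matrix acquisition. For a camera whose
#' frame rate scales inversely with the field-of-detection side,
#' \eqn{f_{cam} = r/\sqrt{FOD}}, the planner reports the number of pupil
#' correction modes supported by the FOD,
#' \eqn{N_c = \pi(\sqrt{FOD} / 2\delta_d)^2}, the number of scan positions
#' needed to cover the field of illumination at the diffraction-limited
#' scan interval, \eqn{N_s = FOI/\delta_d^2}, and the total acquisition time
#' \eqn{T = N_s/f_{cam}}. Mode and frame counts are rounded to the nearest
#' integer.
#'
#' @param optics an [optics_config()].
#' @param foi_side side of the (square) field of illumination, micrometres.
#' @param fod_side side of the (square) field of detection, micrometres.
#' @param r camera rate coefficient in 1/um (frame rate = r / fod_side, Hz).
#' @return an object of class `acquisition_plan` with elements
#'   `foi_side`, `fod_side`, `r`, `N_s`, `N_c`, `f_cam` (Hz), `T` (s).
#' @examples
#' opt <- optics_config(0.9, 1.0)
#' plan_acquisition(opt, foi_side = 50, fod_side = 50, r = 40000)
#' @export
plan_acquisition <- function(optics, foi_side, fod_side, r) {
  stopifnot(inherits(optics, "optics_config"))
  if (!is.numeric(foi_side) || foi_side <= 0 ||
      !is.numeric(fod_side) || fod_side <= 0 || !is.numeric(r) || r <= 0)
    stop_invalid("foi_side, fod_side and r must all be positive")
  dd <- diffraction_limit(optics)
  N_c <- round(pi * (fod_side / (2 * dd))^2)
  N_s <- round(foi_side^2 / dd^2)
  f_cam <- r / fod_side
  structure(list(optics = optics, foi_side = foi_side, fod_side = fod_side,
                 r = r, N_s = as.integer(N_s), N_c = as.integer(N_c),
                 f_cam = f_cam, T = N_s / f_cam),
            class = "acquisition_plan")
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat("Acquisition plan (FOI", x$foi_side, "um, FOD", x$fod_side, "um):\n")
  cat("  correction modes N_c =", x$N_c, "\n")
  cat("  scan positions  N_s =", x$N_s, "\n")
  cat("  camera rate f_cam =", signif(x$f_cam, 5), "Hz; total time T =",
      signif(x$T, 4), "s\n")
  invisible(x)
}
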