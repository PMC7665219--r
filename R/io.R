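# Persistence and fixtures. Stacks and fits are stored as a versioned
# hierarchical list (groups /stack, /meta, /truth) serialized with R's
# native format; phase maps and images export to 32-bit float TIFF.

RMCLASS_CONTAINER_VERSION <- 1L

#' Read and write field stacks and fits
#'
#' `write_stack()`/`read_stack()` persist a `field_stack` (complex frames,
#' scan maps, optics metadata and the synthetic /truth group) losslessly;
#' `write_result()`/`read_result()` do the same for `class_fit` /
#' `local_class_fit` objects. Files carry a container version that is
#' checked on read.
#'
#' @param stack a `field_stack`.
#' @param path file path.
#' @return `read_stack()` returns the `field_stack`; writers return `path`
#'   invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "field_stack"))
  obj <- list(version = RMCLASS_CONTAINER_VERSION, kind = "field_stack",
              stack = unclass(stack))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  obj <- read_container(path, "field_stack")
  structure(obj$stack, class = "field_stack")
}

#' @rdname write_stack
#' @param result a `class_fit` or `local_class_fit`.
#' @export
write_result <- function(result, path) {
  if (!inherits(result, "class_fit") && !inherits(result, "local_class_fit"))
    stop_invalid("write_result() takes a class_fit or local_class_fit")
  obj <- list(version = RMCLASS_CONTAINER_VERSION, kind = class(result)[1],
              result = result)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_result <- function(path) {
  obj <- read_container(path, c("class_fit", "local_class_fit"))
  obj$result
}

read_container <- function(path, kinds) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop_invalid("unreadable container: %s", path))
  if (!is.list(obj) || is.null(obj$version) || is.null(obj$kind))
    stop_invalid("not a container file: %s", path)
  if (obj$version != RMCLASS_CONTAINER_VERSION)
    stop_invalid("container version %s not supported (expected %d)",
                 obj$version, RMCLASS_CONTAINER_VERSION)
  if (!obj$kind %in% kinds)
    stop_invalid("container holds '%s', expected %s", obj$kind,
                 paste(kinds, collapse = "/"))
  obj
}

#' Export a matrix as 32-bit float TIFF
#'
#' Phase maps (radians) and intensity images (unitless) are written as a
#' single-channel float TIFF; complex input exports `Mod(x)`.
#'
#' @param x numeric/complex matrix, `pupil_phase` or image.
#' @param path output file path.
#' @param normalize rescale into `[0, 1]` (required by some viewers);
#'   default keeps physical values.
#' @export
export_tiff <- function(x, path, normalize = FALSE) {
  if (inherits(x, "pupil_phase")) x <- fft_shift(x$phase)
  if (is.complex(x)) x <- Mod(x)
  x <- as.matrix(x)
  if (normalize) {
    rg <- range(x)
    x <- if (diff(rg) > 0) (x - rg[1]) / diff(rg) else x * 0
  }
  tiff::writeTIFF(x, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Deterministic benchmark fixtures
#'
#' Small, fully synthetic acquisitions with stored ground truth, regenerated
#' bit-identically from a seed:
#' \describe{
#'   \item{`siemens_star_smallgrid`}{64 x 64 px Siemens star, full-grid FOI
#'     and FOD (32 x 32 scan), independent input/output speckle screens with
#'     about 500 effective modes, noise free.}
#'   \item{`noisy_ssmr008`}{same acquisition with multiple-scattering noise
#'     calibrated to a confocal single-to-multiple intensity ratio of 0.08.}
#'   \item{`two_patch_aniso`}{96 x 96 px filament phantom over a weak diffuse
#'     speckle background, central 64 x 64 px FOI (32 x 32 scan) split into
#'     left/right isoplanatic patches with independent reciprocity-consistent
#'     screens (about 150 modes each); the ground-truth patch size is half
#'     the FOI (32 px, 7.2 um) and the backscattered energy of the two
#'     halves is balanced.}
#' }
#'
#' @param name fixture name.
#' @param seed integer seed (default 1).
#' @return a list with the `field_stack` (`$stack`), its `optics` and the
#'   generating parameters; the injected screens sit in `stack$truth`.
#' @export
make_fixture <- function(name = c("siemens_star_smallgrid", "two_patch_aniso",
                                  "noisy_ssmr008"), seed = 1) {
  name <- match.arg(name)
  opt <- optics_config(wavelength = 0.9, na = 1.0, grid_size = 64)
  if (name %in% c("siemens_star_smallgrid", "noisy_ssmr008")) {
    obj <- make_siemens_star(16, 64)
    phi_i <- make_pupil_phase(opt, "speckle", list(n_modes = 500, rms = 1.8),
                              seed = seed * 1000L + 1L)
    phi_o <- make_pupil_phase(opt, "speckle", list(n_modes = 500, rms = 1.8),
                              seed = seed * 1000L + 2L, side = "output")
    ssmr <- if (name == "noisy_ssmr008") 0.08 else Inf
    stack <- simulate_scan(obj, phi_i, phi_o, opt, ssmr = ssmr,
                           seed = seed * 1000L + 3L)
    list(stack = stack, optics = opt, object = obj,
         phi_i = phi_i, phi_o = phi_o, ssmr = ssmr, seed = seed)
  } else {
    opt <- optics_config(wavelength = 0.9, na = 1.0, grid_size = 96)
    fil <- make_filaments(n = 10, width_px = 2, side_px = 96,
                          seed = seed * 1000L + 4L)
    # weak diffuse speckle reflectance everywhere: irregular tissue structure
    # at the focal plane backscatters single-scattered light even between
    # fibres, and those returns drive the correction in fibre-free tiles
    bg <- with_seed(seed * 1000L + 9L, {
      a <- matrix(0.2 * sqrt(-log(stats::runif(96 * 96))), 96, 96)
      a * exp(1i * matrix(stats::runif(96 * 96, 0, 2 * pi), 96, 96))
    })
    z <- unclass(fil) + bg
    # balance the backscattered energy of the two halves so neither patch
    # dominates a whole-field (single-tile) correction
    p_l <- sqrt(mean(Mod(z[, 1:48])^2)); p_r <- sqrt(mean(Mod(z[, 49:96])^2))
    s0 <- (p_l + p_r) / 2
    z[, 1:48] <- z[, 1:48] * (s0 / p_l)
    z[, 49:96] <- z[, 49:96] * (s0 / p_r)
    obj <- new_object_map(pmin(Mod(z), 1) * exp(1i * Arg(z)))
    # reciprocity-consistent medium: detection screen = mirrored illumination
    mk <- function(s) {
      phi_i <- make_pupil_phase(opt, "speckle", list(n_modes = 150, rms = 1.5),
                                seed = s)
      list(phi_i = phi_i, phi_o = mirror_pupil(phi_i))
    }
    screens <- list(mk(seed * 1000L + 5L), mk(seed * 1000L + 7L))
    nsy <- 32L
    patch_map <- matrix(rep(c(1L, 2L), each = nsy * nsy / 2), nsy, nsy)
    stack <- simulate_scan(obj, optics = opt, foi_px = 64L,
                           patch_map = patch_map, screens = screens)
    list(stack = stack, optics = opt, object = obj, screens = screens,
         patch_map = patch_map, patch_px = 32L, fod_px = 48L, seed = seed)
  }
}
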