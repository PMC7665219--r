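#' De-scan / laboratory frame conversion
#'
#' A scanned acquisition records each reflected field in de-scanned camera
#' coordinates `r_cam`; the laboratory-frame field follows from
#' `E_lab(r_o; r_i) = E_cam(r_o - r_i; r_i)`, i.e. every frame is shifted back
#' by its own illumination position. Shifts are exact integer pixel moves.
#'
#' When the recorded field of detection spans the full (periodic) simulation
#' grid the shift is circular; otherwise frames are placed into a common
#' output window (the field of illumination dilated by half the field of
#' detection on every side) and pixels outside the measured FOD stay zero:
#' the zeros are honest "no data" entries, not measurements.
#'
#' @param stack a `field_stack` with frame label `"descanned"`.
#' @return a `field_stack` with frame label `"lab"`, frames living in a
#'   common output window; `window_origin` gives the object-grid pixel
#'   coordinate of window element `[1, 1]`.
#' @export
descan_to_lab <- function(stack) {
  stopifnot(inherits(stack, "field_stack"))
  if (stack$frame != "descanned")
    stop_invalid("descan_to_lab() expects a de-scanned stack")
  f <- stack$fod_px
  cc <- floor(f / 2) + 1          # r_cam = 0 pixel inside each frame
  ns <- nrow(stack$scan_px)
  if (stack$full_grid) {
    n <- stack$grid_px
    out <- array(0i, dim = c(n, n, ns))
    for (s in seq_len(ns)) {
      y <- stack$scan_px[s, 1]; x <- stack$scan_px[s, 2]
      out[, , s] <- circ_shift(stack$frames[, , s], y - cc, x - cc)
    }
    origin <- c(1L, 1L)
    wdim <- c(n, n)
  } else {
    ys <- range(stack$scan_px[, 1]); xs <- range(stack$scan_px[, 2])
    origin <- c(ys[1] - (cc - 1L), xs[1] - (cc - 1L))
    wdim <- c(ys[2] + (f - cc) - origin[1] + 1L,
              xs[2] + (f - cc) - origin[2] + 1L)
    out <- array(0i, dim = c(wdim, ns))
    for (s in seq_len(ns)) {
      y0 <- stack$scan_px[s, 1] - (cc - 1L) - origin[1] + 1L
      x0 <- stack$scan_px[s, 2] - (cc - 1L) - origin[2] + 1L
      out[y0:(y0 + f - 1L), x0:(x0 + f - 1L), s] <- stack$frames[, , s]
    }
  }
  lab <- stack
  lab$frames <- out
  lab$frame <- "lab"
  lab$window_origin <- as.integer(origin)
  lab$window_dim <- as.integer(wdim)
  lab
}

# Inverse of descan_to_lab on the common support (used by round-trip tests).
lab_to_descan <- function(stack) {
  stopifnot(inherits(stack, "field_stack"), stack$frame == "lab")
  f <- stack$fod_px
  cc <- floor(f / 2) + 1
  ns <- nrow(stack$scan_px)
  out <- array(0i, dim = c(f, f, ns))
  if (stack$full_grid) {
    for (s in seq_len(ns)) {
      y <- stack$scan_px[s, 1]; x <- stack$scan_px[s, 2]
      out[, , s] <- circ_shift(stack$frames[, , s], cc - y, cc - x)
    }
  } else {
    for (s in seq_len(ns)) {
      y0 <- stack$scan_px[s, 1] - (cc - 1L) - stack$window_origin[1] + 1L
      x0 <- stack$scan_px[s, 2] - (cc - 1L) - stack$window_origin[2] + 1L
      out[, , s] <- stack$frames[y0:(y0 + f - 1L), x0:(x0 + f - 1L), s]
    }
  }
  ds <- stack
  ds$frames <- out
  ds$frame <- "descanned"
  ds$window_origin <- NULL
  ds$window_dim <- NULL
  ds
}

#' Assemble the space-domain reflection matrix
#'
#' Flattens every laboratory-frame field image into a column vector and
#' assigns it to the column of its illumination position: entry
#' `R[r_o, r_i]` is the field detected at output pixel `r_o` for focused
#' illumination at `r_i`. Flattening is column-major with the y index
#' fastest; the index maps are carried with the object.
#'
#' @param stack a lab-frame `field_stack` (see [descan_to_lab()]).
#' @return an object of class `reflection_matrix`: the complex matrix `m`
#'   (rows = output-window pixels, columns = scan positions) plus the row and
#'   column index maps, pixel pitches and optics metadata.
#' @export
assemble_matrix <- function(stack) {
  stopifnot(inherits(stack, "field_stack"))
  if (stack$frame != "lab")
    stop_invalid("assemble_matrix() expects a lab-frame stack; run descan_to_lab() first")
  d <- dim(stack$frames)
  m <- matrix(stack$frames, nrow = d[1] * d[2], ncol = d[3])
  structure(list(m = m,
                 row_dims = d[1:2],
                 window_origin = stack$window_origin,
                 scan_px = stack$scan_px,
                 scan_dims = stack$scan_dims,
                 scan_step_px = stack$scan_step_px,
                 pitch = stack$optics$pixel_pitch,
                 square = FALSE,
                 optics = stack$optics),
            class = "reflection_matrix")
}

#' Restrict the output window to the scan lattice
#'
#' Samples the output rows of a full-pixel reflection matrix at the scan
#' positions, producing the square matrix used by the spectral transform.
#' This is alias-free whenever the detected field is bandlimited by the NA
#' and the scan step equals the diffraction limit (Nyquist for `k_NA`).
#'
#' @param R a `reflection_matrix` from [assemble_matrix()].
#' @return a square `reflection_matrix` whose rows and columns are both
#'   indexed by the scan positions.
#' @export
square_matrix <- function(R) {
  stopifnot(inherits(R, "reflection_matrix"))
  if (R$square) return(R)
  idx <- row_index_of(R, R$scan_px)
  out <- R
  out$m <- R$m[idx, , drop = FALSE]
  out$row_dims <- R$scan_dims
  out$row_positions <- R$scan_px
  out$square <- TRUE
  out$pitch_out <- R$scan_step_px * R$pitch
  out
}

# Linear row index of object-grid pixel positions (ny x 2 matrix) in the
# flattened output window.
row_index_of <- function(R, pos) {
  ry <- pos[, 1] - R$window_origin[1] + 1L
  rx <- pos[, 2] - R$window_origin[2] + 1L
  if (any(ry < 1 | ry > R$row_dims[1] | rx < 1 | rx > R$row_dims[2]))
    stop_invalid("positions outside the output window")
  (rx - 1L) * R$row_dims[1] + ry
}

#' @export
print.reflection_matrix <- function(x, ...) {
  cat("Reflection matrix R(r_o; r_i): ", nrow(x$m), " x ", ncol(x$m),
      if (x$square) " (scan-lattice rows)" else " (pixel rows)", "\n", sep = "")
  cat("  scan grid ", x$scan_dims[1], " x ", x$scan_dims[2],
      ", step ", x$scan_step_px, " px, ||R||_F = ",
      signif(sqrt(sum(Mod(x$m)^2)), 5), "\n", sep = "")
  invisible(x)
}

#' Position <-> spatial-frequency basis conversion
#'
#' `to_spectral()` applies a unitary 2-D discrete Fourier transform to the
#' output side and the inverse transform to the input side of a square
#' reflection matrix (`R~ = F R F^-1`), yielding the matrix between input
#' and output transverse wavevectors; `from_spectral()` inverts it. Both are
#' unitary, so the Frobenius norm is preserved to machine precision and the
#' round trip is the identity.
#'
#' @param R a square `reflection_matrix` (see [square_matrix()]); passing a
#'   non-square matrix is an error directing the caller to pad or restrict.
#' @return `to_spectral()`: an object of class `spectral_matrix` with fields
#'   `m`, `dims`, `ky`, `kx` (rad/um, FFT order), `mask` (NA-disk logical,
#'   entries outside the NA are retained in `m` but flagged), `k_na`,
#'   `pitch_out` and a `template` used to rebuild the space-domain object.
#' @export
to_spectral <- function(R) {
  stopifnot(inherits(R, "reflection_matrix"))
  if (!isTRUE(R$square) || nrow(R$m) != ncol(R$m))
    stop_invalid(paste0("to_spectral() needs a square scan-lattice matrix; ",
                        "use square_matrix() or pad_to_square() first"))
  ny <- R$row_dims[1]; nx <- R$row_dims[2]
  mt <- transform_sides(R$m, ny, nx, forward = TRUE)
  kg <- k_grid(ny, nx, R$pitch_out)
  k_na <- k_cutoff(R$optics)
  kr <- sqrt(kg$kyy^2 + kg$kxx^2)
  mask <- kr < k_na * (1 - 1e-12)
  template <- R
  template$m <- NULL
  structure(list(m = mt, dims = c(ny, nx), ky = kg$ky, kx = kg$kx,
                 dk = c(kg$ky[2] - kg$ky[1], kg$kx[2] - kg$kx[1]),
                 mask = mask, k_na = k_na, pitch_out = R$pitch_out,
                 optics = R$optics, template = template),
            class = "spectral_matrix")
}

#' @rdname to_spectral
#' @param Rt a `spectral_matrix`.
#' @export
from_spectral <- function(Rt) {
  stopifnot(inherits(Rt, "spectral_matrix"))
  out <- Rt$template
  out$m <- transform_sides(Rt$m, Rt$dims[1], Rt$dims[2], forward = FALSE)
  out
}

# Apply F . F^-1 (forward = TRUE) or F^-1 . F (forward = FALSE) to the output
# (column images) and input (row images) sides of a flattened matrix.
transform_sides <- function(m, ny, nx, forward = TRUE) {
  n <- ny * nx
  colf <- if (forward) ufft2 else uifft2
  rowf <- if (forward) uifft2 else ufft2
  a <- vapply(seq_len(n),
              function(j) as.vector(colf(matrix(m[, j], ny, nx))),
              complex(n))
  b <- vapply(seq_len(n),
              function(i) as.vector(rowf(matrix(a[i, ], ny, nx))),
              complex(n))
  t(b)
}

#' Confocal (OCM) image from the reflection matrix
#'
#' The conventional optical-coherence-microscopy image is the intensity of
#' the matrix diagonal: the field detected at the illumination position. A
#' finite confocal pinhole sums the detected intensity over output pixels
#' within `pinhole_radius_airy` Airy radii (1 Airy radius =
#' \eqn{0.61\lambda/\alpha}) of each scan position; radius 0 keeps the exact
#' diagonal.
#'
#' @param R a `reflection_matrix` (pixel rows give the finest pinhole
#'   sampling; scan-lattice rows are supported).
#' @param pinhole_radius_airy pinhole radius in Airy units (>= 0).
#' @return numeric matrix over the scan grid (summed intensity).
#' @export
ocm_image <- function(R, pinhole_radius_airy = 1.0) {
  stopifnot(inherits(R, "reflection_matrix"))
  if (pinhole_radius_airy < 0) stop_invalid("pinhole radius must be >= 0")
  pitch <- if (isTRUE(R$square)) R$pitch_out else R$pitch
  r_px <- pinhole_radius_airy * 0.61 * R$optics$wavelength / R$optics$na / pitch
  rd <- R$row_dims
  rmax <- floor(r_px)
  off <- expand.grid(dy = -rmax:rmax, dx = -rmax:rmax)
  off <- off[off$dy^2 + off$dx^2 <= r_px^2, , drop = FALSE]
  ns <- ncol(R$m)
  img <- numeric(ns)
  for (s in seq_len(ns)) {
    if (isTRUE(R$square)) {
      # rows are the scan positions themselves, in scan (column-major) order
      py <- ((s - 1L) %% rd[1]) + 1L
      px <- ((s - 1L) %/% rd[1]) + 1L
    } else {
      py <- R$scan_px[s, 1] - R$window_origin[1] + 1L
      px <- R$scan_px[s, 2] - R$window_origin[2] + 1L
    }
    yy <- py + off$dy; xx <- px + off$dx
    ok <- yy >= 1 & yy <= rd[1] & xx >= 1 & xx <= rd[2]
    idx <- (xx[ok] - 1) * rd[1] + yy[ok]
    img[s] <- sum(Mod(R$m[idx, s])^2)
  }
  matrix(img, R$scan_dims[1], R$scan_dims[2])
}
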