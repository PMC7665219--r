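# CLASS: closed-loop accumulation of single scattering.
#
# Working representation: a spectral matrix R~(k_o; k_i) on an (ny x nx)
# k-grid per side, flattened column-major (k_y fastest). The momentum
# difference Dk = k_o - k_i is indexed on the full UNWRAPPED difference set,
# a (2*ny-1) x (2*nx-1) grid: with scanning at the diffraction limit the
# object spectrum extends to twice the NA cutoff, so wrapping differences
# periodically would conflate distinct object frequencies.

# Precomputed index machinery shared by all per-iteration operations.
spectral_context <- function(Rt) {
  ny <- Rt$dims[1]; nx <- Rt$dims[2]
  fy <- round(fft_freq(ny) * ny)              # integer frequencies
  fx <- round(fft_freq(nx) * nx)
  fyv <- rep(fy, times = nx)                  # per-mode freq, col-major
  fxv <- rep(fx, each = ny)
  ndy <- 2L * ny - 1L; ndx <- 2L * nx - 1L
  dy <- outer(fyv, fyv, "-")                  # k_o - k_i, output rows
  dx <- outer(fxv, fxv, "-")
  didx <- (dx + nx - 1L) * ndy + (dy + ny)    # 1 .. ndy*ndx
  storage.mode(didx) <- "integer"
  nd <- ndy * ndx
  dval_y <- ((seq_len(nd) - 1L) %% ndy) - (ny - 1L)
  dval_x <- ((seq_len(nd) - 1L) %/% ndy) - (nx - 1L)
  neg_d <- (-dval_x + nx - 1L) * ndy + (-dval_y + ny)
  neg_k <- {
    iy <- match(-fyv, fy); ix <- match(-fxv, fx)
    ifelse(is.na(iy) | is.na(ix), NA_integer_, (ix - 1L) * ny + iy)
  }
  list(ny = ny, nx = nx, ndy = ndy, ndx = ndx,
       didx = didx, didx_neg = matrix(neg_d[didx], nrow(didx), ncol(didx)),
       neg_d = neg_d, neg_k = neg_k,
       mask = as.vector(Rt$mask))
}

sum_by_group <- function(v, group, n_groups) {
  rs <- rowsum(cbind(Re(v), Im(v)), group)
  # every group 1..n_groups occurs by construction of the difference set
  complex(real = rs[, 1], imaginary = rs[, 2])
}

# CLASS spectrum as a vector over the flattened difference set.
class_spectrum_vec <- function(m, ctx) {
  sum_by_group(as.vector(m), as.vector(ctx$didx), ctx$ndy * ctx$ndx)
}

# Objective: total intensity of the confocal image reconstructed on the
# refined (half-step) lattice that supports the full difference set; by
# Parseval this equals the CLASS-spectrum energy up to a constant, and it is
# non-decreasing under the alignment sweeps.
objective_from_spectrum <- function(svec, ctx) {
  sum(Mod(svec)^2) / (ctx$ndy * ctx$ndx)
}

#' CLASS spectrum of a spectral reflection matrix
#'
#' Sums all matrix entries sharing the same momentum difference
#' \eqn{\Delta k = k_o - k_i} (anti-diagonal sums). After aberration
#' correction these coherent sums are proportional to the object spectrum
#' \eqn{\tilde O(\Delta k)}; before correction the phase-scrambled entries
#' add incoherently. The difference set is the full (unwrapped)
#' \eqn{(2n_y-1) \times (2n_x-1)} grid.
#'
#' @param Rt a `spectral_matrix` (see [to_spectral()]).
#' @return complex matrix over the difference grid, `Delta k = 0` at element
#'   `[ny, nx]`.
#' @export
class_spectrum <- function(Rt) {
  stopifnot(inherits(Rt, "spectral_matrix"))
  ctx <- spectral_context(Rt)
  matrix(class_spectrum_vec(Rt$m, ctx), ctx$ndy, ctx$ndx)
}

phase_step_i <- function(m, svec, ctx) {
  z <- colSums(Conj(m) * matrix(svec[ctx$didx], nrow(m), ncol(m)))
  p <- Arg(z)                                  # Arg(0+0i) == 0: no-op tie-break
  p[!ctx$mask] <- 0
  p
}

# Row-wise analogue of the input step. The mirrored spectrum lookup
# S(-Dk') refers to the row re-indexed by Dk' = k_i - k_o, i.e. each entry
# is matched with S(k_o - k_i): only this reading leaves the fully corrected
# matrix a fixed point (for the opposite sign the products carry the squared
# object spectrum's phase and the step is biased on asymmetric objects).
phase_step_o <- function(m, svec, ctx) {
  z <- rowSums(Conj(m) * matrix(svec[ctx$didx], nrow(m), ncol(m)))
  p <- Arg(z)
  p[!ctx$mask] <- 0
  p
}

#' Single CLASS phase-estimation and correction steps
#'
#' `input_phase_step()` estimates the per-`k_i` phase increment by aligning
#' every matrix column (re-indexed by the momentum difference) with the
#' current CLASS spectrum; `output_phase_step()` does the same row-wise with
#' the mirrored spectrum; `apply_step()` multiplies the matrix by the phase
#' factors on both sides (per-entry modulus is preserved exactly). Phases are
#' only ever updated inside the NA mask; where the alignment sum vanishes the
#' increment is 0.
#'
#' These are the building blocks iterated by [run_class()]; they are exported
#' for inspection and unit testing.
#'
#' @param Rt a `spectral_matrix`.
#' @param spectrum optional precomputed [class_spectrum()] matrix.
#' @return for the phase steps, a numeric matrix of phase increments (rad) on
#'   the k-grid; for `apply_step()`, the updated `spectral_matrix`.
#' @export
input_phase_step <- function(Rt, spectrum = NULL) {
  ctx <- spectral_context(Rt)
  svec <- if (is.null(spectrum)) class_spectrum_vec(Rt$m, ctx) else as.vector(spectrum)
  matrix(phase_step_i(Rt$m, svec, ctx), Rt$dims[1], Rt$dims[2])
}

#' @rdname input_phase_step
#' @export
output_phase_step <- function(Rt, spectrum = NULL) {
  ctx <- spectral_context(Rt)
  svec <- if (is.null(spectrum)) class_spectrum_vec(Rt$m, ctx) else as.vector(spectrum)
  matrix(phase_step_o(Rt$m, svec, ctx), Rt$dims[1], Rt$dims[2])
}

#' @rdname input_phase_step
#' @param phi_i,phi_o phase increment matrices on the k-grid (radians).
#' @export
apply_step <- function(Rt, phi_i, phi_o) {
  stopifnot(inherits(Rt, "spectral_matrix"))
  Rt$m <- Rt$m * outer(exp(1i * as.vector(phi_o)), exp(1i * as.vector(phi_i)))
  Rt
}

masked_rms <- function(p, mask) {
  v <- p[mask]
  v <- wrap_phase(v - circ_mean(v))
  sqrt(mean(v^2))
}

# The CLASS sweep engine, shared by the global and local (reciprocity-mode)
# solvers. Operates on the raw matrix; reciprocity = TRUE replaces the input
# phase estimate by the mirrored output estimate phi_i(k) = phi_o(-k), the
# variant used when the matrix has few (or zero-padded) real columns.
class_iterate <- function(m, ctx, tol_rms_rad, max_iter, reciprocity = FALSE) {
  n <- length(ctx$mask)
  acc_i <- numeric(n); acc_o <- numeric(n)
  log_it <- vector("list", max_iter)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    svec <- class_spectrum_vec(m, ctx)
    obj <- objective_from_spectrum(svec, ctx)
    phi_o <- phase_step_o(m, svec, ctx)
    if (reciprocity) {
      phi_i <- numeric(n)
      ok <- !is.na(ctx$neg_k)
      phi_i[ok] <- phi_o[ctx$neg_k[ok]]
      phi_i[!ctx$mask] <- 0
    } else {
      phi_i <- phase_step_i(m, svec, ctx)
    }
    rms_i <- masked_rms(phi_i, ctx$mask)
    rms_o <- masked_rms(phi_o, ctx$mask)
    m <- m * outer(exp(1i * phi_o), exp(1i * phi_i))
    acc_i <- acc_i + phi_i
    acc_o <- acc_o + phi_o
    log_it[[it]] <- c(iteration = it, objective = obj,
                      rms_increment_i = rms_i, rms_increment_o = rms_o)
    done <- if (reciprocity) rms_o < tol_rms_rad
            else rms_i < tol_rms_rad && rms_o < tol_rms_rad
    if (done) { converged <- TRUE; break }
  }
  svec <- class_spectrum_vec(m, ctx)
  list(m = m, acc_i = acc_i, acc_o = acc_o,
       objective = objective_from_spectrum(svec, ctx),
       log = as.data.frame(do.call(rbind, log_it[seq_len(iter)])),
       converged = converged, iterations = iter)
}

#' Fit pupil aberrations by the CLASS algorithm
#'
#' Iteratively estimates the input and output pupil phase maps from a
#' spectral reflection matrix by the closed-loop accumulation of single
#' scattering: each sweep (i) forms the CLASS spectrum (anti-diagonal sums),
#' (ii) estimates per-mode phase increments that align every column and row
#' with it, (iii) applies the increments as pure phase factors, and repeats
#' until the masked RMS (piston removed) of both increments drops below
#' `tol_rms_rad` or `max_iter` is reached. The accumulated phases converge to
#' the correction (conjugate) phases; the fit reports the retrieved
#' aberration maps `phi_i`, `phi_o` (their negation, wrapped, piston
#' removed), the corrected matrix in both bases, and the aberration-corrected
#' confocal (CLASS) image from the diagonal of the corrected space-domain
#' matrix. The algorithm is deterministic.
#'
#' The objective logged per iteration is the total intensity of the
#' reconstructed confocal image; it is non-decreasing over iterations on
#' reflection data. The estimate is defined modulo piston and complementary
#' linear tilts (a global image shift); comparisons with ground truth should
#' use [phase_agreement()], which removes both.
#'
#' @param Rt a square `spectral_matrix` (from [to_spectral()]), or a
#'   de-scanned `field_stack`, or a `reflection_matrix`, which are converted.
#' @param tol_rms_rad convergence tolerance on the per-iteration phase
#'   increment RMS (radians).
#' @param max_iter maximum number of sweeps; non-convergence sets
#'   `converged = FALSE` with a warning flag, not an error.
#' @return an object of class `class_fit`; see Details. Methods:
#'   [print()], [summary()], [coef()] (list of the two aberration maps),
#'   [fitted()] (CLASS image), [residuals()] (non-confocal intensity left in
#'   the corrected matrix), [plot()].
#' @examples
#' opt <- optics_config(0.9, 1.0, grid_size = 32)
#' obj <- make_siemens_star(8, 32)
#' pi_ <- make_pupil_phase(opt, "speckle", list(n_modes = 40, rms = 1.2), seed = 1)
#' po_ <- make_pupil_phase(opt, "speckle", list(n_modes = 40, rms = 1.2), seed = 2,
#'                         side = "output")
#' st <- simulate_scan(obj, pi_, po_, opt)
#' fit <- run_class(st, max_iter = 10)
#' fit
#' @export
run_class <- function(Rt, tol_rms_rad = 0.01, max_iter = 50) {
  if (inherits(Rt, "field_stack"))
    Rt <- to_spectral(square_matrix(assemble_matrix(
      if (Rt$frame == "descanned") descan_to_lab(Rt) else Rt)))
  if (inherits(Rt, "reflection_matrix")) Rt <- to_spectral(square_matrix(Rt))
  stopifnot(inherits(Rt, "spectral_matrix"))
  ctx <- spectral_context(Rt)
  it <- class_iterate(Rt$m, ctx, tol_rms_rad, max_iter, reciprocity = FALSE)
  if (!it$converged)
    warning("CLASS did not reach tol_rms_rad = ", tol_rms_rad, " in ",
            max_iter, " iterations")
  m <- it$m
  acc_i <- it$acc_i; acc_o <- it$acc_o
  iter <- it$iterations
  final_obj <- it$objective
  log_df <- it$log

  Rt_c <- Rt; Rt_c$m <- m
  R_c <- from_spectral(Rt_c)
  R_0 <- from_spectral(Rt)
  ny <- Rt$dims[1]; nx <- Rt$dims[2]
  cls_img <- matrix(Mod(diag(R_c$m))^2, ny, nx)
  ocm_img <- matrix(Mod(diag(R_0$m))^2, ny, nx)

  as_map <- function(acc, side) {
    p <- wrap_phase(-acc)
    p[ctx$mask] <- wrap_phase(p[ctx$mask] - circ_mean(p[ctx$mask]))
    p[!ctx$mask] <- 0
    new_pupil_phase(matrix(p, ny, nx), Rt$mask, Rt$ky, Rt$kx, Rt$k_na,
                    side, Rt$optics)
  }
  structure(list(phi_i = as_map(acc_i, "input"),
                 phi_o = as_map(acc_o, "output"),
                 correction_i = matrix(acc_i, ny, nx),
                 correction_o = matrix(acc_o, ny, nx),
                 spectral = Rt, spectral_corrected = Rt_c,
                 R_corrected = R_c,
                 image = cls_img, ocm = ocm_img,
                 log = log_df, objective = final_obj,
                 converged = it$converged, iterations = iter,
                 tol_rms_rad = tol_rms_rad),
            class = "class_fit")
}

#' Aberration-corrected confocal image of a CLASS fit
#'
#' @param fit a `class_fit`.
#' @return numeric matrix over the scan grid: squared modulus of the
#'   diagonal of the corrected space-domain matrix.
#' @export
class_image <- function(fit) {
  stopifnot(inherits(fit, "class_fit"))
  fit$image
}

#' @export
print.class_fit <- function(x, ...) {
  cat("CLASS fit:", x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged",
      "(tol", x$tol_rms_rad, "rad RMS)\n")
  cat("  k-grid", x$spectral$dims[1], "x", x$spectral$dims[2], "with",
      sum(x$spectral$mask), "NA-disk modes\n")
  cat("  confocal intensity gain:",
      signif(sum(x$image) / sum(x$ocm), 4), "\n")
  invisible(x)
}

#' @export
summary.class_fit <- function(object, ...) {
  s <- list(iterations = object$iterations, converged = object$converged,
            n_modes = sum(object$spectral$mask),
            objective = object$objective,
            gain = sum(object$image) / sum(object$ocm),
            rms_i = stats::sd(object$phi_i$phase[object$phi_i$mask]),
            rms_o = stats::sd(object$phi_o$phase[object$phi_o$mask]),
            log = object$log)
  class(s) <- "summary.class_fit"
  s
}

#' @export
print.summary.class_fit <- function(x, ...) {
  cat("CLASS aberration retrieval\n")
  cat("  iterations:        ", x$iterations,
      if (x$converged) " (converged)" else " (max_iter hit)", "\n", sep = "")
  cat("  NA-disk modes:     ", x$n_modes, "\n", sep = "")
  cat("  retrieved RMS phase (rad): input ", signif(x$rms_i, 3),
      ", output ", signif(x$rms_o, 3), "\n", sep = "")
  cat("  confocal intensity gain over OCM: ", signif(x$gain, 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.class_fit <- function(object, ...) {
  list(phi_i = object$phi_i$phase, phi_o = object$phi_o$phase)
}

#' @export
fitted.class_fit <- function(object, ...) object$image

#' @export
residuals.class_fit <- function(object, ...) {
  # non-confocal intensity per scan position left after correction: the
  # energy the correction could not refocus (multiple-scattering estimate)
  tot <- colSums(Mod(object$R_corrected$m)^2)
  matrix(tot - Mod(diag(object$R_corrected$m))^2,
         object$spectral$dims[1], object$spectral$dims[2])
}

#' @export
plot.class_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  show <- function(img, main) {
    graphics::image(t(img)[, rev(seq_len(nrow(img)))], asp = 1, axes = FALSE,
                    col = grDevices::hcl.colors(64, "Inferno"), main = main)
  }
  show(x$ocm, "OCM (uncorrected)")
  show(x$image, "CLASS (corrected)")
  img <- fft_shift(x$phi_i$phase * ifelse(x$phi_i$mask, 1, NA))
  graphics::image(t(img)[, rev(seq_len(nrow(img)))], asp = 1, axes = FALSE,
                  col = grDevices::hcl.colors(64, "Spectral"),
                  main = "retrieved phi_i")
  graphics::plot(x$log$iteration, x$log$objective, type = "b",
                 xlab = "iteration", ylab = "objective",
                 main = "confocal intensity")
  invisible(x)
}

#' Sample a fine-grid pupil screen on another k-grid
#'
#' Injected truth screens live on the simulation k-grid; retrieved maps live
#' on the scan-lattice (or tile-lattice) k-grid. When the target grid is a
#' subset of the source grid the lookup is exact; otherwise the complex
#' phasor \eqn{e^{i\phi}} is interpolated bilinearly and the phase taken,
#' which is wrap-safe.
#'
#' @param pupil a `pupil_phase` on the fine grid.
#' @param ky,kx target wavevector vectors (rad/um, FFT order), e.g. from a
#'   `spectral_matrix` or a fitted map.
#' @return numeric matrix of phases sampled at the target grid.
#' @export
sample_pupil <- function(pupil, ky, kx) {
  stopifnot(inherits(pupil, "pupil_phase"))
  dk <- pupil$dk
  n <- nrow(pupil$phase)
  iy <- round(ky / dk[1]); ix <- round(kx / dk[2])
  if (max(abs(iy * dk[1] - ky), abs(ix * dk[2] - kx)) < 1e-6 * dk[1]) {
    return(matrix(pupil$phase[cbind(rep((iy %% n) + 1, times = length(kx)),
                                    rep((ix %% n) + 1, each = length(ky)))],
                  length(ky), length(kx)))
  }
  if (max(abs(ky)) >= (n / 2 - 1) * dk[1] || max(abs(kx)) >= (n / 2 - 1) * dk[2])
    stop_invalid("target k-grid extends beyond the pupil k-grid")
  z <- exp(1i * pupil$phase)
  at <- function(fy, fx) {                  # integer frequencies -> value
    z[cbind(((fy %% n) + 1), ((fx %% n) + 1))]
  }
  fy <- ky / dk[1]; fx <- kx / dk[2]
  fyv <- rep(fy, times = length(fx)); fxv <- rep(fx, each = length(fy))
  y0 <- floor(fyv); x0 <- floor(fxv)
  wy <- fyv - y0; wx <- fxv - x0
  zi <- (1 - wy) * (1 - wx) * at(y0, x0) + wy * (1 - wx) * at(y0 + 1, x0) +
    (1 - wy) * wx * at(y0, x0 + 1) + wy * wx * at(y0 + 1, x0 + 1)
  matrix(Arg(zi), length(ky), length(kx))
}
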