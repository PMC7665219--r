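# Internal numeric helpers shared across modules. All angles are radians,
# lengths are micrometres, spatial frequencies rad/um.

#' Wrap phase values to (-pi, pi]
#'
#' @param x numeric vector/matrix of phases in radians.
#' @return object of the same shape with every value wrapped to (-pi, pi].
#' @export
wrap_phase <- function(x) pi - (pi - x) %% (2 * pi)

# DFT sample frequencies in cycles-per-unit, standard FFT (wrap-around) order.
fft_freq <- function(n, d = 1) {
  c(0:floor((n - 1) / 2), -ceiling((n - 1) / 2):-1) / (n * d)
}

# Transverse wavevector grid (rad/um) for an n x n (or ny x nx) field of given
# pixel pitch; returned in FFT order so it aligns with fft() output.
k_grid <- function(ny, nx = ny, pitch = 1) {
  ky <- 2 * pi * fft_freq(ny, pitch)
  kx <- 2 * pi * fft_freq(nx, pitch)
  list(ky = ky, kx = kx,
       kyy = matrix(ky, ny, nx), kxx = matrix(kx, ny, nx, byrow = TRUE))
}

# Unitary 2-D DFTs (norm-preserving); zero frequency at element [1, 1].
ufft2 <- function(x) stats::fft(x) / sqrt(length(x))
uifft2 <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

# Circular shift of a matrix by (sy, sx) pixels (positive = down/right).
circ_shift <- function(m, sy, sx) {
  ny <- nrow(m); nx <- ncol(m)
  sy <- ((sy %% ny) + ny) %% ny
  sx <- ((sx %% nx) + nx) %% nx
  if (sy == 0 && sx == 0) return(m)
  # m_out[i, j] = m[i - sy, j - sx] with periodic indexing
  m[((seq_len(ny) - 1 - sy) %% ny) + 1, ((seq_len(nx) - 1 - sx) %% nx) + 1,
    drop = FALSE]
}

#' Re-centre an FFT-ordered matrix
#'
#' Moves the zero-frequency (or zero-shift) element from `[1, 1]` to the
#' centre pixel `floor(n/2) + 1` for display; `ifft_shift()` undoes it.
#'
#' @param m a matrix in FFT (wrap-around) order.
#' @return the re-centred matrix.
#' @export
fft_shift <- function(m) {
  circ_shift(m, floor(nrow(m) / 2), floor(ncol(m) / 2))
}

#' @rdname fft_shift
#' @export
ifft_shift <- function(m) {
  circ_shift(m, -floor(nrow(m) / 2), -floor(ncol(m) / 2))
}

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# i.i.d. circular complex Gaussian with total variance sigma2 per draw.
rcnorm <- function(n, sigma2 = 1) {
  complex(real = stats::rnorm(n, sd = sqrt(sigma2 / 2)),
          imaginary = stats::rnorm(n, sd = sqrt(sigma2 / 2)))
}

# Circular mean of phases (piston); returns 0 for empty input.
circ_mean <- function(x) {
  if (length(x) == 0) return(0)
  z <- mean(exp(1i * x))
  if (Mod(z) == 0) 0 else Arg(z)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
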