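# Locally varying (anisoplanatic) aberration correction: the field of
# illumination is tiled into subregions no larger than the isoplanatic patch
# and CLASS runs per tile on a rectangular sub-matrix whose output window is
# enlarged by the field of detection, so the full FOD-supported mode set is
# retained even for small tiles.

#' Tile the field of illumination into subregions
#'
#' Partitions the scan grid into square subregions of the requested side,
#' each extended by an overlap margin on every side (clipped at the
#' boundary). Cores tile the FOI exactly; margins are used for blending by
#' [stitch()].
#'
#' @param stack a `field_stack`.
#' @param subregion_side subregion (core) side in micrometres.
#' @param margin overlap margin in micrometres; default 10% of the side.
#' @return an object of class `foi_tiling`: list of tiles, each holding the
#'   core and margin scan-index ranges and its scan-position subset.
#' @export
tile_foi <- function(stack, subregion_side, margin = 0.1 * subregion_side) {
  stopifnot(inherits(stack, "field_stack"))
  step_um <- stack$scan_step_px * stack$optics$pixel_pitch
  foi_um <- stack$scan_dims * step_um
  if (subregion_side > max(foi_um) + 1e-9)
    stop_invalid("subregion_side exceeds the field of illumination")
  if (margin < 0) stop_invalid("margin must be >= 0")
  bs <- max(1L, as.integer(round(subregion_side / step_um)))
  ms <- as.integer(round(margin / step_um))
  nty <- ceiling(stack$scan_dims[1] / bs)
  ntx <- ceiling(stack$scan_dims[2] / bs)
  tiles <- list()
  for (tx in seq_len(ntx)) for (ty in seq_len(nty)) {
    cy <- c((ty - 1L) * bs + 1L, min(ty * bs, stack$scan_dims[1]))
    cx <- c((tx - 1L) * bs + 1L, min(tx * bs, stack$scan_dims[2]))
    fy <- c(max(1L, cy[1] - ms), min(stack$scan_dims[1], cy[2] + ms))
    fx <- c(max(1L, cx[1] - ms), min(stack$scan_dims[2], cx[2] + ms))
    iy <- fy[1]:fy[2]; ix <- fx[1]:fx[2]
    scan_idx <- as.integer(outer(iy, (ix - 1L) * stack$scan_dims[1], "+"))
    tiles[[length(tiles) + 1L]] <-
      list(row = ty, col = tx, core = list(y = cy, x = cx),
           full = list(y = fy, x = fx), scan_idx = scan_idx)
  }
  structure(list(tiles = tiles, n_tiles = c(nty, ntx),
                 scan_dims = stack$scan_dims, block_scan = bs,
                 margin_scan = ms, step_um = step_um,
                 subregion_side = subregion_side, margin = margin),
            class = "foi_tiling")
}

#' @export
print.foi_tiling <- function(x, ...) {
  cat("FOI tiling: ", x$n_tiles[1], " x ", x$n_tiles[2], " tiles of ",
      x$block_scan, " scan steps (", signif(x$block_scan * x$step_um, 3),
      " um), margin ", x$margin_scan, " steps\n", sep = "")
  invisible(x)
}

#' Rectangular per-subregion reflection matrix
#'
#' Extracts the `N_o x N_i` sub-matrix of one tile: columns are the scan
#' positions inside the tile (including its margin), rows are lab-frame
#' positions on the scan-step lattice over the tile's output window — the
#' tile field dilated by half the analysis field of detection on every side,
#' so `N_o` corresponds to the pixels in `(sqrt(FOD) + sqrt(FOI))^2`. Output
#' positions never measured by any frame are zero (honest missing data).
#'
#' @param stack a lab-frame `field_stack` (see [descan_to_lab()]).
#' @param tile one element of `tile_foi()$tiles`.
#' @param fod_px analysis field-of-detection side in pixels (defaults to the
#'   recorded FOD).
#' @return a `reflection_matrix` with lattice rows (not yet square); carries
#'   `real_cols` metadata for [pad_to_square()].
#' @export
build_sub_matrix <- function(stack, tile, fod_px = stack$fod_px) {
  stopifnot(inherits(stack, "field_stack"))
  if (stack$frame != "lab")
    stop_invalid("build_sub_matrix() expects a lab-frame stack")
  step <- stack$scan_step_px
  scan <- stack$scan_px[tile$scan_idx, , drop = FALSE]
  tsy <- tile$full$y[2] - tile$full$y[1] + 1L
  tsx <- tile$full$x[2] - tile$full$x[1] + 1L
  whole <- stack$full_grid &&
    tsy == stack$scan_dims[1] && tsx == stack$scan_dims[2] &&
    fod_px >= stack$grid_px
  pad <- if (whole) 0L else floor(floor(fod_px / 2) / step)
  if (stack$full_grid) {
    # the periodic grid holds grid_px/step distinct lattice sites; a larger
    # window would duplicate rows and double-count measurements
    max_pad <- max(0L, (stack$grid_px %/% step - max(tsy, tsx)) %/% 2L)
    pad <- min(pad, max_pad)
  }
  lat_y <- seq(min(scan[, 1]) - pad * step, max(scan[, 1]) + pad * step, by = step)
  lat_x <- seq(min(scan[, 2]) - pad * step, max(scan[, 2]) + pad * step, by = step)
  ny <- length(lat_y); nx <- length(lat_x)
  n_i <- nrow(scan)
  m <- matrix(0i, ny * nx, n_i)
  wd <- stack$window_dim
  for (j in seq_len(n_i)) {
    fr <- stack$frames[, , tile$scan_idx[j]]
    if (stack$full_grid) {
      yy <- ((lat_y - 1L) %% stack$grid_px) + 1L
      xx <- ((lat_x - 1L) %% stack$grid_px) + 1L
      m[, j] <- as.vector(fr[yy, xx])
    } else {
      yy <- lat_y - stack$window_origin[1] + 1L
      xx <- lat_x - stack$window_origin[2] + 1L
      oky <- yy >= 1L & yy <= wd[1]; okx <- xx >= 1L & xx <= wd[2]
      sub <- matrix(0i, ny, nx)
      sub[oky, okx] <- fr[yy[oky], xx[okx]]
      m[, j] <- as.vector(sub)
    }
  }
  structure(list(m = m, row_dims = c(ny, nx),
                 lattice = list(y = lat_y, x = lat_x),
                 window_origin = c(lat_y[1], lat_x[1]),
                 scan_px = scan, scan_dims = c(tsy, tsx),
                 scan_step_px = step, pitch = stack$optics$pixel_pitch,
                 pitch_out = step * stack$optics$pixel_pitch,
                 square = FALSE, lattice_rows = TRUE,
                 fod_px = fod_px, optics = stack$optics),
            class = "reflection_matrix")
}

#' Zero-pad a rectangular sub-matrix to square
#'
#' Appends zero columns so that the column index set equals the row index
#' set (the output-window lattice): real columns keep the lattice position
#' of their scan position, every other lattice position gets an all-zero
#' column. Zero columns contribute nothing to the CLASS sums; the Frobenius
#' norm is unchanged.
#'
#' @param R a lattice-row `reflection_matrix` from [build_sub_matrix()].
#' @return a square `reflection_matrix` with `real_cols` marking the columns
#'   holding data.
#' @export
pad_to_square <- function(R) {
  stopifnot(inherits(R, "reflection_matrix"))
  if (is.null(R$lattice)) stop_invalid("pad_to_square() needs lattice rows")
  n_o <- prod(R$row_dims); n_i <- ncol(R$m)
  if (n_o < n_i) stop_invalid("N_o < N_i: output window smaller than the tile")
  ry <- match(R$scan_px[, 1], R$lattice$y)
  rx <- match(R$scan_px[, 2], R$lattice$x)
  if (anyNA(ry) || anyNA(rx))
    stop_invalid("scan positions do not lie on the output lattice")
  cols <- (rx - 1L) * R$row_dims[1] + ry
  m2 <- matrix(0i, n_o, n_o)
  m2[, cols] <- R$m
  out <- R
  out$m <- m2
  out$square <- TRUE
  out$real_cols <- cols
  out
}

#' Locally varying CLASS correction
#'
#' Runs the CLASS algorithm independently in every tile of a field-of-
#' illumination tiling, on the zero-padded rectangular sub-matrix of each
#' tile, so that the retrieved aberration maps keep the full set of modes
#' supported by the analysis field of detection even when the tile shrinks
#' to the isoplanatic-patch size. In the default `"reciprocity"` mode only
#' the output map is estimated per sweep and the input increment is its
#' mirror \eqn{\phi_i(k) = \phi_o(-k)} — appropriate because the padded
#' matrix has few real columns; `"two_sided"` runs the full two-map
#' iteration.
#'
#' @param stack a `field_stack` (de-scanned stacks are converted).
#' @param tiling a [tile_foi()] tiling.
#' @param tol_rms_rad,max_iter convergence controls per tile.
#' @param mode `"reciprocity"` or `"two_sided"`.
#' @param fod_px analysis FOD side in pixels (default: recorded FOD).
#' @return object of class `local_class_fit`: per-tile results (aberration
#'   maps on the tile k-grid, corrected tile image over the tile's scan
#'   positions, diagnostics), the stitched corrected image and the tiling.
#'   Per-tile non-convergence is flagged, not fatal.
#' @export
run_local_class <- function(stack, tiling, tol_rms_rad = 0.01, max_iter = 50,
                            mode = c("reciprocity", "two_sided"),
                            fod_px = stack$fod_px) {
  stopifnot(inherits(stack, "field_stack"), inherits(tiling, "foi_tiling"))
  mode <- match.arg(mode)
  if (stack$frame == "descanned") stack <- descan_to_lab(stack)
  dd <- diffraction_limit(stack$optics)
  fod_um <- fod_px * stack$optics$pixel_pitch
  n_modes_fod <- round(pi * (fod_um / (2 * dd))^2)
  tiles <- vector("list", length(tiling$tiles))
  for (t in seq_along(tiling$tiles)) {
    tile <- tiling$tiles[[t]]
    Rsq <- pad_to_square(build_sub_matrix(stack, tile, fod_px))
    Rt <- to_spectral(Rsq)
    ctx <- spectral_context(Rt)
    it <- class_iterate(Rt$m, ctx, tol_rms_rad, max_iter,
                        reciprocity = mode == "reciprocity")
    m_c <- it$m
    # corrected space-domain matrix; tile image from the real columns only
    Rt_c <- Rt; Rt_c$m <- m_c
    R_c <- from_spectral(Rt_c)
    conf <- diag(R_c$m)[Rsq$real_cols]
    conf0 <- diag(from_spectral(Rt)$m)[Rsq$real_cols]
    img <- matrix(Mod(conf)^2, tile$full$y[2] - tile$full$y[1] + 1L,
                  tile$full$x[2] - tile$full$x[1] + 1L)
    img0 <- matrix(Mod(conf0)^2, nrow(img), ncol(img))
    as_map <- function(acc, side) {
      p <- wrap_phase(-acc)
      mk <- as.vector(Rt$mask)
      p[mk] <- wrap_phase(p[mk] - circ_mean(p[mk]))
      p[!mk] <- 0
      new_pupil_phase(matrix(p, Rt$dims[1], Rt$dims[2]), Rt$mask,
                      Rt$ky, Rt$kx, Rt$k_na, side, Rt$optics)
    }
    tiles[[t]] <- list(row = tile$row, col = tile$col,
                       phi_i = as_map(it$acc_i, "input"),
                       phi_o = as_map(it$acc_o, "output"),
                       image = img, image_uncorrected = img0,
                       objective_gain = sum(img) / max(sum(img0), 1e-300),
                       converged = it$converged,
                       iterations = it$iterations,
                       n_modes = n_modes_fod,
                       log = it$log)
  }
  stitched <- stitch_tiles(tiles, tiling)
  stitched0 <- stitch_tiles(tiles, tiling, field = "image_uncorrected")
  structure(list(tiles = tiles, tiling = tiling, mode = mode,
                 fod_px = fod_px, n_modes = n_modes_fod,
                 image = stitched, ocm = stitched0,
                 optics = stack$optics),
            class = "local_class_fit")
}

# Separable raised-cosine blending weight for one tile along one axis.
tile_weight_1d <- function(core, full, m, n_total) {
  p <- full[1]:full[2]
  w <- rep(1, length(p))
  if (m > 0) {
    if (core[1] > 1) {                      # left ramp over [c0-m, c0+m)
      u <- ((core[1] + m) - p) / (2 * m)
      w <- w * ifelse(u <= 0, 1, cos(pi * pmin(u, 1) / 2)^2)
    }
    if (core[2] < n_total) {                # right ramp over (c1-m, c1+m]
      u <- (p - (core[2] - m)) / (2 * m)
      w <- w * ifelse(u <= 0, 1, cos(pi * pmin(u, 1) / 2)^2)
    }
  }
  w
}

stitch_tiles <- function(tiles, tiling, field = "image") {
  out <- matrix(0, tiling$scan_dims[1], tiling$scan_dims[2])
  wsum <- matrix(0, tiling$scan_dims[1], tiling$scan_dims[2])
  for (t in seq_along(tiles)) {
    tile <- tiling$tiles[[t]]
    wy <- tile_weight_1d(tile$core$y, tile$full$y, tiling$margin_scan,
                         tiling$scan_dims[1])
    wx <- tile_weight_1d(tile$core$x, tile$full$x, tiling$margin_scan,
                         tiling$scan_dims[2])
    w <- outer(wy, wx)
    ys <- tile$full$y[1]:tile$full$y[2]
    xs <- tile$full$x[1]:tile$full$x[2]
    out[ys, xs] <- out[ys, xs] + w * tiles[[t]][[field]]
    wsum[ys, xs] <- wsum[ys, xs] + w
  }
  out / wsum
}

#' Stitch corrected tile images
#'
#' Blends the per-tile corrected images of a [run_local_class()] fit with
#' raised-cosine weights across the overlap margins; weights form a
#' partition of unity over the field of illumination.
#'
#' @param fit a `local_class_fit`.
#' @return numeric matrix over the scan grid.
#' @export
stitch <- function(fit) {
  stopifnot(inherits(fit, "local_class_fit"))
  stitch_tiles(fit$tiles, fit$tiling)
}

#' @export
print.local_class_fit <- function(x, ...) {
  nt <- length(x$tiles)
  conv <- sum(vapply(x$tiles, function(t) t$converged, logical(1)))
  cat("Local CLASS fit: ", x$tiling$n_tiles[1], " x ", x$tiling$n_tiles[2],
      " tiles (", conv, "/", nt, " converged), mode ", x$mode, "\n", sep = "")
  cat("  modes per aberration map (FOD-supported): ", x$n_modes, "\n", sep = "")
  cat("  stitched confocal gain: ", signif(sum(x$image) / sum(x$ocm), 4),
      "\n", sep = "")
  invisible(x)
}

#' @export
fitted.local_class_fit <- function(object, ...) object$image

#' @export
coef.local_class_fit <- function(object, ...) {
  lapply(object$tiles, function(t) list(phi_i = t$phi_i$phase,
                                        phi_o = t$phi_o$phase))
}

#' @export
plot.local_class_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  show <- function(img, main) {
    graphics::image(t(img)[, rev(seq_len(nrow(img)))], asp = 1, axes = FALSE,
                    col = grDevices::hcl.colors(64, "Inferno"), main = main)
  }
  show(x$ocm, "uncorrected")
  show(x$image, "local CLASS, stitched")
  invisible(x)
}

#' Estimate the isoplanatic-patch size
#'
#' Sweeps candidate subregion sides, runs the local CLASS correction for
#' each, and returns the side that maximises the mean corrected confocal
#' intensity: subregions larger than the isoplanatic patch average
#' incompatible aberrations and lose intensity, smaller ones gain nothing.
#' A plateau (top candidates within 2%) is flagged.
#'
#' @param stack a `field_stack`.
#' @param candidate_sides numeric vector of candidate subregion sides (um);
#'   a single candidate is returned as-is with a warning.
#' @param ... passed to [run_local_class()].
#' @return object of class `isoplanatic_search`: `side` (the estimate),
#'   `sweep` (data frame of candidate, mean corrected intensity), `plateau`.
#' @export
estimate_isoplanatic_size <- function(stack, candidate_sides, ...) {
  stopifnot(inherits(stack, "field_stack"))
  if (length(candidate_sides) < 1) stop_invalid("need at least one candidate")
  if (length(candidate_sides) == 1) {
    warning("single candidate side; returning it without a sweep")
    return(structure(list(side = candidate_sides, plateau = FALSE,
                          sweep = data.frame(side = candidate_sides,
                                             mean_intensity = NA_real_)),
                     class = "isoplanatic_search"))
  }
  if (stack$frame == "descanned") stack <- descan_to_lab(stack)
  vals <- vapply(candidate_sides, function(s) {
    fit <- run_local_class(stack, tile_foi(stack, s), ...)
    mean(fit$image)
  }, numeric(1))
  best <- which.max(vals)
  srt <- sort(vals, decreasing = TRUE)
  plateau <- length(srt) > 1 && (srt[1] - srt[2]) / srt[1] < 0.02
  structure(list(side = candidate_sides[best],
                 sweep = data.frame(side = candidate_sides,
                                    mean_intensity = vals),
                 plateau = plateau),
            class = "isoplanatic_search")
}

#' @export
print.isoplanatic_search <- function(x, ...) {
  cat("Isoplanatic-patch search: best side =", x$side, "um",
      if (x$plateau) "(plateau)" else "", "\n")
  print(x$sweep)
  invisible(x)
}
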