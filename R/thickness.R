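#' Log-ratio thickness model
#'
#' Parameters of the EELS-style log-ratio thickness estimate
#' `Z = lambda * ln(I0 / I)`: the inelastic mean free path `lambda` of
#' electrons through the specimen (332 nm by default, appropriate for a
#' hydrated-density peptide crystal at 300 kV) and the incident intensity
#' `I0` in electrons per frame.
#'
#' @param lambda_mfp_nm mean free path, nm (> 0).
#' @param i0_e incident intensity estimate, electrons per frame (> 0).
#' @return an object of class `ThicknessModel`.
#' @export
thickness_model <- function(lambda_mfp_nm = 332, i0_e) {
  if (lambda_mfp_nm <= 0) stop("lambda_mfp_nm must be > 0")
  if (!is.finite(i0_e) || i0_e <= 0) stop("i0_e must be > 0")
  structure(list(lambda_mfp_nm = lambda_mfp_nm, i0_e = i0_e),
            class = "ThicknessModel")
}

#' Estimate the incident intensity from a vacuum region
#'
#' `I0` is the mean transmitted intensity over scan positions sampling
#' vacuum (a hole in the support film) minus two standard deviations of
#' those values, a conservative allowance for beam-current fluctuation.
#'
#' @param transmitted a `VirtualImage` from [transmitted_intensity_map()].
#' @param vacuum_region a [region_mask()] of vacuum scan positions.
#' @return `I0` in electrons per frame.
#' @export
estimate_i0 <- function(transmitted, vacuum_region) {
  stopifnot(inherits(transmitted, "VirtualImage"),
            inherits(vacuum_region, "RegionMask"))
  v <- transmitted$values[vacuum_region$mask]
  if (length(v) == 0) stop("empty vacuum region")
  i0 <- mean(v) - 2 * stats::sd(v)
  if (length(v) == 1) i0 <- v  # zero-variance degenerate case
  if (!is.finite(i0) || i0 <= 0) {
    stop("estimated I0 is non-positive; check the vacuum region")
  }
  i0
}

#' Per-scan-position thickness map from the log-ratio model
#'
#' `Z_xy = lambda * ln(I0 / I_xy)`. Pixels with `I_xy <= 0` are flagged
#' invalid; pixels brighter than `I0` (apparent negative thickness, from
#' noise around vacuum) are clamped to 0 and counted in a message.
#'
#' @param transmitted a `VirtualImage` of transmitted electrons per frame.
#' @param model a [thickness_model()].
#' @return an object of class `ThicknessMap`: scan-shaped `z_nm`, logical
#'   `valid`, and the model.
#' @export
thickness_map <- function(transmitted, model) {
  stopifnot(inherits(transmitted, "VirtualImage"),
            inherits(model, "ThicknessModel"))
  i_xy <- transmitted$values
  valid <- i_xy > 0
  z <- matrix(NA_real_, nrow(i_xy), ncol(i_xy))
  z[valid] <- model$lambda_mfp_nm * log(model$i0_e / i_xy[valid])
  n_clamped <- sum(z[valid] < 0)
  if (n_clamped > 0) {
    message(sprintf("thickness_map: %d pixel(s) brighter than I0 clamped to 0",
                    n_clamped))
    z[valid & z < 0] <- 0
  }
  structure(list(z_nm = z, valid = valid, model = model),
            class = "ThicknessMap")
}

#' @export
print.ThicknessMap <- function(x, ...) {
  zz <- x$z_nm[x$valid]
  cat(sprintf("ThicknessMap: %d x %d scan px, %d valid, z in [%.3g, %.3g] nm\n",
              nrow(x$z_nm), ncol(x$z_nm), sum(x$valid),
              min(zz), max(zz)))
  invisible(x)
}

# Best integer shift (d_row, d_col) aligning `img` onto `ref`, by maximizing
# the correlation of the overlap over shifts within +/- max_shift.
best_integer_shift <- function(ref, img, max_shift = 8) {
  best <- c(0L, 0L); best_score <- -Inf
  nr <- nrow(ref); nc <- ncol(ref)
  grid <- expand.grid(dr = -max_shift:max_shift, dc = -max_shift:max_shift)
  grid <- grid[order(grid$dr^2 + grid$dc^2), ]  # ties favour small shifts
  for (g in seq_len(nrow(grid))) {
    dr <- grid$dr[g]; dc <- grid$dc[g]
    r1 <- max(1, 1 + dr):min(nr, nr + dr)
    c1 <- max(1, 1 + dc):min(nc, nc + dc)
    if (length(r1) < 4 || length(c1) < 4) next
    a <- ref[r1, c1]
    b <- img[r1 - dr, c1 - dc]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      score <- -mean((a - b)^2)  # degenerate: fall back to mean SSD
    } else {
      score <- stats::cor(as.vector(a), as.vector(b))
    }
    if (score > best_score + 1e-12) {
      best_score <- score
      best <- c(as.integer(dr), as.integer(dc))
    }
  }
  best
}

#' Prepare thickness maps as an aligned, background-corrected tilt stack
#'
#' The input a tomographic reconstruction would consume: consecutive maps
#' are aligned by integer-pixel cross-correlation (cumulative, relative to
#' the first map), cropped to the field of view common to the whole series
#' (sample drift removes the rest), a flat background measured on a vacuum
#' strip is subtracted, and negative values are clipped to zero.
#'
#' @param maps list (length >= 2) of [thickness_map()] objects or plain
#'   matrices.
#' @param tilts optional tilt angles carried through to the output.
#' @param max_shift_px alignment search radius, px.
#' @param vacuum_strip logical matrix (input shape) marking vacuum pixels
#'   for the background estimate; `NULL` picks the border strip (width 2)
#'   with the lowest mean in the first map.
#' @return list with `stack` (3D array `rows x cols x n` of the aligned,
#'   cropped, background-subtracted maps), `shifts` (n x 2), `crop`
#'   (row/col ranges kept) and `tilts`.
#' @export
prepare_tilt_images <- function(maps, tilts = NULL, max_shift_px = 8,
                                vacuum_strip = NULL) {
  stopifnot(is.list(maps), length(maps) >= 2)
  imgs <- lapply(maps, function(m) {
    z <- if (inherits(m, "ThicknessMap")) m$z_nm else m
    z[!is.finite(z)] <- 0
    z
  })
  nr <- nrow(imgs[[1]]); nc <- ncol(imgs[[1]])
  stopifnot(all(vapply(imgs, function(m) nrow(m) == nr && ncol(m) == nc,
                       logical(1))))
  n <- length(imgs)
  shifts <- matrix(0L, n, 2)
  for (i in 2:n) {
    rel <- best_integer_shift(imgs[[i - 1]], imgs[[i]], max_shift_px)
    shifts[i, ] <- shifts[i - 1, ] + rel
  }
  # shifts[i, ] is the correction that aligns map i onto map 1
  r_lo <- 1 + max(0, max(shifts[, 1])); r_hi <- nr + min(0, min(shifts[, 1]))
  c_lo <- 1 + max(0, max(shifts[, 2])); c_hi <- nc + min(0, min(shifts[, 2]))
  if (r_lo > r_hi || c_lo > c_hi) {
    stop("no common field of view after alignment cropping")
  }
  if (is.null(vacuum_strip)) {
    cand <- list(imgs[[1]][1:min(2, nr), , drop = FALSE],
                 imgs[[1]][max(1, nr - 1):nr, , drop = FALSE],
                 imgs[[1]][, 1:min(2, nc), drop = FALSE],
                 imgs[[1]][, max(1, nc - 1):nc, drop = FALSE])
    pick <- which.min(vapply(cand, mean, numeric(1)))
    vacuum_strip <- matrix(FALSE, nr, nc)
    if (pick == 1) vacuum_strip[1:min(2, nr), ] <- TRUE
    if (pick == 2) vacuum_strip[max(1, nr - 1):nr, ] <- TRUE
    if (pick == 3) vacuum_strip[, 1:min(2, nc)] <- TRUE
    if (pick == 4) vacuum_strip[, max(1, nc - 1):nc] <- TRUE
  }
  out <- array(0, dim = c(r_hi - r_lo + 1, c_hi - c_lo + 1, n))
  for (i in seq_len(n)) {
    aligned <- shift_matrix(imgs[[i]], shifts[i, 1], shifts[i, 2], fill = 0)
    bg <- mean(imgs[[i]][vacuum_strip])
    cropped <- aligned[r_lo:r_hi, c_lo:c_hi, drop = FALSE] - bg
    cropped[cropped < 0] <- 0
    out[, , i] <- cropped
  }
  list(stack = out, shifts = shifts,
       crop = list(rows = c(r_lo, r_hi), cols = c(c_lo, c_hi)),
       tilts = tilts)
}

#' Write a thickness map as 32-bit TIFF (with scale sidecar)
#'
#' Invalid pixels are written as 0.
#'
#' @param map a [thickness_map()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_thickness_tiff <- function(map, path) {
  stopifnot(inherits(map, "ThicknessMap"))
  z <- map$z_nm
  z[!map$valid] <- 0
  write_float_tiff(z, path)
}
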