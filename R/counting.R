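#' Detector noise model for hybrid electron counting
#'
#' @param dark_map per-pixel dark level, ADU (detector-shaped matrix).
#' @param sigma_adu Gaussian read-noise width, ADU (> 0).
#' @param gain_adu_per_electron single-electron gain, ADU (> 0).
#' @param threshold_adu counting threshold, ADU (> 0); readings at or below
#'   it are treated as noise.
#' @param k_sigma the multiple of `sigma_adu` the threshold was derived
#'   from (metadata).
#' @return an object of class `NoiseModel`.
#' @export
noise_model <- function(dark_map, sigma_adu, gain_adu_per_electron,
                        threshold_adu, k_sigma = NA_real_) {
  stopifnot(is.matrix(dark_map))
  if (!is.finite(sigma_adu) || sigma_adu <= 0) stop("sigma_adu must be > 0")
  if (!is.finite(gain_adu_per_electron) || gain_adu_per_electron <= 0) {
    stop("gain_adu_per_electron must be > 0")
  }
  if (!is.finite(threshold_adu) || threshold_adu <= 0) {
    stop("threshold_adu must be > 0")
  }
  structure(list(dark_map = dark_map, sigma_adu = sigma_adu,
                 gain_adu_per_electron = gain_adu_per_electron,
                 threshold_adu = threshold_adu, k_sigma = k_sigma),
            class = "NoiseModel")
}

#' @export
print.NoiseModel <- function(x, ...) {
  cat(sprintf(
    "NoiseModel: sigma %.3g ADU, gain %.4g ADU/e-, threshold %.4g ADU (k = %g), dark median %.4g ADU\n",
    x$sigma_adu, x$gain_adu_per_electron, x$threshold_adu, x$k_sigma,
    stats::median(x$dark_map)))
  invisible(x)
}

#' Estimate the per-pixel dark level from a sparse stack
#'
#' With sparse electron arrival almost every reading of a pixel is dark, so
#' the temporal per-pixel median across all scan positions recovers the dark
#' level robustly even at pixels occasionally struck by electrons.
#'
#' @param stack a raw-ADU [frame_stack()] with at least 16 frames.
#' @return detector-shaped matrix of per-pixel dark levels (ADU).
#' @export
estimate_dark <- function(stack) {
  stopifnot(inherits(stack, "FrameStack4D"))
  d <- dim(stack$data)
  if (d[1] * d[2] < 16) {
    stop("estimate_dark needs at least 16 frames, got ", d[1] * d[2])
  }
  m <- frames_matrix(stack$data)
  matrix(apply(m, 2, stats::median), d[3], d[4])
}

#' Fit a Gaussian read-noise model and counting threshold
#'
#' Fits the central (noise) mode of the dark-subtracted pixel-value
#' distribution, ignoring the positive tail contributed by electron events:
#' the location and scale are estimated by median/MAD and refined once by
#' the trimmed standard deviation within 4 robust sigma. The counting
#' threshold is `k_sigma * sigma`. Unless supplied, the single-electron
#' gain is estimated as the mode (kernel density peak) of the above-threshold
#' values, where single hits dominate for sparse data.
#'
#' @param stack a raw-ADU [frame_stack()].
#' @param dark_map per-pixel dark map, e.g. from [estimate_dark()].
#' @param k_sigma threshold multiple of the fitted sigma (default 4).
#' @param gain_adu_per_electron known gain, ADU/e-; `NULL` to estimate.
#' @return a [noise_model()].
#' @export
fit_noise_model <- function(stack, dark_map, k_sigma = 4,
                            gain_adu_per_electron = NULL) {
  stopifnot(inherits(stack, "FrameStack4D"), is.matrix(dark_map))
  if (k_sigma <= 0) stop("k_sigma must be > 0")
  d <- dim(stack$data)
  m <- frames_matrix(stack$data)
  resid <- as.vector(sweep(m, 2, as.vector(dark_map)))
  if (stats::sd(resid) == 0) {
    stop("degenerate histogram: all dark-subtracted values identical")
  }
  mu <- stats::median(resid)
  s <- stats::mad(resid)
  if (s == 0) s <- stats::sd(resid)
  for (i in 1:2) {
    core <- resid[abs(resid - mu) < 4 * s]
    mu <- mean(core)
    s <- stats::sd(core)
    if (!is.finite(s) || s == 0) {
      stop("degenerate histogram: no spread in the central mode")
    }
  }
  threshold <- k_sigma * s
  gain <- gain_adu_per_electron
  if (is.null(gain)) {
    events <- resid[resid > threshold]
    if (length(events) < 50) {
      stop("too few above-threshold events to estimate the gain; ",
           "supply gain_adu_per_electron")
    }
    # fixed narrow bandwidth: the coincident-beam tail would otherwise set
    # a huge Silverman bandwidth and smear the single-electron mode
    dens <- stats::density(events, bw = max(s / 2, 0.5), n = 2048)
    gain <- dens$x[which.max(dens$y)]
  }
  noise_model(dark_map, sigma_adu = s, gain_adu_per_electron = gain,
              threshold_adu = threshold, k_sigma = k_sigma)
}

#' Convert a dark-subtracted frame to hybrid electron counts
#'
#' Per pixel, a value `v` becomes 0 when `v <= threshold`, otherwise
#' `max(1, round(v / gain))`: thresholding gives counting's noise rejection
#' while quantizing by the single-electron gain retains the multiplicity of
#' coincident arrivals that pure binary counting discards.
#'
#' @param frame dark-subtracted numeric matrix (or array), ADU.
#' @param model a [noise_model()].
#' @return integer matrix/array of electron counts.
#' @export
hybridize <- function(frame, model) {
  stopifnot(inherits(model, "NoiseModel"))
  if (model$gain_adu_per_electron <= 0) stop("non-positive gain")
  out <- ifelse(frame <= model$threshold_adu, 0,
                pmax(1, round(frame / model$gain_adu_per_electron)))
  storage.mode(out) <- "integer"
  out
}

#' Binary (single-bit) counting of a dark-subtracted frame
#'
#' Comparison baseline for [hybridize()]: every above-threshold pixel maps
#' to exactly one count, so coincident arrivals are undercounted.
#'
#' @inheritParams hybridize
#' @return integer matrix/array of 0/1 counts.
#' @export
binarize <- function(frame, model) {
  stopifnot(inherits(model, "NoiseModel"))
  out <- ifelse(frame <= model$threshold_adu, 0L, 1L)
  storage.mode(out) <- "integer"
  out
}

#' Convert a whole raw stack to hybrid counts
#'
#' Subtracts the model's dark map from every frame, then applies
#' [hybridize()] (or [binarize()]) elementwise.
#'
#' @param stack a raw-ADU [frame_stack()].
#' @param model a [noise_model()].
#' @param method `"hybrid"` or `"binary"`.
#' @return a `FrameStack4D` with `dtype_tag = "hybrid_counts"`.
#' @export
count_stack <- function(stack, model, method = c("hybrid", "binary")) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "FrameStack4D"), inherits(model, "NoiseModel"))
  d <- dim(stack$data)
  stopifnot(all(dim(model$dark_map) == d[3:4]))
  dark4 <- array(rep(as.vector(model$dark_map), each = d[1] * d[2]), dim = d)
  resid <- stack$data - dark4
  counts <- if (method == "hybrid") hybridize(resid, model) else
    binarize(resid, model)
  frame_stack(counts, stack$geometry, dtype_tag = "hybrid_counts")
}

#' Align all frames of a stack to a common beam centre
#'
#' Finds the primary (unscattered) beam in each frame as the brightest
#' pixel, requires it to stand out from the dark level by more than
#' `5 * sigma_adu`, computes the intensity centre of mass within a window
#' of `beam_window_radius_px` around it, and shifts the frame by whole
#' pixels so that centre lands on the central detector pixel. Vacated
#' pixels are filled with the dark map (or 0 when none is given) so that
#' later dark subtraction zeroes them. Frames with no qualifying maximum
#' are flagged unalignable and left unshifted.
#'
#' @param stack a raw-ADU [frame_stack()].
#' @param beam_window_radius_px centre-of-mass window radius, px (> 0).
#' @param dark_map optional per-pixel dark map (defaults to all zero).
#' @param sigma_adu read-noise width used for the seed test (default 0:
#'   any value above dark qualifies).
#' @return list with `stack` (aligned `FrameStack4D`) and `alignment`
#'   (class `AlignmentResult`: data frame of per-frame shifts with columns
#'   `scan_row, scan_col, d_row, d_col, alignable`, plus the common centre).
#' @export
align_to_common_centre <- function(stack, beam_window_radius_px,
                                   dark_map = NULL, sigma_adu = 0) {
  stopifnot(inherits(stack, "FrameStack4D"))
  if (beam_window_radius_px <= 0) stop("beam_window_radius_px must be > 0")
  d <- dim(stack$data)
  dark <- dark_map %||% matrix(0, d[3], d[4])
  stopifnot(all(dim(dark) == d[3:4]))
  centre <- det_centre_px(d[3:4])
  out <- stack$data
  rows <- matrix(seq_len(d[3]), d[3], d[4])
  cols <- matrix(seq_len(d[4]), d[3], d[4], byrow = TRUE)
  nfr <- d[1] * d[2]
  s_row <- integer(nfr); s_col <- integer(nfr)
  s_dr <- integer(nfr); s_dc <- integer(nfr); s_ok <- logical(nfr)
  n_bad <- 0L
  i <- 0L
  for (sr in seq_len(d[1])) {
    for (sc in seq_len(d[2])) {
      i <- i + 1L
      s_row[i] <- sr; s_col[i] <- sc
      fr <- stack$data[sr, sc, , ] - dark
      peak <- arrayInd(which.max(fr), d[3:4])
      if (fr[peak] <= 5 * sigma_adu) {
        n_bad <- n_bad + 1L
        s_ok[i] <- FALSE
        next
      }
      win <- abs(rows - peak[1]) <= beam_window_radius_px &
        abs(cols - peak[2]) <= beam_window_radius_px
      w <- pmax(fr, 0) * win
      com_r <- sum(w * rows) / sum(w)
      com_c <- sum(w * cols) / sum(w)
      dr <- as.integer(round(centre[1] - com_r))
      dc <- as.integer(round(centre[2] - com_c))
      if (dr != 0L || dc != 0L) {
        out[sr, sc, , ] <- shift_matrix(stack$data[sr, sc, , ], dr, dc,
                                        fill = dark)
      }
      s_dr[i] <- dr; s_dc[i] <- dc; s_ok[i] <- TRUE
    }
  }
  shifts <- data.frame(scan_row = s_row, scan_col = s_col,
                       d_row = s_dr, d_col = s_dc, alignable = s_ok)
  if (n_bad > 0) {
    message(sprintf("align_to_common_centre: %d frame(s) unalignable (no pixel above dark + 5 sigma)",
                    n_bad))
  }
  shifts <- shifts[order(shifts$scan_row, shifts$scan_col), ]
  rownames(shifts) <- NULL
  aligned <- frame_stack(out, stack$geometry, dtype_tag = stack$dtype_tag)
  res <- structure(list(shifts = shifts, common_centre = centre),
                   class = "AlignmentResult")
  list(stack = aligned, alignment = res)
}

#' Serialize a noise model to a plain-text sidecar
#'
#' @param model a [noise_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_noise_model <- function(model, path) {
  stopifnot(inherits(model, "NoiseModel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("FORMAT = STEM4D_NOISE_MODEL_V1",
               paste("SIGMA_ADU =", fmt_num(model$sigma_adu)),
               paste("GAIN_ADU_PER_ELECTRON =",
                     fmt_num(model$gain_adu_per_electron)),
               paste("THRESHOLD_ADU =", fmt_num(model$threshold_adu)),
               paste("K_SIGMA =", fmt_num(model$k_sigma)),
               paste("DARK_ROWS =", nrow(model$dark_map)),
               paste("DARK_COLS =", ncol(model$dark_map))), con)
  utils::write.table(format(model$dark_map, digits = 17, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a noise model written by [write_noise_model()]
#'
#' @param path file path.
#' @return a [noise_model()].
#' @export
read_noise_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:7]
  kv <- parse_kv_lines(hdr)
  nr <- as.integer(kv[["DARK_ROWS"]])
  vals <- scan(text = lines[-(1:7)], quiet = TRUE)
  dark <- matrix(vals, nrow = nr, byrow = TRUE)
  noise_model(dark, sigma_adu = as.numeric(kv[["SIGMA_ADU"]]),
              gain_adu_per_electron = as.numeric(kv[["GAIN_ADU_PER_ELECTRON"]]),
              threshold_adu = as.numeric(kv[["THRESHOLD_ADU"]]),
              k_sigma = as.numeric(kv[["K_SIGMA"]]))
}
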