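#' Annular virtual detector in diffraction space
#'
#' A digital analogue of an annular dark-field detector: pixels whose
#' distance `d` from the centre satisfies `inner <= d < outer` are
#' integrated. `outer = Inf` extends to the detector edge; `inner = 0`
#' with a finite `outer` gives a bright-field disc.
#'
#' @param inner_radius_px inner radius, px (>= 0).
#' @param outer_radius_px outer radius, px (> inner; may be `Inf`).
#' @param centre `(row, col)` detector centre; `NULL` uses the stack's
#'   central pixel at evaluation time.
#' @return an object of class `VirtualDetector`.
#' @export
virtual_detector <- function(inner_radius_px, outer_radius_px = Inf,
                             centre = NULL) {
  if (inner_radius_px < 0) stop("inner_radius_px must be >= 0")
  if (outer_radius_px <= inner_radius_px) {
    stop("outer_radius_px must exceed inner_radius_px")
  }
  structure(list(centre = centre, inner_radius_px = inner_radius_px,
                 outer_radius_px = outer_radius_px),
            class = "VirtualDetector")
}

detector_mask <- function(det, shape) {
  centre <- det$centre %||% det_centre_px(shape)
  dist <- dist_from(shape, centre)
  dist >= det$inner_radius_px & dist < det$outer_radius_px
}

new_virtual_image <- function(values, detector, source_tag) {
  structure(list(values = values, detector = detector,
                 source_tag = source_tag),
            class = "VirtualImage")
}

#' @export
print.VirtualImage <- function(x, ...) {
  cat(sprintf("VirtualImage [%s]: %d x %d scan px, range [%.4g, %.4g]\n",
              x$source_tag, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

# Sum of the masked detector pixels at every scan position.
virtual_sum <- function(stack, mask) {
  m <- frames_matrix(stack$data)
  v <- as.numeric(m %*% as.numeric(mask))
  matrix(v, dim(stack$data)[1], dim(stack$data)[2])
}

#' Reconstruct a scan-space virtual image from diffraction space
#'
#' At each scan position, sums the diffraction intensity falling inside the
#' virtual detector's annulus - the digital equivalent of recording with an
#' annular dark-field (or, with a disc, bright-field) detector during the
#' scan. Virtual imaging is linear in the stack, and a bright-field disc
#' plus the complementary annulus to the detector edge partition every
#' recorded count exactly.
#'
#' @param stack a [frame_stack()] (raw ADU or hybrid counts).
#' @param det a [virtual_detector()].
#' @return a `VirtualImage` (scan-shaped `values`, the detector used and
#'   the source dtype tag).
#' @export
virtual_image <- function(stack, det) {
  stopifnot(inherits(stack, "FrameStack4D"), inherits(det, "VirtualDetector"))
  shape <- det_shape(stack)
  mask <- detector_mask(det, shape)
  if (!any(mask)) stop("empty annulus: virtual detector does not intersect the frame")
  new_virtual_image(virtual_sum(stack, mask), det, stack$dtype_tag)
}

#' Estimate the central-beam disc radius of a diffraction pattern
#'
#' Radius at which the azimuthally averaged intensity first falls below
#' `floor_frac` of its central value - a simple, deterministic measure of
#' the primary-beam disc size on an aggregate pattern.
#'
#' @param pattern 2D pattern (typically the sum over all scan positions).
#' @param centre `(row, col)`; `NULL` uses the central pixel.
#' @param floor_frac fraction of the central radial intensity defining the
#'   disc edge (default 0.02).
#' @return disc radius in pixels (at least 1).
#' @export
beam_disc_radius <- function(pattern, centre = NULL, floor_frac = 0.02) {
  stopifnot(is.matrix(pattern))
  centre <- centre %||% det_centre_px(dim(pattern))
  dist <- dist_from(dim(pattern), centre)
  rmax <- floor(min(dim(pattern)) / 2) - 1
  prof <- vapply(seq_len(rmax), function(r) {
    sel <- dist >= (r - 1) & dist < r
    if (any(sel)) mean(pattern[sel]) else 0
  }, numeric(1))
  ref <- prof[1]
  below <- which(prof < floor_frac * ref)
  if (length(below) == 0) return(rmax)
  max(1L, below[1] - 1L)
}

#' Transmitted-intensity map for thickness estimation
#'
#' Estimates the transmitted electrons at every scan position as the sum of
#' two terms in electron units: the central-beam disc integrated on the raw
#' dark-subtracted detector values divided by the gain (the beam is too
#' intense for counting - coincidence saturates it), and discs of radius
#' `peak_radius_px` at each Bragg peak integrated on hybrid counts (the
#' sparse elastic signal, where counting is accurate). Omitting the elastic
#' term systematically overestimates the apparent transmission loss, so a
#' missing peak list only produces a beam-only map with a warning.
#'
#' @param stack_raw raw-ADU [frame_stack()], dark-subtracted (or supply
#'   `dark_map`).
#' @param beam a [virtual_detector()] disc covering the central beam.
#' @param gain_adu_per_electron single-electron gain used to convert the
#'   beam term to electrons.
#' @param peaks a peak list from [find_peaks()] (or any data frame with
#'   `det_row`, `det_col`), or `NULL`.
#' @param stack_counts hybrid-count [frame_stack()] aligned with
#'   `stack_raw`; required when `peaks` is given.
#' @param peak_radius_px integration disc radius at each peak, px.
#' @param dark_map optional per-pixel dark map subtracted from `stack_raw`.
#' @return a `VirtualImage` whose values are electrons per frame.
#' @export
transmitted_intensity_map <- function(stack_raw, beam, gain_adu_per_electron,
                                      peaks = NULL, stack_counts = NULL,
                                      peak_radius_px = 3, dark_map = NULL) {
  stopifnot(inherits(stack_raw, "FrameStack4D"),
            inherits(beam, "VirtualDetector"))
  if (gain_adu_per_electron <= 0) stop("gain_adu_per_electron must be > 0")
  shape <- det_shape(stack_raw)
  beam_mask <- detector_mask(beam, shape)
  if (!any(beam_mask)) stop("beam disc does not intersect the frame")
  data <- stack_raw$data
  if (!is.null(dark_map)) {
    d <- dim(data)
    data <- data - array(rep(as.vector(dark_map), each = d[1] * d[2]), dim = d)
  }
  raw <- frame_stack(data, stack_raw$geometry, dtype_tag = "raw_adu")
  beam_e <- virtual_sum(raw, beam_mask) / gain_adu_per_electron
  if (is.null(peaks)) {
    warning("no Bragg peak list supplied: transmitted map omits elastically ",
            "scattered electrons and will overestimate transmission loss")
    return(new_virtual_image(beam_e, beam, "electrons"))
  }
  if (is.null(stack_counts)) {
    stop("stack_counts (hybrid counts) is required when peaks are supplied")
  }
  stopifnot(inherits(stack_counts, "FrameStack4D"),
            stack_counts$dtype_tag == "hybrid_counts",
            all(det_shape(stack_counts) == shape))
  pk <- as.data.frame(peaks)
  peak_mask <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(nrow(pk))) {
    peak_mask <- peak_mask |
      (dist_from(shape, c(pk$det_row[i], pk$det_col[i])) <= peak_radius_px)
  }
  peak_mask <- peak_mask & !beam_mask
  peak_e <- if (any(peak_mask)) virtual_sum(stack_counts, peak_mask) else
    matrix(0, dim(data)[1], dim(data)[2])
  new_virtual_image(beam_e + peak_e, beam, "electrons")
}

#' Write a virtual image (or any float map) as 32-bit TIFF
#'
#' Values are stored scaled into \[0, 1\]; the multiplier is recorded in a
#' plain-text sidecar `<path>.scale` so [read_float_tiff()] restores the
#' original scale.
#'
#' @param values numeric matrix.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_float_tiff <- function(values, path) {
  stopifnot(is.matrix(values), all(is.finite(values)))
  lo <- min(values, 0)
  hi <- max(values)
  scale <- max(hi - lo, .Machine$double.eps)
  tiff::writeTIFF((values - lo) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  writeLines(c(paste("SCALE =", fmt_num(scale)), paste("OFFSET =", fmt_num(lo))),
             paste0(path, ".scale"))
  invisible(path)
}

#' Read a float map written by [write_float_tiff()]
#'
#' @param path TIFF path.
#' @return numeric matrix on the original scale.
#' @export
read_float_tiff <- function(path) {
  kv <- parse_kv_lines(readLines(paste0(path, ".scale")))
  m <- tiff::readTIFF(path)
  m * as.numeric(kv[["SCALE"]]) + as.numeric(kv[["OFFSET"]])
}
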