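#' Sum hybrid-count frames over a scan region
#'
#' The elementwise sum of the diffraction patterns at every scan position
#' selected by the region mask: the region-selected diffraction pattern for
#' this scan's orientation. Total counts are conserved exactly.
#'
#' @param stack a hybrid-count [frame_stack()].
#' @param region a [region_mask()] over the stack's scan grid.
#' @return integer detector-shaped matrix.
#' @export
sum_region <- function(stack, region) {
  stopifnot(inherits(stack, "FrameStack4D"), inherits(region, "RegionMask"))
  if (stack$dtype_tag != "hybrid_counts") {
    stop("sum_region expects hybrid counts; run count_stack() first")
  }
  d <- dim(stack$data)
  if (!all(dim(region$mask) == d[1:2])) {
    stop("region mask shape does not match the scan grid")
  }
  m <- frames_matrix(stack$data)
  sel <- which(as.vector(region$mask))
  pat <- colSums(m[sel, , drop = FALSE])
  matrix(as.integer(round(pat)), d[3], d[4])
}

#' Assemble an ordered diffraction tilt series from region-selected sums
#'
#' Sums each tilt's stack over its region and orders the results by tilt
#' angle. Tilts must be unique; entries whose region selects no scan
#' position are skipped with a warning (a gap in the series).
#'
#' @param stacks list of hybrid-count [frame_stack()], one per tilt.
#' @param regions a single [region_mask()] reused for every tilt, or a
#'   list with one region per tilt.
#' @return an object of class `TiltSeries`: list of entries
#'   `(tilt_deg, pattern, label, n_frames_summed)` plus per-entry geometry.
#' @export
assemble_series <- function(stacks, regions) {
  stopifnot(is.list(stacks), length(stacks) >= 1)
  if (inherits(regions, "RegionMask")) {
    regions <- rep(list(regions), length(stacks))
  }
  stopifnot(length(regions) == length(stacks))
  tilts <- vapply(stacks, function(s) s$geometry$tilt_deg, numeric(1))
  if (anyDuplicated(tilts)) {
    stop("duplicate tilt angles: ",
         paste(unique(tilts[duplicated(tilts)]), collapse = ", "))
  }
  ds <- det_shape(stacks[[1]])
  ord <- order(tilts)
  entries <- list()
  geoms <- list()
  n_skipped <- 0L
  for (i in ord) {
    if (!all(det_shape(stacks[[i]]) == ds)) {
      stop("all stacks must share the detector shape")
    }
    n_sel <- sum(regions[[i]]$mask)
    if (n_sel == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    entries[[length(entries) + 1L]] <- list(
      tilt_deg = tilts[i],
      pattern = sum_region(stacks[[i]], regions[[i]]),
      label = regions[[i]]$label,
      n_frames_summed = n_sel)
    geoms[[length(geoms) + 1L]] <- stacks[[i]]$geometry
  }
  if (n_skipped > 0) {
    warning(sprintf("%d tilt(s) skipped: empty region", n_skipped))
  }
  structure(list(entries = entries, geometry = geoms), class = "TiltSeries")
}

#' @export
print.TiltSeries <- function(x, ...) {
  n <- length(x$entries)
  if (n == 0) {
    cat("TiltSeries: empty\n")
  } else {
    t0 <- x$entries[[1]]$tilt_deg
    t1 <- x$entries[[n]]$tilt_deg
    cat(sprintf("TiltSeries: %d pattern(s), tilts %g..%g deg\n", n, t0, t1))
  }
  invisible(x)
}

#' @export
length.TiltSeries <- function(x) length(x$entries)

#' Export a tilt series as a directory of SMV images
#'
#' One SMV file per summed pattern, named by sequence
#' (`pattern_001.img`, ...), with `OSC_START` (and `PHI`) set to the tilt
#' angle and `OSC_RANGE` to `osc_range_deg` (0 marks stills).
#'
#' @param series a [assemble_series()] result.
#' @param out_dir output directory (created if missing).
#' @param osc_range_deg oscillation range written per image.
#' @param pedestal,pixel_size_mm,distance_mm passed to [write_smv()].
#' @return character vector of file paths (empty, with a warning, for an
#'   empty series).
#' @export
export_series_smv <- function(series, out_dir, osc_range_deg = 0,
                              pedestal = 0, pixel_size_mm = 0.01,
                              distance_mm = 1000) {
  stopifnot(inherits(series, "TiltSeries"))
  if (length(series$entries) == 0) {
    warning("empty tilt series: nothing exported")
    return(character(0))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(series$entries))
  for (i in seq_along(series$entries)) {
    e <- series$entries[[i]]
    paths[i] <- file.path(out_dir, sprintf("pattern_%03d.img", i))
    write_smv(e$pattern, series$geometry[[i]], osc_start_deg = e$tilt_deg,
              osc_range_deg = osc_range_deg, path = paths[i],
              pedestal = pedestal, pixel_size_mm = pixel_size_mm,
              distance_mm = distance_mm)
  }
  paths
}

#' Exposure and geometry budget of a scanned-diffraction tilt series
#'
#' The dose bookkeeping that makes coarse-stepped nanobeam scanning gentle:
#' the area mapped by one scan step (`step^2`) versus the area actually
#' illuminated by the probe (`pi * (FWHM/2)^2`), their ratio, and the
#' nominal dose accumulated over the full series
#' (`n_tilts * dose_per_frame`).
#'
#' @param geom a [scan_geometry()].
#' @param n_tilts number of tilts in the series (> 0).
#' @return an object of class `ExposureBudget` with fields
#'   `probe_area_nm2`, `step_area_nm2`, `area_ratio`, `dose_per_frame`,
#'   `n_tilts`, `nominal_series_dose_e_per_A2`.
#' @export
exposure_budget <- function(geom, n_tilts) {
  stopifnot(inherits(geom, "ScanGeometry"))
  if (n_tilts <= 0) stop("n_tilts must be > 0")
  probe_area <- pi * (geom$probe_fwhm_nm / 2)^2
  step_area <- geom$step_nm^2
  structure(
    list(probe_area_nm2 = probe_area, step_area_nm2 = step_area,
         area_ratio = step_area / probe_area,
         dose_per_frame = geom$dose_e_per_A2_per_frame,
         n_tilts = as.integer(n_tilts),
         nominal_series_dose_e_per_A2 =
           n_tilts * geom$dose_e_per_A2_per_frame),
    class = "ExposureBudget")
}

#' @export
print.ExposureBudget <- function(x, ...) {
  cat(sprintf(
    paste0("ExposureBudget: step area %.4g nm^2, probe area %.4g nm^2, ",
           "ratio %.3g; %d tilt(s) x %g e-/A^2 = %.4g e-/A^2 nominal\n"),
    x$step_area_nm2, x$probe_area_nm2, x$area_ratio, x$n_tilts,
    x$dose_per_frame, x$nominal_series_dose_e_per_A2))
  invisible(x)
}

#' Accumulated dose of a continuously rotated selected-area dataset
#'
#' `dose = rate * angular_range / angular_rate`: the exposure rate times
#' the time spent sweeping the angular range.
#'
#' @param rate_e_per_A2_per_s exposure rate, e-/A^2/s (>= 0).
#' @param ang_range_deg total angular range swept, degrees (> 0).
#' @param ang_rate_deg_per_s rotation rate, degrees/s (> 0).
#' @return dose in e-/A^2.
#' @export
selected_area_dose <- function(rate_e_per_A2_per_s, ang_range_deg,
                               ang_rate_deg_per_s) {
  if (rate_e_per_A2_per_s < 0) stop("rate must be >= 0")
  if (ang_range_deg <= 0) stop("ang_range_deg must be > 0")
  if (ang_rate_deg_per_s <= 0) stop("zero or negative angular rate")
  rate_e_per_A2_per_s * (ang_range_deg / ang_rate_deg_per_s)
}

#' Compare reflection magnitudes between two datasets by linear regression
#'
#' Matches reflections on identical `(h, k, l)`, keeps those with
#' `I/sigma` above `i_over_sigma_min` in both sets, scales each set's
#' intensities to equal totals, converts to Fourier magnitudes `sqrt(I)`
#' and fits a least-squares line. Symmetry expansion/merging is not
#' applied - matching is on literal indices; merging belongs to external
#' crystallographic software.
#'
#' @param refl_a,refl_b data frames with columns `h, k, l, I, sigma`.
#' @param i_over_sigma_min signal-to-noise cutoff (default 2).
#' @return list with `slope`, `intercept`, `r` (Pearson correlation of the
#'   magnitudes) and `n` (matched reflections used).
#' @export
compare_magnitudes <- function(refl_a, refl_b, i_over_sigma_min = 2) {
  need <- c("h", "k", "l", "I", "sigma")
  stopifnot(all(need %in% names(refl_a)), all(need %in% names(refl_b)))
  a <- refl_a[refl_a$I > 0 & refl_a$I / refl_a$sigma > i_over_sigma_min, ]
  b <- refl_b[refl_b$I > 0 & refl_b$I / refl_b$sigma > i_over_sigma_min, ]
  m <- merge(a, b, by = c("h", "k", "l"), suffixes = c("_a", "_b"))
  if (nrow(m) < 3) {
    stop("fewer than 3 common reflections after the I/sigma filter")
  }
  ia <- m$I_a / sum(m$I_a)
  ib <- m$I_b / sum(m$I_b)
  fa <- sqrt(ia); fb <- sqrt(ib)
  fit <- stats::lm(fb ~ fa)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(fa, fb), n = nrow(m))
}

#' Read a whitespace-delimited reflection list
#'
#' Columns: `h k l I sigma` (a header line is optional).
#'
#' @param path file path.
#' @return data frame with columns `h, k, l, I, sigma`.
#' @export
read_reflections <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, header = has_header)
  if (!has_header) names(df) <- c("h", "k", "l", "I", "sigma")
  stopifnot(ncol(df) >= 5)
  df[, c("h", "k", "l", "I", "sigma")]
}
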