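#' Bin a diffraction pattern by block summation
#'
#' Non-overlapping `factor x factor` block sums, used to boost the contrast
#' of weak Bragg peaks before template matching. Dimensions that are not
#' divisible by the factor are edge-cropped with a warning; total counts on
#' the cropped field are conserved exactly.
#'
#' @param pattern 2D numeric matrix.
#' @param factor integer binning factor >= 1 (default 5).
#' @return binned matrix.
#' @export
bin_pattern <- function(pattern, factor = 5L) {
  stopifnot(is.matrix(pattern))
  factor <- as.integer(factor)
  if (factor < 1) stop("binning factor must be >= 1")
  if (factor == 1L) return(pattern)
  nr <- nrow(pattern) %/% factor * factor
  nc <- ncol(pattern) %/% factor * factor
  if (nr < factor || nc < factor) stop("pattern smaller than one bin")
  if (nr != nrow(pattern) || nc != ncol(pattern)) {
    warning(sprintf("pattern cropped from %d x %d to %d x %d for binning",
                    nrow(pattern), ncol(pattern), nr, nc))
    pattern <- pattern[seq_len(nr), seq_len(nc)]
  }
  a <- array(pattern, dim = c(factor, nr %/% factor, factor, nc %/% factor))
  apply(a, c(2, 4), sum)
}

# Flat circular template of the given diameter; pixels whose centre lies
# within diameter/2 of the template centre are 1.
disc_template <- function(diameter_px) {
  ctr <- (diameter_px + 1) / 2
  d <- dist_from(c(diameter_px, diameter_px), c(ctr, ctr))
  (d <= diameter_px / 2) * 1
}

gaussian_template <- function(diameter_px) {
  ctr <- (diameter_px + 1) / 2
  gaussian_image(c(diameter_px, diameter_px), c(ctr, ctr), diameter_px / 4)
}

# Normalized cross-correlation of `img` against `tmpl` at every valid
# template placement; result indexed by the template's top-left corner.
ncc_map <- function(img, tmpl) {
  h <- nrow(tmpl); w <- ncol(tmpl)
  nr <- nrow(img) - h + 1; nc <- ncol(img) - w + 1
  if (nr < 1 || nc < 1) stop("template larger than the (binned) pattern")
  t0 <- tmpl - mean(tmpl)
  t_norm <- sqrt(sum(t0^2))
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      win <- img[i:(i + h - 1), j:(j + w - 1)]
      v <- win - mean(win)
      denom <- sqrt(sum(v^2)) * t_norm
      out[i, j] <- if (denom > 0) sum(v * t0) / denom else 0
    }
  }
  out
}

new_peak_list <- function(df, bin_factor, template_diameter_binned_px) {
  structure(df, class = c("PeakList", "data.frame"),
            bin_factor = bin_factor,
            template_diameter_binned_px = template_diameter_binned_px)
}

#' @export
print.PeakList <- function(x, ...) {
  cat(sprintf("PeakList: %d peak(s) (bin factor %d, template %d binned px)\n",
              nrow(x), attr(x, "bin_factor"),
              attr(x, "template_diameter_binned_px")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Localize Bragg peaks by binning and circular-template matching
#'
#' Bins the pattern (factor 5 by default), computes the normalized
#' cross-correlation against a circular template (6 binned pixels in
#' diameter by default), keeps local maxima above `ncc_min`, applies
#' greedy non-maximum suppression at `min_separation_binned_px`, and maps
#' the surviving coordinates back to unbinned pixels using the bin-centre
#' convention (binned pixel `b` maps to unbinned `(b - 1) * factor +
#' (factor + 1) / 2`). Peaks inside the central-beam exclusion zone are
#' dropped; by default the zone is twice the beam-disc radius estimated
#' from the pattern itself.
#'
#' @param pattern 2D summed diffraction pattern (unbinned).
#' @param bin_factor binning factor (default 5).
#' @param template_diameter_binned_px circular template diameter in binned
#'   px (default 6).
#' @param ncc_min minimum normalized cross-correlation score in (0, 1).
#' @param min_separation_binned_px non-maximum suppression radius, binned
#'   px; defaults to the template diameter.
#' @param exclude_centre_radius_px central exclusion radius in unbinned px;
#'   `NULL` uses `2 * beam_disc_radius(pattern)`.
#' @param template `"disc"` (flat circular, default) or `"gaussian"`.
#' @param centre pattern centre `(row, col)` in unbinned px; `NULL` uses
#'   the central pixel.
#' @return a `PeakList`: data frame with columns `det_row, det_col`
#'   (unbinned px), `ncc_score`, `integrated_counts`.
#' @export
find_peaks <- function(pattern, bin_factor = 5L,
                       template_diameter_binned_px = 6L, ncc_min = 0.5,
                       min_separation_binned_px = template_diameter_binned_px,
                       exclude_centre_radius_px = NULL,
                       template = c("disc", "gaussian"), centre = NULL) {
  stopifnot(is.matrix(pattern))
  template <- match.arg(template)
  if (ncc_min <= 0 || ncc_min >= 1) stop("ncc_min must lie in (0, 1)")
  centre <- centre %||% det_centre_px(dim(pattern))
  excl <- exclude_centre_radius_px %||% (2 * beam_disc_radius(pattern, centre))
  binned <- suppressWarnings(bin_pattern(pattern, bin_factor))
  tmpl <- if (template == "disc") disc_template(template_diameter_binned_px)
          else gaussian_template(template_diameter_binned_px)
  ncc <- ncc_map(binned, tmpl)
  half <- (template_diameter_binned_px - 1) / 2
  # candidate local maxima above threshold (8-neighbourhood, ties kept once)
  cand <- which(ncc >= ncc_min, arr.ind = TRUE)
  is_max <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    nb <- ncc[max(1, r - 1):min(nrow(ncc), r + 1),
              max(1, c - 1):min(ncol(ncc), c + 1)]
    is_max[i] <- ncc[r, c] >= max(nb)
  }
  cand <- cand[is_max, , drop = FALSE]
  scores <- ncc[cand]
  ord <- order(scores, decreasing = TRUE)
  acc_r <- numeric(0); acc_c <- numeric(0); acc_s <- numeric(0)
  for (i in ord) {
    br <- cand[i, 1] + half  # binned-pixel centre of the template placement
    bc <- cand[i, 2] + half
    if (length(acc_r) &&
        any(sqrt((acc_r - br)^2 + (acc_c - bc)^2) < min_separation_binned_px)) {
      next
    }
    acc_r <- c(acc_r, br); acc_c <- c(acc_c, bc); acc_s <- c(acc_s, scores[i])
  }
  # bin-centre convention back to unbinned coordinates
  ur <- (acc_r - 1) * bin_factor + (bin_factor + 1) / 2
  uc <- (acc_c - 1) * bin_factor + (bin_factor + 1) / 2
  keep <- sqrt((ur - centre[1])^2 + (uc - centre[2])^2) > excl
  ur <- ur[keep]; uc <- uc[keep]; acc_s <- acc_s[keep]
  int_radius <- template_diameter_binned_px / 2 * bin_factor
  counts <- vapply(seq_along(ur), function(i) {
    sum(pattern[dist_from(dim(pattern), c(ur[i], uc[i])) <= int_radius])
  }, numeric(1))
  df <- data.frame(det_row = ur, det_col = uc, ncc_score = acc_s,
                   integrated_counts = counts)
  df <- df[order(-df$ncc_score), , drop = FALSE]
  rownames(df) <- NULL
  new_peak_list(df, bin_factor, template_diameter_binned_px)
}

#' Label full-field peaks with the crystal regions they arise from
#'
#' For a multi-crystal field of view: each peak of the full-field pattern
#' is labelled with every region whose own (region-selected) peak list has
#' a peak within `match_radius_px`; peaks matching no region are labelled
#' `"unassigned"`. This separates coincident reciprocal lattices without
#' any multi-lattice indexing.
#'
#' @param full_field a `PeakList` from the whole-field pattern.
#' @param per_region named list of `PeakList`, one per region; unnamed
#'   lists are labelled `region_1, region_2, ...`.
#' @param match_radius_px matching radius in unbinned px.
#' @return the full-field peak data frame with added columns `labels`
#'   (semicolon-joined region names) and `n_regions`.
#' @export
assign_peaks_to_regions <- function(full_field, per_region, match_radius_px = 5) {
  stopifnot(length(per_region) >= 1)
  nms <- names(per_region) %||% rep("", length(per_region))
  nms[!nzchar(nms)] <- paste0("region_", which(!nzchar(nms)))
  df <- as.data.frame(full_field)
  labels <- character(nrow(df))
  n_regions <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    hit <- character(0)
    for (j in seq_along(per_region)) {
      pr <- as.data.frame(per_region[[j]])
      if (nrow(pr) == 0) next
      d <- sqrt((pr$det_row - df$det_row[i])^2 +
                  (pr$det_col - df$det_col[i])^2)
      if (any(d <= match_radius_px)) hit <- c(hit, nms[j])
    }
    labels[i] <- if (length(hit)) paste(hit, collapse = ";") else "unassigned"
    n_regions[i] <- length(hit)
  }
  df$labels <- labels
  df$n_regions <- n_regions
  df
}

#' Write a peak list as tab-separated text
#'
#' @param peaks a `PeakList` or the labelled data frame from
#'   [assign_peaks_to_regions()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.table(as.data.frame(peaks), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak list written by [write_peaks()]
#'
#' @param path file path.
#' @return data frame of peaks.
#' @export
read_peaks <- function(path) {
  utils::read.delim(path)
}
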