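#' Scan-space region mask ("digital aperture")
#'
#' A boolean selection of scan positions whose diffraction patterns will be
#' combined; the post-acquisition replacement for a physical selected-area
#' aperture.
#'
#' @param mask logical scan-shaped matrix with at least one `TRUE` pixel.
#' @param label small-integer region id.
#' @param provenance named list recording how the mask was made
#'   (threshold, morphology radii, ...).
#' @return an object of class `RegionMask`.
#' @export
region_mask <- function(mask, label = 1L, provenance = list()) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("a valid region needs at least one TRUE pixel")
  structure(list(mask = mask, label = as.integer(label),
                 provenance = provenance),
            class = "RegionMask")
}

#' @export
print.RegionMask <- function(x, ...) {
  cat(sprintf("RegionMask %d: %d of %d scan px\n", x$label, sum(x$mask),
              length(x$mask)))
  invisible(x)
}

#' Segment crystal regions from a virtual dark-field image
#'
#' Thresholds the image (Otsu by default), cleans the binary map by
#' morphological opening then closing with disc structuring elements,
#' labels 8-connected components and drops those smaller than
#' `min_area_px`. On a virtual dark-field image crystal pixels integrate
#' Bragg-scattered electrons and stand out strongly from the support film,
#' so global thresholding is usually sufficient.
#'
#' @param img a `VirtualImage` from [virtual_image()], or a plain matrix.
#' @param threshold `"otsu"` or an absolute numeric threshold.
#' @param open_radius_px,close_radius_px disc radii for opening/closing
#'   (0 skips the step).
#' @param min_area_px minimum component area kept, scan px.
#' @return list of [region_mask()] sorted by area, largest first; empty
#'   list when nothing exceeds the threshold.
#' @export
segment_crystals <- function(img, threshold = "otsu", open_radius_px = 1,
                             close_radius_px = 1, min_area_px = 4) {
  values <- if (inherits(img, "VirtualImage")) img$values else img
  stopifnot(is.matrix(values), all(is.finite(values)))
  if (open_radius_px < 0 || close_radius_px < 0) stop("radii must be >= 0")
  rng <- range(values)
  if (identical(threshold, "otsu")) {
    if (rng[1] == rng[2]) return(list())
    v01 <- (values - rng[1]) / (rng[2] - rng[1])
    thr <- EBImage::otsu(v01) * (rng[2] - rng[1]) + rng[1]
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    thr <- threshold
  }
  bin <- values > thr
  if (!any(bin)) return(list())
  bin <- morph_open_close(bin, open_radius_px, close_radius_px)
  if (!any(bin)) return(list())
  lab <- label_components(bin)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  keep <- keep[order(areas[keep], decreasing = TRUE)]
  prov <- list(threshold = thr, threshold_method = if (identical(threshold, "otsu")) "otsu" else "absolute",
               open_radius_px = open_radius_px,
               close_radius_px = close_radius_px, min_area_px = min_area_px)
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    out[[i]] <- region_mask(lab == keep[i], label = i, provenance = prov)
  }
  out
}

# Opening then closing with disc structuring elements of the given radii.
# The field is padded with background first so regions touching the image
# border are not distorted by the morphology's edge handling.
morph_open_close <- function(bin, open_radius_px, close_radius_px) {
  p <- max(open_radius_px, close_radius_px) + 1
  m <- matrix(0, nrow(bin) + 2 * p, ncol(bin) + 2 * p)
  m[p + seq_len(nrow(bin)), p + seq_len(ncol(bin))] <- bin * 1
  if (open_radius_px > 0) {
    m <- EBImage::opening(m, EBImage::makeBrush(2 * open_radius_px + 1, "disc"))
  }
  if (close_radius_px > 0) {
    m <- EBImage::closing(m, EBImage::makeBrush(2 * close_radius_px + 1, "disc"))
  }
  m[p + seq_len(nrow(bin)), p + seq_len(ncol(bin))] > 0.5
}

#' Scan coordinates selected by a region mask
#'
#' @param region a [region_mask()].
#' @return integer matrix with columns `row`, `col`, ordered row-major
#'   (row varies slowest).
#' @export
mask_to_indices <- function(region) {
  stopifnot(inherits(region, "RegionMask"))
  idx <- which(region$mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("row", "col")
  rownames(idx) <- NULL
  idx
}

#' Region mask from a polygon "digital aperture"
#'
#' Rasterizes a polygon drawn in scan coordinates into a [region_mask()],
#' the manual alternative to [segment_crystals()].
#'
#' @param vertices n x 2 matrix of `(row, col)` vertices.
#' @param shape scan shape `(rows, cols)`.
#' @param label region id.
#' @return a [region_mask()].
#' @export
region_from_polygon <- function(vertices, shape, label = 1L) {
  m <- polygon_mask(vertices, shape)
  region_mask(m, label = label,
              provenance = list(threshold_method = "polygon",
                                vertices = vertices))
}

#' Read a polygon region from a JSON vertex list
#'
#' Expects a JSON object `{"shape": [rows, cols], "vertices": [[r,c], ...]}`.
#'
#' @param path JSON file path.
#' @param label region id.
#' @return a [region_mask()].
#' @export
read_polygon_json <- function(path, label = 1L) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  region_from_polygon(matrix(as.numeric(j$vertices), ncol = 2,
                             byrow = !is.matrix(j$vertices)),
                      shape = as.integer(j$shape), label = label)
}

#' Write region masks as an 8-bit TIFF
#'
#' One page per region; pixel value 1 inside the region, 0 outside.
#'
#' @param regions list of [region_mask()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_region_masks <- function(regions, path) {
  stopifnot(length(regions) >= 1)
  pages <- lapply(regions, function(r) r$mask / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}

#' Read region masks written by [write_region_masks()]
#'
#' @param path TIFF path.
#' @return list of [region_mask()].
#' @export
read_region_masks <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(seq_along(pages), function(i) {
    region_mask(pages[[i]] > 0, label = i)
  })
}
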