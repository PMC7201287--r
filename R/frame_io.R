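#' Scan and detector geometry for one 4D-STEM acquisition
#'
#' Bundles the scan-space sampling of a nanobeam diffraction scan: the scan
#' step, the probe size (full width at half maximum), the goniometer tilt at
#' which the scan was recorded, the electron dose accumulated per frame and
#' the electron wavelength. The default wavelength, 0.0197 Angstrom,
#' corresponds to a 300 kV accelerating voltage.
#'
#' @param step_nm scan step between adjacent probe positions, nm (> 0).
#' @param probe_fwhm_nm probe full width at half maximum, nm (> 0).
#' @param tilt_deg goniometer tilt of this scan, degrees, in \[-90, 90\].
#' @param dose_e_per_A2_per_frame electron dose per frame, e-/A^2 (>= 0).
#' @param wavelength_A electron wavelength, Angstrom.
#' @return an object of class `ScanGeometry`.
#' @export
scan_geometry <- function(step_nm, probe_fwhm_nm, tilt_deg = 0,
                          dose_e_per_A2_per_frame = 1,
                          wavelength_A = 0.0197) {
  if (!is.numeric(step_nm) || length(step_nm) != 1 || step_nm <= 0) {
    stop("step_nm must be a positive scalar")
  }
  if (!is.numeric(probe_fwhm_nm) || length(probe_fwhm_nm) != 1 ||
      probe_fwhm_nm <= 0) {
    stop("probe_fwhm_nm must be a positive scalar")
  }
  if (!is.numeric(tilt_deg) || length(tilt_deg) != 1 ||
      tilt_deg < -90 || tilt_deg > 90) {
    stop("tilt_deg must lie in [-90, 90]")
  }
  if (dose_e_per_A2_per_frame < 0) stop("dose_e_per_A2_per_frame must be >= 0")
  if (wavelength_A <= 0) stop("wavelength_A must be > 0")
  structure(
    list(step_nm = as.numeric(step_nm),
         probe_fwhm_nm = as.numeric(probe_fwhm_nm),
         tilt_deg = as.numeric(tilt_deg),
         dose_e_per_A2_per_frame = as.numeric(dose_e_per_A2_per_frame),
         wavelength_A = as.numeric(wavelength_A)),
    class = "ScanGeometry")
}

#' @export
print.ScanGeometry <- function(x, ...) {
  cat(sprintf(
    "ScanGeometry: step %g nm, probe FWHM %g nm, tilt %g deg, dose %g e-/A^2/frame, lambda %g A\n",
    x$step_nm, x$probe_fwhm_nm, x$tilt_deg, x$dose_e_per_A2_per_frame,
    x$wavelength_A))
  invisible(x)
}

#' One tilt angle's 4D diffraction scan
#'
#' A 4D array of detector readings indexed `[scan_row, scan_col, det_row,
#' det_col]` plus its [scan_geometry()]. `dtype_tag` records whether values
#' are raw detector units (`"raw_adu"`) or quantized electron counts
#' (`"hybrid_counts"`); hybrid counts must be non-negative integers.
#'
#' @param data 4D numeric array `(scan_rows, scan_cols, det_rows, det_cols)`.
#' @param geometry a `ScanGeometry`.
#' @param dtype_tag `"raw_adu"` or `"hybrid_counts"`.
#' @return an object of class `FrameStack4D`.
#' @export
frame_stack <- function(data, geometry, dtype_tag = c("raw_adu", "hybrid_counts")) {
  dtype_tag <- match.arg(dtype_tag)
  if (!is.array(data) || length(dim(data)) != 4) {
    stop("data must be a 4D array (scan_rows, scan_cols, det_rows, det_cols)")
  }
  if (any(dim(data) < 1)) stop("all four dimensions must be >= 1")
  if (!inherits(geometry, "ScanGeometry")) stop("geometry must be a ScanGeometry")
  if (dtype_tag == "hybrid_counts" && !is_count_like(data)) {
    stop("hybrid_counts data must be non-negative integers")
  }
  structure(list(data = data, geometry = geometry, dtype_tag = dtype_tag),
            class = "FrameStack4D")
}

#' @export
print.FrameStack4D <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("FrameStack4D [%s]: scan %d x %d, detector %d x %d, tilt %g deg\n",
              x$dtype_tag, d[1], d[2], d[3], d[4], x$geometry$tilt_deg))
  invisible(x)
}

scan_shape <- function(stack) dim(stack$data)[1:2]
det_shape <- function(stack) dim(stack$data)[3:4]

## ---- geometry <-> key=value header helpers -------------------------------

geometry_to_kv <- function(g) {
  c(STEP_NM = fmt_num(g$step_nm),
    PROBE_FWHM_NM = fmt_num(g$probe_fwhm_nm),
    TILT_DEG = fmt_num(g$tilt_deg),
    DOSE_E_PER_A2_PER_FRAME = fmt_num(g$dose_e_per_A2_per_frame),
    WAVELENGTH_A = fmt_num(g$wavelength_A))
}

geometry_from_kv <- function(kv) {
  scan_geometry(step_nm = as.numeric(kv[["STEP_NM"]]),
                probe_fwhm_nm = as.numeric(kv[["PROBE_FWHM_NM"]]),
                tilt_deg = as.numeric(kv[["TILT_DEG"]]),
                dose_e_per_A2_per_frame = as.numeric(kv[["DOSE_E_PER_A2_PER_FRAME"]]),
                wavelength_A = as.numeric(kv[["WAVELENGTH_A"]]))
}

stack_header_kv <- function(stack, dtype) {
  d <- dim(stack$data)
  c(FORMAT = "STEM4D_CONTAINER_V1",
    SCAN_ROWS = d[1], SCAN_COLS = d[2], DET_ROWS = d[3], DET_COLS = d[4],
    DTYPE = dtype, DTYPE_TAG = stack$dtype_tag, BYTE_ORDER = "little_endian",
    geometry_to_kv(stack$geometry))
}

write_kv_lines <- function(kv, con) {
  writeLines(paste(names(kv), unname(kv), sep = " = "), con)
}

parse_kv_lines <- function(lines) {
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  m <- regmatches(lines, regexpr(" = ", lines, fixed = TRUE), invert = TRUE)
  kv <- vapply(m, function(p) trimws(p[2]), character(1))
  names(kv) <- vapply(m, function(p) trimws(p[1]), character(1))
  kv
}

# Payload is row-major over (scan_row, scan_col, det_row, det_col): the last
# index varies fastest, so readers in any language can use C ordering.
payload_vector <- function(data) as.vector(aperm(data, c(4, 3, 2, 1)))

payload_to_array <- function(v, dims) {
  aperm(array(v, dim = rev(dims)), c(4, 3, 2, 1))
}

## ---- read/write of 4D stacks ---------------------------------------------

#' Write a 4D frame stack
#'
#' Three dialects are supported, all lossless for integer data:
#' \describe{
#'   \item{`container`}{a single self-describing file: an ASCII `KEY = value`
#'     header terminated by an `END_HEADER` line, then the payload in
#'     row-major order, little-endian. Hybrid counts are stored as `int32`,
#'     raw detector values as `float64`.}
#'   \item{`raw_binary`}{a flat little-endian payload at `path` plus a text
#'     sidecar header `<path>.hdr` with shape, dtype, endianness and geometry.}
#'   \item{`tiff_stack`}{a multi-page 16-bit TIFF, one detector frame per
#'     page ordered row-major over scan positions (scan row varies slowest),
#'     plus a text sidecar `<path>.meta` with scan shape and geometry. Values
#'     must be integers in 0..65535.}
#' }
#'
#' @param stack a [frame_stack()].
#' @param path output file path.
#' @param dialect one of `"container"`, `"raw_binary"`, `"tiff_stack"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path,
                        dialect = c("container", "raw_binary", "tiff_stack")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(stack, "FrameStack4D"))
  if (dir.exists(path)) stop("path is a directory, expected a file path: ", path)
  d <- dim(stack$data)
  if (dialect == "container" || dialect == "raw_binary") {
    is_int <- stack$dtype_tag == "hybrid_counts"
    dtype <- if (is_int) "int32" else "float64"
    kv <- stack_header_kv(stack, dtype)
    v <- payload_vector(stack$data)
    if (dialect == "container") {
      con <- file(path, "wb")
      on.exit(close(con))
      writeLines(paste(names(kv), unname(kv), sep = " = "), con)
      writeLines("END_HEADER", con)
      if (is_int) {
        writeBin(as.integer(v), con, size = 4L, endian = "little")
      } else {
        writeBin(as.double(v), con, size = 8L, endian = "little")
      }
    } else {
      con <- file(path, "wb")
      on.exit(close(con))
      if (is_int) {
        writeBin(as.integer(v), con, size = 4L, endian = "little")
      } else {
        writeBin(as.double(v), con, size = 8L, endian = "little")
      }
      hcon <- file(paste0(path, ".hdr"), "w")
      write_kv_lines(kv, hcon)
      close(hcon)
    }
  } else {
    if (!is_count_like(stack$data) || max(stack$data) > 65535) {
      stop("tiff_stack requires integer values in 0..65535")
    }
    pages <- vector("list", d[1] * d[2])
    k <- 1L
    for (r in seq_len(d[1])) {        # scan row varies slowest: row-major
      for (cc in seq_len(d[2])) {
        pages[[k]] <- stack$data[r, cc, , ] / 65535
        k <- k + 1L
      }
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                    reduce = FALSE)
    kv <- stack_header_kv(stack, "uint16")
    mcon <- file(paste0(path, ".meta"), "w")
    write_kv_lines(kv, mcon)
    close(mcon)
  }
  invisible(path)
}

read_container_header <- function(con) {
  lines <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0) stop("unterminated container header")
    if (identical(ln, "END_HEADER")) break
    lines <- c(lines, ln)
  }
  parse_kv_lines(lines)
}

#' Read a 4D frame stack written by [write_stack()]
#'
#' @param path file path.
#' @param dialect one of `"container"`, `"raw_binary"`, `"tiff_stack"`.
#' @return a [frame_stack()].
#' @export
read_stack <- function(path,
                       dialect = c("container", "raw_binary", "tiff_stack")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "container") {
    con <- file(path, "rb")
    on.exit(close(con))
    kv <- read_container_header(con)
    dims <- as.integer(kv[c("SCAN_ROWS", "SCAN_COLS", "DET_ROWS", "DET_COLS")])
    n <- prod(dims)
    v <- if (kv[["DTYPE"]] == "int32") {
      readBin(con, "integer", n = n, size = 4L, endian = "little")
    } else {
      readBin(con, "double", n = n, size = 8L, endian = "little")
    }
    if (length(v) != n) {
      stop(sprintf("container payload shape mismatch: expected %d values, found %d",
                   n, length(v)))
    }
  } else if (dialect == "raw_binary") {
    hdr <- paste0(path, ".hdr")
    if (!file.exists(hdr)) stop("missing sidecar header: ", hdr)
    kv <- parse_kv_lines(readLines(hdr))
    dims <- as.integer(kv[c("SCAN_ROWS", "SCAN_COLS", "DET_ROWS", "DET_COLS")])
    n <- prod(dims)
    size <- if (kv[["DTYPE"]] == "int32") 4L else 8L
    expected <- n * size
    actual <- file.size(path)
    if (actual != expected) {
      stop(sprintf("raw_binary payload shape mismatch: expected %d bytes, found %d",
                   expected, actual))
    }
    con <- file(path, "rb")
    on.exit(close(con))
    v <- if (size == 4L) {
      readBin(con, "integer", n = n, size = 4L, endian = "little")
    } else {
      readBin(con, "double", n = n, size = 8L, endian = "little")
    }
  } else {
    meta <- paste0(path, ".meta")
    if (!file.exists(meta)) stop("missing sidecar metadata: ", meta)
    kv <- parse_kv_lines(readLines(meta))
    dims <- as.integer(kv[c("SCAN_ROWS", "SCAN_COLS", "DET_ROWS", "DET_COLS")])
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != dims[1] * dims[2]) {
      stop(sprintf("tiff_stack page-count mismatch: expected %d pages, found %d",
                   dims[1] * dims[2], length(pages)))
    }
    data <- array(0, dim = dims)
    k <- 1L
    for (r in seq_len(dims[1])) {
      for (cc in seq_len(dims[2])) {
        data[r, cc, , ] <- round(pages[[k]] * 65535)
        k <- k + 1L
      }
    }
    return(frame_stack(data, geometry_from_kv(kv), dtype_tag = kv[["DTYPE_TAG"]]))
  }
  data <- payload_to_array(v, dims)
  frame_stack(data, geometry_from_kv(kv), dtype_tag = kv[["DTYPE_TAG"]])
}

## ---- SMV export ----------------------------------------------------------

#' Write a diffraction pattern as an SMV image
#'
#' Writes the crystallographic SMV still-image format: a 512-byte ASCII
#' header followed by the pattern as row-major unsigned 16-bit little-endian
#' values. A constant pedestal is added before clipping to 0..65535 so that
#' downstream integration software can measure background below weak peaks;
#' pixels exceeding 65535 after the pedestal are clipped and counted in a
#' warning.
#'
#' @param pattern non-negative 2D numeric matrix (detector rows x cols).
#' @param geometry a [scan_geometry()]; supplies `WAVELENGTH`.
#' @param osc_start_deg,osc_range_deg oscillation start and range, degrees
#'   (`osc_range_deg = 0` marks a still).
#' @param path output file path.
#' @param pedestal constant offset added to every pixel (default 0).
#' @param pixel_size_mm,distance_mm detector pixel size and camera length
#'   written to the header.
#' @param beam_centre `(row, col)` beam centre in pixels; defaults to the
#'   pattern centre.
#' @return `path`, invisibly.
#' @export
write_smv <- function(pattern, geometry, osc_start_deg, osc_range_deg, path,
                      pedestal = 0, pixel_size_mm = 0.01, distance_mm = 1000,
                      beam_centre = NULL) {
  stopifnot(is.matrix(pattern))
  if (any(pattern < 0)) stop("pattern must be non-negative")
  if (dir.exists(path)) stop("path is a directory, expected a file path: ", path)
  beam_centre <- beam_centre %||% det_centre_px(dim(pattern))
  v <- round(pattern + pedestal)
  n_clip <- sum(v > 65535)
  if (n_clip > 0) {
    warning(sprintf("%d pixels exceeded 65535 after pedestal and were clipped",
                    n_clip))
    v[v > 65535] <- 65535
  }
  hdr_fields <- c(
    sprintf("HEADER_BYTES=  512;"),
    "DIM=2;",
    "BYTE_ORDER=little_endian;",
    "TYPE=unsigned_short;",
    sprintf("SIZE1=%d;", ncol(pattern)),
    sprintf("SIZE2=%d;", nrow(pattern)),
    sprintf("PIXEL_SIZE=%g;", pixel_size_mm),
    sprintf("DISTANCE=%g;", distance_mm),
    sprintf("WAVELENGTH=%g;", geometry$wavelength_A),
    sprintf("PHI=%g;", osc_start_deg),
    sprintf("OSC_START=%g;", osc_start_deg),
    sprintf("OSC_RANGE=%g;", osc_range_deg),
    sprintf("BEAM_CENTER_X=%g;", beam_centre[2] * pixel_size_mm),
    sprintf("BEAM_CENTER_Y=%g;", beam_centre[1] * pixel_size_mm))
  header <- paste0("{\n", paste(hdr_fields, collapse = "\n"), "\n}\n")
  if (nchar(header, type = "bytes") > 512) stop("SMV header exceeds 512 bytes")
  header <- paste0(header,
                   strrep(" ", 512 - nchar(header, type = "bytes")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  # row-major payload: transpose so columns (SIZE1) vary fastest
  writeBin(as.integer(as.vector(t(v))), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an SMV image written by [write_smv()]
#'
#' A minimal parser for the SMV dialect this package writes (and the common
#' subset produced by detector vendors): 512-byte ASCII header with
#' `KEY=value;` entries, unsigned 16-bit little-endian payload.
#'
#' @param path file path.
#' @return a list with `header` (named character vector) and `data`
#'   (integer matrix, detector rows x cols).
#' @export
read_smv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", n = 512L)
  txt <- rawToChar(raw_hdr[raw_hdr != as.raw(0)])
  body <- sub(".*\\{", "", sub("\\}.*", "", txt))
  entries <- strsplit(body, ";")[[1]]
  entries <- trimws(entries)
  entries <- entries[grepl("=", entries)]
  kv <- sub("^[^=]*=", "", entries)
  names(kv) <- trimws(sub("=.*$", "", entries))
  kv <- trimws(kv)
  nb <- as.integer(kv[["HEADER_BYTES"]])
  if (nb != 512L) {
    seek(con, where = nb, origin = "start")
  }
  size1 <- as.integer(kv[["SIZE1"]]); size2 <- as.integer(kv[["SIZE2"]])
  v <- readBin(con, "integer", n = size1 * size2, size = 2L, signed = FALSE,
               endian = "little")
  if (length(v) != size1 * size2) {
    stop(sprintf("SMV payload mismatch: expected %d values, found %d",
                 size1 * size2, length(v)))
  }
  list(header = kv, data = t(matrix(v, nrow = size1, ncol = size2)))
}
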