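#' Configuration for the synthetic 4D-STEM tilt-series simulator
#'
#' Describes a scanned nanobeam diffraction acquisition over a needle-shaped
#' crystal on a support film with a vacuum hole, recorded on a noisy
#' integrating detector. Defaults reproduce the acquisition geometry of a
#' cryogenic nanobeam diffraction-tomography experiment on peptide
#' nanocrystals: a 12 nm FWHM probe stepped on a 40 nm grid over a 30 x 70
#' scan, 1 e-/A^2 dose per frame, tilts from -45 to 45 degrees in 1 degree
#' steps. The detector is a scaled-down stand-in (128 x 128 rather than a
#' full direct-detection chip); the per-frame electron budget is scaled with
#' it so that per-pixel occupancy away from the central beam stays sparse,
#' the regime electron counting requires.
#'
#' The diffraction model is kinematic: a reflection `(h,k,l)` with
#' reciprocal vector `g` (detector-pixel units, components
#' `(row, col, out-of-plane)`) is excited at tilt `theta` (rotation about
#' the detector-row axis) when its rotated out-of-plane component is below
#' `excitation_tol`. The central beam and the excited Bragg spots are
#' rendered as smooth-edged discs of radius `beam_radius_px` /
#' `spot_radius_px` (the convergent-beam disc shape a focused nanoprobe
#' produces) at the projected in-plane positions; excited spots share a
#' fraction `diffracted_fraction` of the transmitted beam in proportion to
#' `sf_table` intensities. Transmission through the crystal follows
#' `exp(-thickness / lambda_mfp_nm)`. Multiple electron arrivals in one
#' pixel simply sum in the analog readout - exactly the coincidence that
#' hybrid counting must recover.
#'
#' @param scan_shape integer `(rows, cols)` of the scan grid.
#' @param step_nm,probe_fwhm_nm scan step and probe FWHM, nm.
#' @param tilt_min_deg,tilt_max_deg,tilt_step_deg tilt range and step,
#'   degrees; `tilt_step_deg` must be > 0.
#' @param det_shape integer `(rows, cols)` of the detector.
#' @param gain_adu_per_electron single-electron gain, ADU (> 0).
#' @param read_noise_sigma_adu Gaussian read-noise width, ADU (>= 0).
#' @param dark_level_adu constant detector dark level, ADU.
#' @param dose_e_per_A2_per_frame nominal dose bookkeeping value, e-/A^2.
#' @param beam_e_per_frame expected incident electrons per frame reaching
#'   the detector.
#' @param bg_rate_e_per_px expected diffuse background electrons per
#'   detector pixel per frame.
#' @param beam_radius_px rendered central-beam disc radius, px.
#' @param spot_radius_px rendered Bragg-spot disc radius, px; the default
#'   (15) makes a 5x-binned spot match a 6-binned-px circular template.
#' @param edge_sigma_px logistic edge width of the rendered discs, px.
#' @param diffracted_fraction fraction of transmitted electrons carried by
#'   excited Bragg spots (0..1).
#' @param excitation_tol excitation-error tolerance on the rotated
#'   out-of-plane component, detector-px units.
#' @param lambda_mfp_nm electron mean free path through the crystal, nm.
#' @param lattice 3x3 matrix whose columns are the three reciprocal basis
#'   vectors in detector-pixel units, rows = `(row, col, out_of_plane)`.
#' @param lattices optional list of such matrices, one per crystal; default
#'   recycles `lattice`.
#' @param sf_table data frame `h, k, l, intensity` of relative reflection
#'   intensities.
#' @param crystal_polygons list of n x 2 `(row, col)` vertex matrices in
#'   scan coordinates, one polygon per crystal; must lie inside the scan.
#' @param thickness_profile scan-shaped matrix of crystal thickness, nm;
#'   `NULL` builds a cylindrical needle profile of peak thickness
#'   `max_thickness_nm` for each polygon.
#' @param max_thickness_nm peak thickness used by the default profile, nm.
#' @param vacuum_polygon n x 2 vertex matrix marking the vacuum hole.
#' @param seed integer; fully determines the simulated output.
#' @return an object of class `SimulationConfig`.
#' @export
sim_config <- function(scan_shape = c(30L, 70L),
                       step_nm = 40,
                       probe_fwhm_nm = 12,
                       tilt_min_deg = -45, tilt_max_deg = 45,
                       tilt_step_deg = 1,
                       det_shape = c(128L, 128L),
                       gain_adu_per_electron = 32,
                       read_noise_sigma_adu = 5,
                       dark_level_adu = 100,
                       dose_e_per_A2_per_frame = 1,
                       beam_e_per_frame = 20000,
                       bg_rate_e_per_px = 0.002,
                       beam_radius_px = 8,
                       spot_radius_px = 15,
                       edge_sigma_px = 1.5,
                       diffracted_fraction = 0.15,
                       excitation_tol = 0.9,
                       lambda_mfp_nm = 332,
                       lattice = default_lattice(),
                       lattices = NULL,
                       sf_table = default_sf_table(),
                       crystal_polygons = default_crystal_polygons(scan_shape),
                       thickness_profile = NULL,
                       max_thickness_nm = 360,
                       vacuum_polygon = default_vacuum_polygon(scan_shape),
                       seed = 1L) {
  chk <- function(ok, field, msg) if (!ok) stop(sprintf("%s: %s", field, msg))
  chk(length(scan_shape) == 2 && all(scan_shape >= 1), "scan_shape",
      "must be two positive integers")
  chk(length(det_shape) == 2 && all(det_shape >= 8), "det_shape",
      "must be two integers >= 8")
  chk(tilt_step_deg > 0, "tilt_step_deg", "must be > 0")
  chk(tilt_max_deg >= tilt_min_deg, "tilt_max_deg", "must be >= tilt_min_deg")
  chk(gain_adu_per_electron > 0, "gain_adu_per_electron", "must be > 0")
  chk(read_noise_sigma_adu >= 0, "read_noise_sigma_adu", "must be >= 0")
  chk(dose_e_per_A2_per_frame >= 0, "dose_e_per_A2_per_frame", "must be >= 0")
  chk(beam_e_per_frame >= 0, "beam_e_per_frame", "must be >= 0")
  chk(bg_rate_e_per_px >= 0, "bg_rate_e_per_px", "must be >= 0")
  chk(beam_radius_px > 0, "beam_radius_px", "must be > 0")
  chk(spot_radius_px > 0, "spot_radius_px", "must be > 0")
  chk(edge_sigma_px > 0, "edge_sigma_px", "must be > 0")
  chk(diffracted_fraction >= 0 && diffracted_fraction <= 1,
      "diffracted_fraction", "must lie in [0, 1]")
  chk(excitation_tol > 0, "excitation_tol", "must be > 0")
  chk(lambda_mfp_nm > 0, "lambda_mfp_nm", "must be > 0")
  chk(is.matrix(lattice) && all(dim(lattice) == c(3, 3)), "lattice",
      "must be a 3x3 matrix of reciprocal basis vectors")
  chk(is.data.frame(sf_table) &&
        all(c("h", "k", "l", "intensity") %in% names(sf_table)) &&
        all(sf_table$intensity > 0), "sf_table",
      "must be a data frame with columns h, k, l, intensity > 0")
  chk(is.list(crystal_polygons), "crystal_polygons", "must be a list")
  for (p in crystal_polygons) {
    chk(is.matrix(p) && ncol(p) == 2, "crystal_polygons",
        "each polygon must be an n x 2 (row, col) matrix")
    chk(all(p[, 1] >= 0.5 & p[, 1] <= scan_shape[1] + 0.5 &
              p[, 2] >= 0.5 & p[, 2] <= scan_shape[2] + 0.5),
        "crystal_polygons", "polygon vertices must lie inside scan_shape")
  }
  if (!is.null(thickness_profile)) {
    chk(is.matrix(thickness_profile) &&
          all(dim(thickness_profile) == scan_shape) &&
          all(thickness_profile >= 0), "thickness_profile",
        "must be a non-negative scan-shaped matrix")
  }
  chk(length(seed) == 1 && is.finite(seed), "seed", "must be a single integer")
  lattices <- lattices %||% rep(list(lattice), length(crystal_polygons))
  chk(length(lattices) >= length(crystal_polygons), "lattices",
      "need one lattice per crystal polygon")
  structure(
    list(scan_shape = as.integer(scan_shape), step_nm = step_nm,
         probe_fwhm_nm = probe_fwhm_nm,
         tilt_min_deg = tilt_min_deg, tilt_max_deg = tilt_max_deg,
         tilt_step_deg = tilt_step_deg, det_shape = as.integer(det_shape),
         gain_adu_per_electron = gain_adu_per_electron,
         read_noise_sigma_adu = read_noise_sigma_adu,
         dark_level_adu = dark_level_adu,
         dose_e_per_A2_per_frame = dose_e_per_A2_per_frame,
         beam_e_per_frame = beam_e_per_frame,
         bg_rate_e_per_px = bg_rate_e_per_px,
         beam_radius_px = beam_radius_px, spot_radius_px = spot_radius_px,
         edge_sigma_px = edge_sigma_px,
         diffracted_fraction = diffracted_fraction,
         excitation_tol = excitation_tol, lambda_mfp_nm = lambda_mfp_nm,
         lattices = lattices, sf_table = sf_table,
         crystal_polygons = crystal_polygons,
         thickness_profile = thickness_profile,
         max_thickness_nm = max_thickness_nm,
         vacuum_polygon = vacuum_polygon, seed = as.integer(seed)),
    class = "SimulationConfig")
}

#' Default reciprocal lattice for the simulator
#'
#' Columns are the reciprocal basis vectors `a*`, `b*`, `c*` in
#' detector-pixel units; rows are `(row, col, out_of_plane)` components.
#' `a*` lies along the tilt (detector-row) axis so its reflections stay
#' excited across the whole tilt range; `c*` points mostly out of plane so
#' higher-order layers come into the Bragg condition only at specific tilts.
#'
#' @return a 3x3 numeric matrix.
#' @export
default_lattice <- function() {
  cbind(a = c(44, 0, 0.01),
        b = c(-5, 48, -0.03),
        c = c(8, 12, 3.2))
}

#' Default relative structure-factor table
#'
#' Deterministic smoothly varying relative intensities over a small block of
#' Miller indices; purely a stand-in for a real structure.
#'
#' @return data frame with columns `h, k, l, intensity`.
#' @export
default_sf_table <- function() {
  g <- expand.grid(h = -3:3, k = -3:3, l = -2:2)
  g <- g[!(g$h == 0 & g$k == 0 & g$l == 0), ]
  g$intensity <- exp(-0.10 * (g$h^2 + g$k^2 + g$l^2)) *
    (0.35 + 0.65 * abs(cos(1.7 * g$h + 0.9 * g$k + 2.3 * g$l)))
  rownames(g) <- NULL
  g
}

default_crystal_polygons <- function(scan_shape) {
  # needle along the scan-column direction, ~40% of the rows wide
  r0 <- scan_shape[1] * 0.30; r1 <- scan_shape[1] * 0.70
  c0 <- scan_shape[2] * 0.10; c1 <- scan_shape[2] * 0.80
  list(cbind(c(r0, r0, r1, r1), c(c0, c1, c1, c0)))
}

default_vacuum_polygon <- function(scan_shape) {
  c0 <- scan_shape[2] * 0.88
  cbind(c(0.5, 0.5, scan_shape[1] + 0.5, scan_shape[1] + 0.5),
        c(c0, scan_shape[2] + 0.5, scan_shape[2] + 0.5, c0))
}

# Cylindrical needle thickness: peak thickness on the polygon axis row,
# elliptical fall-off towards the polygon's row extremes.
default_thickness_profile <- function(config) {
  z <- matrix(0, config$scan_shape[1], config$scan_shape[2])
  for (p in config$crystal_polygons) {
    mask <- polygon_mask(p, config$scan_shape)
    if (!any(mask)) next
    rows <- range(which(rowSums(mask) > 0))
    axis <- mean(rows)
    half <- (rows[2] - rows[1]) / 2 + 1
    for (r in seq_len(nrow(z))) {
      sel <- mask[r, ]
      if (!any(sel)) next
      frac <- 1 - ((r - axis) / half)^2
      z[r, sel] <- pmax(z[r, sel], config$max_thickness_nm * sqrt(max(frac, 0)))
    }
  }
  z
}

sim_tilts <- function(config) {
  seq(config$tilt_min_deg, config$tilt_max_deg, by = config$tilt_step_deg)
}

# Reflections of `lattice` excited at tilt theta (deg): rotation about the
# detector-row axis mixes the column and out-of-plane components.
excited_reflections <- function(lattice, sf_table, theta_deg, det_shape,
                                excitation_tol, margin_px = 6) {
  th <- theta_deg * pi / 180
  g <- lattice %*% t(as.matrix(sf_table[, c("h", "k", "l")]))
  gr <- g[1, ]
  gc <- cos(th) * g[2, ] - sin(th) * g[3, ]
  gz <- sin(th) * g[2, ] + cos(th) * g[3, ]
  centre <- det_centre_px(det_shape)
  row <- centre[1] + gr
  col <- centre[2] + gc
  keep <- abs(gz) < excitation_tol &
    row >= 1 + margin_px & row <= det_shape[1] - margin_px &
    col >= 1 + margin_px & col <= det_shape[2] - margin_px
  data.frame(h = sf_table$h[keep], k = sf_table$k[keep], l = sf_table$l[keep],
             det_row = row[keep], det_col = col[keep],
             intensity = sf_table$intensity[keep])
}

#' Simulate a seeded synthetic 4D-STEM tilt series with ground truth
#'
#' Generates one raw-ADU [frame_stack()] per tilt angle plus the ground
#' truth needed for validation: true electron arrivals per pixel, the crystal
#' mask(s), excited Bragg-peak positions per tilt and the thickness map. Per
#' frame the expected electron image is a central Gaussian beam plus diffuse
#' background plus, at scan positions inside a crystal polygon, Gaussian
#' Bragg spots of the excited reflections; arrivals are Poisson and the
#' detector reading is `round(arrivals * gain + dark + N(0, read_noise))`.
#' Electrons transmitted through thickness `t` are attenuated by
#' `exp(-t / lambda_mfp_nm)` and split between the central beam and the
#' excited spots according to `diffracted_fraction`.
#'
#' The configured `seed` fully determines the output (the caller's RNG
#' state is preserved).
#'
#' @param config a [sim_config()].
#' @return a list with `stacks` (list of raw-ADU `FrameStack4D`, one per
#'   tilt) and `ground_truth` (class `GroundTruth`: `electron_counts`,
#'   `crystal_masks`, `peak_positions`, `thickness_nm`, `tilts_deg`).
#' @export
simulate_tilt_series <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  ss <- config$scan_shape; ds <- config$det_shape
  nfr <- prod(ss); npx <- prod(ds)
  centre <- det_centre_px(ds)
  tilts <- sim_tilts(config)

  masks <- lapply(config$crystal_polygons, polygon_mask, shape = ss)
  thickness <- config$thickness_profile %||% default_thickness_profile(config)
  # crystal membership per scan position (first polygon wins on overlap)
  member <- matrix(0L, ss[1], ss[2])
  for (i in rev(seq_along(masks))) member[masks[[i]]] <- i

  beam_unit <- smooth_disc_image(ds, centre, config$beam_radius_px,
                                 config$edge_sigma_px)
  beam_unit <- beam_unit / sum(beam_unit)
  transmission <- exp(-thickness / config$lambda_mfp_nm)

  stacks <- vector("list", length(tilts))
  counts_gt <- vector("list", length(tilts))
  peak_rows <- list()

  with_seed(config$seed, {
    for (ti in seq_along(tilts)) {
      theta <- tilts[ti]
      # per-crystal unit spot images and excited reflection tables
      spot_units <- vector("list", length(masks))
      for (ci in seq_along(masks)) {
        refl <- excited_reflections(config$lattices[[ci]], config$sf_table,
                                    theta, ds, config$excitation_tol,
                                    margin_px = ceiling(config$spot_radius_px))
        if (nrow(refl) > 0) {
          u <- matrix(0, ds[1], ds[2])
          for (ri in seq_len(nrow(refl))) {
            u <- u + refl$intensity[ri] *
              smooth_disc_image(ds, c(refl$det_row[ri], refl$det_col[ri]),
                                config$spot_radius_px, config$edge_sigma_px)
          }
          spot_units[[ci]] <- u / sum(u)
          peak_rows[[length(peak_rows) + 1L]] <-
            data.frame(tilt_deg = theta, crystal = ci,
                       h = refl$h, k = refl$k, l = refl$l,
                       det_row = refl$det_row, det_col = refl$det_col,
                       rel_intensity = refl$intensity)
        } else {
          spot_units[[ci]] <- NULL
        }
      }
      # expected-electron image per frame, frames x pixels
      lam <- matrix(config$bg_rate_e_per_px, nfr, npx)
      total_e <- config$beam_e_per_frame * as.vector(transmission)
      memb <- as.vector(member)
      fd <- rep(0, nfr)
      for (ci in seq_along(masks)) {
        if (!is.null(spot_units[[ci]])) {
          fd[memb == ci] <- config$diffracted_fraction
        }
      }
      lam <- lam + outer(total_e * (1 - fd), as.vector(beam_unit))
      for (ci in seq_along(masks)) {
        if (is.null(spot_units[[ci]])) next
        sel <- memb == ci
        if (!any(sel)) next
        lam[sel, ] <- lam[sel, ] +
          outer(total_e[sel] * config$diffracted_fraction,
                as.vector(spot_units[[ci]]))
      }
      arrivals <- matrix(stats::rpois(length(lam), lam), nfr, npx)
      adu <- arrivals * config$gain_adu_per_electron + config$dark_level_adu
      if (config$read_noise_sigma_adu > 0) {
        adu <- adu + stats::rnorm(length(adu), 0, config$read_noise_sigma_adu)
      }
      adu <- round(adu)
      geom <- scan_geometry(config$step_nm, config$probe_fwhm_nm,
                            tilt_deg = theta,
                            dose_e_per_A2_per_frame = config$dose_e_per_A2_per_frame)
      dim(adu) <- c(ss, ds)
      dim(arrivals) <- c(ss, ds)
      stacks[[ti]] <- frame_stack(adu, geom, dtype_tag = "raw_adu")
      storage.mode(arrivals) <- "integer"
      counts_gt[[ti]] <- arrivals
    }
  })

  peaks <- if (length(peak_rows)) do.call(rbind, peak_rows) else
    data.frame(tilt_deg = numeric(0), crystal = integer(0), h = integer(0),
               k = integer(0), l = integer(0), det_row = numeric(0),
               det_col = numeric(0), rel_intensity = numeric(0))
  gt <- structure(
    list(electron_counts = counts_gt, crystal_masks = masks,
         peak_positions = peaks, thickness_nm = thickness,
         tilts_deg = tilts),
    class = "GroundTruth")
  list(stacks = stacks, ground_truth = gt)
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat(sprintf(
    "SimulationConfig: scan %d x %d, detector %d x %d, tilts %g..%g by %g deg, %d crystal(s), seed %d\n",
    x$scan_shape[1], x$scan_shape[2], x$det_shape[1], x$det_shape[2],
    x$tilt_min_deg, x$tilt_max_deg, x$tilt_step_deg,
    length(x$crystal_polygons), x$seed))
  invisible(x)
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth: %d tilt(s), %d crystal mask(s), %d peak position(s)\n",
              length(x$tilts_deg), length(x$crystal_masks),
              nrow(x$peak_positions)))
  invisible(x)
}

## ---- ground-truth and config serialization -------------------------------

write_matrix_txt <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("ROWS = %d", nrow(m)), con)
  writeLines(sprintf("COLS = %d", ncol(m)), con)
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

read_matrix_txt <- function(path) {
  lines <- readLines(path)
  nr <- as.integer(sub(".*= *", "", lines[1]))
  vals <- scan(text = lines[-(1:2)], quiet = TRUE)
  matrix(vals, nrow = nr, byrow = TRUE)
}

#' Write simulator ground truth to a directory
#'
#' Everything is stored in plain formats that round-trip losslessly:
#' electron counts as integer container stacks, crystal masks and the
#' thickness map as text matrices, peak positions as tab-separated text.
#'
#' @param gt a `GroundTruth` from [simulate_tilt_series()].
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "GroundTruth"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  for (i in seq_along(gt$electron_counts)) {
    g <- scan_geometry(1, 1, tilt_deg = gt$tilts_deg[i])
    st <- frame_stack(gt$electron_counts[[i]], g, dtype_tag = "hybrid_counts")
    write_stack(st, file.path(path, sprintf("counts_%03d.s4dc", i)),
                dialect = "container")
  }
  for (i in seq_along(gt$crystal_masks)) {
    write_matrix_txt(gt$crystal_masks[[i]] * 1L,
                     file.path(path, sprintf("crystal_mask_%02d.txt", i)))
  }
  write_matrix_txt(gt$thickness_nm, file.path(path, "thickness_nm.txt"))
  utils::write.table(gt$peak_positions, file.path(path, "peak_positions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("N_TILTS = %d", length(gt$tilts_deg)),
               sprintf("N_CRYSTALS = %d", length(gt$crystal_masks)),
               paste("TILTS_DEG =", paste(fmt_num(gt$tilts_deg), collapse = " "))),
             file.path(path, "ground_truth.txt"))
  invisible(path)
}

#' Read ground truth written by [write_ground_truth()]
#'
#' @param path directory path.
#' @return a `GroundTruth` object.
#' @export
read_ground_truth <- function(path) {
  kv <- parse_kv_lines(readLines(file.path(path, "ground_truth.txt")))
  n_tilts <- as.integer(kv[["N_TILTS"]])
  n_cry <- as.integer(kv[["N_CRYSTALS"]])
  tilts <- as.numeric(strsplit(kv[["TILTS_DEG"]], " +")[[1]])
  counts <- lapply(seq_len(n_tilts), function(i) {
    read_stack(file.path(path, sprintf("counts_%03d.s4dc", i)),
               dialect = "container")$data
  })
  masks <- lapply(seq_len(n_cry), function(i) {
    read_matrix_txt(file.path(path, sprintf("crystal_mask_%02d.txt", i))) > 0.5
  })
  peaks <- utils::read.delim(file.path(path, "peak_positions.tsv"))
  structure(
    list(electron_counts = counts, crystal_masks = masks,
         peak_positions = peaks,
         thickness_nm = read_matrix_txt(file.path(path, "thickness_nm.txt")),
         tilts_deg = tilts),
    class = "GroundTruth")
}

#' Serialize a simulation configuration as a flat key-value text file
#'
#' Scalars map to single `KEY = value` lines; composite fields are
#' flattened (lattices as nine numbers column-major, polygons and the
#' structure-factor table as repeated indexed keys, the thickness profile as
#' one line per scan row). [read_sim_config()] restores an identical object.
#'
#' @param config a [sim_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "SimulationConfig"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(k, v) writeLines(paste(k, "=", v), con)
  num_fields <- c("step_nm", "probe_fwhm_nm", "tilt_min_deg", "tilt_max_deg",
                  "tilt_step_deg", "gain_adu_per_electron",
                  "read_noise_sigma_adu", "dark_level_adu",
                  "dose_e_per_A2_per_frame", "beam_e_per_frame",
                  "bg_rate_e_per_px", "beam_radius_px", "spot_radius_px",
                  "edge_sigma_px",
                  "diffracted_fraction", "excitation_tol", "lambda_mfp_nm",
                  "max_thickness_nm", "seed")
  w("format", "STEM4D_SIM_CONFIG_V1")
  w("scan_shape", paste(config$scan_shape, collapse = " "))
  w("det_shape", paste(config$det_shape, collapse = " "))
  for (f in num_fields) w(f, fmt_num(config[[f]]))
  for (i in seq_along(config$lattices)) {
    w(sprintf("lattice_%d", i),
      paste(fmt_num(as.vector(config$lattices[[i]])), collapse = " "))
  }
  for (i in seq_along(config$crystal_polygons)) {
    w(sprintf("crystal_polygon_%d", i),
      paste(fmt_num(as.vector(t(config$crystal_polygons[[i]]))), collapse = " "))
  }
  w("vacuum_polygon",
    paste(fmt_num(as.vector(t(config$vacuum_polygon))), collapse = " "))
  for (i in seq_len(nrow(config$sf_table))) {
    w(sprintf("sf_%d", i),
      paste(config$sf_table$h[i], config$sf_table$k[i], config$sf_table$l[i],
            fmt_num(config$sf_table$intensity[i])))
  }
  if (!is.null(config$thickness_profile)) {
    for (r in seq_len(nrow(config$thickness_profile))) {
      w(sprintf("thickness_row_%d", r),
        paste(fmt_num(config$thickness_profile[r, ]), collapse = " "))
    }
  }
  invisible(path)
}

#' Read a configuration written by [write_sim_config()]
#'
#' @param path file path.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  kv <- parse_kv_lines(readLines(path))
  if (!identical(unname(kv[["format"]]), "STEM4D_SIM_CONFIG_V1")) {
    stop("not a stem4d simulation config: ", path)
  }
  nums <- function(key) as.numeric(strsplit(kv[[key]], " +")[[1]])
  pick <- function(prefix) {
    keys <- grep(paste0("^", prefix, "_[0-9]+$"), names(kv), value = TRUE)
    keys[order(as.integer(sub(paste0(prefix, "_"), "", keys)))]
  }
  lat_keys <- pick("lattice")
  lattices <- lapply(lat_keys, function(k) matrix(nums(k), 3, 3))
  lattice <- if (length(lattices)) lattices[[1]] else default_lattice()
  if (!length(lattices)) lattices <- NULL
  poly_keys <- pick("crystal_polygon")
  polys <- lapply(poly_keys, function(k) {
    matrix(nums(k), ncol = 2, byrow = TRUE)
  })
  sf_keys <- pick("sf")
  sf <- do.call(rbind, lapply(sf_keys, function(k) {
    v <- nums(k)
    data.frame(h = v[1], k = v[2], l = v[3], intensity = v[4])
  }))
  th_keys <- pick("thickness_row")
  thickness <- if (length(th_keys)) {
    do.call(rbind, lapply(th_keys, nums))
  } else NULL
  sim_config(
    scan_shape = as.integer(nums("scan_shape")),
    det_shape = as.integer(nums("det_shape")),
    step_nm = as.numeric(kv[["step_nm"]]),
    probe_fwhm_nm = as.numeric(kv[["probe_fwhm_nm"]]),
    tilt_min_deg = as.numeric(kv[["tilt_min_deg"]]),
    tilt_max_deg = as.numeric(kv[["tilt_max_deg"]]),
    tilt_step_deg = as.numeric(kv[["tilt_step_deg"]]),
    gain_adu_per_electron = as.numeric(kv[["gain_adu_per_electron"]]),
    read_noise_sigma_adu = as.numeric(kv[["read_noise_sigma_adu"]]),
    dark_level_adu = as.numeric(kv[["dark_level_adu"]]),
    dose_e_per_A2_per_frame = as.numeric(kv[["dose_e_per_A2_per_frame"]]),
    beam_e_per_frame = as.numeric(kv[["beam_e_per_frame"]]),
    bg_rate_e_per_px = as.numeric(kv[["bg_rate_e_per_px"]]),
    beam_radius_px = as.numeric(kv[["beam_radius_px"]]),
    spot_radius_px = as.numeric(kv[["spot_radius_px"]]),
    edge_sigma_px = as.numeric(kv[["edge_sigma_px"]]),
    diffracted_fraction = as.numeric(kv[["diffracted_fraction"]]),
    excitation_tol = as.numeric(kv[["excitation_tol"]]),
    lambda_mfp_nm = as.numeric(kv[["lambda_mfp_nm"]]),
    max_thickness_nm = as.numeric(kv[["max_thickness_nm"]]),
    seed = as.integer(as.numeric(kv[["seed"]])),
    lattice = lattice, lattices = lattices,
    sf_table = sf, crystal_polygons = polys,
    thickness_profile = thickness,
    vacuum_polygon = matrix(nums("vacuum_polygon"), ncol = 2, byrow = TRUE))
}
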