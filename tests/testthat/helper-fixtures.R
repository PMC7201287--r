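# Shared simulator fixtures. Problem sizes are reduced (small scan grid,
# 128 px detector, few tilts); all noise/dose/SNR defaults of sim_config()
# are left untouched.

# Small needle-on-film field of view with a vacuum strip on the right.
small_needle_config <- function(crystal_polygons = list(
                                  cbind(c(2.5, 2.5, scan_shape[1] - 2.5,
                                          scan_shape[1] - 2.5),
                                        c(2.5, scan_shape[2] - 2.6,
                                          scan_shape[2] - 2.6, 2.5))),
                                seed = 7L,
                                scan_shape = c(10L, 16L),
                                det_shape = c(128L, 128L),
                                tilt_min_deg = -2, tilt_max_deg = 2,
                                ...) {
  sim_config(scan_shape = scan_shape, det_shape = det_shape,
             tilt_min_deg = tilt_min_deg, tilt_max_deg = tilt_max_deg,
             tilt_step_deg = 1,
             crystal_polygons = crystal_polygons,
             vacuum_polygon = cbind(c(0.5, 0.5, scan_shape[1] + 0.5,
                                      scan_shape[1] + 0.5),
                                    c(scan_shape[2] - 1.6, scan_shape[2] + 0.5,
                                      scan_shape[2] + 0.5,
                                      scan_shape[2] - 1.6)),
             seed = seed, ...)
}

# Beam-blanked companion acquisition: the dark reference.
dark_reference_for <- function(cfg, tilt_index = 1L) {
  dcfg <- cfg
  dcfg$beam_e_per_frame <- 0
  dcfg$bg_rate_e_per_px <- 0
  dcfg$crystal_polygons <- list()
  dcfg$lattices <- list()
  dcfg$seed <- cfg$seed + 1000L
  estimate_dark(simulate_tilt_series(dcfg)$stacks[[tilt_index]])
}

# One cached simulation shared by the heavier tests (helpers persist for
# the whole test run).
.fixture_cache <- new.env(parent = emptyenv())

needle_fixture <- function() {
  if (!is.null(.fixture_cache$needle)) return(.fixture_cache$needle)
  cfg <- small_needle_config()
  sim <- simulate_tilt_series(cfg)
  dark <- dark_reference_for(cfg)
  nm <- fit_noise_model(sim$stacks[[3]], dark)
  counted <- lapply(sim$stacks, count_stack, model = nm)
  .fixture_cache$needle <- list(cfg = cfg, sim = sim, dark = dark, nm = nm,
                                counted = counted)
  .fixture_cache$needle
}

# Two separated crystallites with in-plane rotated lattices, single scan
# at zero tilt (multi-crystal field of view).
rotate_lattice <- function(lat, angle_deg) {
  th <- angle_deg * pi / 180
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot %*% lat
}

two_crystal_config <- function(seed = 11L) {
  polys <- list(cbind(c(2.5, 2.5, 9.5, 9.5), c(1.5, 7.5, 7.5, 1.5)),
                cbind(c(2.5, 2.5, 9.5, 9.5), c(11.5, 17.5, 17.5, 11.5)))
  sim_config(scan_shape = c(12L, 20L), det_shape = c(128L, 128L),
             tilt_min_deg = 0, tilt_max_deg = 0, tilt_step_deg = 1,
             crystal_polygons = polys,
             lattices = list(default_lattice(),
                             rotate_lattice(default_lattice(), 28)),
             vacuum_polygon = cbind(c(0.5, 0.5, 12.5, 12.5),
                                    c(18.6, 20.5, 20.5, 18.6)),
             seed = seed)
}

two_crystal_fixture <- function() {
  if (!is.null(.fixture_cache$two)) return(.fixture_cache$two)
  cfg <- two_crystal_config()
  sim <- simulate_tilt_series(cfg)
  dark <- dark_reference_for(cfg)
  nm <- fit_noise_model(sim$stacks[[1]], dark,
                        gain_adu_per_electron = cfg$gain_adu_per_electron)
  counted <- count_stack(sim$stacks[[1]], nm)
  .fixture_cache$two <- list(cfg = cfg, sim = sim, dark = dark, nm = nm,
                             counted = counted)
  .fixture_cache$two
}

# Greedy matching of found peaks to ground-truth positions; returns recall
# and precision at the given radius, ignoring truth inside the exclusion
# zone (peaks under the beam are not observable).
peak_match_stats <- function(found, truth, radius_px, centre,
                             exclude_radius_px) {
  keep <- sqrt((truth$det_row - centre[1])^2 +
                 (truth$det_col - centre[2])^2) > exclude_radius_px
  truth <- truth[keep, , drop = FALSE]
  if (nrow(truth) == 0) return(c(recall = NA, precision = NA, n_truth = 0))
  matched_truth <- logical(nrow(truth))
  matched_found <- logical(nrow(found))
  for (i in seq_len(nrow(found))) {
    d <- sqrt((truth$det_row - found$det_row[i])^2 +
                (truth$det_col - found$det_col[i])^2)
    j <- which(!matched_truth & d <= radius_px)
    if (length(j)) {
      matched_truth[j[which.min(d[j])]] <- TRUE
      matched_found[i] <- TRUE
    }
  }
  c(recall = mean(matched_truth), precision = mean(matched_found),
    n_truth = nrow(truth))
}

# Tiny hybrid-count stack with given tilt, for assembly/export tests.
tiny_count_stack <- function(tilt_deg, scan = c(2L, 2L), det = c(8L, 8L),
                             value = 1L) {
  data <- array(value, dim = c(scan, det))
  frame_stack(data, scan_geometry(40, 12, tilt_deg = tilt_deg),
              dtype_tag = "hybrid_counts")
}

full_region <- function(scan = c(2L, 2L)) {
  region_mask(matrix(TRUE, scan[1], scan[2]))
}

polygon_as_mask <- function(vertices, shape) {
  region_from_polygon(vertices, shape)$mask
}
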