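test_that("temporal median recovers the dark level and resists bright frames", {
  # constant frames
  st <- frame_stack(array(7, dim = c(4L, 4L, 3L, 3L)), scan_geometry(40, 12))
  expect_true(all(estimate_dark(st) == 7))

  # dark 10 with one bright outlier frame among 100 at one pixel
  data <- array(10, dim = c(10L, 10L, 4L, 4L))
  data[1, 1, 2, 2] <- 5000
  st <- frame_stack(data, scan_geometry(40, 12))
  expect_identical(estimate_dark(st)[2, 2], 10)

  # too few frames
  st <- frame_stack(array(1, dim = c(3L, 5L, 2L, 2L)), scan_geometry(40, 12))
  expect_error(estimate_dark(st), "at least 16 frames")
})

test_that("dark map from a beam-blanked acquisition matches the configured level", {
  cfg <- small_needle_config()
  dark <- dark_reference_for(cfg)
  # per-pixel median of N = 160 gaussian readings, sigma 5: standard error
  # ~ 1.25 sigma / sqrt(N) (+0.5 for integer ADU rounding); the worst of
  # 16384 pixels is expected near sqrt(2 log 16384) ~ 4.4 of those
  n <- prod(cfg$scan_shape)
  se <- 1.253 * cfg$read_noise_sigma_adu / sqrt(n)
  err <- abs(dark - cfg$dark_level_adu)
  expect_lt(stats::quantile(err, 0.99), 3 * se + 0.5)
  expect_lt(max(err), 5 * se + 0.5)
})

test_that("noise-model fit recovers sigma, threshold and gain", {
  # pure Gaussian residuals around a known dark level
  set.seed(1)
  d <- c(8L, 8L, 16L, 16L)
  resid <- rnorm(prod(d), 0, 5)
  st <- frame_stack(array(100 + resid, dim = d), scan_geometry(40, 12))
  dark <- matrix(100, 16, 16)
  nm <- fit_noise_model(st, dark, k_sigma = 4, gain_adu_per_electron = 32)
  s_oracle <- sd(resid)  # sample standard deviation of the generated noise
  expect_equal(nm$sigma_adu, s_oracle, tolerance = 0.03)
  expect_equal(nm$threshold_adu, 4 * nm$sigma_adu)

  # degenerate: identical values everywhere
  st0 <- frame_stack(array(100, dim = d), scan_geometry(40, 12))
  expect_error(fit_noise_model(st0, dark), "degenerate")

  # simulated sparse electrons: fitted gain within 10% of the true 32
  fx <- needle_fixture()
  expect_equal(fx$nm$gain_adu_per_electron, 32, tolerance = 0.1)
  expect_equal(fx$nm$sigma_adu, 5, tolerance = 0.1)
})

test_that("hybridize applies the threshold/quantization rule exactly", {
  nm <- noise_model(matrix(0, 2, 2), sigma_adu = 5,
                    gain_adu_per_electron = 32, threshold_adu = 20)
  # direct evaluation of the stated rule
  v <- matrix(c(0, 19, 35, 70), 2, 2)
  expect_identical(hybridize(v, nm), matrix(c(0L, 0L, 1L, 2L), 2, 2))
  expect_identical(hybridize(matrix(0, 3, 3), nm), matrix(0L, 3, 3))
  # above threshold but far below one gain still yields one electron
  expect_identical(hybridize(matrix(21, 1, 1), nm), matrix(1L, 1, 1))
  # binary counting collapses multiplicity
  expect_identical(binarize(v, nm), matrix(c(0L, 0L, 1L, 1L), 2, 2))
})

test_that("hybridize is monotone and dominates binarize elementwise", {
  nm <- noise_model(matrix(0, 2, 2), 5, 32, 20)
  set.seed(2)
  for (i in 1:20) {
    v <- matrix(runif(64, -10, 300), 8, 8)
    h <- hybridize(v, nm); b <- binarize(v, nm)
    expect_true(all(b <= h))
    ord <- order(v)
    expect_true(all(diff(h[ord]) >= 0))
  }
})

test_that("noiseless simulated frames hybridize to the exact true arrivals", {
  cfg <- small_needle_config(read_noise_sigma_adu = 0, dark_level_adu = 0,
                             tilt_min_deg = 0, tilt_max_deg = 0,
                             scan_shape = c(6L, 10L))
  sim <- simulate_tilt_series(cfg)
  nm <- noise_model(matrix(0, 128, 128), sigma_adu = 1,
                    gain_adu_per_electron = cfg$gain_adu_per_electron,
                    threshold_adu = cfg$gain_adu_per_electron / 2)
  counted <- count_stack(sim$stacks[[1]], nm)
  expect_identical(counted$data, sim$ground_truth$electron_counts[[1]])
})

test_that("binary counting degrades with occupancy while hybrid stays accurate", {
  # beam-only acquisitions of increasing intensity on a small detector:
  # per-pixel occupancy rises and binary counting saturates
  rel_err <- function(est, truth) abs(est - truth) / truth
  bin_err <- hyb_err <- numeric(3)
  doses <- c(200, 2000, 20000)
  for (i in seq_along(doses)) {
    cfg <- sim_config(scan_shape = c(5L, 8L), det_shape = c(32L, 32L),
                      tilt_min_deg = 0, tilt_max_deg = 0,
                      crystal_polygons = list(), beam_radius_px = 4,
                      beam_e_per_frame = doses[i], bg_rate_e_per_px = 0,
                      vacuum_polygon = cbind(c(0.5, 0.5, 5.5, 5.5),
                                             c(0.5, 8.5, 8.5, 0.5)),
                      seed = 5L)
    sim <- simulate_tilt_series(cfg)
    truth <- sum(sim$ground_truth$electron_counts[[1]])
    dark <- matrix(cfg$dark_level_adu, 32, 32)
    nm <- noise_model(dark, cfg$read_noise_sigma_adu,
                      cfg$gain_adu_per_electron,
                      threshold_adu = 4 * cfg$read_noise_sigma_adu)
    hyb <- count_stack(sim$stacks[[1]], nm, method = "hybrid")
    bin <- count_stack(sim$stacks[[1]], nm, method = "binary")
    hyb_err[i] <- rel_err(sum(hyb$data), truth)
    bin_err[i] <- rel_err(sum(bin$data), truth)
    expect_lte(sum(bin$data), sum(hyb$data))
  }
  expect_true(all(diff(bin_err) > 0))   # binary error grows with occupancy
  expect_true(all(hyb_err < 0.02))      # hybrid error stays bounded
  expect_true(all(hyb_err < bin_err))
})

test_that("alignment recovers delta-function offsets with the sign flipped", {
  d <- c(1L, 1L, 33L, 33L)  # centre pixel (17, 17)
  mk <- function(r, cc) {
    a <- array(0, dim = d); a[1, 1, r, cc] <- 100
    frame_stack(a, scan_geometry(40, 12))
  }
  res <- align_to_common_centre(mk(17, 17), beam_window_radius_px = 3)
  expect_identical(unlist(res$alignment$shifts[1, c("d_row", "d_col")],
                          use.names = FALSE), c(0L, 0L))
  res <- align_to_common_centre(mk(19, 14), beam_window_radius_px = 3)
  expect_identical(unlist(res$alignment$shifts[1, c("d_row", "d_col")],
                          use.names = FALSE), c(-2L, 3L))
  expect_identical(res$stack$data[1, 1, 17, 17], 100)
})

test_that("alignment recovers known per-frame beam offsets on simulated data", {
  fx <- needle_fixture()
  st <- fx$sim$stacks[[3]]
  d <- dim(st$data)
  set.seed(9)
  offsets <- cbind(sample(-3:3, d[1] * d[2], replace = TRUE),
                   sample(-3:3, d[1] * d[2], replace = TRUE))
  shifted <- st$data
  i <- 0L
  for (sr in seq_len(d[1])) for (sc in seq_len(d[2])) {
    i <- i + 1L
    shifted[sr, sc, , ] <- stem4d:::shift_matrix(
      st$data[sr, sc, , ], offsets[i, 1], offsets[i, 2], fill = fx$dark)
  }
  # window must cover the whole beam disc from any seed pixel on it:
  # radius > disc diameter (16 px) but short of the nearest spot (29 px)
  res <- align_to_common_centre(
    frame_stack(shifted, st$geometry), beam_window_radius_px = 20,
    dark_map = fx$dark, sigma_adu = fx$nm$sigma_adu)
  expect_true(all(res$alignment$shifts$alignable))
  expect_identical(cbind(res$alignment$shifts$d_row,
                         res$alignment$shifts$d_col),
                   -offsets)
})

test_that("frames without a qualifying beam are flagged unalignable", {
  d <- c(1L, 2L, 17L, 17L)
  a <- array(0, dim = d)
  a[1, 2, 5, 5] <- 100  # second frame has signal, first does not
  st <- frame_stack(a, scan_geometry(40, 12))
  expect_message(
    res <- align_to_common_centre(st, beam_window_radius_px = 3,
                                  sigma_adu = 3),
    "unalignable")
  expect_identical(res$alignment$shifts$alignable, c(FALSE, TRUE))
  expect_identical(unlist(res$alignment$shifts[1, c("d_row", "d_col")],
                          use.names = FALSE), c(0L, 0L))
})

test_that("noise models serialize to text and back", {
  nm <- noise_model(matrix(rnorm(16, 100, 1), 4, 4), 5.25, 31.75, 21, 4)
  path <- file.path(withr::local_tempdir(), "noise.txt")
  write_noise_model(nm, path)
  back <- read_noise_model(path)
  expect_equal(back$dark_map, nm$dark_map)
  expect_identical(back$sigma_adu, nm$sigma_adu)
  expect_identical(back$gain_adu_per_electron, nm$gain_adu_per_electron)
  expect_identical(back$threshold_adu, nm$threshold_adu)
})
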