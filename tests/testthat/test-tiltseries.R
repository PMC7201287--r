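test_that("sum_region reproduces a single frame and conserves counts", {
  fx <- two_crystal_fixture()
  hc <- fx$counted
  d <- dim(hc$data)
  one <- matrix(FALSE, d[1], d[2]); one[4, 5] <- TRUE
  pat <- sum_region(hc, region_mask(one))
  expect_identical(pat + 0L, hc$data[4, 5, , ] + 0L, ignore_attr = TRUE)
  all_of_it <- region_mask(matrix(TRUE, d[1], d[2]))
  expect_identical(sum(sum_region(hc, all_of_it)), sum(hc$data))
})

test_that("region sums are additive over disjoint masks", {
  fx <- two_crystal_fixture()
  hc <- fx$counted
  d <- dim(hc$data)
  set.seed(12)
  for (i in 1:5) {
    sel <- matrix(runif(d[1] * d[2]) < 0.5, d[1], d[2])
    a <- sel & matrix(runif(d[1] * d[2]) < 0.5, d[1], d[2])
    b <- sel & !a
    if (!any(a) || !any(b)) next
    expect_identical(sum_region(hc, region_mask(sel)),
                     sum_region(hc, region_mask(a)) +
                       sum_region(hc, region_mask(b)))
  }
})

test_that("sum_region rejects raw stacks and mismatched masks", {
  raw <- frame_stack(array(1.5, dim = c(2L, 2L, 4L, 4L)),
                     scan_geometry(40, 12))
  expect_error(sum_region(raw, full_region()), "hybrid counts")
  hc <- tiny_count_stack(0)
  expect_error(sum_region(hc, region_mask(matrix(TRUE, 3, 3))),
               "does not match")
})

test_that("a 1-degree series from -40 to 40 assembles 81 ordered patterns", {
  tilts <- seq(-40, 40, by = 1)
  stacks <- lapply(tilts, tiny_count_stack)
  series <- assemble_series(stacks, full_region())
  expect_length(series, 81L)
  got <- vapply(series$entries, function(e) e$tilt_deg, numeric(1))
  expect_identical(got, tilts)
  expect_identical(series$entries[[1]]$n_frames_summed, 4L)
})

test_that("shuffled input tilts come out sorted; duplicates are rejected", {
  tilts <- c(3, -5, 0, 7, -2)
  series <- assemble_series(lapply(tilts, tiny_count_stack), full_region())
  expect_identical(vapply(series$entries, function(e) e$tilt_deg, numeric(1)),
                   sort(tilts))
  expect_error(
    assemble_series(lapply(c(1, 2, 1), tiny_count_stack), full_region()),
    "duplicate tilt angles")
  single <- assemble_series(list(tiny_count_stack(5)), full_region())
  expect_length(single, 1L)
})

test_that("empty regions create logged gaps in the series", {
  stacks <- lapply(c(-1, 0, 1), tiny_count_stack)
  m_ok <- matrix(TRUE, 2, 2)
  m_empty <- structure(list(mask = matrix(FALSE, 2, 2), label = 1L,
                            provenance = list()), class = "RegionMask")
  expect_warning(
    series <- assemble_series(stacks, list(full_region(), m_empty,
                                           full_region())),
    "1 tilt\\(s\\) skipped")
  expect_length(series, 2L)
  expect_identical(vapply(series$entries, function(e) e$tilt_deg, numeric(1)),
                   c(-1, 1))
})

test_that("SMV export writes one parseable file per pattern with its tilt", {
  tilts <- c(-1, 0, 1)
  series <- assemble_series(lapply(tilts, tiny_count_stack), full_region())
  dir <- file.path(withr::local_tempdir(), "smv")
  paths <- export_series_smv(series, dir, osc_range_deg = 1)
  expect_length(paths, 3)
  expect_identical(basename(paths),
                   c("pattern_001.img", "pattern_002.img", "pattern_003.img"))
  for (i in seq_along(paths)) {
    smv <- read_smv(paths[i])
    expect_equal(as.numeric(smv$header[["OSC_START"]]), tilts[i])
    expect_equal(as.numeric(smv$header[["OSC_RANGE"]]), 1)
    # counts conserved through export at zero pedestal (value 1 everywhere,
    # 4 frames summed)
    expect_true(all(smv$data == 4))
  }
  empty <- structure(list(entries = list(), geometry = list()),
                     class = "TiltSeries")
  expect_warning(out <- export_series_smv(empty, dir), "empty")
  expect_length(out, 0)
})

test_that("exposure budget reproduces the printed dose arithmetic", {
  geom <- scan_geometry(step_nm = 40, probe_fwhm_nm = 12,
                        dose_e_per_A2_per_frame = 1)
  b <- exposure_budget(geom, n_tilts = 81)
  expect_identical(b$step_area_nm2, 1600)
  expect_equal(b$probe_area_nm2, pi * 36)       # ~113 nm^2
  expect_equal(b$area_ratio, 1600 / (pi * 36))  # ~14
  expect_identical(b$nominal_series_dose_e_per_A2, 81)
  # algebraic identity: step = FWHM * sqrt(pi) / 2 makes the ratio exactly 1
  g1 <- scan_geometry(step_nm = 12 * sqrt(pi) / 2, probe_fwhm_nm = 12)
  expect_equal(exposure_budget(g1, 1)$area_ratio, 1)
  expect_error(exposure_budget(geom, 0), "n_tilts")
})

test_that("selected-area dose is rate times sweep time", {
  expect_identical(selected_area_dose(0.01, 90, 0.3), 3)
  expect_identical(selected_area_dose(0, 90, 0.3), 0)
  # doubling the rotation rate halves the dose
  expect_identical(selected_area_dose(0.01, 90, 0.6),
                   selected_area_dose(0.01, 90, 0.3) / 2)
  expect_error(selected_area_dose(0.01, 90, 0), "angular rate")
})

test_that("magnitude comparison is exact on identical and scaled sets", {
  set.seed(21)
  refl <- data.frame(h = rep(1:5, each = 4), k = rep(1:4, 5),
                     l = rep(0:1, 10), I = runif(20, 10, 1000),
                     sigma = runif(20, 1, 3))
  same <- compare_magnitudes(refl, refl)
  expect_equal(same$slope, 1)
  expect_equal(same$r, 1)
  doubled <- refl; doubled$I <- 2 * doubled$I; doubled$sigma <- 2 * doubled$sigma
  sc <- compare_magnitudes(refl, doubled)
  expect_equal(sc$slope, 1)
  expect_equal(sc$r, 1)
  expect_error(compare_magnitudes(refl[1:2, ], refl[1:2, ]),
               "fewer than 3")
})

test_that("correlation under Gaussian perturbation matches the closed form", {
  # oracle: corr(F, F + e) = sd(F) / sqrt(sd(F)^2 + sd(e)^2) for independent e
  set.seed(22)
  n <- 4000
  hkl <- expand.grid(h = 1:20, k = 1:20, l = 1:10)[1:n, ]
  f_true <- runif(n, 20, 80)
  noise_sd <- 10
  fb <- f_true + rnorm(n, 0, noise_sd)
  fb[fb < 0.1] <- 0.1
  a <- data.frame(hkl, I = f_true^2, sigma = 1)
  b <- data.frame(hkl, I = fb^2, sigma = 1)
  res <- compare_magnitudes(a, b, i_over_sigma_min = 0)
  rho_expected <- sd(f_true) / sqrt(sd(f_true)^2 + noise_sd^2)
  expect_equal(res$r, rho_expected, tolerance = 0.03)
})

test_that("reflection lists read from whitespace text with or without header", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "refl.txt")
  writeLines(c("1 2 3 100.5 2.5", "2 0 1 50 1"), p1)
  df <- read_reflections(p1)
  expect_identical(df$h, c(1L, 2L))
  expect_identical(df$I, c(100.5, 50))
  p2 <- file.path(dir, "refl2.txt")
  writeLines(c("h k l I sigma", "1 2 3 100.5 2.5"), p2)
  expect_identical(read_reflections(p2)$sigma, 2.5)
})
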