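count_stack_from_frames <- function(frames, scan = NULL) {
  # frames: list of detector matrices laid out on a 1 x n scan
  n <- length(frames)
  det <- dim(frames[[1]])
  data <- array(0L, dim = c(1L, n, det[1], det[2]))
  for (i in seq_len(n)) data[1, i, , ] <- frames[[i]]
  frame_stack(data, scan_geometry(40, 12), dtype_tag = "hybrid_counts")
}

test_that("virtual detector validation and empty annulus are rejected", {
  expect_error(virtual_detector(-1, 5), "inner_radius_px")
  expect_error(virtual_detector(5, 5), "outer_radius_px")
  st <- count_stack_from_frames(list(matrix(1L, 9, 9)))
  expect_error(virtual_image(st, virtual_detector(100, 101)), "empty annulus")
})

test_that("electrons inside the mask are invisible to the annular detector", {
  fr <- matrix(0L, 17, 17)
  fr[9, 9] <- 5L; fr[8, 10] <- 2L   # all within radius 3 of the centre
  st <- count_stack_from_frames(list(fr))
  vi <- virtual_image(st, virtual_detector(4, Inf))
  expect_identical(as.vector(vi$values), 0)
})

test_that("counts outside the mask are summed per scan position (hand oracle)", {
  fr <- matrix(0L, 17, 17)
  fr[9, 9] <- 50L                     # central beam, inside mask
  fr[1, 1] <- 1L; fr[15, 2] <- 1L; fr[9, 16] <- 1L  # 3 scattered counts
  st <- count_stack_from_frames(list(fr, matrix(0L, 17, 17)))
  vi <- virtual_image(st, virtual_detector(5, Inf))
  expect_identical(vi$values[1, 1], 3)
  expect_identical(vi$values[1, 2], 0)
})

test_that("bright-field disc and complementary annulus partition all counts", {
  fx <- needle_fixture()
  hc <- fx$counted[[3]]
  r <- 12
  bf <- virtual_image(hc, virtual_detector(0, r))
  adf <- virtual_image(hc, virtual_detector(r, Inf))
  totals <- apply(hc$data, c(1, 2), sum)
  expect_identical(bf$values + adf$values, totals + 0)
})

test_that("virtual imaging is linear in the stack", {
  set.seed(4)
  det <- virtual_detector(2, 6)
  mk <- function() {
    frame_stack(array(sample(0:9, 2 * 3 * 12 * 12, replace = TRUE),
                      dim = c(2L, 3L, 12L, 12L)),
                scan_geometry(40, 12), dtype_tag = "hybrid_counts")
  }
  a <- mk(); b <- mk()
  ab <- frame_stack(a$data + b$data, a$geometry, dtype_tag = "hybrid_counts")
  expect_identical(virtual_image(ab, det)$values,
                   virtual_image(a, det)$values + virtual_image(b, det)$values)
})

test_that("the virtual dark field is bright on the crystal, dim on support", {
  fx <- needle_fixture()
  hc <- fx$counted[[3]]
  agg <- apply(hc$data, c(3, 4), sum)
  adf <- virtual_image(hc, virtual_detector(1.5 * beam_disc_radius(agg), Inf))
  mask <- fx$sim$ground_truth$crystal_masks[[1]]
  vacuum <- polygon_as_mask(fx$cfg$vacuum_polygon, fx$cfg$scan_shape)
  off <- !mask & !vacuum
  expect_gt(mean(adf$values[mask]), 20 * mean(adf$values[off]))
})

test_that("transmitted map adds beam and Bragg electrons (hand oracle)", {
  # constructed 17x17 frame: beam of 100 e at the centre disc, two spots of
  # 5 e each well outside it, gain 10
  det <- c(17L, 17L)
  gain <- 10
  raw <- matrix(0, det[1], det[2])
  raw[9, 9] <- 60 * gain; raw[9, 10] <- 40 * gain       # beam: 100 e
  raw[2, 2] <- 3 * gain; raw[3, 2] <- 2 * gain          # spot A: 5 e
  raw[15, 16] <- 5 * gain                               # spot B: 5 e
  raw_st <- frame_stack(array(raw, dim = c(1L, 1L, det)),
                        scan_geometry(40, 12))
  cnt_st <- frame_stack(array(as.integer(round(raw / gain)),
                              dim = c(1L, 1L, det)),
                        scan_geometry(40, 12), dtype_tag = "hybrid_counts")
  peaks <- data.frame(det_row = c(2.5, 15), det_col = c(2, 16))
  tim <- transmitted_intensity_map(raw_st, virtual_detector(0, 4), gain,
                                   peaks = peaks, stack_counts = cnt_st,
                                   peak_radius_px = 2)
  expect_equal(tim$values[1, 1], 110)
  # without the peak list: central beam only, with a warning
  expect_warning(
    tim0 <- transmitted_intensity_map(raw_st, virtual_detector(0, 4), gain),
    "overestimate")
  expect_equal(tim0$values[1, 1], 100)
})

test_that("transmission is lower through the crystal than through vacuum", {
  fx <- needle_fixture()
  st <- fx$sim$stacks[[3]]
  hc <- fx$counted[[3]]
  agg <- apply(hc$data, c(3, 4), sum)
  rb <- beam_disc_radius(agg)
  pk <- find_peaks(agg)
  tim <- transmitted_intensity_map(st, virtual_detector(0, rb + 4),
                                   fx$cfg$gain_adu_per_electron,
                                   peaks = pk, stack_counts = hc,
                                   peak_radius_px = 18, dark_map = fx$dark)
  mask <- fx$sim$ground_truth$crystal_masks[[1]]
  vacuum <- polygon_as_mask(fx$cfg$vacuum_polygon, fx$cfg$scan_shape)
  expect_gt(min(tim$values[vacuum]), max(tim$values[mask]))
})

test_that("float TIFF export restores values through the scale sidecar", {
  m <- matrix(rnorm(30, 500, 100), 5, 6)
  path <- file.path(withr::local_tempdir(), "map.tif")
  write_float_tiff(m, path)
  expect_equal(read_float_tiff(path), m, tolerance = 1e-6)
})
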