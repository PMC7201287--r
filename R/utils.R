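# Internal geometry and raster helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation calls do not perturb user randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Centre pixel of a detector of `shape` = c(rows, cols), 1-based.
det_centre_px <- function(shape) {
  c(shape[1] %/% 2L + 1L, shape[2] %/% 2L + 1L)
}

# Matrix of Euclidean distances (in px) of every pixel centre from `centre`.
dist_from <- function(shape, centre) {
  dr <- (seq_len(shape[1]) - centre[1])^2
  dc <- (seq_len(shape[2]) - centre[2])^2
  sqrt(outer(dr, dc, `+`))
}

# Unnormalized 2D Gaussian image exp(-d^2 / 2 sigma^2) at `centre`.
gaussian_image <- function(shape, centre, sigma) {
  gr <- exp(-((seq_len(shape[1]) - centre[1])^2) / (2 * sigma^2))
  gc <- exp(-((seq_len(shape[2]) - centre[2])^2) / (2 * sigma^2))
  outer(gr, gc)
}

# Smooth-edged disc: ~1 inside `radius`, logistic fall-off of width
# `edge_sigma` at the rim. The profile of a convergent-beam (CBED) disc.
smooth_disc_image <- function(shape, centre, radius, edge_sigma = 1.5) {
  d <- dist_from(shape, centre)
  1 / (1 + exp((d - radius) / edge_sigma))
}

# Rasterize a polygon given as an n x 2 matrix of (row, col) vertices into a
# logical mask over a grid of `shape`; a pixel is inside when its integer
# centre falls inside the polygon (even-odd rule).
polygon_mask <- function(vertices, shape) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2, nrow(vertices) >= 3)
  py <- rep(seq_len(shape[1]), times = shape[2])  # rows
  px <- rep(seq_len(shape[2]), each = shape[1])   # cols
  inside <- rep(FALSE, length(px))
  n <- nrow(vertices)
  j <- n
  for (i in seq_len(n)) {
    yi <- vertices[i, 1]; xi <- vertices[i, 2]
    yj <- vertices[j, 1]; xj <- vertices[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nrow = shape[1], ncol = shape[2])
}

# 8-connected component labelling of a logical matrix. Returns an integer
# matrix of labels (0 = background), numbered in discovery order.
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nb_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  current <- 0L
  queue <- integer(sum(mask))
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    current <- current + 1L
    lab[start] <- current
    queue[1L] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      idx <- queue[head]; head <- head + 1L
      r <- ((idx - 1L) %% nr) + 1L
      c <- ((idx - 1L) %/% nr) + 1L
      rr <- r + nb_r; cc <- c + nb_c
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nidx <- (cc[ok] - 1L) * nr + rr[ok]
      nidx <- nidx[mask[nidx] & lab[nidx] == 0L]
      if (length(nidx)) {
        lab[nidx] <- current
        queue[(tail + 1L):(tail + length(nidx))] <- nidx
        tail <- tail + length(nidx)
      }
    }
  }
  lab
}

# Shift a matrix by integer (d_row, d_col), filling vacated pixels with
# `fill` (a scalar or a matrix of the same shape).
shift_matrix <- function(m, d_row, d_col, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- if (is.matrix(fill)) fill else matrix(fill, nr, nc)
  src_r <- seq_len(nr) - d_row
  src_c <- seq_len(nc) - d_col
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  if (any(ok_r) && any(ok_c)) {
    out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  }
  out
}

# Collapse a 4D stack array (sr, sc, dr, dc) into a frames x pixels matrix;
# frame index runs column-major over (scan_row, scan_col), matching R's
# native array order, so `matrix(v, sr, sc)` maps values back to scan space.
frames_matrix <- function(data) {
  d <- dim(data)
  dim(data) <- c(d[1] * d[2], d[3] * d[4])
  data
}

fmt_num <- function(x) sprintf("%.17g", x)

is_count_like <- function(x) {
  all(is.finite(x)) && all(x >= 0) && all(abs(x - round(x)) < 1e-9)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
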