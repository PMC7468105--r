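#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All seeded operations in the package go through
# this so that identical seeds give bit-identical output.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
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

# Derive a child seed from a base seed and a stream index, kept inside the
# 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.double(seed) * 1103L + as.double(stream) * 12979L) %% 2147483587
}

#' Largest-remainder allocation of n items to fractional targets
#'
#' Allocates `n` into `length(fractions)` integer parts whose sum is `n`,
#' minimising the deviation from `n * fractions`. Each part first receives
#' `floor(n * f)`; the remaining items go to the parts with the largest
#' fractional remainders, ties broken toward the earlier-listed part.
#' This is the rounding rule used by every stratified split in the package.
#'
#' @param n non-negative integer to allocate.
#' @param fractions numeric vector of non-negative fractions summing to 1
#'   (within 1e-6).
#' @return integer vector of allocations summing to `n`.
#' @examples
#' largest_remainder(10, c(0.72, 0.18, 0.10))  # 7 2 1
#' @export
largest_remainder <- function(n, fractions) {
  stopifnot(n >= 0, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop("fractions must sum to 1")
  }
  target <- n * fractions
  base <- floor(target + 1e-9)
  rem <- target - base
  left <- n - sum(base)
  if (left > 0) {
    # order by remainder descending, ties by original position
    ord <- order(-rem, seq_along(rem))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# --- polygon utilities ------------------------------------------------------

# Polygons are n x 2 matrices of (x, y) vertices, 0-based pixel coordinates,
# implicitly closed. A pixel (x, y) is sampled at its centre (x + 0.5, y + 0.5).

as_polygon <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2 || nrow(p) < 3) stop("polygon must be an n x 2 matrix with n >= 3")
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y")
  p
}

polygon_area <- function(poly) {
  p <- as_polygon(poly)
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# Integer half-open bounding box c(x0, y0, x1, y1) of a polygon.
polygon_bbox <- function(poly) {
  p <- as_polygon(poly)
  c(floor(min(p[, 1])), floor(min(p[, 2])),
    ceiling(max(p[, 1])), ceiling(max(p[, 2])))
}

# Even-odd point-in-polygon test, vectorised over query points.
points_in_polygon <- function(px, py, poly) {
  p <- as_polygon(poly)
  n <- nrow(p)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- p[i, 1]; yi <- p[i, 2]
    xj <- p[j, 1]; yj <- p[j, 2]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      flip <- crosses & (px < xint)
      inside <- xor(inside, flip)
    }
    j <- i
  }
  inside
}

# Rasterise a polygon into a binary matrix covering the half-open box
# [x0, x1) x [y0, y1). Rows index y, columns index x (row 1 = y0).
rasterize_polygon <- function(poly, bbox) {
  x0 <- bbox[1]; y0 <- bbox[2]; x1 <- bbox[3]; y1 <- bbox[4]
  w <- x1 - x0; h <- y1 - y0
  if (w <= 0 || h <= 0) return(matrix(0L, max(h, 0), max(w, 0)))
  xs <- (x0:(x1 - 1)) + 0.5
  ys <- (y0:(y1 - 1)) + 0.5
  px <- rep(xs, each = h)
  py <- rep(ys, times = w)
  m <- matrix(as.integer(points_in_polygon(px, py, poly)), nrow = h, ncol = w)
  m
}

# --- separable truncated-Gaussian smoothing ---------------------------------

# Smooth a matrix with a separable Gaussian kernel truncated at `radius`
# (default 2*sigma) and renormalised; image edges are replicated. The
# truncation gives the kernel compact support: values farther than `radius`
# from any differing pixel are untouched exactly.
smooth_matrix <- function(m, sigma, radius = ceiling(2 * sigma)) {
  if (sigma <= 0) return(m)
  off <- (-radius):radius
  k <- stats::dnorm(off, sd = sigma)
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  # rows (y direction)
  out <- matrix(0, nr, nc)
  for (i in seq_along(off)) {
    idx <- pmin(pmax(seq_len(nr) + off[i], 1L), nr)
    out <- out + k[i] * m[idx, , drop = FALSE]
  }
  # columns (x direction)
  res <- matrix(0, nr, nc)
  for (i in seq_along(off)) {
    idx <- pmin(pmax(seq_len(nc) + off[i], 1L), nc)
    res <- res + k[i] * out[, idx, drop = FALSE]
  }
  res
}

# --- affine sampling --------------------------------------------------------

# Bilinear sampling of matrix `img` at fractional (x, y) positions given in
# the same 0-based pixel-centre convention as the rest of the package
# (position (x, y) means the centre of pixel (x, y), i.e. matrix cell
# [y + 1, x + 1]). Positions outside the image return `fill`.
bilinear_sample <- function(img, xq, yq, fill) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(xq); y0 <- floor(yq)
  fx <- xq - x0; fy <- yq - y0
  get_px <- function(xi, yi) {
    ok <- xi >= 0 & xi <= nc - 1 & yi >= 0 & yi <= nr - 1
    v <- rep(fill, length(xi))
    if (any(ok)) v[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  v00 <- get_px(x0, y0)
  v10 <- get_px(x0 + 1, y0)
  v01 <- get_px(x0, y0 + 1)
  v11 <- get_px(x0 + 1, y0 + 1)
  top <- v00 * (1 - fx) + v10 * fx
  bot <- v01 * (1 - fx) + v11 * fx
  top * (1 - fy) + bot * fy
}

# Apply the affine map q = A %*% (p - c) + c + t to an image by inverse
# mapping: for every output pixel q the input position p = Ainv %*% (q - c - t)
# + c is sampled bilinearly. `A` is 2x2, `shift` length-2 (x, y) in pixels,
# centre defaults to the image centre. Out-of-range samples take `fill`.
affine_warp <- function(img, A, shift = c(0, 0), centre = NULL, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(centre)) centre <- c((nc - 1) / 2, (nr - 1) / 2)
  Ainv <- solve(A)
  qx <- rep(0:(nc - 1), each = nr)
  qy <- rep(0:(nr - 1), times = nc)
  dx <- qx - centre[1] - shift[1]
  dy <- qy - centre[2] - shift[2]
  px <- Ainv[1, 1] * dx + Ainv[1, 2] * dy + centre[1]
  py <- Ainv[2, 1] * dx + Ainv[2, 2] * dy + centre[2]
  matrix(bilinear_sample(img, px, py, fill), nrow = nr, ncol = nc)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
clip255 <- function(x) pmin(pmax(x, 0), 255)
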