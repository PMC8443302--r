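# Internal numeric / image helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage seed from the global run seed
#'
#' A single global seed is expanded per stage through a counter-based affine
#' map so that stages are independently reproducible: re-running one stage
#' with the same global seed always sees the same stream, regardless of what
#' other stages did. Result is kept below 2^31 (R integers are 32-bit).
#'
#' @param seed integer global seed.
#' @param counter non-negative integer stage counter (0, 1, 2, ...).
#' @return an integer seed.
#' @export
stage_seed <- function(seed, counter = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(counter))
  # 32-bit LCG-style mix, kept in double to avoid integer overflow
  s <- (abs(seed) %% 2147483647) + 1
  s <- (s * 48271 + 7919 * (counter + 1)) %% 2147483647
  as.integer(s)
}

# Pixel-center coordinate grids (1-based, row/col), as matrices
pixel_grid <- function(nrow, ncol) {
  list(row = matrix(seq_len(nrow), nrow, ncol),
       col = matrix(seq_len(ncol), nrow, ncol, byrow = TRUE))
}

# Radial distance (in pixels) of every pixel centre from (row0, col0)
radial_map <- function(nrow, ncol, row0, col0) {
  g <- pixel_grid(nrow, ncol)
  sqrt((g$row - row0)^2 + (g$col - col0)^2)
}

gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) return(1)
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Column-wise 1D convolution of a matrix with replicate padding
conv_cols_replicate <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  if (r == 0L) return(m * k)
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
              m[rep(nrow(m), r), , drop = FALSE])
  out <- stats::filter(mp, k, sides = 2L)
  matrix(out[(r + 1L):(r + nrow(m)), ], nrow(m), ncol(m))
}

conv1_replicate <- function(x, k)
  as.numeric(conv_cols_replicate(matrix(x, ncol = 1L), k))

# Separable Gaussian blur of a matrix (replicate-padded edges)
blur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel(sigma)
  t(conv_cols_replicate(t(conv_cols_replicate(img, k)), k))
}

# Separable Gaussian blur of a 3D array; sigma may be length 3, matching
# dim(arr) axis order
blur3d <- function(arr, sigma) {
  sigma <- rep(sigma, length.out = 3L)
  d <- dim(arr)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    k <- gaussian_kernel(sigma[ax])
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    dp <- dim(a)
    a <- conv_cols_replicate(matrix(a, dp[1L]), k)
    dim(a) <- dp
    arr <- aperm(a, order(perm))
  }
  stopifnot(identical(dim(arr), d))
  arr
}

# Bilinear rotation of a matrix about its centre (degrees, CCW in row/col
# space); out-of-field pixels filled with `fill`.
rotate_image <- function(img, angle_deg, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  th <- angle_deg * pi / 180
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  g <- pixel_grid(nr, nc)
  # inverse map: destination -> source
  dr <- g$row - cr; dc <- g$col - cc
  sr <- cr + cos(th) * dr + sin(th) * dc
  sc <- cc - sin(th) * dr + cos(th) * dc
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- matrix(fill, nr, nc)
    out[ok] <- img[cbind(r[ok], c[ok])]
    out
  }
  (1 - fr) * (1 - fc) * val(r0, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) +
    fr * fc * val(r0 + 1, c0 + 1)
}

# Ordinary least-squares line fit returning slope, intercept and R^2
ols_line <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop("degenerate x vector in line fit (zero variance)")
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot == 0) 1 else max(0, 1 - ss_res / ss_tot)
  list(slope = slope, intercept = intercept, r2 = r2)
}

clamp01 <- function(x) {   # dim-preserving, unlike pmin/pmax with scalars
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
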