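# Shared small helpers: grids, finite differences, assertions.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Pixel-center coordinate grids in millimetres
#'
#' Pixel (1,1) of the matrix is the image top-left; x increases with the
#' column index, y with the row index (downward). Coordinates are the pixel
#' centres of a 0-based half-open pixel grid, so pixel (1,1) sits at 0 mm.
#'
#' @param nrow,ncol matrix dimensions.
#' @param spacing pixel spacing in mm.
#' @return list with matrices `x` and `y` (mm).
#' @keywords internal
coord_grid <- function(nrow, ncol, spacing) {
  x <- matrix(rep((seq_len(ncol) - 1) * spacing, each = nrow), nrow, ncol)
  y <- matrix(rep((seq_len(nrow) - 1) * spacing, times = ncol), nrow, ncol)
  list(x = x, y = y)
}

# Finite difference of a matrix along an axis ("x" = columns, "y" = rows):
# central differences in the interior, one-sided at the two borders.
# Optionally each raw difference is wrapped into (-pi, pi] before dividing
# by the step (for wrapped-phase maps).
fd_axis <- function(m, spacing, axis = c("x", "y"), wrap = FALSE) {
  axis <- match.arg(axis)
  if (nrow(m) < 3 || ncol(m) < 3) stopf("degenerate grid: need at least 3x3")
  flip <- axis == "y"
  if (flip) m <- t(m)
  n <- ncol(m)
  wr <- function(d) if (wrap) ((d + pi) %% (2 * pi)) - pi else d
  g <- matrix(0, nrow(m), n)
  g[, 2:(n - 1)] <- (wr(m[, 3:n] - m[, 2:(n - 1)]) +
                     wr(m[, 2:(n - 1)] - m[, 1:(n - 2)])) / (2 * spacing)
  g[, 1] <- wr(m[, 2] - m[, 1]) / spacing
  g[, n] <- wr(m[, n] - m[, n - 1]) / spacing
  if (flip) t(g) else g
}

# Gaussian blur via FFT (periodic boundaries), sigma in pixels.
fft_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  f1 <- c(0:floor(n1 / 2), -(ceiling(n1 / 2) - 1):-1) / n1
  f2 <- c(0:floor(n2 / 2), -(ceiling(n2 / 2) - 1):-1) / n2
  h <- exp(-2 * pi^2 * sigma^2 * outer(f1^2, f2^2, `+`))
  Re(stats::fft(stats::fft(m) * h, inverse = TRUE)) / (n1 * n2)
}

# Binary mask erosion by a 1-pixel 4-neighbourhood, applied `steps` times.
erode_mask <- function(mask, steps = 1) {
  m <- mask
  for (s in seq_len(steps)) {
    p <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
    p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    i <- 2:(nrow(m) + 1); j <- 2:(ncol(m) + 1)
    m <- p[i, j] & p[i - 1, j] & p[i + 1, j] & p[i, j - 1] & p[i, j + 1]
  }
  m
}

draw_pool <- function(pool, n = 1) {
  if (length(pool) != 2 || pool[1] > pool[2])
    stopf("parameter pool must be c(min, max) with min <= max")
  stats::runif(n, pool[1], pool[2])
}
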