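# Input conditioning: resampling to the training grid, de-rectification of
# magnitude tag images, and intensity normalization for network input.

# Catmull-Rom (a = -0.5) cubic convolution kernel.
cubic_kernel <- function(t) {
  a <- -0.5
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# Interpolation weight matrix mapping n_in samples at spacing d_in to
# n_out samples at spacing d_out, both centred on the same physical span.
interp_weights <- function(n_in, d_in, n_out, d_out, method = "cubic") {
  off <- ((n_in - 1) * d_in - (n_out - 1) * d_out) / 2
  pos <- (off + (seq_len(n_out) - 1) * d_out) / d_in  # 0-based source units
  W <- matrix(0, n_out, n_in)
  if (method == "nearest") {
    j <- pmin(pmax(round(pos) + 1, 1), n_in)
    W[cbind(seq_len(n_out), j)] <- 1
    return(W)
  }
  i0 <- floor(pos)
  for (k in -1:2) {
    j <- pmin(pmax(i0 + k + 1, 1), n_in)   # clamp at borders
    w <- cubic_kernel(pos - (i0 + k))
    W[cbind(seq_len(n_out), j)] <- W[cbind(seq_len(n_out), j)] + w
  }
  sweep(W, 1, rowSums(W), "/")
}

resample_matrix <- function(m, d_in, n_out, d_out, method = "cubic") {
  d_in <- rep(d_in, length.out = 2)  # (row, col) spacing
  Wy <- interp_weights(nrow(m), d_in[1], n_out, d_out, method)
  Wx <- interp_weights(ncol(m), d_in[2], n_out, d_out, method)
  Wy %*% m %*% t(Wx)
}

#' Resample a tagged frame pair to the training grid
#'
#' Bicubic (Catmull-Rom) interpolation of both tag images to an isotropic
#' `target_spacing` grid of `target_size` pixels, centred on the source
#' field of view (crop/pad as needed). Masks, when present, are resampled
#' with nearest-neighbour interpolation. Tag spacing metadata is unchanged
#' (it is a physical distance in mm). Inputs already on the target grid are
#' returned unchanged.
#'
#' @param pair a `tagged_pair`; `pixel_spacing` may be a scalar or a
#'   `(row, col)` pair for anisotropic acquisitions.
#' @param target_spacing target pixel spacing in mm (default 1.1).
#' @param target_size output matrix size (default 256).
#' @return the resampled `tagged_pair`.
#' @export
resample_pair <- function(pair, target_spacing = 1.1, target_size = 256) {
  sp <- pair$pixel_spacing
  if (is.null(sp) || any(sp <= 0)) stopf("missing pixel spacing metadata")
  if (length(sp) == 1 && sp == target_spacing &&
      nrow(pair$I_h) == target_size && ncol(pair$I_h) == target_size)
    return(pair)
  out <- pair
  for (nm in intersect(c("I_h", "I_v", "I_do", "I_To"), names(pair))) {
    if (is.matrix(pair[[nm]]))
      out[[nm]] <- resample_matrix(pair[[nm]], sp, target_size,
                                   target_spacing)
  }
  if (!is.null(pair$masks)) {
    out$masks <- lapply(pair$masks, function(m)
      resample_matrix(m * 1, sp, target_size, target_spacing,
                      method = "nearest") > 0.5)
  }
  out$pixel_spacing <- target_spacing
  out
}

#' De-rectify a magnitude tag image using its phase
#'
#' Magnitude reconstruction rectifies the signed sinusoidal tag pattern,
#' doubling the tag frequency and corrupting the harmonic phase. The sign
#' is recovered from the complex phase: the slowly varying inhomogeneity
#' phase `phi_e` is first detrended by a least-squares degree-2 polynomial
#' fit (on the doubled-angle phase, which is blind to the rectification pi
#' jumps), and pixels whose residual wrapped phase deviates by more than
#' pi/2 are assigned the negative lobe. Output is `sign * magnitude`.
#'
#' @param magnitude magnitude image (non-negative matrix).
#' @param phase co-registered wrapped phase image; an error is raised when
#'   absent, directing users to a signed-mode acquisition.
#' @return signed tag image matrix.
#' @export
derectify <- function(magnitude, phase) {
  if (missing(phase) || is.null(phase))
    stopf(paste("phase image required to de-rectify; acquire in signed",
                "(complex) mode or supply the phase series"))
  n1 <- nrow(magnitude); n2 <- ncol(magnitude)
  u <- seq(-1, 1, length.out = n1); v <- seq(-1, 1, length.out = n2)
  xx <- matrix(rep(v, each = n1), n1, n2)
  yy <- matrix(rep(u, times = n2), n1, n2)
  basis <- cbind(1, c(xx), c(yy), c(xx)^2, c(xx) * c(yy), c(yy)^2)
  # doubled-angle phase is 2 phi_e regardless of the rectification sign
  ph2 <- Arg(exp(2i * phase))
  coef <- qr.solve(basis, c(ph2))
  phi_e_hat <- matrix(basis %*% coef, n1, n2) / 2
  resid <- Arg(exp(1i * (phase - phi_e_hat)))
  s <- ifelse(abs(resid) > pi / 2, -1, 1)
  s * magnitude
}

#' Normalize a tagged pair for network input
#'
#' Scales both tag images jointly into \[-1, 1\] by the maximum absolute
#' intensity of the pair; the scale is recorded on the object so the
#' normalization can be inverted.
#'
#' @param pair a `tagged_pair`.
#' @return the normalized pair with attribute field `norm_scale`.
#' @export
normalize_pair <- function(pair) {
  sc <- max(abs(pair$I_h), abs(pair$I_v), 1e-12)
  pair$I_h <- pair$I_h / sc
  pair$I_v <- pair$I_v / sc
  pair$norm_scale <- sc
  pair
}
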