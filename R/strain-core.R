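#' Continuum-mechanics kernel for 2D Eulerian strain
#'
#' The deformation of a tissue slice is described by the motion x = x(X, t)
#' taking material (reference) coordinates X to spatial coordinates x. Its
#' gradient F = dx/dX (the deformation gradient) defines the left
#' Cauchy-Green tensor B = F F' and the Eulerian strain
#' e = (I - B^-1) / 2, a symmetric 2x2 tensor expressed directly in spatial
#' coordinates. Its eigenvalues are the principal strains (maximum stretching
#' eps_p1 and maximum contraction eps_p2) with perpendicular principal
#' directions n1, n2.
#'
#' All per-pixel tensor fields are stored as plain matrices (one matrix per
#' tensor component) on the spatial image grid; coordinates are in mm with
#' pixel (1,1) at the image top-left, x rightward (columns), y downward
#' (rows). Strains are dimensionless.
#'
#' @name strain_core
NULL

new_strain_field <- function(exx, eyy, exy, mask = NULL) {
  structure(list(exx = exx, eyy = eyy, exy = exy,
                 mask = mask %||% matrix(TRUE, nrow(exx), ncol(exx))),
            class = "strain_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Finite-difference gradient of a per-pixel field
#'
#' Central differences in the interior, one-sided differences at the image
#' borders (second-order accurate in the interior; exact for quadratics).
#'
#' @param field a matrix (scalar map), or a list with matrices `ux`, `uy`
#'   (a displacement field).
#' @param spacing pixel spacing in mm (ignored if `field` carries its own
#'   `pixel_spacing`).
#' @return for a scalar map, a list `d_dx`, `d_dy`; for a displacement field,
#'   a list of the four Jacobian components `duxdx`, `duxdy`, `duydx`,
#'   `duydy` (units: field units per mm).
#' @export
finite_difference_gradient <- function(field, spacing = NULL) {
  if (is.matrix(field)) {
    if (is.null(spacing) || spacing <= 0) stopf("positive `spacing` required")
    return(list(d_dx = fd_axis(field, spacing, "x"),
                d_dy = fd_axis(field, spacing, "y")))
  }
  spacing <- field$pixel_spacing %||% spacing
  if (is.null(spacing) || spacing <= 0) stopf("positive `spacing` required")
  list(duxdx = fd_axis(field$ux, spacing, "x"),
       duxdy = fd_axis(field$ux, spacing, "y"),
       duydx = fd_axis(field$uy, spacing, "x"),
       duydy = fd_axis(field$uy, spacing, "y"))
}

#' Eulerian strain from a forward deformation gradient field
#'
#' Computes e = (I - (F F')^-1) / 2 per pixel. Pixels where det F <= 0
#' (possible on noisy numeric gradients; impossible for true soft-tissue
#' motion) are flagged invalid in the mask rather than raising an error.
#'
#' @param f list of per-pixel matrices `f11`, `f12`, `f21`, `f22` holding the
#'   components of F (row = spatial, column = material).
#' @return a `strain_field`: matrices `exx`, `eyy`, `exy` and a logical
#'   validity `mask`.
#' @export
strain_from_forward_gradient <- function(f) {
  det <- f$f11 * f$f22 - f$f12 * f$f21
  ok <- is.finite(det) & det > 0
  # G = F^-1 computed per pixel by the 2x2 adjugate, then e = (I - G'G)/2.
  d <- ifelse(ok, det, 1)
  g <- list(f11 =  f$f22 / d, f12 = -f$f12 / d,
            f21 = -f$f21 / d, f22 =  f$f11 / d)
  e <- strain_from_inverse_gradient(g)
  e$mask <- e$mask & ok
  e$exx[!ok] <- NA_real_; e$eyy[!ok] <- NA_real_; e$exy[!ok] <- NA_real_
  e
}

#' Eulerian strain from an inverse deformation gradient field
#'
#' With G = F^-1 (the gradient of the inverse motion X(x, t), as estimated
#' e.g. from harmonic phase), B^-1 = G'G and e = (I - G'G) / 2 directly in
#' spatial coordinates.
#'
#' @param g list of per-pixel matrices `f11`, `f12`, `f21`, `f22` holding G.
#' @return a `strain_field`.
#' @export
strain_from_inverse_gradient <- function(g) {
  # G'G = [[g11^2+g21^2, g11 g12 + g21 g22], [., g12^2+g22^2]]
  exx <- 0.5 * (1 - (g$f11^2 + g$f21^2))
  eyy <- 0.5 * (1 - (g$f12^2 + g$f22^2))
  exy <- -0.5 * (g$f11 * g$f12 + g$f21 * g$f22)
  ok <- is.finite(exx) & is.finite(eyy) & is.finite(exy)
  new_strain_field(exx, eyy, exy, ok)
}

#' Principal decomposition of a 2D strain field
#'
#' Closed-form eigen-decomposition of each symmetric 2x2 tensor. `eps_p1` is
#' the larger eigenvalue (maximum stretching), `eps_p2` the smaller (maximum
#' contraction); `n1`, `n2` are unit principal directions with the sign
#' convention that the first nonzero component is >= 0.
#'
#' @param e a `strain_field`.
#' @return an object of class `principal_strain`: matrices `eps_p1`,
#'   `eps_p2`, direction components `n1x`, `n1y`, `n2x`, `n2y`, and the
#'   validity `mask`.
#' @export
principal_decomposition <- function(e) {
  m <- (e$exx + e$eyy) / 2
  r <- sqrt(((e$exx - e$eyy) / 2)^2 + e$exy^2)
  p1 <- m + r
  p2 <- m - r
  # Eigenvector for p1: (exy, p1 - exx), or (1, 0) when the tensor is
  # (numerically) already diagonal with exx >= eyy, (0, 1) otherwise.
  vx <- e$exy
  vy <- p1 - e$exx
  deg <- abs(vx) < 1e-14 & abs(vy) < 1e-14
  vx[deg] <- 1; vy[deg] <- 0
  nrm <- sqrt(vx^2 + vy^2)
  n1x <- vx / nrm; n1y <- vy / nrm
  # sign: first nonzero component >= 0
  flip <- (n1x < 0) | (abs(n1x) < 1e-14 & n1y < 0)
  n1x[flip] <- -n1x[flip]; n1y[flip] <- -n1y[flip]
  n2x <- -n1y; n2y <- n1x
  flip2 <- (n2x < 0) | (abs(n2x) < 1e-14 & n2y < 0)
  n2x[flip2] <- -n2x[flip2]; n2y[flip2] <- -n2y[flip2]
  new_principal_strain(p1, p2, n1x, n1y, n2x, n2y, e$mask)
}

new_principal_strain <- function(eps_p1, eps_p2, n1x = NULL, n1y = NULL,
                                 n2x = NULL, n2y = NULL, mask = NULL) {
  structure(list(eps_p1 = eps_p1, eps_p2 = eps_p2,
                 n1x = n1x, n1y = n1y, n2x = n2x, n2y = n2y,
                 mask = mask %||% matrix(TRUE, nrow(eps_p1), ncol(eps_p1))),
            class = "principal_strain")
}

#' @export
print.principal_strain <- function(x, ...) {
  cat(sprintf("<principal_strain> %d x %d pixels, %d valid\n",
              nrow(x$eps_p1), ncol(x$eps_p1), sum(x$mask)))
  cat(sprintf("  eps_p1 in [%.3f, %.3f]; eps_p2 in [%.3f, %.3f]\n",
              min(x$eps_p1[x$mask]), max(x$eps_p1[x$mask]),
              min(x$eps_p2[x$mask]), max(x$eps_p2[x$mask])))
  invisible(x)
}

#' Tidy a principal strain map into a long tibble
#'
#' @param x a `principal_strain`.
#' @param ... unused.
#' @return a tibble with one row per valid pixel: `row`, `col`, `eps_p1`,
#'   `eps_p2`.
#' @export
tidy.principal_strain <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  tibble::tibble(row = idx[, 1], col = idx[, 2],
                 eps_p1 = x$eps_p1[idx], eps_p2 = x$eps_p2[idx])
}
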