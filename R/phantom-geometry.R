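#' Parameter pools and imaging profiles for the phantom simulator
#'
#' The simulator draws every anatomical, functional and imaging parameter
#' uniformly from a (min, max) pool, mirroring a Monte-Carlo design: each
#' cine is a fresh draw. Two built-in profiles are provided:
#'
#' * `"full"`: 256 x 256 matrix at 1.1 mm/pixel (281.6 mm field of view),
#'   8 mm tag spacing — the scale used for HARP experiments.
#' * `"desk"`: 64 x 64 matrix at 2.2 mm/pixel with all geometry pools scaled
#'   by 1/2 (same organ proportions and identical strain distributions,
#'   since strain is dimensionless and the motion model is scale-invariant).
#'   Sized for CPU-scale network training.
#'
#' Lengths are mm, angles radians, times in frame units.
#'
#' @param profile `"full"` or `"desk"`.
#' @return a list with `matrix_size`, `pixel_spacing`, `tag_spacing`, and
#'   `pools` (named list of `c(min, max)` pools).
#' @export
simulator_profile <- function(profile = c("full", "desk")) {
  profile <- match.arg(profile)
  s <- if (profile == "full") 1 else 0.5
  list(
    profile = profile,
    matrix_size = if (profile == "full") 256L else 64L,
    pixel_spacing = if (profile == "full") 1.1 else 2.2,
    tag_spacing = 8,
    pools = list(
      # geometry (offsets are relative to the image centre, mm)
      lv_cx_off = s * c(-30, 0),    lv_cy_off = s * c(-15, 15),
      lv_inner = s * c(18, 30),     lv_wall = s * c(8, 14),
      liver_dist = s * c(75, 105),  liver_angle = c(-0.5, 0.5),
      liver_inner = s * c(45, 70),  liver_wall = s * c(15, 30),
      theta1 = c(2.6, 3.7),         theta2 = c(0.7, 1.5),
      # motion (dimensionless / radians)
      lv_contraction = c(0.08, 0.28), liver_contraction = c(0.02, 0.10),
      lv_rotation = c(-0.12, 0.12),
      # acquisition
      snr = c(8, 30), speckle_sd = c(0.10, 0.30), speckle_grain = c(1.5, 3),
      fade_tau = c(10, 20), phi_e_amp = c(0.0, 0.6),
      # anatomical intensities (arbitrary units)
      int_myo = c(0.7, 1.0), int_liver = c(0.5, 0.9),
      int_blood = c(0.10, 0.25), int_bg = c(0.3, 0.7)
    )
  )
}

#' Draw an annulus geometry from parameter pools
#'
#' The left ventricle is a complete annulus; the liver is an annulus sector
#' with angular position `theta1` and width `theta2`. All parameters are
#' drawn uniformly from their pools using the current RNG state (seed the
#' session RNG, or pass `seed`, for reproducibility).
#'
#' @param prof a [simulator_profile()] list.
#' @param seed optional integer seed.
#' @return a list of class `annulus_geometry`.
#' @export
sample_geometry <- function(prof = simulator_profile("full"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- prof$pools
  ctr <- (prof$matrix_size - 1) * prof$pixel_spacing / 2
  ang <- draw_pool(p$liver_angle)
  dist <- draw_pool(p$liver_dist)
  lv_inner <- draw_pool(p$lv_inner)
  liver_inner <- draw_pool(p$liver_inner)
  g <- list(
    lv_center = c(ctr + draw_pool(p$lv_cx_off), ctr + draw_pool(p$lv_cy_off)),
    lv_inner_radius = lv_inner,
    lv_outer_radius = lv_inner + draw_pool(p$lv_wall),
    liver_center = c(ctr + dist * cos(ang), ctr + dist * sin(ang)),
    liver_inner_radius = liver_inner,
    liver_outer_radius = liver_inner + draw_pool(p$liver_wall),
    theta1 = draw_pool(p$theta1),
    theta2 = draw_pool(p$theta2)
  )
  stopifnot(g$lv_inner_radius > 0, g$lv_outer_radius > g$lv_inner_radius,
            g$liver_inner_radius > 0,
            g$liver_outer_radius > g$liver_inner_radius,
            g$theta2 > 0, g$theta2 <= 2 * pi)
  structure(g, class = "annulus_geometry")
}

#' Draw a motion model from parameter pools
#'
#' Peak inner-radius contraction fractions per organ, a raised-cosine
#' systolic time profile peaking at `peak_frame` (0-based) and returning to
#' rest by the last frame, and an optional rigid rotation of the ventricle.
#' The deformation is incompressible (area-preserving) by construction.
#'
#' @inheritParams sample_geometry
#' @param n_frames frames per cine.
#' @param peak_frame 0-based index of peak contraction.
#' @return a list of class `motion_model`.
#' @export
sample_motion <- function(prof = simulator_profile("full"), n_frames = 7,
                          peak_frame = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_frames < 2) stopf("a cine needs at least 2 frames")
  p <- prof$pools
  m <- list(contraction = c(lv = draw_pool(p$lv_contraction),
                            liver = draw_pool(p$liver_contraction)),
            rotation = c(lv = draw_pool(p$lv_rotation), liver = 0),
            n_frames = as.integer(n_frames),
            peak_frame = as.integer(peak_frame),
            incompressible = TRUE)
  stopifnot(all(m$contraction > 0), all(m$contraction <= 0.6))
  structure(m, class = "motion_model")
}

#' Systolic time profile
#'
#' Raised-cosine ramp from 0 at frame 0 to 1 at `peak_frame`, then a
#' raised-cosine relaxation back to 0 at the final frame.
#'
#' @param t 0-based frame index (vectorized).
#' @param motion a `motion_model`.
#' @return profile value(s) in \[0, 1\].
#' @export
time_profile <- function(t, motion) {
  pk <- motion$peak_frame
  last <- motion$n_frames - 1
  up <- (1 - cos(pi * pmin(t, pk) / max(pk, 1))) / 2
  dn <- if (last > pk) (1 + cos(pi * (pmax(t, pk) - pk) / (last - pk))) / 2 else 1
  ifelse(t <= pk, up, dn)
}

#' Incompressible annulus motion maps
#'
#' Radially symmetric area-preserving contraction about an organ centre:
#' with the inner radius contracted from `r0i` to `ri(t)` and
#' `delta(t) = r0i^2 - ri(t)^2`, a material point at radius R maps to
#' spatial radius `sqrt(R^2 - delta)`, plus an optional rigid rotation.
#' Annulus area is preserved exactly and the outer radius follows
#' `r_o(t) = sqrt(r0o^2 - delta)`. Both the forward map x(X, t) and its
#' closed-form inverse X(x, t) are returned.
#'
#' @param geom an `annulus_geometry`.
#' @param motion a `motion_model`.
#' @param t 0-based frame index.
#' @param organ `"lv"` or `"liver"`.
#' @return list with `forward(X, Y)`, `inverse(x, y)` (both take/return mm
#'   coordinates as a list of two matrices/vectors), `r_i`, `r_o`, `delta`,
#'   `rot`, `center`, and the reference radii.
#' @export
annulus_motion <- function(geom, motion, t, organ = c("lv", "liver")) {
  organ <- match.arg(organ)
  ctr <- if (organ == "lv") geom$lv_center else geom$liver_center
  r0i <- if (organ == "lv") geom$lv_inner_radius else geom$liver_inner_radius
  r0o <- if (organ == "lv") geom$lv_outer_radius else geom$liver_outer_radius
  s <- time_profile(t, motion)
  ri <- r0i * (1 - motion$contraction[[organ]] * s)
  delta <- r0i^2 - ri^2
  if (ri <= 0 || delta >= r0i^2)
    stopf("annulus collapses: contraction too large")
  rot <- motion$rotation[[organ]] * s
  forward <- function(X, Y) {
    dx <- X - ctr[1]; dy <- Y - ctr[2]
    R <- sqrt(dx^2 + dy^2)
    r2 <- R^2 - delta
    r <- sqrt(pmax(r2, 0))
    th <- atan2(dy, dx) + rot
    list(x = ctr[1] + r * cos(th), y = ctr[2] + r * sin(th))
  }
  inverse <- function(x, y) {
    dx <- x - ctr[1]; dy <- y - ctr[2]
    rho <- sqrt(dx^2 + dy^2)
    R <- sqrt(rho^2 + delta)
    th <- atan2(dy, dx) - rot
    list(x = ctr[1] + R * cos(th), y = ctr[2] + R * sin(th))
  }
  list(forward = forward, inverse = inverse,
       r_i = ri, r_o = sqrt(r0o^2 - delta), delta = delta, rot = rot,
       center = ctr, r0_i = r0i, r0_o = r0o)
}

# Spatial-domain organ masks at frame t. Returns logical matrices on the
# image grid: lv (deformed annulus), blood (inside the contracted inner
# radius), liver (deformed sector), background. Masks are disjoint; the
# ventricle takes precedence over the liver where draws overlap.
organ_masks <- function(geom, motion, t, grid) {
  lv <- annulus_motion(geom, motion, t, "lv")
  li <- annulus_motion(geom, motion, t, "liver")
  dxl <- grid$x - lv$center[1]; dyl <- grid$y - lv$center[2]
  rho_lv <- sqrt(dxl^2 + dyl^2)
  m_lv <- rho_lv >= lv$r_i & rho_lv <= lv$r_o
  m_blood <- rho_lv < lv$r_i
  dxv <- grid$x - li$center[1]; dyv <- grid$y - li$center[2]
  rho_li <- sqrt(dxv^2 + dyv^2)
  th <- (atan2(dyv, dxv) - li$rot - geom$theta1) %% (2 * pi)
  m_li <- rho_li >= li$r_i & rho_li <= li$r_o & th <= geom$theta2 &
    !m_lv & !m_blood
  list(lv = m_lv, blood = m_blood, liver = m_li,
       background = !(m_lv | m_blood | m_li))
}

#' Analytic ground-truth principal strain maps
#'
#' Closed-form Eulerian strain of the incompressible radial annulus motion,
#' evaluated on the spatial grid. In polar coordinates about the organ
#' centre the deformation gradient is diagonal, F = diag(dr/dR, r/R), so at
#' a spatial pixel at radius rho (material radius R = sqrt(rho^2 + delta))
#' the principal strains are `eps_p1 = (1 - (rho/R)^2) / 2` in the radial
#' direction and `eps_p2 = (1 - (R/rho)^2) / 2` circumferentially. A rigid
#' rotation leaves the strain unchanged. Strain is identically zero outside
#' the moving organs.
#'
#' @inheritParams annulus_motion
#' @param grid coordinate grid from [coord_grid()]; built from `prof` if
#'   missing.
#' @param prof a [simulator_profile()] (used only when `grid` is missing).
#' @return a `principal_strain` whose `mask` is all-true; attribute
#'   `organ_mask` marks moving-tissue pixels.
#' @export
analytic_ground_truth <- function(geom, motion, t, grid = NULL,
                                  prof = simulator_profile("full")) {
  if (is.null(grid))
    grid <- coord_grid(prof$matrix_size, prof$matrix_size, prof$pixel_spacing)
  dims <- dim(grid$x)
  p1 <- matrix(0, dims[1], dims[2]); p2 <- p1
  n1x <- matrix(1, dims[1], dims[2]); n1y <- matrix(0, dims[1], dims[2])
  masks <- organ_masks(geom, motion, t, grid)
  for (organ in c("lv", "liver")) {
    mm <- annulus_motion(geom, motion, t, organ)
    sel <- masks[[organ]]
    if (!any(sel)) next
    dx <- grid$x[sel] - mm$center[1]; dy <- grid$y[sel] - mm$center[2]
    rho <- sqrt(dx^2 + dy^2)
    R <- sqrt(rho^2 + mm$delta)
    p1[sel] <- 0.5 * (1 - (rho / R)^2)
    p2[sel] <- 0.5 * (1 - (R / rho)^2)
    # radial principal direction, sign convention first nonzero comp >= 0
    nx <- dx / rho; ny <- dy / rho
    fl <- nx < 0 | (abs(nx) < 1e-14 & ny < 0)
    nx[fl] <- -nx[fl]; ny[fl] <- -ny[fl]
    n1x[sel] <- nx; n1y[sel] <- ny
  }
  out <- new_principal_strain(p1, p2, n1x, n1y, -n1y, n1x)
  attr(out, "organ_mask") <- masks$lv | masks$liver
  out
}

# Dense inverse-motion material-coordinate maps X(x, t) on the grid.
# Outside the moving organs (background, blood pool) the map is identity.
material_coordinates <- function(geom, motion, t, grid) {
  Xm <- grid$x; Ym <- grid$y
  masks <- organ_masks(geom, motion, t, grid)
  for (organ in c("lv", "liver")) {
    mm <- annulus_motion(geom, motion, t, organ)
    sel <- masks[[organ]]
    if (!any(sel)) next
    inv <- mm$inverse(grid$x[sel], grid$y[sel])
    Xm[sel] <- inv$x; Ym[sel] <- inv$y
  }
  list(X = Xm, Y = Ym, masks = masks)
}
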