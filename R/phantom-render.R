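#' Draw acquisition parameters from their pools
#'
#' Tag spacing and pixel spacing come from the profile; SNR, speckle
#' statistics, tag-fading time constant and the field-inhomogeneity phase
#' amplitude are drawn uniformly from the profile pools.
#'
#' @inheritParams sample_geometry
#' @return list of class `acquisition_params`.
#' @export
sample_acquisition <- function(prof = simulator_profile("full"),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- prof$pools
  if (prof$tag_spacing <= 2 * prof$pixel_spacing)
    stopf("tag carrier above Nyquist: tag_spacing must exceed 2 pixels")
  structure(list(
    tag_spacing = prof$tag_spacing,
    f_d = 1 / prof$tag_spacing,
    omega_d = 2 * pi / prof$tag_spacing,
    pixel_spacing = prof$pixel_spacing,
    matrix_size = prof$matrix_size,
    snr = draw_pool(p$snr),
    speckle_sd = draw_pool(p$speckle_sd),
    speckle_grain = draw_pool(p$speckle_grain),
    fade_tau = draw_pool(p$fade_tau),
    phi_e_coef = stats::runif(6, -1, 1) * draw_pool(p$phi_e_amp),
    intensities = c(myo = draw_pool(p$int_myo), liver = draw_pool(p$int_liver),
                    blood = draw_pool(p$int_blood), bg = draw_pool(p$int_bg))
  ), class = "acquisition_params")
}

# Synthetic anatomical background standing in for a chest image behind the
# moving organs (seeded by the caller's RNG): smooth low-frequency shading,
# a handful of elliptical "organ" regions with distinct intensities and
# sharp (1 px) boundaries, and fine speckle-scale texture — the
# piecewise-structured statistics of anatomical MR images, whose edges
# spread broadband energy across k-space.
background_texture <- function(n, amplitude, grain = 6) {
  z <- fft_blur(matrix(stats::rnorm(n * n), n, n), grain)
  z <- (z - min(z)) / (max(z) - min(z) + 1e-12)
  bg <- 0.3 + 0.7 * z
  ij <- coord_grid(n, n, 1)
  n_blob <- sample(5:10, 1)
  for (b in seq_len(n_blob)) {
    cx <- stats::runif(1, 0, n); cy <- stats::runif(1, 0, n)
    ax <- stats::runif(1, n / 16, n / 4); ay <- stats::runif(1, n / 16, n / 4)
    th <- stats::runif(1, 0, pi)
    dx <- ij$x - cx; dy <- ij$y - cy
    u <- (dx * cos(th) + dy * sin(th)) / ax
    v <- (-dx * sin(th) + dy * cos(th)) / ay
    lvl <- stats::runif(1, 0.1, 1.1)
    w <- fft_blur((u^2 + v^2 <= 1) * 1, 1)
    bg <- bg * (1 - w) + lvl * w
  }
  fine <- fft_blur(matrix(stats::rnorm(n * n), n, n), 1.2)
  bg <- pmax(bg * (1 + 0.25 * fine / stats::sd(fine)), 0)
  amplitude * bg
}

# Anatomical (spin-density) image from region masks and drawn intensities,
# with a gentle radial shading inside organs so they are not flat.
anatomical_image <- function(masks, acq, bg) {
  io <- bg
  io[masks$lv] <- acq$intensities[["myo"]]
  io[masks$liver] <- acq$intensities[["liver"]]
  io[masks$blood] <- acq$intensities[["blood"]]
  io
}

#' Render a noise-free tagged frame pair
#'
#' Implements the image-domain tagging model: the tag pattern is a material
#' property laid down at the reference configuration, so the intensity at a
#' spatial pixel x is determined by its material coordinate X(x, t):
#' `I_d(x, t) = I_do(x, t) + I_To(x, t) cos(omega_d X(x, t) . n_d)`.
#' `I_h` carries horizontal tag lines (carrier along y, direction y-hat) and
#' `I_v` vertical lines (carrier along x). Tag preparation leaves the
#' longitudinal magnetization fully modulated, so at frame 0 the image is
#' the signed pattern `I_o cos(omega_d X . n_d)` (negative lobes present);
#' longitudinal relaxation then fades the tag term by
#' `A_T(t) = exp(-t / fade_tau)` while the untagged anatomical term
#' recovers as `A_d(t) = 1 - A_T(t)`. The blood pool is rendered untagged
#' (tag washout by through-plane flow).
#'
#' @param geom,motion,t as in [annulus_motion()].
#' @param acq an `acquisition_params`.
#' @param bg background texture matrix (from the internal generator or user
#'   supplied); built automatically if `NULL`.
#' @return a `tagged_pair`: images `I_h`, `I_v`, component images `I_do`,
#'   `I_To`, tag patterns `T_h`, `T_v`, inhomogeneity phase `phi_e`,
#'   metadata, and the material-coordinate maps used.
#' @export
render_tagged_pair <- function(geom, motion, t, acq, bg = NULL) {
  n <- acq$matrix_size
  if (acq$tag_spacing <= 2 * acq$pixel_spacing)
    stopf("tag carrier above Nyquist")
  grid <- coord_grid(n, n, acq$pixel_spacing)
  mat <- material_coordinates(geom, motion, t, grid)
  if (is.null(bg)) bg <- background_texture(n, acq$intensities[["bg"]])
  io <- anatomical_image(mat$masks, acq, bg)
  T_v <- cos(acq$omega_d * mat$X)   # vertical lines: carrier along x
  T_h <- cos(acq$omega_d * mat$Y)   # horizontal lines: carrier along y
  tag_gain <- matrix(1, n, n)
  tag_gain[mat$masks$blood] <- 0
  a_T <- exp(-t / acq$fade_tau)
  I_do <- (1 - a_T) * io
  I_To <- a_T * io * tag_gain
  u <- seq(-1, 1, length.out = n)
  xx <- matrix(rep(u, each = n), n, n); yy <- matrix(rep(u, times = n), n, n)
  cf <- acq$phi_e_coef
  phi_e <- cf[1] + cf[2] * xx + cf[3] * yy + cf[4] * xx^2 +
    cf[5] * xx * yy + cf[6] * yy^2
  structure(list(
    I_h = I_do + I_To * T_h,
    I_v = I_do + I_To * T_v,
    I_do = I_do, I_To = I_To, T_h = T_h, T_v = T_v, phi_e = phi_e,
    pixel_spacing = acq$pixel_spacing, tag_spacing = acq$tag_spacing,
    frame = t, masks = mat$masks,
    material = list(X = mat$X, Y = mat$Y)
  ), class = "tagged_pair")
}

#' Degrade a rendered pair with speckle, phase and noise
#'
#' Applies a smoothed log-normal speckle field of mean one, then white
#' Gaussian noise at the drawn SNR (noise sd = mean absolute clean
#' intensity / SNR). Temporal tag fading is part of image formation and is
#' applied by [render_tagged_pair()] through `acq$fade_tau`. The
#' inhomogeneity phase `phi_e` is retained on the object for
#' complex/rectified output. Deterministic under the caller's RNG state.
#'
#' @param pair a `tagged_pair` from [render_tagged_pair()].
#' @param acq an `acquisition_params`; with `snr = Inf` and
#'   `speckle_sd = 0` the output equals the input bit-exactly.
#' @param rectified if `TRUE`, also attach magnitude/phase companions
#'   (`I_h_mag`, `I_h_phase`, ...) emulating a rectified-magnitude
#'   reconstruction carrying `phi_e`.
#' @return the degraded `tagged_pair`.
#' @export
degrade <- function(pair, acq, rectified = FALSE) {
  if (acq$snr <= 0) stopf("SNR must be > 0")
  n <- nrow(pair$I_h)
  S <- matrix(1, n, n)
  if (acq$speckle_sd > 0) {
    z <- fft_blur(matrix(stats::rnorm(n * n), n, n), acq$speckle_grain)
    z <- z / stats::sd(z) * acq$speckle_sd
    S <- exp(z - acq$speckle_sd^2 / 2)
  }
  out <- pair
  for (d in c("h", "v")) {
    Td <- pair[[paste0("T_", d)]]
    clean <- S * (pair$I_do + pair$I_To * Td)
    if (is.finite(acq$snr)) {
      sdn <- mean(abs(clean)) / acq$snr
      clean <- clean + matrix(stats::rnorm(n * n, sd = sdn), n, n)
    }
    out[[paste0("I_", d)]] <- clean
    if (rectified) {
      cx <- clean * exp(1i * pair$phi_e)
      out[[paste0("I_", d, "_mag")]] <- Mod(cx)
      out[[paste0("I_", d, "_phase")]] <- Arg(cx)
    }
  }
  out
}

#' Jointly tile-shuffle images and strain maps
#'
#' The moving-region bounding box is padded up to a multiple of `tile_px`
#' (kept inside the image), divided into square tiles, and the SAME random
#' tile permutation is applied to every image channel and every strain
#' channel. Used as a training augmentation that decouples strain learning
#' from organ shape; per-channel pixel multisets are preserved.
#'
#' @param channels named list of matrices (image and strain channels).
#' @param mask logical matrix of moving-tissue pixels defining the box.
#' @param tile_px tile side in pixels.
#' @return list of shuffled matrices (same names).
#' @export
tile_shuffle <- function(channels, mask, tile_px) {
  dims <- dim(channels[[1]])
  if (tile_px > min(dims)) stopf("tile larger than image")
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(channels)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  span <- function(a0, a1, nmax) {
    len <- ceiling((a1 - a0 + 1) / tile_px) * tile_px
    a0 <- max(1, min(a0, nmax - len + 1))
    c(a0, a0 + len - 1)
  }
  rr <- span(r0, r1, dims[1]); cc <- span(c0, c1, dims[2])
  ntr <- (rr[2] - rr[1] + 1) / tile_px
  ntc <- (cc[2] - cc[1] + 1) / tile_px
  perm <- sample.int(ntr * ntc)
  tile_of <- function(k) {  # k is 1-based tile index, column-major
    ti <- (k - 1) %% ntr
    tj <- (k - 1) %/% ntr
    list(rows = rr[1] + ti * tile_px + 0:(tile_px - 1),
         cols = cc[1] + tj * tile_px + 0:(tile_px - 1))
  }
  out <- channels
  for (nm in names(channels)) {
    m <- channels[[nm]]
    for (k in seq_along(perm)) {
      src <- tile_of(perm[k]); dst <- tile_of(k)
      out[[nm]][dst$rows, dst$cols] <- channels[[nm]][src$rows, src$cols]
    }
  }
  out
}

#' Simulate one tagging cine with ground truth
#'
#' Draws geometry, motion and acquisition parameters from the profile pools
#' (under the current RNG state), renders and degrades every frame, and
#' attaches the analytic ground-truth principal strain, displacement maps
#' and region masks per frame. Ground-truth strain is exactly zero at frame
#' 0 and outside the moving organs at all frames.
#'
#' @inheritParams sample_geometry
#' @param n_frames,peak_frame see [sample_motion()].
#' @param degrade_frames apply [degrade()] to each frame (default `TRUE`).
#' @param rectified attach rectified magnitude/phase companions.
#' @return a `simulated_cine`: `frames` (list of `tagged_pair`), `truth`
#'   (list of `principal_strain`), `displacement` (list of `ux`/`uy`
#'   matrices), `geom`, `motion`, `acq`.
#' @export
simulate_cine <- function(prof = simulator_profile("full"), n_frames = 7,
                          peak_frame = 4, seed = NULL,
                          degrade_frames = TRUE, rectified = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  geom <- sample_geometry(prof)
  motion <- sample_motion(prof, n_frames = n_frames, peak_frame = peak_frame)
  acq <- sample_acquisition(prof)
  n <- prof$matrix_size
  bg <- background_texture(n, acq$intensities[["bg"]])
  grid <- coord_grid(n, n, prof$pixel_spacing)
  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  disp <- vector("list", n_frames)
  for (t in seq_len(n_frames) - 1) {
    pair <- render_tagged_pair(geom, motion, t, acq, bg = bg)
    truth[[t + 1]] <- analytic_ground_truth(geom, motion, t, grid)
    disp[[t + 1]] <- list(ux = grid$x - pair$material$X,
                          uy = grid$y - pair$material$Y,
                          pixel_spacing = prof$pixel_spacing)
    if (degrade_frames) pair <- degrade(pair, acq, rectified = rectified)
    frames[[t + 1]] <- pair
  }
  structure(list(frames = frames, truth = truth, displacement = disp,
                 geom = geom, motion = motion, acq = acq, prof = prof),
            class = "simulated_cine")
}

#' @export
print.simulated_cine <- function(x, ...) {
  cat(sprintf("<simulated_cine> %d frames, %d x %d px @ %.2f mm, SNR %.1f\n",
              length(x$frames), x$prof$matrix_size, x$prof$matrix_size,
              x$prof$pixel_spacing, x$acq$snr))
  invisible(x)
}

#' Generate a dataset of simulated cines on disk
#'
#' Writes each cine to a dataset container directory as it is generated
#' (cines are not held in memory), assigning cines to splits in the given
#' proportions. For training cines, tile-shuffled copies of every frame are
#' stored alongside the originals. Fully reproducible under `seed`.
#'
#' @param path container directory (created; refuses to overwrite an
#'   existing container unless `overwrite = TRUE`).
#' @param n_cines number of cines.
#' @param split named numeric vector of cine counts, e.g.
#'   `c(train = 300, val = 100, test = 200)`; must sum to `n_cines`.
#' @param prof a [simulator_profile()].
#' @param n_frames,peak_frame per-cine frame layout.
#' @param seed integer seed driving all randomness.
#' @param tile_px tile size for the training-split shuffle.
#' @param overwrite allow writing into an existing container.
#' @return the container handle (see [open_container()]), invisibly.
#' @export
generate_dataset <- function(path, n_cines, split = c(test = n_cines),
                             prof = simulator_profile("full"),
                             n_frames = 7, peak_frame = 4, seed = 1,
                             tile_px = 16, overwrite = FALSE) {
  if (n_cines < 1) stopf("n_cines must be >= 1")
  if (sum(split) != n_cines) stopf("split counts must sum to n_cines")
  con <- create_container(path, prof, seed = seed, overwrite = overwrite)
  assignment <- rep(names(split), times = split)
  set.seed(seed)
  for (k in seq_len(n_cines)) {
    cine <- simulate_cine(prof, n_frames = n_frames, peak_frame = peak_frame)
    sh <- NULL
    if (assignment[k] == "train") {
      sh <- lapply(seq_along(cine$frames), function(i) {
        fr <- cine$frames[[i]]; tr <- cine$truth[[i]]
        mask <- fr$masks$lv | fr$masks$liver
        tile_shuffle(list(I_h = fr$I_h, I_v = fr$I_v,
                          eps_p1 = tr$eps_p1, eps_p2 = tr$eps_p2),
                     mask, tile_px)
      })
    }
    write_cine(con, k, cine, split = assignment[k], shuffled = sh)
  }
  invisible(open_container(path))
}
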