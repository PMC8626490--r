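#' Pooled pixelwise correlation between strain maps
#'
#' Pearson correlation between estimated and reference principal strain
#' maps over masked pixels, pooled across however many frames are supplied,
#' separately for eps_p1 and eps_p2. Also reports the over/under-estimation
#' quadrant counts (K: eps_p1 overestimated, L: eps_p1 underestimated,
#' M: eps_p2 underestimated in magnitude, N: eps_p2 overestimated in
#' magnitude, i.e. more negative than the reference).
#'
#' @param est,ref `principal_strain` objects, or lists of them (pooled).
#' @param mask logical matrix (or list of matrices) selecting evaluation
#'   pixels; defaults to the intersection of the two validity masks.
#' @param keep_scatter number of pixel pairs retained for scatter plotting
#'   (uniformly subsampled; 0 keeps none).
#' @return object of class `strain_comparison`.
#' @export
pixel_correlation <- function(est, ref, mask = NULL, keep_scatter = 5000) {
  if (inherits(est, "principal_strain")) est <- list(est)
  if (inherits(ref, "principal_strain")) ref <- list(ref)
  if (is.matrix(mask) || is.null(mask)) mask <- rep(list(mask), length(est))
  px <- purrr::pmap(list(est, ref, mask), function(e, r, m) {
    if (is.null(m)) m <- e$mask & r$mask else m <- m & e$mask & r$mask
    tibble::tibble(est_p1 = e$eps_p1[m], ref_p1 = r$eps_p1[m],
                   est_p2 = e$eps_p2[m], ref_p2 = r$eps_p2[m])
  })
  px <- dplyr::bind_rows(px)
  if (nrow(px) == 0) stopf("evaluation mask is empty")
  r_of <- function(a, b) {
    if (stats::sd(b) == 0) return(NA_real_)  # undefined R flagged as NA
    stats::cor(a, b)
  }
  cmp <- structure(list(
    n_pixels = nrow(px),
    R = c(eps_p1 = r_of(px$est_p1, px$ref_p1),
          eps_p2 = r_of(px$est_p2, px$ref_p2)),
    quadrants = c(K = sum(px$est_p1 > px$ref_p1),
                  L = sum(px$est_p1 < px$ref_p1),
                  M = sum(px$est_p2 > px$ref_p2),
                  N = sum(px$est_p2 < px$ref_p2)),
    scatter = if (keep_scatter > 0 && nrow(px) > keep_scatter)
      px[sort(sample.int(nrow(px), keep_scatter)), ] else px
  ), class = "strain_comparison")
  cmp
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat(sprintf("<strain_comparison> %d pooled pixels\n", x$n_pixels))
  cat(sprintf("  R(eps_p1) = %.3f, R(eps_p2) = %.3f\n",
              x$R[["eps_p1"]], x$R[["eps_p2"]]))
  invisible(x)
}

#' @rdname pixel_correlation
#' @param x a `strain_comparison`.
#' @param ... unused.
#' @export
tidy.strain_comparison <- function(x, ...) {
  tibble::tibble(channel = c("eps_p1", "eps_p2"),
                 R = unname(x$R),
                 n_pixels = x$n_pixels)
}

#' @rdname pixel_correlation
#' @export
glance.strain_comparison <- function(x, ...) {
  tibble::tibble(R_eps_p1 = x$R[["eps_p1"]], R_eps_p2 = x$R[["eps_p2"]],
                 n_pixels = x$n_pixels,
                 K = x$quadrants[["K"]], L = x$quadrants[["L"]],
                 M = x$quadrants[["M"]], N = x$quadrants[["N"]])
}

#' Absolute-error histogram per 0.05 strain bin
#'
#' Pixels are binned by their REFERENCE strain value into left-closed
#' 0.05-wide bins covering \[0, 0.5\] for eps_p1 and \[-0.5, 0\] for
#' eps_p2 (10 bins per channel); each nonempty bin reports the median and
#' interquartile range of the absolute error `|est - ref|`. Empty bins are
#' absent from the output, not zero.
#'
#' @inheritParams pixel_correlation
#' @return a tibble of class `error_histogram`: `channel`, `bin_lo`,
#'   `bin_hi`, `n`, `median_abs_err`, `iqr_abs_err`.
#' @export
abs_error_histogram <- function(est, ref, mask = NULL) {
  if (inherits(est, "principal_strain")) est <- list(est)
  if (inherits(ref, "principal_strain")) ref <- list(ref)
  if (is.matrix(mask) || is.null(mask)) mask <- rep(list(mask), length(est))
  px <- dplyr::bind_rows(purrr::pmap(list(est, ref, mask), function(e, r, m) {
    if (is.null(m)) m <- e$mask & r$mask else m <- m & e$mask & r$mask
    dplyr::bind_rows(
      tibble::tibble(channel = "eps_p1", est = e$eps_p1[m],
                     ref = r$eps_p1[m]),
      tibble::tibble(channel = "eps_p2", est = e$eps_p2[m],
                     ref = r$eps_p2[m]))
  }))
  edges <- function(ch) if (ch == "eps_p1") seq(0, 0.5, 0.05)
                        else seq(-0.5, 0, 0.05)
  out <- px |>
    dplyr::group_by(.data$channel) |>
    dplyr::group_modify(function(d, key) {
      br <- edges(key$channel)
      bin <- findInterval(d$ref, br, rightmost.closed = FALSE,
                          left.open = FALSE)
      ok <- bin >= 1 & bin <= 10 & d$ref < br[11]
      d <- d[ok, ]; bin <- bin[ok]
      err <- abs(d$est - d$ref)
      tibble::tibble(bin_lo = br[sort(unique(bin))],
                     bin_hi = br[sort(unique(bin)) + 1],
                     n = as.integer(table(bin)),
                     median_abs_err = tapply(err, bin, stats::median),
                     iqr_abs_err = tapply(err, bin, stats::IQR))
    }) |>
    dplyr::ungroup()
  class(out) <- c("error_histogram", class(out))
  out
}

#' Sample square patches for artifact review
#'
#' Draws `n` square patches of at least `patch_mm` per side (side =
#' `ceiling(patch_mm / pixel_spacing)` pixels) with centres uniformly
#' sampled from moving-organ pixels, half from early-systole frames (the
#' first third of frames up to peak contraction) and half from late-systole
#' frames (the last third up to peak). Reproducible under `seed`. The
#' sampler reproduces the blinded-review protocol; the artifact grading
#' itself is a human rating and is not automated.
#'
#' @param cine a `simulated_cine`.
#' @param maps list of `principal_strain` per frame to cut patches from
#'   (defaults to the cine ground truth).
#' @param n number of patches.
#' @param patch_mm physical patch side.
#' @param seed integer seed.
#' @return tibble of class `patch_set`: `patch`, `phase`, `frame`, `row`,
#'   `col`, `side_px`, plus list-columns `eps_p1`, `eps_p2` of patch
#'   matrices.
#' @export
sample_patches <- function(cine, maps = cine$truth, n = 100, patch_mm = 5,
                           seed = 1) {
  set.seed(seed)
  spacing <- cine$prof$pixel_spacing
  side <- ceiling(patch_mm / spacing)
  pk <- cine$motion$peak_frame
  early <- seq_len(max(1, ceiling((pk + 1) / 3)))           # 1-based frames
  late <- seq.int(pk + 1 - max(1, ceiling((pk + 1) / 3)) + 1, pk + 1)
  draw_phase <- function(frames, n_ph, phase) {
    rows <- vector("list", n_ph)
    for (i in seq_len(n_ph)) {
      f <- sample(frames, 1)
      m <- cine$frames[[f]]$masks$lv | cine$frames[[f]]$masks$liver
      half <- side %/% 2
      m[c(seq_len(half), nrow(m) - seq_len(half) + 1), ] <- FALSE
      m[, c(seq_len(half), ncol(m) - seq_len(half) + 1)] <- FALSE
      idx <- which(m, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      ctr <- idx[sample.int(nrow(idx), 1), ]
      rows[[i]] <- tibble::tibble(
        phase = phase, frame = f, row = ctr[1], col = ctr[2],
        side_px = side,
        eps_p1 = list(maps[[f]]$eps_p1[ctr[1] - half + seq_len(side) - 1,
                                       ctr[2] - half + seq_len(side) - 1]),
        eps_p2 = list(maps[[f]]$eps_p2[ctr[1] - half + seq_len(side) - 1,
                                       ctr[2] - half + seq_len(side) - 1]))
    }
    dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(draw_phase(early, n %/% 2, "early_systole"),
                          draw_phase(late, n - n %/% 2, "late_systole"))
  if (nrow(out) < n)
    warning(sprintf("insufficient organ area: %d of %d patches drawn",
                    nrow(out), n))
  out$patch <- seq_len(nrow(out))
  class(out) <- c("patch_set", class(out))
  out[, c("patch", "phase", "frame", "row", "col", "side_px",
          "eps_p1", "eps_p2")]
}
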