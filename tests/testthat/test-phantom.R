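prof_full <- simulator_profile("full")

test_that("parameter pools draw uniformly and deterministically", {
  prof <- prof_full
  g1 <- sample_geometry(prof, seed = 5)
  g2 <- sample_geometry(prof, seed = 5)
  expect_identical(g1, g2)
  expect_gte(g1$lv_inner_radius, prof$pools$lv_inner[1])
  expect_lte(g1$lv_inner_radius, prof$pools$lv_inner[2])
  # degenerate pool min == max
  set.seed(1)
  expect_equal(tagstrain:::draw_pool(c(4, 4)), 4)
  expect_error(tagstrain:::draw_pool(c(5, 2)), "pool")
  # law of large numbers on a [20, 30] pool
  set.seed(2)
  expect_equal(mean(tagstrain:::draw_pool(c(20, 30), 1e4)), 25,
               tolerance = 0.2 / 25)
})

test_that("annulus motion preserves area and inverts exactly", {
  geom <- test_geometry(prof_full)
  motion <- test_motion(contraction = 0.2)
  mm <- annulus_motion(geom, motion, 4, "lv")
  r0i <- geom$lv_inner_radius; r0o <- geom$lv_outer_radius
  expect_equal(mm$r_i, r0i * 0.8)
  expect_equal(mm$r_o, sqrt(r0o^2 - (r0i^2 - mm$r_i^2)))
  expect_equal(pi * (mm$r_o^2 - mm$r_i^2), pi * (r0o^2 - r0i^2))
  # identity at frame 0
  mm0 <- annulus_motion(geom, motion, 0, "lv")
  f0 <- mm0$forward(geom$lv_center[1] + 30, geom$lv_center[2])
  expect_equal(f0$x, geom$lv_center[1] + 30)
  # forward-then-inverse round trip on random interior points
  set.seed(11)
  R <- runif(1e4, r0i, r0o); th <- runif(1e4, 0, 2 * pi)
  X <- geom$lv_center[1] + R * cos(th); Y <- geom$lv_center[2] + R * sin(th)
  fw <- mm$forward(X, Y); iv <- mm$inverse(fw$x, fw$y)
  expect_lt(max(abs(iv$x - X), abs(iv$y - Y)), 1e-9)
})

test_that("motion model rejects unphysical parameters", {
  expect_error(sample_motion(prof_full, n_frames = 1), "frames")
  bad <- test_motion()
  bad$contraction <- c(lv = 1.2, liver = 0.05)
  expect_error(annulus_motion(test_geometry(prof_full), bad, 4, "lv"),
               "collapses")
})

test_that("analytic ground truth matches the closed-form annulus values", {
  geom <- test_geometry(prof_full)
  geom$lv_inner_radius <- 25; geom$lv_outer_radius <- 35
  motion <- test_motion(contraction = 0.2, rotation = 0)
  # at peak, r_i 25 -> 20; evaluate at the spatial radius of material R = 30
  mm <- annulus_motion(geom, motion, 4, "lv")
  rho <- sqrt(30^2 - mm$delta)
  pt <- list(x = matrix(geom$lv_center[1] + rho, 3, 3),
             y = matrix(geom$lv_center[2], 3, 3))
  gt <- analytic_ground_truth(geom, motion, 4, grid = pt)
  expect_equal(gt$eps_p1[2, 2], 0.125, tolerance = 1e-6)
  expect_equal(gt$eps_p2[2, 2], -1 / 6, tolerance = 1e-6)
  # identity motion: all-zero maps
  gt0 <- analytic_ground_truth(geom, motion, 0, prof = prof_full)
  expect_equal(max(abs(gt0$eps_p1)), 0)
  expect_equal(max(abs(gt0$eps_p2)), 0)
  # rigid rotation leaves the maps unchanged
  motion_rot <- test_motion(contraction = 0.2, rotation = 0.2)
  gtr <- analytic_ground_truth(geom, motion_rot, 4, prof = prof_full)
  gtn <- analytic_ground_truth(geom, motion, 4, prof = prof_full)
  expect_equal(gtr$eps_p1, gtn$eps_p1, tolerance = 1e-12)
  expect_equal(gtr$eps_p2, gtn$eps_p2, tolerance = 1e-12)
})

test_that("rendered tags carry the 8 mm carrier and advect with stretch", {
  fx <- low_strain_frame()
  n <- prof_full$matrix_size
  # at t = 0 the column-direction FFT peaks at the carrier frequency
  sp <- Mod(stats::fft(fx$pair0$I_v[n / 2, ]))
  carrier_bin <- which.max(sp[2:(n / 2)])
  expect_equal(carrier_bin, round(n * 1.1 / 8), tolerance = 0.51)
  # period in pixels ~ 8 / 1.1
  expect_equal(n / carrier_bin, 8 / 1.1, tolerance = 0.03)
  # zero tag amplitude leaves the untagged anatomical image
  expect_equal(fx$pair$I_v - fx$pair$I_To * fx$pair$T_v, fx$pair$I_do,
               tolerance = 1e-12)
  # uniform stretch of the tag pattern scales the rendered period
  g <- tagstrain:::coord_grid(64, 256, 1.1)
  lam <- 1.25
  tone <- cos(2 * pi / 8 * g$x / lam)
  sp2 <- Mod(stats::fft(tone[1, ]))
  expect_equal(which.max(sp2[2:128]), round(256 * 1.1 / 8 / lam),
               tolerance = 0.51)
  # carrier above Nyquist errors
  acq_bad <- fx$acq; acq_bad$tag_spacing <- 2
  expect_error(render_tagged_pair(fx$geom, fx$motion, 0, acq_bad),
               "Nyquist")
})

test_that("degradation is identity-exact, calibrated, and fades tags", {
  fx <- low_strain_frame()
  out <- degrade(fx$pair, fx$acq)  # snr = Inf, speckle 0
  expect_identical(out$I_h, fx$pair$I_h)
  # Gaussian noise calibration at SNR 10 on a constant image
  pair_const <- fx$pair
  pair_const$I_do <- matrix(1, 256, 256)
  pair_const$I_To <- matrix(0, 256, 256)
  pair_const$I_h <- pair_const$I_do
  pair_const$I_v <- pair_const$I_do
  acq10 <- fx$acq; acq10$snr <- 10
  set.seed(4)
  noisy <- degrade(pair_const, acq10)
  expect_equal(sd(noisy$I_v - pair_const$I_v), 1 / 10, tolerance = 0.05)
  acq_bad <- fx$acq; acq_bad$snr <- 0
  expect_error(degrade(fx$pair, acq_bad), "SNR")
  # tag contrast vanishes as the fading time constant goes to zero: the
  # carrier peak collapses to the residual anatomy-edge leakage (~1 %)
  acq_fade <- clean_acquisition(prof_full); acq_fade$fade_tau <- 1e-6
  late <- render_tagged_pair(fx$geom, fx$motion, 4, acq_fade)
  expect_lt(max(abs(late$I_To)), 1e-6)
  carrier <- function(img) {
    k <- round(256 * 1.1 / 8)
    max(Mod(stats::fft(img))[1:2, k + 0:2])
  }
  expect_lt(carrier(late$I_v), 0.05 * carrier(fx$pair$I_v))
})

test_that("tile shuffling permutes jointly and preserves histograms", {
  set.seed(6)
  img1 <- matrix(rnorm(64 * 64), 64)
  img2 <- matrix(rnorm(64 * 64), 64)
  mask <- matrix(FALSE, 64, 64); mask[17:48, 13:44] <- TRUE
  ch <- list(a = img1, b = img2, marker = img1)
  sh <- tile_shuffle(ch, mask, 8)
  # per-channel pixel multisets unchanged
  expect_equal(sort(sh$a), sort(img1))
  expect_equal(sort(sh$b), sort(img2))
  # identical channels stay identical => same permutation applied
  expect_identical(sh$a, sh$marker)
  # single tile spanning the box is the identity
  one <- tile_shuffle(list(a = img1), mask, 32)
  expect_identical(one$a, img1)
  expect_error(tile_shuffle(list(a = img1), mask, 128), "tile larger")
})

test_that("simulated cines have coherent ground truth and masks", {
  prof <- simulator_profile("desk")
  cine <- simulate_cine(prof, seed = 12)
  expect_length(cine$frames, 7)
  # frame 0 strain is exactly zero
  expect_equal(max(abs(cine$truth[[1]]$eps_p1)), 0)
  expect_equal(max(abs(cine$truth[[1]]$eps_p2)), 0)
  # masks disjoint
  m <- cine$frames[[5]]$masks
  expect_equal(max(m$lv + m$blood + m$liver + m$background), 1)
  # organ area approximately conserved across frames (pixelization)
  a <- vapply(cine$frames, function(f) sum(f$masks$lv), numeric(1))
  expect_lt(max(abs(a - a[1])) / a[1], 0.06)
  # strain zero outside the moving organs
  bg <- m$background | m$blood
  expect_equal(max(abs(cine$truth[[5]]$eps_p1[bg])), 0)
  # reproducibility
  cine2 <- simulate_cine(prof, seed = 12)
  expect_identical(cine$frames[[3]]$I_h, cine2$frames[[3]]$I_h)
})

test_that("dataset generation writes reproducible split containers", {
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  prof <- simulator_profile("desk")
  con1 <- generate_dataset(d1, 3, split = c(train = 1, test = 2),
                           prof = prof, seed = 9)
  con2 <- generate_dataset(d2, 3, split = c(train = 1, test = 2),
                           prof = prof, seed = 9)
  idx <- container_index(con1)
  expect_equal(idx$split, c("train", "test", "test"))
  c1 <- read_cine(con1, 2); c2 <- read_cine(con2, 2)
  expect_identical(c1$frames[[4]]$I_v, c2$frames[[4]]$I_v)
  expect_identical(c1$truth[[4]]$eps_p2, c2$truth[[4]]$eps_p2)
  # training cines carry tile-shuffled copies; test cines do not
  expect_false(is.null(read_cine(con1, 1)$shuffled))
  expect_null(c1$shuffled)
  # refuses silent overwrite
  expect_error(generate_dataset(d1, 1, prof = prof, seed = 9), "overwrite")
  unlink(c(d1, d2), recursive = TRUE)
})
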