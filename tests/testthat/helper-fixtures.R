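# Shared fixtures, built once per test run and memoised. All fixtures are
# generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# A fixed low-strain phantom layout (no random draws): LV annulus plus a
# liver sector, peak inner-radius contraction 12% -> |eps| <= ~0.14.
test_geometry <- function(prof = simulator_profile("full")) {
  ctr <- (prof$matrix_size - 1) * prof$pixel_spacing / 2
  s <- prof$pixel_spacing * prof$matrix_size / (1.1 * 256)
  structure(list(
    lv_center = c(ctr - 15 * s, ctr),
    lv_inner_radius = 24 * s, lv_outer_radius = 35 * s,
    liver_center = c(ctr + 90 * s, ctr + 10 * s),
    liver_inner_radius = 55 * s, liver_outer_radius = 75 * s,
    theta1 = 3.0, theta2 = 1.2), class = "annulus_geometry")
}

test_motion <- function(contraction = 0.12, rotation = 0.05,
                        n_frames = 7L, peak_frame = 4L) {
  structure(list(contraction = c(lv = contraction, liver = 0.05),
                 rotation = c(lv = rotation, liver = 0),
                 n_frames = as.integer(n_frames),
                 peak_frame = as.integer(peak_frame),
                 incompressible = TRUE), class = "motion_model")
}

# Noise-free acquisition (identity degradation).
clean_acquisition <- function(prof = simulator_profile("full")) {
  set.seed(2)
  acq <- sample_acquisition(prof)
  acq$snr <- Inf; acq$speckle_sd <- 0
  acq
}

# A noise-free low-strain frame pair at peak contraction + its ground truth.
low_strain_frame <- function() fixture("low_strain_frame", function() {
  prof <- simulator_profile("full")
  geom <- test_geometry(prof)
  motion <- test_motion()
  acq <- clean_acquisition(prof)
  set.seed(3)
  list(pair = render_tagged_pair(geom, motion, 4, acq),
       pair0 = render_tagged_pair(geom, motion, 0, acq),
       truth = analytic_ground_truth(geom, motion, 4, prof = prof),
       geom = geom, motion = motion, acq = acq, prof = prof)
})

# Small in-memory desk-profile sample sets for network tests.
desk_samples <- function(n_cines, seed) {
  prof <- simulator_profile("desk")
  set.seed(seed)
  out <- list()
  for (k in seq_len(n_cines)) {
    cine <- simulate_cine(prof)
    for (i in seq_along(cine$frames)) {
      fr <- normalize_pair(cine$frames[[i]])
      tr <- cine$truth[[i]]
      n <- prof$matrix_size
      out[[length(out) + 1]] <- list(
        x = array(c(fr$I_h, fr$I_v), c(n, n, 2)),
        y = array(c(tr$eps_p1, tr$eps_p2), c(n, n, 2)),
        mask = fr$masks$lv | fr$masks$liver)
    }
  }
  out
}

as_principal <- function(y) new_principal_strain_test(y[, , 1], y[, , 2])

new_principal_strain_test <- function(p1, p2) {
  structure(list(eps_p1 = p1, eps_p2 = p2,
                 mask = matrix(TRUE, nrow(p1), ncol(p1))),
            class = "principal_strain")
}
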