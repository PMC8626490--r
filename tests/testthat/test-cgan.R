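test_that("architecture specs reproduce the published layer layout", {
  gs <- generator_spec(256)
  expect_equal(gs$enc, c(64, 128, 256, 512, 512, 512, 512, 512))
  expect_equal(gs$dec, c(512, 512, 512, 512, 256, 128, 64, 32))
  expect_equal(gs$head, c(16, 8, 2))
  expect_equal(gs$n_stages, 8)  # 256 -> 1 x 1 bottleneck
  ds <- discriminator_spec(256)
  expect_equal(ds$channels, c(64, 128, 256, 512, 1))
  expect_equal(ds$strides, c(2, 2, 2, 1, 1))
  expect_error(generator_spec(100), "power of two")
})

test_that("generator and discriminator map the contracted shapes", {
  set.seed(21)
  G <- build_generator(generator_spec(64, 1 / 16))
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  y <- tagstrain:::gen_forward(G, x)
  expect_equal(dim(y), c(64, 64, 2))
  expect_true(all(is.finite(y)))
  expect_true(all(abs(y) < 0.5))  # bounded output activation
  # encoder halves the spatial size at every stage
  a <- x
  for (i in seq_along(G$enc)) {
    a <- tagstrain:::stage_fw(G$enc[[i]], a)
    expect_equal(dim(a)[1], 64 / 2^i)
  }
  # inference determinism
  expect_identical(y, tagstrain:::gen_forward(G, x))
  expect_error(tagstrain:::gen_forward(G, array(0, c(32, 32, 2))), "input")
  D <- build_discriminator(discriminator_spec(64, 1 / 16))
  s <- tagstrain:::disc_forward(D, array(rnorm(64 * 64 * 4), c(64, 64, 4)))
  expect_equal(dim(s), c(8, 8, 1))  # three stride-2 stages: 64 -> 8
  expect_true(all(s > 0 & s < 1))
  expect_error(tagstrain:::disc_forward(D, x), "4-channel")
})

test_that("backpropagation matches finite differences", {
  set.seed(22)
  G <- build_generator(generator_spec(16, 0.05))
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  truth <- array(rnorm(16 * 16 * 2, sd = 0.1), c(16, 16, 2))
  lossf <- function() pixelwise_loss(
    truth, tagstrain:::gen_forward(G, x, train = TRUE), 10)
  pl <- lossf()
  tagstrain:::gen_backward(G, pl$grad)
  stages <- tagstrain:::all_stages(G)
  for (si in c(1, 4, length(stages))) {
    e <- stages[[si]]
    j <- 3
    g_an <- e$dw[j]; h <- 1e-5; w0 <- e$w[j]
    e$w[j] <- w0 + h; l1 <- lossf()$L_G
    e$w[j] <- w0 - h; l2 <- lossf()$L_G
    e$w[j] <- w0
    expect_equal(g_an, (l1 - l2) / (2 * h), tolerance = 1e-4)
  }
})

test_that("loss arithmetic follows the weighted-L1 and adversarial forms", {
  # K = kappa |E_p|_1 + 1 at a (0.18, -0.28) truth pixel with kappa = 10
  truth <- array(0, c(2, 2, 2)); truth[1, 1, ] <- c(0.18, -0.28)
  pred <- truth
  pl <- pixelwise_loss(truth, pred, kappa = 10)
  expect_equal(pl$K[1, 1], 5.6)
  expect_equal(pl$K[2, 2], 1)    # zero-strain pixel
  expect_equal(pl$L_G, 0)        # perfect prediction
  pred[1, 1, 1] <- 0.28
  expect_equal(pixelwise_loss(truth, pred, 10)$L_G, 5.6 * 0.1 / 4)
  expect_error(pixelwise_loss(truth, array(0, c(3, 3, 2)), 10), "mismatch")
  # adversarial terms at uniform D = 0.5
  s <- array(0.5, c(4, 4, 1))
  al <- adversarial_losses(s, s)
  expect_equal(al$L_D, 1 - log(0.5))
  # discriminator optimum: scores at the correct extremes beat uniform 0.5
  good <- adversarial_losses(array(1 - 1e-7, c(4, 4, 1)),
                             array(1e-7, c(4, 4, 1)))
  expect_lt(good$disc_loss, al$disc_loss)
  # score clipping keeps losses finite at exact 0/1
  expect_true(is.finite(adversarial_losses(array(1, c(2, 2, 1)),
                                           array(0, c(2, 2, 1)))$disc_loss))
})

test_that("named schemes instantiate the published weight table", {
  w <- lapply(c("d-only", "g-only", "d-g1", "d-g2"), function(s) {
    sc <- training_scheme(s); c(sc$alpha1, sc$alpha2)
  })
  expect_equal(w, list(c(0, 1), c(1, 0), c(1e4, 1), c(1e3, 1)))
  sc <- training_scheme("g-only")
  expect_equal(sc$kappa, 10)
  expect_equal(sc$lr, 2e-4)
  expect_equal(c(sc$beta1, sc$beta2), c(0.5, 0.9))
})

test_that("scheme weights decouple the loss components", {
  set.seed(23)
  mk <- function() list(x = array(rnorm(16 * 16 * 2), c(16, 16, 2)),
                        y = array(rnorm(16 * 16 * 2, sd = 0.05),
                                  c(16, 16, 2)))
  data <- replicate(3, mk(), simplify = FALSE)
  # G-Only: no discriminator is ever built
  fit_g <- train_strain_mapper(data, training_scheme("g-only"), epochs = 1,
                               width_scale = 0.05, seed = 1)
  expect_null(fit_g$discriminator)
  # D-Only: alpha1 = 0 silences the pixelwise gradient; flagged experimental
  expect_message(
    fit_d <- train_strain_mapper(data, training_scheme("d-only"),
                                 epochs = 1, width_scale = 0.05, seed = 1),
    "experimental")
  expect_s3_class(fit_d$discriminator, "strain_discriminator")
})

test_that("a small generator fits a toy mapping and predicts repeatably", {
  set.seed(24)
  mk <- function() {
    x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
    y <- array(0.2 * tanh(x), c(16, 16, 2))  # smooth pixelwise target
    list(x = x, y = y)
  }
  data <- replicate(8, mk(), simplify = FALSE)
  fit <- train_strain_mapper(data, training_scheme("g-only"), epochs = 8,
                             val_data = data[1:2], width_scale = 0.1,
                             seed = 2)
  expect_lt(tail(fit$losses$train_L_G, 1), fit$losses$train_L_G[1])
  expect_equal(nrow(fit$losses), 8)
  p1 <- predict_strain(fit, data[[1]]$x)
  p2 <- predict_strain(fit, data[[1]]$x)
  expect_identical(p1$eps_p1, p2$eps_p1)
  expect_s3_class(p1, "principal_strain")
  # broom-style accessors
  expect_named(glance(fit), c("scheme", "epochs", "final_train_L_G",
                              "final_val_L_G", "n_parameters"))
  expect_equal(nrow(tidy(fit)), 16)
  # checkpoint round trip preserves predictions
  ck <- file.path(tempdir(), "mapper.rds")
  save_model(fit, ck)
  fit2 <- load_model(ck)
  expect_equal(predict_strain(fit2, data[[1]]$x)$eps_p1, p1$eps_p1)
  meta <- jsonlite::read_json(paste0(ck, ".json"))
  expect_equal(meta$scheme, "g-only")
  unlink(c(ck, paste0(ck, ".json")))
})

test_that("prediction guards against unpreprocessed input", {
  set.seed(25)
  mk <- function() list(x = array(rnorm(16 * 16 * 2), c(16, 16, 2)),
                        y = array(0, c(16, 16, 2)))
  fit <- train_strain_mapper(replicate(2, mk(), simplify = FALSE),
                             training_scheme("g-only"), epochs = 1,
                             width_scale = 0.05, seed = 1)
  big <- structure(list(I_h = matrix(0, 64, 64), I_v = matrix(0, 64, 64),
                        pixel_spacing = 1.1, tag_spacing = 8),
                   class = "tagged_pair")
  expect_error(predict_strain(fit, big), "resample")
})
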