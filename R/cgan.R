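#' Generator architecture specification
#'
#' The generator is a U-net followed by three convolutional head layers.
#' All kernels are 4 x 4. At full scale (256 x 256 input) the encoder has
#' eight stride-2 stages with 64, 128, 256, 512, 512, 512, 512, 512 feature
#' maps (halving the spatial size down to a 1 x 1 bottleneck), the decoder
#' eight up-stages with 512, 512, 512, 512, 256, 128, 64, 32 maps and skip
#' connections concatenating each encoder feature to its mirrored decoder
#' stage, and the head three stride-1 stages with 16, 8 and 2 maps. Every
#' stage except the first and last is followed by per-sample normalization
#' and leaky-ReLU; the output is scaled to (-0.5, 0.5) by `0.5 tanh`,
#' matching the physical principal-strain range. Smaller input sizes drop
#' trailing 512 stages; `width_scale` shrinks the feature maps uniformly
#' for CPU-scale training.
#'
#' @param size input size (power of 2; 256 is the full-scale default).
#' @param width_scale multiplier on feature-map counts (1 = full scale).
#' @return list of class `generator_spec`.
#' @export
generator_spec <- function(size = 256, width_scale = 1) {
  n <- as.integer(round(log2(size)))
  if (2^n != size || n < 4) stopf("size must be a power of two >= 16")
  wschan <- function(ch) pmax(as.integer(round(ch * width_scale)), 2L)
  enc <- wschan(c(64, 128, 256, rep(512, n - 3)))
  dec <- wschan(c(rep(512, n - 4), 256, 128, 64, 32))
  head <- c(max(4L, wschan(16)), max(4L, wschan(8)), 2L)
  structure(list(size = as.integer(size), n_stages = n, in_channels = 2L,
                 enc = enc, dec = dec, head = head,
                 width_scale = width_scale),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' Five 4 x 4 convolution stages with 64, 128, 256, 512 and 1 feature maps;
#' the first three use stride 2 so a 256 x 256 x 4 input (tag pair
#' concatenated with a strain map pair) yields a 32 x 32 patch-score map,
#' squashed to (0, 1) by a sigmoid. Normalization on stages 2-4,
#' leaky-ReLU on all but the last.
#'
#' @inheritParams generator_spec
#' @return list of class `discriminator_spec`.
#' @export
discriminator_spec <- function(size = 256, width_scale = 1) {
  ch <- pmax(as.integer(round(c(64, 128, 256, 512) * width_scale)), 2L)
  structure(list(size = as.integer(size), in_channels = 4L,
                 channels = c(ch, 1L), strides = c(2L, 2L, 2L, 1L, 1L),
                 width_scale = width_scale),
            class = "discriminator_spec")
}

#' Build a generator network
#'
#' Instantiates the U-net + head with fresh parameters (seed the session
#' RNG for reproducible initialization). The 1 x 1 bottleneck stage carries
#' no normalization (a per-sample statistic of a single spatial element is
#' degenerate).
#'
#' @param spec a [generator_spec()].
#' @return object of class `strain_generator`.
#' @export
build_generator <- function(spec = generator_spec()) {
  n <- spec$n_stages
  enc <- vector("list", n)
  cin <- spec$in_channels
  for (i in seq_len(n)) {
    enc[[i]] <- nn_stage("conv", cin, spec$enc[i], stride = 2,
                         norm = i != 1 && i != n)
    cin <- spec$enc[i]
  }
  dec <- vector("list", n)
  for (i in seq_len(n)) {
    cin <- if (i == 1) spec$enc[n] else spec$dec[i - 1] + spec$enc[n - i + 1]
    dec[[i]] <- nn_stage("tconv", cin, spec$dec[i], stride = 2, norm = TRUE)
  }
  head <- list(
    nn_stage("conv", spec$dec[n], spec$head[1], stride = 1, norm = TRUE),
    nn_stage("conv", spec$head[1], spec$head[2], stride = 1, norm = TRUE),
    nn_stage("conv", spec$head[2], spec$head[3], stride = 1, norm = FALSE,
             act = "tanh_half"))
  structure(list(enc = enc, dec = dec, head = head, spec = spec),
            class = "strain_generator")
}

gen_forward <- function(G, x, train = FALSE) {
  if (!all(dim(x) == c(G$spec$size, G$spec$size, 2L)))
    stopf("generator expects %d x %d x 2 input", G$spec$size, G$spec$size)
  n <- G$spec$n_stages
  e <- vector("list", n)
  a <- x
  for (i in seq_len(n)) { a <- stage_fw(G$enc[[i]], a, train); e[[i]] <- a }
  d <- NULL
  for (i in seq_len(n)) {
    inp <- if (i == 1) e[[n]] else concat_ch(d, e[[n - i + 1]])
    d <- stage_fw(G$dec[[i]], inp, train)
  }
  for (h in G$head) d <- stage_fw(h, d, train)
  d
}

gen_backward <- function(G, dy) {
  n <- G$spec$n_stages
  g <- dy
  for (h in rev(G$head)) g <- stage_bw(h, g)
  grad_e <- vector("list", n)
  add_grad <- function(a, b) if (is.null(a)) b else a + b
  for (i in rev(seq_len(n))) {
    gin <- stage_bw(G$dec[[i]], g)
    if (i == 1) {
      grad_e[[n]] <- add_grad(grad_e[[n]], gin)
    } else {
      cd <- G$spec$dec[i - 1]
      g <- gin[, , seq_len(cd), drop = FALSE]
      grad_e[[n - i + 1]] <- add_grad(
        grad_e[[n - i + 1]],
        gin[, , cd + seq_len(dim(gin)[3] - cd), drop = FALSE])
    }
  }
  h <- grad_e[[n]]
  for (j in rev(seq_len(n))) {
    h <- stage_bw(G$enc[[j]], h)
    if (j > 1) h <- h + grad_e[[j - 1]]
  }
  invisible(h)
}

#' Build a discriminator network
#'
#' @param spec a [discriminator_spec()].
#' @return object of class `strain_discriminator`.
#' @export
build_discriminator <- function(spec = discriminator_spec()) {
  ch <- spec$channels; st <- spec$strides
  stages <- vector("list", 5)
  cin <- spec$in_channels
  for (i in 1:5) {
    stages[[i]] <- nn_stage("conv", cin, ch[i], stride = st[i],
                            norm = i %in% 2:4,
                            act = if (i == 5) "sigmoid" else "lrelu")
    cin <- ch[i]
  }
  structure(list(stages = stages, spec = spec),
            class = "strain_discriminator")
}

disc_forward <- function(D, x, train = FALSE) {
  if (dim(x)[3] != 4L) stopf("discriminator expects a 4-channel input")
  a <- x
  for (s in D$stages) a <- stage_fw(s, a, train)
  a
}

disc_backward <- function(D, dy) {
  g <- dy
  for (s in rev(D$stages)) g <- stage_bw(s, g)
  g
}

clear_grads <- function(stages) {
  for (e in stages) { e$dw <- NULL; e$db <- NULL
                      e$dgamma <- NULL; e$dbeta <- NULL }
  invisible(NULL)
}

all_stages <- function(net) {
  if (inherits(net, "strain_generator")) c(net$enc, net$dec, net$head)
  else net$stages
}

n_parameters <- function(net) {
  sum(vapply(all_stages(net), function(e)
    length(e$w) + length(e$b) +
      if (e$norm) length(e$gamma) + length(e$beta) else 0L, numeric(1)))
}

#' Strain-weighted pixelwise generator loss
#'
#' `L_G = mean_pixels( K * (|d_p1| + |d_p2|) )` with the per-pixel weight
#' `K = kappa * (|eps_p1| + |eps_p2|) + 1` computed from the ground-truth
#' maps. The weight counteracts the rarity of high-strain pixels; kappa
#' defaults to 10.
#'
#' @param truth,pred H x W x 2 arrays (ground-truth and predicted principal
#'   strain maps).
#' @param kappa weighting constant (>= 0).
#' @return list with `L_G`, the `K` weight matrix, and `grad`, the loss
#'   gradient with respect to `pred`.
#' @export
pixelwise_loss <- function(truth, pred, kappa = 10) {
  if (!all(dim(truth) == dim(pred))) stopf("shape mismatch")
  if (kappa < 0) stopf("kappa must be >= 0")
  K <- kappa * (abs(truth[, , 1]) + abs(truth[, , 2])) + 1
  d <- pred - truth
  npix <- dim(truth)[1] * dim(truth)[2]
  L_G <- sum(K * (abs(d[, , 1]) + abs(d[, , 2]))) / npix
  grad <- array(0, dim(truth))
  grad[, , 1] <- K * sign(d[, , 1]) / npix
  grad[, , 2] <- K * sign(d[, , 2]) / npix
  list(L_G = L_G, K = K, grad = grad)
}

#' Adversarial loss terms from discriminator patch scores
#'
#' The discriminator maximizes `log D(real) + 1 - log D(fake)` (implemented
#' as its negation for minimization) and the generator's adversarial term
#' is `L_D = 1 - log D(fake)`, both averaged over the patch-score map.
#' Scores are clipped to `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param d_real,d_fake patch-score arrays in (0, 1); `d_real` may be
#'   `NULL` when only the generator term is needed.
#' @return list with `disc_loss` (minimization form), `L_D`, and gradients
#'   `grad_real`, `grad_fake_disc`, `grad_fake_gen` with respect to the
#'   scores.
#' @export
adversarial_losses <- function(d_real, d_fake) {
  eps <- 1e-7
  sf <- pmin(pmax(d_fake, eps), 1 - eps)
  nf <- length(sf)
  L_D <- 1 - mean(log(sf))
  grad_fake_gen <- array(-1 / (sf * nf), dim(d_fake))
  out <- list(L_D = L_D, grad_fake_gen = grad_fake_gen,
              grad_fake_disc = array(1 / (sf * nf), dim(d_fake)))
  if (!is.null(d_real)) {
    sr <- pmin(pmax(d_real, eps), 1 - eps)
    out$disc_loss <- -(mean(log(sr)) + 1 - mean(log(sf)))
    out$grad_real <- array(-1 / (sr * length(sr)), dim(d_real))
  }
  out
}

#' Named training schemes
#'
#' The four loss-weighting schemes: the generator objective is
#' `min alpha1 * L_G + alpha2 * L_D` with `(alpha1, alpha2)` equal to
#' (0, 1) for D-Only, (1, 0) for G-Only, (1e4, 1) for D-G1 and (1e3, 1)
#' for D-G2. All schemes use kappa = 10 and Adam with learning rate 2e-4
#' and momenta (0.5, 0.9).
#'
#' @param name one of `"d-only"`, `"g-only"`, `"d-g1"`, `"d-g2"`.
#' @return list of class `training_scheme`.
#' @export
training_scheme <- function(name = c("g-only", "d-g1", "d-g2", "d-only")) {
  name <- match.arg(name)
  w <- switch(name,
              "d-only" = c(0, 1), "g-only" = c(1, 0),
              "d-g1" = c(1e4, 1), "d-g2" = c(1e3, 1))
  structure(list(name = name, alpha1 = w[1], alpha2 = w[2], kappa = 10,
                 lr = 2e-4, beta1 = 0.5, beta2 = 0.9),
            class = "training_scheme")
}

#' Train the pixel-to-pixel strain mapper
#'
#' Alternating per-sample updates: when the scheme has a nonzero
#' adversarial weight, the discriminator is stepped on a (real, fake) score
#' pair, then the generator is stepped on
#' `alpha1 * grad L_G + alpha2 * grad L_D`; with `alpha2 = 0` (G-Only) the
#' discriminator is never built or updated. Per-epoch training and
#' validation `L_G` are recorded. Deterministic under `seed`. Training
#' aborts with diagnostics if a loss becomes non-finite.
#'
#' @param train_data,val_data lists of samples, each a list with `x`
#'   (H x W x 2 normalized tag pair) and `y` (H x W x 2 ground-truth
#'   principal strain).
#' @param scheme a [training_scheme()].
#' @param epochs training epochs.
#' @param width_scale feature-map multiplier passed to the specs.
#' @param seed integer seed for initialization and sample order.
#' @param verbose print per-epoch losses.
#' @return object of class `strain_mapper`: generator, optional
#'   discriminator, scheme, and a tibble of loss curves.
#' @export
train_strain_mapper <- function(train_data, scheme = training_scheme("g-only"),
                                epochs = 10, val_data = NULL,
                                width_scale = 1, seed = 1, verbose = FALSE) {
  set.seed(seed)
  size <- dim(train_data[[1]]$x)[1]
  G <- build_generator(generator_spec(size, width_scale))
  D <- NULL
  if (scheme$alpha2 > 0) D <- build_discriminator(
    discriminator_spec(size, width_scale))
  if (scheme$name == "d-only")
    message("d-only scheme is experimental: the pixelwise loss is excluded ",
            "from generator updates and training may not converge")
  losses <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(train_data))
    lg_sum <- 0
    for (s in ord) {
      x <- train_data[[s]]$x; y <- train_data[[s]]$y
      yhat <- gen_forward(G, x, train = TRUE)
      pl <- pixelwise_loss(y, yhat, scheme$kappa)
      if (!is.finite(pl$L_G))
        stopf("training diverged: non-finite L_G at epoch %d", ep)
      lg_sum <- lg_sum + pl$L_G
      dy <- scheme$alpha1 * pl$grad
      if (!is.null(D)) {
        sr <- disc_forward(D, concat_ch(x, y), train = TRUE)
        sfd <- disc_forward(D, concat_ch(x, yhat), train = TRUE)
        # NB: the second forward overwrote cached activations, so step the
        # discriminator in two half-updates: fake branch then real branch.
        al <- adversarial_losses(sr, sfd)
        disc_backward(D, al$grad_fake_disc)
        sr <- disc_forward(D, concat_ch(x, y), train = TRUE)
        disc_backward(D, al$grad_real)
        for (e in D$stages) adam_step(e, scheme$lr, scheme$beta1, scheme$beta2)
        # generator adversarial gradient through a fresh fake pass
        sfg <- disc_forward(D, concat_ch(x, yhat), train = TRUE)
        alg <- adversarial_losses(NULL, sfg)
        dinp <- disc_backward(D, alg$grad_fake_gen)
        clear_grads(D$stages)
        dy <- dy + scheme$alpha2 * dinp[, , 3:4, drop = FALSE]
      }
      gen_backward(G, dy)
      for (e in all_stages(G)) adam_step(e, scheme$lr, scheme$beta1,
                                         scheme$beta2)
    }
    lg_val <- NA_real_
    if (!is.null(val_data)) {
      lg_val <- mean(vapply(val_data, function(sm)
        pixelwise_loss(sm$y, gen_forward(G, sm$x), scheme$kappa)$L_G,
        numeric(1)))
    }
    losses[[ep]] <- tibble::tibble(epoch = ep,
                                   train_L_G = lg_sum / length(train_data),
                                   val_L_G = lg_val)
    if (verbose)
      message(sprintf("epoch %d: train L_G %.4f val L_G %.4f", ep,
                      lg_sum / length(train_data), lg_val))
  }
  structure(list(generator = G, discriminator = D, scheme = scheme,
                 losses = dplyr::bind_rows(losses), size = size,
                 width_scale = width_scale, seed = seed),
            class = "strain_mapper")
}

#' Predict principal strain maps from a tagged frame pair
#'
#' Single deterministic forward pass; channel 1 is eps_p1, channel 2
#' eps_p2 (bounded in (-0.5, 0.5) by the output activation). The pair is
#' intensity-normalized to \[-1, 1\] before the pass.
#'
#' @param model a fitted `strain_mapper`.
#' @param pair a `tagged_pair` on the model's grid, or an H x W x 2 array.
#' @return a `principal_strain` (no principal directions: the network maps
#'   magnitudes only).
#' @export
predict_strain <- function(model, pair) {
  if (inherits(pair, "tagged_pair")) {
    if (nrow(pair$I_h) != model$size)
      stopf(paste("input is %d px but the model expects %d px;",
                  "resample with resample_pair() first"),
            nrow(pair$I_h), model$size)
    pair <- normalize_pair(pair)
    x <- array(c(pair$I_h, pair$I_v), c(model$size, model$size, 2))
  } else {
    x <- pair
  }
  y <- gen_forward(model$generator, x, train = FALSE)
  new_principal_strain(y[, , 1], y[, , 2])
}

#' @export
print.strain_mapper <- function(x, ...) {
  cat(sprintf("<strain_mapper> scheme %s, %d x %d input, %s parameters\n",
              x$scheme$name, x$size, x$size,
              format(n_parameters(x$generator), big.mark = ",")))
  if (nrow(x$losses))
    cat(sprintf("  final train L_G %.4f, val L_G %.4f over %d epochs\n",
                utils::tail(x$losses$train_L_G, 1),
                utils::tail(x$losses$val_L_G, 1), nrow(x$losses)))
  invisible(x)
}

#' @rdname predict_strain
#' @param object a `strain_mapper`.
#' @param ... unused.
#' @export
tidy.strain_mapper <- function(object, ...) {
  tidyr::pivot_longer(object$losses, -"epoch", names_to = "split",
                      values_to = "L_G",
                      names_pattern = "(train|val)_L_G")
}

#' @rdname predict_strain
#' @export
glance.strain_mapper <- function(object, ...) {
  tibble::tibble(scheme = object$scheme$name,
                 epochs = nrow(object$losses),
                 final_train_L_G = utils::tail(object$losses$train_L_G, 1),
                 final_val_L_G = utils::tail(object$losses$val_L_G, 1),
                 n_parameters = n_parameters(object$generator))
}

#' Save / load a fitted strain mapper
#'
#' Network stages are converted to plain lists with a JSON-able metadata
#' header (scheme, seed, size) so checkpoints survive serialization.
#'
#' @param model a `strain_mapper`.
#' @param path file path (.rds).
#' @export
save_model <- function(model, path) {
  obj <- model
  obj$generator$enc <- stages_to_list(model$generator$enc)
  obj$generator$dec <- stages_to_list(model$generator$dec)
  obj$generator$head <- stages_to_list(model$generator$head)
  if (!is.null(model$discriminator))
    obj$discriminator$stages <- stages_to_list(model$discriminator$stages)
  saveRDS(obj, path)
  jsonlite::write_json(list(scheme = model$scheme$name, seed = model$seed,
                            size = model$size,
                            width_scale = model$width_scale),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  obj$generator$enc <- stages_from_list(obj$generator$enc)
  obj$generator$dec <- stages_from_list(obj$generator$dec)
  obj$generator$head <- stages_from_list(obj$generator$head)
  if (!is.null(obj$discriminator))
    obj$discriminator$stages <- stages_from_list(obj$discriminator$stages)
  obj
}
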