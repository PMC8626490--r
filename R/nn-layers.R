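# Compact single-sample CNN engine backing the strain-mapper networks:
# convolution / transposed-convolution stages with per-sample normalization
# and leaky-ReLU, explicit backward passes, and Adam updates. Stages are
# environments so parameters and Adam state update in place during training.

nn_stage <- function(type = c("conv", "tconv"), cin, cout, k = 4, stride = 2,
                     norm = TRUE, act = c("lrelu", "none", "tanh_half",
                                          "sigmoid")) {
  type <- match.arg(type); act <- match.arg(act)
  e <- new.env(parent = emptyenv())
  e$type <- type; e$cin <- cin; e$cout <- cout; e$k <- k
  e$stride <- stride; e$act <- act; e$norm <- norm
  if (type == "conv") {
    e$w <- matrix(stats::rnorm(cout * k * k * cin, sd = 0.02), cout)
  } else {
    e$w <- matrix(stats::rnorm(cin * k * k * cout, sd = 0.02), cin)
  }
  e$b <- numeric(cout)
  if (norm) { e$gamma <- rep(1, cout); e$beta <- numeric(cout) }
  e$adam <- list()
  e
}

lrelu_fw <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
lrelu_bw <- function(x, dy, slope = 0.2) ifelse(x > 0, dy, slope * dy)

stage_fw <- function(e, x, train = TRUE) {
  h <- dim(x)[1]; w <- dim(x)[2]
  if (dim(x)[3] != e$cin) stopf("stage expects %d channels, got %d",
                                e$cin, dim(x)[3])
  if (e$type == "conv") {
    oh <- if (e$stride == 2) h %/% 2 else h
    ow <- if (e$stride == 2) w %/% 2 else w
    z <- conv2d_fw(x, e$w, e$b, e$k, e$stride, 1L, 1L, oh, ow)
  } else {
    z <- tconv2d_fw(x, e$w, e$b, e$k, e$stride, 1L, 1L, 2L * h, 2L * w)
  }
  if (train) { e$x <- x; e$z <- z }
  a <- z
  if (e$norm) {
    nf <- inorm_fw(a, e$gamma, e$beta, 1e-5)
    if (train) { e$xhat <- nf$xhat; e$istd <- nf$istd }
    a <- nf$y
  }
  if (train) e$pre_act <- a
  switch(e$act,
         lrelu = lrelu_fw(a),
         tanh_half = 0.5 * tanh(a),
         sigmoid = 1 / (1 + exp(-a)),
         none = a)
}

stage_bw <- function(e, dy) {
  da <- switch(e$act,
               lrelu = lrelu_bw(e$pre_act, dy),
               tanh_half = dy * 0.5 * (1 - tanh(e$pre_act)^2),
               sigmoid = { s <- 1 / (1 + exp(-e$pre_act)); dy * s * (1 - s) },
               none = dy)
  if (e$norm) {
    nb <- inorm_bw(da, e$xhat, e$istd, e$gamma)
    e$dgamma <- (e$dgamma %||% 0) + nb$dgamma
    e$dbeta <- (e$dbeta %||% 0) + nb$dbeta
    da <- nb$dx
  }
  if (e$type == "conv") {
    bk <- conv2d_bw(e$x, e$w, da, e$k, e$stride, 1L, 1L)
  } else {
    bk <- tconv2d_bw(e$x, e$w, da, e$k, e$stride, 1L, 1L)
  }
  e$dw <- (e$dw %||% 0) + bk$dw
  e$db <- (e$db %||% 0) + bk$db
  bk$dx
}

adam_step <- function(e, lr, beta1, beta2, eps = 1e-8) {
  upd <- function(name, grad_name) {
    g <- e[[grad_name]]
    if (is.null(g)) return()
    st <- e$adam[[name]] %||% list(m = 0 * g, v = 0 * g, t = 0)
    st$t <- st$t + 1
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mh <- st$m / (1 - beta1^st$t)
    vh <- st$v / (1 - beta2^st$t)
    e[[name]] <- e[[name]] - lr * mh / (sqrt(vh) + eps)
    e$adam[[name]] <- st
    e[[grad_name]] <- NULL
  }
  upd("w", "dw"); upd("b", "db")
  if (e$norm) { upd("gamma", "dgamma"); upd("beta", "dbeta") }
  invisible(e)
}

concat_ch <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

# Serialize a network (list of stage environments) to plain lists and back,
# so fitted models survive saveRDS round trips.
stages_to_list <- function(x) {
  if (is.environment(x))
    return(mget(intersect(c("type", "cin", "cout", "k", "stride", "act",
                            "norm", "w", "b", "gamma", "beta"),
                          ls(x)), envir = x))
  if (is.list(x)) return(lapply(x, stages_to_list))
  x
}

stages_from_list <- function(x) {
  if (is.list(x) && !is.null(x$type) && x$type %in% c("conv", "tconv")) {
    e <- new.env(parent = emptyenv())
    for (nm in names(x)) e[[nm]] <- x[[nm]]
    e$adam <- list()
    return(e)
  }
  if (is.list(x)) return(lapply(x, stages_from_list))
  x
}
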