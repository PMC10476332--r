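#' GAN training configuration
#'
#' Defaults follow the published training recipe: reconstruction weight
#' lambda = 1000 on the mean absolute error, 500 epochs, batch size 64,
#' Adam with learning rate 0.01. The learning rate is exposed because
#' 0.01 is aggressive for adversarial training; if training diverges on
#' user data, 1e-3 is the documented fallback.
#'
#' @param lambda Reconstruction (L1) weight (>= 0).
#' @param epochs Training epochs (>= 1).
#' @param batch Batch size (>= 1).
#' @param lr Adam learning rate.
#' @param seed RNG seed governing initialization, shuffling and updates.
#' @return A `gan_config` list.
#' @export
gan_config <- function(lambda = 1000, epochs = 500, batch = 64,
                       lr = 0.01, seed = NULL) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (epochs < 1 || batch < 1) stop("epochs and batch must be >= 1",
                                    call. = FALSE)
  structure(list(lambda = lambda, epochs = as.integer(epochs),
                 batch = as.integer(batch), lr = lr, seed = seed),
            class = "gan_config")
}

#' Build the pattern generator network
#'
#' Encoder-decoder over the 200-row phase axis: three stride-2
#' convolutions (16, 32, 64 filters, kernel 2, LeakyReLU) compress the
#' sequence 200 -> 100 -> 50 -> 25, three transposed convolutions (32,
#' 16, 4 filters) expand it back to 200, and a final width-200 dense
#' layer with sigmoid, applied along the phase axis and shared across
#' channels, maps every value into (0, 1). The input length must be
#' divisible by 8 (three stride-2 stages), which is why patterns enter
#' on the 200-row half-open grid.
#'
#' @param seed RNG seed for weight initialization.
#' @return An `nn_model`.
#' @export
build_generator <- function(seed = NULL) {
  with_seed(seed, nn_sequential(
    nn_conv_k2s2(4, 16, "lrelu"),
    nn_conv_k2s2(16, 32, "lrelu"),
    nn_conv_k2s2(32, 64, "lrelu"),
    nn_tconv_k2s2(64, 32, "lrelu"),
    nn_tconv_k2s2(32, 16, "lrelu"),
    nn_tconv_k2s2(16, 4, "lrelu"),
    nn_dense_time(200, 200, "sigmoid")
  ))
}

#' Build the conditional discriminator network
#'
#' Scores condition/candidate pairs: the interpolated sketch and the
#' candidate pattern are concatenated along the channel axis (8
#' channels), passed through three stride-2 convolutions (16, 32, 64
#' filters, LeakyReLU), an 80-unit LSTM with LeakyReLU state activation,
#' and a single linear output unit producing a realness logit per batch
#' item (sigmoid applied inside the loss).
#'
#' @param seed RNG seed for weight initialization.
#' @return An `nn_model`.
#' @export
build_discriminator <- function(seed = NULL) {
  with_seed(seed, nn_sequential(
    nn_conv_k2s2(8, 16, "lrelu"),
    nn_conv_k2s2(16, 32, "lrelu"),
    nn_conv_k2s2(32, 64, "lrelu"),
    nn_lstm(64, 80, "lrelu"),
    nn_dense(80, 1, "linear")
  ))
}

# binary cross-entropy from logits: mean(softplus(z) - t*z)
bce_logits <- function(z, target) {
  mean(ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z))) - target * z)
}
bce_logits_grad <- function(z, target) {
  (1 / (1 + exp(-z)) - target) / length(z)
}

#' GAN objective
#'
#' The conditional-GAN objective with an L1 reconstruction term: the
#' generator minimizes `BCE(score_fake, 1) + lambda * MAE(real, fake)`,
#' the discriminator minimizes `BCE(score_real, 1) + BCE(score_fake, 0)`.
#'
#' @param real,fake Arrays/matrices of identical shape (target pattern
#'   and generator output).
#' @param score_real,score_fake Discriminator logits.
#' @param cfg A [gan_config()] (supplies lambda).
#' @return List with `generator`, `discriminator`, and the generator
#'   decomposition `g_adversarial`, `g_reconstruction`.
#' @export
gan_loss <- function(real, fake, score_real, score_fake, cfg = gan_config()) {
  if (!all(dim(as.array(real)) == dim(as.array(fake)))) {
    stop("real and fake must have identical shape", call. = FALSE)
  }
  g_adv <- bce_logits(score_fake, 1)
  g_rec <- cfg$lambda * mean(abs(real - fake))
  d_loss <- bce_logits(score_real, 1) + bce_logits(score_fake, 0)
  list(generator = g_adv + g_rec, discriminator = d_loss,
       g_adversarial = g_adv, g_reconstruction = g_rec)
}

corpus_arrays <- function(corpus) {
  n <- length(corpus)
  X <- array(0, c(n, 200, 4)); Y <- array(0, c(n, 200, 4))
  for (i in seq_len(n)) {
    X[i, , ] <- unclass(interpolate_input(corpus[[i]]$sketch))
    Y[i, , ] <- unclass(corpus[[i]]$target)
  }
  list(X = X, Y = Y)
}

#' Train the conditional GAN
#'
#' Alternates one discriminator and one generator update per minibatch.
#' The discriminator sees (sketch, target) pairs as real and (sketch,
#' generated) pairs as fake; the generator is driven by the adversarial
#' term plus the lambda-weighted mean absolute reconstruction error.
#' Batch order, initialization and updates are deterministic given the
#' config seed.
#'
#' @param corpus A `gait_corpus` of normalized sketch/target pairs.
#' @param cfg A [gan_config()].
#' @return A `trained_gan`: generator, discriminator and a `train_state`
#'   with per-epoch loss traces (`g_loss`, `g_adv`, `g_rec`, `d_loss`).
#' @export
train_gan <- function(corpus, cfg = gan_config()) {
  if (length(corpus) == 0L) stop("training corpus is empty", call. = FALSE)
  with_seed(cfg$seed, {
    G <- build_generator()
    D <- build_discriminator()
    opt_g <- optimizer("adam", lr = cfg$lr)
    opt_d <- optimizer("adam", lr = cfg$lr)
    da <- corpus_arrays(corpus)
    n <- dim(da$X)[1]
    tr <- list(g_loss = numeric(cfg$epochs), g_adv = numeric(cfg$epochs),
               g_rec = numeric(cfg$epochs), d_loss = numeric(cfg$epochs))
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      batches <- split(idx, ceiling(seq_along(idx) / cfg$batch))
      acc <- c(g = 0, ga = 0, gr = 0, d = 0)
      for (b in batches) {
        Xb <- da$X[b, , , drop = FALSE]
        Yb <- da$Y[b, , , drop = FALSE]
        nb <- length(b)

        # --- discriminator update
        fake <- nn_forward(G, Xb)$out
        r_real <- nn_forward(D, abind3(Xb, Yb))
        r_fake <- nn_forward(D, abind3(Xb, fake))
        dz_real <- bce_logits_grad(r_real$out, 1)
        dz_fake <- bce_logits_grad(r_fake$out, 0)
        g_real <- nn_backward(D, r_real$caches, dz_real)$grads
        g_fake <- nn_backward(D, r_fake$caches, dz_fake)$grads
        sd <- opt_step(opt_d, D, add_grads(g_real, g_fake))
        opt_d <- sd$opt; D <- sd$model

        # --- generator update (discriminator frozen)
        rg <- nn_forward(G, Xb)
        fake <- rg$out
        rd <- nn_forward(D, abind3(Xb, fake))
        losses <- gan_loss(Yb, fake, r_real$out, rd$out, cfg)
        dz <- bce_logits_grad(rd$out, 1)
        d_in <- nn_backward(D, rd$caches, dz)$dX
        d_fake_adv <- d_in[, , 5:8, drop = FALSE]
        d_fake_rec <- cfg$lambda * sign(fake - Yb) / length(Yb)
        gg <- nn_backward(G, rg$caches, d_fake_adv + d_fake_rec)$grads
        sg <- opt_step(opt_g, G, gg)
        opt_g <- sg$opt; G <- sg$model

        if (!is.finite(losses$generator) || !is.finite(losses$discriminator)) {
          stop(sprintf(paste0("non-finite GAN loss at epoch %d ",
                              "(g = %g, d = %g); try a lower learning rate"),
                       ep, losses$generator, losses$discriminator),
               call. = FALSE)
        }
        w <- nb / n
        acc <- acc + w * c(losses$generator, losses$g_adversarial,
                           losses$g_reconstruction, losses$discriminator)
      }
      tr$g_loss[ep] <- acc[["g"]]; tr$g_adv[ep] <- acc[["ga"]]
      tr$g_rec[ep] <- acc[["gr"]]; tr$d_loss[ep] <- acc[["d"]]
    }
    structure(list(generator = G, discriminator = D, config = cfg,
                   train_state = list(epochs = cfg$epochs, traces = tr)),
              class = "trained_gan")
  })
}

abind3 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3] + dim(b)[3]))
  out[, , seq_len(d[3])] <- a
  out[, , d[3] + seq_len(dim(b)[3])] <- b
  out
}

add_grads <- function(g1, g2) {
  lapply(seq_along(g1), function(i) {
    out <- g1[[i]]
    for (nm in names(out)) out[[nm]] <- out[[nm]] + g2[[i]][[nm]]
    out
  })
}

#' @export
print.trained_gan <- function(x, ...) {
  tr <- x$train_state$traces
  cat(sprintf(paste0("<trained_gan> %d epochs, %d generator params; final ",
                     "g_loss %.4f (adv %.4f + rec %.4f), d_loss %.4f\n"),
              x$train_state$epochs, nn_n_params(x$generator),
              tr$g_loss[length(tr$g_loss)], tr$g_adv[length(tr$g_adv)],
              tr$g_rec[length(tr$g_rec)], tr$d_loss[length(tr$d_loss)]))
  invisible(x)
}

#' Generate a gait pattern from a sketch
#'
#' Interpolates the normalized 11-node sketch onto the 200-row grid and
#' forwards it through the trained generator. The generator takes no
#' noise input, so generation is deterministic: the same sketch always
#' yields the same pattern.
#'
#' @param sketch A normalized `discretized_pattern`.
#' @param gan A `trained_gan` (or an `nn_model` generator).
#' @return A normalized 200-row `gait_pattern` with values in (0, 1).
#' @export
generate <- function(sketch, gan) {
  stopifnot(inherits(sketch, "discretized_pattern"))
  G <- if (inherits(gan, "trained_gan")) gan$generator
       else if (inherits(gan, "nn_model")) gan
       else stop("gan must be a trained_gan (see train_gan())",
                 call. = FALSE)
  X <- array(unclass(interpolate_input(sketch)), c(1, 200, 4))
  out <- nn_forward(G, X)$out
  gait_pattern(matrix(out, 200, 4), units = "normalized")
}
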