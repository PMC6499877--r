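#' Training configuration for the denoising autoencoder
#'
#' Defaults follow the schedule used for this analysis in the field:
#' Adam with learning rate `1e-5`, batches of 100 corrupted samples,
#' 2000 optimizer steps, input corruption with zero-mean Gaussian noise
#' of SD 12 (in z-units — deliberately much larger than the unit-SD
#' patterns, so the network must learn pattern-shaped attractors rather
#' than copy its input), and a hidden layer of `floor(0.1 * v)` units.
#' The hidden activation is a rectifier by default; the logistic
#' alternative is available for comparison.  Weights start at small
#' Gaussian values (`init_sd`); the small scale matters because the
#' corrupted inputs are large, and a large initial weight scale makes
#' the early loss explode under this fixed schedule.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Corrupted samples per optimizer step (the 8 training
#'   items are resampled with replacement and freshly corrupted).
#' @param iterations Optimizer steps.
#' @param corruption_sd Input corruption SD, z-units.
#' @param activation `"relu"` or `"logistic"` hidden nonlinearity.
#' @param hidden_frac Hidden size as a fraction of the voxel count.
#' @param init_sd SD of the Gaussian weight initialisation.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabiliser.
#' @return An `ae_config` list.
#' @export
ae_config <- function(learning_rate = 1e-5, batch_size = 100, iterations = 2000,
                      corruption_sd = 12, activation = c("relu", "logistic"),
                      hidden_frac = 0.1, init_sd = 0.01,
                      beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  activation <- match.arg(activation)
  stopifnot(learning_rate > 0, batch_size >= 1, iterations >= 1,
            corruption_sd >= 0, hidden_frac > 0, init_sd > 0)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations), corruption_sd = corruption_sd,
                 activation = activation, hidden_frac = hidden_frac,
                 init_sd = init_sd, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon),
            class = "ae_config")
}

#' Corrupt a pattern with additive Gaussian noise
#'
#' @param y A voxel pattern (vector) or `v x n` matrix of patterns.
#' @param sd Corruption SD (z-units).
#' @param seed Optional integer seed for a reproducible draw.
#' @return `y` plus i.i.d. `N(0, sd^2)` noise, same shape.
#' @export
corrupt <- function(y, sd = 12, seed = NULL) {
  stopifnot(sd >= 0)
  if (sd == 0) return(y)
  noise <- with_seed(seed, stats::rnorm(length(y), sd = sd))
  if (is.matrix(y)) y + matrix(noise, nrow(y), ncol(y)) else y + noise
}

ae_activation <- function(x, kind) {
  switch(kind, relu = pmax(x, 0), logistic = 1 / (1 + exp(-x)))
}

ae_activation_grad <- function(pre, act, kind) {
  switch(kind, relu = (pre > 0) * 1, logistic = act * (1 - act))
}

new_ae_params <- function(v, config, seed) {
  k <- max(1L, as.integer(floor(config$hidden_frac * v)))
  list(
    W_e = with_seed(seed, matrix(stats::rnorm(k * v, sd = config$init_sd), k, v)),
    b_e = numeric(k),
    b_d = numeric(v)
  )
}

#' Autoencoder forward pass
#'
#' Hidden layer `h = phi(W_e y + b_e)`; linear output layer
#' `y_r = W_d h + b_d` with the decoding weights tied to the transpose
#' of the encoding weights (`W_d = W_e'` — never stored separately, so
#' the tie holds by construction after every update).
#'
#' @param params Autoencoder parameters (a trained `denoising_ae` or its
#'   `params` list).
#' @param y Input pattern (length `v` vector or `v x n` matrix).
#' @param activation Hidden nonlinearity; taken from the trained model
#'   when available.
#' @return List with `h_pre`, `h` (`k x n`) and `y_r` (`v x n`).
#' @export
ae_forward <- function(params, y, activation = NULL) {
  p <- ae_params_of(params)
  if (is.null(activation)) activation <- ae_activation_of(params)
  ym <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  if (nrow(ym) != ncol(p$W_e)) {
    stop(sprintf("pattern has %d voxels but autoencoder expects %d",
                 nrow(ym), ncol(p$W_e)), call. = FALSE)
  }
  h_pre <- p$W_e %*% ym + p$b_e
  h <- ae_activation(h_pre, activation)
  y_r <- crossprod(p$W_e, h) + p$b_d
  list(h_pre = h_pre, h = h, y_r = y_r)
}

ae_params_of <- function(params) {
  if (inherits(params, "denoising_ae")) params$params else params
}

ae_activation_of <- function(params) {
  if (inherits(params, "denoising_ae")) params$config$activation else "relu"
}

#' Loss and gradients of the tied-weight autoencoder
#'
#' Mean squared distance between the clean targets and the restorations
#' of the corrupted inputs, with gradients for `W_e` (both its encoding
#' and its tied decoding role), `b_e` and `b_d`.
#'
#' @param params Parameter list (`W_e`, `b_e`, `b_d`).
#' @param y_c Corrupted inputs, `v x n`.
#' @param y Clean targets, `v x n`.
#' @param activation Hidden nonlinearity.
#' @return List with `loss` and gradients `W_e`, `b_e`, `b_d`.
#' @export
ae_gradients <- function(params, y_c, y, activation = "relu") {
  f <- ae_forward(params, y_c, activation)
  err <- f$y_r - y
  e <- 2 * err / length(y)
  dh <- params$W_e %*% e
  dh_pre <- dh * ae_activation_grad(f$h_pre, f$h, activation)
  list(
    loss = mean(err^2),
    W_e = dh_pre %*% t(y_c) + f$h %*% t(e),
    b_e = rowSums(dh_pre),
    b_d = rowSums(e)
  )
}

adam_new <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, config) {
  state$t <- state$t + 1L
  b1 <- config$beta1
  b2 <- config$beta2
  for (nm in names(params)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] -
      config$learning_rate * mhat / (sqrt(vhat) + config$epsilon)
  }
  list(params = params, state = state)
}

#' Train the denoising autoencoder on perceptual patterns
#'
#' The training set comprises the four average perceptual voxel patterns
#' plus four all-zero patterns (so that inputs carrying no signal are
#' restored to zero rather than to an arbitrary attractor).  Every
#' optimizer step draws `batch_size` items from these eight with
#' replacement and corrupts them afresh, then takes one Adam step on the
#' mean squared restoration error.  Training aborts with diagnostics if
#' the loss becomes non-finite.
#'
#' @param perceptual The four average perceptual patterns: a `v x 4`
#'   matrix or an average `pattern_set` from [average_letter_patterns()].
#' @param config An [ae_config()].
#' @param seed Integer seed (initialisation, batch sampling, corruption).
#' @return A `denoising_ae`: list with `params`, `config`, `v`, `k`,
#'   `loss` (per-step trajectory) and `seed`.
#' @export
train_autoencoder <- function(perceptual, config = ae_config(), seed = 1) {
  if (inherits(perceptual, "pattern_set") || is.data.frame(perceptual)) {
    perceptual <- pattern_matrix(perceptual)
  }
  stopifnot(is.matrix(perceptual))
  if (ncol(perceptual) != 4) {
    stop(sprintf("expected 4 average perceptual patterns, got %d", ncol(perceptual)),
         call. = FALSE)
  }
  v <- nrow(perceptual)
  items <- cbind(perceptual, matrix(0, v, ncol(perceptual)))
  params <- new_ae_params(v, config, derive_seed(seed, "init"))
  state <- adam_new(params)
  losses <- numeric(config$iterations)
  with_seed(derive_seed(seed, "train"), {
    for (it in seq_len(config$iterations)) {
      idx <- sample.int(ncol(items), config$batch_size, replace = TRUE)
      y <- items[, idx, drop = FALSE]
      y_c <- y + matrix(stats::rnorm(length(y), sd = config$corruption_sd),
                        v, config$batch_size)
      g <- ae_gradients(params, y_c, y, config$activation)
      losses[it] <- g$loss
      if (!is.finite(g$loss)) {
        stop(sprintf(
          "autoencoder training diverged at step %d (loss %g); last finite loss %g",
          it, g$loss, if (it > 1) losses[it - 1] else NA_real_
        ), call. = FALSE)
      }
      upd <- adam_step(params, g[c("W_e", "b_e", "b_d")], state, config)
      params <- upd$params
      state <- upd$state
    }
  })
  structure(
    list(params = params, config = config, v = v, k = nrow(params$W_e),
         loss = losses, seed = as.integer(seed)),
    class = "denoising_ae"
  )
}

#' @export
print.denoising_ae <- function(x, ...) {
  cat(sprintf(
    "<denoising_ae> %d voxels -> %d hidden (%s), final loss %.4g over %d steps\n",
    x$v, x$k, x$config$activation, x$loss[length(x$loss)], length(x$loss)
  ))
  invisible(x)
}

#' Denoise voxel patterns with a trained autoencoder
#'
#' A plain forward pass (no corruption at inference): imagery patterns
#' are projected onto the perceptual attractor landscape the autoencoder
#' learned, and the restored patterns can be fed to [reconstruct()] for
#' "processed" reconstructions.
#'
#' @param ae A trained `denoising_ae`.
#' @param y Pattern vector or `v x n` matrix.
#' @return Restored pattern(s), same shape as `y`.
#' @export
denoise <- function(ae, y) {
  if (!inherits(ae, "denoising_ae")) {
    stop("denoise() needs a trained 'denoising_ae'", call. = FALSE)
  }
  out <- ae_forward(ae, y)$y_r
  if (is.matrix(y)) out else drop(out)
}
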