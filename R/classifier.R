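#' Training configuration for the softmax classifier head
#'
#' Defaults: Adam with learning rate `1e-4`, full batches of 96 (the
#' size of a three-run training fold), 250 optimizer steps,
#' cross-entropy loss.  The head weights start at zero — the problem is
#' convex given the frozen hidden representations, so no random
#' initialisation is needed and training is deterministic whenever the
#' batch is the full fold.
#'
#' @inheritParams ae_config
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(learning_rate = 1e-4, batch_size = 96,
                              iterations = 250, beta1 = 0.9, beta2 = 0.999,
                              epsilon = 1e-8) {
  stopifnot(learning_rate > 0, batch_size >= 1, iterations >= 1)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations), beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon),
            class = "classifier_config")
}

#' Hidden representation of voxel patterns
#'
#' Encodes patterns through the (frozen) pretrained encoder of the
#' autoencoder: `h = phi(W_e y + b_e)`.
#'
#' @param ae A trained `denoising_ae`.
#' @param y Pattern vector or `v x n` matrix.
#' @return A `k x n` matrix of hidden activations.
#' @export
hidden_rep <- function(ae, y) {
  stopifnot(inherits(ae, "denoising_ae"))
  ae_forward(ae, y)$h
}

letter_levels <- c("H", "T", "S", "C")

# Train P softmax heads jointly on shared hidden representations.
# h: k x n; labels: n x P matrix of class indices (1..n_class).
# Heads are independent; stacking them into one k x (n_class * P) weight
# matrix turns the whole permutation null into a handful of BLAS calls.
train_softmax_heads <- function(h, labels, config, n_class = 4, seed = NULL) {
  k <- nrow(h)
  n <- ncol(h)
  labels <- as.matrix(labels)
  np <- ncol(labels)
  wide <- n_class * np
  # one-hot targets, classes blocked by head: column (p-1)*n_class + c
  tm <- matrix(0, wide, n)
  for (p_i in seq_len(np)) {
    tm[cbind((p_i - 1) * n_class + labels[, p_i], seq_len(n))] <- 1
  }
  params <- list(W = matrix(0, k, wide), b = numeric(wide))
  state <- adam_new(params)
  losses <- numeric(config$iterations)
  head_of_row <- rep(seq_len(np), each = n_class)
  with_seed(seed, {
    for (it in seq_len(config$iterations)) {
      idx <- if (config$batch_size < n) {
        sample.int(n, config$batch_size)
      } else {
        seq_len(n)
      }
      hb <- h[, idx, drop = FALSE]
      tb <- tm[, idx, drop = FALSE]
      logits <- crossprod(params$W, hb) + params$b        # wide x batch
      expl <- exp(sweep(logits, 2, apply(logits, 2, max), "-"))
      denom <- rowsum(expl, head_of_row)                  # np x batch
      probs <- expl / denom[head_of_row, , drop = FALSE]
      losses[it] <- -sum(tb * log(pmax(probs, 1e-12))) / (ncol(hb) * np)
      delta <- (probs - tb) / ncol(hb)
      grads <- list(W = hb %*% t(delta), b = rowSums(delta))
      upd <- adam_step(params, grads, state, config)
      params <- upd$params
      state <- upd$state
    }
  })
  list(W = params$W, b = params$b, loss = losses, n_heads = np, n_class = n_class)
}

softmax_head_predict <- function(heads, h) {
  logits <- crossprod(heads$W, h) + heads$b               # wide x n
  np <- heads$n_heads
  nc <- heads$n_class
  # class argmax within each head's block
  out <- matrix(0L, ncol(h), np)
  for (p_i in seq_len(np)) {
    block <- logits[(p_i - 1) * nc + seq_len(nc), , drop = FALSE]
    out[, p_i] <- max.col(t(block), ties.method = "first")
  }
  out
}

#' Train the softmax classifier head on imagery patterns
#'
#' Stacks a four-unit softmax output layer onto the frozen encoder of a
#' pretrained autoencoder and trains only the head (multinomial logistic
#' regression on the hidden representations, cross-entropy loss, Adam).
#' The encoder weights and biases are read but never modified.
#'
#' @param ae A trained `denoising_ae` (encoder stays frozen).
#' @param patterns Training patterns: a `pattern_set` of imagery single
#'   trials, or a `v x n` matrix with `labels` supplied.
#' @param config A [classifier_config()].
#' @param labels Letter labels (required for matrix input).
#' @param seed Optional seed (only used when `batch_size` is smaller than
#'   the training set, making minibatch sampling stochastic).
#' @return A `classifier_head`: list with `W` (`k x 4`), `b`, `loss`
#'   trajectory and the class `levels`.
#' @export
train_classifier_head <- function(ae, patterns, config = classifier_config(),
                                  labels = NULL, seed = NULL) {
  stopifnot(inherits(ae, "denoising_ae"))
  if (inherits(patterns, "pattern_set") || is.data.frame(patterns)) {
    labels <- patterns$letter
    patterns <- pattern_matrix(patterns)
  }
  if (is.null(labels)) stop("labels are required for matrix input", call. = FALSE)
  lab <- factor(labels, levels = letter_levels)
  missing <- letter_levels[!letter_levels %in% lab]
  if (length(missing)) {
    stop(sprintf("training set lacks class(es): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  h <- hidden_rep(ae, patterns)
  heads <- train_softmax_heads(h, matrix(as.integer(lab), ncol = 1), config,
                               seed = seed)
  structure(list(W = heads$W, b = heads$b, loss = heads$loss,
                 levels = letter_levels, k = nrow(heads$W)),
            class = "classifier_head")
}

#' @export
#' @param object A `classifier_head`.
#' @param ae The autoencoder providing the frozen encoder.
#' @param y Patterns to classify (`v x n` matrix or vector).
#' @param ... Unused.
#' @rdname train_classifier_head
predict.classifier_head <- function(object, ae, y, ...) {
  h <- hidden_rep(ae, if (is.matrix(y)) y else matrix(y, ncol = 1))
  heads <- list(W = object$W, b = object$b, n_heads = 1L, n_class = 4L)
  factor(object$levels[softmax_head_predict(heads, h)[, 1]],
         levels = object$levels)
}

check_imagery_runs <- function(pset) {
  img <- pset[pset$condition == "imagery" & pset$kind == "single_trial", ]
  if (nrow(img) == 0) stop("no imagery single-trial patterns found", call. = FALSE)
  counts <- table(img$run, img$letter)
  if (length(unique(img$run)) < 2) {
    stop("leave-one-run-out needs at least 2 imagery runs", call. = FALSE)
  }
  if (length(unique(as.vector(counts))) != 1 || ncol(counts) < 2) {
    stop("imagery runs are unbalanced across letters; leave-one-run-out requires ",
         "identical per-letter trial counts in every run", call. = FALSE)
  }
  img
}

#' Leave-one-run-out classification of imagery patterns
#'
#' For each imagery run, trains the classifier head on the trials of the
#' remaining runs and tests on the held-out run.  With the standard
#' 4-run x 32-trial design every fold trains on 96 patterns and tests
#' on 32.
#'
#' @param pset A `pattern_set` containing the imagery single trials.
#' @param ae A trained `denoising_ae`.
#' @param config A [classifier_config()].
#' @return A `loro_result`: list with a per-fold tibble
#'   (`run, n_train, n_test, accuracy`) and the mean accuracy.
#' @export
loro_cross_validate <- function(pset, ae, config = classifier_config()) {
  img <- check_imagery_runs(pset)
  y <- pattern_matrix(img)
  lab <- factor(img$letter, levels = letter_levels)
  h <- hidden_rep(ae, y)
  runs <- sort(unique(img$run))
  folds <- purrr::map_dfr(runs, function(r) {
    test <- img$run == r
    heads <- train_softmax_heads(h[, !test, drop = FALSE],
                                 matrix(as.integer(lab[!test]), ncol = 1), config)
    pred <- softmax_head_predict(heads, h[, test, drop = FALSE])[, 1]
    tibble::tibble(run = r, n_train = sum(!test), n_test = sum(test),
                   accuracy = mean(pred == as.integer(lab[test])))
  })
  structure(list(folds = folds, mean_accuracy = mean(folds$accuracy)),
            class = "loro_result")
}

#' @export
print.loro_result <- function(x, ...) {
  cat(sprintf("<loro_result> mean accuracy %.3f over %d folds\n",
              x$mean_accuracy, nrow(x$folds)))
  invisible(x)
}

#' Permutation test of leave-one-run-out accuracy
#'
#' Builds the null distribution of decoding accuracy by repeating the
#' leave-one-run-out procedure with the *training* labels randomly
#' scrambled (test labels intact), and compares the observed mean
#' accuracy to the 95th percentile of the null (nearest-rank rule).
#' With four balanced classes the null mean sits at the theoretical
#' chance level of 25%.
#'
#' @param pset A `pattern_set` with imagery single trials.
#' @param ae A trained `denoising_ae`.
#' @param config A [classifier_config()].
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the scrambles.
#' @return A `permutation_result`: list with `observed`, `null`
#'   (accuracies), `null_mean`, `threshold` (95th percentile) and
#'   `significant`.
#' @export
permutation_test <- function(pset, ae, config = classifier_config(),
                             n_perm = 1000, seed = 1) {
  if (n_perm < 100) {
    warning("fewer than 100 permutations: the 95th-percentile threshold is unstable",
            call. = FALSE)
  }
  img <- check_imagery_runs(pset)
  observed <- loro_cross_validate(pset, ae, config)
  y <- pattern_matrix(img)
  lab <- as.integer(factor(img$letter, levels = letter_levels))
  h <- hidden_rep(ae, y)
  runs <- sort(unique(img$run))
  correct <- numeric(n_perm)
  total <- 0L
  for (ri in seq_along(runs)) {
    test <- img$run == runs[ri]
    lab_train <- lab[!test]
    perm_labels <- with_seed(derive_seed(seed, "fold", ri), {
      vapply(seq_len(n_perm), function(i) sample(lab_train), integer(length(lab_train)))
    })
    heads <- train_softmax_heads(h[, !test, drop = FALSE], perm_labels, config)
    pred <- softmax_head_predict(heads, h[, test, drop = FALSE])  # n_test x n_perm
    correct <- correct + colSums(pred == lab[test])
    total <- total + sum(test)
  }
  null_acc <- correct / total
  threshold <- sort(null_acc)[ceiling(0.95 * n_perm)]
  structure(
    list(observed = observed$mean_accuracy, folds = observed$folds,
         null = null_acc, null_mean = mean(null_acc), threshold = threshold,
         n_perm = as.integer(n_perm),
         significant = observed$mean_accuracy > threshold,
         seed = as.integer(seed)),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed %.3f vs null mean %.3f (95th pct %.3f, %d perms)%s\n",
    x$observed, x$null_mean, x$threshold, x$n_perm,
    if (x$significant) " *" else ""
  ))
  invisible(x)
}
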