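#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a contrast test
#'
#' @param x A [contrast_test()] result.
#' @param ... Unused.
#' @return One-row tibble with the test statistics.
#' @method tidy contrast_result
#' @export
tidy.contrast_result <- function(x, ...) {
  tibble::tibble(
    target = x$target, estimate = mean(x$contrast), t = x$t, df = x$df,
    p_value = x$p_value, alpha_corrected = x$alpha_corrected,
    significant = x$significant, degenerate = x$degenerate
  )
}

#' @rdname tidy.contrast_result
#' @method glance contrast_result
#' @export
glance.contrast_result <- function(x, ...) tidy.contrast_result(x, ...)

#' Tidy leave-one-run-out results
#'
#' @param x A [loro_cross_validate()] result.
#' @param ... Unused.
#' @return Per-fold tibble (`tidy`) or one-row summary (`glance`).
#' @method tidy loro_result
#' @export
tidy.loro_result <- function(x, ...) x$folds

#' @rdname tidy.loro_result
#' @method glance loro_result
#' @export
glance.loro_result <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy, n_folds = nrow(x$folds))
}

#' Tidy a permutation test
#'
#' @param x A [permutation_test()] result.
#' @param ... Unused.
#' @return `tidy`: the null accuracies, one row per permutation;
#'   `glance`: one-row summary.
#' @method tidy permutation_result
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$null), null_accuracy = x$null)
}

#' @rdname tidy.permutation_result
#' @method glance permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(
    observed = x$observed, null_mean = x$null_mean, threshold_95 = x$threshold,
    n_perm = x$n_perm, significant = x$significant
  )
}

#' Summarise a trained autoencoder
#'
#' @param x A [train_autoencoder()] result.
#' @param ... Unused.
#' @return One-row tibble with sizes and initial/final loss.
#' @method glance denoising_ae
#' @export
glance.denoising_ae <- function(x, ...) {
  tibble::tibble(
    v = x$v, k = x$k, activation = x$config$activation,
    iterations = length(x$loss),
    initial_loss = x$loss[1], final_loss = x$loss[length(x$loss)]
  )
}
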