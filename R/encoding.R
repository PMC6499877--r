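#' Predict a voxel pattern from a physical letter stimulus
#'
#' Pushes a binary letter raster through the forward encoding matrix
#' (`W %*% vectorize_image(letter)`) and z-normalises the result across
#' voxels, yielding the activation pattern the pRF model expects that
#' letter to evoke.
#'
#' @param w An [encoding_matrix()].
#' @param letter A `vf_letter` raster (or any raster on the same grid).
#' @return A z-scored numeric vector of length `v`.
#' @export
predict_pattern <- function(w, letter) {
  stopifnot(inherits(w, "encoding_matrix"))
  check_same_grid(attr(w, "grid"), attr(letter, "grid"),
                  "encoding matrix and stimulus")
  drive <- drop(unclass(w) %*% vectorize_image(unclass(letter)))
  znormalize(drive)
}

#' Predicted patterns for a set of letters
#'
#' @param w An [encoding_matrix()].
#' @param letters Named list of letter rasters, e.g. [letter_set()].
#' @return A `v x length(letters)` matrix with one z-scored predicted
#'   pattern per column.
#' @export
predicted_pattern_matrix <- function(w, letters) {
  vapply(letters, function(l) predict_pattern(w, l), numeric(nrow(w)))
}

#' Regress an observed pattern on predicted letter patterns
#'
#' Ordinary least squares of one observed (average imagery) voxel pattern
#' on the four model-predicted letter patterns plus an intercept.  Run
#' once per subject, imagined letter and ROI, the four betas quantify how
#' much each physical letter's predicted topography contributes to the
#' observed imagery pattern.
#'
#' @param observed Observed voxel pattern (length `v`).
#' @param predictors A `v x 4` matrix of predicted patterns with letter
#'   column names.
#' @param max_kappa Condition-number bound above which the predictors are
#'   rejected as collinear.
#' @return A tibble with `term` (`"(Intercept)"` and letter names) and
#'   `estimate`.
#' @export
fit_letter_regression <- function(observed, predictors, max_kappa = 1e8) {
  stopifnot(is.matrix(predictors))
  if (length(observed) != nrow(predictors)) {
    stop("observed pattern and predictors have different voxel counts", call. = FALSE)
  }
  if (length(observed) < ncol(predictors) + 1) {
    stop("need more voxels than regression terms", call. = FALSE)
  }
  kap <- kappa(cbind(1, predictors), exact = TRUE)
  if (!is.finite(kap) || kap > max_kappa) {
    stop(sprintf("predicted letter patterns are collinear (condition number %.3g)",
                 kap), call. = FALSE)
  }
  fit <- stats::lm.fit(cbind("(Intercept)" = 1, predictors), observed)
  tibble::tibble(term = names(fit$coefficients), estimate = unname(fit$coefficients))
}

#' Target-versus-rest contrast on letter betas
#'
#' For each subject, forms the contrast `3 * beta_target - sum(other
#' betas)` (weights `(3, -1, -1, -1)`, summing to zero) and tests it
#' against zero with a one-sample t test across subjects.  The family of
#' 4 imagined letters x 3 single-area ROIs gives 12 tests, so the
#' Bonferroni-corrected cutoff defaults to `0.05 / 12 = 0.0042`.
#'
#' @param betas A subjects-by-letters matrix of regression betas (letter
#'   column names), or a tibble with columns `subject`, `letter`,
#'   `estimate`.
#' @param target The imagined letter whose physical counterpart is
#'   contrasted against the rest.
#' @param alpha Family-wise significance level.
#' @param n_tests Number of tests in the family (for the Bonferroni
#'   correction).
#' @return A `contrast_result`: list with the per-subject contrast
#'   values, `t`, `df`, `p_value`, `alpha_corrected`, `significant`, and
#'   a `degenerate` flag (zero contrast variance).
#' @export
contrast_test <- function(betas, target, alpha = 0.05, n_tests = 12) {
  if (is.data.frame(betas)) {
    betas <- betas |>
      tidyr::pivot_wider(id_cols = "subject", names_from = "letter",
                         values_from = "estimate") |>
      dplyr::select(-"subject") |>
      as.matrix()
  }
  stopifnot(is.matrix(betas), target %in% colnames(betas))
  if (nrow(betas) < 3) {
    stop(sprintf("contrast test needs at least 3 subjects, got %d", nrow(betas)),
         call. = FALSE)
  }
  weights <- ifelse(colnames(betas) == target, 3, -1)
  stopifnot(sum(weights) == 0)
  con <- drop(betas %*% weights)
  alpha_c <- alpha / n_tests
  if (stats::sd(con) == 0) {
    res <- list(target = target, contrast = con, weights = weights,
                t = NA_real_, df = length(con) - 1, p_value = NA_real_,
                alpha = alpha, alpha_corrected = alpha_c,
                significant = NA, degenerate = TRUE)
  } else {
    tt <- stats::t.test(con, mu = 0)
    res <- list(target = target, contrast = con, weights = weights,
                t = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, alpha = alpha, alpha_corrected = alpha_c,
                significant = tt$p.value < alpha_c, degenerate = FALSE)
  }
  structure(res, class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<contrast_result> letter %s: degenerate (zero contrast variance)\n",
                x$target))
  } else {
    cat(sprintf(
      "<contrast_result> letter %s: t(%d) = %.2f, p = %.4g (alpha_c = %.4f)%s\n",
      x$target, x$df, x$t, x$p_value, x$alpha_corrected,
      if (isTRUE(x$significant)) " *" else ""
    ))
  }
  invisible(x)
}

#' Fisher z transform
#'
#' `fisher_z()` maps correlations to the z scale (`atanh`) for averaging
#' and regression; `fisher_z_inv()` maps back (`tanh`).
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @return Transformed values.
#' @export
fisher_z <- function(r) {
  stopifnot(all(abs(r) <= 1, na.rm = TRUE))
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher z value(s).
#' @export
fisher_z_inv <- function(z) tanh(z)
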