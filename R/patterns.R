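#' High-pass filter a run with a Fourier basis
#'
#' Removes slow drifts by regressing out an intercept, a linear trend,
#' and sine/cosine pairs at 1 .. `n_cycles` cycles per run from every
#' voxel's time course, returning the residuals.
#'
#' @param ts A `v x n_volumes` matrix (or a single time course).
#' @param n_cycles Highest drift frequency removed, in cycles per run.
#' @return Filtered series with the same shape as the input.
#' @export
highpass_fourier <- function(ts, n_cycles = 3) {
  vec <- is.null(dim(ts))
  if (vec) ts <- matrix(ts, nrow = 1)
  n <- ncol(ts)
  need <- 2 + 2 * n_cycles
  if (n < need) {
    stop(sprintf("run has %d volumes; at least %d are needed for %d drift cycles",
                 n, need, n_cycles), call. = FALSE)
  }
  t01 <- seq_len(n) / n
  x <- cbind(1, t01)
  for (k in seq_len(n_cycles)) {
    x <- cbind(x, sin(2 * pi * k * t01), cos(2 * pi * k * t01))
  }
  qx <- qr(x)
  resid <- t(qr.resid(qx, t(ts)))
  out <- if (vec) drop(resid) else resid
  keep_grid_attr(out, ts)
}

keep_grid_attr <- function(out, src) {
  g <- attr(src, "grid")
  if (!is.null(g)) attr(out, "grid") <- g
  out
}

#' Z-normalise each voxel's time course
#'
#' Per voxel (row), subtracts the temporal mean and divides by the
#' temporal SD, removing signal offsets and inter-run scale differences.
#' Voxels with a constant series cannot be normalised; they are set to
#' zero and their indices recorded in the `"constant_voxels"` attribute
#' (with a warning), so downstream selection can exclude them.
#'
#' @param ts A `v x n_volumes` matrix.
#' @return The normalised matrix.
#' @export
znormalize_run <- function(ts) {
  stopifnot(is.matrix(ts))
  out <- znormalize_rows(ts)
  flagged <- attr(out, "constant_voxels")
  if (length(flagged)) {
    warning(sprintf("%d voxel(s) had constant time courses and were zeroed",
                    length(flagged)), call. = FALSE)
  }
  out
}

znormalize_rows <- function(ts) {
  mu <- rowMeans(ts)
  sd <- apply(ts, 1, stats::sd)
  const <- which(sd == 0 | !is.finite(sd))
  sd[const] <- 1
  out <- (ts - mu) / sd
  out[const, ] <- 0
  out <- keep_grid_attr(out, ts)
  if (length(const)) attr(out, "constant_voxels") <- const
  out
}

#' Z-normalise a voxel pattern across voxels
#'
#' Spatial z-scoring of a single activation pattern: mean 0, SD 1 across
#' voxels.  Constant patterns are rejected (their z-score is undefined).
#'
#' @param x Numeric vector (one value per voxel).
#' @return The z-scored vector.
#' @export
znormalize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("pattern is constant across voxels; z-normalization undefined",
         call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Extract single-trial voxel patterns
#'
#' For every trial, averages the BOLD volumes at `onset + window` (the
#' two volumes 6-9 s after onset by default, straddling the HRF peak)
#' and z-normalises the result across voxels.  Trials whose window would
#' extend past the end of the run are dropped with a warning.
#'
#' @param runs Either an `imagery_session` or a named list of
#'   voxel-by-volume matrices whose names are `"perception"` /
#'   `"imagery_<run>"` matching the design.
#' @param design A [session_design()]; taken from the session if omitted.
#' @param window Volume offsets averaged per trial, relative to onset.
#' @return A `pattern_set`: a tibble with one row per trial
#'   (`condition, run, trial, letter, kind, pattern`), where `pattern`
#'   is a list-column of z-scored length-`v` vectors.
#' @export
extract_trial_patterns <- function(runs, design = NULL, window = c(2, 3)) {
  if (inherits(runs, "imagery_session")) {
    if (is.null(design)) design <- runs$design
    runs <- runs$runs
  }
  stopifnot(inherits(design, "session_design"), is.list(runs))
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(design))) {
    cond <- design$condition[i]
    run_id <- design$run[i]
    key <- if (cond == "perception") "perception" else paste0("imagery_", run_id)
    ts <- runs[[key]]
    if (is.null(ts)) stop(sprintf("run '%s' missing from input", key), call. = FALSE)
    cols <- design$onset[i] + window
    if (max(cols) > ncol(ts)) {
      dropped <- dropped + 1L
      next
    }
    pat <- znormalize(rowMeans(ts[, cols, drop = FALSE]))
    rows[[length(rows) + 1]] <- tibble::tibble(
      condition = cond, run = run_id, trial = design$trial[i],
      letter = design$letter[i], kind = "single_trial", pattern = list(pat)
    )
  }
  if (dropped > 0) {
    warning(sprintf("%d trial(s) dropped: extraction window extends past run end",
                    dropped), call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pattern_set", class(out))
  out
}

#' Average single-trial patterns per letter
#'
#' Arithmetic mean of all single-trial patterns of each letter (pooled
#' over runs), z-normalised across voxels.
#'
#' @param pset A `pattern_set` from [extract_trial_patterns()].
#' @param condition Which condition to average (`"perception"` or
#'   `"imagery"`).
#' @param letters Letters that must be present.
#' @return A `pattern_set` tibble with one `kind = "average"` row per
#'   letter.
#' @export
average_letter_patterns <- function(pset, condition = c("perception", "imagery"),
                                    letters = c("H", "T", "S", "C")) {
  condition <- match.arg(condition)
  cond_label <- condition
  sub <- pset[pset$condition == condition & pset$kind == "single_trial", ]
  missing <- setdiff(letters, unique(sub$letter))
  if (length(missing)) {
    stop(sprintf("no %s trials for letter(s): %s", condition,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- sub |>
    dplyr::group_by(.data$letter) |>
    dplyr::summarise(
      condition = cond_label, run = NA_integer_, trial = NA_integer_,
      kind = "average",
      pattern = list(znormalize(rowMeans(do.call(cbind, .data$pattern)))),
      .groups = "drop"
    ) |>
    dplyr::select("condition", "run", "trial", "letter", "kind", "pattern")
  out <- out[match(letters, out$letter), ]
  class(out) <- c("pattern_set", class(out))
  out
}

#' Stack a pattern set into a voxel-by-pattern matrix
#'
#' @param pset A `pattern_set`.
#' @return A `v x n` matrix, one column per row of `pset`.
#' @export
pattern_matrix <- function(pset) {
  stopifnot(nrow(pset) > 0)
  do.call(cbind, pset$pattern)
}
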