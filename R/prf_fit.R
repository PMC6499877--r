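#' Polar search grid for pRF fitting
#'
#' Candidate pRF locations on a circular grid of `n_angles` polar angles
#' by `n_ecc` eccentricities whose density decays exponentially with
#' eccentricity (fine sampling near fixation, coarse in the periphery):
#' `ecc_k = ecc_max * (exp(decay * k / n_ecc) - 1) / (exp(decay) - 1)`.
#' Each location is paired with every size-eccentricity slope in
#' `slopes`, so the default grid spans `100 * 100 * 10 = 100000`
#' candidate models per voxel.
#'
#' @param ecc_max Largest candidate eccentricity, degrees.
#' @param decay Exponential density decay; as `decay -> 0` the spacing
#'   approaches uniform.
#' @param n_angles,n_ecc Grid resolution.
#' @param slopes Candidate size-eccentricity slopes.
#' @param sigma_floor Minimum candidate pRF size, degrees.
#' @return A `prf_search_grid`: list with a `locations` tibble
#'   (`x0, y0, ecc, angle`) and the remaining settings.
#' @examples
#' g <- prf_search_grid(5, n_angles = 10, n_ecc = 10)
#' nrow(g$locations)
#' @export
prf_search_grid <- function(ecc_max = 5, decay = 3, n_angles = 100, n_ecc = 100,
                            slopes = seq(0.1, 1, by = 0.1), sigma_floor = 0.1) {
  if (ecc_max <= 0 || decay <= 0) {
    stop("ecc_max and decay must be positive", call. = FALSE)
  }
  stopifnot(n_angles >= 1, n_ecc >= 1, length(slopes) >= 1, all(slopes > 0),
            sigma_floor > 0)
  k <- seq_len(n_ecc)
  ecc <- ecc_max * (exp(decay * k / n_ecc) - 1) / (exp(decay) - 1)
  angle <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  loc <- tidyr::expand_grid(ecc = ecc, angle = angle)
  loc$x0 <- loc$ecc * cos(loc$angle)
  loc$y0 <- loc$ecc * sin(loc$angle)
  structure(
    list(locations = loc[, c("x0", "y0", "ecc", "angle")],
         slopes = sort(slopes), sigma_floor = sigma_floor,
         ecc_max = ecc_max, decay = decay),
    class = "prf_search_grid"
  )
}

#' @export
print.prf_search_grid <- function(x, ...) {
  cat(sprintf("<prf_search_grid> %d locations x %d slopes = %d candidates\n",
              nrow(x$locations), length(x$slopes),
              nrow(x$locations) * length(x$slopes)))
  invisible(x)
}

# All candidate models, ordered by (ecc, slope, angle) so that a strict
# arg-max scan breaks ties toward the smallest eccentricity, then the
# smallest slope.
search_candidates <- function(grid) {
  cand <- tidyr::expand_grid(grid$locations, slope = grid$slopes)
  cand$sigma <- pmax(cand$slope * cand$ecc, grid$sigma_floor)
  cand[order(cand$ecc, cand$slope, cand$angle), ]
}

#' Predict a voxel's time course from its pRF
#'
#' The forward model used both for fitting and for the encoding analysis:
#' per volume, the overlap between the unit-mass Gaussian pRF profile and
#' the stimulus frame, convolved with the HRF.  The prediction is linear
#' in frame intensity.
#'
#' @param prf A list or one-row data frame with `x0`, `y0`, `sigma`.
#' @param frames `p x n_volumes` stimulus frames with a `grid` attribute.
#' @param hrf An [hrf_double_gamma()] kernel.
#' @return Numeric vector of length `n_volumes`.
#' @export
predict_timecourse <- function(prf, frames, hrf) {
  grid <- attr(frames, "grid")
  if (is.null(grid)) stop("frames must carry a 'grid' attribute", call. = FALSE)
  g <- gaussian_rf_matrix(prf$x0[1], prf$y0[1], prf$sigma[1], grid)
  drop(convolve_hrf(g %*% frames, hrf))
}

#' Fit pRF parameters by grid search
#'
#' For every voxel, finds the candidate (location, slope) on the search
#' grid whose predicted time course has the highest Pearson correlation
#' with the observed series.  The goodness-of-fit score is that
#' correlation; it is amplitude-free, so the arbitrary gain between
#' neural drive and measured z-units does not matter.  Ties are broken
#' deterministically toward the smallest eccentricity, then the smallest
#' slope.  Voxels with a constant observed series get `valid = FALSE`
#' and an `NA` score.
#'
#' @param ts Observed series: a `v x n_volumes` matrix (or one voxel's
#'   vector).
#' @param frames Mapping-run frames with a `grid` attribute.
#' @param hrf An [hrf_double_gamma()] kernel.
#' @param grid A [prf_search_grid()].
#' @param chunk_size Candidates evaluated per block (memory control).
#' @return A `prf_fits` tibble: `voxel, x0, y0, ecc, sigma, slope, score,
#'   valid`.
#' @export
fit_prf <- function(ts, frames, hrf, grid = prf_search_grid(),
                    chunk_size = 10000) {
  stopifnot(inherits(grid, "prf_search_grid"))
  if (is.null(dim(ts))) ts <- matrix(ts, nrow = 1)
  stim_grid <- attr(frames, "grid")
  if (is.null(stim_grid)) stop("frames must carry a 'grid' attribute", call. = FALSE)
  n_vol <- ncol(frames)
  if (ncol(ts) != n_vol) {
    stop(sprintf("series length (%d) does not match frame count (%d)",
                 ncol(ts), n_vol), call. = FALSE)
  }
  v <- nrow(ts)

  # observed series, row-standardised for fast Pearson correlations
  mu <- rowMeans(ts)
  sds <- apply(ts, 1, stats::sd)
  invalid <- which(sds == 0 | !is.finite(sds))
  sds[invalid] <- 1
  obs_std <- (ts - mu) / sds
  obs_std <- obs_std / sqrt(pmax(rowSums(obs_std^2), .Machine$double.eps))

  fc <- frames %*% hrf_conv_matrix(n_vol, hrf)   # p x T, HRF applied once
  cand <- search_candidates(grid)
  n_cand <- nrow(cand)
  best_score <- rep(-Inf, v)
  best_idx <- rep(1L, v)

  for (start in seq(1, n_cand, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1, n_cand)
    g <- gaussian_rf_matrix(cand$x0[idx], cand$y0[idx], cand$sigma[idx],
                            stim_grid, normalize = FALSE)
    pred <- g %*% fc                              # n_chunk x T
    pm <- rowMeans(pred)
    psd <- sqrt(rowSums((pred - pm)^2))
    flat <- psd == 0 | !is.finite(psd)
    psd[flat] <- 1
    pred <- (pred - pm) / psd
    r <- tcrossprod(pred, obs_std)                # n_chunk x v Pearson r
    r[flat, ] <- -Inf
    chunk_best <- apply(r, 2, which.max)
    chunk_score <- r[cbind(chunk_best, seq_len(v))]
    better <- chunk_score > best_score            # strict: earliest candidate wins ties
    best_score[better] <- chunk_score[better]
    best_idx[better] <- idx[chunk_best[better]]
  }

  out <- tibble::tibble(
    voxel = seq_len(v),
    x0 = cand$x0[best_idx], y0 = cand$y0[best_idx],
    ecc = cand$ecc[best_idx], sigma = cand$sigma[best_idx],
    slope = cand$slope[best_idx],
    score = best_score, valid = TRUE
  )
  if (length(invalid)) {
    out$score[invalid] <- NA_real_
    out$valid[invalid] <- FALSE
  }
  structure(out, search_grid = grid,
            class = c("prf_fits", class(tibble::tibble())))
}

hrf_conv_matrix <- function(n, hrf) {
  k <- as.numeric(hrf)
  ct <- matrix(0, n, n)
  for (j in seq_along(k)) {
    idx <- seq_len(n - j + 1)
    ct[cbind(idx, idx + j - 1)] <- k[j]
  }
  ct
}

#' Select well-fit voxels
#'
#' Keeps voxels whose pRF fit score reaches `threshold`.  The retained
#' count matters downstream (it is a strong predictor of reconstruction
#' and decoding quality), so it is recorded in the `"n_selected"`
#' attribute.
#'
#' @param fits A `prf_fits` tibble.
#' @param threshold Minimum fit correlation, in `[0, 1)`.
#' @return The filtered `prf_fits`.
#' @export
select_voxels <- function(fits, threshold = 0.2) {
  stopifnot(threshold >= 0, threshold < 1)
  keep <- fits$valid & !is.na(fits$score) & fits$score >= threshold
  if (!any(keep)) {
    stop(sprintf(
      "no voxels reach fit threshold %.2f (max score %.3f); lower the threshold",
      threshold, max(fits$score, na.rm = TRUE)
    ), call. = FALSE)
  }
  out <- fits[keep, ]
  attr(out, "n_selected") <- nrow(out)
  out
}

#' Assemble the forward encoding matrix
#'
#' Builds the voxel-by-pixel matrix `W` whose row `i` is voxel `i`'s
#' Gaussian pRF profile evaluated at the pixel centres of `grid`, scaled
#' to unit row sum.  `W %*% vectorize_image(img)` predicts the (un-scaled)
#' activation pattern evoked by `img`; the unit-sum normalisation fixes
#' the arbitrary gain, which pattern z-scoring absorbs anyway.
#'
#' @param prfs A data frame with `x0`, `y0`, `sigma` per voxel — fitted
#'   parameters ([fit_prf()] output, typically after [select_voxels()]) or
#'   a `voxel_population` for noiseless ground-truth analyses.
#' @param grid The [vf_grid()] of the reconstruction raster.
#' @return An `encoding_matrix`: a `v x p` matrix with attributes `grid`
#'   and `voxels` (original voxel indices).
#' @export
encoding_matrix <- function(prfs, grid = vf_grid()) {
  stopifnot(is.data.frame(prfs), all(c("x0", "y0", "sigma") %in% names(prfs)),
            nrow(prfs) >= 1, inherits(grid, "vf_grid"))
  w <- gaussian_rf_matrix(prfs$x0, prfs$y0, prfs$sigma, grid, normalize = TRUE)
  vox <- if ("voxel" %in% names(prfs)) prfs$voxel else seq_len(nrow(prfs))
  structure(w, grid = grid, voxels = vox,
            class = c("encoding_matrix", "matrix", "array"))
}

#' @export
print.encoding_matrix <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<encoding_matrix> %d voxels x %d pixels (%dx%d raster)\n",
              nrow(x), ncol(x), g$n_rows, g$n_cols))
  invisible(x)
}
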