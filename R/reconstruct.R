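#' Pixel outdegree of an encoding matrix
#'
#' The outdegree of pixel `j` is the total encoding mass mapping that
#' pixel to cortex — the `j`-th column sum of `W` ("mass" mode), or the
#' number of voxels whose pRF profile at the pixel exceeds a threshold
#' ("count" mode).  Used as pixel-specific L2 regularisation weight in
#' the inverse problem, it down-weights densely sampled (foveal) pixels
#' less than sparsely sampled ones and thereby accounts for cortical
#' magnification.  Pixels covered by no pRF get a small floor
#' (`eps_rel * max(outdegree)`) so the regularised normal matrix stays
#' positive definite; such pixels are then shrunk to zero in every
#' reconstruction.
#'
#' @param w An [encoding_matrix()].
#' @param mode `"mass"` (default) or `"count"`.
#' @param count_threshold Profile value above which a pRF "covers" a
#'   pixel (count mode only).
#' @param eps_rel Relative floor for zero-coverage pixels.
#' @return An `outdegree` object: the length-`p` diagonal of `D`, with a
#'   `floored` attribute marking zero-coverage pixels.
#' @export
outdegree <- function(w, mode = c("mass", "count"), count_threshold = 1e-4,
                      eps_rel = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(inherits(w, "encoding_matrix"))
  d <- switch(mode,
    mass = colSums(w),
    count = colSums(unclass(w) > count_threshold)
  )
  zero <- d == 0
  if (all(zero)) stop("encoding matrix has no mass on the raster", call. = FALSE)
  d[zero] <- eps_rel * max(d)
  structure(as.numeric(d), floored = which(zero), mode = mode,
            grid = attr(w, "grid"), class = "outdegree")
}

#' Projection matrix from cortex to the visual field
#'
#' Solves the regularised inverse problem
#' `min_x ||y - W x||^2 + x' D x`, whose minimiser is
#' `x = (W'W + D)^{-1} W' y`, and stores the projection
#' `W_VF = (W'W + D)^{-1} W'` in factored form.  Because `p` (pixels)
#' typically far exceeds `v` (voxels), the inverse is computed through
#' the Woodbury identity,
#' `W_VF = D^{-1} W' (I_v + W D^{-1} W')^{-1}`,
#' which needs only a `v x v` symmetric positive-definite Cholesky solve
#' — the `p x p` normal matrix is never formed and no explicit inverse
#' of an ill-conditioned matrix is taken.
#'
#' The outdegree diagonal fixes the *profile* of the penalty across
#' pixels; its overall weight against the data-fit term depends on the
#' (arbitrary) amplitude convention of `W`.  To make reconstructions
#' invariant to that convention, the penalty is rescaled by
#' `lambda = trace(W'W) / trace(D)` by default, which balances the two
#' terms; pass an explicit `lambda` to regularise more (`> auto`) or
#' less.
#'
#' @param w An [encoding_matrix()].
#' @param d An [outdegree()] (defaults to the mass outdegree of `w`).
#' @param lambda Overall regularisation weight multiplying `D`;
#'   `NULL` (default) uses the trace-balancing weight.
#' @return A `vf_projection` object.  Use [reconstruct()] to apply it and
#'   `as.matrix()` to materialise the dense `p x v` matrix.
#' @export
projection_matrix <- function(w, d = outdegree(w), lambda = NULL) {
  stopifnot(inherits(w, "encoding_matrix"), inherits(d, "outdegree"))
  if (length(d) != ncol(w)) {
    stop("outdegree length does not match pixel count", call. = FALSE)
  }
  if (any(d <= 0) || !all(is.finite(unclass(w)))) {
    stop("W'W + D is not positive definite: nonpositive outdegree entries",
         call. = FALSE)
  }
  if (is.null(lambda)) lambda <- sum(unclass(w)^2) / sum(d)
  stopifnot(is.numeric(lambda), lambda > 0)
  dinv <- 1 / (lambda * as.numeric(d))
  wm <- unclass(w)
  k <- tcrossprod(wm * rep(dinv, each = nrow(wm)), wm)  # W D^-1 W', v x v
  m <- diag(nrow(wm)) + (k + t(k)) / 2                  # symmetrise roundoff
  ch <- tryCatch(chol(m), error = function(e) {
    ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf("normal system is not positive definite (smallest eigenvalue %.3g)",
                 ev), call. = FALSE)
  })
  structure(
    list(w = wm, dinv = dinv, chol = ch, lambda = lambda,
         grid = attr(w, "grid"),
         v = nrow(wm), p = ncol(wm), voxels = attr(w, "voxels")),
    class = "vf_projection"
  )
}

#' @export
print.vf_projection <- function(x, ...) {
  cat(sprintf("<vf_projection> %d pixels x %d voxels (factored)\n", x$p, x$v))
  invisible(x)
}

#' @export
as.matrix.vf_projection <- function(x, ...) {
  minv <- chol2inv(x$chol)
  x$dinv * crossprod(x$w, minv)
}

#' Reconstruct the visual field from a voxel pattern
#'
#' Applies the projection matrix: `x = W_VF %*% y`.  Linear in `y`.
#'
#' @param proj A [projection_matrix()].
#' @param y A voxel pattern (length `v`) or a `v x n` matrix of patterns.
#' @return For a vector, a `vf_image` raster (matrix with a `grid`
#'   attribute); for a matrix, a `p x n` matrix of vectorized
#'   reconstructions with a `grid` attribute.
#' @export
reconstruct <- function(proj, y) {
  stopifnot(inherits(proj, "vf_projection"))
  vec <- is.null(dim(y))
  ym <- if (vec) matrix(y, ncol = 1) else y
  if (nrow(ym) != proj$v) {
    stop(sprintf("pattern has %d voxels but projection expects %d",
                 nrow(ym), proj$v), call. = FALSE)
  }
  z <- backsolve(proj$chol, forwardsolve(t(proj$chol), ym))
  x <- proj$dinv * crossprod(proj$w, z)
  if (vec) {
    img <- devectorize_image(drop(x), proj$grid)
    structure(img, grid = proj$grid, class = c("vf_image", "matrix", "array"))
  } else {
    structure(x, grid = proj$grid)
  }
}

#' First-level reconstruction quality
#'
#' Pearson correlation, over all pixels, between a reconstruction and the
#' binary letter stimulus it should depict.  Use [fisher_z()] when
#' averaging these correlations.
#'
#' @param x A reconstruction: `vf_image` raster, vectorized image, or a
#'   `p x n` matrix of vectorized reconstructions.
#' @param letter The corresponding `vf_letter` raster.
#' @return A correlation (or a vector of correlations for matrix input).
#' @export
first_level_r <- function(x, letter) {
  lv <- vectorize_image(unclass(letter))
  xg <- attr(x, "grid")
  if (!is.null(xg)) check_same_grid(xg, attr(letter, "grid"),
                                    "reconstruction and stimulus")
  xm <- if (is.matrix(x) && all(dim(x) == dim(letter))) {
    vectorize_image(unclass(x))                       # a raster on the same grid
  } else if (is.null(dim(x))) {
    x
  } else if (ncol(x) == 1) {
    drop(x)
  } else {
    x
  }
  if (is.matrix(xm)) {
    if (nrow(xm) != length(lv)) stop("pixel counts differ", call. = FALSE)
    return(apply(xm, 2, function(col) pearson_or_flag(col, lv)))
  }
  if (length(xm) != length(lv)) stop("pixel counts differ", call. = FALSE)
  pearson_or_flag(xm, lv)
}

pearson_or_flag <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: constant image", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Second-level reconstruction quality
#'
#' Letters differ in mutual similarity, so a geometry-preserving
#' reconstruction should reproduce the *pattern* of similarities: this
#' metric correlates the `choose(4, 2) = 6` pairwise correlations among
#' the physical letters with the 6 pairwise correlations among their
#' reconstructions.
#'
#' @param recons Reconstructions for all four letters: a named list of
#'   rasters/vectors or a `p x 4` matrix, in the same letter order as
#'   `letters`.
#' @param letters The four `vf_letter` rasters (named list).
#' @return The second-level correlation, with the two pairwise vectors
#'   attached as attributes `pairwise_letters` and `pairwise_recons`.
#' @export
second_level_r <- function(recons, letters) {
  if (length(letters) != 4 || !setequal(names(letters), c("H", "T", "S", "C"))) {
    stop("letters must be a named list covering H, T, S, C", call. = FALSE)
  }
  lm_ <- vapply(letters, function(l) vectorize_image(unclass(l)),
                numeric(length(letters[[1]])))
  rm_ <- if (is.matrix(recons)) recons else {
    if (!setequal(names(recons), names(letters))) {
      stop(sprintf("missing reconstruction(s): %s",
                   paste(setdiff(names(letters), names(recons)), collapse = ", ")),
           call. = FALSE)
    }
    vapply(names(letters), function(nm) {
      r <- recons[[nm]]
      if (is.matrix(r)) vectorize_image(unclass(r)) else as.numeric(r)
    }, numeric(nrow(lm_)))
  }
  if (ncol(rm_) != 4) stop("need reconstructions for all four letters", call. = FALSE)
  pl <- pairwise_cors(lm_)
  pr <- pairwise_cors(rm_)
  structure(stats::cor(pl, pr), pairwise_letters = pl, pairwise_recons = pr)
}

pairwise_cors <- function(m) {
  cm <- stats::cor(m)
  cm[lower.tri(cm)]
}
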