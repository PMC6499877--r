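#' Sample a synthetic retinotopic voxel population
#'
#' Draws `n` voxels whose population receptive fields (pRFs) are isotropic
#' 2-D Gaussians.  Centres cover the visual field uniformly (over a square
#' of half-width `ecc_max` by default, or a disc of radius `ecc_max`);
#' pRF size follows the linear size-eccentricity relation
#' `sigma = max(slope * eccentricity, sigma_floor)` plus optional Gaussian
#' jitter, mirroring the organisation of early visual areas where the
#' slope of that relation differs between V1, V2 and V3.
#'
#' The population also carries the generative parameters used when
#' simulating sessions: the per-volume BOLD noise level, and the imagery
#' condition's attenuation gain and inflated noise (imagery is modelled
#' as an attenuated, noisier copy of the perceptual drive).
#'
#' @param n Number of voxels.
#' @param ecc_max Half-width of the sampled field in degrees.
#' @param slope Size-eccentricity slope, in `[0.1, 1]`.
#' @param jitter_sd SD of Gaussian jitter added to sigma, degrees.
#' @param seed Integer seed.
#' @param coverage `"square"` (default) or `"disc"` centre coverage.
#' @param sigma_floor Minimum pRF size in degrees.
#' @param roi ROI label, one of `"V1"`, `"V2"`, `"V3"`.
#' @param noise_sd Additive white-noise SD for mapping/perception runs
#'   (z-units).
#' @param imagery_gain Multiplicative attenuation of the perceptual drive
#'   during imagery, in `(0, 1]`; `0` is allowed as a negative control.
#' @param imagery_noise_sd Noise SD for imagery runs (z-units).
#' @return A `voxel_population`: a tibble with columns
#'   `voxel, x0, y0, ecc, sigma, slope` and generative attributes.
#' @examples
#' pop <- sample_population(100, seed = 1)
#' attr(pop, "roi")
#' @export
sample_population <- function(n, ecc_max = 5, slope = 0.3, jitter_sd = 0,
                              seed = 1, coverage = c("square", "disc"),
                              sigma_floor = 0.1, roi = "V1", noise_sd = 1,
                              imagery_gain = 0.5, imagery_noise_sd = 2) {
  coverage <- match.arg(coverage)
  if (!is.numeric(n) || n <= 0) stop("n must be a positive count", call. = FALSE)
  if (slope < 0.1 || slope > 1) {
    stop(sprintf("slope must lie in [0.1, 1], got %g", slope), call. = FALSE)
  }
  stopifnot(ecc_max > 0, jitter_sd >= 0, sigma_floor > 0, noise_sd >= 0,
            imagery_gain >= 0, imagery_gain <= 1, imagery_noise_sd >= 0,
            roi %in% c("V1", "V2", "V3"))
  n <- as.integer(n)
  prfs <- with_seed(seed, {
    if (coverage == "square") {
      x0 <- stats::runif(n, -ecc_max, ecc_max)
      y0 <- stats::runif(n, -ecc_max, ecc_max)
    } else {
      r <- ecc_max * sqrt(stats::runif(n))
      th <- stats::runif(n, 0, 2 * pi)
      x0 <- r * cos(th)
      y0 <- r * sin(th)
    }
    ecc <- sqrt(x0^2 + y0^2)
    sigma <- pmax(slope * ecc, sigma_floor)
    if (jitter_sd > 0) sigma <- pmax(sigma + stats::rnorm(n, sd = jitter_sd), sigma_floor / 2)
    tibble::tibble(voxel = seq_len(n), x0 = x0, y0 = y0, ecc = ecc,
                   sigma = sigma, slope = slope)
  })
  as_voxel_population(prfs, roi = roi, noise_sd = noise_sd,
                      imagery_gain = imagery_gain,
                      imagery_noise_sd = imagery_noise_sd,
                      sigma_floor = sigma_floor, seed = as.integer(seed))
}

#' Build a voxel population from explicit pRF parameters
#'
#' Lower-level companion to [sample_population()] for constructing
#' populations with hand-picked centres and sizes (e.g. pRFs placed on
#' the nodes of a search grid for closed-loop recovery studies).
#'
#' @param prfs A data frame with columns `x0`, `y0`, `sigma` and
#'   optionally `slope`.
#' @inheritParams sample_population
#' @return A `voxel_population`.
#' @export
as_voxel_population <- function(prfs, roi = "V1", noise_sd = 1,
                                imagery_gain = 0.5, imagery_noise_sd = 2,
                                sigma_floor = 0.1, seed = NA_integer_) {
  stopifnot(is.data.frame(prfs), all(c("x0", "y0", "sigma") %in% names(prfs)))
  if (any(prfs$sigma <= 0)) stop("all pRF sigmas must be positive", call. = FALSE)
  prfs <- tibble::as_tibble(prfs)
  if (!"voxel" %in% names(prfs)) prfs$voxel <- seq_len(nrow(prfs))
  if (!"ecc" %in% names(prfs)) prfs$ecc <- sqrt(prfs$x0^2 + prfs$y0^2)
  if (!"slope" %in% names(prfs)) prfs$slope <- NA_real_
  structure(prfs, roi = roi, noise_sd = noise_sd, imagery_gain = imagery_gain,
            imagery_noise_sd = imagery_noise_sd, sigma_floor = sigma_floor,
            seed = seed, class = c("voxel_population", class(tibble::tibble())))
}

# Evaluate the Gaussian receptive-field profile of every voxel at every
# pixel centre of `grid`.  Returns a v x p matrix; with `normalize = TRUE`
# rows are scaled to unit sum (rows that receive no mass on the raster are
# left at zero).  Written to avoid more than two v x p temporaries.
gaussian_rf_matrix <- function(x0, y0, sigma, grid, normalize = TRUE) {
  px <- pixel_centers(grid)
  m <- tcrossprod(cbind(x0, y0), cbind(px$x, px$y))  # v x p cross-terms
  m <- 2 * m
  m <- m - (x0^2 + y0^2)          # recycles down columns (v-vector)
  m <- sweep(m, 2, px$x^2 + px$y^2, "-")
  m <- m * (1 / (2 * sigma^2))    # per-voxel scale, recycled down columns
  m <- exp(m)
  if (normalize) {
    rs <- rowSums(m)
    rs[rs == 0] <- 1
    m <- m / rs
  }
  m
}

#' Simulate a BOLD run from a voxel population and stimulus frames
#'
#' The neural drive of each voxel at each volume is the overlap between
#' its Gaussian pRF and the binary stimulus frame (sum over pixels of the
#' pRF profile times the frame).  The drive is convolved with the HRF,
#' white Gaussian noise is added, and each voxel's series is z-normalised
#' across time.
#'
#' @param pop A `voxel_population`.
#' @param frames A `p x n_volumes` matrix of per-volume stimulus frames
#'   (pixels in row-major order) carrying a `grid` attribute, e.g. from
#'   [render_bar_apertures()].
#' @param hrf An [hrf_double_gamma()] kernel.
#' @param noise_sd Additive noise SD; defaults to the population's value.
#' @param seed Integer seed for the noise draw.
#' @param znorm Z-normalise each voxel's series across time.
#' @return A `v x n_volumes` matrix of simulated BOLD time courses with
#'   attribute `grid`.
#' @export
simulate_run <- function(pop, frames, hrf, noise_sd = NULL, seed = 1,
                         znorm = TRUE) {
  stopifnot(inherits(pop, "voxel_population"), is.matrix(frames))
  grid <- attr(frames, "grid")
  if (is.null(grid)) stop("frames must carry a 'grid' attribute", call. = FALSE)
  if (nrow(frames) != grid$n_rows * grid$n_cols) {
    stop(sprintf(
      "frame grid mismatch: frames have %d pixels but grid is %d x %d (%d pixels)",
      nrow(frames), grid$n_rows, grid$n_cols, grid$n_rows * grid$n_cols
    ), call. = FALSE)
  }
  if (is.null(noise_sd)) noise_sd <- attr(pop, "noise_sd")
  stopifnot(noise_sd >= 0)
  g <- gaussian_rf_matrix(pop$x0, pop$y0, pop$sigma, grid)
  drive <- g %*% frames
  bold <- convolve_hrf(drive, hrf)
  if (noise_sd > 0) {
    bold <- bold + with_seed(seed, matrix(stats::rnorm(length(bold), sd = noise_sd),
                                          nrow(bold), ncol(bold)))
  }
  if (znorm) bold <- znormalize_rows(bold)
  structure(bold, grid = grid)
}

#' Trial design of a simulated scanning session
#'
#' Builds the trial bookkeeping for one perception run and several imagery
#' runs: per imagery run each letter occurs exactly `trials_per_run / 4`
#' times (8 by default), stimulation/imagery phases last `stim_s` seconds,
#' and rest phases alternate pseudo-randomly between the values in
#' `rest_s`.  Onsets are expressed as 1-based volume indices.
#'
#' @param n_imagery_runs Number of imagery runs.
#' @param trials_per_run Trials per imagery run (balanced across letters).
#' @param perception_trials_per_letter Perception trials per letter.
#' @param tr Repetition time in seconds.
#' @param stim_s Stimulation/imagery phase duration, seconds.
#' @param rest_s Candidate rest durations, seconds (alternated randomly).
#' @param lead_in_vols,tail_vols Baseline volumes at run start/end.
#' @param letters Letter labels.
#' @param seed Integer seed for trial orders and rest durations.
#' @return A `session_design`: a tibble with one row per trial
#'   (`condition, run, trial, letter, onset, stim_vols`) and attributes
#'   `tr`, `run_vols` (named volume counts per run) and `seed`.
#' @examples
#' d <- session_design(seed = 1)
#' table(d$condition, d$letter)
#' @export
session_design <- function(n_imagery_runs = 4, trials_per_run = 32,
                           perception_trials_per_letter = 8, tr = 3,
                           stim_s = 6, rest_s = c(9, 12),
                           lead_in_vols = 4, tail_vols = 4,
                           letters = c("H", "T", "S", "C"), seed = 1) {
  stopifnot(n_imagery_runs >= 1, trials_per_run >= length(letters),
            trials_per_run %% length(letters) == 0,
            perception_trials_per_letter >= 1, tr > 0, stim_s > 0,
            all(rest_s > 0))
  stim_vols <- max(1L, as.integer(round(stim_s / tr)))
  rest_vols <- pmax(1L, as.integer(round(rest_s / tr)))
  build_run <- function(condition, run, n_per_letter) {
    lab <- sample(rep(letters, n_per_letter))
    rests <- sample(rest_vols, length(lab), replace = TRUE)
    onsets <- lead_in_vols + 1 + c(0, cumsum((stim_vols + rests)[-length(lab)]))
    tibble::tibble(condition = condition, run = run, trial = seq_along(lab),
                   letter = lab, onset = as.integer(onsets),
                   stim_vols = stim_vols,
                   run_end = as.integer(onsets[length(lab)] + stim_vols +
                                          rests[length(lab)] + tail_vols - 1))
  }
  design <- with_seed(seed, {
    runs <- list(build_run("perception", 1L, perception_trials_per_letter))
    for (r in seq_len(n_imagery_runs)) {
      runs[[length(runs) + 1]] <- build_run("imagery", as.integer(r),
                                            trials_per_run / length(letters))
    }
    dplyr::bind_rows(runs)
  })
  run_vols <- design |>
    dplyr::group_by(.data$condition, .data$run) |>
    dplyr::summarise(n_vols = max(.data$run_end), .groups = "drop")
  design$run_end <- NULL
  structure(design, tr = tr, run_vols = run_vols, letters = letters,
            seed = as.integer(seed),
            class = c("session_design", class(tibble::tibble())))
}

#' Simulate a full scanning session
#'
#' Generates BOLD time series for the perception and imagery runs of a
#' design (and optionally a bar-mapping run).  Perception trials drive
#' each voxel with the overlap between its pRF and the letter raster;
#' imagery trials drive voxels with `imagery_gain` times that overlap and
#' receive the population's inflated imagery noise.  All runs share the
#' same population, and the returned object records the generating ground
#' truth.
#'
#' @param pop A `voxel_population`.
#' @param design A [session_design()].
#' @param letters A named list of letter rasters from [letter_set()].
#' @param hrf An [hrf_double_gamma()] kernel.
#' @param seed Master seed; per-run noise seeds are derived from it.
#' @param apertures Optional [render_bar_apertures()] frames; when given,
#'   a mapping run is simulated as well.
#' @return An `imagery_session`: list with elements `runs` (named list of
#'   voxel-by-volume matrices: `perception`, `imagery_1` ..., optionally
#'   `mapping`), `design`, `pop`, `letters`, `grid`, `hrf`, `seed`.
#' @export
generate_session <- function(pop, design, letters, hrf, seed = 1,
                             apertures = NULL) {
  stopifnot(inherits(pop, "voxel_population"), inherits(design, "session_design"))
  need <- attr(design, "letters")
  if (!all(need %in% names(letters))) {
    stop(sprintf("missing letter raster(s): %s",
                 paste(setdiff(need, names(letters)), collapse = ", ")),
         call. = FALSE)
  }
  grid <- attr(letters[[1]], "grid")
  for (l in letters) check_same_grid(attr(l, "grid"), grid, "letter rasters")

  g <- gaussian_rf_matrix(pop$x0, pop$y0, pop$sigma, grid)
  lmat <- vapply(need, function(l) vectorize_image(unclass(letters[[l]])),
                 numeric(grid$n_rows * grid$n_cols))
  drive_per_letter <- g %*% lmat   # v x 4
  v <- nrow(pop)
  run_vols <- attr(design, "run_vols")
  gain <- attr(pop, "imagery_gain")

  sim_one <- function(cond, run_id) {
    tr_rows <- design[design$condition == cond & design$run == run_id, ]
    n_vols <- run_vols$n_vols[run_vols$condition == cond & run_vols$run == run_id]
    drive <- matrix(0, v, n_vols)
    scale <- if (cond == "imagery") gain else 1
    for (i in seq_len(nrow(tr_rows))) {
      cols <- tr_rows$onset[i] + seq_len(tr_rows$stim_vols[i]) - 1
      drive[, cols] <- drive[, cols] + scale * drive_per_letter[, tr_rows$letter[i]]
    }
    bold <- convolve_hrf(drive, hrf)
    nsd <- if (cond == "imagery") attr(pop, "imagery_noise_sd") else attr(pop, "noise_sd")
    if (nsd > 0) {
      bold <- bold + with_seed(derive_seed(seed, cond, run_id),
                               matrix(stats::rnorm(length(bold), sd = nsd), v, n_vols))
    }
    znormalize_rows(bold)
  }

  runs <- list(perception = sim_one("perception", 1L))
  for (r in unique(design$run[design$condition == "imagery"])) {
    runs[[paste0("imagery_", r)]] <- sim_one("imagery", r)
  }
  if (!is.null(apertures)) {
    runs$mapping <- simulate_run(pop, apertures, hrf,
                                 seed = derive_seed(seed, "mapping"))
  }
  structure(
    list(runs = runs, design = design, pop = pop, letters = letters,
         grid = grid, hrf = hrf, seed = as.integer(seed)),
    class = "imagery_session"
  )
}

#' @export
print.imagery_session <- function(x, ...) {
  cat(sprintf("<imagery_session> %d voxels (%s), runs: %s\n",
              nrow(x$pop), attr(x$pop, "roi"),
              paste(names(x$runs), collapse = ", ")))
  invisible(x)
}
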