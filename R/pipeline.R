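#' Configuration for the end-to-end simulation pipeline
#'
#' Bundles every tunable of the simulate -> fit -> extract -> encode ->
#' reconstruct -> denoise -> classify pipeline.  Unknown arguments are
#' rejected (the function signature is the schema).  Per-ROI population
#' settings follow the size-eccentricity slopes of early visual areas
#' (larger pRFs in V2/V3 than V1).
#'
#' @param n_subjects Simulated subjects.
#' @param n_voxels Voxels per single-area ROI.
#' @param roi_slopes Named size-eccentricity slopes per ROI.
#' @param extent,n_px Reconstruction raster: full width (degrees) and
#'   pixels per side.
#' @param mapping_px Raster side used for the bar-mapping stimulus and
#'   pRF fitting (coarser than the reconstruction raster for speed; pRF
#'   parameters are in degrees, so the two rasters interoperate).
#' @param stroke_width Letter stroke width, degrees.
#' @param noise_sd,imagery_gain,imagery_noise_sd Generative noise and
#'   imagery attenuation settings (see [sample_population()]).
#' @param fit_prfs Fit pRFs from the simulated mapping run (`TRUE`) or
#'   use the generating parameters directly (`FALSE`, noiseless oracle).
#' @param search A [prf_search_grid()] used when fitting.
#' @param selection_threshold Minimum pRF fit score ([select_voxels()]).
#' @param ae An [ae_config()].
#' @param classifier A [classifier_config()].
#' @param n_perm Label permutations for the decoding null.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional directory for CSV/JSON/PNG artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 1,
                            n_voxels = 2000,
                            roi_slopes = c(V1 = 0.2, V2 = 0.3, V3 = 0.4),
                            extent = 10, n_px = 150, mapping_px = 50,
                            stroke_width = 1.2,
                            noise_sd = 1, imagery_gain = 0.5,
                            imagery_noise_sd = 2,
                            fit_prfs = TRUE,
                            search = prf_search_grid(ecc_max = extent / 2,
                                                     n_angles = 40, n_ecc = 30),
                            selection_threshold = 0.2,
                            ae = ae_config(),
                            classifier = classifier_config(),
                            n_perm = 1000,
                            seed = 1,
                            out_dir = NULL) {
  stopifnot(n_subjects >= 1, n_voxels >= 10, length(roi_slopes) >= 1,
            !is.null(names(roi_slopes)), extent > 0, n_px >= 16,
            mapping_px >= 16, n_perm >= 1,
            inherits(search, "prf_search_grid"), inherits(ae, "ae_config"),
            inherits(classifier, "classifier_config"))
  structure(
    list(n_subjects = as.integer(n_subjects), n_voxels = as.integer(n_voxels),
         roi_slopes = roi_slopes, extent = extent, n_px = as.integer(n_px),
         mapping_px = as.integer(mapping_px), stroke_width = stroke_width,
         noise_sd = noise_sd, imagery_gain = imagery_gain,
         imagery_noise_sd = imagery_noise_sd, fit_prfs = fit_prfs,
         search = search, selection_threshold = selection_threshold,
         ae = ae, classifier = classifier, n_perm = as.integer(n_perm),
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full simulation and analysis pipeline
#'
#' For every simulated subject and ROI (each single area plus their
#' union "V1V2V3"): simulate the session, obtain pRF parameters (grid
#' search on the mapping run, or ground truth), build the encoding
#' matrix, extract voxel patterns, run the encoding regression,
#' reconstruct average perception and imagery patterns (raw and
#' denoised) with first- and second-level quality metrics, train the
#' autoencoder, and classify imagery trials with a leave-one-run-out
#' permutation test.  With three or more subjects the target-versus-rest
#' contrast analysis is added across subjects.  Fully deterministic for
#' a fixed master seed.  A stage that fails marks its subject x ROI
#' combination failed in the report and later stages for it are skipped.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report`: list of tibbles (`status`, `selection`,
#'   `encoding_betas`, `contrasts`, `reconstruction`, `second_level`,
#'   `classification`) plus the echoed `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  grid <- vf_grid(config$n_px, config$n_px, config$extent)
  letters <- letter_set(grid, stroke_width = config$stroke_width)
  map_grid <- vf_grid(config$mapping_px, config$mapping_px, config$extent)
  hrf <- hrf_double_gamma(tr = 3)
  rois <- names(config$roi_slopes)

  status <- list(); selection <- list(); betas_tbl <- list()
  recon_tbl <- list(); second_tbl <- list(); class_tbl <- list()

  for (s in seq_len(config$n_subjects)) {
    design <- session_design(seed = derive_seed(config$seed, "design", s))
    apertures <- if (config$fit_prfs) {
      render_bar_apertures(map_grid, seed = derive_seed(config$seed, "bar", s))
    }
    roi_data <- list()
    for (roi in rois) {
      res <- tryCatch(
        run_subject_roi(s, roi, config, grid, map_grid, letters, design,
                        apertures, hrf),
        error = function(e) list(error = conditionMessage(e))
      )
      roi_data[[roi]] <- res
      status[[length(status) + 1]] <- tibble::tibble(
        subject = s, roi = roi,
        status = if (is.null(res$error)) "ok" else "failed",
        message = res$error %||% NA_character_
      )
    }
    # combined ROI: union of the single-area voxel populations
    ok <- purrr::keep(roi_data, ~ is.null(.x$error))
    if (length(ok) == length(rois) && length(rois) > 1) {
      combined <- tryCatch(
        run_combined_roi(s, ok, config, grid, letters, design, hrf),
        error = function(e) list(error = conditionMessage(e))
      )
      roi_data[[paste(rois, collapse = "")]] <- combined
      status[[length(status) + 1]] <- tibble::tibble(
        subject = s, roi = paste(rois, collapse = ""),
        status = if (is.null(combined$error)) "ok" else "failed",
        message = combined$error %||% NA_character_
      )
    }
    for (roi in names(roi_data)) {
      r <- roi_data[[roi]]
      if (!is.null(r$error)) next
      selection[[length(selection) + 1]] <- r$selection
      betas_tbl[[length(betas_tbl) + 1]] <- r$betas
      recon_tbl[[length(recon_tbl) + 1]] <- r$reconstruction
      second_tbl[[length(second_tbl) + 1]] <- r$second_level
      class_tbl[[length(class_tbl) + 1]] <- r$classification
      if (!is.null(config$out_dir)) write_roi_artifacts(r, config$out_dir)
    }
  }

  betas_all <- dplyr::bind_rows(betas_tbl)
  contrasts <- if (config$n_subjects >= 3 && nrow(betas_all) > 0) {
    single <- betas_all[betas_all$roi %in% rois, ]
    purrr::map_dfr(rois, function(roi) {
      purrr::map_dfr(letter_levels, function(tgt) {
        b <- single[single$roi == roi & single$imagined == tgt &
                      single$predictor != "(Intercept)", ]
        wide <- tidyr::pivot_wider(b, id_cols = "subject",
                                   names_from = "predictor",
                                   values_from = "estimate")
        ct <- contrast_test(as.matrix(wide[letter_levels]), tgt,
                            n_tests = 4 * length(rois))
        tibble::tibble(roi = roi, letter = tgt, t = ct$t, df = ct$df,
                       p_value = ct$p_value, alpha_corrected = ct$alpha_corrected,
                       significant = ct$significant)
      })
    })
  } else {
    tibble::tibble()
  }

  report <- structure(
    list(status = dplyr::bind_rows(status),
         selection = dplyr::bind_rows(selection),
         encoding_betas = betas_all,
         contrasts = contrasts,
         reconstruction = dplyr::bind_rows(recon_tbl),
         second_level = dplyr::bind_rows(second_tbl),
         classification = dplyr::bind_rows(class_tbl),
         config = config),
    class = "pipeline_report"
  )
  if (!is.null(config$out_dir)) write_report_tables(report, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_subject_roi <- function(s, roi, config, grid, map_grid, letters, design,
                            apertures, hrf) {
  pop <- sample_population(
    config$n_voxels, ecc_max = config$extent / 2,
    slope = config$roi_slopes[[roi]], roi = roi,
    noise_sd = config$noise_sd, imagery_gain = config$imagery_gain,
    imagery_noise_sd = config$imagery_noise_sd,
    seed = derive_seed(config$seed, "pop", s, roi)
  )
  session <- generate_session(pop, design, letters, hrf,
                              seed = derive_seed(config$seed, "session", s, roi),
                              apertures = apertures)
  if (config$fit_prfs) {
    mapping <- highpass_fourier(session$runs$mapping)
    fits <- fit_prf(mapping, apertures, hrf, config$search)
    kept <- select_voxels(fits, config$selection_threshold)
  } else {
    kept <- tibble::as_tibble(pop)[, c("voxel", "x0", "y0", "ecc", "sigma", "slope")]
    kept$score <- NA_real_
  }
  analyse_roi(s, roi, config, grid, letters, design, session, kept)
}

run_combined_roi <- function(s, ok_rois, config, grid, letters, design, hrf) {
  kept <- dplyr::bind_rows(purrr::imap(ok_rois, function(r, nm) {
    dplyr::mutate(r$kept, source_roi = nm)
  }))
  runs <- stats::setNames(
    purrr::map(names(ok_rois[[1]]$kept_runs), function(run_nm) {
      do.call(rbind, purrr::map(ok_rois, ~ .x$kept_runs[[run_nm]]))
    }),
    names(ok_rois[[1]]$kept_runs)
  )
  roi_name <- paste(names(ok_rois), collapse = "")
  analyse_roi(s, roi_name, config, grid, letters, design,
              session = list(runs = runs, design = design), kept = kept,
              already_selected = TRUE)
}

analyse_roi <- function(s, roi, config, grid, letters, design, session, kept,
                        already_selected = FALSE) {
  # restrict runs to the selected voxels (imagery/perception only)
  run_names <- grep("^(perception|imagery)", names(session$runs), value = TRUE)
  kept_runs <- purrr::map(session$runs[run_names], function(ts) {
    if (already_selected) ts else ts[kept$voxel, , drop = FALSE]
  })
  w <- encoding_matrix(kept, grid)
  pset <- extract_trial_patterns(kept_runs, design)
  perc_avg <- average_letter_patterns(pset, "perception")
  img_avg <- average_letter_patterns(pset, "imagery")

  predictors <- predicted_pattern_matrix(w, letters)
  betas <- purrr::map_dfr(letter_levels, function(tgt) {
    obs <- img_avg$pattern[[match(tgt, img_avg$letter)]]
    fit <- fit_letter_regression(obs, predictors)
    tibble::tibble(subject = s, roi = roi, imagined = tgt,
                   predictor = fit$term, estimate = fit$estimate)
  })

  proj <- projection_matrix(w)
  ae <- train_autoencoder(pattern_matrix(perc_avg), config$ae,
                          seed = derive_seed(config$seed, "ae", s, roi))

  recon_sets <- list(
    list(condition = "perception", denoised = FALSE, pats = pattern_matrix(perc_avg)),
    list(condition = "imagery", denoised = FALSE, pats = pattern_matrix(img_avg)),
    list(condition = "imagery", denoised = TRUE,
         pats = denoise(ae, pattern_matrix(img_avg)))
  )
  recon_rows <- list(); second_rows <- list(); images <- list()
  for (rs in recon_sets) {
    x <- reconstruct(proj, rs$pats)            # p x 4
    colnames(x) <- perc_avg$letter
    r1 <- vapply(seq_len(4), function(i) first_level_r(x[, i], letters[[perc_avg$letter[i]]]),
                 numeric(1))
    recon_rows[[length(recon_rows) + 1]] <- tibble::tibble(
      subject = s, roi = roi, condition = rs$condition, denoised = rs$denoised,
      letter = perc_avg$letter, first_level_r = r1
    )
    second_rows[[length(second_rows) + 1]] <- tibble::tibble(
      subject = s, roi = roi, condition = rs$condition, denoised = rs$denoised,
      second_level_r = as.numeric(second_level_r(x[, letter_levels], letters))
    )
    images[[paste(rs$condition, rs$denoised, sep = "_")]] <- x
  }

  perm <- permutation_test(pset, ae, config$classifier, n_perm = config$n_perm,
                           seed = derive_seed(config$seed, "perm", s, roi))
  list(
    subject = s, roi = roi, kept = kept, kept_runs = kept_runs,
    selection = tibble::tibble(subject = s, roi = roi, n_selected = nrow(kept)),
    betas = betas,
    reconstruction = dplyr::bind_rows(recon_rows),
    second_level = dplyr::bind_rows(second_rows),
    classification = tibble::tibble(
      subject = s, roi = roi, mean_accuracy = perm$observed,
      null_mean = perm$null_mean, threshold_95 = perm$threshold,
      significant = perm$significant
    ),
    images = images, grid = attr(w, "grid"), error = NULL
  )
}

write_roi_artifacts <- function(r, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(r$images)) {
    x <- r$images[[nm]]
    for (l in colnames(x)) {
      img <- devectorize_image(x[, l], r$grid)
      write_image_png(
        img,
        file.path(out_dir, sprintf("recon_s%02d_%s_%s_%s.png", r$subject, r$roi, nm, l)),
        grid = r$grid,
        meta = list(subject = r$subject, roi = r$roi, set = nm, letter = l)
      )
    }
  }
  invisible(NULL)
}

write_report_tables <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tbls <- c("status", "selection", "encoding_betas", "contrasts",
            "reconstruction", "second_level", "classification")
  for (nm in tbls) {
    if (nrow(report[[nm]] %||% tibble::tibble()) > 0) {
      utils::write.csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  cfg <- report$config
  cfg_json <- list(
    n_subjects = cfg$n_subjects, n_voxels = cfg$n_voxels,
    roi_slopes = as.list(cfg$roi_slopes), extent = cfg$extent, n_px = cfg$n_px,
    mapping_px = cfg$mapping_px, stroke_width = cfg$stroke_width,
    noise_sd = cfg$noise_sd, imagery_gain = cfg$imagery_gain,
    imagery_noise_sd = cfg$imagery_noise_sd, fit_prfs = cfg$fit_prfs,
    selection_threshold = cfg$selection_threshold, n_perm = cfg$n_perm,
    seed = cfg$seed
  )
  jsonlite::write_json(cfg_json, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d subject(s), ROIs: %s\n",
              x$config$n_subjects, paste(unique(x$status$roi), collapse = ", ")))
  print(x$classification)
  invisible(x)
}

#' Generate a packaged synthetic dataset
#'
#' Convenience fixture builder: `"tiny"` gives one 200-voxel subject on
#' coarse rasters (for fast end-to-end checks), `"default"` six
#' 2000-voxel subjects at full raster resolution.  The trial structure
#' (4 imagery runs x 32 trials, 8 perception trials per letter) is the
#' same at both sizes.  A value checksum makes regeneration verifiable.
#'
#' @param size `"tiny"` or `"default"`.
#' @param seed Master seed.
#' @return A list with `subjects` (list of `imagery_session`), `letters`,
#'   `grid`, `size` and `checksum`.
#' @export
make_fixture <- function(size = c("tiny", "default"), seed = 1) {
  size <- match.arg(size)
  n_px <- if (size == "tiny") 64L else 150L
  n_vox <- if (size == "tiny") 200L else 2000L
  n_subj <- if (size == "tiny") 1L else 6L
  grid <- vf_grid(n_px, n_px, 10)
  letters <- letter_set(grid)
  hrf <- hrf_double_gamma(tr = 3)
  subjects <- purrr::map(seq_len(n_subj), function(s) {
    pop <- sample_population(n_vox, ecc_max = 5,
                             seed = derive_seed(seed, "fixture-pop", s))
    design <- session_design(seed = derive_seed(seed, "fixture-design", s))
    generate_session(pop, design, letters, hrf,
                     seed = derive_seed(seed, "fixture-session", s))
  })
  checksum <- sum(vapply(subjects, function(sub) {
    sum(vapply(sub$runs, function(m) sum(round(m, 6)), numeric(1)))
  }, numeric(1)))
  list(subjects = subjects, letters = letters, grid = grid, size = size,
       checksum = round(checksum, 4), seed = as.integer(seed))
}
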