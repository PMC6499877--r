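test_that("search-grid eccentricities follow the exponential-density map", {
  g <- prf_search_grid(ecc_max = 5, decay = 3)
  expect_equal(nrow(g$locations), 10000)
  ecc <- sort(unique(g$locations$ecc))
  expect_length(ecc, 100)
  k <- 1:100
  expect_equal(ecc, 5 * (exp(3 * k / 100) - 1) / (exp(3) - 1), tolerance = 1e-12)
  expect_true(all(diff(diff(ecc)) > 0))  # spacing strictly increasing
  expect_equal(max(ecc), 5)

  # decay -> 0 approaches uniform spacing
  g0 <- prf_search_grid(ecc_max = 5, decay = 1e-6, n_ecc = 50)
  ecc0 <- sort(unique(g0$locations$ecc))
  expect_equal(ecc0, seq(5 / 50, 5, length.out = 50), tolerance = 1e-4)

  # 10 slopes x 10000 locations = 100000 candidate models
  cand <- prfrecon:::search_candidates(g)
  expect_equal(nrow(cand), 100000)
  expect_true(all(diff(cand$ecc) >= 0))

  expect_error(prf_search_grid(-1), "positive")
  expect_error(prf_search_grid(5, decay = 0), "positive")
})

test_that("predicted time courses are linear in the frames and match the simulator", {
  g <- vf_grid(24, 24, 8)
  hrf <- fixture("hrf3")
  ap <- render_bar_apertures(g, seed = 1)
  prf <- list(x0 = 1, y0 = -0.5, sigma = 0.8)

  zero <- matrix(0, 24 * 24, 10)
  attr(zero, "grid") <- g
  expect_equal(predict_timecourse(prf, zero, hrf), rep(0, 10))

  tc1 <- predict_timecourse(prf, ap, hrf)
  ap2 <- ap * 2
  attr(ap2, "grid") <- g
  expect_equal(predict_timecourse(prf, ap2, hrf), 2 * tc1, tolerance = 1e-12)

  pop <- as_voxel_population(tibble::tibble(x0 = 1, y0 = -0.5, sigma = 0.8),
                             noise_sd = 0)
  sim <- simulate_run(pop, ap, hrf, noise_sd = 0, seed = 1, znorm = FALSE)
  expect_equal(unname(sim[1, ]), tc1, tolerance = 1e-10)
})

test_that("noiseless series generated on the grid are recovered exactly", {
  map_grid <- vf_grid(32, 32, 16)
  ap <- render_bar_apertures(map_grid, seed = 1)
  hrf <- fixture("hrf3")
  sg <- prf_search_grid(ecc_max = 8, n_angles = 16, n_ecc = 12)
  cand <- prfrecon:::search_candidates(sg)
  identifiable <- cand$slope * cand$ecc > sg$sigma_floor + 1e-9
  set.seed(5)
  idx <- sample(which(identifiable), 30)
  pop <- as_voxel_population(cand[idx, c("x0", "y0", "sigma", "slope")],
                             noise_sd = 0)
  ts <- simulate_run(pop, ap, hrf, noise_sd = 0, seed = 1)
  fits <- fit_prf(ts, ap, hrf, sg)
  expect_equal(fits$x0, pop$x0)
  expect_equal(fits$y0, pop$y0)
  expect_equal(fits$slope, pop$slope)
  expect_true(all(fits$score > 1 - 1e-9))

  # the winner's score agrees with an independent recomputation, and beats
  # random rival candidates
  for (vox in c(1, 17)) {
    r_win <- cor(predict_timecourse(fits[vox, ], ap, hrf), ts[vox, ])
    expect_equal(r_win, fits$score[vox], tolerance = 1e-9)
    set.seed(vox)
    rivals <- cand[sample(nrow(cand), 40), ]
    r_riv <- vapply(seq_len(40), function(i)
      cor(predict_timecourse(rivals[i, ], ap, hrf), ts[vox, ]), numeric(1))
    expect_true(all(r_riv <= r_win + 1e-9))
  }
})

test_that("off-grid ground truth is recovered within one grid cell", {
  map_grid <- vf_grid(32, 32, 16)
  ap <- render_bar_apertures(map_grid, seed = 2)
  hrf <- fixture("hrf3")
  sg <- prf_search_grid(ecc_max = 8, n_angles = 24, n_ecc = 16)
  ecc_levels <- sort(unique(sg$locations$ecc))
  set.seed(9)
  # mid-eccentricity truths nudged off the grid nodes
  base_k <- sample(6:14, 20, replace = TRUE)
  ecc <- ecc_levels[base_k] * runif(20, 0.98, 1.02)
  th <- runif(20, 0, 2 * pi)
  truth <- tibble::tibble(x0 = ecc * cos(th), y0 = ecc * sin(th),
                          sigma = pmax(0.4 * ecc, 0.1))
  pop <- as_voxel_population(truth, noise_sd = 0)
  ts <- simulate_run(pop, ap, hrf, noise_sd = 0, seed = 1)
  fits <- fit_prf(ts, ap, hrf, sg)
  # local grid spacing at the true eccentricity (radial and angular)
  spacing <- vapply(seq_len(20), function(i) {
    k <- findInterval(ecc[i], ecc_levels)
    radial <- ecc_levels[min(k + 1, length(ecc_levels))] -
      ecc_levels[max(k, 1)]
    angular <- ecc[i] * 2 * pi / 24
    sqrt(radial^2 + angular^2)
  }, numeric(1))
  d <- sqrt((fits$x0 - truth$x0)^2 + (fits$y0 - truth$y0)^2)
  expect_gte(mean(d <= spacing), 0.95)
})

test_that("constant observed series are flagged invalid", {
  map_grid <- vf_grid(24, 24, 10)
  ap <- render_bar_apertures(map_grid, seed = 1)
  sg <- prf_search_grid(ecc_max = 5, n_angles = 8, n_ecc = 6)
  ts <- rbind(rep(1, ncol(ap)),
              predict_timecourse(list(x0 = 1, y0 = 1, sigma = 1), ap, fixture("hrf3")))
  fits <- fit_prf(ts, ap, fixture("hrf3"), sg)
  expect_false(fits$valid[1])
  expect_true(is.na(fits$score[1]))
  expect_true(fits$valid[2])
  expect_error(fit_prf(ts[, 1:10], ap, fixture("hrf3"), sg), "frame count")
})

test_that("voxel selection filters by score with monotone retention", {
  fits <- tibble::tibble(
    voxel = 1:100, x0 = 0, y0 = 0, ecc = 0, sigma = 1, slope = 0.3,
    score = seq(0, 0.99, length.out = 100), valid = TRUE
  )
  fits$valid[1] <- FALSE
  expect_equal(nrow(select_voxels(fits, 0)), 99)  # all valid voxels kept
  kept <- vapply(c(0, 0.2, 0.5, 0.8), function(th) nrow(select_voxels(fits, th)),
                 numeric(1))
  expect_true(all(diff(kept) < 0))
  expect_equal(attr(select_voxels(fits, 0.5), "n_selected"), 50)
  expect_error(select_voxels(fits, 0.999), "lower the threshold")
})

test_that("encoding-matrix rows are unit-sum Gaussian profiles", {
  g <- vf_grid(16, 16, 10)
  prfs <- tibble::tibble(x0 = c(0, 2, -30), y0 = c(0, -1, 30),
                         sigma = c(3, 0.5, 0.5))
  w <- encoding_matrix(prfs, g)
  expect_true(all(w >= 0))
  expect_true(all(is.finite(w)))
  expect_equal(unname(rowSums(w)[1:2]), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(rowSums(w)[3]), 0)  # pRF entirely off the raster

  # independent per-pixel summation oracle for one voxel
  ax <- prfrecon:::grid_axes(g)
  oracle <- numeric(16 * 16)
  idx <- 1
  for (i in 1:16) {
    for (j in 1:16) {
      oracle[idx] <- exp(-((ax$x[j] - 2)^2 + (ax$y[i] + 1)^2) / (2 * 0.5^2))
      idx <- idx + 1
    }
  }
  oracle <- oracle / sum(oracle)
  expect_equal(unname(w[2, ]), oracle, tolerance = 1e-12)

  # a wide central Gaussian is nearly flat over the innermost pixels
  px <- pixel_centers(g)
  inner <- px$x^2 + px$y^2 <= 1
  expect_lt(max(w[1, inner]) / min(w[1, inner]), 1.2)
})

test_that("pRF-based predictions match the letter drive of the simulator", {
  g <- fixture("grid48")
  letters <- fixture("letters48")
  pop <- fixture("pop400")
  w <- fixture("w400")
  lv <- vectorize_image(unclass(letters$T))
  drive <- drop(unclass(w) %*% lv)
  # same overlap computed through the session generator's internals
  g2 <- prfrecon:::gaussian_rf_matrix(pop$x0, pop$y0, pop$sigma, g)
  expect_equal(drive, drop(g2 %*% lv), tolerance = 1e-12)
})
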