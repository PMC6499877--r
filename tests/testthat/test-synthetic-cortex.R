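test_that("the double-gamma HRF has a positive integral and peaks near 6 s", {
  h <- hrf_double_gamma(tr = 3)
  expect_gt(sum(h), 0)
  expect_equal(max(h), 1)
  expect_equal((which.max(h) - 1) * 3, 6)  # sampled peak at 6 s
  h1 <- hrf_double_gamma(tr = 1)
  expect_equal(which.max(h1) - 1, 6)
  expect_error(hrf_double_gamma(tr = 3, ratio = -1))
})

test_that("population sampling is seeded, validated, and follows the size-ecc relation", {
  pop <- sample_population(2000, ecc_max = 5, slope = 0.3, jitter_sd = 0, seed = 7)
  expect_equal(nrow(pop), 2000)
  expect_identical(
    unclass(sample_population(2000, ecc_max = 5, slope = 0.3, seed = 7))$x0,
    unclass(pop)$x0
  )
  # jitter 0 forces the deterministic relation
  expect_equal(pop$sigma, pmax(0.3 * pop$ecc, 0.1))

  # least-squares slope recovered from the generated parameters
  above_floor <- pop$sigma > 0.1
  fit <- lm(sigma ~ ecc, data = pop[above_floor, ])
  expect_equal(unname(coef(fit)["ecc"]), 0.3, tolerance = 1e-10)

  popj <- sample_population(3000, ecc_max = 5, slope = 0.3, jitter_sd = 0.05, seed = 8)
  fitj <- lm(sigma ~ ecc, data = popj[popj$sigma > 0.12, ])
  ci <- confint(fitj)["ecc", ]
  expect_gt(0.3, ci[1])
  expect_lt(0.3, ci[2])

  expect_error(sample_population(0), "positive count")
  expect_error(sample_population(10, slope = 0.05), "slope")
  expect_error(sample_population(10, slope = 1.2), "slope")
})

test_that("an impulse frame yields an HRF-shaped series and off-screen pRFs get no drive", {
  g <- vf_grid(24, 24, 8)
  hrf <- fixture("hrf3")
  pop <- as_voxel_population(
    tibble::tibble(x0 = c(0, 50), y0 = c(0, 50), sigma = c(1, 1)),
    noise_sd = 0
  )
  frames <- matrix(0, 24 * 24, 12)
  frames[, 1] <- 1  # full-field impulse at the first volume
  attr(frames, "grid") <- g
  ts <- simulate_run(pop, frames, hrf, noise_sd = 0, seed = 1, znorm = FALSE)
  kernel <- c(as.numeric(hrf), rep(0, 12))[1:12]
  # voxel 1: drive * HRF kernel exactly
  expect_equal(ts[1, ] / max(ts[1, ]), kernel / max(kernel), tolerance = 1e-9)
  # voxel 2 sits far outside every frame: zero drive
  expect_equal(unname(ts[2, ]), rep(0, 12))

  # with noise, the off-screen voxel carries pure noise at unit variance after z-norm
  tsn <- simulate_run(pop, frames, hrf, noise_sd = 0.5, seed = 2)
  expect_equal(mean(tsn[2, ]), 0, tolerance = 1e-9)
  expect_equal(sd(tsn[2, ]), 1, tolerance = 1e-9)
})

test_that("grid mismatches between frames and expectations are rejected", {
  g <- vf_grid(24, 24, 8)
  frames <- matrix(0, 100, 5)  # wrong pixel count
  attr(frames, "grid") <- g
  pop <- fixture("pop400")
  expect_error(simulate_run(pop, frames, fixture("hrf3")), "24 x 24")
  expect_error(simulate_run(pop, matrix(0, 10, 5), fixture("hrf3")), "grid")
})

test_that("session designs keep exact per-letter trial bookkeeping", {
  d <- fixture("design1")
  img <- d[d$condition == "imagery", ]
  expect_equal(nrow(img), 4 * 32)
  counts <- table(img$run, img$letter)
  expect_true(all(counts == 8))
  perc <- d[d$condition == "perception", ]
  expect_true(all(table(perc$letter) == 8))
  # onsets strictly increasing within each run
  for (r in unique(img$run)) {
    expect_true(all(diff(img$onset[img$run == r]) > 0))
  }
  expect_identical(
    unclass(session_design(seed = 7))$onset, unclass(d)$onset
  )
})

test_that("imagery drive is an attenuated copy of perception and vanishes at gain 0", {
  g <- vf_grid(32, 32, 10)
  letters <- letter_set(g)
  hrf <- fixture("hrf3")
  design <- session_design(seed = 2)
  set.seed(1)
  base <- tibble::tibble(x0 = runif(40, -4, 4), y0 = runif(40, -4, 4),
                         sigma = rep(1, 40))
  pop0 <- as_voxel_population(base, noise_sd = 0, imagery_gain = 0,
                              imagery_noise_sd = 0)
  ses0 <- generate_session(pop0, design, letters, hrf, seed = 3)
  expect_true(all(ses0$runs$imagery_1 == 0))  # no drive, no noise
  expect_gt(max(abs(ses0$runs$perception)), 0)

  # missing letter raster is rejected
  expect_error(generate_session(pop0, design, letters[c("H", "T")], hrf),
               "missing letter")
})

test_that("raising imagery noise never improves expected reconstruction quality", {
  g <- vf_grid(32, 32, 10)
  letters <- letter_set(g)
  hrf <- fixture("hrf3")
  noise_levels <- c(0.5, 2, 6)
  mean_r <- vapply(seq_along(noise_levels), function(li) {
    rs <- vapply(1:20, function(rep) {
      pop <- sample_population(80, ecc_max = 5, imagery_noise_sd = noise_levels[li],
                               seed = 1000 + rep)
      ses <- generate_session(pop, session_design(seed = 2000 + rep), letters, hrf,
                              seed = 3000 + li * 100 + rep)
      pset <- extract_trial_patterns(ses)
      avg <- average_letter_patterns(pset, "imagery")
      w <- encoding_matrix(pop, g)
      x <- reconstruct(projection_matrix(w), pattern_matrix(avg))
      mean(vapply(1:4, function(i) first_level_r(x[, i], letters[[avg$letter[i]]]),
                  numeric(1)))
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_r) < 0))
})
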