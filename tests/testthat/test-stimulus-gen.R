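test_that("grid calibration places symmetric pixel centres at the stated resolution", {
  g <- vf_grid(150, 150, 10)
  expect_equal(g$deg_per_px, 10 / 150)
  px <- pixel_centers(g)
  expect_equal(nrow(px), 150 * 150)
  # symmetric about fixation
  expect_equal(sum(px$x), 0, tolerance = 1e-9)
  expect_equal(sum(px$y), 0, tolerance = 1e-9)
  expect_equal(max(px$x), -min(px$x))
})

test_that("vectorization is row-major and round-trips exactly", {
  g <- vf_grid(150, 150, 10)
  expect_length(vectorize_image(matrix(0, 150, 150)), 22500)
  expect_equal(vectorize_image(matrix(0, 3, 3)), rep(0, 9))

  m <- matrix(1:6, 2, 3, byrow = TRUE)
  expect_equal(vectorize_image(m), 1:6)  # rows concatenated in order

  g2 <- vf_grid(20, 20, 5)
  for (seed in 1:5) {
    set.seed(seed)
    img <- matrix(rbinom(400, 1, 0.3), 20, 20)
    expect_identical(devectorize_image(vectorize_image(img), g2), img)
  }
  expect_error(devectorize_image(rep(0, 10), g2), "reshaped")
})

test_that("letter T is a top bar plus a central vertical bar", {
  g <- vf_grid(60, 60, 10)
  img <- render_letter("T", g, stroke_width = 1.2)
  px <- pixel_centers(g)
  on <- vectorize_image(unclass(img)) == 1
  expect_gt(sum(on), 0)
  top_bar <- px$y[on] >= 4 - 1.2 & abs(px$x[on]) <= 4
  vertical <- abs(px$x[on]) <= 0.6
  expect_true(all(top_bar | vertical))
  # both strokes actually present
  expect_gt(sum(top_bar & !vertical), 0)
  expect_gt(sum(vertical & px$y[on] < 0), 0)
})

test_that("letter H matches a brute-force point-in-stroke rasterization", {
  g <- vf_grid(30, 30, 10)
  sw <- 1.0
  img <- render_letter("H", g, stroke_width = sw)
  ax <- prfrecon:::grid_axes(g)
  oracle <- matrix(0, 30, 30)
  for (i in 1:30) {
    for (j in 1:30) {
      x <- ax$x[j]
      y <- ax$y[i]
      left <- x >= -4 && x <= -4 + sw && abs(y) <= 4
      right <- x >= 4 - sw && x <= 4 && abs(y) <= 4
      cross <- x > -4 + sw && x < 4 - sw && abs(y) <= sw / 2
      if (left || right || cross) oracle[i, j] <- 1
    }
  }
  expect_equal(unclass(img), oracle, ignore_attr = TRUE)
  expect_equal(sum(img), sum(oracle))
})

test_that("invalid letter requests are rejected with the offending id", {
  g <- fixture("grid48")
  expect_error(render_letter("X", g), "X")
  expect_error(render_letter("H", g, stroke_width = 9), "stroke_width")
  expect_error(render_letter("H", g, stroke_width = 0), "stroke_width")
})

test_that("letter rasters are binary, non-empty, distinct, and inside the guide box", {
  g <- fixture("grid48")
  letters <- fixture("letters48")
  px <- pixel_centers(g)
  half <- 4 + g$deg_per_px / 2
  for (l in letters) {
    v <- vectorize_image(unclass(l))
    expect_true(all(v %in% c(0, 1)))
    expect_gt(sum(v), 0)
    expect_true(all(abs(px$x[v == 1]) <= half))
    expect_true(all(abs(px$y[v == 1]) <= half))
  }
  cm <- cor(sapply(letters, function(l) vectorize_image(unclass(l))))
  off_diag <- cm[upper.tri(cm)]
  expect_true(all(off_diag < 1))
  expect_equal(length(off_diag), 6)
})

test_that("bar apertures form 288 seeded frames of the stated band width", {
  g <- fixture("grid48")
  ap <- render_bar_apertures(g, seed = 3)
  expect_equal(ncol(ap), 4 * 12 * 6)
  expect_true(all(ap %in% c(0, 1)))
  expect_identical(unclass(render_bar_apertures(g, seed = 3)), unclass(ap))
  expect_false(identical(attr(render_bar_apertures(g, seed = 4), "sequence"),
                         attr(ap, "sequence")))

  # band width in pixels for cardinal orientations
  seq_tbl <- attr(ap, "sequence")
  expected_px <- round(1.33 / g$deg_per_px)
  for (f in which(seq_tbl$orientation == 0)[1:3]) {
    img <- devectorize_image(ap[, f], g)
    band_px <- sum(rowSums(img) > 0)   # orientation 0 = horizontal band
    expect_lte(abs(band_px - expected_px), 1)
  }
})

test_that("step order is a randomized permutation within each orientation block", {
  ap <- render_bar_apertures(fixture("grid48"), seed = 5)
  seq_tbl <- attr(ap, "sequence")
  blocks <- split(seq_tbl$step, list(seq_tbl$orientation, seq_tbl$repetition))
  expect_length(blocks, 24)
  for (b in blocks) expect_setequal(b, 1:12)
  # at least one block is not in sorted order
  expect_true(any(vapply(blocks, function(b) !all(b == sort(b)), logical(1))))
})

test_that("the union of steps at each orientation covers every pixel", {
  g <- vf_grid(40, 40, 10)
  ap <- render_bar_apertures(g, seed = 1)
  seq_tbl <- attr(ap, "sequence")
  for (ori in unique(seq_tbl$orientation)) {
    cols <- seq_tbl$frame[seq_tbl$orientation == ori & seq_tbl$repetition == 1]
    covered <- rowSums(ap[, cols, drop = FALSE]) > 0
    expect_true(all(covered), label = sprintf("coverage at %d deg", ori))
  }
})

test_that("rasters export to PNG with a JSON sidecar", {
  path <- file.path(tempdir(), "letter.png")
  on.exit(unlink(c(path, paste0(path, ".json"))))
  write_image_png(unclass(fixture("letters48")$H), path, grid = fixture("grid48"),
                  meta = list(letter = "H"))
  expect_true(file.exists(path))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$letter, "H")
  expect_equal(side$extent_deg, 10)
})
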