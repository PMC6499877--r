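test_that("outdegree is the column mass of the encoding matrix", {
  w <- fixture("w400")
  d <- outdegree(w)
  expect_length(d, ncol(w))
  expect_true(all(d > 0))
  # explicit per-column summation oracle
  oracle <- numeric(ncol(w))
  for (j in seq_len(ncol(w))) oracle[j] <- sum(w[, j])
  floored <- attr(d, "floored")
  keep <- setdiff(seq_len(ncol(w)), floored)
  expect_equal(as.numeric(d)[keep], oracle[keep], tolerance = 1e-12)
  # unit-sum rows conserve total mass: trace(D) ~ v (up to the floor term)
  expect_equal(sum(oracle), sum(rowSums(w)), tolerance = 1e-9)

  # pixels outside every pRF get the epsilon floor
  g <- vf_grid(16, 16, 10)
  w2 <- encoding_matrix(tibble::tibble(x0 = 4, y0 = 4, sigma = 0.2), g)
  d2 <- outdegree(w2)
  expect_gt(length(attr(d2, "floored")), 0)
  expect_equal(unname(as.numeric(d2)[attr(d2, "floored")[1]]),
               1e-6 * max(d2))

  dc <- outdegree(w, mode = "count", count_threshold = 1e-4)
  keepc <- setdiff(seq_len(ncol(w)), attr(dc, "floored"))
  expect_true(all(as.numeric(dc)[keepc] == round(as.numeric(dc)[keepc])))
})

test_that("the identity encoding model halves its input (closed form)", {
  g <- vf_grid(2, 2, 2)
  w <- manual_encoding_matrix(diag(4), g)
  proj <- projection_matrix(w, lambda = 1)   # D = colSums = 1
  expect_equal(proj$lambda, 1)
  y <- c(1, -2, 3, 0.5)
  x <- reconstruct(proj, y)
  expect_equal(vectorize_image(unclass(x)), y / 2, tolerance = 1e-12)
  # trace balance gives the same here: tr(W'W) = tr(D) = 4
  expect_equal(projection_matrix(w)$lambda, 1)
})

test_that("the factored projection satisfies its defining normal equations", {
  set.seed(12)
  g <- vf_grid(3, 4, 4)
  w <- manual_encoding_matrix(matrix(runif(6 * 12), 6, 12), g)
  d <- outdegree(w)
  proj <- projection_matrix(w, d)
  wvf <- as.matrix(proj)
  lhs <- (crossprod(w) + diag(proj$lambda * as.numeric(d))) %*% wvf
  rhs <- t(unclass(w))
  expect_lt(norm(lhs - rhs, "F"), 1e-8 * norm(rhs, "F"))

  # Woodbury solve equals the direct dense inverse
  direct <- solve(crossprod(w) + diag(proj$lambda * as.numeric(d)), t(unclass(w)))
  expect_equal(wvf, direct, tolerance = 1e-9)
})

test_that("reconstruction equals the minimiser found by an iterative solver", {
  set.seed(13)
  g <- vf_grid(3, 4, 4)
  w <- manual_encoding_matrix(matrix(runif(8 * 12), 8, 12), g)
  d <- outdegree(w)
  proj <- projection_matrix(w, d)
  y <- rnorm(8)
  x_pkg <- reconstruct(proj, matrix(y, ncol = 1))[, 1]
  dd <- proj$lambda * as.numeric(d)
  obj <- function(x) sum((y - unclass(w) %*% x)^2) + sum(dd * x^2)
  grd <- function(x) -2 * drop(crossprod(unclass(w), y - unclass(w) %*% x)) + 2 * dd * x
  opt <- optim(rep(0, 12), obj, grd, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(x_pkg, opt$par, tolerance = 1e-5)
})

test_that("reconstruction is linear and validates its input", {
  proj <- fixture("proj400")
  y1 <- rnorm(400)
  y2 <- rnorm(400)
  expect_equal(max(abs(reconstruct(proj, rep(0, 400)))), 0)
  lin <- reconstruct(proj, 2 * y1 - 3 * y2)
  expect_equal(unclass(lin),
               unclass(2 * reconstruct(proj, y1) - 3 * reconstruct(proj, y2)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(reconstruct(proj, rnorm(10)), "400")
})

test_that("stronger regularisation never enlarges the reconstruction", {
  w <- fixture("w400")
  d <- outdegree(w)
  set.seed(14)
  y <- rnorm(400)
  base <- projection_matrix(w, d)$lambda
  norms <- vapply(base * c(1, 2, 5, 20), function(l) {
    sqrt(sum(reconstruct(projection_matrix(w, d, lambda = l), y)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("first-level quality is an exact Pearson correlation", {
  letters <- fixture("letters48")
  t_img <- letters$T
  expect_equal(first_level_r(t_img, t_img), 1)
  neg <- structure(-unclass(t_img), grid = attr(t_img, "grid"),
                   class = class(t_img))
  expect_equal(first_level_r(neg, t_img), -1)

  set.seed(15)
  x <- rnorm(48 * 48)
  lv <- vectorize_image(unclass(t_img))
  oracle <- sum((x - mean(x)) * (lv - mean(lv))) /
    sqrt(sum((x - mean(x))^2) * sum((lv - mean(lv))^2))
  expect_equal(first_level_r(x, t_img), oracle, tolerance = 1e-12)
  expect_error(first_level_r(rep(1, 48 * 48), t_img), "constant")
})

test_that("second-level quality compares the two 6-element pairwise vectors", {
  letters <- fixture("letters48")
  ident <- lapply(letters, identity)
  r <- second_level_r(ident, letters)
  expect_equal(as.numeric(r), 1)
  expect_length(attr(r, "pairwise_letters"), 6)
  expect_length(attr(r, "pairwise_recons"), 6)

  # independent-noise reconstructions carry no similarity structure
  set.seed(16)
  rs <- vapply(1:200, function(i) {
    noise <- matrix(rnorm(48 * 48 * 4), ncol = 4)
    as.numeric(second_level_r(noise, letters))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.12)

  expect_error(second_level_r(ident[1:3], letters), "reconstruction|letter")
  expect_error(second_level_r(ident, letters[1:3]), "H, T, S, C")
})
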