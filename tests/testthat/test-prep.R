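test_that("inclusion filter keeps metabolites at or above the nonmissing threshold", {
  # 60 metabolites, 18 with > 50% missing: the filter keeps 42
  n <- 100
  vals <- with_test_seed(3, matrix(exp(rnorm(n * 60)), n, 60))
  dimnames(vals) <- list(sprintf("S%03d", 1:n), sprintf("met%02d", 1:60))
  for (j in 43:60) vals[sample.int(n, 55), j] <- NA   # 55% missing
  panel <- metabolite_panel(vals, state = "raw")
  kept <- filter_metabolites(panel, 0.5)
  expect_equal(ncol(kept$values), 42L)
  expect_identical(colnames(kept$values), colnames(vals)[1:42])

  # boundary: measured in exactly 50% of samples -> retained (inclusive)
  vb <- vals[, 1:2, drop = FALSE]
  vb[1:(n / 2), 2] <- NA
  pb <- filter_metabolites(metabolite_panel(vb, state = "raw"), 0.5)
  expect_equal(ncol(pb$values), 2L)

  # no missingness -> identity
  pc <- filter_metabolites(metabolite_panel(vals[, 1:10], state = "raw"), 0.5)
  expect_identical(pc$values, vals[, 1:10])

  # zeros count as missing quantifications
  vz <- vals[, 1:2]
  vz[1:60, 2] <- 0
  pz <- filter_metabolites(metabolite_panel(vz, state = "raw"), 0.5)
  expect_equal(colnames(pz$values), colnames(vz)[1])
})

test_that("dilution estimation reproduces exact scalar dilution factors", {
  profile <- c(2, 0.5, 1.2, 4, 0.1)
  cvec <- c(0.5, 1, 1.5, 2, 0.8, 1.1)
  vals <- outer(cvec, profile)
  p <- log_transform(metabolite_panel(vals, state = "raw"))
  d <- estimate_dilution(p)
  expect_equal(unname(d$log_dilution), log(cvec) - median(log(cvec)),
               tolerance = 1e-12)

  # all samples identical -> all dilutions zero
  p2 <- log_transform(metabolite_panel(outer(rep(1, 5), profile), state = "raw"))
  expect_equal(unname(estimate_dilution(p2)$log_dilution), rep(0, 5))
})

test_that("dilution estimate matches hand-computed median quotients on a toy matrix", {
  v <- matrix(c(1.0, 2.0, 0.5, 4.0,
                2.0, 4.0, 1.0, 8.0,
                1.5, 1.0, 0.7, 3.0,
                0.8, 2.5, 0.4, 5.0,
                1.1, 2.2, 0.6, 4.4), 5, 4, byrow = TRUE)
  p <- log_transform(metabolite_panel(v, state = "raw"))
  got <- estimate_dilution(p)
  # hand computation: per-metabolite median log, then per-sample median deviation
  lv <- log(v)
  ref <- apply(lv, 2, median)
  expected <- apply(lv, 1, function(r) median(r - ref))
  expect_equal(unname(got$log_dilution), expected)
  expect_equal(unname(got$reference), unname(ref))

  # sample with too few usable metabolites is flagged
  v2 <- v
  v2[1, 1:2] <- NA
  p2 <- log_transform(metabolite_panel(v2, state = "raw"))
  expect_warning(d2 <- estimate_dilution(p2, min_metabolites = 3L), "flagged|missing")
  expect_false(anyNA(d2$log_dilution[-1]))
  expect_true(is.na(d2$log_dilution[1]))
})

test_that("restricted cubic spline basis has k-1 columns and linear tails", {
  x <- with_test_seed(5, rnorm(500))
  B <- rcs_basis(x, n_knots = 4L, name = "x")
  expect_equal(ncol(B), 3L)
  expect_equal(length(attr(B, "knots")), 4L)

  # beyond the outer knots the basis is linear: second differences vanish
  kn <- attr(B, "knots")
  grid_hi <- seq(kn[4] + 0.5, kn[4] + 3, length.out = 30)
  grid_lo <- seq(kn[1] - 3, kn[1] - 0.5, length.out = 30)
  for (grid in list(grid_hi, grid_lo)) {
    Bg <- rcs_basis(grid, knots = kn, name = "x")
    for (j in seq_len(ncol(Bg)))
      expect_lt(max(abs(diff(diff(Bg[, j])))), 1e-8)
  }

  # data linear in x: the fitted spline regression reproduces the line
  y <- 2 + 3 * x
  fit <- lm(y ~ B)
  expect_lt(max(abs(fitted(fit) - y)), 1e-9)
  expect_lt(max(abs(coef(fit)[3:4])), 1e-9)

  # degenerate distribution -> error naming the variable
  expect_error(rcs_basis(rep(1, 100), n_knots = 4L, name = "weird"), "weird")
})

test_that("regression-based normalisation removes planted dilution structure", {
  n <- 400; m <- 8
  base <- with_test_seed(11, matrix(rnorm(n * m, 0, 0.4), n, m))
  d <- with_test_seed(12, rnorm(n, 0, 0.5))
  kappa <- seq(-0.3, 0.3, length.out = m)
  lv <- base + outer(d, rep(1, m)) + sweep(outer(d^2, rep(1, m)), 2, kappa, "*")
  rownames(lv) <- sprintf("S%03d", seq_len(n))
  panel <- metabolite_panel(lv, state = "log")
  dil <- dilution_estimate(setNames(d, rownames(lv)))

  np <- normalise_regression_based(panel, dil)
  expect_identical(np$state, "normalised")
  # residual correlation with the dilution is numerically zero
  for (j in seq_len(m))
    expect_lt(abs(cor(np$values[, j], d)), 1e-6)
  # recovery of the dilution-free truth up to a per-metabolite constant
  err <- np$values - base
  expect_lt(max(apply(err, 2, sd)), 0.08)

  # idempotence: renormalising changes values by < 1e-8
  np2 <- normalise_regression_based(metabolite_panel(np$values, state = "log"), dil)
  expect_lt(max(abs(np2$values - np$values)), 1e-8)

  # dilution identically zero -> output equals input
  dil0 <- dilution_estimate(setNames(rep(0, n), rownames(lv)))
  np0 <- normalise_regression_based(panel, dil0)
  expect_identical(np0$values, panel$values)
})

test_that("normalisation reduces to subtractive PQN in the exact linear limit", {
  # common unit slope, no noise: normalised value = log conc - dilution
  n <- 200; m <- 5
  base <- matrix(rep(c(1, 2, 0.5, -1, 0.3), each = n), n, m)
  d <- with_test_seed(13, rnorm(n, 0, 0.5))
  lv <- base + d
  rownames(lv) <- paste0("S", seq_len(n))
  np <- normalise_regression_based(metabolite_panel(lv, state = "log"),
                                   dilution_estimate(setNames(d, rownames(lv))))
  expect_equal(unname(np$values), unname(lv - d), tolerance = 1e-9)
})

test_that("metabolites with few usable samples fall back to a linear dilution fit", {
  n <- 25  # below 10 * n_knots
  d <- with_test_seed(14, rnorm(n, 0, 0.5))
  lv <- matrix(1 + d + rnorm(n, 0, 0.01), n, 1)
  rownames(lv) <- paste0("S", seq_len(n))
  np <- normalise_regression_based(metabolite_panel(lv, state = "log"),
                                   dilution_estimate(setNames(d, rownames(lv))))
  expect_identical(attr(np, "report")[[1]]$fit, "linear")
})

test_that("k-SD outlier rule masks exactly the extreme cells in a single pass", {
  # one point sitting between 4 and 5 SD of the full sample (a single
  # outlier cannot exceed (n-1)/sqrt(n) SD, so the base must be large)
  x <- c(seq(-1.5, 1.5, length.out = 59), 5.0)
  dev <- abs(x - mean(x)) / sd(x)
  stopifnot(dev[60] > 4, dev[60] < 5, max(dev[-60]) < 2)
  v <- matrix(x, ncol = 1, dimnames = list(paste0("S", 1:60), "m1"))
  p <- exclude_outliers(metabolite_panel(v, state = "normalised"), 4)
  expect_identical(unname(p$mask[, 1]), dev > 4)
  expect_equal(sum(p$mask), 1L)
  expect_true(p$mask["S60", 1])
  # values themselves are untouched, only membership changes
  expect_identical(p$values, v)

  # same shape with the extreme point pulled to ~3.5 SD: nothing masked
  x2 <- x; x2[60] <- 3.8
  stopifnot(max(abs(x2 - mean(x2)) / sd(x2)) < 4)
  p2 <- exclude_outliers(metabolite_panel(matrix(x2, ncol = 1), state = "normalised"), 4)
  expect_equal(sum(p2$mask), 0L)

  # constant vector: SD = 0, no exclusions
  p3 <- exclude_outliers(metabolite_panel(matrix(1, 10, 1), state = "normalised"), 4)
  expect_equal(sum(p3$mask), 0L)
})

test_that("panel state machine enforces processing order", {
  p <- toy_panel()
  expect_error(estimate_dilution(p), "log state")
  expect_error(exclude_outliers(p), "normalised state")
  expect_error(log_transform(log_transform(p)), "raw state")
  expect_error(metabolite_panel(matrix(-1, 2, 2), state = "raw"), "nonnegative")
})
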