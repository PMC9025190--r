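test_that("Benjamini-Hochberg q-values match the step-up rule", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.37), 0.37)
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")

  # brute-force step-up: q_i = min over p_(j) >= p_(i) of p_(j) m / j
  brute <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  for (s in 1:25) {
    p <- with_test_seed(s, runif(sample(2:40, 1))^2)
    q <- fdr_bh(p)
    expect_equal(q, brute(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("covariate designs have the documented column structure", {
  co <- default_cohort()$cohort
  basic <- covariate_design(co$covariates, "basic")
  # rcs(age): 3, sex: 1, age x sex: 1, rcs(waist): 3
  expect_equal(ncol(basic), 8L)
  full <- covariate_design(co$covariates, "full")
  # + smoking, hypertonia, hba1c, education, rcs(egfr): 3, urine_ph, alcohol
  expect_equal(ncol(full), 17L)
  expect_error(covariate_design(co$covariates[, c("age", "sex")], "basic"),
               "waist")

  y <- setNames(rnorm(nrow(co$covariates)), rownames(co$covariates))
  x <- setNames(rnorm(nrow(co$covariates)), rownames(co$covariates))
  fr <- build_frame(y, x, co$covariates, tier = "basic")
  expect_equal(ncol(fr$X), 9L)  # predictor + 8 covariate columns
  expect_equal(length(fr$y), nrow(co$covariates))  # no missingness: full n

  # a sample missing urinary pH is dropped in the full tier only
  cov2 <- co$covariates
  cov2$urine_ph[3] <- NA
  frb <- build_frame(y, x, cov2, tier = "basic")
  frf <- build_frame(y, x, cov2, tier = "full")
  expect_equal(length(frb$y), nrow(cov2))
  expect_equal(length(frf$y), nrow(cov2) - 1L)
  expect_false(rownames(cov2)[3] %in% frf$sample_ids)

  expect_error(build_frame(y, setNames(rep(1, length(x)), names(x)),
                           co$covariates), "constant")
})

test_that("mixed-model fit reduces to least squares when batch variance is absent", {
  co <- default_cohort()$cohort
  n <- nrow(co$covariates)
  x <- setNames(rnorm(n), rownames(co$covariates))
  y <- setNames(0.4 * x + rnorm(n, 0, 0.5), rownames(co$covariates))

  fr <- build_frame(y, x, co$covariates, tier = "basic")
  got <- fit_lmm(fr)
  ref <- ols_coefs(cbind(1, fr$X), fr$y)
  expect_equal(got$b, unname(ref[2]), tolerance = 1e-6)
  expect_true(got$ci_low <= got$b && got$b <= got$ci_high)
  expect_true(got$converged)

  # single batch falls back to OLS with a warning
  cov1 <- co$covariates
  cov1$batch <- "B01"
  fr1 <- build_frame(y, x, cov1, tier = "basic")
  expect_warning(got1 <- fit_lmm(fr1), "OLS")
  expect_equal(got1$b, unname(ref[2]), tolerance = 1e-6)
})

test_that("mixed-model slope recovery under genuine batch structure", {
  # direct simulation: n = 400, 8 batches, batch SD 0.5, slope 0.4
  n <- 400
  reps <- 40
  hits <- ok3se <- 0
  for (s in seq_len(reps)) {
    dat <- with_test_seed(1000 + s, {
      batch <- sample(rep_len(sprintf("B%02d", 1:8), n))
      x <- rnorm(n)
      off <- setNames(rnorm(8, 0, 0.5), sprintf("B%02d", 1:8))
      age <- rnorm(n, 50, 10); sex <- rbinom(n, 1, 0.5); waist <- rnorm(n, 88, 12)
      y <- 0.4 * x + off[batch] + rnorm(n)
      ids <- sprintf("S%03d", 1:n)
      list(covs = data.frame(age = age, sex = sex, waist = waist, batch = batch,
                             row.names = ids),
           x = setNames(x, ids), y = setNames(y, ids))
    })
    fr <- build_frame(dat$y, dat$x, dat$covs, tier = "basic")
    r <- fit_lmm(fr)
    if (abs(r$b - 0.4) < 3 * r$se) ok3se <- ok3se + 1
    if (r$ci_low <= 0.4 && 0.4 <= r$ci_high) hits <- hits + 1
  }
  expect_gte(ok3se / reps, 0.95)
  expect_gte(hits / reps, 0.85)   # coarse here; tight coverage is asserted at scale
})

test_that("presence-mode coefficients equal the adjusted group difference", {
  co <- default_cohort()$cohort
  pr <- default_cohort()$prep
  vals <- panel_values(pr$panel)
  pres <- setNames(as.numeric(unclass(co$abundance)[, "genus_20"] > 0),
                   rownames(co$abundance))
  cov1 <- co$covariates
  cov1$batch <- "B01"  # single batch: the fit is plain least squares
  fr <- build_frame(vals[, "succinate"], pres, cov1, tier = "basic")
  got <- suppressWarnings(fit_lmm(fr))
  ref <- ols_coefs(cbind(1, fr$X), fr$y)
  expect_equal(got$b, unname(ref[2]), tolerance = 1e-8)
})

test_that("the abundance screen recovers planted effects and re-tests them fully adjusted", {
  fix <- default_cohort()
  co <- fix$cohort
  sc <- suppressWarnings(run_screen(fix$prep$panel, co$abundance, co$covariates,
                                    mode = "abundance"))
  basic <- sc[sc$tier == "basic", ]
  et <- co$truth$effect_table
  planted <- paste(sprintf("genus_%02d", et$genus),
                   colnames(co$panel$values)[et$metabolite])
  found <- paste(basic$predictor, basic$response)[!is.na(basic$q) & basic$q < 0.05]
  expect_true(all(planted %in% found))
  # significant pairs reappear as full-tier rows with stable signs
  full <- sc[sc$tier == "full", ]
  expect_true(all(found %in% paste(full$predictor, full$response)))
  m <- merge(basic, full, by = c("predictor", "response"))
  expect_true(all(sign(m$b.x[paste(m$predictor, m$response) %in% planted]) ==
                  sign(m$b.y[paste(m$predictor, m$response) %in% planted])))
})

test_that("screen results are invariant to input row order", {
  fix <- default_cohort()
  co <- fix$cohort
  pan <- fix$prep$panel
  perm <- with_test_seed(2, sample(nrow(co$covariates)))
  pan2 <- metabolite_panel(pan$values[perm, ], state = "normalised",
                           mask = pan$mask[perm, ])
  tab2 <- abundance_table(unclass(co$abundance)[perm, ],
                          depth = attr(co$abundance, "depth"))
  a <- suppressWarnings(run_screen(pan, co$abundance, co$covariates,
                                   mode = "presence", check_nonlinearity = FALSE))
  b <- suppressWarnings(run_screen(pan2, tab2, co$covariates[perm, ],
                                   mode = "presence", check_nonlinearity = FALSE))
  a <- a[order(a$tier, a$predictor, a$response), ]
  b <- b[order(b$tier, b$predictor, b$response), ]
  expect_equal(a$b, b$b, tolerance = 1e-8)
  expect_equal(a$p, b$p, tolerance = 1e-6)
})

test_that("the diversity screen finds the diversity-driven metabolite", {
  fix <- default_cohort()
  co <- fix$cohort
  sc <- suppressWarnings(run_screen(fix$prep$panel, co$abundance, co$covariates,
                                    mode = "diversity"))
  basic <- sc[sc$tier == "basic", ]
  hip <- basic[basic$predictor == "shannon" & basic$response == "hippurate", ]
  expect_lt(hip$q, 0.05)
  expect_gt(hip$b, 0)
  expect_true("p_nonlinear" %in% names(basic))
})

test_that("bootstrap p-values behave in the exact and null limits", {
  co <- default_cohort()$cohort
  n <- nrow(co$covariates)
  ids <- rownames(co$covariates)
  cov1 <- co$covariates
  cov1$batch <- "B01"

  # exact linear relation: bootstrap SE collapses, p ~ 0
  x <- setNames(rnorm(n), ids)
  fr <- build_frame(setNames(2 * x, ids), x, cov1, tier = "basic")
  bp <- suppressWarnings(bootstrap_p(fr, n_rep = 150, seed = 4, engine = "ols"))
  expect_lt(bp$boot_se, 1e-8)
  expect_equal(bp$p, 0)

  # null simulation: bootstrap p agrees with the model p
  y <- setNames(rnorm(n), ids)
  frn <- build_frame(y, x, cov1, tier = "basic")
  ref <- suppressWarnings(fit_lmm(frn))
  bpn <- suppressWarnings(bootstrap_p(frn, n_rep = 400, seed = 5, engine = "ols"))
  expect_lt(abs(bpn$p - ref$p), 0.15)
  # determinism
  bpn2 <- suppressWarnings(bootstrap_p(frn, n_rep = 400, seed = 5, engine = "ols"))
  expect_identical(bpn$p, bpn2$p)

  # heavy-tailed predictor with a real effect stays significant
  xh <- setNames(exp(rnorm(n, 0, 1.2)), ids)
  yh <- setNames(0.25 * xh + rnorm(n), ids)
  frh <- build_frame(yh, xh, cov1, tier = "basic")
  refh <- suppressWarnings(fit_lmm(frh))
  expect_lt(refh$p, 1e-4)
  bph <- suppressWarnings(bootstrap_p(frh, n_rep = 400, seed = 6, engine = "ols"))
  expect_lt(bph$p, 0.05)
})

test_that("screens can attach bootstrap sensitivity p-values to re-tested pairs", {
  fix <- default_cohort()
  co <- fix$cohort
  sc <- suppressWarnings(run_screen(fix$prep$panel, co$abundance, co$covariates,
                                    mode = "diversity", check_nonlinearity = FALSE,
                                    boot = 100L, boot_seed = 7L))
  expect_true("boot_p" %in% names(sc))
  full <- sc[sc$tier == "full", ]
  basic <- sc[sc$tier == "basic", ]
  expect_true(all(is.na(basic$boot_p)))
  expect_true(all(!is.na(full$boot_p)))
  # the strongly planted diversity association stays significant under the
  # bootstrap recalculation
  hip <- full[full$predictor == "shannon" & full$response == "hippurate", ]
  expect_lt(hip$boot_p, 0.05)
})
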