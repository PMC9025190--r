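test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(n_samples = 4, n_batches = 8), "n_samples < n_batches")
  expect_error(sim_config(noise_sd = -1), "SDs")
  expect_error(sim_config(mediation_fraction = 1.6), "mediation_fraction")
  expect_error(sim_config(effect_table = data.frame(genus = 99, metabolite = 1,
                                                    slope = 1)),
               "effect index out of range")
  expect_error(sim_config(focal_metabolite = 0), "out of range")
})

test_that("the generator is deterministic under its seed", {
  a <- simulate_cohort(sim_config(n_samples = 60, seed = 5))
  b <- simulate_cohort(sim_config(n_samples = 60, seed = 5))
  c <- simulate_cohort(sim_config(n_samples = 60, seed = 6))
  expect_identical(unclass(a$abundance), unclass(b$abundance))
  expect_identical(a$panel$values, b$panel$values)
  expect_identical(a$markers, b$markers)
  expect_identical(a$truth$log_dilution, b$truth$log_dilution)
  expect_false(identical(unclass(a$abundance), unclass(c$abundance)))
})

test_that("compositional structure: counts at depth, proportions at one", {
  co <- default_cohort()$cohort
  expect_true(all(rowSums(co$abundance) == co$config$read_depth))
  expect_lt(max(abs(rowSums(co$truth$relative_abundance_true) - 1)), 1e-12)
  expect_true(all(unclass(co$abundance) >= 0))
  # raw concentrations nonnegative where present
  expect_true(all(co$panel$values >= 0, na.rm = TRUE))
})

test_that("noise-free limit makes the planted metabolite exactly affine in its genus", {
  cfg <- sim_config(n_samples = 80, n_genera = 10, n_metabolites = 6,
                    zero_inflation = 0, dilution_sd = 0, batch_sd = 0,
                    noise_sd = 0, missing_rate = 0,
                    effect_table = data.frame(genus = 4L, metabolite = 2L,
                                              slope = 5),
                    marker_totals = numeric(0), seed = 31)
  co <- simulate_cohort(cfg)
  x <- co$truth$relative_abundance_true[, 4]
  # residual after removing the genus term is a function of covariates only;
  # with covariate effects also zeroed it is an exact affine function
  y <- log(co$panel$values[, 2])
  covs <- co$covariates
  res <- residuals(lm(y ~ x + I((covs$age - 50) / 10) + covs$sex))
  expect_lt(max(abs(res)), 1e-10)
  fit <- lm(y ~ x + I((covs$age - 50) / 10) + covs$sex)
  expect_equal(unname(coef(fit)["x"]), 5, tolerance = 1e-8)
})

test_that("with no planted effects genus-metabolite correlations vanish", {
  cfg <- sim_config(n_samples = 2000, n_genera = 12, n_metabolites = 8,
                    effect_table = data.frame(genus = integer(),
                                              metabolite = integer(),
                                              slope = numeric()),
                    diversity_loading = 0, marker_totals = numeric(0),
                    missing_rate = 0, seed = 17)
  co <- simulate_cohort(cfg)
  rel <- relative_abundance(co$abundance)
  lv <- log(co$panel$values)
  cors <- sapply(1:8, function(m) cor(rel[, m], lv[, m]))
  expect_lt(max(abs(cors)), 4 / sqrt(2000) + 0.02)
})

test_that("a planted slope is recovered by least squares on the generator output", {
  cfg <- sim_config(n_samples = 500, n_genera = 10, n_metabolites = 6,
                    effect_table = data.frame(genus = 3L, metabolite = 2L,
                                              slope = 0.8),
                    noise_sd = 0.3, dilution_sd = 0, batch_sd = 0,
                    missing_rate = 0, marker_totals = numeric(0), seed = 7)
  co <- simulate_cohort(cfg)
  x <- co$truth$relative_abundance_true[, 3]
  y <- log(co$panel$values[, 2])
  fit <- summary(lm(y ~ x + I((co$covariates$age - 50) / 10) + co$covariates$sex))
  b <- fit$coefficients["x", ]
  expect_lt(abs(b["Estimate"] - 0.8), 3 * b["Std. Error"])
})

test_that("planted mediation truth satisfies the exact decomposition", {
  co <- default_cohort()$cohort
  tr <- co$truth$marker_truth
  expect_equal(tr$direct + tr$indirect, tr$total, tolerance = 1e-12)
  expect_equal(tr$indirect / tr$total,
               rep(co$config$mediation_fraction, nrow(tr)), tolerance = 1e-12)
  # markers really are linear in true Shannon entropy and the mediator path:
  # regressing out both leaves no diversity signal
  ggt <- log(co$markers$ggt)
  res <- residuals(lm(ggt ~ co$truth$shannon_true + co$truth$mediator_path))
  expect_lt(abs(cor(res, co$truth$shannon_true)), 1e-10)
})

test_that("standardised slope calibration hits the target effect size", {
  cfg <- sim_config(n_samples = 4000, n_genera = 10, n_metabolites = 6,
                    effect_table = data.frame(genus = integer(),
                                              metabolite = integer(),
                                              slope = numeric()),
                    missing_rate = 0, marker_totals = numeric(0), seed = 77)
  sl <- standardised_slope(cfg, genus = 5, effect = 0.25)
  cfg2 <- sim_config(n_samples = 4000, n_genera = 10, n_metabolites = 6,
                     effect_table = data.frame(genus = 5L, metabolite = 2L,
                                               slope = sl),
                     dilution_sd = 0, batch_sd = 0, missing_rate = 0,
                     marker_totals = numeric(0), seed = 77)
  co <- simulate_cohort(cfg2)
  x <- co$truth$relative_abundance_true[, 5]
  y <- log(co$panel$values[, 2])
  r <- residuals(lm(y ~ I((co$covariates$age - 50) / 10) + co$covariates$sex))
  eff <- coef(lm(r ~ x))[2] * sd(x) / cfg2$noise_sd
  expect_lt(abs(unname(eff) - 0.25), 0.05)
})

test_that("toy reconstruction databases honour carriage probabilities", {
  full <- simulate_reconstruction_db(10, 4, 1, seed = 1)
  expect_equal(nrow(full$carriage), 40L)
  empty <- simulate_reconstruction_db(10, 4, 0, seed = 1)
  expect_equal(nrow(empty$carriage), 0L)
  expect_s3_class(empty, "recon_db")

  db <- simulate_reconstruction_db(50, 5, 0.3, seed = 1)
  phat <- nrow(db$carriage) / 250
  expect_lt(abs(phat - 0.3), 2.576 * sqrt(0.3 * 0.7 / 250))
  # deterministic under seed
  db2 <- simulate_reconstruction_db(50, 5, 0.3, seed = 1)
  expect_identical(db$carriage, db2$carriage)
  # secretors are exactly the strains carrying a produce reaction
  prod <- db$reactions$reaction_id[db$reactions$role == "produce"]
  expect_setequal(db$secretion$strain_id,
                  unique(db$carriage$strain_id[db$carriage$reaction_id %in% prod]))
  expect_error(simulate_reconstruction_db(5, 5, 1.2), "carriage_prob")
})
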