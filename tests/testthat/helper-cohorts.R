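# Shared synthetic fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# A mid-sized default cohort used by several test files.
default_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    cfg <- sim_config(n_samples = 300, seed = 42)
    .fixtures$cohort <- simulate_cohort(cfg)
    .fixtures$prep <- suppressWarnings(prepare_panel(.fixtures$cohort$panel))
  }
  list(cohort = .fixtures$cohort, prep = .fixtures$prep)
}

# Small raw panel with controlled missingness pattern.
toy_panel <- function(n = 20, m = 5, seed = 1) {
  vals <- with_test_seed(seed, matrix(exp(rnorm(n * m)), n, m))
  metabolite_panel(vals, state = "raw")
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Direct normal-equation least squares, used as an independent check.
ols_coefs <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))
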