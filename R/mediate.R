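#' Mediation analysis by product of coefficients
#'
#' Decomposes the effect of an exposure (Shannon entropy) on an outcome
#' (health marker) into direct and indirect components through a mediator
#' (metabolite prediction score or normalised metabolite), using linear
#' mediator and outcome models with the full covariate tier. Batch enters
#' as fixed dummy covariates so the linear decomposition identity
#' `total = direct + indirect` holds to machine precision. The indirect
#' effect is the product of the exposure-to-mediator coefficient `a` and
#' the mediator-to-outcome coefficient `b` given exposure (equal, in
#' linear models, to the difference total - direct). The proportion
#' mediated is `100 * indirect / total` and may exceed 100% when the
#' direct effect's sign opposes the total effect. Confidence intervals are
#' percentile bootstrap over case resamples, with the proportion computed
#' within each resample.
#'
#' @param exposure,mediator,outcome named numeric vectors (shared sample
#'   IDs; listwise deletion applied).
#' @param covariates covariate data.frame (rownames = sample IDs); a
#'   `batch` column, when present, is dummy-coded into the design. `NULL`
#'   for unadjusted mediation.
#' @param tier covariate tier (default `"full"`).
#' @param n_boot bootstrap replications (default 2000); 0 skips the
#'   bootstrap (point estimates only, CIs reported as NA).
#' @param seed integer seed (same seed, same CI endpoints).
#' @param conf confidence level (default 0.95).
#' @param n_knots spline knots for covariates (default 4).
#' @return object of class `mediation_result`: effects (`total`, `direct`,
#'   `indirect`, `a`, `b`), `proportion_mediated` (%), bootstrap `ci`
#'   (rows: total, direct, indirect, proportion), `n`, `n_boot`, `seed`,
#'   `total_near_zero` flag.
#' @export
mediate <- function(exposure, mediator, outcome, covariates = NULL,
                    tier = c("full", "basic"), n_boot = 2000L, seed = 1L,
                    conf = 0.95, n_knots = 4L) {
  tier <- match.arg(tier)
  ids <- Reduce(intersect, list(names(exposure), names(mediator), names(outcome)))
  if (!is.null(covariates)) ids <- intersect(ids, rownames(covariates))
  if (!length(ids)) stop_miomet("no shared sample IDs")
  W <- NULL
  if (!is.null(covariates)) {
    cov_use <- covariates[ids, , drop = FALSE]
    W <- covariate_design(cov_use, tier = tier, n_knots = n_knots)
    if ("batch" %in% names(cov_use)) {
      bf <- factor(cov_use$batch)
      if (nlevels(bf) > 1L)
        W <- cbind(W, model.matrix(~ bf)[, -1L, drop = FALSE])
    }
  }
  x <- exposure[ids]; m <- mediator[ids]; y <- outcome[ids]
  ok <- !is.na(x) & !is.na(m) & !is.na(y)
  if (!is.null(W)) ok <- ok & complete.cases(W)
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  W <- if (is.null(W)) matrix(numeric(0), sum(ok), 0) else W[ok, , drop = FALSE]
  n <- length(y)
  if (n < ncol(W) + 4L) stop_miomet("too few complete cases")

  est <- function(x, m, y, W) {
    cf_m <- lm.fit(cbind(1, x, W), m)$coefficients
    cf_y <- lm.fit(cbind(1, x, m, W), y)$coefficients
    cf_t <- lm.fit(cbind(1, x, W), y)$coefficients
    a <- unname(cf_m[2L]); b <- unname(cf_y[3L])
    direct <- unname(cf_y[2L]); total <- unname(cf_t[2L])
    c(total = total, direct = direct, indirect = a * b, a = a, b = b,
      proportion = if (abs(total) > 1e-12) 100 * a * b / total else NA_real_)
  }
  point <- est(x, m, y, W)
  total_near_zero <- abs(point[["total"]]) < 1e-8

  if (n_boot == 0L) {
    ci <- matrix(NA_real_, 4L, 2L,
                 dimnames = list(c("total", "direct", "indirect", "proportion"),
                                 c("lower", "upper")))
    return(structure(list(effects = point[c("total", "direct", "indirect",
                                            "a", "b")],
                          proportion_mediated = point[["proportion"]],
                          ci = ci, n = n, n_boot = 0L, seed = seed,
                          conf = conf, total_near_zero = total_near_zero),
                     class = "mediation_result"))
  }
  boot <- with_seed(seed, {
    res <- matrix(NA_real_, n_boot, 4L,
                  dimnames = list(NULL, c("total", "direct", "indirect",
                                          "proportion")))
    for (r in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      e <- tryCatch(est(x[idx], m[idx], y[idx], W[idx, , drop = FALSE]),
                    error = function(err) NULL)
      if (!is.null(e)) res[r, ] <- e[c("total", "direct", "indirect",
                                       "proportion")]
    }
    res
  })
  al <- (1 - conf) / 2
  ci <- t(apply(boot, 2, quantile, probs = c(al, 1 - al), na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  structure(list(effects = point[c("total", "direct", "indirect", "a", "b")],
                 proportion_mediated = point[["proportion"]],
                 ci = ci, n = n, n_boot = n_boot, seed = seed,
                 conf = conf, total_near_zero = total_near_zero),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  e <- x$effects
  cat(sprintf("<mediation_result> n = %d, %d bootstrap replicates\n", x$n, x$n_boot))
  cat(sprintf("  total %.4f, direct %.4f, indirect %.4f\n",
              e[["total"]], e[["direct"]], e[["indirect"]]))
  if (is.na(x$proportion_mediated)) {
    cat("  proportion mediated: not defined (total effect near zero)\n")
  } else {
    cat(sprintf("  proportion mediated: %.1f%% (95%% CI %.1f%%, %.1f%%)\n",
                x$proportion_mediated, x$ci["proportion", "lower"],
                x$ci["proportion", "upper"]))
  }
  invisible(x)
}

#' Biomarker association screen
#'
#' Screens health markers (inflammation, metabolic health, liver injury)
#' on associations with each of a set of predictors (urinary metabolite,
#' Shannon entropy, microbiome-based prediction score), one fully adjusted
#' mixed-model fit per marker x predictor with a batch random intercept.
#' Right-skewed markers (CRP, GGT, ALAT, ASAT by default) are
#' log-transformed before fitting.
#'
#' @param markers data.frame of marker columns (rownames = sample IDs).
#' @param predictors named list of named numeric vectors.
#' @param covariates covariate data.frame with `batch` column.
#' @param tier covariate tier (default `"full"`).
#' @param log_markers marker names to log-transform (positive values
#'   required).
#' @param n_knots spline knots (default 4).
#' @return data.frame: `marker`, `predictor`, `b`, `se`, `ci_low`,
#'   `ci_high`, `p`, `q` (BH within the screen), `n`.
#' @export
biomarker_screen <- function(markers, predictors, covariates,
                             tier = c("full", "basic"),
                             log_markers = c("crp", "ggt", "alat", "asat"),
                             n_knots = 4L) {
  tier <- match.arg(tier)
  marker_names <- setdiff(names(markers), "sample_id")
  rows <- list()
  for (k in marker_names) {
    yk <- markers[[k]]
    names(yk) <- rownames(markers)
    if (k %in% log_markers) {
      yk[yk <= 0] <- NA_real_
      yk <- log(yk)
    }
    for (p in names(predictors)) {
      fr <- build_frame(yk, predictors[[p]], covariates, tier = tier,
                        n_knots = n_knots)
      rows[[paste(k, p)]] <- cbind(
        data.frame(marker = k, predictor = p, stringsAsFactors = FALSE),
        fit_lmm(fr))
    }
  }
  out <- do.call(rbind, rows)
  out$q <- fdr_bh(out$p)
  rownames(out) <- NULL
  out
}
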