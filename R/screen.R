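#' Covariate design matrix with spline coding
#'
#' Builds the fixed-effects covariate columns used by every regression in
#' the pipeline. The basic tier consists of age (restricted cubic spline,
#' 4 knots at the 5/33/66/95 percentiles), sex, a linear-age x sex
#' interaction, and waist circumference (same spline coding). The full
#' tier adds smoking, hypertonia, HbA1c, years of education, eGFR
#' (spline-coded), urinary pH, and alcohol intake.
#'
#' @param covariates data.frame with columns `age`, `sex`, `waist` and, for
#'   the full tier, `smoking`, `hypertonia`, `hba1c`, `education`, `egfr`,
#'   `urine_ph`, `alcohol`.
#' @param tier `"basic"` or `"full"`.
#' @param n_knots spline knots (default 4).
#' @return numeric matrix (rows = rows of `covariates`, may contain NA for
#'   incomplete rows).
#' @export
covariate_design <- function(covariates, tier = c("basic", "full"),
                             n_knots = 4L) {
  tier <- match.arg(tier)
  need <- c("age", "sex", "waist")
  if (tier == "full")
    need <- c(need, "smoking", "hypertonia", "hba1c", "education", "egfr",
              "urine_ph", "alcohol")
  missing_cols <- setdiff(need, names(covariates))
  if (length(missing_cols))
    stop_miomet("covariates missing: ", paste(missing_cols, collapse = ", "))
  X <- cbind(rcs_basis(covariates$age, n_knots = n_knots, name = "age"),
             sex = covariates$sex,
             age_sex = covariates$age * covariates$sex,
             rcs_basis(covariates$waist, n_knots = n_knots, name = "waist"))
  if (tier == "full") {
    X <- cbind(X,
               smoking = covariates$smoking,
               hypertonia = covariates$hypertonia,
               hba1c = covariates$hba1c,
               education = covariates$education,
               rcs_basis(covariates$egfr, n_knots = n_knots, name = "egfr"),
               urine_ph = covariates$urine_ph,
               alcohol = covariates$alcohol)
  }
  X
}

#' Assemble a model frame for one association fit
#'
#' Joins a response, the predictor of interest and the tier's covariate
#' design on shared sample IDs, performs listwise deletion of incomplete
#' rows, and drops collinear covariate columns (recorded in the result).
#' The predictor of interest is always the first design column.
#'
#' @param response named numeric vector (e.g. one normalised metabolite).
#' @param predictor named numeric vector (genus abundance, presence or a
#'   diversity measure).
#' @param covariates covariate data.frame with rownames = sample IDs and a
#'   `batch` column (the random-intercept grouping).
#' @param tier `"basic"` or `"full"`.
#' @param n_knots spline knots (default 4).
#' @return object of class `model_frame`: list with `y`, `X` (predictor
#'   first, no intercept column), `groups` (batch factor), `sample_ids`,
#'   `n_dropped`, `dropped_columns`.
#' @export
build_frame <- function(response, predictor, covariates,
                        tier = c("basic", "full"), n_knots = 4L) {
  tier <- match.arg(tier)
  ids <- Reduce(intersect, list(names(response), names(predictor),
                                rownames(covariates)))
  if (!length(ids)) stop_miomet("no shared sample IDs")
  cov_use <- covariates[ids, , drop = FALSE]
  W <- covariate_design(cov_use, tier = tier, n_knots = n_knots)
  y <- response[ids]
  x <- predictor[ids]
  g <- as.character(cov_use$batch)
  ok <- !is.na(y) & !is.na(x) & complete.cases(W) & !is.na(g)
  n_dropped <- sum(!ok)
  y <- y[ok]; x <- x[ok]; W <- W[ok, , drop = FALSE]; g <- g[ok]
  if (length(unique(x)) < 2L)
    stop_miomet("predictor constant after listwise deletion")
  X <- cbind(predictor = x, W)
  # drop collinear covariate columns (never the predictor)
  q <- qr(cbind(1, X))
  if (q$rank < ncol(X) + 1L) {
    keep <- sort(q$pivot[seq_len(q$rank)])
    keep <- setdiff(keep, 1L) - 1L   # column indices into X
    if (!1L %in% keep) stop_miomet("predictor collinear with covariates")
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    X <- X[, keep, drop = FALSE]
  } else dropped <- character()
  structure(list(y = y, X = X, groups = factor(g), sample_ids = ids[ok],
                 n_dropped = n_dropped, dropped_columns = dropped),
            class = "model_frame")
}

#' @export
print.model_frame <- function(x, ...) {
  cat(sprintf("<model_frame> n = %d, %d fixed columns, %d group(s), %d row(s) dropped\n",
              length(x$y), ncol(x$X), nlevels(x$groups), x$n_dropped))
  invisible(x)
}

#' Fit the linear mixed model of one association
#'
#' Gaussian linear mixed model with a random intercept per sequencing
#' batch, fit by REML, reporting the Wald coefficient, SE, normal-theory
#' 95% CI and two-tailed p-value for the predictor of interest (the first
#' design column). With fewer than two batches the fit falls back to OLS
#' with a warning. Non-convergence yields a flagged row with missing
#' p-value rather than an error.
#'
#' @param frame a [build_frame()] result.
#' @param conf confidence level (default 0.95).
#' @return one-row data.frame (class `association_result`): `b`, `se`,
#'   `ci_low`, `ci_high`, `p`, `n`, `n_groups`, `converged`.
#' @export
fit_lmm <- function(frame, conf = 0.95) {
  stopifnot(inherits(frame, "model_frame"))
  z <- qnorm(1 - (1 - conf) / 2)
  n <- length(frame$y)
  result <- function(b, se, converged = TRUE) {
    data.frame(b = b, se = se, ci_low = b - z * se, ci_high = b + z * se,
               p = if (converged) 2 * pnorm(-abs(b / se)) else NA_real_,
               n = n, n_groups = nlevels(frame$groups), converged = converged)
  }
  if (nlevels(frame$groups) < 2L) {
    warning("fewer than 2 groups: falling back to OLS")
    fit <- lm(frame$y ~ frame$X)
    b <- coef(fit)[2L]
    se <- sqrt(diag(vcov(fit)))[2L]
    return(result(unname(b), unname(se)))
  }
  d <- data.frame(.y = frame$y, .g = frame$groups)
  d$.X <- frame$X
  fit <- tryCatch(
    suppressMessages(lme4::lmer(.y ~ .X + (1 | .g), data = d, REML = TRUE,
                                control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore", check.scaleX = "ignore"))),
    error = function(e) NULL)
  if (is.null(fit)) return(result(NA_real_, NA_real_, converged = FALSE))
  fe <- lme4::fixef(fit)
  vc <- as.matrix(vcov(fit))
  j <- which(names(fe) == ".Xpredictor")
  result(unname(fe[j]), sqrt(vc[j, j]))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement:
#' `q_i = min over p_(j) >= p_(i) of p_(j) * m / rank(j)`.
#'
#' @param p_values vector of p-values in \[0,1\] (NA passed through).
#' @return vector of q-values.
#' @export
fdr_bh <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_miomet("p-values must be in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Case-resampling bootstrap p-value for one association
#'
#' Non-parametric bootstrap of the predictor coefficient: cases are
#' resampled within batch (preserving the random-intercept design), the
#' model is refit per replicate, and the two-tailed p-value is computed
#' from the normal approximation with the bootstrap SE. A percentile-t
#' variant is available. Replicates in which the predictor becomes
#' constant are skipped and counted.
#'
#' @param frame a [build_frame()] result.
#' @param n_rep bootstrap replications (>= 100; default 2000).
#' @param seed integer seed (deterministic).
#' @param variant `"normal"` (bootstrap-SE normal approximation, default)
#'   or `"percentile_t"`.
#' @param engine `"lmm"` refits the mixed model per replicate (default);
#'   `"ols"` refits by least squares, appropriate when the batch variance
#'   is of no interest.
#' @return list: `p`, `boot_se`, `b`, `n_rep_used`, `n_skipped`.
#' @export
bootstrap_p <- function(frame, n_rep = 2000L, seed = 1L,
                        variant = c("normal", "percentile_t"),
                        engine = c("lmm", "ols")) {
  stopifnot(inherits(frame, "model_frame"))
  variant <- match.arg(variant)
  engine <- match.arg(engine)
  if (n_rep < 100L) stop_miomet("n_rep must be >= 100")
  fit0 <- if (engine == "lmm") fit_lmm(frame) else ols_row(frame)
  idx_by_group <- split(seq_along(frame$y), frame$groups)
  stats <- with_seed(seed, {
    out <- matrix(NA_real_, n_rep, 2L)
    for (r in seq_len(n_rep)) {
      idx <- unlist(lapply(idx_by_group, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]),
        use.names = FALSE)
      x <- frame$X[idx, 1L]
      if (length(unique(x)) < 2L) next
      sub <- structure(list(y = frame$y[idx],
                            X = frame$X[idx, , drop = FALSE],
                            groups = droplevels(frame$groups[idx])),
                       class = "model_frame")
      row <- tryCatch(
        if (engine == "lmm" && nlevels(sub$groups) > 1L)
          suppressWarnings(fit_lmm(sub)) else ols_row(sub),
        error = function(e) NULL)
      if (!is.null(row) && isTRUE(row$converged))
        out[r, ] <- c(row$b, row$se)
    }
    out
  })
  used <- !is.na(stats[, 1L])
  bs <- stats[used, , drop = FALSE]
  boot_se <- sd(bs[, 1L])
  p <- if (variant == "normal") {
    2 * pnorm(-abs(fit0$b / boot_se))
  } else {
    tstar <- (bs[, 1L] - fit0$b) / bs[, 2L]
    t0 <- fit0$b / fit0$se
    mean(abs(tstar) >= abs(t0))
  }
  list(p = p, boot_se = boot_se, b = fit0$b,
       n_rep_used = sum(used), n_skipped = n_rep - sum(used))
}

# OLS fit shaped like an association_result row.
ols_row <- function(frame, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  fit <- lm.fit(cbind(1, frame$X), frame$y)
  rss <- sum(fit$residuals^2)
  dfree <- length(frame$y) - fit$rank
  XtXinv <- chol2inv(qr.R(fit$qr))
  b <- fit$coefficients[2L]
  se <- sqrt(rss / dfree * XtXinv[2L, 2L])
  data.frame(b = unname(b), se = se, ci_low = unname(b) - z * se,
             ci_high = unname(b) + z * se, p = 2 * pnorm(-abs(b / se)),
             n = length(frame$y), n_groups = nlevels(frame$groups),
             converged = TRUE)
}

#' Run an association screen
#'
#' The three screening engines of the pipeline. In `abundance` mode the
#' predictor is the genus relative abundance, in `presence` mode a 0/1
#' presence indicator, in `diversity` mode the Shannon entropy and species
#' richness are each tested against every included metabolite. Eligibility
#' rules (see [eligibility()]) restrict the tested pairs in the first two
#' modes. Every pair is fit under the basic covariate tier with a batch
#' random intercept; Benjamini-Hochberg q-values are computed within the
#' screen (one family per mode), and pairs significant at `fdr_level` are
#' re-fit under the full covariate tier. In diversity mode a secondary
#' spline-coded fit of the diversity predictor provides a likelihood-ratio
#' p-value for nonlinearity.
#'
#' @param panel normalised [metabolite_panel()].
#' @param table rarefied [abundance_table()].
#' @param covariates covariate data.frame (rownames = sample IDs, `batch`
#'   column).
#' @param mode `"abundance"`, `"presence"` or `"diversity"`.
#' @param fdr_level FDR threshold for full-tier re-testing (default 0.05).
#' @param diversity optional precomputed [diversity_vector()] data.frame.
#' @param n_knots spline knots for covariates (default 4).
#' @param check_nonlinearity in diversity mode, also report `p_nonlinear`
#'   (default TRUE).
#' @param boot bootstrap replications for the sensitivity p-value attached
#'   to the full-tier re-tested pairs (`boot_p` column); 0 (default)
#'   disables it; 2000 replications mirror the published sensitivity
#'   analyses.
#' @param boot_seed seed for the bootstrap (default 1).
#' @return data.frame of class `screen_result`: one row per tested pair
#'   and tier (`basic` rows for all pairs, `full` rows for the re-tested
#'   significant ones) with `predictor`, `response`, `b`, `se`, `ci_low`,
#'   `ci_high`, `p`, `q`, `tier`, `n` (plus `boot_p` when `boot > 0`).
#' @export
run_screen <- function(panel, table, covariates,
                       mode = c("abundance", "presence", "diversity"),
                       fdr_level = 0.05, diversity = NULL, n_knots = 4L,
                       check_nonlinearity = TRUE, boot = 0L, boot_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "metabolite_panel"))
  vals <- panel_values(panel)
  if (mode == "diversity") {
    div <- diversity %||% diversity_vector(table)
    met_frac <- colMeans(!is.na(vals))
    mets <- colnames(vals)[met_frac >= 0.5]
    pairs <- expand.grid(genus = c("shannon", "richness"), metabolite = mets,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    predictors <- list(shannon = setNames(div$shannon, div$sample_id),
                       richness = setNames(as.numeric(div$richness), div$sample_id))
    get_pred <- function(nm) predictors[[nm]]
  } else {
    pairs <- eligibility(table, panel, mode = mode)
    rel <- relative_abundance(table)
    get_pred <- function(nm) {
      x <- if (mode == "abundance") rel[, nm] else as.numeric(unclass(table)[, nm] > 0)
      setNames(x, rownames(table))
    }
  }
  if (!nrow(pairs)) {
    warning("no eligible pairs for this screen")
    return(empty_screen_result())
  }
  fit_tier <- function(tier, sel = seq_len(nrow(pairs))) {
    rows <- lapply(sel, function(i) {
      fr <- build_frame(vals[, pairs$metabolite[i]], get_pred(pairs$genus[i]),
                        covariates, tier = tier, n_knots = n_knots)
      cbind(data.frame(predictor = pairs$genus[i],
                       response = pairs$metabolite[i],
                       stringsAsFactors = FALSE),
            fit_lmm(fr), tier = tier)
    })
    do.call(rbind, rows)
  }
  basic <- fit_tier("basic")
  basic$q <- fdr_bh(basic$p)
  if (mode == "diversity" && check_nonlinearity)
    basic$p_nonlinear <- vapply(seq_len(nrow(pairs)), function(i)
      nonlinearity_p(vals[, pairs$metabolite[i]], get_pred(pairs$genus[i]),
                     covariates, n_knots = n_knots), numeric(1))
  sig <- which(!is.na(basic$q) & basic$q < fdr_level)
  out <- basic
  if (length(sig)) {
    full <- fit_tier("full", sig)
    full$q <- fdr_bh(full$p)
    if (mode == "diversity" && check_nonlinearity) full$p_nonlinear <- NA_real_
    if (boot > 0L) {
      basic$boot_p <- NA_real_
      full$boot_p <- vapply(seq_along(sig), function(k) {
        i <- sig[k]
        fr <- build_frame(vals[, pairs$metabolite[i]], get_pred(pairs$genus[i]),
                          covariates, tier = "full", n_knots = n_knots)
        suppressWarnings(bootstrap_p(fr, n_rep = boot,
                                     seed = boot_seed + k)$p)
      }, numeric(1))
    }
    out <- rbind(basic, full)
  }
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

empty_screen_result <- function() {
  structure(data.frame(predictor = character(), response = character(),
                       b = numeric(), se = numeric(), ci_low = numeric(),
                       ci_high = numeric(), p = numeric(), n = integer(),
                       n_groups = integer(), converged = logical(),
                       tier = character(), q = numeric(),
                       stringsAsFactors = FALSE),
            class = c("screen_result", "data.frame"))
}

# Likelihood-ratio p for nonlinearity of a diversity predictor: ML mixed
# fits with linear vs spline-coded predictor, chi-square on the extra
# spline terms.
nonlinearity_p <- function(response, predictor, covariates, n_knots = 4L) {
  fr <- build_frame(response, predictor, covariates, tier = "basic",
                    n_knots = n_knots)
  spl <- try(rcs_basis(fr$X[, 1L], n_knots = n_knots, name = "pred"),
             silent = TRUE)
  if (inherits(spl, "try-error")) return(NA_real_)
  d <- data.frame(.y = fr$y, .g = fr$groups)
  d$.X <- fr$X
  d$.S <- spl[, -1L, drop = FALSE]
  ctrl <- lme4::lmerControl(calc.derivs = FALSE, check.conv.singular = "ignore", check.scaleX = "ignore")
  f0 <- tryCatch(suppressMessages(
    lme4::lmer(.y ~ .X + (1 | .g), data = d, REML = FALSE, control = ctrl)),
    error = function(e) NULL)
  f1 <- tryCatch(suppressMessages(
    lme4::lmer(.y ~ .X + .S + (1 | .g), data = d, REML = FALSE, control = ctrl)),
    error = function(e) NULL)
  if (is.null(f0) || is.null(f1)) return(NA_real_)
  ll <- 2 * (as.numeric(logLik(f1)) - as.numeric(logLik(f0)))
  df <- attr(logLik(f1), "df") - attr(logLik(f0), "df")
  pchisq(max(ll, 0), df = df, lower.tail = FALSE)
}
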