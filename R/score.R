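#' Elastic-net fit of a metabolite on genus abundances
#'
#' Minimises the penalised least-squares objective
#' \deqn{Q = \frac{1}{2n}\sum_i (y_i - \beta_0 - x_i\beta)^2 +
#'   \lambda \sum_j \left(\frac{1-\alpha}{2}\beta_j^2 + \alpha|\beta_j|\right)}
#' by cyclic coordinate descent with soft-thresholding. The intercept is
#' unpenalised (handled exactly by centring); predictors are standardised
#' internally by default and coefficients are reported on the original
#' scale. At `alpha = 0` the update is the pure ridge update (no soft
#' threshold).
#'
#' @param y numeric response vector.
#' @param X numeric predictor matrix (samples x genera).
#' @param lambda penalty strength (scalar, >= 0) or a decreasing vector
#'   (a path, solved with warm starts).
#' @param alpha elastic-net mixing parameter in \[0,1\].
#' @param standardise standardise columns before penalisation (default
#'   TRUE); zero-variance columns get coefficient 0.
#' @param tol convergence tolerance on the maximum coefficient change
#'   (default 1e-7, on the standardised scale).
#' @param max_iter sweep limit (default 1e5).
#' @param objective evaluate Q at the solution (default TRUE; path fits
#'   inside cross-validation skip it).
#' @return object of class `enet_fit`: `beta0`, `beta` (named, original
#'   scale; a matrix for a path), `lambda`, `alpha`, `objective` (value of
#'   Q at the solution, per lambda), `converged`.
#' @export
enet_fit <- function(y, X, lambda, alpha, standardise = TRUE, tol = 1e-7,
                     max_iter = 100000L, objective = TRUE) {
  X <- as.matrix(X)
  if (anyNA(y) || anyNA(X) || any(!is.finite(y)) || any(!is.finite(X)))
    stop_miomet("non-finite entries in y or X")
  if (any(lambda < 0)) stop_miomet("lambda must be >= 0")
  if (alpha < 0 || alpha > 1) stop_miomet("alpha must be in [0, 1]")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  xs <- if (standardise) sqrt(colMeans(Xc^2)) else rep(1, ncol(X))
  ok <- xs > 0
  Xs <- sweep(Xc[, ok, drop = FALSE], 2, xs[ok], "/")
  ym <- mean(y)
  yc <- y - ym
  sol <- enet_path_cpp(Xs, yc, alpha, lambda, tol, as.integer(max_iter))
  if (!all(sol$converged))
    stop_miomet(sprintf("coordinate descent did not converge for %d lambda value(s) (max sweeps %d, tol %g)",
                        sum(!sol$converged), max_iter, tol))
  beta <- matrix(0, ncol(X), length(lambda),
                 dimnames = list(colnames(X), NULL))
  beta[ok, ] <- sol$beta / xs[ok]
  beta0 <- ym - drop(crossprod(beta, xm))
  obj <- if (objective) {
    vapply(seq_along(lambda), function(l) {
      r <- yc - Xc %*% beta[, l]
      sum(r^2) / (2 * n) +
        lambda[l] * sum((1 - alpha) / 2 * beta[, l]^2 + alpha * abs(beta[, l]))
    }, numeric(1))
  } else rep(NA_real_, length(lambda))
  structure(list(beta0 = if (length(lambda) == 1L) beta0[1L] else beta0,
                 beta = if (length(lambda) == 1L) beta[, 1L] else beta,
                 lambda = lambda, alpha = alpha, objective = obj,
                 converged = TRUE, n = n),
            class = "enet_fit")
}

#' @export
print.enet_fit <- function(x, ...) {
  nz <- if (is.matrix(x$beta)) colSums(x$beta != 0) else sum(x$beta != 0)
  cat(sprintf("<enet_fit> alpha = %.2f, %d lambda value(s), nonzero: %s\n",
              x$alpha, length(x$lambda),
              paste(utils::head(nz, 5), collapse = " ")))
  if (!is.null(x$r2_oos))
    cat(sprintf("  chosen lambda = %.4g, out-of-sample R^2 = %.3f\n",
                x$lambda_chosen, x$r2_oos))
  invisible(x)
}

#' Elastic-net objective value
#'
#' Evaluates the penalised objective Q at arbitrary coefficients; used by
#' tests to compare solvers.
#' @param y,X data. @param beta0,beta coefficients. @param lambda,alpha
#'   penalty parameters.
#' @return scalar objective value.
#' @export
enet_objective <- function(y, X, beta0, beta, lambda, alpha) {
  r <- y - beta0 - as.matrix(X) %*% beta
  sum(r^2) / (2 * length(y)) +
    lambda * sum((1 - alpha) / 2 * beta^2 + alpha * abs(beta))
}

# lambda_max: smallest lambda with an all-zero solution at this alpha
# (alpha floored at 0.001 so the ridge end of the grid stays finite).
enet_lambda_max <- function(yc, Xs, alpha) {
  max(abs(crossprod(Xs, yc))) / length(yc) / max(alpha, 0.001)
}

#' Cross-validated elastic-net grid search
#'
#' Grid search over the alpha mixing values and a per-alpha lambda path of
#' `n_lambda` log-spaced values from the smallest lambda giving an
#' all-zero solution down to `lambda_min_ratio` times it. Folds are
#' assigned by a seeded permutation; for every (alpha, lambda) the
#' cross-validated prediction error is pooled over folds, the minimising
#' pair is selected (minimum mean CV error; no 1-SE rule), the model is
#' refit on all data, and the out-of-sample R-squared
#' `1 - SSE_oos / SST_oos` (pooled over folds, possibly negative) is
#' reported.
#'
#' @inheritParams enet_fit
#' @param alphas alpha grid (default `seq(0, 1, by = 0.1)`).
#' @param n_lambda path length per alpha (default 100).
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max
#'   (default 0.001).
#' @param n_folds folds (default 10; requires `n >= 2 * n_folds`).
#' @param seed integer seed for the fold permutation.
#' @return an `enet_fit` (refit on all data at the chosen pair) augmented
#'   with `alpha_chosen`, `lambda_chosen`, `r2_oos`, `r2_folds`,
#'   `cv_mse` (per-alpha matrix list), `score` (per-sample prediction on
#'   the fitted cohort) and `folds`.
#' @export
enet_cv <- function(y, X, alphas = seq(0, 1, by = 0.1), n_lambda = 100L,
                    lambda_min_ratio = 0.001, n_folds = 10L, seed = 1L,
                    standardise = TRUE, tol = 1e-7) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < 2L * n_folds) stop_miomet("need n >= 2 * n_folds")
  if (any(alphas < 0 | alphas > 1)) stop_miomet("alpha grid must lie in [0, 1]")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  fold <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  ## shared lambda path per alpha, computed on the full data
  xm <- colMeans(X); Xc <- sweep(X, 2, xm)
  xs <- if (standardise) sqrt(colMeans(Xc^2)) else rep(1, ncol(X))
  Xs <- sweep(Xc[, xs > 0, drop = FALSE], 2, xs[xs > 0], "/")
  yc <- y - mean(y)
  paths <- lapply(alphas, function(a) {
    lmax <- enet_lambda_max(yc, Xs, a)
    exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
  })
  sse <- matrix(0, length(alphas), n_lambda)
  pred_oos <- matrix(NA_real_, n, length(alphas) * n_lambda)
  n_eval <- 0L
  skipped <- 0L
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- !tr
    if (length(unique(y[tr])) < 2L || sd(y[tr]) == 0) {
      skipped <- skipped + 1L
      message(sprintf("enet_cv: fold %d skipped (constant response)", f))
      next
    }
    n_eval <- n_eval + sum(te)
    for (ai in seq_along(alphas)) {
      fit <- enet_fit(y[tr], X[tr, , drop = FALSE], paths[[ai]], alphas[ai],
                      standardise = standardise, tol = tol, objective = FALSE)
      pr <- sweep(X[te, , drop = FALSE] %*% fit$beta, 2, fit$beta0, "+")
      err <- sweep(pr, 1, y[te], "-")
      sse[ai, ] <- sse[ai, ] + colSums(err^2)
      pred_oos[te, (ai - 1L) * n_lambda + seq_len(n_lambda)] <- pr
    }
  }
  if (n_eval == 0L) stop_miomet("all folds skipped")
  best <- which(sse == min(sse), arr.ind = TRUE)[1L, ]
  ai <- best[1L]; li <- best[2L]
  alpha_chosen <- alphas[ai]
  lambda_chosen <- paths[[ai]][li]
  ## pooled out-of-sample R^2 at the chosen pair
  ph <- pred_oos[, (ai - 1L) * n_lambda + li]
  use <- !is.na(ph)
  sst <- sum((y[use] - mean(y))^2)
  r2_oos <- 1 - sum((y[use] - ph[use])^2) / sst
  r2_folds <- vapply(seq_len(n_folds), function(f) {
    te <- fold == f & use
    if (!any(te)) return(NA_real_)
    1 - sum((y[te] - ph[te])^2) / sum((y[te] - mean(y))^2)
  }, numeric(1))
  fit <- enet_fit(y, X, lambda_chosen, alpha_chosen,
                  standardise = standardise, tol = tol)
  fit$alpha_chosen <- alpha_chosen
  fit$lambda_chosen <- lambda_chosen
  fit$lambda_index <- unname(li)
  fit$r2_oos <- r2_oos
  fit$r2_folds <- r2_folds
  fit$cv_mse <- sse / n_eval
  fit$alphas <- alphas
  fit$folds <- fold
  fit$folds_skipped <- skipped
  fit$score <- drop(fit$beta0 + X %*% fit$beta)
  names(fit$score) <- rownames(X)
  fit
}

#' Per-sample microbiome-based prediction score
#'
#' Applies a fitted elastic net to a genus abundance matrix: score =
#' beta0 + X beta. Columns must cover the fit's genus set; missing genera
#' are an error naming the offenders.
#'
#' @param fit an [enet_fit()] (single-lambda).
#' @param X genus abundance matrix with column names.
#' @param metabolite optional source metabolite name carried along.
#' @return data.frame of class `prediction_score` with `sample_id`,
#'   `score`.
#' @export
predict_score <- function(fit, X, metabolite = NA_character_) {
  stopifnot(inherits(fit, "enet_fit"))
  if (is.matrix(fit$beta)) stop_miomet("predict_score needs a single-lambda fit")
  X <- as.matrix(X)
  missing_g <- setdiff(names(fit$beta), colnames(X))
  if (length(missing_g))
    stop_miomet("genus set mismatch; missing: ", paste(missing_g, collapse = ", "))
  score <- drop(fit$beta0 + X[, names(fit$beta), drop = FALSE] %*% fit$beta)
  out <- data.frame(sample_id = rownames(X) %||% seq_along(score),
                    score = unname(score), stringsAsFactors = FALSE)
  attr(out, "metabolite") <- metabolite
  class(out) <- c("prediction_score", "data.frame")
  out
}
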