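#' Construct a metabolite panel
#'
#' A metabolite panel holds a samples x metabolites concentration matrix
#' together with its processing state. Raw concentrations are in mM and must
#' be nonnegative where present; `NA` marks missing quantifications. The
#' panel moves through the states `raw` -> `log` -> `normalised`; the
#' outlier mask is only ever set in the `normalised` state.
#'
#' @param values numeric matrix, samples in rows (rownames = sample IDs),
#'   metabolites in columns (colnames = metabolite IDs).
#' @param state one of `"raw"`, `"log"`, `"normalised"`.
#' @param mask logical matrix of the same dimension; `TRUE` marks cells
#'   excluded as outliers. `NULL` means no exclusions.
#' @return an object of class `metabolite_panel`.
#' @export
metabolite_panel <- function(values, state = c("raw", "log", "normalised"),
                             mask = NULL) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values))
    stop_miomet("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("met", seq_len(ncol(values)))
  if (state == "raw" && any(values < 0, na.rm = TRUE))
    stop_miomet("raw concentrations must be nonnegative")
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
  } else {
    if (!identical(dim(mask), dim(values)))
      stop_miomet("mask dimensions must equal value dimensions")
    if (state != "normalised" && any(mask))
      stop_miomet("outlier mask may only be set in the normalised state")
  }
  structure(list(values = values, state = state, mask = mask),
            class = "metabolite_panel")
}

#' @export
print.metabolite_panel <- function(x, ...) {
  cat(sprintf("<metabolite_panel> %d samples x %d metabolites, state = %s\n",
              nrow(x$values), ncol(x$values), x$state))
  cat(sprintf("  missing cells: %d; masked outliers: %d\n",
              sum(is.na(x$values)), sum(x$mask)))
  invisible(x)
}

#' @export
dim.metabolite_panel <- function(x) dim(x$values)

# Values with outlier-masked cells set to NA (the analysis view).
#' Extract analysis-ready values from a panel
#'
#' Returns the value matrix with outlier-masked cells replaced by `NA`.
#' @param panel a [metabolite_panel()].
#' @return numeric matrix.
#' @export
panel_values <- function(panel) {
  v <- panel$values
  v[panel$mask] <- NA_real_
  v
}

#' Log-transform a raw metabolite panel
#'
#' Natural-log transform of raw concentrations. Zero concentrations are
#' treated as missing (below quantification) since the log is undefined and
#' downstream inclusion rules count non-zero measurements.
#'
#' @param panel a raw [metabolite_panel()].
#' @return a `metabolite_panel` in `log` state.
#' @export
log_transform <- function(panel) {
  stopifnot(inherits(panel, "metabolite_panel"))
  if (panel$state != "raw") stop_miomet("panel must be in raw state")
  v <- panel$values
  v[!is.na(v) & v <= 0] <- NA_real_
  metabolite_panel(log(v), state = "log")
}

#' Inclusion filter on metabolite missingness
#'
#' Restricts a raw panel to metabolites with at least
#' `min_nonmissing_fraction` present, non-zero quantifications. The
#' comparison is inclusive: a metabolite measured in exactly the threshold
#' fraction of samples is retained. Column order is preserved.
#'
#' @param panel a raw [metabolite_panel()].
#' @param min_nonmissing_fraction required fraction in (0, 1]; default 0.5
#'   (metabolites with more than 50% missing quantifications are excluded).
#' @return filtered `metabolite_panel`.
#' @export
filter_metabolites <- function(panel, min_nonmissing_fraction = 0.5) {
  stopifnot(inherits(panel, "metabolite_panel"))
  if (panel$state != "raw") stop_miomet("panel must be in raw state")
  f <- min_nonmissing_fraction
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stop_miomet("`min_nonmissing_fraction` must be in (0, 1]")
  v <- panel$values
  frac <- colMeans(!is.na(v) & v > 0)
  keep <- frac >= f
  if (!any(keep)) warning("no metabolite passed the inclusion filter")
  metabolite_panel(v[, keep, drop = FALSE], state = "raw")
}

#' Estimate per-sample urine dilution factors (probabilistic quotient)
#'
#' Classical probabilistic quotient normalisation on the log scale: the
#' reference profile is the per-metabolite median log concentration, and a
#' sample's log dilution factor is the median, over the metabolites present
#' in that sample, of (sample log value - reference value). Samples with
#' fewer than `min_metabolites` usable metabolites get a missing dilution
#' and are flagged.
#'
#' @param panel a [metabolite_panel()] in `log` state.
#' @param min_metabolites minimum usable metabolites per sample (default 3).
#' @return an object of class `dilution_estimate` with elements
#'   `log_dilution` (named per-sample vector), `reference` (per-metabolite
#'   median log concentration) and `flagged` (sample IDs with missing
#'   dilution).
#' @export
estimate_dilution <- function(panel, min_metabolites = 3L) {
  stopifnot(inherits(panel, "metabolite_panel"))
  if (panel$state != "log") stop_miomet("panel must be in log state")
  v <- panel$values
  reference <- apply(v, 2, median, na.rm = TRUE)
  dev <- sweep(v, 2, reference, "-")
  n_used <- rowSums(!is.na(dev))
  d <- apply(dev, 1, median, na.rm = TRUE)
  d[n_used < min_metabolites] <- NA_real_
  flagged <- rownames(v)[n_used < min_metabolites]
  if (length(flagged))
    warning(sprintf("%d sample(s) with < %d usable metabolites; dilution set missing",
                    length(flagged), min_metabolites))
  structure(list(log_dilution = d, reference = reference, flagged = flagged),
            class = "dilution_estimate")
}

#' Construct a dilution estimate from known values
#'
#' Wraps a per-sample log dilution vector (e.g. the generator's planted
#' truth, or an external estimate) as a `dilution_estimate` usable by
#' [normalise_regression_based()].
#'
#' @param log_dilution named numeric vector of per-sample log dilution
#'   factors.
#' @param reference optional per-metabolite reference profile.
#' @return a `dilution_estimate`.
#' @export
dilution_estimate <- function(log_dilution, reference = NULL) {
  if (is.null(names(log_dilution)))
    stop_miomet("log_dilution must be named by sample ID")
  structure(list(log_dilution = log_dilution, reference = reference,
                 flagged = character()),
            class = "dilution_estimate")
}

#' @export
print.dilution_estimate <- function(x, ...) {
  cat(sprintf("<dilution_estimate> %d samples (%d flagged); SD(log dilution) = %.3f\n",
              length(x$log_dilution), length(x$flagged),
              sd(x$log_dilution, na.rm = TRUE)))
  invisible(x)
}

#' Restricted cubic spline basis
#'
#' Harrell-style restricted cubic spline design columns: for k knots the
#' basis has k - 1 columns (the linear term plus k - 2 restricted cubic
#' terms), is continuous with continuous first and second derivatives, and
#' is constrained to be linear beyond the outer knots. Knots are placed at
#' empirical percentiles; the default four knots sit at the 5th, 33rd, 66th
#' and 95th percentiles.
#'
#' @param values numeric vector to expand.
#' @param n_knots number of knots (>= 3); default 4.
#' @param knots optional explicit knot locations (overrides `n_knots`).
#' @param probs percentile positions when `n_knots` knots are requested;
#'   defaults to c(0.05, 0.33, 0.66, 0.95) for 4 knots, equally spaced
#'   between 0.05 and 0.95 otherwise.
#' @param name variable name used in error messages and column names.
#' @return numeric matrix with `length(knots) - 1` columns and a `knots`
#'   attribute.
#' @export
rcs_basis <- function(values, n_knots = 4L, knots = NULL, probs = NULL,
                      name = deparse(substitute(values))) {
  if (is.null(knots)) {
    if (n_knots < 3L) stop_miomet("n_knots must be >= 3")
    if (is.null(probs)) {
      probs <- if (n_knots == 4L) c(0.05, 0.33, 0.66, 0.95)
               else seq(0.05, 0.95, length.out = n_knots)
    }
    knots <- quantile(values, probs = probs, na.rm = TRUE, names = FALSE,
                      type = 7)
  }
  knots <- sort(knots)
  if (anyDuplicated(knots))
    stop_miomet(sprintf("tied knots for variable '%s': distribution too degenerate for a spline", name))
  k <- length(knots)
  scl <- (knots[k] - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(NA_real_, length(values), k - 1L)
  out[, 1L] <- values
  denom <- knots[k] - knots[k - 1L]
  for (j in seq_len(k - 2L)) {
    out[, j + 1L] <- (pos3(values - knots[j]) -
                      pos3(values - knots[k - 1L]) * (knots[k] - knots[j]) / denom +
                      pos3(values - knots[k]) * (knots[k - 1L] - knots[j]) / denom) / scl
  }
  colnames(out) <- c(name, paste0(name, "'", strrep("'", seq_len(k - 2L) - 1L)))
  attr(out, "knots") <- knots
  out
}

#' Regression-based dilution normalisation
#'
#' For each metabolite, regresses the log concentration on a restricted
#' cubic spline of the estimated log dilution factor (least squares) and
#' replaces the value by its residual plus the fitted value at dilution 0.
#' This removes metabolite-specific, possibly nonlinear
#' dilution-concentration dependencies while anchoring each metabolite at
#' its undiluted level. Metabolites with fewer than `10 * n_knots` usable
#' samples fall back to a linear-in-dilution fit (recorded in the report).
#'
#' @param panel a [metabolite_panel()] in `log` state.
#' @param dilution a [estimate_dilution()] result for the same samples.
#' @param n_knots spline knots for the dilution response (default 4).
#' @return a `metabolite_panel` in `normalised` state, with attribute
#'   `report` (per-metabolite fit summary: n used, spline or linear fit,
#'   residual SD).
#' @export
normalise_regression_based <- function(panel, dilution, n_knots = 4L) {
  stopifnot(inherits(panel, "metabolite_panel"),
            inherits(dilution, "dilution_estimate"))
  if (panel$state != "log") stop_miomet("panel must be in log state")
  v <- panel$values
  d <- dilution$log_dilution[rownames(v)]
  if (sd(d, na.rm = TRUE) == 0) {
    # no dilution variation: normalisation is the identity
    res <- metabolite_panel(v, state = "normalised")
    attr(res, "report") <- setNames(rep(list(list(n = nrow(v), fit = "none",
                                                  resid_sd = NA_real_)),
                                        ncol(v)), colnames(v))
    return(res)
  }
  out <- v
  report <- vector("list", ncol(v))
  names(report) <- colnames(v)
  for (m in seq_len(ncol(v))) {
    use <- !is.na(v[, m]) & !is.na(d)
    n_use <- sum(use)
    if (n_use < 3L) {
      report[[m]] <- list(n = n_use, fit = "none", resid_sd = NA_real_)
      next
    }
    linear_fallback <- n_use < 10L * n_knots
    B <- if (linear_fallback) {
      matrix(d[use], ncol = 1, dimnames = list(NULL, "dil"))
    } else {
      basis <- try(rcs_basis(d[use], n_knots = n_knots, name = "dil"),
                   silent = TRUE)
      if (inherits(basis, "try-error")) {
        linear_fallback <- TRUE
        matrix(d[use], ncol = 1, dimnames = list(NULL, "dil"))
      } else basis
    }
    fit <- lm.fit(cbind(1, B), v[use, m])
    # fitted value at dilution 0: spline basis evaluated at 0 with training knots
    b0 <- if (linear_fallback) {
      matrix(0, 1, 1)
    } else {
      rcs_basis(0, knots = attr(B, "knots"), name = "dil")
    }
    at0 <- drop(cbind(1, b0) %*% fit$coefficients)
    out[use, m] <- fit$residuals + at0
    report[[m]] <- list(n = n_use,
                        fit = if (linear_fallback) "linear" else "rcs",
                        resid_sd = sd(fit$residuals))
  }
  res <- metabolite_panel(out, state = "normalised")
  attr(res, "report") <- report
  res
}

#' Mask outliers by the k-standard-deviation rule
#'
#' Single-pass exclusion per metabolite: cells whose normalised value
#' deviates from the metabolite mean by more than `sd_multiplier` standard
#' deviations (mean and SD over present values) are masked. No iteration;
#' metabolites with zero SD get no exclusions.
#'
#' @param panel a [metabolite_panel()] in `normalised` state.
#' @param sd_multiplier positive multiplier, default 4.
#' @return the panel with its outlier mask set.
#' @export
exclude_outliers <- function(panel, sd_multiplier = 4) {
  stopifnot(inherits(panel, "metabolite_panel"))
  if (panel$state != "normalised") stop_miomet("panel must be in normalised state")
  if (!is.numeric(sd_multiplier) || sd_multiplier <= 0)
    stop_miomet("`sd_multiplier` must be positive")
  v <- panel$values
  mask <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
  for (m in seq_len(ncol(v))) {
    x <- v[, m]
    mu <- mean(x, na.rm = TRUE)
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) next
    mask[, m] <- !is.na(x) & abs(x - mu) > sd_multiplier * s
  }
  metabolite_panel(v, state = "normalised", mask = mask)
}

#' Full metabolite preparation chain
#'
#' Convenience wrapper: inclusion filter on the raw panel, log transform,
#' dilution estimation, regression-based normalisation, and k-SD outlier
#' masking, in that order.
#'
#' @inheritParams filter_metabolites
#' @inheritParams normalise_regression_based
#' @inheritParams exclude_outliers
#' @return list with elements `panel` (normalised, outlier-masked
#'   [metabolite_panel()]) and `dilution` (the [estimate_dilution()] result).
#' @export
prepare_panel <- function(panel, min_nonmissing_fraction = 0.5, n_knots = 4L,
                          sd_multiplier = 4) {
  p <- filter_metabolites(panel, min_nonmissing_fraction)
  p <- log_transform(p)
  dil <- estimate_dilution(p)
  p <- normalise_regression_based(p, dil, n_knots = n_knots)
  p <- exclude_outliers(p, sd_multiplier = sd_multiplier)
  list(panel = p, dilution = dil)
}
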