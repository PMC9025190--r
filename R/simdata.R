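#' Configuration for the synthetic cohort generator
#'
#' Collects and validates every parameter of the synthetic cohort: sample
#' and feature counts, sequencing depth, the compositional model
#' (log-normal latent abundances with per-genus zero inflation and
#' multinomial read resampling), planted genus-metabolite effects, urine
#' dilution confounding, batch structure, and the planted mediation of
#' diversity effects on health markers through a focal "hippurate-like"
#' metabolite.
#'
#' @param n_samples,n_genera,n_metabolites,n_batches positive integers.
#' @param read_depth 16S reads per sample (default 10000).
#' @param zero_inflation probability that a genus is structurally absent
#'   from a sample; scalar or length-`n_genera` vector (default 0.25).
#' @param effect_table data.frame with columns `genus`, `metabolite`,
#'   `slope`: planted additive effects of genus relative abundance on log
#'   metabolite concentration.
#' @param dilution_sd SD of the per-sample log dilution factor (default 0.5).
#' @param batch_sd SD of per-batch, per-metabolite offsets (default 0.3).
#' @param mediation_fraction planted proportion of each diversity-to-marker
#'   effect routed through the focal metabolite, in \[0, 1.5\]; values above
#'   1 encode a direct effect whose sign opposes the total (default 0.78).
#' @param noise_sd residual SD of log metabolite concentrations (default 0.3).
#' @param seed integer seed; one global RNG stream per generator call.
#' @param diversity_loading slope of true Shannon entropy on the focal
#'   metabolite's log concentration (default 0.5); must be nonzero when
#'   planted marker effects are requested.
#' @param focal_metabolite column index of the diversity-driven metabolite
#'   (default 1).
#' @param dilution_curvature half-range of the per-metabolite quadratic
#'   dilution response coefficient (default 0.3); the response of
#'   metabolite m to log dilution d is `d + kappa_m * d^2` with
#'   `kappa_m ~ U(-c, c)`, so dilution is metabolite-specific and nonlinear
#'   while the median response across metabolites stays close to d.
#' @param latent_sd SD of the per-sample latent log abundances (default 1).
#' @param latent_mean_range range of genus latent log means, spread linearly
#'   across genera to give a realistic rank-abundance curve (default
#'   c(2.5, -2.5)).
#' @param missing_rate per-metabolite probability of a missing
#'   quantification, scalar or vector; the default (`NULL`) gives 30% of
#'   metabolites (the last ones in column order) a 60% missing rate and
#'   the rest 5%, so that a 60-metabolite panel retains 42 after the
#'   50%-missingness inclusion filter.
#' @param marker_totals named vector of planted total effects of Shannon
#'   entropy on health markers (default GGT -0.5, ALAT -0.4,
#'   triglycerides -0.45, all on the analysis (log where applicable) scale).
#' @param marker_noise_sd residual SD of health markers (default 0.5).
#' @param marker_pathway `"metabolite"` (markers load on the realised
#'   dilution-free focal metabolite, making the planted mediated proportion
#'   the exact estimand of product-of-coefficients mediation) or
#'   `"microbial"` (markers load on the noise-free microbial component, so
#'   a genus-based prediction score is the least attenuated mediator).
#' @return validated object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 500L, n_genera = 50L, n_metabolites = 60L,
                       n_batches = 8L, read_depth = 10000L,
                       zero_inflation = 0.25,
                       effect_table = default_effect_table(n_genera,
                                                           n_metabolites),
                       dilution_sd = 0.5, batch_sd = 0.3,
                       mediation_fraction = 0.78, noise_sd = 0.3,
                       seed = 1L,
                       diversity_loading = 0.5, focal_metabolite = 1L,
                       dilution_curvature = 0.3, latent_sd = 1,
                       latent_mean_range = c(2.5, -2.5),
                       missing_rate = NULL,
                       marker_totals = c(ggt = -0.5, alat = -0.4,
                                         triglycerides = -0.45),
                       marker_noise_sd = 0.5,
                       marker_pathway = c("metabolite", "microbial")) {
  if (is.null(missing_rate)) {
    n_high <- round(0.3 * n_metabolites)
    missing_rate <- c(rep(0.05, n_metabolites - n_high), rep(0.60, n_high))
  }
  cfg <- list(n_samples = as.integer(n_samples), n_genera = as.integer(n_genera),
              n_metabolites = as.integer(n_metabolites),
              n_batches = as.integer(n_batches), read_depth = as.integer(read_depth),
              zero_inflation = zero_inflation, effect_table = effect_table,
              dilution_sd = dilution_sd, batch_sd = batch_sd,
              mediation_fraction = mediation_fraction, noise_sd = noise_sd,
              seed = as.integer(seed), diversity_loading = diversity_loading,
              focal_metabolite = as.integer(focal_metabolite),
              dilution_curvature = dilution_curvature, latent_sd = latent_sd,
              latent_mean_range = latent_mean_range, missing_rate = missing_rate,
              marker_totals = marker_totals, marker_noise_sd = marker_noise_sd,
              marker_pathway = match.arg(marker_pathway))
  with(cfg, {
    if (n_samples < 1L || n_genera < 1L || n_metabolites < 1L || n_batches < 1L)
      stop_miomet("sample/feature counts must be positive")
    if (read_depth < 1L) stop_miomet("read_depth must be >= 1")
    if (n_samples < n_batches)
      stop_miomet("configuration error: n_samples < n_batches")
    if (any(c(dilution_sd, batch_sd, noise_sd, latent_sd, marker_noise_sd) < 0))
      stop_miomet("all SDs must be >= 0")
    if (any(zero_inflation < 0 | zero_inflation > 1))
      stop_miomet("zero_inflation must be a probability")
    if (mediation_fraction < 0 || mediation_fraction > 1.5)
      stop_miomet("mediation_fraction must be in [0, 1.5]")
    if (focal_metabolite < 1L || focal_metabolite > n_metabolites)
      stop_miomet("configuration error: focal_metabolite out of range")
    if (nrow(effect_table)) {
      if (!all(c("genus", "metabolite", "slope") %in% names(effect_table)))
        stop_miomet("effect_table needs columns genus, metabolite, slope")
      if (any(effect_table$genus < 1 | effect_table$genus > n_genera) ||
          any(effect_table$metabolite < 1 | effect_table$metabolite > n_metabolites))
        stop_miomet("configuration error: effect index out of range")
    }
    if (length(marker_totals) && diversity_loading == 0)
      stop_miomet("planted marker effects need a nonzero diversity_loading")
  })
  structure(cfg, class = "sim_config")
}

#' Default planted genus-metabolite effects
#'
#' Three planted effects on non-focal metabolites (metabolites 2-4), left
#' for the association screens to recover; the focal metabolite (index 1)
#' is driven by diversity alone. Indices are clamped to the configured
#' table dimensions.
#' @param n_genera,n_metabolites table dimensions the indices must fit.
#' @return data.frame with columns `genus`, `metabolite`, `slope`.
#' @export
default_effect_table <- function(n_genera = 50L, n_metabolites = 60L) {
  et <- data.frame(genus = pmin(c(3L, 10L, 17L), n_genera),
                   metabolite = pmin(c(2L, 3L, 4L), n_metabolites),
                   slope = c(8, -6, 7))
  et[!duplicated(et[, c("genus", "metabolite")]) &
       et$metabolite > 1L & et$genus >= 1L, , drop = FALSE]
}

#' Simulate a joint microbiome-metabolome-phenotype cohort
#'
#' Draws a full synthetic cohort under a [sim_config()]: a genus count
#' table at fixed read depth, a raw metabolite panel (concentrations in
#' mM with missingness), a host covariate table, a health-marker table,
#' and the complete ground truth needed for recovery tests.
#'
#' The compositional model draws per-sample latent log abundances
#' `N(mu_g, latent_sd^2)`, zeroes each genus independently with its
#' zero-inflation probability, renormalises, and resamples reads with a
#' multinomial at `read_depth`. Log metabolite concentrations are the sum
#' of an intercept, planted genus slopes times true relative abundances,
#' the diversity loading on the focal metabolite, covariate terms, a
#' metabolite-specific (quadratic) response to the log dilution factor,
#' batch offsets, and Gaussian noise; concentrations are exported
#' exponentiated. Health markers are linear in true Shannon entropy with
#' `mediation_fraction` of the planted total effect routed through the
#' focal metabolite axis.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort` with elements `abundance`
#'   ([abundance_table()] of counts summing to `read_depth` per sample),
#'   `panel` (raw [metabolite_panel()]), `covariates` (data.frame),
#'   `markers` (data.frame), `truth` (list: per-sample log dilution,
#'   batch offsets, planted effects, true Shannon entropy, microbial
#'   components, mediator-path values, and planted total/direct/indirect
#'   effects per marker).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_samples; G <- cfg$n_genera; M <- cfg$n_metabolites
  with_seed(cfg$seed, {
    sample_ids <- sprintf("S%04d", seq_len(n))
    genus_ids <- sprintf("genus_%02d", seq_len(G))
    met_ids <- c("hippurate", "succinate", "formate", "indoxyl_sulfate",
                 sprintf("met_%02d", seq_len(max(0L, M - 4L)) + 4L))[seq_len(M)]
    # focal metabolite keeps a recognisable name
    if (cfg$focal_metabolite != 1L)
      met_ids[cfg$focal_metabolite] <- "hippurate"

    batch <- sample(rep_len(sprintf("B%02d", seq_len(cfg$n_batches)), n))

    ## host covariates (distributions loosely typical of an adult cohort)
    age <- pmin(pmax(rnorm(n, 50, 14), 20), 90)
    sex <- rbinom(n, 1L, 0.55)
    waist <- rnorm(n, 88, 13) + 4 * (1 - sex)
    smoking <- rbinom(n, 1L, 0.22)
    hypertonia <- rbinom(n, 1L, 0.40)
    hba1c <- rnorm(n, 5.2, 0.55)
    education <- pmax(round(rnorm(n, 12, 2.5)), 8)
    egfr <- pmax(rnorm(n, 92, 17), 20)
    urine_ph <- rnorm(n, 6.1, 0.5)
    alcohol <- abs(rnorm(n, 8.5, 13))
    covariates <- data.frame(sample_id = sample_ids, age = age, sex = sex,
                             waist = waist, smoking = smoking,
                             hypertonia = hypertonia, hba1c = hba1c,
                             education = education, egfr = egfr,
                             urine_ph = urine_ph, alcohol = alcohol,
                             batch = batch, row.names = sample_ids,
                             stringsAsFactors = FALSE)

    ## compositional genus model
    mu <- seq(cfg$latent_mean_range[1], cfg$latent_mean_range[2], length.out = G)
    zi <- rep_len(cfg$zero_inflation, G)
    lat <- matrix(rnorm(n * G, 0, cfg$latent_sd), n, G)
    lat <- sweep(lat, 2, mu, "+")
    present <- matrix(rbinom(n * G, 1L, rep(1 - zi, each = n)), n, G)
    a <- present * exp(lat)
    empty <- rowSums(a) == 0
    if (any(empty)) a[empty, which.max(mu)] <- exp(mu[which.max(mu)])
    p_true <- a / rowSums(a)
    h_true <- apply(p_true, 1, shannon)
    counts <- t(apply(p_true, 1, function(p) drop(rmultinom(1, cfg$read_depth, p))))
    dimnames(counts) <- list(sample_ids, genus_ids)

    ## dilution, batch and covariate structure of the metabolome
    d <- rnorm(n, 0, cfg$dilution_sd)
    kappa <- runif(M, -cfg$dilution_curvature, cfg$dilution_curvature)
    batch_levels <- sort(unique(batch))
    boff <- matrix(rnorm(length(batch_levels) * M, 0, cfg$batch_sd),
                   length(batch_levels), M,
                   dimnames = list(batch_levels, met_ids))
    beta_age <- rnorm(M, 0, 0.10)
    beta_sex <- rnorm(M, 0, 0.15)
    intercepts <- rnorm(M, 0, 0.5)

    ## microbial components: planted genus slopes + diversity loading
    comp <- matrix(0, n, M, dimnames = list(sample_ids, met_ids))
    et <- cfg$effect_table
    if (nrow(et)) for (r in seq_len(nrow(et)))
      comp[, et$metabolite[r]] <- comp[, et$metabolite[r]] +
        et$slope[r] * p_true[, et$genus[r]]
    comp[, cfg$focal_metabolite] <- comp[, cfg$focal_metabolite] +
      cfg$diversity_loading * h_true

    covar_term <- outer((age - 50) / 10, beta_age) + outer(sex, beta_sex)
    noise <- matrix(rnorm(n * M, 0, cfg$noise_sd), n, M)
    path_free <- sweep(comp + covar_term + noise + boff[batch, ], 2, intercepts, "+")
    dil_term <- outer(d, rep(1, M)) + sweep(outer(d^2, rep(1, M)), 2, kappa, "*")
    log_conc <- path_free + dil_term

    values <- exp(log_conc)
    miss_rate <- rep_len(cfg$missing_rate, M)
    miss <- matrix(runif(n * M) < rep(miss_rate, each = n), n, M)
    values[miss] <- NA_real_
    dimnames(values) <- list(sample_ids, met_ids)

    ## health markers with planted mediation through the focal metabolite
    mediator_path <- path_free[, cfg$focal_metabolite]
    marker_names <- c("crp", "fibrinogen", "wbc", "triglycerides", "tc_hdl",
                      "glucose", "hba1c", "ggt", "alat", "asat")
    log_scale_markers <- c("crp", "ggt", "alat", "asat")
    f <- cfg$mediation_fraction
    a_path <- cfg$diversity_loading
    markers_latent <- matrix(rnorm(n * length(marker_names), 0, cfg$marker_noise_sd),
                             n, length(marker_names),
                             dimnames = list(sample_ids, marker_names))
    markers_latent <- markers_latent + outer((age - 50) / 10,
                                             rep(0.1, length(marker_names)))
    marker_truth <- NULL
    if (length(cfg$marker_totals)) {
      bad <- setdiff(names(cfg$marker_totals), marker_names)
      if (length(bad)) stop_miomet("unknown marker(s): ", paste(bad, collapse = ", "))
      rows <- lapply(names(cfg$marker_totals), function(k) {
        total <- cfg$marker_totals[[k]]
        direct <- (1 - f) * total
        indirect <- f * total
        b_path <- indirect / a_path
        carrier <- if (cfg$marker_pathway == "metabolite") mediator_path
                   else comp[, cfg$focal_metabolite]
        markers_latent[, k] <<- markers_latent[, k] + direct * h_true +
          b_path * carrier
        data.frame(marker = k, total = total, direct = direct,
                   indirect = indirect,
                   proportion_mediated = 100 * f,
                   b_path = b_path, stringsAsFactors = FALSE)
      })
      marker_truth <- do.call(rbind, rows)
    }
    markers <- as.data.frame(markers_latent)
    for (k in intersect(log_scale_markers, marker_names))
      markers[[k]] <- exp(markers[[k]])
    markers <- cbind(sample_id = sample_ids, markers)
    rownames(markers) <- sample_ids

    truth <- list(log_dilution = setNames(d, sample_ids),
                  dilution_curvature = setNames(kappa, met_ids),
                  batch_offsets = boff,
                  effect_table = et,
                  shannon_true = setNames(h_true, sample_ids),
                  relative_abundance_true = structure(p_true,
                    dimnames = list(sample_ids, genus_ids)),
                  microbial_component = comp,
                  mediator_path = setNames(mediator_path, sample_ids),
                  dilution_free_log = structure(path_free,
                    dimnames = list(sample_ids, met_ids)),
                  marker_truth = marker_truth,
                  focal_metabolite = met_ids[cfg$focal_metabolite],
                  diversity_loading = cfg$diversity_loading,
                  mediation_fraction = cfg$mediation_fraction,
                  log_scale_markers = log_scale_markers,
                  seed = cfg$seed)

    structure(list(abundance = abundance_table(counts, depth = cfg$read_depth),
                   panel = metabolite_panel(values, state = "raw"),
                   covariates = covariates, markers = markers, truth = truth,
                   config = cfg),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> n = %d, %d genera, %d metabolites, %d batches (seed %d)\n",
              x$config$n_samples, x$config$n_genera, x$config$n_metabolites,
              x$config$n_batches, x$config$seed))
  invisible(x)
}

#' Planted slope for a target standardised effect
#'
#' Converts a standardised effect size (slope x SD(genus relative
#' abundance) / residual SD) into the raw slope to plant in an
#' `effect_table`, using the population SD of the genus's relative
#' abundance under the configured compositional model (estimated once from
#' a large calibration draw, deterministic in the config seed).
#'
#' @param config a [sim_config()].
#' @param genus genus index.
#' @param effect target standardised effect size.
#' @param n_cal calibration sample size (default 20000).
#' @return raw slope on the log-concentration scale.
#' @export
standardised_slope <- function(config, genus, effect, n_cal = 20000L) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  sd_x <- with_seed(cfg$seed + 1000003L, {
    G <- cfg$n_genera
    mu <- seq(cfg$latent_mean_range[1], cfg$latent_mean_range[2], length.out = G)
    zi <- rep_len(cfg$zero_inflation, G)
    lat <- matrix(rnorm(n_cal * G, 0, cfg$latent_sd), n_cal, G)
    lat <- sweep(lat, 2, mu, "+")
    present <- matrix(rbinom(n_cal * G, 1L, rep(1 - zi, each = n_cal)), n_cal, G)
    a <- present * exp(lat)
    empty <- rowSums(a) == 0
    if (any(empty)) a[empty, which.max(mu)] <- exp(mu[which.max(mu)])
    sd(a[, genus] / rowSums(a))
  })
  effect * cfg$noise_sd / sd_x
}

#' Simulate a toy genome-scale reconstruction database
#'
#' Stands in for a curated reconstruction resource: `n_strains` strains
#' (each assigned to a phylum) carry each of `n_reactions` reactions
#' independently with probability `carriage_prob`. Each reaction is tagged
#' with the metabolite it involves and a role (produce, degrade or
#' transport, cycled in order). A strain is secretion-capable for the
#' metabolite when it carries at least one `produce` reaction.
#'
#' @param n_strains,n_reactions positive integers.
#' @param carriage_prob probability in \[0, 1\].
#' @param seed integer seed (deterministic output).
#' @param metabolite metabolite name the reactions involve (default
#'   "benzoate").
#' @param phyla phylum labels strains are assigned to (recycled).
#' @param strain_ids optional explicit strain IDs (e.g. a cohort's genus
#'   IDs, so the toy database maps onto a simulated community); overrides
#'   `n_strains`.
#' @return object of class `recon_db`: list with data.frames `strains`
#'   (strain_id, phylum), `reactions` (reaction_id, metabolite, role),
#'   `carriage` (strain_id, reaction_id) and `secretion`
#'   (strain_id, metabolite).
#' @export
simulate_reconstruction_db <- function(n_strains, n_reactions, carriage_prob,
                                       seed = 1L, metabolite = "benzoate",
                                       phyla = c("Actinobacteria", "Bacteroidetes",
                                                 "Firmicutes", "Proteobacteria"),
                                       strain_ids = NULL) {
  if (!is.null(strain_ids)) n_strains <- length(strain_ids)
  if (n_strains < 1L || n_reactions < 1L)
    stop_miomet("n_strains and n_reactions must be positive")
  if (carriage_prob < 0 || carriage_prob > 1)
    stop_miomet("carriage_prob must be in [0, 1]")
  with_seed(seed, {
    strains <- data.frame(strain_id = strain_ids %||%
                            sprintf("strain_%03d", seq_len(n_strains)),
                          phylum = sample(rep_len(phyla, n_strains)),
                          stringsAsFactors = FALSE)
    reactions <- data.frame(reaction_id = sprintf("%s_rxn_%02d", metabolite,
                                                  seq_len(n_reactions)),
                            metabolite = metabolite,
                            role = rep_len(c("produce", "degrade", "transport"),
                                           n_reactions),
                            stringsAsFactors = FALSE)
    carried <- matrix(runif(n_strains * n_reactions) < carriage_prob,
                      n_strains, n_reactions)
    idx <- which(carried, arr.ind = TRUE)
    carriage <- data.frame(strain_id = strains$strain_id[idx[, 1]],
                           reaction_id = reactions$reaction_id[idx[, 2]],
                           stringsAsFactors = FALSE)
    produce_rxn <- reactions$reaction_id[reactions$role == "produce"]
    secretors <- unique(carriage$strain_id[carriage$reaction_id %in% produce_rxn])
    secretion <- data.frame(strain_id = secretors,
                            metabolite = rep_len(metabolite, length(secretors)),
                            stringsAsFactors = FALSE)
    recon_db(strains, reactions, carriage, secretion)
  })
}
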