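#' Pipeline configuration
#'
#' Assembles and validates the configuration of an end-to-end run. Either
#' a simulation block (a [sim_config()] or its argument list) or a set of
#' input table paths must be supplied. Stage toggles and parameters cover
#' every step: normalisation (knots, SD rule, inclusion threshold),
#' diversity, the three association screens, the elastic-net score, the
#' mediation analyses and the reaction-abundance annotation.
#'
#' @param out_dir output directory (created if absent).
#' @param seed global integer seed; all stage seeds derive from it.
#' @param sim a [sim_config()], a list of [sim_config()] arguments, or
#'   `NULL` when inputs are read from files.
#' @param inputs named list of paths (`abundance`, `metabolite`,
#'   `covariates`, `markers`, optionally `recon`) when `sim` is `NULL`.
#' @param stages character vector of stages to run, a subset of the
#'   default order.
#' @param n_knots,sd_rule,min_nonmissing normalisation parameters.
#' @param fdr_level screen FDR threshold.
#' @param screen_modes which screens to run.
#' @param score_metabolite metabolite to fit the prediction score for
#'   (default `"hippurate"`).
#' @param alphas,n_lambda,n_folds elastic-net grid parameters.
#' @param mediate_markers markers to mediate (default the planted set).
#' @param mediator `"score"` or `"metabolite"`: the mediator variable for
#'   the mediation stage.
#' @param n_boot bootstrap replications for mediation CIs.
#' @param recon list of toy reconstruction parameters (`n_reactions`,
#'   `carriage_prob`, `metabolite`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = list(), inputs = NULL,
                            stages = c("simulate", "normalise", "diversity",
                                       "screen", "score", "mediate", "annotate"),
                            n_knots = 4L, sd_rule = 4, min_nonmissing = 0.5,
                            fdr_level = 0.05,
                            screen_modes = c("abundance", "presence", "diversity"),
                            score_metabolite = "hippurate",
                            alphas = seq(0, 1, by = 0.1), n_lambda = 100L,
                            n_folds = 10L,
                            mediate_markers = c("ggt", "alat", "triglycerides"),
                            mediator = c("metabolite", "score"),
                            n_boot = 500L,
                            recon = list(n_reactions = 6L, carriage_prob = 0.4,
                                         metabolite = "benzoate")) {
  mediator <- match.arg(mediator)
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(sim) && "simulate" %in% stages)
    stages <- setdiff(stages, "simulate")
  if (!is.null(sim) && !inherits(sim, "sim_config")) {
    sim$seed <- sim$seed %||% seed
    sim <- do.call(sim_config, sim)
  }
  if (is.null(sim) && is.null(inputs))
    stop_miomet("either a simulation block or input paths are required")
  if (is.null(sim)) {
    need <- c("abundance", "metabolite", "covariates", "markers")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) stop_miomet("inputs missing: ", paste(miss, collapse = ", "))
    for (p in unlist(inputs)) if (!file.exists(p))
      stop_miomet("input path does not exist: ", p)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 inputs = inputs, stages = stages, n_knots = n_knots,
                 sd_rule = sd_rule, min_nonmissing = min_nonmissing,
                 fdr_level = fdr_level, screen_modes = screen_modes,
                 score_metabolite = score_metabolite, alphas = alphas,
                 n_lambda = as.integer(n_lambda), n_folds = as.integer(n_folds),
                 mediate_markers = mediate_markers, mediator = mediator,
                 n_boot = as.integer(n_boot), recon = recon),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate (or load), normalise,
#' diversity, screens, prediction score, mediation, annotation — persisting
#' every intermediate as TSV/JSON under `out_dir` and writing a
#' machine-readable run manifest (package version, seeds, parameters, and
#' input/output row counts at every filtering step). Identical
#' configuration and seed give byte-identical outputs. Any stage failure
#' aborts with the stage name; outputs of completed stages remain on disk.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the in-memory results of each stage and
#'   the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "miomet",
                   version = as.character(utils::packageVersion("miomet")),
                   seed = cfg$seed,
                   stages = cfg$stages,
                   parameters = cfg[c("n_knots", "sd_rule", "min_nonmissing",
                                      "fdr_level", "score_metabolite",
                                      "n_lambda", "n_folds", "mediator",
                                      "n_boot")],
                   counts = list())
  res <- list()
  out <- function(name) file.path(cfg$out_dir, name)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_miomet(sprintf("pipeline stage '%s' failed: %s", name,
                          conditionMessage(e))))
  }

  ## --- simulate / load -------------------------------------------------
  if ("simulate" %in% cfg$stages && !is.null(cfg$sim)) {
    cohort <- stage("simulate", simulate_cohort(cfg$sim))
    stage("simulate", {
      write_table(cohort$abundance, out("abundance.tsv"))
      write_table(cohort$panel, out("metabolites_raw.tsv"))
      write_table(cohort$covariates, out("covariates.tsv"))
      write_table(cohort$markers, out("markers.tsv"))
      truth_out <- cohort$truth[c("log_dilution", "effect_table",
                                  "marker_truth", "focal_metabolite",
                                  "diversity_loading", "mediation_fraction",
                                  "seed")]
      jsonlite::write_json(truth_out, out("truth.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, dataframe = "rows")
    })
  } else {
    cohort <- stage("load", list(
      abundance = read_table(cfg$inputs$abundance, "abundance"),
      panel = read_table(cfg$inputs$metabolite, "metabolite"),
      covariates = read_table(cfg$inputs$covariates, "covariates"),
      markers = read_table(cfg$inputs$markers, "markers"),
      truth = NULL))
  }
  res$cohort <- cohort
  manifest$counts$samples <- nrow(cohort$abundance)
  manifest$counts$genera <- ncol(cohort$abundance)
  manifest$counts$metabolites_raw <- ncol(cohort$panel$values)

  ## --- normalise -------------------------------------------------------
  if ("normalise" %in% cfg$stages) {
    prep <- stage("normalise",
                  prepare_panel(cohort$panel,
                                min_nonmissing_fraction = cfg$min_nonmissing,
                                n_knots = cfg$n_knots,
                                sd_multiplier = cfg$sd_rule))
    res$panel <- prep$panel
    res$dilution <- prep$dilution
    stage("normalise", {
      write_table(prep$panel, out("metabolites_normalised.tsv"))
      rep_json <- lapply(attr(prep$panel, "report"), function(r)
        r[c("n", "fit", "resid_sd")])
      jsonlite::write_json(list(fits = rep_json,
                                masked_outliers = sum(prep$panel$mask)),
                           out("normalisation_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
    kept <- ncol(prep$panel$values)
    manifest$counts$metabolites_kept <- kept
    manifest$counts$metabolites_dropped <-
      manifest$counts$metabolites_raw - kept
    manifest$counts$outlier_cells_masked <- sum(prep$panel$mask)
    manifest$normalised <- TRUE
  } else {
    # screens consume raw log values; flagged in the manifest
    res$panel <- log_transform(cohort$panel)
    res$panel$state <- "normalised"
    manifest$normalised <- FALSE
  }

  ## --- diversity -------------------------------------------------------
  if (any(c("diversity", "screen", "score", "mediate", "annotate") %in%
          cfg$stages)) {
    div <- stage("diversity", diversity_vector(cohort$abundance))
    res$diversity <- div
    if ("diversity" %in% cfg$stages)
      stage("diversity", write_table(div, out("diversity.tsv")))
  }

  ## --- screens ---------------------------------------------------------
  if ("screen" %in% cfg$stages) {
    for (mode in cfg$screen_modes) {
      sc <- stage(paste0("screen_", mode),
                  suppressWarnings(run_screen(res$panel, cohort$abundance,
                                              cohort$covariates, mode = mode,
                                              fdr_level = cfg$fdr_level,
                                              diversity = res$diversity,
                                              n_knots = cfg$n_knots)))
      res$screens[[mode]] <- sc
      stage(paste0("screen_", mode),
            write_table(as.data.frame(sc), out(paste0("screen_", mode, ".tsv"))))
      manifest$counts[[paste0("pairs_", mode)]] <-
        sum(sc$tier == "basic")
      manifest$counts[[paste0("significant_", mode)]] <-
        sum(sc$tier == "basic" & !is.na(sc$q) & sc$q < cfg$fdr_level)
    }
  }

  ## --- prediction score ------------------------------------------------
  if (any(c("score", "mediate") %in% cfg$stages)) {
    met <- cfg$score_metabolite
    vals <- panel_values(res$panel)
    if (!met %in% colnames(vals))
      stop_miomet(sprintf("pipeline stage 'score' failed: metabolite '%s' not in panel", met))
    y <- vals[, met]
    keep <- !is.na(y)
    rel <- relative_abundance(cohort$abundance)
    fit <- stage("score", enet_cv(y[keep], rel[keep, , drop = FALSE],
                                  alphas = cfg$alphas, n_lambda = cfg$n_lambda,
                                  n_folds = cfg$n_folds, seed = cfg$seed + 1L))
    score <- stage("score", predict_score(fit, rel, metabolite = met))
    res$score_fit <- fit
    res$score <- score
    if ("score" %in% cfg$stages) stage("score", {
      write_table(score, out("score.tsv"))
      jsonlite::write_json(list(metabolite = met, alpha = fit$alpha_chosen,
                                lambda = fit$lambda_chosen,
                                r2_oos = fit$r2_oos,
                                n_nonzero = sum(fit$beta != 0),
                                nonzero = names(fit$beta)[fit$beta != 0]),
                           out("score_summary.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    })
    manifest$counts$score_n <- sum(keep)
    manifest$counts$score_nonzero <- sum(fit$beta != 0)
  }

  ## --- mediation -------------------------------------------------------
  if ("mediate" %in% cfg$stages) {
    shan <- setNames(res$diversity$shannon, res$diversity$sample_id)
    mediator <- if (cfg$mediator == "score") {
      setNames(res$score$score, res$score$sample_id)
    } else {
      panel_values(res$panel)[, cfg$score_metabolite]
    }
    med_rows <- list()
    for (k in cfg$mediate_markers) {
      yk <- cohort$markers[[k]]
      names(yk) <- rownames(cohort$markers)
      if (k %in% c("crp", "ggt", "alat", "asat")) yk <- log(yk)
      m <- stage("mediate", mediate(shan, mediator, yk,
                                    covariates = cohort$covariates,
                                    n_boot = cfg$n_boot,
                                    seed = cfg$seed + 2L))
      res$mediation[[k]] <- m
      med_rows[[k]] <- data.frame(
        marker = k, total = m$effects[["total"]],
        direct = m$effects[["direct"]], indirect = m$effects[["indirect"]],
        proportion_mediated = m$proportion_mediated,
        prop_ci_low = m$ci["proportion", "lower"],
        prop_ci_high = m$ci["proportion", "upper"],
        n = m$n, stringsAsFactors = FALSE)
    }
    med_df <- do.call(rbind, med_rows)
    stage("mediate", {
      write_table(med_df, out("mediation.tsv"))
      jsonlite::write_json(med_df, out("mediation.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, dataframe = "rows")
    })
  }

  ## --- annotation ------------------------------------------------------
  if ("annotate" %in% cfg$stages) {
    db <- stage("annotate", if (!is.null(cfg$inputs$recon)) {
      read_recon_db(cfg$inputs$recon)
    } else {
      simulate_reconstruction_db(
        n_strains = ncol(cohort$abundance),
        n_reactions = cfg$recon$n_reactions,
        carriage_prob = cfg$recon$carriage_prob,
        seed = cfg$seed + 3L, metabolite = cfg$recon$metabolite,
        strain_ids = colnames(cohort$abundance))
    })
    ra <- stage("annotate", map_reaction_abundance(cohort$abundance, db,
                                                   cfg$recon$metabolite))
    frx <- stage("annotate", {
      shan <- setNames(res$diversity$shannon, res$diversity$sample_id)
      covs <- cohort$covariates[names(shan),
                                c("age", "sex", "waist"), drop = FALSE]
      do.call(rbind, lapply(colnames(ra$abundance), function(r) {
        row <- tryCatch(fractional_regress(ra$abundance[, r], shan, covs),
                        error = function(e) NULL)
        if (is.null(row)) return(NULL)
        cbind(data.frame(reaction = r,
                         role = db$reactions$role[db$reactions$reaction_id == r],
                         stringsAsFactors = FALSE), row)
      }))
    })
    res$recon_db <- db
    res$reaction_abundance <- ra
    res$fractional <- frx
    stage("annotate", {
      write_recon_db(db, out("recon_db.tsv"))
      write_table(ra$abundance, out("reaction_abundance.tsv"))
      if (!is.null(frx)) write_table(frx, out("fractional_regression.tsv"))
      sec <- secretion_capability(db, cfg$recon$metabolite)
      write_table(sec, out("secretion_capability.tsv"))
    })
    manifest$counts$reactions_mapped <- ncol(ra$abundance)
    manifest$counts$unmapped_taxa <- length(ra$unmapped_taxa)
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
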