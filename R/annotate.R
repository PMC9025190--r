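#' Construct a reconstruction database
#'
#' A minimal genome-scale reconstruction summary: which strain carries
#' which metabolic reaction, what metabolite each reaction involves and in
#' what role (produce, degrade or transport), and which strains can secrete
#' which metabolites. Reaction IDs map to exactly one role: the table is
#' reaction-keyed, not gene-keyed.
#'
#' @param strains data.frame with columns `strain_id`, `phylum`.
#' @param reactions data.frame with columns `reaction_id`, `metabolite`,
#'   `role` (from produce/degrade/transport).
#' @param carriage data.frame with columns `strain_id`, `reaction_id`.
#' @param secretion data.frame with columns `strain_id`, `metabolite`.
#' @return object of class `recon_db`.
#' @export
recon_db <- function(strains, reactions, carriage, secretion) {
  if (!all(c("strain_id", "phylum") %in% names(strains)))
    stop_miomet("strains needs strain_id, phylum")
  if (!all(c("reaction_id", "metabolite", "role") %in% names(reactions)))
    stop_miomet("reactions needs reaction_id, metabolite, role")
  if (!all(reactions$role %in% c("produce", "degrade", "transport")))
    stop_miomet("reaction roles must be produce, degrade or transport")
  if (anyDuplicated(reactions$reaction_id))
    stop_miomet("a reaction_id must map to a single role")
  if (nrow(carriage)) {
    if (!all(carriage$strain_id %in% strains$strain_id))
      stop_miomet("carriage references unknown strains")
    if (!all(carriage$reaction_id %in% reactions$reaction_id))
      stop_miomet("carriage references unknown reactions")
  }
  structure(list(strains = strains, reactions = reactions,
                 carriage = carriage, secretion = secretion),
            class = "recon_db")
}

#' @export
print.recon_db <- function(x, ...) {
  cat(sprintf("<recon_db> %d strains, %d reactions (%s), %d carriage pairs, %d secretors\n",
              nrow(x$strains), nrow(x$reactions),
              paste(unique(x$reactions$metabolite), collapse = ", "),
              nrow(x$carriage), nrow(x$secretion)))
  invisible(x)
}

#' Write / read a reconstruction database as TSV
#'
#' Long format with one row per (strain, reaction) carriage pair plus one
#' row per carriage-free strain (empty reaction fields), columns:
#' strain_id, phylum, reaction_id, metabolite, role, secretes.
#'
#' @param db a [recon_db()].
#' @param path file path.
#' @return `read_recon_db` returns a [recon_db()].
#' @export
write_recon_db <- function(db, path) {
  stopifnot(inherits(db, "recon_db"))
  rows <- merge(merge(db$carriage, db$strains, by = "strain_id"),
                db$reactions, by = "reaction_id")
  lonely <- setdiff(db$strains$strain_id, rows$strain_id)
  if (length(lonely)) {
    extra <- db$strains[db$strains$strain_id %in% lonely, ]
    rows <- rbind(rows,
                  data.frame(reaction_id = "", strain_id = extra$strain_id,
                             phylum = extra$phylum, metabolite = "", role = "",
                             stringsAsFactors = FALSE))
  }
  rows$secretes <- as.integer(rows$strain_id %in% db$secretion$strain_id)
  rows <- rows[order(rows$strain_id, rows$reaction_id),
               c("strain_id", "phylum", "reaction_id", "metabolite", "role",
                 "secretes")]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recon_db
#' @export
read_recon_db <- function(path) {
  rows <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(strain_id = "character",
                                    reaction_id = "character",
                                    metabolite = "character",
                                    role = "character"))
  strains <- unique(rows[, c("strain_id", "phylum")])
  has_rxn <- !is.na(rows$reaction_id) & rows$reaction_id != ""
  reactions <- unique(rows[has_rxn, c("reaction_id", "metabolite", "role")])
  carriage <- rows[has_rxn, c("strain_id", "reaction_id")]
  secretors <- unique(rows$strain_id[rows$secretes == 1L])
  met <- if (nrow(reactions)) reactions$metabolite[1] else NA_character_
  secretion <- data.frame(strain_id = secretors,
                          metabolite = rep_len(met, length(secretors)),
                          stringsAsFactors = FALSE)
  recon_db(strains, reactions, carriage, secretion)
}

#' Map community abundances onto reaction abundances
#'
#' For each sample and each reaction of the named metabolite, the reaction
#' abundance is the sum of the relative abundances of the taxa present in
#' the database that carry the reaction. Taxa absent from the database
#' contribute to the unmapped share `1 - mapped_fraction`; every reaction
#' abundance is therefore bounded by the per-sample mapped fraction and
#' lies in \[0, 1\].
#'
#' @param table an [abundance_table()]; column names are matched against
#'   `strain_id` in the database.
#' @param db a [recon_db()].
#' @param metabolite metabolite name whose reactions are mapped; `NULL`
#'   maps every reaction in the database.
#' @return object of class `reaction_abundance`: list with `abundance`
#'   (samples x reactions matrix in \[0,1\]), `mapped_fraction` (per-sample),
#'   `unmapped_taxa` (taxa not found in the database) and `reactions`
#'   (the reaction metadata used).
#' @export
map_reaction_abundance <- function(table, db, metabolite = NULL) {
  stopifnot(inherits(table, "abundance_table"), inherits(db, "recon_db"))
  rel <- relative_abundance(table)
  rxns <- db$reactions
  if (!is.null(metabolite)) rxns <- rxns[rxns$metabolite == metabolite, ]
  mapped_taxa <- intersect(colnames(rel), db$strains$strain_id)
  unmapped <- setdiff(colnames(rel), db$strains$strain_id)
  mapped_fraction <- rowSums(rel[, mapped_taxa, drop = FALSE])
  if (!nrow(rxns)) {
    warning(sprintf("no reactions in the database%s",
                    if (is.null(metabolite)) "" else paste0(" for ", metabolite)))
    ab <- matrix(numeric(0), nrow(rel), 0, dimnames = list(rownames(rel), NULL))
    return(structure(list(abundance = ab, mapped_fraction = mapped_fraction,
                          unmapped_taxa = unmapped, reactions = rxns),
                     class = "reaction_abundance"))
  }
  ab <- sapply(rxns$reaction_id, function(r) {
    carriers <- intersect(db$carriage$strain_id[db$carriage$reaction_id == r],
                          mapped_taxa)
    if (!length(carriers)) return(rep(0, nrow(rel)))
    rowSums(rel[, carriers, drop = FALSE])
  })
  ab <- matrix(ab, nrow = nrow(rel),
               dimnames = list(rownames(rel), rxns$reaction_id))
  structure(list(abundance = ab, mapped_fraction = mapped_fraction,
                 unmapped_taxa = unmapped, reactions = rxns),
            class = "reaction_abundance")
}

#' @export
print.reaction_abundance <- function(x, ...) {
  cat(sprintf("<reaction_abundance> %d samples x %d reactions; mean mapped fraction %.3f\n",
              nrow(x$abundance), ncol(x$abundance), mean(x$mapped_fraction)))
  invisible(x)
}

#' Secretion capability per phylum
#'
#' Counts secretion-capable strains for a metabolite per phylum, together
#' with the within-phylum share.
#'
#' @param db a [recon_db()].
#' @param metabolite metabolite name.
#' @return data.frame with columns `phylum`, `n_strains`, `n_secretors`,
#'   `share`.
#' @export
secretion_capability <- function(db, metabolite) {
  stopifnot(inherits(db, "recon_db"))
  secretors <- db$secretion$strain_id[db$secretion$metabolite == metabolite]
  if (!nrow(db$secretion) || !any(db$secretion$metabolite == metabolite))
    warning(sprintf("no secretion records for '%s'", metabolite))
  phyla <- sort(unique(db$strains$phylum))
  n_all <- table(factor(db$strains$phylum, levels = phyla))
  n_sec <- table(factor(db$strains$phylum[db$strains$strain_id %in% secretors],
                        levels = phyla))
  data.frame(phylum = phyla, n_strains = as.integer(n_all),
             n_secretors = as.integer(n_sec),
             share = as.numeric(n_sec) / as.numeric(n_all),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fractional regression of a reaction abundance on diversity
#'
#' Quasi-likelihood regression for an outcome in \[0,1\] (both endpoints
#' allowed) with a logit mean function, the Papke-Wooldridge fractional
#' logit. Fit by `glm(quasibinomial)`, with heteroscedasticity-robust
#' sandwich standard errors. The exponentiated coefficient is reported as
#' an odds ratio.
#'
#' @param outcome numeric vector in \[0,1\] (a reaction abundance column).
#' @param shannon per-sample Shannon entropy (predictor of interest).
#' @param covariates optional data.frame of additional covariates entered
#'   linearly (rows matched by position).
#' @param conf confidence level (default 0.95).
#' @return data.frame (one row) with `b` (logit-scale coefficient on
#'   Shannon), `se` (robust), `or`, `ci_low`, `ci_high` (robust, on the OR
#'   scale), `p` (two-tailed) and `n`.
#' @export
fractional_regress <- function(outcome, shannon, covariates = NULL,
                               conf = 0.95) {
  if (any(outcome < 0 | outcome > 1, na.rm = TRUE))
    stop_miomet("outcome must lie in [0, 1]")
  df <- data.frame(.y = outcome, shannon = shannon)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df$.y)) < 2L) stop_miomet("outcome is constant")
  fit <- glm(.y ~ ., data = df, family = quasibinomial(link = "logit"))
  vc <- sandwich::sandwich(fit)
  b <- coef(fit)[["shannon"]]
  se <- sqrt(vc["shannon", "shannon"])
  z <- qnorm(1 - (1 - conf) / 2)
  data.frame(b = b, se = se, or = exp(b),
             ci_low = exp(b - z * se), ci_high = exp(b + z * se),
             p = 2 * pnorm(-abs(b / se)), n = nrow(df))
}
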