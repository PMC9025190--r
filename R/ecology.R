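#' Construct an abundance table
#'
#' Samples x taxa matrix of nonnegative read counts (or relative
#' abundances). Rownames are sample IDs, colnames genus/taxon IDs.
#'
#' @param counts numeric matrix, no negative entries.
#' @param depth depth flag: `"raw"` or the rarefaction depth (integer) the
#'   table has been normalised to.
#' @return object of class `abundance_table` (a matrix with a `depth`
#'   attribute).
#' @export
abundance_table <- function(counts, depth = "raw") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_miomet("`counts` must be a numeric matrix")
  if (any(counts < 0, na.rm = TRUE)) stop_miomet("negative abundances")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  structure(counts, depth = depth, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d taxa, depth = %s\n",
              nrow(x), ncol(x), paste(attr(x, "depth"), collapse = "")))
  invisible(x)
}

#' Relative abundances of a table
#'
#' @param table an [abundance_table()].
#' @return matrix of row-wise proportions (rows sum to 1).
#' @export
relative_abundance <- function(table) {
  tot <- rowSums(table)
  if (any(tot <= 0)) stop_miomet("samples with zero total reads")
  sweep(unclass(table), 1, tot, "/")
}

#' Rarefy a count table to fixed depth
#'
#' Per sample, draws `depth` reads without replacement from the observed
#' reads (a multivariate hypergeometric draw), the standard fixed-depth
#' normalisation for 16S count tables. Samples with fewer than `depth`
#' total reads are dropped (with a message). Subsampling with replacement
#' (multinomial on the observed proportions) is available via
#' `replace = TRUE`.
#'
#' @param table an [abundance_table()] of counts.
#' @param depth target read count per sample (positive integer).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param replace draw with replacement instead (default FALSE).
#' @return rarefied [abundance_table()]; every row sums exactly to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L, replace = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0)
    stop_miomet("`depth` must be a positive integer")
  depth <- as.integer(depth)
  counts <- round(unclass(table))
  tot <- rowSums(counts)
  keep <- tot >= depth
  if (!all(keep))
    message(sprintf("rarefy: dropping %d sample(s) below depth %d", sum(!keep), depth))
  counts <- counts[keep, , drop = FALSE]
  tot <- tot[keep]
  out <- with_seed(seed, {
    res <- counts
    for (i in seq_len(nrow(counts))) {
      if (tot[i] == depth) next  # already at depth: returned unchanged
      if (replace) {
        res[i, ] <- drop(rmultinom(1, depth, counts[i, ]))
      } else {
        taxa <- rep.int(seq_len(ncol(counts)), counts[i, ])
        drawn <- taxa[sample.int(length(taxa), depth)]
        res[i, ] <- tabulate(drawn, nbins = ncol(counts))
      }
    }
    res
  })
  abundance_table(out, depth = depth)
}

#' Shannon entropy of an abundance vector
#'
#' H = -sum p_i log p_i over positive entries, natural log (nats), with
#' p the normalised abundance vector.
#'
#' @param row nonnegative abundance vector with positive sum.
#' @return Shannon entropy in nats.
#' @export
shannon <- function(row) {
  if (any(row < 0, na.rm = TRUE)) stop_miomet("negative abundances")
  s <- sum(row, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) stop_miomet("all-zero abundance vector")
  p <- row[!is.na(row) & row > 0] / s
  -sum(p * log(p))
}

#' Species richness of a count vector
#'
#' Number of taxa with strictly positive counts.
#'
#' @param row nonnegative count vector.
#' @return integer richness.
#' @export
richness <- function(row) {
  if (any(row < 0, na.rm = TRUE)) stop_miomet("negative abundances")
  sum(row > 0, na.rm = TRUE)
}

#' Per-sample alpha-diversity vector
#'
#' @param table an [abundance_table()] (ideally rarefied, so that richness
#'   is depth-comparable).
#' @return data.frame with columns `sample_id`, `shannon` (nats),
#'   `richness`.
#' @export
diversity_vector <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  m <- unclass(table)
  data.frame(sample_id = rownames(m),
             shannon = apply(m, 1, shannon),
             richness = as.integer(apply(m, 1, richness)),
             row.names = rownames(m), stringsAsFactors = FALSE)
}

#' Eligible genus-metabolite pairs for a screen
#'
#' Applies the prevalence/missingness rules that define which pairs enter
#' each association screen. In `abundance` mode a pair is eligible when the
#' genus is present (count > 0) in at least 50% of shared samples and the
#' metabolite has at least 50% present, non-zero quantifications. In
#' `presence` mode the genus prevalence must lie in the closed interval
#' \[0.20, 0.80\] (both bounds inclusive), crossed with metabolites passing
#' the same 50% rule.
#'
#' @param table an [abundance_table()].
#' @param panel a [metabolite_panel()] (any state; missingness is evaluated
#'   on present, non-zero cells of its values).
#' @param mode `"abundance"` or `"presence"`.
#' @param prevalence_min,prevalence_max genus prevalence bounds; defaults
#'   0.5/1 in abundance mode, 0.2/0.8 in presence mode.
#' @param metabolite_min minimum metabolite non-missing fraction (0.5).
#' @return data.frame with columns `genus`, `metabolite`.
#' @export
eligibility <- function(table, panel, mode = c("abundance", "presence"),
                        prevalence_min = NULL, prevalence_max = NULL,
                        metabolite_min = 0.5) {
  stopifnot(inherits(table, "abundance_table"), inherits(panel, "metabolite_panel"))
  mode <- match.arg(mode)
  shared <- intersect(rownames(table), rownames(panel$values))
  if (!length(shared)) stop_miomet("no shared samples between table and panel")
  a <- unclass(table)[shared, , drop = FALSE]
  v <- panel_values(panel)[shared, , drop = FALSE]
  prev <- colMeans(a > 0)
  if (panel$state == "raw") {
    met_frac <- colMeans(!is.na(v) & v > 0)
  } else {
    met_frac <- colMeans(!is.na(v))
  }
  lo <- prevalence_min %||% if (mode == "abundance") 0.5 else 0.2
  hi <- prevalence_max %||% if (mode == "abundance") 1.0 else 0.8
  genera <- colnames(a)[prev >= lo & prev <= hi]
  mets <- colnames(v)[met_frac >= metabolite_min]
  if (!length(genera) || !length(mets))
    return(data.frame(genus = character(), metabolite = character(),
                      stringsAsFactors = FALSE))
  expand.grid(genus = genera, metabolite = mets,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}
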