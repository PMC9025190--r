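#' Read a typed pipeline table
#'
#' Reads a tab-delimited table (UTF-8, '.' decimal, header row, first
#' column `sample_id`) and validates it against the requested schema.
#' Duplicate sample IDs and non-numeric cells in numeric columns are
#' errors naming the offender.
#'
#' @param path file path.
#' @param kind one of `"abundance"` (returns an [abundance_table()]),
#'   `"metabolite"` (raw [metabolite_panel()]; empty cells become NA),
#'   `"covariates"` or `"markers"` (data.frame with sample IDs as
#'   rownames), `"recon"` (a [recon_db()]).
#' @return typed table, see `kind`.
#' @export
read_table <- function(path, kind = c("abundance", "metabolite", "covariates",
                                      "markers", "recon")) {
  kind <- match.arg(kind)
  if (kind == "recon") return(read_recon_db(path))
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", ""))
  if (names(df)[1L] != "sample_id")
    stop_miomet("first column must be 'sample_id' in ", path)
  ids <- as.character(df$sample_id)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_miomet("duplicated sample ID(s): ", paste(unique(dup), collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  if (kind %in% c("abundance", "metabolite")) {
    for (j in seq_along(body)) {
      if (!is.numeric(body[[j]])) {
        bad <- which(!is.na(body[[j]]))[1L]
        stop_miomet(sprintf("non-numeric cell in column '%s', row %s",
                            names(body)[j], ids[bad]))
      }
    }
    m <- as.matrix(body)
    rownames(m) <- ids
    return(if (kind == "abundance") abundance_table(m)
           else metabolite_panel(m, state = "raw"))
  }
  rownames(df) <- ids
  df
}

#' Write a pipeline table as TSV
#'
#' Tab-delimited, UTF-8, '.' decimal, header row, first column
#' `sample_id`. Missing (and outlier-masked) cells are emitted as empty
#' fields.
#'
#' @param x matrix with rownames, [metabolite_panel()],
#'   [abundance_table()] or data.frame with a `sample_id` column.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_table <- function(x, path) {
  if (inherits(x, "metabolite_panel")) x <- panel_values(x)
  if (inherits(x, "abundance_table")) x <- unclass(x)
  if (is.matrix(x))
    x <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  stopifnot(is.data.frame(x))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}
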