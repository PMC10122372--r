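# Abundance containers, relative-abundance normalization and the
# prevalence-abundance filter applied before all downstream analysis.

#' Construct an abundance table
#'
#' Samples are rows, taxa are columns, values are relative abundances
#' (fractions). Unfiltered tables must have rows summing to 1; once the
#' prevalence filter has removed taxa the table is *not* re-closed (the
#' relationship matrix standardizes each taxon independently, so re-closure
#' would silently change results).
#'
#' @param abundance Numeric matrix, samples x taxa, with row and column names.
#' @param ranks Optional named character vector mapping taxon id to rank
#'   (e.g. `"genus"`).
#' @param taxonomy Optional named character vector mapping taxon id to a
#'   higher-level label (phylum), used as node metadata in networks.
#' @param filtered Logical; `TRUE` once taxa have been removed, which
#'   relaxes the row-closure invariant.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(abundance, ranks = NULL, taxonomy = NULL,
                            filtered = FALSE) {
  stopifnot(is.matrix(abundance), is.numeric(abundance))
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix must have sample row names and taxon column names")
  if (anyDuplicated(colnames(abundance)))
    stop("taxon ids must be unique")
  if (anyDuplicated(rownames(abundance)))
    stop("sample ids must be unique")
  if (any(abundance < 0 | abundance > 1, na.rm = TRUE))
    stop("relative abundances must lie in [0, 1]")
  if (!filtered) {
    rs <- rowSums(abundance)
    if (any(abs(rs - 1) > 1e-9))
      stop("each unfiltered sample row must sum to 1 (max deviation ",
           format(max(abs(rs - 1))), ")")
  }
  structure(list(abundance = abundance, ranks = ranks, taxonomy = taxonomy,
                 filtered = filtered),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa%s\n",
              nrow(x$abundance), ncol(x$abundance),
              if (x$filtered) " (filtered, not re-closed)" else ""))
  invisible(x)
}

# Accept either an abundance_table or a bare samples x taxa matrix.
as_abundance_matrix <- function(table) {
  if (inherits(table, "abundance_table")) table$abundance
  else if (is.matrix(table)) table
  else stop("expected an abundance_table or a samples x taxa matrix")
}

#' Convert a count table to relative abundances
#'
#' Each sample row is divided by its total count so that rows sum to 1.
#'
#' @param counts Nonnegative numeric matrix, samples x taxa, with dimnames.
#' @param ranks,taxonomy Passed through to [abundance_table()].
#' @return An `abundance_table`.
#' @examples
#' m <- matrix(c(2, 2, 1, 3), 2, 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2")))
#' relative_abundance(m)$abundance
#' @export
relative_abundance <- function(counts, ranks = NULL, taxonomy = NULL) {
  stopifnot(is.matrix(counts), is.numeric(counts))
  if (any(counts < 0)) stop("counts must be nonnegative")
  tot <- rowSums(counts)
  zero <- tot <= 0
  if (any(zero))
    stop("sample(s) with zero total count: ",
         paste(rownames(counts)[zero], collapse = ", "))
  abundance_table(counts / tot, ranks = ranks, taxonomy = taxonomy)
}

#' Prevalence-abundance filter
#'
#' Retains taxa whose relative abundance exceeds `min_abundance` (strictly)
#' in strictly more than `min_prevalence` of the samples — the conventional
#' "> 0.01% in more than 50% of samples" rule with both boundaries read as
#' strict. Retained abundances are not re-closed.
#'
#' @param table An `abundance_table` (or samples x taxa matrix).
#' @param min_abundance Abundance threshold as a fraction (default `1e-4`,
#'   i.e. 0.01%).
#' @param min_prevalence Prevalence threshold as a fraction of samples
#'   (default `0.5`).
#' @return A filtered `abundance_table`; the removed taxon ids are available
#'   via `attr(, "removed")`.
#' @export
prevalence_filter <- function(table, min_abundance = 1e-4,
                              min_prevalence = 0.5) {
  stopifnot(min_abundance >= 0, min_prevalence >= 0, min_prevalence <= 1)
  ab <- as_abundance_matrix(table)
  prev <- colMeans(ab > min_abundance)
  keep <- prev > min_prevalence
  if (!any(keep))
    stop("prevalence filter removed every taxon; review min_abundance/",
         "min_prevalence thresholds")
  removed <- colnames(ab)[!keep]
  out <- abundance_table(ab[, keep, drop = FALSE],
                         ranks = if (inherits(table, "abundance_table"))
                           table$ranks[colnames(ab)[keep]] else NULL,
                         taxonomy = if (inherits(table, "abundance_table"))
                           table$taxonomy[colnames(ab)[keep]] else NULL,
                         filtered = TRUE)
  attr(out, "removed") <- removed
  out
}
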