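# Shared helpers: deterministic seed substreams, TSV I/O, small utilities.

#' Derive a per-stage substream seed from a global seed
#'
#' One global seed is split into independent substreams so that individual
#' simulation stages can be regenerated on their own. The derivation is a
#' fixed integer hash kept below 2^31 - 1.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label (e.g. `"abundance"`, `"phenotypes"`).
#' @return An integer seed for `set.seed()`.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read a tab-separated table
#'
#' @param path File path. First column is used as row names when
#'   `rownames = TRUE`.
#' @param rownames Logical; treat the first column as row identifiers.
#' @return A data frame.
#' @export
read_tsv_table <- function(path, rownames = TRUE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (rownames) {
    rn <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
    rownames(df) <- rn
  }
  df
}

#' Write a table as TSV with a one-line header
#'
#' @param x Matrix or data frame.
#' @param path Output path.
#' @param id_col Name for the row-identifier column written first.
#' @export
write_tsv_table <- function(x, path, id_col = "id") {
  df <- as.data.frame(x, check.names = FALSE)
  if (!is.null(rownames(x)) && !identical(rownames(x), as.character(seq_len(nrow(df))))) {
    df <- cbind(stats::setNames(data.frame(rownames(x), stringsAsFactors = FALSE), id_col), df)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Population (divide-by-n) variance of a vector / matrix columns.
pop_var <- function(x) {
  x <- x[!is.na(x)]
  mean((x - mean(x))^2)
}

col_pop_var <- function(m) {
  mu <- colMeans(m)
  colMeans(m^2) - mu^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
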