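# Metabolomics table processing: QC-based feature filtering, probabilistic
# quotient normalization (dilution correction) with log transform, origin
# partitioning of metabolites, and hypergeometric pathway enrichment.

#' Construct a metabolite intensity table
#'
#' @param intensity Numeric matrix, samples x features; nonnegative, `NA`
#'   marks a missing (undetected) value.
#' @param is_qc Logical vector flagging pooled QC samples (rows).
#' @param state Normalization state: `"raw"`, `"pqn"` or `"pqn+log"`.
#' @return A `metabolite_table`.
#' @export
metabolite_table <- function(intensity, is_qc, state = "raw") {
  stopifnot(is.matrix(intensity), is.numeric(intensity),
            length(is_qc) == nrow(intensity), is.logical(is_qc),
            state %in% c("raw", "pqn", "pqn+log"))
  if (is.null(rownames(intensity)) || is.null(colnames(intensity)))
    stop("intensity matrix must have sample and feature names")
  if (state != "pqn+log" && any(intensity < 0, na.rm = TRUE))
    stop("intensities must be nonnegative")
  structure(list(intensity = intensity, is_qc = is_qc, state = state),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("metabolite_table [%s]: %d samples (%d QC) x %d features\n",
              x$state, nrow(x$intensity), sum(x$is_qc), ncol(x$intensity)))
  invisible(x)
}

# "Detected" = non-missing and strictly positive.
detected <- function(x) !is.na(x) & x > 0

#' QC-based feature filter
#'
#' Removes features detected in fewer than `qc_presence_min` of the QC
#' samples, and features whose relative standard deviation (population
#' SD / mean) across detected QC values strictly exceeds `rsd_max`.
#'
#' @param table A raw `metabolite_table` with at least 3 QC samples.
#' @param qc_presence_min Minimum detected fraction of QC samples
#'   (default 0.5; a feature detected in exactly half the QC samples is
#'   kept).
#' @param rsd_max Maximum QC relative standard deviation (default 0.30,
#'   strict).
#' @return The filtered `metabolite_table`; removed features are recorded in
#'   `attr(, "removed")` as `list(low_presence =, high_rsd =)`.
#' @export
qc_filter <- function(table, qc_presence_min = 0.5, rsd_max = 0.30) {
  stopifnot(inherits(table, "metabolite_table"))
  qc <- table$intensity[table$is_qc, , drop = FALSE]
  if (nrow(qc) == 0L) stop("no QC samples present")
  if (nrow(qc) < 3L) stop("need at least 3 QC samples")
  pres <- colMeans(detected(qc))
  low <- pres < qc_presence_min
  rsd <- apply(qc, 2L, function(v) {
    v <- v[detected(v)]
    if (length(v) < 2L) return(NA_real_)
    sqrt(pop_var(v)) / mean(v)
  })
  high <- !low & !is.na(rsd) & rsd > rsd_max
  keep <- !(low | high)
  out <- metabolite_table(table$intensity[, keep, drop = FALSE], table$is_qc,
                          state = table$state)
  attr(out, "removed") <- list(
    low_presence = colnames(table$intensity)[low],
    high_rsd = colnames(table$intensity)[high])
  attr(out, "qc_rsd") <- rsd[keep]
  out
}

#' Probabilistic quotient normalization (+ log transform)
#'
#' Each sample's intensities are divided by the median, across features, of
#' the ratio sample/reference — the most probable dilution quotient. The
#' reference is the feature-wise median of the QC samples (`"qc_median"`,
#' default) or of all samples (`"median"`). Features whose reference value
#' is zero or missing are excluded from quotient computation (messaged).
#' With `log_transform = TRUE` the normalized values are then natural-log
#' transformed with offset = half the minimum positive normalized value.
#'
#' @param table A `metabolite_table` in `"raw"` state (run [qc_filter()]
#'   first).
#' @param reference `"qc_median"` or `"median"`.
#' @param log_transform Apply the log step (default `TRUE`).
#' @return A `metabolite_table` in state `"pqn"` or `"pqn+log"`, with
#'   per-sample dilution quotients in `attr(, "quotients")` and the log
#'   offset (if any) in `attr(, "log_offset")`.
#' @export
pqn_normalize <- function(table, reference = c("qc_median", "median"),
                          log_transform = TRUE) {
  stopifnot(inherits(table, "metabolite_table"))
  if (table$state != "raw")
    stop("pqn_normalize expects a raw table (state is '", table$state, "')")
  reference <- match.arg(reference)
  x <- table$intensity
  ref_rows <- if (reference == "qc_median" && any(table$is_qc))
    x[table$is_qc, , drop = FALSE] else x
  ref <- apply(ref_rows, 2L, function(v) stats::median(v[detected(v)]))
  usable <- !is.na(ref) & ref > 0
  if (!any(usable)) stop("reference profile is entirely zero/missing")
  if (any(!usable))
    message(sum(!usable), " feature(s) with zero/missing reference excluded ",
            "from quotient computation")
  q <- apply(x[, usable, drop = FALSE], 1L, function(s) {
    r <- s / ref[usable]
    stats::median(r[is.finite(r) & !is.na(s)])
  })
  if (any(!is.finite(q) | q <= 0))
    stop("non-positive dilution quotient for sample(s): ",
         paste(rownames(x)[!is.finite(q) | q <= 0], collapse = ", "))
  norm <- x / q
  state <- "pqn"
  offset <- NULL
  if (log_transform) {
    pos <- norm[detected(norm)]
    offset <- if (length(pos)) min(pos) / 2 else 1
    norm <- log(norm + offset)
    state <- "pqn+log"
  }
  out <- metabolite_table(norm, table$is_qc, state = state)
  attr(out, "quotients") <- stats::setNames(q, rownames(x))
  attr(out, "log_offset") <- offset
  out
}

#' Construct an origin annotation
#'
#' Maps each metabolite to exactly one origin category (host, microbiota,
#' cometabolism, drug, food, environment, unknown) and to zero or more
#' pathway ids.
#'
#' @param origin Named character vector: feature id -> category.
#' @param pathways Named list: feature id -> character vector of pathway
#'   ids (features may be absent = no membership).
#' @return An `origin_annotation`.
#' @export
origin_annotation <- function(origin, pathways = list()) {
  cats <- c("host", "microbiota", "cometabolism", "drug", "food",
            "environment", "unknown")
  stopifnot(is.character(origin), !is.null(names(origin)))
  if (anyDuplicated(names(origin)))
    stop("duplicate origin annotation for feature(s): ",
         paste(unique(names(origin)[duplicated(names(origin))]), collapse = ", "))
  bad <- setdiff(unique(origin), cats)
  if (length(bad)) stop("unknown origin categor(ies): ",
                        paste(bad, collapse = ", "))
  structure(list(origin = origin, pathways = pathways),
            class = "origin_annotation")
}

#' Partition metabolites by origin
#'
#' Tallies features into the four reported groups: host, microbiota,
#' cometabolism and "others" (drug + food + environment + unknown).
#' Unannotated features count as unknown.
#'
#' @param features Character vector of feature ids.
#' @param annotation An `origin_annotation`.
#' @return List with `counts` (named integer vector over host, microbiota,
#'   cometabolism, others; sums to `length(features)`), `detail` (counts for
#'   the raw seven categories) and `features_by_group`.
#' @export
classify_origins <- function(features, annotation) {
  stopifnot(inherits(annotation, "origin_annotation"))
  org <- annotation$origin[features]
  org[is.na(org)] <- "unknown"
  names(org) <- features
  grp <- ifelse(org %in% c("host", "microbiota", "cometabolism"), org, "others")
  lev <- c("host", "microbiota", "cometabolism", "others")
  counts <- stats::setNames(
    as.integer(table(factor(grp, levels = lev))), lev)
  stopifnot(sum(counts) == length(features))
  list(counts = counts,
       detail = table(factor(org, levels = c("host", "microbiota",
                                             "cometabolism", "drug", "food",
                                             "environment", "unknown"))),
       features_by_group = split(features, factor(grp, levels = lev)))
}

#' Hypergeometric pathway enrichment by origin category
#'
#' Within each origin category (host, microbiota, cometabolism, plus the
#' pooled "all"), tests every pathway represented in that category's
#' universe for over-representation among the differential features:
#' one-sided tail p = P(X >= k) with X ~ Hypergeometric(N, K, n), where N is
#' the category universe size, K the pathway size in that universe, n the
#' number of differential features in the category and k the overlap.
#'
#' @param differential Character vector of differential feature ids (must be
#'   a subset of `universe`).
#' @param universe Character vector of all tested feature ids.
#' @param annotation An `origin_annotation` providing origin categories and
#'   pathway memberships.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return An `enrichment_result` data frame: `pathway`, `origin`, `k`, `K`,
#'   `n`, `N`, `p`, `significant`.
#' @export
pathway_enrichment <- function(differential, universe, annotation,
                               alpha = 0.05) {
  stopifnot(inherits(annotation, "origin_annotation"))
  if (!all(differential %in% universe))
    stop("differential features must be a subset of the universe")
  cls <- classify_origins(universe, annotation)$features_by_group
  sets <- c(cls[c("host", "microbiota", "cometabolism")],
            list(all = universe))
  rows <- list()
  for (cat in names(sets)) {
    uni <- sets[[cat]]
    if (!length(uni)) next
    diff_c <- intersect(differential, uni)
    pw_members <- annotation$pathways[intersect(names(annotation$pathways), uni)]
    pw <- sort(unique(unlist(pw_members)))
    for (pid in pw) {
      in_pw <- names(pw_members)[vapply(pw_members, function(v) pid %in% v,
                                        logical(1))]
      K <- length(in_pw)
      k <- length(intersect(diff_c, in_pw))
      N <- length(uni)
      n_d <- length(diff_c)
      p <- stats::phyper(k - 1L, K, N - K, n_d, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = pid, origin = cat, k = k, K = K, n = n_d, N = N, p = p)
    }
  }
  if (!length(rows))
    return(structure(data.frame(pathway = character(), origin = character(),
                                k = integer(), K = integer(), n = integer(),
                                N = integer(), p = numeric(),
                                significant = logical()),
                     class = c("enrichment_result", "data.frame")))
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}
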