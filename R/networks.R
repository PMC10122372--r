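# Per-group Spearman co-occurrence networks, structural comparison
# (shared/unique edges, harmonic closeness, eigenvector centrality) and
# feature-phenotype correlation panels.

# Spearman rho and p for one pair. cor.test computes the exact null
# distribution for n < 10 without ties, and the t approximation on the
# rank correlation (tie-tolerant) otherwise.
spearman_test <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L || pop_var(x) == 0 || pop_var(y) == 0)
    return(c(rho = NA_real_, p = NA_real_, n = length(x)))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  c(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Build a Spearman co-occurrence network
#'
#' All pairwise Spearman correlations among taxa within one sample group;
#' p-values are Benjamini-Hochberg adjusted across all pairs, and an edge
#' is retained when `|rho| > rho_min` and adjusted p < `alpha`
#' (the conventional dual threshold |rho| > 0.70, p.adjust < 0.05).
#' Constant taxa are excluded from pairing (with a warning).
#'
#' @param table An `abundance_table` or samples x taxa matrix for one group.
#' @param group Label stored on the network (e.g. `"HOS"`).
#' @param rho_min Absolute correlation threshold (default 0.70, strict).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param p_adjust Adjustment method for [stats::p.adjust()] (default
#'   `"BH"`).
#' @return A `correlation_network`: `group`, `nodes` (taxon, mean abundance,
#'   phylum), `edges` (all tested pairs with rho, p, p_adj, sign, retained),
#'   and the thresholds used.
#' @export
cooccurrence_network <- function(table, group = "", rho_min = 0.70,
                                 alpha = 0.05, p_adjust = "BH") {
  x <- as_abundance_matrix(table)
  if (nrow(x) < 5L) stop("need at least 5 samples per group")
  if (ncol(x) < 2L) stop("need at least 2 taxa")
  v <- col_pop_var(x)
  if (any(v == 0)) {
    warning("excluding ", sum(v == 0), " constant taxa from the network")
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("fewer than 2 non-constant taxa")
  prs <- utils::combn(colnames(x), 2L)
  res <- apply(prs, 2L, function(pr) spearman_test(x[, pr[1]], x[, pr[2]]))
  edges <- data.frame(taxon_a = prs[1, ], taxon_b = prs[2, ],
                      rho = res["rho", ], p = res["p", ],
                      row.names = NULL)
  edges$p_adj <- stats::p.adjust(edges$p, p_adjust)
  edges$sign <- ifelse(edges$rho >= 0, 1L, -1L)
  edges$retained <- !is.na(edges$rho) & abs(edges$rho) > rho_min &
    edges$p_adj < alpha
  phylum <- if (inherits(table, "abundance_table") && !is.null(table$taxonomy))
    unname(table$taxonomy[colnames(x)]) else NA_character_
  nodes <- data.frame(taxon = colnames(x), mean_abundance = colMeans(x),
                      phylum = phylum, row.names = NULL)
  structure(list(group = group, nodes = nodes, edges = edges,
                 rho_min = rho_min, alpha = alpha, p_adjust = p_adjust),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network '%s': %d nodes, %d retained edges (|rho| > %g, %s p < %g)\n",
              x$group, nrow(x$nodes), sum(x$edges$retained), x$rho_min,
              x$p_adjust, x$alpha))
  invisible(x)
}

retained_edges <- function(net) net$edges[net$edges$retained, , drop = FALSE]

# Canonical signed edge key: unordered pair + correlation sign.
edge_keys <- function(edges, signed = TRUE) {
  a <- pmin(edges$taxon_a, edges$taxon_b)
  b <- pmax(edges$taxon_a, edges$taxon_b)
  if (signed) paste(a, b, edges$sign, sep = "||") else paste(a, b, sep = "||")
}

as_igraph <- function(net) {
  e <- retained_edges(net)
  igraph::graph_from_data_frame(
    e[, c("taxon_a", "taxon_b", "rho")],
    directed = FALSE,
    vertices = net$nodes$taxon)
}

#' Compare two co-occurrence networks
#'
#' An edge is shared when the same unordered taxon pair is retained in both
#' networks with the same correlation sign (a sign flip is a structural
#' difference, not a similarity). Node centralities: harmonic closeness
#' (mean of inverse shortest-path distances, defined on disconnected
#' graphs) on each full network, and eigenvector centrality on each
#' network's largest connected component. Ranks are aligned on the nodes
#' common to both networks.
#'
#' @param a,b `correlation_network` objects built with identical thresholds.
#' @return A `network_comparison`: `shared_edges` (data frame), `n_shared`,
#'   `n_unique_a`, `n_unique_b`, `closeness` (per-node values and ranks in
#'   each network, with rank discrepancy), `eigenvector` (largest-component
#'   centrality per network), `empty` flag.
#' @export
compare_networks <- function(a, b) {
  stopifnot(inherits(a, "correlation_network"),
            inherits(b, "correlation_network"))
  if (a$rho_min != b$rho_min || a$alpha != b$alpha ||
      a$p_adjust != b$p_adjust)
    stop("networks were built with different thresholds; rebuild with ",
         "identical rho_min/alpha/p_adjust before comparing")
  ea <- retained_edges(a); eb <- retained_edges(b)
  ka <- edge_keys(ea); kb <- edge_keys(eb)
  shared_keys <- intersect(ka, kb)
  shared <- ea[ka %in% shared_keys, c("taxon_a", "taxon_b", "rho", "sign"),
               drop = FALSE]
  names(shared)[names(shared) == "rho"] <- "rho_a"
  shared$rho_b <- eb$rho[match(edge_keys(shared), kb)]
  empty <- nrow(ea) == 0L && nrow(eb) == 0L

  centr <- function(net) {
    g <- as_igraph(net)
    n <- igraph::vcount(g)
    hc <- if (n > 1L)
      igraph::harmonic_centrality(g, mode = "all", normalized = TRUE)
    else stats::setNames(numeric(n), net$nodes$taxon)
    ev <- stats::setNames(rep(NA_real_, n), igraph::V(g)$name)
    comp <- igraph::components(g)
    if (comp$no > 0L && max(comp$csize) >= 2L) {
      big <- which.max(comp$csize)
      sub <- igraph::induced_subgraph(g, which(comp$membership == big))
      evc <- igraph::eigen_centrality(sub)$vector
      ev[names(evc)] <- evc
    }
    list(closeness = hc, eigenvector = ev)
  }
  ca <- centr(a); cb <- centr(b)
  common <- intersect(a$nodes$taxon, b$nodes$taxon)
  closeness <- data.frame(
    taxon = common,
    closeness_a = unname(ca$closeness[common]),
    closeness_b = unname(cb$closeness[common]))
  closeness$rank_a <- rank(-closeness$closeness_a, ties.method = "min")
  closeness$rank_b <- rank(-closeness$closeness_b, ties.method = "min")
  closeness$rank_discrepancy <- abs(closeness$rank_a - closeness$rank_b)
  structure(list(
    group_a = a$group, group_b = b$group,
    shared_edges = shared, n_shared = nrow(shared),
    n_unique_a = nrow(ea) - nrow(shared),
    n_unique_b = nrow(eb) - nrow(shared),
    closeness = closeness,
    eigenvector = list(a = ca$eigenvector, b = cb$eigenvector),
    discrepancy = if (nrow(closeness))
      mean(closeness$rank_discrepancy) else 0,
    empty = empty),
    class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("network_comparison %s vs %s: %d shared, %d/%d unique edges%s\n",
              x$group_a, x$group_b, x$n_shared, x$n_unique_a, x$n_unique_b,
              if (x$empty) " [both empty]" else ""))
  invisible(x)
}

#' Spearman correlations between features and a target variable
#'
#' Per-feature Spearman rho and p against a per-sample target (e.g. plasma
#' OSI, or a pathway abundance). Features with fewer than `min_n` paired
#' observations are skipped (messaged). Significance stars: `*` p < 0.05,
#' `**` p < 0.01, `***` p < 0.001.
#'
#' @param features Samples x features matrix (or container).
#' @param target Numeric per-sample vector aligned with rows.
#' @param min_n Minimum paired observations (default 5).
#' @return Data frame: `feature`, `rho`, `p`, `n`, `stars`.
#' @export
feature_phenotype_correlations <- function(features, target, min_n = 5L) {
  x <- as_feature_matrix(features)
  stopifnot(nrow(x) == length(target))
  res <- lapply(colnames(x), function(f) {
    st <- spearman_test(x[, f], target)
    if (st[["n"]] < min_n) return(NULL)
    data.frame(feature = f, rho = st[["rho"]], p = st[["p"]], n = st[["n"]])
  })
  skipped <- sum(vapply(res, is.null, logical(1)))
  if (skipped) message(skipped, " feature(s) skipped (< ", min_n,
                       " paired observations)")
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame(feature = character(), rho = numeric(),
                                      p = numeric(), n = integer(),
                                      stars = character()))
  out$stars <- cut(out$p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  out$stars <- as.character(out$stars)
  rownames(out) <- NULL
  out
}
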