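# Two-group differential features: Kruskal-Wallis screening, a bootstrapped
# linear-discriminant effect size on the conventional per-million scale
# (LEfSe-style), and Wilcoxon rank-sum + fold change for metabolites.

as_feature_matrix <- function(table) {
  if (inherits(table, "abundance_table")) table$abundance
  else if (inherits(table, "metabolite_table")) table$intensity
  else if (is.matrix(table)) table
  else as.matrix(table)
}

# Tie-corrected Kruskal-Wallis H from values and a group factor.
kw_statistic <- function(v, groups) {
  r <- rank(v)
  n <- length(v)
  rbar <- tapply(r, groups, mean)
  ng <- tabulate(groups)
  H <- 12 / (n * (n + 1)) * sum(ng * (rbar - (n + 1) / 2)^2)
  ties <- table(r)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (C > 0) H / C else 0
}

# Exact permutation p for the KW H statistic: enumerate every assignment of
# the pooled observations to the group sizes and take P(H >= H_obs).
kw_exact_p <- function(v, groups) {
  groups <- as.factor(groups)
  h_obs <- kw_statistic(v, groups)
  sizes <- tabulate(groups)
  n <- length(v)
  hs <- numeric(0)
  # enumerate group labellings; the last group is fixed implicitly
  recurse2 <- function(avail, gi, lab) {
    if (gi == length(sizes)) {
      lab[avail] <- gi
      hs[length(hs) + 1L] <<- kw_statistic(v, factor(lab))
      return(invisible())
    }
    for (pick in utils::combn(seq_along(avail), sizes[gi], simplify = FALSE)) {
      lab2 <- lab; lab2[avail[pick]] <- gi
      recurse2(avail[-pick], gi + 1L, lab2)
    }
  }
  recurse2(seq_len(n), 1L, integer(n))
  mean(hs >= h_obs - 1e-9)
}

# Number of distinct assignments for the exact enumeration.
kw_enum_size <- function(sizes) {
  n <- sum(sizes)
  out <- 1
  for (s in sizes[-length(sizes)]) { out <- out * choose(n, s); n <- n - s }
  out
}

#' Kruskal-Wallis screen over features
#'
#' Per-feature Kruskal-Wallis rank test (tie-corrected H). With two groups
#' this is asymptotically equivalent to the Wilcoxon rank-sum test
#' (H = z^2). For small designs the permutation null of H is enumerated
#' exactly; larger designs use the chi-square approximation. Constant
#' features get p = 1 by convention and are flagged.
#'
#' @param table Samples x features matrix (or `abundance_table` /
#'   `metabolite_table`).
#' @param groups Group labels aligned with the rows.
#' @param exact `"auto"` (exact when the enumeration has at most
#'   `max_enum` assignments), `TRUE`, or `FALSE`.
#' @param max_enum Enumeration budget for `exact = "auto"` (default 10000).
#' @return Data frame: `feature`, `statistic`, `p`, `constant`, `exact`.
#' @export
kruskal_wallis_screen <- function(table, groups, exact = "auto",
                                  max_enum = 10000) {
  x <- as_feature_matrix(table)
  groups <- as.factor(groups)
  stopifnot(nrow(x) == length(groups), nlevels(groups) >= 2L)
  if (any(table(groups) < 2L)) stop("each group needs at least 2 samples")
  use_exact <- isTRUE(exact) ||
    (identical(exact, "auto") && kw_enum_size(tabulate(groups)) <= max_enum)
  res <- lapply(colnames(x), function(f) {
    v <- x[, f]
    if (length(unique(v)) == 1L)
      return(data.frame(feature = f, statistic = 0, p = 1, constant = TRUE,
                        exact = FALSE))
    h <- kw_statistic(v, groups)
    p <- if (use_exact) kw_exact_p(v, groups)
    else stats::pchisq(h, df = nlevels(groups) - 1L, lower.tail = FALSE)
    data.frame(feature = f, statistic = h, p = p, constant = FALSE,
               exact = use_exact)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Rescale each sample row to per-million of its total (the scale on which
# the conventional "LDA score > 2" threshold operates).
scale_per_million <- function(x) {
  tot <- rowSums(x)
  if (any(tot <= 0)) stop("sample(s) with zero total; cannot rescale")
  x / tot * 1e6
}

#' Bootstrapped linear-discriminant effect size
#'
#' For each bootstrap round a stratified subsample (fraction `subsample`
#' per class, without replacement) is drawn and a two-class
#' diagonal-regularized linear discriminant is fitted on the per-million
#' scale. With `w` the unit-norm discriminant direction,
#' `d = w . (mu_1 - mu_0)` the projected class-mean difference, and
#' `Delta_f` the raw class-mean difference of feature `f`, the per-feature
#' effect is `0.5 * (|w_f * d| + |Delta_f|)`; the reported score is
#' `log10(1 + mean over bootstraps of the effect)`. Deterministic given
#' `seed`; the caller's RNG state is untouched.
#'
#' @param table Samples x features matrix of nonnegative values; rows are
#'   rescaled to per-million internally.
#' @param groups Exactly two group labels aligned with the rows.
#' @param n_boot Bootstrap rounds (default 30).
#' @param subsample Stratified subsampling fraction (default 2/3).
#' @param seed Integer seed.
#' @return Data frame: `feature`, `lda_score`, `higher_in` (group with the
#'   larger overall mean).
#' @export
lda_effect_size <- function(table, groups, n_boot = 30L, subsample = 2/3,
                            seed = 1L) {
  x <- as_feature_matrix(table)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L) stop("lda_effect_size requires exactly two groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 samples")
  x <- scale_per_million(x)
  idx <- split(seq_len(nrow(x)), groups)
  take <- vapply(idx, function(i)
    max(2L, as.integer(ceiling(length(i) * subsample))), integer(1))
  if (any(take > lengths(idx))) take <- pmin(take, lengths(idx))

  effects <- with_seed(substream_seed(seed, "lda"), {
    acc <- matrix(0, n_boot, ncol(x))
    for (b in seq_len(n_boot)) {
      sub <- unlist(lapply(seq_along(idx),
                           function(g) sample(idx[[g]], take[g])))
      g <- groups[sub]
      x0 <- x[sub[g == levels(groups)[1]], , drop = FALSE]
      x1 <- x[sub[g == levels(groups)[2]], , drop = FALSE]
      delta <- colMeans(x1) - colMeans(x0)
      s2 <- (col_pop_var(x0) * nrow(x0) + col_pop_var(x1) * nrow(x1)) /
        (nrow(x0) + nrow(x1) - 2)
      eps <- 1e-6 * mean(s2) + 1e-12  # diagonal regularization
      w <- delta / (s2 + eps)
      nw <- sqrt(sum(w^2))
      if (nw > 0) w <- w / nw
      d <- sum(w * delta)
      acc[b, ] <- 0.5 * (abs(w * d) + abs(delta))
    }
    colMeans(acc)
  })
  mu_by <- vapply(idx, function(i) colMeans(x[i, , drop = FALSE]),
                  numeric(ncol(x)))
  higher <- levels(groups)[max.col(if (is.matrix(mu_by)) mu_by else rbind(mu_by))]
  data.frame(feature = colnames(x), lda_score = log10(1 + effects),
             higher_in = higher, row.names = NULL)
}

#' LEfSe-style differential taxa
#'
#' Kruskal-Wallis screen followed by the bootstrapped LDA effect size;
#' a taxon is flagged significant when p < `alpha` and LDA score >
#' `lda_min` (the conventional thresholds alpha = 0.05, LDA > 2).
#' Benjamini-Hochberg adjusted p-values are reported for transparency but
#' do not enter the flag.
#'
#' @inheritParams lda_effect_size
#' @param alpha Raw p-value threshold (default 0.05).
#' @param lda_min LDA score threshold (default 2).
#' @return A `differential_features` data frame: `feature`, `mean_*` per
#'   group, `higher_in`, `fold_change`, `statistic`, `p`, `p_adj`,
#'   `lda_score`, `significant`.
#' @export
lefse_differential <- function(table, groups, alpha = 0.05, lda_min = 2,
                               n_boot = 30L, subsample = 2/3, seed = 1L) {
  x <- as_feature_matrix(table)
  groups <- as.factor(as.character(groups))
  kw <- kruskal_wallis_screen(x, groups)
  ld <- lda_effect_size(x, groups, n_boot = n_boot, subsample = subsample,
                        seed = seed)
  stopifnot(identical(kw$feature, ld$feature))
  mu <- vapply(levels(groups),
               function(g) colMeans(x[groups == g, , drop = FALSE]),
               numeric(ncol(x)))
  if (!is.matrix(mu)) mu <- rbind(mu)
  num <- if ("HOS" %in% levels(groups)) "HOS" else levels(groups)[2L]
  den <- setdiff(levels(groups), num)
  fc <- fold_change_safe(mu[, num], mu[, den], x)
  out <- data.frame(feature = kw$feature,
                    stats::setNames(as.data.frame(mu),
                                    paste0("mean_", levels(groups))),
                    higher_in = ld$higher_in,
                    fold_change = fc$fc, fc_pseudo = fc$pseudo,
                    statistic = kw$statistic, p = kw$p,
                    p_adj = stats::p.adjust(kw$p, "BH"),
                    lda_score = ld$lda_score,
                    row.names = NULL)
  out$significant <- out$p < alpha & out$lda_score > lda_min
  class(out) <- c("differential_features", class(out))
  out
}

# Fold change numerator/denominator with a pseudo-count fallback when the
# denominator mean is zero (flagged).
fold_change_safe <- function(num, den, x) {
  pseudo <- den == 0 | num == 0
  if (any(pseudo)) {
    pos <- x[x > 0]
    pc <- if (length(pos)) min(pos) / 2 else 0.5
    fc <- (num + pc) / (den + pc)
    fc[!pseudo] <- num[!pseudo] / den[!pseudo]
  } else fc <- num / den
  list(fc = fc, pseudo = pseudo)
}

#' Wilcoxon rank-sum differential features with fold change
#'
#' Per-feature two-sided Wilcoxon rank-sum test: exact for groups of at
#' most 25 samples without ties, otherwise the normal approximation with
#' tie and continuity correction. Fold change is mean(`numerator`) /
#' mean(`denominator`) (HOS/LOS convention); a zero denominator switches to
#' a pseudo-count scale and is flagged. Significance is raw p < `alpha`;
#' BH-adjusted p-values are reported alongside.
#'
#' @param table Samples x features matrix (or container).
#' @param groups Two group labels aligned with rows.
#' @param numerator Group placed in the fold-change numerator (default
#'   `"HOS"`; falls back to the second level if absent).
#' @param alpha Significance level (default 0.05).
#' @return A `differential_features` data frame.
#' @export
wilcoxon_fold_change <- function(table, groups, numerator = "HOS",
                                 alpha = 0.05) {
  x <- as_feature_matrix(table)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("wilcoxon_fold_change requires exactly two groups")
  if (!numerator %in% lv) numerator <- lv[2L]
  den_g <- setdiff(lv, numerator)
  xi <- x[groups == numerator, , drop = FALSE]
  xd <- x[groups == den_g, , drop = FALSE]
  if (nrow(xi) < 2L || nrow(xd) < 2L) stop("each group needs >= 2 samples")
  exact_ok <- nrow(xi) <= 25L && nrow(xd) <= 25L
  res <- lapply(seq_len(ncol(x)), function(j) {
    a <- xi[, j]; b <- xd[, j]
    if (length(unique(c(a, b))) == 1L) {
      stat <- length(a) * length(b) / 2; p <- 1
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(a, b, exact = exact_ok && !any(duplicated(c(a, b))),
                           correct = TRUE))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    data.frame(statistic = stat, p = p)
  })
  res <- do.call(rbind, res)
  fc <- fold_change_safe(colMeans(xi), colMeans(xd), x)
  out <- data.frame(feature = colnames(x),
                    mean_num = colMeans(xi), mean_den = colMeans(xd),
                    higher_in = ifelse(colMeans(xi) >= colMeans(xd),
                                       numerator, den_g),
                    fold_change = fc$fc, fc_pseudo = fc$pseudo,
                    statistic = res$statistic, p = res$p,
                    p_adj = stats::p.adjust(res$p, "BH"),
                    row.names = NULL)
  names(out)[names(out) == "mean_num"] <- paste0("mean_", numerator)
  names(out)[names(out) == "mean_den"] <- paste0("mean_", den_g)
  out$significant <- out$p < alpha
  class(out) <- c("differential_features", class(out))
  out
}
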