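# Oxidative stress index, extreme-group selection with covariate matching,
# and the plasma-parameter group statistics (Student's t / one-way ANOVA).

#' Construct a phenotype table
#'
#' Per-sample oxidative-stress phenotype and covariates. Units follow the
#' assays: TOS in micromolar, T-AOC in millimolar, OSI dimensionless
#' (TOS and T-AOC on a common concentration scale before division).
#'
#' @param df Data frame with at least a `sample_id` column; recognised
#'   columns are `tos` (uM), `taoc` (mM), `osi`, `parity`, `milk_yield`
#'   (kg/d), `bcs` (body condition score, 1-5); any further columns are kept
#'   as plasma-panel entries.
#' @return A `phenotype_table` data frame.
#' @export
phenotype_table <- function(df) {
  stopifnot(is.data.frame(df), "sample_id" %in% names(df))
  if (anyDuplicated(df$sample_id)) stop("sample ids must be unique")
  for (col in intersect(c("tos", "taoc"), names(df))) {
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop("negative concentrations in column '", col, "'")
  }
  if (all(c("tos", "taoc", "osi") %in% names(df))) {
    ok <- !is.na(df$tos) & !is.na(df$taoc) & df$taoc > 0 & !is.na(df$osi)
    expect <- compute_osi(df$tos[ok], df$taoc[ok])
    if (any(abs(df$osi[ok] - expect) > 1e-9))
      stop("osi column inconsistent with TOS/T-AOC (uM over mM)")
  }
  class(df) <- c("phenotype_table", class(df))
  df
}

# Conversion factors to millimolar.
.to_mM <- c(M = 1e3, mM = 1, uM = 1e-3, nM = 1e-6)

#' Compute the oxidative stress index
#'
#' OSI = TOS / T-AOC after harmonizing both concentrations to a common
#' scale (millimolar). The assays are conventionally reported with TOS in
#' micromolar and T-AOC in millimolar, which are the defaults.
#'
#' @param tos Total oxidative status (vectorized).
#' @param taoc Total antioxidant capacity (vectorized); must be positive.
#' @param tos_unit,taoc_unit One of `"M"`, `"mM"`, `"uM"`, `"nM"`.
#' @return Dimensionless OSI value(s).
#' @examples
#' compute_osi(183, 0.53)  # ~0.345
#' @export
compute_osi <- function(tos, taoc, tos_unit = "uM", taoc_unit = "mM") {
  if (!tos_unit %in% names(.to_mM) || !taoc_unit %in% names(.to_mM))
    stop("unknown concentration unit; use one of: ",
         paste(names(.to_mM), collapse = ", "))
  if (any(tos < 0, na.rm = TRUE)) stop("TOS must be nonnegative")
  if (any(taoc <= 0, na.rm = TRUE))
    stop("T-AOC must be strictly positive (invalid assay value)")
  (tos * .to_mM[[tos_unit]]) / (taoc * .to_mM[[taoc_unit]])
}

# Two-sided pooled-variance t-test p-value that tolerates degenerate inputs
# (both groups constant and equal -> p = 1).
match_p <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  if (pop_var(c(x, y)) == 0) return(1)
  if (pop_var(x) == 0 && pop_var(y) == 0)
    return(if (mean(x) == mean(y)) 1 else 0)
  stats::t.test(x, y, var.equal = TRUE)$p.value
}

#' Select extreme-phenotype groups matched on covariates
#'
#' Ranks samples by OSI, takes the `k` lowest (LOS) and `k` highest (HOS),
#' then greedily swaps in next-ranked candidates from the middle of the
#' ranking until every matching covariate's two-group pooled t-test has
#' p > `match_alpha` ("similar phenotypic characteristics"). The procedure
#' is deterministic: ties are broken by sample id, and each swap is the one
#' that most improves the worst matching p-value, preferring the smallest
#' displacement in OSI rank.
#'
#' @param phenotypes A `phenotype_table` (needs `osi` plus the matching
#'   covariate columns).
#' @param k Group size (default 9).
#' @param matching Character vector of covariate columns to balance
#'   (default `c("milk_yield", "parity", "bcs")`).
#' @param match_alpha Matching significance level (default 0.10): all
#'   matching covariates must compare at p > `match_alpha`.
#' @param max_iter Swap budget.
#' @return A `group_assignment`: data frame (`sample_id`, `label` in
#'   LOS/HOS/unassigned) with attributes `k` and `matching_report` (covariate
#'   group means and final p-values).
#' @export
select_extreme_groups <- function(phenotypes, k = 9L,
                                  matching = c("milk_yield", "parity", "bcs"),
                                  match_alpha = 0.10, max_iter = 200L) {
  df <- as.data.frame(phenotypes)
  stopifnot("osi" %in% names(df), all(matching %in% names(df)))
  if (any(is.na(df$osi))) stop("OSI must be present for all samples")
  n <- nrow(df)
  if (2L * k > n) stop("2k exceeds the number of samples")
  if (diff(range(df$osi)) == 0)
    stop("all OSI values are equal: no extreme groups exist")

  ord <- order(df$osi, df$sample_id)  # deterministic under sample reordering
  los <- ord[seq_len(k)]
  hos <- ord[seq.int(n - k + 1L, n)]
  rank_of <- integer(n); rank_of[ord] <- seq_len(n)

  report <- function(los, hos) {
    do.call(rbind, lapply(matching, function(cv) {
      data.frame(covariate = cv,
                 mean_los = mean(df[[cv]][los]),
                 mean_hos = mean(df[[cv]][hos]),
                 p = match_p(df[[cv]][los], df[[cv]][hos]))
    }))
  }
  min_p <- function(los, hos)
    min(vapply(matching, function(cv) match_p(df[[cv]][los], df[[cv]][hos]),
               numeric(1)))

  if (length(matching)) {
    cur <- min_p(los, hos)
    iter <- 0L
    while (cur <= match_alpha && iter < max_iter) {
      iter <- iter + 1L
      middle <- setdiff(seq_len(n), c(los, hos))
      best <- list(p = cur, move = NULL, disp = Inf)
      for (side in c("los", "hos")) {
        grp <- if (side == "los") los else hos
        for (mi in seq_along(grp)) {
          for (cand in middle) {
            new_grp <- grp; new_grp[mi] <- cand
            p <- if (side == "los") min_p(new_grp, hos) else min_p(los, new_grp)
            disp <- abs(rank_of[cand] - rank_of[grp[mi]])
            if (p > best$p + 1e-12 ||
                (abs(p - best$p) <= 1e-12 && disp < best$disp)) {
              best <- list(p = p, move = list(side = side, mi = mi, cand = cand),
                           disp = disp)
            }
          }
        }
      }
      if (is.null(best$move) || best$p <= cur) break
      if (best$move$side == "los") los[best$move$mi] <- best$move$cand
      else hos[best$move$mi] <- best$move$cand
      cur <- best$p
    }
    if (cur <= match_alpha) {
      rep <- report(los, hos)
      cond <- structure(
        class = c("gutosi_matching_error", "error", "condition"),
        list(message = paste0(
          "no assignment satisfies covariate matching at alpha = ",
          match_alpha, " (best worst-case p = ", signif(cur, 3), ")"),
          call = sys.call(-1), best_attempt = list(
            los = df$sample_id[los], hos = df$sample_id[hos],
            matching_report = rep)))
      stop(cond)
    }
  }

  label <- rep("unassigned", n)
  label[los] <- "LOS"; label[hos] <- "HOS"
  out <- data.frame(sample_id = df$sample_id, label = label,
                    stringsAsFactors = FALSE)
  out <- out[order(out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- k
  attr(out, "matching_report") <- report(los, hos)
  class(out) <- c("group_assignment", class(out))
  out
}

#' Compare a measurement between groups
#'
#' Two groups: two-sided Student's t test with pooled variance. More than
#' two groups: one-way ANOVA, with all pairwise two-sided pooled-variance t
#' tests reported post hoc (unadjusted). Significance bands follow the
#' convention P <= 0.05 significant, 0.05 < P <= 0.10 a trend.
#'
#' @param values Numeric per-sample measurements.
#' @param groups Group labels, same length as `values`.
#' @return A `test_result` list: `statistic`, `p_value`, `test`, `summary`
#'   (per-group mean, SEM, n) and, for >2 groups, `pairwise` (data frame of
#'   unadjusted pairwise t tests).
#' @export
compare_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  summ <- do.call(rbind, lapply(names(tab), function(g) {
    x <- values[groups == g]
    data.frame(group = g, mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
               n = length(x))
  }))
  if (length(tab) == 2L) {
    g <- names(tab)
    tt <- stats::t.test(values[groups == g[1]], values[groups == g[2]],
                        var.equal = TRUE)
    res <- list(statistic = unname(tt$statistic), p_value = tt$p.value,
                test = "Student's t (pooled variance)", summary = summ,
                pairwise = NULL)
  } else {
    fit <- stats::aov(values ~ factor(groups))
    an <- summary(fit)[[1]]
    pw <- do.call(rbind, apply(utils::combn(names(tab), 2L), 2L, function(pr) {
      tt <- stats::t.test(values[groups == pr[1]], values[groups == pr[2]],
                          var.equal = TRUE)
      data.frame(group_a = pr[1], group_b = pr[2],
                 statistic = unname(tt$statistic), p = tt$p.value)
    }))
    res <- list(statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
                test = "one-way ANOVA", summary = summ, pairwise = pw)
  }
  class(res) <- "test_result"
  res
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
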