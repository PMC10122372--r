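# Independent brute-force oracles used across the suite. These deliberately
# take the dumbest correct route (dense linear algebra, full enumeration,
# BFS) so that they share no code path with the implementation they check.

# Restricted log-likelihood at variance ratio lambda, computed densely:
# V0 = lambda*M + I, GLS fixed effects, residual variance profiled out.
oracle_reml_loglik <- function(lambda, y, design, kernel) {
  X <- design; M <- kernel
  n <- length(y); p <- ncol(X)
  V0 <- lambda * M + diag(n)
  Vi <- solve(V0)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  s2e <- drop(t(r) %*% Vi %*% r) / (n - p)
  ld_V <- as.numeric(determinant(V0, logarithm = TRUE)$modulus)
  ld_X <- as.numeric(determinant(XtVX, logarithm = TRUE)$modulus)
  as.numeric(-0.5 * ((n - p) * log(s2e) + ld_V + ld_X +
                       (n - p) * (1 + log(2 * pi))))
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every split of the
# pooled sample, mirroring the two-sided rule 2 * min(tail prob, incl. obs).
oracle_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(n, n1), 2L, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  if (u_obs > mu) min(1, 2 * mean(us >= u_obs))
  else if (u_obs < mu) min(1, 2 * mean(us <= u_obs))
  else 1
}

# Exact Kruskal-Wallis permutation p: every assignment of the pooled values
# to the observed group sizes; tie-corrected H computed from scratch.
oracle_kw_p <- function(v, groups) {
  groups <- as.factor(groups)
  H <- function(lab) {
    r <- rank(v); n <- length(v)
    rbar <- tapply(r, lab, mean); ng <- table(lab)
    h <- 12 / (n * (n + 1)) * sum(ng * (rbar - (n + 1) / 2)^2)
    tt <- table(r)
    h / (1 - sum(tt^3 - tt) / (n^3 - n))
  }
  h_obs <- H(groups)
  sizes <- as.integer(table(groups))
  labs <- list(integer(length(v)))
  avail0 <- seq_along(v)
  out <- new.env(); out$hs <- numeric(0)
  rec <- function(avail, gi, lab) {
    if (gi == length(sizes)) {
      lab[avail] <- gi
      out$hs <- c(out$hs, H(factor(lab)))
      return(invisible())
    }
    cmb <- utils::combn(seq_along(avail), sizes[gi], simplify = FALSE)
    for (pick in cmb) {
      lab2 <- lab; lab2[avail[pick]] <- gi
      rec(avail[-pick], gi + 1L, lab2)
    }
  }
  rec(avail0, 1L, integer(length(v)))
  mean(out$hs >= h_obs - 1e-9)
}

# Exact two-sided Spearman permutation p: all n! permutations.
oracle_spearman_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  rho_obs <- suppressWarnings(cor(x, y, method = "spearman"))
  rx <- rank(x)
  rhos <- vapply(perms(rank(y)), function(p) cor(rx, p), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# Harmonic closeness by BFS shortest paths on an unweighted edge list.
oracle_harmonic_closeness <- function(nodes, edges) {
  adj <- stats::setNames(lapply(nodes, function(n) character()), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  vapply(nodes, function(src) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[src] <- 0
    frontier <- src
    while (length(frontier)) {
      nxt <- character()
      for (u in frontier) for (w in adj[[u]]) if (is.infinite(dist[w])) {
        dist[w] <- dist[u] + 1; nxt <- c(nxt, w)
      }
      frontier <- unique(nxt)
    }
    d <- dist[setdiff(nodes, src)]
    mean(1 / d)   # 1/Inf = 0 for unreachable nodes
  }, numeric(1))
}

# Upper-tail hypergeometric p by direct combinatorial summation.
oracle_hyper_p <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Benjamini-Hochberg step-up from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- prev
  }
  adj
}

# Median-of-ratios dilution quotient, straight from the definition.
oracle_pqn_quotients <- function(x, ref) {
  apply(x, 1L, function(s) stats::median(s / ref, na.rm = TRUE))
}

rand_composition <- function(n, k, seed) {
  set.seed(seed)
  m <- matrix(rexp(n * k), n, k,
              dimnames = list(paste0("s", seq_len(n)), paste0("t", seq_len(k))))
  m / rowSums(m)
}
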