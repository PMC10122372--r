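toy_table <- function(x) {
  dimnames(x) <- list(paste0("s", seq_len(nrow(x))),
                      paste0("t", seq_len(ncol(x))))
  x
}

test_that("perfectly concordant taxa form a retained edge with rho = 1", {
  set.seed(1)
  base <- sort(runif(9))
  x <- toy_table(cbind(base, base * 2 + 1, rnorm(9)))
  net <- cooccurrence_network(x, group = "G")
  e <- net$edges[net$edges$taxon_a == "t1" & net$edges$taxon_b == "t2", ]
  expect_equal(e$rho, 1)
  expect_true(e$retained)
})

test_that("rho matches the brute-force rank formula on tie-free data", {
  set.seed(2)
  x <- toy_table(cbind(rnorm(9), rnorm(9)))
  net <- cooccurrence_network(x)
  rho_brute <- 1 - 6 * sum((rank(x[, 1]) - rank(x[, 2]))^2) / (9 * (9^2 - 1))
  expect_equal(net$edges$rho, rho_brute, tolerance = 1e-12)
})

test_that("edge p-values are BH adjusted (verified against the definition)", {
  set.seed(3)
  x <- toy_table(matrix(rnorm(9 * 6), 9, 6))
  net <- cooccurrence_network(x)
  expect_equal(net$edges$p_adj, oracle_bh(net$edges$p), tolerance = 1e-12)
  expect_true(all(net$edges$p_adj >= net$edges$p - 1e-12))
})

test_that("networks are invariant to monotone transformation of a taxon", {
  set.seed(4)
  x <- toy_table(matrix(rexp(9 * 5), 9, 5))
  n1 <- cooccurrence_network(x)
  x2 <- x; x2[, 2] <- exp(x2[, 2])   # strictly monotone
  n2 <- cooccurrence_network(x2)
  expect_equal(n1$edges$rho, n2$edges$rho, tolerance = 1e-12)
  expect_equal(n1$edges$p, n2$edges$p, tolerance = 1e-12)
})

test_that("constant taxa are excluded from pairing with a warning", {
  set.seed(5)
  x <- toy_table(cbind(matrix(runif(18), 9, 2), 0.3))
  expect_warning(net <- cooccurrence_network(x), "constant")
  expect_false("t3" %in% c(net$edges$taxon_a, net$edges$taxon_b))
})

test_that("self-comparison shares every edge; sign flips break sharing", {
  set.seed(6)
  base <- sort(runif(9))
  x <- toy_table(cbind(base, base + runif(9, 0, 1e-3), -base, rnorm(9)))
  net <- cooccurrence_network(x, group = "A")
  cmp <- compare_networks(net, net)
  expect_equal(cmp$n_unique_a, 0L)
  expect_equal(cmp$n_unique_b, 0L)
  expect_equal(cmp$n_shared, sum(net$edges$retained))

  # flip one edge's sign in a copied network: that edge must not be shared
  net2 <- net
  i <- which(net2$edges$retained)[1]
  net2$edges$rho[i] <- -net2$edges$rho[i]
  net2$edges$sign[i] <- -net2$edges$sign[i]
  cmp2 <- compare_networks(net, net2)
  expect_equal(cmp2$n_shared, sum(net$edges$retained) - 1L)
  expect_equal(cmp2$n_unique_a, 1L)
  # shared-edge content is symmetric
  cmp3 <- compare_networks(net2, net)
  expect_setequal(edge_ids <- paste(cmp2$shared_edges$taxon_a,
                                    cmp2$shared_edges$taxon_b),
                  paste(cmp3$shared_edges$taxon_a, cmp3$shared_edges$taxon_b))
})

test_that("comparison demands identical thresholds", {
  set.seed(7)
  x <- toy_table(matrix(runif(45), 9, 5))
  a <- cooccurrence_network(x, rho_min = 0.7)
  b <- cooccurrence_network(x, rho_min = 0.8)
  expect_error(compare_networks(a, b), "thresholds")
})

test_that("harmonic closeness matches brute-force BFS on a 5-node toy", {
  # path graph a-b-c-d plus isolated e (disconnected on purpose)
  nodes <- letters[1:5]
  edges <- data.frame(taxon_a = c("a", "b", "c"), taxon_b = c("b", "c", "d"))
  fake_net <- function() {
    structure(list(
      group = "T",
      nodes = data.frame(taxon = nodes, mean_abundance = 1, phylum = NA),
      edges = data.frame(taxon_a = edges$taxon_a, taxon_b = edges$taxon_b,
                         rho = 0.9, p = 1e-5, p_adj = 1e-4, sign = 1L,
                         retained = TRUE),
      rho_min = 0.7, alpha = 0.05, p_adjust = "BH"),
      class = "correlation_network")
  }
  cmp <- compare_networks(fake_net(), fake_net())
  hc <- oracle_harmonic_closeness(nodes, edges)
  got <- setNames(cmp$closeness$closeness_a, cmp$closeness$taxon)
  expect_equal(got[nodes], hc, tolerance = 1e-12, ignore_attr = TRUE)
  # eigenvector centrality is reported on the largest component
  ev <- cmp$eigenvector$a
  expect_true(all(is.finite(ev[c("a", "b", "c", "d")])))
  expect_true(is.na(ev[["e"]]))
})

test_that("comparing empty networks yields flagged zeros", {
  set.seed(8)
  x <- toy_table(matrix(rnorm(9 * 4), 9, 4))
  net <- cooccurrence_network(x, rho_min = 0.999, alpha = 1e-9)
  cmp <- compare_networks(net, net)
  expect_true(cmp$empty)
  expect_equal(cmp$n_shared, 0L)
  expect_equal(cmp$n_unique_a + cmp$n_unique_b, 0L)
})

test_that("feature-target correlations hit the trivial extremes", {
  set.seed(9)
  target <- rnorm(9)
  x <- toy_table(cbind(target, -target, rnorm(9)))
  res <- feature_phenotype_correlations(x, target)
  expect_equal(res$rho[res$feature == "t1"], 1)
  expect_equal(res$rho[res$feature == "t2"], -1)
  expect_true(all(res$stars[res$feature %in% c("t1", "t2")] == "***"))
})

test_that("Spearman p equals the permutation enumeration for n <= 7", {
  set.seed(10)
  for (n in 5:7) {
    x <- sample(100, n); y <- sample(100, n)
    res <- feature_phenotype_correlations(
      matrix(x, n, 1, dimnames = list(paste0("s", 1:n), "f")), y, min_n = 5)
    expect_equal(res$p, oracle_spearman_p(x, y), tolerance = 1e-12,
                 label = paste("n =", n))
  }
})

test_that("features with too few paired observations are skipped", {
  x <- matrix(c(1, 2, 3, 4, NA, NA, NA, NA, NA), 9, 1,
              dimnames = list(paste0("s", 1:9), "sparse"))
  x <- cbind(x, dense = 1:9)
  expect_message(res <- feature_phenotype_correlations(x, 9:1), "skipped")
  expect_identical(res$feature, "dense")
})
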