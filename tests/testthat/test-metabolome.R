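mk_met <- function(x, n_qc) {
  n <- nrow(x)
  metabolite_table(x, is_qc = c(rep(FALSE, n - n_qc), rep(TRUE, n_qc)))
}

test_that("QC presence filter removes features below 50% detection", {
  x <- rbind(bio1 = c(10, 10), bio2 = c(10, 10),
             qc1 = c(10, 10), qc2 = c(10, NA), qc3 = c(10, NA))
  colnames(x) <- c("keep", "drop")
  out <- qc_filter(mk_met(x, 3))
  expect_identical(colnames(out$intensity), "keep")
  expect_identical(attr(out, "removed")$low_presence, "drop")
})

test_that("QC RSD uses population SD with a strict 30% boundary", {
  x <- rbind(bio = c(100, 100, 100),
             qc1 = c(100, 100, 100),
             qc2 = c(100, 150, 170),
             qc3 = c(100, 200, 240))
  colnames(x) <- c("flat", "borderline", "noisy")
  # borderline: QC (100,150,200-ish) -> pop SD/mean = 27.2% -> retained
  x["qc3", "borderline"] <- 200
  rsd <- function(v) sqrt(mean((v - mean(v))^2)) / mean(v)
  expect_equal(rsd(c(100, 150, 200)), 0.2721655, tolerance = 1e-6)
  stopifnot(rsd(x[2:4, "noisy"]) > 0.30)
  out <- qc_filter(mk_met(x, 3))
  expect_setequal(colnames(out$intensity), c("flat", "borderline"))
  expect_identical(attr(out, "removed")$high_rsd, "noisy")
})

test_that("QC filtering is idempotent and demands 3 QC samples", {
  sim <- simulate_metabolome(8, n_qc = 4, n_features = 60, seed = 3)
  once <- qc_filter(sim$table)
  twice <- qc_filter(once)
  expect_identical(once$intensity, twice$intensity)
  x <- sim$table$intensity[1:9, ]
  expect_error(qc_filter(metabolite_table(x, c(rep(FALSE, 7), TRUE, TRUE))),
               "3 QC")
})

test_that("PQN recovers noiseless dilution factors exactly", {
  ref <- c(a = 100, b = 200, c = 50, d = 400)
  x <- rbind(s1 = 2 * ref, s2 = 0.5 * ref, qc1 = ref, qc2 = ref, qc3 = ref)
  out <- pqn_normalize(mk_met(x, 3), log_transform = FALSE)
  q <- attr(out, "quotients")
  expect_equal(unname(q[c("s1", "s2")]), c(2, 0.5), tolerance = 1e-12)
  expect_equal(out$intensity["s1", ], ref, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(out$intensity["s2", ], ref, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(out$state, "pqn")
})

test_that("PQN quotients equal brute-force median of ratios", {
  sim <- simulate_metabolome(5, n_qc = 4, n_features = 20,
                             qc_missing_frac = 0, seed = 8)
  tab <- qc_filter(sim$table)
  out <- pqn_normalize(tab, log_transform = FALSE)
  ref <- apply(tab$intensity[tab$is_qc, ], 2L, median)
  expect_equal(unname(attr(out, "quotients")),
               unname(oracle_pqn_quotients(tab$intensity, ref)),
               tolerance = 1e-12)
})

test_that("identical samples give quotients of 1; scaling a sample is undone", {
  ref <- runif(10, 10, 100); names(ref) <- paste0("f", 1:10)
  x <- rbind(s1 = ref, s2 = ref, qc1 = ref, qc2 = ref, qc3 = ref)
  out <- pqn_normalize(mk_met(x, 3), log_transform = FALSE)
  expect_true(all(abs(attr(out, "quotients") - 1) < 1e-12))

  x2 <- x; x2["s1", ] <- x2["s1", ] * 13
  out2 <- pqn_normalize(mk_met(x2, 3), log_transform = FALSE)
  expect_equal(out2$intensity["s1", ], out$intensity["s1", ],
               tolerance = 1e-12)
})

test_that("log step uses half the minimum positive value and updates state", {
  sim <- simulate_metabolome(6, n_qc = 3, n_features = 15,
                             qc_missing_frac = 0, seed = 5)
  out <- pqn_normalize(sim$table)
  expect_equal(out$state, "pqn+log")
  expect_true(is.finite(attr(out, "log_offset")))
  expect_error(pqn_normalize(out), "raw")
})

test_that("origin partition tallies and conserves the feature count", {
  feats <- paste0("m", 1:10)
  ann <- origin_annotation(setNames(
    c(rep("host", 3), rep("microbiota", 2), rep("cometabolism", 4), "food"),
    feats))
  cls <- classify_origins(feats, ann)
  expect_equal(unname(cls$counts),
               c(3L, 2L, 4L, 1L))
  expect_equal(sum(cls$counts), 10L)
  # unannotated features fall into others/unknown
  cls2 <- classify_origins(c(feats, "m11"), ann)
  expect_equal(unname(cls2$counts["others"]), 2L)
  expect_equal(sum(cls2$counts), 11L)
  # empty annotation: everything is others
  cls3 <- classify_origins(feats, origin_annotation(setNames(character(0),
                                                             character(0))))
  expect_equal(unname(cls3$counts["others"]), 10L)
})

test_that("duplicate annotations are rejected", {
  expect_error(origin_annotation(setNames(c("host", "food"), c("m1", "m1"))),
               "duplicate")
})

test_that("hypergeometric enrichment matches exact combinatorial sums", {
  # spec-sized example: N = 100, K = 5, n = 10, k = 3
  expect_equal(phyper(2, 5, 95, 10, lower.tail = FALSE),
               oracle_hyper_p(3, 5, 10, 100), tolerance = 1e-12)
  set.seed(19)
  for (rep_ in 1:20) {
    N <- sample(5:30, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    feats <- paste0("m", seq_len(N))
    ann <- origin_annotation(
      setNames(rep("cometabolism", N), feats),
      pathways = setNames(c(lapply(seq_len(K), function(i) "pw"),
                            lapply(seq_len(N - K), function(i) character())),
                          feats))
    diff <- sample(feats, n)
    res <- pathway_enrichment(diff, feats, ann)
    row <- res[res$origin == "cometabolism" & res$pathway == "pw", ]
    expect_equal(row$p, oracle_hyper_p(row$k, K, n, N), tolerance = 1e-12)
  }
})

test_that("enrichment edge cases: zero overlap and saturated differentials", {
  feats <- paste0("m", 1:12)
  ann <- origin_annotation(
    setNames(rep("microbiota", 12), feats),
    pathways = setNames(c(lapply(1:4, function(i) "pwA"),
                          lapply(1:8, function(i) "pwB")), feats))
  # differential set disjoint from pwA -> k = 0 -> p = 1
  res <- pathway_enrichment(feats[5:7], feats, ann)
  rowA <- res[res$pathway == "pwA" & res$origin == "microbiota", ]
  expect_equal(rowA$k, 0L)
  expect_equal(rowA$p, 1)
  # differential = universe -> k = K deterministically -> p = 1
  res2 <- pathway_enrichment(feats, feats, ann)
  expect_true(all(res2$p == 1))
  expect_true(all(res2$k == res2$K))
  expect_error(pathway_enrichment("nope", feats, ann), "subset")
})
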