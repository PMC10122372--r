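test_that("simulated abundances are closed compositions, deterministic by seed", {
  a <- simulate_abundance_table(3, 2, seed = 1)
  expect_true(all(abs(rowSums(a$table$abundance) - 1) < 1e-12))
  b <- simulate_abundance_table(3, 2, seed = 1)
  expect_identical(a$table$abundance, b$table$abundance)
  c_ <- simulate_abundance_table(3, 2, seed = 2)
  expect_false(identical(a$table$abundance, c_$table$abundance))
  expect_error(simulate_abundance_table(1, 5), "at least 2")
  expect_error(simulate_abundance_table(
    10, 5, correlation_blocks = list(list(taxa = "genus_099", rho = 0.5))),
    "unknown taxa")
})

test_that("correlation blocks raise within-block rank correlation", {
  sim <- simulate_abundance_table(
    200, 50, correlation_blocks = list(list(taxa = 1:5, rho = 0.9)),
    seed = 7)
  ab <- sim$table$abundance
  rho <- cor(ab, method = "spearman")
  inblock <- rho[1:5, 1:5][upper.tri(matrix(0, 5, 5))]
  outblock <- rho[6:50, 6:50][upper.tri(matrix(0, 45, 45))]
  expect_gt(mean(inblock), mean(outblock))
  expect_gt(mean(inblock), 0.5)
})

test_that("marginal abundances span at least 3 orders of magnitude", {
  sim <- simulate_abundance_table(100, 80, seed = 3)
  mu <- colMeans(sim$table$abundance)
  expect_gt(log10(max(mu) / min(mu)), 3)
})

test_that("phenotype generator respects the variance split at the extremes", {
  ab <- simulate_abundance_table(30, 20, seed = 5)
  p0 <- simulate_phenotypes(ab$table, 0, seed = 1)
  expect_true(all(p0$truth$microbial_effect == 0))
  expect_false(all(p0$truth$residual == 0))
  p1 <- simulate_phenotypes(ab$table, 1, seed = 1)
  expect_true(all(p1$truth$residual == 0))
  expect_false(all(p1$truth$microbial_effect == 0))
  expect_error(simulate_phenotypes(ab$table, 1.2), "\\[0, 1\\]")
})

test_that("microbial effect variance converges to sigma2_m * mean diag M", {
  ab <- simulate_abundance_table(40, 30, seed = 11)
  M <- build_relationship_matrix(ab$table)$M
  s2m_target <- 0.6 * 0.16
  effs <- vapply(1:200, function(s)
    simulate_phenotypes(ab$table, 0.6, seed = s)$truth$microbial_effect,
    numeric(40))
  emp <- mean(apply(effs, 1, var))
  expect_equal(emp, s2m_target * mean(diag(M)), tolerance = 0.15)
})

test_that("phenotype tables from the generator are unit-consistent", {
  ab <- simulate_abundance_table(50, 25, seed = 13)
  ph <- simulate_phenotypes(ab$table, 0.4, seed = 2)$phenotypes
  ok <- !is.na(ph$tos)
  expect_equal(ph$osi[ok], compute_osi(ph$tos[ok], ph$taoc[ok]),
               tolerance = 1e-9)
  expect_true(all(ph$parity %in% 1:5))
})

test_that("metabolome generator honors QC noise and missingness settings", {
  clean <- simulate_metabolome(4, n_qc = 3, n_features = 30, qc_rsd = 0,
                               bio_noise_sd = 0, qc_missing_frac = 0, seed = 1)
  qc <- clean$table$intensity[clean$table$is_qc, ]
  expect_equal(qc[1, ], qc[2, ], tolerance = 1e-12)
  expect_equal(qc[1, ], qc[3, ], tolerance = 1e-12)

  noisy <- simulate_metabolome(6, n_qc = 4, n_features = 100,
                               qc_missing_frac = 0.1, seed = 2)
  miss <- noisy$truth$qc_missing_features
  expect_length(miss, 10)
  qcn <- noisy$table$intensity[noisy$table$is_qc, ]
  pres <- colMeans(!is.na(qcn[, miss, drop = FALSE]) &
                     qcn[, miss, drop = FALSE] > 0)
  expect_true(all(pres < 0.5))
  filt <- qc_filter(noisy$table)
  expect_true(all(miss %in% attr(filt, "removed")$low_presence))
  expect_error(simulate_metabolome(5, n_qc = 2), "3 QC")
  expect_error(simulate_metabolome(5, dilution_range = c(-1, 2)), "positive")
})

test_that("noiseless dilution factors are exactly recoverable via PQN", {
  sim <- simulate_metabolome(3, n_qc = 3, n_features = 40, qc_rsd = 0,
                             bio_noise_sd = 0, qc_missing_frac = 0, seed = 4)
  out <- pqn_normalize(sim$table, log_transform = FALSE)
  q <- attr(out, "quotients")[!sim$table$is_qc]
  expect_equal(unname(q), unname(sim$truth$dilution_factors),
               tolerance = 1e-12)
})

test_that("two-group study bundles are deterministic and carry valid truth", {
  b1 <- simulate_two_group_study(seed = 3)
  b2 <- simulate_two_group_study(seed = 3)
  expect_identical(b1$abundance$abundance, b2$abundance$abundance)
  expect_identical(b1$metabolome$intensity, b2$metabolome$intensity)
  tr <- b1$truth
  expect_true(all(names(tr$differential_taxa) %in%
                    colnames(b1$abundance$abundance)))
  expect_true(all(names(tr$differential_metabolites) %in%
                    colnames(b1$metabolome$intensity)))
  expect_true(all(tr$dilution_factors > 0))
  expect_gte(tr$true_microbiability, 0)
  expect_lte(tr$true_microbiability, 1)
  # OSI separation: HOS stochastically above LOS
  ph <- as.data.frame(b1$phenotypes)
  expect_gt(mean(ph$osi[ph$group == "HOS"]), mean(ph$osi[ph$group == "LOS"]))
  # every feature gets exactly one origin
  expect_false(anyDuplicated(names(b1$annotation$origin)) > 0)
  expect_error(simulate_two_group_study(n_per_group = 2), "at least 3")
  expect_error(simulate_two_group_study(
    diff_taxa = c(genus_999 = 4)), "unknown taxa")
})

test_that("planted 4-fold taxon shift at 9+9 is detected at p < 0.05", {
  hits <- vapply(1:5, function(s) {
    b <- simulate_two_group_study(seed = s)
    planted <- names(b$truth$differential_taxa)
    scr <- kruskal_wallis_screen(b$abundance, b$groups)
    mean(scr$p[scr$feature %in% planted] < 0.05)
  }, numeric(1))
  expect_gt(mean(hits), 0.8)  # power check across seeds
})

test_that("study bundles round-trip through TSV/JSON on disk", {
  b <- simulate_two_group_study(n_per_group = 3, n_cohort = 12, n_taxa = 20,
                                n_features = 30, seed = 9)
  dir <- tempfile("bundle_")
  files <- write_study_bundle(b, dir)
  expect_true(all(file.exists(files)))
  ab <- as.matrix(read_tsv_table(files["group_abundance"]))
  expect_equal(unname(ab), unname(b$abundance$abundance), tolerance = 1e-12)
  tr <- jsonlite::read_json(files["truth"])
  expect_equal(tr$true_microbiability, 0.431)
})
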