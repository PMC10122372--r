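# Synthetic-data generators with known ground truth. Every downstream stage
# (filtering, relationship matrix, REML, differential features, metabolome
# processing, networks) is exercised against data whose generating
# parameters are recorded in a `synthetic_truth` object.

new_truth <- function(...) {
  tr <- list(...)
  if (!is.null(tr$true_microbiability))
    stopifnot(tr$true_microbiability >= 0, tr$true_microbiability <= 1)
  if (!is.null(tr$dilution_factors)) stopifnot(all(tr$dilution_factors > 0))
  structure(tr, class = "synthetic_truth")
}

#' Simulate a compositional abundance table
#'
#' Logistic-normal generator: latent per-taxon log abundances follow a
#' one-factor-per-block Gaussian model (block members share a latent factor
#' inducing the requested within-block correlation), then each sample is
#' closed to sum to 1. Baseline taxon means are spread over ~4 orders of
#' magnitude so that the 0.01% prevalence filter has work to do.
#'
#' @param n_samples,n_taxa Dimensions (both >= 2).
#' @param correlation_blocks List of `list(taxa = <ids or indices>,
#'   rho = <within-block correlation>)`.
#' @param seed Integer seed; identical seeds give identical tables.
#' @param log_sd Per-taxon latent log-abundance SD (default 0.7).
#' @return List: `table` (an `abundance_table` with genus ranks and phylum
#'   taxonomy) and `truth` (`synthetic_truth` with the block spec and seed).
#' @export
simulate_abundance_table <- function(n_samples, n_taxa,
                                     correlation_blocks = list(),
                                     seed = 1L, log_sd = 0.7) {
  if (n_samples < 2L || n_taxa < 2L)
    stop("n_samples and n_taxa must both be at least 2")
  taxa <- sprintf("genus_%03d", seq_len(n_taxa))
  samples <- sprintf("cow_%03d", seq_len(n_samples))
  blocks <- lapply(correlation_blocks, function(bl) {
    ids <- if (is.numeric(bl$taxa)) {
      if (any(bl$taxa < 1 | bl$taxa > n_taxa))
        stop("correlation block references unknown taxa")
      taxa[bl$taxa]
    } else {
      if (!all(bl$taxa %in% taxa))
        stop("correlation block references unknown taxa: ",
             paste(setdiff(bl$taxa, taxa), collapse = ", "))
      bl$taxa
    }
    stopifnot(bl$rho >= 0, bl$rho <= 1)
    list(taxa = ids, rho = bl$rho)
  })
  ab <- with_seed(substream_seed(seed, "abundance"), {
    # taxon baselines: log10 means uniform over [-4, 0] -> ~4 decades
    mu <- log(10) * stats::runif(n_taxa, -4, 0)
    X <- matrix(stats::rnorm(n_samples * n_taxa), n_samples, n_taxa)
    for (bl in blocks) {
      j <- match(bl$taxa, taxa)
      f <- stats::rnorm(n_samples)
      X[, j] <- sqrt(bl$rho) * f + sqrt(1 - bl$rho) * X[, j]
    }
    lat <- sweep(X * log_sd, 2L, mu, "+")
    e <- exp(lat)
    e / rowSums(e)
  })
  dimnames(ab) <- list(samples, taxa)
  phyla <- paste0("Phylum_", LETTERS[1:6])
  taxonomy <- stats::setNames(
    phyla[(seq_len(n_taxa) - 1L) %% length(phyla) + 1L], taxa)
  tab <- abundance_table(ab, ranks = stats::setNames(rep("genus", n_taxa), taxa),
                         taxonomy = taxonomy)
  list(table = tab,
       truth = new_truth(correlation_blocks = blocks, seed = seed,
                         log_sd = log_sd))
}

#' Simulate phenotypes under the microbiability mixed model
#'
#' Generates `y = u + X c + m + e` with `m ~ N(0, sigma2_m * M)` where M is
#' the relationship matrix built from the supplied abundance table,
#' `sigma2_m = true_microbiability * total_variance` and residual variance
#' `(1 - true_microbiability) * total_variance`. Covariates: parity as
#' small integers (1-5) and milk yield around 36.9 kg/d (SD 8.04), plus a
#' body condition score; their effects are recorded in the truth object.
#' The phenotype is interpreted as OSI; TOS (uM) is back-computed from a
#' simulated T-AOC so the table is internally unit-consistent (TOS is NA
#' for the rare draws where y <= 0).
#'
#' @param abundance An `abundance_table` (or list as returned by
#'   [simulate_abundance_table()]).
#' @param true_microbiability Fraction in \[0, 1\] of phenotypic variance
#'   from the microbiome.
#' @param covariate_effects Named slopes for `parity` and `milk_yield`
#'   (phenotype units per covariate unit).
#' @param total_variance Total phenotypic variance (default 0.16, i.e.
#'   SD 0.4 on the OSI scale).
#' @param intercept Baseline phenotype level (default 0.66, a typical
#'   cohort-mean OSI).
#' @param seed Integer seed.
#' @return List: `phenotypes` (a `phenotype_table`), `truth`
#'   (`synthetic_truth` with the drawn microbial effect `m`, residuals,
#'   slopes and variance split).
#' @export
simulate_phenotypes <- function(abundance, true_microbiability,
                                covariate_effects = c(parity = 0.02,
                                                      milk_yield = -0.005),
                                total_variance = 0.16, intercept = 0.66,
                                seed = 1L) {
  if (true_microbiability < 0 || true_microbiability > 1)
    stop("true_microbiability must lie in [0, 1]")
  tab <- if (is.list(abundance) && !inherits(abundance, "abundance_table"))
    abundance$table else abundance
  A <- as_abundance_matrix(tab)
  n <- nrow(A)
  rm_ <- build_relationship_matrix(tab)
  eg <- eigen(rm_$M, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  s2m <- true_microbiability * total_variance
  s2e <- (1 - true_microbiability) * total_variance
  out <- with_seed(substream_seed(seed, "phenotypes"), {
    parity <- sample(1:5, n, replace = TRUE,
                     prob = c(0.25, 0.3, 0.25, 0.15, 0.05))
    milk <- stats::rnorm(n, 36.9, 8.04)
    bcs <- round(pmin(5, pmax(1, stats::rnorm(n, 2.75, 0.35))) * 4) / 4
    m <- if (s2m > 0) drop(eg$vectors %*% (sqrt(s2m * d) * stats::rnorm(n)))
    else numeric(n)
    e <- if (s2e > 0) stats::rnorm(n, sd = sqrt(s2e)) else numeric(n)
    y <- intercept + covariate_effects[["parity"]] * parity +
      covariate_effects[["milk_yield"]] * milk + m + e
    taoc <- pmax(stats::rnorm(n, 0.53, 0.03), 0.05)
    list(parity = parity, milk = milk, bcs = bcs, m = m, e = e, y = y,
         taoc = taoc)
  })
  tos <- ifelse(out$y > 0, out$y * out$taoc * 1e3, NA_real_)  # uM
  ph <- phenotype_table(data.frame(
    sample_id = rownames(A), tos = tos, taoc = out$taoc, osi = out$y,
    parity = out$parity, milk_yield = out$milk, bcs = out$bcs,
    stringsAsFactors = FALSE))
  list(phenotypes = ph,
       truth = new_truth(true_microbiability = true_microbiability,
                         covariate_effects = covariate_effects,
                         total_variance = total_variance,
                         sigma2_m = s2m, sigma2_e = s2e,
                         microbial_effect = out$m, residual = out$e,
                         seed = seed))
}

#' Simulate a metabolomics intensity table with QC replicates
#'
#' Each biological sample is the base feature profile times a per-sample
#' dilution factor times multiplicative log-normal noise; QC samples are
#' the base profile with coefficient of variation `qc_rsd`. A fraction of
#' features is set missing in most QC samples to exercise the 50%-presence
#' filter.
#'
#' @param n_samples Biological samples.
#' @param n_qc QC samples (>= 3).
#' @param n_features Feature count.
#' @param dilution_range Positive interval for the uniform per-sample
#'   dilution factors (default `c(0.5, 2)`).
#' @param qc_rsd Target QC coefficient of variation (default 0.1).
#' @param bio_noise_sd SD of the biological multiplicative log-noise
#'   (default 0.3).
#' @param qc_missing_frac Fraction of features made undetectable in > 50%
#'   of QC samples (default 0.05).
#' @param seed Integer seed.
#' @return List: `table` (raw `metabolite_table`; QC rows last) and `truth`
#'   (`synthetic_truth` with `dilution_factors`, `base_profile` and
#'   `qc_missing_features`).
#' @export
simulate_metabolome <- function(n_samples, n_qc = 6L, n_features = 200L,
                                dilution_range = c(0.5, 2), qc_rsd = 0.1,
                                bio_noise_sd = 0.3, qc_missing_frac = 0.05,
                                seed = 1L) {
  if (n_qc < 3L) stop("need at least 3 QC samples")
  if (any(dilution_range <= 0)) stop("dilution bounds must be positive")
  feats <- sprintf("met_%04d", seq_len(n_features))
  bio <- sprintf("sample_%03d", seq_len(n_samples))
  qc <- sprintf("QC_%02d", seq_len(n_qc))
  res <- with_seed(substream_seed(seed, "metabolome"), {
    base <- exp(stats::runif(n_features, log(1e3), log(1e7)))
    dil <- stats::runif(n_samples, dilution_range[1], dilution_range[2])
    noise <- function(nr, sd) {
      if (sd == 0) matrix(1, nr, n_features)
      else matrix(exp(stats::rnorm(nr * n_features, -sd^2 / 2, sd)),
                  nr, n_features)
    }
    qc_sd <- if (qc_rsd == 0) 0 else sqrt(log(1 + qc_rsd^2))
    Xb <- (dil %o% base) * noise(n_samples, bio_noise_sd)
    Xq <- rep(1, n_qc) %o% base * noise(n_qc, qc_sd)
    miss <- sample(feats, round(qc_missing_frac * n_features))
    if (length(miss)) {
      # undetected in all but one QC sample -> presence < 50%
      Xq[seq_len(n_qc - 1L), match(miss, feats)] <- NA
    }
    list(Xb = Xb, Xq = Xq, base = base, dil = dil, miss = miss)
  })
  x <- rbind(res$Xb, res$Xq)
  dimnames(x) <- list(c(bio, qc), feats)
  tab <- metabolite_table(x, is_qc = c(rep(FALSE, n_samples), rep(TRUE, n_qc)))
  list(table = tab,
       truth = new_truth(dilution_factors = stats::setNames(res$dil, bio),
                         base_profile = stats::setNames(res$base, feats),
                         qc_missing_features = res$miss, qc_rsd = qc_rsd,
                         seed = seed))
}

#' Simulate a complete two-group oxidative-stress study
#'
#' Emulates the study's two tiers with one consistent ground truth:
#' an association cohort (compositional abundances plus phenotypes drawn
#' under the microbiability mixed model, used for variance-component
#' estimation and extreme-group selection), and an extreme-group comparison
#' set of `n_per_group` HOS and LOS samples (default 9 + 9) carrying
#' planted multiplicative taxon shifts, planted log2 fold changes in the
#' metabolome, group-separated OSI, and an origin/pathway annotation in
#' which the planted differential metabolites concentrate in two target
#' pathways.
#'
#' @param n_per_group Samples per group (>= 3; default 9).
#' @param n_cohort Association-cohort size (default 63).
#' @param n_taxa Taxa in both tiers (default 120).
#' @param n_features Metabolome features (default 300).
#' @param n_qc QC samples (default 6).
#' @param true_microbiability Cohort ground truth (default 0.431).
#' @param diff_taxa Named numeric vector: taxon id (or index) ->
#'   multiplicative HOS/LOS abundance shift. Default: 5 taxa at 4-fold.
#' @param diff_metabolites Named numeric vector: feature id (or index) ->
#'   log2 fold change in HOS. Default: 10 features at log2 FC in
#'   {-1.5, ..., 1.5}.
#' @param osi_means,osi_sd Group OSI means (LOS, HOS) and common SD.
#' @param seed Integer seed.
#' @return List with `cohort` (abundance table + phenotypes + truth),
#'   `groups` (per-sample labels), `abundance`, `metabolome`, `annotation`,
#'   and `truth` (planted effects and parameters).
#' @export
simulate_two_group_study <- function(n_per_group = 9L, n_cohort = 63L,
                                     n_taxa = 120L, n_features = 300L,
                                     n_qc = 6L,
                                     true_microbiability = 0.431,
                                     diff_taxa = NULL,
                                     diff_metabolites = NULL,
                                     osi_means = c(LOS = 0.34, HOS = 1.02),
                                     osi_sd = 0.20, seed = 1L) {
  if (n_per_group < 3L) stop("group sizes must be at least 3")
  taxa <- sprintf("genus_%03d", seq_len(n_taxa))
  feats <- sprintf("met_%04d", seq_len(n_features))
  if (is.null(diff_taxa)) {
    j <- utils::head(seq(5L, n_taxa, by = 12L), 5L)
    if (!length(j)) j <- n_taxa
    diff_taxa <- stats::setNames(rep(4, length(j)), taxa[j])
  }
  if (is.null(names(diff_taxa)))
    stop("diff_taxa must be a named vector of multiplicative effects")
  if (!all(names(diff_taxa) %in% taxa))
    stop("diff_taxa references unknown taxa: ",
         paste(setdiff(names(diff_taxa), taxa), collapse = ", "))
  if (is.null(diff_metabolites)) {
    j <- utils::head(seq(10L, n_features, by = 25L), 10L)
    if (!length(j)) j <- n_features
    diff_metabolites <- stats::setNames(
      seq(-1.5, 1.5, length.out = length(j)), feats[j])
  }
  if (!all(names(diff_metabolites) %in% feats))
    stop("diff_metabolites references unknown features: ",
         paste(setdiff(names(diff_metabolites), feats), collapse = ", "))

  # Tier 1: association cohort under the mixed model.
  coh_ab <- simulate_abundance_table(
    n_cohort, n_taxa,
    correlation_blocks = list(list(taxa = taxa[1:6], rho = 0.8),
                              list(taxa = taxa[7:12], rho = 0.6)),
    seed = substream_seed(seed, "cohort"))
  # Phenotypes are generated from the prevalence-filtered table so that the
  # planted microbiability refers to the estimand the analysis computes
  # (the study's M is likewise built after the 0.01%/50% filter); taxa below
  # the filter carry no phenotype signal.
  coh_filtered <- prevalence_filter(coh_ab$table)
  coh_ph <- simulate_phenotypes(coh_filtered, true_microbiability,
                                seed = substream_seed(seed, "cohort_ph"))

  # Tier 2: the 2k extreme-group animals with planted effects.
  n2 <- 2L * n_per_group
  grp_samples <- c(sprintf("LOS_%02d", seq_len(n_per_group)),
                   sprintf("HOS_%02d", seq_len(n_per_group)))
  labels <- stats::setNames(rep(c("LOS", "HOS"), each = n_per_group),
                            grp_samples)
  grp <- with_seed(substream_seed(seed, "groups"), {
    mu <- log(10) * stats::runif(n_taxa, -4, 0)
    lat <- matrix(stats::rnorm(n2 * n_taxa), n2, n_taxa)
    # Very tight co-occurrence blocks: with k = 9 samples per group and BH
    # across all pairs, only near-perfectly concordant taxon pairs can be
    # retained, as in real genus tables where strongly co-varying taxa
    # drive the networks. Blocks are shared between groups; group-specific
    # noise makes some edges unique to one group.
    blocks2 <- Filter(function(bl) max(bl$j) <= ceiling(n_taxa / 3),
                      list(list(j = 1:8, rho = 0.99),
                           list(j = 9:14, rho = 0.97),
                           list(j = 15:19, rho = 0.95)))
    for (bl in blocks2) {
      f <- stats::rnorm(n2)
      lat[, bl$j] <- sqrt(bl$rho) * f + sqrt(1 - bl$rho) * lat[, bl$j]
    }
    lat <- sweep(lat * 0.7, 2L, mu, "+")
    j <- match(names(diff_taxa), taxa)
    lat[labels == "HOS", j] <-
      sweep(lat[labels == "HOS", j, drop = FALSE], 2L, log(diff_taxa), "+")
    e <- exp(lat)
    ab <- e / rowSums(e)
    osi <- c(stats::rnorm(n_per_group, osi_means[["LOS"]], osi_sd),
             stats::rnorm(n_per_group, osi_means[["HOS"]], osi_sd))
    osi <- pmax(osi, 0.01)
    parity <- sample(1:4, n2, replace = TRUE)
    milk <- stats::rnorm(n2, 36.9, 8.04)
    bcs <- round(pmin(5, pmax(1, stats::rnorm(n2, 2.75, 0.35))) * 4) / 4
    taoc <- pmax(stats::rnorm(n2, 0.53, 0.03), 0.05)
    list(ab = ab, osi = osi, parity = parity, milk = milk, bcs = bcs,
         taoc = taoc)
  })
  dimnames(grp$ab) <- list(grp_samples, taxa)
  phyla <- paste0("Phylum_", LETTERS[1:6])
  gr_tab <- abundance_table(
    grp$ab, ranks = stats::setNames(rep("genus", n_taxa), taxa),
    taxonomy = stats::setNames(phyla[(seq_len(n_taxa) - 1L) %% 6L + 1L], taxa))
  gr_ph <- phenotype_table(data.frame(
    sample_id = grp_samples, tos = grp$osi * grp$taoc * 1e3, taoc = grp$taoc,
    osi = grp$osi, parity = grp$parity, milk_yield = grp$milk, bcs = grp$bcs,
    group = unname(labels), stringsAsFactors = FALSE))

  # Metabolome for the group animals + planted log2 fold changes in HOS.
  met <- simulate_metabolome(n2, n_qc = n_qc, n_features = n_features,
                             seed = substream_seed(seed, "met"))
  mx <- met$table$intensity
  rownames(mx)[seq_len(n2)] <- grp_samples
  jm <- match(names(diff_metabolites), feats)
  hos_rows <- which(rownames(mx) %in% grp_samples[labels == "HOS"])
  mx[hos_rows, jm] <- sweep(mx[hos_rows, jm, drop = FALSE], 2L,
                            2^diff_metabolites, "*")
  met_tab <- metabolite_table(mx, met$table$is_qc)

  # Origin + pathway annotation; planted differentials concentrate in two
  # target pathways (microbiota / cometabolism) so enrichment can find them.
  ann <- with_seed(substream_seed(seed, "annotation"), {
    cats <- sample(c("host", "microbiota", "cometabolism", "drug", "food",
                     "environment", "unknown"),
                   n_features, replace = TRUE,
                   prob = c(0.02, 0.07, 0.17, 0.11, 0.29, 0.01, 0.33))
    names(cats) <- feats
    cats[names(diff_metabolites)] <-
      rep(c("microbiota", "cometabolism"),
          length.out = length(diff_metabolites))
    pw_ids <- sprintf("path_%02d", 1:20)
    pws <- lapply(feats, function(f) {
      k <- sample(0:3, 1L, prob = c(0.3, 0.4, 0.2, 0.1))
      if (k == 0L) character() else sample(pw_ids[3:20], k)
    })
    names(pws) <- feats
    half <- length(diff_metabolites) %/% 2L
    for (f in names(diff_metabolites)[seq_len(half)])
      pws[[f]] <- unique(c("path_01", pws[[f]]))
    for (f in names(diff_metabolites)[seq.int(half + 1L,
                                              length(diff_metabolites))])
      pws[[f]] <- unique(c("path_02", pws[[f]]))
    origin_annotation(cats, pws)
  })

  list(cohort = list(abundance = coh_ab$table,
                     phenotypes = coh_ph$phenotypes,
                     truth = coh_ph$truth,
                     abundance_truth = coh_ab$truth),
       groups = labels,
       abundance = gr_tab,
       phenotypes = gr_ph,
       metabolome = met_tab,
       annotation = ann,
       truth = new_truth(true_microbiability = true_microbiability,
                         differential_taxa = diff_taxa,
                         differential_metabolites = diff_metabolites,
                         dilution_factors = met$truth$dilution_factors,
                         osi_means = osi_means, osi_sd = osi_sd,
                         n_per_group = n_per_group, seed = seed))
}

#' Write a simulated study bundle to disk
#'
#' All tables as TSV with a one-line header; the truth object as JSON.
#'
#' @param bundle Output of [simulate_two_group_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    cohort_abundance = file.path(dir, "cohort_abundance.tsv"),
    cohort_phenotypes = file.path(dir, "cohort_phenotypes.tsv"),
    group_abundance = file.path(dir, "group_abundance.tsv"),
    group_phenotypes = file.path(dir, "group_phenotypes.tsv"),
    metabolome = file.path(dir, "metabolome_intensities.tsv"),
    annotation = file.path(dir, "metabolite_annotation.tsv"),
    truth = file.path(dir, "truth.json"))
  write_tsv_table(bundle$cohort$abundance$abundance, files["cohort_abundance"],
                  id_col = "sample_id")
  utils::write.table(as.data.frame(bundle$cohort$phenotypes),
                     files["cohort_phenotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_tsv_table(bundle$abundance$abundance, files["group_abundance"],
                  id_col = "sample_id")
  utils::write.table(as.data.frame(bundle$phenotypes),
                     files["group_phenotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  met <- cbind(data.frame(sample_id = rownames(bundle$metabolome$intensity),
                          is_qc = bundle$metabolome$is_qc),
               as.data.frame(bundle$metabolome$intensity))
  utils::write.table(met, files["metabolome"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann <- data.frame(
    feature = names(bundle$annotation$origin),
    origin = unname(bundle$annotation$origin),
    pathways = vapply(names(bundle$annotation$origin), function(f)
      paste(bundle$annotation$pathways[[f]] %||% character(), collapse = ";"),
      character(1)))
  utils::write.table(ann, files["annotation"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tr <- bundle$truth
  tr_json <- lapply(unclass(tr), function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
  jsonlite::write_json(tr_json, files["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(files)
}
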