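# Orchestration of the full study flow: simulate (or ingest) -> extreme
# groups -> prevalence filter -> microbiability -> differential features ->
# metabolome workflow -> co-occurrence networks -> report, with a
# machine-readable run manifest (hashes, decisions in effect, timings).

#' Build and validate a run configuration
#'
#' Every analysis threshold is a named, defaulted field, so the zero-config
#' behavior reproduces the conventional thresholds (0.01% / 50% prevalence
#' filter, |rho| > 0.70 with BH-adjusted p < 0.05 networks, LDA score > 2,
#' QC presence 50% / RSD 30%). Configuration may also be read from a YAML
#' file.
#'
#' @param ... Named fields overriding the defaults (see Details).
#' @param file Optional YAML file whose fields are merged (explicit `...`
#'   arguments win).
#' @return A validated `run_config` list.
#' @details Fields: `seed`, `out_dir`, `simulate` (logical), simulation
#'   shape (`n_per_group`, `n_cohort`, `n_taxa`, `n_features`,
#'   `true_microbiability`), input paths when `simulate = FALSE`
#'   (`abundance`, `phenotypes`, `metabolome`, `annotation`), thresholds
#'   (`min_abundance`, `min_prevalence`, `rho_min`, `alpha`, `lda_min`,
#'   `qc_presence_min`, `rsd_max`, `match_alpha`), `covariates`,
#'   `phenotype_col`, `k`.
#' @export
run_config <- function(..., file = NULL) {
  defaults <- list(
    seed = 1L, out_dir = tempfile("gutosi_run_"), simulate = TRUE,
    n_per_group = 9L, n_cohort = 63L, n_taxa = 120L, n_features = 300L,
    true_microbiability = 0.431,
    abundance = NULL, phenotypes = NULL, metabolome = NULL, annotation = NULL,
    min_abundance = 1e-4, min_prevalence = 0.5,
    rho_min = 0.70, alpha = 0.05, lda_min = 2,
    qc_presence_min = 0.5, rsd_max = 0.30, match_alpha = 0.10,
    covariates = c("parity", "milk_yield"), phenotype_col = "osi", k = 9L)
  cfg <- defaults
  if (!is.null(file)) cfg <- utils::modifyList(cfg, yaml::read_yaml(file))
  override <- list(...)
  if (length(override)) {
    unknown <- setdiff(names(override), names(defaults))
    if (length(unknown)) stop("unknown config field(s): ",
                              paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(cfg, override)
  }
  check_frac <- function(field, lo = 0, hi = 1) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || v < lo || v > hi)
      stop("config field '", field, "' must be a number in [", lo, ", ",
           hi, "]")
  }
  for (f in c("min_abundance", "min_prevalence", "alpha", "qc_presence_min",
              "rsd_max", "match_alpha", "true_microbiability"))
    check_frac(f)
  check_frac("rho_min", 0, 1)
  if (!is.numeric(cfg$lda_min) || cfg$lda_min < 0)
    stop("config field 'lda_min' must be nonnegative")
  if (cfg$k < 3L) stop("config field 'k' must be at least 3")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

stage_hashes <- function(files) {
  h <- tools::md5sum(files)
  stats::setNames(unname(h), basename(files))
}

#' Run the full study pipeline
#'
#' Executes the stages in dependency order, writing every stage's tables
#' under `config$out_dir` and recording a manifest (per-stage output
#' hashes, decisions in effect, timings). Reruns with an identical config
#' and seed produce bit-identical stage outputs.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with `manifest` and all stage `outputs`.
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("gutosi")),
    seed = config$seed,
    decisions = list(
      sigma2_p_convention = "model (sigma2_m + sigma2_e)",
      p_adjust = "BH",
      shared_edge_rule = "same unordered pair and same correlation sign",
      prevalence_boundaries = "strict (> 0.01% in > 50% of samples)",
      fold_change_orientation = "HOS/LOS"),
    stages = list())
  outputs <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    list(result = res, elapsed = proc.time()[["elapsed"]] - t0, name = name)
  }
  add_stage <- function(name, files, elapsed) {
    manifest$stages[[name]] <<- list(outputs = as.list(stage_hashes(files)),
                                     elapsed_s = round(elapsed, 3))
  }

  # -- stage: inputs (simulate or ingest) ------------------------------------
  st <- t_stage("inputs", {
    if (isTRUE(config$simulate)) {
      simulate_two_group_study(
        n_per_group = config$k, n_cohort = config$n_cohort,
        n_taxa = config$n_taxa, n_features = config$n_features,
        true_microbiability = config$true_microbiability, seed = config$seed)
    } else {
      read_study_inputs(config)
    }
  })
  bundle <- st$result
  files <- write_study_bundle(bundle, file.path(config$out_dir, "inputs"))
  add_stage("inputs", files, st$elapsed)
  outputs$bundle <- bundle

  # -- stage: redox (OSI groups on the cohort) -------------------------------
  st <- t_stage("redox", {
    select_extreme_groups(bundle$cohort$phenotypes, k = config$k,
                          matching = c("milk_yield", "parity", "bcs"),
                          match_alpha = config$match_alpha)
  })
  ga <- st$result
  f <- file.path(config$out_dir, "group_assignment.tsv")
  utils::write.table(as.data.frame(ga), f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add_stage("redox", f, st$elapsed)
  outputs$group_assignment <- ga

  # -- stage: filter ---------------------------------------------------------
  st <- t_stage("filter", {
    list(cohort = prevalence_filter(bundle$cohort$abundance,
                                    config$min_abundance,
                                    config$min_prevalence),
         groups = prevalence_filter(bundle$abundance, config$min_abundance,
                                    config$min_prevalence))
  })
  filt <- st$result
  f <- file.path(config$out_dir, "filtered_cohort_abundance.tsv")
  write_tsv_table(filt$cohort$abundance, f, id_col = "sample_id")
  add_stage("filter", f, st$elapsed)
  outputs$filtered <- filt

  # -- stage: microbiability -------------------------------------------------
  st <- t_stage("microbiability", {
    ph <- as.data.frame(bundle$cohort$phenotypes)
    M <- build_relationship_matrix(filt$cohort)
    fit <- fit_lmm_reml(ph[[config$phenotype_col]],
                        ph[, config$covariates, drop = FALSE], M)
    list(M = M, fit = fit)
  })
  f1 <- file.path(config$out_dir, "relationship_matrix.tsv")
  write_tsv_table(st$result$M$M, f1, id_col = "sample_id")
  f2 <- file.path(config$out_dir, "microbiability_fit.json")
  fit <- st$result$fit
  jsonlite::write_json(list(
    sigma2_m = fit$sigma2_m, sigma2_e = fit$sigma2_e,
    microbiability = fit$microbiability,
    sigma2_p_convention = fit$sigma2_p_convention,
    beta = as.list(fit$beta), loglik = fit$loglik,
    boundary = fit$boundary, n_taxa = st$result$M$n_taxa),
    f2, auto_unbox = TRUE, digits = NA)
  add_stage("microbiability", c(f1, f2), st$elapsed)
  outputs$microbiability <- st$result

  # -- stage: differential taxa (LEfSe-style) --------------------------------
  st <- t_stage("differential", {
    lefse_differential(filt$groups, bundle$groups, alpha = config$alpha,
                       lda_min = config$lda_min,
                       seed = substream_seed(config$seed, "lefse"))
  })
  f <- file.path(config$out_dir, "differential_taxa.tsv")
  utils::write.table(as.data.frame(st$result), f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add_stage("differential", f, st$elapsed)
  outputs$differential_taxa <- st$result

  # -- stage: metabolome -----------------------------------------------------
  st <- t_stage("metabolome", {
    qcd <- qc_filter(bundle$metabolome, config$qc_presence_min,
                     config$rsd_max)
    norm <- pqn_normalize(qcd)
    bio <- !norm$is_qc
    diffm <- wilcoxon_fold_change(norm$intensity[bio, , drop = FALSE],
                                  bundle$groups[rownames(norm$intensity)[bio]],
                                  alpha = config$alpha)
    universe <- colnames(norm$intensity)
    sig <- diffm$feature[diffm$significant]
    org <- classify_origins(universe, bundle$annotation)
    enr <- pathway_enrichment(sig, universe, bundle$annotation,
                              alpha = config$alpha)
    list(qc_filtered = qcd, normalized = norm, differential = diffm,
         origins = org, enrichment = enr)
  })
  f1 <- file.path(config$out_dir, "differential_metabolites.tsv")
  utils::write.table(as.data.frame(st$result$differential), f1, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  f2 <- file.path(config$out_dir, "pathway_enrichment.tsv")
  utils::write.table(as.data.frame(st$result$enrichment), f2, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  add_stage("metabolome", c(f1, f2), st$elapsed)
  outputs$metabolome <- st$result

  # -- stage: networks -------------------------------------------------------
  st <- t_stage("networks", {
    ab <- filt$groups$abundance
    g <- bundle$groups[rownames(ab)]
    nets <- lapply(c(LOS = "LOS", HOS = "HOS"), function(lab) {
      cooccurrence_network(ab[g == lab, , drop = FALSE], group = lab,
                           rho_min = config$rho_min, alpha = config$alpha)
    })
    list(networks = nets, comparison = compare_networks(nets$HOS, nets$LOS))
  })
  f1 <- file.path(config$out_dir, "network_edges.tsv")
  all_edges <- do.call(rbind, lapply(st$result$networks, function(net) {
    e <- retained_edges(net)
    if (nrow(e)) cbind(group = net$group, e) else NULL
  }))
  if (is.null(all_edges))
    all_edges <- data.frame(group = character(), taxon_a = character(),
                            taxon_b = character(), rho = numeric())
  utils::write.table(all_edges, f1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f2 <- file.path(config$out_dir, "network_comparison.tsv")
  utils::write.table(st$result$comparison$closeness, f2, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  add_stage("networks", c(f1, f2), st$elapsed)
  outputs$networks <- st$result

  # -- manifest + report -----------------------------------------------------
  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  outputs$manifest <- manifest
  render_report(manifest, outputs, file.path(config$out_dir, "report.md"))
  invisible(list(manifest = manifest, outputs = outputs, config = config))
}

# Read user-supplied study inputs (TSV tables) into the bundle layout.
read_study_inputs <- function(config) {
  need <- c("abundance", "phenotypes", "metabolome", "annotation")
  miss <- need[vapply(need, function(f) is.null(config[[f]]), logical(1))]
  if (length(miss))
    stop("simulate = FALSE requires input path(s): ",
         paste(miss, collapse = ", "))
  ab <- as.matrix(read_tsv_table(config$abundance))
  ph <- utils::read.delim(config$phenotypes, sep = "\t",
                          stringsAsFactors = FALSE)
  met_df <- utils::read.delim(config$metabolome, sep = "\t",
                              stringsAsFactors = FALSE)
  is_qc <- as.logical(met_df$is_qc)
  mx <- as.matrix(met_df[, setdiff(names(met_df), c("sample_id", "is_qc"))])
  rownames(mx) <- met_df$sample_id
  ann_df <- utils::read.delim(config$annotation, sep = "\t",
                              stringsAsFactors = FALSE)
  pws <- strsplit(ifelse(is.na(ann_df$pathways), "", ann_df$pathways), ";",
                  fixed = TRUE)
  pws <- lapply(pws, function(v) v[nzchar(v)])
  names(pws) <- ann_df$feature
  groups <- stats::setNames(ph$group, ph$sample_id)
  tab <- abundance_table(ab, filtered = FALSE)
  list(cohort = list(abundance = tab, phenotypes = phenotype_table(ph),
                     truth = NULL),
       groups = groups,
       abundance = tab,
       phenotypes = phenotype_table(ph),
       metabolome = metabolite_table(mx, is_qc),
       annotation = origin_annotation(
         stats::setNames(ann_df$origin, ann_df$feature), pws))
}

#' Render a run report
#'
#' Writes a markdown summary: group statistics in a mean/SEM/p layout,
#' differential feature lists, origin partition and network comparison.
#' Regenerating the report from the same manifest and outputs reproduces it
#' bit for bit.
#'
#' @param manifest Run manifest (from [run_study()]).
#' @param outputs Stage outputs (from [run_study()]).
#' @param path Output file (default `report.md` next to the manifest).
#' @return Invisibly, the report path.
#' @export
render_report <- function(manifest, outputs, path = "report.md") {
  ln <- character()
  add <- function(...) ln <<- c(ln, paste0(...))
  add("# Study run report")
  add("")
  add("Seed: ", manifest$seed, "; package version ",
      manifest$package_version)
  add("")
  add("## Decisions in effect")
  for (d in names(manifest$decisions))
    add("- ", d, ": ", manifest$decisions[[d]])
  add("")
  if (!is.null(outputs$group_assignment)) {
    rep_ <- attr(outputs$group_assignment, "matching_report")
    add("## Extreme groups (matching report)")
    add("")
    add("| covariate | LOS mean | HOS mean | p |")
    add("|---|---|---|---|")
    for (i in seq_len(nrow(rep_)))
      add("| ", rep_$covariate[i], " | ", signif(rep_$mean_los[i], 4), " | ",
          signif(rep_$mean_hos[i], 4), " | ", signif(rep_$p[i], 3), " |")
    add("")
  }
  if (!is.null(outputs$microbiability)) {
    fit <- outputs$microbiability$fit
    add("## Microbiability")
    add("")
    add(sprintf("sigma2_m = %.5g, sigma2_e = %.5g, microbiability = %.3f (%s)",
                fit$sigma2_m, fit$sigma2_e, fit$microbiability,
                fit$sigma2_p_convention))
    add("")
  }
  diff_section <- function(title, df) {
    add("## ", title)
    add("")
    sig <- df[df$significant, , drop = FALSE]
    if (!nrow(sig)) {
      add("no significant features")
    } else {
      add("| feature | higher in | fold change | p |")
      add("|---|---|---|---|")
      for (i in seq_len(nrow(sig)))
        add("| ", sig$feature[i], " | ", sig$higher_in[i], " | ",
            signif(sig$fold_change[i], 3), " | ", signif(sig$p[i], 3), " |")
    }
    add("")
  }
  if (!is.null(outputs$differential_taxa))
    diff_section("Differential taxa (Kruskal-Wallis + LDA score)",
                 outputs$differential_taxa)
  if (!is.null(outputs$metabolome)) {
    diff_section("Differential metabolites (Wilcoxon)",
                 outputs$metabolome$differential)
    add("## Metabolite origins")
    add("")
    cts <- outputs$metabolome$origins$counts
    add(paste(sprintf("%s: %d", names(cts), cts), collapse = ", "))
    add("")
  }
  if (!is.null(outputs$networks)) {
    cmp <- outputs$networks$comparison
    add("## Co-occurrence network comparison")
    add("")
    add(sprintf("%s-specific edges: %d; %s-specific edges: %d; shared: %d",
                cmp$group_a, cmp$n_unique_a, cmp$group_b, cmp$n_unique_b,
                cmp$n_shared))
    add("")
  }
  writeLines(ln, path)
  invisible(path)
}
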