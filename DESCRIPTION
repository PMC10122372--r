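Package: gutosi
Title: Gut Microbiome Contributions to Host Oxidative Stress
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking gut (fecal) microbiome composition to
    systemic oxidative stress in postpartum dairy cattle. Computes the
    oxidative stress index (OSI = TOS/T-AOC) and selects matched extreme
    phenotype groups; builds a microbial relationship matrix from genus-level
    relative abundances and estimates "microbiability" (the fraction of
    phenotypic variance explained by microbial composition) by restricted
    maximum likelihood; screens differential taxa with a Kruskal-Wallis test
    plus a bootstrapped linear-discriminant effect size (LEfSe-style);
    processes metabolomics intensity tables (QC filtering, probabilistic
    quotient normalization, origin partitioning, hypergeometric pathway
    enrichment); and builds and compares per-group Spearman co-occurrence
    networks. A synthetic-data generator with known ground truth makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
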