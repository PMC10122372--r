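---
title: "Methods: estimating microbiome contributions to host oxidative stress"
author: "gutosi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating microbiome contributions to host oxidative stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Postpartum dairy cows frequently develop systemic oxidative stress, with
consequences for health and milk production. A scalar phenotype for redox
status is the oxidative stress index,

$$\mathrm{OSI} = \frac{\mathrm{TOS}}{\mathrm{T\text{-}AOC}},$$

the ratio of plasma total oxidative status (assayed in µM) to total
antioxidant capacity (assayed in mM), divided after conversion to a common
concentration scale. `compute_osi()` performs this harmonization and
refuses non-positive T-AOC values, which indicate a failed assay rather
than a computable phenotype.

The package asks, on any cohort with genus-level fecal microbiome profiles
and per-animal phenotypes: *how much of the variation in OSI is
attributable to gut microbial composition, and which taxa, metabolites and
pathways travel with it?* Every stage is also exercisable on synthetic
data with known ground truth, so the whole pipeline is testable without
access to cohort data.

## The microbiability model

The core estimand is the analogue of heritability with taxa in place of
markers. With phenotype vector $y$ (OSI), fixed covariates $c$ (parity and
milk yield by default) and intercept $u$:

$$y = u + Kc + m + e, \qquad
m \sim N(0, \sigma^2_m M), \qquad e \sim N(0, \sigma^2_e I),$$

where the microbial relationship matrix is built from the genus
relative-abundance table $A$,

$$M_{ij} = \frac{1}{N}\sum_{a=1}^{N}
\frac{(A_{ia}-\bar A_a)(A_{ja}-\bar A_a)}{\sigma^2_a},$$

i.e. $M = ZZ^\top/N$ with each taxon column centered and scaled to unit
variance. We use the population (divide-by-$n$) variance for
$\sigma^2_a$, so that $\operatorname{tr}(M) = n$ and the mean diagonal is
1 — the common convention for relationship matrices, which makes
$\sigma^2_m$ directly interpretable on the phenotype scale. Zero-variance
taxa carry no relational information and are dropped (with a warning)
before standardization. Microbiability is reported as

$$m^2 = \frac{\sigma^2_m}{\sigma^2_m + \sigma^2_e},$$

the model-based phenotypic-variance convention. The alternative (dividing
by the raw sample variance of $y$) is not used, but the convention in
effect is recorded in every fit (`sigma2_p_convention`) and in the run
manifest, so reports are unambiguous.

### REML implementation

`fit_lmm_reml()` maximizes the restricted likelihood of $y$ under
$V = \sigma^2_m M + \sigma^2_e I$. Because $M$ enters only through its
eigenstructure, it is eigendecomposed once, $y$ and $X = [1\,|\,K]$ are
rotated into the eigenbasis, and the restricted likelihood is profiled
down to one dimension in $\lambda = \sigma^2_m/\sigma^2_e$ with
closed-form $\hat\sigma^2_e(\lambda)$. The search runs on
$\log\lambda \in [\log 10^{-6}, \log 10^6]$: a 401-point bracketing grid
followed by `optimize()` refinement to tolerance $10^{-8}$ on
$\log\lambda$. This formulation is numerically stable even though $M$ is
singular (its rows sum to zero, and with fewer taxa than samples its rank
is at most the taxon count); tiny negative eigenvalues from round-off are
clamped at zero. Boundary optima are flagged, and data with zero residual
variance (phenotype exactly in the covariate span) return a degenerate
fit with both variances at zero rather than a spurious interior optimum.

The test suite cross-checks the optimizer against an independent
brute-force oracle that evaluates the same restricted likelihood by dense
`solve()`/`determinant()` algebra on a 2001-point grid — a deliberately
different numerical route.

No standard error accompanies the point estimate by default; an optional
seeded parametric bootstrap (`microbiability_bootstrap()`) is provided.

### What the recovery simulations show

With $n = 400$ samples and 150 taxa, the REML estimate recovers true
microbiability in $\{0, 0.2, 0.431, 0.6\}$ with mean absolute bias below
0.05 and strictly increasing means (20 seeds per level; 0.431 mirrors a
plausible operating point for a strong microbiome-phenotype association).
One caveat is intrinsic rather than implementational: for independent
standardized taxa the sampling SD of $\hat m^2$ is bounded below by
roughly $\sqrt{2N_{\text{taxa}}}/n \approx 0.043$ at this design size, so
under a true value of 0 a non-trivial fraction of estimates exceeds 0.05.
A stricter null calibration would require more samples, fewer taxa, or
stronger sample-to-sample relatedness than this design provides.

## Group selection and plasma statistics

`select_extreme_groups()` mirrors the study design of contrasting extreme
phenotypes with "similar phenotypic characteristics": rank all animals by
OSI, take the $k$ lowest (LOS) and $k$ highest (HOS), then greedily swap
in next-ranked candidates from the middle of the ranking until every
matching covariate (milk yield, parity, body condition score by default)
compares at $p >$ `match_alpha` (default 0.10, the conventional "trend"
boundary) under a pooled-variance t test. The procedure is deterministic
— ties break on sample id and each swap maximizes the worst matching
p-value, preferring the smallest displacement in OSI rank — because no
published selection algorithm exists to reproduce exactly; determinism
and an explicit matching report are what make the choice auditable. When
no assignment in the candidate pool satisfies matching, the error carries
the best attempt.

`compare_groups()` applies Student's t test (pooled variance) for two
groups and one-way ANOVA for more, with all pairwise unadjusted t tests
as the post-hoc report. Pairwise tests are deliberately unadjusted: the
reference analyses report pairwise p-values for multi-group designs
without naming an adjustment, and emitting raw values keeps every
adjustment option open downstream. Significance bands follow the field
convention: $P \le 0.05$ significant, $0.05 < P \le 0.10$ a trend.

## Abundance filtering

`prevalence_filter()` retains taxa with relative abundance strictly above
0.01% ($10^{-4}$) in strictly more than 50% of samples. Both boundaries
are strict because that is the literal reading of the rule; the tests pin
the boundary cases (a taxon above threshold in exactly half the samples
is removed). Filtered tables are *not* re-closed: the relationship matrix
standardizes each taxon independently, so re-closure would alter results
without any methodological basis. The filter is idempotent and
order-independent, and both properties are tested.

## Differential features

Taxa are screened with a per-feature Kruskal–Wallis test (tie-corrected
$H$; the permutation null is enumerated exactly for small designs, with
the chi-square approximation above an enumeration budget of 10,000
assignments) and scored with a bootstrapped linear-discriminant effect
size on the conventional per-million scale:

* 30 bootstrap rounds, each a stratified two-thirds subsample without
  replacement;
* a diagonal-regularized two-class discriminant (regularization
  $10^{-6}\times$ the mean pooled variance) — appropriate when features
  outnumber samples, where a full covariance estimate is singular;
* per-feature effect $\tfrac12(|w_f d| + |\Delta_f|)$, with $w$ the
  unit-norm discriminant direction, $d = w\cdot(\mu_1-\mu_0)$ the
  projected class-mean difference and $\Delta_f$ the raw class-mean
  difference;
* final score $\log_{10}(1 + \text{mean effect})$, deterministic under a
  fixed seed.

A taxon is flagged when raw $p < 0.05$ *and* LDA score $> 2$ — the
conventional dual gate on this scale. The subsample fraction, bootstrap
count and effect formula are fixed and documented precisely because the
procedure is a family of similar tools rather than a single reference
implementation; scores here are reproducible but carry no claim of
numerical identity to any external program. Benjamini–Hochberg columns
are always emitted for transparency, but do not enter the flag (the
convention for this analysis style is raw-p gating). There is no
within-class ("subclass") stage: the design has none.

Metabolites use the two-sided Wilcoxon rank-sum test — exact for groups
of at most 25 without ties, normal approximation with tie and continuity
correction otherwise — flagged at raw $p < 0.05$, with fold change
mean(HOS)/mean(LOS). The orientation is fixed as HOS/LOS and recorded in
the output column names; a zero denominator switches to a half-minimum
pseudo-count scale and is flagged per feature.

## Metabolome processing

`qc_filter()` removes features detected (non-missing and $> 0$; no
detection floor is imposed beyond positivity) in fewer than 50% of pooled
QC samples, then features whose relative standard deviation across QC
samples exceeds 30% (population SD over mean, strict boundary).
`pqn_normalize()` divides each sample by its most probable dilution
quotient — the median across features of sample/reference ratios, with
the reference the feature-wise median of QC samples (falling back to all
samples when no QC exists) — then applies a natural-log transform with
offset equal to half the minimum positive normalized value (recorded in
the output). PQN makes the pipeline invariant to per-sample scaling, and
noiseless dilution factors are recovered exactly; both are tested.

`classify_origins()` partitions metabolites into host, microbiota,
cometabolism and "others" (drug + food + environment + unknown) from a
user-supplied annotation table — a local stand-in for an online origin
database lookup, which keeps the pipeline offline and reproducible.
`pathway_enrichment()` tests each pathway within each origin category by
the one-sided hypergeometric tail $P(X \ge k)$, flagged at $p < 0.05$.

## Co-occurrence networks

Within each group, all taxon pairs are correlated by Spearman's rho
(exact p-values for $n < 10$ without ties, t approximation otherwise),
p-values are Benjamini–Hochberg adjusted across all pairs (the adjustment
method is recorded in the output, since "adjusted p" alone is ambiguous),
and an edge is retained when $|\rho| > 0.70$ and adjusted $p < 0.05$.
`compare_networks()` counts an edge as shared only when the same
unordered pair is retained in both networks *with the same sign* — an
edge that flips sign between groups is evidence of difference, not
similarity. Centralities: harmonic closeness (mean of inverse
shortest-path distances), chosen because co-occurrence graphs are
routinely disconnected and classic closeness is undefined there; and
eigenvector centrality on each network's largest connected component.
Shortest paths are unweighted — the retention rule already guarantees
every edge is strong.

## The synthetic-data generator

`simulate_abundance_table()` draws latent per-taxon log abundances from a
one-factor-per-block Gaussian model (block members share a latent factor,
giving controllable within-block correlation — the reason for choosing a
logistic-normal over a Dirichlet, which cannot express correlation
structure) and closes each sample to sum to 1. Taxon baselines span about
four orders of magnitude so the 0.01% filter has realistic work to do.
Covariates are cosmetically realistic (parity 1–5; milk yield normal with
mean 36.9 kg/d, SD 8.04; body condition score around 2.75), matching a
typical postpartum cohort description.

`simulate_phenotypes()` generates $y$ under exactly the microbiability
model above, with $\sigma^2_m = m^2_{\text{true}} \times$ total variance
(default total variance 0.16, i.e. SD 0.4 on the OSI scale around a
baseline of 0.66). The drawn microbial and residual effects are recorded
in the truth object, so recovery tests compare against known components.

`simulate_two_group_study()` emulates the full two-tier design: an
association cohort for variance-component estimation and group selection,
plus an extreme-group comparison set (default 9 + 9) with planted
multiplicative taxon shifts (default 4-fold), planted metabolite log2
fold changes, group-separated OSI (means 0.34 vs 1.02, SD 0.2 — the scale
of a strong two-group redox contrast), per-sample dilution factors, QC
replicates, and an origin/pathway annotation whose planted differential
metabolites concentrate in two target pathways. Two generator decisions
deserve emphasis:

* **Truth is defined on the estimand.** Cohort phenotypes are generated
  from the *prevalence-filtered* abundance table, because the analysis
  builds $M$ after filtering; defining truth on the unfiltered table
  would plant microbial variance in taxa the analysis is designed never
  to see, making "recovery" ill-posed.
* **Tier separation.** Planted fold changes cannot be imposed on the
  cohort's own OSI extremes without destroying the generative covariance
  $\sigma^2_m M$, so the comparison tier is a separate draw sharing the
  master seed. The two tiers are consistent in design (same taxa, same
  covariate distributions, OSI separation matching the cohort's tails)
  but not sample-identical.
* **Tight co-occurrence blocks.** With 9 samples per group and BH
  adjustment across thousands of pairs, only near-perfectly concordant
  pairs can pass the dual edge threshold; the comparison tier therefore
  embeds blocks with latent correlation 0.95–0.99, emulating the strongly
  co-varying taxa that drive real co-occurrence networks at this sample
  size.

What the generator does *not* emulate: sequencing depth and count noise
(tables are continuous compositions), sample-to-sample relatedness from
shared environment, zero inflation beyond what closure induces,
retention-time or m/z structure in the metabolome, and database-accurate
origin assignments. Passing tests therefore demonstrate correctness of
the estimators and pipeline plumbing under a known model, not robustness
to every artifact of real sequencing or LC–MS data.

Determinism: one master seed is split into fixed per-stage substreams
(`substream_seed()`), so any stage can be regenerated independently and
identical seeds give bit-identical outputs; all random routines restore
the caller's RNG state.

## Pipeline, configuration and problem sizes

`run_config()` validates every threshold by name; the zero-configuration
defaults are the conventional thresholds throughout (0.01%/50% filter,
$|\rho| > 0.70$ with BH $p < 0.05$, LDA $> 2$, QC presence 50% and RSD
30%, matching $\alpha$ 0.10). `run_study()` executes simulate/ingest →
group selection → filter → microbiability → differential taxa →
metabolome → networks → report, writes every table as TSV, and records a
manifest with per-output MD5 hashes, the decisions in effect (variance
convention, adjustment method, sign rule, fold-change orientation) and
stage timings. Reruns with the same configuration are bit-identical, which
the tests verify by hash.

Problem sizes used by the test suite were chosen to make each check
informative at interactive runtimes: recovery simulations use $n = 400$
samples and 150 taxa with 20 seeds per level; the REML oracle comparison
uses $n = 50$ against a 2001-point grid; exact-test enumeration covers
all two-group designs up to $6+6$, three-group designs up to $3+3+3$, and
Spearman permutations up to $n = 7$; the end-to-end run uses a 400-cow
cohort with 9 + 9 extreme groups.

## Known limitations

* The LDA effect size is one fixed member of a family of similar scoring
  procedures; absolute scores should not be compared across tools.
* Compositionality is handled by convention (relative abundances,
  rank-based correlation), not by compositionally-aware methods such as
  centered log-ratio models; strong negative closure correlations can
  inflate co-exclusion edges in small samples.
* The microbiability model uses a single microbial kernel; host genetics
  and microbiome are not modeled jointly, so microbial variance may
  absorb genetically structured signal in real cohorts.
* Parity enters the covariate design numerically by default; factor
  coding is available by passing expanded covariate columns.
* The null sampling SD of $\hat m^2$ at moderate design sizes is set by
  the information bound discussed above; near-zero estimates should be
  interpreted with that bound in mind.
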