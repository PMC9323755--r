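---
title: "Methods: summary-statistics multi-omics gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistics multi-omics gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicsmr)
```

# The inference chain

`omicsmr` prioritizes likely causal genes for a quantitative trait (the
motivating application is blood pressure) from three kinds of summary
statistics — a GWAS of the trait, cis-eQTLs for gene expression, and
cis-mQTLs for DNA methylation — plus an LD reference panel. No
individual-level outcome data are required. The stages are:

1. **SMR** (summary-data-based Mendelian randomization): for each molecular
   probe, the ratio estimate at the top cis instrument tests whether the
   feature and the trait share a causal variant.
2. **HEIDI**: a heterogeneity test over the instrument's LD neighbourhood
   that flags loci where the apparent sharing is driven by two distinct
   variants in LD (linkage) rather than one shared variant.
3. **Summary TWAS**: a gene-level Z combining cis prediction weights with
   GWAS z-scores and reference LD, with a prediction-performance filter and
   an approximate-Bayes-factor colocalization screen.
4. **3×SMR mediation**: the intersection of trait~eQTL, trait~mQTL and
   mQTL~eQTL scans supports DNA → methylation → expression → trait chains.
5. **Integration**: six-source evidence scoring, tissue prioritization by
   average squared Z, replication in an independent cohort, cross-tissue
   direction consistency, and Fisher's exact drug-target enrichment.

Every stage is exercised end-to-end on a bundled synthetic-data generator
with planted ground truth, which is itself first-class, tested code.

# The SMR ratio test and HEIDI

For exposure effect $b_{zx}$ (SD of the molecular feature per allele) and
outcome effect $b_{zy}$ at the same instrument SNP,
$\hat b_{xy} = b_{zy} / b_{zx}$ estimates the feature-to-trait effect in SD
units, with delta-method variance
$\mathrm{var}(\hat b_{xy}) \approx \mathrm{var}(b_{zy})/b_{zx}^2 +
b_{zy}^2\,\mathrm{var}(b_{zx})/b_{zx}^4$. The test statistic
$T_\mathrm{SMR} = z_{zy}^2 z_{zx}^2 / (z_{zy}^2 + z_{zx}^2)$ is referred to
$\chi^2_1$; it is symmetric in the two z-scores and bounded by
$\min(z_{zx}^2, z_{zy}^2)$.

**Instrument selection.** The cis SNP (default window ±2 Mb) with the
smallest exposure p-value below $5\times10^{-8}$; ties broken by larger
$|z|$, then smaller position. Probes without an eligible instrument are
skipped, not errors.

**HEIDI.** Candidates are cis SNPs with exposure $p < 1.57\times10^{-3}$
and $0.05 \le r^2 \le 0.9$ with the top SNP, capped at the 20 most
significant; with fewer than 3 candidates the test is not performed and the
probe is retained with a "not testable" flag. For each candidate $i$,
$d_i = \hat b_{xy}(i) - \hat b_{xy}(\mathrm{top})$ is standardized using the
delta-method covariance of the per-SNP ratios, where the LD-induced
covariance between outcome effects at SNPs $i, j$ is
$r_{ij}\,se_i\,se_j$ (and analogously for exposure effects; exposure and
outcome cohorts are independent). $T_\mathrm{HEIDI} = \sum_i z_{d_i}^2$ is
referred to $\sum_k \lambda_k \chi^2_1$ with $\lambda_k$ the eigenvalues of
the correlation matrix of the $z_d$ vector, evaluated by Imhof-type
numerical integration with a Satterthwaite (scaled chi-square) fallback.

**Second-order ratio covariance.** HEIDI candidates sit exactly in the
regime where instruments are only moderately strong
($3.2 \lesssim |z_{zx}| \lesssim 6$), and there the usual first-order delta
covariance understates $\mathrm{var}(d_i)$: writing
$q_i = 1/z_{zx,i}^2$, the neglected terms are of relative order $q$. We
therefore carry the expansion one order further; with
$u_i = se_{zy,i}/b_{zx,i}$, $w_i = b_{zy,i}\,se_{zx,i}/b_{zx,i}^2$,

$$\mathrm{cov}(\hat a_i, \hat a_j) \approx r_{ij} u_i u_j (1 + q_i + q_j)
  + r_{ij} w_i w_j (1 + 3 q_i + 3 q_j)
  + r_{ij}^2 \left( u_i u_j \sqrt{q_i q_j} + 2 w_i w_j \sqrt{q_i q_j}
  \right).$$

In the $i = j$ limit this reduces to the exact fourth-moment expansion of a
normal ratio's variance
($c_y^2 + c_x^2 + 3 c_y^2 c_x^2 + 8 c_x^4$ in coefficient-of-variation
units). In our calibration experiments the first-order formula gave a
chain-scenario (true single shared causal variant) rejection rate of about
0.02 at the nominal 0.01 level; the second-order covariance brings it to
approximately the nominal rate while leaving the linkage-scenario rejection
rate essentially at 1.

**Multiple testing.** The Bonferroni denominator is the number of probes
actually tested in a run (those with an eligible instrument), not the
number of probes in the file, so the threshold is dataset-specific. The
HEIDI pass threshold is $P_\mathrm{HEIDI} \ge 0.01$; untestable probes are
retained with a flag rather than discarded.

# Summary TWAS

**Weights.** Per gene, ridge regression of expression on cis SNP dosages
(closed form), with the penalty chosen from a small grid by k-fold
cross-validation (deterministic fold assignment given a seed). Ridge rather
than elastic net is a deliberate simplification: it is closed-form and
deterministic, which matters for reproducible validation on synthetic data;
real-data users accustomed to sparse PredictDB-style models should expect
denser weights. The reported prediction performance is the signed squared
correlation between out-of-fold predictions and observed expression
($\mathrm{sign}(r)\,r^2$, so chance-level models centre at 0 and can be
negative) with a one-sided correlation-test p-value; the performance filter
is $cv\,R^2 > 0.01$ and $p < 0.05$.

**Statistic.** $Z_g = \sum_l w_{lg} (\sigma_l / \sigma_g) z_l$ with
$\sigma_l$ the SNP dosage SD in the reference panel and
$\sigma_g^2 = w^\top \Sigma w$, $\Sigma$ the panel dosage covariance of the
model SNPs. Model SNPs missing from the GWAS are dropped and $\sigma_g$
recomputed; a gene is skipped when more than half its absolute weight mass
is lost. On simulated data the statistic agrees with the individual-level
oracle (regressing the trait on model-predicted expression in the same
cohort) with correlation > 0.99.

**Colocalization.** Per SNP and trait, the log approximate Bayes factor is
$\tfrac12[\ln(V/(V+W)) + z^2 W/(V+W)]$ with $V = se^2$ and effect-variance
prior $W = 0.15^2$ (quantitative-trait default). Posteriors for H0–H4
follow from the standard configuration sums with priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$, computed in log space. The pass
rule PP4 ≥ 0.5 is a configurable convention: the notion of "acceptable
evidence of colocalization" has no single community definition, so the
threshold is exposed and logged.

# 3×SMR mediation

Three scans — trait~eQTL, trait~mQTL, and mQTL~eQTL (site–gene pairs within
2 Mb, each pair using the site's top mQTL instrument with the gene's
cis-eQTL records as outcome) — are each filtered by their own Bonferroni
threshold and HEIDI. A (site, gene) chain is emitted only when all three
legs pass; by construction no chain can appear with a missing leg. The
direction-consistency flag,
$\mathrm{sign}(b_{m \to y}) = \mathrm{sign}(b_{m \to e}\, b_{e \to y})$, is
reported but not used as a filter: sign bookkeeping across three noisy
ratio estimates is informative for inspection, and nothing in the
integration logic requires coherence, so we surface rather than enforce it.

A caveat the planted-truth tests make explicit: SMR cannot distinguish a
single pleiotropic variant from a causal chain at one locus. Pleiotropy-
scenario loci correctly pass SMR and HEIDI; they are excluded from chains
only because their methylation has no genetic signal. This is a design
property of the method, not an implementation artefact.

# The synthetic-data generator

**LD model.** Within each block, latent Gaussians follow an AR(1) process
with parameter $\rho$; each of two haplotypes per individual is
dichotomized at the MAF quantile and summed to a 0/1/2 dosage. Blocks are
independent; four cohorts (reference, GWAS, eQTL, mQTL) are drawn from the
same population with separate RNG streams keyed by cohort name, so
resizing one cohort never perturbs another. This latent-Gaussian model was
chosen over haplotype copying because it is analytically checkable (the
adjacent-SNP dosage correlation is verified against a Monte-Carlo oracle
pushing $10^6$ latent draws through the same dichotomization) and
sufficient to create the linkage confounding HEIDI must detect. Dosage
correlations are attenuated relative to the latent $\rho^{|i-j|}$; the
linkage scenario targets its causal-pair correlation on the latent scale by
picking the SNP pair with $\rho^{|i-j|}$ closest to `linkage_r`.

**Scenarios.** Per locus, one of: `chain`
($g \to m \to e \to y$ with coefficients `beta_xm`, `beta_me`, `beta_ey`),
`direct` ($g \to e \to y$, methylation pure noise), `pleiotropy`
($g \to e$ and $g \to y$ separately, no $e \to y$ path), `linkage`
(expression driven by one SNP, trait by a second, correlated SNP), and
`null`. Under `null` the molecular phenotypes keep their QTL effects while
the trait has no genetic component: this is the natural null for the ratio
test (a valid instrument with zero effect), and it is what makes
null-scenario probes testable in the calibration experiments. Methylation
carries no genetic effect under `direct`, `pleiotropy` and `linkage` —
otherwise every such locus would produce a (correct, but unwanted here)
single-variant-pleiotropy chain and the mediation recovery experiment
could not separate chains from distractors.

**Unit-variance construction.** Each noise variance defaults to the
complement of the locus's genetic variance, so every phenotype has unit
population variance and the path coefficients are exactly the SD-scale
estimands of the ratio test: under `chain`, $\hat b_{xy}$ from the
trait~eQTL scan consistently estimates `beta_ey`. The final column
standardization is then a no-op in expectation. Users who override the
noise variances change the estimand scale accordingly.

**What the generator does not emulate.** Imputation noise, genotyping
error, relatedness, allele-frequency/LD mismatch between cohorts and
reference, binary traits, trans-QTLs, and strand ambiguity (all simulated
alleles are A/G; harmonization of ambiguous alleles is still implemented
and tested for externally supplied files). Passing tests therefore
demonstrate statistical correctness of the machinery under a clean
generative model, not robustness to real-data artefacts.

# Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `cis_window` | 2e6 | bp; instrument search radius around a probe |
| `p_instrument` | 5e-8 | instrument significance threshold |
| HEIDI candidate p | 1.57e-3 | exposure p cap (z > 3.16) |
| HEIDI r² range | [0.05, 0.9] | LD with top SNP |
| HEIDI cap / minimum | 20 / 3 | candidates used / needed |
| `heidi_threshold` | 0.01 | pass requires P_HEIDI at or above |
| `alpha` | 0.05 | family-wise target; Bonferroni per scan |
| `r2_min`, `perf_p` | 0.01, 0.05 | TWAS performance filter |
| `p1`, `p2`, `p12`, `W` | 1e-4, 1e-4, 1e-5, 0.0225 | COLOC priors |
| `pp4_min` | 0.5 | colocalization pass |
| `r2_proxy` / `window_bp` | 0.5 / 1e6 | proxy expansion |
| `pair_window` | 2e6 | site-gene pairing in the mQTL~eQTL scan |
| `ambiguous_window` | 0.15 | freq window for dropping A/T, C/G variants |

The instrument threshold, HEIDI candidate rules and pass threshold follow
the established SMR-software defaults; the proxy window (1 Mb) and the
ambiguous-allele window (0.15) are standard GWAS-QC conventions adopted
where no published value existed. The 2 Mb site–gene pairing window mirrors
the cis logic of the other scans.

# Numerical choices

* **Mixture tail probability**: Imhof integration with relative tolerance
  1e-8 over (0, ∞); when the integral fails or leaves [0, 1], a
  Satterthwaite scaled-chi-square with matched first two moments is used.
  Probabilities are floored at 1e-300.
* **Singular LD submatrices** in HEIDI are ridge-regularized by 1e-6 on the
  diagonal (logged), and negative eigenvalues are clipped at zero.
* **Degenerate inputs**: zero-variance SNPs are dropped from summary
  statistics with a warning and are errors in LD queries; perfect
  associations keep their record with p floored at the smallest
  representable double; empty gene lists and empty QTL tables propagate as
  empty results, not errors.
* **Tie-breaks** are total and documented: instruments (p, then |z|, then
  bp), proxy-to-lead assignment (r², then distance), nearest gene (smaller
  start coordinate), tissue ranking (grand mean, then name).
* **Two-sided exact test**: the point-probability convention (sum of
  outcome probabilities ≤ observed, with a 1e-7 relative tolerance),
  matching `fisher.test`.

# Validation problem sizes

The packaged experiments run at: 2,000 null probes (GWAS n = 20,000, eQTL
n = 5,000) for SMR calibration; 200 chain loci for effect recovery
(`beta_ey` = 0.3); 250 linkage and 400 chain loci for HEIDI discrimination
(`linkage_r` = 0.7, 20 SNPs per block, latent AR(1) ρ = 0.85, LD reference
n = 2,000); 120 genes for the summary-vs-individual TWAS agreement; 100
replicates per colocalization scenario; and a 40-locus mediation dataset
with 10 planted chains among 30 distractors. Loci are simulated in
independent batches (blocks are independent by construction) to bound
memory. Effect sizes (`beta_xm` = `beta_me` = 0.5, `beta_ey` = 0.3,
`beta_xe` = 0.3–0.4, `beta_xy` = 0.1–0.15) were chosen once for adequate
power at these sample sizes; no published effect-size distributions exist
for the real datasets these stand in for, so they are test-power choices,
not realism claims.

The mediation study needs two extra budgeting steps. First, the trait is
shared across loci, so the summed per-locus genetic variance must stay
within the unit trait-variance budget or every standardized effect shrinks
(the generator warns when the budget is exceeded). Second, the molecular
instruments must stay in the weak-to-moderate per-SNP R² regime
(top z ≈ 15–20, R² ≲ 10%): the covariance approximation behind HEIDI,
$\mathrm{cov}(\hat b_i, \hat b_j) \approx r_{ij}\,se_i\,se_j$, treats the
per-SNP association as a small perturbation, and planting implausibly
strong molecular effects (instrument z ≈ 40, R² ≈ 25%) measurably inflates
the HEIDI tail — a regime real cis-QTL instruments rarely enter. The forty
loci therefore use `beta_xm` = 0.5, `beta_me` = 0.7, `beta_ey` = 0.2,
`beta_xe` = 0.5 with common-variant MAF 0.2–0.5, keeping the total genetic
trait variance near 0.8 of the budget while every chain leg retains a
worst-case expected |z| of about 6 — i.e., the planted chains genuinely
clear the scan power thresholds that the recovery claim presupposes, and
the HEIDI screen operates inside its stated applicability regime.

# A small worked run

```{r demo}
cfg <- run_config(sim = sim_config(
  n_gwas = 2000, n_eqtl = 1000, n_mqtl = 1000, n_ref = 500,
  n_blocks = 6, snps_per_block = 8, rho = 0.8,
  scenarios = c("chain", "direct", "null", "chain", "pleiotropy", "null"),
  seed = 7))
out <- file.path(tempdir(), "demo-run")
res <- run_all(cfg, out)
res$esmr[, c("probe", "topSNP", "b_SMR", "p_SMR", "p_HEIDI", "pass")]
```

At this deliberately small scale most planted loci do not reach the
genome-wide instrument threshold or the Bonferroni bar — power analysis is
what the full-size experiments in `scripts/acceptance.R` are for.

# Known limitations

* Sample overlap between exposure and outcome cohorts is not modelled or
  corrected; the generator draws disjoint cohorts to match.
* Single-instrument SMR only (no multi-SNP extensions); no conditional or
  fine-mapped TWAS; each tissue is an independent run.
* The gene namespace is plain symbols; identifier mapping is the caller's
  responsibility.
* "Novel" means absent from a caller-supplied known-gene list; the package
  makes no literature claim.
* The enrichment universe defaults to the genes observed in the run, is
  configurable, and is reported beside every result — fold changes are not
  comparable across differently chosen universes.
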