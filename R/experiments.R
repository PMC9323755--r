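# Simulation experiments: calibration, power and recovery studies run
# against planted ground truth. These are the package's own validation
# surface; each function simulates data with the synth module, runs the
# corresponding analysis stage, and reports the measured rates.

#' Null calibration of the SMR ratio test
#'
#' Simulates loci where the molecular phenotype has a strong cis-QTL but the
#' trait has no genetic component, scans them with \code{\link{smr_scan}},
#' and reports the empirical fraction of probes with P_SMR < 0.05 together
#' with the Kolmogorov-Smirnov uniformity statistic and p-value. Loci are
#' simulated in independent batches to bound memory.
#'
#' @param n_probes total null probes
#' @param n_gwas,n_eqtl cohort sizes
#' @param batches number of independent batches
#' @param seed master seed
#' @return list(rate_p05, ks_stat, ks_p, n_probes)
#' @export
calibrate_smr_null <- function(n_probes = 2000, n_gwas = 20000,
                               n_eqtl = 5000, batches = 20, seed = 1) {
  per <- ceiling(n_probes / batches)
  pvals <- numeric(0)
  for (b in seq_len(batches)) {
    cfg <- sim_config(n_gwas = n_gwas, n_eqtl = n_eqtl, n_mqtl = 30,
                      n_ref = 200, n_blocks = per, snps_per_block = 3,
                      rho = 0.5, scenarios = "null",
                      seed = substream_seed(seed, paste0("null-batch-", b)))
    geno <- simulate_panel(cfg)
    ph_g <- simulate_phenotypes(geno$gwas, cfg, geno$map, "gwas")
    ph_e <- simulate_phenotypes(geno$eqtl, cfg, geno$map, "eqtl")
    ann <- probe_annotation(cfg, geno$map)
    genes <- ann[ann$class == "gene", ]
    probes <- data.frame(probe_id = genes$id, probe_chr = genes$chr,
                         probe_bp = as.integer((genes$start + genes$end) / 2),
                         gene_id = genes$id, stringsAsFactors = FALSE)
    gwas <- compute_summary_stats(geno$gwas, ph_g$y, geno$map)
    eqtl <- qtl_summary(geno$eqtl, ph_e$e, geno$map, probes)
    panel <- ld_panel(geno$ref, geno$map)
    sc <- smr_scan(gwas, eqtl, panel, heidi = FALSE)
    pvals <- c(pvals, sc$p_SMR)
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  list(rate_p05 = mean(pvals < 0.05), ks_stat = unname(ks$statistic),
       ks_p = ks$p.value, n_probes = length(pvals))
}

#' Recovery of the expression-to-trait effect by the SMR ratio estimate
#'
#' Simulates chain loci (SNP -> methylation -> expression -> trait) and
#' reports the mean b_SMR across loci, which estimates the
#' expression-to-trait path coefficient in SD units.
#'
#' @param n_loci number of planted chain loci (independent replicates)
#' @param beta_ey true expression-to-trait effect
#' @param n_gwas,n_eqtl cohort sizes
#' @param seed master seed
#' @return list(mean_bxy, se_mean, beta_ey, n_loci)
#' @export
recover_smr_effect <- function(n_loci = 200, beta_ey = 0.3,
                               n_gwas = 20000, n_eqtl = 5000, seed = 1) {
  per <- 10L  # keep per-dataset trait variance from chain loci below 1
  batches <- ceiling(n_loci / per)
  bxy <- numeric(0)
  for (b in seq_len(batches)) {
    cfg <- sim_config(n_gwas = n_gwas, n_eqtl = n_eqtl, n_mqtl = 30,
                      n_ref = 200, n_blocks = per, snps_per_block = 3,
                      rho = 0.5, scenarios = "chain", beta_ey = beta_ey,
                      seed = substream_seed(seed, paste0("chain-batch-", b)))
    geno <- simulate_panel(cfg)
    ph_g <- simulate_phenotypes(geno$gwas, cfg, geno$map, "gwas")
    ph_e <- simulate_phenotypes(geno$eqtl, cfg, geno$map, "eqtl")
    ann <- probe_annotation(cfg, geno$map)
    genes <- ann[ann$class == "gene", ]
    probes <- data.frame(probe_id = genes$id, probe_chr = genes$chr,
                         probe_bp = as.integer((genes$start + genes$end) / 2),
                         gene_id = genes$id, stringsAsFactors = FALSE)
    gwas <- compute_summary_stats(geno$gwas, ph_g$y, geno$map)
    eqtl <- qtl_summary(geno$eqtl, ph_e$e, geno$map, probes)
    panel <- ld_panel(geno$ref, geno$map)
    sc <- smr_scan(gwas, eqtl, panel, heidi = FALSE)
    bxy <- c(bxy, sc$b_SMR)
  }
  bxy <- bxy[seq_len(min(length(bxy), n_loci))]
  list(mean_bxy = mean(bxy), se_mean = sd(bxy) / sqrt(length(bxy)),
       beta_ey = beta_ey, n_loci = length(bxy))
}

#' HEIDI discrimination of linkage from a single shared causal variant
#'
#' Simulates loci under the linkage scenario (two distinct causal SNPs in
#' LD) and under the chain scenario (one shared causal SNP) and reports the
#' HEIDI rejection rate (P_HEIDI < \code{p_reject}) in each, plus their
#' ratio. HEIDI should reject linkage loci far more often than causal loci.
#'
#' @param n_linkage,n_chain numbers of replicate loci
#' @param linkage_r target correlation between the two causal SNPs
#' @param n_gwas,n_eqtl,n_ref cohort sizes
#' @param p_reject rejection threshold
#' @param seed master seed
#' @return list(linkage_rate, chain_rate, ratio, n_linkage, n_chain)
#' @export
heidi_discrimination <- function(n_linkage = 250, n_chain = 400,
                                 linkage_r = 0.7, n_gwas = 20000,
                                 n_eqtl = 5000, n_ref = 2000,
                                 p_reject = 0.01, seed = 1) {
  run_scenario <- function(scenario, n_loci, per, label) {
    ph <- numeric(0)
    batches <- ceiling(n_loci / per)
    for (b in seq_len(batches)) {
      cfg <- sim_config(
        n_gwas = n_gwas, n_eqtl = n_eqtl, n_mqtl = 30, n_ref = n_ref,
        n_blocks = per, snps_per_block = 20, rho = 0.85,
        scenarios = scenario, beta_xe = 0.4, beta_xy = 0.15,
        beta_xm = 0.5, beta_me = 0.5, beta_ey = 0.3,
        linkage_r = linkage_r,
        seed = substream_seed(seed, paste0(label, "-batch-", b)))
      geno <- simulate_panel(cfg)
      ph_g <- simulate_phenotypes(geno$gwas, cfg, geno$map, "gwas")
      ph_e <- simulate_phenotypes(geno$eqtl, cfg, geno$map, "eqtl")
      ann <- probe_annotation(cfg, geno$map)
      genes <- ann[ann$class == "gene", ]
      probes <- data.frame(probe_id = genes$id, probe_chr = genes$chr,
                           probe_bp = as.integer((genes$start + genes$end) / 2),
                           gene_id = genes$id, stringsAsFactors = FALSE)
      gwas <- compute_summary_stats(geno$gwas, ph_g$y, geno$map)
      eqtl <- qtl_summary(geno$eqtl, ph_e$e, geno$map, probes,
                          cis_window = 25000)
      panel <- ld_panel(geno$ref, geno$map)
      sc <- smr_scan(gwas, eqtl, panel)
      ph <- c(ph, sc$p_HEIDI[sc$heidi_testable])
    }
    ph[seq_len(min(length(ph), n_loci))]
  }
  pl <- run_scenario("linkage", n_linkage, 25L, "linkage")
  pc <- run_scenario("chain", n_chain, 10L, "chain")
  lr <- mean(pl < p_reject)
  cr <- mean(pc < p_reject)
  list(linkage_rate = lr, chain_rate = cr,
       ratio = if (cr > 0) lr / cr else Inf,
       n_linkage = length(pl), n_chain = length(pc))
}

#' Agreement between the summary TWAS Z and the individual-level z
#'
#' Trains prediction weights on the expression cohort, computes the summary
#' statistic for every gene against GWAS-cohort summary statistics (using
#' the GWAS cohort itself as the LD panel), and compares with the oracle:
#' the z statistic of regressing the trait on the model-predicted expression
#' in the same cohort.
#'
#' @param n_genes number of genes (half with a cis effect, half null)
#' @param n_gwas,n_eqtl cohort sizes
#' @param seed master seed
#' @return list(correlation, n_genes)
#' @export
twas_oracle_agreement <- function(n_genes = 120, n_gwas = 2000,
                                  n_eqtl = 1500, seed = 1) {
  cfg <- sim_config(n_gwas = n_gwas, n_eqtl = n_eqtl, n_mqtl = 30,
                    n_ref = 200, n_blocks = n_genes, snps_per_block = 5,
                    rho = 0.7, scenarios = c("direct", "null"),
                    beta_xe = 0.4, beta_ey = 0.1,
                    seed = substream_seed(seed, "twas-oracle"))
  ds <- simulate_dataset(cfg)
  models <- train_weights(ds$genotypes$eqtl, ds$phenotypes$eqtl$e, ds$map,
                          ds$annotation, seed = substream_seed(seed, "folds"))
  panel_gwas <- ld_panel(ds$genotypes$gwas, ds$map)
  tw <- twas_scan(ds$gwas, models, panel_gwas)
  y <- ds$phenotypes$gwas$y
  z_ind <- vapply(tw$gene, function(g) {
    m <- models[[g]]
    pred <- as.numeric(ds$genotypes$gwas[, m$snp, drop = FALSE] %*% m$weight)
    pc <- pred - mean(pred)
    sxx <- sum(pc^2)
    b <- sum(pc * (y - mean(y))) / sxx
    rss <- sum((y - mean(y) - b * pc)^2)
    b / sqrt(rss / ((length(y) - 2) * sxx))
  }, numeric(1))
  list(correlation = cor(tw$zscore, z_ind), n_genes = nrow(tw))
}

#' Colocalization behaviour under shared, distinct and absent signals
#'
#' Simulates loci with (i) one variant affecting both expression and trait,
#' (ii) two uncorrelated variants, one per trait, and (iii) no signal, runs
#' \code{\link{coloc_abf}} per locus, and reports how often the expected
#' hypothesis (PP4 / PP3 / PP0) is modal.
#'
#' @param n_reps replicates per scenario
#' @param n_gwas,n_eqtl cohort sizes
#' @param seed master seed
#' @return list(shared_pp4_modal, distinct_pp3_modal, null_pp0_modal, n_reps)
#' @export
coloc_scenario_rates <- function(n_reps = 100, n_gwas = 10000,
                                 n_eqtl = 3000, seed = 1) {
  run_type <- function(scenario, rho, beta_xe, beta_xm, label) {
    per <- 25L
    modal <- character(0)
    for (b in seq_len(ceiling(n_reps / per))) {
      cfg <- sim_config(n_gwas = n_gwas, n_eqtl = n_eqtl, n_mqtl = 30,
                        n_ref = 200, n_blocks = per, snps_per_block = 10,
                        rho = rho, scenarios = scenario,
                        beta_xe = beta_xe, beta_xy = 0.15,
                        beta_xm = beta_xm, linkage_r = 0,
                        seed = substream_seed(seed, paste0(label, "-", b)))
      ds <- simulate_dataset(cfg)
      for (l in seq_len(per)) {
        gene <- sprintf("G%04d", l)
        e <- ds$eqtl[ds$eqtl$probe_id == gene &
                       ds$eqtl$snp %in% ds$map$snp[ds$map$block == l], ,
                     drop = FALSE]
        g <- ds$gwas[ds$gwas$snp %in% e$snp, , drop = FALSE]
        pp <- coloc_abf(g, qtl_to_assoc(e, gene))
        modal <- c(modal, names(pp)[which.max(as.numeric(pp[1, ]))])
      }
    }
    modal[seq_len(min(length(modal), n_reps))]
  }
  shared <- run_type("pleiotropy", rho = 0.7, beta_xe = 0.4, beta_xm = 0.5,
                     label = "shared")
  distinct <- run_type("linkage", rho = 0, beta_xe = 0.4, beta_xm = 0.5,
                       label = "distinct")
  null <- run_type("null", rho = 0.7, beta_xe = 0, beta_xm = 0,
                   label = "null")
  list(shared_pp4_modal = mean(shared == "PP4"),
       distinct_pp3_modal = mean(distinct == "PP3"),
       null_pp0_modal = mean(null == "PP0"),
       n_reps = n_reps)
}

#' Recovery of planted mediation chains by the 3xSMR intersection
#'
#' Simulates a dataset with planted chain loci among direct, pleiotropy and
#' null distractors, runs \code{\link{run_3smr}} and
#' \code{\link{intersect_chains}}, and scores recall and the number of false
#' chains against the planted truth.
#'
#' The planted effect sizes are budgeted so that (i) the summed genetic
#' trait variance of all forty loci stays within the unit-variance budget
#' (no standardized effect shrinks), (ii) every chain leg has a worst-case
#' expected |z| around 6 at the default cohort sizes, and (iii) molecular
#' instruments stay in the weak-to-moderate per-SNP R^2 regime (z ~ 15-20,
#' R^2 below ~10%) where the summary-statistic covariance approximation
#' behind HEIDI (cov of slopes = r se se) is accurate — planting implausibly
#' strong molecular effects visibly inflates the HEIDI tail. Hence
#' beta_xm = 0.5, beta_me = 0.7, beta_ey = 0.2, common-variant loci
#' (MAF 0.2-0.5).
#'
#' @param n_chain,n_direct,n_pleiotropy,n_null locus counts per scenario
#' @param n_gwas,n_eqtl,n_mqtl,n_ref cohort sizes
#' @param seed master seed
#' @return list(recall, false_chains, n_chains_called, truth_pairs)
#' @export
mediation_recovery <- function(n_chain = 10, n_direct = 10,
                               n_pleiotropy = 10, n_null = 10,
                               n_gwas = 20000, n_eqtl = 5000, n_mqtl = 5000,
                               n_ref = 2000, seed = 1) {
  scen <- c(rep("chain", n_chain), rep("direct", n_direct),
            rep("pleiotropy", n_pleiotropy), rep("null", n_null))
  cfg <- sim_config(n_gwas = n_gwas, n_eqtl = n_eqtl, n_mqtl = n_mqtl,
                    n_ref = n_ref, n_blocks = length(scen),
                    snps_per_block = 10, rho = 0.8, scenarios = scen,
                    maf_range = c(0.2, 0.5),
                    beta_xm = 0.5, beta_me = 0.7, beta_ey = 0.2,
                    beta_xe = 0.5, beta_xy = 0.1,
                    seed = substream_seed(seed, "mediation"))
  ds <- simulate_dataset(cfg)
  scans <- run_3smr(ds$gwas, ds$eqtl, ds$mqtl, ds$panel)
  chains <- intersect_chains(scans$esmr, scans$msmr, scans$m2e)
  truth_pairs <- ds$truth[ds$truth$chain, c("site", "gene")]
  called <- paste(chains$site, chains$gene)
  planted <- paste(truth_pairs$site, truth_pairs$gene)
  list(recall = if (length(planted)) mean(planted %in% called) else NA_real_,
       false_chains = sum(!called %in% planted),
       n_chains_called = nrow(chains),
       truth_pairs = nrow(truth_pairs))
}

#' Rank-one rate for a tissue with inflated association variance
#'
#' Generates per-tissue TWAS Z tables in which one tissue's Z scores are
#' drawn with inflated variance, ranks tissues with
#' \code{\link{tissue_priority}}, and reports how often the planted tissue
#' ranks first.
#'
#' @param n_reps replicates
#' @param n_tissues,n_genes panel dimensions
#' @param inflation SD inflation factor for the planted tissue
#' @param seed master seed
#' @return list(rank1_rate, n_reps)
#' @export
tissue_ranking_rate <- function(n_reps = 100, n_tissues = 8, n_genes = 50,
                                inflation = 1.3, seed = 1) {
  traits <- c("SBP", "DBP", "PP")
  methods <- c("MX", "SMR")
  hits <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    with_seed(substream_seed(seed, paste0("tissue-", r)), {
      grid <- expand.grid(tissue = sprintf("tissue%02d", seq_len(n_tissues)),
                          trait = traits, method = methods,
                          gene = sprintf("G%03d", seq_len(n_genes)),
                          stringsAsFactors = FALSE)
      sdv <- ifelse(grid$tissue == "tissue01", inflation, 1)
      grid$zscore <- rnorm(nrow(grid), 0, sdv)
      tp <- tissue_priority(grid)
      hits[r] <- tp$tissues$tissue[1] == "tissue01"
    })
  }
  list(rank1_rate = mean(hits), n_reps = n_reps)
}
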