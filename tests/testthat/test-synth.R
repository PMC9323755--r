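# Synthetic-data generator: determinism, LD structure, causal architecture
# and summary-statistic correctness.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(rho = 1.2), "rho")
  expect_error(sim_config(rho = -0.1), "rho")
  expect_error(sim_config(n_ref = 10), "cohort sizes")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(scenarios = "volcanic"), "unknown scenario")
  # a single locus explaining >= 10% of trait variance only warns
  expect_warning(sim_config(beta_ey = 0.5, scenarios = "chain"),
                 "10%")
})

test_that("identical seeds give byte-identical outputs", {
  cfg <- sim_config(n_gwas = 200, n_eqtl = 150, n_mqtl = 150, n_ref = 100,
                    n_blocks = 3, snps_per_block = 4, seed = 11,
                    scenarios = c("chain", "null", "direct"))
  g1 <- simulate_panel(cfg)
  g2 <- simulate_panel(cfg)
  expect_identical(g1, g2)
  d1 <- tempfile(); d2 <- tempfile()
  emit_dataset(d1, cfg)
  emit_dataset(d2, cfg)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the data
  g3 <- simulate_panel(sim_config(n_gwas = 200, n_eqtl = 150, n_mqtl = 150,
                                  n_ref = 100, n_blocks = 3,
                                  snps_per_block = 4, seed = 12,
                                  scenarios = c("chain", "null", "direct")))
  expect_false(identical(g1$ref, g3$ref))
})

test_that("rho = 0 gives independent SNPs; cohorts are independent", {
  cfg <- sim_config(n_gwas = 1000, n_eqtl = 1000, n_mqtl = 100, n_ref = 2000,
                    n_blocks = 4, snps_per_block = 10, rho = 0,
                    scenarios = "null", seed = 5)
  g <- simulate_panel(cfg)
  adj <- vapply(seq_len(ncol(g$ref) - 1), function(j)
    cor(g$ref[, j], g$ref[, j + 1]), numeric(1))
  expect_lt(mean(abs(adj)), 3 / sqrt(cfg$n_ref))
  # distinct RNG streams: same-index individuals in different cohorts are
  # uncorrelated
  cc <- vapply(seq_len(ncol(g$ref)), function(j)
    cor(g$gwas[1:1000, j], g$eqtl[1:1000, j]), numeric(1))
  expect_lt(mean(abs(cc)), 3 / sqrt(1000))
})

test_that("adjacent-SNP dosage correlation matches the Monte-Carlo oracle", {
  # oracle: push 1e6 latent AR(1) pairs through the same double
  # dichotomization and take the empirical dosage correlation
  rho <- 0.9; maf <- 0.3
  set.seed(101)
  nmc <- 1e6
  thr <- qnorm(maf)
  dos <- function() {
    z1 <- rnorm(nmc)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(nmc)
    cbind(z1 < thr, z2 < thr)
  }
  h1 <- dos(); h2 <- dos()
  oracle_r <- cor(h1[, 1] + h2[, 1], h1[, 2] + h2[, 2])
  cfg <- sim_config(n_gwas = 30, n_eqtl = 30, n_mqtl = 30, n_ref = 5000,
                    n_blocks = 2, snps_per_block = 2, rho = rho,
                    maf_range = c(maf, maf), scenarios = "null", seed = 7)
  g <- simulate_panel(cfg)
  emp_r <- cor(g$ref[, 1], g$ref[, 2])
  expect_lt(abs(emp_r - oracle_r), 0.05)
})

test_that("null loci give N(0,1) SNP-trait z scores (mean z^2 near 1)", {
  cfg <- sim_config(n_gwas = 4000, n_eqtl = 100, n_mqtl = 100, n_ref = 100,
                    n_blocks = 250, snps_per_block = 8, rho = 0.5,
                    scenarios = "null", seed = 21)
  g <- simulate_panel(cfg)
  ph <- simulate_phenotypes(g$gwas, cfg, g$map, "gwas")
  ss <- compute_summary_stats(g$gwas, ph$y, g$map)
  expect_gte(nrow(ss), 2000)
  expect_gt(mean(ss$z^2), 0.9)
  expect_lt(mean(ss$z^2), 1.1)
})

test_that("a broken chain (beta_xm = 0) leaves the trait independent of genotype", {
  cfg <- sim_config(n_gwas = 8000, n_eqtl = 100, n_mqtl = 100, n_ref = 100,
                    n_blocks = 1, snps_per_block = 3, rho = 0.5,
                    beta_xm = 0, scenarios = "chain", seed = 31)
  g <- simulate_panel(cfg)
  ph <- simulate_phenotypes(g$gwas, cfg, g$map, "gwas")
  causal <- ph$truth$causal_snp[1]
  expect_lt(abs(cor(g$gwas[, causal], ph$y)), 4 / sqrt(cfg$n_gwas))
})

test_that("chain methylation-expression correlation matches the path oracle", {
  # linear-Gaussian path model with unit variances: corr(m, e) = beta_me
  cfg <- sim_config(n_gwas = 100, n_eqtl = 20000, n_mqtl = 100, n_ref = 100,
                    n_blocks = 1, snps_per_block = 3,
                    beta_xm = 0.5, beta_me = 0.5, beta_ey = 0.3,
                    scenarios = "chain", seed = 13)
  g <- simulate_panel(cfg)
  ph <- simulate_phenotypes(g$eqtl, cfg, g$map, "eqtl")
  expect_lt(abs(cor(ph$m[, 1], ph$e[, 1]) - 0.5), 0.03)
})

test_that("marginal slope at the causal SNP recovers the path product", {
  cfg <- sim_config(n_gwas = 20000, n_eqtl = 100, n_mqtl = 100, n_ref = 100,
                    n_blocks = 1, snps_per_block = 3,
                    beta_xm = 0.5, beta_me = 0.5, beta_ey = 0.3,
                    scenarios = "chain", seed = 17)
  g <- simulate_panel(cfg)
  ph <- simulate_phenotypes(g$gwas, cfg, g$map, "gwas")
  ss <- compute_summary_stats(g$gwas, ph$y, g$map)
  rec <- ss[ss$snp == ph$truth$causal_snp[1], ]
  path <- 0.5 * 0.5 * 0.3
  expect_lt(abs(rec$b - path), 2.81 * rec$se)
})

test_that("summary statistics equal the closed-form OLS oracle", {
  set.seed(3)
  n <- 500
  G <- cbind(rbinom(n, 2, 0.2), rbinom(n, 2, 0.45))
  map <- data.frame(snp = c("a", "b"), chr = 1L, bp = c(1L, 2L),
                    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  y <- rnorm(n) + 0.2 * G[, 1]
  ss <- compute_summary_stats(G, y, map)
  for (j in 1:2) {
    # brute-force arithmetic oracle
    gx <- G[, j] - mean(G[, j]); yc <- y - mean(y)
    b <- sum(gx * yc) / sum(gx^2)
    se <- sqrt(sum((yc - b * gx)^2) / ((n - 2) * sum(gx^2)))
    expect_lt(abs(ss$b[j] - b), 1e-10)
    expect_lt(abs(ss$se[j] - se), 1e-10)
    expect_equal(ss$z[j], ss$b[j] / ss$se[j], tolerance = 1e-12)
  }
})

test_that("perfect association keeps the record with underflowed p", {
  set.seed(4)
  n <- 200
  G <- cbind(rbinom(n, 2, 0.3))
  map <- data.frame(snp = "s", chr = 1L, bp = 1L, a1 = "A", a2 = "G",
                    stringsAsFactors = FALSE)
  ss <- compute_summary_stats(G, as.numeric(G[, 1]), map)
  expect_equal(nrow(ss), 1)
  expect_gt(abs(ss$z), 1e7)
  expect_equal(ss$p, .Machine$double.xmin)
})

test_that("zero-variance SNPs are dropped with a warning", {
  set.seed(5)
  n <- 100
  G <- cbind(rbinom(n, 2, 0.3), rep(2L, n))
  map <- data.frame(snp = c("ok", "mono"), chr = 1L, bp = c(1L, 2L),
                    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  expect_warning(ss <- compute_summary_stats(G, rnorm(n), map), "mono")
  expect_equal(ss$snp, "ok")
})

test_that("permuted phenotype gives uniform p-values", {
  cfg <- sim_config(n_gwas = 500, n_eqtl = 100, n_mqtl = 100, n_ref = 100,
                    n_blocks = 625, snps_per_block = 8, rho = 0.6,
                    scenarios = "null", seed = 23)
  g <- simulate_panel(cfg)
  ph <- simulate_phenotypes(g$gwas, cfg, g$map, "gwas")
  set.seed(99)
  yperm <- sample(ph$y)
  ss <- compute_summary_stats(g$gwas, yperm, g$map)
  expect_gte(nrow(ss), 5000)
  d <- suppressWarnings(ks.test(ss$p, "punif"))$statistic
  expect_lt(unname(d), 1.628 / sqrt(nrow(ss)))  # 1% critical value
})

test_that("truth table covers every locus with correct chain flags", {
  ds <- small_dataset()
  cfg <- ds$config
  expect_equal(nrow(ds$truth), cfg$n_blocks)
  expect_equal(sum(ds$truth$chain),
               sum(cfg$scenarios == "chain"))
  expect_setequal(ds$truth$gene, sprintf("G%04d", seq_len(cfg$n_blocks)))
  # chain flag true only when all three chain betas are nonzero
  expect_true(all(ds$truth$chain ==
                    (ds$truth$beta_xm != 0 & ds$truth$beta_me != 0 &
                       ds$truth$beta_ey != 0)))
})

test_that("linkage scenario plants two correlated causal SNPs", {
  cfg <- sim_config(n_gwas = 100, n_eqtl = 100, n_mqtl = 100, n_ref = 4000,
                    n_blocks = 1, snps_per_block = 20, rho = 0.85,
                    linkage_r = 0.7, scenarios = "linkage", seed = 37)
  g <- simulate_panel(cfg)
  ph <- simulate_phenotypes(g$ref, cfg, g$map, "ref")
  tr <- ph$truth
  expect_false(is.na(tr$causal_snp2))
  r <- cor(g$ref[, tr$causal_snp], g$ref[, tr$causal_snp2])
  # dosage correlation is attenuated relative to the latent target
  expect_gt(r, 0.4)
  expect_lt(r, 0.85)
})
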