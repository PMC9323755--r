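# SMR ratio test, instrument selection, HEIDI, and the chi-square mixture
# tail probability.

test_that("smr_test arithmetic matches hand-computed cases", {
  # symmetric z = 2 case: T = 16/8 = 2
  st <- smr_test(assoc_rec("s", b = 0.2, se = 0.1),
                 assoc_rec("s", b = 0.02, se = 0.01))
  expect_equal(st$t_smr, 2.0)
  # null outcome: T = 0, P = 1, b_xy = 0
  st0 <- smr_test(assoc_rec("s", b = 0.2, se = 0.1),
                  assoc_rec("s", b = 0, se = 0.01))
  expect_equal(st0$t_smr, 0)
  expect_equal(st0$p_smr, 1)
  expect_equal(st0$b_xy, 0)
  # delta-method example
  st1 <- smr_test(assoc_rec("s", b = 0.5, se = 0.05),
                  assoc_rec("s", b = 0.1, se = 0.02))
  expect_equal(st1$b_xy, 0.2)
  expect_equal(st1$se_xy, sqrt(0.0004 / 0.25 + 0.01 * 0.0025 / 0.0625),
               tolerance = 1e-12)
  expect_equal(st1$se_xy, 0.04472136, tolerance = 1e-6)
  # zero exposure effect is an error
  expect_error(smr_test(assoc_rec("s", b = 0, se = 0.1),
                        assoc_rec("s", b = 0.1, se = 0.02)), "ratio")
})

test_that("delta-method se matches a Monte-Carlo ratio-of-normals oracle", {
  set.seed(77)
  nmc <- 2e6
  bzy <- rnorm(nmc, 0.1, 0.02)
  bzx <- rnorm(nmc, 0.5, 0.05)
  mc_sd <- sd(bzy / bzx)
  st <- smr_test(assoc_rec("s", b = 0.5, se = 0.05),
                 assoc_rec("s", b = 0.1, se = 0.02))
  expect_lt(abs(st$se_xy - mc_sd) / mc_sd, 0.05)
})

test_that("T_SMR is exchange-invariant and bounded by min(z1^2, z2^2)", {
  set.seed(12)
  for (i in 1:200) {
    e <- assoc_rec("s", b = rnorm(1), se = runif(1, 0.01, 0.2))
    o <- assoc_rec("s", b = rnorm(1), se = runif(1, 0.01, 0.2))
    if (e$b == 0 || o$b == 0) next
    t1 <- smr_test(e, o)$t_smr
    t2 <- smr_test(o, e)$t_smr
    expect_equal(t1, t2, tolerance = 1e-12)
    expect_lte(t1, min((e$b / e$se)^2, (o$b / o$se)^2) + 1e-12)
  }
})

test_that("instrument selection honors thresholds and tie rules", {
  q <- data.frame(
    probe_id = "g", probe_bp = 5000,
    snp = c("a", "b", "c", "d"),
    snp_bp = c(1000, 2000, 3000, 5e6 + 5000),
    b = c(0.5, 0.5, 0.1, 0.9), se = c(0.05, 0.05, 0.05, 0.05),
    stringsAsFactors = FALSE
  )
  q$z <- q$b / q$se
  q$p <- c(1e-10, 1e-10, 1e-3, 1e-20)
  # d is outside the cis window; a and b tie on p and |z| -> smaller bp
  top <- select_top_instrument(q, cis_window = 2e6, p_instrument = 5e-8)
  expect_equal(top$snp, "a")
  # no eligible instrument
  expect_null(select_top_instrument(q[3, ], cis_window = 2e6,
                                    p_instrument = 5e-8))
  # selection equals brute-force argmin on a random table
  set.seed(4)
  qq <- data.frame(probe_id = "g", probe_bp = 0,
                   snp = sprintf("s%02d", 1:40),
                   snp_bp = sample(1e6, 40),
                   b = rnorm(40), se = runif(40, 0.01, 0.1),
                   stringsAsFactors = FALSE)
  qq$z <- qq$b / qq$se
  qq$p <- 2 * pnorm(-abs(qq$z)) * 1e-6  # force some below 5e-8
  eligible <- qq[qq$p < 5e-8, ]
  expect_equal(select_top_instrument(qq)$snp,
               eligible$snp[which.min(eligible$p)])
})

test_that("chi-square mixture tail matches Monte Carlo and 1-df case", {
  lambda <- c(1.8, 0.9, 0.4, 0.1)
  set.seed(50)
  draws <- colSums(lambda * matrix(rchisq(4 * 2e5, 1), 4))
  for (q in c(2, 5, 10)) {
    mc <- mean(draws > q)
    expect_lt(abs(pchisq_mixture(q, lambda) - mc),
              3 * sqrt(mc * (1 - mc) / 2e5) + 1e-4)
  }
  # single unit weight reduces to chi-square 1
  expect_equal(pchisq_mixture(3.84, 1), pchisq(3.84, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(pchisq_mixture(0, c(1, 2)), 1)
})

test_that("HEIDI is 1 for identical ratios and absent with < 3 candidates", {
  ds <- small_dataset()
  q <- ds$eqtl[ds$eqtl$probe_id == "G0001", ]
  # outcome proportional to exposure: all per-SNP ratios identical
  out <- qtl_to_assoc(ds$eqtl, "G0001")
  out$b <- 0.5 * q$b
  out$se <- pmax(q$se, 1e-4)
  top <- q$snp[which.min(q$p)]
  h <- heidi_test(q, out, ds$panel, top)
  if (!is.na(h$p_heidi)) {
    expect_lt(h$t_heidi, 1e-18)
    expect_equal(h$p_heidi, 1)
  }
  # too few candidates: absent, flagged by nsnp < 3
  h2 <- heidi_test(q[1:3, ], out[1:3, ], ds$panel, top)
  expect_true(is.na(h2$p_heidi))
  expect_lt(h2$nsnp, 3)
})

test_that("smr_scan recovers planted effects and keeps untestable HEIDI probes", {
  ds <- small_dataset()
  sc <- smr_scan(ds$gwas, ds$eqtl, ds$panel)
  expect_true(all(sc$p_SMR > 0 & sc$p_SMR <= 1))
  expect_true(all(sc$t_SMR >= 0))
  expect_equal(unique(sc$p_bonf), 0.05 / nrow(sc))
  # chain probes estimate beta_ey = 0.3
  chain_genes <- ds$truth$gene[ds$truth$scenario == "chain"]
  est <- sc$b_SMR[sc$gene_id %in% chain_genes]
  expect_true(all(abs(est - 0.3) < 0.15))
  # probes with untestable HEIDI are retained, not dropped
  if (any(!sc$heidi_testable)) {
    nt <- sc[!sc$heidi_testable, ]
    expect_true(all(is.na(nt$p_HEIDI)))
  }
})

test_that("P_SMR is uniform under the trait null", {
  cal <- calibrate_smr_null(n_probes = 300, n_gwas = 4000, n_eqtl = 2000,
                            batches = 3, seed = 4)
  expect_gt(cal$ks_p, 0.01)
  expect_gt(cal$rate_p05, 0.02)
  expect_lt(cal$rate_p05, 0.09)
})

test_that("b_SMR bias shrinks as the exposure sample grows", {
  r_small <- recover_smr_effect(n_loci = 60, n_gwas = 8000, n_eqtl = 600,
                                seed = 6)
  r_large <- recover_smr_effect(n_loci = 60, n_gwas = 8000, n_eqtl = 6000,
                                seed = 6)
  expect_lt(abs(r_large$mean_bxy - 0.3), abs(r_small$mean_bxy - 0.3) + 0.02)
  expect_lt(abs(r_large$mean_bxy - 0.3), 0.05)
})
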