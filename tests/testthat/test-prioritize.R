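# Evidence merging, tissue prioritization, replication and cross-tissue
# consistency.

test_that("evidence merging scores and tiers follow the six-source rule", {
  ev <- merge_evidence(ns_genes = c("A", "D"), ml_genes = "D",
                       mx_genes = c("A", "B", "D"), smr_genes = c("A", "D"),
                       depict_genes = c("A", "C"), chain_genes = c("D", "Z"),
                       known_genes = c("A", "B"))
  # D: NS+ML+MX+SMR+SMR3 = 5 -> high; A: NS+MX+SMR+DEPICT = 4 -> high
  expect_equal(ev$score[ev$gene == "D"], 5)
  expect_equal(ev$tier[ev$gene == "D"], "high")
  expect_equal(ev$score[ev$gene == "A"], 4)
  # B: MX only -> base, known; C: DEPICT only -> base member with score 1
  expect_equal(ev$tier[ev$gene == "B"], "base")
  expect_equal(ev$score[ev$gene == "C"], 1)
  # Z has only mediation evidence: not a base member at all
  expect_false("Z" %in% ev$gene)
  # novel flags
  expect_false(ev$novel[ev$gene == "A"])
  expect_true(ev$novel[ev$gene == "C"])
  # empty inputs give an empty table
  expect_equal(nrow(merge_evidence()), 0)
})

test_that("merging is idempotent, order-independent and monotone", {
  ev1 <- merge_evidence(ns_genes = c("A", "B", "A"), mx_genes = "B")
  ev2 <- merge_evidence(ns_genes = c("B", "A"), mx_genes = c("B", "B"))
  expect_equal(ev1, ev2)
  # adding a source never decreases any gene's score
  ev3 <- merge_evidence(ns_genes = c("A", "B"), mx_genes = "B",
                        depict_genes = "A")
  common <- intersect(ev1$gene, ev3$gene)
  expect_true(all(ev3$score[match(common, ev3$gene)] >=
                    ev1$score[match(common, ev1$gene)]))
})

test_that("tissue scores average squared Z and rank deterministically", {
  d <- expand.grid(tissue = c("aorta", "tibial"), trait = "SBP",
                   method = "MX", gene = paste0("g", 1:10),
                   stringsAsFactors = FALSE)
  d$zscore <- ifelse(d$tissue == "aorta", 2, 1)
  tp <- tissue_priority(d)
  expect_equal(tp$cells$S[tp$cells$tissue == "aorta"], 4)
  expect_equal(tp$tissues$tissue[1], "aorta")
  # permuting gene order leaves S unchanged
  tp2 <- tissue_priority(d[sample(nrow(d)), ])
  expect_equal(tp$tissues, tp2$tissues)
  # relabeling tissues permutes ranks identically
  d2 <- d
  d2$tissue <- ifelse(d$tissue == "aorta", "tibial", "aorta")
  tp3 <- tissue_priority(d2)
  expect_equal(tp3$tissues$tissue[1], "tibial")
})

test_that("a variance-inflated tissue ranks first", {
  rr <- tissue_ranking_rate(n_reps = 30, seed = 2)
  expect_gte(rr$rank1_rate, 0.95)
})

test_that("replication uses min p over methods and traits of evidence", {
  rep_res <- data.frame(
    gene = c("A", "A", "B", "B", "C"),
    method = c("MX", "SMR", "MX", "SMR", "MX"),
    trait = c("SBP", "DBP", "SBP", "SBP", "PP"),
    p = c(0.04, 0.5, 0.2, 0.3, 0.01), stringsAsFactors = FALSE
  )
  r <- replicate_genes(c("A", "B", "D"), rep_res)
  expect_true(r$replicated[r$gene == "A"])   # 0.04 < 0.05 in one method
  expect_false(r$replicated[r$gene == "B"])
  expect_false(r$testable[r$gene == "D"])    # absent -> not replicated
  expect_equal(attr(r, "fraction"), 1 / 3)
  # excluding untestable genes changes the denominator only
  r2 <- replicate_genes(c("A", "B", "D"), rep_res,
                        count_missing = "exclude")
  expect_equal(attr(r2, "fraction"), 1 / 2)
  # traits of evidence restrict the minimum
  sel <- data.frame(gene = "A", traits = "DBP", stringsAsFactors = FALSE)
  r3 <- replicate_genes(sel, rep_res)
  expect_false(r3$replicated)  # only the DBP run (p = 0.5) counts
  # alpha = 0: nothing replicates
  r4 <- replicate_genes(c("A", "C"), rep_res, alpha = 0)
  expect_false(any(r4$replicated))
})

test_that("cross-tissue consistency requires matching signs and nominal p", {
  res <- data.frame(
    gene = "G", tissue = c("aorta", "aorta", "tibial", "tibial"),
    method = c("MX", "SMR", "MX", "SMR"), trait = "SBP",
    effect = c(2.1, 0.3, 1.0, -0.2), p = c(0.03, 0.2, 0.3, 0.4),
    stringsAsFactors = FALSE
  )
  # aorta: both positive, MX nominally significant -> TRUE
  cc <- cross_tissue_consistency("G", res, traits_of_evidence = "SBP")
  expect_true(cc$consistent)
  expect_equal(dim(cc$signs), c(2L, 2L))
  # discordant signs everywhere -> FALSE
  res2 <- res
  res2$effect <- c(2.1, -0.3, 1.0, -0.2)
  expect_false(cross_tissue_consistency("G", res2)$consistent)
  # untested gene -> NA flag
  expect_true(is.na(cross_tissue_consistency("H", res)$consistent))
})
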