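# 3xSMR mediation: intersect trait~eQTL, trait~mQTL and mQTL~eQTL scans into
# DNA -> methylation -> expression -> trait chains, plus the nearest-gene
# distance analysis of mediation-significant methylation sites.

#' Run the three SMR scans of the mediation analysis
#'
#' ESMR: trait outcome vs eQTL exposure. MSMR: trait outcome vs mQTL
#' exposure. M2E: each gene's cis-eQTL records act as the outcome for every
#' methylation site within \code{pair_window} of the gene (the site's mQTL
#' records are the exposure). Each scan gets its own Bonferroni threshold
#' (alpha / probes or pairs tested in that scan) and the HEIDI filter at
#' \code{heidi_threshold}.
#'
#' @param gwas trait association table
#' @param eqtl,mqtl long cis-QTL tables
#' @param panel an \code{\link{ld_panel}}
#' @param alpha family-wise error target per scan
#' @param cis_window instrument cis window
#' @param pair_window maximum site-to-gene distance for the M2E scan
#' @param p_instrument instrument threshold
#' @param heidi_threshold HEIDI pass threshold
#' @return list(esmr, msmr, m2e); m2e rows carry site and gene ids
#' @export
run_3smr <- function(gwas, eqtl, mqtl, panel, alpha = 0.05,
                     cis_window = 2e6, pair_window = 2e6,
                     p_instrument = 5e-8, heidi_threshold = 0.01) {
  esmr <- smr_scan(gwas, eqtl, panel, alpha, cis_window, p_instrument,
                   heidi = TRUE, heidi_threshold = heidi_threshold)
  msmr <- smr_scan(gwas, mqtl, panel, alpha, cis_window, p_instrument,
                   heidi = TRUE, heidi_threshold = heidi_threshold)
  m2e <- m2e_scan(mqtl, eqtl, panel, alpha, cis_window, pair_window,
                  p_instrument, heidi_threshold)
  list(esmr = esmr, msmr = msmr, m2e = m2e)
}

# mQTL (exposure) vs eQTL (outcome) scan over site-gene pairs within
# pair_window; Bonferroni denominator = pairs actually tested
m2e_scan <- function(mqtl, eqtl, panel, alpha = 0.05, cis_window = 2e6,
                     pair_window = 2e6, p_instrument = 5e-8,
                     heidi_threshold = 0.01) {
  if (!nrow(mqtl) || !nrow(eqtl)) return(empty_m2e_table())
  sites <- unique(mqtl[, c("probe_id", "probe_bp")])
  genes <- unique(eqtl[, c("probe_id", "probe_bp")])
  mgroups <- split(mqtl, mqtl$probe_id)
  egroups <- split(eqtl, eqtl$probe_id)
  rows <- list()
  for (si in seq_len(nrow(sites))) {
    sq <- mgroups[[sites$probe_id[si]]]
    near <- genes[abs(genes$probe_bp - sites$probe_bp[si]) <= pair_window, ,
                  drop = FALSE]
    for (gi in seq_len(nrow(near))) {
      gene <- near$probe_id[gi]
      outcome <- qtl_to_assoc(egroups[[gene]], gene)
      h <- suppressWarnings(harmonize_alleles(sq, outcome))
      if (!nrow(h$a)) next
      sq2 <- sq[match(h$a$snp, sq$snp), , drop = FALSE]
      inst <- select_top_instrument(sq2, cis_window, p_instrument)
      if (is.null(inst)) next
      orec <- h$b[match(inst$snp, h$b$snp), , drop = FALSE]
      if (!nrow(orec) || is.na(orec$b[1])) next
      st <- smr_test(inst, orec)
      hres <- heidi_test(sq2, h$b, panel, inst$snp)
      rows[[length(rows) + 1L]] <- data.frame(
        site = sites$probe_id[si], gene = gene, topSNP = inst$snp,
        b_SMR = st$b_xy, se_SMR = st$se_xy, t_SMR = st$t_smr,
        p_SMR = st$p_smr, p_HEIDI = hres$p_heidi, nsnp_HEIDI = hres$nsnp,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) return(empty_m2e_table())
  res <- do.call(rbind, rows)
  res$heidi_testable <- !is.na(res$p_HEIDI)
  res$n_tested <- nrow(res)
  res$p_bonf <- alpha / nrow(res)
  res$pass <- res$p_SMR < res$p_bonf &
    (!res$heidi_testable | res$p_HEIDI >= heidi_threshold)
  rownames(res) <- NULL
  res
}

empty_m2e_table <- function() {
  data.frame(site = character(), gene = character(), topSNP = character(),
             b_SMR = numeric(), se_SMR = numeric(), t_SMR = numeric(),
             p_SMR = numeric(), p_HEIDI = numeric(), nsnp_HEIDI = integer(),
             heidi_testable = logical(), n_tested = integer(),
             p_bonf = numeric(), pass = logical(), stringsAsFactors = FALSE)
}

#' Intersect the three SMR scans into mediation chains
#'
#' A (site, gene) chain is emitted iff the site passes the trait~mQTL scan,
#' the gene passes the trait~eQTL scan, and the pair passes the mQTL~eQTL
#' scan. The direction-consistent flag — sign(b_m2y) == sign(b_m2e * b_e2y) —
#' is informational, not a filter.
#'
#' @param esmr,msmr trait~eQTL and trait~mQTL scan tables
#'   (\code{\link{smr_scan}})
#' @param m2e mQTL~eQTL pair table (\code{\link{run_3smr}})
#' @return chain table: site, gene, b_m2e, b_e2y, b_m2y, p_SMR and p_HEIDI
#'   per leg, consistent
#' @export
intersect_chains <- function(esmr, msmr, m2e) {
  ep <- esmr[esmr$pass, , drop = FALSE]
  mp <- msmr[msmr$pass, , drop = FALSE]
  pp <- m2e[m2e$pass, , drop = FALSE]
  hit <- pp[pp$site %in% mp$probe & pp$gene %in% ep$probe, , drop = FALSE]
  if (!nrow(hit))
    return(data.frame(site = character(), gene = character(),
                      b_m2e = numeric(), b_e2y = numeric(), b_m2y = numeric(),
                      p_m2e = numeric(), p_e2y = numeric(), p_m2y = numeric(),
                      heidi_m2e = numeric(), heidi_e2y = numeric(),
                      heidi_m2y = numeric(), consistent = logical(),
                      stringsAsFactors = FALSE))
  ei <- match(hit$gene, ep$probe)
  mi <- match(hit$site, mp$probe)
  out <- data.frame(
    site = hit$site, gene = hit$gene,
    b_m2e = hit$b_SMR, b_e2y = ep$b_SMR[ei], b_m2y = mp$b_SMR[mi],
    p_m2e = hit$p_SMR, p_e2y = ep$p_SMR[ei], p_m2y = mp$p_SMR[mi],
    heidi_m2e = hit$p_HEIDI, heidi_e2y = ep$p_HEIDI[ei],
    heidi_m2y = mp$p_HEIDI[mi],
    stringsAsFactors = FALSE
  )
  out$consistent <- ifelse(
    out$b_m2e != 0 & out$b_e2y != 0 & out$b_m2y != 0,
    sign(out$b_m2y) == sign(out$b_m2e * out$b_e2y), NA
  )
  rownames(out) <- NULL
  out
}

#' Distance from methylation sites to their nearest genes
#'
#' For each site, the nearest gene by minimal bp gap (0 when the site falls
#' inside the gene body; coordinates 1-based inclusive). When two genes are
#' equidistant the gene with the smaller start coordinate is chosen. Genes
#' are partitioned by presence in \code{evidence_genes} and the per-group
#' median and quartiles of the distances are reported, with a descriptive
#' rank-sum comparison.
#'
#' @param sites data frame (id, bp) of methylation sites
#' @param annotation probe annotation; rows with class == "gene" are used
#' @param evidence_genes character vector of genes with functional evidence
#' @return list(distances, summary, rank_sum_p)
#' @export
nearest_gene_distances <- function(sites, annotation, evidence_genes) {
  genes <- annotation[annotation$class == "gene", , drop = FALSE]
  if (!nrow(genes)) stop("empty gene annotation")
  ord <- order(genes$start)
  genes <- genes[ord, , drop = FALSE]
  dist_one <- function(bp) {
    d <- ifelse(bp >= genes$start & bp <= genes$end, 0,
                pmin(abs(bp - genes$start), abs(bp - genes$end)))
    i <- which(d == min(d))[1]  # genes sorted by start: ties -> smaller start
    c(dist = d[i], idx = i)
  }
  hits <- t(vapply(sites$bp, dist_one, numeric(2)))
  distances <- data.frame(
    site = sites$id, gene = genes$id[hits[, "idx"]],
    distance_bp = hits[, "dist"],
    has_evidence = genes$id[hits[, "idx"]] %in% evidence_genes,
    stringsAsFactors = FALSE
  )
  qs <- function(x) if (length(x)) quantile(x, c(0.25, 0.5, 0.75)) else
    rep(NA_real_, 3)
  summ <- do.call(rbind, lapply(split(distances$distance_bp,
                                      distances$has_evidence), qs))
  summary_df <- data.frame(
    group = ifelse(rownames(summ) == "TRUE", "with_evidence",
                   "without_evidence"),
    q25 = summ[, 1], median = summ[, 2], q75 = summ[, 3],
    n = as.integer(table(distances$has_evidence)[rownames(summ)]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  rs <- if (length(unique(distances$has_evidence)) == 2)
    suppressWarnings(wilcox.test(distance_bp ~ has_evidence,
                                 data = distances)$p.value)
  else NA_real_
  list(distances = distances, summary = summary_df, rank_sum_p = rs)
}
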