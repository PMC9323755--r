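# Summary-data-based Mendelian randomization: ratio test at the top cis-QTL
# instrument, and the HEIDI heterogeneity filter that flags loci where the
# signal is driven by two distinct variants in LD (linkage) rather than one
# shared variant.

#' Select the top cis instrument for a probe
#'
#' The SNP with the smallest exposure p-value within \code{cis_window} of the
#' probe position, subject to p < \code{p_instrument}. Ties are broken by
#' larger |z|, then smaller bp.
#'
#' @param probe_qtl QTL records for one probe (long-format rows)
#' @param cis_window cis radius in bp around the probe position
#' @param p_instrument instrument significance threshold
#' @return the selected row (1-row data frame), or NULL when no SNP qualifies
#' @export
select_top_instrument <- function(probe_qtl, cis_window = 2e6,
                                  p_instrument = 5e-8) {
  cis <- probe_qtl[abs(probe_qtl$snp_bp - probe_qtl$probe_bp) <= cis_window &
                     probe_qtl$p < p_instrument, , drop = FALSE]
  if (!nrow(cis)) return(NULL)
  ord <- order(cis$p, -abs(cis$z), cis$snp_bp)
  cis[ord[1], , drop = FALSE]
}

#' SMR ratio test for one exposure/outcome record pair
#'
#' b_xy = b_zy / b_zx with the delta-method standard error
#' sqrt(se_zy^2/b_zx^2 + b_zy^2 se_zx^2 / b_zx^4). The test statistic is
#' T_SMR = z_zy^2 z_zx^2 / (z_zy^2 + z_zx^2), referred to a 1-df chi-square.
#'
#' @param exposure_rec,outcome_rec 1-row association records (b, se) with
#'   harmonized alleles
#' @return data frame: b_xy, se_xy, t_smr, p_smr
#' @export
smr_test <- function(exposure_rec, outcome_rec) {
  b_zx <- exposure_rec$b; se_zx <- exposure_rec$se
  b_zy <- outcome_rec$b;  se_zy <- outcome_rec$se
  if (b_zx == 0) stop("undefined ratio: exposure effect is zero")
  z_zx <- b_zx / se_zx; z_zy <- b_zy / se_zy
  b_xy <- b_zy / b_zx
  se_xy <- sqrt(se_zy^2 / b_zx^2 + b_zy^2 * se_zx^2 / b_zx^4)
  denom <- z_zx^2 + z_zy^2
  t_smr <- if (denom == 0) 0 else (z_zx^2 * z_zy^2) / denom
  data.frame(b_xy = b_xy, se_xy = se_xy, t_smr = t_smr,
             p_smr = pchisq(t_smr, df = 1, lower.tail = FALSE))
}

# Delta-method covariance of the per-SNP ratio estimates a_i = b_zy_i/b_zx_i,
# with LD-induced covariance r_ij se_i se_j within each of the (independent)
# exposure and outcome samples. Includes the second-order expansion terms in
# the exposure noise (q_i = 1/z_zx_i^2): the first-order formula understates
# var(a_i - a_j) when candidate instruments are only moderately strong
# (z_zx ~ 3-6, exactly the HEIDI candidate regime), which inflates the
# heterogeneity statistic under the single-causal-variant null.
ratio_cov <- function(b_zx, se_zx, b_zy, se_zy, R) {
  u <- se_zy / b_zx           # outcome-noise scale
  w <- b_zy * se_zx / b_zx^2  # exposure-noise scale
  q <- (se_zx / b_zx)^2       # squared coefficient of variation = 1/z_zx^2
  Q <- outer(q, q, "+")
  a2 <- u * sqrt(q)
  b2 <- w * sqrt(q)
  R * tcrossprod(u) * (1 + Q) +
    R * tcrossprod(w) * (1 + 3 * Q) +
    (R * R) * (tcrossprod(a2) + 2 * tcrossprod(b2))
}

#' HEIDI heterogeneity test
#'
#' Candidate SNPs are cis SNPs with exposure p < \code{p_candidate} whose LD
#' with the top instrument satisfies 0.05 <= r^2 <= 0.9, capped at the 20
#' most significant. For each candidate the difference d_i between its ratio
#' estimate and the top SNP's is standardized using the delta-method
#' covariance (including the LD-induced covariance between outcome effects,
#' and analogously for exposure effects). T_HEIDI = sum z_d^2 is referred to
#' the distribution of a weighted sum of 1-df chi-squares with weights the
#' eigenvalues of the correlation matrix of the z_d vector, evaluated by
#' Imhof-type integration (Satterthwaite fallback). With fewer than 3
#' candidates the test is not performed (returned p is NA); such probes are
#' retained downstream with a "not testable" flag.
#'
#' @param probe_qtl exposure QTL records for one probe
#' @param outcome_recs outcome association records (SNP-keyed, harmonized to
#'   the exposure's allele coding)
#' @param panel an \code{\link{ld_panel}}
#' @param top_snp id of the selected instrument
#' @param p_candidate exposure p-value cap for candidate SNPs
#' @param r2_range allowed r^2 with the top SNP
#' @param cap maximum number of candidates (most significant kept)
#' @param min_snps minimum candidates for the test to run
#' @return list(t_heidi, p_heidi, nsnp) — p_heidi NA when not testable
#' @export
heidi_test <- function(probe_qtl, outcome_recs, panel, top_snp,
                       p_candidate = 1.57e-3, r2_range = c(0.05, 0.9),
                       cap = 20L, min_snps = 3L) {
  not_testable <- function(n) list(t_heidi = NA_real_, p_heidi = NA_real_,
                                   nsnp = n)
  ex <- probe_qtl[probe_qtl$snp %in% outcome_recs$snp &
                    probe_qtl$snp %in% panel$map$snp, , drop = FALSE]
  if (!top_snp %in% ex$snp) return(not_testable(0L))
  usable <- panel$sd[match(ex$snp, panel$map$snp)] > 0
  ex <- ex[usable, , drop = FALSE]
  top_i <- match(top_snp, ex$snp)
  if (is.na(top_i)) return(not_testable(0L))
  r_top <- as.numeric(cor(panel$G[, top_snp],
                          panel$G[, ex$snp, drop = FALSE]))
  r2_top <- r_top^2
  cand <- which(ex$p < p_candidate &
                  r2_top >= r2_range[1] & r2_top <= r2_range[2] &
                  seq_len(nrow(ex)) != top_i)
  if (length(cand) > cap) cand <- cand[order(ex$p[cand])][seq_len(cap)]
  if (length(cand) < min_snps) return(not_testable(length(cand)))
  sel <- c(top_i, cand)
  exs <- ex[sel, , drop = FALSE]
  outs <- outcome_recs[match(exs$snp, outcome_recs$snp), , drop = FALSE]
  R <- ld_matrix(panel, exs$snp)
  # guard against a numerically singular LD submatrix
  if (rcond(R) < 1e-10) {
    R <- R + diag(1e-6, nrow(R))
    message("HEIDI: ridge-regularized a singular LD submatrix for ",
            probe_qtl$probe_id[1])
  }
  V <- ratio_cov(exs$b, exs$se, outs$b, outs$se, R)
  a <- outs$b / exs$b
  m <- length(cand)
  d <- a[-1] - a[1]
  # cov(d_i, d_j) = V[i,j] - V[i,top] - V[j,top] + V[top,top]
  Vd <- V[-1, -1, drop = FALSE] -
    matrix(V[-1, 1], m, m) - matrix(V[-1, 1], m, m, byrow = TRUE) + V[1, 1]
  sdd <- sqrt(diag(Vd))
  if (any(!is.finite(sdd)) || any(sdd <= 0)) return(not_testable(m))
  z_d <- d / sdd
  t_heidi <- sum(z_d^2)
  Rd <- Vd / tcrossprod(sdd)
  lambda <- eigen(Rd, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  list(t_heidi = t_heidi,
       p_heidi = pchisq_mixture(t_heidi, lambda),
       nsnp = m)
}

#' SMR scan over all probes of a QTL dataset
#'
#' For every probe with an eligible cis instrument: harmonize alleles with
#' the outcome, run the ratio test, and (optionally) the HEIDI filter. The
#' Bonferroni threshold is alpha divided by the number of probes actually
#' tested in this run. \code{pass} requires p_SMR below that threshold and
#' either p_HEIDI >= \code{heidi_threshold} or an untestable HEIDI (fewer
#' than 3 candidate SNPs), which is retained with \code{heidi_testable =
#' FALSE}.
#'
#' @param gwas outcome association table (SNP-keyed)
#' @param qtl long exposure QTL table
#' @param panel an \code{\link{ld_panel}}
#' @param alpha family-wise error target for the Bonferroni threshold
#' @param cis_window,p_instrument instrument selection parameters
#' @param heidi run the HEIDI filter?
#' @param heidi_threshold HEIDI pass threshold (default 0.01)
#' @return data frame: probe, gene_id, topSNP, b_SMR, se_SMR, t_SMR, p_SMR,
#'   t_HEIDI, p_HEIDI, nsnp_HEIDI, heidi_testable, n_tested, p_bonf, pass
#' @export
smr_scan <- function(gwas, qtl, panel, alpha = 0.05, cis_window = 2e6,
                     p_instrument = 5e-8, heidi = TRUE,
                     heidi_threshold = 0.01) {
  if (!nrow(qtl))
    return(empty_smr_table())
  groups <- split(qtl, qtl$probe_id)
  rows <- vector("list", length(groups))
  k <- 0L
  for (pid in names(groups)) {
    pq <- groups[[pid]]
    h <- suppressWarnings(harmonize_alleles(pq, gwas))
    if (!nrow(h$a)) next
    pq2 <- pq[match(h$a$snp, pq$snp), , drop = FALSE]
    out <- h$b
    inst <- select_top_instrument(pq2, cis_window, p_instrument)
    if (is.null(inst)) next
    orec <- out[match(inst$snp, out$snp), , drop = FALSE]
    st <- smr_test(inst, orec)
    hres <- if (heidi)
      heidi_test(pq2, out, panel, inst$snp)
    else list(t_heidi = NA_real_, p_heidi = NA_real_, nsnp = NA_integer_)
    k <- k + 1L
    rows[[k]] <- data.frame(
      probe = pid, gene_id = pq2$gene_id[1], topSNP = inst$snp,
      b_SMR = st$b_xy, se_SMR = st$se_xy, t_SMR = st$t_smr,
      p_SMR = st$p_smr, t_HEIDI = hres$t_heidi, p_HEIDI = hres$p_heidi,
      nsnp_HEIDI = hres$nsnp, stringsAsFactors = FALSE
    )
  }
  if (k == 0L) return(empty_smr_table())
  res <- do.call(rbind, rows[seq_len(k)])
  res$heidi_testable <- !is.na(res$p_HEIDI)
  res$n_tested <- nrow(res)
  res$p_bonf <- alpha / nrow(res)
  res$pass <- res$p_SMR < res$p_bonf &
    (!res$heidi_testable | res$p_HEIDI >= heidi_threshold)
  rownames(res) <- NULL
  res
}

empty_smr_table <- function() {
  data.frame(probe = character(), gene_id = character(), topSNP = character(),
             b_SMR = numeric(), se_SMR = numeric(), t_SMR = numeric(),
             p_SMR = numeric(), t_HEIDI = numeric(), p_HEIDI = numeric(),
             nsnp_HEIDI = integer(), heidi_testable = logical(),
             n_tested = integer(), p_bonf = numeric(), pass = logical(),
             stringsAsFactors = FALSE)
}

#' Reshape one probe's QTL records into a SNP-keyed association table
#'
#' Used when a molecular feature (e.g. a gene's expression) serves as the
#' outcome of an SMR run, as in the methylation-to-expression leg.
#'
#' @param qtl long QTL table
#' @param probe probe id to extract
#' @return association data frame (snp, a1, a2, freq, b, se, z, p, n)
#' @export
qtl_to_assoc <- function(qtl, probe) {
  d <- qtl[qtl$probe_id == probe, , drop = FALSE]
  data.frame(snp = d$snp, a1 = d$a1, a2 = d$a2, freq = d$freq,
             b = d$b, se = d$se, z = d$z, p = d$p, n = d$n,
             row.names = NULL, stringsAsFactors = FALSE)
}
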