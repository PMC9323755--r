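# Summary-based TWAS: ridge-trained cis prediction weights, the
# MetaXcan-style gene-level Z statistic computed from GWAS z-scores and
# reference LD, and the approximate-Bayes-factor colocalization screen.

#' Train cis prediction weights for each gene
#'
#' Ridge regression of expression on cis SNP dosages with the penalty chosen
#' by k-fold cross-validation over a small grid (closed-form solve per
#' fold). The reported prediction performance is the signed squared
#' correlation between out-of-fold predictions and observed expression
#' (sign(r) * r^2, so chance-level models center at 0 and can go negative),
#' with a one-sided correlation-test p-value. Fold assignment is
#' deterministic given \code{seed}.
#'
#' @param genotypes training-cohort dosage matrix
#' @param expression matrix of expression values (individuals x genes, named
#'   columns)
#' @param map SNP map for the genotype columns
#' @param annotation probe annotation (rows with class == "gene" are used)
#' @param cis_window cis radius around the gene centre
#' @param k_folds cross-validation folds; genes are skipped when the cohort
#'   has fewer than 2 * k_folds individuals
#' @param lambdas ridge penalty grid
#' @param seed fold-assignment seed
#' @return list of models; each has gene, snp, a1, a2, freq, weight, lambda,
#'   cv_r2, cv_p
#' @export
train_weights <- function(genotypes, expression, map, annotation,
                          cis_window = 1e6, k_folds = 5,
                          lambdas = c(0.1, 1, 10, 100, 1000), seed = 1) {
  n <- nrow(genotypes)
  if (n < 2 * k_folds) {
    warning("cohort smaller than 2 * k_folds; no models trained")
    return(list())
  }
  genes <- annotation[annotation$class == "gene", , drop = FALSE]
  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  models <- list()
  for (gi in seq_len(nrow(genes))) {
    gene <- genes$id[gi]
    if (!gene %in% colnames(expression)) next
    centre <- (genes$start[gi] + genes$end[gi]) / 2
    cis <- which(abs(map$bp - centre) <= cis_window)
    if (!length(cis)) next
    X <- genotypes[, cis, drop = FALSE]
    sds <- apply(X, 2, sd)
    cis <- cis[sds > 0]
    if (!length(cis)) next
    X <- genotypes[, cis, drop = FALSE]
    y <- expression[, gene]
    Xc <- scale(X, center = TRUE, scale = FALSE)
    yc <- y - mean(y)
    p <- ncol(Xc)
    cv_pred <- matrix(NA_real_, n, length(lambdas))
    for (f in seq_len(k_folds)) {
      tr <- folds != f
      mu_x <- colMeans(X[tr, , drop = FALSE])
      Xt <- sweep(X[tr, , drop = FALSE], 2, mu_x)
      yt <- y[tr] - mean(y[tr])
      XtX <- crossprod(Xt)
      Xty <- crossprod(Xt, yt)
      Xv <- sweep(X[!tr, , drop = FALSE], 2, mu_x)
      for (li in seq_along(lambdas)) {
        w <- solve(XtX + diag(lambdas[li], p), Xty)
        cv_pred[!tr, li] <- mean(y[tr]) + Xv %*% w
      }
    }
    mse <- colMeans((cv_pred - y)^2)
    best <- which.min(mse)
    r <- suppressWarnings(cor(cv_pred[, best], y))
    if (!is.finite(r)) r <- 0
    cv_r2 <- sign(r) * r^2
    cv_p <- if (abs(r) >= 1) .Machine$double.xmin else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      pt(tt, df = n - 2, lower.tail = FALSE)  # one-sided: positive skill
    }
    w <- as.numeric(solve(crossprod(Xc) + diag(lambdas[best], p),
                          crossprod(Xc, yc)))
    if (all(w == 0)) next
    models[[gene]] <- list(
      gene = gene, snp = map$snp[cis], a1 = map$a1[cis], a2 = map$a2[cis],
      freq = colMeans(X) / 2, weight = w, lambda = lambdas[best],
      cv_r2 = cv_r2, cv_p = cv_p
    )
  }
  models
}

#' Flatten trained models to the flat store format
#' @param models list from \code{\link{train_weights}}
#' @return data frame: gene, SNP, A1, A2, weight, cv_r2, cv_p
#' @export
model_table <- function(models) {
  do.call(rbind, lapply(models, function(m)
    data.frame(gene = m$gene, SNP = m$snp, A1 = m$a1, A2 = m$a2,
               weight = m$weight, cv_r2 = m$cv_r2, cv_p = m$cv_p,
               row.names = NULL, stringsAsFactors = FALSE)))
}

#' MetaXcan-style gene-level Z from GWAS summary statistics
#'
#' Z_g = sum_l w_l (sigma_l / sigma_g) z_l, with sigma_l the SNP dosage SD in
#' the reference panel and sigma_g^2 = w' Sigma w, Sigma the panel dosage
#' covariance of the model SNPs. Model SNPs missing from the GWAS are
#' dropped and sigma_g recomputed from the remaining weights; the gene is
#' skipped when more than half of the absolute weight mass is lost, or when
#' sigma_g = 0.
#'
#' @param model one element of \code{\link{train_weights}}'s output
#' @param gwas association table
#' @param panel an \code{\link{ld_panel}}
#' @param max_weight_loss maximum tolerated fraction of |weight| mass lost
#' @return 1-row data frame (gene, zscore, p, sigma_g, n_snps, pred_perf_r2,
#'   pred_perf_p) or NULL when the gene is skipped
#' @export
metaxcan_z <- function(model, gwas, panel, max_weight_loss = 0.5) {
  mrec <- data.frame(snp = model$snp, a1 = model$a1, a2 = model$a2,
                     freq = model$freq, b = model$weight,
                     stringsAsFactors = FALSE)
  h <- suppressWarnings(harmonize_alleles(mrec, gwas))
  keep <- h$a$snp[h$a$snp %in% panel$map$snp]
  keep <- keep[panel$sd[match(keep, panel$map$snp)] > 0]
  lost <- 1 - sum(abs(model$weight[model$snp %in% keep])) /
    sum(abs(model$weight))
  if (!length(keep) || lost > max_weight_loss) {
    warning("gene ", model$gene, " skipped: ",
            round(100 * lost), "% of model weight mass unavailable")
    return(NULL)
  }
  w <- model$weight[match(keep, model$snp)]
  z <- h$b$z[match(keep, h$b$snp)]
  Gm <- panel$G[, keep, drop = FALSE]
  Sigma <- cov(Gm)
  sig_g2 <- as.numeric(t(w) %*% Sigma %*% w)
  if (sig_g2 <= 0) {
    warning("gene ", model$gene, " skipped: zero predicted-expression variance")
    return(NULL)
  }
  sig_l <- sqrt(diag(Sigma))
  zg <- sum(w * sig_l * z) / sqrt(sig_g2)
  data.frame(gene = model$gene, zscore = zg, p = z_to_p(zg),
             sigma_g = sqrt(sig_g2), n_snps = length(keep),
             pred_perf_r2 = model$cv_r2, pred_perf_p = model$cv_p,
             stringsAsFactors = FALSE)
}

#' Colocalization priors and effect-variance prior
#' @param p1,p2 prior probability a SNP is associated with trait 1 / trait 2
#'   only
#' @param p12 prior probability a SNP is associated with both
#' @param W prior variance of the effect size (quantitative-trait default
#'   0.15^2)
#' @return list of validated priors
#' @export
coloc_config <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, W = 0.15^2) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, p12 > 0, p12 < 1, W > 0)
  if (p12 > min(p1, p2))
    warning("p12 exceeds min(p1, p2); unusual prior configuration")
  list(p1 = p1, p2 = p2, p12 = p12, W = W)
}

#' Colocalization posteriors from approximate Bayes factors
#'
#' Per SNP and trait, log ABF = 0.5 [ln(V/(V+W)) + z^2 W/(V+W)] with V = se^2.
#' The five hypothesis posteriors (H0 no association, H1/H2 single-trait,
#' H3 two distinct causal variants, H4 one shared variant) follow from the
#' standard sums over SNP configurations with priors p1, p2, p12, computed in
#' log space.
#'
#' @param trait1_recs,trait2_recs association records over the same region;
#'   matched by SNP id after harmonization
#' @param config a \code{\link{coloc_config}}
#' @return 1-row data frame PP0..PP4 with attributes \code{nsnps} and
#'   \code{testable}; with fewer than 2 shared SNPs the posteriors are NA and
#'   \code{testable} is FALSE
#' @export
coloc_abf <- function(trait1_recs, trait2_recs, config = coloc_config()) {
  h <- suppressWarnings(harmonize_alleles(trait1_recs, trait2_recs))
  nsnps <- nrow(h$a)
  if (nsnps < 2) {
    out <- data.frame(PP0 = NA_real_, PP1 = NA_real_, PP2 = NA_real_,
                      PP3 = NA_real_, PP4 = NA_real_)
    attr(out, "nsnps") <- nsnps
    attr(out, "testable") <- FALSE
    return(out)
  }
  labf <- function(rec, W) {
    V <- rec$se^2
    z <- rec$b / rec$se
    0.5 * (log(V / (V + W)) + z^2 * W / (V + W))
  }
  l1 <- labf(h$a, config$W)
  l2 <- labf(h$b, config$W)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls4 <- logsumexp(l1 + l2)
  # sum_{i != j} ABF1_i ABF2_j = S1*S2 - sum_i ABF1_i ABF2_i, in log space
  delta <- ls4 - (ls1 + ls2)
  ls3 <- if (delta >= 0) -Inf else ls1 + ls2 + log1p(-exp(delta))
  lh <- c(0,
          log(config$p1) + ls1,
          log(config$p2) + ls2,
          log(config$p1) + log(config$p2) + ls3,
          log(config$p12) + ls4)
  pp <- exp(lh - logsumexp(lh))
  out <- data.frame(PP0 = pp[1], PP1 = pp[2], PP2 = pp[3], PP3 = pp[4],
                    PP4 = pp[5])
  attr(out, "nsnps") <- nsnps
  attr(out, "testable") <- TRUE
  out
}

#' Summary-TWAS scan over all trained models
#'
#' Computes the gene-level Z and p for every model, applies the prediction
#' performance filter (cv R2 > \code{r2_min} and performance p <
#' \code{perf_p}), the Bonferroni significance threshold alpha / (genes
#' tested), and — when an eQTL table is supplied — the COLOC screen on the
#' significant genes (trait 1 = GWAS, trait 2 = that gene's cis-eQTL
#' records). \code{pass} = significant, performant, and (if tested)
#' colocalized at PP4 >= \code{pp4_min}.
#'
#' @param gwas association table
#' @param models list from \code{\link{train_weights}}
#' @param panel an \code{\link{ld_panel}}
#' @param alpha family-wise error target
#' @param eqtl optional long eQTL table for the COLOC screen
#' @param r2_min,perf_p prediction performance filter
#' @param pp4_min colocalization pass threshold
#' @param coloc a \code{\link{coloc_config}}
#' @return data frame: gene, zscore, p, sigma_g, n_snps, pred_perf_r2,
#'   pred_perf_p, perf_pass, sig, PP0..PP4, colocalized, pass
#' @export
twas_scan <- function(gwas, models, panel, alpha = 0.05, eqtl = NULL,
                      r2_min = 0.01, perf_p = 0.05, pp4_min = 0.5,
                      coloc = coloc_config()) {
  res <- do.call(rbind, lapply(models, metaxcan_z, gwas = gwas,
                               panel = panel))
  if (is.null(res) || !nrow(res)) return(res)
  res$perf_pass <- res$pred_perf_r2 > r2_min & res$pred_perf_p < perf_p
  res$p_bonf <- alpha / nrow(res)
  res$sig <- res$p < res$p_bonf
  res$PP0 <- res$PP1 <- res$PP2 <- res$PP3 <- res$PP4 <- NA_real_
  res$colocalized <- NA
  if (!is.null(eqtl)) {
    for (i in which(res$sig & res$perf_pass)) {
      gene <- res$gene[i]
      e <- eqtl[eqtl$gene_id == gene & eqtl$probe_id == gene, , drop = FALSE]
      if (!nrow(e)) e <- eqtl[eqtl$gene_id == gene, , drop = FALSE]
      if (!nrow(e)) next
      region <- gwas[gwas$snp %in% e$snp, , drop = FALSE]
      cc <- coloc_abf(region, qtl_to_assoc(e, e$probe_id[1]), coloc)
      if (isTRUE(attr(cc, "testable"))) {
        res[i, c("PP0", "PP1", "PP2", "PP3", "PP4")] <- cc[1, ]
        res$colocalized[i] <- cc$PP4 >= pp4_min
      }
    }
  }
  res$pass <- res$sig & res$perf_pass &
    (is.na(res$colocalized) | res$colocalized)
  rownames(res) <- NULL
  res
}
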