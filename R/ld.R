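# LD computation from a reference panel and r^2-based proxy expansion.

#' Construct an LD panel
#'
#' Wraps a reference dosage matrix with its SNP map and caches column means
#' and SDs. Pairwise correlations are computed on demand.
#'
#' @param genotypes dosage matrix (individuals x SNPs, named columns)
#' @param map SNP map data frame (snp, chr, bp, ...) matched to columns
#' @return an object of class \code{ld_panel}
#' @export
ld_panel <- function(genotypes, map) {
  stopifnot(ncol(genotypes) == nrow(map))
  colnames(genotypes) <- map$snp
  sds <- apply(genotypes, 2, sd)
  structure(list(G = genotypes, map = map, sd = sds,
                 n = nrow(genotypes)),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("LD panel: %d individuals x %d SNPs (%d monomorphic)\n",
              x$n, ncol(x$G), sum(x$sd == 0)))
  invisible(x)
}

snp_index <- function(panel, snps) {
  idx <- match(snps, panel$map$snp)
  if (anyNA(idx))
    stop("SNP(s) absent from panel: ",
         paste(snps[is.na(idx)], collapse = ", "))
  idx
}

#' Pearson LD correlation between two SNPs
#'
#' @param panel an \code{\link{ld_panel}}
#' @param snp_i,snp_j SNP ids
#' @return correlation r of the dosage vectors
#' @export
ld_r <- function(panel, snp_i, snp_j) {
  i <- snp_index(panel, snp_i); j <- snp_index(panel, snp_j)
  if (panel$sd[i] == 0 || panel$sd[j] == 0)
    stop("undefined LD: zero-variance SNP (",
         if (panel$sd[i] == 0) snp_i else snp_j, ")")
  cor(panel$G[, i], panel$G[, j])
}

#' LD correlation matrix for a set of SNPs
#' @param panel an \code{\link{ld_panel}}
#' @param snps SNP ids
#' @return correlation matrix
#' @export
ld_matrix <- function(panel, snps) {
  idx <- snp_index(panel, snps)
  if (any(panel$sd[idx] == 0))
    stop("undefined LD: zero-variance SNP(s): ",
         paste(snps[panel$sd[idx] == 0], collapse = ", "))
  r <- cor(panel$G[, idx, drop = FALSE])
  dimnames(r) <- list(snps, snps)
  r
}

#' Expand lead SNPs to their LD proxies ("in silico sequencing")
#'
#' Returns every SNP within \code{window_bp} of a lead whose squared dosage
#' correlation with that lead reaches \code{r2_threshold}, including the lead
#' itself. A proxy reachable from several leads is assigned to the lead with
#' the larger r^2, ties broken by smaller bp distance.
#'
#' @param panel an \code{\link{ld_panel}}
#' @param lead_snps character vector of lead SNP ids; leads absent from the
#'   panel are skipped with a warning
#' @param r2_threshold minimum r^2 (default 0.50)
#' @param window_bp search radius around each lead (default 1 Mb)
#' @return data frame: lead_snp, proxy_snp, r2, distance_bp
#' @export
proxy_expand <- function(panel, lead_snps, r2_threshold = 0.50,
                         window_bp = 1e6) {
  present <- lead_snps %in% panel$map$snp
  if (any(!present))
    warning("lead SNP(s) absent from panel, skipped: ",
            paste(lead_snps[!present], collapse = ", "))
  leads <- lead_snps[present]
  rows <- vector("list", length(leads))
  for (k in seq_along(leads)) {
    li <- snp_index(panel, leads[k])
    if (panel$sd[li] == 0) {
      warning("lead SNP has zero variance, skipped: ", leads[k])
      next
    }
    lbp <- panel$map$bp[li]
    cand <- which(abs(panel$map$bp - lbp) <= window_bp & panel$sd > 0)
    r <- as.numeric(cor(panel$G[, li], panel$G[, cand, drop = FALSE]))
    r2 <- r * r
    hit <- r2 >= r2_threshold - 1e-12 | cand == li
    rows[[k]] <- data.frame(
      lead_snp = leads[k], proxy_snp = panel$map$snp[cand[hit]],
      r2 = ifelse(cand[hit] == li, 1, r2[hit]),
      distance_bp = abs(panel$map$bp[cand[hit]] - lbp),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(lead_snp = character(), proxy_snp = character(),
                      r2 = numeric(), distance_bp = numeric()))
  # best-lead assignment: larger r2, then smaller distance
  ord <- order(out$proxy_snp, -out$r2, out$distance_bp)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(out$proxy_snp), , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$lead_snp, -out$r2), , drop = FALSE]
}
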