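# Variant-consequence prioritization and multilayer molecular-association
# lookups from local tables.

#' Genes carrying nonsynonymous variation linked to lead SNPs
#'
#' Expands the leads to their r^2 proxies in the panel, joins to the variant
#' consequence table, and returns genes with at least one nonsynonymous
#' proxy. Each gene is annotated with its nsSNPs, whether any nsSNP is itself
#' a lead, and a severity flag requiring BOTH predictors adverse (SIFT
#' "deleterious" AND PolyPhen "possibly_damaging" or "probably_damaging").
#'
#' @param lead_snps character vector of lead SNP ids
#' @param panel an \code{\link{ld_panel}}
#' @param consequence_table data frame: SNP, gene, consequence, sift,
#'   polyphen (labels; sift in deleterious/tolerated/NA, polyphen in
#'   probably_damaging/possibly_damaging/benign/NA)
#' @param r2_threshold proxy r^2 threshold (default 0.50)
#' @param window_bp proxy search radius
#' @return data frame: gene, ns_snps, n_ns, lead_is_ns, severe
#' @export
coding_consequences <- function(lead_snps, panel, consequence_table,
                                r2_threshold = 0.50, window_bp = 1e6) {
  prox <- proxy_expand(panel, lead_snps, r2_threshold, window_bp)
  ns <- consequence_table[consequence_table$consequence == "nonsynonymous", ,
                          drop = FALSE]
  hit <- merge(prox, ns, by.x = "proxy_snp", by.y = "SNP")
  if (!nrow(hit))
    return(data.frame(gene = character(), ns_snps = character(),
                      n_ns = integer(), lead_is_ns = logical(),
                      severe = logical(), stringsAsFactors = FALSE))
  hit$severe_snp <- !is.na(hit$sift) & hit$sift == "deleterious" &
    !is.na(hit$polyphen) &
    hit$polyphen %in% c("possibly_damaging", "probably_damaging")
  hit$is_lead <- hit$proxy_snp %in% lead_snps
  out <- do.call(rbind, lapply(split(hit, hit$gene), function(g)
    data.frame(gene = g$gene[1],
               ns_snps = paste(sort(unique(g$proxy_snp)), collapse = ","),
               n_ns = length(unique(g$proxy_snp)),
               lead_is_ns = any(g$is_lead),
               severe = any(g$severe_snp),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Leads associated with all four molecular layers
#'
#' A lead is returned when it has at least one association at
#' p < \code{p_threshold} in EVERY one of the four supplied QTL lookup
#' tables (methylation, expression, protein, metabolite). The reported gene
#' is the nearby gene supplied with the lead.
#'
#' @param lead_snps data frame with columns snp and gene (the annotated
#'   nearby gene per lead)
#' @param qtl_tables named list of four data frames (methylation, expression,
#'   protein, metabolite), each with columns SNP and p
#' @param p_threshold association significance threshold (default
#'   genome-wide, 5e-8)
#' @return data frame: snp, gene, and the per-layer minimum p
#' @export
multilayer_hits <- function(lead_snps, qtl_tables, p_threshold = 5e-8) {
  layers <- c("methylation", "expression", "protein", "metabolite")
  missing <- setdiff(layers, names(qtl_tables))
  if (length(missing))
    stop("missing QTL layer table(s): ", paste(missing, collapse = ", "))
  minp <- function(tab, snp) {
    p <- tab$p[tab$SNP == snp]
    if (length(p)) min(p) else NA_real_
  }
  rows <- lapply(seq_len(nrow(lead_snps)), function(i) {
    snp <- lead_snps$snp[i]
    ps <- vapply(layers, function(l) minp(qtl_tables[[l]], snp), numeric(1))
    if (any(is.na(ps)) || any(ps >= p_threshold)) return(NULL)
    data.frame(snp = snp, gene = lead_snps$gene[i],
               p_methylation = ps[1], p_expression = ps[2],
               p_protein = ps[3], p_metabolite = ps[4],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(snp = character(), gene = character(),
                      p_methylation = numeric(), p_expression = numeric(),
                      p_protein = numeric(), p_metabolite = numeric(),
                      stringsAsFactors = FALSE)
  out
}
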