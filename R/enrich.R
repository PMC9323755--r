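# Fisher's exact enrichment of prioritized genes in supplied gene sets, with
# fold-change reporting, and drug-gene annotation.

#' Fisher's exact enrichment of a gene set among prioritized genes
#'
#' Builds the 2x2 table (overlap a, prioritized-only b, set-only c, neither
#' d) over the stated universe and computes the exact hypergeometric
#' greater-tail p, a two-sided p by the point-probability method (sum of
#' outcome probabilities no larger than the observed one), the odds ratio,
#' and the fold change FC = a / ((a+b)(a+c)/N). Genes outside the universe
#' are clipped with a warning.
#'
#' @param prioritized_genes character vector
#' @param gene_set character vector
#' @param universe character vector defining N
#' @return data frame: a, b, c, d, n_universe, odds_ratio, fold_change,
#'   p_greater, p_two_sided
#' @export
fisher_enrichment <- function(prioritized_genes, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  pg <- unique(prioritized_genes)
  gs <- unique(gene_set)
  outside <- c(setdiff(pg, universe), setdiff(gs, universe))
  if (length(outside)) {
    warning(sprintf("%d gene(s) outside the universe were clipped",
                    length(outside)))
    pg <- intersect(pg, universe)
    gs <- intersect(gs, universe)
  }
  N <- length(universe)
  a <- length(intersect(pg, gs))
  b <- length(pg) - a
  c_ <- length(gs) - a
  d <- N - a - b - c_
  expected <- (a + b) * (a + c_) / N
  fc <- if (expected > 0) a / expected else NA_real_
  or <- if (b > 0 && c_ > 0) (a * d) / (b * c_) else Inf
  ps <- fisher_exact_counts(a, b, c_, d)
  data.frame(a = a, b = b, c = c_, d = d, n_universe = N,
             odds_ratio = or, fold_change = fc,
             p_greater = max(ps$p_greater, .Machine$double.xmin),
             p_two_sided = max(ps$p_two_sided, .Machine$double.xmin))
}

#' Exact hypergeometric p-values for a 2x2 table
#'
#' Count-level core of \code{\link{fisher_enrichment}}: with margins fixed,
#' the overlap count follows the hypergeometric distribution. The
#' greater-tail p is P(K >= a); the two-sided p uses the point-probability
#' method (sum of outcome probabilities no larger than the observed one, up
#' to a 1e-7 relative tolerance).
#'
#' @param a,b,c,d the 2x2 counts (overlap, row-only, column-only, neither)
#' @return list(p_greater, p_two_sided)
#' @export
fisher_exact_counts <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c   # gene-set size
  n <- a + b   # prioritized-set size
  p_greater <- phyper(a - 1, K, N - K, n, lower.tail = FALSE)
  kk <- max(0, n + K - N):min(n, K)
  dens <- dhyper(kk, K, N - K, n)
  p_two <- min(1, sum(dens[dens <= dhyper(a, K, N - K, n) * (1 + 1e-7)]))
  list(p_greater = p_greater, p_two_sided = p_two)
}

#' Annotate prioritized genes with drug-gene interactions
#'
#' Per gene: whether it is drugged (has an interaction of type "drug") or
#' druggable (category "druggable"), the interacting drugs, whether any
#' interacting drug is primarily indicated for hyper-/hypotension, whether
#' any has blood-pressure-related adverse effects, and a repurposing flag
#' (drugged, but only by drugs without the BP indication).
#'
#' @param prioritized_genes character vector
#' @param drug_table data frame: drug_id, gene, interaction_type ("drug" or
#'   "druggable"), indication ("hypertension", "hypotension" or "other"),
#'   adverse_bp (0/1)
#' @return data frame: gene, drugged, druggable, drugs, bp_indicated,
#'   bp_adverse, repurposing_candidate
#' @export
drug_annotations <- function(prioritized_genes, drug_table) {
  rows <- lapply(unique(prioritized_genes), function(g) {
    dt <- drug_table[drug_table$gene == g, , drop = FALSE]
    drugged_rows <- dt[dt$interaction_type == "drug", , drop = FALSE]
    drugged <- nrow(drugged_rows) > 0
    bp_ind <- drugged &&
      any(drugged_rows$indication %in% c("hypertension", "hypotension"))
    data.frame(
      gene = g,
      drugged = drugged,
      druggable = any(dt$interaction_type == "druggable"),
      drugs = paste(sort(unique(drugged_rows$drug_id)), collapse = ","),
      bp_indicated = bp_ind,
      bp_adverse = drugged && any(drugged_rows$adverse_bp == 1),
      repurposing_candidate = drugged && !bp_ind,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
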