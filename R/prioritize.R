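# Evidence merging, six-source scoring, tissue prioritization, replication
# and cross-tissue direction consistency.

#' Merge prioritization evidence into a scored gene table
#'
#' Base-list membership is the union of the four merge sources: coding
#' consequences (NS), multilayer molecular associations (ML), TWAS (MX or
#' SMR), and coregulation (DEPICT). The mediation source (3xSMR) contributes
#' to the six-source score but not to base membership. The score counts the
#' six boolean sources {NS, ML, MX, SMR, DEPICT, SMR3}; tiers: base (>= 1
#' merge source), multi (score >= 2), high (score >= 4). The novel flag marks
#' genes absent from a caller-supplied known-gene list.
#'
#' @param ns_genes,ml_genes,mx_genes,smr_genes,depict_genes character vectors
#'   of gene symbols per evidence source
#' @param chain_genes genes supported by the 3xSMR mediation analysis
#' @param known_genes previously reported genes (for the novel flag)
#' @return data frame: gene, NS, ML, MX, SMR, DEPICT, SMR3, score, tier,
#'   novel
#' @export
merge_evidence <- function(ns_genes = character(), ml_genes = character(),
                           mx_genes = character(), smr_genes = character(),
                           depict_genes = character(),
                           chain_genes = character(),
                           known_genes = character()) {
  base <- sort(unique(c(ns_genes, ml_genes, mx_genes, smr_genes,
                        depict_genes)))
  if (!length(base))
    return(data.frame(gene = character(), NS = logical(), ML = logical(),
                      MX = logical(), SMR = logical(), DEPICT = logical(),
                      SMR3 = logical(), score = integer(), tier = character(),
                      novel = logical(), stringsAsFactors = FALSE))
  out <- data.frame(
    gene = base,
    NS = base %in% ns_genes, ML = base %in% ml_genes,
    MX = base %in% mx_genes, SMR = base %in% smr_genes,
    DEPICT = base %in% depict_genes, SMR3 = base %in% chain_genes,
    stringsAsFactors = FALSE
  )
  out$score <- rowSums(out[, c("NS", "ML", "MX", "SMR", "DEPICT", "SMR3")])
  out$tier <- ifelse(out$score >= 4, "high",
                     ifelse(out$score >= 2, "multi", "base"))
  out$novel <- !(out$gene %in% known_genes)
  out
}

#' Tissue prioritization by average squared Z
#'
#' S = mean(Z^2) over the genes tested in each tissue x trait x method cell;
#' tissues are ranked by the grand mean of S across their cells, descending,
#' ties broken by tissue name. Empty cells are omitted with a warning and a
#' tissue with no nonempty cells is dropped.
#'
#' @param twas_results data frame with columns tissue, trait, method, gene,
#'   zscore (rows = per-gene TWAS results, stacked over tissues)
#' @return list(cells, tissues): per-cell S values, and the ranked tissue
#'   table (tissue, grand_mean, rank)
#' @export
tissue_priority <- function(twas_results) {
  need <- c("tissue", "trait", "method", "zscore")
  missing <- setdiff(need, names(twas_results))
  if (length(missing))
    stop("twas_results lacks column(s): ", paste(missing, collapse = ", "))
  keep <- is.finite(twas_results$zscore)
  d <- twas_results[keep, , drop = FALSE]
  if (!nrow(d)) stop("no finite Z scores supplied")
  key <- interaction(d$tissue, d$trait, d$method, drop = TRUE)
  cells <- do.call(rbind, lapply(split(d, key), function(g)
    data.frame(tissue = g$tissue[1], trait = g$trait[1],
               method = g$method[1], S = mean(g$zscore^2),
               n_genes = nrow(g), stringsAsFactors = FALSE)))
  rownames(cells) <- NULL
  grand <- vapply(split(cells$S, cells$tissue), mean, numeric(1))
  tissues <- data.frame(tissue = names(grand), grand_mean = unname(grand),
                        stringsAsFactors = FALSE)
  tissues <- tissues[order(-tissues$grand_mean, tissues$tissue), ,
                     drop = FALSE]
  tissues$rank <- seq_len(nrow(tissues))
  rownames(tissues) <- NULL
  list(cells = cells, tissues = tissues)
}

#' Replication of selected genes in an independent cohort
#'
#' Per gene, the minimum replication p across methods and (when supplied)
#' the traits of evidence; replicated = min p < alpha. Genes absent from the
#' replication results are marked not testable and, by default, counted as
#' not replicated (the conservative choice); set
#' \code{count_missing = "exclude"} to drop them from the denominator.
#'
#' @param selected data frame with column gene and optionally traits (comma
#'   separated traits of evidence), or a character vector of genes
#' @param replication_results data frame: gene, method, trait, p (stacked
#'   over the replication TWAS runs)
#' @param alpha replication significance threshold
#' @param count_missing "not_replicated" (default) or "exclude"
#' @return data frame gene, min_p, testable, replicated, with attribute
#'   \code{fraction} = replicated / denominator
#' @export
replicate_genes <- function(selected, replication_results, alpha = 0.05,
                            count_missing = c("not_replicated", "exclude")) {
  count_missing <- match.arg(count_missing)
  if (is.character(selected))
    selected <- data.frame(gene = selected, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(selected)), function(i) {
    g <- selected$gene[i]
    rr <- replication_results[replication_results$gene == g, , drop = FALSE]
    if (!is.null(selected$traits) && !is.na(selected$traits[i]) &&
        nzchar(selected$traits[i])) {
      traits <- trimws(strsplit(selected$traits[i], ",")[[1]])
      rr <- rr[rr$trait %in% traits, , drop = FALSE]
    }
    if (!nrow(rr))
      return(data.frame(gene = g, min_p = NA_real_, testable = FALSE,
                        replicated = FALSE, stringsAsFactors = FALSE))
    mp <- min(rr$p)
    data.frame(gene = g, min_p = mp, testable = TRUE,
               replicated = mp < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  denom <- if (count_missing == "exclude") sum(out$testable) else nrow(out)
  attr(out, "fraction") <- if (denom > 0) sum(out$replicated) / denom else
    NA_real_
  out
}

#' Cross-tissue direction consistency for one gene
#'
#' Builds the tissue x method matrix of effect signs and sets the flag TRUE
#' iff some tissue shows a nominally significant association (p < alpha) for
#' a trait of evidence with the SAME effect sign in both TWAS methods in
#' that tissue (and trait). A gene untested everywhere gets flag NA.
#'
#' @param gene gene symbol
#' @param per_tissue_results data frame: gene, tissue, method ("MX"/"SMR"),
#'   trait, effect (signed: Z or b), p
#' @param traits_of_evidence traits in which the gene carried evidence; NULL
#'   means all traits count
#' @param alpha nominal significance threshold
#' @return list(signs = tissue x method sign matrix, consistent = flag)
#' @export
cross_tissue_consistency <- function(gene, per_tissue_results,
                                     traits_of_evidence = NULL,
                                     alpha = 0.05) {
  d <- per_tissue_results[per_tissue_results$gene == gene, , drop = FALSE]
  if (!is.null(traits_of_evidence))
    d <- d[d$trait %in% traits_of_evidence, , drop = FALSE]
  if (!nrow(d))
    return(list(signs = NULL, consistent = NA))
  tiss <- sort(unique(d$tissue))
  meth <- sort(unique(d$method))
  signs <- matrix(NA_real_, length(tiss), length(meth),
                  dimnames = list(tiss, meth))
  for (i in seq_len(nrow(d)))
    signs[d$tissue[i], d$method[i]] <- sign(d$effect[i])
  flag <- FALSE
  for (tt in tiss) for (tr in unique(d$trait)) {
    cell <- d[d$tissue == tt & d$trait == tr, , drop = FALSE]
    if (length(unique(cell$method)) < 2) next
    sgn <- tapply(sign(cell$effect), cell$method, function(s) s[1])
    if (length(unique(sgn)) == 1 && any(cell$p < alpha)) flag <- TRUE
  }
  list(signs = signs, consistent = flag)
}
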