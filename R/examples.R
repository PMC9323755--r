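# Bundled published summary tables used as worked-example inputs for the
# evidence-scoring and replication operations.

#' Bundled evidence table for highly prioritized blood-pressure genes
#'
#' Fifteen genes, each with its supporting prioritization sources among
#' \{NS, ML, MX, SMR, DEPICT, SMR3\} (coding consequence, multilayer
#' molecular association, the two TWAS engines, coregulation, mediation).
#'
#' @return data frame: gene, evidence (comma-separated source labels)
#' @export
example_evidence_table <- function() {
  path <- system.file("extdata", "highly_prioritized_evidence.tsv",
                      package = "omicsmr")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Bundled replication table for novel blood-pressure genes
#'
#' The newly identified multi-evidence genes that replicated in an
#' independent cohort, with the minimum replication p across TWAS methods
#' and traits of evidence. The number of genes submitted to replication
#' (including the non-replicated ones, which the table does not list) is
#' recorded in the file header and returned as the \code{n_submitted}
#' attribute.
#'
#' @return data frame: gene, n_evidence, traits, min_p_rep; attribute
#'   \code{n_submitted}
#' @export
example_replication_table <- function() {
  path <- system.file("extdata", "novel_gene_replication.tsv",
                      package = "omicsmr")
  header <- readLines(path, n = 10)
  nsub <- sub(".*novel_genes_submitted:\\s*", "",
              grep("novel_genes_submitted", header, value = TRUE)[1])
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  attr(out, "n_submitted") <- as.integer(nsub)
  out
}

#' Evidence source lists from the bundled evidence table
#'
#' Splits the comma-separated evidence strings into the six per-source gene
#' vectors expected by \code{\link{merge_evidence}}.
#'
#' @param tab output of \code{\link{example_evidence_table}}
#' @return named list of character vectors (NS, ML, MX, SMR, DEPICT, SMR3)
#' @export
evidence_source_lists <- function(tab = example_evidence_table()) {
  src <- strsplit(tab$evidence, ",")
  has <- function(lab) tab$gene[vapply(src, function(s) lab %in% s,
                                       logical(1))]
  list(NS = has("NS"), ML = has("ML"), MX = has("MX"), SMR = has("SMR"),
       DEPICT = has("DEPICT"), SMR3 = has("SMR3"))
}
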