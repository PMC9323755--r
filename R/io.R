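# Readers and writers for every flat-text format the pipeline touches, plus
# allele harmonization. Coordinates are 1-based inclusive throughout.

MA_COLS <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")
QTL_COLS <- c("probe_id", "probe_chr", "probe_bp", "gene_id", "SNP",
              "snp_chr", "snp_bp", "A1", "A2", "freq", "b", "se", "p", "N")

#' Read GWAS summary statistics (COJO .ma dialect)
#'
#' Whitespace-separated columns \code{SNP A1 A2 freq b se p N} with a header
#' row. Rows violating the record invariants (se <= 0, freq outside (0,1),
#' p outside (0,1], non-numeric effect fields) are rejected with a warning
#' naming the offending line numbers. z is recomputed as b/se; a missing p is
#' filled in from z.
#'
#' @param path file path
#' @return association data frame (snp, a1, a2, freq, b, se, z, p, n)
#' @export
read_gwas <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  missing <- setdiff(MA_COLS, names(d))
  if (length(missing))
    stop("GWAS file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  for (cc in c("freq", "b", "se", "p", "N"))
    d[[cc]] <- suppressWarnings(as.numeric(d[[cc]]))
  ok <- is.finite(d$b) & is.finite(d$se) & d$se > 0 &
    is.finite(d$freq) & d$freq > 0 & d$freq < 1 &
    (is.na(d$p) | (d$p > 0 & d$p <= 1)) & is.finite(d$N) & d$N > 0
  if (any(!ok))
    warning(sprintf("%s: rejected %d row(s) failing record invariants (lines %s)",
                    basename(path), sum(!ok),
                    paste(which(!ok) + 1L, collapse = ",")))
  d <- d[ok, , drop = FALSE]
  z <- d$b / d$se
  p <- ifelse(is.na(d$p), z_to_p(z), d$p)
  data.frame(snp = as.character(d$SNP), a1 = toupper(d$A1), a2 = toupper(d$A2),
             freq = d$freq, b = d$b, se = d$se, z = z, p = p, n = d$N,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write GWAS summary statistics in the .ma dialect
#' @param tab association data frame as returned by \code{\link{read_gwas}}
#'   or \code{\link{compute_summary_stats}}
#' @param path output path
#' @export
write_gwas <- function(tab, path) {
  out <- data.frame(SNP = tab$snp, A1 = tab$a1, A2 = tab$a2,
                    freq = tab$freq, b = tab$b, se = tab$se, p = tab$p,
                    N = tab$n)
  utils::write.table(format(out, digits = 17, scientific = FALSE, trim = TRUE),
                     path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a flat cis-QTL table
#'
#' Columns: \code{probe_id probe_chr probe_bp gene_id SNP snp_chr snp_bp
#' A1 A2 freq b se p N}. Validation mirrors \code{\link{read_gwas}}.
#'
#' @param path file path
#' @return long QTL data frame grouped by probe
#' @export
read_qtl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  missing <- setdiff(QTL_COLS, names(d))
  if (length(missing))
    stop("QTL file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  for (cc in c("freq", "b", "se", "p", "N"))
    d[[cc]] <- suppressWarnings(as.numeric(d[[cc]]))
  ok <- is.finite(d$b) & is.finite(d$se) & d$se > 0 &
    is.finite(d$freq) & d$freq > 0 & d$freq < 1
  if (any(!ok))
    warning(sprintf("%s: rejected %d row(s) failing record invariants (lines %s)",
                    basename(path), sum(!ok),
                    paste(which(!ok) + 1L, collapse = ",")))
  d <- d[ok, , drop = FALSE]
  data.frame(probe_id = as.character(d$probe_id), probe_chr = d$probe_chr,
             probe_bp = d$probe_bp, gene_id = as.character(d$gene_id),
             snp = as.character(d$SNP), snp_chr = d$snp_chr,
             snp_bp = d$snp_bp, a1 = toupper(d$A1), a2 = toupper(d$A2),
             freq = d$freq, b = d$b, se = d$se, z = d$b / d$se,
             p = ifelse(is.na(d$p), z_to_p(d$b / d$se), d$p), n = d$N,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a flat cis-QTL table
#' @param tab long QTL data frame
#' @param path output path
#' @export
write_qtl <- function(tab, path) {
  out <- data.frame(probe_id = tab$probe_id, probe_chr = tab$probe_chr,
                    probe_bp = tab$probe_bp, gene_id = tab$gene_id,
                    SNP = tab$snp, snp_chr = tab$snp_chr, snp_bp = tab$snp_bp,
                    A1 = tab$a1, A2 = tab$a2, freq = tab$freq, b = tab$b,
                    se = tab$se, p = tab$p, N = tab$n)
  utils::write.table(format(out, digits = 17, scientific = FALSE, trim = TRUE),
                     path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a genotype panel and its SNP map
#'
#' Panel: one row per individual, one whitespace-separated column per SNP,
#' values in \{0,1,2\}. Map: columns \code{SNP chr bp A1 A2}.
#'
#' @param path panel file
#' @param map_path SNP map file
#' @return list(genotypes, map)
#' @export
read_panel <- function(path, map_path) {
  g <- as.matrix(utils::read.table(path, header = FALSE))
  bad <- which(!(g == 0 | g == 1 | g == 2), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("panel %s: non-{0,1,2} entry at row %d, column %d",
                 basename(path), bad[1, 1], bad[1, 2]))
  storage.mode(g) <- "integer"
  m <- utils::read.table(map_path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("SNP", "chr", "bp", "A1", "A2")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("SNP map lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(m) != ncol(g))
    stop("SNP map rows do not match panel columns")
  map <- data.frame(snp = m$SNP, chr = m$chr, bp = m$bp,
                    a1 = toupper(m$A1), a2 = toupper(m$A2),
                    stringsAsFactors = FALSE)
  if ("maf" %in% names(m)) map$maf <- m$maf
  if ("block" %in% names(m)) map$block <- m$block
  colnames(g) <- map$snp
  list(genotypes = g, map = map)
}

#' Write a genotype panel and its SNP map
#' @param genotypes dosage matrix
#' @param map SNP map data frame
#' @param path,map_path output paths
#' @export
write_panel <- function(genotypes, map, path, map_path) {
  utils::write.table(genotypes, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  out <- data.frame(SNP = map$snp, chr = map$chr, bp = map$bp,
                    A1 = map$a1, A2 = map$a2)
  if (!is.null(map$maf)) out$maf <- map$maf
  if (!is.null(map$block)) out$block <- map$block
  utils::write.table(out, map_path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  invisible(path)
}

#' Read a plain gene list (one symbol per line)
#'
#' Used for coregulation (DEPICT-style) gene lists, known-gene lists and
#' gene sets. An empty file yields an empty character vector.
#'
#' @param path file path
#' @param header if TRUE the first line is a set name, returned as the
#'   \code{"name"} attribute
#' @return character vector of gene symbols
#' @export
read_gene_list <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  nm <- NULL
  if (header && length(x)) {
    nm <- x[1]
    x <- x[-1]
  }
  x <- x[nzchar(x)]
  if (!is.null(nm)) attr(x, "name") <- nm
  x
}

#' Write a tab-separated results table with a header
#' @param table data frame
#' @param path output path
#' @export
write_results <- function(table, path) {
  utils::write.table(table, path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  invisible(path)
}

ALLELE_COMP <- c(A = "T", T = "A", C = "G", G = "C")

is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize effect alleles between two summary-statistic sources
#'
#' Records are matched by SNP id. When the allele pair is swapped in source b
#' relative to source a, b's effect sign is flipped and its frequency
#' replaced by 1 - freq; strand flips (complementary alleles) are resolved
#' the same way. Strand-ambiguous variants (A/T or C/G) are dropped whenever
#' either source has |freq - 0.5| < \code{ambiguous_window}, because the
#' strand cannot be inferred from frequency there. Allele sets that cannot be
#' reconciled are dropped. Drops are logged via warnings, never errors, and
#' the operation is involutive: harmonizing already-harmonized records
#' changes nothing.
#'
#' @param record_a,record_b association data frames with columns
#'   snp, a1, a2, freq, b (z/p optional)
#' @param ambiguous_window frequency window around 0.5 inside which
#'   ambiguous-allele variants are dropped
#' @return list(a, b, dropped) where a and b are aligned to a's allele coding
#' @export
harmonize_alleles <- function(record_a, record_b, ambiguous_window = 0.15) {
  common <- intersect(record_a$snp, record_b$snp)
  a <- record_a[match(common, record_a$snp), , drop = FALSE]
  b <- record_b[match(common, record_b$snp), , drop = FALSE]
  direct <- a$a1 == b$a1 & a$a2 == b$a2
  swap <- a$a1 == b$a2 & a$a2 == b$a1
  flip1 <- unname(ALLELE_COMP[b$a1]); flip2 <- unname(ALLELE_COMP[b$a2])
  strand <- !direct & !swap & a$a1 == flip1 & a$a2 == flip2
  strand_swap <- !direct & !swap & a$a1 == flip2 & a$a2 == flip1
  ambiguous <- is_ambiguous_pair(a$a1, a$a2) &
    (abs(a$freq - 0.5) < ambiguous_window |
       abs(b$freq - 0.5) < ambiguous_window)
  reconcilable <- direct | swap | strand | strand_swap
  keep <- reconcilable & !ambiguous
  dropped <- common[!keep]
  if (length(dropped))
    warning(sprintf("harmonization dropped %d SNP(s): %s", length(dropped),
                    paste(utils::head(dropped, 10), collapse = ", ")))
  a <- a[keep, , drop = FALSE]
  b <- b[keep, , drop = FALSE]
  doflip <- (swap | strand_swap)[keep]
  if (any(doflip)) {
    b$b[doflip] <- -b$b[doflip]
    b$freq[doflip] <- 1 - b$freq[doflip]
    if (!is.null(b$z)) b$z[doflip] <- -b$z[doflip]
  }
  b$a1 <- a$a1
  b$a2 <- a$a2
  list(a = a, b = b, dropped = dropped)
}
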