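# Synthetic cohort generator with planted causal architectures.
#
# Four independent cohorts (LD reference, GWAS, eQTL, mQTL) are drawn from a
# common block-LD population: within each block, latent Gaussians follow an
# AR(1) process with parameter rho; each of two haplotypes per individual is
# dichotomized at the MAF quantile and the two indicators are summed to a
# 0/1/2 dosage. Per-locus causal architectures plant SNP -> methylation ->
# expression -> trait chains (or confounded variants thereof) whose path
# coefficients are exactly recoverable on the SD scale, because every noise
# variance defaults to the complement of the genetic variance so all
# phenotypes have unit population variance.

SCENARIOS <- c("chain", "direct", "pleiotropy", "linkage", "null")

#' Simulation configuration
#'
#' @param n_gwas,n_eqtl,n_mqtl,n_ref cohort sizes (individuals, each >= 30)
#' @param n_blocks number of LD blocks (= loci; one gene and one DNA
#'   methylation site per block)
#' @param snps_per_block SNPs per block
#' @param rho AR(1) correlation of the latent Gaussians within a block,
#'   in [0, 1)
#' @param maf_range closed interval within (0, 0.5] from which per-SNP minor
#'   allele frequencies are drawn (shared across cohorts)
#' @param beta_xm,beta_me,beta_ey chain path coefficients: SNP -> methylation
#'   (per allele, SD units), methylation -> expression (SD per SD),
#'   expression -> trait (SD per SD)
#' @param beta_xe,beta_xy direct effects used by the direct / pleiotropy /
#'   linkage scenarios: SNP -> expression and SNP -> trait (per allele)
#' @param linkage_r target dosage correlation between the two distinct causal
#'   SNPs of the linkage scenario
#' @param var_m,var_e,var_y noise variances for methylation, expression and
#'   trait; \code{NULL} (default) uses the complement of the genetic variance
#'   so each phenotype has unit population variance
#' @param scenarios character vector of per-locus scenario labels from
#'   \{chain, direct, pleiotropy, linkage, null\}, recycled to
#'   \code{n_blocks}
#' @param spacing_bp fixed inter-SNP spacing on the single synthetic
#'   chromosome (1-based positions)
#' @param block_gap_bp extra gap between consecutive blocks
#' @param seed integer RNG seed; fully determines all outputs
#' @return an object of class \code{sim_config}
#' @export
sim_config <- function(n_gwas = 20000, n_eqtl = 5000, n_mqtl = 5000,
                       n_ref = 1000,
                       n_blocks = 10, snps_per_block = 10, rho = 0.8,
                       maf_range = c(0.1, 0.5),
                       beta_xm = 0.5, beta_me = 0.5, beta_ey = 0.3,
                       beta_xe = 0.3, beta_xy = 0.1,
                       linkage_r = 0.7,
                       var_m = NULL, var_e = NULL, var_y = NULL,
                       scenarios = "chain",
                       spacing_bp = 1000, block_gap_bp = 10000,
                       seed = 1) {
  ns <- c(n_gwas = n_gwas, n_eqtl = n_eqtl, n_mqtl = n_mqtl, n_ref = n_ref)
  if (any(ns < 30)) stop_config("all cohort sizes must be >= 30")
  if (!is.numeric(rho) || rho < 0 || rho >= 1)
    stop_config("rho must lie in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_config("maf_range must be a closed interval within (0, 0.5]")
  if (n_blocks < 1 || snps_per_block < 1)
    stop_config("panel dimensions must be positive")
  scenarios <- rep_len(scenarios, n_blocks)
  bad <- setdiff(unique(scenarios), SCENARIOS)
  if (length(bad))
    stop_config("unknown scenario label(s): %s", paste(bad, collapse = ", "))
  cfg <- list(
    n_gwas = as.integer(n_gwas), n_eqtl = as.integer(n_eqtl),
    n_mqtl = as.integer(n_mqtl), n_ref = as.integer(n_ref),
    n_blocks = as.integer(n_blocks),
    snps_per_block = as.integer(snps_per_block),
    rho = rho, maf_range = maf_range,
    beta_xm = beta_xm, beta_me = beta_me, beta_ey = beta_ey,
    beta_xe = beta_xe, beta_xy = beta_xy, linkage_r = linkage_r,
    var_m = var_m, var_e = var_e, var_y = var_y,
    scenarios = scenarios,
    spacing_bp = spacing_bp, block_gap_bp = block_gap_bp,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  # per-locus trait variance check (warn only)
  vc <- vapply(seq_len(n_blocks), function(l)
    locus_trait_variance(cfg, scenarios[l]), numeric(1))
  if (any(vc >= 0.10))
    warning("some loci contribute >= 10% of trait variance; ",
            "ratio estimates remain valid but the trait is oligogenic")
  cfg
}

# population variance contributed to the (pre-standardization) trait by one
# locus, using the midpoint MAF for the warning heuristic
locus_trait_variance <- function(cfg, scenario) {
  vg <- 2 * mean(cfg$maf_range) * (1 - mean(cfg$maf_range))
  switch(scenario,
    chain = cfg$beta_ey^2,       # var(e) = 1 by construction
    direct = cfg$beta_ey^2,
    pleiotropy = cfg$beta_xy^2 * vg,
    linkage = cfg$beta_xy^2 * vg,
    null = 0
  )
}

# latent AR(1) Gaussian haplotype block, dichotomized at the MAF quantile
ar1_block <- function(n, p, rho) {
  x <- matrix(rnorm(n * p), n, p)
  if (rho > 0 && p > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:p) x[, j] <- rho * x[, j - 1] + s * x[, j]
  }
  x
}

dichotomize_block <- function(n, p, rho, thr) {
  h1 <- ar1_block(n, p, rho)
  h2 <- ar1_block(n, p, rho)
  tm <- matrix(thr, n, p, byrow = TRUE)
  g <- (h1 < tm) + (h2 < tm)
  storage.mode(g) <- "integer"
  g
}

#' Simulate the genotype panel for all four cohorts
#'
#' @param config a \code{\link{sim_config}} object
#' @return list with integer dosage matrices \code{ref}, \code{gwas},
#'   \code{eqtl}, \code{mqtl} (individuals x SNPs) and a \code{map}
#'   data frame (snp, chr, bp, a1, a2, maf, block)
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  P <- config$n_blocks * config$snps_per_block
  maf <- with_seed(substream_seed(config$seed, "maf"),
                   runif(P, config$maf_range[1], config$maf_range[2]))
  thr <- qnorm(maf)
  block <- rep(seq_len(config$n_blocks), each = config$snps_per_block)
  bp <- (seq_len(P) - 1L) * config$spacing_bp + 1L +
    (block - 1L) * config$block_gap_bp
  map <- data.frame(
    snp = sprintf("rs%05d", seq_len(P)), chr = 1L, bp = as.integer(bp),
    a1 = "A", a2 = "G", maf = maf, block = block,
    stringsAsFactors = FALSE
  )
  sizes <- c(ref = config$n_ref, gwas = config$n_gwas,
             eqtl = config$n_eqtl, mqtl = config$n_mqtl)
  out <- lapply(names(sizes), function(co) {
    with_seed(substream_seed(config$seed, paste0("geno:", co)), {
      n <- sizes[[co]]
      g <- matrix(0L, n, P)
      for (b in seq_len(config$n_blocks)) {
        idx <- which(block == b)
        g[, idx] <- dichotomize_block(n, length(idx), config$rho, thr[idx])
      }
      colnames(g) <- map$snp
      g
    })
  })
  names(out) <- names(sizes)
  out$map <- map
  out
}

# indices of the causal SNP(s) within a block; the linkage scenario picks the
# pair whose latent AR(1) correlation rho^|i-j| is closest to linkage_r
causal_indices <- function(config, block_cols) {
  p <- length(block_cols)
  mid <- block_cols[ceiling(p / 2)]
  if (p == 1) return(c(mid, mid))
  d <- if (config$rho > 0) {
    dd <- round(log(max(config$linkage_r, 1e-8)) / log(config$rho))
    max(1, min(p - 1, dd))
  } else 1
  i <- max(1, ceiling(p / 2) - ceiling(d / 2))
  j <- min(p, i + d)
  c(block_cols[i], block_cols[j])
}

#' Simulate methylation, expression and trait phenotypes for one cohort
#'
#' Applies the per-locus causal architecture to a cohort's genotypes. Under
#' \code{chain}: m = beta_xm g + e_m, e = beta_me m + e_e, and the locus
#' contributes beta_ey * e to the trait. \code{direct} drives expression from
#' the SNP with no methylation leg; \code{pleiotropy} gives the SNP separate
#' paths to expression and trait; \code{linkage} drives expression from one
#' SNP and the trait from a second, correlated SNP; \code{null} keeps the
#' molecular QTL effects but leaves the trait without any genetic component
#' (the natural null for the ratio test: a valid instrument, zero effect).
#' All phenotype columns are standardized to zero mean and unit variance.
#'
#' @param genotypes dosage matrix for one cohort (individuals x SNPs)
#' @param config a \code{\link{sim_config}}
#' @param map SNP map from \code{\link{simulate_panel}}
#' @param cohort label used to derive the noise RNG stream
#' @return list with matrices \code{m}, \code{e} (individuals x loci),
#'   vector \code{y}, and the \code{truth} data frame
#' @export
simulate_phenotypes <- function(genotypes, config, map, cohort = "gwas") {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(genotypes)
  L <- config$n_blocks
  with_seed(substream_seed(config$seed, paste0("pheno:", cohort)), {
    m <- matrix(0, n, L)
    e <- matrix(0, n, L)
    ycontrib <- matrix(0, n, L)
    truth <- vector("list", L)
    var_c <- numeric(L)
    for (l in seq_len(L)) {
      sc <- config$scenarios[l]
      cols <- which(map$block == l)
      ci <- causal_indices(config, cols)
      g1 <- genotypes[, ci[1]]
      g2 <- genotypes[, ci[2]]
      vg1 <- 2 * map$maf[ci[1]] * (1 - map$maf[ci[1]])
      vg2 <- 2 * map$maf[ci[2]] * (1 - map$maf[ci[2]])
      noise <- function(target_var, user) {
        v <- user %||% target_var
        if (v <= 0)
          stop_config("nonpositive noise variance at locus %d: reduce effect sizes", l)
        rnorm(n, 0, sqrt(v))
      }
      b <- list(xm = 0, me = 0, ey = 0, xe = 0, xy = 0)
      if (sc == "chain") {
        b$xm <- config$beta_xm; b$me <- config$beta_me; b$ey <- config$beta_ey
        m[, l] <- b$xm * g1 + noise(1 - b$xm^2 * vg1, config$var_m)
        e[, l] <- b$me * m[, l] + noise(1 - b$me^2, config$var_e)
        ycontrib[, l] <- b$ey * e[, l]
        var_c[l] <- b$ey^2
      } else if (sc == "direct") {
        b$xe <- config$beta_xe; b$ey <- config$beta_ey
        m[, l] <- noise(1, config$var_m)
        e[, l] <- b$xe * g1 + noise(1 - b$xe^2 * vg1, config$var_e)
        ycontrib[, l] <- b$ey * e[, l]
        var_c[l] <- b$ey^2
      } else if (sc == "pleiotropy") {
        b$xe <- config$beta_xe; b$xy <- config$beta_xy
        m[, l] <- noise(1, config$var_m)
        e[, l] <- b$xe * g1 + noise(1 - b$xe^2 * vg1, config$var_e)
        ycontrib[, l] <- b$xy * (g1 - mean(g1))
        var_c[l] <- b$xy^2 * vg1
      } else if (sc == "linkage") {
        b$xe <- config$beta_xe; b$xy <- config$beta_xy
        m[, l] <- noise(1, config$var_m)
        e[, l] <- b$xe * g1 + noise(1 - b$xe^2 * vg1, config$var_e)
        ycontrib[, l] <- b$xy * (g2 - mean(g2))
        var_c[l] <- b$xy^2 * vg2
      } else { # null: molecular QTLs present, trait unaffected
        b$xm <- config$beta_xm; b$xe <- config$beta_xe
        m[, l] <- b$xm * g1 + noise(1 - b$xm^2 * vg1, config$var_m)
        e[, l] <- b$xe * g1 + noise(1 - b$xe^2 * vg1, config$var_e)
        var_c[l] <- 0
      }
      truth[[l]] <- data.frame(
        locus = l, scenario = sc,
        causal_snp = map$snp[ci[1]],
        causal_snp2 = if (sc == "linkage") map$snp[ci[2]] else NA_character_,
        site = sprintf("cg%04d", l), gene = sprintf("G%04d", l),
        beta_xm = b$xm, beta_me = b$me, beta_ey = b$ey,
        beta_xe = b$xe, beta_xy = b$xy,
        chain = (sc == "chain" && b$xm != 0 && b$me != 0 && b$ey != 0),
        stringsAsFactors = FALSE
      )
    }
    if (is.null(config$var_y) && sum(var_c) > 0.95)
      warning(sprintf(
        "planted loci contribute %.2f of the unit trait-variance budget; ",
        sum(var_c)),
        "noise variance floored at 0.05, so standardized effects shrink")
    vy <- config$var_y %||% max(1 - sum(var_c), 0.05)
    y <- rowSums(ycontrib) + rnorm(n, 0, sqrt(vy))
    std <- function(x) {
      s <- sd(x)
      if (s == 0) x - mean(x) else (x - mean(x)) / s
    }
    m <- apply(m, 2, std); e <- apply(e, 2, std); y <- std(y)
    colnames(m) <- sprintf("cg%04d", seq_len(L))
    colnames(e) <- sprintf("G%04d", seq_len(L))
    list(m = m, e = e, y = y, truth = do.call(rbind, truth))
  })
}

#' Per-SNP marginal linear-regression summary statistics
#'
#' Simple-regression slope, standard error, z, and two-sided p (t reference
#' with n - 2 df) for one phenotype against every SNP column. Zero-variance
#' SNPs are dropped with a warning.
#'
#' @param genotypes dosage matrix (individuals x SNPs, named columns)
#' @param phenotype numeric vector, one value per individual
#' @param map SNP map; rows matched to genotype columns
#' @return data frame with columns snp, chr, bp, a1, a2, freq, b, se, z, p, n
#' @export
compute_summary_stats <- function(genotypes, phenotype, map) {
  stopifnot(nrow(genotypes) == length(phenotype),
            ncol(genotypes) == nrow(map))
  n <- length(phenotype)
  gc_ <- scale(genotypes, center = TRUE, scale = FALSE)
  sxx <- colSums(gc_^2)
  keep <- sxx > 0
  if (any(!keep))
    warning(sprintf("dropped %d zero-variance SNP(s): %s", sum(!keep),
                    paste(map$snp[!keep], collapse = ", ")))
  yc <- phenotype - mean(phenotype)
  syy <- sum(yc^2)
  sxy <- as.numeric(crossprod(gc_[, keep, drop = FALSE], yc))
  sxx <- sxx[keep]
  b <- sxy / sxx
  rss <- pmax(syy - b * sxy, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  z <- ifelse(se > 0, b / se, sign(b) * Inf)
  p <- pmax(2 * pt(-abs(z), df = n - 2), .Machine$double.xmin)
  data.frame(
    snp = map$snp[keep], chr = map$chr[keep], bp = map$bp[keep],
    a1 = map$a1[keep], a2 = map$a2[keep],
    freq = colMeans(genotypes[, keep, drop = FALSE]) / 2,
    b = b, se = se, z = z, p = p, n = n,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# long cis-QTL table: per probe, association records for every SNP within
# cis_window of the probe position
qtl_summary <- function(genotypes, pheno_matrix, map, probes,
                        cis_window = 2e6) {
  n <- nrow(genotypes)
  gc_ <- scale(genotypes, center = TRUE, scale = FALSE)
  sxx <- colSums(gc_^2)
  keep <- which(sxx > 0)
  yc <- scale(pheno_matrix, center = TRUE, scale = FALSE)
  syy <- colSums(yc^2)
  bmat <- crossprod(gc_[, keep, drop = FALSE], yc)  # P x L of Sxy
  freq <- colMeans(genotypes[, keep, drop = FALSE]) / 2
  out <- vector("list", nrow(probes))
  for (k in seq_len(nrow(probes))) {
    pos <- probes$probe_bp[k]
    cis <- which(abs(map$bp[keep] - pos) <= cis_window)
    if (!length(cis)) next
    ki <- keep[cis]
    sxy <- bmat[cis, k]
    b <- sxy / sxx[ki]
    rss <- pmax(syy[k] - b * sxy, 0)
    se <- sqrt(rss / ((n - 2) * sxx[ki]))
    z <- ifelse(se > 0, b / se, sign(b) * Inf)
    p <- pmax(2 * pt(-abs(z), df = n - 2), .Machine$double.xmin)
    out[[k]] <- data.frame(
      probe_id = probes$probe_id[k], probe_chr = probes$probe_chr[k],
      probe_bp = pos, gene_id = probes$gene_id[k],
      snp = map$snp[ki], snp_chr = map$chr[ki], snp_bp = map$bp[ki],
      a1 = map$a1[ki], a2 = map$a2[ki], freq = freq[cis],
      b = b, se = se, z = z, p = p, n = n,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Gene and methylation-site annotation for a simulated dataset
#'
#' One gene and one DNAm site per block; the gene spans 1 kb around the
#' block centre, the site sits inside the gene body.
#'
#' @param config a \code{\link{sim_config}}
#' @param map SNP map
#' @return data frame (id, chr, start, end, strand, class, locus)
#' @export
probe_annotation <- function(config, map) {
  L <- config$n_blocks
  centre <- vapply(seq_len(L), function(b) {
    bpb <- map$bp[map$block == b]
    as.integer(round(mean(range(bpb))))
  }, integer(1))
  rbind(
    data.frame(id = sprintf("G%04d", seq_len(L)), chr = 1L,
               start = pmax(centre - 500L, 1L), end = centre + 500L,
               strand = "+", class = "gene", locus = seq_len(L),
               stringsAsFactors = FALSE),
    data.frame(id = sprintf("cg%04d", seq_len(L)), chr = 1L,
               start = centre + 200L, end = centre + 200L,
               strand = "+", class = "dnam_site", locus = seq_len(L),
               stringsAsFactors = FALSE)
  )
}

#' Simulate a complete dataset in memory
#'
#' Runs the panel, phenotype and summary-statistic generators and returns
#' every table the downstream stages consume.
#'
#' @param config a \code{\link{sim_config}}
#' @param cis_window cis window used when building the QTL tables
#' @return list: \code{gwas} (association table), \code{eqtl}, \code{mqtl}
#'   (long cis-QTL tables), \code{panel} (\code{\link{ld_panel}} on the
#'   reference cohort), \code{genotypes}, \code{phenotypes} (per cohort),
#'   \code{annotation}, \code{map}, \code{truth}, \code{config}
#' @export
simulate_dataset <- function(config, cis_window = 2e6) {
  geno <- simulate_panel(config)
  map <- geno$map
  ph_gwas <- simulate_phenotypes(geno$gwas, config, map, "gwas")
  ph_eqtl <- simulate_phenotypes(geno$eqtl, config, map, "eqtl")
  ph_mqtl <- simulate_phenotypes(geno$mqtl, config, map, "mqtl")
  ann <- probe_annotation(config, map)
  genes <- ann[ann$class == "gene", ]
  sites <- ann[ann$class == "dnam_site", ]
  gene_probes <- data.frame(probe_id = genes$id, probe_chr = genes$chr,
                            probe_bp = as.integer((genes$start + genes$end) / 2),
                            gene_id = genes$id, stringsAsFactors = FALSE)
  site_probes <- data.frame(probe_id = sites$id, probe_chr = sites$chr,
                            probe_bp = sites$start,
                            gene_id = sprintf("G%04d", sites$locus),
                            stringsAsFactors = FALSE)
  list(
    gwas = compute_summary_stats(geno$gwas, ph_gwas$y, map),
    eqtl = qtl_summary(geno$eqtl, ph_eqtl$e, map, gene_probes, cis_window),
    mqtl = qtl_summary(geno$mqtl, ph_mqtl$m, map, site_probes, cis_window),
    panel = ld_panel(geno$ref, map),
    genotypes = geno[c("ref", "gwas", "eqtl", "mqtl")],
    phenotypes = list(gwas = ph_gwas, eqtl = ph_eqtl, mqtl = ph_mqtl),
    annotation = ann, map = map, truth = ph_gwas$truth, config = config
  )
}

#' Write a simulated dataset to disk
#'
#' Emits the GWAS .ma file, flat eQTL/mQTL tables, the reference genotype
#' panel with its SNP map, the annotation, and the planted-truth table.
#' Re-running with the same config reproduces identical files.
#'
#' @param outdir writable output directory (created if missing)
#' @param config a \code{\link{sim_config}}
#' @param cis_window cis window for the QTL tables
#' @return (invisibly) list with the dataset and the written file paths
#' @export
emit_dataset <- function(outdir, config, cis_window = 2e6) {
  ds <- simulate_dataset(config, cis_window)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  paths <- list(
    gwas = file.path(outdir, "gwas_trait.ma"),
    eqtl = file.path(outdir, "eqtl.tsv"),
    mqtl = file.path(outdir, "mqtl.tsv"),
    panel = file.path(outdir, "panel_ref.txt"),
    map = file.path(outdir, "panel_ref.map"),
    annotation = file.path(outdir, "annotation.tsv"),
    truth = file.path(outdir, "truth.tsv")
  )
  write_gwas(ds$gwas, paths$gwas)
  write_qtl(ds$eqtl, paths$eqtl)
  write_qtl(ds$mqtl, paths$mqtl)
  write_panel(ds$genotypes$ref, ds$map, paths$panel, paths$map)
  write_results(ds$annotation, paths$annotation)
  write_results(ds$truth, paths$truth)
  invisible(list(dataset = ds, paths = paths))
}
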