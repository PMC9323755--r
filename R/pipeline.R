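# End-to-end orchestration: synth -> SMR / TWAS -> mediation -> prioritize
# -> enrich, with deterministic provenance.

#' Assemble a full run configuration
#'
#' @param sim a \code{\link{sim_config}} for the synthetic dataset
#' @param alpha family-wise error target per scan
#' @param cis_window instrument cis window (bp)
#' @param p_instrument instrument p threshold
#' @param heidi_threshold HEIDI pass threshold
#' @param r2_proxy proxy-expansion r^2 threshold
#' @param r2_min,perf_p TWAS prediction performance filter
#' @param pp4_min colocalization pass threshold
#' @param coloc a \code{\link{coloc_config}}
#' @param train_cis_window cis window for weight training
#' @param known_genes,depict_genes,drug_table optional file paths (plain gene
#'   lists; drug interaction table) merged into the evidence stage
#' @param stages character vector of stages to run, in fixed order
#' @return an object of class \code{run_config}
#' @export
run_config <- function(sim = sim_config(), alpha = 0.05, cis_window = 2e6,
                       p_instrument = 5e-8, heidi_threshold = 0.01,
                       r2_proxy = 0.5, r2_min = 0.01, perf_p = 0.05,
                       pp4_min = 0.5, coloc = coloc_config(),
                       train_cis_window = 1e6,
                       known_genes = NULL, depict_genes = NULL,
                       drug_table = NULL,
                       stages = c("simulate", "smr", "twas", "mediate",
                                  "prioritize", "enrich")) {
  cfg <- list(sim = sim, alpha = alpha, cis_window = cis_window,
              p_instrument = p_instrument,
              heidi_threshold = heidi_threshold, r2_proxy = r2_proxy,
              r2_min = r2_min, perf_p = perf_p, pp4_min = pp4_min,
              coloc = coloc, train_cis_window = train_cis_window,
              known_genes = known_genes, depict_genes = depict_genes,
              drug_table = drug_table, stages = stages)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror \code{\link{run_config}} arguments; the \code{sim}
#' block mirrors \code{\link{sim_config}} arguments.
#'
#' @param path YAML file
#' @return a \code{run_config}
#' @export
run_config_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim$scenarios)) {
    # YAML parses a bare `null` token as NULL; it means the null scenario
    y$sim$scenarios <- vapply(as.list(y$sim$scenarios), function(s)
      if (is.null(s)) "null" else as.character(s), character(1))
  }
  sim <- do.call(sim_config, y$sim %||% list())
  rest <- y[setdiff(names(y), "sim")]
  do.call(run_config, c(list(sim = sim), rest))
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[order(names(unclass(config)))]), tf)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline
#'
#' Executes the configured stages in order, writing each stage's tables to
#' \code{outdir} together with a manifest (stage, output, row count) and a
#' provenance block (config hash, seed, package version). A stage failure
#' writes a FAILED marker and aborts downstream stages while preserving
#' completed outputs. Identical configurations produce identical manifests.
#'
#' @param config a \code{\link{run_config}}
#' @param outdir output directory (created if needed)
#' @return (invisibly) list of in-memory stage results
#' @export
run_all <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  results <- list()
  note <- function(stage, file, n)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, output = file, rows = n, stringsAsFactors = FALSE)
  run_stage <- function(stage, fun) {
    if (!stage %in% config$stages) return(TRUE)
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      writeLines(c(stage, conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      warning(sprintf("stage '%s' failed: %s; downstream stages skipped",
                      stage, conditionMessage(e)))
      FALSE
    })
    ok
  }

  ok <- run_stage("simulate", function() {
    em <- emit_dataset(outdir, config$sim, config$cis_window)
    results$dataset <<- em$dataset
    note("simulate", "gwas_trait.ma", nrow(em$dataset$gwas))
    note("simulate", "eqtl.tsv", nrow(em$dataset$eqtl))
    note("simulate", "mqtl.tsv", nrow(em$dataset$mqtl))
    note("simulate", "truth.tsv", nrow(em$dataset$truth))
  })

  ok <- ok && run_stage("smr", function() {
    ds <- results$dataset
    results$esmr <<- smr_scan(ds$gwas, ds$eqtl, ds$panel, config$alpha,
                              config$cis_window, config$p_instrument,
                              heidi_threshold = config$heidi_threshold)
    write_results(results$esmr, file.path(outdir, "smr_eqtl.tsv"))
    note("smr", "smr_eqtl.tsv", nrow(results$esmr))
  })

  ok <- ok && run_stage("twas", function() {
    ds <- results$dataset
    models <- train_weights(ds$genotypes$eqtl, ds$phenotypes$eqtl$e,
                            ds$map, ds$annotation,
                            cis_window = config$train_cis_window,
                            seed = config$sim$seed)
    results$models <<- models
    results$twas <<- twas_scan(ds$gwas, models, ds$panel, config$alpha,
                               eqtl = ds$eqtl, r2_min = config$r2_min,
                               perf_p = config$perf_p,
                               pp4_min = config$pp4_min,
                               coloc = config$coloc)
    write_results(results$twas, file.path(outdir, "twas.tsv"))
    note("twas", "twas.tsv", nrow(results$twas))
  })

  ok <- ok && run_stage("mediate", function() {
    ds <- results$dataset
    scans <- run_3smr(ds$gwas, ds$eqtl, ds$mqtl, ds$panel, config$alpha,
                      config$cis_window,
                      p_instrument = config$p_instrument,
                      heidi_threshold = config$heidi_threshold)
    results$scans <<- scans
    results$chains <<- intersect_chains(scans$esmr, scans$msmr, scans$m2e)
    write_results(scans$msmr, file.path(outdir, "smr_mqtl.tsv"))
    write_results(scans$m2e, file.path(outdir, "smr_m2e.tsv"))
    write_results(results$chains, file.path(outdir, "chains.tsv"))
    note("mediate", "chains.tsv", nrow(results$chains))
  })

  ok <- ok && run_stage("prioritize", function() {
    ds <- results$dataset
    depict <- if (!is.null(config$depict_genes))
      read_gene_list(config$depict_genes) else character()
    known <- if (!is.null(config$known_genes))
      read_gene_list(config$known_genes) else character()
    mx <- if (!is.null(results$twas)) results$twas$gene[results$twas$pass]
      else character()
    smrg <- if (!is.null(results$esmr))
      results$esmr$gene_id[results$esmr$pass] else character()
    chains <- if (!is.null(results$chains)) unique(results$chains$gene)
      else character()
    results$evidence <<- merge_evidence(
      mx_genes = mx, smr_genes = smrg, depict_genes = depict,
      chain_genes = chains, known_genes = known)
    write_results(results$evidence, file.path(outdir, "evidence.tsv"))
    note("prioritize", "evidence.tsv", nrow(results$evidence))
  })

  ok <- ok && run_stage("enrich", function() {
    if (is.null(config$drug_table) || !nrow(results$evidence)) return()
    dt <- utils::read.table(config$drug_table, header = TRUE,
                            stringsAsFactors = FALSE)
    ann <- drug_annotations(results$evidence$gene, dt)
    universe <- results$dataset$truth$gene
    bp_targets <- unique(dt$gene[dt$interaction_type == "drug" &
                                   dt$indication %in%
                                   c("hypertension", "hypotension")])
    results$enrichment <<- fisher_enrichment(results$evidence$gene,
                                             intersect(bp_targets, universe),
                                             universe)
    write_results(ann, file.path(outdir, "drug_annotations.tsv"))
    write_results(results$enrichment, file.path(outdir, "enrichment.tsv"))
    note("enrich", "enrichment.tsv", 1L)
  })

  # truth-aware evaluation: per-mechanism recall / precision
  if (ok && !is.null(results$dataset)) {
    results$truth_eval <- truth_evaluation(results)
    if (!is.null(results$truth_eval)) {
      write_results(results$truth_eval, file.path(outdir, "truth_eval.tsv"))
      note("evaluate", "truth_eval.tsv", nrow(results$truth_eval))
    }
  }

  man <- do.call(rbind, manifest)
  write_results(man, file.path(outdir, "manifest.tsv"))
  writeLines(c(
    paste0("config_hash: ", config_hash(config)),
    paste0("seed: ", config$sim$seed),
    paste0("omicsmr_version: ",
           as.character(utils::packageVersion("omicsmr")))
  ), file.path(outdir, "provenance.txt"))
  invisible(results)
}

# recall/precision of the SMR and chain calls against the planted truth
truth_evaluation <- function(results) {
  truth <- results$dataset$truth
  out <- list()
  if (!is.null(results$esmr) && nrow(results$esmr)) {
    causal <- truth$gene[truth$scenario %in% c("chain", "direct",
                                               "pleiotropy")]
    called <- results$esmr$gene_id[results$esmr$pass]
    out$smr <- data.frame(
      analysis = "smr_eqtl",
      recall = if (length(causal)) mean(causal %in% called) else NA_real_,
      precision = if (length(called)) mean(called %in% causal) else NA_real_,
      n_called = length(called), stringsAsFactors = FALSE)
  }
  if (!is.null(results$chains)) {
    planted <- truth$gene[truth$chain]
    called <- unique(results$chains$gene)
    out$chain <- data.frame(
      analysis = "mediation_chain",
      recall = if (length(planted)) mean(planted %in% called) else NA_real_,
      precision = if (length(called)) mean(called %in% planted) else
        NA_real_,
      n_called = length(called), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
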