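# Shared fixtures built in code.

# small mixed-scenario dataset reused by several test files
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_gwas = 4000, n_eqtl = 2000, n_mqtl = 2000, n_ref = 800,
        n_blocks = 8, snps_per_block = 10, rho = 0.8,
        scenarios = c("chain", "direct", "pleiotropy", "linkage", "null",
                      "chain", "direct", "null"),
        seed = 42)
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})

# hand-built LD panel: 6 SNPs with known structure
toy_panel <- function(n = 400, seed = 9) {
  set.seed(seed)
  g1 <- rbinom(n, 2, 0.3)
  g2 <- g1                        # duplicate of g1
  g3 <- 2L - g1                   # complement: r = -1
  g4 <- rbinom(n, 2, 0.4)         # independent
  g5 <- ifelse(runif(n) < 0.8, g1, rbinom(n, 2, 0.3))  # partial LD with g1
  g6 <- rbinom(n, 2, 0.25)        # independent
  G <- cbind(g1, g2, g3, g4, g5, g6)
  map <- data.frame(snp = paste0("s", 1:6), chr = 1L,
                    bp = c(100L, 200L, 300L, 400L, 500L, 600L),
                    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  ld_panel(G, map)
}

# minimal association record constructor
assoc_rec <- function(snp, b, se, a1 = "A", a2 = "G", freq = 0.3,
                      n = 1000) {
  data.frame(snp = snp, a1 = a1, a2 = a2, freq = freq, b = b, se = se,
             z = b / se, p = 2 * pnorm(-abs(b / se)), n = n,
             stringsAsFactors = FALSE)
}
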