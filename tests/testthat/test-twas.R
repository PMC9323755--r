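# Prediction-weight training, the summary TWAS statistic, and COLOC.

test_that("ridge solution equals the normal-equations oracle", {
  set.seed(21)
  n <- 120; p <- 6
  G <- matrix(rbinom(n * p, 2, 0.3), n, p)
  map <- data.frame(snp = paste0("s", 1:p), chr = 1L,
                    bp = seq(100, by = 100, length.out = p),
                    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  ann <- data.frame(id = "G1", chr = 1L, start = 1L, end = 700L,
                    strand = "+", class = "gene", stringsAsFactors = FALSE)
  y <- G[, 2] * 0.4 + rnorm(n)
  expr <- matrix(y, ncol = 1, dimnames = list(NULL, "G1"))
  lambda <- 7
  m <- train_weights(G, expr, map, ann, k_folds = 4, lambdas = lambda,
                     seed = 2)[["G1"]]
  Xc <- scale(G, center = TRUE, scale = FALSE)
  oracle <- solve(crossprod(Xc) + diag(lambda, p),
                  crossprod(Xc, y - mean(y)))
  expect_lt(max(abs(m$weight - as.numeric(oracle))), 1e-8)
})

test_that("perfect heritability gives cv R2 near 1 with a dominant weight", {
  set.seed(31)
  n <- 300; p <- 4
  G <- matrix(rbinom(n * p, 2, 0.4), n, p)
  map <- data.frame(snp = paste0("s", 1:p), chr = 1L,
                    bp = seq(100, by = 100, length.out = p),
                    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  ann <- data.frame(id = "G1", chr = 1L, start = 1L, end = 500L,
                    strand = "+", class = "gene", stringsAsFactors = FALSE)
  expr <- matrix(as.numeric(G[, 3]), ncol = 1, dimnames = list(NULL, "G1"))
  m <- train_weights(G, expr, map, ann, seed = 2)[["G1"]]
  expect_gt(m$cv_r2, 0.99)
  expect_equal(which.max(abs(m$weight)), 3L)
})

test_that("permuted expression yields chance-level prediction performance", {
  ds <- small_dataset()
  set.seed(8)
  eperm <- ds$phenotypes$eqtl$e[sample(nrow(ds$phenotypes$eqtl$e)), ]
  models <- train_weights(ds$genotypes$eqtl, eperm, ds$map, ds$annotation,
                          seed = 3)
  r2 <- vapply(models, `[[`, numeric(1), "cv_r2")
  pv <- vapply(models, `[[`, numeric(1), "cv_p")
  expect_lt(mean(r2), 0.01)                   # centered at or below zero
  expect_lt(mean(r2 > 0.01 & pv < 0.05), 0.3) # near the nominal FP rate
})

test_that("single-SNP and duplicate-SNP models collapse to the SNP z", {
  set.seed(41)
  n <- 500
  g <- rbinom(n, 2, 0.3)
  G <- cbind(g, g, rbinom(n, 2, 0.4))
  map <- data.frame(snp = c("dup1", "dup2", "other"), chr = 1L,
                    bp = c(100L, 200L, 300L), a1 = "A", a2 = "G",
                    stringsAsFactors = FALSE)
  panel <- ld_panel(G, map)
  gwas <- assoc_rec(c("dup1", "dup2", "other"), b = c(0.11, 0.11, -0.02),
                    se = c(0.03, 0.03, 0.03))
  m1 <- list(gene = "g1", snp = "dup1", a1 = "A", a2 = "G", freq = 0.3,
             weight = 1, cv_r2 = 0.5, cv_p = 1e-4)
  z1 <- metaxcan_z(m1, gwas, panel)
  expect_equal(z1$zscore, gwas$z[1], tolerance = 1e-12)
  # duplicate columns with weights (1, 1): numerator 2*sigma*z, sigma_g =
  # 2*sigma
  m2 <- list(gene = "g2", snp = c("dup1", "dup2"), a1 = c("A", "A"),
             a2 = c("G", "G"), freq = c(0.3, 0.3), weight = c(1, 1),
             cv_r2 = 0.5, cv_p = 1e-4)
  z2 <- metaxcan_z(m2, gwas, panel)
  expect_equal(z2$zscore, gwas$z[1], tolerance = 1e-12)
  # sigma_g^2 equals w' Sigma w
  expect_equal(z2$sigma_g^2,
               as.numeric(t(c(1, 1)) %*% cov(G[, 1:2]) %*% c(1, 1)),
               tolerance = 1e-12)
})

test_that("Z is invariant to flipping a SNP's allele coding everywhere", {
  set.seed(43)
  n <- 400
  G <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.4))
  map <- data.frame(snp = c("s1", "s2"), chr = 1L, bp = c(100L, 200L),
                    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  panel <- ld_panel(G, map)
  gwas <- assoc_rec(c("s1", "s2"), b = c(0.1, 0.05), se = c(0.03, 0.03))
  m <- list(gene = "g", snp = c("s1", "s2"), a1 = c("A", "A"),
            a2 = c("G", "G"), freq = c(0.3, 0.4), weight = c(0.6, -0.2),
            cv_r2 = 0.4, cv_p = 1e-3)
  z0 <- metaxcan_z(m, gwas, panel)$zscore
  # flip s1 in the GWAS only; harmonization must flip it back
  gwas_f <- gwas
  gwas_f$a1[1] <- "G"; gwas_f$a2[1] <- "A"
  gwas_f$b[1] <- -gwas_f$b[1]; gwas_f$z[1] <- -gwas_f$z[1]
  gwas_f$freq[1] <- 1 - gwas_f$freq[1]
  z1 <- metaxcan_z(m, gwas_f, panel)$zscore
  expect_equal(z1, z0, tolerance = 1e-12)
})

test_that("genes losing most weight mass or all variance are skipped", {
  set.seed(44)
  n <- 200
  G <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.4))
  map <- data.frame(snp = c("s1", "s2"), chr = 1L, bp = c(100L, 200L),
                    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  panel <- ld_panel(G, map)
  gwas <- assoc_rec("s2", b = 0.05, se = 0.03)  # s1 absent from GWAS
  m <- list(gene = "g", snp = c("s1", "s2"), a1 = c("A", "A"),
            a2 = c("G", "G"), freq = c(0.3, 0.4), weight = c(0.9, 0.1),
            cv_r2 = 0.4, cv_p = 1e-3)
  expect_warning(res <- metaxcan_z(m, gwas, panel), "weight mass")
  expect_null(res)
})

test_that("coloc posteriors match hand-computed ABF sums", {
  # independent oracle: direct evaluation of the configuration sums
  oracle <- function(z1, se1, z2, se2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                     W = 0.15^2) {
    ab <- function(z, se) {
      V <- se^2
      sqrt(V / (V + W)) * exp(z^2 * W / (V + W) / 2)
    }
    A1 <- ab(z1, se1); A2 <- ab(z2, se2)
    s1 <- sum(A1); s2 <- sum(A2); s4 <- sum(A1 * A2)
    h <- c(1, p1 * s1, p2 * s2, p1 * p2 * (s1 * s2 - s4), p12 * s4)
    h / sum(h)
  }
  se1 <- rep(0.03, 4); se2 <- rep(0.05, 4)
  z1 <- c(8, 2, 0.5, -1); z2 <- c(7.5, 1, 0, 0.3)
  t1 <- assoc_rec(paste0("s", 1:4), b = z1 * se1, se = se1)
  t2 <- assoc_rec(paste0("s", 1:4), b = z2 * se2, se = se2)
  pp <- coloc_abf(t1, t2)
  expect_equal(as.numeric(pp[1, ]),
               oracle(z1, se1, z2, se2), tolerance = 1e-10)
  expect_equal(sum(as.numeric(pp[1, ])), 1, tolerance = 1e-9)
  # strong shared signal: PP4 modal
  expect_equal(which.max(as.numeric(pp[1, ])), 5L)
  # all z = 0: PP0 > 0.99
  t0a <- assoc_rec(paste0("s", 1:5), b = 0, se = 0.03)
  t0b <- assoc_rec(paste0("s", 1:5), b = 0, se = 0.05)
  pp0 <- coloc_abf(t0a, t0b)
  expect_gt(pp0$PP0, 0.99)
  # distinct strong signals at different SNPs: PP3 modal
  za <- c(9, 0.2, -0.1, 0.4); zb <- c(0.1, -0.3, 8.5, 0.2)
  pp3 <- coloc_abf(assoc_rec(paste0("s", 1:4), b = za * 0.03, se = 0.03),
                   assoc_rec(paste0("s", 1:4), b = zb * 0.05, se = 0.05))
  expect_equal(which.max(as.numeric(pp3[1, ])), 4L)
  # single-SNP region is not testable
  ppx <- coloc_abf(t1[1, ], t2[1, ])
  expect_false(attr(ppx, "testable"))
})

test_that("PP4 is monotone in the shared prior p12", {
  se1 <- rep(0.03, 6); se2 <- rep(0.05, 6)
  set.seed(5)
  t1 <- assoc_rec(paste0("s", 1:6), b = rnorm(6, 0, 3) * se1, se = se1)
  t2 <- assoc_rec(paste0("s", 1:6), b = rnorm(6, 0, 3) * se2, se = se2)
  pp4 <- vapply(c(1e-6, 1e-5, 1e-4), function(p12)
    coloc_abf(t1, t2, coloc_config(p12 = p12))$PP4, numeric(1))
  expect_true(all(diff(pp4) > 0))
})

test_that("twas_scan is deterministic and applies its filters", {
  ds <- small_dataset()
  models <- train_weights(ds$genotypes$eqtl, ds$phenotypes$eqtl$e, ds$map,
                          ds$annotation, seed = 1)
  t1 <- twas_scan(ds$gwas, models, ds$panel, eqtl = ds$eqtl)
  t2 <- twas_scan(ds$gwas, models, ds$panel, eqtl = ds$eqtl)
  expect_identical(t1, t2)
  expect_true(all(t1$p_bonf == 0.05 / nrow(t1)))
  expect_true(all(t1$pass == (t1$sig & t1$perf_pass &
                                (is.na(t1$colocalized) | t1$colocalized))))
  # null genes are not called
  null_genes <- ds$truth$gene[ds$truth$scenario == "null"]
  expect_false(any(t1$pass[t1$gene %in% null_genes]))
})

test_that("warns when p12 exceeds the single-trait priors", {
  expect_warning(coloc_config(p12 = 2e-4), "p12")
})
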