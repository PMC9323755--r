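# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' Each cohort / stage draws from its own RNG stream so that reordering
#' stages, or resizing one cohort, cannot silently shift the random numbers
#' used by another. The derivation is a small deterministic string hash kept
#' below 2^31.
#'
#' @param seed master integer seed
#' @param key stream label, e.g. "gwas" or "pheno:eqtl"
#' @return an integer seed
#' @keywords internal
substream_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Two-sided p-value from a z score (normal reference)
#' @keywords internal
z_to_p <- function(z) 2 * pnorm(-abs(z))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' Upper tail of a positively weighted sum of 1-df chi-square variables
#'
#' Evaluates P(sum_k lambda_k * chisq_1 > q) by Imhof-type numerical
#' integration of the characteristic function; falls back to Satterthwaite
#' moment matching (scaled chi-square with matched mean and variance) when
#' the integral fails to converge or returns a value outside [0, 1].
#'
#' @param q observed statistic (scalar, >= 0)
#' @param lambda vector of non-negative weights
#' @param tol relative tolerance for the numerical integration
#' @return upper-tail probability in (0, 1]
#' @export
pchisq_mixture <- function(q, lambda, tol = 1e-8) {
  lambda <- lambda[lambda > 1e-10 * max(lambda, 0)]
  if (length(lambda) == 0L) return(1)
  if (q <= 0) return(1)
  satt <- function() {
    sc <- sum(lambda^2) / sum(lambda)
    df <- sum(lambda)^2 / sum(lambda^2)
    pchisq(q / sc, df = df, lower.tail = FALSE)
  }
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    lrho <- 0.25 * colSums(log1p(outer(lambda^2, u^2)))
    sin(theta) / (u * exp(lrho))
  }
  # finite upper limit where the integrand envelope 1/(u rho(u)) is
  # negligible; the oscillatory tail beyond contributes < 1e-12
  envelope <- function(u) 1 / (u * exp(0.25 * sum(log1p(lambda^2 * u^2))))
  upper <- 1
  while (envelope(upper) > 1e-12 && upper < 1e9) upper <- upper * 2
  res <- tryCatch(
    integrate(integrand, lower = 0, upper = upper,
              rel.tol = tol, subdivisions = 20000L),
    error = function(e) NULL
  )
  if (is.null(res)) return(satt())
  p <- 0.5 + res$value / pi
  if (!is.finite(p) || p < -0.01 || p > 1.01) return(satt())
  min(max(p, 1e-300), 1)
}
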