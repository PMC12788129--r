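# Shared statistical primitives used across modules.

#' Vectorised two-sided Fisher exact test for 2x2 tables
#'
#' Tests independence in tables \code{[[mc_a, uc_a], [mc_b, uc_b]]}, i.e.
#' methylated/unmethylated read counts in two samples. The two-sided p-value
#' sums the probabilities of all tables (under the hypergeometric null with
#' fixed margins) that are no more probable than the observed one, matching
#' \code{stats::fisher.test}.
#'
#' Duplicate tables are computed once, so the function is fast on the tens of
#' thousands of near-identical low-count tables a methylome produces.
#'
#' @param mc_a,uc_a Methylated and unmethylated counts in sample A.
#' @param mc_b,uc_b Methylated and unmethylated counts in sample B.
#' @return Numeric vector of two-sided p-values in `[0, 1]`.
#' @export
fisher_exact_2x2 <- function(mc_a, uc_a, mc_b, uc_b) {
  n <- length(mc_a)
  stopifnot(length(uc_a) == n, length(mc_b) == n, length(uc_b) == n)
  if (n == 0L) return(numeric(0))
  if (any(c(mc_a, uc_a, mc_b, uc_b) < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  key <- paste(mc_a, uc_a, mc_b, uc_b, sep = ":")
  uniq <- !duplicated(key)
  p_u <- vapply(which(uniq), function(i) {
    .fisher_2x2_one(mc_a[i], uc_a[i], mc_b[i], uc_b[i])
  }, numeric(1))
  names(p_u) <- key[uniq]
  unname(p_u[key])
}

# One table: x successes in sample A; margins m (total mc), n (total uc),
# k (sample A depth). p = sum of dhyper over the support where the table
# probability does not exceed the observed (with a relative tolerance for
# floating-point ties, as fisher.test does).
.fisher_2x2_one <- function(a, b, c, d) {
  if (a + b == 0 || c + d == 0) stop("both samples must have at least one read")
  m <- a + c
  nn <- b + d
  k <- a + b
  lo <- max(0L, k - nn)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, nn, k)
  obs <- stats::dhyper(a, m, nn, k)
  min(1, sum(dens[dens <= obs * (1 + 1e-07)]))
}

#' One-sided binomial test p-values against a background rate
#'
#' Upper-tail p-value for observing at least `mc` methylated reads out of
#' `total` when the per-read success probability is `rate` (the bisulfite
#' conversion-failure rate). Vectorised.
#'
#' @param mc Observed methylated-read counts.
#' @param total Total covering reads.
#' @param rate Null per-read methylation probability.
#' @return Numeric vector of p-values.
#' @keywords internal
binom_upper_p <- function(mc, total, rate) {
  stats::pbinom(mc - 1, total, rate, lower.tail = FALSE)
}

#' Exact conditional test for a negative-binomial count pair
#'
#' Given two counts assumed to be independent negative-binomial with the same
#' mean and a common dispersion `d`, the distribution of the first count
#' conditional on the pair total is beta-binomial with both shape parameters
#' `1/d`; at `d = 0` it reduces to Binomial(total, 1/2). The two-sided
#' p-value sums the conditional probabilities of outcomes no more likely than
#' the observed one (the "minimum-likelihood" convention of exact tests).
#'
#' @param x1,x2 Non-negative integer counts.
#' @param dispersion Common negative-binomial dispersion (>= 0).
#' @return Two-sided p-value.
#' @export
nb_exact_pair_test <- function(x1, x2, dispersion = 0) {
  stopifnot(length(x1) == 1L, length(x2) == 1L, x1 >= 0, x2 >= 0,
            dispersion >= 0)
  n <- x1 + x2
  if (n == 0) return(1)
  support <- 0:n
  if (dispersion == 0) {
    logd <- stats::dbinom(support, n, 0.5, log = TRUE)
  } else {
    r <- 1 / dispersion
    logd <- lchoose(n, support) +
      lgamma(support + r) + lgamma(n - support + r) - lgamma(n + 2 * r) +
      lgamma(2 * r) - 2 * lgamma(r)
  }
  obs <- logd[x1 + 1L]
  min(1, sum(exp(logd[logd <= obs + 1e-07])))
}

# Format a proportion as a percentage rounded to 2 decimal places.
as_pct <- function(x) round(100 * x, 2)
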