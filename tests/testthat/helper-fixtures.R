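# Shared fixtures and independent oracles.

make_meth <- function(chrom, pos, strand, context, mc, total) {
  data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
             mc_count = mc, total_count = total, stringsAsFactors = FALSE)
}

random_meth_records <- function(n, seed) {
  set.seed(seed)
  total <- rpois(n, 12)
  make_meth(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
            pos = sample.int(100000, n),
            strand = sample(c("+", "-"), n, replace = TRUE),
            context = sample(c("CG", "CHG", "CHH"), n, replace = TRUE),
            mc = rbinom(n, total, 0.4), total = total)
}

# Small simulated dataset reused across test files (built once).
sim_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(
        simulate_dataset(sim_config(seed = 42, chrom_length = 50000,
                                    n_genes = 24)))
    }
    cache
  }
})

# Independent Fisher oracle: enumerate every 2x2 table with the observed
# margins, compute each table's probability from first principles
# (log-factorials, no dhyper), and sum those no more probable than observed.
oracle_fisher_p <- function(a, b, c, d) {
  lf <- function(n) if (n == 0) 0 else sum(log(seq_len(n)))
  m <- a + c; nn <- b + d; k <- a + b; N <- m + nn
  ptab <- function(x) {
    # P(table with top-left x) under fixed margins
    exp(lf(m) + lf(nn) + lf(k) + lf(N - k) - lf(N) -
          lf(x) - lf(m - x) - lf(k - x) - lf(nn - k + x))
  }
  support <- max(0, k - nn):min(k, m)
  probs <- vapply(support, ptab, numeric(1))
  obs <- ptab(a)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Independent rank-sum oracle: enumerate all group assignments directly.
oracle_ranksum_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  idx <- utils::combn(length(r), n1)
  sums <- apply(idx, 2, function(i) sum(r[i]))
  mu <- n1 * (length(r) + 1) / 2
  obs <- sum(r[seq_len(n1)])
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}
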