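# PSNP selection, allele-count aggregation, TMM factors (with edgeR as the
# independent cross-check), dispersion estimation and the NB exact bias test.

test_that("PSNP selection keeps hom-different parents with a het F1", {
  v <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 400),
                  ref = "A", alt = "G",
                  gt_mother = c("hom_ref", "hom_ref", "hom_ref", "het"),
                  gt_father = c("hom_alt", "hom_ref", "hom_alt", "hom_alt"),
                  gt_f1 = c("het", "hom_ref", "hom_alt", "het"),
                  stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 50, end = 150,
                      strand = "+", stringsAsFactors = FALSE)
  ps <- identify_psnps(v, genes)
  expect_equal(ps$pos, 100)            # others: same GT / F1 not het / parent het
  expect_equal(ps$maternal_allele, "A")
  expect_equal(ps$paternal_allele, "G")
  expect_equal(ps$gene_id, "g1")
})

test_that("per-gene counts are per-SNP means with zero-coverage PSNPs ignored", {
  ps <- data.frame(chrom = "chr1", pos = c(10, 20, 30),
                   maternal_allele = "A", paternal_allele = "G",
                   gene_id = "g1", stringsAsFactors = FALSE)
  d <- data.frame(chrom = "chr1", pos = c(10, 20, 30), sample = "f1",
                  maternal_reads = c(30, 10, 0), paternal_reads = c(10, 30, 0),
                  stringsAsFactors = FALSE)
  agg <- aggregate_allele_counts(d, ps)
  expect_equal(agg$maternal, 20)
  expect_equal(agg$paternal, 20)
  expect_equal(agg$n_psnps, 2)         # the zero-coverage PSNP is ignored
  agg1 <- aggregate_allele_counts(d[1, ], ps)
  expect_equal(c(agg1$maternal, agg1$paternal), c(30, 10))
  # sums behind the flag
  aggs <- aggregate_allele_counts(d, ps, sum_counts = TRUE)
  expect_equal(aggs$maternal, 40)
})

test_that("TMM factors satisfy identity, 2x scaling and permutation invariance", {
  set.seed(31)
  a <- rnbinom(500, mu = 200, size = 5) + 1
  m <- cbind(a, a)
  expect_equal(unname(tmm_factors(m)), c(1, 1))

  m2 <- cbind(a, 2 * a)
  f <- tmm_factors(m2)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-9)
  expect_equal(prod(f), 1, tolerance = 1e-12)

  perm <- sample(nrow(m2))
  expect_equal(unname(tmm_factors(m2[perm, ])), unname(f))
  # global rescaling leaves factors unchanged
  expect_equal(unname(tmm_factors(3 * m2)), unname(f), tolerance = 1e-9)
  expect_error(tmm_factors(cbind(a, 0 * a)), "all-zero")
})

test_that("TMM agrees with edgeR on heterogeneous libraries", {
  set.seed(32)
  n <- 2000
  mu <- rgamma(n, 2, scale = 150)
  y1 <- rnbinom(n, mu = mu, size = 8)
  y2 <- rnbinom(n, mu = 1.7 * mu, size = 8)
  de <- sample(n, 100)                 # some genuinely changed genes
  y2[de] <- rnbinom(100, mu = 5 * mu[de], size = 8)
  m <- cbind(y1, y2)
  ours <- tmm_factors(m, ref_col = 1)
  ef <- edgeR::calcNormFactors(m, method = "TMM", refColumn = 1)
  eff <- colSums(m) * ef
  eff <- eff / exp(mean(log(eff)))     # same geometric-mean-1 convention
  expect_equal(unname(ours), unname(eff), tolerance = 0.02)
})

test_that("method-of-moments dispersion recovers truth and floors at zero", {
  set.seed(33)
  mu <- rgamma(2000, 2, scale = 150) + 5
  pois <- cbind(rpois(2000, mu), rpois(2000, mu))
  expect_lt(estimate_dispersion(pois), 0.02)

  nb <- cbind(rnbinom(2000, mu = mu, size = 5), rnbinom(2000, mu = mu, size = 5))
  expect_equal(estimate_dispersion(nb), 0.2, tolerance = 0.05)

  dup <- cbind(rep(7, 50), rep(7, 50))
  expect_equal(estimate_dispersion(dup), 0)
  expect_error(estimate_dispersion(cbind(1:5, 1:5)), ">= 20 genes")
})

test_that("NB exact pair test matches the binomial exact test at zero dispersion", {
  for (x in list(c(10, 20), c(3, 3), c(0, 8), c(45, 28))) {
    expect_equal(nb_exact_pair_test(x[1], x[2], 0),
                 stats::binom.test(x[1], sum(x), 0.5)$p.value,
                 tolerance = 1e-12)
  }
  expect_equal(nb_exact_pair_test(0, 0, 0.1), 1)
  # overdispersion makes the same split less surprising
  expect_gt(nb_exact_pair_test(30, 10, 0.2), nb_exact_pair_test(30, 10, 0))
})

test_that("bias calls respect both the significance and the fold threshold", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      maternal = c(100, 300, 130, 0),
                      paternal = c(100, 100, 100, 0),
                      stringsAsFactors = FALSE)
  calls <- allelic_bias_test(genes, c(1, 1), dispersion = 0.05)
  expect_equal(calls$klass[1], "NONE")
  expect_equal(calls$klass[2], "MATERNAL_BIAS")
  expect_equal(calls$klass[3], "NONE")     # fold 1.3 < 1.5 regardless of p
  expect_equal(calls$klass[4], "NONE")
  expect_equal(calls$p_value[4], 1)

  # label swap flips directions only
  swapped <- allelic_bias_test(transform(genes, maternal = paternal,
                                         paternal = maternal),
                               c(1, 1), dispersion = 0.05)
  map <- c(MATERNAL_BIAS = "PATERNAL_BIAS", PATERNAL_BIAS = "MATERNAL_BIAS",
           NONE = "NONE")
  expect_equal(unname(map[calls$klass]), swapped$klass)
  expect_equal(calls$p_value, swapped$p_value)
})

test_that("allelic-total regression recovers the fair-split line", {
  x <- c(10, 100, 1000, 5000)
  fit <- allelic_total_regression(x, x)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  expect_error(allelic_total_regression(1:2, 1:2), "at least 3")

  # each allele ~ half the total: slope ~ 1, intercept ~ log2(1/2) = -1
  set.seed(34)
  total <- rnbinom(800, mu = rgamma(800, 2, scale = 300), size = 10) + 2
  mat <- rbinom(800, total, 0.5)
  fit2 <- allelic_total_regression(mat, total)
  expect_equal(fit2$slope, 1, tolerance = 0.05)
  expect_equal(fit2$intercept, -1, tolerance = 0.2)
  expect_gt(fit2$r_squared, 0.9)
})

test_that("bias summary conserves counts", {
  calls <- data.frame(gene_id = letters[1:5],
                      log2_fold = c(2, -2, 0, 1.2, 0.1),
                      p_value = c(1e-5, 1e-4, 0.9, 0.01, 0.7),
                      klass = c("MATERNAL_BIAS", "PATERNAL_BIAS", "NONE",
                                "MATERNAL_BIAS", "NONE"),
                      stringsAsFactors = FALSE)
  s <- bias_summary(calls)
  expect_equal(unname(s$counts), c(2, 1, 2))
  expect_equal(s$n_biased, 3)
  expect_equal(nrow(s$volcano), 5)
  s0 <- bias_summary(calls[0, ])
  expect_equal(unname(s0$counts), c(0, 0, 0))
})
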