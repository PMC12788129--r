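# Integration of PSMS origin sets with expression bias: cross-tabulations,
# co-regulation strata, the rank-sum/t allelic methylation tests against a
# permutation oracle, and the monoallelic summary.

integ_fixture <- function() {
  # 4 genes: biparental unbiased, biparental biased, maternal-only biased,
  # paternal-only unbiased
  data.frame(gene_id = c("g1", "g2", "g3", "g4"),
             n_psms_maternal = c(3, 2, 4, 0),
             n_psms_paternal = c(2, 3, 0, 5),
             meth_maternal_allele = c(0.5, 0.6, 0.7, NA),
             meth_paternal_allele = c(0.4, 0.5, NA, 0.8),
             bias_klass = c("NONE", "MATERNAL_BIAS", "PATERNAL_BIAS", "NONE"),
             category = c("BIPARENTAL", "BIPARENTAL", "MATERNAL_ONLY",
                          "PATERNAL_ONLY"), stringsAsFactors = FALSE)
}

test_that("gene integration table categorises origin sets and joins bias calls", {
  gene_psms <- data.frame(
    gene_id = c("g1", "g1", "g2"), chrom = "chr1", pos = c(10, 20, 30),
    strand = "+", origin_parent = c("mother", "father", "mother"),
    stringsAsFactors = FALSE)
  am <- data.frame(chrom = "chr1", pos = c(10, 20, 30), strand = "+",
                   context = "CG", mc_c = c(4, 1, 5), total_c = c(5, 5, 5),
                   mc_nonc = 0, total_nonc = 5, stringsAsFactors = FALSE)
  bias <- data.frame(gene_id = "g1", klass = "MATERNAL_BIAS",
                     stringsAsFactors = FALSE)
  tab <- gene_integration_table(gene_psms, bias, am)
  expect_equal(tab$category, c("BIPARENTAL", "MATERNAL_ONLY"))
  expect_equal(tab$meth_maternal_allele, c(0.8, 1.0))
  expect_equal(tab$meth_paternal_allele, c(0.2, NA))
  expect_equal(tab$bias_klass, c("MATERNAL_BIAS", "NONE"))
  # category partition is exhaustive and exclusive
  expect_true(all(table(tab$gene_id) == 1))
})

test_that("cross-tabulation percentages are 2-dp and sum to 100", {
  ct <- cross_tabulate(integ_fixture(), "mother")
  expect_equal(ct$count, c(1, 1, 1))
  expect_equal(sum(ct$pct), 100, tolerance = 0.011)
  ct2 <- cross_tabulate_counts(c(no_bias = 10, maternal_bias = 0,
                                 paternal_bias = 0))
  expect_equal(ct2$pct, c(100, 0, 0))
  expect_error(cross_tabulate(integ_fixture()[0, ], "mother"), "no genes")
})

test_that("co-regulation strata partition genes and report fractions", {
  cs <- coregulation_sets(integ_fixture())
  expect_equal(sum(cs$count[cs$stratum == "unbiased"]), 2)
  expect_equal(sum(cs$count[cs$stratum == "biased"]), 2)
  expect_equal(sum(cs$pct[cs$stratum == "biased"]), 100, tolerance = 0.011)
  one <- integ_fixture()[1, ]
  cs1 <- coregulation_sets(one)
  expect_equal(cs1$pct[cs1$stratum == "unbiased" &
                         cs1$category == "BIPARENTAL"], 100)
})

test_that("rank-sum test matches the permutation oracle; t-test handles degeneracy", {
  # identical lists -> p = 1 under mid-rank ties
  expect_equal(allelic_methylation_test(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5),
                                        "wilcoxon"), 1)
  # {0,0,0} vs {1,1,1}: 2 of the C(6,3)=20 assignments are as extreme
  expect_equal(allelic_methylation_test(c(0, 0, 0), c(1, 1, 1), "wilcoxon"),
               0.1)
  expect_equal(allelic_methylation_test(c(0, 0, 0), c(1, 1, 1), "wilcoxon"),
               oracle_ranksum_p(c(0, 0, 0), c(1, 1, 1)))
  # random small lists against the oracle (with and without ties)
  set.seed(55)
  for (i in 1:20) {
    x <- round(runif(sample(3:5, 1)), 1)
    y <- round(runif(sample(3:5, 1)), 1)
    expect_equal(allelic_methylation_test(x, y, "wilcoxon"),
                 oracle_ranksum_p(x, y))
  }
  # below min_sites -> missing
  expect_true(is.na(allelic_methylation_test(0.5, c(0.1, 0.2, 0.3),
                                             "wilcoxon")))
  expect_true(is.na(allelic_methylation_test(0.5, c(0.1, 0.2, 0.3), "ttest")))
  # Welch t on a clear shift
  expect_lt(allelic_methylation_test(c(0.1, 0.12, 0.11, 0.13),
                                     c(0.8, 0.82, 0.81, 0.83), "ttest"), 0.01)
  expect_equal(allelic_methylation_test(rep(0.3, 4), rep(0.3, 4), "ttest"), 1)
})

test_that("significant fraction reports percentage of tested genes", {
  p <- c(0.01, 0.2, NA, 0.03, 0.8, NA)
  sf <- significant_fraction(p, alpha = 0.05)
  expect_equal(sf$n_tested, 4)
  expect_equal(sf$n_significant, 2)
  expect_equal(sf$pct, 50)
  expect_equal(significant_fraction(c(0.5, 0.9))$pct, 0)
  # null calibration: uniform p-values reject at ~alpha
  set.seed(56)
  sf0 <- significant_fraction(runif(5000), alpha = 0.05)
  expect_lt(abs(sf0$pct / 100 - 0.05), 0.01)
})

test_that("allelic methylation tests hold their type-I error on null genes", {
  set.seed(57)
  n_genes <- 5000
  p_w <- p_t <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    # both alleles' PSMS levels from the same beta distribution: no true ASM
    x <- rbeta(sample(3:6, 1), 2, 2)
    y <- rbeta(sample(3:6, 1), 2, 2)
    p_w[i] <- allelic_methylation_test(x, y, "wilcoxon")
    p_t[i] <- allelic_methylation_test(x, y, "ttest")
  }
  expect_lte(mean(p_w < 0.05), 0.06)
  expect_lte(mean(p_t < 0.05), 0.06)
})

test_that("monoallelic summary counts dominance within each origin and transposes under label swap", {
  fx <- rbind(integ_fixture(),
              data.frame(gene_id = "g5", n_psms_maternal = 2,
                         n_psms_paternal = 0, meth_maternal_allele = 0.4,
                         meth_paternal_allele = NA,
                         bias_klass = "MATERNAL_BIAS",
                         category = "MATERNAL_ONLY", stringsAsFactors = FALSE))
  ms <- monoallelic_summary(fx)
  expect_equal(ms$count[ms$meth_origin == "maternal"], c(1, 1))
  expect_equal(ms$pct[ms$meth_origin == "maternal"], c(50, 50))
  # label swap: exchange origins and bias directions -> transposed table
  swapped <- transform(fx,
    n_psms_maternal = n_psms_paternal, n_psms_paternal = n_psms_maternal,
    bias_klass = c(MATERNAL_BIAS = "PATERNAL_BIAS",
                   PATERNAL_BIAS = "MATERNAL_BIAS", NONE = "NONE")[bias_klass],
    category = c(BIPARENTAL = "BIPARENTAL", MATERNAL_ONLY = "PATERNAL_ONLY",
                 PATERNAL_ONLY = "MATERNAL_ONLY")[category])
  ms2 <- monoallelic_summary(swapped)
  expect_equal(ms2$count[ms2$meth_origin == "paternal" &
                           ms2$expr_dominance == "paternal"],
               ms$count[ms$meth_origin == "maternal" &
                          ms$expr_dominance == "maternal"])
  expect_equal(sum(ms2$count), sum(ms$count))
  # empty stratum -> zeros
  ms0 <- monoallelic_summary(integ_fixture()[1, ])
  expect_true(all(ms0$count == 0))
})
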