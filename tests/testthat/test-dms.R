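# Per-site Fisher tests against the enumeration oracle and the eight-way
# inheritance classification.

dms_row <- function(level_pa, level_pb, level_f1, p_ab, p_fa, p_fb) {
  data.frame(level_pa = level_pa, level_pb = level_pb, level_f1 = level_f1,
             p_ab = p_ab, p_fa = p_fa, p_fb = p_fb)
}

test_that("site Fisher p-values equal the enumeration oracle for totals <= 200", {
  expect_equal(fisher_site_test(10, 0, 0, 10), 2 / choose(20, 10))
  expect_equal(fisher_site_test(5, 5, 5, 5), 1)
  expect_equal(fisher_site_test(8, 2, 2, 8), oracle_fisher_p(8, 2, 2, 8))
  expect_error(fisher_site_test(0, 0, 3, 5), "at least one")

  set.seed(101)
  for (i in 1:300) {
    na <- sample.int(100, 1); nb <- sample.int(100, 1)
    a <- rbinom(1, na, runif(1)); b <- rbinom(1, nb, runif(1))
    p <- fisher_exact_2x2(a, na - a, b, nb - b)
    expect_equal(p, oracle_fisher_p(a, na - a, b, nb - b), tolerance = 1e-12)
  }
  # spot cross-check against stats::fisher.test
  for (tab in list(c(8, 2, 2, 8), c(12, 30, 25, 11), c(0, 9, 4, 5))) {
    expect_equal(fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4]),
                 stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("classification rules map significance patterns to the eight classes", {
  a <- 0.01
  # parents differ, F1 strictly between and distinct from both -> ADDITIVE
  expect_equal(classify_dms(dms_row(0.9, 0.1, 0.5, 1e-5, 1e-3, 1e-3), a),
               "ADDITIVE")
  # F1 indistinguishable from high parent -> HIGH_PARENT
  expect_equal(classify_dms(dms_row(0.9, 0.1, 0.88, 1e-5, 0.8, 1e-4), a),
               "HIGH_PARENT")
  expect_equal(classify_dms(dms_row(0.1, 0.9, 0.12, 1e-5, 0.7, 1e-4), a),
               "LOW_PARENT")
  # F1 beyond the parental range
  expect_equal(classify_dms(dms_row(0.6, 0.2, 0.95, 1e-5, 1e-3, 1e-6), a),
               "ABOVE_HIGH_PARENT")
  expect_equal(classify_dms(dms_row(0.6, 0.2, 0.01, 1e-5, 1e-6, 1e-3), a),
               "BELOW_LOW_PARENT")
  # parents equal, F1 above/below both
  expect_equal(classify_dms(dms_row(0.1, 0.12, 0.8, 0.9, 1e-6, 1e-6), a),
               "ABOVE_PARENT")
  expect_equal(classify_dms(dms_row(0.8, 0.82, 0.1, 0.7, 1e-6, 1e-6), a),
               "BELOW_PARENT")
  # parents differ but F1 indistinguishable from both -> AMBIGUOUS
  expect_equal(classify_dms(dms_row(0.5, 0.2, 0.35, 5e-3, 0.2, 0.2), a),
               "AMBIGUOUS")
  expect_error(classify_dms(dms_row(0.5, 0.5, 0.5, 0.9, 0.9, 0.9), a),
               "DMS rows only")
})

test_that("classification is a total, exclusive partition under fuzzing", {
  set.seed(202)
  n <- 5000
  rec <- dms_row(runif(n), runif(n), runif(n),
                 runif(n)^3, runif(n)^3, runif(n)^3)
  is_dms <- rec$p_ab < 0.01 | rec$p_fa < 0.01 | rec$p_fb < 0.01
  rec <- rec[is_dms, ]
  kl <- classify_dms(rec, 0.01)
  expect_equal(length(kl), nrow(rec))          # total
  expect_true(all(kl %in% c("ADDITIVE", "LOW_PARENT", "HIGH_PARENT",
                            "ABOVE_HIGH_PARENT", "BELOW_LOW_PARENT",
                            "ABOVE_PARENT", "BELOW_PARENT", "AMBIGUOUS")))
  # swapping parent labels fixes ADDITIVE and the value-anchored classes
  rec_sw <- dms_row(rec$level_pb, rec$level_pa, rec$level_f1,
                    rec$p_ab, rec$p_fb, rec$p_fa)
  kl_sw <- classify_dms(rec_sw, 0.01)
  expect_equal(kl_sw, kl)
})

test_that("DMS detection is monotone in alpha and excludes low-coverage sites", {
  ds <- sim_small()
  tab_strict <- dms_table(ds$father, ds$mother, ds$f1, "CG", alpha = 1e-12)
  tab <- dms_table(ds$father, ds$mother, ds$f1, "CG", alpha = 0.01)
  expect_lte(nrow(tab_strict), nrow(tab))
  expect_true(all(tab$total_pa >= 4 & tab$total_pb >= 4 & tab$total_f1 >= 4))
  expect_true(all(tab$p_ab < 0.01 | tab$p_fa < 0.01 | tab$p_fb < 0.01))
})

test_that("class proportions sum to one per chromosome", {
  ds <- sim_small()
  tab <- dms_table(ds$father, ds$mother, ds$f1, "CG")
  pr <- dms_class_proportions(tab)
  for (ch in unique(pr$chrom)) {
    expect_equal(sum(pr$proportion[pr$chrom == ch]), 1, tolerance = 1e-12)
  }
  expect_error(dms_class_proportions(tab[0, ]), "no DMS")
})

test_that("mostly-additive simulations are dominated by additive-family classes", {
  cfg <- sim_config(seed = 9, chrom_length = 60000, n_genes = 10,
                    coverage = 30,
                    inheritance_weights = c(additive = 1, maternal_like = 0,
                                            paternal_like = 0,
                                            above_parent = 0, below_parent = 0))
  ds <- suppressMessages(simulate_dataset(cfg))
  tab <- dms_table(ds$father, ds$mother, ds$f1, "CG")
  kl <- table(factor(tab$klass, levels = c("ADDITIVE", "LOW_PARENT",
                                           "HIGH_PARENT", "ABOVE_HIGH_PARENT",
                                           "BELOW_LOW_PARENT", "ABOVE_PARENT",
                                           "BELOW_PARENT", "AMBIGUOUS")))
  transgressive <- kl[["ABOVE_HIGH_PARENT"]] + kl[["BELOW_LOW_PARENT"]]
  expect_lt(transgressive / nrow(tab), 0.01)
})

test_that("upset sets are exclusive per pair and conserve the DMS count", {
  ds <- sim_small()
  tab <- dms_table(ds$father, ds$mother, ds$f1, "CG")
  up <- upset_counts(tab)
  m <- up$membership
  expect_false(any(m[, "PA<PB"] & m[, "PA>PB"]))
  expect_false(any(m[, "PA<F1"] & m[, "PA>F1"]))
  expect_false(any(m[, "PB<F1"] & m[, "PB>F1"]))
  expect_equal(sum(up$intersections$count), sum(rowSums(m) > 0))
  # a site significant in exactly one pair belongs to exactly one set
  one <- dms_row(0.1, 0.9, 0.5, 1e-6, 0.5, 0.5)
  one <- cbind(one, chrom = "chr1")
  expect_equal(sum(upset_counts(one)$membership), 1)
})
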