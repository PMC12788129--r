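# Window geometry, the pooled Fisher test against the enumeration oracle,
# merge rules, and DMR inheritance classification.

two_sample_sites <- function(pos, mc_a, tot_a, mc_b, tot_b, context = "CG") {
  list(a = make_meth("chr1", pos, "+", context, mc_a, tot_a),
       b = make_meth("chr1", pos, "+", context, mc_b, tot_b))
}

test_that("windows require enough covered sites in both samples", {
  p <- dmr_params(window_bp = 1000, step_bp = 1000, min_sites = 5)
  s <- two_sample_sites(c(100, 200, 300, 400, 500), 5, 10, 1, 10)
  w <- make_windows(s$a, s$b, "CG", p)
  expect_equal(nrow(w), 1)
  expect_equal(w$n_sites, 5)
  expect_equal(w$mc_a, 25)
  expect_equal(w$total_b, 50)

  # a site below coverage in one sample drops the window below min_sites
  s2 <- two_sample_sites(c(100, 200, 300, 400, 500), 5, 10,
                         1, c(10, 10, 10, 10, 3))
  expect_equal(nrow(make_windows(s2$a, s2$b, "CG", p)), 0)
  # no covered sites at all
  expect_equal(nrow(make_windows(s$a[0, ], s$b, "CG", p)), 0)

  # step = window -> windows disjoint
  s3 <- two_sample_sites(seq(50, 4950, by = 50), 5, 10, 1, 10)
  w3 <- make_windows(s3$a, s3$b, "CG", p)
  expect_true(all(diff(w3$start) >= p$window_bp))
  expect_equal(sum(w3$n_sites), length(seq(50, 4950, by = 50)))
})

test_that("window test matches the exact hypergeometric oracle and analytic fold", {
  s <- two_sample_sites(1:5, c(2, 2, 2, 2, 2), 2, 0, 2)
  w <- test_window(make_windows(s$a, s$b, "CG",
                                dmr_params(min_sites = 5, min_cov = 1)))
  # pooled (10 mC, 0 uC) vs (0 mC, 10 uC): p = 2 / C(20,10)
  expect_equal(w$p_value, 2 / choose(20, 10))
  expect_equal(w$direction, "a>b")

  # pooled (50,50) vs (25,75): p from the oracle, fold ~ 0.5/0.25
  s2 <- two_sample_sites(1:5, 10, 20, 5, 20)
  w2 <- test_window(make_windows(s2$a, s2$b, "CG",
                                 dmr_params(min_sites = 5, min_cov = 1)))
  expect_equal(w2$p_value, oracle_fisher_p(50, 50, 25, 75))
  expect_equal(w2$p_value, stats::fisher.test(matrix(c(50, 50, 25, 75), 2,
                                                     byrow = TRUE))$p.value)
  expect_equal(w2$fold_change, (0.5 + 0.001) / (0.25 + 0.001))
  expect_equal(w2$fold_change, 2, tolerance = 0.01)

  # identical pooled counts: p = 1, fold = 1
  s3 <- two_sample_sites(1:5, 4, 10, 4, 10)
  w3 <- test_window(make_windows(s3$a, s3$b, "CG",
                                 dmr_params(min_sites = 5, min_cov = 1)))
  expect_equal(w3$p_value, 1)
  expect_equal(w3$fold_change, 1)
})

test_that("significant windows merge by direction and every DMR meets all thresholds", {
  # two overlapping significant windows, same direction -> one DMR
  pos <- seq(100, 1500, by = 100)
  s <- two_sample_sites(pos, 9, 10, 0, 10)
  p <- dmr_params(window_bp = 1000, step_bp = 500, min_sites = 5)
  d <- call_dmrs(s$a, s$b, "CG", p)
  expect_equal(nrow(d), 1)
  expect_equal(d$direction, "a>b")
  expect_gte(d$fold_change, 2)
  expect_lte(d$p_value, 0.05)
  expect_gte(d$n_sites, 5)

  # adjacent opposite-direction blocks -> two DMRs
  pos1 <- seq(100, 1000, by = 100)
  pos2 <- seq(1100, 2000, by = 100)
  a <- rbind(make_meth("chr1", pos1, "+", "CG", 9, 10),
             make_meth("chr1", pos2, "+", "CG", 0, 10))
  b <- rbind(make_meth("chr1", pos1, "+", "CG", 0, 10),
             make_meth("chr1", pos2, "+", "CG", 9, 10))
  p2 <- dmr_params(window_bp = 1000, step_bp = 1000, min_sites = 5)
  d2 <- call_dmrs(a, b, "CG", p2)
  expect_equal(nrow(d2), 2)
  expect_setequal(d2$direction, c("a>b", "a<b"))

  # merging is idempotent: calling on the same data twice gives the same set
  expect_identical(call_dmrs(s$a, s$b, "CG", p), d)
})

test_that("a strong simulated difference yields a DMR over the region", {
  # one 5 kb region with delta level ~0.6 at 15x coverage
  set.seed(5)
  pos <- sort(sample(1:20000, 900))
  in_region <- pos >= 8000 & pos <= 13000
  tot_a <- rpois(900, 15); tot_b <- rpois(900, 15)
  p_a <- ifelse(in_region, 0.8, 0.2)
  a <- make_meth("chr1", pos, "+", "CG", rbinom(900, tot_a, p_a), tot_a)
  b <- make_meth("chr1", pos, "+", "CG", rbinom(900, tot_b, 0.2), tot_b)
  d <- call_dmrs(a, b, "CG")
  hit <- d$start <= 13000 & d$end >= 8000 & d$direction == "a>b"
  expect_true(any(hit))
})

test_that("DMR inheritance follows overlap/direction logic and is label-symmetric", {
  dmr <- function(start, end, dir) {
    data.frame(chrom = "chr1", start = start, end = end, context = "CG",
               n_sites = 10, level_a = ifelse(dir == "a>b", 0.8, 0.2),
               level_b = ifelse(dir == "a>b", 0.2, 0.8),
               fold_change = 4, direction = dir, p_value = 1e-4,
               stringsAsFactors = FALSE)
  }
  parental <- rbind(dmr(1000, 2000, "a>b"),    # father > mother
                    dmr(5000, 6000, "a<b"),
                    dmr(9000, 9500, "a>b"))
  # F1 like father in region 1: F1 > mother there, no F1-vs-father DMR
  f1_vs_mother <- dmr(1500, 2500, "a>b")
  # F1 like mother in region 2: F1 > father (mother-high), consistent
  f1_vs_father <- dmr(5200, 5800, "a>b")
  res <- classify_dmr_inheritance(parental, f1_vs_father, f1_vs_mother)
  expect_equal(res$calls$category,
               c("LIKE_FATHER", "LIKE_MOTHER", "UNRESOLVED"))

  # overlap with DMRs in both F1 comparisons -> UNRESOLVED
  res2 <- classify_dmr_inheritance(parental[1, ], dmr(900, 1100, "a<b"),
                                   f1_vs_mother)
  expect_equal(res2$calls$category, "UNRESOLVED")

  # swapping parent labels swaps LIKE_FATHER and LIKE_MOTHER counts
  swap_dir <- function(d) transform(d, direction = ifelse(direction == "a>b",
                                                          "a<b", "a>b"),
                                    level_a = level_b, level_b = level_a)
  res_sw <- classify_dmr_inheritance(swap_dir(parental), f1_vs_mother,
                                     f1_vs_father)
  expect_equal(sum(res_sw$calls$category == "LIKE_FATHER"),
               sum(res$calls$category == "LIKE_MOTHER"))
  expect_equal(sum(res_sw$calls$category == "LIKE_MOTHER"),
               sum(res$calls$category == "LIKE_FATHER"))
})

test_that("maternal-like simulations classify parental DMRs as LIKE_MOTHER", {
  cfg <- sim_config(seed = 21, chrom_length = 100000, n_genes = 40,
                    inheritance_weights = c(additive = 0, maternal_like = 1,
                                            paternal_like = 0,
                                            above_parent = 0,
                                            below_parent = 0))
  ds <- suppressMessages(simulate_dataset(cfg))
  par <- call_dmrs(ds$father, ds$mother, "CG")
  vf <- call_dmrs(ds$f1, ds$father, "CG")
  vm <- call_dmrs(ds$f1, ds$mother, "CG")
  expect_gt(nrow(par), 0)
  res <- classify_dmr_inheritance(par, vf, vm)
  expect_true(all(res$calls$category == "LIKE_MOTHER"))
})

test_that("transmitted fraction is a 2-dp percentage and errors on empty input", {
  calls <- data.frame(category = c(rep("LIKE_FATHER", 3),
                                   rep("UNRESOLVED", 7)))
  expect_equal(transmitted_fraction(calls, "LIKE_FATHER"), 30)
  expect_equal(transmitted_fraction(calls, "LIKE_MOTHER"), 0)
  expect_error(transmitted_fraction(calls[0, , drop = FALSE], "LIKE_FATHER"),
               "no DMR")
})
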