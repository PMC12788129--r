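# Integration of parent-specific methylation with allelic expression:
# per-gene PSMS origin sets, co-regulation categories, allelic methylation
# tests (rank-sum and Welch t), and monoallelic-methylation vs
# expression-dominance summaries.

#' Build per-gene integration records
#'
#' Joins gene-assigned PSMSs with allelic-bias calls. The allelic
#' methylation level of a parent-derived allele is the mean F1
#' cytosine-allele methylation level (`mc_c / total_c`) over the gene's
#' PSMSs originating from that parent.
#'
#' @param gene_psms PSMS-gene assignments from [assign_psms_to_genes()].
#' @param bias_calls Allelic-bias calls from [allelic_bias_test()].
#' @param f1_allele_meth Allele-resolved F1 methylation table.
#' @return data.frame with one row per gene having >= 1 PSMS: gene_id,
#'   n_psms_maternal, n_psms_paternal, meth_maternal_allele,
#'   meth_paternal_allele (NA when that origin has no covered PSMS),
#'   bias_klass (NONE when the gene has no expression call), category in
#'   BIPARENTAL / MATERNAL_ONLY / PATERNAL_ONLY.
#' @export
gene_integration_table <- function(gene_psms, bias_calls, f1_allele_meth) {
  if (!nrow(gene_psms)) stop("no PSMS-gene assignments supplied")
  key <- paste(f1_allele_meth$chrom, f1_allele_meth$pos,
               f1_allele_meth$strand, sep = ":")
  i <- match(paste(gene_psms$chrom, gene_psms$pos, gene_psms$strand,
                   sep = ":"), key)
  gene_psms$level <- ifelse(!is.na(i) & f1_allele_meth$total_c[i] >= 1,
                            f1_allele_meth$mc_c[i] / f1_allele_meth$total_c[i],
                            NA_real_)
  genes <- sort(unique(gene_psms$gene_id))
  n_m <- n_p <- integer(length(genes))
  mm <- mp <- rep(NA_real_, length(genes))
  for (k in seq_along(genes)) {
    g <- gene_psms[gene_psms$gene_id == genes[k], ]
    n_m[k] <- sum(g$origin_parent == "mother")
    n_p[k] <- sum(g$origin_parent == "father")
    lm_ <- g$level[g$origin_parent == "mother" & !is.na(g$level)]
    lp_ <- g$level[g$origin_parent == "father" & !is.na(g$level)]
    if (length(lm_)) mm[k] <- mean(lm_)
    if (length(lp_)) mp[k] <- mean(lp_)
  }
  bias <- bias_calls$klass[match(genes, bias_calls$gene_id)]
  bias[is.na(bias)] <- "NONE"
  category <- ifelse(n_m > 0 & n_p > 0, "BIPARENTAL",
                     ifelse(n_m > 0, "MATERNAL_ONLY", "PATERNAL_ONLY"))
  data.frame(gene_id = genes, n_psms_maternal = n_m, n_psms_paternal = n_p,
             meth_maternal_allele = mm, meth_paternal_allele = mp,
             bias_klass = bias, category = category, stringsAsFactors = FALSE)
}

#' Cross-tabulate expression bias among genes with PSMSs of one origin
#'
#' @param records Integration table from [gene_integration_table()], or any
#'   data.frame with n_psms_maternal / n_psms_paternal and bias_klass.
#' @param origin `"mother"` or `"father"`: restrict to genes with >= 1 PSMS
#'   of this origin.
#' @return data.frame with bias class (NONE, MATERNAL_BIAS, PATERNAL_BIAS),
#'   count and percentage (2 dp).
#' @export
cross_tabulate <- function(records, origin = c("mother", "father")) {
  origin <- match.arg(origin)
  n_col <- if (origin == "mother") records$n_psms_maternal else
    records$n_psms_paternal
  sub <- records[n_col > 0, , drop = FALSE]
  if (!nrow(sub)) stop("no genes with PSMSs of origin ", origin)
  cross_tabulate_counts(c(
    no_bias = sum(sub$bias_klass == "NONE"),
    maternal_bias = sum(sub$bias_klass == "MATERNAL_BIAS"),
    paternal_bias = sum(sub$bias_klass == "PATERNAL_BIAS")))
}

#' Percentages for a no-bias / maternal-bias / paternal-bias tally
#'
#' @param counts Named numeric vector (no_bias, maternal_bias,
#'   paternal_bias).
#' @return data.frame with klass, count, pct (percentage to 2 dp).
#' @export
cross_tabulate_counts <- function(counts) {
  data.frame(klass = names(counts), count = as.numeric(counts),
             pct = as_pct(as.numeric(counts) / sum(counts)),
             stringsAsFactors = FALSE)
}

#' Co-regulation category counts stratified by expression bias
#'
#' Splits genes into the unbiased (`bias_klass == "NONE"`) and biased
#' strata and counts the BIPARENTAL / MATERNAL_ONLY / PATERNAL_ONLY
#' regulation categories in each.
#'
#' @param records Integration table from [gene_integration_table()].
#' @return data.frame with stratum, category, count, pct.
#' @export
coregulation_sets <- function(records) {
  strata <- list(unbiased = records[records$bias_klass == "NONE", ],
                 biased = records[records$bias_klass != "NONE", ])
  cats <- c("BIPARENTAL", "MATERNAL_ONLY", "PATERNAL_ONLY")
  out <- do.call(rbind, lapply(names(strata), function(s) {
    sub <- strata[[s]]
    counts <- vapply(cats, function(k) sum(sub$category == k), numeric(1))
    data.frame(stratum = s, category = cats, count = as.numeric(counts),
               pct = if (sum(counts)) as_pct(counts / sum(counts)) else
                 rep(NA_real_, length(cats)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Exact two-sided rank-sum p via enumeration of all group assignments (ties
# handled by mid-ranks); falls back to the normal approximation with tie
# correction for large groups.
.ranksum_p <- function(x, y, max_enum = 20000) {
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(1)
  r <- rank(pooled)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  if (choose(length(pooled), n1) <= max_enum) {
    combos <- utils::combn(length(pooled), n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    mu <- n1 * (length(pooled) + 1) / 2
    mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
  } else {
    n2 <- length(y)
    N <- n1 + n2
    mu <- n1 * (N + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(1)
    2 * stats::pnorm(-abs(obs - mu) / sqrt(sigma2))
  }
}

#' Test for allelic methylation difference within one gene
#'
#' Compares the per-PSMS F1 methylation levels of the maternal-derived and
#' paternal-derived alleles with either an exact two-sided rank-sum test
#' (mid-ranks for ties, full enumeration for small groups) or Welch's
#' two-sided t-test. Returns NA when either allele has fewer than
#' `min_sites` level observations.
#'
#' @param maternal_levels,paternal_levels Per-PSMS methylation levels of the
#'   two alleles.
#' @param method `"wilcoxon"` or `"ttest"`.
#' @param min_sites Minimum observations per allele (default 3).
#' @return Two-sided p-value, or NA when untestable.
#' @export
allelic_methylation_test <- function(maternal_levels, paternal_levels,
                                     method = c("wilcoxon", "ttest"),
                                     min_sites = 3) {
  method <- match.arg(method)
  x <- maternal_levels[!is.na(maternal_levels)]
  y <- paternal_levels[!is.na(paternal_levels)]
  if (length(x) < min_sites || length(y) < min_sites) return(NA_real_)
  if (method == "wilcoxon") {
    .ranksum_p(x, y)
  } else {
    if (stats::sd(c(x, y)) == 0) return(1)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(if (mean(x) == mean(y)) 1 else 0)
    tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
  }
}

#' Fraction of tested genes with a significant allelic methylation difference
#'
#' @param p_values Per-gene p-values (NA = untested).
#' @param alpha Significance level (default 0.05).
#' @return List with n_tested, n_significant, pct (percentage to 2 dp).
#' @export
significant_fraction <- function(p_values, alpha = 0.05) {
  tested <- p_values[!is.na(p_values)]
  list(n_tested = length(tested), n_significant = sum(tested < alpha),
       pct = if (length(tested)) as_pct(mean(tested < alpha)) else NA_real_)
}

#' Monoallelic methylation vs expression dominance
#'
#' Restricted to genes with biased expression and single-origin PSMSs
#' (monoallelic methylation): for each methylation origin, counts of genes
#' with maternal vs paternal expression dominance, with percentages.
#'
#' @param records Integration table from [gene_integration_table()].
#' @return data.frame with meth_origin (maternal/paternal monoallelic),
#'   expr_dominance, count, pct (percentages within each origin).
#' @export
monoallelic_summary <- function(records) {
  sub <- records[records$bias_klass %in% c("MATERNAL_BIAS", "PATERNAL_BIAS") &
                   records$category != "BIPARENTAL", , drop = FALSE]
  out <- do.call(rbind, lapply(c("MATERNAL_ONLY", "PATERNAL_ONLY"),
                               function(cat) {
    s <- sub[sub$category == cat, ]
    counts <- c(maternal_dominant = sum(s$bias_klass == "MATERNAL_BIAS"),
                paternal_dominant = sum(s$bias_klass == "PATERNAL_BIAS"))
    data.frame(meth_origin = if (cat == "MATERNAL_ONLY") "maternal" else
                 "paternal",
               expr_dominance = c("maternal", "paternal"),
               count = as.numeric(counts),
               pct = if (sum(counts)) as_pct(counts / sum(counts)) else
                 c(0, 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
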