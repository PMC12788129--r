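# Parent-specific SNP (PSNP) identification, per-gene allele counting, TMM
# normalisation, negative-binomial allelic-bias calling and the
# allelic-vs-total expression regression.

#' Identify parent-specific SNPs (PSNPs)
#'
#' A PSNP is a biallelic SNP at which the two parents are homozygous for
#' different alleles and the F1 is heterozygous carrying exactly those two
#' alleles. Each PSNP is annotated with the gene whose span contains it, if
#' any.
#'
#' @param variants Variant data.frame from [read_vcf_minimal()].
#' @param annotation Gene annotation data.frame.
#' @param samples Named character vector mapping roles to VCF sample names:
#'   `c(mother = ..., father = ..., f1 = ...)`.
#' @return data.frame of PSNPs with chrom, pos, maternal_allele,
#'   paternal_allele, gene_id (NA when intergenic).
#' @export
identify_psnps <- function(variants, annotation,
                           samples = c(mother = "mother", father = "father",
                                       f1 = "f1")) {
  gt <- function(role) variants[[paste0("gt_", samples[[role]])]]
  gm <- gt("mother"); gf <- gt("father"); gh <- gt("f1")
  keep <- !is.na(gm) & !is.na(gf) & !is.na(gh) &
    gm %in% c("hom_ref", "hom_alt") & gf %in% c("hom_ref", "hom_alt") &
    gm != gf & gh == "het"
  v <- variants[keep, , drop = FALSE]
  maternal <- ifelse(gm[keep] == "hom_ref", v$ref, v$alt)
  paternal <- ifelse(gf[keep] == "hom_ref", v$ref, v$alt)
  out <- data.frame(chrom = v$chrom, pos = v$pos, maternal_allele = maternal,
                    paternal_allele = paternal, gene_id = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(out) && nrow(annotation)) {
    snp <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$pos, out$pos))
    gn <- GenomicRanges::GRanges(annotation$chrom,
                                 IRanges::IRanges(annotation$start,
                                                  annotation$end))
    h <- GenomicRanges::findOverlaps(snp, gn, select = "first")
    out$gene_id <- ifelse(is.na(h), NA_character_, annotation$gene_id[h])
  }
  rownames(out) <- NULL
  out
}

#' Aggregate per-SNP allele reads into per-gene counts
#'
#' Per-gene counts are the mean over the gene's covered PSNPs of the per-SNP
#' maternal and paternal read counts, rounded to the nearest integer (means
#' rather than sums, so genes with many PSNPs are not inflated). PSNPs with
#' zero total reads are ignored; genes with no covered PSNP are excluded.
#'
#' @param allele_depths Allele depth data.frame (chrom, pos, maternal_reads,
#'   paternal_reads).
#' @param psnps PSNP data.frame from [identify_psnps()] (rows without a
#'   gene_id are dropped).
#' @param sum_counts Sum instead of averaging per-SNP reads (default FALSE).
#' @return data.frame with gene_id, n_psnps, maternal, paternal.
#' @export
aggregate_allele_counts <- function(allele_depths, psnps, sum_counts = FALSE) {
  psnps <- psnps[!is.na(psnps$gene_id), , drop = FALSE]
  key_d <- paste(allele_depths$chrom, allele_depths$pos, sep = ":")
  key_p <- paste(psnps$chrom, psnps$pos, sep = ":")
  i <- match(key_d, key_p)
  keep <- !is.na(i) &
    (allele_depths$maternal_reads + allele_depths$paternal_reads) > 0
  d <- allele_depths[keep, , drop = FALSE]
  d$gene_id <- psnps$gene_id[i[keep]]
  if (!nrow(d)) {
    return(data.frame(gene_id = character(), n_psnps = integer(),
                      maternal = numeric(), paternal = numeric(),
                      stringsAsFactors = FALSE))
  }
  agg <- if (sum_counts) {
    stats::aggregate(cbind(maternal_reads, paternal_reads) ~ gene_id, d, sum)
  } else {
    stats::aggregate(cbind(maternal_reads, paternal_reads) ~ gene_id, d, mean)
  }
  n <- stats::aggregate(pos ~ gene_id, d, length)
  out <- data.frame(gene_id = agg$gene_id,
                    n_psnps = n$pos[match(agg$gene_id, n$gene_id)],
                    maternal = round(agg$maternal_reads),
                    paternal = round(agg$paternal_reads),
                    stringsAsFactors = FALSE)
  out[order(out$gene_id), ]
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values normalisation: for each library, the weighted
#' mean of per-gene log2 expression ratios against a reference library,
#' after trimming 30% of the M-values and 5% of the A-values from each tail
#' (weights are inverse asymptotic variances of M). Genes with a zero count
#' in either library are excluded. The returned factor folds in the library
#' size (it is the full effective scale of the library) and the factors are
#' rescaled to geometric mean 1, so dividing counts by them makes libraries
#' comparable.
#'
#' @param count_matrix Numeric matrix, genes x libraries (>= 2 columns).
#' @param ref_col Reference library column (default: the library whose upper
#'   quartile of scaled counts is closest to the mean upper quartile, as is
#'   conventional).
#' @return Numeric vector of per-library scaling factors, geometric mean 1.
#' @export
tmm_factors <- function(count_matrix, ref_col = NULL) {
  m <- as.matrix(count_matrix)
  if (ncol(m) < 2) stop("TMM needs at least two libraries")
  if (any(m < 0)) stop("counts must be non-negative")
  lib <- colSums(m)
  if (any(lib == 0)) stop("all-zero library")
  if (is.null(ref_col)) {
    uq <- apply(m, 2, function(x) stats::quantile(x / sum(x), 0.75))
    ref_col <- which.min(abs(uq - mean(uq)))
  }
  tmm_one <- function(k) {
    if (k == ref_col) return(1)
    y <- m[, k]; r <- m[, ref_col]
    keep <- y > 0 & r > 0
    y <- y[keep]; r <- r[keep]
    if (!length(y)) return(1)
    M <- log2((y / lib[k]) / (r / lib[ref_col]))
    A <- (log2(y / lib[k]) + log2(r / lib[ref_col])) / 2
    w <- (lib[k] - y) / (lib[k] * y) + (lib[ref_col] - r) / (lib[ref_col] * r)
    loM <- stats::quantile(M, 0.3, type = 1)
    hiM <- stats::quantile(M, 0.7, type = 1)
    loA <- stats::quantile(A, 0.05, type = 1)
    hiA <- stats::quantile(A, 0.95, type = 1)
    keep2 <- M >= loM & M <= hiM & A >= loA & A <= hiA
    if (!any(keep2) || all(w[keep2] == 0)) return(1)
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }
  f <- lib * vapply(seq_len(ncol(m)), tmm_one, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  f
}

#' Method-of-moments common dispersion for count pairs
#'
#' For gene-wise count pairs assumed equal-mean within a gene, the first
#' count given the pair total is beta-binomial with both shapes `1/d`; the
#' expected value of `(x1 - x2)^2 / n` is then `1 + (n - 1) d / (d + 2)`.
#' Averaging `((x1 - x2)^2 / n - 1) / (n - 1)` across genes estimates
#' `phi = d / (d + 2)`, inverted and floored at zero. Under Poisson (or
#' binomial-split) counts the estimate is ~0.
#'
#' @param count_pairs Two-column matrix or data.frame of non-negative counts.
#' @return Common negative-binomial dispersion (>= 0).
#' @export
estimate_dispersion <- function(count_pairs) {
  m <- as.matrix(count_pairs)
  stopifnot(ncol(m) == 2)
  if (nrow(m) < 20) {
    stop("need >= 20 genes to estimate dispersion; pass a fixed dispersion instead")
  }
  n <- m[, 1] + m[, 2]
  keep <- n >= 2
  if (!any(keep)) return(0)
  t_stat <- (m[keep, 1] - m[keep, 2])^2 / n[keep]
  phi <- mean((t_stat - 1) / (n[keep] - 1))
  if (!is.finite(phi) || phi <= 0) return(0)
  phi <- min(phi, 0.999)
  2 * phi / (1 - phi)
}

#' Negative-binomial exact test for allelic expression bias
#'
#' Counts are scaled by the per-allele TMM factors, rounded, and tested with
#' the exact conditional negative-binomial pair test at the supplied common
#' dispersion. A gene is called biased only when the p-value is below
#' `alpha` *and* the normalised fold change reaches `fold_threshold`;
#' direction follows the larger normalised count.
#'
#' @param gene_counts data.frame with gene_id, maternal, paternal.
#' @param factors Length-2 numeric: TMM factors for (maternal, paternal).
#' @param dispersion Common NB dispersion.
#' @param fold_threshold Minimum normalised fold change (default 1.5).
#' @param alpha Significance level (default 0.05).
#' @return data.frame with gene_id, maternal, paternal, norm_maternal,
#'   norm_paternal, log2_fold (maternal over paternal), p_value, klass in
#'   MATERNAL_BIAS / PATERNAL_BIAS / NONE.
#' @export
allelic_bias_test <- function(gene_counts, factors = c(1, 1), dispersion = 0,
                              fold_threshold = 1.5, alpha = 0.05) {
  stopifnot(length(factors) == 2, all(factors > 0), dispersion >= 0)
  nm <- gene_counts$maternal / factors[1]
  np <- gene_counts$paternal / factors[2]
  xm <- round(nm); xp <- round(np)
  p <- mapply(nb_exact_pair_test, xm, xp,
              MoreArgs = list(dispersion = dispersion))
  fold <- pmax(nm, np) / pmin(nm, np)   # Inf when one allele is 0, NaN when both
  log2_fold <- log2((nm + 0.5) / (np + 0.5))
  klass <- rep("NONE", nrow(gene_counts))
  biased <- p < alpha & !is.nan(fold) & fold >= fold_threshold
  klass[biased & nm > np] <- "MATERNAL_BIAS"
  klass[biased & np > nm] <- "PATERNAL_BIAS"
  data.frame(gene_id = gene_counts$gene_id, maternal = gene_counts$maternal,
             paternal = gene_counts$paternal, norm_maternal = nm,
             norm_paternal = np, log2_fold = log2_fold, p_value = p,
             klass = klass, stringsAsFactors = FALSE)
}

#' Regression of allelic on total expression
#'
#' Ordinary least squares of log2(allelic + 1) on log2(total + 1).
#'
#' @param allelic Per-gene allelic counts (one allele).
#' @param total Per-gene total counts.
#' @param log_transformed Set TRUE when inputs are already log2 scale.
#' @return List with slope, intercept, r_squared.
#' @export
allelic_total_regression <- function(allelic, total, log_transformed = FALSE) {
  stopifnot(length(allelic) == length(total))
  if (length(allelic) < 3) stop("need at least 3 points")
  x <- if (log_transformed) total else log2(total + 1)
  y <- if (log_transformed) allelic else log2(allelic + 1)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  fit <- stats::lm(y ~ x)
  # collinear input is a legitimate degenerate case; silence the perfect-fit
  # warning from summary.lm
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Summarise allelic-bias calls
#'
#' @param calls data.frame from [allelic_bias_test()].
#' @return List with `counts` (named tally per class), `n_biased`, and
#'   `volcano` (gene_id, log2_fold, neg_log10_p) for plotting.
#' @export
bias_summary <- function(calls) {
  classes <- c("MATERNAL_BIAS", "PATERNAL_BIAS", "NONE")
  counts <- vapply(classes, function(k) sum(calls$klass == k), numeric(1))
  volcano <- if (nrow(calls)) {
    data.frame(gene_id = calls$gene_id, log2_fold = calls$log2_fold,
               neg_log10_p = -log10(pmax(calls$p_value, 1e-300)),
               klass = calls$klass, stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), log2_fold = numeric(),
               neg_log10_p = numeric(), klass = character(),
               stringsAsFactors = FALSE)
  }
  list(counts = counts,
       n_biased = unname(counts["MATERNAL_BIAS"] + counts["PATERNAL_BIAS"]),
       volcano = volcano)
}
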