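# Global methylome summaries: per-site levels, methylated-site calling
# against the bisulfite conversion-failure rate, context proportions,
# chromosome means and mid-parent values, gene metaplots, element-class
# levels, and the lambda spike-in conversion rate.

#' Per-site methylation level (mC/C ratio)
#'
#' @param records Methylation call data.frame; rows with zero coverage yield
#'   NA (they are excluded by callers upstream).
#' @return Numeric vector of levels in `[0, 1]`.
#' @export
methylation_level <- function(records) {
  ifelse(records$total_count >= 1, records$mc_count / records$total_count,
         NA_real_)
}

#' Call methylated cytosines against the conversion-failure rate
#'
#' A site is called methylated when a one-sided binomial test of its
#' methylated-read count against the conversion-failure rate rejects at
#' `alpha`. Optional Benjamini-Hochberg correction across tested sites.
#'
#' @param methylome Methylation call data.frame.
#' @param fail_rate Probability an unmethylated cytosine reads as methylated
#'   (1 - bisulfite conversion rate).
#' @param alpha Significance level.
#' @param bh Apply BH correction across all covered sites (default FALSE).
#' @return The subset of rows called methylated, with a `p_meth` column.
#' @export
call_methylated_sites <- function(methylome, fail_rate = 0.006, alpha = 0.05,
                                  bh = FALSE) {
  stopifnot(fail_rate >= 0, fail_rate < 1)
  covered <- methylome[methylome$total_count >= 1, , drop = FALSE]
  p <- binom_upper_p(covered$mc_count, covered$total_count, fail_rate)
  if (bh) p <- stats::p.adjust(p, method = "BH")
  covered$p_meth <- p
  covered[p <= alpha, , drop = FALSE]
}

#' Context proportions of methylated cytosines
#'
#' @param methylated_sites data.frame of sites called methylated.
#' @return List with `counts` (named mC tally per context), `total`, and
#'   `proportions` (fractions summing to 1).
#' @export
context_proportions <- function(methylated_sites) {
  if (!nrow(methylated_sites)) stop("no methylated sites supplied")
  counts <- vapply(METH_CONTEXTS, function(cx) {
    sum(methylated_sites$context == cx)
  }, numeric(1))
  list(counts = counts, total = sum(counts), proportions = counts / sum(counts))
}

#' Context proportions from mC tallies
#'
#' Recomputes the proportion of methylated cytosines per context from
#' pre-counted totals (as printed in a summary table).
#'
#' @param counts Named numeric vector with elements CG, CHG, CHH.
#' @return Named proportions in percent, rounded to 2 decimals.
#' @export
context_proportions_from_counts <- function(counts) {
  stopifnot(all(METH_CONTEXTS %in% names(counts)))
  counts <- counts[METH_CONTEXTS]
  as_pct(counts / sum(counts))
}

#' Per-chromosome mean methylation levels
#'
#' Unweighted mean of per-site levels per chromosome for one context,
#' restricted to sites with coverage at least `min_cov`.
#'
#' @param methylome Methylation call data.frame.
#' @param context One of CG, CHG, CHH.
#' @param min_cov Minimum coverage per site (default 4).
#' @return data.frame with chrom, n_sites, mean_level (NA when no site
#'   qualifies).
#' @export
chromosome_mean_levels <- function(methylome, context, min_cov = 4) {
  stopifnot(context %in% METH_CONTEXTS)
  sub <- methylome[methylome$context == context &
                     methylome$total_count >= min_cov, , drop = FALSE]
  chroms <- sort(unique(methylome$chrom))
  lev <- methylation_level(sub)
  out <- data.frame(chrom = chroms,
                    n_sites = vapply(chroms, function(ch) sum(sub$chrom == ch),
                                     numeric(1)),
                    stringsAsFactors = FALSE)
  out$mean_level <- vapply(chroms, function(ch) {
    x <- lev[sub$chrom == ch]
    if (length(x)) mean(x) else NA_real_
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Mid-parent value
#'
#' Arithmetic mean of the maternal and paternal values.
#'
#' @param maternal_level,paternal_level Numeric vectors in `[0, 1]`.
#' @return `(maternal_level + paternal_level) / 2`.
#' @export
mid_parent_value <- function(maternal_level, paternal_level) {
  stopifnot(all(maternal_level >= 0 & maternal_level <= 1, na.rm = TRUE),
            all(paternal_level >= 0 & paternal_level <= 1, na.rm = TRUE))
  (maternal_level + paternal_level) / 2
}

#' Bisulfite conversion rate from a lambda spike-in
#'
#' The unmethylated lambda contig measures chemical conversion efficiency:
#' rate = 1 - (sum mc / sum total) over all lambda cytosines.
#'
#' @param lambda_methylome Methylation calls on the lambda contig.
#' @return Conversion rate in `[0, 1]`.
#' @export
conversion_rate <- function(lambda_methylome) {
  tot <- sum(lambda_methylome$total_count)
  if (tot == 0) stop("lambda contig has zero coverage")
  1 - sum(lambda_methylome$mc_count) / tot
}

#' Gene metaplot profile (upstream / body / downstream)
#'
#' Mean methylation level in fixed-width upstream and downstream flank bins
#' and length-normalised gene-body bins; minus-strand genes are reversed so
#' bin 1 is always the most upstream. Sites are points, so each site falls in
#' exactly one bin even for genes shorter than `n_bins` bp.
#'
#' @param methylome Methylation call data.frame.
#' @param genes Gene annotation data.frame.
#' @param context One of CG, CHG, CHH.
#' @param flank_bp Flank width in bp (default 2000).
#' @param n_bins Bins per region (default 20).
#' @param min_cov Minimum site coverage (default 4).
#' @return data.frame with region (upstream/body/downstream), bin (1-based
#'   within region), mean_level and n_sites.
#' @export
metaplot_profile <- function(methylome, genes, context, flank_bp = 2000,
                             n_bins = 20, min_cov = 4) {
  stopifnot(flank_bp >= 0, n_bins >= 1, context %in% METH_CONTEXTS)
  sub <- methylome[methylome$context == context &
                     methylome$total_count >= min_cov, , drop = FALSE]
  sub$level <- methylation_level(sub)
  sites <- GenomicRanges::GRanges(sub$chrom, IRanges::IRanges(sub$pos, sub$pos))
  ext <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1, genes$start - flank_bp), genes$end + flank_bp))
  hits <- GenomicRanges::findOverlaps(sites, ext)
  si <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  pos <- sub$pos[si]
  gstart <- genes$start[gi]; gend <- genes$end[gi]
  minus <- genes$strand[gi] == "-"
  # Distance upstream of the 5' end is flank; position within body is
  # length-normalised; downstream flank mirrors. Orientation-aware.
  region <- character(length(si)); bin <- integer(length(si))
  in_body <- pos >= gstart & pos <= gend
  before <- pos < gstart   # left flank in genome coordinates
  after <- pos > gend
  frac_body <- (pos - gstart + 0.5) / (gend - gstart + 1)
  frac_body[minus] <- 1 - frac_body[minus]
  region[in_body] <- "body"
  bin[in_body] <- pmin(n_bins, floor(frac_body[in_body] * n_bins) + 1L)
  frac_left <- (pos - (gstart - flank_bp) + 0.5) / flank_bp   # 0 at far left
  frac_right <- (pos - gend - 0.5) / flank_bp                 # 0 at gene end
  region[before & !minus] <- "upstream"
  bin[before & !minus] <- pmin(n_bins, pmax(1L, floor(frac_left[before & !minus] * n_bins) + 1L))
  region[after & !minus] <- "downstream"
  bin[after & !minus] <- pmin(n_bins, pmax(1L, floor(frac_right[after & !minus] * n_bins) + 1L))
  # Minus strand: genomic left flank is downstream, reversed bin order.
  region[before & minus] <- "downstream"
  bin[before & minus] <- pmin(n_bins, pmax(1L, n_bins - floor(frac_left[before & minus] * n_bins)))
  region[after & minus] <- "upstream"
  bin[after & minus] <- pmin(n_bins, pmax(1L, n_bins - floor(frac_right[after & minus] * n_bins)))
  keep <- nzchar(region)
  df <- data.frame(region = region[keep], bin = bin[keep],
                   level = sub$level[si][keep], stringsAsFactors = FALSE)
  grid <- expand.grid(region = c("upstream", "body", "downstream"),
                      bin = seq_len(n_bins), stringsAsFactors = FALSE)
  grid$mean_level <- mapply(function(r, b) {
    x <- df$level[df$region == r & df$bin == b]
    if (length(x)) mean(x) else NA_real_
  }, grid$region, grid$bin)
  grid$n_sites <- mapply(function(r, b) {
    sum(df$region == r & df$bin == b)
  }, grid$region, grid$bin)
  grid[order(match(grid$region, c("upstream", "body", "downstream")), grid$bin), ]
}

#' Mean methylation level per annotated element class
#'
#' Unweighted mean of per-site levels within each class's intervals; a site
#' inside two classes contributes to both.
#'
#' @param methylome Methylation call data.frame.
#' @param element_beds Named list of interval data.frames (chrom, start, end;
#'   1-based inclusive), one per element class.
#' @param context One of CG, CHG, CHH.
#' @param min_cov Minimum site coverage (default 4).
#' @return data.frame with class, n_sites, mean_level (NA for empty classes).
#' @export
element_levels <- function(methylome, element_beds, context, min_cov = 4) {
  stopifnot(context %in% METH_CONTEXTS)
  sub <- methylome[methylome$context == context &
                     methylome$total_count >= min_cov, , drop = FALSE]
  lev <- methylation_level(sub)
  sites <- GenomicRanges::GRanges(sub$chrom, IRanges::IRanges(sub$pos, sub$pos))
  res <- lapply(names(element_beds), function(cls) {
    iv <- element_beds[[cls]]
    if (!nrow(iv)) {
      return(data.frame(class = cls, n_sites = 0L, mean_level = NA_real_,
                        stringsAsFactors = FALSE))
    }
    gr <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start, iv$end))
    inside <- IRanges::overlapsAny(sites, gr)
    data.frame(class = cls, n_sites = sum(inside),
               mean_level = if (any(inside)) mean(lev[inside]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
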