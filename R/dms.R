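# Per-site differential methylation among father (PA), mother (PB) and F1,
# and the eight-way inheritance classification of differentially methylated
# sites (DMSs).
#
# Classes: ADDITIVE, LOW_PARENT, HIGH_PARENT, ABOVE_HIGH_PARENT,
# BELOW_LOW_PARENT (parents differ); ABOVE_PARENT, BELOW_PARENT (parents
# equal); AMBIGUOUS when no branch fits. Significance is a raw two-sided
# Fisher exact p < alpha per pair (default alpha 0.01), with classification
# driven by the pattern of the three pairwise tests plus level ordering.

DMS_CLASSES <- c("ADDITIVE", "LOW_PARENT", "HIGH_PARENT", "ABOVE_HIGH_PARENT",
                 "BELOW_LOW_PARENT", "ABOVE_PARENT", "BELOW_PARENT",
                 "AMBIGUOUS")

#' Fisher exact test for one site in two samples
#'
#' @param mc_a,uc_a Methylated/unmethylated read counts in sample A.
#' @param mc_b,uc_b Counts in sample B.
#' @return Two-sided p-value.
#' @export
fisher_site_test <- function(mc_a, uc_a, mc_b, uc_b) {
  if (mc_a + uc_a == 0 || mc_b + uc_b == 0) {
    stop("each sample needs at least one covering read")
  }
  fisher_exact_2x2(mc_a, uc_a, mc_b, uc_b)
}

#' Build the per-site DMS table for a trio
#'
#' Joins the three samples' records of one context on (chrom, pos, strand),
#' keeps sites covered >= min_cov in all three (low-coverage sites are
#' excluded as untestable, not classed AMBIGUOUS), computes the three
#' pairwise Fisher p-values and classifies every DMS.
#'
#' @param father,mother,f1 Methylation call data.frames (father = PA,
#'   mother = PB).
#' @param context One of CG, CHG, CHH.
#' @param alpha Per-pair significance threshold (default 0.01, uncorrected).
#' @param min_cov Minimum per-site coverage in every sample (default 4).
#' @return data.frame with one row per DMS (at least one pairwise p < alpha):
#'   coordinates, per-sample counts and levels, p_ab, p_fa, p_fb, klass.
#' @export
dms_table <- function(father, mother, f1, context, alpha = 0.01, min_cov = 4) {
  pick <- function(m) m[m$context == context & m$total_count >= min_cov, ]
  a <- pick(father); b <- pick(mother); h <- pick(f1)
  key <- function(m) paste(m$chrom, m$pos, m$strand, sep = ":")
  ia <- match(key(h), key(a)); ib <- match(key(h), key(b))
  keep <- !is.na(ia) & !is.na(ib)
  h <- h[keep, ]; ia <- ia[keep]; ib <- ib[keep]
  df <- data.frame(chrom = h$chrom, pos = h$pos, strand = h$strand,
                   context = context,
                   mc_pa = a$mc_count[ia], total_pa = a$total_count[ia],
                   mc_pb = b$mc_count[ib], total_pb = b$total_count[ib],
                   mc_f1 = h$mc_count, total_f1 = h$total_count,
                   stringsAsFactors = FALSE)
  df$level_pa <- df$mc_pa / df$total_pa
  df$level_pb <- df$mc_pb / df$total_pb
  df$level_f1 <- df$mc_f1 / df$total_f1
  df$p_ab <- fisher_exact_2x2(df$mc_pa, df$total_pa - df$mc_pa,
                              df$mc_pb, df$total_pb - df$mc_pb)
  df$p_fa <- fisher_exact_2x2(df$mc_f1, df$total_f1 - df$mc_f1,
                              df$mc_pa, df$total_pa - df$mc_pa)
  df$p_fb <- fisher_exact_2x2(df$mc_f1, df$total_f1 - df$mc_f1,
                              df$mc_pb, df$total_pb - df$mc_pb)
  dms <- df[df$p_ab < alpha | df$p_fa < alpha | df$p_fb < alpha, , drop = FALSE]
  if (nrow(dms)) {
    dms$klass <- classify_dms(dms, alpha = alpha)
  } else {
    dms$klass <- character(0)
  }
  rownames(dms) <- NULL
  dms
}

#' Classify DMSs into the eight inheritance categories
#'
#' Decision rules (each site must already be a DMS, i.e. have at least one
#' pairwise p < alpha):
#'
#' * Parents differ (`p_ab < alpha`), where low/high is the parent with the
#'   smaller/larger level:
#'   - `ADDITIVE`: F1 differs from both parents and its level lies strictly
#'     between them.
#'   - `LOW_PARENT` / `HIGH_PARENT`: F1 indistinguishable from that parent
#'     but distinguishable from the other.
#'   - `ABOVE_HIGH_PARENT` / `BELOW_LOW_PARENT`: F1 differs from both and
#'     lies above the higher / below the lower parent.
#'   - otherwise `AMBIGUOUS`.
#' * Parents equal (`p_ab >= alpha`):
#'   - `ABOVE_PARENT` / `BELOW_PARENT`: F1 differs from both parents and is
#'     above / below both.
#'   - otherwise `AMBIGUOUS`.
#'
#' @param records data.frame with level_pa, level_pb, level_f1, p_ab, p_fa,
#'   p_fb (as built by [dms_table()]).
#' @param alpha Significance threshold.
#' @return Character vector of classes, one per row.
#' @export
classify_dms <- function(records, alpha = 0.01) {
  is_dms <- records$p_ab < alpha | records$p_fa < alpha | records$p_fb < alpha
  if (any(!is_dms)) stop("classify_dms expects DMS rows only")
  n <- nrow(records)
  klass <- rep("AMBIGUOUS", n)
  lo <- pmin(records$level_pa, records$level_pb)
  hi <- pmax(records$level_pa, records$level_pb)
  p_lo <- ifelse(records$level_pa <= records$level_pb, records$p_fa, records$p_fb)
  p_hi <- ifelse(records$level_pa <= records$level_pb, records$p_fb, records$p_fa)
  f1 <- records$level_f1
  diff_par <- records$p_ab < alpha
  sig_both <- records$p_fa < alpha & records$p_fb < alpha
  klass[diff_par & sig_both & f1 > lo & f1 < hi] <- "ADDITIVE"
  klass[diff_par & p_lo >= alpha & p_hi < alpha] <- "LOW_PARENT"
  klass[diff_par & p_hi >= alpha & p_lo < alpha] <- "HIGH_PARENT"
  klass[diff_par & sig_both & f1 > hi] <- "ABOVE_HIGH_PARENT"
  klass[diff_par & sig_both & f1 < lo] <- "BELOW_LOW_PARENT"
  klass[!diff_par & sig_both & f1 > hi] <- "ABOVE_PARENT"
  klass[!diff_par & sig_both & f1 < lo] <- "BELOW_PARENT"
  klass
}

#' DMS class proportions, globally and per chromosome
#'
#' @param records DMS table with `chrom` and `klass` columns.
#' @param by_chromosome Also tabulate per chromosome (default TRUE).
#' @return data.frame with chrom ("all" for the global row), klass, count,
#'   proportion; proportions sum to 1 within each chrom.
#' @export
dms_class_proportions <- function(records, by_chromosome = TRUE) {
  if (!nrow(records)) stop("no DMS records supplied")
  tab_one <- function(sub, label) {
    counts <- vapply(DMS_CLASSES, function(k) sum(sub$klass == k), numeric(1))
    data.frame(chrom = label, klass = DMS_CLASSES, count = counts,
               proportion = counts / nrow(sub), stringsAsFactors = FALSE)
  }
  out <- tab_one(records, "all")
  if (by_chromosome) {
    for (ch in sort(unique(records$chrom))) {
      out <- rbind(out, tab_one(records[records$chrom == ch, ], ch))
    }
  }
  rownames(out) <- NULL
  out
}

#' Directional pairwise-difference set memberships and intersection counts
#'
#' The six sets are the significant directional differences of the three
#' pairs: PA<PB, PA>PB, PA<F1, PA>F1, PB<F1, PB>F1 (significance at `alpha`
#' on the corresponding pairwise test). Returns per-site membership flags and
#' the count of every observed intersection pattern (an upset-plot table).
#'
#' @param records DMS table from [dms_table()].
#' @param alpha Significance threshold (default 0.01).
#' @return List with `membership` (logical matrix, one column per set) and
#'   `intersections` (data.frame pattern/count).
#' @export
upset_counts <- function(records, alpha = 0.01) {
  m <- cbind(
    `PA<PB` = records$p_ab < alpha & records$level_pa < records$level_pb,
    `PA>PB` = records$p_ab < alpha & records$level_pa > records$level_pb,
    `PA<F1` = records$p_fa < alpha & records$level_pa < records$level_f1,
    `PA>F1` = records$p_fa < alpha & records$level_pa > records$level_f1,
    `PB<F1` = records$p_fb < alpha & records$level_pb < records$level_f1,
    `PB>F1` = records$p_fb < alpha & records$level_pb > records$level_f1)
  pat <- apply(m, 1, function(r) paste(colnames(m)[r], collapse = "&"))
  tab <- table(pattern = pat[nzchar(pat)])
  inter <- as.data.frame(tab, responseName = "count", stringsAsFactors = FALSE)
  list(membership = m, intersections = inter)
}
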