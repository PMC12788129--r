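# Sliding-window differential methylation between two samples and
# classification of parental-DMR inheritance in the F1 by interval overlap.
#
# A DMR is a (merged run of) window(s) with >= min_sites covered context
# sites in both samples, a >= 2-fold difference in pooled methylation level
# and a two-sided Fisher exact p <= 0.05 on the pooled 2x2 read-count table.

#' Default DMR calling parameters
#'
#' Window geometry is not fixed by any published convention for this method;
#' defaults follow common WGBS practice (1 kb windows, 100 bp step, >= 5
#' context sites with >= 4x coverage in both samples).
#'
#' @param window_bp Window width in bp.
#' @param step_bp Step between window starts in bp.
#' @param min_sites Minimum covered context sites per window, per sample.
#' @param min_cov Minimum per-site coverage in each sample.
#' @param min_fold Minimum pooled-level fold change.
#' @param max_p Fisher p-value threshold.
#' @param epsilon Pseudo-level added to both pooled levels in the fold ratio.
#' @return Named list of parameters.
#' @export
dmr_params <- function(window_bp = 1000, step_bp = 100, min_sites = 5,
                       min_cov = 4, min_fold = 2, max_p = 0.05,
                       epsilon = 0.001) {
  stopifnot(window_bp >= step_bp, step_bp >= 1, min_sites >= 1, min_cov >= 1)
  list(window_bp = window_bp, step_bp = step_bp, min_sites = min_sites,
       min_cov = min_cov, min_fold = min_fold, max_p = max_p,
       epsilon = epsilon)
}

# Inner-join the two samples' records of one context on (chrom, pos, strand),
# keeping sites covered >= min_cov in both.
.shared_sites <- function(meth_a, meth_b, context, min_cov) {
  a <- meth_a[meth_a$context == context & meth_a$total_count >= min_cov, ]
  b <- meth_b[meth_b$context == context & meth_b$total_count >= min_cov, ]
  key_a <- paste(a$chrom, a$pos, a$strand, sep = ":")
  key_b <- paste(b$chrom, b$pos, b$strand, sep = ":")
  i <- match(key_a, key_b)
  keep <- !is.na(i)
  data.frame(chrom = a$chrom[keep], pos = a$pos[keep], strand = a$strand[keep],
             mc_a = a$mc_count[keep], total_a = a$total_count[keep],
             mc_b = b$mc_count[i[keep]], total_b = b$total_count[i[keep]],
             stringsAsFactors = FALSE)
}

#' Build sliding windows with pooled counts for a sample pair
#'
#' Windows step along each chromosome; a window is kept when it holds at
#' least `min_sites` sites of the requested context covered in both samples.
#' Pooled methylated/total read counts per sample are attached.
#'
#' @param meth_a,meth_b Methylation call data.frames for the two samples.
#' @param context One of CG, CHG, CHH.
#' @param params Parameter list from [dmr_params()].
#' @return data.frame of windows: chrom, start, end, n_sites, mc_a, total_a,
#'   mc_b, total_b.
#' @export
make_windows <- function(meth_a, meth_b, context, params = dmr_params()) {
  sh <- .shared_sites(meth_a, meth_b, context, params$min_cov)
  out <- list()
  for (ch in sort(unique(sh$chrom))) {
    s <- sh[sh$chrom == ch, ]
    s <- s[order(s$pos), ]
    if (!nrow(s)) next
    last_start <- max(1, max(s$pos) - params$window_bp + 1)
    starts <- seq(1, last_start + params$step_bp - 1, by = params$step_bp)
    ends <- starts + params$window_bp - 1
    # cumulative sums over position-sorted sites allow O(1) window pooling
    cs_mc_a <- cumsum(s$mc_a); cs_t_a <- cumsum(s$total_a)
    cs_mc_b <- cumsum(s$mc_b); cs_t_b <- cumsum(s$total_b)
    lo <- findInterval(starts - 1, s$pos)   # sites strictly before window
    hi <- findInterval(ends, s$pos)         # sites up to window end
    n <- hi - lo
    keep <- n >= params$min_sites
    if (!any(keep)) next
    at <- function(cs, i) ifelse(i == 0, 0, cs[pmax(i, 1)])
    out[[ch]] <- data.frame(
      chrom = ch, start = starts[keep], end = ends[keep], n_sites = n[keep],
      mc_a = at(cs_mc_a, hi[keep]) - at(cs_mc_a, lo[keep]),
      total_a = at(cs_t_a, hi[keep]) - at(cs_t_a, lo[keep]),
      mc_b = at(cs_mc_b, hi[keep]) - at(cs_mc_b, lo[keep]),
      total_b = at(cs_t_b, hi[keep]) - at(cs_t_b, lo[keep]),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_sites = numeric(), mc_a = numeric(), total_a = numeric(),
                      mc_b = numeric(), total_b = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Test windows for differential methylation
#'
#' Two-sided Fisher exact test on each window's pooled 2x2 table
#' (methylated vs unmethylated reads in samples A and B), plus pooled levels
#' and the level fold change `(level_a + eps) / (level_b + eps)` (or its
#' inverse, whichever is >= 1, with the direction recorded).
#'
#' @param windows Window data.frame from [make_windows()].
#' @param epsilon Pseudo-level guarding against division by zero.
#' @return The windows with level_a, level_b, fold_change, direction
#'   (`"a>b"`/`"a<b"`), p_value appended. Windows with zero pooled total in
#'   either sample are dropped.
#' @export
test_window <- function(windows, epsilon = 0.001) {
  windows <- windows[windows$total_a > 0 & windows$total_b > 0, , drop = FALSE]
  if (!nrow(windows)) {
    windows$level_a <- windows$level_b <- windows$fold_change <- numeric(0)
    windows$direction <- character(0)
    windows$p_value <- numeric(0)
    return(windows)
  }
  windows$level_a <- windows$mc_a / windows$total_a
  windows$level_b <- windows$mc_b / windows$total_b
  ratio <- (windows$level_a + epsilon) / (windows$level_b + epsilon)
  windows$fold_change <- pmax(ratio, 1 / ratio)
  windows$direction <- ifelse(windows$level_a >= windows$level_b, "a>b", "a<b")
  windows$p_value <- fisher_exact_2x2(windows$mc_a,
                                      windows$total_a - windows$mc_a,
                                      windows$mc_b,
                                      windows$total_b - windows$mc_b)
  windows
}

#' Call differentially methylated regions between two samples
#'
#' Significant windows (p <= max_p, fold >= min_fold) are merged when
#' overlapping or book-ended with the same direction; each merged DMR reports
#' recomputed pooled levels over its extent and the minimum window p. Merged
#' regions whose recomputed pooled statistics no longer meet the thresholds
#' are dropped, so every emitted DMR satisfies all three criteria.
#'
#' @param meth_a,meth_b Methylation call data.frames.
#' @param context One of CG, CHG, CHH.
#' @param params Parameter list from [dmr_params()].
#' @return data.frame of DMRs: chrom, start, end, context, n_sites, level_a,
#'   level_b, fold_change, direction, p_value.
#' @export
call_dmrs <- function(meth_a, meth_b, context, params = dmr_params()) {
  win <- test_window(make_windows(meth_a, meth_b, context, params),
                     params$epsilon)
  sig <- win[win$p_value <= params$max_p &
               win$fold_change >= params$min_fold, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      context = character(), n_sites = numeric(),
                      level_a = numeric(), level_b = numeric(),
                      fold_change = numeric(), direction = character(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  sh <- .shared_sites(meth_a, meth_b, context, params$min_cov)
  out <- list()
  for (dir in unique(sig$direction)) {
    sd_ <- sig[sig$direction == dir, ]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      sd_$chrom, IRanges::IRanges(sd_$start, sd_$end)))
    merged <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                         start = GenomicRanges::start(gr),
                         end = GenomicRanges::end(gr),
                         stringsAsFactors = FALSE)
    # min window p within each merged region
    wgr <- GenomicRanges::GRanges(sd_$chrom, IRanges::IRanges(sd_$start, sd_$end))
    hit <- GenomicRanges::findOverlaps(wgr, gr)
    minp <- tapply(sd_$p_value[S4Vectors::queryHits(hit)],
                   S4Vectors::subjectHits(hit), min)
    merged$p_value <- as.numeric(minp[as.character(seq_len(nrow(merged)))])
    # recompute pooled levels over the merged extent
    for (i in seq_len(nrow(merged))) {
      s <- sh[sh$chrom == merged$chrom[i] & sh$pos >= merged$start[i] &
                sh$pos <= merged$end[i], ]
      merged$n_sites[i] <- nrow(s)
      merged$level_a[i] <- sum(s$mc_a) / sum(s$total_a)
      merged$level_b[i] <- sum(s$mc_b) / sum(s$total_b)
    }
    ratio <- (merged$level_a + params$epsilon) / (merged$level_b + params$epsilon)
    merged$fold_change <- pmax(ratio, 1 / ratio)
    merged$direction <- dir
    merged$context <- context
    keep <- merged$fold_change >= params$min_fold &
      merged$p_value <= params$max_p & merged$n_sites >= params$min_sites &
      ((dir == "a>b") == (merged$level_a >= merged$level_b))
    out[[dir]] <- merged[keep, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) return(empty)
  res <- res[order(res$chrom, res$start), c("chrom", "start", "end", "context",
                                            "n_sites", "level_a", "level_b",
                                            "fold_change", "direction",
                                            "p_value")]
  rownames(res) <- NULL
  res
}

#' Classify parental-DMR inheritance in the F1
#'
#' For DMR sets called as father-vs-mother (`parental`), F1-vs-father and
#' F1-vs-mother (all with sample A first: father, F1, F1 respectively), a
#' parental DMR is `LIKE_FATHER` when it overlaps (>= 1 bp) an F1-vs-mother
#' DMR whose direction matches the parental difference and overlaps no
#' F1-vs-father DMR; `LIKE_MOTHER` symmetrically; otherwise `UNRESOLVED`.
#'
#' @param parental DMRs from `call_dmrs(father, mother, ...)`.
#' @param f1_vs_father DMRs from `call_dmrs(f1, father, ...)`.
#' @param f1_vs_mother DMRs from `call_dmrs(f1, mother, ...)`.
#' @return List with `calls` (parental DMRs plus a `category` column) and
#'   `venn` (per-source-set counts by overlap pattern with the other two
#'   sets).
#' @export
classify_dmr_inheritance <- function(parental, f1_vs_father, f1_vs_mother) {
  gr <- function(d) GenomicRanges::GRanges(d$chrom,
                                           IRanges::IRanges(d$start, d$end))
  overlaps_consistent <- function(dmrs, others, flip) {
    # flip = TRUE when consistency means opposite direction labels
    if (!nrow(dmrs) || !nrow(others)) {
      return(list(any = rep(FALSE, nrow(dmrs)),
                  consistent = rep(FALSE, nrow(dmrs))))
    }
    # DMR sets may live on disjoint chromosome sets; that is a valid
    # no-overlap outcome, not a warning condition
    h <- suppressWarnings(GenomicRanges::findOverlaps(gr(dmrs), gr(others)))
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    ok <- if (flip) dmrs$direction[qi] != others$direction[si]
          else dmrs$direction[qi] == others$direction[si]
    list(any = seq_len(nrow(dmrs)) %in% qi,
         consistent = seq_len(nrow(dmrs)) %in% qi[ok])
  }
  # parental direction "a>b" = father > mother. F1 like father then implies
  # f1 > mother, i.e. F1-vs-mother direction "a>b" (same label); F1 like
  # mother implies f1 < father, i.e. F1-vs-father direction "a<b" (opposite).
  vm <- overlaps_consistent(parental, f1_vs_mother, flip = FALSE)
  vf <- overlaps_consistent(parental, f1_vs_father, flip = TRUE)
  category <- rep("UNRESOLVED", nrow(parental))
  category[vm$consistent & !vf$any] <- "LIKE_FATHER"
  category[vf$consistent & !vm$any] <- "LIKE_MOTHER"
  calls <- parental
  calls$category <- category
  sets <- list(parental = parental, f1_vs_father = f1_vs_father,
               f1_vs_mother = f1_vs_mother)
  venn <- do.call(rbind, lapply(names(sets), function(nm) {
    d <- sets[[nm]]
    others <- setdiff(names(sets), nm)
    if (!nrow(d)) {
      return(data.frame(set = character(0), pattern = character(0),
                        count = integer(0), stringsAsFactors = FALSE))
    }
    o1 <- suppressWarnings(IRanges::overlapsAny(gr(d), gr(sets[[others[1]]])))
    o2 <- suppressWarnings(IRanges::overlapsAny(gr(d), gr(sets[[others[2]]])))
    pat <- paste0(nm,
                  ifelse(o1, paste0("&", others[1]), ""),
                  ifelse(o2, paste0("&", others[2]), ""))
    as.data.frame(table(pattern = pat), responseName = "count",
                  stringsAsFactors = FALSE) |>
      (\(x) cbind(set = nm, x))()
  }))
  rownames(venn) <- NULL
  list(calls = calls, venn = venn)
}

#' Fraction of parental DMRs in an inheritance category
#'
#' @param calls DMR inheritance calls (data.frame with a `category` column).
#' @param category One of LIKE_FATHER, LIKE_MOTHER, UNRESOLVED.
#' @return Percentage to 2 decimal places.
#' @export
transmitted_fraction <- function(calls, category) {
  if (!nrow(calls)) stop("no DMR inheritance calls supplied")
  as_pct(sum(calls$category == category) / nrow(calls))
}
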