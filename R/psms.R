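# Parent-specific methylation site (PSMS) identification: the five-rule
# mutual-verification procedure combining the trio genotypes (resequencing)
# with the trio methylomes (WGBS) and the allele-resolved F1 methylation.
#
# A PSMS is a cytosine present in only one parent's genome (C<->non-C SNP)
# that is methylated in the F1, with all methylation support on the
# cytosine-carrying allele.

#' Identify parent-specific methylation sites
#'
#' Applies the five conjunctive rules to every allele-resolved F1 candidate
#' site:
#'
#' 1. (i) the parents are homozygous for different alleles at the SNP, with
#'    a cytosine base (C or G) in exactly one parent;
#' 2. (ii) the F1 is heterozygous carrying exactly the two parental alleles;
#' 3. (iii) the genotype calls are consistent with the WGBS data: the
#'    cytosine-carrying parent's methylome has a record at the position and
#'    strand, the other parent's has none (bisulfite reads cannot genotype a
#'    C/T variant directly, so presence/absence concordance of methylome
#'    records stands in for sequence-level consistency);
#' 4. (iv) methylation support attributed to the non-cytosine allele in the
#'    F1 is exactly zero;
#' 5. (v) the F1 cytosine is called methylated by the one-sided binomial
#'    test against the conversion-failure rate at `alpha` (on the merged F1
#'    record at the site).
#'
#' @param variants Trio variant data.frame from [read_vcf_minimal()].
#' @param meth_mother,meth_father Parental methylomes.
#' @param meth_f1 F1 methylome (merged over alleles).
#' @param f1_allele_meth Allele-resolved F1 methylation table
#'   ([read_allele_meth_table()] format).
#' @param fail_rate Conversion-failure rate for rule (v) (default 0.006).
#' @param alpha Significance level for rule (v) (default 0.05).
#' @param samples Named vector mapping roles to VCF sample names.
#' @param rules Subset of rules to apply (default all five); used for
#'   ablation analyses.
#' @return data.frame of PSMS calls with chrom, pos, strand, context,
#'   origin_parent, mc_count, total_count (F1 merged record), the five rule
#'   flags, and a `candidates` attribute with all evaluated sites.
#' @export
identify_psms <- function(variants, meth_mother, meth_father, meth_f1,
                          f1_allele_meth, fail_rate = 0.006, alpha = 0.05,
                          samples = c(mother = "mother", father = "father",
                                      f1 = "f1"),
                          rules = 1:5) {
  if (is.null(f1_allele_meth) || !nrow(f1_allele_meth)) {
    stop("allele-resolved F1 methylation table is required (rule iv)")
  }
  cand <- f1_allele_meth
  key <- function(chrom, pos) paste(chrom, pos, sep = ":")
  vkey <- key(variants$chrom, variants$pos)
  iv <- match(key(cand$chrom, cand$pos), vkey)
  gt <- function(role) variants[[paste0("gt_", samples[[role]])]][iv]
  gm <- gt("mother"); gf <- gt("father"); gh <- gt("f1")
  has_var <- !is.na(iv)
  ref <- variants$ref[iv]; alt <- variants$alt[iv]
  hom_diff <- has_var & !is.na(gm) & !is.na(gf) &
    gm %in% c("hom_ref", "hom_alt") & gf %in% c("hom_ref", "hom_alt") &
    gm != gf
  mother_base <- ifelse(gm == "hom_ref", ref, alt)
  father_base <- ifelse(gf == "hom_ref", ref, alt)
  is_c <- function(base, strand) {
    (strand == "+" & base == "C") | (strand == "-" & base == "G")
  }
  mother_c <- is_c(mother_base, cand$strand)
  father_c <- is_c(father_base, cand$strand)
  rule1 <- hom_diff & xor(mother_c, father_c)
  origin <- ifelse(mother_c & !father_c, "mother",
                   ifelse(father_c & !mother_c, "father", NA_character_))
  rule2 <- has_var & !is.na(gh) & gh == "het"
  mkey <- function(m) paste(m$chrom, m$pos, m$strand, sep = ":")
  ckey <- mkey(cand)
  in_mother <- ckey %in% mkey(meth_mother)
  in_father <- ckey %in% mkey(meth_father)
  rule3 <- ifelse(is.na(origin), FALSE,
                  ifelse(origin == "mother", in_mother & !in_father,
                         in_father & !in_mother))
  rule4 <- cand$mc_nonc == 0
  f1i <- match(ckey, mkey(meth_f1))
  mc_f1 <- meth_f1$mc_count[f1i]
  total_f1 <- meth_f1$total_count[f1i]
  rule5 <- !is.na(f1i) & total_f1 >= 1 &
    binom_upper_p(ifelse(is.na(mc_f1), 0, mc_f1),
                  ifelse(is.na(total_f1), 0, total_f1), fail_rate) <= alpha
  flags <- cbind(rule_i = rule1, rule_ii = rule2, rule_iii = rule3,
                 rule_iv = rule4, rule_v = rule5)
  pass <- rowSums(flags[, rules, drop = FALSE]) == length(rules)
  out <- data.frame(chrom = cand$chrom, pos = cand$pos, strand = cand$strand,
                    context = cand$context, origin_parent = origin,
                    mc_count = mc_f1, total_count = total_f1,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(flags))
  res <- out[pass & !is.na(origin), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "candidates") <- out
  res
}

#' Assign PSMSs to genes
#'
#' A PSMS is assigned to every gene whose span extended by `flank_bp`
#' contains it (multi-assignment allowed).
#'
#' @param psms PSMS data.frame from [identify_psms()].
#' @param annotation Gene annotation data.frame.
#' @param flank_bp Flank in bp added to both gene ends (default 2000).
#' @return data.frame with gene_id, chrom, pos, strand, origin_parent; one
#'   row per (PSMS, gene) assignment.
#' @export
assign_psms_to_genes <- function(psms, annotation, flank_bp = 2000) {
  if (!nrow(psms) || !nrow(annotation)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      pos = numeric(), strand = character(),
                      origin_parent = character(), stringsAsFactors = FALSE))
  }
  sgr <- GenomicRanges::GRanges(psms$chrom, IRanges::IRanges(psms$pos, psms$pos))
  ggr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(pmax(1, annotation$start - flank_bp),
                     annotation$end + flank_bp))
  h <- GenomicRanges::findOverlaps(sgr, ggr)
  qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
  out <- data.frame(gene_id = annotation$gene_id[si], chrom = psms$chrom[qi],
                    pos = psms$pos[qi], strand = psms$strand[qi],
                    origin_parent = psms$origin_parent[qi],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Precision and recall of PSMS calls against simulation ground truth
#'
#' Set comparison on (chrom, pos, origin). Truth is restricted to sites
#' whose true cytosine-allele propensity exceeds `min_propensity`, so recall
#' is measured against sites that are genuinely methylated.
#'
#' @param psms PSMS calls.
#' @param ground_truth Truth table from the simulator (`truth$psms`).
#' @param min_propensity Truth methylation-propensity cutoff for the recall
#'   denominator (default 0.5).
#' @return List with precision, recall, n_called, n_true.
#' @export
psms_precision_on_truth <- function(psms, ground_truth, min_propensity = 0.5) {
  called <- paste(psms$chrom, psms$pos, psms$origin_parent, sep = ":")
  all_true <- paste(ground_truth$chrom, ground_truth$pos, ground_truth$origin,
                    sep = ":")
  strong <- all_true[ground_truth$propensity > min_propensity]
  precision <- if (length(called)) mean(called %in% all_true) else NA_real_
  recall <- if (length(strong)) mean(strong %in% called) else NA_real_
  list(precision = precision, recall = recall, n_called = length(called),
       n_true = length(strong))
}
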