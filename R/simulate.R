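# Ground-truthed synthetic trio generator: two diverged parental genomes with
# homozygous SNPs (a configurable fraction creating/destroying a cytosine in
# exactly one parent), beta-distributed per-site methylation propensities,
# Poisson coverage with binomial read counts under bisulfite conversion
# failure, F1 methylomes as fair allele mixtures under region-wise
# inheritance modes, an unmethylated lambda spike-in, and negative-binomial
# allelic expression with a configurable fraction of truly biased genes.

#' Simulation configuration
#'
#' Defaults emulate the sequencing setting the analysis assumes: ~15x
#' Poisson coverage, 0.6% bisulfite conversion failure, context-specific
#' methylation propensities (high CG ~0.8, CHG ~0.7, low CHH ~0.2), SNP rate
#' 0.005/bp with half the SNPs exchanging a cytosine for a non-cytosine base
#' in one parent, and 10% of genes with a true 3-fold allelic expression
#' bias at mean 300 reads per gene.
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_chromosomes,chrom_length Genome shape (default 2 x 250 kb).
#' @param n_genes Number of non-overlapping genes (default 300).
#' @param gene_length Min/max gene length in bp.
#' @param snp_rate Per-bp probability of a homozygous-different SNP.
#' @param c_snp_fraction Fraction of SNPs that are C<->non-C.
#' @param coverage Mean Poisson read depth per cytosine.
#' @param conversion_failure Probability an unmethylated C reads methylated.
#' @param beta_params Named list of Beta(shape1, shape2) per context for
#'   parental methylation propensities.
#' @param inheritance_weights Mixture over region inheritance modes
#'   (additive, maternal_like, paternal_like, above_parent, below_parent);
#'   must sum to 1.
#' @param region_bp Width of the regions carrying one inheritance mode.
#' @param trans_delta Propensity shift for transgressive regions.
#' @param dmr_region_rate Fraction of regions with regional methylation
#'   divergence between the parents (one parent shifted high, the other
#'   low), the substrate for parental DMRs.
#' @param dmr_effect Strength of the regional divergence shift in (0, 1].
#' @param aei_fraction Fraction of genes with true allelic expression bias.
#' @param aei_fold True maternal:paternal (or inverse) expression fold.
#' @param rna_mean Mean reads per gene per PSNP site.
#' @param rna_dispersion Gene-level negative-binomial dispersion of totals.
#' @param lambda_length Length of the unmethylated lambda spike-in contig.
#' @return Validated configuration list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_chromosomes = 2, chrom_length = 250000,
                       n_genes = 300, gene_length = c(500, 1200),
                       snp_rate = 0.005, c_snp_fraction = 0.5, coverage = 15,
                       conversion_failure = 0.006,
                       beta_params = list(CG = c(4, 1), CHG = c(3.5, 1.5),
                                          CHH = c(1, 4)),
                       inheritance_weights = c(additive = 0.6,
                                               maternal_like = 0.15,
                                               paternal_like = 0.15,
                                               above_parent = 0.05,
                                               below_parent = 0.05),
                       region_bp = 10000, trans_delta = 0.3,
                       dmr_region_rate = 0.2, dmr_effect = 0.7,
                       aei_fraction = 0.1, aei_fold = 3, rna_mean = 300,
                       rna_dispersion = 0.1, lambda_length = 20000) {
  cfg <- as.list(environment())
  stopifnot(seed == round(seed), n_chromosomes >= 1, chrom_length >= 1000,
            snp_rate >= 0, snp_rate <= 1, c_snp_fraction >= 0,
            c_snp_fraction <= 1, coverage > 0, conversion_failure >= 0,
            conversion_failure < 1, aei_fraction >= 0, aei_fraction <= 1,
            aei_fold >= 1, rna_mean > 0, rna_dispersion >= 0,
            trans_delta >= 0, trans_delta <= 1, dmr_region_rate >= 0,
            dmr_region_rate <= 1, dmr_effect > 0, dmr_effect <= 1)
  if (abs(sum(inheritance_weights) - 1) > 1e-8) {
    stop("inheritance_weights must sum to 1")
  }
  if (!all(METH_CONTEXTS %in% names(beta_params))) {
    stop("beta_params needs entries for CG, CHG and CHH")
  }
  class(cfg) <- "sim_config"
  cfg
}

.rand_seq <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# Cytosine sites of one chromosome sequence (character vector), both strands,
# with context read 5'->3' on the site's own strand. Sites within 2 bp of
# either chromosome end are dropped.
.cytosine_sites <- function(seq) {
  L <- length(seq)
  if (L < 5) {
    return(data.frame(pos = integer(), strand = character(),
                      context = character(), stringsAsFactors = FALSE))
  }
  plus <- which(seq == "C")
  plus <- plus[plus <= L - 2]
  ctx_p <- ifelse(seq[plus + 1] == "G", "CG",
                  ifelse(seq[plus + 2] == "G", "CHG", "CHH"))
  minus <- which(seq == "G")
  minus <- minus[minus >= 3]
  ctx_m <- ifelse(seq[minus - 1] == "C", "CG",
                  ifelse(seq[minus - 2] == "C", "CHG", "CHH"))
  out <- data.frame(pos = c(plus, minus),
                    strand = rep(c("+", "-"), c(length(plus), length(minus))),
                    context = c(ctx_p, ctx_m), stringsAsFactors = FALSE)
  out[order(out$pos, out$strand), ]
}

#' Simulate two diverged parental genomes, their trio VCF and genes
#'
#' Parents are homozygous-different at every emitted variant and the F1 is
#' heterozygous. A fraction `c_snp_fraction` of variants places a cytosine
#' (C on the plus or G giving a minus-strand cytosine) in exactly one parent
#' and a non-cytosine base (A/T) in the other; the remaining variants are
#' A<->T swaps that leave cytosine content untouched. The mother's genome is
#' the reference (ref allele maternal, alt paternal).
#'
#' @param config A [sim_config()].
#' @return List with `genomes` (per parent, list of chromosome base
#'   vectors), `lambda_seq`, `variants` (trio VCF data.frame with a
#'   `snp_truth` attribute giving type and origin per SNP), `genes`.
#' @export
simulate_parental_genomes <- function(config) {
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  mother <- father <- stats::setNames(vector("list", length(chroms)), chroms)
  var_rows <- list()
  for (ch in chroms) {
    L <- config$chrom_length
    seq_m <- .rand_seq(L)
    seq_f <- seq_m
    pos <- which(stats::runif(L) < config$snp_rate)
    # keep SNPs away from chromosome ends so contexts are well-defined
    pos <- pos[pos > 2 & pos <= L - 2]
    if (length(pos)) {
      is_c <- stats::runif(length(pos)) < config$c_snp_fraction
      origin <- ifelse(stats::runif(length(pos)) < 0.5, "mother", "father")
      for (i in seq_along(pos)) {
        p <- pos[i]
        if (is_c[i]) {
          c_base <- sample(c("C", "G"), 1)
          o_base <- sample(c("A", "T"), 1)
          if (origin[i] == "mother") {
            seq_m[p] <- c_base; seq_f[p] <- o_base
          } else {
            seq_m[p] <- o_base; seq_f[p] <- c_base
          }
        } else {
          seq_m[p] <- sample(c("A", "T"), 1)
          seq_f[p] <- setdiff(c("A", "T"), seq_m[p])
          origin[i] <- NA_character_
        }
      }
      var_rows[[ch]] <- data.frame(
        chrom = ch, pos = pos, ref = seq_m[pos], alt = seq_f[pos],
        gt_mother = "hom_ref", gt_father = "hom_alt", gt_f1 = "het",
        dp_mother = NA_real_, dp_father = NA_real_, dp_f1 = NA_real_,
        snp_type = ifelse(is_c, "c_snp", "at_snp"), c_origin = origin,
        stringsAsFactors = FALSE)
    }
    mother[[ch]] <- seq_m
    father[[ch]] <- seq_f
  }
  variants <- if (length(var_rows)) do.call(rbind, var_rows) else
    data.frame(chrom = character(), pos = numeric(), ref = character(),
               alt = character(), gt_mother = character(),
               gt_father = character(), gt_f1 = character(),
               dp_mother = numeric(), dp_father = numeric(),
               dp_f1 = numeric(), snp_type = character(),
               c_origin = character(), stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  attr(variants, "samples") <- c("mother", "father", "f1")
  genes <- .place_genes(config, chroms)
  list(genomes = list(mother = mother, father = father),
       lambda_seq = .rand_seq(config$lambda_length),
       variants = variants, genes = genes)
}

# Non-overlapping gene placement: genes are spread over chromosomes with
# random lengths and random gaps filling the remaining space.
.place_genes <- function(config, chroms) {
  per <- diff(round(seq(0, config$n_genes, length.out = length(chroms) + 1)))
  rows <- list()
  idx <- 0L
  for (k in seq_along(chroms)) {
    ni <- per[k]
    if (ni == 0) next
    len <- sample(seq(config$gene_length[1], config$gene_length[2]), ni,
                  replace = TRUE)
    space <- config$chrom_length - sum(len)
    if (space < ni + 1) {
      stop("chrom_length too small for n_genes of the requested lengths")
    }
    gaps <- as.vector(stats::rmultinom(1, space, rep(1, ni + 1)))
    starts <- cumsum(gaps[seq_len(ni)] + c(0, len[-ni])) + 1
    rows[[k]] <- data.frame(
      gene_id = sprintf("gene%04d", idx + seq_len(ni)), chrom = chroms[k],
      start = starts, end = starts + len - 1,
      strand = sample(c("+", "-"), ni, replace = TRUE),
      stringsAsFactors = FALSE)
    idx <- idx + ni
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Observed per-read methylation probability under conversion failure.
.obs_p <- function(p, fail) p * (1 - fail) + (1 - p) * fail

#' Simulate the trio methylomes and the lambda spike-in table
#'
#' Every genomic cytosine of each parent receives a Beta-distributed latent
#' methylation propensity (per context); read depth is Poisson and
#' methylated-read counts binomial with the conversion-failure rate mixed
#' in. F1 reads pick an allele by a fair coin; allele propensities follow
#' the region's inheritance mode (additive regions pass parental
#' propensities through unchanged; maternal-/paternal-like regions copy one
#' parent; transgressive regions shift both alleles by `trans_delta`). At a
#' C<->non-C SNP the parent lacking the cytosine emits no record, and F1
#' reads on the non-cytosine allele contribute coverage but never
#' methylation support; those sites are also reported allele-resolved.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_parental_genomes()].
#' @return List with methylomes `mother`, `father`, `f1`, `lambda_meth`,
#'   `f1_allele_meth`, and `truth` (site propensities, region modes, true
#'   parent-specific cytosines with origin).
#' @export
simulate_methylomes <- function(config, sim) {
  set.seed(config$seed + 1L)
  fail <- config$conversion_failure
  draw_prop <- function(ctx) {
    p <- numeric(length(ctx))
    for (cx in METH_CONTEXTS) {
      i <- ctx == cx
      bp <- config$beta_params[[cx]]
      p[i] <- stats::rbeta(sum(i), bp[1], bp[2])
    }
    p
  }
  sample_counts <- function(n, p) {
    cov <- stats::rpois(n, config$coverage)
    mc <- stats::rbinom(n, cov, .obs_p(p, fail))
    list(cov = cov, mc = mc)
  }
  parents <- list(mother = list(), father = list())
  site_tabs <- list(mother = list(), father = list())
  for (par in names(parents)) {
    for (ch in names(sim$genomes[[par]])) {
      s <- .cytosine_sites(sim$genomes[[par]][[ch]])
      s$chrom <- ch
      s$propensity <- draw_prop(s$context)
      site_tabs[[par]][[ch]] <- s
    }
  }
  modes <- names(config$inheritance_weights)
  region_rows <- list()
  meth <- list(mother = list(), father = list(), f1 = list())
  allele_rows <- list()
  truth_psms <- list()
  for (ch in names(sim$genomes$mother)) {
    sm <- site_tabs$mother[[ch]]
    sf <- site_tabs$father[[ch]]
    # region grid: inheritance mode plus regional parental divergence (the
    # substrate for parental DMRs between the two diverged methylomes)
    n_reg <- ceiling(config$chrom_length / config$region_bp)
    rate <- config$dmr_region_rate
    div_state <- sample(c("none", "mother_high", "father_high"), n_reg,
                        replace = TRUE,
                        prob = c(1 - rate, rate / 2, rate / 2))
    reg_mode <- sample(modes, n_reg, replace = TRUE,
                       prob = config$inheritance_weights)
    reg_of <- function(pos) pmin(n_reg, (pos - 1) %/% config$region_bp + 1)
    shift_up <- function(p) 1 - (1 - p) * (1 - config$dmr_effect)
    shift_dn <- function(p) p * (1 - config$dmr_effect)
    st_m <- div_state[reg_of(sm$pos)]
    sm$propensity <- ifelse(st_m == "mother_high", shift_up(sm$propensity),
                            ifelse(st_m == "father_high",
                                   shift_dn(sm$propensity), sm$propensity))
    st_f <- div_state[reg_of(sf$pos)]
    sf$propensity <- ifelse(st_f == "father_high", shift_up(sf$propensity),
                            ifelse(st_f == "mother_high",
                                   shift_dn(sf$propensity), sf$propensity))
    site_tabs$mother[[ch]] <- sm   # truth records the shifted propensities
    site_tabs$father[[ch]] <- sf
    # parental methylomes
    for (par in c("mother", "father")) {
      s <- if (par == "mother") sm else sf
      cnt <- sample_counts(nrow(s), s$propensity)
      meth[[par]][[ch]] <- data.frame(
        chrom = ch, pos = s$pos, strand = s$strand, context = s$context,
        mc_count = cnt$mc, total_count = cnt$cov, stringsAsFactors = FALSE)
    }
    region_rows[[ch]] <- data.frame(
      chrom = ch, start = (seq_len(n_reg) - 1) * config$region_bp + 1,
      end = pmin(seq_len(n_reg) * config$region_bp, config$chrom_length),
      mode = reg_mode, divergence = div_state, stringsAsFactors = FALSE)
    # F1: shared cytosines (both alleles) vs single-allele cytosines
    key_m <- paste(sm$pos, sm$strand)
    key_f <- paste(sf$pos, sf$strand)
    im <- match(key_f, key_m)
    shared_f <- which(!is.na(im))
    shared <- data.frame(pos = sf$pos[shared_f], strand = sf$strand[shared_f],
                         context = sm$context[im[shared_f]],
                         pm = sm$propensity[im[shared_f]],
                         pp = sf$propensity[shared_f],
                         stringsAsFactors = FALSE)
    mode_of <- reg_mode[pmin(n_reg, (shared$pos - 1) %/% config$region_bp + 1)]
    f1m <- shared$pm
    f1p <- shared$pp
    f1m[mode_of == "maternal_like"] <- shared$pm[mode_of == "maternal_like"]
    f1p[mode_of == "maternal_like"] <- shared$pm[mode_of == "maternal_like"]
    f1m[mode_of == "paternal_like"] <- shared$pp[mode_of == "paternal_like"]
    f1p[mode_of == "paternal_like"] <- shared$pp[mode_of == "paternal_like"]
    up <- mode_of == "above_parent"
    f1m[up] <- f1p[up] <- pmin(1, pmax(shared$pm, shared$pp)[up] + config$trans_delta)
    dn <- mode_of == "below_parent"
    f1m[dn] <- f1p[dn] <- pmax(0, pmin(shared$pm, shared$pp)[dn] - config$trans_delta)
    cov <- stats::rpois(nrow(shared), config$coverage)
    cov_m <- stats::rbinom(nrow(shared), cov, 0.5)
    mc <- stats::rbinom(nrow(shared), cov_m, .obs_p(f1m, fail)) +
      stats::rbinom(nrow(shared), cov - cov_m, .obs_p(f1p, fail))
    f1_shared <- data.frame(chrom = ch, pos = shared$pos,
                            strand = shared$strand, context = shared$context,
                            mc_count = mc, total_count = cov,
                            stringsAsFactors = FALSE)
    # single-allele cytosines (C<->non-C SNP sites)
    only_m <- setdiff(seq_len(nrow(sm)), im[shared_f])
    only_f <- which(is.na(im))
    single <- rbind(
      if (length(only_m)) cbind(sm[only_m, c("pos", "strand", "context",
                                             "propensity")],
                                origin = "mother"),
      if (length(only_f)) cbind(sf[only_f, c("pos", "strand", "context",
                                             "propensity")],
                                origin = "father"))
    if (!is.null(single) && nrow(single)) {
      cov <- stats::rpois(nrow(single), config$coverage)
      cov_c <- stats::rbinom(nrow(single), cov, 0.5)
      mc_c <- stats::rbinom(nrow(single), cov_c, .obs_p(single$propensity, fail))
      f1_single <- data.frame(chrom = ch, pos = single$pos,
                              strand = single$strand, context = single$context,
                              mc_count = mc_c, total_count = cov,
                              stringsAsFactors = FALSE)
      allele_rows[[ch]] <- data.frame(
        chrom = ch, pos = single$pos, strand = single$strand,
        context = single$context, origin = single$origin,
        mc_c = mc_c, total_c = cov_c, mc_nonc = 0L,
        total_nonc = cov - cov_c, stringsAsFactors = FALSE)
      truth_psms[[ch]] <- data.frame(
        chrom = ch, pos = single$pos, strand = single$strand,
        origin = single$origin, propensity = single$propensity,
        stringsAsFactors = FALSE)
    } else {
      f1_single <- NULL
    }
    f1_tab <- rbind(f1_shared, f1_single)
    meth$f1[[ch]] <- f1_tab[order(f1_tab$pos, f1_tab$strand), ]
  }
  lam_sites <- .cytosine_sites(sim$lambda_seq)
  lam_cnt <- sample_counts(nrow(lam_sites), rep(0, nrow(lam_sites)))
  lambda_meth <- data.frame(chrom = "lambda", pos = lam_sites$pos,
                            strand = lam_sites$strand,
                            context = lam_sites$context,
                            mc_count = lam_cnt$mc, total_count = lam_cnt$cov,
                            stringsAsFactors = FALSE)
  bind <- function(l) {
    out <- do.call(rbind, l)
    rownames(out) <- NULL
    out
  }
  truth <- list(
    site_propensities = list(mother = bind(site_tabs$mother),
                             father = bind(site_tabs$father)),
    regions = bind(region_rows),
    psms = bind(truth_psms))
  list(mother = bind(meth$mother), father = bind(meth$father),
       f1 = bind(meth$f1), lambda_meth = lambda_meth,
       f1_allele_meth = bind(allele_rows), truth = truth)
}

#' Simulate allele-resolved RNA read counts per PSNP
#'
#' Each gene's latent expression is Gamma-distributed so per-SNP totals are
#' negative-binomial with dispersion `rna_dispersion` around `rna_mean`;
#' reads at each PSNP are assigned to the maternal allele by a binomial draw
#' with probability `aei_fold / (1 + aei_fold)` (or its complement) for the
#' `aei_fraction` of genes with a true bias, and 1/2 otherwise. Genes
#' without any PSNP are excluded and recorded in the truth table.
#'
#' @param config A [sim_config()].
#' @param genes Gene annotation data.frame.
#' @param variants Trio variant data.frame (every row is a usable PSNP).
#' @return List with `allele_depths` (chrom, pos, sample, maternal_reads,
#'   paternal_reads) and `gene_truth` (gene_id, bias_class, true_fold).
#' @export
simulate_allelic_counts <- function(config, genes, variants) {
  set.seed(config$seed + 2L)
  snp <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, variants$pos))
  gn <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  h <- GenomicRanges::findOverlaps(snp, gn, select = "first")
  in_gene <- !is.na(h)
  snp_gene <- genes$gene_id[h[in_gene]]
  v <- variants[in_gene, , drop = FALSE]
  covered_genes <- unique(snp_gene)
  excluded <- setdiff(genes$gene_id, covered_genes)
  bias_class <- rep("NONE", length(covered_genes))
  biased <- stats::runif(length(covered_genes)) < config$aei_fraction
  bias_class[biased] <- sample(c("MATERNAL_BIAS", "PATERNAL_BIAS"),
                               sum(biased), replace = TRUE)
  pi_m <- ifelse(bias_class == "MATERNAL_BIAS",
                 config$aei_fold / (1 + config$aei_fold),
                 ifelse(bias_class == "PATERNAL_BIAS",
                        1 / (1 + config$aei_fold), 0.5))
  lambda <- if (config$rna_dispersion > 0) {
    stats::rgamma(length(covered_genes), shape = 1 / config$rna_dispersion,
                  scale = config$rna_mean * config$rna_dispersion)
  } else {
    rep(config$rna_mean, length(covered_genes))
  }
  gi <- match(snp_gene, covered_genes)
  total <- stats::rpois(nrow(v), lambda[gi])
  mat <- stats::rbinom(nrow(v), total, pi_m[gi])
  allele_depths <- data.frame(chrom = v$chrom, pos = v$pos, sample = "f1",
                              maternal_reads = mat,
                              paternal_reads = total - mat,
                              stringsAsFactors = FALSE)
  gene_truth <- data.frame(gene_id = covered_genes, bias_class = bias_class,
                           true_fold = ifelse(bias_class == "NONE", 1,
                                              config$aei_fold),
                           stringsAsFactors = FALSE)
  attr(gene_truth, "excluded_genes") <- excluded
  if (length(excluded)) {
    message(length(excluded), " gene(s) without PSNPs excluded from allelic counts")
  }
  list(allele_depths = allele_depths, gene_truth = gene_truth)
}

#' Simulate a complete dataset in memory
#'
#' Runs the genome, methylome and allelic-count generators in order under
#' the configuration's seed.
#'
#' @param config A [sim_config()].
#' @return List with all generator outputs: genomes/variants/genes,
#'   methylomes, lambda table, allele-resolved F1 methylation, allele
#'   depths, and ground truth.
#' @export
simulate_dataset <- function(config = sim_config()) {
  g <- simulate_parental_genomes(config)
  m <- simulate_methylomes(config, g)
  a <- simulate_allelic_counts(config, g$genes, g$variants)
  list(config = config, variants = g$variants, genes = g$genes,
       mother = m$mother, father = m$father, f1 = m$f1,
       lambda_meth = m$lambda_meth, f1_allele_meth = m$f1_allele_meth,
       allele_depths = a$allele_depths,
       truth = c(m$truth, list(gene_bias = a$gene_truth)))
}

#' Write a complete simulated dataset to a directory
#'
#' Emits every file the pipeline consumes (methylomes, lambda table, trio
#' VCF, gene annotation, allele depths, allele-resolved F1 methylation) plus
#' ground-truth tables and a JSON manifest listing row counts.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param force Overwrite an existing non-empty directory (default FALSE).
#' @return The manifest, invisibly.
#' @export
emit_dataset <- function(config, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    stop(out_dir, " exists and is not empty (use force = TRUE)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(config)
  p <- function(f) file.path(out_dir, f)
  write_meth_table(ds$mother, p("meth_mother.tsv"))
  write_meth_table(ds$father, p("meth_father.tsv"))
  write_meth_table(ds$f1, p("meth_f1.tsv"))
  write_meth_table(ds$lambda_meth, p("meth_lambda.tsv"))
  write_vcf_minimal(ds$variants, p("trio.vcf"))
  write_gene_table(ds$genes, p("genes.tsv"))
  write_allele_depth_table(ds$allele_depths, p("allele_depths.tsv"))
  write_allele_meth_table(ds$f1_allele_meth, p("f1_allele_meth.tsv"))
  utils::write.table(ds$truth$psms, p("truth_psms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth$gene_bias, p("truth_gene_bias.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth$regions, p("truth_regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c("meth_mother.tsv", "meth_father.tsv", "meth_f1.tsv",
             "meth_lambda.tsv", "trio.vcf", "genes.tsv", "allele_depths.tsv",
             "f1_allele_meth.tsv", "truth_psms.tsv", "truth_gene_bias.tsv",
             "truth_regions.tsv")
  rows <- c(nrow(ds$mother), nrow(ds$father), nrow(ds$f1),
            nrow(ds$lambda_meth), nrow(ds$variants), nrow(ds$genes),
            nrow(ds$allele_depths), nrow(ds$f1_allele_meth),
            nrow(ds$truth$psms), nrow(ds$truth$gene_bias),
            nrow(ds$truth$regions))
  manifest <- list(seed = config$seed,
                   files = stats::setNames(as.list(rows), files))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
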