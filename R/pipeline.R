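# End-to-end orchestration: simulate (optional) -> profile -> dmr -> dms ->
# allelic -> psms -> integrate, with deterministic seeding, per-stage error
# reporting and a JSON run manifest.

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Seed forwarded to the simulator.
#' @param simulate Simulator overrides (list of [sim_config()] arguments),
#'   or NULL to read pre-existing inputs from `inputs`.
#' @param inputs Named list of file paths (meth_mother, meth_father,
#'   meth_f1, lambda, vcf, genes, allele_depths, f1_allele_meth); ignored
#'   when simulating.
#' @param contexts Methylation contexts to analyse.
#' @param min_cov Minimum per-site coverage.
#' @param fail_rate Conversion-failure rate; NULL = estimate from the
#'   lambda spike-in.
#' @param dms_alpha Per-pair DMS significance threshold.
#' @param bias_alpha,bias_fold Allelic-bias test threshold and fold.
#' @param flank_bp PSMS-to-gene assignment flank.
#' @param dmr DMR parameters from [dmr_params()].
#' @return Configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, simulate = list(),
                            inputs = NULL, contexts = METH_CONTEXTS,
                            min_cov = 4, fail_rate = NULL, dms_alpha = 0.01,
                            bias_alpha = 0.05, bias_fold = 1.5,
                            flank_bp = 2000, dmr = dmr_params()) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with [pipeline_config()] fields (nested `simulate`
#'   and `dmr` sections map to [sim_config()] and [dmr_params()] arguments).
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$dmr)) raw$dmr <- do.call(dmr_params, raw$dmr)
  do.call(pipeline_config, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Runs every stage in order and writes all result tables beneath
#' `config$out_dir`, plus `manifest.json` recording the seed, parameters
#' and per-output row counts. Given the same configuration (including seed)
#' the numeric outputs are identical between runs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage's in-memory results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    nrow(df)
  }
  rows <- list()
  # -- stage 1: simulate or load ------------------------------------------
  if (!is.null(config$simulate)) {
    ds <- .stage("simulate", {
      sc <- do.call(sim_config, c(list(seed = config$seed), config$simulate))
      simulate_dataset(sc)
    })
  } else {
    ds <- .stage("load", {
      ins <- config$inputs
      need <- c("meth_mother", "meth_father", "meth_f1", "lambda", "vcf",
                "genes", "allele_depths", "f1_allele_meth")
      missing <- setdiff(need, names(ins))
      if (length(missing)) stop("missing inputs: ", paste(missing, collapse = ", "))
      for (f in unlist(ins)) if (!file.exists(f)) stop("no such file: ", f)
      list(mother = read_meth_table(ins$meth_mother),
           father = read_meth_table(ins$meth_father),
           f1 = read_meth_table(ins$meth_f1),
           lambda_meth = read_meth_table(ins$lambda),
           variants = read_vcf_minimal(ins$vcf),
           genes = read_gene_table(ins$genes),
           allele_depths = read_allele_depth_table(ins$allele_depths),
           f1_allele_meth = read_allele_meth_table(ins$f1_allele_meth),
           truth = NULL)
    })
  }
  # -- stage 2: profile ----------------------------------------------------
  prof <- .stage("profile", {
    conv <- conversion_rate(ds$lambda_meth)
    fail <- if (is.null(config$fail_rate)) 1 - conv else config$fail_rate
    samples <- c("mother", "father", "f1")
    ctx_rows <- lapply(samples, function(s) {
      mc <- call_methylated_sites(ds[[s]], fail_rate = fail)
      cp <- context_proportions(mc)
      data.frame(sample = s, context = METH_CONTEXTS,
                 mc_count = as.numeric(cp$counts),
                 proportion = as.numeric(cp$proportions),
                 stringsAsFactors = FALSE)
    })
    chrom_rows <- list()
    for (cx in config$contexts) {
      lev <- lapply(samples, function(s) {
        chromosome_mean_levels(ds[[s]], cx, min_cov = config$min_cov)
      })
      df <- data.frame(context = cx, chrom = lev[[1]]$chrom,
                       mother = lev[[1]]$mean_level,
                       father = lev[[2]]$mean_level, f1 = lev[[3]]$mean_level,
                       stringsAsFactors = FALSE)
      df$mpv <- mid_parent_value(df$mother, df$father)
      chrom_rows[[cx]] <- df
    }
    meta <- lapply(config$contexts, function(cx) {
      cbind(context = cx,
            metaplot_profile(ds$f1, ds$genes, cx, min_cov = config$min_cov))
    })
    list(conversion_rate = conv, fail_rate = fail,
         context_proportions = do.call(rbind, ctx_rows),
         chromosome_levels = do.call(rbind, chrom_rows),
         metaplot = do.call(rbind, meta))
  })
  rows$context_proportions <- tsv(prof$context_proportions,
                                  "context_proportions.tsv")
  rows$chromosome_levels <- tsv(prof$chromosome_levels,
                                "chromosome_levels.tsv")
  rows$metaplot <- tsv(prof$metaplot, "metaplot_f1.tsv")
  # -- stage 3: dmr --------------------------------------------------------
  dmr <- .stage("dmr", {
    res <- list()
    for (cx in config$contexts) {
      parental <- call_dmrs(ds$father, ds$mother, cx, config$dmr)
      f1_vs_father <- call_dmrs(ds$f1, ds$father, cx, config$dmr)
      f1_vs_mother <- call_dmrs(ds$f1, ds$mother, cx, config$dmr)
      inh <- classify_dmr_inheritance(parental, f1_vs_father, f1_vs_mother)
      res[[cx]] <- list(parental = parental, f1_vs_father = f1_vs_father,
                        f1_vs_mother = f1_vs_mother, calls = inh$calls,
                        venn = inh$venn)
    }
    res
  })
  for (cx in names(dmr)) {
    rows[[paste0("dmr_parental_", cx)]] <-
      tsv(dmr[[cx]]$calls, paste0("dmr_parental_", cx, ".tsv"))
    if (nrow(dmr[[cx]]$parental)) {
      bed <- dmr[[cx]]$parental
      bed$name <- bed$context
      bed$score <- round(-log10(pmax(bed$p_value, 1e-300)), 3)
      bed$strand <- "."
      write_bed(bed, file.path(config$out_dir,
                               paste0("dmr_parental_", cx, ".bed")))
    }
    rows[[paste0("dmr_venn_", cx)]] <-
      tsv(dmr[[cx]]$venn, paste0("dmr_venn_", cx, ".tsv"))
  }
  # -- stage 4: dms --------------------------------------------------------
  dms <- .stage("dms", {
    res <- list()
    for (cx in config$contexts) {
      tab <- dms_table(ds$father, ds$mother, ds$f1, cx,
                       alpha = config$dms_alpha, min_cov = config$min_cov)
      res[[cx]] <- list(table = tab,
                        proportions = if (nrow(tab))
                          dms_class_proportions(tab) else NULL)
    }
    res
  })
  for (cx in names(dms)) {
    rows[[paste0("dms_", cx)]] <- tsv(dms[[cx]]$table,
                                      paste0("dms_", cx, ".tsv"))
    if (!is.null(dms[[cx]]$proportions)) {
      tsv(dms[[cx]]$proportions, paste0("dms_proportions_", cx, ".tsv"))
    }
  }
  # -- stage 5: allelic expression ----------------------------------------
  allelic <- .stage("allelic", {
    psnps <- identify_psnps(ds$variants, ds$genes)
    counts <- aggregate_allele_counts(ds$allele_depths, psnps)
    if (!nrow(counts)) stop("no genes with covered PSNPs")
    factors <- tmm_factors(as.matrix(counts[, c("maternal", "paternal")]))
    disp <- if (nrow(counts) >= 20) {
      estimate_dispersion(counts[, c("maternal", "paternal")])
    } else 0
    calls <- allelic_bias_test(counts, factors, disp,
                               fold_threshold = config$bias_fold,
                               alpha = config$bias_alpha)
    total <- counts$maternal + counts$paternal
    reg <- list(maternal = allelic_total_regression(counts$maternal, total),
                paternal = allelic_total_regression(counts$paternal, total))
    list(psnps = psnps, counts = counts, factors = factors,
         dispersion = disp, calls = calls, regression = reg,
         summary = bias_summary(calls))
  })
  rows$psnps <- tsv(allelic$psnps, "psnps.tsv")
  rows$allelic_calls <- tsv(allelic$calls, "allelic_bias_calls.tsv")
  tsv(allelic$summary$volcano, "allelic_volcano.tsv")
  # -- stage 6: psms -------------------------------------------------------
  psms <- .stage("psms", {
    calls <- identify_psms(ds$variants, ds$mother, ds$father, ds$f1,
                           ds$f1_allele_meth, fail_rate = prof$fail_rate,
                           alpha = 0.05)
    by_gene <- assign_psms_to_genes(calls, ds$genes,
                                    flank_bp = config$flank_bp)
    list(calls = calls, by_gene = by_gene)
  })
  rows$psms <- tsv(psms$calls, "psms.tsv")
  rows$psms_by_gene <- tsv(psms$by_gene, "psms_by_gene.tsv")
  # -- stage 7: integrate --------------------------------------------------
  integ <- .stage("integrate", {
    if (!nrow(psms$by_gene)) stop("no PSMSs assigned to genes")
    tab <- gene_integration_table(psms$by_gene, allelic$calls,
                                  ds$f1_allele_meth)
    key <- paste(ds$f1_allele_meth$chrom, ds$f1_allele_meth$pos,
                 ds$f1_allele_meth$strand, sep = ":")
    lev_of <- function(g, org) {
      s <- psms$by_gene[psms$by_gene$gene_id == g &
                          psms$by_gene$origin_parent == org, ]
      i <- match(paste(s$chrom, s$pos, s$strand, sep = ":"), key)
      i <- i[!is.na(i) & ds$f1_allele_meth$total_c[i] >= 1]
      ds$f1_allele_meth$mc_c[i] / ds$f1_allele_meth$total_c[i]
    }
    bi <- tab$gene_id[tab$category == "BIPARENTAL"]
    wil <- tt <- rep(NA_real_, length(bi))
    for (k in seq_along(bi)) {
      lm_ <- lev_of(bi[k], "mother"); lp_ <- lev_of(bi[k], "father")
      wil[k] <- allelic_methylation_test(lm_, lp_, "wilcoxon")
      # Welch t only on genes passing a normality screen on both alleles
      if (length(lm_) >= 3 && length(lp_) >= 3 &&
          length(unique(lm_)) > 1 && length(unique(lp_)) > 1 &&
          stats::shapiro.test(lm_)$p.value > 0.05 &&
          stats::shapiro.test(lp_)$p.value > 0.05) {
        tt[k] <- allelic_methylation_test(lm_, lp_, "ttest")
      }
    }
    meth_tests <- data.frame(gene_id = bi, wilcoxon_p = wil, ttest_p = tt,
                             stringsAsFactors = FALSE)
    list(table = tab,
         cross_mother = cross_tabulate(tab, "mother"),
         cross_father = cross_tabulate(tab, "father"),
         coregulation = coregulation_sets(tab),
         meth_tests = meth_tests,
         sig_wilcoxon = significant_fraction(wil),
         sig_ttest = significant_fraction(tt),
         monoallelic = monoallelic_summary(tab))
  })
  rows$integration <- tsv(integ$table, "gene_integration.tsv")
  tsv(integ$cross_mother, "cross_tab_maternal_psms.tsv")
  tsv(integ$cross_father, "cross_tab_paternal_psms.tsv")
  tsv(integ$coregulation, "coregulation.tsv")
  tsv(integ$meth_tests, "allelic_methylation_tests.tsv")
  tsv(integ$monoallelic, "monoallelic_summary.tsv")
  manifest <- list(
    seed = config$seed,
    stages = c("simulate/load", "profile", "dmr", "dms", "allelic", "psms",
               "integrate"),
    conversion_rate = prof$conversion_rate,
    dispersion = allelic$dispersion,
    tmm_factors = as.list(allelic$factors),
    rows = rows)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(data = ds, profile = prof, dmr = dmr, dms = dms,
                 allelic = allelic, psms = psms, integration = integ,
                 manifest = manifest))
}
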