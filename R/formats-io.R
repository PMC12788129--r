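# Readers and writers for the pipeline's on-disk formats. All genomic
# coordinates are 1-based inclusive in memory; BED is converted to 0-based
# half-open only at the file boundary.

METH_CONTEXTS <- c("CG", "CHG", "CHH")
METH_COLUMNS <- c("chrom", "pos", "strand", "context", "mc_count", "total_count")

#' Validate a methylation call table
#'
#' Checks the invariants every per-cytosine record must satisfy: positive
#' 1-based positions, strand in `+`/`-`, context in CG/CHG/CHH, non-negative
#' counts with `mc_count <= total_count`.
#'
#' @param records A data.frame with columns chrom, pos, strand, context,
#'   mc_count, total_count.
#' @param what Label used in error messages.
#' @return The validated data.frame, invisibly reordered by (chrom, pos, strand).
#' @export
validate_meth_records <- function(records, what = "methylation table") {
  if (!all(METH_COLUMNS %in% names(records))) {
    stop(what, ": missing columns ",
         paste(setdiff(METH_COLUMNS, names(records)), collapse = ", "))
  }
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) stop(what, ": ", msg, " (first offending row ", i[1], ")")
  }
  bad(is.na(records$pos) | records$pos < 1, "pos must be an integer >= 1")
  bad(!(records$strand %in% c("+", "-")), "strand must be '+' or '-'")
  bad(!(records$context %in% METH_CONTEXTS), "context must be CG, CHG or CHH")
  bad(is.na(records$mc_count) | records$mc_count < 0, "negative mc_count")
  bad(is.na(records$total_count) | records$total_count < 0, "negative total_count")
  bad(records$mc_count > records$total_count, "mc_count exceeds total_count")
  records[order(records$chrom, records$pos, records$strand), , drop = FALSE]
}

#' Read a 6-column methylation call table
#'
#' Tab-delimited with a header line: chrom, pos (1-based), strand, context,
#' mc_count, total_count. Rows are returned sorted by (chrom, pos, strand).
#'
#' @param path File path.
#' @return data.frame of methylation call records.
#' @export
read_meth_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (!all(METH_COLUMNS %in% names(raw))) {
    stop(path, ": expected header with columns ",
         paste(METH_COLUMNS, collapse = ", "))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop(path, ": malformed ", col, " at line ", bad[1] + 1L)  # +1 for header
    }
    v
  }
  df <- data.frame(chrom = raw$chrom, pos = num("pos"), strand = raw$strand,
                   context = raw$context, mc_count = num("mc_count"),
                   total_count = num("total_count"), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  out <- validate_meth_records(df, what = path)
  rownames(out) <- NULL
  out
}

#' Write a methylation call table
#'
#' @param records Validated methylation call data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_meth_table <- function(records, path) {
  records <- validate_meth_records(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a minimal trio VCF
#'
#' Parses a VCF 4.x with a GT entry in FORMAT. Only biallelic SNP rows are
#' kept; multiallelic and indel rows are skipped and counted (attribute
#' `n_skipped`). Genotypes are coded `hom_ref`, `het`, `hom_alt`; `./.` is NA.
#'
#' @param path VCF file path.
#' @return data.frame with chrom, pos, ref, alt, then `gt_<sample>` and
#'   `dp_<sample>` columns per sample; attribute `samples` holds sample names
#'   in file order and `n_skipped` the number of skipped rows.
#' @export
read_vcf_minimal <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop(path, ": no #CHROM header line")
  cols <- strsplit(sub("^#", "", lines[hdr[1]]), "\t")[[1]]
  if (length(cols) < 10 || cols[9] != "FORMAT") {
    stop(path, ": VCF must carry FORMAT and at least one sample column")
  }
  samples <- cols[10:length(cols)]
  body <- lines[seq_along(lines) > hdr[1]]
  body <- body[nzchar(body)]
  n_skipped <- 0L
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    ref <- f[4]; alt <- f[5]
    if (nchar(ref) != 1L || nchar(alt) != 1L || grepl(",", alt) ||
        !ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T")) {
      n_skipped <- n_skipped + 1L
      next
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i)) stop(path, ": record without GT in FORMAT at ", f[1], ":", f[2])
    dp_i <- match("DP", fmt)
    calls <- f[10:(9 + length(samples))]
    gt <- character(length(samples))
    dp <- rep(NA_real_, length(samples))
    for (s in seq_along(samples)) {
      parts <- strsplit(calls[s], ":", fixed = TRUE)[[1]]
      g <- parts[gt_i]
      al <- strsplit(g, "[/|]")[[1]]
      if (length(al) != 2L || !all(al %in% c("0", "1", "."))) {
        stop(path, ": malformed GT '", g, "' at ", f[1], ":", f[2])
      }
      gt[s] <- if (any(al == ".")) NA_character_
               else c("hom_ref", "het", "hom_alt")[sum(as.integer(al)) + 1L]
      if (!is.na(dp_i) && length(parts) >= dp_i) {
        dp[s] <- suppressWarnings(as.numeric(parts[dp_i]))
      }
    }
    rows[[i]] <- c(list(chrom = f[1], pos = as.numeric(f[2]), ref = ref,
                        alt = alt), as.list(stats::setNames(gt, paste0("gt_", samples))),
                   as.list(stats::setNames(dp, paste0("dp_", samples))))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(chrom = character(), pos = numeric(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE)
    for (s in samples) {
      out[[paste0("gt_", s)]] <- character()
      out[[paste0("dp_", s)]] <- numeric()
    }
  } else {
    out <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
  }
  if (any(!is.na(out$pos) & out$pos < 1)) stop(path, ": positions must be >= 1")
  attr(out, "samples") <- samples
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a minimal trio VCF
#'
#' @param variants data.frame as returned by [read_vcf_minimal()].
#' @param path Output path.
#' @param samples Sample names; defaults to the `samples` attribute.
#' @return The path, invisibly.
#' @export
write_vcf_minimal <- function(variants, path, samples = attr(variants, "samples")) {
  if (is.null(samples)) {
    samples <- sub("^gt_", "", grep("^gt_", names(variants), value = TRUE))
  }
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  if (nrow(variants)) {
    gt_cols <- lapply(samples, function(s) {
      g <- variants[[paste0("gt_", s)]]
      ifelse(is.na(g), "./.", gt_code[g])
    })
    body <- do.call(paste, c(list(variants$chrom, variants$pos, ".",
                                  variants$ref, variants$alt, ".", "PASS",
                                  ".", "GT"), gt_cols, list(sep = "\t")))
    writeLines(body, con)
  }
  invisible(path)
}

#' Write intervals as BED
#'
#' Internal coordinates are 1-based inclusive; the file is standard 0-based
#' half-open BED. With name/score/strand columns present a BED6 is written.
#'
#' @param intervals data.frame with chrom, start, end and optionally name,
#'   score, strand.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) && any(intervals$start > intervals$end)) {
    stop("interval start > end")
  }
  if (nrow(intervals) && any(intervals$start < 1)) stop("start must be >= 1")
  df <- data.frame(chrom = intervals$chrom, start = intervals$start - 1L,
                   end = intervals$end, stringsAsFactors = FALSE)
  if (!is.null(intervals$name)) {
    df$name <- intervals$name
    df$score <- if (is.null(intervals$score)) 0 else intervals$score
    df$strand <- if (is.null(intervals$strand)) "." else intervals$strand
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a BED file into 1-based inclusive intervals
#'
#' @param path BED3+ file path.
#' @return data.frame with chrom, start, end (1-based inclusive) and, when
#'   present, name, score, strand.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(chrom = raw[[1]], start = raw[[2]] + 1L, end = raw[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(raw) >= 6) {
    out$name <- raw[[4]]; out$score <- raw[[5]]; out$strand <- raw[[6]]
  } else if (ncol(raw) >= 4) out$name <- raw[[4]]
  if (any(out$start > out$end + 1)) stop(path, ": malformed BED interval")
  out
}

#' Read a gene annotation table
#'
#' Tab-delimited with header: gene_id, chrom, start, end, strand (1-based
#' inclusive).
#'
#' @param path File path.
#' @return data.frame of gene annotations.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    stop(path, ": expected columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) stop(path, ": duplicated gene_id")
  if (any(df$start > df$end)) stop(path, ": gene with start > end")
  df
}

#' Write a gene annotation table
#' @param genes Gene annotation data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-SNP allele depth table
#'
#' Tab-delimited with header: chrom, pos, sample, maternal_reads,
#' paternal_reads.
#'
#' @param path File path.
#' @return data.frame of allele depth records.
#' @export
read_allele_depth_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "sample", "maternal_reads", "paternal_reads")
  if (!all(need %in% names(df))) {
    stop(path, ": expected columns ", paste(need, collapse = ", "))
  }
  if (any(df$maternal_reads < 0 | df$paternal_reads < 0)) {
    stop(path, ": negative allele read counts")
  }
  df
}

#' Write a per-SNP allele depth table
#' @param depths Allele depth data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_allele_depth_table <- function(depths, path) {
  utils::write.table(depths, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allele-resolved F1 methylation table
#'
#' One row per parent-specific cytosine candidate in the F1: methylated/total
#' read counts attributed to the cytosine-carrying allele (`mc_c`, `total_c`)
#' and to the non-cytosine allele (`mc_nonc`, `total_nonc`).
#'
#' @param path File path.
#' @return data.frame of allele-resolved methylation records.
#' @export
read_allele_meth_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "context", "mc_c", "total_c",
            "mc_nonc", "total_nonc")
  if (!all(need %in% names(df))) {
    stop(path, ": expected columns ", paste(need, collapse = ", "))
  }
  if (any(df$mc_c > df$total_c) || any(df$mc_nonc > df$total_nonc)) {
    stop(path, ": methylated counts exceed totals")
  }
  df
}

#' Write an allele-resolved F1 methylation table
#' @param records Allele-resolved methylation data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_allele_meth_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
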