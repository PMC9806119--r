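# Intron retention: per-intron retention ratios from intronic coverage and
# exact-spanning spliced reads, the gene-level high-retention burden, and
# differential retention between conditions.

#' Per-intron retention ratio
#'
#' ratio = intronic_depth / (intronic_depth + spliced_reads), where
#' intronic_depth is the mean per-base coverage over the intron and
#' spliced_reads the count on the junction exactly spanning it.
#'
#' @param intronic_depth Non-negative mean intronic coverage.
#' @param spliced_reads Non-negative spliced read count.
#' @return Ratio in \[0, 1\]; `NA` where both inputs are 0 (undefined;
#'   the intron is excluded downstream).
#' @export
intron_retention_ratio <- function(intronic_depth, spliced_reads) {
  if (any(intronic_depth < 0) || any(spliced_reads < 0)) {
    stop("negative coverage or read counts")
  }
  out <- intronic_depth / (intronic_depth + spliced_reads)
  out[intronic_depth + spliced_reads == 0] <- NA_real_
  out
}

#' Read a per-intron coverage table
#'
#' @param path TSV with header
#'   `gene_id contig intron_start intron_end strand mean_depth`.
#' @return data.frame with those columns.
#' @export
read_intron_coverage <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "contig", "intron_start", "intron_end", "strand",
            "mean_depth")
  if (!all(need %in% names(x))) {
    stop("intron coverage table must have columns: ",
         paste(need, collapse = ", "))
  }
  if (any(x$mean_depth < 0)) stop("negative mean_depth")
  x
}

#' Score introns: attach spliced reads and retention ratios
#'
#' Only introns whose exactly spanning junction is detected in the sample's
#' junction table are scorable; others get `NA` ratios.
#'
#' @param coverage data.frame from [read_intron_coverage()].
#' @param junctions Junction table with contig, start, end, strand,
#'   unique_reads.
#' @return `coverage` with `spliced_reads` and `ir_ratio` columns.
#' @export
score_intron_retention <- function(coverage, junctions) {
  jmap <- tapply(junctions$unique_reads,
                 junction_key(junctions$contig, junctions$start,
                              junctions$end, junctions$strand), sum)
  key <- junction_key(coverage$contig, coverage$intron_start,
                      coverage$intron_end, coverage$strand)
  spliced <- jmap[key]
  coverage$spliced_reads <- as.integer(ifelse(is.na(spliced), NA, spliced))
  coverage$ir_ratio <- NA_real_
  ok <- !is.na(coverage$spliced_reads)
  coverage$ir_ratio[ok] <- intron_retention_ratio(coverage$mean_depth[ok],
                                                  coverage$spliced_reads[ok])
  coverage
}

#' Gene-level high-retention burden
#'
#' A gene is flagged when any of its scorable introns has a retention ratio
#' strictly above `threshold`; the proportion is taken over genes above the
#' TPM gate with at least one scorable intron.
#'
#' @param records Scored intron table from [score_intron_retention()].
#' @param idx An `AnnotationIndex`.
#' @param threshold Retention threshold (default 0.25, strict >).
#' @param tpm_gate Expression gate (strict >, default 10).
#' @param sample_id Label carried into the result.
#' @return A `RetentionResult`: list with sample_id, n_genes_high_retention,
#'   n_genes_expressed, proportion, flagged_genes.
#' @export
gene_retention_metric <- function(records, idx, threshold = 0.25,
                                  tpm_gate = 10, sample_id = "sample") {
  expressed <- idx$genes$gene_id[idx$genes$tpm > tpm_gate]
  r <- records[records$gene_id %in% expressed & !is.na(records$ir_ratio), ,
               drop = FALSE]
  if (!nrow(r)) stop("no scorable introns in expressed genes")
  per_gene <- tapply(r$ir_ratio, r$gene_id, max)
  flagged <- names(per_gene)[per_gene > threshold]
  structure(list(
    sample_id = sample_id,
    n_genes_high_retention = length(flagged),
    n_genes_expressed = length(per_gene),
    proportion = length(flagged) / length(per_gene),
    flagged_genes = flagged
  ), class = "RetentionResult")
}

#' @export
print.RetentionResult <- function(x, ...) {
  cat(sprintf("RetentionResult '%s': %d / %d genes with a highly retained intron (%.3f)\n",
              x$sample_id, x$n_genes_high_retention, x$n_genes_expressed,
              x$proportion))
  invisible(x)
}

#' Differential intron retention between two conditions
#'
#' Introns are matched on their interval key; each gets the retention-ratio
#' difference and a two-sided Fisher exact test on the rounded
#' (intronic depth, spliced reads) evidence counts, Benjamini-Hochberg
#' corrected. Introns scorable in only one condition are skipped.
#'
#' @param records1,records2 Scored intron tables from
#'   [score_intron_retention()].
#' @return data.frame with intron key columns, ir_ratio1, ir_ratio2,
#'   delta_ir, p_value, fdr.
#' @export
differential_retention <- function(records1, records2) {
  key1 <- junction_key(records1$contig, records1$intron_start,
                       records1$intron_end, records1$strand)
  key2 <- junction_key(records2$contig, records2$intron_start,
                       records2$intron_end, records2$strand)
  common <- intersect(key1[!is.na(records1$ir_ratio)],
                      key2[!is.na(records2$ir_ratio)])
  r1 <- records1[match(common, key1), , drop = FALSE]
  r2 <- records2[match(common, key2), , drop = FALSE]
  if (!length(common)) {
    return(data.frame(gene_id = character(0), contig = character(0),
                      intron_start = integer(0), intron_end = integer(0),
                      strand = character(0), ir_ratio1 = numeric(0),
                      ir_ratio2 = numeric(0), delta_ir = numeric(0),
                      p_value = numeric(0), fdr = numeric(0)))
  }
  p <- vapply(seq_along(common), function(i) {
    tab <- matrix(round(c(r1$mean_depth[i], r1$spliced_reads[i],
                          r2$mean_depth[i], r2$spliced_reads[i])), nrow = 2)
    if (sum(tab) == 0) return(1)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  data.frame(
    gene_id = r1$gene_id, contig = r1$contig,
    intron_start = r1$intron_start, intron_end = r1$intron_end,
    strand = r1$strand,
    ir_ratio1 = r1$ir_ratio, ir_ratio2 = r2$ir_ratio,
    delta_ir = r1$ir_ratio - r2$ir_ratio,
    p_value = p, fdr = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
}
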