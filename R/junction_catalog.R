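# Junction catalogue: read per-sample splice-junction tables, classify each
# canonical junction against the annotation, and select high-confidence
# unannotated junctions (reads >= 10% of the gene's highest-depth annotated
# junction, within robustly expressed genes).

JUNCTION_STATUSES <- c("annotated", "both_sites_annotated_novel_pairing",
                       "donor_only_annotated", "acceptor_only_annotated",
                       "neither_annotated")

#' Read a STAR-style splice-junction table
#'
#' Consumes the 9-column `SJ.out.tab` dialect: contig, intron start, intron
#' end (1-based inclusive), strand code (0 undefined / 1 plus / 2 minus),
#' intron motif code (0 non-canonical; 1 GT/AG, 2 CT/AC, 3 GC/AG, 4 CT/GC,
#' 5 AT/AC, 6 GT/AT), annotation flag, unique reads, multimapping reads,
#' maximum overhang. Motif codes 1 and 2 are the canonical GT-AG pattern
#' (code 2 is its minus-strand reading); rows with strand code 0 but a
#' stranded motif have the strand resolved from the motif.
#'
#' @param path Path to the junction table.
#' @return data.frame with columns contig, start, end, strand, motif_code,
#'   canonical, unique_reads, multi_reads, overhang.
#' @export
read_junction_table <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) != 9L) {
    stop("junction table ", path, ": expected 9 tab-separated columns, found ",
         ncol(raw))
  }
  names(raw) <- c("contig", "start", "end", "strand_code", "motif_code",
                  "annotated_flag", "unique_reads", "multi_reads", "overhang")
  if (any(raw$unique_reads < 0) || any(raw$multi_reads < 0)) {
    stop("junction table ", path, ": negative read counts")
  }
  if (any(raw$start > raw$end)) {
    stop("junction table ", path, ": intron start > end")
  }
  strand <- c("*", "+", "-")[raw$strand_code + 1L]
  # motif-strand concordance: GT/AG and GC/AG and GT/AT are plus-strand
  # readings, CT/AC and CT/GC and AT/AC their minus-strand counterparts
  motif_strand <- c("*", "+", "-", "+", "-", "+", "-")[raw$motif_code + 1L]
  undet <- strand == "*" & motif_strand != "*"
  strand[undet] <- motif_strand[undet]
  data.frame(
    contig = as.character(raw$contig),
    start = as.integer(raw$start), end = as.integer(raw$end),
    strand = strand, motif_code = as.integer(raw$motif_code),
    canonical = raw$motif_code %in% c(1L, 2L),
    unique_reads = as.integer(raw$unique_reads),
    multi_reads = as.integer(raw$multi_reads),
    overhang = as.integer(raw$overhang),
    stringsAsFactors = FALSE
  )
}

#' Assign junctions to genes by strand-aware overlap
#'
#' A junction overlapping several gene spans is assigned to the overlapping
#' gene with the highest TPM (ties broken by the lexicographically smallest
#' gene_id); junctions overlapping no same-strand gene get `NA`.
#'
#' @param junctions data.frame from [read_junction_table()].
#' @param idx An `AnnotationIndex`.
#' @return The input with an `assigned_gene` column added.
#' @export
assign_junctions_to_genes <- function(junctions, idx) {
  if (!nrow(junctions)) {
    junctions$assigned_gene <- character(0)
    return(junctions)
  }
  jr <- GenomicRanges::GRanges(
    junctions$contig, IRanges::IRanges(junctions$start, junctions$end),
    strand = junctions$strand
  )
  hits <- GenomicRanges::findOverlaps(jr, idx$gene_ranges, ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(hits)
  gene <- idx$genes$gene_id[S4Vectors::subjectHits(hits)]
  tpm <- idx$genes$tpm[S4Vectors::subjectHits(hits)]
  assigned <- rep(NA_character_, nrow(junctions))
  if (length(qh)) {
    ord <- order(qh, -tpm, gene)  # per junction: highest TPM, then smallest id
    first <- !duplicated(qh[ord])
    assigned[qh[ord][first]] <- gene[ord][first]
  }
  junctions$assigned_gene <- assigned
  junctions
}

#' Classify junctions by annotation status
#'
#' Each junction receives exactly one status: `annotated` for an exact
#' (contig, start, end, strand) match against the annotated-junction
#' universe; otherwise `both_sites_annotated_novel_pairing` when both its
#' donor and acceptor positions are annotated splice sites (the exon-skipping
#' pattern), `donor_only_annotated` / `acceptor_only_annotated` when exactly
#' one is (hemi-annotated), and `neither_annotated` when neither is (fully
#' novel).
#'
#' @param junctions data.frame with contig, start, end, strand columns.
#' @param idx An `AnnotationIndex`.
#' @return The input with a `status` column added.
#' @export
classify_junctions <- function(junctions, idx) {
  key <- junction_key(junctions$contig, junctions$start, junctions$end,
                      junctions$strand)
  dkey <- site_key(junctions$contig,
                   donor_position(junctions$start, junctions$end, junctions$strand),
                   junctions$strand)
  akey <- site_key(junctions$contig,
                   acceptor_position(junctions$start, junctions$end, junctions$strand),
                   junctions$strand)
  d <- dkey %in% idx$donor_keys
  a <- akey %in% idx$acceptor_keys
  status <- ifelse(key %in% idx$junction_keys, "annotated",
            ifelse(d & a, "both_sites_annotated_novel_pairing",
            ifelse(d, "donor_only_annotated",
            ifelse(a, "acceptor_only_annotated", "neither_annotated"))))
  junctions$status <- factor(status, levels = JUNCTION_STATUSES)
  junctions
}

#' Select high-confidence unannotated junctions
#'
#' Within each robustly expressed gene (TPM strictly above `tpm_gate`), the
#' highest-depth annotated junction observed in the sample sets the reference
#' depth D; canonical unannotated junctions with unique reads of at least
#' `fraction` * D are kept. Genes in which no annotated junction was observed
#' with reads > 0 are skipped (D undefined).
#'
#' @param junctions data.frame from [classify_junctions()] with
#'   `assigned_gene` and `unique_reads`.
#' @param idx An `AnnotationIndex`.
#' @param sample_id Label carried into the result.
#' @param fraction Minimum fraction of the gene's maximum annotated depth
#'   (default 0.1; the threshold is inclusive).
#' @param tpm_gate Expression gate; genes must exceed it strictly (default 10).
#' @return An `UnannotatedCallSet`: list with `sample_id`, `kept`
#'   (data.frame of kept junctions), `max_annotated_depth` (named integer per
#'   gene), `genes_with_unannotated` (character), `eligible_genes` (genes
#'   entering the denominator: multi-exon, TPM above gate, with an observed
#'   annotated junction).
#' @export
select_high_confidence_unannotated <- function(junctions, idx, sample_id = "sample",
                                               fraction = 0.1, tpm_gate = 10) {
  if (!"status" %in% names(junctions)) junctions <- classify_junctions(junctions, idx)
  if (!"assigned_gene" %in% names(junctions)) {
    junctions <- assign_junctions_to_genes(junctions, idx)
  }
  expressed <- eligible_genes(idx, tpm_gate)
  j <- junctions[junctions$canonical & !is.na(junctions$assigned_gene) &
                   junctions$assigned_gene %in% expressed, , drop = FALSE]

  ann <- j[j$status == "annotated" & j$unique_reads > 0, , drop = FALSE]
  max_depth <- vapply(split(ann$unique_reads, ann$assigned_gene), max,
                      numeric(1))
  una <- j[j$status != "annotated", , drop = FALSE]
  una <- una[una$assigned_gene %in% names(max_depth), , drop = FALSE]
  keep <- una$unique_reads >= fraction * max_depth[una$assigned_gene]
  kept <- una[keep, , drop = FALSE]
  rownames(kept) <- NULL

  structure(list(
    sample_id = sample_id,
    kept = kept,
    max_annotated_depth = max_depth,
    genes_with_unannotated = unique(kept$assigned_gene),
    eligible_genes = intersect(expressed, names(max_depth)),
    fraction = fraction, tpm_gate = tpm_gate
  ), class = "UnannotatedCallSet")
}

#' @export
print.UnannotatedCallSet <- function(x, ...) {
  cat(sprintf("UnannotatedCallSet '%s': %d kept junctions in %d / %d eligible genes\n",
              x$sample_id, nrow(x$kept), length(x$genes_with_unannotated),
              length(x$eligible_genes)))
  invisible(x)
}

#' Proportion of expressed genes with high-confidence unannotated splicing
#'
#' Numerator: genes with at least one kept unannotated junction. Denominator:
#' multi-exon genes above the TPM gate with at least one observed annotated
#' junction.
#'
#' @param call_set An `UnannotatedCallSet`.
#' @return Proportion in \[0, 1\].
#' @export
gene_unannotated_proportion <- function(call_set) {
  n <- length(call_set$eligible_genes)
  if (n == 0L) stop("no expressed multi-exon genes with observed annotated junctions")
  length(call_set$genes_with_unannotated) / n
}

#' Genes with unannotated splicing in every replicate
#'
#' @param call_sets List of `UnannotatedCallSet`.
#' @return Character vector: the intersection of `genes_with_unannotated`.
#' @export
consistent_unannotated_genes <- function(call_sets) {
  Reduce(intersect, lapply(call_sets, function(cs) cs$genes_with_unannotated))
}
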