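# Exon inclusion (percent-spliced-in), the per-sample exon commitment score,
# and differential exon usage between conditions.

#' Length-normalized exon inclusion level
#'
#' psi = (I / len_inclusion) / (I / len_inclusion + S / len_skip). With
#' junction-only counting the inclusion isoform is supported by two junctions
#' and the skipping isoform by one, so the effective lengths default to 2
#' and 1.
#'
#' @param inclusion_reads Reads supporting the two inclusion junctions (I).
#' @param skip_reads Reads on the skipping junction (S).
#' @param len_inclusion,len_skip Effective lengths (defaults 2 and 1).
#' @return psi in \[0, 1\]; `NA` where I + S = 0 (undefined, event excluded).
#' @export
exon_inclusion_level <- function(inclusion_reads, skip_reads,
                                 len_inclusion = 2, len_skip = 1) {
  stopifnot(len_inclusion > 0, len_skip > 0)
  if (any(inclusion_reads < 0 | skip_reads < 0)) stop("negative read counts")
  i <- inclusion_reads / len_inclusion
  s <- skip_reads / len_skip
  out <- i / (i + s)
  out[inclusion_reads + skip_reads == 0] <- NA_real_
  out
}

#' Enumerate skipped-exon events from the annotation
#'
#' One candidate event per distinct internal exon of each transcript: the two
#' flanking introns are the inclusion junctions and the junction joining the
#' flanking exons (skipping the internal one) is the skip junction. Events are
#' deduplicated on the skip-junction key so the same exon skipped in several
#' transcripts appears once per distinct skip junction.
#'
#' @param idx An `AnnotationIndex`.
#' @return data.frame with event_id, gene_id, transcript_id, contig, strand,
#'   exon_start, exon_end, exon_index, and the three junction coordinate
#'   pairs (inc1_/inc2_/skip_ start and end).
#' @export
enumerate_skipped_exon_events <- function(idx) {
  rows <- lapply(idx$transcripts, function(t) {
    n <- nrow(t$exons)
    if (n < 3L) return(NULL)
    k <- 2:(n - 1L)  # internal exons, genomic order
    data.frame(
      gene_id = t$gene_id, transcript_id = t$transcript_id,
      contig = t$contig, strand = t$strand,
      exon_start = t$exons$start[k], exon_end = t$exons$end[k],
      exon_index = k,
      up_start = t$exons$start[k - 1L], up_end = t$exons$end[k - 1L],
      down_start = t$exons$start[k + 1L], down_end = t$exons$end[k + 1L],
      inc1_start = t$exons$end[k - 1L] + 1L, inc1_end = t$exons$start[k] - 1L,
      inc2_start = t$exons$end[k] + 1L, inc2_end = t$exons$start[k + 1L] - 1L,
      skip_start = t$exons$end[k - 1L] + 1L, skip_end = t$exons$start[k + 1L] - 1L,
      stringsAsFactors = FALSE
    )
  })
  ev <- do.call(rbind, rows)
  if (is.null(ev)) return(NULL)
  key <- junction_key(ev$contig, ev$skip_start, ev$skip_end, ev$strand)
  ev <- ev[!duplicated(key), , drop = FALSE]
  ev$event_id <- paste0(ev$gene_id, ":", ev$contig, ":",
                        ev$exon_start, "-", ev$exon_end, ":",
                        ev$skip_start, "-", ev$skip_end)
  rownames(ev) <- NULL
  ev
}

#' Count inclusion and skip reads for skipped-exon events
#'
#' @param events data.frame from [enumerate_skipped_exon_events()].
#' @param junctions Junction table (one sample, or several pooled) with
#'   contig, start, end, strand, unique_reads.
#' @return `events` with columns `inclusion_reads` (sum of the two inclusion
#'   junctions), `skip_reads`, and `psi`.
#' @export
count_exon_events <- function(events, junctions) {
  jmap <- stats::setNames(
    junctions$unique_reads,
    junction_key(junctions$contig, junctions$start, junctions$end,
                 junctions$strand)
  )
  jmap <- tapply(unname(jmap), names(jmap), sum)  # pool duplicate rows
  lookup <- function(contig, s, e, strand) {
    v <- jmap[junction_key(contig, s, e, strand)]
    ifelse(is.na(v), 0L, v)
  }
  events$inclusion_reads <-
    lookup(events$contig, events$inc1_start, events$inc1_end, events$strand) +
    lookup(events$contig, events$inc2_start, events$inc2_end, events$strand)
  events$skip_reads <-
    lookup(events$contig, events$skip_start, events$skip_end, events$strand)
  events$psi <- exon_inclusion_level(events$inclusion_reads, events$skip_reads)
  events
}

#' Collapse duplicate exons to their minimum inclusion level
#'
#' When the same exon is skipped by multiple alternate splice junctions, one
#' record per distinct skipped-exon interval is kept, carrying the minimum
#' reported inclusion level among the duplicates.
#'
#' @param events data.frame with contig, strand, exon_start, exon_end, psi.
#' @return Deduplicated events, each with the minimal psi of its group.
#' @export
collapse_duplicate_exons <- function(events) {
  key <- paste(events$contig, events$exon_start, events$exon_end,
               events$strand, sep = ":")
  ord <- order(key, events$psi, na.last = TRUE)
  out <- events[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  out <- out[order(match(paste(out$contig, out$exon_start, out$exon_end,
                               out$strand, sep = ":"), unique(key))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample exon commitment score
#'
#' The fraction of quantified nonredundant exons that are essentially always
#' included (psi > hi) or always excluded (psi < lo), both strict. Events are
#' restricted to genes above the TPM gate, duplicate exons are collapsed to
#' their minimum psi, and events with total junction depth below
#' `min_depth` or undefined psi are excluded.
#'
#' @param events data.frame with gene_id, contig, strand, exon coordinates,
#'   inclusion_reads, skip_reads, psi.
#' @param idx An `AnnotationIndex` (supplies TPM).
#' @param hi,lo Commitment bounds (defaults 0.99 and 0.01, strict).
#' @param tpm_gate Expression gate (strict >, default 10).
#' @param min_depth Minimum I + S for an event to be scored (default 10).
#' @param sample_id Label carried into the result.
#' @return A `CommitmentResult`: list with sample_id, n_included_committed,
#'   n_excluded_committed, n_total, score.
#' @export
exon_commitment_score <- function(events, idx, hi = 0.99, lo = 0.01,
                                  tpm_gate = 10, min_depth = 10,
                                  sample_id = "sample") {
  expressed <- idx$genes$gene_id[idx$genes$tpm > tpm_gate]
  ev <- events[events$gene_id %in% expressed, , drop = FALSE]
  ev <- ev[!is.na(ev$psi) &
             ev$inclusion_reads + ev$skip_reads >= min_depth, , drop = FALSE]
  ev <- collapse_duplicate_exons(ev)
  if (!nrow(ev)) stop("no scorable exon events after filtering")
  n_in <- sum(ev$psi > hi)
  n_ex <- sum(ev$psi < lo)
  structure(list(
    sample_id = sample_id,
    n_included_committed = n_in, n_excluded_committed = n_ex,
    n_total = nrow(ev),
    score = (n_in + n_ex) / nrow(ev)
  ), class = "CommitmentResult")
}

#' @export
print.CommitmentResult <- function(x, ...) {
  cat(sprintf("CommitmentResult '%s': score %.3f (%d included + %d excluded of %d exons)\n",
              x$sample_id, x$score, x$n_included_committed,
              x$n_excluded_committed, x$n_total))
  invisible(x)
}

#' Differential exon inclusion between two conditions
#'
#' Replicates are pooled per condition; each event gets a two-sided Fisher
#' exact test on the 2x2 table of (inclusion, skip) reads, Benjamini-Hochberg
#' correction across events, and the length-normalized inclusion-level
#' difference psi1 - psi2. Events quantified in only one condition are
#' skipped.
#'
#' @param events1,events2 Counted event tables from [count_exon_events()]
#'   (same event universe; matched on event_id).
#' @return data.frame with event_id, gene_id, I1, S1, I2, S2, psi1, psi2,
#'   delta_psi, p_value, fdr.
#' @export
differential_inclusion <- function(events1, events2) {
  common <- intersect(events1$event_id, events2$event_id)
  e1 <- events1[match(common, events1$event_id), , drop = FALSE]
  e2 <- events2[match(common, events2$event_id), , drop = FALSE]
  ok <- (e1$inclusion_reads + e1$skip_reads > 0) &
        (e2$inclusion_reads + e2$skip_reads > 0)
  e1 <- e1[ok, , drop = FALSE]; e2 <- e2[ok, , drop = FALSE]
  if (!nrow(e1)) {
    return(data.frame(event_id = character(0), gene_id = character(0),
                      I1 = integer(0), S1 = integer(0), I2 = integer(0),
                      S2 = integer(0), psi1 = numeric(0), psi2 = numeric(0),
                      delta_psi = numeric(0), p_value = numeric(0),
                      fdr = numeric(0)))
  }
  p <- vapply(seq_len(nrow(e1)), function(i) {
    stats::fisher.test(matrix(c(e1$inclusion_reads[i], e1$skip_reads[i],
                                e2$inclusion_reads[i], e2$skip_reads[i]),
                              nrow = 2))$p.value
  }, numeric(1))
  psi1 <- exon_inclusion_level(e1$inclusion_reads, e1$skip_reads)
  psi2 <- exon_inclusion_level(e2$inclusion_reads, e2$skip_reads)
  data.frame(
    event_id = e1$event_id, gene_id = e1$gene_id,
    I1 = e1$inclusion_reads, S1 = e1$skip_reads,
    I2 = e2$inclusion_reads, S2 = e2$skip_reads,
    psi1 = psi1, psi2 = psi2, delta_psi = psi1 - psi2,
    p_value = p, fdr = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
}
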