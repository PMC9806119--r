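# Consequence classification of skipped exons: frame effect, premature
# termination codons (PTCs), the 50-nt NMD rule, and conserved-domain loss.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Frame effect of removing a stretch of coding sequence
#'
#' Only the CDS-overlapping length of the skipped exon counts toward the
#' mod-3 test: `noncoding` when the exon does not overlap the CDS, `in_frame`
#' when the overlapping length is divisible by 3, `frameshift` otherwise.
#'
#' @param cds_overlap_length Number of CDS bases the skipped exon removes.
#' @return One of "noncoding", "in_frame", "frameshift".
#' @export
classify_frame_effect <- function(cds_overlap_length) {
  ifelse(cds_overlap_length == 0, "noncoding",
         ifelse(cds_overlap_length %% 3 == 0, "in_frame", "frameshift"))
}

# Transcript-coordinate span [a, b] of exon k (genomic-order index) within t.
exon_tx_span <- function(t, exon_index) {
  ord <- tx_exon_order(t)
  lens <- t$exons$end - t$exons$start + 1L
  pos <- match(exon_index, ord)
  a <- if (pos == 1L) 1L else sum(lens[ord[seq_len(pos - 1L)]]) + 1L
  c(a, a + lens[exon_index] - 1L)
}

# CDS bases of t removed by skipping exon k.
exon_cds_overlap <- function(t, exon_index) {
  if (is.na(t$cds_start)) return(0L)
  span <- exon_tx_span(t, exon_index)
  max(0L, min(span[2L], t$cds_end) - max(span[1L], t$cds_start) + 1L)
}

#' Construct the isoform produced by skipping one internal exon
#'
#' Removes the exon's bases from the spliced parent sequence, remaps the CDS
#' offsets (shifted left when the exon lies upstream of the CDS start,
#' shortened when it overlaps the CDS body), and recomputes the transcript
#' coordinates of the remaining exon-exon junctions.
#'
#' @param t A coding `TranscriptModel` with at least 3 exons.
#' @param exon_index Genomic-order index of the exon to skip; must be
#'   internal (not first or last).
#' @param genome A `DNAStringSet`.
#' @return A `SkippedIsoform`: list with parent_id, gene_id, exon_index,
#'   skipped exon genomic interval, sequence, cds_start, stop_end (transcript
#'   coordinate of the last base of the remapped annotated stop codon, `NA`
#'   when the skip removes or disrupts it), junction_positions (transcript
#'   coordinate of the last base of each non-final exon), start_lost,
#'   stop_lost flags.
#' @export
construct_skipped_isoform <- function(t, exon_index, genome) {
  n <- nrow(t$exons)
  if (exon_index <= 1L || exon_index >= n) {
    stop("unsupported event: exon ", exon_index, " of ", n, " is not internal")
  }
  parent_seq <- transcript_sequence(t, genome)
  span <- exon_tx_span(t, exon_index)
  a <- span[1L]; b <- span[2L]
  L <- b - a + 1L
  seq <- paste0(substr(parent_seq, 1L, a - 1L),
                substr(parent_seq, b + 1L, nchar(parent_seq)))

  ord <- tx_exon_order(t)
  keep <- ord[ord != exon_index]
  lens <- (t$exons$end - t$exons$start + 1L)[keep]
  junctions <- cumsum(lens)[-length(lens)]

  cs <- t$cds_start; ce <- t$cds_end
  start_lost <- FALSE; stop_lost <- FALSE
  cs2 <- NA_integer_; stop_end <- NA_integer_
  if (!is.na(cs)) {
    # start codon = [cs, cs+2]; annotated stop codon = [ce-2, ce]
    if (a <= cs + 2L && b >= cs) {
      start_lost <- TRUE
    } else if (b < cs) {
      cs2 <- cs - L
      stop_end <- ce - L
    } else {
      cs2 <- cs
      if (a <= ce && b >= ce - 2L) {
        stop_lost <- TRUE           # annotated stop codon disrupted
      } else if (a > ce) {
        stop_end <- ce              # exon in the 3' UTR
      } else {
        stop_end <- ce - (min(b, ce) - max(a, cs) + 1L)
      }
    }
  }

  structure(list(
    parent_id = t$transcript_id, gene_id = t$gene_id,
    exon_index = exon_index,
    exon_start = t$exons$start[exon_index], exon_end = t$exons$end[exon_index],
    skipped_length = L, sequence = seq,
    cds_start = cs2, stop_end = stop_end,
    junction_positions = junctions,
    start_lost = start_lost, stop_lost = stop_lost
  ), class = "SkippedIsoform")
}

#' Scan a skipped isoform for a premature termination codon
#'
#' Translates from the remapped CDS start in the new reading frame; the first
#' in-frame stop codon lying strictly upstream of the remapped annotated stop
#' is the PTC. Returns `NULL` when translation reaches the annotated stop (or
#' runs off the transcript with no stop).
#'
#' @param iso A `SkippedIsoform` with a CDS (`start_lost` must be FALSE).
#' @return `NULL`, or list(ptc_start, ptc_end): transcript coordinates of the
#'   stop codon's first and last base in the skipped isoform.
#' @export
scan_for_ptc <- function(iso) {
  if (iso$start_lost || is.na(iso$cds_start)) {
    stop("isoform has no intact CDS start; PTC scan not applicable")
  }
  s <- iso$sequence
  from <- iso$cds_start
  n_codons <- (nchar(s) - from + 1L) %/% 3L
  if (n_codons < 1L) return(NULL)
  starts <- from + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(s, starts, starts + 2L)
  hit <- which(codons %in% STOP_CODONS)
  if (!length(hit)) return(NULL)
  ptc_start <- starts[hit[1L]]
  ptc_end <- ptc_start + 2L
  if (!is.na(iso$stop_end) && ptc_end >= iso$stop_end) return(NULL)
  list(ptc_start = ptc_start, ptc_end = ptc_end)
}

#' Apply the 50-nt NMD rule
#'
#' A PTC marks the isoform as NMD-targeting when it lies more than
#' `rule_distance` nucleotides upstream of the final exon-exon junction.
#' Distance is measured from the last base of the stop codon to the junction
#' (the last base of the penultimate exon); since the final junction is the
#' 3'-most one, a PTC more than `rule_distance` upstream of any junction
#' satisfies this test and vice versa.
#'
#' @param ptc_end Transcript coordinate of the PTC's last base.
#' @param iso A `SkippedIsoform`.
#' @param rule_distance Distance threshold in nt (default 50, strict >).
#' @return TRUE/FALSE; FALSE for isoforms with no remaining junction.
#' @export
is_nmd_targeting <- function(ptc_end, iso, rule_distance = 50) {
  if (!length(iso$junction_positions)) return(FALSE)
  last_junction <- max(iso$junction_positions)
  (last_junction - ptc_end) > rule_distance
}

#' Read a protein domain table
#'
#' @param path TSV with header `protein_id domain_id aa_start aa_end`
#'   (1-based inclusive protein coordinates). The protein_id convention is
#'   the transcript_id of the coding transcript.
#' @return data.frame of domain intervals.
#' @export
read_domain_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("protein_id", "domain_id", "aa_start", "aa_end")
  if (!all(need %in% names(x))) {
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(x$aa_start > x$aa_end) || any(x$aa_start < 1)) {
    stop("invalid domain intervals")
  }
  x
}

#' Conserved domains removed by an in-frame exon skip
#'
#' Maps the skipped exon's CDS overlap to protein coordinates (rounding
#' outward to whole codons when the exon starts or ends mid-codon) and
#' returns the domains whose intervals overlap that span by at least one
#' amino acid.
#'
#' @param t The parent `TranscriptModel` (coding).
#' @param exon_index Genomic-order index of the skipped exon.
#' @param domains data.frame from [read_domain_table()].
#' @return Character vector of affected domain_ids (empty when the protein is
#'   absent from the table, with a warning).
#' @export
domain_restoration <- function(t, exon_index, domains) {
  span <- exon_tx_span(t, exon_index)
  rs <- max(span[1L], t$cds_start) - t$cds_start + 1L
  re <- min(span[2L], t$cds_end) - t$cds_start + 1L
  if (re < rs) return(character(0))
  aa_start <- (rs - 1L) %/% 3L + 1L   # outward rounding to whole codons
  aa_end <- (re - 1L) %/% 3L + 1L
  d <- domains[domains$protein_id == t$transcript_id, , drop = FALSE]
  if (!nrow(d)) {
    if (!t$transcript_id %in% domains$protein_id) {
      warning("protein ", t$transcript_id, " absent from domain table")
    }
    return(character(0))
  }
  unique(d$domain_id[d$aa_start <= aa_end & d$aa_end >= aa_start])
}

#' Classify the consequence of a skipped-exon event
#'
#' Every transcript of the gene in which the skipped exon is internal is
#' evaluated; the event is NMD-targeting when any affected isoform yields a
#' PTC more than `rule_distance` nt upstream of its final exon-exon junction.
#' In-frame events are routed to domain analysis. Each event is therefore
#' counted once as NMD-targeting, domain-affecting, or neither.
#'
#' @param gene_id,exon_start,exon_end The skipped exon.
#' @param idx An `AnnotationIndex`.
#' @param genome A `DNAStringSet`.
#' @param domains Optional domain table from [read_domain_table()].
#' @param rule_distance NMD distance threshold (default 50).
#' @return A `ConsequenceCall`: list with gene_id, exon interval,
#'   frame_effect (of the first evaluated coding transcript; "noncoding" when
#'   no coding transcript contains the exon internally), nmd_targeting,
#'   ptc_position / distance_to_reference_junction (from the first isoform
#'   with a qualifying PTC, else the first PTC found), affected_domains,
#'   category ("nmd" / "domain" / "neither"), n_isoforms_evaluated.
#' @export
classify_consequence <- function(gene_id, exon_start, exon_end, idx, genome,
                                 domains = NULL, rule_distance = 50) {
  frame_effect <- "noncoding"
  nmd <- FALSE
  ptc_position <- NA_integer_
  dist <- NA_integer_
  affected <- character(0)
  n_eval <- 0L

  for (t in idx$transcripts) {
    if (t$gene_id != gene_id) next
    k <- which(t$exons$start == exon_start & t$exons$end == exon_end)
    if (length(k) != 1L || k == 1L || k == nrow(t$exons)) next
    ov <- exon_cds_overlap(t, k)
    fe <- classify_frame_effect(ov)
    n_eval <- n_eval + 1L
    if (fe == "noncoding") next
    if (frame_effect == "noncoding") frame_effect <- fe
    if (fe == "frameshift") {
      frame_effect <- "frameshift"
      iso <- construct_skipped_isoform(t, k, genome)
      if (iso$start_lost) next
      ptc <- scan_for_ptc(iso)
      if (!is.null(ptc)) {
        hit <- is_nmd_targeting(ptc$ptc_end, iso, rule_distance)
        if (is.na(ptc_position) || (hit && !nmd)) {
          ptc_position <- ptc$ptc_start
          dist <- if (length(iso$junction_positions)) {
            max(iso$junction_positions) - ptc$ptc_end
          } else NA_integer_
        }
        nmd <- nmd || hit
      }
    } else if (!is.null(domains)) {
      affected <- union(affected, domain_restoration(t, k, domains))
    }
  }

  category <- if (nmd) "nmd" else if (length(affected)) "domain" else "neither"
  structure(list(
    gene_id = gene_id, exon_start = exon_start, exon_end = exon_end,
    frame_effect = frame_effect, nmd_targeting = nmd,
    ptc_position = ptc_position, distance_to_reference_junction = dist,
    affected_domains = affected, category = category,
    n_isoforms_evaluated = n_eval
  ), class = "ConsequenceCall")
}

#' Consequence calls for a table of skipped-exon events
#'
#' @param events data.frame with gene_id, exon_start, exon_end (deduplicated
#'   exon intervals are evaluated once).
#' @param idx,genome,domains,rule_distance See [classify_consequence()].
#' @return data.frame: one row per distinct skipped exon with frame_effect,
#'   nmd_targeting, ptc_position, distance_to_reference_junction,
#'   affected_domains (comma-joined), category.
#' @export
consequence_table <- function(events, idx, genome, domains = NULL,
                              rule_distance = 50) {
  key <- paste(events$gene_id, events$exon_start, events$exon_end)
  ev <- events[!duplicated(key), , drop = FALSE]
  calls <- lapply(seq_len(nrow(ev)), function(i) {
    classify_consequence(ev$gene_id[i], ev$exon_start[i], ev$exon_end[i],
                         idx, genome, domains, rule_distance)
  })
  data.frame(
    gene_id = ev$gene_id, exon_start = ev$exon_start, exon_end = ev$exon_end,
    frame_effect = vapply(calls, `[[`, character(1), "frame_effect"),
    nmd_targeting = vapply(calls, `[[`, logical(1), "nmd_targeting"),
    ptc_position = vapply(calls, `[[`, integer(1), "ptc_position"),
    distance_to_reference_junction =
      vapply(calls, `[[`, integer(1), "distance_to_reference_junction"),
    affected_domains = vapply(calls, function(x)
      paste(x$affected_domains, collapse = ","), character(1)),
    category = vapply(calls, `[[`, character(1), "category"),
    stringsAsFactors = FALSE
  )
}
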