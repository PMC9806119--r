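#' @importFrom stats median p.adjust phyper fisher.test wilcox.test rbinom
#'   rnbinom rpois runif rbeta setNames complete.cases
#' @importFrom utils read.table write.table head
NULL

#' Junction identity key
#'
#' Coordinates are 1-based, fully inclusive, matching both GTF and the STAR
#' junction-table dialect: a junction is keyed by (contig, first intronic
#' base, last intronic base, strand).
#'
#' @param contig,start,end,strand Junction coordinates.
#' @return Character key `contig:start:end:strand`.
#' @export
junction_key <- function(contig, start, end, strand) {
  paste(contig, start, end, strand, sep = ":")
}

site_key <- function(contig, pos, strand) {
  paste(contig, pos, strand, sep = ":")
}

# Donor = 5' intron boundary in transcript orientation, so on the minus strand
# the donor has the larger genomic coordinate.
donor_position <- function(start, end, strand) ifelse(strand == "+", start, end)
acceptor_position <- function(start, end, strand) ifelse(strand == "+", end, start)

#' Read a genome FASTA into a genome sequence object
#'
#' @param fasta_path Path to an (uncompressed or gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by contig name, uppercased.
#' @export
read_genome <- function(fasta_path) {
  g <- Biostrings::readDNAStringSet(fasta_path)
  # FASTA headers may carry descriptions after the first token
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract genomic sequence, strand-aware
#'
#' Lookup by (contig, start, end, strand); minus strand returns the reverse
#' complement. Coordinates are 1-based inclusive.
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param contig,start,end,strand Interval to extract.
#' @return Character nucleotide string.
#' @export
genome_sequence <- function(genome, contig, start, end, strand = "+") {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  if (start < 1L || end > length(genome[[contig]])) {
    stop("coordinates [", start, ",", end, "] exceed contig ", contig, " bounds")
  }
  s <- Biostrings::subseq(genome[[contig]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

new_transcript_model <- function(transcript_id, gene_id, contig, strand,
                                 exons, cds_start = NA_integer_,
                                 cds_end = NA_integer_) {
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L) {
    if (any(exons$start[-1L] - exons$end[-nrow(exons)] < 2L)) {
      stop("transcript ", transcript_id,
           ": exons overlap or are not separated by at least one intronic base")
    }
  }
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id,
    contig = contig, strand = strand, exons = exons,
    cds_start = cds_start, cds_end = cds_end
  ), class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cds <- if (is.na(x$cds_start)) "non-coding" else
    sprintf("CDS %d-%d (tx coords)", x$cds_start, x$cds_end)
  cat(sprintf("TranscriptModel %s (%s) %s:%s, %d exons, %s\n",
              x$transcript_id, x$gene_id, x$contig, x$strand,
              nrow(x$exons), cds))
  invisible(x)
}

transcript_length <- function(t) sum(t$exons$end - t$exons$start + 1L)

# Exon order in transcript (5'->3') orientation.
tx_exon_order <- function(t) {
  if (t$strand == "+") seq_len(nrow(t$exons)) else rev(seq_len(nrow(t$exons)))
}

# Map a genomic position to a transcript coordinate (NA if intronic/outside).
genomic_to_tx <- function(t, pos) {
  ord <- tx_exon_order(t)
  offset <- 0L
  for (i in ord) {
    s <- t$exons$start[i]; e <- t$exons$end[i]
    if (pos >= s && pos <= e) {
      within <- if (t$strand == "+") pos - s else e - pos
      return(offset + within + 1L)
    }
    offset <- offset + (e - s + 1L)
  }
  NA_integer_
}

# Map a transcript coordinate back to a genomic position.
tx_to_genomic <- function(t, tpos) {
  ord <- tx_exon_order(t)
  offset <- 0L
  for (i in ord) {
    len <- t$exons$end[i] - t$exons$start[i] + 1L
    if (tpos <= offset + len) {
      within <- tpos - offset - 1L
      return(if (t$strand == "+") t$exons$start[i] + within
             else t$exons$end[i] - within)
    }
    offset <- offset + len
  }
  NA_integer_
}

#' Spliced transcript sequence
#'
#' Concatenates exonic sequence in 5'->3' transcript orientation;
#' minus-strand transcripts are reverse-complemented. The result has length
#' equal to the sum of exon lengths.
#'
#' @param t A `TranscriptModel`.
#' @param genome A `DNAStringSet`.
#' @return Character nucleotide string.
#' @export
transcript_sequence <- function(t, genome) {
  if (!t$contig %in% names(genome)) stop("unknown contig: ", t$contig)
  w <- length(genome[[t$contig]])
  if (any(t$exons$start < 1L) || any(t$exons$end > w)) {
    stop("transcript ", t$transcript_id, ": exon exceeds contig bounds")
  }
  pieces <- Biostrings::extractAt(
    genome[[t$contig]],
    IRanges::IRanges(t$exons$start, t$exons$end)
  )
  s <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  if (t$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Enumerate the introns of a transcript
#'
#' @param t A `TranscriptModel`.
#' @return data.frame with columns `start`, `end`: the gaps between
#'   consecutive exons, 1-based inclusive of the first and last intronic base,
#'   in genomic order. Zero rows for single-exon transcripts.
#' @export
enumerate_introns <- function(t) {
  n <- nrow(t$exons)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = t$exons$end[-n] + 1L, end = t$exons$start[-1L] - 1L)
}

# Pre-scan a GTF for structurally malformed lines so parse failures carry a
# line number (rtracklayer reports only the first offending record).
validate_gtf_lines <- function(gtf_path) {
  lines <- readLines(gtf_path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nf < 9L]
  if (length(bad)) {
    stop("malformed GTF line ", bad[1L], " in ", gtf_path,
         ": expected 9 tab-separated fields, found ", nf[match(bad[1L], which(body))])
  }
  invisible(TRUE)
}

#' Load annotation and expression into a queryable index
#'
#' Parses a GTF (Ensembl attribute dialect) with gene/transcript/exon and
#' optional CDS features, attaches per-gene TPM from an expression table, and
#' enumerates the annotated-junction universe together with strand-aware
#' donor and acceptor site sets. CDS features are taken to include the stop
#' codon; annotations that separate a `stop_codon` feature should have it
#' merged into the CDS first.
#'
#' @param gtf_path Path to a GTF file.
#' @param expression_table Path to a TSV with header `gene_id<TAB>tpm`, or
#'   `NULL` for tpm = 0 everywhere. Genes absent from the table get tpm = 0.
#' @return An `AnnotationIndex`: a list with elements `genes` (data.frame:
#'   gene_id, contig, strand, start, end, tpm, multi_exon), `transcripts`
#'   (named list of `TranscriptModel`), `junctions` (data.frame of the
#'   deduplicated annotated-junction universe with gene_id), `junction_keys`,
#'   `donor_keys`, `acceptor_keys` (character sets), and `gene_ranges`
#'   (GRanges used for junction-to-gene assignment).
#' @export
load_annotation <- function(gtf_path, expression_table = NULL) {
  validate_gtf_lines(gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (!all(c("type", "gene_id") %in% colnames(meta))) {
    stop("GTF lacks type/gene_id attributes")
  }

  ex <- gr[meta$type == "exon"]
  if (length(ex) == 0L) stop("GTF contains no exon features")
  cds <- gr[meta$type %in% c("CDS", "cds")]

  exd <- data.frame(
    contig = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = as.character(S4Vectors::mcols(ex)$gene_id),
    transcript_id = as.character(S4Vectors::mcols(ex)$transcript_id),
    stringsAsFactors = FALSE
  )
  cdsd <- if (length(cds)) data.frame(
    start = GenomicRanges::start(cds), end = GenomicRanges::end(cds),
    transcript_id = as.character(S4Vectors::mcols(cds)$transcript_id),
    stringsAsFactors = FALSE
  ) else data.frame(start = integer(0), end = integer(0),
                    transcript_id = character(0))

  transcripts <- list()
  for (tid in unique(exd$transcript_id)) {
    rows <- exd[exd$transcript_id == tid, , drop = FALSE]
    if (length(unique(rows$contig)) > 1L) {
      stop("transcript ", tid, ": exons on multiple contigs (validation error)")
    }
    t <- new_transcript_model(
      tid, rows$gene_id[1L], rows$contig[1L], rows$strand[1L],
      data.frame(start = rows$start, end = rows$end)
    )
    crow <- cdsd[cdsd$transcript_id == tid, , drop = FALSE]
    if (nrow(crow)) {
      # CDS 5'-most / 3'-most bases in transcript orientation
      gpos <- sort(c(crow$start, crow$end))
      g5 <- if (t$strand == "+") min(crow$start) else max(crow$end)
      g3 <- if (t$strand == "+") max(crow$end) else min(crow$start)
      t$cds_start <- genomic_to_tx(t, g5)
      t$cds_end <- genomic_to_tx(t, g3)
      if (is.na(t$cds_start) || is.na(t$cds_end)) {
        stop("transcript ", tid, ": CDS boundary not exonic")
      }
      if ((t$cds_end - t$cds_start + 1L) %% 3L != 0L) {
        stop("transcript ", tid, ": CDS length not divisible by 3")
      }
    }
    transcripts[[tid]] <- t
  }

  # Annotated junction universe, deduplicated across transcripts
  jl <- lapply(transcripts, function(t) {
    intr <- enumerate_introns(t)
    if (!nrow(intr)) return(NULL)
    data.frame(contig = t$contig, start = intr$start, end = intr$end,
               strand = t$strand, gene_id = t$gene_id,
               stringsAsFactors = FALSE)
  })
  junctions <- do.call(rbind, jl)
  if (is.null(junctions)) {
    junctions <- data.frame(contig = character(0), start = integer(0),
                            end = integer(0), strand = character(0),
                            gene_id = character(0))
  }
  junctions <- junctions[!duplicated(junction_key(
    junctions$contig, junctions$start, junctions$end, junctions$strand
  )), , drop = FALSE]
  rownames(junctions) <- NULL

  tpm <- stats::setNames(numeric(0), character(0))
  if (!is.null(expression_table)) {
    et <- utils::read.table(expression_table, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!all(c("gene_id", "tpm") %in% names(et))) {
      stop("expression table must have columns gene_id, tpm")
    }
    if (any(et$tpm < 0)) stop("negative TPM in expression table")
    tpm <- stats::setNames(et$tpm, et$gene_id)
  }

  gid <- vapply(transcripts, function(t) t$gene_id, character(1))
  genes <- do.call(rbind, lapply(split(names(transcripts), gid), function(tids) {
    ts <- transcripts[tids]
    data.frame(
      gene_id = ts[[1L]]$gene_id, contig = ts[[1L]]$contig,
      strand = ts[[1L]]$strand,
      start = min(vapply(ts, function(t) min(t$exons$start), integer(1))),
      end = max(vapply(ts, function(t) max(t$exons$end), integer(1))),
      stringsAsFactors = FALSE
    )
  }))
  rownames(genes) <- NULL
  genes$tpm <- unname(ifelse(genes$gene_id %in% names(tpm),
                             tpm[genes$gene_id], 0))
  genes$multi_exon <- genes$gene_id %in% junctions$gene_id

  gene_ranges <- GenomicRanges::GRanges(
    genes$contig, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand, gene_id = genes$gene_id
  )

  structure(list(
    genes = genes,
    transcripts = transcripts,
    junctions = junctions,
    junction_keys = junction_key(junctions$contig, junctions$start,
                                 junctions$end, junctions$strand),
    donor_keys = unique(site_key(
      junctions$contig,
      donor_position(junctions$start, junctions$end, junctions$strand),
      junctions$strand)),
    acceptor_keys = unique(site_key(
      junctions$contig,
      acceptor_position(junctions$start, junctions$end, junctions$strand),
      junctions$strand)),
    gene_ranges = gene_ranges
  ), class = "AnnotationIndex")
}

#' @export
print.AnnotationIndex <- function(x, ...) {
  cat(sprintf("AnnotationIndex: %d genes, %d transcripts, %d annotated junctions\n",
              nrow(x$genes), length(x$transcripts), nrow(x$junctions)))
  cat(sprintf("  genes with TPM > 10: %d; multi-exon genes: %d\n",
              sum(x$genes$tpm > 10), sum(x$genes$multi_exon)))
  invisible(x)
}

#' Genes eligible for the unannotated-junction analysis
#'
#' Robustly expressed (TPM strictly above the gate) and multi-exon genes;
#' single-exon genes have no annotated junction, so the 10%-of-max
#' denominator is undefined for them.
#'
#' @param idx An `AnnotationIndex`.
#' @param tpm_gate Expression gate (default 10, strict).
#' @return Character vector of gene ids.
#' @export
eligible_genes <- function(idx, tpm_gate = 10) {
  idx$genes$gene_id[idx$genes$tpm > tpm_gate & idx$genes$multi_exon]
}
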