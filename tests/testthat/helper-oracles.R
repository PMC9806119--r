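# Independent brute-force oracles. These deliberately share no code with the
# package implementation paths they check.

# Upper-tail hypergeometric probability by explicit enumeration of the tail.
oracle_hyper_tail <- function(k, size_a, size_b, n_universe) {
  if (k == 0) return(1)
  i <- k:min(size_a, size_b)
  sum(exp(lchoose(size_a, i) + lchoose(n_universe - size_a, size_b - i) -
            lchoose(n_universe, size_b)))
}

# Two-sided Fisher exact p for a 2x2 table by enumerating all tables with the
# observed margins (sum of probabilities <= observed, with tolerance).
oracle_fisher_2x2 <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  xs <- max(0, k - n):min(k, m)
  probs <- exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

ORACLE_STOPS <- c("TAA", "TAG", "TGA")
ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(ORACLE_COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# Splice-translate-measure oracle for NMD targeting: removes exon `skip`
# (genomic-order index) from the transcript, and -- when the removed stretch
# of coding sequence is frame-disrupting -- translates codon by codon from
# the (remapped) CDS start and applies the >50-nt final-junction distance
# rule literally. Works directly on genomic substrings.
oracle_nmd <- function(t, skip, genome, rule_distance = 50) {
  contig <- as.character(genome[[t$contig]])
  ex <- t$exons[-skip, , drop = FALSE]
  pieces <- substring(contig, ex$start, ex$end)
  if (t$strand == "-") {
    pieces <- rev(vapply(pieces, oracle_revcomp, character(1)))
  }
  seq <- paste(pieces, collapse = "")
  lens <- nchar(pieces)
  junctions <- cumsum(lens)[-length(lens)]

  # transcript-coordinate span of the skipped exon
  ord <- if (t$strand == "+") seq_len(nrow(t$exons)) else rev(seq_len(nrow(t$exons)))
  tx_lens <- (t$exons$end - t$exons$start + 1)[ord]
  skip_pos <- match(skip, ord)
  skip_a <- if (skip_pos == 1) 1 else sum(tx_lens[seq_len(skip_pos - 1)]) + 1
  skip_b <- skip_a + tx_lens[skip_pos] - 1

  cs0 <- t$cds_start; ce0 <- t$cds_end
  cds_removed <- max(0, min(skip_b, ce0) - max(skip_a, cs0) + 1)
  if (cds_removed %% 3 == 0) return(list(nmd = FALSE, reason = "not frameshift"))
  if (skip_a <= cs0 + 2 && skip_b >= cs0) return(list(nmd = FALSE, reason = "start lost"))

  cs <- if (skip_b < cs0) cs0 - (skip_b - skip_a + 1) else cs0
  stop_end <- if (skip_a <= ce0 && skip_b >= ce0 - 2) NA else
    if (skip_a > ce0) ce0 else ce0 - cds_removed

  pos <- cs
  ptc_end <- NA
  while (pos + 2 <= nchar(seq)) {
    codon <- substr(seq, pos, pos + 2)
    if (codon %in% ORACLE_STOPS) {
      if (!is.na(stop_end) && pos + 2 >= stop_end) break  # annotated stop reached
      ptc_end <- pos + 2
      break
    }
    pos <- pos + 3
  }
  if (is.na(ptc_end) || !length(junctions)) {
    return(list(nmd = FALSE, ptc_end = ptc_end))
  }
  list(nmd = (max(junctions) - ptc_end) > rule_distance, ptc_end = ptc_end)
}
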