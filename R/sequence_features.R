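# Sequence-feature profiling of event sets: GC content, exon/intron lengths,
# and splice-site strength under a trainable log-odds position-weight-matrix
# scorer. Window conventions follow the common maximum-entropy scorer so
# externally computed scores can be slotted in: donor 9-mer = last 3 exonic +
# first 6 intronic bases; acceptor 23-mer = last 20 intronic + first 3 exonic.

DONOR_WIDTH <- 9L
ACCEPTOR_WIDTH <- 23L
DNA_BASES <- c("A", "C", "G", "T")

#' GC content of a nucleotide string
#'
#' @param seq Nonempty nucleotide string; N bases are excluded from both
#'   numerator and denominator.
#' @return (G + C) / non-N length; `NA` for all-N sequences.
#' @export
gc_content <- function(seq) {
  vapply(seq, function(s) {
    if (!nzchar(s)) stop("empty sequence")
    b <- strsplit(toupper(s), "")[[1L]]
    b <- b[b != "N"]
    if (!length(b)) return(NA_real_)
    sum(b %in% c("G", "C")) / length(b)
  }, numeric(1), USE.NAMES = FALSE)
}

# Donor / acceptor windows of a junction (intron [start, end], strand-aware).
# Returns NA when a window runs off the contig.
site_window <- function(genome, contig, start, end, strand, kind) {
  w <- length(genome[[contig]])
  if (kind == "donor") {
    rng <- if (strand == "+") c(start - 3L, start + 5L) else c(end - 5L, end + 3L)
  } else {
    rng <- if (strand == "+") c(end - 19L, end + 3L) else c(start - 3L, start + 19L)
  }
  if (rng[1L] < 1L || rng[2L] > w) return(NA_character_)
  genome_sequence(genome, contig, rng[1L], rng[2L], strand)
}

site_windows <- function(genome, junctions, kind) {
  vapply(seq_len(nrow(junctions)), function(i) {
    site_window(genome, junctions$contig[i], junctions$start[i],
                junctions$end[i], junctions$strand[i], kind)
  }, character(1))
}

count_matrix <- function(windows, width) {
  m <- matrix(0, nrow = 4L, ncol = width, dimnames = list(DNA_BASES, NULL))
  for (wdw in windows) {
    b <- strsplit(wdw, "")[[1L]]
    for (p in seq_len(width)) {
      if (b[p] %in% DNA_BASES) m[b[p], p] <- m[b[p], p] + 1
    }
  }
  m
}

#' Train a splice-site position-weight-matrix model from the annotation
#'
#' Donor and acceptor probability matrices are estimated from all annotated
#' junctions with fully resolvable windows (strand-aware extraction; sites
#' whose window runs off the contig are skipped with a warning). The
#' background is the pooled base composition of the training windows.
#'
#' @param idx An `AnnotationIndex`.
#' @param genome A `DNAStringSet`.
#' @param pseudocount Added per base per column before normalization
#'   (default 0.5).
#' @return A `SpliceSiteModel`: list with `donor` and `acceptor` probability
#'   matrices (columns sum to 1), `background` (named base frequencies), and
#'   `pseudocount`.
#' @export
train_pwm_from_annotation <- function(idx, genome, pseudocount = 0.5) {
  j <- idx$junctions
  if (!nrow(j)) stop("no annotated junctions to train on")
  dw <- site_windows(genome, j, "donor")
  aw <- site_windows(genome, j, "acceptor")
  if (anyNA(dw) || anyNA(aw)) {
    warning(sum(is.na(dw)) + sum(is.na(aw)),
            " site window(s) ran off a contig; skipped")
  }
  dw <- dw[!is.na(dw)]; aw <- aw[!is.na(aw)]
  if (!length(dw) || !length(aw)) stop("no resolvable training windows")

  normalize <- function(counts) {
    p <- counts + pseudocount
    sweep(p, 2L, colSums(p), "/")
  }
  # background = pooled composition across all window positions
  all_counts <- rowSums(count_matrix(dw, DONOR_WIDTH)) +
    rowSums(count_matrix(aw, ACCEPTOR_WIDTH))
  bg <- (all_counts + pseudocount) / sum(all_counts + pseudocount)

  structure(list(
    donor = normalize(count_matrix(dw, DONOR_WIDTH)),
    acceptor = normalize(count_matrix(aw, ACCEPTOR_WIDTH)),
    background = bg,
    pseudocount = pseudocount,
    n_donor = length(dw), n_acceptor = length(aw)
  ), class = "SpliceSiteModel")
}

#' @export
print.SpliceSiteModel <- function(x, ...) {
  cat(sprintf("SpliceSiteModel: donor 9-mer PWM (%d sites), acceptor 23-mer PWM (%d sites), pseudocount %.2g\n",
              x$n_donor, x$n_acceptor, x$pseudocount))
  invisible(x)
}

#' Log-odds splice-site score
#'
#' Sum over window positions of log2(p_model / p_background); higher means a
#' stronger site. N bases contribute 0.
#'
#' @param model A `SpliceSiteModel`.
#' @param window Nucleotide string of the correct width (9 for donor, 23 for
#'   acceptor).
#' @param kind "donor" or "acceptor".
#' @return Numeric log2-odds score.
#' @export
splice_site_score <- function(model, window, kind = c("donor", "acceptor")) {
  kind <- match.arg(kind)
  width <- if (kind == "donor") DONOR_WIDTH else ACCEPTOR_WIDTH
  if (nchar(window) != width) {
    stop(kind, " window must be ", width, " nt, got ", nchar(window))
  }
  pwm <- model[[kind]]
  b <- strsplit(toupper(window), "")[[1L]]
  score <- 0
  for (p in seq_len(width)) {
    if (b[p] %in% DNA_BASES) {
      score <- score + log2(pwm[b[p], p] / model$background[b[p]])
    }
  }
  unname(score)
}

score_junction_sites <- function(model, genome, junctions) {
  dw <- site_windows(genome, junctions, "donor")
  aw <- site_windows(genome, junctions, "acceptor")
  data.frame(
    donor_score = vapply(dw, function(w) {
      if (is.na(w)) NA_real_ else splice_site_score(model, w, "donor")
    }, numeric(1), USE.NAMES = FALSE),
    acceptor_score = vapply(aw, function(w) {
      if (is.na(w)) NA_real_ else splice_site_score(model, w, "acceptor")
    }, numeric(1), USE.NAMES = FALSE)
  )
}

# All annotated exons / introns of expressed genes, deduplicated by interval.
annotated_exon_table <- function(idx, tpm_gate = 10) {
  expressed <- idx$genes$gene_id[idx$genes$tpm > tpm_gate]
  rows <- lapply(idx$transcripts, function(t) {
    if (!t$gene_id %in% expressed) return(NULL)
    data.frame(contig = t$contig, start = t$exons$start, end = t$exons$end,
               strand = t$strand, stringsAsFactors = FALSE)
  })
  ex <- do.call(rbind, rows)
  if (is.null(ex)) stop("no exons in expressed genes")
  ex[!duplicated(paste(ex$contig, ex$start, ex$end, ex$strand)), , drop = FALSE]
}

annotated_intron_table <- function(idx, tpm_gate = 10) {
  expressed <- idx$genes$gene_id[idx$genes$tpm > tpm_gate]
  j <- idx$junctions[idx$junctions$gene_id %in% expressed, , drop = FALSE]
  if (!nrow(j)) stop("no annotated introns in expressed genes")
  j
}

feature_row <- function(feature, set_values, baseline_values) {
  set_values <- set_values[!is.na(set_values)]
  baseline_values <- baseline_values[!is.na(baseline_values)]
  p <- if (length(set_values) && length(baseline_values)) {
    suppressWarnings(stats::wilcox.test(set_values, baseline_values,
                                        exact = FALSE)$p.value)
  } else NA_real_
  data.frame(
    feature = feature,
    set_mean = mean(set_values), set_median = stats::median(set_values),
    baseline_mean = mean(baseline_values),
    baseline_median = stats::median(baseline_values),
    n_set = length(set_values), n_baseline = length(baseline_values),
    p_value = p, stringsAsFactors = FALSE
  )
}

#' Feature summary of a skipped-exon event set against annotation baselines
#'
#' Computes set means/medians for the skipped exon length, flanking exon and
#' intron lengths, and the four splice-site scores of a skipping event
#' (upstream-exon donor, skipped-exon acceptor, skipped-exon donor,
#' downstream-exon acceptor), alongside annotation-wide baselines over all
#' exons/introns of expressed genes and a two-sided rank-test p-value per
#' feature (Bonferroni-corrected across features).
#'
#' @param events Event table from [enumerate_skipped_exon_events()] (any
#'   subset).
#' @param idx An `AnnotationIndex`.
#' @param genome A `DNAStringSet`.
#' @param model A `SpliceSiteModel`.
#' @param tpm_gate Expression gate for baselines (default 10).
#' @return data.frame: one row per feature with set/baseline statistics,
#'   p_value and p_bonferroni.
#' @export
exon_event_feature_summary <- function(events, idx, genome, model,
                                       tpm_gate = 10) {
  if (!nrow(events)) stop("empty event set")
  base_ex <- annotated_exon_table(idx, tpm_gate)
  base_in <- annotated_intron_table(idx, tpm_gate)
  base_scores <- score_junction_sites(model, genome, base_in)

  up_don <- score_junction_sites(
    model, genome,
    data.frame(contig = events$contig, start = events$inc1_start,
               end = events$inc1_end, strand = events$strand))
  down_acc <- score_junction_sites(
    model, genome,
    data.frame(contig = events$contig, start = events$inc2_start,
               end = events$inc2_end, strand = events$strand))

  rows <- rbind(
    feature_row("skipped_exon_length",
                events$exon_end - events$exon_start + 1,
                base_ex$end - base_ex$start + 1),
    feature_row("upstream_exon_length",
                events$up_end - events$up_start + 1,
                base_ex$end - base_ex$start + 1),
    feature_row("downstream_exon_length",
                events$down_end - events$down_start + 1,
                base_ex$end - base_ex$start + 1),
    feature_row("upstream_intron_length",
                events$inc1_end - events$inc1_start + 1,
                base_in$end - base_in$start + 1),
    feature_row("downstream_intron_length",
                events$inc2_end - events$inc2_start + 1,
                base_in$end - base_in$start + 1),
    feature_row("upstream_exon_donor_score", up_don$donor_score,
                base_scores$donor_score),
    feature_row("skipped_exon_acceptor_score", up_don$acceptor_score,
                base_scores$acceptor_score),
    feature_row("skipped_exon_donor_score", down_acc$donor_score,
                base_scores$donor_score),
    feature_row("downstream_exon_acceptor_score", down_acc$acceptor_score,
                base_scores$acceptor_score)
  )
  rows$p_bonferroni <- pmin(1, rows$p_value * nrow(rows))
  rows
}

#' Feature summary of an intron set against annotation baselines
#'
#' Lengths, GC content, and donor/acceptor scores of the given introns,
#' against baselines over all annotated introns of expressed genes.
#'
#' @param introns data.frame with contig, intron_start, intron_end, strand
#'   (e.g. a scored retention table).
#' @param idx,genome,model,tpm_gate See [exon_event_feature_summary()].
#' @return data.frame of per-feature statistics with p_bonferroni.
#' @export
intron_feature_summary <- function(introns, idx, genome, model,
                                   tpm_gate = 10) {
  if (!nrow(introns)) stop("empty intron set")
  base_in <- annotated_intron_table(idx, tpm_gate)
  base_scores <- score_junction_sites(model, genome, base_in)
  base_gc <- gc_content(vapply(seq_len(nrow(base_in)), function(i) {
    genome_sequence(genome, base_in$contig[i], base_in$start[i],
                    base_in$end[i], base_in$strand[i])
  }, character(1)))

  set <- data.frame(contig = introns$contig, start = introns$intron_start,
                    end = introns$intron_end, strand = introns$strand,
                    stringsAsFactors = FALSE)
  set_scores <- score_junction_sites(model, genome, set)
  set_gc <- gc_content(vapply(seq_len(nrow(set)), function(i) {
    genome_sequence(genome, set$contig[i], set$start[i], set$end[i],
                    set$strand[i])
  }, character(1)))

  rows <- rbind(
    feature_row("intron_length", set$end - set$start + 1,
                base_in$end - base_in$start + 1),
    feature_row("intron_gc", set_gc, base_gc),
    feature_row("donor_score", set_scores$donor_score,
                base_scores$donor_score),
    feature_row("acceptor_score", set_scores$acceptor_score,
                base_scores$acceptor_score)
  )
  rows$p_bonferroni <- pmin(1, rows$p_value * nrow(rows))
  rows
}
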