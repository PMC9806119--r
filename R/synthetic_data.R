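# Seeded synthetic-data generator. Emits a self-contained fixture bundle --
# genome FASTA, GTF annotation, expression table, per-sample junction tables,
# per-intron coverage, protein-domain table -- with known ground truth
# (per-exon true inclusion, per-intron true retention, injected unannotated
# junctions with class labels, per-event consequence labels), so that every
# pipeline stage is testable without controlled-access data.
#
# Gene architecture: each gene carries two annotated isoforms -- the full
# transcript and a skip isoform lacking one designated internal "event" exon
# (so the skipping junction itself is annotated and inclusion levels are
# measured on annotated junctions only). Injected unannotated junctions are
# separate, controlled coordinates in one of the three taxonomy classes:
# exon-skip (both sites annotated, novel pairing), hemi-annotated, and fully
# novel.

NON_STOP_CODONS <- {
  all_codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                      collapse = "")
  setdiff(all_codons, STOP_CODONS)
}

rand_seq <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rand_codons <- function(n) paste(sample(NON_STOP_CODONS, n, replace = TRUE),
                                 collapse = "")

#' Simulation configuration
#'
#' Defaults encode the bundled "paper-shape" contrast: condition A emulates a
#' blood naive-B-cell-like state (30% of eligible genes carrying an injected
#' unannotated junction, largely uncommitted exon inclusion, high intron
#' retention) and condition B a differentiated-like state (5% injected,
#' committed inclusion, low retention).
#'
#' @param seed Mandatory integer seed; every emitted file is deterministic
#'   under it.
#' @param n_genes Number of genes (default 120).
#' @param exons_per_gene Inclusive range (default 4..8; at least 4 so every
#'   gene has two distinct internal exons).
#' @param exon_length,intron_length Inclusive uniform ranges in nt.
#' @param gc_exon,gc_intron GC content of untranslated exonic / intronic
#'   sequence.
#' @param minus_fraction Fraction of genes on the minus strand.
#' @param frameshift_fraction Fraction of event exons whose length is not
#'   divisible by 3.
#' @param domain_fraction Fraction of in-frame event exons whose codon span
#'   is covered by a protein domain (ground-truth "domain" events).
#' @param expressed_fraction Fraction of genes given TPM above the gate.
#' @param depth_mean,depth_dispersion Negative-binomial junction depth
#'   (dispersion is the NB overdispersion; variance = mu + disp * mu^2).
#' @param injected_depth_fraction Injected unannotated junction depth as a
#'   fraction of the gene's maximum annotated depth in the sample.
#' @param n_replicates Replicates per condition.
#' @param conditions Named list; per condition: `unannotated_gene_fraction`,
#'   `committed_fraction` (exons with true psi in {0, 1}),
#'   `psi_beta` (shape pair for uncommitted exons),
#'   `gene_high_retention_fraction` (genes given at least one intron with
#'   true retention in 0.35..0.7; other introns get 0..0.1).
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(seed,
                              n_genes = 120L,
                              exons_per_gene = c(4L, 8L),
                              exon_length = c(90L, 300L),
                              intron_length = c(120L, 600L),
                              gc_exon = 0.5, gc_intron = 0.45,
                              minus_fraction = 0.4,
                              frameshift_fraction = 0.5,
                              domain_fraction = 0.5,
                              expressed_fraction = 0.85,
                              depth_mean = 200, depth_dispersion = 0.1,
                              injected_depth_fraction = 0.15,
                              n_replicates = 2L,
                              conditions = list(
                                A = list(unannotated_gene_fraction = 0.30,
                                         committed_fraction = 0.3,
                                         psi_beta = c(2, 2),
                                         gene_high_retention_fraction = 0.6),
                                B = list(unannotated_gene_fraction = 0.05,
                                         committed_fraction = 0.9,
                                         psi_beta = c(2, 2),
                                         gene_high_retention_fraction = 0.1)
                              )) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(exons_per_gene[1L] >= 4L, n_genes >= 1L,
            frameshift_fraction >= 0, frameshift_fraction <= 1,
            injected_depth_fraction >= 0, injected_depth_fraction <= 1)
  structure(as.list(environment()), class = "SimulationConfig")
}

# Map a transcript-orientation locus position to the plus-strand genome.
locus_to_genomic <- function(pos, strand, locus_len) {
  if (strand == "+") pos else locus_len - pos + 1L
}

locus_interval_to_genomic <- function(s, e, strand, locus_len) {
  a <- locus_to_genomic(s, strand, locus_len)
  b <- locus_to_genomic(e, strand, locus_len)
  c(min(a, b), max(a, b))
}

# Build one gene: sequences, isoforms, event exon, injected-junction
# candidate, domain intervals, and consequence truth. Uses the current RNG
# stream.
build_gene <- function(gi, cfg) {
  gene_id <- sprintf("G%04d", gi)
  contig <- sprintf("ctg%04d", gi)
  strand <- if (stats::runif(1) < cfg$minus_fraction) "-" else "+"
  n_ex <- sample(seq(cfg$exons_per_gene[1L], cfg$exons_per_gene[2L]), 1L)
  lens <- sample(seq(cfg$exon_length[1L], cfg$exon_length[2L]), n_ex,
                 replace = TRUE)
  ilens <- sample(seq(cfg$intron_length[1L], cfg$intron_length[2L]),
                  n_ex - 1L, replace = TRUE)
  k <- sample(2:(n_ex - 1L), 1L)  # event exon (transcript order)
  frameshift <- stats::runif(1) < cfg$frameshift_fraction
  rem <- lens[k] %% 3L
  if (frameshift && rem == 0L) lens[k] <- lens[k] + sample(1:2, 1L)
  if (!frameshift && rem != 0L) lens[k] <- lens[k] + (3L - rem)

  total <- sum(lens)
  utr5 <- sample(30:min(60L, lens[1L] - 6L), 1L)
  utr3 <- sample(40:min(80L, lens[n_ex] - 6L), 1L)
  cds_len <- total - utr5 - utr3
  utr3 <- utr3 + cds_len %% 3L           # keep CDS divisible by 3
  cds_len <- total - utr5 - utr3
  stopifnot(cds_len >= 9L, utr5 + 3L <= lens[1L], utr3 + 3L <= lens[n_ex])

  mrna <- paste0(rand_seq(utr5, cfg$gc_exon), "ATG",
                 rand_codons(cds_len / 3L - 2L), "TAA",
                 rand_seq(utr3, cfg$gc_exon))
  cds_start <- utr5 + 1L
  cds_end <- utr5 + cds_len

  # transcript-orientation locus: pad | e1 | i1 | ... | en | pad
  pad <- 50L
  introns <- vapply(ilens, function(il)
    paste0("GT", rand_seq(il - 4L, cfg$gc_intron), "AG"), character(1))
  exon_seqs <- substring(mrna, cumsum(c(0L, lens[-n_ex])) + 1L, cumsum(lens))
  pieces <- character(2L * n_ex - 1L)
  pieces[seq(1L, by = 2L, length.out = n_ex)] <- exon_seqs
  if (n_ex > 1L) pieces[seq(2L, by = 2L, length.out = n_ex - 1L)] <- introns
  locus <- paste0(rand_seq(pad, cfg$gc_intron), paste(pieces, collapse = ""),
                  rand_seq(pad, cfg$gc_intron))
  M <- nchar(locus)

  # exon locus coordinates (transcript orientation)
  la <- integer(n_ex); lb <- integer(n_ex)
  cursor <- pad
  for (j in seq_len(n_ex)) {
    la[j] <- cursor + 1L
    lb[j] <- cursor + lens[j]
    cursor <- lb[j] + if (j < n_ex) ilens[j] else 0L
  }

  contig_seq <- if (strand == "+") locus else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(locus)))
  gmap <- function(s, e) locus_interval_to_genomic(s, e, strand, M)
  ex_g <- t(vapply(seq_len(n_ex), function(j) gmap(la[j], lb[j]), integer(2)))

  # injected unannotated junction candidate (locus coordinates span the
  # excised interval, i.e. behave like an intron)
  cls <- sample(c("exon_skip", "hemi", "novel"), 1L)
  internal <- setdiff(2:(n_ex - 1L), k)
  if (cls == "exon_skip" && !length(internal)) cls <- "hemi"
  if (cls == "exon_skip") {
    k2 <- if (length(internal) == 1L) internal else sample(internal, 1L)
    inj <- c(lb[k2 - 1L] + 1L, la[k2 + 1L] - 1L)
  } else {
    m <- sample(seq_len(n_ex - 1L), 1L)      # host intron
    is_ <- lb[m] + 1L; ie_ <- la[m + 1L] - 1L
    inj <- if (cls == "hemi") {
      # anchor either the donor or the acceptor at an annotated site
      if (stats::runif(1) < 0.5) c(is_, ie_ - 37L) else c(is_ + 37L, ie_)
    } else c(is_ + 23L, ie_ - 23L)
  }
  inj_g <- gmap(inj[1L], inj[2L])

  # consequence ground truth by direct forward construction on the mRNA
  exon_tx <- cbind(cumsum(c(0L, lens[-n_ex])) + 1L, cumsum(lens))
  a <- exon_tx[k, 1L]; b <- exon_tx[k, 2L]
  frame_effect <- if (lens[k] %% 3L == 0L) "in_frame" else "frameshift"
  truth_category <- "neither"; ptc_dist <- NA_integer_
  domain_rows <- NULL
  prot_len <- cds_len / 3L - 1L
  if (frame_effect == "frameshift") {
    # frameshift-gene proteins still get a domain record (clear of the event
    # exon) so every coding protein appears in the domain table
    rs <- max(a, cds_start) - cds_start + 1L
    aa1 <- (rs - 1L) %/% 3L + 1L
    if (aa1 > 4L) {
      domain_rows <- data.frame(protein_id = paste0(gene_id, ".t1"),
                                domain_id = paste0("DECOY_", gene_id),
                                aa_start = 1L, aa_end = min(10L, aa1 - 2L),
                                stringsAsFactors = FALSE)
    }
    skipped <- paste0(substr(mrna, 1L, a - 1L), substr(mrna, b + 1L, total))
    jpos <- cumsum(lens[-k]); jpos <- jpos[-length(jpos)]
    nc <- (nchar(skipped) - cds_start + 1L) %/% 3L
    st <- cds_start + 3L * (seq_len(nc) - 1L)
    codons <- substring(skipped, st, st + 2L)
    hit <- which(codons %in% STOP_CODONS)
    if (length(hit)) {
      ptc_end <- st[hit[1L]] + 2L
      ptc_dist <- max(jpos) - ptc_end
      if (ptc_dist > 50L) truth_category <- "nmd"
    }
  } else {
    # protein-coordinate span of the event exon, rounded outward
    rs <- max(a, cds_start) - cds_start + 1L
    re <- min(b, cds_end) - cds_start + 1L
    aa <- c((rs - 1L) %/% 3L + 1L, (re - 1L) %/% 3L + 1L)
    if (stats::runif(1) < cfg$domain_fraction) {
      ds <- max(1L, aa[1L] - sample(0:10, 1L))
      de <- min(prot_len, aa[2L] + sample(0:10, 1L))
      domain_rows <- data.frame(protein_id = paste0(gene_id, ".t1"),
                                domain_id = paste0("DOM_", gene_id),
                                aa_start = ds, aa_end = de,
                                stringsAsFactors = FALSE)
      truth_category <- "domain"
    }
    # a decoy domain well away from the event exon (never overlapping)
    if (aa[1L] > 4L) {
      domain_rows <- rbind(domain_rows, data.frame(
        protein_id = paste0(gene_id, ".t1"),
        domain_id = paste0("DECOY_", gene_id),
        aa_start = 1L, aa_end = min(10L, aa[1L] - 2L),
        stringsAsFactors = FALSE))
    }
  }

  list(
    gene_id = gene_id, contig = contig, strand = strand,
    contig_seq = contig_seq, n_exons = n_ex, event_exon = k,
    exons_genomic = ex_g, exon_lens = lens, intron_lens = ilens,
    cds_start = cds_start, cds_end = cds_end,
    event_exon_genomic = ex_g[k, ],
    injected = list(class = cls, start = inj_g[1L], end = inj_g[2L]),
    frame_effect = frame_effect, truth_category = truth_category,
    ptc_distance = ptc_dist, domains = domain_rows
  )
}

#' Simulate an annotated synthetic transcriptome
#'
#' Generates multi-exon genes with valid CDS (ATG start, single in-frame stop
#' at the CDS end, no internal stops in the reference), GT/AG dinucleotides
#' at every annotated intron boundary (transcript orientation), two annotated
#' isoforms per gene (full + event-exon skip, the skip isoform non-coding),
#' a protein-domain table, per-gene TPM, and all condition-level ground
#' truth. Deterministic under `cfg$seed`.
#'
#' @param cfg A `SimulationConfig`.
#' @return A `SyntheticAnnotation`: list with `genome` (DNAStringSet),
#'   `transcripts` (list of `TranscriptModel`), `expression` (data.frame
#'   gene_id/tpm), `domains` (data.frame), `genes` (per-gene plan), and
#'   `truth` (lists: exons with per-condition true psi, introns with
#'   per-condition true retention, injected junction keys with class and
#'   per-condition membership, consequence labels).
#' @export
simulate_annotation <- function(cfg) {
  set.seed(cfg$seed)
  genes <- lapply(seq_len(cfg$n_genes), build_gene, cfg = cfg)
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")

  genome <- Biostrings::DNAStringSet(
    stats::setNames(vapply(genes, `[[`, character(1), "contig_seq"),
                    vapply(genes, `[[`, character(1), "contig")))

  transcripts <- list()
  for (g in genes) {
    ex <- data.frame(start = g$exons_genomic[, 1L], end = g$exons_genomic[, 2L])
    t1 <- new_transcript_model(paste0(g$gene_id, ".t1"), g$gene_id, g$contig,
                               g$strand, ex)
    t1$cds_start <- g$cds_start; t1$cds_end <- g$cds_end
    t2 <- new_transcript_model(paste0(g$gene_id, ".t2"), g$gene_id, g$contig,
                               g$strand, ex[-g$event_exon, , drop = FALSE])
    transcripts[[t1$transcript_id]] <- t1
    transcripts[[t2$transcript_id]] <- t2
  }

  expressed <- stats::runif(cfg$n_genes) < cfg$expressed_fraction
  tpm <- ifelse(expressed, stats::runif(cfg$n_genes, 15, 500),
                stats::runif(cfg$n_genes, 0, 9))
  expression <- data.frame(gene_id = names(genes), tpm = round(tpm, 3),
                           stringsAsFactors = FALSE)

  domains <- do.call(rbind, lapply(genes, `[[`, "domains"))
  rownames(domains) <- NULL

  cond_names <- names(cfg$conditions)
  # per-exon true inclusion of the event exon, per condition
  psi <- sapply(cond_names, function(cn) {
    cc <- cfg$conditions[[cn]]
    committed <- stats::runif(cfg$n_genes) < cc$committed_fraction
    ifelse(committed, sample(c(0, 1), cfg$n_genes, replace = TRUE),
           stats::rbeta(cfg$n_genes, cc$psi_beta[1L], cc$psi_beta[2L]))
  })
  truth_exons <- data.frame(
    gene_id = names(genes),
    contig = vapply(genes, `[[`, character(1), "contig"),
    strand = vapply(genes, `[[`, character(1), "strand"),
    exon_start = vapply(genes, function(g) g$event_exon_genomic[1L], integer(1)),
    exon_end = vapply(genes, function(g) g$event_exon_genomic[2L], integer(1)),
    stringsAsFactors = FALSE
  )
  for (cn in cond_names) truth_exons[[paste0("psi_", cn)]] <- psi[, cn]

  # per-intron true retention, per condition (full isoform introns)
  intron_rows <- do.call(rbind, lapply(genes, function(g) {
    t1 <- transcripts[[paste0(g$gene_id, ".t1")]]
    intr <- enumerate_introns(t1)
    data.frame(gene_id = g$gene_id, contig = g$contig, strand = g$strand,
               intron_start = intr$start, intron_end = intr$end,
               stringsAsFactors = FALSE)
  }))
  rownames(intron_rows) <- NULL
  for (cn in cond_names) {
    cc <- cfg$conditions[[cn]]
    hi_gene <- names(genes)[stats::runif(cfg$n_genes) <
                              cc$gene_high_retention_fraction]
    r <- stats::runif(nrow(intron_rows), 0, 0.1)
    for (gid in hi_gene) {
      rows <- which(intron_rows$gene_id == gid)
      pick <- rows[sample.int(length(rows), 1L)]
      r[pick] <- stats::runif(1L, 0.35, 0.7)
    }
    intron_rows[[paste0("r_", cn)]] <- r
  }

  # injected unannotated junctions: candidate per gene; per-condition
  # membership drawn over eligible (expressed) genes
  inj <- data.frame(
    gene_id = names(genes),
    contig = vapply(genes, `[[`, character(1), "contig"),
    strand = vapply(genes, `[[`, character(1), "strand"),
    start = vapply(genes, function(g) g$injected$start, integer(1)),
    end = vapply(genes, function(g) g$injected$end, integer(1)),
    class = vapply(genes, function(g) g$injected$class, character(1)),
    stringsAsFactors = FALSE
  )
  eligible <- expression$gene_id[expression$tpm > 10]
  for (cn in cond_names) {
    frac <- cfg$conditions[[cn]]$unannotated_gene_fraction
    n_pick <- round(frac * length(eligible))
    picked <- sample(eligible, n_pick)
    inj[[paste0("in_", cn)]] <- inj$gene_id %in% picked
  }

  truth_consequence <- data.frame(
    gene_id = names(genes),
    exon_start = truth_exons$exon_start, exon_end = truth_exons$exon_end,
    frame_effect = vapply(genes, `[[`, character(1), "frame_effect"),
    category = vapply(genes, `[[`, character(1), "truth_category"),
    ptc_distance = vapply(genes, `[[`, integer(1), "ptc_distance"),
    stringsAsFactors = FALSE
  )

  structure(list(
    cfg = cfg, genome = genome, transcripts = transcripts,
    expression = expression, domains = domains, genes = genes,
    truth = list(exons = truth_exons, introns = intron_rows,
                 injected = inj, consequence = truth_consequence)
  ), class = "SyntheticAnnotation")
}

sample_seed <- function(cfg, condition, replicate) {
  ci <- match(condition, names(cfg$conditions))
  (cfg$seed + 7919L * ci + 104729L * replicate) %% .Machine$integer.max
}

#' Simulate one sample's junction counts
#'
#' Per gene, constitutive annotated junctions draw negative-binomial depths;
#' the event exon draws a total depth n and splits it as inclusion reads
#' I ~ Binomial(n, 2 psi* / (1 + psi*)) (halved over the two inclusion
#' junctions) versus skip reads n - I, inverting the length-normalized
#' inclusion formula so the estimated psi is unbiased for psi*. Injected
#' unannotated junctions present in the condition get depths at the
#' configured fraction of the gene's maximum annotated depth in this sample.
#'
#' @param sim A `SyntheticAnnotation`.
#' @param condition Condition name from the config.
#' @param replicate Replicate number (seeds the sample's RNG stream).
#' @return data.frame in the parsed junction-table representation (contig,
#'   start, end, strand, motif_code, canonical, unique_reads, multi_reads,
#'   overhang), zero-read junctions omitted.
#' @export
simulate_junction_counts <- function(sim, condition, replicate = 1L) {
  cfg <- sim$cfg
  if (!condition %in% names(cfg$conditions)) stop("unknown condition ", condition)
  set.seed(sample_seed(cfg, condition, replicate))
  size <- 1 / cfg$depth_dispersion
  psi_col <- paste0("psi_", condition)
  in_col <- paste0("in_", condition)

  rows <- list()
  for (gi in seq_along(sim$genes)) {
    g <- sim$genes[[gi]]
    t1 <- sim$transcripts[[paste0(g$gene_id, ".t1")]]
    t2 <- sim$transcripts[[paste0(g$gene_id, ".t2")]]
    intr <- enumerate_introns(t1)
    skip_j <- setdiff(
      junction_key(g$contig, enumerate_introns(t2)$start,
                   enumerate_introns(t2)$end, g$strand),
      junction_key(g$contig, intr$start, intr$end, g$strand))
    skip_se <- as.integer(strsplit(skip_j, ":")[[1L]][2:3])

    # which introns flank the event exon (genomic coordinates)
    ev <- g$event_exon_genomic
    flank <- which(intr$end == ev[1L] - 1L | intr$start == ev[2L] + 1L)
    psi_true <- sim$truth$exons[[psi_col]][gi]

    n_ev <- stats::rnbinom(1L, size = size, mu = cfg$depth_mean)
    w <- 2 * psi_true / (1 + psi_true)
    I <- stats::rbinom(1L, n_ev, w)
    inc1 <- stats::rbinom(1L, I, 0.5)
    counts <- integer(nrow(intr))
    const <- setdiff(seq_len(nrow(intr)), flank)
    counts[const] <- stats::rnbinom(length(const), size = size,
                                    mu = cfg$depth_mean)
    counts[flank] <- c(inc1, I - inc1)
    S <- n_ev - I

    df <- data.frame(contig = g$contig, start = c(intr$start, skip_se[1L]),
                     end = c(intr$end, skip_se[2L]), strand = g$strand,
                     unique_reads = c(counts, S), annotated = TRUE,
                     stringsAsFactors = FALSE)

    if (sim$truth$injected[[in_col]][gi]) {
      D <- max(df$unique_reads)
      if (D > 0) {
        df <- rbind(df, data.frame(
          contig = g$contig, start = g$injected$start, end = g$injected$end,
          strand = g$strand,
          unique_reads = as.integer(ceiling(cfg$injected_depth_fraction * D)),
          annotated = FALSE, stringsAsFactors = FALSE))
      }
    }
    rows[[gi]] <- df[df$unique_reads > 0, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$motif_code <- ifelse(out$strand == "+", 1L, 2L)
  out$canonical <- TRUE
  out$multi_reads <- 0L
  out$overhang <- 30L
  out[, c("contig", "start", "end", "strand", "motif_code", "canonical",
          "unique_reads", "multi_reads", "overhang", "annotated")]
}

#' Simulate one sample's per-intron coverage table
#'
#' For true retention r*, the mean intronic depth is drawn as
#' Poisson(s * r* / (1 - r*)) where s is the sample's spliced read count on
#' the junction spanning the intron, so the expected retention ratio
#' approximates r*; r* = 0 gives zero depth.
#'
#' @param sim A `SyntheticAnnotation`.
#' @param junctions The same sample's junction table from
#'   [simulate_junction_counts()].
#' @param condition,replicate As in [simulate_junction_counts()].
#' @return data.frame: gene_id, contig, intron_start, intron_end, strand,
#'   mean_depth, plus the true retention column `r_true`.
#' @export
simulate_intron_coverage <- function(sim, junctions, condition,
                                     replicate = 1L) {
  cfg <- sim$cfg
  set.seed((sample_seed(cfg, condition, replicate) + 1L) %%
             .Machine$integer.max)
  tr <- sim$truth$introns
  r <- tr[[paste0("r_", condition)]]
  jmap <- tapply(junctions$unique_reads,
                 junction_key(junctions$contig, junctions$start,
                              junctions$end, junctions$strand), sum)
  s <- jmap[junction_key(tr$contig, tr$intron_start, tr$intron_end, tr$strand)]
  s[is.na(s)] <- 0
  lambda <- ifelse(r > 0, s * r / (1 - r), 0)
  data.frame(
    gene_id = tr$gene_id, contig = tr$contig,
    intron_start = tr$intron_start, intron_end = tr$intron_end,
    strand = tr$strand,
    mean_depth = stats::rpois(nrow(tr), lambda),
    r_true = r, stringsAsFactors = FALSE
  )
}

#' Write a junction table in the 9-column STAR dialect
#'
#' @param junctions Parsed junction table (as from
#'   [simulate_junction_counts()]).
#' @param path Output path.
#' @export
write_sj_table <- function(junctions, path) {
  raw <- data.frame(
    junctions$contig, junctions$start, junctions$end,
    c("+" = 1L, "-" = 2L, "*" = 0L)[junctions$strand],
    junctions$motif_code,
    if ("annotated" %in% names(junctions)) as.integer(junctions$annotated) else 0L,
    junctions$unique_reads, junctions$multi_reads, junctions$overhang
  )
  utils::write.table(raw, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

# Genomic CDS intervals of a coding transcript (for GTF emission).
cds_genomic_intervals <- function(t) {
  if (is.na(t$cds_start)) return(NULL)
  ord <- tx_exon_order(t)
  lens <- t$exons$end - t$exons$start + 1L
  offset <- 0L
  out <- list()
  for (i in ord) {
    a <- offset + 1L; b <- offset + lens[i]
    lo <- max(a, t$cds_start); hi <- min(b, t$cds_end)
    if (lo <= hi) {
      g1 <- tx_to_genomic(t, lo); g2 <- tx_to_genomic(t, hi)
      out[[length(out) + 1L]] <- c(min(g1, g2), max(g1, g2))
    }
    offset <- b
  }
  do.call(rbind, out)
}

#' Write the annotation of a synthetic transcriptome as GTF
#'
#' Emits gene, transcript, exon and CDS features in the Ensembl attribute
#' dialect; CDS features include the stop codon (the loader's convention).
#'
#' @param sim A `SyntheticAnnotation`.
#' @param path Output path.
#' @export
write_gtf <- function(sim, path) {
  lines <- character(0)
  attr_str <- function(gid, tid = NULL) {
    if (is.null(tid)) sprintf('gene_id "%s";', gid)
    else sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
  }
  fmt <- function(contig, feature, start, end, strand, attrs) {
    sprintf("%s\tsynthetic\t%s\t%d\t%d\t.\t%s\t.\t%s",
            contig, feature, start, end, strand, attrs)
  }
  for (g in sim$genes) {
    tids <- paste0(g$gene_id, c(".t1", ".t2"))
    span <- range(g$exons_genomic)
    lines <- c(lines, fmt(g$contig, "gene", span[1L], span[2L], g$strand,
                          attr_str(g$gene_id)))
    for (tid in tids) {
      t <- sim$transcripts[[tid]]
      lines <- c(lines, fmt(g$contig, "transcript", min(t$exons$start),
                            max(t$exons$end), g$strand,
                            attr_str(g$gene_id, tid)))
      for (i in seq_len(nrow(t$exons))) {
        lines <- c(lines, fmt(g$contig, "exon", t$exons$start[i],
                              t$exons$end[i], g$strand,
                              attr_str(g$gene_id, tid)))
      }
      cds <- cds_genomic_intervals(t)
      if (!is.null(cds)) for (i in seq_len(nrow(cds))) {
        lines <- c(lines, fmt(g$contig, "CDS", cds[i, 1L], cds[i, 2L],
                              g$strand, attr_str(g$gene_id, tid)))
      }
    }
  }
  writeLines(lines, path)
}

#' Write a complete fixture bundle
#'
#' Emits genome FASTA, GTF, expression TSV, domain TSV, per-sample junction
#' tables (`sj_<condition>_rep<i>.tab`) and intron coverage tables, and the
#' ground-truth TSVs. All files are deterministic under the config seed.
#'
#' @param cfg A `SimulationConfig`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the `SyntheticAnnotation` and all paths.
#' @export
write_fixture_bundle <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_annotation(cfg)
  p <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    expression = file.path(dir, "expression.tsv"),
    domains = file.path(dir, "domains.tsv")
  )
  Biostrings::writeXStringSet(sim$genome, p$genome)
  write_gtf(sim, p$gtf)
  utils::write.table(sim$expression, p$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$domains, p$domains, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  p$sj <- list(); p$coverage <- list()
  for (cn in names(cfg$conditions)) {
    for (r in seq_len(cfg$n_replicates)) {
      j <- simulate_junction_counts(sim, cn, r)
      cov <- simulate_intron_coverage(sim, j, cn, r)
      sj_path <- file.path(dir, sprintf("sj_%s_rep%d.tab", cn, r))
      cov_path <- file.path(dir, sprintf("intron_coverage_%s_rep%d.tsv", cn, r))
      write_sj_table(j, sj_path)
      utils::write.table(
        cov[, c("gene_id", "contig", "intron_start", "intron_end", "strand",
                "mean_depth")],
        cov_path, sep = "\t", quote = FALSE, row.names = FALSE)
      p$sj[[cn]][[r]] <- sj_path
      p$coverage[[cn]][[r]] <- cov_path
    }
  }

  truth_paths <- list(
    exons = file.path(dir, "ground_truth_exons.tsv"),
    introns = file.path(dir, "ground_truth_introns.tsv"),
    junctions = file.path(dir, "ground_truth_junctions.tsv"),
    consequence = file.path(dir, "ground_truth_consequence.tsv")
  )
  utils::write.table(sim$truth$exons, truth_paths$exons, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$introns, truth_paths$introns, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$injected, truth_paths$junctions, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$consequence, truth_paths$consequence,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  p$truth <- truth_paths
  invisible(list(sim = sim, paths = p))
}

#' Constructed NMD boundary fixture
#'
#' Builds, deterministically and without randomness, a 4-exon coding gene in
#' which skipping exon 2 (length = 1 mod 3) frameshifts exons 3 and 4 and
#' places the first in-frame stop codon at exactly `distance` nt upstream of
#' the skipped isoform's final exon-exon junction. The backbone is poly-C so
#' no unintended stop codon can arise in either reading frame; the reference
#' frame translates cleanly to its annotated terminal stop.
#'
#' @param distance Target distance in nt (last junction minus the PTC's last
#'   base); `distance > 50` makes the skip NMD-targeting under the 50-nt
#'   rule.
#' @param gene_id,contig Identifiers.
#' @param strand "+" or "-" (the minus-strand gene is the reverse-complement
#'   embedding of the same transcript).
#' @return List with `genome` (DNAStringSet), `transcript` (the coding
#'   `TranscriptModel`), and `expected` (nmd flag, distance, skipped-isoform
#'   PTC coordinates).
#' @export
nmd_boundary_gene <- function(distance, gene_id = "NMDFIX", contig = "ctgNMD",
                              strand = "+") {
  distance <- as.integer(distance)
  l1 <- 60L; l2 <- 100L                       # l2 mod 3 = 1 -> frameshift
  l3 <- distance + 12L                        # keeps the PTC codon in frame
  cs <- 10L
  # provisional l4, then fix CDS length mod 3
  l4 <- 40L
  total <- function(l4) l1 + l2 + l3 + l4
  ce <- function(l4) total(l4) - 9L
  adj <- (ce(l4) - cs + 1L) %% 3L
  l4 <- l4 + (3L - adj) %% 3L
  T_ <- total(l4); ce_ <- ce(l4)

  mrna <- rep("C", T_)
  mrna[cs:(cs + 2L)] <- c("A", "T", "G")
  # PTC in the skipped frame: last base at p = l1 + l3 - distance of the
  # skipped isoform; in reference coordinates the codon shifts right by l2
  p <- l1 + l3 - distance
  stopifnot((p - 2L - cs) %% 3L == 0L, p - 2L > l1)
  q <- p - 2L + l2
  mrna[q:(q + 2L)] <- c("T", "A", "A")
  mrna[(ce_ - 2L):ce_] <- c("T", "A", "A")    # annotated stop, reference frame
  mrna <- paste(mrna, collapse = "")

  lens <- c(l1, l2, l3, l4)
  pad <- 20L; ilen <- 80L
  exon_seqs <- substring(mrna, cumsum(c(0L, lens[-4L])) + 1L, cumsum(lens))
  intron <- paste0("GT", strrep("C", ilen - 4L), "AG")
  locus <- paste0(strrep("C", pad),
                  paste(rbind(exon_seqs, c(rep(intron, 3L), ""))[1:7],
                        collapse = ""),
                  strrep("C", pad))
  M <- nchar(locus)
  la <- integer(4L); lb <- integer(4L); cursor <- pad
  for (j in 1:4) {
    la[j] <- cursor + 1L; lb[j] <- cursor + lens[j]
    cursor <- lb[j] + if (j < 4L) ilen else 0L
  }
  ex_g <- t(vapply(1:4, function(j)
    locus_interval_to_genomic(la[j], lb[j], strand, M), integer(2)))
  contig_seq <- if (strand == "+") locus else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(locus)))

  t1 <- new_transcript_model(paste0(gene_id, ".t1"), gene_id, contig, strand,
                             data.frame(start = ex_g[, 1L], end = ex_g[, 2L]))
  t1$cds_start <- cs; t1$cds_end <- ce_

  list(
    genome = Biostrings::DNAStringSet(stats::setNames(contig_seq, contig)),
    transcript = t1,
    expected = list(nmd = distance > 50L, distance = distance,
                    ptc_end_skipped = p, last_junction_skipped = l1 + l3)
  )
}
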