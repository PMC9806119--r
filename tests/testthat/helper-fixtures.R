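# In-code fixtures: a tiny hand-written annotation and writers for the toy
# input files the loaders consume.

gtf_line <- function(contig, feature, start, end, strand, gene, tx = NULL) {
  attrs <- if (is.null(tx)) sprintf('gene_id "%s";', gene) else
    sprintf('gene_id "%s"; transcript_id "%s";', gene, tx)
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s",
          contig, feature, start, end, strand, attrs)
}

write_expression <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# One plus-strand gene: 3 exons [101,200], [301,400], [501,600] on chrT.
# Junctions: [201,300] and [401,500].
toy_gtf_lines <- function(gene = "GENE1", tx = "GENE1.t1", strand = "+",
                          contig = "chrT") {
  c(gtf_line(contig, "gene", 101, 600, strand, gene),
    gtf_line(contig, "transcript", 101, 600, strand, gene, tx),
    gtf_line(contig, "exon", 101, 200, strand, gene, tx),
    gtf_line(contig, "exon", 301, 400, strand, gene, tx),
    gtf_line(contig, "exon", 501, 600, strand, gene, tx))
}

toy_idx <- function(tpm = 100, extra_lines = NULL) {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(toy_gtf_lines(), extra_lines), gtf)
  expr <- write_expression(data.frame(gene_id = "GENE1", tpm = tpm))
  load_annotation(gtf, expr)
}

# Write a 9-column STAR-dialect junction table from a list of row vectors.
write_sj_rows <- function(rows, path = tempfile(fileext = ".tab")) {
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

# A parsed-representation junction data.frame for in-memory use.
make_junctions <- function(contig, start, end, strand, unique_reads,
                           canonical = TRUE) {
  data.frame(contig = contig, start = start, end = end, strand = strand,
             motif_code = ifelse(strand == "+", 1L, 2L),
             canonical = canonical, unique_reads = unique_reads,
             multi_reads = 0L, overhang = 30L, stringsAsFactors = FALSE)
}

# Event table with prescribed inclusion levels for commitment-score tests.
make_commitment_events <- function(psi, gene = "GENE1") {
  n <- length(psi)
  data.frame(
    gene_id = gene, contig = "chrT", strand = "+",
    exon_start = seq(1000L, by = 100L, length.out = n),
    exon_end = seq(1050L, by = 100L, length.out = n),
    inclusion_reads = round(100 * psi * 2), skip_reads = round(100 * (1 - psi)),
    psi = psi)
}

# Small cached paper-shape style bundle shared by pipeline-level tests.
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "splicefid_bundle")
      cfg <- simulation_config(seed = 42L, n_genes = 60L)
      cache <<- list(dir = dir, cfg = cfg,
                     bundle = write_fixture_bundle(cfg, dir))
    }
    cache
  }
})
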