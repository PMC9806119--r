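test_that("generation is fully deterministic under the seed", {
  d1 <- tempfile(); d2 <- tempfile()
  cfg <- simulation_config(seed = 5L, n_genes = 15L)
  write_fixture_bundle(cfg, d1)
  write_fixture_bundle(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  cfg2 <- simulation_config(seed = 6L, n_genes = 15L)
  d3 <- tempfile()
  write_fixture_bundle(cfg2, d3)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("every emitted intron is GT..AG and every CDS translates to a single terminal stop", {
  b <- shared_bundle()
  sim <- b$bundle$sim
  genome <- sim$genome
  for (t in sim$transcripts) {
    intr <- enumerate_introns(t)
    for (i in seq_len(nrow(intr))) {
      s <- genome_sequence(genome, t$contig, intr$start[i], intr$end[i],
                           t$strand)
      expect_equal(substr(s, 1, 2), "GT")
      expect_equal(substring(s, nchar(s) - 1), "AG")
    }
    if (is.na(t$cds_start)) next
    cds <- substr(transcript_sequence(t, genome), t$cds_start, t$cds_end)
    expect_equal(nchar(cds) %% 3, 0)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(substring(aa, nchar(aa)), "*")
    expect_false(grepl("[*]", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("the emitted annotation round-trips through the loader", {
  b <- shared_bundle()
  idx <- load_annotation(file.path(b$dir, "annotation.gtf"),
                         file.path(b$dir, "expression.tsv"))
  sim <- b$bundle$sim
  expect_equal(nrow(idx$genes), sim$cfg$n_genes)
  expect_equal(length(idx$transcripts), 2L * sim$cfg$n_genes)
  # CDS offsets survive the GTF round trip
  for (tid in names(sim$transcripts)[seq(1, 40, by = 7)]) {
    expect_equal(idx$transcripts[[tid]]$cds_start, sim$transcripts[[tid]]$cds_start)
    expect_equal(idx$transcripts[[tid]]$cds_end, sim$transcripts[[tid]]$cds_end)
  }
})

test_that("junction sampling inverts the inclusion-level formula without bias", {
  cfg <- simulation_config(seed = 30L, n_genes = 8L)
  sim <- simulate_annotation(cfg)
  # fully included / excluded exons produce no skip / no inclusion reads
  tr <- sim$truth$exons
  j <- simulate_junction_counts(sim, "A", 1)
  idx_keys <- junction_key(j$contig, j$start, j$end, j$strand)
  for (i in which(tr$psi_A == 1)) {
    g <- sim$genes[[tr$gene_id[i]]]
    t2 <- sim$transcripts[[paste0(g$gene_id, ".t2")]]
    t1 <- sim$transcripts[[paste0(g$gene_id, ".t1")]]
    skip_key <- setdiff(
      junction_key(g$contig, enumerate_introns(t2)$start,
                   enumerate_introns(t2)$end, g$strand),
      junction_key(g$contig, enumerate_introns(t1)$start,
                   enumerate_introns(t1)$end, g$strand))
    expect_false(skip_key %in% idx_keys)
  }

  # mean estimated psi approaches truth over seeded replicates
  set.seed(31)
  psi_true <- 0.5
  w <- 2 * psi_true / (1 + psi_true)
  I <- rbinom(200, 400, w)
  psi_hat <- exon_inclusion_level(I, 400 - I)
  expect_lt(abs(mean(psi_hat) - psi_true), 0.01)
})

test_that("injected junctions at exactly the filter fraction are always kept", {
  cfg <- simulation_config(seed = 33L, n_genes = 25L,
                           injected_depth_fraction = 0.1)
  d <- tempfile()
  b <- write_fixture_bundle(cfg, d)
  idx <- load_annotation(file.path(d, "annotation.gtf"),
                         file.path(d, "expression.tsv"))
  j <- read_junction_table(file.path(d, "sj_A_rep1.tab"))
  j <- classify_junctions(assign_junctions_to_genes(j, idx), idx)
  cs <- select_high_confidence_unannotated(j, idx, "A1")
  inj <- b$sim$truth$injected
  expect_setequal(cs$genes_with_unannotated, inj$gene_id[inj$in_A])
})

test_that("zero retention yields zero depth and high retention is recovered", {
  b <- shared_bundle()
  sim <- b$bundle$sim
  j <- simulate_junction_counts(sim, "B", 1)
  cov <- simulate_intron_coverage(sim, j, "B", 1)
  expect_true(all(cov$mean_depth[cov$r_true == 0] == 0))
  sc <- score_intron_retention(
    cov[, c("gene_id", "contig", "intron_start", "intron_end", "strand",
            "mean_depth")], j)
  ok <- !is.na(sc$ir_ratio) & cov$r_true > 0.35
  expect_gt(sum(ok), 2)
  expect_lt(mean(abs(sc$ir_ratio[ok] - cov$r_true[ok])), 0.08)
})

test_that("the NMD boundary fixture realizes its configured distance exactly", {
  for (d in c(49L, 50L, 51L, 52L)) {
    fx <- nmd_boundary_gene(d)
    expect_equal(fx$expected$nmd, d > 50)
    # reference CDS is clean: translate to a single terminal stop
    cds <- substr(transcript_sequence(fx$transcript, fx$genome),
                  fx$transcript$cds_start, fx$transcript$cds_end)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_false(grepl("[*]", substr(aa, 1, nchar(aa) - 1)))
    expect_equal(substring(aa, nchar(aa)), "*")
  }
})
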