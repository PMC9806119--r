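test_that("the STAR junction dialect is parsed faithfully", {
  path <- write_sj_rows(list(
    c("chr1", 101, 200, 1, 1, 0, 57, 3, 20),
    c("chr1", 301, 400, 2, 2, 0, 10, 0, 25),
    c("chr1", 501, 600, 0, 0, 0, 4, 0, 12),   # non-canonical, no strand
    c("chr1", 701, 800, 0, 2, 0, 6, 0, 12)))  # strand resolved from CT-AC motif
  j <- read_junction_table(path)
  expect_equal(j$contig[1], "chr1")
  expect_equal(j$start[1], 101L)
  expect_equal(j$end[1], 200L)
  expect_equal(j$strand[1:4], c("+", "-", "*", "-"))
  expect_equal(j$canonical, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(j$unique_reads[1], 57L)

  expect_error(read_junction_table(write_sj_rows(list(c("chr1", 1, 2, 1)))),
               "9 tab-separated columns")
  expect_error(read_junction_table(
    write_sj_rows(list(c("chr1", 101, 200, 1, 1, 0, -5, 0, 20)))),
    "negative")
})

test_that("junction status follows the donor/acceptor taxonomy", {
  # second gene on minus strand to exercise strand-aware site sets
  minus <- c(gtf_line("chrM", "gene", 101, 600, "-", "GENE2"),
             gtf_line("chrM", "transcript", 101, 600, "-", "GENE2", "GENE2.t1"),
             gtf_line("chrM", "exon", 101, 200, "-", "GENE2", "GENE2.t1"),
             gtf_line("chrM", "exon", 301, 400, "-", "GENE2", "GENE2.t1"),
             gtf_line("chrM", "exon", 501, 600, "-", "GENE2", "GENE2.t1"))
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(toy_gtf_lines(), minus), gtf)
  expr <- write_expression(data.frame(gene_id = c("GENE1", "GENE2"),
                                      tpm = c(100, 100)))
  idx <- load_annotation(gtf, expr)

  j <- make_junctions(
    contig = c("chrT", "chrT", "chrT", "chrT", "chrM"),
    start = c(201L, 201L, 201L, 221L, 201L),
    end = c(300L, 500L, 350L, 350L, 500L),
    strand = c("+", "+", "+", "+", "-"),
    unique_reads = 10L)
  j <- classify_junctions(j, idx)
  expect_equal(as.character(j$status),
               c("annotated",
                 "both_sites_annotated_novel_pairing",  # exon-skip pattern
                 "donor_only_annotated",                # annotated donor into intron
                 "neither_annotated",
                 "both_sites_annotated_novel_pairing"))

  # minus strand: donor is the larger coordinate, so [201,350] on chrM has
  # an annotated *acceptor* (201) only
  jm <- classify_junctions(make_junctions("chrM", 201L, 350L, "-", 5L), idx)
  expect_equal(as.character(jm$status), "acceptor_only_annotated")

  # every canonical junction gets exactly one status
  expect_false(anyNA(j$status))
})

test_that("the 10%-of-max selection applies its boundary inclusively and gates on TPM", {
  run_case <- function(tpm, una_reads) {
    idx <- toy_idx(tpm = tpm)
    j <- make_junctions(
      contig = "chrT",
      start = c(201L, 401L, 201L),
      end = c(300L, 500L, 500L),
      strand = "+",
      unique_reads = c(200L, 120L, una_reads))
    select_high_confidence_unannotated(j, idx, sample_id = "s")
  }
  expect_equal(run_case(12, 20L)$kept$unique_reads, 20L)   # 10% of 200: kept
  expect_equal(nrow(run_case(12, 19L)$kept), 0L)           # just below: dropped
  cs <- run_case(9, 50L)                                   # TPM gate strict
  expect_equal(nrow(cs$kept), 0L)
  expect_length(cs$eligible_genes, 0L)
  expect_error(gene_unannotated_proportion(cs), "no expressed")
})

test_that("selection is order-invariant and monotone in its thresholds", {
  b <- shared_bundle()
  idx <- load_annotation(file.path(b$dir, "annotation.gtf"),
                         file.path(b$dir, "expression.tsv"))
  j <- read_junction_table(file.path(b$dir, "sj_A_rep1.tab"))
  j <- classify_junctions(assign_junctions_to_genes(j, idx), idx)

  cs <- select_high_confidence_unannotated(j, idx, "a")
  set.seed(7)
  perm <- j[sample.int(nrow(j)), , drop = FALSE]
  cs_perm <- select_high_confidence_unannotated(perm, idx, "a")
  key <- function(cs) sort(junction_key(cs$kept$contig, cs$kept$start,
                                        cs$kept$end, cs$kept$strand))
  expect_equal(key(cs), key(cs_perm))

  # lowering the fraction never removes a kept junction
  cs_lo <- select_high_confidence_unannotated(j, idx, "a", fraction = 0.05)
  expect_true(all(key(cs) %in% key(cs_lo)))
  # raising the TPM gate never adds a gene
  cs_hi <- select_high_confidence_unannotated(j, idx, "a", tpm_gate = 100)
  expect_true(all(cs_hi$genes_with_unannotated %in% cs$genes_with_unannotated))
})

test_that("injected junctions at 15% of max depth are recovered exactly", {
  b <- shared_bundle()
  idx <- load_annotation(file.path(b$dir, "annotation.gtf"),
                         file.path(b$dir, "expression.tsv"))
  sim <- b$bundle$sim
  j <- simulate_junction_counts(sim, "A", 1)
  j <- classify_junctions(assign_junctions_to_genes(j, idx), idx)
  cs <- select_high_confidence_unannotated(j, idx, "A1")

  inj <- sim$truth$injected
  truth_genes <- inj$gene_id[inj$in_A]
  # recall and precision both 1 at the gene level
  expect_setequal(cs$genes_with_unannotated, truth_genes)
  # and at the junction level
  truth_keys <- junction_key(inj$contig[inj$in_A], inj$start[inj$in_A],
                             inj$end[inj$in_A], inj$strand[inj$in_A])
  kept_keys <- junction_key(cs$kept$contig, cs$kept$start, cs$kept$end,
                            cs$kept$strand)
  expect_setequal(kept_keys, truth_keys)
})

test_that("multi-sample consistency intersects per-sample gene sets", {
  cs1 <- structure(list(genes_with_unannotated = c("a", "b", "c")),
                   class = "UnannotatedCallSet")
  cs2 <- structure(list(genes_with_unannotated = c("b", "c", "d")),
                   class = "UnannotatedCallSet")
  expect_setequal(consistent_unannotated_genes(list(cs1, cs2)), c("b", "c"))
})
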