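test_that("frame effect follows the CDS-overlap mod-3 rule", {
  expect_equal(classify_frame_effect(48), "in_frame")
  expect_equal(classify_frame_effect(50), "frameshift")
  expect_equal(classify_frame_effect(0), "noncoding")
  expect_equal(classify_frame_effect(c(3, 4, 0)),
               c("in_frame", "frameshift", "noncoding"))
})

# 3-exon fixture whose exon-2 skip creates a junction-spanning TGA:
# e1 ATGCCCTG | e2 G | e3 ACCTAA; reference reads ATG CCC TGG ACC TAA.
ptc_fixture <- function() {
  contig <- paste0("ATGCCCTG", "GTACAG", "G", "GTACAG", "ACCTAA")
  genome <- Biostrings::DNAStringSet(setNames(contig, "fix"))
  t <- splicefid:::new_transcript_model(
    "fix.t1", "FIX", "fix", "+",
    data.frame(start = c(1L, 15L, 22L), end = c(8L, 15L, 27L)))
  t$cds_start <- 1L; t$cds_end <- 15L
  list(genome = genome, t = t)
}

test_that("skipped isoforms are constructed with remapped CDS and junctions", {
  fx <- ptc_fixture()
  iso <- construct_skipped_isoform(fx$t, 2L, fx$genome)
  expect_equal(iso$sequence, "ATGCCCTGACCTAA")       # exon1 + exon3
  expect_equal(iso$junction_positions, 8L)           # one remaining junction
  expect_equal(iso$cds_start, 1L)
  expect_equal(iso$stop_end, 14L)                    # stop shifted left by 1

  expect_error(construct_skipped_isoform(fx$t, 1L, fx$genome), "not internal")
  expect_error(construct_skipped_isoform(fx$t, 3L, fx$genome), "not internal")

  # exon wholly inside the 5' UTR: CDS shifts left, coding part unchanged
  utr_contig <- paste0("CCCCCC", "GTAG", "CC", "GTAG", "ATGAAACCCTAA")
  g2 <- Biostrings::DNAStringSet(setNames(utr_contig, "u"))
  t2 <- splicefid:::new_transcript_model(
    "u.t1", "U", "u", "+",
    data.frame(start = c(1L, 11L, 17L), end = c(6L, 12L, 28L)))
  t2$cds_start <- 9L; t2$cds_end <- 20L
  iso2 <- construct_skipped_isoform(t2, 2L, g2)
  expect_equal(iso2$cds_start, 7L)
  expect_equal(substr(iso2$sequence, iso2$cds_start, iso2$stop_end),
               "ATGAAACCCTAA")

  # 4-exon transcript, skip exon 3: junctions at len(e1) and len(e1)+len(e2)
  g3 <- Biostrings::DNAStringSet(setNames(strrep("C", 100), "c4"))
  t3 <- splicefid:::new_transcript_model(
    "c4.t1", "C4", "c4", "+",
    data.frame(start = c(1L, 21L, 41L, 61L), end = c(10L, 25L, 50L, 80L)))
  iso3 <- construct_skipped_isoform(t3, 3L, g3)
  expect_equal(iso3$junction_positions, c(10L, 15L))
})

test_that("PTC scanning finds junction-spanning stops and respects the annotated stop", {
  fx <- ptc_fixture()
  iso <- construct_skipped_isoform(fx$t, 2L, fx$genome)
  ptc <- scan_for_ptc(iso)
  expect_equal(ptc$ptc_start, 7L)                    # TGA spans the new junction
  expect_equal(ptc$ptc_end, 9L)
  # PTC downstream of the only remaining junction: not NMD-targeting
  expect_false(is_nmd_targeting(ptc$ptc_end, iso))

  # in-frame skip with no internal stop: absent
  g <- Biostrings::DNAStringSet(setNames(
    paste0("ATGCCCCCC", "GTAG", "CCCCCC", "GTAG", "CCCTAACCC"), "if"))
  t_if <- splicefid:::new_transcript_model(
    "if.t1", "IF", "if", "+",
    data.frame(start = c(1L, 14L, 24L), end = c(9L, 19L, 32L)))
  t_if$cds_start <- 1L; t_if$cds_end <- 21L
  iso_if <- construct_skipped_isoform(t_if, 2L, g)
  expect_null(scan_for_ptc(iso_if))
})

test_that("the 50-nt rule is strict at its boundary on constructed fixtures", {
  for (strand in c("+", "-")) {
    for (d in c(50L, 51L, 120L, -5L)) {
      fx <- nmd_boundary_gene(d, strand = strand)
      # event exon = transcript-order exon 2 (genomic index 3 on minus strand)
      k <- if (strand == "+") 2L else 3L
      iso <- construct_skipped_isoform(fx$transcript, k, fx$genome)
      ptc <- scan_for_ptc(iso)
      expect_false(is.null(ptc))
      expect_equal(max(iso$junction_positions) - ptc$ptc_end, d)
      expect_equal(is_nmd_targeting(ptc$ptc_end, iso), d > 50,
                   info = sprintf("strand %s distance %d", strand, d))
      # the independent splice-translate-measure oracle agrees
      o <- oracle_nmd(fx$transcript, k, fx$genome)
      expect_equal(o$nmd, d > 50)
    }
  }
})

test_that("domain overlap maps exon codons to protein coordinates with outward rounding", {
  t <- splicefid:::new_transcript_model(
    "p.t1", "P", "p", "+",
    data.frame(start = c(1L, 21L, 41L), end = c(10L, 30L, 60L)))
  t$cds_start <- 5L; t$cds_end <- 34L
  # exon 2 occupies tx 11..20 -> CDS 7..16 -> amino acids 3..6 (outward)
  dom <- function(s, e) data.frame(protein_id = "p.t1", domain_id = "D",
                                   aa_start = s, aa_end = e)
  expect_equal(domain_restoration(t, 2L, dom(2, 4)), "D")
  expect_equal(domain_restoration(t, 2L, dom(6, 9)), "D")   # via rounding
  expect_length(domain_restoration(t, 2L, dom(7, 10)), 0L)
  expect_warning(out <- domain_restoration(
    t, 2L, data.frame(protein_id = "other", domain_id = "D",
                      aa_start = 1, aa_end = 5)), "absent")
  expect_length(out, 0L)
})

test_that("event-level consequence calls reproduce generator ground truth", {
  b <- shared_bundle()
  idx <- load_annotation(file.path(b$dir, "annotation.gtf"),
                         file.path(b$dir, "expression.tsv"))
  genome <- read_genome(file.path(b$dir, "genome.fa"))
  domains <- read_domain_table(file.path(b$dir, "domains.tsv"))
  truth <- b$bundle$sim$truth$consequence

  calls <- consequence_table(truth, idx, genome, domains)
  expect_equal(calls$frame_effect, truth$frame_effect)
  expect_equal(calls$category, truth$category)
  # the invariant partition: NMD only from frameshifts, domains only in-frame
  expect_true(all(calls$frame_effect[calls$nmd_targeting] == "frameshift"))
  expect_true(all(calls$frame_effect[calls$affected_domains != ""] == "in_frame"))
})
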