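test_that("GC content excludes N bases", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GATC"), 0.5)
  expect_equal(gc_content("GCNNAT"), 0.5)
  expect_true(is.na(gc_content("NNN")))
  expect_error(gc_content(""), "empty")
})

manual_model <- function() {
  donor <- matrix(0.25, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  donor[, 4] <- c(0.1, 0.1, 0.7, 0.1)
  donor[, 5] <- c(0.1, 0.1, 0.1, 0.7)
  acceptor <- matrix(0.25, 4, 23, dimnames = list(c("A", "C", "G", "T"), NULL))
  list(donor = donor, acceptor = acceptor,
       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
}

test_that("splice-site scores equal the manual log-odds sum", {
  m <- manual_model()
  # consensus-matching window: only positions 4 (G) and 5 (T) informative
  expect_equal(splice_site_score(m, "AAAGTAAAA", "donor"),
               2 * log2(0.7 / 0.25), tolerance = 1e-12)
  # two-position deviation, hand-computed
  expect_equal(splice_site_score(m, "AAACAAAAA", "donor"),
               log2(0.1 / 0.25) + log2(0.1 / 0.25), tolerance = 1e-12)
  # N contributes zero
  expect_equal(splice_site_score(m, "AAANTAAAA", "donor"),
               log2(0.7 / 0.25), tolerance = 1e-12)
  # background-typical window scores ~0 under the uniform acceptor
  expect_equal(splice_site_score(m, strrep("A", 23), "acceptor"), 0)
  expect_error(splice_site_score(m, "AAAA", "donor"), "9 nt")
})

test_that("a single training site with zero pseudocount is its own argmax", {
  contig <- paste0(strrep("C", 30), "AAG", "GTAAGT", strrep("C", 40),
                   strrep("T", 18), "AG", "GCC", strrep("C", 30))
  # intron spans the GTAAGT...AG stretch
  istart <- 34L; iend <- 33L + 6L + 40L + 20L
  genome <- Biostrings::DNAStringSet(setNames(contig, "c1"))
  idx <- list(junctions = data.frame(contig = "c1", start = istart,
                                     end = iend, strand = "+",
                                     gene_id = "g"))
  m <- train_pwm_from_annotation(idx, genome, pseudocount = 0)
  own <- splicefid:::site_window(genome, "c1", istart, iend, "+", "donor")
  best <- splice_site_score(m, own, "donor")
  set.seed(13)
  for (i in 1:20) {
    mut <- strsplit(own, "")[[1]]
    pos <- sample(9, 1)
    mut[pos] <- setdiff(c("A", "C", "G", "T"), mut[pos])[sample(3, 1)]
    expect_lt(splice_site_score(m, paste(mut, collapse = ""), "donor"), best)
  }
})

test_that("PWM training recovers known column frequencies from sampled sites", {
  set.seed(14)
  true_donor <- matrix(runif(36), 4, 9,
                       dimnames = list(c("A", "C", "G", "T"), NULL))
  true_donor <- sweep(true_donor, 2, colSums(true_donor), "/")
  n <- 10000L
  block <- 64L
  bases <- c("A", "C", "G", "T")
  windows <- vapply(seq_len(n), function(i)
    paste(apply(true_donor, 2, function(p) sample(bases, 1, prob = p)),
          collapse = ""), character(1))
  filler <- function(k) paste(sample(bases, k, replace = TRUE), collapse = "")
  contig <- paste(vapply(windows, function(w) paste0(w, filler(block - 9L)),
                         character(1)), collapse = "")
  offs <- (seq_len(n) - 1L) * block
  idx <- list(junctions = data.frame(
    contig = "c1", start = offs + 4L, end = offs + 40L, strand = "+",
    gene_id = "g"))
  genome <- Biostrings::DNAStringSet(setNames(contig, "c1"))
  m <- train_pwm_from_annotation(idx, genome, pseudocount = 0.5)
  expect_lt(max(abs(m$donor - true_donor)), 0.02)
})

test_that("minus-strand windows are the reverse complement of the plus extraction", {
  b <- shared_bundle()
  genome <- read_genome(file.path(b$dir, "genome.fa"))
  idx <- load_annotation(file.path(b$dir, "annotation.gtf"),
                         file.path(b$dir, "expression.tsv"))
  j <- idx$junctions[idx$junctions$strand == "-", ][1:5, ]
  for (i in seq_len(nrow(j))) {
    w <- splicefid:::site_window(genome, j$contig[i], j$start[i], j$end[i],
                                 "-", "donor")
    plus <- genome_sequence(genome, j$contig[i], j$end[i] - 5L, j$end[i] + 3L,
                            "+")
    expect_equal(w, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(plus))))
    # and the window starts with the GT dinucleotide at intronic position 4
    expect_equal(substr(w, 4, 5), "GT")
  }
})

test_that("a set equal to its baseline population shows zero differences", {
  b <- shared_bundle()
  genome <- read_genome(file.path(b$dir, "genome.fa"))
  idx <- load_annotation(file.path(b$dir, "annotation.gtf"),
                         file.path(b$dir, "expression.tsv"))
  model <- train_pwm_from_annotation(idx, genome)
  base <- splicefid:::annotated_intron_table(idx)
  set <- data.frame(contig = base$contig, intron_start = base$start,
                    intron_end = base$end, strand = base$strand)
  fs <- intron_feature_summary(set, idx, genome, model)
  expect_equal(fs$set_mean, fs$baseline_mean, tolerance = 1e-12)
  expect_equal(fs$set_median, fs$baseline_median, tolerance = 1e-12)
  expect_true(all(fs$p_bonferroni >= fs$p_value - 1e-12))
})

test_that("weakened skipped-exon acceptors are detected against baseline", {
  # rebuild the bundle genome with the 20 intronic acceptor bases of each
  # event exon's upstream intron replaced by poly-A (destroying the AG)
  b <- shared_bundle()
  idx <- load_annotation(file.path(b$dir, "annotation.gtf"),
                         file.path(b$dir, "expression.tsv"))
  genome <- read_genome(file.path(b$dir, "genome.fa"))
  truth <- b$bundle$sim$truth$exons
  chars <- as.list(setNames(as.character(genome), names(genome)))
  ev <- enumerate_skipped_exon_events(idx)
  ev <- ev[match(paste(truth$contig, truth$exon_start, truth$exon_end),
                 paste(ev$contig, ev$exon_start, ev$exon_end)), ]
  ev <- ev[!is.na(ev$event_id), ]
  for (i in seq_len(nrow(ev))) {
    s <- ev$inc1_start[i]; e <- ev$inc1_end[i]; ct <- ev$contig[i]
    if (ev$strand[i] == "+") {
      substr(chars[[ct]], e - 19L, e) <- strrep("A", 20)
    } else {
      substr(chars[[ct]], s, s + 19L) <- strrep("A", 20)
    }
  }
  genome2 <- Biostrings::DNAStringSet(unlist(chars))
  model <- train_pwm_from_annotation(idx, genome2)
  fs <- exon_event_feature_summary(ev, idx, genome2, model)
  acc <- fs[fs$feature == "skipped_exon_acceptor_score", ]
  don <- fs[fs$feature == "upstream_exon_donor_score", ]
  expect_lt(acc$set_mean, acc$baseline_mean - 1)   # clearly weakened
  expect_lt(abs(don$set_mean - don$baseline_mean), 1)  # donors untouched
  expect_lt(acc$p_bonferroni, 1e-3)
})
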