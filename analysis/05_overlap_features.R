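#!/usr/bin/env Rscript
# Step 5: cross-sample overlap statistics and sequence features.
#
# Pairwise shared proportions and hypergeometric p-values for the per-sample
# high-confidence unannotated junction sets, and a sequence-feature profile
# (lengths, GC, splice-site strength under a PWM trained on the annotation)
# of exons with increased inclusion in condition B versus annotation-wide
# baselines.

suppressMessages(library(splicefid))
dir <- "results/bundle"
idx <- load_annotation(file.path(dir, "annotation.gtf"),
                       file.path(dir, "expression.tsv"))
genome <- read_genome(file.path(dir, "genome.fa"))

samples <- expand.grid(cond = c("A", "B"), rep = 1:2, stringsAsFactors = FALSE)
junctions <- list(); kept <- list()
for (i in seq_len(nrow(samples))) {
  sid <- sprintf("%s_rep%d", samples$cond[i], samples$rep[i])
  j <- read_junction_table(file.path(dir, sprintf("sj_%s_rep%d.tab",
                                                  samples$cond[i], samples$rep[i])))
  j <- classify_junctions(assign_junctions_to_genes(j, idx), idx)
  junctions[[sid]] <- j
  cs <- select_high_confidence_unannotated(j, idx, sample_id = sid)
  kept[[sid]] <- junction_key(cs$kept$contig, cs$kept$start, cs$kept$end,
                              cs$kept$strand)
}
universe <- unique(unlist(lapply(junctions, function(j) {
  ok <- j$canonical & !is.na(j$assigned_gene)
  junction_key(j$contig[ok], j$start[ok], j$end[ok], j$strand[ok])
})))
sets <- lapply(names(kept), function(sid) junction_set(sid, kept[[sid]], universe))
m <- pairwise_matrix(sets)
write.table(m$long, "results/05_overlap.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Pairwise shared proportions of unannotated junctions:\n")
print(round(m$proportion, 3))
cat("-log10 hypergeometric p:\n")
print(round(m$neg_log10_p, 2))

model <- train_pwm_from_annotation(idx, genome)
diff <- read.table("results/03_differential_inclusion.tsv", header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
events <- enumerate_skipped_exon_events(idx)
up_in_b <- events[events$event_id %in%
                    diff$event_id[diff$fdr < 0.05 & diff$delta_psi < 0], ]
if (nrow(up_in_b)) {
  fs <- exon_event_feature_summary(up_in_b, idx, genome, model)
  write.table(fs, "results/05_features.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat(sprintf("Feature profile of %d exons with increased inclusion in B:\n",
              nrow(up_in_b)))
  print(fs[, c("feature", "set_mean", "baseline_mean", "p_bonferroni")])
}
cat("Wrote results/05_overlap.tsv and results/05_features.tsv\n")
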