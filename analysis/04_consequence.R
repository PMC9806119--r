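#!/usr/bin/env Rscript
# Step 4: consequences of significantly altered exon skipping.
#
# Takes the events called at FDR < 0.05 in step 3, determines the reading
# frame effect of each skipped exon, scans frameshifted isoforms for
# premature termination codons, applies the 50-nt NMD rule, and overlaps
# in-frame skips with the protein-domain table. Compares calls against the
# generator's ground truth.

suppressMessages(library(splicefid))
dir <- "results/bundle"
idx <- load_annotation(file.path(dir, "annotation.gtf"),
                       file.path(dir, "expression.tsv"))
genome <- read_genome(file.path(dir, "genome.fa"))
domains <- read_domain_table(file.path(dir, "domains.tsv"))

diff <- read.table("results/03_differential_inclusion.tsv", header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
events <- enumerate_skipped_exon_events(idx)
sig <- events[events$event_id %in% diff$event_id[diff$fdr < 0.05], ]
cat(sprintf("Classifying %d significantly altered skipped exons\n", nrow(sig)))

calls <- consequence_table(sig, idx, genome, domains)
write.table(calls, "results/04_consequence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Category counts among altered exons:\n")
print(table(calls$category))

truth <- read.table(file.path(dir, "ground_truth_consequence.tsv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
key <- function(d) paste(d$gene_id, d$exon_start, d$exon_end)
m <- match(key(calls), key(truth))
hit <- !is.na(m)
if (any(hit)) {
  agree <- mean(calls$category[hit] == truth$category[m[hit]])
  cat(sprintf("Agreement with ground truth on %d matched event exons: %.1f%%\n",
              sum(hit), 100 * agree))
}
cat("Wrote results/04_consequence.tsv\n")
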