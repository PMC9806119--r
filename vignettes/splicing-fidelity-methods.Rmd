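---
title: "Methods: quantifying splicing fidelity from junction count data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying splicing fidelity from junction count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the quantities it
computes, the assumptions behind them, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the design choices
made where the design was genuinely open.

## The analysis model

The package treats a sample as a set of observed splice junctions with
unique-read counts (the STAR `SJ.out.tab` dialect), optionally accompanied by
per-intron mean coverage and gene-level TPM. All coordinates are 1-based and
fully inclusive; a junction's identity is the tuple (contig, first intronic
base, last intronic base, strand), which makes junction tables and GTF introns
directly comparable without off-by-one adjustments. Donor and acceptor are
defined in transcript orientation: on the minus strand the donor is the
intron boundary with the larger genomic coordinate. All site sets are
strand-aware.

### Unannotated junction discovery

A junction is *annotated* when its exact tuple occurs among the introns of
any annotated transcript. Otherwise it is classified by whether its donor
and acceptor positions occur in the annotation's strand-aware site sets:
both (a novel pairing of known sites, the signature of exon skipping),
exactly one (hemi-annotated), or neither (fully novel). Only canonical
junctions (GT-AG motif, on either strand) enter the analysis; non-canonical
rows are retained in parsed tables but flagged.

The high-confidence filter works per gene: within each robustly expressed
gene (TPM strictly greater than 10), the highest unique-read count over the
gene's *observed* annotated junctions defines the reference depth D, and
unannotated junctions with reads ≥ 0.1·D are kept (the boundary is
inclusive; "at least 10%"). Genes in which no annotated junction was observed
with nonzero reads are skipped — with D = 0 the filter would keep everything.
Single-exon genes are excluded outright since D is undefined for them. The
headline per-sample metric is the number of genes with at least one kept
junction divided by the number of eligible genes (multi-exon, expressed, with
an observed annotated junction). Junctions overlapping several gene spans are
assigned to the same-strand overlapping gene with the highest TPM, ties
broken by lexicographically smallest gene id; whether the original analysis
required same-strand overlap is not documented, so strand-awareness is this
package's choice, recorded here.

### Exon inclusion and commitment

For a skipped-exon event with I reads on the two inclusion junctions and S
reads on the skip junction, the length-normalized inclusion level is

ψ = (I / 2) / (I / 2 + S / 1),

the junction-only form of the standard percent-spliced-in estimator (two
inclusion junctions versus one skip junction; exon-body counting is not
implemented). Events with I + S = 0 are undefined and excluded, not scored
as zero. When the same exon is skipped by several alternative junctions, the
minimum ψ is kept. The per-sample commitment score is

(#{ψ > 0.99} + #{ψ < 0.01}) / #exons,

with strict inequalities at both bounds, over deduplicated exons of expressed
genes. Events with total depth below `min_event_depth` (default 10) are
excluded from commitment scoring so that ψ estimates from a handful of reads
do not dilute the score; the depth floor the reference tooling applies
internally is not documented, so 10 is this package's configurable default.

Differential inclusion pools replicates per condition and applies a
two-sided Fisher exact test to each event's 2×2 table (I₁, S₁; I₂, S₂), with
Benjamini–Hochberg correction across events. A hierarchical
likelihood model over replicates (as in dedicated differential-splicing
tools) would borrow strength across events; the exact test was chosen to
keep the artifact self-contained and its null behaviour provable — the test
suite verifies agreement with an exhaustive table-enumeration oracle and
that all-null simulations yield zero discoveries at FDR < 0.05. Two gates
are used downstream: FDR < 0.05 for event sets and FDR < 0.0005 for
high-confidence cross-dataset comparisons.

### Intron retention

The per-intron retention ratio is mean intronic depth / (mean intronic depth
+ exact-spanning spliced reads). This is a deliberate simplification of
dedicated intron-retention estimators, which trim intron ends and mask
low-mappability regions; the simplification preserves the quantity's meaning
and thresholding behaviour, and the intronic depth arrives as a precomputed
per-intron mean (from a table or the generator) — no BAM pileup is
performed. Only introns whose spanning junction is detected in the sample
are scorable. The gene-level burden is the proportion of expressed genes
(with ≥ 1 scorable intron) having any intron with ratio strictly above 0.25.
Whether the original denominator included genes with no measurable introns
is unstated; requiring a scorable intron avoids counting genes the data
cannot speak to.

### Consequences of exon skipping

Each altered skipped exon is classified by the length of its CDS overlap
modulo 3 (only the CDS-overlapping bases count; exons outside the CDS are
noncoding skips). For frameshifting skips, the skipped isoform is
reconstructed at the sequence level: the exon's bases are removed from the
spliced transcript, the CDS start is remapped (shifted when the exon lies in
the 5' UTR; flagged start-lost when the start codon itself is removed), and
translation proceeds codon by codon from the remapped start. The first
in-frame stop strictly upstream of the remapped annotated stop is the PTC.

The NMD rule: an isoform is NMD-targeting when its PTC lies more than 50 nt
upstream of an exon–exon junction. Distance is measured from the last base
of the stop codon to the junction (the last base of the preceding exon), and
the test is applied at the *final* junction — the canonical formulation of
the 50–55 nt boundary rule. Because the final junction is the 3'-most one, a
PTC more than 50 nt upstream of any junction is equivalently more than 50 nt
upstream of the final one, so the literal "a splice junction" reading and
the final-junction reading coincide. When several transcripts contain the
skipped exon internally, every affected isoform is evaluated and the event
is NMD-targeting if any isoform qualifies.

In-frame skips are mapped to protein coordinates (rounding outward to whole
codons when the exon starts or ends mid-codon) and intersected with a
user-supplied protein-domain interval table; one amino acid of overlap marks
a domain as affected. Domain evidence is an input table rather than a web
service, so domain significance filtering happens upstream of this package.
In-frame skips that create a novel junction-spanning stop codon are still
routed to domain analysis; the PTC path is reserved for frameshifts. Each
event is counted once as NMD-targeting, domain-affecting, or neither, with
NMD taking precedence.

### Overlap statistics

Two junction (or event) sets on a common universe are compared by the shared
proportion |A∩B| / |A∪B| and the exact upper-tail hypergeometric probability
P(X ≥ k), computed with the log-space-stable distribution function. The
union denominator keeps the statistic in [0, 1] with value 1 for identical
sets; the |A|+|B| convention is available as an option since the phrase
"total number in the two datasets" is ambiguous. The universe is likewise a
convention: for unannotated-junction comparisons the package uses all
canonical gene-assigned junctions observed in the compared samples within
expressed genes; for altered-event comparisons, all events tested in both.
Both choices are recorded in outputs, because hypergeometric p-values depend
strongly on the universe size.

### Sequence features

Splice-site strength is a log-odds position-weight-matrix score,
Σ log₂(p_model / p_background), with windows matching the maximum-entropy
scorer conventions (donor: 3 exonic + 6 intronic = 9 nt; acceptor: 20
intronic + 3 exonic = 23 nt) so externally computed scores can be slotted
in. The matrices are trained on all annotated junctions of the supplied
annotation with a pseudocount (default 0.5); the background is the pooled
base composition of the training windows. This scorer is a package-native
substitute for published maximum-entropy models: scores are comparable
within a run, not numerically comparable to published scores. Event sets are
summarized by lengths, GC content (N bases excluded), and site scores at the
four positions of a skipping event, against annotation-wide per-exon and
per-intron baselines, with two-sided rank tests and Bonferroni correction
across features.

## Thresholds and parameters

| Parameter | Default | Meaning |
|---|---|---|
| `tpm_gate` | 10 | expression gate, strict > |
| `unannotated_fraction` | 0.1 | fraction of gene max annotated depth, inclusive ≥ |
| `commit_hi`, `commit_lo` | 0.99, 0.01 | commitment bounds, strict |
| `ir_threshold` | 0.25 | retention threshold, strict > |
| `fdr`, `fdr_high_confidence` | 0.05, 0.0005 | BH gates |
| `nmd_distance` | 50 nt | PTC-to-final-junction rule, strict > |
| `min_event_depth` | 10 reads | I + S floor for commitment scoring |

## The synthetic-data generator

`simulate_annotation()` builds multi-exon genes (default 120 genes, 4–8
exons of 90–300 nt, introns of 120–600 nt, 40% on the minus strand), each
with a valid CDS — ATG start, a single in-frame stop at the CDS end, no
internal stops — and GT/AG dinucleotides at every intron boundary in
transcript orientation. Every gene carries two annotated isoforms: the full
transcript and a skip isoform lacking one designated internal event exon, so
the skipping junction used for ψ quantification is itself annotated and the
unannotated-junction analysis is not confounded by skipping reads. Injected
unannotated junctions are separate controlled coordinates, one candidate per
gene, in the three taxonomy classes (exon-skip of a second internal exon,
hemi-annotated, fully novel), emitted per condition for a configured
fraction of expressed genes at a configured fraction (default 0.15) of the
gene's maximum annotated depth.

Counts are drawn per sample: junction depths are negative binomial (mean
200, dispersion 0.1 — standard RNA-seq overdispersion at desk scale), and
the event exon's depth n is split as I ~ Binomial(n, 2ψ*/(1+ψ*)) inclusion
reads versus n − I skip reads, inverting the length-normalized ψ formula so
the estimator is unbiased for ψ* (verified to |bias| < 0.01 at depth 400).
Intron coverage is Poisson with mean s·r*/(1−r*) given s spliced reads, so
the expected retention ratio approximates r*. The bundled "paper-shape"
defaults encode the contrast the package is designed to measure: condition A
(blood-naive-B-cell-like) with 30% of expressed genes carrying injected
unannotated junctions, 30% committed exons (the rest ψ* ~ Beta(2, 2)), and
60% of genes given a high-retention intron (r* in 0.35–0.7); condition B
(differentiated-like) with 5%, 90%, and 10%. Gene count, depth, and length
ranges are desk-scale choices that keep a full run in seconds while leaving
every per-gene statistic well determined.

NMD boundary behaviour is exercised by *constructed*, non-random fixtures:
`nmd_boundary_gene(distance)` builds a 4-exon gene on a poly-C backbone in
which skipping exon 2 (length ≡ 1 mod 3) places the first stop of the
shifted frame at exactly `distance` nt upstream of the final junction, with
the reference frame provably stop-free; distances of 50 and 51 nt pin the
strict boundary on both strands.

What the generator does not emulate: read-level alignment artifacts
(mismapping, soft-clipping, overhang effects), mappability structure inside
introns, non-canonical splice motifs, poly(A)-selection bias against nascent
transcripts (which inflates apparent retention in real total-RNA data),
correlated expression between conditions, and multi-gene loci with
overlapping annotation. Passing tests therefore demonstrate correctness of
the estimators and rules on clean count data, not robustness to alignment
pathology.

## Numerical and degenerate-input conventions

Undefined ratios (ψ with I + S = 0, retention with depth + spliced = 0) are
NA and excluded, never coerced to 0. Hypergeometric tails are computed in
log space and match exhaustive enumeration to relative error below 1e-10 for
universes up to 1000 (and remain stable to 1e6). Ties in junction-to-gene
assignment break lexicographically after the TPM criterion, making runs
deterministic; all simulation randomness is governed by a single seed, with
per-sample streams derived from it. Fisher tests on retention evidence round
the mean depth to integer counts. The duplicate-exon collapse keeps row
identity of the minimal-ψ record, so event metadata stays attached.

## Known limitations

The Fisher-exact differential engine treats pooled counts as independent
reads and will be anticonservative under strong biological replicate
variability; per-replicate ψ values are reported alongside for dispersion
inspection. The retention estimator inherits the biases of mean-coverage
summaries (it does not mask repetitive intron interiors). The PWM scorer is
position-independent by construction and weaker than maximum-entropy models
at capturing dependencies between splice-site positions. Domain calls are
only as complete as the supplied domain table. The NMD rule is the classical
distance heuristic; NMD efficiency, uORFs, and long-3'UTR triggers are out
of scope.
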