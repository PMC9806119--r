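# End-to-end orchestration: one configuration object, one driver that runs
# every stage over a set of samples and writes stable TSV outputs plus a run
# manifest. The analysis/ scripts are thin narrative wrappers over this.

#' Pipeline configuration
#'
#' Consolidates every threshold and convention. Defaults are the analysis
#' gates used throughout: TPM > 10 expression gate, 10%-of-max unannotated
#' junction fraction, commitment bounds 0.99/0.01, retention threshold 0.25,
#' event FDR 0.05 and high-confidence FDR 0.0005, 50-nt NMD distance,
#' minimum event depth 10, union denominator for shared proportions.
#'
#' @param gtf,genome,expression Paths to annotation, genome FASTA and
#'   expression TSV.
#' @param junction_tables Named list: condition -> character vector of
#'   junction-table paths (replicates).
#' @param coverage_tables Named list mirroring `junction_tables` (optional).
#' @param domain_table Path to a domain TSV (optional).
#' @param tpm_gate,unannotated_fraction,commit_hi,commit_lo,ir_threshold,fdr,fdr_high_confidence,nmd_distance,min_event_depth,shared_denominator
#'   Thresholds and conventions (see above).
#' @return A `RunConfig` list.
#' @export
pipeline_config <- function(gtf, genome, expression,
                            junction_tables, coverage_tables = NULL,
                            domain_table = NULL,
                            tpm_gate = 10, unannotated_fraction = 0.1,
                            commit_hi = 0.99, commit_lo = 0.01,
                            ir_threshold = 0.25, fdr = 0.05,
                            fdr_high_confidence = 0.0005,
                            nmd_distance = 50, min_event_depth = 10,
                            shared_denominator = "union") {
  stopifnot(tpm_gate >= 0, unannotated_fraction >= 0,
            commit_lo < commit_hi, ir_threshold >= 0, ir_threshold <= 1,
            fdr > 0, fdr <= 1, nmd_distance >= 0)
  for (p in c(gtf, genome, expression, unlist(junction_tables),
              unlist(coverage_tables), domain_table)) {
    if (!is.null(p) && !file.exists(p)) stop("input does not exist: ", p)
  }
  structure(as.list(environment()), class = "RunConfig")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis over a fixture bundle or real inputs
#'
#' Stages, in order: junction classification and unannotated-junction
#' selection per sample; exon inclusion and per-sample commitment scores;
#' intron retention per sample (when coverage tables are given); differential
#' inclusion between the first two conditions; consequence classification of
#' significantly altered skipped exons; pairwise unannotated-junction overlap
#' statistics; sequence-feature summaries. One TSV per stage is written under
#' `out_dir`, plus `manifest.tsv` recording every threshold and input.
#'
#' @param cfg A `RunConfig` from [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of in-memory stage results (annotation index,
#'   call_sets, commitment, retention, differential, consequence, overlap,
#'   features, and the per-sample proportions table).
#' @export
run_pipeline <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  idx <- load_annotation(cfg$gtf, cfg$expression)
  genome <- read_genome(cfg$genome)
  domains <- if (!is.null(cfg$domain_table)) read_domain_table(cfg$domain_table)

  conditions <- names(cfg$junction_tables)
  samples <- list()
  for (cn in conditions) {
    paths <- cfg$junction_tables[[cn]]
    for (r in seq_along(paths)) {
      sid <- sprintf("%s_rep%d", cn, r)
      samples[[sid]] <- list(condition = cn, replicate = r,
                             junctions = NULL, path = paths[r])
    }
  }

  # --- junction catalogue ---------------------------------------------------
  call_sets <- list()
  junction_rows <- list()
  for (sid in names(samples)) {
    j <- read_junction_table(samples[[sid]]$path)
    j <- assign_junctions_to_genes(j, idx)
    j <- classify_junctions(j, idx)
    samples[[sid]]$junctions <- j
    cs <- select_high_confidence_unannotated(
      j, idx, sample_id = sid, fraction = cfg$unannotated_fraction,
      tpm_gate = cfg$tpm_gate)
    call_sets[[sid]] <- cs
    kept_key <- junction_key(cs$kept$contig, cs$kept$start, cs$kept$end,
                             cs$kept$strand)
    junction_rows[[sid]] <- data.frame(
      sample_id = sid,
      junction = junction_key(j$contig, j$start, j$end, j$strand),
      status = as.character(j$status), unique_reads = j$unique_reads,
      gene_id = j$assigned_gene,
      kept = junction_key(j$contig, j$start, j$end, j$strand) %in% kept_key,
      stringsAsFactors = FALSE
    )
  }
  write_tsv(do.call(rbind, junction_rows), file.path(out_dir, "junctions.tsv"))

  proportions <- data.frame(
    sample_id = names(samples),
    condition = vapply(samples, `[[`, character(1), "condition"),
    unannotated_gene_proportion = vapply(call_sets, gene_unannotated_proportion,
                                         numeric(1)),
    stringsAsFactors = FALSE
  )

  # --- inclusion & commitment ----------------------------------------------
  events <- enumerate_skipped_exon_events(idx)
  commitment <- list()
  counted <- list()
  for (sid in names(samples)) {
    counted[[sid]] <- count_exon_events(events, samples[[sid]]$junctions)
    commitment[[sid]] <- exon_commitment_score(
      counted[[sid]], idx, hi = cfg$commit_hi, lo = cfg$commit_lo,
      tpm_gate = cfg$tpm_gate, min_depth = cfg$min_event_depth,
      sample_id = sid)
  }
  proportions$commitment_score <- vapply(commitment, function(x) x$score,
                                         numeric(1))

  # --- intron retention -----------------------------------------------------
  retention <- list()
  scored_introns <- list()
  if (!is.null(cfg$coverage_tables)) {
    for (cn in conditions) {
      paths <- cfg$coverage_tables[[cn]]
      for (r in seq_along(paths)) {
        sid <- sprintf("%s_rep%d", cn, r)
        cov <- read_intron_coverage(paths[r])
        sc <- score_intron_retention(cov, samples[[sid]]$junctions)
        scored_introns[[sid]] <- sc
        retention[[sid]] <- gene_retention_metric(
          sc, idx, threshold = cfg$ir_threshold, tpm_gate = cfg$tpm_gate,
          sample_id = sid)
      }
    }
    proportions$retention_proportion <-
      vapply(names(samples), function(sid) {
        if (sid %in% names(retention)) retention[[sid]]$proportion else NA_real_
      }, numeric(1))
  }
  write_tsv(proportions, file.path(out_dir, "sample_summary.tsv"))

  # --- differential inclusion between the first two conditions --------------
  differential <- NULL
  consequence <- NULL
  if (length(conditions) >= 2L) {
    pool <- function(cn) {
      sids <- names(samples)[vapply(samples, function(s)
        s$condition == cn, logical(1))]
      jj <- do.call(rbind, lapply(sids, function(sid) samples[[sid]]$junctions))
      count_exon_events(events, jj)
    }
    differential <- differential_inclusion(pool(conditions[1L]),
                                           pool(conditions[2L]))
    write_tsv(differential, file.path(out_dir, "differential_inclusion.tsv"))

    sig <- differential[differential$fdr < cfg$fdr, , drop = FALSE]
    if (nrow(sig)) {
      sig_ev <- events[match(sig$event_id, events$event_id), , drop = FALSE]
      consequence <- consequence_table(sig_ev, idx, genome, domains,
                                       rule_distance = cfg$nmd_distance)
      write_tsv(consequence, file.path(out_dir, "consequence.tsv"))
    }
  }

  # --- cross-sample overlap of unannotated junctions ------------------------
  overlap <- NULL
  if (length(call_sets) >= 2L) {
    all_keys <- lapply(names(samples), function(sid) {
      j <- samples[[sid]]$junctions
      expressed <- eligible_genes(idx, cfg$tpm_gate)
      j <- j[j$canonical & !is.na(j$assigned_gene) &
               j$assigned_gene %in% expressed, , drop = FALSE]
      junction_key(j$contig, j$start, j$end, j$strand)
    })
    universe <- unique(unlist(all_keys))
    sets <- lapply(names(samples), function(sid) {
      cs <- call_sets[[sid]]
      junction_set(sid, junction_key(cs$kept$contig, cs$kept$start,
                                     cs$kept$end, cs$kept$strand), universe)
    })
    overlap <- pairwise_matrix(sets, denominator = cfg$shared_denominator)
    write_tsv(overlap$long, file.path(out_dir, "overlap.tsv"))
  }

  # --- sequence features ----------------------------------------------------
  model <- train_pwm_from_annotation(idx, genome)
  feat_events <- if (!is.null(differential) && nrow(differential)) {
    sig <- differential[differential$fdr < cfg$fdr & differential$delta_psi > 0, ,
                        drop = FALSE]
    if (nrow(sig)) events[match(sig$event_id, events$event_id), , drop = FALSE]
  }
  features <- if (!is.null(feat_events) && nrow(feat_events)) {
    exon_event_feature_summary(feat_events, idx, genome, model,
                               tpm_gate = cfg$tpm_gate)
  }
  if (!is.null(features)) write_tsv(features, file.path(out_dir, "features.tsv"))

  manifest <- data.frame(
    key = c("tpm_gate", "unannotated_fraction", "commit_hi", "commit_lo",
            "ir_threshold", "fdr", "fdr_high_confidence", "nmd_distance",
            "min_event_depth", "shared_denominator", "gtf", "genome",
            "expression", "n_samples"),
    value = c(cfg$tpm_gate, cfg$unannotated_fraction, cfg$commit_hi,
              cfg$commit_lo, cfg$ir_threshold, cfg$fdr,
              cfg$fdr_high_confidence, cfg$nmd_distance, cfg$min_event_depth,
              cfg$shared_denominator, cfg$gtf, cfg$genome, cfg$expression,
              length(samples)),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(
    idx = idx, genome = genome, call_sets = call_sets,
    proportions = proportions, commitment = commitment,
    retention = retention, scored_introns = scored_introns,
    differential = differential, consequence = consequence,
    overlap = overlap, features = features, model = model
  ))
}
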