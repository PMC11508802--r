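# One-call pipeline: trim -> QC filter -> align -> classify -> tally ->
# select, for a single sample.

#' Run the full classification pipeline on one sample
#'
#' Primer-trims the reads, applies the length/quality filter, aligns the
#' kept reads against the reference database, classifies each read by
#' filtered-hit majority-rule LCA, tallies the assigned reads into a
#' sample profile and applies the top-taxon selection rule.
#'
#' @param reads A [read_set()] of raw (untrimmed) reads.
#' @param db A [reference_db()].
#' @param primers List with `fwd`/`rev` primer strings.
#' @param read_cfg A [read_filter_config()].
#' @param hit_cfg A [hit_filter_config()].
#' @param lca_cfg An [lca_config()].
#' @param sel_cfg A [selection_config()].
#' @param seed_k Aligner seed length.
#' @param scheme A [scoring_scheme()].
#' @param max_primer_mismatch Mismatches tolerated when trimming.
#' @param sample_id Profile label (defaults to the reads' sample id).
#' @param metadata Metadata list attached to the profile.
#' @return List of class `pipeline_result`: `qc` (QC report), `kept`
#'   (filtered [read_set()]), `hits`, `assignments`, `profile`.
#' @export
run_pipeline <- function(reads, db, primers = rbcla_primers(),
                         read_cfg = read_filter_config(),
                         hit_cfg = hit_filter_config(),
                         lca_cfg = lca_config(),
                         sel_cfg = selection_config(),
                         seed_k = 11L, scheme = scoring_scheme(),
                         max_primer_mismatch = 2L,
                         sample_id = NULL, metadata = list()) {
  if (is.null(sample_id)) {
    sample_id <- if (length(reads)) reads$sample_id[1] else "sample"
  }
  trimmed <- trim_reads(reads, primers$fwd, primers$rev,
                        max_primer_mismatch)
  qc <- filter_reads(trimmed, read_cfg)
  hits <- align_reads(qc$kept, db, seed_k = seed_k, scheme = scheme)
  assignments <- classify_reads(qc$kept, hits, db, hit_cfg, lca_cfg)
  profile <- select_taxa(tally(assignments, sample_id, metadata), sel_cfg)
  structure(list(qc = qc$report, kept = qc$kept, hits = hits,
                 assignments = assignments, profile = profile),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$qc)
  st <- table(factor(x$assignments$status,
                     levels = c("Assigned", "Unresolved", "Unassigned")))
  cat(sprintf("Assignments: %d assigned, %d unresolved, %d unassigned\n",
              st[["Assigned"]], st[["Unresolved"]], st[["Unassigned"]]))
  print(x$profile)
  invisible(x)
}
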