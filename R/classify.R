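# Per-read taxonomic assignment: identity/coverage hit filtering, the
# top-bitscore window, and majority-rule lowest-common-ancestor voting
# ascending the rank ladder from species.

#' Hit filtering configuration
#'
#' Two sequential filters are applied to a read's hits: (1) keep hits with
#' percent identity of at least `min_pct_identity` and alignment coverage
#' of at least `min_coverage`; (2) among the survivors, keep only hits
#' whose bitscore is within `bitscore_window` (a fraction) of the best
#' surviving bitscore. Coverage is `100 * aln_len / denominator`, where
#' the denominator is the read length after trimming by default
#' (`coverage_denominator = "read"`); `"reference"` and `"amplicon"`
#' denominators are available for sensitivity analyses.
#'
#' @param min_pct_identity Identity floor in percent (inclusive).
#' @param min_coverage Coverage floor in percent (inclusive).
#' @param bitscore_window Fraction of the top bitscore (0.05 keeps hits
#'   with bitscore at least 95% of the best survivor's).
#' @param coverage_denominator One of `"read"`, `"reference"`,
#'   `"amplicon"`.
#' @return A list of class `hit_filter_config`.
#' @export
hit_filter_config <- function(min_pct_identity = 80, min_coverage = 80,
                              bitscore_window = 0.05,
                              coverage_denominator = c("read", "reference",
                                                       "amplicon")) {
  stopifnot(min_pct_identity >= 0, min_pct_identity <= 100,
            min_coverage >= 0, min_coverage <= 100,
            bitscore_window >= 0, bitscore_window <= 1)
  structure(list(min_pct_identity = min_pct_identity,
                 min_coverage = min_coverage,
                 bitscore_window = bitscore_window,
                 coverage_denominator = match.arg(coverage_denominator)),
            class = "hit_filter_config")
}

#' Majority-rule LCA configuration
#'
#' @param majority_fraction Fraction of assignments that must agree on a
#'   taxon name for a rank to be decided (default 0.75); must exceed 0.5
#'   so the winner is unique.
#' @param vote_denominator Whether the vote at a rank is taken over
#'   `"all"` surviving hits (default; hits whose lineage lacks the rank
#'   count against the majority) or only over hits `"annotated"` at that
#'   rank.
#' @return A list of class `lca_config`.
#' @export
lca_config <- function(majority_fraction = 0.75,
                       vote_denominator = c("all", "annotated")) {
  stopifnot(majority_fraction > 0.5, majority_fraction <= 1)
  structure(list(majority_fraction = majority_fraction,
                 vote_denominator = match.arg(vote_denominator)),
            class = "lca_config")
}

#' Filter a read's alignment hits
#'
#' Applies the identity/coverage filter, then the top-bitscore window
#' computed over the identity/coverage survivors (strictly in that
#' order). Empty input gives empty output.
#'
#' @param hits Hit data frame for one read.
#' @param read_len Length of the (trimmed) read in bases.
#' @param cfg A [hit_filter_config()].
#' @param ref_len Named vector of reference lengths (required when
#'   `coverage_denominator = "reference"`).
#' @param amplicon_len Expected amplicon length (required when
#'   `coverage_denominator = "amplicon"`).
#' @return The surviving hits, input order preserved.
#' @export
filter_hits <- function(hits, read_len, cfg = hit_filter_config(),
                        ref_len = NULL, amplicon_len = NULL) {
  stopifnot(read_len > 0)
  if (nrow(hits) == 0L) return(hits)
  denom <- switch(cfg$coverage_denominator,
    read = rep(read_len, nrow(hits)),
    reference = {
      if (is.null(ref_len)) {
        stop_typed("config_error",
                   "reference coverage denominator needs ref_len")
      }
      unname(ref_len[hits$ref_id])
    },
    amplicon = {
      if (is.null(amplicon_len)) {
        stop_typed("config_error",
                   "amplicon coverage denominator needs amplicon_len")
      }
      rep(amplicon_len, nrow(hits))
    })
  coverage <- 100 * hits$aln_len / denom
  step1 <- hits[hits$pct_identity >= cfg$min_pct_identity &
                  coverage >= cfg$min_coverage, , drop = FALSE]
  if (nrow(step1) == 0L) return(step1)
  top <- max(step1$bitscore)
  out <- step1[step1$bitscore >= (1 - cfg$bitscore_window) * top, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Majority-rule lowest common ancestor of a set of lineages
#'
#' Starting at species and ascending the rank ladder: at each rank, if a
#' single taxon name is shared by at least `majority_fraction` of the
#' lineages, the vote is decided and the agreeing lineage truncated at
#' that rank is returned with status `"Assigned"`. If the top rank is
#' exhausted without agreement the status is `"Unresolved"`. By default
#' the vote at a rank is taken over all lineages, including those that
#' lack an annotation at that rank (see [lca_config()]).
#'
#' @param lineages Character vector of lineage strings (one per
#'   assignment/hit; duplicates count once each).
#' @param cfg An [lca_config()].
#' @return List with elements `status` (`"Assigned"`/`"Unresolved"`),
#'   `lineage` (truncated lineage string or `NA`), `rank` (decided rank
#'   or `NA`).
#' @export
majority_lca <- function(lineages, cfg = lca_config()) {
  n <- length(lineages)
  if (n == 0L) {
    stop_typed("empty_input_error", "majority_lca needs at least one lineage")
  }
  parsed <- lapply(lineages, parse_lineage)
  ranks <- tax_ranks()
  for (ri in 7:1) {
    at <- vapply(parsed, function(l) l[[ri]], "")
    known <- !is.na(at)
    if (!any(known)) next
    tab <- table(at[known])
    denom <- if (cfg$vote_denominator == "all") n else sum(known)
    top <- max(tab)
    if (top >= cfg$majority_fraction * denom) {
      winner <- names(tab)[which.max(tab)]
      src <- parsed[known][[match(winner, at[known])]]
      return(list(status = "Assigned",
                  lineage = format_lineage(truncate_lineage(src, ranks[ri])),
                  rank = ranks[ri]))
    }
  }
  list(status = "Unresolved", lineage = NA_character_, rank = NA_character_)
}

#' Classify one read from its hits
#'
#' Runs [filter_hits()], maps surviving reference ids to lineages, and
#' applies [majority_lca()]. A read with no surviving hits is
#' `"Unassigned"`; a read whose survivors reach no majority at any rank
#' is `"Unresolved"`; both carry no lineage.
#'
#' @param read_id Read identifier (recorded in the output).
#' @param hits Hit data frame for this read.
#' @param read_len Trimmed read length in bases.
#' @param db A [reference_db()]; every hit `ref_id` must be present.
#' @param hcfg A [hit_filter_config()].
#' @param lcfg An [lca_config()].
#' @return One-row data frame: `read_id`, `status`, `rank`, `lineage`,
#'   `n_hits_used`.
#' @export
classify_read <- function(read_id, hits, read_len, db,
                          hcfg = hit_filter_config(),
                          lcfg = lca_config()) {
  surv <- filter_hits(hits, read_len, hcfg)
  if (nrow(surv) == 0L) {
    return(data.frame(read_id = read_id, status = "Unassigned",
                      rank = NA_character_, lineage = NA_character_,
                      n_hits_used = 0L, stringsAsFactors = FALSE))
  }
  pos <- match(surv$ref_id, db$records$id)
  if (anyNA(pos)) {
    stop_typed("unknown_reference_error",
               "hit references unknown reference id(s): %s",
               paste(unique(surv$ref_id[is.na(pos)]), collapse = ", "))
  }
  res <- majority_lca(db$records$lineage[pos], lcfg)
  data.frame(read_id = read_id, status = res$status, rank = res$rank,
             lineage = res$lineage, n_hits_used = nrow(surv),
             stringsAsFactors = FALSE)
}

#' Classify every read in a set
#'
#' @param reads A [read_set()].
#' @param hits Hit data frame over all reads (e.g. from [align_reads()]
#'   or [read_hit_table()]).
#' @inheritParams classify_read
#' @return Assignment data frame, one row per read in `reads`.
#' @export
classify_reads <- function(reads, hits, db, hcfg = hit_filter_config(),
                           lcfg = lca_config()) {
  lens <- read_lengths(reads)
  split_hits <- split(seq_len(nrow(hits)), hits$read_id)
  out <- lapply(seq_along(reads$id), function(i) {
    idx <- split_hits[[reads$id[i]]]
    h <- if (is.null(idx)) empty_hits() else hits[idx, , drop = FALSE]
    classify_read(reads$id[i], h, max(lens[i], 1L), db, hcfg, lcfg)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write per-read assignments as TSV
#'
#' @param assignments Assignment data frame from [classify_reads()].
#' @param path Output path.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(assignments)
}
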