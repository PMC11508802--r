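# Per-sample taxon profiles: tallying assigned reads, the top-taxon 1%
# selection rule, genus collapsing, small-sample exclusion and per-taxon
# read-set extraction for external consensus polishing.

#' Construct a sample profile
#'
#' @param sample_id Sample label.
#' @param counts Named numeric vector: taxon label (lineage string) to
#'   unit count (reads or ASV units).
#' @param selected Character vector of selected taxon labels (subset of
#'   `names(counts)`).
#' @param supra_genus Labels that could not be collapsed to genus level
#'   (family or higher).
#' @param metadata Named list of sample tags (e.g. `sample_type`,
#'   `treatment`, `group`).
#' @return Object of class `sample_profile`.
#' @export
sample_profile <- function(sample_id, counts = numeric(0),
                           selected = character(0),
                           supra_genus = character(0),
                           metadata = list()) {
  stopifnot(all(selected %in% names(counts)),
            all(supra_genus %in% names(counts)))
  structure(list(sample_id = sample_id,
                 counts = counts,
                 selected = selected,
                 supra_genus = supra_genus,
                 total_units = sum(counts),
                 metadata = metadata),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf("Sample '%s': %d taxa, %g units\n",
              x$sample_id, length(x$counts), x$total_units))
  if (length(x$counts)) {
    ord <- order(-x$counts)
    for (i in ord) {
      nm <- names(x$counts)[i]
      mark <- if (nm %in% x$selected) "*" else " "
      flag <- if (nm %in% x$supra_genus) " [supra-genus]" else ""
      cat(sprintf(" %s %-50s %g%s\n", mark, nm, x$counts[i], flag))
    }
  }
  invisible(x)
}

#' Taxon selection / sample exclusion configuration
#'
#' @param rel_threshold Fraction of the top taxon's count at or above
#'   which a taxon is selected (default 0.01, i.e. the 1% rule,
#'   inclusive).
#' @param min_sample_units Minimum total assigned units for a sample to
#'   be retained; the comparison is strict "fewer than", so a sample with
#'   exactly this total is kept. 50 suits per-read nanopore counts; 3000
#'   suits denoised short-read (ASV) units.
#' @param presence_min_count Minimum count for a taxon to count as
#'   detected in a replicate (default 1).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(rel_threshold = 0.01, min_sample_units = 50L,
                             presence_min_count = 1L) {
  stopifnot(rel_threshold > 0, rel_threshold <= 1, min_sample_units >= 0,
            presence_min_count >= 0)
  structure(list(rel_threshold = rel_threshold,
                 min_sample_units = as.integer(min_sample_units),
                 presence_min_count = as.integer(presence_min_count)),
            class = "selection_config")
}

#' Tally assignments into a sample profile
#'
#' Counts assigned reads per taxon label; `Unassigned` and `Unresolved`
#' reads are excluded from both the counts and the total.
#'
#' @param assignments Assignment data frame (see [classify_reads()]).
#' @param sample_id Sample label for the profile.
#' @param metadata Optional metadata list.
#' @return A [sample_profile()].
#' @export
tally <- function(assignments, sample_id, metadata = list()) {
  ok <- assignments$status == "Assigned"
  counts <- numeric(0)
  if (any(ok)) {
    tab <- table(assignments$lineage[ok])
    counts <- stats::setNames(as.numeric(tab), names(tab))
  }
  sample_profile(sample_id, counts, metadata = metadata)
}

#' Select taxa by the top-taxon relative-abundance rule
#'
#' The taxon with the highest count is selected, together with every
#' taxon whose count is greater than or equal to `rel_threshold` times
#' that maximum (1% by default, inclusive). Ties for the top count all
#' anchor the same threshold. Non-selected taxa remain in the counts but
#' are flagged out via the `selected` set.
#'
#' @param profile A [sample_profile()].
#' @param cfg A [selection_config()].
#' @return The profile with its `selected` set populated.
#' @export
select_taxa <- function(profile, cfg = selection_config()) {
  if (length(profile$counts) == 0L) {
    profile$selected <- character(0)
    return(profile)
  }
  m <- max(profile$counts)
  profile$selected <- names(profile$counts)[profile$counts >= cfg$rel_threshold * m]
  profile
}

#' Drop samples with too few assigned units
#'
#' Removes profiles whose total assigned units fall strictly below
#' `min_sample_units` ("fewer than"); a sample at exactly the threshold
#' is kept.
#'
#' @param profiles List of [sample_profile()]s.
#' @param cfg A [selection_config()].
#' @return List with elements `kept` and `dropped` (a partition of the
#'   input, order preserved).
#' @export
drop_small_samples <- function(profiles, cfg = selection_config()) {
  totals <- vapply(profiles, function(p) p$total_units, 0)
  keep <- totals >= cfg$min_sample_units
  list(kept = profiles[keep], dropped = profiles[!keep])
}

#' Collapse a profile to genus level
#'
#' Species-level labels are truncated to their genus and counts merged;
#' genus-level labels pass through; labels resolved above genus (family
#' or higher) cannot be brought down to genus without external
#' information and are retained unchanged, flagged supra-genus. The
#' selected set is remapped through the same collapsing; total units are
#' conserved.
#'
#' @param profile A [sample_profile()] whose labels are lineage strings.
#' @return The collapsed profile.
#' @export
collapse_to_genus <- function(profile) {
  if (length(profile$counts) == 0L) return(profile)
  labels <- names(profile$counts)
  gi <- match("genus", tax_ranks())
  mapped <- vapply(labels, function(lb) {
    lin <- parse_lineage(lb)
    if (lineage_depth(lin) > gi) {
      format_lineage(truncate_lineage(lin, "genus"))
    } else {
      lb
    }
  }, "", USE.NAMES = FALSE)
  supra <- unique(mapped[vapply(mapped, function(lb) {
    lineage_depth(parse_lineage(lb)) < gi
  }, TRUE, USE.NAMES = FALSE)])
  counts <- tapply(profile$counts, mapped, sum)
  counts <- stats::setNames(as.numeric(counts), names(counts))
  selected <- unique(mapped[labels %in% profile$selected])
  sample_profile(profile$sample_id, counts, selected = selected,
                 supra_genus = supra, metadata = profile$metadata)
}

#' Per-taxon read id sets for selected taxa
#'
#' For each selected taxon of a profile, the exact read ids assigned to
#' it — the read bundles handed to an external consensus polisher.
#'
#' @param profile A [sample_profile()] after [select_taxa()].
#' @param assignments The assignment data frame the profile was tallied
#'   from.
#' @return Named list mapping each selected taxon label to a character
#'   vector of read ids.
#' @export
consensus_read_sets <- function(profile, assignments) {
  ok <- assignments$status == "Assigned"
  out <- lapply(profile$selected, function(tx) {
    assignments$read_id[ok & assignments$lineage == tx]
  })
  stats::setNames(out, profile$selected)
}

#' Write selected per-taxon read bundles as FASTQ files
#'
#' @param profile A [sample_profile()] after [select_taxa()].
#' @param assignments Assignment data frame.
#' @param reads The [read_set()] the assignments came from.
#' @param dir Output directory (created if needed); one FASTQ per
#'   selected taxon.
#' @return Invisibly, the named vector of paths written.
#' @export
write_consensus_read_sets <- function(profile, assignments, reads, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sets <- consensus_read_sets(profile, assignments)
  paths <- character(0)
  for (tx in names(sets)) {
    safe <- gsub("[^A-Za-z0-9_]+", "_", tx)
    path <- file.path(dir, paste0(profile$sample_id, "_", safe, ".fastq"))
    write_fastq(reads[reads$id %in% sets[[tx]]], path)
    paths[tx] <- path
  }
  invisible(paths)
}

#' Write profiles as a long-format TSV
#'
#' Columns: sample, taxon, count, selected, supra_genus.
#'
#' @param profiles List of [sample_profile()]s.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    if (length(p$counts) == 0L) return(NULL)
    data.frame(sample = p$sample_id, taxon = names(p$counts),
               count = unname(p$counts),
               selected = names(p$counts) %in% p$selected,
               supra_genus = names(p$counts) %in% p$supra_genus,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample = character(0), taxon = character(0),
                      count = numeric(0), selected = logical(0),
                      supra_genus = logical(0))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(out)
}
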