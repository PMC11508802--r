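# Contamination accounting: dietary vs contaminant read fractions,
# replicate detection matrices, group-wise target summaries and the
# taxon x sample abundance matrix.

profile_group <- function(p) {
  md <- p$metadata
  if (!is.null(md$group)) return(as.character(md$group))
  paste(c(md$sample_type, md$treatment), collapse = " / ")
}

# count of profile units matching a target taxon (rank-aware)
target_count <- function(profile, target) {
  if (length(profile$counts) == 0L) return(0)
  hit <- vapply(names(profile$counts), taxon_matches, TRUE, target = target,
                USE.NAMES = FALSE)
  sum(profile$counts[hit])
}

#' Contaminant fraction of a sample
#'
#' Units not attributable to any dietary taxon are counted as
#' contaminant. Diet matching is rank-aware: a profile label matches a
#' diet taxon when one lineage is a rank-wise prefix of the other, so a
#' diet entry at genus level (e.g. `"g__Vicia"`) captures species-level
#' detections of the same genus. The over-threshold flag uses a strict
#' inequality (a sample at exactly the threshold is not flagged).
#'
#' @param profile A tallied [sample_profile()].
#' @param diet_taxa Character vector of dietary taxon labels (lineage
#'   strings, or bare taxon names matched against any rank).
#' @param threshold Percent contaminant above which the sample is
#'   flagged (default 5, strict `>`).
#' @return List of class `contamination_report`: `sample_id`,
#'   `diet_taxa`, `pct_contaminant`, `flag_over_threshold`, `threshold`.
#' @export
contamination_fraction <- function(profile, diet_taxa, threshold = 5) {
  if (profile$total_units == 0) {
    stop_typed("empty_input_error",
               "sample '%s' has no assigned units", profile$sample_id)
  }
  labels <- names(profile$counts)
  is_diet <- vapply(labels, function(lb) {
    any(vapply(diet_taxa, function(d) taxon_matches(lb, d), TRUE))
  }, TRUE, USE.NAMES = FALSE)
  pct <- 100 * sum(profile$counts[!is_diet]) / profile$total_units
  structure(list(sample_id = profile$sample_id,
                 diet_taxa = diet_taxa,
                 pct_contaminant = pct,
                 flag_over_threshold = pct > threshold,
                 threshold = threshold),
            class = "contamination_report")
}

#' @export
print.contamination_report <- function(x, ...) {
  cat(sprintf("Sample '%s': %.1f%% contaminant reads (diet: %s)%s\n",
              x$sample_id, x$pct_contaminant,
              paste(x$diet_taxa, collapse = ", "),
              if (x$flag_over_threshold) {
                sprintf("  [> %g%% threshold]", x$threshold)
              } else ""))
  invisible(x)
}

#' Replicate detection matrix for a target taxon
#'
#' For each replicate group (taken from the profiles' `group` metadata,
#' or `sample_type` / `treatment`), counts the replicates in which the
#' target taxon is present with at least `presence_min_count` units.
#' Target matching is rank-aware (see [contamination_fraction()]).
#'
#' @param profiles List of [sample_profile()]s.
#' @param target_taxon Target label (lineage string or bare name).
#' @param presence_min_count Detection floor in units (default 1).
#' @return Data frame with columns `group`, `n_detected`,
#'   `n_replicates`, group order following first appearance.
#' @export
detection_matrix <- function(profiles, target_taxon,
                             presence_min_count = 1L) {
  stopifnot(length(profiles) > 0L)
  groups <- vapply(profiles, profile_group, "")
  detected <- vapply(profiles, function(p) {
    target_count(p, target_taxon) >= presence_min_count
  }, TRUE)
  ord <- unique(groups)
  data.frame(group = ord,
             n_detected = vapply(ord, function(g) sum(detected[groups == g]),
                                 0L),
             n_replicates = vapply(ord, function(g) sum(groups == g), 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group-wise target-taxon read summary
#'
#' Per replicate group: the arithmetic mean of the target taxon's
#' absolute counts and the min-max range of its percentage of each
#' replicate's total units.
#'
#' @inheritParams detection_matrix
#' @return Data frame with columns `group`, `mean_count`, `min_pct`,
#'   `max_pct`.
#' @export
group_target_summary <- function(profiles, target_taxon) {
  stopifnot(length(profiles) > 0L)
  groups <- vapply(profiles, profile_group, "")
  counts <- vapply(profiles, target_count, 0, target = target_taxon)
  totals <- vapply(profiles, function(p) p$total_units, 0)
  pct <- ifelse(totals > 0, 100 * counts / totals, NA_real_)
  ord <- unique(groups)
  data.frame(group = ord,
             mean_count = vapply(ord, function(g) mean(counts[groups == g]), 0),
             min_pct = vapply(ord, function(g) min(pct[groups == g]), 0),
             max_pct = vapply(ord, function(g) max(pct[groups == g]), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Taxon-by-sample abundance matrix
#'
#' Rectangular count table over all taxa and samples; taxa absent from a
#' sample are 0. Rows (taxa) and columns (samples) are sorted
#' lexicographically.
#'
#' @param profiles List of [sample_profile()]s.
#' @return Numeric matrix, taxa in rows, samples in columns.
#' @export
abundance_matrix <- function(profiles) {
  if (length(profiles) == 0L) {
    return(matrix(numeric(0), nrow = 0, ncol = 0))
  }
  samples <- sort(vapply(profiles, function(p) p$sample_id, ""))
  taxa <- sort(unique(unlist(lapply(profiles, function(p) names(p$counts)))))
  m <- matrix(0, nrow = length(taxa), ncol = length(samples),
              dimnames = list(taxa, samples))
  for (p in profiles) {
    if (length(p$counts)) m[names(p$counts), p$sample_id] <- unname(p$counts)
  }
  m
}

#' Stacked relative-abundance barplot
#'
#' One stacked bar per sample, showing each taxon's share of that
#' sample's assigned units.
#'
#' @param profiles List of [sample_profile()]s.
#' @param main Plot title.
#' @param legend Draw a taxon legend?
#' @return Invisibly, the relative-abundance matrix plotted.
#' @export
plot_relative_abundance <- function(profiles, main = "Relative abundance",
                                    legend = TRUE) {
  m <- abundance_matrix(profiles)
  if (ncol(m) == 0L) {
    stop_typed("empty_input_error", "no profiles to plot")
  }
  rel <- sweep(m, 2, pmax(colSums(m), 1), "/")
  cols <- grDevices::hcl.colors(max(nrow(rel), 2L), "Spectral")[seq_len(nrow(rel))]
  op <- graphics::par(mar = c(8, 4, 3, if (legend) 12 else 2), xpd = TRUE)
  on.exit(graphics::par(op))
  graphics::barplot(rel, col = cols, border = NA, las = 2,
                    ylab = "Fraction of assigned units", main = main)
  if (legend && nrow(rel)) {
    short <- vapply(rownames(rel), function(lb) {
      lin <- parse_lineage(lb)
      d <- lineage_depth(lin)
      if (d > 0) lin[[d]] else lb
    }, "")
    graphics::legend("topright", inset = c(-0.45, 0), legend = short,
                     fill = cols, cex = 0.7, bty = "n")
  }
  invisible(rel)
}
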