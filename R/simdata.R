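# Synthetic experiment generator: reference amplicons, long-read error
# model, and replicate designs mixing diet-plant signal with a pollen
# spike, with ground truth so the full pipeline can be validated
# end-to-end.

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-replicate seed derived from a base seed (kept within
# 32-bit integer range)
derive_seed <- function(base_seed, group, replicate) {
  (as.numeric(base_seed) * 7919 + group * 104729 + replicate * 131) %%
    2147483647 + 1
}

.iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

# draw a concrete ACGT instance of an IUPAC string
resolve_iupac <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    s <- .iupac_sets[[ch]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, ""), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Pairwise identity of two amplicons
#'
#' Local-alignment matches relative to the shorter sequence:
#' `100 * matches / min(len)`. Unlike alignment-column identity, this is
#' low for unrelated sequences (a short perfect local match does not
#' dominate) and 100 for identical ones, making it a usable divergence
#' screen for simulated reference sets.
#'
#' @param a,b Nucleotide strings.
#' @param scheme A [scoring_scheme()].
#' @return Identity percent in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, scheme = scoring_scheme()) {
  hit <- local_align(a, b, scheme)
  if (is.null(hit)) return(0)
  matches <- round(hit$pct_identity * hit$aln_len / 100)
  100 * matches / min(nchar(a), nchar(b))
}

#' Simulation configuration
#'
#' Parameters of one simulated sample: the taxon composition, read
#' depth, and an error model in the style of older long-read nanopore
#' chemistry. Unless overridden, the per-base error rate is
#' `10^(-target_mean_q / 10)` split substitution:insertion:deletion =
#' 2:1:1, so the default Q13 gives ~5% total error, matching the quality
#' regime of R9-era amplicon runs.
#'
#' @param composition Named numeric vector mapping reference taxon
#'   (genus name or reference id) to its fraction; must sum to 1.
#' @param n_reads Number of reads to simulate.
#' @param target_mean_q Target mean per-base Phred score.
#' @param q_sd Per-base Phred standard deviation.
#' @param sub_rate,ins_rate,del_rate Per-base error fractions;
#'   `NULL` derives them from `target_mean_q`.
#' @param len_jitter_sd Standard deviation (bases) of random
#'   symmetric end-truncation noise (0 = none).
#' @param seed RNG seed for this sample.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(composition, n_reads, target_mean_q = 13,
                       q_sd = 3, sub_rate = NULL, ins_rate = NULL,
                       del_rate = NULL, len_jitter_sd = 0, seed = 1L) {
  stopifnot(n_reads >= 0, target_mean_q >= 0, q_sd >= 0,
            len_jitter_sd >= 0)
  if (abs(sum(composition) - 1) > 1e-9) {
    stop_typed("config_error", "composition fractions must sum to 1")
  }
  e <- 10^(-target_mean_q / 10)
  if (is.null(sub_rate)) sub_rate <- e / 2
  if (is.null(ins_rate)) ins_rate <- e / 4
  if (is.null(del_rate)) del_rate <- e / 4
  stopifnot(sub_rate >= 0, ins_rate >= 0, del_rate >= 0)
  structure(list(composition = composition, n_reads = as.integer(n_reads),
                 target_mean_q = target_mean_q, q_sd = q_sd,
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, len_jitter_sd = len_jitter_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a divergent synthetic reference set
#'
#' Random amplicons rejection-sampled so that every pair has
#' [pairwise_identity()] below 80%, each with a distinct 7-rank lineage
#' (shared kingdom-order, distinct family/genus/species). Deterministic
#' for a given seed.
#'
#' @param n_taxa Number of reference taxa (`>= 1`).
#' @param amplicon_len Amplicon length in bases.
#' @param seed RNG seed.
#' @param max_identity Rejection threshold (percent identity).
#' @param max_tries Attempts per taxon before giving up.
#' @return A [reference_db()] with taxa named `Genus01`, `Genus02`, ...
#' @export
make_reference_set <- function(n_taxa, amplicon_len = 550L, seed = 1L,
                               max_identity = 80, max_tries = 50L) {
  stopifnot(n_taxa >= 1L, amplicon_len >= 50L)
  with_seed(seed, {
    seqs <- character(0)
    for (i in seq_len(n_taxa)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- random_dna(amplicon_len)
        div <- all(vapply(seqs, function(s) {
          pairwise_identity(cand, s) < max_identity
        }, TRUE))
        if (div) {
          seqs <- c(seqs, cand)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop_typed("simulation_error",
                   "could not generate %d mutually divergent amplicons",
                   n_taxa)
      }
    }
    genus <- sprintf("Genus%02d", seq_len(n_taxa))
    lineage <- sprintf(paste0("k__Plantae;p__Streptophyta;c__Magnoliopsida;",
                              "o__Simulales;f__Family%02d;g__%s;s__%s sim%02d"),
                       seq_len(n_taxa), genus, genus, seq_len(n_taxa))
    reference_db(data.frame(id = sprintf("SIMREF%04d", seq_len(n_taxa)),
                            sequence = seqs, lineage = lineage,
                            stringsAsFactors = FALSE),
                 provenance = list(generator = "make_reference_set",
                                   seed = seed))
  })
}

# genus name of each db record
db_genus <- function(db) {
  vapply(db$records$lineage,
         function(l) parse_lineage(l)[["genus"]], "", USE.NAMES = FALSE)
}

# apply substitutions / insertions / deletions per base
mutate_seq <- function(seq, sub_rate, ins_rate, del_rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  u <- stats::runif(n)
  keep <- u >= del_rate
  subbed <- u >= del_rate & u < del_rate + sub_rate
  bases <- c("A", "C", "G", "T")
  if (any(subbed)) {
    chars[subbed] <- vapply(chars[subbed], function(ch) {
      sample(setdiff(bases, ch), 1L)
    }, "")
  }
  out <- chars[keep]
  ins_at <- stats::runif(length(out)) < ins_rate
  if (any(ins_at)) {
    pieces <- out
    pieces[ins_at] <- paste0(pieces[ins_at],
                             sample(bases, sum(ins_at), replace = TRUE))
    out <- strsplit(paste(pieces, collapse = ""), "", fixed = TRUE)[[1]]
  }
  paste(out, collapse = "")
}

#' Simulate one sample of primer-flanked amplicon reads
#'
#' Each read's source taxon is drawn from the configured composition;
#' the source amplicon gets substitutions, insertions and deletions at
#' the configured per-base rates, is flanked with the rbcLa primers
#' (degenerate bases resolved randomly) so that the trimming stage is
#' exercised, and per-base qualities are drawn around `target_mean_q`.
#' Roughly half the reads are emitted reverse-complemented. A truth
#' table records every read's source.
#'
#' @param db A [reference_db()]; composition names must be genera (or
#'   ids) present in it.
#' @param cfg A [sim_config()].
#' @param sample_id Sample label.
#' @param primers List with `fwd`/`rev` primer strings (default
#'   [rbcla_primers()]).
#' @return List with `reads` (a [read_set()]) and `truth` (data frame
#'   `read_id`, `taxon`, `ref_id`).
#' @export
simulate_sample <- function(db, cfg, sample_id = "sim",
                            primers = rbcla_primers()) {
  taxa <- names(cfg$composition)
  genus <- db_genus(db)
  ref_idx <- lapply(taxa, function(tx) {
    which(genus == tx | db$records$id == tx)
  })
  if (any(lengths(ref_idx) == 0L)) {
    stop_typed("config_error", "composition taxa not in reference db: %s",
               paste(taxa[lengths(ref_idx) == 0L], collapse = ", "))
  }
  with_seed(cfg$seed, {
    n <- cfg$n_reads
    src <- if (n > 0) {
      sample(seq_along(taxa), n, replace = TRUE, prob = cfg$composition)
    } else integer(0)
    ids <- sprintf("%s_read%05d", sample_id, seq_len(n))
    bases <- character(n)
    quals <- vector("list", n)
    refs <- character(n)
    for (i in seq_len(n)) {
      ri <- ref_idx[[src[i]]]
      ri <- if (length(ri) > 1L) sample(ri, 1L) else ri
      refs[i] <- db$records$id[ri]
      amp <- db$records$sequence[ri]
      if (cfg$len_jitter_sd > 0) {
        cut <- abs(round(stats::rnorm(2, 0, cfg$len_jitter_sd)))
        if (sum(cut) < nchar(amp)) {
          amp <- substr(amp, 1 + cut[1], nchar(amp) - cut[2])
        }
      }
      read <- paste0(resolve_iupac(primers$fwd),
                     mutate_seq(amp, cfg$sub_rate, cfg$ins_rate,
                                cfg$del_rate),
                     revcomp(resolve_iupac(primers$rev)))
      if (stats::runif(1) < 0.5) read <- revcomp(read)
      bases[i] <- read
      q <- round(stats::rnorm(nchar(read), cfg$target_mean_q, cfg$q_sd))
      quals[[i]] <- pmin(pmax(q, 1L), 60L)
    }
    list(reads = read_set(ids, bases, quals, sample_id = sample_id),
         truth = data.frame(read_id = ids, taxon = taxa[src],
                            ref_id = refs, stringsAsFactors = FALSE))
  })
}

#' Validate an experiment design table
#'
#' A design is a data frame with one row per replicate group: `label`,
#' `n_replicates`, `diet` (comma-separated diet taxa), `spike_taxon`
#' (`NA` for no spike), `spike_fraction` and `treatment`.
#'
#' @param design Data frame as above.
#' @return The validated design (invisibly usable as-is).
#' @export
experiment_design <- function(design) {
  need <- c("label", "n_replicates", "diet", "spike_taxon",
            "spike_fraction", "treatment")
  stopifnot(is.data.frame(design), all(need %in% names(design)),
            all(design$n_replicates >= 1),
            all(design$spike_fraction >= 0 & design$spike_fraction <= 1))
  design
}

#' A caged-insect pollen-dusting design
#'
#' Nine replicate groups of three, mirroring a controlled
#' surface-contamination experiment: whole insects, dissected guts and
#' exoskeletons, with and without a pollen dusting, with and without
#' disinfectant treatment, plus a pollen-only control. Dusted groups
#' carry the spike taxon at `spike_fraction`; undusted groups carry only
#' the diet taxon.
#'
#' @param diet_taxon Diet plant genus (present in the reference set).
#' @param spike_taxon Pollen genus used for dusting.
#' @param spike_fraction Fraction of reads from the spike in dusted
#'   groups (default 0.95: dusting pollen dominates the amplifiable
#'   template).
#' @param n_replicates Replicates per group.
#' @return A design data frame for [simulate_experiment()].
#' @export
dusting_design <- function(diet_taxon, spike_taxon, spike_fraction = 0.95,
                           n_replicates = 3L) {
  groups <- data.frame(
    label = c("whole_dusted", "whole_dusted_disinfected", "gut_dusted",
              "exoskeleton_dusted", "whole_clean", "whole_clean_disinfected",
              "gut_clean", "exoskeleton_clean", "pollen_only"),
    dusted = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    treatment = c("none", "disinfectant", "none", "none", "none",
                  "disinfectant", "none", "none", "none"),
    stringsAsFactors = FALSE)
  experiment_design(data.frame(
    label = groups$label,
    n_replicates = n_replicates,
    diet = ifelse(groups$label == "pollen_only", "", diet_taxon),
    spike_taxon = ifelse(groups$dusted, spike_taxon, NA_character_),
    spike_fraction = ifelse(groups$label == "pollen_only", 1,
                            ifelse(groups$dusted, spike_fraction, 0)),
    treatment = groups$treatment,
    stringsAsFactors = FALSE))
}

#' Simulate a full replicate-group experiment
#'
#' For each group of the design, each replicate's composition is the
#' diet mixture scaled by `1 - spike_fraction` plus the spike taxon at
#' `spike_fraction`; replicate seeds are derived deterministically from
#' the base seed, group index and replicate index, so any replicate can
#' be regenerated independently.
#'
#' @param db A [reference_db()].
#' @param design An [experiment_design()] data frame.
#' @param base_cfg A [sim_config()] whose composition is ignored (it is
#'   set per group); its `seed` is the experiment base seed.
#' @return List of replicates, each with `label`, `replicate`,
#'   `treatment`, `reads`, `truth`.
#' @export
simulate_experiment <- function(db, design, base_cfg) {
  design <- experiment_design(design)
  out <- list()
  for (g in seq_len(nrow(design))) {
    row <- design[g, ]
    diet <- strsplit(row$diet, ",", fixed = TRUE)[[1]]
    diet <- trimws(diet[nzchar(trimws(diet))])
    comp <- numeric(0)
    if (length(diet) && row$spike_fraction < 1) {
      comp <- stats::setNames(rep((1 - row$spike_fraction) / length(diet),
                                  length(diet)), diet)
    }
    if (!is.na(row$spike_taxon) && row$spike_fraction > 0) {
      comp[row$spike_taxon] <- row$spike_fraction
    }
    if (length(comp) == 0L) {
      stop_typed("config_error",
                 "group '%s' has neither diet nor spike taxa", row$label)
    }
    comp <- comp / sum(comp)
    for (r in seq_len(row$n_replicates)) {
      cfg <- base_cfg
      cfg$composition <- comp
      cfg$seed <- derive_seed(base_cfg$seed, g, r)
      sid <- sprintf("%s_rep%d", row$label, r)
      sim <- simulate_sample(db, cfg, sample_id = sid)
      out[[sid]] <- list(label = row$label, replicate = r,
                         treatment = row$treatment,
                         reads = sim$reads, truth = sim$truth)
    }
  }
  out
}
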