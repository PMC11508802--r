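# Reference database curation: primer-delimited amplicon extraction,
# sequence quality filters, dereplication.

.iupac_chars <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N")

check_iupac <- function(seq, what = "sequence") {
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, .iupac_chars)
  if (length(bad) > 0L) {
    stop_typed("invalid_sequence_error",
               "%s contains non-IUPAC characters: %s", what,
               paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Reference curation configuration
#'
#' Thresholds for building an amplicon reference database. Defaults follow
#' common practice for rbcLa references: up to 5 degenerate (non-ACGT)
#' bases, homopolymer runs of at most 8, and amplicon lengths in
#' \[500, 700\] bases around the ~550-600 b rbcLa fragment.
#'
#' @param fwd_primer,rev_primer IUPAC primer sequences (5'-3', uppercase).
#' @param max_primer_mismatch Mismatches tolerated per primer match.
#' @param max_degenerate_bases Maximum non-ACGT bases in a reference.
#' @param max_homopolymer_run Maximum single-base run length.
#' @param min_len,max_len Inclusive amplicon length bounds (bases).
#' @return A list of class `ref_curation_config`.
#' @export
ref_curation_config <- function(fwd_primer, rev_primer,
                                max_primer_mismatch = 2L,
                                max_degenerate_bases = 5L,
                                max_homopolymer_run = 8L,
                                min_len = 500L, max_len = 700L) {
  stopifnot(nzchar(fwd_primer), nzchar(rev_primer),
            max_primer_mismatch >= 0, max_degenerate_bases >= 0,
            max_homopolymer_run >= 0, min_len <= max_len)
  check_iupac(fwd_primer, "forward primer")
  check_iupac(rev_primer, "reverse primer")
  structure(list(fwd_primer = toupper(fwd_primer),
                 rev_primer = toupper(rev_primer),
                 max_primer_mismatch = as.integer(max_primer_mismatch),
                 max_degenerate_bases = as.integer(max_degenerate_bases),
                 max_homopolymer_run = as.integer(max_homopolymer_run),
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len)),
            class = "ref_curation_config")
}

# id<TAB>lineage table; an empty file is an empty table
read_tax_table <- function(path) {
  if (length(readLines(path, n = 1L)) == 0L) {
    return(data.frame(id = character(0), lineage = character(0)))
  }
  utils::read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character",
                    col.names = c("id", "lineage"))
}

#' Locate primer matches in a sequence
#'
#' All ungapped matches of an IUPAC primer with at most `max_mismatch`
#' mismatches; degenerate codes match whenever the two IUPAC base sets
#' intersect.
#'
#' @param seq Subject nucleotide string.
#' @param primer IUPAC primer string.
#' @param max_mismatch Mismatch tolerance.
#' @return An [IRanges::IRanges] of match locations (possibly empty).
#' @export
find_primer_matches <- function(seq, primer, max_mismatch) {
  if (nchar(seq) < nchar(primer)) return(IRanges::IRanges())
  m <- Biostrings::matchPattern(primer, Biostrings::DNAString(seq),
                                max.mismatch = max_mismatch,
                                with.indels = FALSE, fixed = FALSE)
  methods::as(m, "IRanges")
}

#' Extract the amplicon between two primers
#'
#' Returns the subsequence strictly between the forward primer and the
#' reverse complement of the reverse primer, in forward orientation. Both
#' strands are searched; primer matching is IUPAC-aware (a primer base
#' matches when the two IUPAC sets intersect) with up to
#' `cfg$max_primer_mismatch` mismatches per primer. Among multiple matches
#' the leftmost forward and rightmost reverse match are used, giving the
#' maximal amplicon deterministically.
#'
#' @param seq Uppercase IUPAC nucleotide string.
#' @param cfg A [ref_curation_config()].
#' @return The amplicon string, or `NA_character_` when either primer is
#'   not found within tolerance on either strand.
#' @export
trim_to_amplicon <- function(seq, cfg) {
  check_iupac(seq)
  rev_rc <- revcomp(cfg$rev_primer)
  for (s in c(seq, revcomp(seq))) {
    fwd <- find_primer_matches(s, cfg$fwd_primer, cfg$max_primer_mismatch)
    rev <- find_primer_matches(s, rev_rc, cfg$max_primer_mismatch)
    if (length(fwd) == 0L || length(rev) == 0L) next
    from <- min(IRanges::end(fwd)) + 1L
    to <- max(IRanges::start(rev)) - 1L
    if (from > to) next
    return(substr(s, from, to))
  }
  NA_character_
}

#' Reference sequence quality filter
#'
#' A reference passes when it has no more than `max_degenerate_bases`
#' non-ACGT bases, no single-base run longer than `max_homopolymer_run`,
#' and a length within `[min_len, max_len]`.
#'
#' @inheritParams trim_to_amplicon
#' @return Logical scalar.
#' @export
reference_passes_filters <- function(seq, cfg) {
  check_iupac(seq)
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_degen <- sum(!chars %in% c("A", "C", "G", "T"))
  runs <- rle(chars)
  max_run <- if (length(runs$lengths)) max(runs$lengths) else 0L
  n_degen <= cfg$max_degenerate_bases &&
    max_run <= cfg$max_homopolymer_run &&
    n >= cfg$min_len && n <= cfg$max_len
}

#' Dereplicate reference records
#'
#' Removes records sharing both an identical sequence and an identical
#' lineage string, keeping the first-seen record (and its id) and
#' preserving input order. Records with the same sequence but different
#' taxonomy are both retained.
#'
#' @param records Data frame with columns `id`, `sequence`, `lineage`.
#' @return The dereplicated data frame.
#' @export
dereplicate <- function(records) {
  stopifnot(all(c("id", "sequence", "lineage") %in% names(records)))
  keep <- !duplicated(paste(records$sequence, records$lineage, sep = "\r"))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a reference database object
#'
#' @param records Data frame with columns `id`, `sequence`, `lineage`.
#' @param config The [ref_curation_config()] used, or `NULL`.
#' @param provenance Named list of curation notes (e.g. drop counts).
#' @return Object of class `reference_db`.
#' @export
reference_db <- function(records, config = NULL, provenance = list()) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence", "lineage") %in% names(records)))
  rownames(records) <- NULL
  structure(list(records = records, config = config,
                 provenance = provenance),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("Reference database: %d records\n", nrow(x$records)))
  if (length(x$provenance)) {
    cat("Curation drops:\n")
    for (nm in names(x$provenance)) {
      cat(sprintf("  %s: %s\n", nm, x$provenance[[nm]]))
    }
  }
  invisible(x)
}

#' @export
length.reference_db <- function(x) nrow(x$records)

#' Build a curated reference database from FASTA + taxonomy
#'
#' Runs the full curation pipeline: parse the FASTA and the id-to-lineage
#' TSV, extract the primer-delimited amplicon from each reference, apply
#' the sequence quality filters, and dereplicate. Per-step drop counts are
#' recorded in the returned object's provenance (`n_input`, `no_amplicon`,
#' `failed_filter`, `duplicate`, `n_output`).
#'
#' @param ref_fasta Path to the reference FASTA.
#' @param tax_table Path to a two-column TSV (`id<TAB>lineage-string`,
#'   no header).
#' @param cfg A [ref_curation_config()].
#' @return A [reference_db()].
#' @export
build_db <- function(ref_fasta, tax_table, cfg) {
  seqs <- Biostrings::readDNAStringSet(ref_fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  tax <- read_tax_table(tax_table)
  lineage <- tax$lineage[match(ids, tax$id)]
  if (anyNA(lineage) && length(ids)) {
    missing <- ids[is.na(lineage)]
    stop_typed("missing_taxonomy_error",
               "no taxonomy row for reference id(s): %s",
               paste(missing, collapse = ", "))
  }
  n_input <- length(seqs)
  records <- data.frame(id = ids,
                        sequence = toupper(as.character(seqs)),
                        lineage = if (n_input) lineage else character(0),
                        stringsAsFactors = FALSE)

  amplicons <- vapply(records$sequence, trim_to_amplicon, "", cfg = cfg,
                      USE.NAMES = FALSE)
  no_amplicon <- sum(is.na(amplicons))
  records <- records[!is.na(amplicons), , drop = FALSE]
  records$sequence <- amplicons[!is.na(amplicons)]

  pass <- vapply(records$sequence, reference_passes_filters, TRUE,
                 cfg = cfg, USE.NAMES = FALSE)
  failed_filter <- sum(!pass)
  records <- records[pass, , drop = FALSE]

  derep <- dereplicate(records)
  duplicate <- nrow(records) - nrow(derep)

  reference_db(derep, config = cfg,
               provenance = list(n_input = n_input,
                                 no_amplicon = no_amplicon,
                                 failed_filter = failed_filter,
                                 duplicate = duplicate,
                                 n_output = nrow(derep)))
}

#' Write a reference database to FASTA + taxonomy TSV
#'
#' @param db A [reference_db()].
#' @param fasta_path,tax_path Output paths.
#' @export
write_reference_db <- function(db, fasta_path, tax_path) {
  seqs <- Biostrings::DNAStringSet(db$records$sequence)
  names(seqs) <- db$records$id
  Biostrings::writeXStringSet(seqs, fasta_path)
  utils::write.table(db$records[, c("id", "lineage")], tax_path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(db)
}

#' Read a previously written reference database
#'
#' @param fasta_path,tax_path Paths written by [write_reference_db()].
#' @return A [reference_db()].
#' @export
read_reference_db <- function(fasta_path, tax_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  tax <- read_tax_table(tax_path)
  lineage <- tax$lineage[match(ids, tax$id)]
  if (anyNA(lineage) && length(ids)) {
    stop_typed("missing_taxonomy_error",
               "no taxonomy row for reference id(s): %s",
               paste(ids[is.na(lineage)], collapse = ", "))
  }
  reference_db(data.frame(id = ids,
                          sequence = toupper(as.character(seqs)),
                          lineage = if (length(ids)) lineage else character(0),
                          stringsAsFactors = FALSE))
}

#' rbcLa amplification primers
#'
#' The forward/reverse primer pair targeting the rbcLa plant-barcoding
#' fragment (target-specific parts, without sequencing tags). The reverse
#' primer carries a degenerate base (R), so IUPAC-aware matching is
#' required.
#'
#' @return List with elements `fwd` and `rev`.
#' @export
rbcla_primers <- function() {
  list(fwd = "TGTCACCACAAACAGAGACTAAAGC",
       rev = "GTAAAATCAAGTCCACCRCG")
}
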