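# Long-read amplicon QC: primer trimming, length/quality filtering and the
# QC summary statistics (discard fraction, median length, mean Phred,
# implied error rate).

#' Construct a read set
#'
#' Container for quality-scored amplicon reads. Qualities are integer
#' Phred scores, one per base.
#'
#' @param id Character vector of read ids.
#' @param bases Character vector of uppercase nucleotide strings.
#' @param quals List of integer vectors, `quals[[i]]` parallel to
#'   `bases[i]`.
#' @param sample_id Sample label(s), recycled to the number of reads.
#' @return Object of class `read_set`.
#' @export
read_set <- function(id, bases, quals, sample_id = "sample") {
  stopifnot(length(id) == length(bases), length(quals) == length(bases))
  ok <- vapply(seq_along(bases),
               function(i) length(quals[[i]]) == nchar(bases[i]), TRUE)
  if (!all(ok)) {
    stop_typed("read_error", "quality length differs from base length for read(s): %s",
               paste(id[!ok], collapse = ", "))
  }
  qr <- unlist(quals, use.names = FALSE)
  if (length(qr) && (min(qr) < 0L || max(qr) > 93L)) {
    stop_typed("read_error", "Phred scores must lie in [0, 93]")
  }
  structure(list(id = as.character(id), bases = toupper(bases),
                 quals = lapply(quals, as.integer),
                 sample_id = rep_len(as.character(sample_id), length(id))),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$id)

#' @export
`[.read_set` <- function(x, i) {
  read_set(x$id[i], x$bases[i], x$quals[i], x$sample_id[i])
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads", length(x)))
  if (length(x)) {
    cat(sprintf(" (lengths %d-%d)", min(nchar(x$bases)), max(nchar(x$bases))))
  }
  cat("\n")
  invisible(x)
}

read_lengths <- function(reads) nchar(reads$bases)

#' Read a FASTQ file into a read set
#'
#' Qualities are decoded as Phred+33. Gzip-compressed files are handled
#' transparently.
#'
#' @param path FASTQ path.
#' @param sample_id Sample label applied to all reads (defaults to the
#'   file name without extension).
#' @return A [read_set()].
#' @export
read_fastq <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  }
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      # harmless notice when the writer attached mcols to the records
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  quals <- unname(as.list(methods::as(Biostrings::quality(x), "IntegerList")))
  read_set(id = sub("\\s.*$", "", names(x)),
           bases = unname(as.character(x)),
           quals = quals,
           sample_id = sample_id)
}

#' Write a read set to FASTQ (Phred+33)
#'
#' @param reads A [read_set()].
#' @param path Output path (`.gz` suffix compresses).
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$bases)
  names(seqs) <- reads$id
  enc <- vapply(reads$quals,
                function(q) if (length(q)) rawToChar(as.raw(q + 33L)) else "",
                "")
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(enc),
                              compress = grepl("\\.gz$", path))
  invisible(reads)
}

#' Read filtering configuration
#'
#' Length window and per-read quality floor for long-read amplicon QC.
#' Defaults keep reads of 450-650 bases (the expected rbcLa amplicon
#' window) with a mean Phred of at least 7. Both boundaries are inclusive:
#' reads are discarded only when *longer than* `max_len` or *shorter
#' than* `min_len`, and only when mean quality is *below* `min_mean_q`.
#'
#' @param min_len,max_len Inclusive length bounds in bases.
#' @param min_mean_q Minimum per-read quality (Phred).
#' @param q_aggregate How to aggregate per-base qualities into a per-read
#'   value: `"mean_phred"` (arithmetic mean of Phred scores, default) or
#'   `"mean_error"` (mean of error probabilities, re-expressed as a Phred
#'   score).
#' @return A list of class `read_filter_config`.
#' @export
read_filter_config <- function(min_len = 450L, max_len = 650L,
                               min_mean_q = 7,
                               q_aggregate = c("mean_phred", "mean_error")) {
  stopifnot(min_len <= max_len, min_mean_q >= 0)
  structure(list(min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 min_mean_q = min_mean_q,
                 q_aggregate = match.arg(q_aggregate)),
            class = "read_filter_config")
}

#' Mean Phred score of a quality vector
#'
#' @param quals Integer vector of per-base Phred scores.
#' @return Arithmetic mean (numeric scalar).
#' @export
mean_phred <- function(quals) {
  if (length(quals) == 0L) {
    stop_typed("empty_input_error", "cannot average an empty quality vector")
  }
  mean(quals)
}

# per-read quality under the configured aggregation
read_quality <- function(quals, q_aggregate = "mean_phred") {
  if (q_aggregate == "mean_phred") {
    mean_phred(quals)
  } else {
    -10 * log10(mean(10^(-quals / 10)))
  }
}

#' Convert a Phred score to an error percentage
#'
#' `100 * 10^(-q/10)`: Q13.4 corresponds to a 4.6% per-base error rate.
#'
#' @param q Phred score(s), `q >= 0`.
#' @return Error rate in percent.
#' @export
phred_to_error_pct <- function(q) {
  stopifnot(all(q >= 0))
  100 * 10^(-q / 10)
}

#' Trim amplification primers from a read
#'
#' Removes the forward primer (and anything 5' of it) and the
#' reverse-complemented reverse primer (and anything 3' of it) wherever
#' each is found within `max_mismatch` IUPAC-aware mismatches; qualities
#' are sliced in lockstep. Both strands are examined and the orientation
#' in which more primers are found wins (ties go to the input
#' orientation); a reverse-complemented amplicon is returned re-oriented
#' forward. Reads in which neither primer is found are returned unchanged.
#'
#' @param read A single-read list with elements `id`, `bases`, `quals`,
#'   `sample_id` (e.g. one element of a [read_set()]).
#' @param fwd_primer,rev_primer IUPAC primer strings.
#' @param max_mismatch Mismatches tolerated per primer.
#' @return The trimmed read (same shape as the input).
#' @export
trim_read <- function(read, fwd_primer, rev_primer, max_mismatch = 2L) {
  rev_rc <- revcomp(rev_primer)
  orient <- function(bases, quals) {
    fwd <- find_primer_matches(bases, fwd_primer, max_mismatch)
    rev <- find_primer_matches(bases, rev_rc, max_mismatch)
    from <- if (length(fwd)) min(IRanges::end(fwd)) + 1L else 1L
    to <- if (length(rev)) max(IRanges::start(rev)) - 1L else nchar(bases)
    n_found <- (length(fwd) > 0L) + (length(rev) > 0L)
    if (from > to) return(list(n = n_found, bases = "", quals = integer(0)))
    list(n = n_found, bases = substr(bases, from, to),
         quals = quals[from:to])
  }
  f <- orient(read$bases, read$quals)
  r <- orient(revcomp(read$bases), rev(read$quals))
  best <- if (r$n > f$n) r else f
  if (best$n == 0L) return(read)
  read$bases <- best$bases
  read$quals <- best$quals
  read
}

#' Trim primers from every read in a set
#'
#' Vectorised [trim_read()] over a [read_set()].
#'
#' @param reads A [read_set()].
#' @inheritParams trim_read
#' @return A trimmed [read_set()].
#' @export
trim_reads <- function(reads, fwd_primer, rev_primer, max_mismatch = 2L) {
  for (i in seq_along(reads$id)) {
    tr <- trim_read(list(id = reads$id[i], bases = reads$bases[i],
                         quals = reads$quals[[i]],
                         sample_id = reads$sample_id[i]),
                    fwd_primer, rev_primer, max_mismatch)
    reads$bases[i] <- tr$bases
    reads$quals[[i]] <- tr$quals
  }
  reads
}

#' Length/quality filter with QC summary
#'
#' Keeps reads whose length lies within `[min_len, max_len]` and whose
#' per-read quality is at least `min_mean_q`. The report summarises the
#' filtering: counts and percent discarded are computed over the input,
#' median length (lower median for even counts) and mean quality over the
#' kept reads, and the mean quality's implied per-base error rate via
#' [phred_to_error_pct()].
#'
#' @param reads A [read_set()] (already primer-trimmed).
#' @param cfg A [read_filter_config()].
#' @return List with elements `kept` (a [read_set()]) and `report`
#'   (class `qc_report`).
#' @export
filter_reads <- function(reads, cfg = read_filter_config()) {
  n_input <- length(reads)
  lens <- read_lengths(reads)
  qs <- vapply(reads$quals, function(q) {
    if (length(q) == 0L) return(-Inf)
    read_quality(q, cfg$q_aggregate)
  }, 0)
  keep <- lens >= cfg$min_len & lens <= cfg$max_len & qs >= cfg$min_mean_q
  kept <- reads[keep]
  n_output <- length(kept)
  report <- structure(list(
    n_input = n_input,
    n_output = n_output,
    pct_discarded = discard_pct(n_input, n_output),
    median_len = if (n_output) lower_median(read_lengths(kept)) else NA_real_,
    mean_q = if (n_output) mean(qs[keep]) else NA_real_,
    error_rate_pct = if (n_output) phred_to_error_pct(mean(qs[keep])) else NA_real_
  ), class = "qc_report")
  list(kept = kept, report = report)
}

#' Percent of reads discarded between two counts
#'
#' @param n_input,n_output Read counts before and after filtering.
#' @return `100 * (n_input - n_output) / n_input` (0 when `n_input` is 0).
#' @export
discard_pct <- function(n_input, n_output) {
  stopifnot(n_output <= n_input)
  if (n_input == 0) return(0)
  100 * (n_input - n_output) / n_input
}

# lower median: for even n the n/2-th order statistic (deterministic on
# integer lengths)
lower_median <- function(x) {
  s <- sort(x)
  s[ceiling(length(s) / 2)]
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Read QC report\n")
  cat(sprintf("  input reads:    %d\n", x$n_input))
  cat(sprintf("  kept reads:     %d\n", x$n_output))
  cat(sprintf("  discarded:      %.1f%%\n", x$pct_discarded))
  if (!is.na(x$median_len)) {
    cat(sprintf("  median length:  %d\n", x$median_len))
    cat(sprintf("  mean quality:   Q%.1f (%.1f%% error)\n",
                x$mean_q, x$error_rate_pct))
  }
  invisible(x)
}

#' Serialise a QC report as JSON
#'
#' @param report A `qc_report` from [filter_reads()].
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @export
qc_report_json <- function(report, path = NULL) {
  x <- unclass(report)
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
}
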