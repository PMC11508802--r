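# TaqMan qPCR cycle-threshold summaries: replicate averaging with the
# censored-at-40 convention, detection calls, and the UV time-course
# trend.

#' Construct a CT record
#'
#' One qPCR assay on one sample, with replicate cycle-threshold values.
#' The instrument runs `max_cycles` cycles (40 by default), so a CT equal
#' to `max_cycles` is a censored "no detection" value; such values are
#' kept as point values in averages, reproducing how plate summaries are
#' reported.
#'
#' @param assay Assay name (e.g. `"COX"`, `"NAD"`).
#' @param sample_label Sample label.
#' @param replicate_cts Numeric vector of CT values, each in
#'   `(0, max_cycles]`.
#' @param max_cycles Cycle ceiling (default 40).
#' @return A list of class `ct_record`.
#' @export
ct_record <- function(assay, sample_label, replicate_cts, max_cycles = 40L) {
  if (length(replicate_cts) == 0L) {
    stop_typed("empty_input_error", "ct_record needs at least one replicate")
  }
  if (any(replicate_cts <= 0 | replicate_cts > max_cycles)) {
    stop_typed("ct_range_error",
               "CT values must lie in (0, %d]", max_cycles)
  }
  structure(list(assay = assay, sample_label = sample_label,
                 replicate_cts = as.numeric(replicate_cts),
                 max_cycles = as.integer(max_cycles)),
            class = "ct_record")
}

# round half away from zero (printed-table convention; base round() ties
# to even). The epsilon guards against binary representation of values
# such as 29.995 sitting just below the tie point.
round_half_up <- function(x, digits = 2L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-8) / f
}

#' Average CT over replicates
#'
#' Arithmetic mean of the replicate CTs, censored 40s included as point
#' values, rounded half-up to 2 decimals for reporting. The unrounded
#' mean is retained in the `"raw"` attribute.
#'
#' @param rec A [ct_record()].
#' @return Reported average CT (numeric scalar, attribute `raw`).
#' @export
average_ct <- function(rec) {
  raw <- mean(rec$replicate_cts)
  out <- round_half_up(raw, 2L)
  attr(out, "raw") <- raw
  out
}

#' Display form of a CT value
#'
#' Two decimals with trailing zeros trimmed, as CT tables print them
#' (`30.00` prints as `"30"`, `36.81` as `"36.81"`).
#'
#' @param ct Numeric CT value.
#' @return Character scalar.
#' @export
format_ct <- function(ct) {
  s <- sprintf("%.2f", as.numeric(ct))
  sub("\\.?0+$", "", s)
}

#' Detection call for a CT record
#'
#' Detected if and only if the (unrounded) replicate-average CT is
#' strictly below the cycle ceiling; an all-40 record (e.g. an
#' extraction blank) is never detected.
#'
#' @param rec A [ct_record()].
#' @return Logical scalar.
#' @export
detection_call <- function(rec) {
  mean(rec$replicate_cts) < rec$max_cycles
}

#' UV exposure time-course trend
#'
#' Correlation between UV exposure time and average CT. Rising CT with
#' time means less intact target DNA, so a positive trend indicates
#' progressive degradation. Rank (Spearman) correlation is the primary
#' statistic; the Pearson correlation and a strict-monotone-increase
#' flag are also returned.
#'
#' @param times Exposure times (minutes), strictly increasing, length
#'   at least 3.
#' @param avg_cts Average CT per time point, same length.
#' @return List: `rank_correlation`, `pearson_correlation`,
#'   `monotone_increasing`.
#' @export
uv_trend <- function(times, avg_cts) {
  if (length(times) != length(avg_cts)) {
    stop_typed("length_mismatch_error",
               "times (%d) and avg_cts (%d) differ in length",
               length(times), length(avg_cts))
  }
  stopifnot(length(times) >= 3L, all(diff(times) > 0))
  list(rank_correlation = stats::cor(times, avg_cts, method = "spearman"),
       pearson_correlation = stats::cor(times, avg_cts, method = "pearson"),
       monotone_increasing = all(diff(avg_cts) > 0))
}

#' Read a CT replicate CSV
#'
#' Expected columns: `assay`, `sample`, then one column per replicate CT
#' (`rep1`, `rep2`, ...). Empty replicate cells are allowed (unequal
#' replicate counts across rows).
#'
#' @param path CSV path.
#' @param max_cycles Cycle ceiling applied to every record.
#' @return List of [ct_record()]s.
#' @export
read_ct_csv <- function(path, max_cycles = 40L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("assay", "sample") %in% names(df))) {
    stop_typed("parse_error",
               "CT csv must have 'assay' and 'sample' columns")
  }
  repcols <- setdiff(names(df), c("assay", "sample"))
  lapply(seq_len(nrow(df)), function(i) {
    cts <- suppressWarnings(as.numeric(df[i, repcols]))
    cts <- cts[!is.na(cts)]
    ct_record(df$assay[i], df$sample[i], cts, max_cycles)
  })
}

#' Summarise CT records as a table
#'
#' @param records List of [ct_record()]s.
#' @return Data frame: `assay`, `sample`, `n_reps`, `average_ct`
#'   (reported value), `average_ct_display`, `detected`.
#' @export
summarise_ct <- function(records) {
  data.frame(
    assay = vapply(records, function(r) r$assay, ""),
    sample = vapply(records, function(r) r$sample_label, ""),
    n_reps = vapply(records, function(r) length(r$replicate_cts), 0L),
    average_ct = vapply(records, function(r) as.numeric(average_ct(r)), 0),
    average_ct_display = vapply(records, function(r) format_ct(average_ct(r)), ""),
    detected = vapply(records, detection_call, TRUE),
    stringsAsFactors = FALSE)
}
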