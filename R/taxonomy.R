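# Ranked lineage strings: semicolon-delimited "k__...;p__...;...;s__..."
# truncated lineages simply omit the trailing ranks.

#' Taxonomic rank ladder
#'
#' The fixed, strictly descending rank order used throughout the package.
#' Lineages are compared rank-by-rank from the top; a lineage truncated at
#' rank *r* contains exactly the ranks at or above *r*.
#'
#' @return Character vector of the seven ranks, kingdom first.
#' @export
tax_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

.rank_prefixes <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                    family = "f", genus = "g", species = "s")

#' Parse a lineage string
#'
#' Parses the semicolon-delimited dialect `"k__Plantae;p__...;...;s__..."`
#' into a named character vector over the seven ranks. Ranks absent from the
#' string (either omitted entirely in a truncated lineage, or present with an
#' empty value such as `"s__"`) are `NA`.
#'
#' @param x A single lineage string.
#' @return Named character vector of length 7 (names `tax_ranks()`), `NA`
#'   for unknown ranks.
#' @examples
#' parse_lineage("k__Plantae;f__Fabaceae;g__Vicia")
#' @export
parse_lineage <- function(x) {
  out <- stats::setNames(rep(NA_character_, 7L), tax_ranks())
  if (is.null(x) || length(x) != 1L || is.na(x) || !nzchar(x)) return(out)
  fields <- strsplit(x, ";", fixed = TRUE)[[1]]
  fields <- trimws(fields)
  fields <- fields[nzchar(fields)]
  for (f in fields) {
    if (!grepl("^[kpcofgs]__", f)) {
      stop_typed("lineage_parse_error",
                 sprintf("malformed lineage field '%s' in '%s'", f, x))
    }
    prefix <- substr(f, 1L, 1L)
    rank <- names(.rank_prefixes)[match(prefix, .rank_prefixes)]
    value <- substr(f, 4L, nchar(f))
    if (nzchar(value)) out[[rank]] <- value
  }
  out
}

#' Format a lineage vector as a string
#'
#' Inverse of [parse_lineage()]. With `trim = TRUE` (default) trailing
#' unknown ranks are dropped, which is the canonical form for a lineage
#' truncated at its assigned rank; interior unknown ranks are kept as empty
#' fields (e.g. `"g__"`) so that rank positions stay unambiguous.
#'
#' @param lin Named character vector as returned by [parse_lineage()].
#' @param trim Drop trailing `NA` ranks?
#' @return A lineage string.
#' @export
format_lineage <- function(lin, trim = TRUE) {
  stopifnot(length(lin) == 7L)
  keep <- 7L
  if (trim) {
    known <- which(!is.na(lin))
    if (length(known) == 0L) return("")
    keep <- max(known)
  }
  vals <- lin[seq_len(keep)]
  vals[is.na(vals)] <- ""
  paste0(.rank_prefixes[seq_len(keep)], "__", vals, collapse = ";")
}

#' Truncate a lineage at a rank
#'
#' @param lin Named character vector (see [parse_lineage()]).
#' @param rank One of `tax_ranks()`; ranks below it are set to `NA`.
#' @return Truncated lineage vector.
#' @export
truncate_lineage <- function(lin, rank) {
  ri <- match(rank, tax_ranks())
  if (is.na(ri)) stop_typed("rank_error", sprintf("unknown rank '%s'", rank))
  if (ri < 7L) lin[(ri + 1L):7L] <- NA_character_
  lin
}

# deepest rank index carrying a name; 0L when fully unknown
lineage_depth <- function(lin) {
  known <- which(!is.na(lin))
  if (length(known) == 0L) 0L else max(known)
}

# rank-aware prefix test: every rank known in both must agree, and all of
# a's known ranks must be at or above b's (a is the shallower or equal path)
lineage_is_prefix <- function(a, b) {
  da <- lineage_depth(a)
  if (da == 0L) return(FALSE)
  for (i in seq_len(da)) {
    if (is.na(a[[i]])) next
    if (is.na(b[[i]]) || a[[i]] != b[[i]]) return(FALSE)
  }
  TRUE
}

# does a profile label match a target taxon, rank-aware both ways:
# "g__Vicia" matches "g__Vicia;s__Vicia faba" and vice versa; a bare name
# (no "__") on either side matches when it equals the other's name at any
# rank (or the whole label when both are bare)
taxon_matches <- function(label, target) {
  bare_label <- !grepl("__", label, fixed = TRUE)
  bare_target <- !grepl("__", target, fixed = TRUE)
  if (bare_label && bare_target) return(label == target)
  if (bare_target) {
    lin <- parse_lineage(label)
    return(target %in% lin[!is.na(lin)])
  }
  if (bare_label) {
    lin <- parse_lineage(target)
    return(label %in% lin[!is.na(lin)])
  }
  a <- parse_lineage(target)
  b <- parse_lineage(label)
  lineage_is_prefix(a, b) || lineage_is_prefix(b, a)
}

# typed condition helper: all package errors carry a subclass so callers
# (and tests) can distinguish input problems from bugs
stop_typed <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("pollensift_", class), "pollensift_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
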