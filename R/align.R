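# Read-vs-reference local alignment: a seeded affine-gap local aligner
# (Smith-Waterman via Biostrings' dynamic programming) producing
# BLAST-outfmt6-style hits, plus import/export of external hit tables so
# classification can also run on hits produced by an external search tool.

hit_columns <- c("read_id", "ref_id", "pct_identity", "aln_len",
                 "mismatches", "gap_opens", "read_start", "read_end",
                 "ref_start", "ref_end", "evalue", "bitscore")

empty_hits <- function() {
  data.frame(read_id = character(0), ref_id = character(0),
             pct_identity = numeric(0), aln_len = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             read_start = integer(0), read_end = integer(0),
             ref_start = integer(0), ref_end = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

#' Alignment scoring scheme
#'
#' Match/mismatch scores and affine gap penalties for the local aligner,
#' plus the Karlin-Altschul parameters used to express raw scores as bit
#' scores (`bitscore = (lambda * raw - ln K) / ln 2`). The defaults mirror
#' common megablast-style scoring (+2/-3, gap open -5, gap extend -2,
#' lambda 0.625, K 0.41) so that the downstream 5% top-bitscore window
#' behaves comparably to hits from an external search. A gap of length L
#' costs `|gap_open| + L * |gap_extend|`.
#'
#' @param match,mismatch Per-column scores (`match > 0 > mismatch`).
#' @param gap_open,gap_extend Gap penalties (negative).
#' @param lambda,K Karlin-Altschul scale parameters (positive).
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = -5,
                           gap_extend = -2, lambda = 0.625, K = 0.41) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0,
            lambda > 0, K > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

scheme_matrix <- function(scheme) {
  Biostrings::nucleotideSubstitutionMatrix(match = scheme$match,
                                           mismatch = scheme$mismatch,
                                           baseOnly = FALSE)
}

bit_score <- function(raw, scheme) {
  (scheme$lambda * raw - log(scheme$K)) / log(2)
}

# stats of one pairwiseAlignment result (local): identity over alignment
# columns, gap openings as runs of "-" in either aligned string
aln_stats <- function(pa) {
  p <- as.character(Biostrings::pattern(pa))
  s <- as.character(Biostrings::subject(pa))
  pc <- strsplit(p, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  gaps_p <- pc == "-"
  gaps_s <- sc == "-"
  matches <- sum(!gaps_p & !gaps_s & pc == sc)
  mism <- sum(!gaps_p & !gaps_s & pc != sc)
  gap_opens <- sum(rle(gaps_p)$values) + sum(rle(gaps_s)$values)
  list(aln_len = length(pc), matches = matches, mismatches = mism,
       gap_opens = gap_opens,
       read_start = IRanges::start(Biostrings::pattern(pa)),
       read_end = IRanges::end(Biostrings::pattern(pa)),
       ref_start = IRanges::start(Biostrings::subject(pa)),
       ref_end = IRanges::end(Biostrings::subject(pa)))
}

#' Best local alignment between a read and a reference
#'
#' Affine-gap Smith-Waterman on both strands of the read, keeping the
#' higher-scoring strand. Identity is `100 * matches / aln_len` with
#' `aln_len` counted in alignment columns. For a reverse-strand hit the
#' read coordinates are reported on the input read (ascending) and the
#' reference coordinates are swapped (`ref_start > ref_end`), following
#' the tabular-hit convention. Returns `NULL` when no alignment scores
#' above zero.
#'
#' @param read_seq,ref_seq Nucleotide strings (non-empty).
#' @param scheme A [scoring_scheme()].
#' @param read_id,ref_id Ids recorded in the hit row.
#' @return One-row hit data frame, or `NULL`.
#' @export
local_align <- function(read_seq, ref_seq, scheme = scoring_scheme(),
                        read_id = "read", ref_id = "ref") {
  stopifnot(nzchar(read_seq), nzchar(ref_seq))
  mat <- scheme_matrix(scheme)
  run <- function(q) {
    Biostrings::pairwiseAlignment(Biostrings::DNAString(q),
                                  Biostrings::DNAString(ref_seq),
                                  type = "local",
                                  substitutionMatrix = mat,
                                  gapOpening = -scheme$gap_open,
                                  gapExtension = -scheme$gap_extend)
  }
  fwd <- run(read_seq)
  rev <- run(revcomp(read_seq))
  use_rev <- Biostrings::score(rev) > Biostrings::score(fwd)
  pa <- if (use_rev) rev else fwd
  raw <- Biostrings::score(pa)
  if (raw <= 0) return(NULL)
  st <- aln_stats(pa)
  L <- nchar(read_seq)
  if (use_rev) {
    rs <- L - st$read_end + 1L
    re <- L - st$read_start + 1L
    st$read_start <- rs
    st$read_end <- re
    tmp <- st$ref_start
    st$ref_start <- st$ref_end
    st$ref_end <- tmp
  }
  data.frame(read_id = read_id, ref_id = ref_id,
             pct_identity = 100 * st$matches / st$aln_len,
             aln_len = st$aln_len, mismatches = st$mismatches,
             gap_opens = st$gap_opens,
             read_start = st$read_start, read_end = st$read_end,
             ref_start = st$ref_start, ref_end = st$ref_end,
             evalue = NA_real_, bitscore = bit_score(raw, scheme),
             stringsAsFactors = FALSE)
}

# unique k-mers of a sequence (exact, ACGT and ambiguity letters as-is)
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Build a k-mer seed index over a reference database
#'
#' @param db A [reference_db()].
#' @param k Seed length (`k >= 4`).
#' @return An environment mapping each k-mer to the integer indices of the
#'   reference records containing it, with attribute `k`.
#' @export
seed_index <- function(db, k = 11L) {
  stopifnot(k >= 4L)
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(db$records))) {
    for (km in seq_kmers(db$records$sequence[i], k)) {
      idx[[km]] <- c(idx[[km]], i)
    }
  }
  attr(idx, "k") <- as.integer(k)
  idx
}

# indices of references sharing >= 1 exact seed with the read (either strand)
seed_candidates <- function(read_seq, idx) {
  k <- attr(idx, "k")
  kms <- unique(c(seq_kmers(read_seq, k), seq_kmers(revcomp(read_seq), k)))
  hit <- kms[vapply(kms, exists, TRUE, envir = idx, inherits = FALSE)]
  if (length(hit) == 0L) return(integer(0))
  sort(unique(unlist(mget(hit, envir = idx), use.names = FALSE)))
}

#' Search a read against a reference database
#'
#' k-mer seeded candidate selection (references sharing at least one exact
#' seed with the read on either strand) followed by [local_align()] on
#' every candidate. Hits are sorted by bitscore descending, ties broken by
#' `ref_id` ascending.
#'
#' @param read A single-read list (elements `id`, `bases`).
#' @param db A [reference_db()].
#' @param seed_k Seed length; with `seed_k` equal to the read length only
#'   exact-substring candidates remain.
#' @param scheme A [scoring_scheme()].
#' @param index Optional pre-built [seed_index()]; must match `seed_k`.
#' @return Hit data frame (possibly empty).
#' @export
search_read <- function(read, db, seed_k = 11L, scheme = scoring_scheme(),
                        index = NULL) {
  stopifnot(nrow(db$records) > 0L)
  if (is.null(index)) index <- seed_index(db, seed_k)
  cand <- seed_candidates(read$bases, index)
  hits <- lapply(cand, function(i) {
    local_align(read$bases, db$records$sequence[i], scheme,
                read_id = read$id, ref_id = db$records$id[i])
  })
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (length(hits) == 0L) return(empty_hits())
  out <- do.call(rbind, hits)
  out <- out[order(-out$bitscore, out$ref_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# stats for one batched alignment, from its gapped strings and ranges
pair_stats <- function(gp, gs, rs, re, ss, se) {
  pc <- strsplit(gp, "", fixed = TRUE)[[1]]
  sc <- strsplit(gs, "", fixed = TRUE)[[1]]
  gaps_p <- pc == "-"
  gaps_s <- sc == "-"
  list(aln_len = length(pc),
       matches = sum(!gaps_p & !gaps_s & pc == sc),
       mismatches = sum(!gaps_p & !gaps_s & pc != sc),
       gap_opens = sum(rle(gaps_p)$values) + sum(rle(gaps_s)$values),
       read_start = rs, read_end = re, ref_start = ss, ref_end = se)
}

#' Align every read in a set against a database
#'
#' Seeded search over a whole [read_set()]: the seed index is built once
#' and alignments are batched per candidate reference (both strands).
#' Equivalent to running [search_read()] read by read; reads shorter than
#' `seed_k` or sharing no seed produce no hits. Hits are ordered by read
#' (input order), then bitscore descending, ties by `ref_id`.
#'
#' @param reads A [read_set()].
#' @inheritParams search_read
#' @return Hit data frame over all reads.
#' @export
align_reads <- function(reads, db, seed_k = 11L, scheme = scoring_scheme()) {
  idx <- seed_index(db, seed_k)
  n <- length(reads)
  cand <- lapply(seq_len(n), function(i) {
    if (nzchar(reads$bases[i])) seed_candidates(reads$bases[i], idx)
    else integer(0)
  })
  pair_read <- rep(seq_len(n), lengths(cand))
  pair_ref <- unlist(cand, use.names = FALSE)
  if (length(pair_read) == 0L) return(empty_hits())
  mat <- scheme_matrix(scheme)
  rows <- list()
  for (j in unique(pair_ref)) {
    ri <- pair_read[pair_ref == j]
    pats <- Biostrings::DNAStringSet(reads$bases[ri])
    subj <- Biostrings::DNAString(db$records$sequence[j])
    pf <- Biostrings::pairwiseAlignment(pats, subj, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = -scheme$gap_open,
                                        gapExtension = -scheme$gap_extend)
    pr <- Biostrings::pairwiseAlignment(Biostrings::reverseComplement(pats),
                                        subj, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = -scheme$gap_open,
                                        gapExtension = -scheme$gap_extend)
    sf <- Biostrings::score(pf)
    sr <- Biostrings::score(pr)
    use_rev <- sr > sf
    raw <- pmax(sf, sr)
    ext <- function(pa) list(
      gp = as.character(Biostrings::pattern(pa)),
      gs = as.character(Biostrings::subject(pa)),
      rs = IRanges::start(Biostrings::pattern(pa)),
      re = IRanges::end(Biostrings::pattern(pa)),
      ss = IRanges::start(Biostrings::subject(pa)),
      se = IRanges::end(Biostrings::subject(pa)))
    ef <- ext(pf)
    er <- ext(pr)
    for (p in which(raw > 0)) {
      i <- ri[p]
      L <- nchar(reads$bases[i])
      if (use_rev[p]) {
        st <- pair_stats(er$gp[p], er$gs[p],
                         L - er$re[p] + 1L, L - er$rs[p] + 1L,
                         er$se[p], er$ss[p])
      } else {
        st <- pair_stats(ef$gp[p], ef$gs[p], ef$rs[p], ef$re[p],
                         ef$ss[p], ef$se[p])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = reads$id[i], ref_id = db$records$id[j],
        pct_identity = 100 * st$matches / st$aln_len,
        aln_len = st$aln_len, mismatches = st$mismatches,
        gap_opens = st$gap_opens,
        read_start = st$read_start, read_end = st$read_end,
        ref_start = st$ref_start, ref_end = st$ref_end,
        evalue = NA_real_, bitscore = bit_score(raw[p], scheme),
        read_order = i, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  res <- do.call(rbind, rows)
  res <- res[order(res$read_order, -res$bitscore, res$ref_id), , drop = FALSE]
  res$read_order <- NULL
  rownames(res) <- NULL
  res
}

#' Read a 12-column tabular hit file
#'
#' Parses the classic tab-separated hit dialect (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore) as
#' produced by external search tools, preserving row order.
#'
#' @param path TSV path.
#' @return Hit data frame.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    stop_typed("parse_error",
               "line %d has %d columns, expected 12", bad, nf[bad])
  }
  m <- do.call(rbind, fields)
  num <- m[, 3:12, drop = FALSE]
  storage <- suppressWarnings(matrix(as.numeric(num), nrow = nrow(num)))
  # evalue (column 9 here) may legitimately be NA for internal-aligner hits
  bad_cell <- is.na(storage) & !(col(storage) == 9L & num == "NA")
  if (any(bad_cell)) {
    bad <- which(apply(bad_cell, 1, any))[1]
    stop_typed("parse_error", "non-numeric field on line %d", bad)
  }
  data.frame(read_id = m[, 1], ref_id = m[, 2],
             pct_identity = storage[, 1], aln_len = as.integer(storage[, 2]),
             mismatches = as.integer(storage[, 3]),
             gap_opens = as.integer(storage[, 4]),
             read_start = as.integer(storage[, 5]),
             read_end = as.integer(storage[, 6]),
             ref_start = as.integer(storage[, 7]),
             ref_end = as.integer(storage[, 8]),
             evalue = storage[, 9], bitscore = storage[, 10],
             stringsAsFactors = FALSE)
}

#' Write hits as a 12-column tabular file
#'
#' @param hits Hit data frame.
#' @param path Output TSV path.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(all(hit_columns %in% names(hits)))
  out <- hits[, hit_columns]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "NA")
  invisible(hits)
}
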