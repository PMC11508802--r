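# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately use a different computational route than the
# implementation they check.

# --- full Smith-Waterman (Gotoh affine), score only --------------------
# A gap of length L costs gap_open + L * gap_extend (positive penalties).
sw_score_oracle <- function(a, b, match = 2, mismatch = -3,
                            gap_open = 5, gap_extend = 2) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A)
  m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) + s)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# recover the raw alignment score from a reported bitscore
raw_from_bitscore <- function(bitscore, scheme = scoring_scheme()) {
  (bitscore * log(2) + log(scheme$K)) / scheme$lambda
}

# --- toy taxonomy ------------------------------------------------------
toy_lineages <- function() {
  c(vicia_faba = paste0("k__Plantae;p__Streptophyta;c__Magnoliopsida;",
                        "o__Fabales;f__Fabaceae;g__Vicia;s__Vicia faba"),
    vicia_sativa = paste0("k__Plantae;p__Streptophyta;c__Magnoliopsida;",
                          "o__Fabales;f__Fabaceae;g__Vicia;s__Vicia sativa"),
    urtica = paste0("k__Plantae;p__Streptophyta;c__Magnoliopsida;",
                    "o__Rosales;f__Urticaceae;g__Urtica"))
}

# brute-force majority rank-ascent enumerator, written as a flat matrix
# scan (independent of majority_lca's control flow)
lca_oracle <- function(lineage_strings, fraction = 0.75,
                       denominator = c("all", "annotated")) {
  denominator <- match.arg(denominator)
  n <- length(lineage_strings)
  mat <- t(vapply(lineage_strings, parse_lineage,
                  setNames(character(7), tax_ranks())))
  for (rank in rev(tax_ranks())) {
    vals <- mat[, rank]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) next
    counts <- table(vals)
    denom <- if (denominator == "all") n else length(vals)
    if (max(counts) >= fraction * denom) {
      return(list(status = "Assigned", rank = rank,
                  name = names(counts)[which.max(counts)]))
    }
  }
  list(status = "Unresolved", rank = NA_character_, name = NA_character_)
}

# all multisets of sizes 1..max_size from a pool of items (as index lists)
all_multisets <- function(n_items, max_size) {
  out <- list()
  for (k in seq_len(max_size)) {
    grid <- do.call(expand.grid, rep(list(seq_len(n_items)), k))
    keep <- apply(grid, 1, function(r) all(diff(as.numeric(r)) >= 0))
    rows <- grid[keep, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      out[[length(out) + 1]] <- as.integer(rows[i, ])
    }
  }
  out
}

# --- random fixtures ---------------------------------------------------
random_hitset <- function(n, read_len = 500) {
  if (n == 0) return(pollensift:::empty_hits())
  data.frame(read_id = "r1",
             ref_id = sprintf("REF%03d", sample(999, n)),
             pct_identity = round(runif(n, 60, 100), 2),
             aln_len = sample(seq(250, 600), n, replace = TRUE),
             mismatches = sample(0:40, n, replace = TRUE),
             gap_opens = sample(0:5, n, replace = TRUE),
             read_start = 1L, read_end = read_len,
             ref_start = 1L, ref_end = read_len,
             evalue = NA_real_,
             bitscore = round(runif(n, 100, 260), 2),
             stringsAsFactors = FALSE)
}

# straight-line re-statement of the two-step hit filter
filter_hits_oracle <- function(hits, read_len, min_id = 80, min_cov = 80,
                               window = 0.05) {
  keep1 <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    cov <- 100 * hits$aln_len[i] / read_len
    keep1[i] <- hits$pct_identity[i] >= min_id && cov >= min_cov
  }
  s1 <- hits[keep1, , drop = FALSE]
  if (nrow(s1) == 0) return(s1)
  cutoff <- (1 - window) * max(s1$bitscore)
  out <- s1[s1$bitscore >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_profile <- function(sample_id = "s", n_taxa = NULL) {
  pool <- c(toy_lineages(),
            poaceae = "k__Plantae;p__Streptophyta;c__Magnoliopsida;o__Poales;f__Poaceae",
            pinus = paste0("k__Plantae;p__Streptophyta;c__Pinopsida;",
                           "o__Pinales;f__Pinaceae;g__Pinus;s__Pinus sylvestris"),
            musa = paste0("k__Plantae;p__Streptophyta;c__Magnoliopsida;",
                          "o__Zingiberales;f__Musaceae;g__Musa"))
  if (is.null(n_taxa)) n_taxa <- sample(1:6, 1)
  labs <- sample(pool, n_taxa)
  sample_profile(sample_id,
                 setNames(as.numeric(sample(1:2000, n_taxa)), labs))
}

random_read_set <- function(n, len_range = c(300, 800), q_range = c(2, 30),
                            sample_id = "s") {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  bases <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
  quals <- lapply(lens, function(L) {
    rep(sample(seq(q_range[1], q_range[2]), 1), L)
  })
  read_set(sprintf("r%04d", seq_len(n)), bases, quals, sample_id)
}
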