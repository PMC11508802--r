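empty_hits_df <- function() pollensift:::empty_hits()

mk_hit <- function(ref, pident = 100, len = 500, bit = 200, read = "r1") {
  data.frame(read_id = read, ref_id = ref, pct_identity = pident,
             aln_len = as.integer(len), mismatches = 0L, gap_opens = 0L,
             read_start = 1L, read_end = as.integer(len),
             ref_start = 1L, ref_end = as.integer(len),
             evalue = NA_real_, bitscore = bit, stringsAsFactors = FALSE)
}

test_that("filter_hits applies identity, coverage, then the bitscore window", {
  cfg <- hit_filter_config()
  h <- rbind(mk_hit("a", pident = 85), mk_hit("b", pident = 79))
  expect_identical(filter_hits(h, 500, cfg)$ref_id, "a")
  # coverage: 80% of a 500-base read needs aln_len >= 400
  h2 <- rbind(mk_hit("a", len = 400), mk_hit("b", len = 399))
  expect_identical(filter_hits(h2, 500, cfg)$ref_id, "a")
  # 5% window below the top survivor (0.95 * 200 = 190)
  h3 <- rbind(mk_hit("a", bit = 200), mk_hit("b", bit = 191),
              mk_hit("c", bit = 189))
  expect_identical(filter_hits(h3, 500, cfg)$ref_id, c("a", "b"))
  # a single surviving hit is kept regardless of the window
  expect_identical(nrow(filter_hits(mk_hit("a"), 500, cfg)), 1L)
  # the window is computed after identity/coverage filtering: a strong
  # but low-identity hit must not anchor it
  h4 <- rbind(mk_hit("bad", pident = 70, bit = 400), mk_hit("ok", bit = 200))
  expect_identical(filter_hits(h4, 500, cfg)$ref_id, "ok")
  expect_identical(nrow(filter_hits(empty_hits_df(), 500, cfg)), 0L)
})

test_that("filter_hits agrees with a brute-force re-filter on random hit sets", {
  set.seed(61)
  cfg <- hit_filter_config()
  for (i in 1:200) {
    h <- random_hitset(sample(0:8, 1))
    expect_equal(filter_hits(h, 500, cfg), filter_hits_oracle(h, 500))
  }
})

test_that("each filter stage is monotone in its own threshold", {
  # Because the bitscore window is re-anchored on the identity/coverage
  # survivors, only per-stage monotonicity holds: raising the identity or
  # coverage floor never adds a stage-1 survivor, and narrowing the
  # window never adds a hit for a fixed survivor set.
  set.seed(67)
  for (i in 1:50) {
    h <- random_hitset(sample(1:8, 1))
    wide <- hit_filter_config(bitscore_window = 1)     # window pass-through
    base1 <- filter_hits(h, 500, wide)$ref_id
    for (cfg in list(hit_filter_config(min_pct_identity = 90,
                                       bitscore_window = 1),
                     hit_filter_config(min_coverage = 95,
                                       bitscore_window = 1))) {
      expect_true(all(filter_hits(h, 500, cfg)$ref_id %in% base1))
    }
    basew <- filter_hits(h, 500, hit_filter_config())$ref_id
    expect_true(all(filter_hits(h, 500,
                                hit_filter_config(bitscore_window = 0.01))$ref_id
                    %in% basew))
  }
})

test_that("majority vote assigns at the deepest rank reaching 75%", {
  lin <- toy_lineages()
  # 3 of 4 at genus Vicia: exactly 75% => assigned at genus
  res <- majority_lca(c(lin[["vicia_faba"]], lin[["vicia_faba"]],
                        lin[["vicia_sativa"]], lin[["urtica"]]))
  expect_identical(res$status, "Assigned")
  expect_identical(res$rank, "genus")
  expect_identical(parse_lineage(res$lineage)[["genus"]], "Vicia")
  # identical lineages assign at species, unchanged
  res2 <- majority_lca(rep(lin[["vicia_faba"]], 5))
  expect_identical(res2$rank, "species")
  expect_identical(res2$lineage, unname(lin[["vicia_faba"]]))
  expect_error(majority_lca(character(0)),
               class = "pollensift_empty_input_error")
})

test_that("majority_lca matches the brute-force enumerator on all small multisets", {
  lin <- unname(toy_lineages())
  for (idx in all_multisets(3, 5)) {
    got <- majority_lca(lin[idx])
    want <- lca_oracle(lin[idx])
    expect_identical(got$status, want$status)
    expect_identical(got$rank, want$rank)
    if (got$status == "Assigned") {
      expect_identical(parse_lineage(got$lineage)[[got$rank]], want$name)
    }
  }
})

test_that("unanimous voting reduces to the strict deepest-common-prefix LCA", {
  lin <- unname(toy_lineages()[c("vicia_faba", "vicia_sativa")])
  cfg <- lca_config(majority_fraction = 1.0)
  set.seed(71)
  for (i in 1:30) {
    pick <- sample(lin, sample(1:5, 1), replace = TRUE)
    res <- majority_lca(pick, cfg)
    # strict LCA: deepest rank at which all parsed lineages agree
    mats <- lapply(pick, parse_lineage)
    depth <- 0
    for (ri in 1:7) {
      vals <- vapply(mats, function(m) m[[ri]], "")
      if (!anyNA(vals) && length(unique(vals)) == 1) depth <- ri else break
    }
    expect_identical(res$status, "Assigned")
    expect_identical(res$rank, tax_ranks()[depth])
  }
})

test_that("larger majority fractions assign at equal or higher ranks", {
  lin <- unname(toy_lineages())
  set.seed(73)
  for (i in 1:40) {
    pick <- sample(lin, sample(2:6, 1), replace = TRUE)
    r60 <- majority_lca(pick, lca_config(majority_fraction = 0.6))
    r90 <- majority_lca(pick, lca_config(majority_fraction = 0.9))
    d60 <- if (r60$status == "Assigned") match(r60$rank, tax_ranks()) else 0L
    d90 <- if (r90$status == "Assigned") match(r90$rank, tax_ranks()) else 0L
    expect_lte(d90, d60)
  }
})

toy_db <- function() {
  lin <- toy_lineages()
  reference_db(data.frame(
    id = c("R1", "R2", "R3", "R4"),
    sequence = rep(strrep("ACGT", 25), 4),
    lineage = c(lin[["vicia_faba"]], lin[["vicia_sativa"]],
                lin[["urtica"]],
                "k__Chlorophyta;p__Chlorophyta_p;c__Algae_c;o__Algae_o;f__Algae_f;g__Chlorella;s__Chlorella vulgaris"),
    stringsAsFactors = FALSE))
}

test_that("classify_read reproduces hand-computed labels on a 10-read fixture", {
  db <- toy_db()
  lin <- toy_lineages()
  cases <- list(
    # no hits at all
    list(hits = empty_hits_df(), status = "Unassigned", rank = NA, n = 0L),
    # single clean hit: species of R1
    list(hits = mk_hit("R1", pident = 95, len = 500, bit = 180),
         status = "Assigned", rank = "species", n = 1L),
    # two Vicia species inside the window: genus
    list(hits = rbind(mk_hit("R1", bit = 200), mk_hit("R2", bit = 195)),
         status = "Assigned", rank = "genus", n = 2L),
    # R1+R2+R3 all in window: 2/3 Vicia < 75%, agreement first at class
    list(hits = rbind(mk_hit("R1", bit = 200), mk_hit("R2", bit = 195),
                      mk_hit("R3", bit = 193)),
         status = "Assigned", rank = "class", n = 3L),
    # identity below 80 drops the only hit
    list(hits = mk_hit("R1", pident = 79), status = "Unassigned",
         rank = NA, n = 0L),
    # coverage below 80% drops the only hit
    list(hits = mk_hit("R1", len = 399), status = "Unassigned",
         rank = NA, n = 0L),
    # window excludes the weaker Urtica hit: species of R1
    list(hits = rbind(mk_hit("R1", bit = 200), mk_hit("R3", bit = 189)),
         status = "Assigned", rank = "species", n = 1L),
    # three hits to one reference: species, all hits counted
    list(hits = rbind(mk_hit("R2", bit = 200), mk_hit("R2", bit = 199),
                      mk_hit("R2", bit = 198)),
         status = "Assigned", rank = "species", n = 3L),
    # plant vs green alga split 1/1: no rank reaches 75%
    list(hits = rbind(mk_hit("R1", bit = 200), mk_hit("R4", bit = 199)),
         status = "Unresolved", rank = NA, n = 2L),
    # alga only: species of R4
    list(hits = mk_hit("R4"), status = "Assigned", rank = "species", n = 1L))
  expected_lineage <- c(NA, unname(lin[["vicia_faba"]]),
                        "k__Plantae;p__Streptophyta;c__Magnoliopsida;o__Fabales;f__Fabaceae;g__Vicia",
                        "k__Plantae;p__Streptophyta;c__Magnoliopsida",
                        NA, NA, unname(lin[["vicia_faba"]]),
                        unname(lin[["vicia_sativa"]]), NA,
                        db$records$lineage[4])
  for (i in seq_along(cases)) {
    got <- classify_read(sprintf("read%02d", i), cases[[i]]$hits, 500, db)
    expect_identical(got$status, cases[[i]]$status)
    expect_identical(got$n_hits_used, cases[[i]]$n)
    if (!is.na(cases[[i]]$rank)) {
      expect_identical(got$rank, cases[[i]]$rank)
      expect_identical(got$lineage, expected_lineage[i])
    } else {
      expect_true(is.na(got$lineage))
    }
  }
})

test_that("hits against unknown references raise a typed error", {
  db <- toy_db()
  expect_error(classify_read("r1", mk_hit("NOPE"), 500, db), "NOPE",
               class = "pollensift_unknown_reference_error")
})

test_that("classify_reads maps hit tables onto a read set by id", {
  db <- toy_db()
  reads <- read_set(c("a", "b"), rep(strrep("ACGT", 125), 2),
                    rep(list(rep(20L, 500)), 2))
  hits <- rbind(mk_hit("R1", read = "a"), mk_hit("R3", read = "zzz"))
  out <- classify_reads(reads, hits, db)
  expect_identical(out$status, c("Assigned", "Unassigned"))
  expect_identical(out$read_id, c("a", "b"))
})
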