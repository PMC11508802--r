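FWD <- rbcla_primers()$fwd
REV <- rbcla_primers()$rev

rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

test_that("trim_to_amplicon extracts the region between the primers", {
  cfg <- ref_curation_config(FWD, REV, min_len = 4, max_len = 700)
  seq <- paste0(FWD, "ACGTACGT", rc(REV))
  expect_identical(trim_to_amplicon(seq, cfg), "ACGTACGT")
  # neither primer present
  expect_true(is.na(trim_to_amplicon(strrep("ACGT", 30), cfg)))
  # reverse-complement input comes back in forward orientation
  expect_identical(trim_to_amplicon(rc(seq), cfg), "ACGTACGT")
  # malformed characters rejected
  expect_error(trim_to_amplicon("ACGTXACGT", cfg),
               class = "pollensift_invalid_sequence_error")
})

test_that("trim_to_amplicon tolerates primer mismatches up to the limit", {
  set.seed(41)
  core <- paste(sample(c("A", "C", "G", "T"), 550, replace = TRUE),
                collapse = "")
  fwd_mut <- FWD
  substr(fwd_mut, 10, 10) <- if (substr(FWD, 10, 10) == "A") "C" else "A"
  cfg2 <- ref_curation_config(FWD, REV, max_primer_mismatch = 2)
  seq <- paste0("GGAA", fwd_mut, core, rc(REV), "TTCC")
  expect_identical(trim_to_amplicon(seq, cfg2), core)
  cfg0 <- ref_curation_config(FWD, REV, max_primer_mismatch = 0)
  expect_true(is.na(trim_to_amplicon(seq, cfg0)))
})

test_that("trimmed amplicons never retain a primer at zero tolerance", {
  cfg <- ref_curation_config(FWD, REV, max_primer_mismatch = 1,
                             min_len = 1, max_len = 1000)
  set.seed(7)
  for (i in 1:20) {
    core <- paste(sample(c("A", "C", "G", "T"), sample(100:600, 1),
                         replace = TRUE), collapse = "")
    seq <- paste0(FWD, core, rc(REV))
    if (runif(1) < 0.5) seq <- rc(seq)
    amp <- trim_to_amplicon(seq, cfg)
    expect_false(is.na(amp))
    expect_length(find_primer_matches(amp, FWD, 0L), 0L)
    expect_length(find_primer_matches(amp, rc(REV), 0L), 0L)
  }
})

test_that("reference quality filters apply degenerate, homopolymer and length rules", {
  cfg <- ref_curation_config(FWD, REV, max_degenerate_bases = 5,
                             max_homopolymer_run = 8,
                             min_len = 500, max_len = 650)
  base560 <- strrep("ACGT", 140)
  expect_true(reference_passes_filters(base560, cfg))
  # run of 9 exceeds the homopolymer cap
  run9 <- paste0(strrep("A", 9), substr(base560, 10, 560))
  expect_identical(nchar(run9), 560L)
  expect_false(reference_passes_filters(run9, cfg))
  # 6 degenerate bases exceed the cap of 5 (direct count of non-ACGT)
  degen <- paste0(strrep("N", 6), substr(base560, 7, 560))
  chars <- strsplit(degen, "")[[1]]
  expect_identical(sum(!chars %in% c("A", "C", "G", "T")), 6L)
  expect_false(reference_passes_filters(degen, cfg))
  # length bounds inclusive
  expect_false(reference_passes_filters(strrep("ACGT", 120), cfg))
})

test_that("dereplicate keeps one record per (sequence, lineage) pair", {
  lin <- toy_lineages()
  recs <- data.frame(
    id = c("a", "b", "c"),
    sequence = c("ACGT", "ACGT", "ACGT"),
    lineage = c(lin[["vicia_faba"]], lin[["vicia_faba"]],
                lin[["vicia_sativa"]]),
    stringsAsFactors = FALSE)
  out <- dereplicate(recs)
  # same sequence + same lineage collapses, first id kept;
  # same sequence + different lineage is retained
  expect_identical(out$id, c("a", "c"))
})

test_that("dereplicate is idempotent and never grows on random inputs", {
  set.seed(11)
  pool_seq <- replicate(4, paste(sample(c("A", "C", "G", "T"), 20,
                                        replace = TRUE), collapse = ""))
  for (i in 1:50) {
    n <- sample(0:12, 1)
    recs <- data.frame(id = sprintf("id%02d", seq_len(n)),
                       sequence = sample(pool_seq, n, replace = TRUE),
                       lineage = sample(toy_lineages(), n, replace = TRUE),
                       stringsAsFactors = FALSE)
    once <- dereplicate(recs)
    expect_lte(nrow(once), nrow(recs))
    expect_identical(dereplicate(once), once)
  }
})

make_ref_fixture <- function(dir) {
  lin <- toy_lineages()
  set.seed(5)
  core <- paste(sample(c("A", "C", "G", "T"), 550, replace = TRUE),
                collapse = "")
  good <- paste0(FWD, core, rc(REV))
  seqs <- c(ref1 = good, ref2 = strrep("ACGT", 160), ref3 = good)
  fasta <- file.path(dir, "refs.fasta")
  writeLines(paste0(">", names(seqs), "\n", seqs), fasta)
  tax <- file.path(dir, "refs.tsv")
  writeLines(sprintf("%s\t%s", names(seqs),
                     c(lin[["vicia_faba"]], lin[["urtica"]],
                       lin[["vicia_faba"]])), tax)
  list(fasta = fasta, tax = tax, core = core)
}

test_that("build_db runs trim -> filter -> dereplicate with drop counts", {
  dir <- withr::local_tempdir()
  fx <- make_ref_fixture(dir)
  cfg <- ref_curation_config(FWD, REV, min_len = 500, max_len = 700)
  db <- build_db(fx$fasta, fx$tax, cfg)
  expect_s3_class(db, "reference_db")
  expect_identical(nrow(db$records), 1L)
  expect_identical(db$records$id, "ref1")
  expect_identical(db$records$sequence, fx$core)
  expect_identical(db$provenance$no_amplicon, 1L)
  expect_identical(db$provenance$duplicate, 1L)
  expect_identical(db$provenance$failed_filter, 0L)
  # drop counts account for every input record
  expect_identical(db$provenance$n_input,
                   db$provenance$n_output + db$provenance$no_amplicon +
                     db$provenance$failed_filter + db$provenance$duplicate)
})

test_that("build_db on an empty FASTA yields an empty database", {
  dir <- withr::local_tempdir()
  fasta <- file.path(dir, "empty.fasta")
  tax <- file.path(dir, "empty.tsv")
  file.create(fasta, tax)
  cfg <- ref_curation_config(FWD, REV)
  db <- build_db(fasta, tax, cfg)
  expect_identical(nrow(db$records), 0L)
})

test_that("build_db names the reference missing a taxonomy row", {
  dir <- withr::local_tempdir()
  fx <- make_ref_fixture(dir)
  writeLines(sprintf("%s\t%s", c("ref1", "ref2"),
                     toy_lineages()[c(1, 3)]), fx$tax)
  cfg <- ref_curation_config(FWD, REV)
  expect_error(build_db(fx$fasta, fx$tax, cfg), "ref3",
               class = "pollensift_missing_taxonomy_error")
})

test_that("a clean reference set passes through build_db untouched", {
  dir <- withr::local_tempdir()
  set.seed(19)
  n <- 10
  cores <- replicate(n, paste(sample(c("A", "C", "G", "T"), 550,
                                     replace = TRUE), collapse = ""))
  ids <- sprintf("ok%02d", seq_len(n))
  fasta <- file.path(dir, "ok.fasta")
  writeLines(paste0(">", ids, "\n", FWD, cores, rc(REV)), fasta)
  tax <- file.path(dir, "ok.tsv")
  writeLines(sprintf("%s\tk__Plantae;p__Streptophyta;c__X;o__Y;f__F%02d;g__G%02d;s__G%02d s",
                     ids, 1:n, 1:n, 1:n), tax)
  db <- build_db(fasta, tax, ref_curation_config(FWD, REV))
  expect_identical(nrow(db$records), 10L)
  expect_identical(db$provenance$no_amplicon, 0L)
  expect_identical(db$provenance$failed_filter, 0L)
  expect_identical(db$provenance$duplicate, 0L)
  # round-trip through the on-disk representation
  fa2 <- file.path(dir, "db.fasta")
  tx2 <- file.path(dir, "db.tsv")
  write_reference_db(db, fa2, tx2)
  db2 <- read_reference_db(fa2, tx2)
  expect_identical(db2$records, db$records)
})
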