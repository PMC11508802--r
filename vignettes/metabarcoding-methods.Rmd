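---
title: "Methods: classification and contamination assessment for insect gut-content metabarcoding"
author: "pollensift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classification and contamination assessment for insect gut-content metabarcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollensift)
```

## The problem

Diet analysis of herbivorous insects by plant DNA metabarcoding amplifies a
short barcoding marker — here the rbcLa fragment of the chloroplast rbcL
gene, an amplicon of roughly 550–600 bases — from whole-insect or dissected
gut extracts, sequences the amplicons on a long-read platform, and assigns
each read to a plant taxon against a curated reference database. The
central confound is surface contamination: pollen adhering to the insect
carries plant DNA that is amplified exactly like dietary DNA, so a read
profile mixes gut signal with surface signal. This is acute for
xylem-feeding insects such as the meadow spittlebug, whose food (xylem sap)
carries very little host DNA, so even minor surface pollen can dominate the
amplifiable template.

`pollensift` implements the computational side of this workflow: reference
curation, read QC, alignment, taxonomic classification by majority-rule
lowest common ancestor (LCA), per-sample profiling, contamination
accounting, and qPCR cycle-threshold (CT) summarisation — plus a synthetic
read generator so every stage can be validated end-to-end against a known
ground truth without any sequencing data.

## Reference database curation

`build_db()` runs parse → `trim_to_amplicon()` → `reference_passes_filters()`
→ `dereplicate()` and records per-step drop counts.

Primer matching is IUPAC-aware: a primer base matches a reference base
whenever the two IUPAC sets intersect. This is required because the reverse
rbcLa primer carries a degenerate base (R). Among multiple primer matches,
the leftmost forward and rightmost reverse match are used — the maximal
amplicon, chosen deterministically.

The quality filters drop references with more than `max_degenerate_bases`
non-ACGT bases (default 5), a homopolymer run longer than
`max_homopolymer_run` (default 8), or a length outside `[min_len, max_len]`
(default [500, 700] bases around the expected amplicon). These defaults
follow common reference-curation practice for rbcL; they are configuration
values, not claims about any particular published database, and should be
reviewed per study.

Dereplication removes records sharing *both* sequence and full lineage
string, keeping the first-seen accession. Records with identical sequence
but different taxonomy are deliberately both kept: they are exactly the
cases where the LCA vote must see the ambiguity.

## Read QC

Reads are primer-trimmed on either strand (`trim_reads()`; a
reverse-complement amplicon is re-oriented forward, qualities sliced in
lockstep) and then filtered (`filter_reads()`) to the inclusive length
window 450–650 bases with a per-read quality floor of Phred 7. Both
boundaries follow strict published wording — "greater than 650" / "fewer
than 450" discard, so 450 and 650 survive.

The per-read quality is the arithmetic mean of per-base Phred scores by
default. Averaging in error space
(`read_filter_config(q_aggregate = "mean_error")`) is also available; it is
systematically harsher on reads with a few very poor bases, because the
error-probability mean is dominated by the worst bases. The mean-of-Phred
default matches how single "average quality" figures are conventionally
reported for nanopore runs. The implied error rate is
`phred_to_error_pct(q) = 100 * 10^(-q/10)`; Q13.4 ↔ 4.6%, Q12.1 ↔ 6.2%.

The median read length uses the lower median for even counts so that
integer lengths report deterministically.

## Alignment

Classification needs per-read hits with identities, alignment lengths and
bitscores. The package accepts external 12-column tabular hit files
(`read_hit_table()`, the classic outfmt-6 dialect) and also provides its
own seeded local aligner so that the whole pipeline is testable
desk-scale:

* `local_align()` is an affine-gap Smith–Waterman (both strands of the
  read; the dynamic programming is Biostrings' C implementation). A gap of
  length $L$ costs $|g_{open}| + L\,|g_{ext}|$.
* Scoring defaults are megablast-like: match +2, mismatch −3, gap open −5,
  gap extend −2, with Karlin–Altschul parameters $\lambda = 0.625$,
  $K = 0.41$ converting raw score $S$ to a bitscore
  $S' = (\lambda S - \ln K)/\ln 2$. These defaults make the downstream
  "within 5% of the best bitscore" window behave comparably to hits from an
  external search engine; all values are configurable.
* `search_read()`/`align_reads()` select candidate references sharing at
  least one exact k-mer (default k = 11, either strand) and align only
  those. With divergent references and the error rates simulated here, the
  chance of the true source sharing no error-free 11-mer across a ~550-base
  read is negligible; a completeness test against all-pairs alignment backs
  this up.

E-values are not computed (no database-size statistics); the bitscore is
the ranking statistic and `evalue` is `NA` for internal hits.

## Hit filtering and majority-rule LCA

`filter_hits()` applies, strictly in order: (1) identity ≥ 80% *and*
coverage ≥ 80%; (2) bitscore within 5% of the best **surviving** hit.
Coverage is `100 * aln_len / read_len` by default. The published phrase
"alignment length of at least 80%" does not name a denominator; read-length
coverage was chosen because it is invariant to reference padding, and the
denominator is configurable (`"reference"`, `"amplicon"`).

A consequence of re-anchoring the window on the survivors of step 1 is
that the filter as a whole is *not* monotone in the identity/coverage
thresholds: raising the identity floor can remove the top-bitscore hit,
lower the window anchor, and admit hits that were previously outside the
window. Each stage is monotone in its own threshold; the property tests
assert exactly that.

`majority_lca()` starts at species and ascends the fixed rank ladder
(kingdom > phylum > class > order > family > genus > species). At each rank
a taxon name wins if it is shared by at least 75% of the surviving hits'
lineages. Two design choices matter:

* **Vote denominator.** The vote is taken over *all* surviving hits,
  including those whose lineage lacks the rank under consideration
  (`lca_config(vote_denominator = "all")`). This is conservative: a single
  species-annotated reference cannot win species when most references
  carry no species label. Voting only over annotated lineages is available
  as `"annotated"`.
* **Duplicate lineages.** Each surviving hit votes once, even when several
  hits share a lineage — the vote counts assignments, not unique taxa.

Reads with no surviving hits are `Unassigned`; reads whose survivors never
reach a majority are `Unresolved`. The two statuses are distinct because
they fail for different reasons (no signal vs conflicting signal) and both
are excluded from downstream counts. With `majority_fraction = 1` the
procedure reduces to the classic strict LCA (deepest common prefix) when
all ranks are present.

## Profiles, selection, genus collapsing

`tally()` counts Assigned reads per truncated-lineage label. `select_taxa()`
implements the top-taxon rule: the most abundant taxon is selected together
with every taxon at ≥ 1% of its count (inclusive); tied maxima all anchor
the shared threshold. `drop_small_samples()` removes samples with fewer
than 50 assigned reads (strict; a 3000-unit floor suits denoised
short-read ASV counts instead — the rule is unit-agnostic).

`collapse_to_genus()` merges species-level labels into their genus and
keeps labels resolved above genus as-is with a supra-genus flag: a
family-level call cannot be pushed down to genus without external
information. Totals are conserved; the selected set is remapped through the
same collapsing.

`consensus_read_sets()` extracts the read ids of each selected taxon for
external consensus polishing; the polishing tool itself is out of scope.

## Contamination accounting

`contamination_fraction()` reports the percentage of assigned units not
matching any dietary taxon, with an over-threshold flag at a strict 5%.
Diet matching is rank-aware in both directions: a genus-level diet entry
captures species-level detections of that genus and vice versa, so "the
insect ate *Vicia*" is not contradicted by a *Vicia faba* label.

`detection_matrix()` counts, per replicate group, the replicates in which a
target taxon is present at ≥ 1 unit (the floor is configurable; presence
tables are conventionally reported without a stated count floor).
`group_target_summary()` gives the group-wise mean absolute target count
and min–max percentage range, and `abundance_matrix()` the rectangular
taxon × sample table with deterministic lexicographic ordering.

## qPCR CT summaries

CT values are cycles-to-threshold on a 40-cycle TaqMan run; 40 is the
censoring value and means "no detection". `average_ct()` keeps censored 40s
as point values in the replicate mean — this reproduces printed plate
summaries exactly, at the cost of biasing partially-censored averages
downward in template terms; since such averages are only interpreted as
detected/not detected, the bias is immaterial here. Reported averages are
rounded half away from zero to 2 decimals (printed tables round 29.995 up
to 30, where banker's rounding would give 29.99); display trims trailing
zeros. Detection uses the unrounded mean, strictly below 40.

`uv_trend()` summarises a UV-exposure time course as the rank (Spearman)
correlation of average CT against exposure time, alongside the Pearson
correlation and a strict-monotone flag. Rank correlation is the primary
statistic because the dose–response claim is ordinal (more UV, less intact
DNA) and the statistic is then invariant to monotone transforms of the
time axis; with a strictly increasing series it is exactly +1.

## The synthetic-data generator

`make_reference_set()` draws random amplicons (default 550 bases),
rejection-sampling until every pair is below 80% identity, with distinct
7-rank lineages sharing kingdom–order. Pairwise identity here is
local-alignment matches over the shorter sequence length: raw
alignment-column identity is near 100% for the short chance matches any
two random sequences share, so it cannot serve as a divergence screen,
whereas the match-fraction statistic is ~5–10% for unrelated amplicons and
100% for identical ones.

`simulate_sample()` draws each read's source taxon from the configured
composition, applies substitutions, insertions and deletions, flanks the
amplicon with the rbcLa primers (degenerate positions resolved randomly)
so trimming is exercised, emits about half the reads reverse-complemented,
and draws per-base qualities around the target mean. The default error
model ties the total per-base error to the target quality,
$e = 10^{-Q/10}$, split substitution:insertion:deletion = 2:1:1 — a
long-read-like profile consistent with the Q13/5% regime of R9-era
nanopore amplicon data. The generator does not model homopolymer-biased
errors, chimeras, barcode hopping, or quality-error correlation along the
read; passing end-to-end tests therefore demonstrate correctness of the
pipeline logic under a clean error model, not robustness to every real
nanopore artefact.

`simulate_experiment()` expands a replicate-group design (diet taxa plus
an optional spike taxon at a given fraction) into per-replicate samples.
`dusting_design()` builds the nine-group design used for validation —
whole/gut/exoskeleton × dusted/clean × with/without disinfectant, plus a
pollen-only control, three replicates each — with the spike at 95% of a
dusted replicate's reads, reflecting how thoroughly dusting pollen
dominates the amplifiable template in such experiments. Replicate seeds
derive deterministically from the base seed, group and replicate index, so
any single replicate can be regenerated in isolation. Gut-level dietary
DNA abundance in vivo is unknown (gut dissections in the motivating
setting detected none), so the diet fraction is a free simulation
parameter, not an asserted biological value.

## Validation strategy and problem sizes

Every operation is tested against an independent oracle where one exists:
a hand-written exhaustive Smith–Waterman for the aligner, a brute-force
rank-ascent enumerator for the LCA (exhaustive over all multisets of up to
5 lineages from a 3-taxon toy taxonomy), straight-line re-implementations
for hit filtering, selection, dereplication, exclusion and collapsing
(1000 random instances each), and binomial/CLT bounds for the simulator.
End-to-end, a 2000-read sample at Q13 with a 90/10 diet/pollen composition
must be recovered within 3 binomial standard deviations with ≥ 99%
genus-level accuracy, and the nine-group dusting design (120 reads per
replicate) must show spike detection in every dusted replicate and no
clean replicate. These sizes keep the full validation suite to a few
minutes on one CPU while leaving the binomial bounds tight enough to
detect systematic misassignment.

## Known limitations

* The internal aligner is for validation and desk-scale studies; a
  production run over millions of reads should use an external search tool
  and feed the hits in via `read_hit_table()`.
* E-values are not computed; ranking and windowing use bitscores only.
* Manual curation steps beyond genus collapsing (e.g. deciding that a
  family-level call "is" a particular genus) are intentionally not
  automated.
* The error model is i.i.d. per base; see the generator section for what
  that does and does not validate.
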