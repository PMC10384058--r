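---
title: "Methods: integrative amplicon diversity with taxonomy-informed clustering"
author: "ampliTIC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative amplicon diversity with taxonomy-informed clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliTIC)
```

## The problem

Public repositories hold enormous numbers of 16S rRNA gene amplicons from
unrelated studies. Pooled per taxonomic order, they are a global sampling
effort — but the fragments target different subregions of the gene, vary in
length, and mostly represent taxa with no cultivated representative.
`ampliTIC` turns such a pool into a sequence-based diversity estimate:
molecular families, genera and species (fOTUs, gOTUs, sOTUs), with the
described species mapped onto them and an ecological profile per molecular
species.

The pipeline assumes its input is already aligned to a common reference
alignment and annotated with a ranked taxonomy (both normally produced by an
upstream aligner/classifier); it performs no alignment or re-annotation of
its own.

## Procedure

1. **Dereplication.** Byte-identical alignment rows collapse into one record
   with a multiplicity; the lexicographically smallest id is retained so the
   step is order-free.
2. **Region selection.** Per-column coverage is the number of records with a
   sequenced base (`N` counts, gaps do not). The analysis region is the
   longest contiguous run of columns reaching a fraction (default 0.8) of
   the maximum column coverage; length ties resolve to the leftmost run, and
   a manual override window is accepted. This is an algorithmic rendering of
   what is usually done by inspecting the coverage profile.
3. **Trimming and length filtering.** Records are sliced to the window and
   degapped. The keep rule is *strictly more than* a fraction (default 80%)
   of the bases a designated reference record (conventionally *E. coli*)
   carries in the window; the threshold is therefore the smallest integer
   exceeding `minFraction * expectedBases`. An absolute `minBases` override
   exists because published workflows sometimes state an absolute cutoff
   that is not exactly the fraction rule (229 vs 0.8 x 282 = 225.6); the
   package exposes both and does not guess which was intended.
4. **Cutoff calibration.** Because a subregion compresses evolutionary
   signal, the classical 97/95/90% full-gene thresholds are recalibrated:
   over the trimmed region, pairwise identities among described reference
   species are averaged within three strata — same genus, same family but
   different genus, different families — giving the species, genus and
   family cutoffs. Means are unweighted over pairs, rounded to two decimals;
   an empty stratum or a violated ordering is a hard error, never clamped.
5. **Taxonomy-informed clustering (TIC).** Records are binned by their
   deepest annotated rank (at most genus; shallower records fall into an
   `unclassified` child bin of their deepest annotated ancestor), so
   sequences with conflicting annotated lineages can never co-cluster.
   Within each bin, greedy incremental clustering runs at the family cutoff
   (fOTUs), then within each fOTU at the genus cutoff (gOTUs), then within
   each gOTU at the species cutoff (sOTUs).
6. **Known-species assignment.** Each reference species maps to its
   best-identity sOTU representative; at or above 98% identity the sOTU
   takes the species name, and references that land on the same sOTU merge
   into a slash-joined name (indistinguishable over the region).
7. **Ecology and reporting.** Free-text sample origins map onto a fixed
   category vocabulary; manually assembled systems are excluded outright.
   Per sOTU the package counts positive samples (abundance > 0), samples at
   or above the 0.1% gate, the dominant and maximum-abundance environments,
   and the cosmopolitan flag (>= 50 positive samples). Report tables cover
   known-vs-predicted diversity, per-family breakdowns with half-up-rounded
   percentages, species-per-taxon histograms (bins 1, 2–10, 11–50, >= 51; a
   taxon with exactly 51 species goes to the top bin), and top-N prevalence
   and abundance tables.

## Pairwise identity

The identity primitive is a global (end-to-end) Needleman–Wunsch alignment
with match +1, mismatch −1 and gap −1 (linear gap cost); identity is matched
columns over total alignment columns, so gaps penalise identity, in the
style of identity-over-alignment used by common clustering tools. Two
numerical choices make the value fully deterministic:

* among co-optimal tracebacks, the canonical one prefers diagonal, then a
  gap in the second sequence, then a gap in the first;
* co-optimal alignments can differ in *length* (the score fixes only
  `2 * matches − columns`), so the pair is canonicalised with the
  lexicographically smaller sequence first, making identity exactly
  symmetric.

The kernel is compiled (Rcpp); the test suite checks it against an
independent pure-R dynamic-programming implementation and against the
scores of an established aligner.

## Greedy clustering choices

Incremental clustering processes entries in a canonical order — multiplicity
descending, then length descending, then id ascending — matching the
abundance-first convention of incremental OTU clustering and making results
invariant to input permutation. An entry joins the *first* representative at
or above the cutoff (a best-hit mode is available via `bestHit = TRUE`);
representatives are founding sequences and are never recomputed as
centroids. These conventions are this package's own choices where the
general method leaves them open; they are deliberately the simplest ones
that give determinism, and `oracleCluster()` re-simulates them exhaustively
for bins of up to 40 entries as an in-package cross-check.

Boundary semantics throughout: comparisons against cutoffs and against the
abundance gate are inclusive (`>=`), while the length filter is exclusive
(`>`, "more than 80%"), each following the wording of the convention it
implements.

## The synthetic community generator

Real inputs at repository scale (hundreds of thousands of sequences) are
neither required nor practical for validation; instead the generator plants
a known hierarchy and the tests check that the pipeline recovers it.

**What it emulates.**

* A family > genus > species hierarchy with controlled pairwise identities.
  A random root sequence is mutated along the tree: every family, genus and
  species branch substitutes a fixed number of sites inside the analysis
  region. Site counts follow from the identity targets (for example, two
  species of one genus at target `wg` differ at `2 * round((1−wg)·C/2)`
  sites over a region of `C` bases). Family and genus sites are globally
  disjoint; species sites are disjoint within a genus and recycled
  least-used-first across genera, with a reused site forced to a different
  base than its first use so reuse can shrink a cross-genus distance by at
  most one. A verification pass measures every reference pair and redraws
  (up to 30 attempts, then errors) unless all pairs sit within
  `max(1 pp, 3/C)` of their stratum target; a ladder whose site demand
  exceeds the region length errors immediately as infeasible.
* Fragmentation across studies: each record copies one species sequence
  restricted to one of the configured windows (60/40 weights by default),
  embedded into a gapped master alignment (8 pad columns each side plus an
  interior 4-column all-gap block), so column coverage genuinely varies and
  region selection has a signal. A configurable fraction of fragments is
  truncated to the first 45% of its window, guaranteed below the length
  filter.
* Within-species variability: a fraction of fragments carry substitutions
  confined to their window *outside* the shared analysis region, sized to
  the `withinSpeciesIdentity` target over the window. Keeping the analysis
  region of a species exact is a deliberate modelling choice: the planted
  between-taxon margins (e.g. 0.905 within family against a 0.90 cutoff)
  are narrower than a single substitution on a ~250-base region, so exact
  recovery of the planted partition is only a well-posed expectation when
  within-species noise lives in the flanks. Passing recovery tests
  therefore demonstrate algorithmic correctness of the clustering, not
  robustness to within-species variation at the cutoff boundary — real data
  near a boundary will split or merge clusters.
* Sample metadata and abundances: each sample draws a free-text origin
  label from a built-in synonym table (so the categorizer is exercised on
  realistic strings, including excluded laboratory systems), species get
  Beta(0.7, 1.1) occupancy probabilities, and present species receive
  Gamma(`abundanceAlpha`) weights scaled to a random per-sample total below
  1 — a long-tailed profile in which some species straddle the 0.1% gate by
  construction. The long-tail shape is a modelling choice, not an empirical
  fit, since repository-wide abundance distributions are not published.

**What it does not emulate:** chimeras, sequencing-error quality profiles,
indel evolution, taxonomic misannotation, or correlated occupancy between
related species.

## Default study conditions

Defaults are fixed once and used by the test suite and the acceptance
script: 3 families x 3 genera x 3 species, 282-base master region, windows
`[0,220)` and `[60,282)` (analysis region 160 bases), identity ladder
0.99/0.96/0.92/0.90, 18 fragments per species (486 records), 10% short
fragments, 60 samples, `abundanceAlpha = 0.3`. The cluster-recovery runs use
a *separated* ladder (0.97/0.93/0.905/0.88 against cutoffs 0.96/0.92/0.90)
and wider windows `[0,274)`/`[8,282)`, because 27 species at 93% identity
need more disjoint sites than the default 160-base region offers — with the
default windows that ladder correctly raises the infeasibility error. At the
default (calibration) ladder the planted identities *equal* the cutoffs, so
boundary merges are expected there and recovery is only asserted on the
separated ladder. Ecology-at-scale checks use 200 molecular species by 500
samples. These sizes keep a full validation run in tens of seconds on one
CPU while leaving every code path non-trivially exercised.

## Degenerate inputs and numerical details

* Empty record sets: dereplication and clustering return empty results;
  coverage of an empty collection and an all-zero coverage vector are
  errors.
* A single-species or single-genus reference set cannot calibrate all
  strata and errors, naming the empty stratum.
* Percentages round half away from zero to two decimals (an epsilon absorbs
  binary representation error), matching how printed tables are typically
  rounded; R's default half-even rounding would disagree on exact halves.
* OTU labels are zero-padded ordinals issued in canonical processing order,
  so label text is stable under input permutation.
* All simulation entry points take an integer seed and restore the caller's
  RNG state; identical configuration and seed give byte-identical output
  files.

## Limitations

* Taxonomy binning trusts the input annotation; a misannotated sequence is
  confined to the wrong bin by design (that is the taxonomy bound).
* Greedy incremental clustering is order-dependent in principle; the
  canonical order makes it reproducible but not equivalent to optimal
  partitioning, and counts near a cutoff boundary are sensitive to the
  cutoff's second decimal.
* Identity-over-alignment with linear gap costs is one of several defensible
  identity definitions; calibrated cutoffs are only meaningful relative to
  the same definition used in clustering (the package uses one primitive
  for both).
* The ecological summaries describe incidence in a convenience sample of
  public datasets; positivity and prevalence are repository statistics, not
  design-based estimates of environmental frequency.
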