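---
title: "Models and methods behind barcodeconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind barcodeconcord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeconcord)
```

`barcodeconcord` confronts morphological species hypotheses
(*morphospecies*) with molecular species hypotheses (*putative species*)
derived from COI barcodes, and classifies every disagreement. This
vignette is the package's own account of the models it fits, the
parameters that matter, the numerical choices that were genuinely open,
and what the test suite does and does not demonstrate.

## 1. Distances

All downstream methods consume **uncorrected p-distances**: the
proportion of compared sites at which two aligned sequences differ.
Compared sites are the alignment columns where *both* sequences carry an
unambiguous base (A, C, G, T). Gaps, `N`, `?` and all other IUPAC
ambiguity codes are excluded site-wise — **pairwise deletion**, not
complete deletion. Pairwise deletion was chosen because barcode surveys
routinely compare full-length study sequences against reference records
of very different lengths; complete deletion would let one short record
erase most of the signal for every pair. Pairs sharing fewer than
`min_overlap` sites (default **100**, in sites) have no defined distance
and are flagged `NA` rather than guessed.

Two deliberate contracts:

* p-distance is **not a metric**; no code path relies on the triangle
  inequality (single-linkage chaining, for instance, is defined purely on
  the pairwise graph).
* Before distances are computed the alignment is trimmed so that at
  least `min_common` sites (default **150**) are unambiguous in *every*
  retained sequence. Trimming is greedy: repeatedly drop the sequence
  whose removal most enlarges the shared core (ties: fewest unambiguous
  sites, then lexicographic id). Greedy is not guaranteed globally
  minimal, but the suite checks the first pick is never dominated by any
  single-removal alternative.

## 2. Barcode-gap delimitation

The gap method assumes intraspecific divergences and interspecific
divergences form two distributions separated by a "barcode gap". Given a
prior maximal intraspecific p-distance `P`:

1. sort all defined pairwise distances ascending;
2. scan for the first gap whose **upper edge exceeds `P`** and whose
   width exceeds `X · s`, where `s` is the mean spacing over the trailing
   window of `W = max(3, ceil(0.1 m))` sorted values (`m` = number of
   distances); `X` is the relative gap width, default **1**;
3. cluster by connected components of the graph linking pairs at or below
   the gap midpoint;
4. recurse independently inside every multi-member cluster.

Two design points deserve notice. First, the gap condition is placed on
the gap's *upper* edge: `P` bounds intraspecific divergence, so the
decisive gap is the one that reaches beyond `P`, even when its lower edge
(the largest intraspecific distance) sits below `P`. This is what makes
the clean-gap guarantee hold: whenever the data satisfy
`max intra < min inter`, every prior in `[max intra, min inter)` recovers
the true partition — the property the acceptance suite verifies over 50
seeded replicates at K = 2..6. Second, when the trailing window has zero
spread (tied distances) any positive jump counts as significant;
otherwise two clusters of identical sequences could never be separated.

A consequence worth understanding: **at priors far below the
intraspecific ceiling the method oversplits**, down to near-haplotype
granularity. This is not a defect — deliberate oversplitting at
`P = 0.0001` is exactly how representative sequences are chosen for tree
inference (`select_representatives`: up to 3 random members per oversplit
group, then exact-duplicate haplotype collapsing, all seeded). But it
means that over a log-spaced prior scan (`abgd_scan`, defaults
`[1e-4, 0.1]`, 20 steps) the *majority* of priors fall in the oversplit
regime, so the modal group count across a scan reflects the oversplit
plateau rather than the species number. The scan's informative feature is
the plateau at the true count inside the gap window; the suite asserts
exactly that, plus "count ≥ K below the window", and does not treat the
mode as an estimator.

**Exact numerical fidelity to the original ABGD web tool is a non-goal**;
its local-slope estimation is under-specified, and the windowed rule above
is this package's fixed, deterministic completion of it.

## 3. Single-linkage BIN proxy and the best-match fallback

Barcode Index Numbers are produced by BOLD's refined single-linkage
pipeline, whose refinement stage depends on infrastructure not available
offline. The package therefore provides the transparent core —
single-linkage clustering at a fixed threshold, default **0.022**
p-distance, the conventional BIN seed threshold — as a *proxy*,
cross-checked in the tests against an independent union-find oracle.
Externally computed BIN (or Bayesian Poisson-tree-processes) partitions
can be imported as first-class methods via `read_partition`.

For sequences too short to cluster directly, the fallback rule mirrors
reference-library practice: a query inherits the group of its best match
when the overlap is at least **300 sites** and similarity
(1 − p-distance) at least **0.99**. Ties across distinct groups leave the
query unassigned — reproducibility is preferred over an arbitrary pick.

## 4. Single-threshold GMYC

On a rooted ultrametric tree (ultrametricity enforced within relative
tolerance 1e-6), a threshold time `T` separates between-species
diversification (older) from within-species coalescence (younger).
Scanning branching events from the root, each inter-event interval of
length `x_k` contributes `log b_k − b_k x_k` with

$$ b_k = \lambda_{b}\, n_k^{p_b} + \lambda_{w} \sum_j n_{j,k}\,(n_{j,k}-1)^{p_w} $$

where `n_k` counts between-species lineages and `n_{j,k}` the lineages
inside cluster `j`; the final interval, which ends at the present rather
than at an event, contributes only the survival term `−b_k x_k`. The null
model is the same likelihood with a single process over all events.
Candidate thresholds are the midpoints between consecutive distinct node
heights, completed by the two boundary configurations: below the youngest
node (every tip a singleton species — algebraically identical to the
null, which also guarantees `logL_model ≥ logL_null`) and above the root
(one species, pure coalescence — without it a tree with no structure
could never be reported as a single cluster). Rates are maximized by
Nelder-Mead on the log scale (closed form when the within-process never
appears); the scaling exponents are fixed to 1 by default
(`optimize_p = TRUE` frees them); the likelihood-ratio test uses the
conventional **3 degrees of freedom**.

Measured behaviour the user should know:

* Under a pure-birth null (200 trees, 20 tips) the test is conservative:
  the rejection rate at the 5 % level sits near 2 % — within the
  accepted calibration band but below nominal, as expected when the
  threshold is profiled out and df = 3 is charged.
* On calibrated synthetic genealogies (gap ratio 10) the fit recovers the
  true species count in roughly 80 % of replicates; **every miss is a
  single merge of the shallowest sister-species pair**, the
  single-threshold model's well-known failure mode, and the margin
  between the two optima is typically under one log-likelihood unit.
  Distance-based methods recover the truth essentially always under the
  same conditions, which is precisely why multi-method concordance — and
  the `R` flag — is informative.

## 5. Reference matching and novelty

Best-match lists against a local reference library keep at most **100**
matches per query at **≥ 80 %** similarity, sorted by distance then
reference id, with provisionally named references excluded by default;
each match is classified `NAME_MATCH` / `NAME_MISMATCH` /
`PROVISIONAL_INVOLVED` on whitespace-normalized exact names (synonym
resolution is taxonomy, not computation, and is out of scope). A
morphospecies is flagged *divergent-novel* when the minimum best-match
distance across all its study sequences exceeds **0.05**; queries with an
empty match list count as exceeding, so truly unrepresented lineages are
flagged rather than silently dropped. The per-morphospecies minimum (not
per-sequence) was chosen so that a single well-matched sequence anchors
its morphospecies. `flag_first_barcode` lists described morphospecies
absent from the reference names — candidate first barcodes; provisional
names are excluded there and handled by the resolution table instead.

## 6. Discordance classification

For every study morphospecies, `classify_discordances` evaluates each
method in two scopes — study specimens only (H) and study plus external
(A) — and emits:

* `SPLIT` when any evaluable method places the morphospecies in ≥ 2
  groups; the resolution flag is `_` only when *all* evaluable methods
  split it, `R` otherwise;
* `LUMP` once per connected set of co-lumped morphospecies (a chain
  {X,Y} + {Y,Z} prints one record for {X,Y,Z}, matching how such tables
  are published), with the analogous flag;
* `CONCORDANT` otherwise. A morphospecies can legitimately carry both a
  SPLIT and a LUMP record.

Context H strictly dominates A: an issue already visible in the study's
own data is H even if also visible after merging. Methods whose scope
does not cover a morphospecies are excluded from the "all methods"
quantifier (absence of evidence), never counted as non-splitting.
The category set follows the tabular convention (S/L as categories, R as
an orthogonal flag) rather than the three-way prose reading, because the
tables are the operational ground truth of how such results are reported.

Provisional morphospecies are resolved against described names only:
`SEPARATE` (no described partner under any method), `GROUPED_WITH(name)`
(same single described partner under every method), or `MIXED` with
per-method detail, plus the nearest reference below 0.05 (else
`NO_MATCH`).

## 7. The synthetic-data generator

The generator exists so that every pipeline stage is testable against a
known truth without any download. It emulates:

* a **species tree**: `K` tips on a pure-birth tree, rescaled so the
  *shallowest* split corresponds to the target sister-species divergence
  (`inter_divergence`, default **0.10** p-distance) — deeper pairs
  diverge more, as in real data;
* **within-species genealogies**: random coalescent subtrees grafted onto
  each species tip, root height set to half the Jukes-Cantor time whose
  expected p-distance is `intra_divergence` (default **0.01**), so the
  deepest within-species pair hits the target in expectation;
* **sequences**: a uniform-random root sequence evolved along the grafted
  genealogy under exact Jukes-Cantor transition probabilities (no
  multiple-hit bias), default **650** sites — tree and sequences are
  mutually consistent, and the returned tree is the true genealogy;
* **label injections** that rewrite morphospecies labels only, never the
  truth partition: `CRYPTIC_SPLIT` (two species, one label), `LUMP` (one
  species, two labels), `MISID` (random label swaps), `PROVISIONAL`
  (study specimens of a species get an open-nomenclature name),
  `SHORT_FRAGMENT` (flank masking); plus a `reference_fraction` of
  specimens acting as the EXTERNAL library (described names; a separate
  `provisional_reference_fraction` exercises the provisional-reference
  exclusion).

Defaults — K = 4 species, 5 specimens each, intra 0.01, inter 0.10 (gap
ratio 10) — are the package's fixed study conditions: a clean but not
caricatural barcode gap, the regime in which the surveyed fauna's
well-sampled species typically sit. Calibration is verified empirically:
the realized gap (`max intra < min inter`) holds in ≥ 95 % of seeded
replicates, the mutation process is unbiased against its
genealogy-implied expectations within 15 %, and the shallowest realized
split tracks the inter target within 15 %.

What the generator does **not** emulate: codon structure and selection,
rate variation among sites and lineages, recombination, population
structure, alignment error, and the label noise of real reference
libraries. Passing tests therefore demonstrate algorithmic correctness
under the stated statistical structure, not robustness to every artefact
of real data.

## 8. Numerical and procedural choices

* All stochastic operations take an explicit seed and run through
  `with_seed()`, which restores the caller's RNG state; identical inputs
  and seeds give byte-identical outputs (the pipeline manifest's
  checksums make this checkable).
* Tie-breaks are always deterministic: lexicographic ids in trimming and
  match ordering, smallest index in gap detection, unassigned on
  best-match group ties.
* Undefined distances propagate as `NA` and are rejected exactly where
  the method requires completeness (gap discovery) and skipped where it
  does not (max-within, match lists).
* Problem sizes in the shipped tests (alignments ≤ 12×300 for oracle
  comparisons, 50-replicate recovery suites, 200 null trees at 20 tips,
  pipelines at ≤ 40 specimens) were chosen as the smallest sizes at which
  the checked properties are statistically meaningful.

## 9. Known limitations

* Single-threshold GMYC merges shallow sister pairs (≈ 20 % of replicates
  at the default conditions); a multiple-threshold variant is not
  implemented.
* The BIN proxy is plain single linkage; it will not reproduce BOLD's
  refinement decisions near the threshold.
* Name matching is exact; synonyms and orthographic variants are the
  user's responsibility.
* The gap method's group counts at oversplitting priors are granularity
  artefacts by design; only the plateau inside the gap window estimates
  the species number.
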