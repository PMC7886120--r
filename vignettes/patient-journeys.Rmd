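---
title: "Mining and mapping claims-based patient journeys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and mapping claims-based patient journeys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rulemapper)
```

## The problem

Administrative claims databases record, for every insured patient, a
stream of (patient, ICD-10 diagnosis code, service date) events. For a
disease of interest — the motivating case is major depressive disorder,
ICD-10 category F32 — two questions shape the patient journey: which
combinations of diagnoses tend to precede onset, and which complications
tend to follow it, possibly differently depending on the pre-onset
history. `rulemapper` implements a two-stage analysis of exactly this
design plus a topological summary of the mined rules:

1. **Cohort extraction.** A patient's onset (index date) is their first
   claim in the index category. Pre-onset medical history is the *set* of
   3-character diagnosis categories claimed in the 730 days before the
   index date; post-onset complications are the set claimed in the 730
   days after.
2. **First-stage rule mining.** Pairwise association rules X → Y over
   pre-onset histories, ranked by support.
3. **Stratified second stage.** For a selected pre-onset pair, the cohort
   is restricted to the patients carrying both codes and post-onset rules
   are mined inside that stratum, with the stratum size as the new cohort
   size. Complications whose association exists only in a subgroup
   surface here and are diluted in the pooled analysis.
4. **Mapper graph.** Each surviving rule is a point in the 3-dimensional
   index space (support, confidence, lift); the TDA Mapper construction
   summarizes this point cloud as a graph whose nodes are clusters of
   rules and whose edges mark shared rules.

## Rule indices

For an ordered pair of categories (X, Y) over a cohort of t patients,
write a, b, c, d for the counts of patients with both, X only, Y only,
and neither (a + b + c + d = t). The three indices are

* support = a / t — the fraction of the cohort carrying both codes;
* confidence = a / (a + b) — the conditional frequency of Y given X;
* lift = {a / (a + b)} / {(a + c) / t} — confidence divided by the
  overall frequency of Y, exactly 1 under independence.

Both directions of every frequent pair are evaluated: they share support
but generally differ in confidence and lift. Undefined values (zero
denominators) are signalled as `NA` and never emitted as rules.

Two filters mirror the reporting conventions for this design and are the
package defaults in `rule_filter()`:

* `min_pair_count = 51`: pairs co-occurring in 50 or fewer patients are
  treated as infrequent and dropped;
* `min_confidence = 0.5`: only rules in the upper half of the confidence
  range are reported;
* `top_k = 10` in the pipeline: tables report the top rules by support.

The interpretation of the frequency cut as a *joint* count (a ≥ 51),
applying it before either direction is evaluated, is a design choice of
this package; "occurrences" could in principle also be read as a marginal
count. Reported values stay full precision in the machine-readable
columns of `write_rule_table()`; the presentation columns round to one
decimal on the percent scale, the convention of published rule tables.

Mining uses the Apriori pruning step — a pair is only counted when both
singletons reach the frequency cut — which at pair order is a guarantee,
not a heuristic: a pair can never be more frequent than either member, so
the output provably equals exhaustive enumeration (a property the test
suite checks against a double-loop oracle over randomized matrices).

## Windowing conventions

Windows are half-open and exclude the index date itself: pre =
[index − 730 d, index), post = (index, index + 730 d]. Same-day comorbid
coding at onset is therefore attributed to neither window — the data give
no way to order same-day events, and silently assigning them to history
would manufacture pre-onset signal. The index category itself is excluded
from both code sets. Multiplicity and within-window order are discarded
(sets, not sequences); repeat claims collapse silently. By default no
enrollment-span requirement is imposed (`require_full_windows = FALSE`),
since the cohort size t should count every patient with an index claim;
the option exists because imposing it changes t and hence every support
value.

## The Mapper construction

`run_mapper()` composes six deterministic steps; there is no randomness
anywhere in the chain.

1. **Standardization** (default on). Support and confidence are
   fractions, lift is a ratio around 1; z-scoring each column keeps the
   Euclidean metric from being dominated by whichever column happens to
   spread widest. Raw mode is available.
2. **Distance matrix**: pairwise Euclidean distances.
3. **Filter value**: one real per rule. The default is eccentricity (the
   mean distance from a point to all points), a parameter-free lens that
   orders points from core to periphery; coordinate projection and
   max-variance (first principal component) projection are alternatives.
   No particular filter is canonical for this data; eccentricity is the
   default because it uses the full metric rather than one column.
4. **Cover**: `n_intervals` intervals of equal length
   L = R / (n − (n − 1)·overlap) over the filter range R, consecutive
   intervals overlapping by exactly the fraction `overlap` of L.
   Membership is half-open on the right (last interval closed), so
   overlap = 0 degenerates to an exact partition. Defaults: 5 intervals,
   50% overlap. Two numerical guards matter: the last interval's upper
   edge is clamped to the range maximum (accumulated rounding in
   lo + (n−1)·stride + L can otherwise leave the maximum uncovered by one
   ulp), and a constant filter vector is covered by a single unit-length
   interval.
5. **Per-interval clustering**: single linkage within each interval's
   preimage, cut at the left edge of the first empty bin of a 10-bin
   histogram of merge heights — the classical Mapper heuristic, reading a
   gap in the linkage distances as the within/between-cluster boundary.
   With no empty bin the preimage stays one cluster, as does any preimage
   whose merge heights differ only at rounding-noise scale (relative
   range below 1e-9) — without that guard, equally spaced points shatter
   into singletons because machine noise creates spurious histogram gaps.
6. **Nerve**: one node per cluster, an edge between clusters from
   different intervals sharing at least one rule, weighted by the
   intersection size. Within one interval clusters partition the
   preimage, so same-interval edges cannot exist and are not drawn.

Connected components get deterministic presentation labels (A, B, ...)
ordered by total member count, ties broken by smallest member rule id.
Graphs export to GraphML and DOT with node attributes (size, interval,
mean of each index over members) for coloring in any graph viewer.

A note on the cover parameters: with overlap > 1/2 the stride between
interval starts is less than L/2, so a filter value can lie in more than
two intervals — up to ⌈1/(1 − overlap)⌉. Overlap up to 0.9 is accepted;
the two-interval intuition only holds up to 0.5.

## The synthetic claims generator

The real claims extract behind this design is proprietary, so the
generator is a first-class module rather than a test fixture: it is the
study condition under which every downstream claim is verified. For each
planted rule, X is drawn Bernoulli(p_x) per patient and Y is drawn
Bernoulli(conf) given X, Bernoulli(p_y_base) otherwise, which gives the
closed forms in `expected_indices()`:

* support → p_x · conf,
* confidence → conf,
* lift → conf / (p_x · conf + (1 − p_x) · p_y_base).

Every patient receives exactly one index claim; each present category is
emitted at a uniformly random date strictly inside its window. Dates are
uniform because the analysis discards them once windowing is done — their
distribution only exercises the windowing code. A post-onset rule can be
restricted to a pre-onset stratum (`given_pre`), outside of which X and Y
are independent; this is the ground truth for the stratified stage.

What the generator does *not* emulate: realistic ICD-10 marginal
frequencies, seasonality, enrollment churn, code hierarchies deeper than
the planted pairs, or higher-order dependence among more than two codes.
Passing tests therefore demonstrate that the machinery recovers planted
pairwise structure at realistic cohort sizes — not that any particular
clinical finding would replicate.

## Problem sizes and tolerances in the test suite

Parameter-recovery checks run at cohort size n = 5000 over 20 generator
seeds with the planted pre-onset rule (p_x = 0.4, conf = 0.7,
p_y_base = 0.2): mined support within ±0.03 of 0.28, confidence within
±0.05 of 0.70, lift within ±0.15 of 1.75, allowing one seed in twenty to
fall outside — these bands are a few binomial standard errors at this n.
The stratified check runs at n = 3000 with a stratum of several hundred
patients, where the binomial standard error of the stratified confidence
(≈ 0.015) sits well inside the ±0.05 band. Oracle-equivalence checks use
100 random matrices of up to 200 patients and 12 codes against an
exhaustive double-loop miner, and 1000 random cover configurations verify
coverage and exact consecutive overlap. These sizes keep the full suite
within a few minutes on one CPU while leaving comfortable statistical
margins.

## Known limitations

* Rules are single-antecedent → single-consequent pairs only; the filter
  configuration reserves a hook for higher-order itemsets but none are
  mined.
* No significance testing of rules (no chi-square or p-values): the
  indices are descriptive, as in the underlying design.
* The first F32 claim in the observed data defines onset; with no
  washout period, patients already depressed before data start are
  misclassified as incident.
* One index code per run; no drug, procedure or cost variables; no
  persistent homology — Mapper is the only topological summary.
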