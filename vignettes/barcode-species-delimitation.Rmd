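---
title: "Distance, tree and character based species delimitation from DNA barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance, tree and character based species delimitation from DNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeDelim)
```

## The problem

A DNA barcode survey collects a short standardized marker — for
animals, the 5' fragment of the mitochondrial COI gene, commonly
trimmed to an equal-length frame of around 615 aligned columns — from
many specimens spanning many species. Three families of methods then
assign specimens to species and probe whether the marker delimits
them:

* **distance-based**: pairwise genetic distances; species are
  delimitable when within-species distances stay below
  between-species ones (a positive *barcoding gap*), and an automatic
  gap-discovery procedure partitions the specimens into candidate
  species without a user-supplied threshold;
* **tree-based**: a phenetic tree (neighbor joining on the same
  distances); a species is successfully identified when its specimens
  form a monophyletic group;
* **character-based**: single diagnostic nucleotides — a base fixed
  in every member of a taxon and absent from everything else — which
  identify species without any tree or threshold and can seed
  species-specific assay probes.

`barcodeDelim` implements all three against one shared data model (an
equal-length alignment plus a specimen-to-species/genus/family
table), together with success-rate statistics with binomial
confidence intervals, and a calibrated sequence simulator so the
whole pipeline is testable with known ground truth.

## Distances

Pairwise distances use the Kimura two-parameter (K2P / K80) model,
the standard choice for barcode data. For a pair of sequences, `P`
and `Q` are the proportions of compared sites showing transitions and
transversions, and

$$d = -\tfrac12 \ln\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right].$$

Choices the model leaves open:

* **Pairwise deletion.** Sites where either sequence carries a gap or
  any IUPAC ambiguity code are excluded from that pair only, so `P`
  and `Q` are proportions of the pair's *comparable sites*. The
  per-pair comparable-site count is retained and reported.
* **Saturation.** When `1 - 2P - Q <= 0` or `1 - 2Q <= 0` the log is
  undefined: the pair is flagged saturated and carries `NaN`. Flagged
  pairs are excluded from summary statistics *with a count*, never
  silently — silent exclusion would bias the reported means
  invisibly.
* **Summary conventions.** The intraspecific level pools all
  within-species pairs, the interspecific level all between-species
  pairs; each is summarised by mean, range, sample standard deviation
  (`n - 1` denominator; the convention is not universal, so it is
  stated here) and standard error `SE = SD / sqrt(n_pairs)`. A level
  with no usable pairs is flagged empty rather than zeroed. Table
  outputs print distances to 4 decimals.

The **barcoding gap** is declared positive exactly when the largest
intraspecific distance is below the smallest interspecific one; the
gap range `(max intra, min inter)` is then reported. The histogram
helper bins both levels over the pooled range (default 20 bins) for
the classic two-distribution gap plot.

## Neighbor joining and monophyly

The tree method is standard Saitou–Nei neighbor joining on the K2P
matrix, delegated to `ape::nj()`; the contribution of this package is
the scoring around it, so re-implementing the agglomeration would add
risk without value. Two post-processing decisions:

* **Negative branches** (an occasional NJ artefact) are clamped to
  zero with the deficit pushed onto the edges below the same node, so
  tip-to-tip paths through that node are preserved where possible;
  residual negatives are clamped outright.
* **Bootstrap supports** resample alignment columns with replacement,
  rebuild the NJ tree per replicate (default 1000 replicates, seeded
  and exactly reproducible), and attach to each internal edge of the
  full-data tree the percentage of replicate trees containing that
  bipartition. No consensus tree is built: supports decorate the
  observed tree only. A replicate in which some pair loses all
  comparable sites or saturates is redrawn and counted.

**Monophyly** is assessed on the unrooted tree: a taxon is
monophyletic iff some edge splits exactly its specimens from all
others. This bipartition reading makes the verdict independent of an
arbitrary root; when a real outgroup is available the tree can
instead be rooted on it (outgroup tips are then dropped and clades
read off the rooted tree). Singleton taxa count as monophyletic by
convention — a single specimen cannot contradict itself. Reports
carry both the per-taxon verdicts and the count/percentage summary;
published tables in this literature occasionally print a percentage
inconsistent with its own count (e.g. a genus-level "94.28% (64/70)"
where 64/70 is 91.43%), which is why both are always emitted and
never back-computed from one another.

## Automatic barcode-gap partitioning

The partitioner re-implements the automatic-barcode-gap-discovery
idea at desk scale: it is driven by the ranked pairwise distances
rather than by the original web service's model-based theta limit,
and is validated against the qualitative contract that matters for
surveys — stable group counts across the in-gap range of priors,
recursive counts never below initial ones, exact recovery of planted
partitions.

Given a prior maximum intraspecific divergence `P`:

1. sort all pairwise distances; consider consecutive jumps whose
   upper value exceeds `P`, smallest first;
2. the *local slope* below a jump is the mean of the preceding
   non-zero consecutive spacings (up to a window of 10; a flat run of
   tied distances contributes no spacing, so a tight cluster below a
   jump counts as slope zero; when no spacings exist below, slope is
   zero as well);
3. the first jump strictly wider than `X` times that slope (minimum
   relative gap width, default `X = 1.5`) is the barcode gap; the
   partition threshold is its midpoint;
4. specimens are split into single-linkage connected components under
   `d < threshold`; with no qualifying jump everything stays in one
   group.

The **initial partition** applies this once to the whole matrix. The
**recursive partition** re-runs the search inside every resulting
group on its own sub-matrix, splitting until nothing changes; every
recursive group is a subset of an initial group by construction, and
a locally clean gap can be found even when other groups' distances
fill the same range globally. The procedure is fully deterministic.

The **prior grid** is geometric (log-spaced) with defaults 0.001 to
0.1 in 10 steps, i.e. priors 0.0010, 0.0017, 0.0028, 0.0046, 0.0077,
0.0129, 0.0215, 0.0359, 0.0599, 0.1000 — the conventional sweep for
this method. Because a larger prior only removes candidate jumps, the
initial group count is non-increasing in the prior.

**Concordance** against the morphological species counts groups that
equal exactly one species' specimen set. Published success
percentages for this method do not always state their
numerator/denominator convention, so the raw counts (`n_groups`,
`n_species`, `n_matching_groups`) are reported and any ratio can be
derived; no attempt is made to reverse-engineer a particular printed
figure.

## Diagnostic characters

A diagnostic character for taxon `T` is a pair (alignment column,
base) such that **every** member of `T` carries exactly that base
there and **no** specimen outside `T` can carry it. Only single
positions are considered; compound multi-position diagnostics are out
of scope. Positions are 1-based alignment columns, printed `"G_5"`
style; whether such labels index the trimmed alignment or a longer
amplicon is a real ambiguity in published tables, and this package
fixes the convention to the trimmed alignment frame it was given.

Ambiguity handling is deliberately conservative, so a claimed
diagnostic can never be contradicted by the data at hand:

* a column is ineligible for `T` if any member has a gap or ambiguity
  code there (the taxon is not demonstrably fixed);
* an outside specimen with an ambiguity code whose expansion includes
  the candidate base blocks it (the outsider might carry it).

Two monotonicity properties follow directly and are enforced by
tests: adding specimens to a taxon can only remove its diagnostics
(new members expose polymorphism), and removing other taxa can only
add them (fewer outsiders, weaker exclusion). The second explains the
small-data-set effect seen in barcode surveys: species-level success
ratios rise sharply when diagnosis is restricted to a subset of
species, e.g. one family. `subset_rediagnosis()` reproduces this,
with seeded random subsets. The success ratio at any rank is simply
the percentage of taxa with at least one character.

## Success rates and confidence intervals

An identification method's success rate is `hits / tests` — correct
assignments over queries — kept as an exact ratio and printed as a
percentage to two decimals. Uncertainty uses the Bernoulli
normal-approximation (Wald) interval
`p ± z * sqrt(p(1-p)/n)` with `z = qnorm(1 - alpha/2)` (computed, not
hard-coded, so any level works), clipped to `[0, 1]` since
proportions outside the unit interval are meaningless. The Wald form
is the convention in this literature; its well-known undercoverage
near the boundaries (the interval degenerates to a point at observed
proportions of 0 or 1) is inherited knowingly, and the test suite
asserts empirical coverage against the Wald interval's *own* exact
expectation (by binomial enumeration), not against the nominal level.
Exact (Clopper–Pearson) or Wilson intervals are intentionally not
substituted.

## The simulator and what it does (not) emulate

`simulate_dataset()` produces alignments whose distance structure
matches a real survey: a uniform ancestral sequence; one ancestor per
species; specimens evolved from their species ancestor. Substitutions
follow a per-site independent K80 process parameterised directly in
expected substitutions per site, with closed-form transition/
transversion probabilities at the configured ts/tv ratio — the same
model the distance module inverts, so recovery tests are
self-consistent. Branch lengths are calibrated so the *specimen
level* means hit the targets: species branches get
`(target_inter - target_intra) / 2`, and within-species branches
`target_intra / 2`, making between-species specimen pairs average
`target_inter` once their within-species branches are included.
Species relationships are a star phylogeny by default — sufficient
for distance-structure emulation — with an optional random-coalescent
mode (tree depth rescaled to the same mean divergence) for monophyly
stress tests. Defaults emulate a full survey: 80 species, 2–20
specimens each, 615 columns, intra 0.0046, inter 0.1368, ts/tv 2.

Planted diagnostics overwrite disjoint columns with a base private to
one species (outsiders get the ancestral base), so the diagnostics
scanner has known hits to recover. Note that *unplanted* genuine
diagnostics arise naturally — at moderate interspecific divergence a
species often fixes a base nobody else carries — so recovery tests
assert that all planted characters are found and that everything
reported is confirmed by an exhaustive scan, not that nothing beyond
the planted list appears.

Features of real data deliberately not emulated: indels (the analysis
frame is fixed-length), codon structure and selection, among-site
rate heterogeneity, and shared derived states above the species level
— families in the simulated taxonomy are arbitrary blocks of species,
so family-rank diagnostics on simulated data are expected to be rare
or absent, and family/genus-level results on simulations say nothing
about real higher-rank signal. Passing pipeline tests on simulations
therefore demonstrate internal correctness and calibration, not that
any particular real data set has a gap.

## Numerical and scale choices

* Distances: exact rational `P`, `Q`; the only rounding is in table
  output (4 decimals) and printed percentages (2 decimals).
* Gap detector: slope window 10 spacings; threshold at the jump
  midpoint; ties in distances contribute no slope.
* NJ ties are resolved by `ape::nj`'s deterministic order; tests
  avoid asserting topology on exactly tied inputs, where any
  resolution is legitimate.
* Test and acceptance problem sizes are chosen for desk-scale runs:
  random-instance oracle sweeps use 200 toy alignments and additive
  matrices of 4–8 taxa; parameter-recovery uses eight replicate
  surveys of 12 species (2–12 specimens, 615 columns); the
  acceptance script simulates 20 species with 200 bootstrap
  replicates; the analysis scripts use the full 1000 replicates on
  the same 20-species survey.
* Monte-Carlo assertions fix their seeds; coverage checks run 10,000
  replicates per setting and compare to exact binomial enumeration
  within two Monte-Carlo standard errors.

## Limitations

* The gap partitioner is a faithful-at-desk-scale reading of the
  automatic-gap-discovery idea, not a line-by-line port of the
  original service; group counts on borderline data can differ from
  the web tool even though the qualitative behaviour (in-gap
  stability, initial ≤ recursive) is enforced.
* Monophyly on heavily tied or star-like distance configurations
  depends on arbitrary NJ resolution, as it does in any NJ-based
  workflow.
* Wald intervals are anti-conservative near observed proportions of
  0 or 1; report raw counts alongside, as the report objects do.
* Only NJ is offered for trees: likelihood and Bayesian inference
  belong to dedicated phylogenetics software and are out of scope.
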