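# barcodeDelim

Comparative species delimitation from DNA barcodes, for
biodiversity surveys that sequence a standardized marker (typically
the 5' COI mitochondrial fragment) across many specimens of many
species. The package implements, against one shared data model, the
three method families used to turn such an alignment into species
assignments:

* **Distance-based** — pairwise Kimura two-parameter distances
  `d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]` (P, Q = transition and
  transversion proportions over each pair's comparable sites),
  intra/interspecific summaries, barcoding-gap detection
  (positive iff max intraspecific < min interspecific), and
  automatic barcode-gap partitioning into candidate species: a
  ranked-distance gap detector (first jump above the prior
  intraspecific divergence wider than X times the local slope)
  drives single-linkage splitting, applied once (initial partition)
  or recursively within groups, over a geometric grid of priors.
* **Tree-based** — neighbor joining on the K2P matrix with seeded
  column-bootstrap supports; a species is identified when its
  specimens form a monophyletic group (edge bipartition test on the
  unrooted tree, or clades after outgroup rooting).
* **Character-based** — tree-free single-nucleotide diagnostics: a
  base fixed in every member of a taxon and impossible outside it,
  labelled `G_5` style by 1-based alignment column, with success
  ratios and subset re-diagnosis (fewer taxa can only gain
  characters).

Identification success rates come with Bernoulli (Wald) confidence
intervals `p ± z sqrt(p(1-p)/n)`, and a calibrated K80 simulator
generates multi-species alignments with known ground truth (target
divergences, planted diagnostic sites) so the whole pipeline is
testable without any external data.

## Worked example

Simulate a small survey (6 species, 2–4 specimens each, 615-column
frame, within-species divergence 0.004, between-species 0.12), then
run the three approaches:

```r
library(barcodeDelim)

sim <- simulate_dataset(sim_config(
  n_species = 6, specimens_per_species = c(2, 4), seq_length = 615,
  target_intra = 0.004, target_inter = 0.12, seed = 7
))

dm <- pairwise_matrix(sim$alignment)
s  <- distance_summaries(dm, sim$taxonomy)
print(s$intra)
#> intraspecific distances: mean 0.0040, range 0.0000-0.0115, SD 0.0027, SE 5.013e-04 (n = 30 pairs)
print(s$inter)
#> interspecific distances: mean 0.1278, range 0.1102-0.1434, SD 0.0082, SE 5.808e-04 (n = 201 pairs)
barcoding_gap(s$intra, s$inter)
#> Positive DNA barcoding gap: 0.0115 to 0.1102

tree <- bootstrap_supports(sim$alignment, n_replicates = 100, seed = 1)
monophyly_report(tree, sim$taxonomy, "species")
#> Monophyly at species rank: 6/6 taxa (100.00%)

partition_grid(dm, abgd_config())
#> ABGD partitions over the prior grid:
#>  prior_p n_initial n_recursive
#>  0.00100        20          20
#>  0.00167        14          14
#>  0.00278        14          14
#>  0.00464        11          11
#>  0.00774         6           6
#>  0.01290         6           6
#>  0.02150         6           6
#>  0.03590         6           6
#>  0.05990         6           6
#>  0.10000         6           6

diagnostic_success_ratio(find_diagnostics(sim$alignment, sim$taxonomy, "species"))
#> [1] 100
```

Reading the output: realized divergences sit on their targets
(intraspecific mean 0.0040, interspecific 0.1278); the largest
within-species distance (0.0115) is far below the smallest
between-species one (0.1102), a positive barcoding gap; every
species is monophyletic on the bootstrapped NJ tree; the automatic
partitioner recovers exactly the 6 true species across the whole
in-gap range of priors (0.0077–0.1), splitting identical-sequence
groups only at implausibly small priors; and every species carries
at least one diagnostic nucleotide. `run_all()` assembles the same
numbers, plus Wald intervals, into one comparative report, and
`write_report()` materialises TSV/JSON/Newick artefacts.

The `analysis/` directory holds the same workflow as numbered
scripts (`01_simulate.R` … `06_report.R`), each a thin narrative
driver over these functions that writes its tables under `results/`.

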