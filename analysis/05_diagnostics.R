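#!/usr/bin/env Rscript
# Step 5: character-based identification. Tree-free single-nucleotide
# diagnostic characters at species and family rank, the success
# ratios, and the small-data-set effect: re-diagnosing a random
# subset of species can only gain characters, so its success ratio is
# at least the full-set ratio. Writes diagnostics tables under
# results/diagnostics/.

suppressPackageStartupMessages(library(barcodeDelim))

aln <- read_alignment("results/data/survey.fasta")
tax <- read_taxonomy("results/data/survey_taxonomy.tsv", aln)

diag_sp <- find_diagnostics(aln, tax, "species")
diag_fam <- find_diagnostics(aln, tax, "family")
sub <- subset_rediagnosis(aln, tax, n_taxa = 6L, seed = 17L)

dir.create("results/diagnostics", showWarnings = FALSE, recursive = TRUE)
write_diagnostics_tsv(diag_sp, "results/diagnostics/species.tsv")
write_diagnostics_tsv(diag_fam, "results/diagnostics/family.tsv")
write_diagnostics_tsv(sub, "results/diagnostics/species_subset6.tsv")

print(diag_sp)
print(diag_fam)
cat(sprintf(
  "Random 6-species subset (%s): success ratio %.2f%% (full set %.2f%%)\n",
  paste(attr(sub, "taxon_subset"), collapse = ", "),
  sub$success_ratio, diag_sp$success_ratio
))
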