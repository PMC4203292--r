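#!/usr/bin/env Rscript
# Step 2: pairwise K2P distances, intra/interspecific summaries and
# the barcoding-gap analysis. Writes the pair table, the summary
# table and the gap histogram under results/distances/.

suppressPackageStartupMessages(library(barcodeDelim))

aln <- read_alignment("results/data/survey.fasta")
tax <- read_taxonomy("results/data/survey_taxonomy.tsv", aln)

dm <- pairwise_matrix(aln)
sums <- distance_summaries(dm, tax)
gap <- barcoding_gap(sums$intra, sums$inter)

dir.create("results/distances", showWarnings = FALSE, recursive = TRUE)
write_distance_tsv(dm, "results/distances/pairwise_k2p.tsv", tax)
write_summary_tsv(sums, "results/distances/summaries.tsv")
write.table(
  gap_histogram(dm, tax, 20L), "results/distances/gap_histogram.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)

print(sums$intra)
print(sums$inter)
print(gap)
cat(sprintf("Inter/intra ratio of means: %.2f\n",
            sums$inter$mean / sums$intra$mean))
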