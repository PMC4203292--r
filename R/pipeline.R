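# End-to-end comparison of the three identification approaches on one
# data set: distance-based (barcoding gap + automatic gap
# partitioning), tree-based (NJ monophyly) and character-based
# (diagnostic characters), assembled into one report with Wald
# confidence intervals. The report generator does no arithmetic
# beyond formatting: every number is traceable to one module.

#' Pipeline configuration
#'
#' Defaults pin the standard analysis parameters: 1000 bootstrap
#' replicates, prior grid 0.001-0.1 in 10 geometric steps, minimum
#' relative gap width 1.5, 20 histogram bins, K80 with
#' transition/transversion ratio 2.
#'
#' @param bootstrap_replicates NJ bootstrap replicates.
#' @param seed Seed for the bootstrap resampling.
#' @param abgd An [abgd_config()].
#' @param alpha Significance level for the confidence intervals.
#' @param outgroup Optional outgroup specimen ids for rooting the
#'   monophyly assessment.
#' @param diagnostics_ranks Ranks at which diagnostic characters are
#'   scanned.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(bootstrap_replicates = 1000L, seed = 1L,
                            abgd = abgd_config(), alpha = 0.05,
                            outgroup = NULL,
                            diagnostics_ranks = c("species", "family")) {
  out <- list(
    bootstrap_replicates = as.integer(bootstrap_replicates),
    seed = as.integer(seed), abgd = abgd, alpha = alpha,
    outgroup = outgroup, diagnostics_ranks = diagnostics_ranks
  )
  class(out) <- "pipeline_config"
  out
}

stage_run <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", label, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full comparative analysis
#'
#' Distances and gap report, NJ tree with bootstrap supports and
#' monophyly ratios (species and genus), barcode-gap partitions over
#' the prior grid with concordance against the morphological species,
#' and diagnostic-character success ratios, each ratio with its Wald
#' confidence interval. The headline partition is the initial
#' partition at the first prior attaining the modal group count
#' across the grid (the "stable range" reading of the grid).
#'
#' @param alignment A [barcode_alignment].
#' @param taxonomy A `taxonomy_map`.
#' @param config A [pipeline_config()].
#' @return An object of class `comparative_report`: `rows` (the
#'   Table-style summary data frame) plus all component results
#'   (`distances`, `summaries`, `gap`, `histogram`, `tree`,
#'   `monophyly`, `grid`, `headline_partition`, `concordance`,
#'   `diagnostics`).
#' @export
run_all <- function(alignment, taxonomy, config = pipeline_config()) {
  dm <- stage_run("distances", pairwise_matrix(alignment))
  sums <- stage_run("distances", distance_summaries(dm, taxonomy))
  gap <- stage_run("distances", barcoding_gap(sums$intra, sums$inter))
  hist <- stage_run(
    "distances", gap_histogram(dm, taxonomy, config$abgd$n_bins)
  )
  tree <- stage_run(
    "tree",
    bootstrap_supports(alignment, config$bootstrap_replicates, config$seed)
  )
  mono <- stage_run("tree", list(
    species = monophyly_report(tree, taxonomy, "species", config$outgroup),
    genus = monophyly_report(tree, taxonomy, "genus", config$outgroup)
  ))
  grid <- stage_run("abgd", partition_grid(dm, config$abgd))
  counts <- grid$summary$n_initial
  modal <- as.integer(names(which.max(table(counts))))
  headline <- grid$initial[[which(counts == modal)[1L]]]
  conc <- stage_run("abgd", partition_concordance(headline, taxonomy))
  diags <- stage_run("diagnostics", lapply(
    stats::setNames(config$diagnostics_ranks, config$diagnostics_ranks),
    function(r) find_diagnostics(alignment, taxonomy, r)
  ))
  rows <- list(
    rate_report(
      "monophyly_genus", mono$genus$n_monophyletic,
      mono$genus$n_total, config$alpha
    ),
    rate_report(
      "monophyly_species", mono$species$n_monophyletic,
      mono$species$n_total, config$alpha
    ),
    rate_report(
      "abgd_concordant_groups", conc$n_matching_groups,
      conc$n_groups, config$alpha
    )
  )
  for (r in names(diags)) {
    rows[[length(rows) + 1L]] <- rate_report(
      paste0("diagnostics_", r),
      diags[[r]]$n_taxa_with_diagnostics, diags[[r]]$n_taxa_total,
      config$alpha
    )
  }
  rows_df <- do.call(rbind, lapply(rows, as.data.frame))
  out <- list(
    rows = rows_df, distances = dm, summaries = sums, gap = gap,
    histogram = hist, tree = tree, monophyly = mono, grid = grid,
    headline_partition = headline, concordance = conc,
    diagnostics = diags, config = config
  )
  class(out) <- "comparative_report"
  out
}

#' @export
print.comparative_report <- function(x, ...) {
  cat("Comparative identification report\n")
  print(x$gap)
  cat(sprintf(
    " intra mean %.4f, inter mean %.4f\n",
    x$summaries$intra$mean, x$summaries$inter$mean
  ))
  df <- x$rows
  df$rate_pct <- sprintf("%.2f", df$rate_pct)
  df$ci <- sprintf("[%.2f, %.2f]", df$ci_lower, df$ci_upper)
  print(df[, c("method", "hits", "tests", "rate_pct", "ci")],
        row.names = FALSE)
  invisible(x)
}

#' Write all report artefacts
#'
#' `report.tsv` and `report.json` (summary rows and the distance/gap
#' numbers), the Newick tree, the headline partition and grid
#' summaries, per-rank diagnostics tables and the gap histogram data.
#'
#' @param report A `comparative_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    report$rows, file.path(dir, "report.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(
    list(
      gap = list(
        positive = report$gap$positive,
        max_intra = report$gap$max_intra,
        min_inter = report$gap$min_inter
      ),
      intra = unclass(report$summaries$intra),
      inter = unclass(report$summaries$inter),
      methods = report$rows
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  write_newick(report$tree, file.path(dir, "nj_tree.nwk"))
  write_monophyly_tsv(
    report$monophyly$species, file.path(dir, "monophyly_species.tsv")
  )
  write_monophyly_tsv(
    report$monophyly$genus, file.path(dir, "monophyly_genus.tsv")
  )
  write_grid_tsv(report$grid, file.path(dir, "abgd_grid.tsv"))
  write_partition_tsv(
    report$headline_partition, file.path(dir, "abgd_partition.tsv")
  )
  for (r in names(report$diagnostics)) {
    write_diagnostics_tsv(
      report$diagnostics[[r]],
      file.path(dir, paste0("diagnostics_", r, ".tsv"))
    )
  }
  utils::write.table(
    report$histogram, file.path(dir, "gap_histogram.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}
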