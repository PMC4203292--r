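# Calibrated K80 simulator. Sequences evolve by per-site independent
# substitution under the Kimura two-parameter model, with branch
# "lengths" specified directly in expected substitutions per site, so
# the distances recovered downstream are self-consistent with the
# distance model. Species sit on a star phylogeny by default (enough
# to emulate the intra/inter distance structure of real barcode
# surveys); a random-coalescent mode provides nested structure for
# monophyly stress tests.

# K80 per-site change probabilities after distance d at ts/tv ratio R:
# rates alpha (transition) and beta (each transversion) with
# alpha + 2 beta = d and alpha / (2 beta) = R.
k80_probs <- function(d, ts_tv) {
  beta <- d / (2 * (ts_tv + 1))
  alpha <- d - 2 * beta
  p_ts <- 0.25 + 0.25 * exp(-4 * beta) - 0.5 * exp(-2 * (alpha + beta))
  p_tv_each <- 0.25 - 0.25 * exp(-4 * beta)
  c(ts = p_ts, tv_each = p_tv_each)
}

# evolve an integer-coded sequence (1=A 2=C 3=G 4=T) along a branch
TS_PARTNER <- c(3L, 4L, 1L, 2L) # A<->G, C<->T
TV_1 <- c(2L, 1L, 2L, 1L) # first transversion target (C/A)
TV_2 <- c(4L, 3L, 4L, 3L) # second transversion target (T/G)

evolve_k80 <- function(codes, d, ts_tv) {
  if (d <= 0) return(codes)
  p <- k80_probs(d, ts_tv)
  u <- stats::runif(length(codes))
  out <- codes
  ts <- u < p["ts"]
  tv1 <- !ts & u < p["ts"] + p["tv_each"]
  tv2 <- !ts & !tv1 & u < p["ts"] + 2 * p["tv_each"]
  out[ts] <- TS_PARTNER[codes[ts]]
  out[tv1] <- TV_1[codes[tv1]]
  out[tv2] <- TV_2[codes[tv2]]
  out
}

#' Simulation configuration
#'
#' Defaults emulate a typical multi-species barcode survey: 80
#' species of 2-20 specimens each over a 615-column COI frame, mean
#' within-species K2P divergence about 0.005 and between-species
#' divergence about 0.14, transition/transversion ratio 2.
#'
#' @param n_species Number of species.
#' @param specimens_per_species A single count or a `c(min, max)`
#'   range sampled per species.
#' @param seq_length Alignment columns (default 615).
#' @param target_intra Target mean within-species K2P distance.
#' @param target_inter Target mean between-species K2P distance
#'   (must exceed `target_intra`).
#' @param ts_tv Transition/transversion ratio of the substitution
#'   process.
#' @param n_planted_diagnostics Diagnostic columns planted per
#'   species (private fixed base; 0 to disable).
#' @param structure `"star"` (independent species ancestors) or
#'   `"coalescent"` (random nested species tree).
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 80L,
                       specimens_per_species = c(2L, 20L),
                       seq_length = 615L,
                       target_intra = 0.0046,
                       target_inter = 0.1368,
                       ts_tv = 2,
                       n_planted_diagnostics = 0L,
                       structure = c("star", "coalescent"),
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  structure_mode <- match.arg(structure)
  if (seq_length < 1L) stop("seq_length must be >= 1")
  if (!(target_intra < target_inter)) {
    stop("target_intra must be smaller than target_inter")
  }
  if (n_planted_diagnostics > 0 &&
      n_planted_diagnostics * n_species > seq_length) {
    stop("cannot plant more diagnostic columns than seq_length allows")
  }
  out <- list(
    n_species = as.integer(n_species),
    specimens_per_species = as.integer(specimens_per_species),
    seq_length = as.integer(seq_length),
    target_intra = target_intra, target_inter = target_inter,
    ts_tv = ts_tv,
    n_planted_diagnostics = as.integer(n_planted_diagnostics),
    structure = structure_mode,
    seed = as.integer(seed)
  )
  class(out) <- "sim_config"
  out
}

#' Simulate a multi-species barcode data set with known truth
#'
#' Draws a uniform ancestral sequence, evolves one ancestor per
#' species -- on a star phylogeny with branch
#' `(target_inter - target_intra) / 2` so that specimen-level
#' between-species distances average `target_inter` once the
#' within-species branches are added, or along a scaled random
#' coalescent tree -- then evolves each specimen from its species
#' ancestor with branch `target_intra / 2`. Optionally overwrites
#' disjoint columns with a private fixed base per species so the
#' diagnostics scanner has planted hits to recover. Deterministic
#' given the seed.
#'
#' @param config A [sim_config()].
#' @return List with `alignment` ([barcode_alignment]), `taxonomy`
#'   (`taxonomy_map`; species `sp01`..., one genus per species,
#'   families in blocks of six species) and `truth` (list: the true
#'   `partition`, `planted` diagnostic data frame, realized
#'   `intra_mean` / `inter_mean` as measured by
#'   [distance_summaries()]).
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  K <- config$n_species
  L <- config$seq_length
  spp <- config$specimens_per_species
  n_per <- if (length(spp) == 1L) rep(spp, K) else
    sample(seq(spp[1L], spp[2L]), K, replace = TRUE)
  ancestor <- sample.int(4L, L, replace = TRUE)
  d_sp <- max(0, (config$target_inter - config$target_intra) / 2)
  if (config$structure == "star") {
    species_anc <- lapply(seq_len(K), function(s) {
      evolve_k80(ancestor, d_sp, config$ts_tv)
    })
  } else {
    tr <- ape::rcoal(K, tip.label = paste0("sp", seq_len(K)))
    coph <- ape::cophenetic.phylo(tr)
    scale <- (config$target_inter - config$target_intra) /
      mean(coph[upper.tri(coph)])
    tr$edge.length <- tr$edge.length * scale
    species_anc <- evolve_along_tree(tr, ancestor, config$ts_tv)
    species_anc <- species_anc[paste0("sp", seq_len(K))]
  }
  species <- sprintf("sp%02d", seq_len(K))
  ids <- character(0L)
  rows <- list()
  sp_of <- character(0L)
  for (s in seq_len(K)) {
    for (k in seq_len(n_per[s])) {
      ids <- c(ids, sprintf("%s_%02d", species[s], k))
      rows[[length(rows) + 1L]] <-
        evolve_k80(species_anc[[s]], config$target_intra / 2, config$ts_tv)
      sp_of <- c(sp_of, species[s])
    }
  }
  M <- do.call(rbind, rows)
  # plant private fixed bases on disjoint columns
  planted <- data.frame(
    species = character(0L), position = integer(0L),
    nucleotide = character(0L), stringsAsFactors = FALSE
  )
  if (config$n_planted_diagnostics > 0L) {
    cols <- sample.int(L, K * config$n_planted_diagnostics)
    ci <- 0L
    for (s in seq_len(K)) {
      for (k in seq_len(config$n_planted_diagnostics)) {
        ci <- ci + 1L
        col <- cols[ci]
        x <- ancestor[col] # outsiders get the ancestral base
        y <- TS_PARTNER[x] # members a private transition partner
        M[, col] <- x
        M[sp_of == species[s], col] <- y
        planted <- rbind(planted, data.frame(
          species = species[s], position = col,
          nucleotide = BASES[y], stringsAsFactors = FALSE
        ))
      }
    }
  }
  chars <- matrix(BASES[M], nrow(M), L)
  rownames(chars) <- ids
  alignment <- alignment_from_matrix(chars)
  taxonomy <- taxonomy_map(
    ids,
    species = sp_of,
    genus = paste0("gen_", sp_of),
    family = sprintf("fam%02d", (match(sp_of, species) - 1L) %/% 6L + 1L)
  )
  dm <- pairwise_matrix(alignment)
  sums <- distance_summaries(dm, taxonomy)
  truth <- list(
    partition = split(ids, sp_of),
    planted = planted,
    intra_mean = sums$intra$mean,
    inter_mean = sums$inter$mean
  )
  list(alignment = alignment, taxonomy = taxonomy, truth = truth)
}

# evolve codes down a rooted tree; returns list of tip sequences
# named by tip label
evolve_along_tree <- function(tr, root_codes, ts_tv) {
  n_tip <- length(tr$tip.label)
  seqs <- vector("list", n_tip + tr$Nnode)
  seqs[[n_tip + 1L]] <- root_codes
  ord <- stats::reorder(tr, "cladewise") # parents before children
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1L]
    c <- ord$edge[e, 2L]
    seqs[[c]] <- evolve_k80(seqs[[p]], ord$edge.length[e], ts_tv)
  }
  out <- seqs[seq_len(n_tip)]
  names(out) <- tr$tip.label
  out
}

#' Write a simulated data set to disk
#'
#' FASTA alignment, taxonomy TSV and ground-truth JSON.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @param stem File name stem.
#' @return Invisibly, the three paths.
#' @export
write_simulated <- function(sim, dir, stem = "simulated") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(stem, ".fasta"))
  tsv <- file.path(dir, paste0(stem, "_taxonomy.tsv"))
  js <- file.path(dir, paste0(stem, "_truth.json"))
  write_alignment(sim$alignment, fa)
  write_taxonomy(sim$taxonomy, tsv)
  jsonlite::write_json(sim$truth, js, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, taxonomy = tsv, truth = js))
}

#' Deterministic built-in fixture data sets
#'
#' Small named data sets used throughout the test suites, each
#' constructed to exhibit one behaviour:
#' \describe{
#'   \item{two_clusters}{two well-separated species; positive
#'     barcoding gap, two barcode-gap groups, 100\% monophyly.}
#'   \item{no_gap}{within-species divergence overlaps
#'     between-species divergence; no positive gap.}
#'   \item{intermixed_species}{one species' specimens sit in two
#'     distant clusters; species monophyly below 100\%.}
#'   \item{subset_effect}{a species with no diagnostic character in
#'     the full set gains one when diagnosis is restricted to its own
#'     family.}
#' }
#'
#' @return Named list; each element has `alignment` and `taxonomy`.
#' @export
fixture_library <- function() {
  list(
    two_clusters = fixture_two_clusters(),
    no_gap = fixture_no_gap(),
    intermixed_species = fixture_intermixed(),
    subset_effect = fixture_subset_effect()
  )
}

# helper: sequence string from a base template with substitutions at
# given positions
subst <- function(template, at, base) {
  s <- strsplit(template, "")[[1L]]
  s[at] <- base
  paste(s, collapse = "")
}

fixture_two_clusters <- function() {
  # 2 species x 3 specimens, 120 columns; ~1 within-species change,
  # ~24 between-species changes
  base <- paste(rep(c("A", "C", "G", "T"), 30L), collapse = "")
  sp2_base <- subst(base, seq(1L, 96L, by = 4L), "G") # 24 A->G transitions
  aln <- barcode_alignment(
    c("a1", "a2", "a3", "b1", "b2", "b3"),
    c(
      base,
      subst(base, 2L, "T"), # one C->T transition
      subst(base, 10L, "T"),
      sp2_base,
      subst(sp2_base, 14L, "T"),
      subst(sp2_base, 22L, "T")
    )
  )
  tax <- taxonomy_map(
    aln$ids,
    species = rep(c("spA", "spB"), each = 3L),
    genus = rep(c("genA", "genB"), each = 3L),
    family = rep(c("famA", "famB"), each = 3L)
  )
  list(alignment = aln, taxonomy = tax)
}

fixture_no_gap <- function() {
  # intra divergence of spA (12 changes) exceeds the spA-spB
  # divergence (3 changes): no positive gap
  base <- paste(rep(c("A", "C", "G", "T"), 25L), collapse = "")
  a2 <- subst(base, seq(1L, 48L, by = 4L), "G") # 12 transitions
  b1 <- subst(base, c(50L, 54L, 58L), "T")
  aln <- barcode_alignment(
    c("a1", "a2", "b1", "b2"),
    c(base, a2, b1, b1)
  )
  tax <- taxonomy_map(
    aln$ids,
    species = rep(c("spA", "spB"), each = 2L),
    genus = rep(c("genA", "genB"), each = 2L),
    family = "famX"
  )
  list(alignment = aln, taxonomy = tax)
}

fixture_intermixed <- function() {
  # two distant clusters; spA has one specimen in each, so no edge
  # separates exactly {a1, a2}
  base <- paste(rep(c("A", "C", "G", "T"), 25L), collapse = "")
  far <- subst(base, seq(1L, 80L, by = 4L), "G") # 20 transitions away
  b_shared <- subst(base, 6L, "T")
  c_shared <- subst(far, 14L, "T")
  aln <- barcode_alignment(
    c("a1", "b1", "b2", "a2", "c1", "c2"),
    c(
      base, b_shared, subst(b_shared, 30L, "T"),
      far, c_shared, subst(c_shared, 18L, "T")
    )
  )
  tax <- taxonomy_map(
    aln$ids,
    species = c("spA", "spB", "spB", "spA", "spC", "spC"),
    genus = c("genA", "genB", "genB", "genA", "genC", "genC"),
    family = "famX"
  )
  list(alignment = aln, taxonomy = tax)
}

fixture_subset_effect <- function() {
  # spS1's only private-looking base (G at column 5) is shared with
  # spS3 in the other family, so spS1 has no diagnostic in the full
  # set but gains G_5 within family famF1
  base <- paste(rep("A", 40L), collapse = "")
  s1 <- subst(base, 5L, "G")
  s2 <- subst(base, 10L, "C")
  s3 <- subst(subst(base, 5L, "G"), 15L, "C")
  s4 <- subst(base, 20L, "C")
  aln <- barcode_alignment(
    c("s1a", "s1b", "s2a", "s2b", "s3a", "s3b", "s4a", "s4b"),
    c(s1, s1, s2, s2, s3, s3, s4, s4)
  )
  tax <- taxonomy_map(
    aln$ids,
    species = rep(c("spS1", "spS2", "spS3", "spS4"), each = 2L),
    genus = rep(c("genS1", "genS2", "genS3", "genS4"), each = 2L),
    family = rep(c("famF1", "famF1", "famF2", "famF2"), each = 2L)
  )
  list(alignment = aln, taxonomy = tax)
}
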