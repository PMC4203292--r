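# Tree-free single-nucleotide diagnostic characters. A (position,
# base) pair is diagnostic for a taxon when every member of the taxon
# carries exactly that base at that column and no specimen outside the
# taxon can carry it. Handling is conservative: a column is ineligible
# for a taxon if any member has a gap or ambiguity code there, and an
# outsider with an ambiguity code whose expansion includes the base
# blocks it. Only single positions are considered; compound
# (multi-position) diagnostics are out of scope.

# which alphabet characters can stand for each base
carriers_of <- function(base) {
  names(IUPAC)[vapply(IUPAC, function(x) grepl(base, x, fixed = TRUE),
                      logical(1L))]
}

#' Find single-nucleotide diagnostic characters
#'
#' Scans every alignment column for bases fixed within a taxon and
#' absent (even as an ambiguity-code possibility) outside it, at
#' species, genus or family rank. Positions are reported 1-based on
#' the alignment columns, labelled `"G_5"` style (base, underscore,
#' position).
#'
#' @param alignment A [barcode_alignment].
#' @param taxonomy A `taxonomy_map` covering the alignment.
#' @param rank `"species"`, `"genus"` or `"family"`.
#' @return An object of class `diagnostic_set`: per-taxon character
#'   lists (`taxa`, alphabetical; characters by position), a
#'   Table-style summary data frame (`table`), and the success ratio
#'   (percentage of taxa with at least one diagnostic character).
#' @export
find_diagnostics <- function(alignment, taxonomy,
                             rank = c("species", "genus", "family")) {
  rank <- match.arg(rank)
  groups <- taxon_groups(taxonomy, rank)
  if (length(groups) < 2L) {
    stop("diagnosis is relative: need at least two taxa at rank '",
         rank, "'")
  }
  M <- seq_matrix(alignment)
  L <- ncol(M)
  # per-base: how many specimens could carry that base at each column
  totals <- lapply(BASES, function(b) {
    carr <- matrix(M %in% carriers_of(b), nrow(M), L)
    colSums(carr)
  })
  names(totals) <- BASES
  taxa <- lapply(groups, function(ids) {
    idx <- match(ids, alignment$ids)
    sub <- M[idx, , drop = FALSE]
    f <- sub[1L, ]
    fixed <- colSums(sub != matrix(f, nrow(sub), L, byrow = TRUE)) == 0L
    res <- lapply(BASES, function(b) {
      which(fixed & f == b & totals[[b]] == length(idx))
    })
    pos <- sort(unlist(res, use.names = FALSE))
    data.frame(
      position = pos,
      nucleotide = f[pos],
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  })
  n_with <- sum(vapply(taxa, nrow, integer(1L)) > 0L)
  fam <- if (rank == "species") {
    vapply(groups, function(ids) {
      taxonomy$family[match(ids[1L], taxonomy$specimen_id)]
    }, character(1L))
  } else {
    rep(NA_character_, length(groups))
  }
  tab <- data.frame(
    taxon = names(groups),
    family = fam,
    diagnostic_characters = vapply(taxa, function(df) {
      paste(diag_label(df$position, df$nucleotide), collapse = " ")
    }, character(1L)),
    n_characters = vapply(taxa, nrow, integer(1L)),
    n_individuals = lengths(groups),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(
    list(
      rank = rank, taxa = taxa, table = tab,
      n_taxa_with_diagnostics = n_with, n_taxa_total = length(groups),
      success_ratio = 100 * n_with / length(groups)
    ),
    class = "diagnostic_set"
  )
}

#' @export
print.diagnostic_set <- function(x, ...) {
  cat(sprintf(
    "Diagnostic characters at %s rank: %d/%d taxa (%.2f%%)\n",
    x$rank, x$n_taxa_with_diagnostics, x$n_taxa_total, x$success_ratio
  ))
  with_chars <- x$table[x$table$n_characters > 0L, c(1L, 3L, 4L)]
  if (nrow(with_chars) > 0L) print(with_chars, row.names = FALSE)
  invisible(x)
}

#' Diagnostic character labels
#'
#' `"N_pos"` string form of a diagnostic character, e.g. `"G_5"` for
#' base G at (1-based) alignment column 5, and its inverse.
#'
#' @param position Integer vector of 1-based positions.
#' @param nucleotide Character vector of bases.
#' @return `diag_label()` a character vector; `parse_diag_label()` a
#'   data frame with `position` and `nucleotide`.
#' @export
diag_label <- function(position, nucleotide) {
  if (length(position) == 0L) return(character(0L))
  paste0(nucleotide, "_", position)
}

#' @rdname diag_label
#' @param label Character vector of `"N_pos"` labels.
#' @export
parse_diag_label <- function(label) {
  ok <- grepl("^[ACGT]_[0-9]+$", label)
  if (!all(ok)) {
    stop("malformed diagnostic label(s): ", paste(label[!ok], collapse = ", "))
  }
  data.frame(
    position = as.integer(sub("^[ACGT]_", "", label)),
    nucleotide = sub("_.*$", "", label),
    stringsAsFactors = FALSE
  )
}

#' Diagnostic success ratio
#'
#' The percentage of taxa having at least one diagnostic character.
#'
#' @param diagset A `diagnostic_set`.
#' @return Numeric percentage.
#' @export
diagnostic_success_ratio <- function(diagset) {
  if (diagset$n_taxa_total < 1L) stop("no taxa in diagnostic set")
  100 * diagset$n_taxa_with_diagnostics / diagset$n_taxa_total
}

#' Re-run diagnosis on a subset of taxa
#'
#' Restricts the data set to the chosen taxa (or a reproducible random
#' selection of `n_taxa` of them) and re-runs [find_diagnostics()].
#' With fewer outside taxa the exclusion constraint weakens, so
#' characters can only be gained, never lost -- the mechanism behind
#' the higher success ratios seen on small data sets.
#'
#' @param alignment A [barcode_alignment].
#' @param taxonomy A `taxonomy_map`.
#' @param taxon_subset Character vector of taxa to keep (at `rank`).
#'   Ignored when `n_taxa` is given.
#' @param n_taxa Draw this many taxa at random instead.
#' @param seed Integer seed for the random draw.
#' @param rank Rank of the taxa being diagnosed.
#' @return A `diagnostic_set` for the restricted data set, with the
#'   selection stored in attribute `taxon_subset`.
#' @export
subset_rediagnosis <- function(alignment, taxonomy, taxon_subset = NULL,
                               n_taxa = NULL, seed = 1L,
                               rank = c("species", "genus", "family")) {
  rank <- match.arg(rank)
  all_taxa <- sort(unique(taxonomy[[rank]]))
  if (!is.null(n_taxa)) {
    if (n_taxa < 1L || n_taxa > length(all_taxa)) {
      stop("n_taxa must be between 1 and the number of taxa")
    }
    set.seed(seed)
    taxon_subset <- sort(sample(all_taxa, n_taxa))
  }
  if (is.null(taxon_subset) || length(taxon_subset) == 0L) {
    stop("empty taxon subset")
  }
  unknown <- setdiff(taxon_subset, all_taxa)
  if (length(unknown) > 0L) {
    stop("taxa not present in taxonomy: ", paste(unknown, collapse = ", "))
  }
  keep <- taxonomy$specimen_id[taxonomy[[rank]] %in% taxon_subset]
  sub <- restrict_dataset(alignment, taxonomy, keep)
  out <- find_diagnostics(sub$alignment, sub$taxonomy, rank)
  attr(out, "taxon_subset") <- taxon_subset
  out
}

#' Probe sequences around diagnostic sites
#'
#' Extracts, for each diagnostic character, the taxon-consensus
#' alignment window of `flank` columns either side of the site --
#' candidate capture probes for species-specific assays.
#'
#' @param alignment A [barcode_alignment].
#' @param diagset A `diagnostic_set` computed from it.
#' @param taxonomy The `taxonomy_map` used for the diagnosis.
#' @param flank Columns of context either side of the site.
#' @return Data frame with `taxon`, `label`, `start`, `end`, `probe`
#'   (the window of the taxon's first member; members are fixed at the
#'   site itself).
#' @export
probe_sequences <- function(alignment, diagset, taxonomy, flank = 10L) {
  M <- seq_matrix(alignment)
  groups <- taxon_groups(taxonomy, diagset$rank)
  rows <- list()
  for (taxon in names(diagset$taxa)) {
    df <- diagset$taxa[[taxon]]
    if (nrow(df) == 0L) next
    member <- match(groups[[taxon]][1L], alignment$ids)
    for (k in seq_len(nrow(df))) {
      pos <- df$position[k]
      lo <- max(1L, pos - flank)
      hi <- min(alignment$length, pos + flank)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = taxon,
        label = diag_label(pos, df$nucleotide[k]),
        start = lo, end = hi,
        probe = paste(M[member, lo:hi], collapse = ""),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Write a diagnostic set to TSV
#'
#' Mirrors the usual presentation: taxon, family, space-separated
#' `N_pos` character labels, number of characters, number of
#' individuals.
#'
#' @param diagset A `diagnostic_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_diagnostics_tsv <- function(diagset, path) {
  utils::write.table(
    diagset$table, path, sep = "\t", quote = FALSE, row.names = FALSE,
    na = ""
  )
  invisible(path)
}
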