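# Shared data model: an equal-length barcode alignment and the
# specimen -> (species, genus, family) taxonomy that every downstream
# analysis consumes. No other module parses files.

# IUPAC nucleotide codes and the bases each one can stand for.
IUPAC <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)
ALPHABET <- c(names(IUPAC), "-")
BASES <- c("A", "C", "G", "T")

#' Construct a barcode alignment
#'
#' A `barcode_alignment` holds equal-length aligned sequences keyed by
#' unique specimen identifiers. Alignment columns are the coordinate
#' frame for every position-based result downstream (diagnostic
#' character labels are 1-based column numbers).
#'
#' @param ids Character vector of unique specimen identifiers.
#' @param sequences Character vector of aligned sequences (IUPAC codes
#'   and `-` for gaps), one per specimen, all the same length. Stored
#'   uppercase; input case is ignored.
#' @return An object of class `barcode_alignment` with elements `ids`,
#'   `sequences` (named by `ids`) and `length` (number of columns).
#' @examples
#' aln <- barcode_alignment(c("s1", "s2"), c("ACGT", "ACGA"))
#' aln$length
#' @export
barcode_alignment <- function(ids, sequences) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences)) {
    stop("'ids' and 'sequences' must have the same length")
  }
  if (length(ids) == 0L) stop("alignment must contain at least one record")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate specimen ids: ", paste(unique(dup), collapse = ", "))
  }
  lens <- nchar(sequences)
  if (any(lens < 1L)) stop("alignment length must be >= 1")
  if (length(unique(lens)) > 1L) {
    expected <- as.integer(names(which.max(table(lens))))
    bad <- ids[lens != expected]
    stop(
      "unequal sequence lengths: expected ", expected,
      " columns but record(s) ", paste(bad, collapse = ", "),
      " differ (", paste(lens[lens != expected], collapse = ", "), ")"
    )
  }
  chars <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  bad_chars <- setdiff(chars, ALPHABET)
  if (length(bad_chars) > 0L) {
    stop(
      "characters outside the IUPAC+gap alphabet: ",
      paste(bad_chars, collapse = ", ")
    )
  }
  names(sequences) <- ids
  structure(
    list(ids = ids, sequences = sequences, length = unname(lens[1L])),
    class = "barcode_alignment"
  )
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat(
    "Barcode alignment: ", length(x$ids), " sequences x ",
    x$length, " columns\n", sep = ""
  )
  show <- utils::head(x$ids, 5L)
  cat(" specimens: ", paste(show, collapse = ", "),
      if (length(x$ids) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# alignment as a specimens x columns character matrix
seq_matrix <- function(alignment) {
  m <- matrix(
    unlist(strsplit(alignment$sequences, ""), use.names = FALSE),
    nrow = length(alignment$ids), ncol = alignment$length, byrow = TRUE
  )
  rownames(m) <- alignment$ids
  m
}

# integer coding A=1 C=2 G=3 T=4, NA for gaps/ambiguities (pairwise
# deletion downstream)
code_matrix <- function(alignment) {
  m <- seq_matrix(alignment)
  x <- match(m, BASES)
  dim(x) <- dim(m)
  rownames(x) <- alignment$ids
  x
}

# rebuild an alignment from a character matrix (rows named by specimen)
alignment_from_matrix <- function(m) {
  barcode_alignment(rownames(m), apply(m, 1L, paste, collapse = ""))
}

#' Read a FASTA barcode alignment
#'
#' Reads an aligned FASTA file and validates it: sequences must be of
#' equal length, specimen ids unique, and all characters IUPAC codes or
#' gaps. Lowercase input is accepted and stored uppercase.
#'
#' @param path Path to a FASTA file of pre-aligned sequences.
#' @return A [barcode_alignment].
#' @seealso [write_alignment()], [read_taxonomy()]
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no FASTA records in ", path)
  seqs <- vapply(
    as.character(dna),
    function(s) paste(toupper(s), collapse = ""),
    character(1L)
  )
  barcode_alignment(names(dna), unname(seqs))
}

#' Write a barcode alignment to FASTA
#'
#' Sequences are written uppercase, wrapped at 70 columns. Reading the
#' file back with [read_alignment()] reproduces the alignment exactly.
#'
#' @param alignment A [barcode_alignment].
#' @param path Output file path.
#' @param width Line-wrap width (columns per line).
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(alignment, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(alignment$ids)) {
    writeLines(paste0(">", alignment$ids[i]), con)
    s <- alignment$sequences[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a taxonomy map
#'
#' Maps each specimen to its morphological species, genus and family.
#' These assignments define the intra/interspecific distance partition,
#' the monophyly targets and the reference partition that automatic
#' delimitation is compared against.
#'
#' @param specimen_id,species,genus,family Character vectors of equal
#'   length, one entry per specimen.
#' @return A data frame of class `taxonomy_map`.
#' @export
taxonomy_map <- function(specimen_id, species, genus = NA_character_,
                         family = NA_character_) {
  specimen_id <- as.character(specimen_id)
  if (anyDuplicated(specimen_id)) {
    stop(
      "duplicate specimen ids in taxonomy: ",
      paste(unique(specimen_id[duplicated(specimen_id)]), collapse = ", ")
    )
  }
  species <- as.character(species)
  if (any(is.na(species) | !nzchar(species))) {
    stop("species names must be non-empty for every specimen")
  }
  out <- data.frame(
    specimen_id = specimen_id,
    species = species,
    genus = rep_len(as.character(genus), length(specimen_id)),
    family = rep_len(as.character(family), length(specimen_id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

#' Read a specimen taxonomy table
#'
#' Reads a UTF-8 tab-separated table with header columns
#' `specimen_id`, `species`, `genus`, `family` and checks it against an
#' alignment: every alignment specimen must appear exactly once;
#' table rows for specimens absent from the alignment are dropped with
#' a warning. Rows are returned in alignment order.
#'
#' @param path Path to the TSV file.
#' @param alignment The [barcode_alignment] the table must cover.
#' @return A `taxonomy_map` data frame with one row per alignment
#'   specimen, in alignment order.
#' @export
read_taxonomy <- function(path, alignment) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(
    path, sep = "\t", header = TRUE, quote = "",
    colClasses = "character", check.names = TRUE,
    fileEncoding = "UTF-8"
  )
  need <- c("specimen_id", "species", "genus", "family")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("taxonomy table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(tab$specimen_id, alignment$ids)
  if (length(extra) > 0L) {
    warning(
      "taxonomy rows for specimens absent from the alignment dropped: ",
      paste(extra, collapse = ", ")
    )
    tab <- tab[!tab$specimen_id %in% extra, , drop = FALSE]
  }
  missing_ids <- setdiff(alignment$ids, tab$specimen_id)
  if (length(missing_ids) > 0L) {
    stop(
      "alignment specimens missing from taxonomy table: ",
      paste(missing_ids, collapse = ", ")
    )
  }
  tab <- tab[match(alignment$ids, tab$specimen_id), , drop = FALSE]
  rownames(tab) <- NULL
  taxonomy_map(tab$specimen_id, tab$species, tab$genus, tab$family)
}

#' Write a taxonomy table to TSV
#'
#' @param taxonomy A `taxonomy_map`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(
    as.data.frame(taxonomy), path,
    sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Derive taxonomy from pipe-delimited FASTA headers
#'
#' Fallback header dialect for sequence files that carry their own
#' taxonomy: `specimenID|species|genus|family`. The alignment ids are
#' stripped back to the bare specimen id and a matching taxonomy map is
#' built.
#'
#' @param alignment A [barcode_alignment] whose ids follow the
#'   four-field pipe dialect.
#' @return A list with elements `alignment` (ids stripped) and
#'   `taxonomy` (a `taxonomy_map`).
#' @export
taxonomy_from_headers <- function(alignment) {
  parts <- strsplit(alignment$ids, "|", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields != 4L)) {
    stop(
      "header(s) not in 'specimenID|species|genus|family' form: ",
      paste(alignment$ids[n_fields != 4L], collapse = ", ")
    )
  }
  m <- do.call(rbind, parts)
  aln <- barcode_alignment(m[, 1L], unname(alignment$sequences))
  list(
    alignment = aln,
    taxonomy = taxonomy_map(m[, 1L], m[, 2L], m[, 3L], m[, 4L])
  )
}

# specimen ids grouped by taxon at a rank, alphabetical taxon order
taxon_groups <- function(taxonomy, rank = c("species", "genus", "family")) {
  rank <- match.arg(rank)
  vals <- taxonomy[[rank]]
  if (any(is.na(vals))) {
    stop("taxonomy has missing values at rank '", rank, "'")
  }
  g <- split(taxonomy$specimen_id, vals)
  g[order(names(g))]
}

# restrict alignment + taxonomy to a set of specimen ids (kept in
# alignment order)
restrict_dataset <- function(alignment, taxonomy, ids) {
  keep <- alignment$ids %in% ids
  if (!any(keep)) stop("no specimens left after restriction")
  aln <- barcode_alignment(
    alignment$ids[keep],
    unname(alignment$sequences[keep])
  )
  tax <- taxonomy[match(aln$ids, taxonomy$specimen_id), , drop = FALSE]
  rownames(tax) <- NULL
  class(tax) <- c("taxonomy_map", "data.frame")
  list(alignment = aln, taxonomy = tax)
}
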