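# Tree-based identification: neighbor-joining on the K2P matrix,
# nonparametric bootstrap supports on the full-data tree's
# bipartitions, and per-taxon monophyly scoring.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()]) on the K2P
#' matrix. Negative branch lengths, an occasional NJ artefact, are
#' clamped to zero with the deficit transferred to the adjacent edges
#' below so that path lengths through the node are preserved where
#' possible; any residue is clamped.
#'
#' @param dm A `k2p_dist` (or plain symmetric matrix) of finite
#'   distances.
#' @return An unrooted `phylo` tree whose tip labels are the specimen
#'   ids.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "k2p_dist")) dm$d else as.matrix(dm)
  off <- d[upper.tri(d)]
  if (any(!is.finite(off))) {
    stop(
      "distance matrix contains saturated/undefined entries; ",
      "exclude those specimens before tree building"
    )
  }
  if (nrow(d) < 2L) stop("need at least two taxa")
  if (nrow(d) == 2L) {
    # single edge of the pairwise distance
    tr <- structure(
      list(
        edge = matrix(c(3L, 3L, 1L, 2L), 2L, 2L),
        edge.length = c(d[1L, 2L] / 2, d[1L, 2L] / 2),
        tip.label = rownames(d), Nnode = 1L
      ),
      class = "phylo", order = "cladewise"
    )
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  clamp_negative_edges(tr)
}

# clamp negative branch lengths to zero, pushing the deficit onto the
# edges descending from the same node (preserves tip-to-tip paths
# through that node); terminal negatives are clamped outright
clamp_negative_edges <- function(tr) {
  len <- tr$edge.length
  for (e in which(len < 0)) {
    child <- tr$edge[e, 2L]
    below <- which(tr$edge[, 1L] == child)
    if (length(below) > 0L) len[below] <- len[below] + len[e]
    len[e] <- 0
  }
  len[len < 0] <- 0
  tr$edge.length <- len
  tr
}

#' Bootstrap supports for the NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree
#' per replicate, and attaches to each internal edge of the full-data
#' tree the percentage of replicate trees containing that bipartition
#' (no consensus tree is built). Replicates in which some pair has no
#' comparable sites or is saturated are redrawn and counted.
#'
#' @param alignment A [barcode_alignment].
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the same seed reproduces the supports
#'   exactly.
#' @return The full-data `phylo` tree with integer percentage supports
#'   in `node.label` and attributes `n_replicates` and `n_redrawn`.
#' @export
bootstrap_supports <- function(alignment, n_replicates = 1000L, seed = 1L) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  X <- code_matrix(alignment)
  full <- nj_tree(distance_from_codes(X, alignment$ids))
  set.seed(seed)
  L <- ncol(X)
  reps <- vector("list", n_replicates)
  n_redrawn <- 0L
  for (r in seq_len(n_replicates)) {
    for (attempt in seq_len(100L)) {
      cols <- sample.int(L, L, replace = TRUE)
      d <- k2p_components(X[, cols, drop = FALSE])$d
      if (all(is.finite(d[upper.tri(d)]))) break
      n_redrawn <- n_redrawn + 1L
      if (attempt == 100L) {
        stop("could not draw a bootstrap replicate with all pairs comparable")
      }
    }
    rownames(d) <- colnames(d) <- alignment$ids
    reps[[r]] <- nj_tree(distance_matrix(d))
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  full$node.label <- as.character(round(100 * counts / n_replicates))
  attr(full, "n_replicates") <- n_replicates
  attr(full, "n_redrawn") <- n_redrawn
  full
}

distance_from_codes <- function(X, ids) {
  d <- k2p_components(X)$d
  rownames(d) <- colnames(d) <- ids
  distance_matrix(d)
}

# leaf-index sets of every edge-induced bipartition (one side each);
# includes trivial tip splits
tree_splits <- function(tr) {
  n_tip <- length(tr$tip.label)
  desc <- vector("list", n_tip + tr$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  # edges in postorder so children resolve before parents
  ord <- stats::reorder(tr, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1L]
    c <- ord$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  lapply(seq_len(nrow(tr$edge)), function(e) sort(desc[[tr$edge[e, 2L]]]))
}

#' Per-taxon monophyly report
#'
#' A taxon is monophyletic on the unrooted tree when some edge splits
#' exactly its specimens from everything else (a bipartition test, so
#' the verdict does not depend on an arbitrary rooting). When an
#' outgroup is supplied the tree is rooted on it first, the outgroup
#' tips are dropped, and clades are read off the rooted tree.
#' Singleton taxa count as monophyletic.
#'
#' @param tree A `phylo` tree whose tips are specimen ids.
#' @param taxonomy A `taxonomy_map` covering the tips.
#' @param rank `"species"` or `"genus"`.
#' @param outgroup Optional character vector of outgroup specimen ids.
#' @return A list of class `monophyly_report` with a per-taxon data
#'   frame (`taxa`), `n_monophyletic`, `n_total` and `ratio` (percent).
#' @export
monophyly_report <- function(tree, taxonomy,
                             rank = c("species", "genus"),
                             outgroup = NULL) {
  rank <- match.arg(rank)
  rooted <- !is.null(outgroup)
  if (rooted) {
    if (!all(outgroup %in% tree$tip.label)) {
      stop("outgroup ids not all present in the tree")
    }
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
    tree <- ape::drop.tip(tree, outgroup)
    taxonomy <- taxonomy[!taxonomy$specimen_id %in% outgroup, , drop = FALSE]
  }
  tips <- tree$tip.label
  missing <- setdiff(tips, taxonomy$specimen_id)
  if (length(missing) > 0L) {
    stop("tree tips missing from taxonomy: ", paste(missing, collapse = ", "))
  }
  taxonomy <- taxonomy[taxonomy$specimen_id %in% tips, , drop = FALSE]
  groups <- split(
    match(taxonomy$specimen_id, tips), taxonomy[[rank]]
  )
  groups <- groups[order(names(groups))]
  splits <- tree_splits(tree)
  keys <- vapply(splits, paste, character(1L), collapse = ",")
  n_tip <- length(tips)
  all_idx <- seq_len(n_tip)
  is_mono <- vapply(groups, function(g) {
    g <- sort(g)
    if (length(g) <= 1L || length(g) == n_tip) return(TRUE)
    key <- paste(g, collapse = ",")
    comp <- paste(setdiff(all_idx, g), collapse = ",")
    (key %in% keys) || (!rooted && comp %in% keys)
  }, logical(1L))
  taxa <- data.frame(
    taxon = names(groups),
    rank = rank,
    n_specimens = lengths(groups),
    monophyletic = unname(is_mono),
    stringsAsFactors = FALSE
  )
  rownames(taxa) <- NULL
  structure(
    list(
      rank = rank, taxa = taxa,
      n_monophyletic = sum(is_mono), n_total = length(groups),
      ratio = 100 * sum(is_mono) / length(groups)
    ),
    class = "monophyly_report"
  )
}

#' @export
print.monophyly_report <- function(x, ...) {
  cat(sprintf(
    "Monophyly at %s rank: %d/%d taxa (%.2f%%)\n",
    x$rank, x$n_monophyletic, x$n_total, x$ratio
  ))
  bad <- x$taxa$taxon[!x$taxa$monophyletic]
  if (length(bad) > 0L) {
    cat(" non-monophyletic: ", paste(bad, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` tree (supports, if present, travel as node
#'   labels).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a monophyly report to TSV
#'
#' @param report A `monophyly_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_monophyly_tsv <- function(report, path) {
  out <- report$taxa
  out$monophyletic <- ifelse(out$monophyletic, "yes", "no")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
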