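# Independent oracles and small random-instance generators used across
# the suites. These deliberately re-derive results by the dumbest
# possible route (exhaustive scans, closed forms, enumeration) and
# never call the code paths they check.

IUPAC_EXPAND <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT", "-" = ""
)

# exhaustive (column x taxon x base) diagnostic scan
brute_force_diagnostics <- function(alignment, taxonomy, rank) {
  m <- do.call(rbind, strsplit(unname(alignment$sequences), ""))
  rownames(m) <- alignment$ids
  groups <- split(taxonomy$specimen_id, taxonomy[[rank]])
  groups <- groups[order(names(groups))]
  out <- lapply(groups, function(ids) {
    res <- list()
    outsiders <- setdiff(alignment$ids, ids)
    for (col in seq_len(ncol(m))) {
      member_chars <- unique(m[ids, col])
      if (length(member_chars) != 1L) next
      b <- member_chars
      if (!b %in% c("A", "C", "G", "T")) next
      blocked <- FALSE
      for (o in outsiders) {
        if (grepl(b, IUPAC_EXPAND[[m[o, col]]], fixed = TRUE)) {
          blocked <- TRUE
          break
        }
      }
      if (!blocked) res[[length(res) + 1L]] <- c(col, b)
    }
    if (length(res) == 0L) {
      data.frame(position = integer(0L), nucleotide = character(0L),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(
        position = as.integer(vapply(res, `[[`, character(1L), 1L)),
        nucleotide = vapply(res, `[[`, character(1L), 2L),
        stringsAsFactors = FALSE
      )
    }
  })
  out
}

# random toy data set with occasional ambiguity codes and gaps
random_toy_dataset <- function(n_taxa = 5L, members = 2L:3L, n_cols = 25L,
                               p_odd = 0.03) {
  specimens <- character(0L)
  species <- character(0L)
  seqs <- character(0L)
  pool <- c("A", "C", "G", "T")
  odd <- c("R", "Y", "N", "-", "W", "K")
  for (t in seq_len(n_taxa)) {
    anc <- sample(pool, n_cols, replace = TRUE)
    for (k in seq_len(sample(members, 1L))) {
      s <- anc
      mut <- stats::runif(n_cols) < 0.08
      s[mut] <- sample(pool, sum(mut), replace = TRUE)
      is_odd <- stats::runif(n_cols) < p_odd
      s[is_odd] <- sample(odd, sum(is_odd), replace = TRUE)
      specimens <- c(specimens, sprintf("t%02d_%d", t, k))
      species <- c(species, sprintf("sp%02d", t))
      seqs <- c(seqs, paste(s, collapse = ""))
    }
  }
  list(
    alignment = barcode_alignment(specimens, seqs),
    taxonomy = taxonomy_map(specimens, species,
                            genus = species, family = "famX")
  )
}

# additive distance matrix from a random binary tree with positive
# branch lengths; returns list(d, tree)
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  d <- ape::cophenetic.phylo(tr)
  ord <- paste0("t", seq_len(n))
  list(d = d[ord, ord], tree = tr)
}

# quartet split implied by a distance matrix via the four-point
# condition: returns 1, 2 or 3 for pairings (12|34), (13|24), (14|23)
quartet_from_dist <- function(d, q) {
  s <- c(
    d[q[1L], q[2L]] + d[q[3L], q[4L]],
    d[q[1L], q[3L]] + d[q[2L], q[4L]],
    d[q[1L], q[4L]] + d[q[2L], q[3L]]
  )
  which.min(s)
}

# all quartet splits of a tree, read from its path distances
tree_quartets <- function(tree, labels) {
  pd <- ape::cophenetic.phylo(tree)[labels, labels]
  combs <- utils::combn(length(labels), 4L)
  apply(combs, 2L, function(q) quartet_from_dist(pd, q))
}

# exact coverage of the Wald interval by binomial enumeration
wald_coverage_exact <- function(p, n, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  k <- 0:n
  ph <- k / n
  half <- z * sqrt(ph * (1 - ph) / n)
  covers <- (pmax(0, ph - half) <= p) & (pmin(1, ph + half) >= p)
  sum(stats::dbinom(k, n, p)[covers])
}

# single-linkage components by hand: repeatedly merge any two groups
# linked by a distance below the threshold
components_by_hand <- function(d, thr) {
  groups <- as.list(seq_len(nrow(d)))
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        linked <- any(d[groups[[i]], groups[[j]]] < thr)
        if (linked) {
          groups[[i]] <- sort(c(groups[[i]], groups[[j]]))
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  groups[order(vapply(groups, min, integer(1L)))]
}

# canonical form of a partition for set comparison
partition_key <- function(groups) {
  sort(unname(vapply(groups, function(g) paste(sort(g), collapse = "|"),
                     character(1L))))
}
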