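# Kimura two-parameter (K2P / K80) pairwise distances and the
# intra/interspecific summaries that the barcoding-gap analysis rests
# on. Sites where either sequence carries a gap or an ambiguity code
# are excluded from that pair (pairwise deletion), so P and Q are
# proportions of the pair's comparable sites only.

k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- rep(NaN, length(P)) # NaN marks saturation
  d[is.na(P)] <- NA_real_
  ok <- !is.na(P) & w1 > 0 & w2 > 0
  d[ok] <- pmax(0, -0.5 * log(w1[ok] * sqrt(w2[ok])))
  d
}

#' K2P distance between two aligned sequences
#'
#' Computes the transition proportion `P`, transversion proportion `Q`
#' and the Kimura two-parameter distance
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` over the pair's
#' comparable sites (both bases in `A`/`C`/`G`/`T`). When the log
#' argument is non-positive the pair is saturated: `d` is `NaN` and
#' `saturated` is `TRUE` (the pair is flagged, never silently dropped).
#'
#' @param seq_a,seq_b Aligned sequences of equal length (strings).
#' @return A list of class `k2p_model` with elements `P`, `Q`, `d`,
#'   `comparable_sites` and `saturated`.
#' @examples
#' k2p_distance("ACGTACGTAC", "GCGTACGTAC")$d # one transition in 10
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- match(strsplit(toupper(seq_a), "")[[1L]], BASES)
  b <- match(strsplit(toupper(seq_b), "")[[1L]], BASES)
  if (length(a) != length(b)) stop("sequences must be of equal length")
  comp <- !is.na(a) & !is.na(b)
  n <- sum(comp)
  if (n == 0L) stop("no comparable sites between the two sequences")
  diff <- comp & (a != b)
  ts <- sum(diff & abs(a - b) == 2L) # A<->G (1,3) and C<->T (2,4)
  tv <- sum(diff) - ts
  P <- ts / n
  Q <- tv / n
  d <- k2p_from_pq(P, Q)
  saturated <- is.nan(d)
  if (saturated) {
    warning("saturated pair: K2P distance undefined (1-2P-Q or 1-2Q <= 0)")
  }
  structure(
    list(P = P, Q = Q, d = d, comparable_sites = n, saturated = saturated),
    class = "k2p_model"
  )
}

# distance components from an integer code matrix (rows = specimens);
# returns list of n x n matrices. One vectorised pass per specimen.
k2p_components <- function(X) {
  n <- nrow(X)
  L <- ncol(X)
  d <- P <- Q <- matrix(0, n, n)
  comp <- matrix(L, n, n)
  for (i in seq_len(n - 1L)) {
    a <- X[i, ]
    B <- X[(i + 1L):n, , drop = FALSE]
    A <- matrix(a, nrow(B), L, byrow = TRUE)
    valid <- !is.na(A) & !is.na(B)
    ncomp <- rowSums(valid)
    diff <- valid & (A != B)
    diff[is.na(diff)] <- FALSE
    ts_m <- diff & abs(A - B) == 2L
    ts_m[is.na(ts_m)] <- FALSE
    nts <- rowSums(ts_m)
    ndiff <- rowSums(diff)
    p <- ifelse(ncomp > 0L, nts / ncomp, NA_real_)
    q <- ifelse(ncomp > 0L, (ndiff - nts) / ncomp, NA_real_)
    j <- (i + 1L):n
    P[i, j] <- P[j, i] <- p
    Q[i, j] <- Q[j, i] <- q
    comp[i, j] <- comp[j, i] <- ncomp
    d[i, j] <- d[j, i] <- ifelse(is.na(p), NA_real_, k2p_from_pq(p, q))
  }
  diag(comp) <- rowSums(!is.na(X))
  list(d = d, P = P, Q = Q, comparable = comp)
}

#' Pairwise K2P distance matrix
#'
#' Computes [k2p_distance()] for every unordered pair of specimens in
#' the alignment. Saturated pairs get `NaN` and are flagged in
#' `saturated`; pairs with no comparable sites get `NA`.
#'
#' @param alignment A [barcode_alignment] with at least two records.
#' @return An object of class `k2p_dist`: list with `ids`, symmetric
#'   matrices `d`, `P`, `Q`, `comparable`, and logical matrix
#'   `saturated`.
#' @export
pairwise_matrix <- function(alignment) {
  if (length(alignment$ids) < 2L) stop("need at least two sequences")
  X <- code_matrix(alignment)
  parts <- k2p_components(X)
  sat <- is.nan(parts$d)
  dimnames(parts$d) <- dimnames(parts$P) <- dimnames(parts$Q) <-
    dimnames(parts$comparable) <- dimnames(sat) <-
    list(alignment$ids, alignment$ids)
  structure(
    list(
      ids = alignment$ids, d = parts$d, P = parts$P, Q = parts$Q,
      comparable = parts$comparable, saturated = sat
    ),
    class = "k2p_dist"
  )
}

#' Build a distance matrix object from raw values
#'
#' Wraps an externally supplied symmetric matrix (for example a
#' hand-constructed test matrix) in the container that the
#' partitioning and tree functions accept.
#'
#' @param values Symmetric numeric matrix with zero diagonal.
#' @param ids Specimen ids; defaults to the matrix rownames.
#' @return A `k2p_dist` object (P/Q/comparable unset).
#' @export
distance_matrix <- function(values, ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(ids)) ids <- paste0("t", seq_len(nrow(values)))
  if (nrow(values) != ncol(values)) stop("'values' must be square")
  if (any(abs(values - t(values)) > 1e-12, na.rm = TRUE)) {
    stop("'values' must be symmetric")
  }
  dimnames(values) <- list(ids, ids)
  diag(values) <- 0
  structure(
    list(
      ids = ids, d = values, P = NULL, Q = NULL, comparable = NULL,
      saturated = is.nan(values)
    ),
    class = "k2p_dist"
  )
}

#' @export
print.k2p_dist <- function(x, ...) {
  n <- length(x$ids)
  vals <- x$d[upper.tri(x$d)]
  cat("K2P distance matrix: ", n, " specimens, ", length(vals),
      " pairs\n", sep = "")
  ok <- is.finite(vals)
  if (any(ok)) {
    cat(sprintf(
      " distances: min %.4f, mean %.4f, max %.4f\n",
      min(vals[ok]), mean(vals[ok]), max(vals[ok])
    ))
  }
  n_sat <- sum(x$saturated[upper.tri(x$saturated)])
  if (n_sat > 0L) cat(" saturated pairs: ", n_sat, "\n", sep = "")
  invisible(x)
}

# upper-triangle pair table: id1, id2, value index helpers
pair_index <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  cbind(i, j)
}

summarise_level <- function(values, level, n_excluded) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L) {
    return(structure(
      list(
        level = level, empty = TRUE, mean = NA_real_, min = NA_real_,
        max = NA_real_, sd = NA_real_, se = NA_real_, n_pairs = 0L,
        n_excluded = n_excluded
      ),
      class = "distance_summary"
    ))
  }
  s <- if (n > 1L) stats::sd(values) else 0
  structure(
    list(
      level = level, empty = FALSE, mean = mean(values),
      min = min(values), max = max(values), sd = s,
      se = s / sqrt(n), n_pairs = n, n_excluded = n_excluded
    ),
    class = "distance_summary"
  )
}

#' @export
print.distance_summary <- function(x, ...) {
  if (x$empty) {
    cat(x$level, "distances: no pairs\n")
    return(invisible(x))
  }
  cat(sprintf(
    "%s distances: mean %.4f, range %.4f-%.4f, SD %.4f, SE %.3e (n = %d pairs%s)\n",
    x$level, x$mean, x$min, x$max, x$sd, x$se, x$n_pairs,
    if (x$n_excluded > 0L) paste0(", ", x$n_excluded, " excluded") else ""
  ))
  invisible(x)
}

#' Intraspecific and interspecific distance summaries
#'
#' Splits the pairwise distances into within-species and
#' between-species pairs and summarises each level with mean, range,
#' sample standard deviation (n-1 denominator) and standard error
#' `SE = SD / sqrt(n_pairs)`. Saturated or incomparable pairs are
#' excluded from the statistics and counted in `n_excluded`. A level
#' with no usable pairs is returned with `empty = TRUE`, never as a
#' zero.
#'
#' @param dm A `k2p_dist` from [pairwise_matrix()].
#' @param taxonomy A `taxonomy_map` covering the matrix specimens.
#' @return List with `distance_summary` elements `intra` and `inter`.
#' @export
distance_summaries <- function(dm, taxonomy) {
  sp <- taxonomy$species[match(dm$ids, taxonomy$specimen_id)]
  if (any(is.na(sp))) {
    stop(
      "specimens missing from taxonomy: ",
      paste(dm$ids[is.na(sp)], collapse = ", ")
    )
  }
  n <- length(dm$ids)
  idx <- pair_index(n)
  vals <- dm$d[idx]
  same <- sp[idx[, 1L]] == sp[idx[, 2L]]
  list(
    intra = summarise_level(
      vals[same], "intraspecific", sum(same & !is.finite(vals))
    ),
    inter = summarise_level(
      vals[!same], "interspecific", sum(!same & !is.finite(vals))
    )
  )
}

#' Barcoding-gap report
#'
#' The barcoding gap is positive when the largest intraspecific
#' distance is smaller than the smallest interspecific distance; the
#' gap range is then `(max intra, min inter)`.
#'
#' @param intra,inter `distance_summary` objects from
#'   [distance_summaries()].
#' @return A list of class `gap_report` with `positive` and
#'   `gap_range` (`NULL` when not positive).
#' @export
barcoding_gap <- function(intra, inter) {
  if (isTRUE(intra$empty) || isTRUE(inter$empty)) {
    stop("cannot assess the barcoding gap from an empty distance summary")
  }
  positive <- intra$max < inter$min
  structure(
    list(
      positive = positive,
      gap_range = if (positive) c(max_intra = intra$max, min_inter = inter$min),
      max_intra = intra$max, min_inter = inter$min
    ),
    class = "gap_report"
  )
}

#' @export
print.gap_report <- function(x, ...) {
  if (x$positive) {
    cat(sprintf(
      "Positive DNA barcoding gap: %.4f to %.4f\n",
      x$gap_range[1L], x$gap_range[2L]
    ))
  } else {
    cat(sprintf(
      "No positive DNA barcoding gap (max intra %.4f >= min inter %.4f)\n",
      x$max_intra, x$min_inter
    ))
  }
  invisible(x)
}

#' Histogram of intra- and interspecific distances
#'
#' Bins both distance levels over the pooled range, the data behind
#' the classic barcoding-gap plot.
#'
#' @param dm A `k2p_dist`.
#' @param taxonomy A `taxonomy_map`.
#' @param n_bins Number of bins (>= 2) over the pooled finite range.
#' @return Data frame with columns `level`, `bin_lower`, `bin_upper`,
#'   `count`; counts per level sum to that level's finite pair count.
#' @export
gap_histogram <- function(dm, taxonomy, n_bins = 20L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  sp <- taxonomy$species[match(dm$ids, taxonomy$specimen_id)]
  idx <- pair_index(length(dm$ids))
  vals <- dm$d[idx]
  same <- sp[idx[, 1L]] == sp[idx[, 2L]]
  ok <- is.finite(vals)
  rng <- range(vals[ok])
  if (rng[1L] == rng[2L]) rng[2L] <- rng[1L] + 1e-9
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  bin_of <- function(v) {
    b <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(b, nbins = n_bins)
  }
  data.frame(
    level = rep(c("intraspecific", "interspecific"), each = n_bins),
    bin_lower = rep(breaks[-(n_bins + 1L)], 2L),
    bin_upper = rep(breaks[-1L], 2L),
    count = c(bin_of(vals[same & ok]), bin_of(vals[!same & ok]))
  )
}

#' Write the pairwise distance table to TSV
#'
#' One row per unordered pair: ids, level (when taxonomy is given),
#' P, Q, d and comparable site count, distances printed to 4 decimals.
#'
#' @param dm A `k2p_dist` from [pairwise_matrix()].
#' @param path Output path.
#' @param taxonomy Optional `taxonomy_map` to label pair levels.
#' @return Invisibly, `path`.
#' @export
write_distance_tsv <- function(dm, path, taxonomy = NULL) {
  idx <- pair_index(length(dm$ids))
  out <- data.frame(
    pair_id1 = dm$ids[idx[, 1L]],
    pair_id2 = dm$ids[idx[, 2L]],
    stringsAsFactors = FALSE
  )
  if (!is.null(taxonomy)) {
    sp <- taxonomy$species[match(dm$ids, taxonomy$specimen_id)]
    out$level <- ifelse(
      sp[idx[, 1L]] == sp[idx[, 2L]], "intraspecific", "interspecific"
    )
  }
  out$P <- if (!is.null(dm$P)) round(dm$P[idx], 4L) else NA_real_
  out$Q <- if (!is.null(dm$Q)) round(dm$Q[idx], 4L) else NA_real_
  out$d <- round(dm$d[idx], 4L)
  out$comparable_sites <-
    if (!is.null(dm$comparable)) dm$comparable[idx] else NA_integer_
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write distance summaries to TSV
#'
#' Mirrors the usual summary-table layout: one row per level with
#' Mean, Range, SD and SE.
#'
#' @param summaries List with `intra` and `inter` from
#'   [distance_summaries()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary_tsv <- function(summaries, path) {
  row <- function(s) {
    data.frame(
      level = s$level,
      mean = round(s$mean, 4L),
      range = if (s$empty) NA_character_ else
        sprintf("%.4f-%.4f", s$min, s$max),
      sd = round(s$sd, 4L),
      se = signif(s$se, 5L),
      n_pairs = s$n_pairs,
      n_excluded = s$n_excluded,
      stringsAsFactors = FALSE
    )
  }
  utils::write.table(
    rbind(row(summaries$intra), row(summaries$inter)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
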