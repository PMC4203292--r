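# Automatic barcode-gap partitioning. A ranked-distance gap detector
# (first inter-value jump above the prior that is wider than X times
# the local slope of the ranked-distance curve) drives single-linkage
# splitting of the matrix into candidate species, applied once
# (initial partition) or re-applied inside each group until nothing
# splits (recursive partition), over a geometric grid of prior
# intraspecific divergences. Entirely deterministic.

#' Configuration for barcode-gap partitioning
#'
#' @param p_min,p_max Bounds of the prior intraspecific divergence
#'   grid (0 < p_min < p_max < 1). Defaults 0.001 and 0.1.
#' @param steps Number of grid points (geometric spacing), default 10.
#' @param rel_gap_width Minimum relative gap width `X`: a jump in the
#'   ranked distances qualifies as the barcode gap only if it is wider
#'   than `X` times the local slope below it. Default 1.5.
#' @param n_bins Histogram bins for distance-distribution output,
#'   default 20.
#' @param ts_tv Transition/transversion ratio carried to the K80
#'   distance model, default 2.
#' @return A list of class `abgd_config`.
#' @export
abgd_config <- function(p_min = 0.001, p_max = 0.1, steps = 10L,
                        rel_gap_width = 1.5, n_bins = 20L, ts_tv = 2) {
  if (!(p_min > 0 && p_min < p_max && p_max < 1)) {
    stop("need 0 < p_min < p_max < 1")
  }
  if (steps < 2L) stop("steps must be >= 2")
  if (rel_gap_width <= 0) stop("rel_gap_width must be > 0")
  structure(
    list(
      p_min = p_min, p_max = p_max, steps = as.integer(steps),
      rel_gap_width = rel_gap_width, n_bins = as.integer(n_bins),
      model = "K80", ts_tv = ts_tv
    ),
    class = "abgd_config"
  )
}

#' Locate the barcode gap in a set of pairwise distances
#'
#' Sorts the distances and scans consecutive jumps whose upper value
#' exceeds `prior_p`, in increasing order. The local slope below a
#' jump is the mean of the preceding non-zero consecutive spacings
#' (up to `slope_window` of them); tied distances contribute no
#' spacing, so a flat run of identical values below a jump counts as
#' slope zero. The first jump that is strictly positive and wider
#' than `x * slope` is the barcode gap; the returned threshold is its
#' midpoint. Absence of a qualifying jump is a valid outcome (`NULL`).
#'
#' @param distances Numeric vector of pairwise distances.
#' @param prior_p Prior maximum intraspecific divergence: the gap must
#'   end above this value.
#' @param x Minimum relative gap width.
#' @param slope_window How many spacings below the candidate jump feed
#'   the local slope estimate.
#' @return `NULL`, or a list with `threshold`, `lower`, `upper`,
#'   `width`.
#' @export
find_gap <- function(distances, prior_p, x = 1.5, slope_window = 10L) {
  s <- sort(distances[is.finite(distances)])
  if (length(s) < 2L) return(NULL)
  gaps <- diff(s)
  for (i in which(s[-1L] > prior_p)) {
    w <- gaps[i]
    if (w <= 0) next
    below <- gaps[seq_len(i - 1L)]
    below <- below[below > 0]
    slope <- if (length(below) == 0L) 0 else
      mean(utils::tail(below, slope_window))
    if (w > x * slope) {
      return(list(
        threshold = (s[i] + s[i + 1L]) / 2,
        lower = s[i], upper = s[i + 1L], width = w
      ))
    }
  }
  NULL
}

# single-linkage connected components among 'ids' with edges d < thr;
# returns list of integer index vectors
link_components <- function(d, thr) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- pair_index(n)
  link <- d[idx]
  link <- is.finite(link) & link < thr
  for (k in which(link)) {
    ri <- find(idx[k, 1L])
    rj <- find(idx[k, 2L])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  comps <- split(seq_len(n), roots)
  names(comps) <- NULL
  comps[order(vapply(comps, min, integer(1L)))]
}

as_partition <- function(groups_idx, ids, prior_p, mode, threshold) {
  groups <- lapply(groups_idx, function(g) ids[sort(g)])
  groups <- groups[order(vapply(
    groups_idx, min, integer(1L)
  ))]
  structure(
    list(
      prior_p = prior_p, mode = mode, threshold = threshold,
      groups = groups, n_groups = length(groups)
    ),
    class = "abgd_partition"
  )
}

#' @export
print.abgd_partition <- function(x, ...) {
  cat(sprintf(
    "ABGD %s partition at prior P = %.4g: %d group(s)\n",
    x$mode, x$prior_p, x$n_groups
  ))
  invisible(x)
}

#' Initial barcode-gap partition
#'
#' Finds the barcode gap over the whole distance matrix at one prior
#' and splits the specimens into single-linkage connected components
#' under `d < threshold`. When no gap qualifies everything stays in a
#' single group.
#'
#' @param dm A `k2p_dist`.
#' @param prior_p Prior maximum intraspecific divergence.
#' @param config An [abgd_config()].
#' @return An `abgd_partition` (groups disjoint, covering, sorted by
#'   smallest member).
#' @export
initial_partition <- function(dm, prior_p, config = abgd_config()) {
  n <- length(dm$ids)
  vals <- dm$d[upper.tri(dm$d)]
  g <- find_gap(vals, prior_p, config$rel_gap_width)
  if (is.null(g)) {
    return(as_partition(list(seq_len(n)), dm$ids, prior_p, "initial", NA_real_))
  }
  comps <- link_components(dm$d, g$threshold)
  as_partition(comps, dm$ids, prior_p, "initial", g$threshold)
}

#' Recursive barcode-gap partition
#'
#' Applies [initial_partition()] and then re-runs the gap search
#' inside every resulting group (on its sub-matrix of distances),
#' splitting further until no group splits. Each recursive group is a
#' subset of an initial group by construction.
#'
#' @inheritParams initial_partition
#' @return An `abgd_partition` with `mode = "recursive"`.
#' @export
recursive_partition <- function(dm, prior_p, config = abgd_config()) {
  init <- initial_partition(dm, prior_p, config)
  split_group <- function(idx) {
    if (length(idx) < 3L) return(list(idx))
    sub <- dm$d[idx, idx, drop = FALSE]
    g <- find_gap(sub[upper.tri(sub)], prior_p, config$rel_gap_width)
    if (is.null(g)) return(list(idx))
    comps <- link_components(sub, g$threshold)
    if (length(comps) == 1L) return(list(idx))
    unlist(
      lapply(comps, function(c_idx) split_group(idx[c_idx])),
      recursive = FALSE
    )
  }
  groups_idx <- unlist(
    lapply(init$groups, function(ids) {
      split_group(match(ids, dm$ids))
    }),
    recursive = FALSE
  )
  as_partition(groups_idx, dm$ids, prior_p, "recursive", init$threshold)
}

#' Partitions over a grid of priors
#'
#' Evaluates initial and recursive partitions at `steps`
#' geometrically spaced priors from `p_min` to `p_max` (the classic
#' 0.0010, 0.0017, 0.0028, ... 0.1000 sequence at the defaults).
#'
#' @param dm A `k2p_dist`.
#' @param config An [abgd_config()].
#' @return A list of class `abgd_grid` with `priors`, `initial` and
#'   `recursive` partition lists, and a `summary` data frame
#'   (`prior_p`, `n_initial`, `n_recursive`).
#' @export
partition_grid <- function(dm, config = abgd_config()) {
  priors <- exp(seq(log(config$p_min), log(config$p_max),
                    length.out = config$steps))
  init <- lapply(priors, function(p) initial_partition(dm, p, config))
  rec <- lapply(priors, function(p) recursive_partition(dm, p, config))
  structure(
    list(
      priors = priors, initial = init, recursive = rec,
      summary = data.frame(
        prior_p = priors,
        n_initial = vapply(init, `[[`, integer(1L), "n_groups"),
        n_recursive = vapply(rec, `[[`, integer(1L), "n_groups")
      )
    ),
    class = "abgd_grid"
  )
}

#' @export
print.abgd_grid <- function(x, ...) {
  cat("ABGD partitions over the prior grid:\n")
  s <- x$summary
  s$prior_p <- signif(s$prior_p, 3L)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Concordance of a partition with the morphological species
#'
#' A group matches when it equals exactly the specimen set of one
#' species. Raw counts are reported so any ratio convention can be
#' derived.
#'
#' @param partition An `abgd_partition`.
#' @param taxonomy A `taxonomy_map` covering all specimens.
#' @return List with `n_groups`, `n_species`, `n_matching_groups` and
#'   `match_ratio` (percent of groups that match a species exactly).
#' @export
partition_concordance <- function(partition, taxonomy) {
  species_sets <- taxon_groups(taxonomy, "species")
  keys <- vapply(
    species_sets, function(s) paste(sort(s), collapse = "\r"), character(1L)
  )
  group_keys <- vapply(
    partition$groups, function(g) paste(sort(g), collapse = "\r"),
    character(1L)
  )
  n_match <- sum(group_keys %in% keys)
  list(
    n_groups = partition$n_groups,
    n_species = length(species_sets),
    n_matching_groups = n_match,
    match_ratio = 100 * n_match / partition$n_groups
  )
}

#' Write a partition to TSV
#'
#' One row per specimen: prior, mode, group index, specimen id.
#'
#' @param partition An `abgd_partition`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_partition_tsv <- function(partition, path) {
  out <- data.frame(
    prior_p = partition$prior_p,
    mode = partition$mode,
    group_index = rep(seq_along(partition$groups),
                      lengths(partition$groups)),
    specimen_id = unlist(partition$groups, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the grid summary to TSV
#'
#' Prior versus group count per mode.
#'
#' @param grid An `abgd_grid`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_grid_tsv <- function(grid, path) {
  utils::write.table(
    grid$summary, path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
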