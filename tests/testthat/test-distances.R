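# K2P distances, intra/inter summaries, barcoding gap, histogram

test_that("k2p_distance matches the closed form on known pairs", {
  # identical sequences
  same <- k2p_distance(strrep("ACGT", 10L), strrep("ACGT", 10L))
  expect_equal(same$P, 0)
  expect_equal(same$Q, 0)
  expect_equal(same$d, 0)

  # one A<->G transition among 10 sites: P = 0.1, Q = 0,
  # d = -0.5 * log(0.8)
  one_ts <- k2p_distance("ACGTACGTAC", "GCGTACGTAC")
  expect_equal(one_ts$P, 0.1)
  expect_equal(one_ts$Q, 0)
  expect_equal(one_ts$d, -0.5 * log(0.8), tolerance = 1e-12)

  # all transversions: Q = 1 saturates the log
  expect_warning(sat <- k2p_distance("AAAA", "CCCC"), "saturated")
  expect_true(sat$saturated)
  expect_true(is.nan(sat$d))

  # gaps/ambiguities excluded pairwise
  amb <- k2p_distance("ACGTN-", "GCGTAA")
  expect_equal(amb$comparable_sites, 4L)
  expect_equal(amb$P, 0.25)

  expect_error(k2p_distance("NNNN", "ACGT"), "comparable")
})

test_that("pairwise matrix equals the brute-force per-pair loop", {
  set.seed(11)
  for (rep in 1:5) {
    toy <- random_toy_dataset(n_taxa = 4L, n_cols = 30L)
    dm <- pairwise_matrix(toy$alignment)
    ids <- toy$alignment$ids
    n <- length(ids)
    expect_equal(sum(upper.tri(dm$d)), n * (n - 1L) / 2L)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ref <- suppressWarnings(k2p_distance(
          toy$alignment$sequences[i], toy$alignment$sequences[j]
        ))
        if (ref$saturated) {
          expect_true(is.nan(dm$d[i, j]))
        } else {
          expect_equal(dm$d[i, j], ref$d, tolerance = 1e-12)
        }
        expect_equal(dm$P[i, j], ref$P)
        expect_equal(dm$comparable[i, j], ref$comparable_sites)
      }
    }
  }
})

test_that("pairwise matrix agrees with an independent K80 implementation", {
  set.seed(21)
  n <- 8L
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 300L, replace = TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  }, character(1L))
  # moderate divergence so K80 stays defined
  base <- strsplit(seqs[1L], "")[[1L]]
  seqs <- vapply(seq_len(n), function(i) {
    s <- base
    mut <- sample(300L, 30L + 3L * i)
    s[mut] <- sample(c("A", "C", "G", "T"), length(mut), replace = TRUE)
    paste(s, collapse = "")
  }, character(1L))
  aln <- barcode_alignment(paste0("s", seq_len(n)), seqs)
  dm <- pairwise_matrix(aln)
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(seqs), ""), identity)))
  rownames(bin) <- aln$ids
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(dm$d, ref[aln$ids, aln$ids], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("distance summaries enumerate intra and inter pairs correctly", {
  # 2 species x 2 identical specimens each: 2 intra pairs at 0,
  # 4 inter pairs at the cross distance
  x <- strrep("ACGT", 30L)
  y <- paste0(strrep("GCGT", 15L), strrep("ACGT", 15L)) # 15 transitions
  aln <- barcode_alignment(c("a1", "a2", "b1", "b2"), c(x, x, y, y))
  tax <- taxonomy_map(aln$ids, rep(c("spA", "spB"), each = 2L))
  dm <- pairwise_matrix(aln)
  s <- distance_summaries(dm, tax)
  cross <- k2p_distance(x, y)$d
  expect_equal(s$intra$n_pairs, 2L)
  expect_equal(s$inter$n_pairs, 4L)
  expect_equal(s$intra$mean, 0)
  expect_equal(s$inter$mean, cross)
  expect_equal(s$inter$sd, 0)

  # SE = SD / sqrt(n_pairs) exactly
  toy <- fixture_library()$two_clusters
  s2 <- distance_summaries(pairwise_matrix(toy$alignment), toy$taxonomy)
  expect_equal(s2$intra$se, s2$intra$sd / sqrt(s2$intra$n_pairs))
  expect_equal(s2$inter$se, s2$inter$sd / sqrt(s2$inter$n_pairs))

  # all identical: both means 0, SD 0
  aln0 <- barcode_alignment(c("a1", "a2", "b1"), rep(x, 3L))
  tax0 <- taxonomy_map(aln0$ids, c("spA", "spA", "spB"))
  s0 <- distance_summaries(pairwise_matrix(aln0), tax0)
  expect_equal(s0$intra$mean, 0)
  expect_equal(s0$inter$mean, 0)
  expect_equal(s0$intra$sd, 0)

  # no intra pairs -> empty-flagged, not zero
  aln1 <- barcode_alignment(c("a1", "b1"), c(x, y))
  tax1 <- taxonomy_map(aln1$ids, c("spA", "spB"))
  s1 <- distance_summaries(pairwise_matrix(aln1), tax1)
  expect_true(s1$intra$empty)
  expect_true(is.na(s1$intra$mean))
})

test_that("summaries are invariant to specimen ordering", {
  set.seed(31)
  toy <- random_toy_dataset(n_taxa = 4L, n_cols = 40L, p_odd = 0)
  s <- distance_summaries(pairwise_matrix(toy$alignment), toy$taxonomy)
  perm <- sample(length(toy$alignment$ids))
  aln_p <- barcode_alignment(
    toy$alignment$ids[perm], unname(toy$alignment$sequences[perm])
  )
  s_p <- distance_summaries(pairwise_matrix(aln_p), toy$taxonomy)
  expect_equal(s$intra, s_p$intra)
  expect_equal(s$inter, s_p$inter)
})

test_that("K2P distance dominates the uncorrected divergence", {
  set.seed(41)
  for (rep in 1:20) {
    toy <- random_toy_dataset(n_taxa = 2L, members = 1L:1L,
                              n_cols = 60L, p_odd = 0)
    m <- suppressWarnings(k2p_distance(
      toy$alignment$sequences[1L], toy$alignment$sequences[2L]
    ))
    if (!m$saturated) expect_gte(m$d, m$P + m$Q - 1e-12)
  }
})

test_that("barcoding gap compares the distance extremes", {
  mk <- function(min, max) {
    structure(
      list(level = "x", empty = FALSE, mean = (min + max) / 2,
           min = min, max = max, sd = 0, se = 0, n_pairs = 10L,
           n_excluded = 0L),
      class = "distance_summary"
    )
  }
  pos <- barcoding_gap(mk(0, 0.0182), mk(0.0436, 0.16))
  expect_true(pos$positive)
  expect_equal(unname(pos$gap_range), c(0.0182, 0.0436))

  neg <- barcoding_gap(mk(0, 0.0973), mk(0.0164, 0.23))
  expect_false(neg$positive)
  expect_null(neg$gap_range)

  # intra all zero, any inter > 0 -> positive
  expect_true(barcoding_gap(mk(0, 0), mk(1e-4, 0.1))$positive)

  empty <- structure(list(level = "x", empty = TRUE), class = "distance_summary")
  expect_error(barcoding_gap(empty, mk(0.1, 0.2)), "empty")
})

test_that("gap histogram conserves pair counts and matches hand binning", {
  toy <- fixture_library()$no_gap
  dm <- pairwise_matrix(toy$alignment)
  tax <- toy$taxonomy
  h <- gap_histogram(dm, tax, n_bins = 4L)
  sp <- tax$species[match(dm$ids, tax$specimen_id)]
  vals <- dm$d[upper.tri(dm$d)]
  n_intra <- sum(outer(sp, sp, "==")[upper.tri(dm$d)])
  expect_equal(sum(h$count[h$level == "intraspecific"]), n_intra)
  expect_equal(sum(h$count[h$level == "interspecific"]),
               length(vals) - n_intra)

  # hand binning of the pooled range
  breaks <- seq(min(vals), max(vals), length.out = 5L)
  same <- outer(sp, sp, "==")[upper.tri(dm$d)]
  hand <- table(cut(vals[!same], breaks, include.lowest = TRUE))
  expect_equal(h$count[h$level == "interspecific"], as.vector(hand))

  expect_error(gap_histogram(dm, tax, n_bins = 1L), "n_bins")
})
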