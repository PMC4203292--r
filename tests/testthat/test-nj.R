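# Neighbor-joining, bootstrap supports, monophyly scoring

test_that("NJ recovers additive matrices exactly", {
  # two taxa: one edge of total length d
  d2 <- distance_matrix(matrix(c(0, 0.3, 0.3, 0), 2L, 2L,
                               dimnames = list(c("A", "B"), c("A", "B"))))
  tr2 <- nj_tree(d2)
  expect_equal(sum(tr2$edge.length), 0.3)

  # classic additive 4-taxon matrix: split AB|CD, path lengths
  # reproduce the input
  d4 <- matrix(c(
    0, 3, 5, 6,
    3, 0, 6, 7,
    5, 6, 0, 7,
    6, 7, 7, 0
  ), 4L, 4L, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr4 <- nj_tree(distance_matrix(d4))
  pd <- ape::cophenetic.phylo(tr4)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(pd, d4, tolerance = 1e-10)
  # AB|CD is the implied quartet
  expect_equal(quartet_from_dist(pd, 1:4), 1L)
})

test_that("NJ quartets match the four-point oracle on random additive trees", {
  set.seed(51)
  for (n in 4:8) {
    for (rep in 1:5) {
      gen <- random_additive_matrix(n)
      tr <- nj_tree(distance_matrix(gen$d))
      labels <- paste0("t", seq_len(n))
      got <- tree_quartets(tr, labels)
      want <- apply(utils::combn(n, 4L), 2L, function(q) {
        quartet_from_dist(gen$d, q)
      })
      expect_equal(got, want)
    }
  }
})

test_that("ultrametric two-cluster matrices yield sister clusters", {
  ids <- c("a1", "a2", "a3", "b1", "b2")
  d <- matrix(0.4, 5L, 5L, dimnames = list(ids, ids))
  d[1:3, 1:3] <- 0.05
  d[4:5, 4:5] <- 0.05
  diag(d) <- 0
  tr <- nj_tree(distance_matrix(d))
  tax <- taxonomy_map(ids, c("spA", "spA", "spA", "spB", "spB"))
  rep <- monophyly_report(tr, tax, "species")
  expect_true(all(rep$taxa$monophyletic))
  expect_equal(rep$ratio, 100)
})

test_that("clamped NJ trees never carry negative branch lengths", {
  set.seed(61)
  for (rep in 1:10) {
    n <- 6L
    d <- random_additive_matrix(n)$d
    noise <- matrix(stats::runif(n * n, 0, 0.3), n, n)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    tr <- nj_tree(distance_matrix(d + noise))
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("tree building refuses saturated entries", {
  d <- matrix(c(0, NaN, NaN, 0), 2L, 2L)
  expect_error(nj_tree(distance_matrix(d)), "saturated|undefined")
})

test_that("bootstrap supports are deterministic and saturate on clean signal", {
  toy <- fixture_library()$two_clusters
  tr1 <- bootstrap_supports(toy$alignment, n_replicates = 50L, seed = 9L)
  tr2 <- bootstrap_supports(toy$alignment, n_replicates = 50L, seed = 9L)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  # the two-cluster split is present in every resampled tree
  tax <- toy$taxonomy
  supports <- as.numeric(tr1$node.label)
  expect_true(any(supports == 100, na.rm = TRUE))
  rep <- monophyly_report(tr1, tax, "species")
  expect_equal(rep$ratio, 100)
})

test_that("monophyly scoring matches exhaustive clade reasoning", {
  toy <- fixture_library()$intermixed_species
  tr <- nj_tree(pairwise_matrix(toy$alignment))
  rep <- monophyly_report(tr, toy$taxonomy, "species")
  bad <- rep$taxa[!rep$taxa$monophyletic, "taxon"]
  expect_equal(bad, "spA")
  expect_equal(rep$n_monophyletic, 2L)
  expect_equal(rep$ratio, 100 * 2 / 3, tolerance = 1e-12)

  # every species a singleton -> 100% by convention
  ids <- paste0("s", 1:4)
  base <- strrep("ACGT", 20L)
  aln <- barcode_alignment(ids, c(
    base,
    sub("C", "T", base), # a few scattered substitutions each
    sub("G", "A", base),
    sub("T", "C", base)
  ))
  tax <- taxonomy_map(ids, paste0("sp", 1:4))
  rep1 <- monophyly_report(nj_tree(pairwise_matrix(aln)), tax, "species")
  expect_equal(rep1$ratio, 100)

  expect_error(monophyly_report(tr, toy$taxonomy, "family"))
})

test_that("outgroup rooting does not change ingroup monophyly verdicts", {
  # perfectly additive data: every mutation on its own column, each
  # cluster marked by a shared derived transition plus private ones
  base <- strsplit(strrep("ACGT", 30L), "")[[1L]]
  put <- function(s, at, to) {
    s[at] <- to
    s
  }
  a_sh <- put(base, c(6L, 62L, 66L, 70L), "T")
  b_sh <- put(put(base, seq(1L, 45L, by = 4L), "G"), 26L, "T")
  og <- put(base, seq(3L, 39L, by = 4L), "A")
  seqs <- vapply(list(
    put(a_sh, 2L, "T"), put(a_sh, c(10L, 14L), "T"),
    put(a_sh, c(18L, 22L, 30L), "T"),
    put(b_sh, 34L, "T"), put(b_sh, c(42L, 46L), "T"),
    put(b_sh, c(50L, 54L, 58L), "T"),
    og
  ), paste, character(1L), collapse = "")
  aln <- barcode_alignment(
    c("a1", "a2", "a3", "b1", "b2", "b3", "og1"), seqs
  )
  tax <- taxonomy_map(
    aln$ids,
    c(rep(c("spA", "spB"), each = 3L), "outsp"),
    c(rep(c("genA", "genB"), each = 3L), "outgen"),
    c(rep(c("famA", "famB"), each = 3L), "outfam")
  )
  tr <- nj_tree(pairwise_matrix(aln))
  unrooted <- monophyly_report(tr, tax, "species")
  rooted <- monophyly_report(tr, tax, "species", outgroup = "og1")
  expect_equal(rooted$ratio, 100)
  # same verdict for the shared taxa
  shared <- intersect(unrooted$taxa$taxon, rooted$taxa$taxon)
  expect_equal(
    unrooted$taxa$monophyletic[match(shared, unrooted$taxa$taxon)],
    rooted$taxa$monophyletic[match(shared, rooted$taxa$taxon)]
  )
})
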