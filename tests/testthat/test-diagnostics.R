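# Tree-free diagnostic characters

test_that("diagnostics equal the exhaustive scan on random toy data", {
  set.seed(91)
  for (rep in 1:200) {
    toy <- random_toy_dataset(
      n_taxa = sample(3:6, 1L), n_cols = sample(15:30, 1L)
    )
    got <- find_diagnostics(toy$alignment, toy$taxonomy, "species")
    want <- brute_force_diagnostics(toy$alignment, toy$taxonomy, "species")
    expect_equal(names(got$taxa), names(want))
    for (taxon in names(want)) {
      expect_equal(got$taxa[[taxon]]$position, want[[taxon]]$position)
      expect_equal(got$taxa[[taxon]]$nucleotide, want[[taxon]]$nucleotide)
    }
  }
})

test_that("planted private bases are found exactly", {
  # 3 taxa x 2 specimens, one private fixed base each
  base <- strrep("A", 10L)
  s1 <- sub("^(.{4})A", "\\1G", base) # G at 5
  s2 <- sub("^(.{6})A", "\\1C", base) # C at 7
  s3 <- sub("^(.{8})A", "\\1T", base) # T at 9
  aln <- barcode_alignment(
    c("a1", "a2", "b1", "b2", "c1", "c2"),
    c(s1, s1, s2, s2, s3, s3)
  )
  tax <- taxonomy_map(aln$ids, rep(c("spA", "spB", "spC"), each = 2L))
  ds <- find_diagnostics(aln, tax, "species")
  expect_equal(ds$taxa$spA$position, 5L)
  expect_equal(ds$taxa$spA$nucleotide, "G")
  expect_equal(ds$taxa$spB$position, 7L)
  expect_equal(ds$taxa$spC$position, 9L)
  expect_equal(ds$success_ratio, 100)
})

test_that("identical taxa have no diagnostics and ratio 0", {
  aln <- barcode_alignment(c("a1", "a2", "b1", "b2"),
                           rep(strrep("ACGT", 10L), 4L))
  tax <- taxonomy_map(aln$ids, rep(c("spA", "spB"), each = 2L))
  ds <- find_diagnostics(aln, tax, "species")
  expect_equal(ds$n_taxa_with_diagnostics, 0L)
  expect_equal(diagnostic_success_ratio(ds), 0)

  expect_error(
    find_diagnostics(aln, taxonomy_map(aln$ids, rep("spA", 4L)), "species"),
    "two taxa"
  )
})

test_that("outside ambiguity codes block the bases they could be", {
  # spA fixed G at column 1; outsider carries R (= A or G) there
  aln <- barcode_alignment(
    c("a1", "a2", "b1"),
    c("GAAA", "GAAA", "RCCC")
  )
  tax <- taxonomy_map(aln$ids, c("spA", "spA", "spB"))
  ds <- find_diagnostics(aln, tax, "species")
  expect_false(1L %in% ds$taxa$spA$position)
  # and a member ambiguity makes the column ineligible for its taxon
  aln2 <- barcode_alignment(
    c("a1", "a2", "b1"),
    c("GAAA", "RAAA", "TCCC")
  )
  ds2 <- find_diagnostics(aln2, tax, "species")
  expect_false(1L %in% ds2$taxa$spA$position)
})

test_that("adding a specimen to a taxon never adds diagnostics for it", {
  set.seed(101)
  for (rep in 1:20) {
    toy <- random_toy_dataset(n_taxa = 4L, n_cols = 25L, p_odd = 0)
    before <- find_diagnostics(toy$alignment, toy$taxonomy, "species")
    # append a mutated copy of a spA member
    target <- toy$taxonomy$specimen_id[toy$taxonomy$species == "sp01"][1L]
    s <- strsplit(toy$alignment$sequences[[target]], "")[[1L]]
    mut <- sample(length(s), 3L)
    s[mut] <- sample(c("A", "C", "G", "T"), 3L, replace = TRUE)
    aln2 <- barcode_alignment(
      c(toy$alignment$ids, "extra"),
      c(unname(toy$alignment$sequences), paste(s, collapse = ""))
    )
    tax2 <- taxonomy_map(
      aln2$ids, c(toy$taxonomy$species, "sp01"),
      c(toy$taxonomy$genus, "sp01"), "famX"
    )
    after <- find_diagnostics(aln2, tax2, "species")
    labels_before <- diag_label(before$taxa$sp01$position,
                                before$taxa$sp01$nucleotide)
    labels_after <- diag_label(after$taxa$sp01$position,
                               after$taxa$sp01$nucleotide)
    expect_true(all(labels_after %in% labels_before))
  }
})

test_that("removing other taxa never removes diagnostics", {
  set.seed(111)
  for (rep in 1:20) {
    toy <- random_toy_dataset(n_taxa = 5L, n_cols = 25L)
    full <- find_diagnostics(toy$alignment, toy$taxonomy, "species")
    keep <- sort(sample(unique(toy$taxonomy$species), 3L))
    sub <- subset_rediagnosis(toy$alignment, toy$taxonomy,
                              taxon_subset = keep)
    for (taxon in keep) {
      before <- diag_label(full$taxa[[taxon]]$position,
                           full$taxa[[taxon]]$nucleotide)
      after <- diag_label(sub$taxa[[taxon]]$position,
                          sub$taxa[[taxon]]$nucleotide)
      expect_true(all(before %in% after))
    }
  }
})

test_that("subsetting to one family reveals diagnostics hidden in the full set", {
  toy <- fixture_library()$subset_effect
  full <- find_diagnostics(toy$alignment, toy$taxonomy, "species")
  expect_lt(full$success_ratio, 100)
  expect_equal(nrow(full$taxa$spS1), 0L)

  fam1 <- unique(
    toy$taxonomy$species[toy$taxonomy$family == "famF1"]
  )
  sub <- subset_rediagnosis(toy$alignment, toy$taxonomy,
                            taxon_subset = fam1)
  expect_equal(sub$success_ratio, 100)
  expect_true(
    "G_5" %in% diag_label(sub$taxa$spS1$position, sub$taxa$spS1$nucleotide)
  )

  # subset = everything reproduces the full diagnosis
  all_sp <- sort(unique(toy$taxonomy$species))
  same <- subset_rediagnosis(toy$alignment, toy$taxonomy,
                             taxon_subset = all_sp)
  expect_equal(same$table, full$table)

  expect_error(
    subset_rediagnosis(toy$alignment, toy$taxonomy, taxon_subset = character(0L)),
    "empty"
  )
  expect_error(
    subset_rediagnosis(toy$alignment, toy$taxonomy, taxon_subset = "nope"),
    "not present"
  )
})

test_that("random taxon subsets are reproducible from the seed", {
  toy <- fixture_library()$subset_effect
  a <- subset_rediagnosis(toy$alignment, toy$taxonomy, n_taxa = 2L, seed = 5L)
  b <- subset_rediagnosis(toy$alignment, toy$taxonomy, n_taxa = 2L, seed = 5L)
  expect_identical(attr(a, "taxon_subset"), attr(b, "taxon_subset"))
  expect_equal(a$table, b$table)
})

test_that("diagnostic labels round-trip through the N_pos format", {
  df <- data.frame(position = c(5L, 254L, 600L),
                   nucleotide = c("G", "C", "T"))
  labels <- diag_label(df$position, df$nucleotide)
  expect_equal(labels, c("G_5", "C_254", "T_600"))
  back <- parse_diag_label(labels)
  expect_equal(back$position, df$position)
  expect_equal(back$nucleotide, df$nucleotide)
  expect_error(parse_diag_label("Z_12"), "malformed")
})
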