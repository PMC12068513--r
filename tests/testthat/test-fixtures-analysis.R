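# Fixture generation ground truth; candidate selection and PCA projection.

test_that("fixture corpora are reproducible and fully assembled", {
  a <- generate_fixtures(fixture_spec(n_molecules = 10L, seed = 9L))
  b <- generate_fixtures(fixture_spec(n_molecules = 10L, seed = 9L))
  expect_identical(as.data.frame(unclass(a)), as.data.frame(unclass(b)))
  for (smi in a$smiles) {
    expect_identical(nrow(attachment_points(smi)), 0L)
  }
})

test_that("fixture molecules decompose back to their constituent pieces", {
  fx <- small_fixture_corpus()
  unbridged <- fx[fx$kind == "symmetric" & is.na(fx$bridge), , drop = FALSE]
  for (i in seq_len(min(6L, nrow(unbridged)))) {
    row <- unbridged[i, ]
    d <- decompose(row$smiles)
    expect_identical(reassemble(d$leaves, d$vocab)$smiles,
                     canonicalize(row$smiles)$smiles)
    # leaf multiset: the core plus `degree` copies of the end-group
    stripped <- sort(vapply(d$leaves, function(l) strip_marks(l)$smiles,
                            character(1)))
    want <- sort(c(strip_marks(row$core)$smiles,
                   rep(strip_marks(row$end)$smiles, row$degree)))
    expect_identical(stripped, want)
    # symmetric sites share one mark on the core leaf
    core_leaf <- Filter(function(l) nrow(attachment_points(l)) == row$degree,
                        d$leaves)[[1]]
    expect_identical(length(unique(attachment_points(core_leaf)$mark)), 1L)
  }
})

test_that("contrast fixtures share marks exactly when the ends are equal", {
  fx <- small_fixture_corpus()
  contrast <- fx[fx$kind == "contrast", , drop = FALSE]
  expect_gt(nrow(contrast), 0L)
  for (i in seq_len(nrow(contrast))) {
    row <- contrast[i, ]
    d <- decompose(row$smiles)
    core_leaf <- Filter(function(l) nrow(attachment_points(l)) == 2L,
                        d$leaves)[[1]]
    marks <- attachment_points(core_leaf)$mark
    if (row$ends_equal) {
      expect_identical(marks[1], marks[2])
    } else {
      expect_false(marks[1] == marks[2])
    }
  }
})

test_that("diverse selection flags the per-cluster bandgap minimum", {
  fx <- small_fixture_corpus()
  oracle <- toy_conjugation_oracle()
  tab <- select_diverse_lowest(fx$smiles, k = 4L, predictor = oracle,
                               seed = 1L)
  expect_identical(sum(tab$selected), length(unique(tab$cluster)))
  for (ci in unique(tab$cluster)) {
    sub <- tab[tab$cluster == ci, ]
    expect_identical(sub$bandgap[sub$selected], min(sub$bandgap))
    expect_identical(sum(sub$selected), 1L)
  }
  # identical candidates collapse to one effective cluster and one selection
  expect_message(
    same <- select_diverse_lowest(rep("c1ccccc1", 5L), k = 3L,
                                  predictor = oracle),
    "clamped")
  expect_identical(nrow(same), 1L)
  expect_identical(sum(same$selected), 1L)
})

test_that("PCA projection is deterministic with ordered component variances", {
  fx <- small_fixture_corpus()
  smi <- utils::head(fx$smiles, 10L)
  a <- pca_projection(smi)
  b <- pca_projection(smi)
  expect_equal(a, b)
  expect_gte(stats::var(a$pc1), stats::var(a$pc2))
  # two molecules: all variance on the first axis
  two <- pca_projection(c("c1ccccc1", "c1ccncc1"))
  expect_equal(two$pc2, c(0, 0), tolerance = 1e-8)
  expect_error(pca_projection("c1ccccc1"), "at least 2")
  # candidates and references share one fitted basis
  ab <- pca_projection(smi[1:5], references = smi[6:10])
  expect_identical(ab$set, rep(c("candidate", "reference"), each = 5L))
})
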