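# Cleavable-bond matching, vocabulary construction, recursive decomposition,
# reassembly and the corpus pool.

test_that("cleavable bonds follow the aromatic-single-acyclic rule", {
  expect_identical(nrow(find_cleavable_bonds("c1ccccc1")), 0L)
  expect_identical(nrow(find_cleavable_bonds("Cc1ccccc1")), 1L)
  expect_identical(nrow(find_cleavable_bonds("c1ccccc1-c1ccccc1")), 1L)
  expect_identical(nrow(find_cleavable_bonds("CCCC")), 0L)     # aliphatic only
  expect_identical(nrow(find_cleavable_bonds("C1CCCCC1c1ccccc1")), 1L)
  # double bond to ring is not single, vinyl's internal C=C not matched
  expect_identical(nrow(find_cleavable_bonds("C=Cc1ccccc1")), 1L)
})

test_that("single-cut vocabularies deduplicate by symmetry and sort deterministically", {
  v1 <- build_vocabulary("c1ccccc1-c1ccccc1")
  expect_identical(vocab_size(v1), 1L)
  v2 <- build_vocabulary("Cc1ccccc1")
  expect_identical(vocab_size(v2), 2L)
  v3 <- build_vocabulary("Cc1ccc(cc1)c1ccc(C)cc1")
  expect_identical(vocab_size(v3), 3L)
  # no cleavable bonds: the whole molecule is the single entry
  v4 <- build_vocabulary("c1ccccc1")
  expect_identical(vocab_size(v4), 1L)
  expect_identical(vocab_form(v4, 0L), canonicalize("c1ccccc1")$smiles)
  # reproducible IDs across runs
  v3b <- build_vocabulary("Cc1ccc(cc1)c1ccc(C)cc1")
  expect_identical(as.data.frame(v3), as.data.frame(v3b))
})

test_that("decomposition labels counterparts and terminates at uncleavable leaves", {
  d0 <- decompose("c1ccccc1")
  expect_length(d0$leaves, 1L)
  expect_identical(nrow(attachment_points(d0$leaves[[1]])), 0L)

  db <- decompose("c1ccccc1-c1ccccc1")
  expect_length(db$leaves, 2L)
  marks <- vapply(db$leaves, function(l) attachment_points(l)$mark, integer(1))
  expect_identical(marks, c(0L, 0L))    # both sides reference the phenyl entry

  # core with three distinct substituents: pairwise distinct core marks
  d3 <- decompose("Cc1cc(-c2cccs2)cc(-c2ccccc2)c1")
  expect_length(d3$leaves, 4L)
  core <- Filter(function(l) nrow(attachment_points(l)) == 3L, d3$leaves)
  expect_length(core, 1L)
  cm <- attachment_points(core[[1]])$mark
  expect_identical(length(unique(cm)), 3L)
  # no leaf retains a cleavable bond
  for (l in d3$leaves) expect_identical(nrow(find_cleavable_bonds(l)), 0L)
})

test_that("mark <-> counterpart-form assignments are a bijection", {
  for (smi in utils::head(small_fixture_corpus()$smiles, 8L)) {
    asg <- decompose(smi)$assignments
    expect_identical(anyDuplicated(asg$mark), 0L)
    expect_identical(anyDuplicated(asg$counterpart), 0L)
  }
})

test_that("reassembly inverts decomposition", {
  for (smi in c("c1ccccc1-c1ccccc1", "Cc1ccccc1",
                "Cc1cc(-c2cccs2)cc(-c2ccccc2)c1")) {
    d <- decompose(smi)
    expect_identical(reassemble(d$leaves, d$vocab)$smiles,
                     canonicalize(smi)$smiles)
  }
  # inconsistent leaves are rejected with the orphan marks listed
  d <- decompose("Cc1ccccc1")
  expect_error(reassemble(d$leaves[1], d$vocab), "unresolvable")
})

test_that("memoization does not change the leaf multiset", {
  for (smi in utils::head(small_fixture_corpus()$smiles, 6L)) {
    a <- decompose(smi, memoize = TRUE)
    b <- decompose(smi, memoize = FALSE)
    expect_identical(sort(vapply(a$leaves, function(l) l$smiles, character(1))),
                     sort(vapply(b$leaves, function(l) l$smiles, character(1))))
  }
})

test_that("corpus decomposition merges duplicates and applies the r/n filters", {
  p <- decompose_corpus("c1ccccc1-c1ccccc1")
  expect_identical(nrow(p), 1L)
  expect_identical(p$count, 2L)

  p0 <- decompose_corpus(character(0))
  expect_identical(nrow(p0), 0L)

  corpus <- utils::head(small_fixture_corpus()$smiles, 8L)
  full <- decompose_corpus(corpus, size_cap = 100L, reactive_cap = 10L)
  small_n <- decompose_corpus(corpus, size_cap = 5L, reactive_cap = 10L)
  expect_true(all(small_n$n_heavy <= 5L))
  expect_true(any(full$n_heavy > 5L))
  r1 <- decompose_corpus(corpus, size_cap = 100L, reactive_cap = 1L)
  expect_true(all(r1$n_reactive <= 1L))
  # determinism: identical vocabularies and pools across runs
  full2 <- decompose_corpus(corpus, size_cap = 100L, reactive_cap = 10L)
  expect_identical(as.data.frame(unclass(full)), as.data.frame(unclass(full2)))
  expect_identical(as.data.frame(attr(full, "vocab")),
                   as.data.frame(attr(full2, "vocab")))
})

test_that("vocabulary JSON round-trips", {
  v <- build_vocabulary("Cc1ccc(cc1)c1ccc(C)cc1")
  path <- withr::local_tempfile(fileext = ".json")
  write_vocabulary(v, path)
  v2 <- read_vocabulary(path)
  expect_identical(as.data.frame(v), as.data.frame(v2))
})
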