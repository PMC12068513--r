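# Canonicalization, fingerprints, Tanimoto, marked attachment and capping.

test_that("canonicalization perceives aromaticity and is idempotent", {
  kekule <- canonicalize("C1=CC=CC=C1")
  aromatic <- canonicalize("c1ccccc1")
  expect_identical(kekule$smiles, aromatic$smiles)
  expect_identical(heavy_atoms(aromatic), 6L)
  expect_identical(canonicalize(aromatic$smiles)$smiles, aromatic$smiles)
})

test_that("canonicalization is invariant to atom renumbering", {
  mols <- c("Cc1ccc(C)cc1", "Cc1cc(-c2cccs2)cc(-c2ccccc2)c1",
            "[1*]c1ccc(s1)c1ccc([1*])o1", "CC(=O)Nc1ccc(O)cc1")
  for (smi in mols) {
    can <- canonicalize(smi)$smiles
    for (s in 1:10) {
      expect_identical(canonicalize(renumber_smiles(smi, s))$smiles, can)
    }
  }
})

test_that("invalid SMILES fail with the offending string named", {
  expect_error(canonicalize("xy!!z"), "xy!!z", fixed = TRUE)
  expect_error(canonicalize(""), "invalid")
})

test_that("fingerprints distinguish molecules and are canonical-form determined", {
  fb1 <- morgan_fingerprint("c1ccccc1")
  fb2 <- morgan_fingerprint("C1=CC=CC=C1")
  fp <- morgan_fingerprint("c1ccncc1")
  expect_identical(fb1$bits, fb2$bits)
  expect_gt(length(fb1$bits), 0)
  expect_false(identical(fb1$bits, fp$bits))
  expect_identical(fb1$n_bits, 2048L)
  small <- morgan_fingerprint("c1ccccc1", n_bits = 64L)
  expect_true(all(small$bits >= 1 & small$bits <= 64))
})

test_that("tanimoto matches set arithmetic, is symmetric and bounded", {
  mk <- function(bits) structure(list(bits = bits, radius = 2L,
                                      n_bits = 2048L), class = "symfp")
  expect_equal(tanimoto(mk(c(1, 2, 3)), mk(c(2, 3, 4))), 0.5)
  expect_equal(tanimoto(mk(1:5), mk(1:5)), 1)
  expect_equal(tanimoto(mk(1:3), mk(4:6)), 0)
  expect_error(tanimoto(mk(1:3), morgan_fingerprint("CC", n_bits = 64L)),
               "mismatch")
  mols <- lapply(c("c1ccccc1", "c1ccncc1", "Cc1ccccc1", "c1ccsc1"),
                 morgan_fingerprint)
  for (a in mols) {
    for (b in mols) {
      expect_equal(tanimoto(a, b), tanimoto(b, a))
      expect_gte(tanimoto(a, a), tanimoto(a, b))
      expect_true(tanimoto(a, b) >= 0 && tanimoto(a, b) <= 1)
    }
  }
})

test_that("attachment bonds one fragment copy at every identically marked position", {
  core2 <- canonicalize("[8*]c1ccc([8*])cc1")          # two positions, mark 7
  thio <- canonicalize("[1*]c1ccc(s1)")
  out <- attach_at_mark(core2, 7L, thio)
  expect_identical(heavy_atoms(out), 6L + 2L * 5L)     # atom-count oracle
  expect_identical(nrow(attachment_points(out)), 0L)

  one <- attach_at_mark(canonicalize("[8*]c1ccccc1"), 7L, canonicalize("[1*]C"))
  expect_identical(heavy_atoms(one), 7L)
  expect_identical(one$smiles, canonicalize("Cc1ccccc1")$smiles)

  expect_error(attach_at_mark(core2, 99L, thio), "mark 99")
})

test_that("symmetric attachment gives copies a shared fresh mark", {
  core2 <- canonicalize("[8*]c1ccc([8*])cc1")
  bridge <- canonicalize("*C=C*")
  out <- attach_at_mark(core2, 7L, bridge)
  ap <- attachment_points(out)
  expect_identical(nrow(ap), 2L)
  expect_identical(ap$mark[1], ap$mark[2])
})

test_that("capping removes all open positions with the right atom bookkeeping", {
  m3 <- canonicalize("[1*]c1cc([1*])cc([1*])c1")
  h0 <- heavy_atoms(m3)
  capped <- cap_open_positions(m3, "methyl")
  expect_identical(heavy_atoms(capped), h0 + 3L)
  expect_identical(nrow(attachment_points(capped)), 0L)

  hyd <- cap_open_positions("[1*]c1ccccc1", "hydrogen")
  expect_identical(hyd$smiles, canonicalize("c1ccccc1")$smiles)

  closed <- canonicalize("Cc1ccccc1")
  expect_identical(cap_open_positions(closed, "methyl")$smiles, closed$smiles)

  pyrrole <- cap_open_positions("[1*]n1cccc1", "hydrogen")
  expect_identical(pyrrole$smiles, canonicalize("c1cc[nH]c1")$smiles)
})
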