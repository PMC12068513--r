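# Shared helpers: cheap fixture corpora and a SMILES renumbering oracle.
# Heavyweight objects are built once per test run and memoised here.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  hit <- .cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  assign(key, val, envir = .cache)
  val
}

small_fixture_corpus <- function() {
  cached("fixtures20", generate_fixtures(fixture_spec(n_molecules = 20L,
                                                      seed = 101L)))
}

small_pool <- function() {
  cached("pool", decompose_corpus(small_fixture_corpus()$smiles))
}

# rewrite a SMILES with a random atom renumbering (same molecule, different
# string) -- the oracle for canonicalization permutation invariance
renumber_smiles <- function(smiles, seed) {
  g <- symfrag:::parse_smiles_graph(symfrag:::ob_canonical_smiles(smiles))
  n <- length(g$elem)
  set.seed(seed)
  newpos <- sample.int(n)
  g2 <- g
  for (f in c("elem", "arom", "charge", "hcount", "iso")) {
    g2[[f]][newpos] <- g[[f]]
  }
  g2$bond <- matrix(newpos[g$bond], ncol = 2)
  symfrag:::write_smiles_graph(g2)
}

# a tiny pool with one 4-marked core and simple end-groups, for transition
# and constraint tests on the open grammar
four_mark_pool <- function() {
  c("[1*]c1c([2*])cc([3*])c([4*])c1",
    "[5*]C", "[5*]OC", "[5*]C(F)(F)F", "[5*]c1ccccc1", "[5*]c1ccc(s1)",
    "[5*]C#N", "[6*]c1ccc([7*])s1", "[6*]c1ccc([7*])o1")
}

# the 200-molecule corpus exercised by the whole-pipeline checks, with its
# per-molecule decompositions (memoised: several checks share them)
big_fixture_corpus <- function() {
  cached("fixtures200", generate_fixtures(fixture_spec(n_molecules = 200L,
                                                       seed = 2024L)))
}

big_fixture_decompositions <- function() {
  cached("decomps200",
         lapply(big_fixture_corpus()$smiles, function(s) decompose(s)))
}
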