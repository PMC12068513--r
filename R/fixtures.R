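# Synthetic fixture corpus: molecules assembled from a small library of
# aromatic cores, bridges and end-groups with known symmetry, so that the
# exact constituent fragments and the expected mark structure of every
# molecule are available as ground truth. Every junction bond involves an
# aromatic atom, is single and acyclic, and no library piece contains an
# internal cleavable bond, so decomposition recovers exactly the pieces.

#' Fixture corpus specification
#'
#' @param n_cores number of core variants (cyclic systems carrying the marked
#'   sites), at most the size of the built-in template grid.
#' @param n_bridges number of divalent bridge variants.
#' @param n_endgroups number of monovalent end-group variants.
#' @param symmetry_degree integer vector: the admissible numbers of identical
#'   (same-mark) attachment sites per core; one value is sampled per
#'   symmetric molecule.
#' @param n_molecules corpus size.
#' @param p_bridge probability that a symmetric molecule receives a bridge
#'   between core and end-group.
#' @param p_contrast probability of a "contrast" molecule: a core with two
#'   *differently* marked sites receiving independently sampled end-groups
#'   (sometimes equal, sometimes not) -- the discriminating case for
#'   symmetry-label checks.
#' @param seed RNG seed; corpora are reproducible given the spec.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_cores = 4L, n_bridges = 3L, n_endgroups = 6L,
                         symmetry_degree = c(2L, 3L), n_molecules = 20L,
                         p_bridge = 0.5, p_contrast = 0.3, seed = 1L) {
  stopifnot(n_cores >= 1L, n_bridges >= 1L, n_endgroups >= 1L,
            n_molecules >= 1L, all(symmetry_degree %in% 1:3))
  structure(list(n_cores = n_cores, n_bridges = n_bridges,
                 n_endgroups = n_endgroups,
                 symmetry_degree = as.integer(symmetry_degree),
                 n_molecules = n_molecules, p_bridge = p_bridge,
                 p_contrast = p_contrast, seed = as.integer(seed)),
            class = "fixture_spec")
}

fixture_library <- function(spec) {
  rings <- c("s1", "o1", "[se]1", "cc1")
  core_by_degree <- list(
    `1` = sprintf("[1*]c1ccc(%s)", rings),
    `2` = sprintf("[1*]c1ccc([1*])%s", rings),
    `3` = "[1*]c1cc([1*])cc([1*])c1")
  cores <- lapply(spec$symmetry_degree, function(d) {
    pool <- core_by_degree[[as.character(d)]]
    utils::head(rep_len(pool, max(spec$n_cores, 1L)), spec$n_cores)
  })
  names(cores) <- as.character(spec$symmetry_degree)
  contrast_cores <- utils::head(sprintf("[1*]c1ccc([2*])%s", rings),
                                max(spec$n_cores, 1L))
  bridges <- utils::head(sprintf("[1*]c1ccc([1*])%s",
                                 c("s1", "o1", "cc1", "nc1")),
                         spec$n_bridges)
  ends <- utils::head(c("[1*]C", "[1*]OC", "[1*]C(F)(F)F", "[1*]c1ccccc1",
                        "[1*]c1ccc(s1)", "[1*]N(C)C", "[1*]C#N",
                        "[1*]c1ccc(nc1)"),
                      spec$n_endgroups)
  list(cores = cores, contrast_cores = contrast_cores, bridges = bridges,
       ends = ends)
}

#' Generate a fixture corpus with ground truth
#'
#' Assembles `n_molecules` molecules by marked attachment from the fixture
#' library. Symmetric molecules place one end-group (optionally through one
#' bridge) on all `degree` identically marked core sites; contrast molecules
#' place two independently sampled end-groups on two differently marked
#' sites. The constituent pieces and the expected symmetry of each molecule
#' are recorded alongside.
#'
#' @param spec a [fixture_spec()].
#' @return an object of class `fixture_corpus`: data.frame with columns
#'   `smiles` (canonical, fully assembled), `kind` (`"symmetric"` /
#'   `"contrast"`), `degree`, `core`, `bridge` (`NA` if none), `end`, `end2`
#'   (`NA` unless contrast), `ends_equal`; the library is in
#'   `attr(, "library")`.
#' @export
generate_fixtures <- function(spec = fixture_spec()) {
  lib <- fixture_library(spec)
  core_mols <- lapply(lib$cores, function(v) lapply(v, canonicalize))
  contrast_mols <- lapply(lib$contrast_cores, canonicalize)
  bridge_mols <- lapply(lib$bridges, canonicalize)
  end_mols <- lapply(lib$ends, canonicalize)

  rows <- with_preserved_rng(spec$seed, {
    lapply(seq_len(spec$n_molecules), function(j) {
      contrast <- stats::runif(1) < spec$p_contrast
      if (contrast) {
        ci <- sample.int(length(contrast_mols), 1L)
        e1 <- sample.int(length(end_mols), 1L)
        e2 <- sample.int(length(end_mols), 1L)
        mol <- attach_at_mark(contrast_mols[[ci]], 0L, end_mols[[e1]])
        mol <- attach_at_mark(mol, 1L, end_mols[[e2]])
        data.frame(smiles = mol$smiles, kind = "contrast", degree = 1L,
                   core = lib$contrast_cores[ci], bridge = NA_character_,
                   end = lib$ends[e1], end2 = lib$ends[e2],
                   ends_equal = lib$ends[e1] == lib$ends[e2],
                   stringsAsFactors = FALSE)
      } else {
        d <- if (length(spec$symmetry_degree) == 1L) spec$symmetry_degree
             else sample(spec$symmetry_degree, 1L)
        di <- match(d, spec$symmetry_degree)
        ki <- sample.int(length(core_mols[[di]]), 1L)
        mol <- core_mols[[di]][[ki]]
        bi <- NA_integer_
        mark <- 0L
        if (stats::runif(1) < spec$p_bridge) {
          bi <- sample.int(length(bridge_mols), 1L)
          mol <- attach_at_mark(mol, mark, bridge_mols[[bi]])
          mark <- max(open_marks(mol))
        }
        ei <- sample.int(length(end_mols), 1L)
        mol <- attach_at_mark(mol, mark, end_mols[[ei]])
        data.frame(smiles = mol$smiles, kind = "symmetric", degree = d,
                   core = lib$cores[[di]][ki],
                   bridge = if (is.na(bi)) NA_character_ else lib$bridges[bi],
                   end = lib$ends[ei], end2 = NA_character_,
                   ends_equal = TRUE, stringsAsFactors = FALSE)
      }
    })
  })
  out <- do.call(rbind, rows)
  structure(out, library = lib, class = c("fixture_corpus", "data.frame"))
}
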