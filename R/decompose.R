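# Symmetry-preserving fragment decomposition: cleave single bonds between an
# aromatic ring and an aliphatic chain, or between two aromatic rings,
# recursively (a binary tree of one-bond deletions), labelling each new
# reactive position with the vocabulary ID of the fragment removed there.

#' Find cleavable bonds
#'
#' A bond is cleavable when it is a single, non-aromatic, acyclic bond between
#' two heavy atoms of which at least one is aromatic: this matches single
#' bonds connecting an aromatic ring to an aliphatic chain and inter-ring
#' single bonds between two aromatic systems. Ring bonds are never cleaved.
#'
#' @param mol a [symmol] or SMILES string.
#' @return a data.frame with one row per cleavable bond: `bond` (index into
#'   the graph's bond table), `a1`, `a2` (atom indices, `a1 < a2`), ordered by
#'   canonical atom index.
#' @export
find_cleavable_bonds <- function(mol) {
  mol <- as_symmol(mol)
  g <- mol$graph
  m <- graph_n_bonds(g)
  if (m == 0L) {
    return(data.frame(bond = integer(0), a1 = integer(0), a2 = integer(0)))
  }
  ring <- graph_ring_bonds(g)
  e1 <- g$bond[, 1]; e2 <- g$bond[, 2]
  ok <- g$border == 1L & !g$barom & !ring &
    g$elem[e1] != "*" & g$elem[e2] != "*" &
    (g$arom[e1] | g$arom[e2])
  idx <- which(ok)
  lo <- pmin(e1[idx], e2[idx]); hi <- pmax(e1[idx], e2[idx])
  o <- order(lo, hi)
  data.frame(bond = idx[o], a1 = lo[o], a2 = hi[o])
}

# cleave bond b of graph g; returns both sides as graphs, each with one fresh
# unmarked wildcard, plus the wildcard's atom index on each side
cleave_graph_bond <- function(g, b) {
  a1 <- g$bond[b, 1]; a2 <- g$bond[b, 2]
  gx <- graph_delete_bond(g, b)
  comp <- graph_components(gx)
  side <- function(anchor) {
    keep <- which(comp == comp[anchor])
    sub <- graph_subset(gx, keep)
    pos <- match(anchor, sort(keep))
    sub <- graph_add_atom(sub, "*", FALSE)
    sub <- graph_add_bond(sub, pos, graph_n_atoms(sub), 1L, FALSE)
    list(graph = sub, dummy = graph_n_atoms(sub))
  }
  list(side1 = side(a1), side2 = side(a2))
}

# canonical form with marks stripped (wildcards retained)
stripped_form <- function(g) {
  g$iso[g$elem == "*"] <- NA_integer_
  ob_canonical_smiles(write_smiles_graph(g))
}

#' Build the single-cut fragment vocabulary of a molecule
#'
#' Applies every possible one-bond deletion to the molecule, canonicalizes
#' both resulting fragments (marks stripped, attachment wildcard retained),
#' deduplicates the forms and assigns contiguous integer IDs over the sorted
#' unique forms. A molecule without cleavable bonds yields a vocabulary
#' containing only the whole molecule.
#'
#' @param mol a [symmol] or SMILES string.
#' @return a [fragment_vocabulary].
#' @export
build_vocabulary <- function(mol) {
  mol <- as_symmol(mol)
  fragment_vocabulary(single_cut_forms(mol))
}

single_cut_forms <- function(mol) {
  mol <- as_symmol(mol)
  bonds <- find_cleavable_bonds(mol)
  if (!nrow(bonds)) return(strip_marks(mol)$smiles)
  forms <- character(0)
  for (b in bonds$bond) {
    cut <- cleave_graph_bond(mol$graph, b)
    forms <- c(forms, stripped_form(cut$side1$graph),
               stripped_form(cut$side2$graph))
  }
  unique(forms)
}

#' Recursive symmetry-preserving decomposition
#'
#' Recursively deletes cleavable bonds (always the first in canonical
#' atom-index order), forming a binary tree. At every cleavage the new
#' reactive position on each side is marked with the vocabulary ID of the
#' *other* side's stripped canonical form, so that a leaf's marks record the
#' identities of its former neighbours: two positions on a leaf carry the same
#' mark exactly when the counterparts removed there were identical. Fragments
#' with no cleavable bond are leaves. Previously decomposed fragments are
#' reused from a memo table keyed by the canonical marked form.
#'
#' Counterpart forms that are absent from the single-cut vocabulary (possible
#' from recursion depth 2 on, when a counterpart carries inherited marks) are
#' appended to the vocabulary with the next free ID.
#'
#' @param mol a [symmol] or SMILES string.
#' @param vocab a [fragment_vocabulary], typically from [build_vocabulary()];
#'   built automatically when `NULL`. May be extended (in place) during
#'   recursion.
#' @param memoize reuse previously decomposed fragments (identical output
#'   either way; `FALSE` recomputes every subtree).
#' @return an object of class `decomposition`: list with `leaves` (list of
#'   marked [symmol] fragments), `tree` (nested list: `fragment`, and for
#'   internal nodes `bond` and `children`), `vocab`, and `assignments` (a
#'   data.frame of every distinct (mark, counterpart stripped form) pair
#'   assigned during the recursion -- positions share a mark exactly when
#'   their removed counterparts share a form, so this relation must be a
#'   bijection).
#' @export
decompose <- function(mol, vocab = NULL, memoize = TRUE) {
  mol <- as_symmol(mol)
  if (is.null(vocab)) vocab <- build_vocabulary(mol)
  memo <- new.env(parent = emptyenv())
  assignments <- list()   # every (mark, counterpart form) pair ever assigned

  rec <- function(frag) {
    key <- frag$smiles
    if (memoize) {
      hit <- memo[[key]]
      if (!is.null(hit)) return(hit)
    }
    bonds <- find_cleavable_bonds(frag)
    if (!nrow(bonds)) {
      res <- list(leaves = list(frag), tree = list(fragment = frag$smiles))
    } else {
      b <- bonds$bond[1L]
      cut <- cleave_graph_bond(frag$graph, b)
      g1 <- cut$side1$graph; g2 <- cut$side2$graph
      f1 <- stripped_form(g1); f2 <- stripped_form(g2)
      id1 <- vocab_id(vocab, f1, extend = TRUE)
      id2 <- vocab_id(vocab, f2, extend = TRUE)
      g1$iso[cut$side1$dummy] <- id2 + 1L   # mark = counterpart's ID
      g2$iso[cut$side2$dummy] <- id1 + 1L
      assignments[[length(assignments) + 1L]] <<-
        data.frame(mark = c(id2, id1), counterpart = c(f2, f1),
                   stringsAsFactors = FALSE)
      r1 <- rec(symmol_from_graph(g1))
      r2 <- rec(symmol_from_graph(g2))
      res <- list(
        leaves = c(r1$leaves, r2$leaves),
        tree = list(fragment = frag$smiles,
                    bond = c(bonds$a1[1L], bonds$a2[1L]),
                    children = list(r1$tree, r2$tree)))
    }
    if (memoize) assign(key, res, envir = memo)
    res
  }

  out <- rec(mol)
  asg <- if (length(assignments)) {
    unique(do.call(rbind, assignments))
  } else {
    data.frame(mark = integer(0), counterpart = character(0),
               stringsAsFactors = FALSE)
  }
  structure(list(leaves = out$leaves, tree = out$tree, vocab = vocab,
                 molecule = mol$smiles, assignments = asg),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat("<decomposition> of ", x$molecule, "\n", sep = "")
  cat("  ", length(x$leaves), " leaves; vocabulary size ",
      vocab_size(x$vocab), "\n", sep = "")
  for (l in x$leaves) cat("   - ", l$smiles, "\n", sep = "")
  invisible(x)
}

#' Reassemble a decomposition
#'
#' Inverse of [decompose()], used as the round-trip oracle: joins two
#' fragments whose marks mutually reference each other's stripped canonical
#' forms (fragment `f` carries a mark equal to the vocabulary ID of
#' `strip(g)`, and vice versa), consuming one attachment point on each, until
#' a single unmarked molecule remains. Because several leaves can share a
#' stripped form (e.g. repeated bridges), a locally mutual join may conflict
#' with the original cut order; the search therefore backtracks over join
#' choices, memoising failed pool states.
#'
#' @param leaves list of marked [symmol] fragments (or SMILES strings).
#' @param vocab the [fragment_vocabulary] the marks refer to.
#' @return the reassembled [symmol].
#' @export
reassemble <- function(leaves, vocab) {
  pool0 <- lapply(leaves, as_symmol)
  if (!length(pool0)) stop("no fragments to reassemble", call. = FALSE)

  stripped_id <- function(m) vocab_id(vocab, stripped_form(m$graph))
  marks_of <- function(m) {
    ap <- attachment_points(m)
    ap$mark[!is.na(ap$mark)]
  }
  failed <- new.env(parent = emptyenv())
  pool_key <- function(pool) {
    paste(sort(vapply(pool, function(m) m$smiles, character(1))),
          collapse = "|")
  }

  rec <- function(pool) {
    if (length(pool) == 1L && !length(marks_of(pool[[1L]]))) {
      return(pool[[1L]])
    }
    k <- pool_key(pool)
    if (!is.null(failed[[k]])) return(NULL)
    ids <- vapply(pool, stripped_id, integer(1))
    marks <- lapply(pool, marks_of)
    tried <- character(0)
    for (i in seq_along(pool)) {
      for (j in seq_along(pool)) {
        if (i == j) next
        if (!is.na(ids[j]) && ids[j] %in% marks[[i]] &&
            !is.na(ids[i]) && ids[i] %in% marks[[j]]) {
          sig <- paste(pool[[i]]$smiles, pool[[j]]$smiles)
          if (sig %in% tried) next          # symmetric duplicate join
          tried <- c(tried, sig)
          merged <- join_fragments(pool[[i]], ids[j], pool[[j]], ids[i])
          res <- rec(c(list(merged), pool[-c(i, j)]))
          if (!is.null(res)) return(res)
        }
      }
    }
    assign(k, TRUE, envir = failed)
    NULL
  }

  out <- rec(pool0)
  if (is.null(out)) {
    orphans <- sort(unique(unlist(lapply(pool0, marks_of))))
    stop("cannot reassemble: unresolvable marks {",
         paste(orphans, collapse = ", "), "}", call. = FALSE)
  }
  out
}

# join one attachment point with mark mi on mol i to one with mark mj on mol j
join_fragments <- function(mi_mol, mi, mj_mol, mj) {
  gi <- mi_mol$graph; gj <- mj_mol$graph
  si <- which(gi$elem == "*" & !is.na(gi$iso) & gi$iso == mi + 1L)[1L]
  sj <- which(gj$elem == "*" & !is.na(gj$iso) & gj$iso == mj + 1L)[1L]
  ai <- graph_neighbors(gi, si)
  aj <- graph_neighbors(gj, sj)
  u <- graph_union(gi, gj)
  g <- u$graph
  g <- graph_add_bond(g, ai, u$offset + aj, 1L, FALSE)
  g <- graph_subset(g, setdiff(seq_len(graph_n_atoms(g)), c(si, u$offset + sj)))
  symmol_from_graph(g)
}

#' Decompose a corpus into a filtered fragment pool
#'
#' Builds one global vocabulary over all single-cut fragment forms of the
#' corpus (sorted, deduplicated), decomposes every molecule against it, and
#' merges the resulting leaves into a pool with occurrence counts. Fragments
#' with more than `reactive_cap` reactive positions or more than `size_cap`
#' heavy atoms are filtered out.
#'
#' @param mols list of [symmol] objects or character vector of SMILES.
#' @param size_cap maximum heavy atoms per pool fragment (default 40).
#' @param reactive_cap maximum reactive positions per pool fragment
#'   (default 6).
#' @return an object of class `fragment_pool`: data.frame with columns
#'   `smiles` (canonical marked form), `count`, `n_heavy`, `n_reactive`;
#'   the shared vocabulary is in `attr(, "vocab")`.
#' @export
decompose_corpus <- function(mols, size_cap = 40L, reactive_cap = 6L) {
  if (is.character(mols)) mols <- as.list(mols)
  mols <- lapply(mols, as_symmol)
  empty <- data.frame(smiles = character(0), count = integer(0),
                      n_heavy = integer(0), n_reactive = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(mols)) {
    return(structure(empty, vocab = fragment_vocabulary(),
                     class = c("fragment_pool", "data.frame")))
  }
  forms <- unlist(lapply(mols, single_cut_forms))
  vocab <- fragment_vocabulary(forms)
  leaves <- list()
  for (m in mols) {
    d <- decompose(m, vocab)
    leaves <- c(leaves, d$leaves)
  }
  smi <- vapply(leaves, function(l) l$smiles, character(1))
  tab <- table(smi)
  keys <- names(tab)
  by_key <- leaves[match(keys, smi)]
  n_heavy <- vapply(by_key, heavy_atoms, integer(1))
  n_react <- vapply(by_key, function(l) nrow(attachment_points(l)), integer(1))
  keep <- n_heavy <= size_cap & n_react <= reactive_cap
  pool <- data.frame(smiles = keys[keep], count = as.integer(tab)[keep],
                     n_heavy = n_heavy[keep], n_reactive = n_react[keep],
                     stringsAsFactors = FALSE)
  pool <- pool[order(pool$smiles), , drop = FALSE]
  rownames(pool) <- NULL
  structure(pool, vocab = vocab, class = c("fragment_pool", "data.frame"))
}

#' Select pool fragments by generation role
#'
#' Roles restrict which pool fragments may serve at each stage of the open
#' (patent-style) assembly grammar: cores and end-groups may be any fragment
#' with at least one reactive position, pi-bridges need at least two (one bond
#' to the existing molecule plus one onward position).
#'
#' @param pool a `fragment_pool` from [decompose_corpus()].
#' @param role `"core"`, `"bridge"`, or `"end"`.
#' @return the subset of `pool` rows eligible for the role.
#' @export
pool_role <- function(pool, role = c("core", "bridge", "end")) {
  role <- match.arg(role)
  keep <- switch(role,
                 core = pool$n_reactive >= 1L,
                 bridge = pool$n_reactive >= 2L,
                 end = pool$n_reactive >= 1L)
  pool[keep, , drop = FALSE]
}
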