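#' Molecules with marked attachment points
#'
#' A `symmol` couples the Open Babel canonical SMILES of a molecule (or
#' molecular fragment) with a parsed molecular graph. Attachment points --
#' reactive positions at which another fragment can be bonded -- are
#' represented as wildcard (`*`) atoms. Each attachment point may carry an
#' integer *mark*; identically marked positions are constrained to receive
#' identical fragments during generation, which is how attachment symmetry is
#' preserved.
#'
#' Serialisation dialect: a mark `m` is written as the isotope `m + 1` of the
#' wildcard atom (`[1*]` is mark 0, `[8*]` is mark 7). Isotope 0 and atom-map
#' annotations do not survive Open Babel canonicalisation, so the offset-by-one
#' isotope is the one encoding that round-trips bit-exactly. Unmarked wildcards
#' are written as plain `*`.
#'
#' @param smiles a single SMILES string.
#' @return `as_symmol()` and `canonicalize()` return a `symmol` object.
#' @examples
#' m <- canonicalize("C1=CC=CC=C1")
#' m$smiles            # aromatic-perceived canonical form "c1ccccc1"
#' heavy_atoms(m)
#' @name symmol
NULL

new_symmol <- function(smiles, graph) {
  structure(list(smiles = smiles, graph = graph), class = "symmol")
}

symmol_from_graph <- function(g) {
  can <- ob_canonical_smiles(write_smiles_graph(g))
  new_symmol(can, parse_smiles_graph(can))
}

#' @rdname symmol
#' @export
as_symmol <- function(smiles) {
  if (inherits(smiles, "symmol")) return(smiles)
  canonicalize(smiles)
}

#' Canonicalize a SMILES string
#'
#' Parses a SMILES string, perceives aromaticity, and returns the molecule in
#' Open Babel canonical form. Canonicalization is idempotent and invariant to
#' the atom order of the input.
#'
#' @param smiles a single SMILES string.
#' @return a [symmol] object; `$smiles` holds the canonical string.
#' @export
canonicalize <- function(smiles) {
  if (inherits(smiles, "symmol")) return(smiles)
  stopifnot(is.character(smiles), length(smiles) == 1L)
  can <- ob_canonical_smiles(smiles)
  new_symmol(can, parse_smiles_graph(can))
}

#' @export
print.symmol <- function(x, ...) {
  ap <- attachment_points(x)
  cat("<symmol> ", x$smiles, "\n", sep = "")
  cat("  heavy atoms: ", heavy_atoms(x), sep = "")
  if (nrow(ap)) {
    cat("; attachment points: ",
        paste(sprintf("%d(mark=%s)", ap$atom_index,
                      ifelse(is.na(ap$mark), "-", ap$mark)), collapse = " "),
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
format.symmol <- function(x, ...) x$smiles

#' Number of heavy atoms
#'
#' Counts non-hydrogen atoms; attachment wildcards are not counted.
#'
#' @param mol a [symmol] or SMILES string.
#' @return integer count.
#' @export
heavy_atoms <- function(mol) {
  mol <- as_symmol(mol)
  graph_heavy_atoms(mol$graph)
}

#' Attachment points of a molecule
#'
#' @param mol a [symmol] or SMILES string.
#' @return a data.frame with columns `atom_index` (index of the wildcard atom
#'   in the canonical graph) and `mark` (integer mark, `NA` if unmarked).
#' @export
attachment_points <- function(mol) {
  mol <- as_symmol(mol)
  g <- mol$graph
  idx <- which(g$elem == "*")
  data.frame(atom_index = idx, mark = g$iso[idx] - 1L)
}

#' Open marks of a molecule
#'
#' @param mol a [symmol].
#' @return sorted unique integer marks present on attachment points.
#' @export
open_marks <- function(mol) {
  ap <- attachment_points(mol)
  sort(unique(ap$mark[!is.na(ap$mark)]))
}

#' Strip marks from attachment points
#'
#' Removes the integer labels from all attachment wildcards while keeping the
#' wildcards themselves, and recanonicalizes. This is the vocabulary lookup
#' form of a fragment: fragments differing only in their historical marks map
#' to the same stripped form, while fragments differing in where they attach
#' stay distinct.
#'
#' @param mol a [symmol] or SMILES string.
#' @return a [symmol] with unlabeled wildcards.
#' @export
strip_marks <- function(mol) {
  mol <- as_symmol(mol)
  g <- mol$graph
  g$iso[g$elem == "*"] <- NA_integer_
  symmol_from_graph(g)
}

# ---------------------------------------------------------------------------
# fingerprints

# package-level cache: ECFP calls through Open Babel dominate runtime
.fp_cache <- new.env(parent = emptyenv())

#' Morgan (circular/ECFP) fingerprint
#'
#' Computes an extended-connectivity fingerprint with Open Babel (`ECFP{2r}`
#' for radius `r`), folded to `n_bits` bits. Identical canonical molecules
#' yield identical fingerprints. Defaults follow community practice
#' (radius 2, 2048 bits).
#'
#' @param mol a [symmol] or SMILES string.
#' @param radius circular neighbourhood radius (default 2).
#' @param n_bits folded fingerprint length (default 2048).
#' @return an object of class `symfp`: list with `bits` (sorted integer
#'   positions of the set bits, 1-based), `radius`, `n_bits`.
#' @export
morgan_fingerprint <- function(mol, radius = 2L, n_bits = 2048L) {
  mol <- as_symmol(mol)
  key <- paste(mol$smiles, radius, n_bits, sep = "\r")
  hit <- .fp_cache[[key]]
  if (!is.null(hit)) return(hit)
  raw <- ob_ecfp_bits(mol$smiles, radius)
  on <- which(raw != 0L)
  folded <- sort(unique(((on - 1L) %% as.integer(n_bits)) + 1L))
  fp <- structure(list(bits = folded, radius = as.integer(radius),
                       n_bits = as.integer(n_bits)), class = "symfp")
  assign(key, fp, envir = .fp_cache)
  fp
}

#' @export
print.symfp <- function(x, ...) {
  cat("<symfp> radius ", x$radius, ", ", x$n_bits, " bits, popcount ",
      length(x$bits), "\n", sep = "")
  invisible(x)
}

# dense 0/1 vector form, used by clustering and PCA
fp_dense <- function(fp) {
  v <- integer(fp$n_bits)
  v[fp$bits] <- 1L
  v
}

fp_matrix <- function(mols, radius = 2L, n_bits = 2048L) {
  fps <- lapply(mols, morgan_fingerprint, radius = radius, n_bits = n_bits)
  do.call(rbind, lapply(fps, fp_dense))
}

#' Tanimoto similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|` over the set bits. Identical non-empty
#' fingerprints give 1; two empty fingerprints give 0 by convention.
#'
#' @param a,b `symfp` objects of equal `n_bits`.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "symfp"), inherits(b, "symfp"))
  if (a$n_bits != b$n_bits) {
    stop("fingerprint length mismatch: ", a$n_bits, " vs ", b$n_bits,
         call. = FALSE)
  }
  un <- length(union(a$bits, b$bits))
  if (un == 0L) return(0)
  length(intersect(a$bits, b$bits)) / un
}

# ---------------------------------------------------------------------------
# attachment and capping (graph-level workers + symmol-level API)

# bond `frag` at every wildcard of `g` carrying `mark` (single bonds).
# The fragment's first attachment point (canonical order) is the bonding
# point; its remaining attachment points become open positions with fresh
# marks. With several identically marked positions, corresponding open
# positions on the attached copies share one fresh mark, so symmetric sites
# remain constrained to identical future attachments.
# `mark_base`: fresh marks are chosen strictly above this floor as well as
# above every mark present on either graph; callers that consume marks over a
# trajectory pass a monotone counter so mark values are never recycled.
graph_attach_at_mark <- function(g, mark, fg, mark_base = 0L) {
  sites <- which(g$elem == "*" & !is.na(g$iso) & g$iso == mark + 1L)
  if (!length(sites)) {
    stop("no attachment point carries mark ", mark, call. = FALSE)
  }
  fsites <- which(fg$elem == "*")
  if (!length(fsites)) {
    stop("fragment has no free attachment point", call. = FALSE)
  }
  fhook <- fsites[1L]
  fanchor <- graph_neighbors(fg, fhook)
  if (length(fanchor) != 1L) {
    stop("fragment attachment point must have exactly one neighbor",
         call. = FALSE)
  }
  frest <- setdiff(fsites, fhook)
  # fresh marks: one per remaining fragment attachment point, shared by copies
  used <- c(g$iso[g$elem == "*"], fg$iso[fg$elem == "*"])
  used <- used[!is.na(used)]
  base <- max(c(used, as.integer(mark_base)), 0L)
  fresh <- if (length(frest)) base + seq_along(frest) else integer(0)

  repeat {
    s <- which(g$elem == "*" & !is.na(g$iso) & g$iso == mark + 1L)
    if (!length(s)) break
    s <- s[1L]
    anchor <- graph_neighbors(g, s)
    if (length(anchor) != 1L) {
      stop("attachment wildcard at atom ", s, " must have exactly one neighbor",
           call. = FALSE)
    }
    u <- graph_union(g, fg)
    g <- u$graph
    off <- u$offset
    g$iso[off + frest] <- fresh
    g$iso[off + fhook] <- NA_integer_
    # join the two anchors directly; both wildcards are consumed
    g <- graph_add_bond(g, anchor, off + fanchor, 1L, FALSE)
    g <- graph_subset(g, setdiff(seq_len(graph_n_atoms(g)), c(s, off + fhook)))
  }
  g
}

graph_cap_open <- function(g, cap = c("hydrogen", "methyl")) {
  cap <- match.arg(cap)
  repeat {
    s <- which(g$elem == "*")
    if (!length(s)) break
    s <- s[1L]
    if (cap == "methyl") {
      g$elem[s] <- "C"
      g$arom[s] <- FALSE
      g$iso[s] <- NA_integer_
      g$hcount[s] <- NA_integer_
    } else {
      nb <- graph_neighbors(g, s)
      g <- graph_subset(g, setdiff(seq_len(graph_n_atoms(g)), s))
      nb <- nb - (nb > s)
      # hydrogen capping frees one valence slot; bare aromatic N/P cannot
      # absorb it implicitly (pyrrole-type nitrogen), so make it explicit
      for (a in nb) {
        if (g$arom[a] && g$elem[a] %in% c("N", "P") && is.na(g$hcount[a])) {
          g$hcount[a] <- 1L
        } else if (!is.na(g$hcount[a])) {
          g$hcount[a] <- g$hcount[a] + 1L
        }
      }
    }
  }
  g
}

#' Attach a fragment at a marked position
#'
#' Bonds one copy of `frag` (by a single bond) at *every* attachment point of
#' `mol` that carries `mark`; those attachment points are consumed. The
#' fragment's first free attachment point is the bonding site. Its remaining
#' attachment points become new open positions with fresh marks; when several
#' identically marked positions are filled at once, corresponding new
#' positions on the copies share a fresh mark, so the attachment symmetry
#' propagates.
#'
#' @param mol a [symmol] with at least one attachment point carrying `mark`.
#' @param mark integer mark to fill.
#' @param frag a [symmol] fragment with at least one free attachment point.
#' @return the product [symmol].
#' @export
attach_at_mark <- function(mol, mark, frag) {
  mol <- as_symmol(mol)
  frag <- as_symmol(frag)
  symmol_from_graph(graph_attach_at_mark(mol$graph, mark, frag$graph))
}

#' Cap all open attachment points
#'
#' Replaces every attachment wildcard either by a hydrogen (wildcard removed;
#' heavy-atom count unchanged) or by a methyl group (one heavy atom added per
#' capped position). A molecule without open positions is returned unchanged.
#'
#' @param mol a [symmol] or SMILES string.
#' @param cap `"hydrogen"` or `"methyl"`.
#' @return a [symmol] with no attachment points.
#' @export
cap_open_positions <- function(mol, cap = c("hydrogen", "methyl")) {
  mol <- as_symmol(mol)
  cap <- match.arg(cap)
  if (!any(mol$graph$elem == "*")) return(mol)
  symmol_from_graph(graph_cap_open(mol$graph, cap))
}
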