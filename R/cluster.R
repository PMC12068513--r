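#' k-means clustering of a fragment pool
#'
#' Partitions fragments by k-means over their Morgan fingerprint vectors
#' (Euclidean distance), so that chemically similar fragments share a cluster.
#' Used to factor wide fragment-choice actions into a cluster choice followed
#' by a within-cluster choice. `k` defaults to 100 and is clamped to the
#' number of distinct fingerprints (fragments with identical fingerprints
#' always share a cluster).
#'
#' @param pool a `fragment_pool`, a list of [symmol], or a character vector of
#'   fragment SMILES.
#' @param k_clusters requested number of clusters (default 100).
#' @param seed integer seed for centroid initialisation; the global RNG state
#'   is saved and restored.
#' @param radius,n_bits fingerprint parameters (see [morgan_fingerprint()]).
#' @return an object of class `fragment_clusters`: list with `assignment`
#'   (integer vector, cluster index in `0 .. k-1` per pool row), `k`, and
#'   `members` (list of row-index vectors per cluster).
#' @export
cluster_fragments <- function(pool, k_clusters = 100L, seed = 1L,
                              radius = 2L, n_bits = 512L) {
  smiles <- if (is.data.frame(pool)) pool$smiles
            else if (is.character(pool)) pool
            else vapply(pool, function(m) as_symmol(m)$smiles, character(1))
  n <- length(smiles)
  if (n == 0L) stop("cannot cluster an empty fragment pool", call. = FALSE)
  X <- fp_matrix(lapply(smiles, as_symmol), radius = radius, n_bits = n_bits)
  key <- apply(X, 1L, paste, collapse = "")
  uniq <- !duplicated(key)
  Xu <- X[uniq, , drop = FALSE]
  k <- min(as.integer(k_clusters), nrow(Xu))
  if (k < k_clusters) {
    message("k clamped from ", k_clusters, " to ", k,
            " (distinct fingerprints)")
  }
  assign_u <- if (k == nrow(Xu)) {
    seq_len(nrow(Xu))
  } else {
    with_preserved_rng(seed, {
      stats::kmeans(Xu, centers = k, iter.max = 50L, nstart = 1L)$cluster
    })
  }
  assignment <- assign_u[match(key, key[uniq])] - 1L
  members <- split(seq_len(n), assignment)
  structure(list(assignment = assignment, k = k, members = members,
                 smiles = smiles),
            class = "fragment_clusters")
}

#' @export
print.fragment_clusters <- function(x, ...) {
  cat("<fragment_clusters> ", length(x$assignment), " fragments in ", x$k,
      " clusters\n", sep = "")
  invisible(x)
}

# evaluate `expr` under a fixed seed without disturbing the caller's RNG
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
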