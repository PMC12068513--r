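# Candidate-analysis helpers: cluster-then-pick selection of a diverse final
# slate, and a 2-D PCA projection of fingerprint space for inspection.

#' Select a diverse slate of best candidates
#'
#' Deduplicates the candidates by canonical form, k-means-clusters their
#' Morgan fingerprints into `k` clusters, and flags, within each cluster, the
#' candidate with the lowest predicted bandgap (equivalently the highest
#' property reward). With fewer distinct candidates than `k`, `k` is clamped.
#'
#' @param candidates character vector of SMILES (e.g. a search ledger's
#'   molecules).
#' @param k number of clusters (default 5).
#' @param predictor a [property_predictor()] scoring the bandgap.
#' @param seed clustering seed.
#' @param radius,n_bits fingerprint parameters.
#' @return a `candidate_table` data.frame: `smiles`, `bandgap`, `cluster`
#'   (0-based), `selected` (exactly one `TRUE` per cluster).
#' @export
select_diverse_lowest <- function(candidates, k = 5L, predictor,
                                  seed = 1L, radius = 2L, n_bits = 2048L) {
  smi <- unique(as_smiles_vector(candidates))
  if (length(smi) < 1L) stop("no candidates", call. = FALSE)
  cl <- cluster_fragments(smi, k_clusters = k, seed = seed,
                          radius = radius, n_bits = n_bits)
  bg <- predict(predictor, smi)
  tab <- data.frame(smiles = smi, bandgap = bg, cluster = cl$assignment,
                    selected = FALSE, stringsAsFactors = FALSE)
  for (ci in unique(tab$cluster)) {
    idx <- which(tab$cluster == ci)
    tab$selected[idx[which.min(tab$bandgap[idx])]] <- TRUE
  }
  tab <- tab[order(tab$cluster, tab$bandgap), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("candidate_table", "data.frame"))
}

#' 2-D PCA projection of fingerprint space
#'
#' Fits a principal-component basis on the Morgan fingerprints of candidates
#' and optional reference molecules together, and returns the coordinates of
#' every molecule on the first two components (for plotting generated
#' candidates against known materials).
#'
#' @param candidates character vector of SMILES.
#' @param references optional second set sharing the fitted basis.
#' @param radius,n_bits fingerprint parameters.
#' @return data.frame `(smiles, set, pc1, pc2)` with `set` in
#'   `"candidate"` / `"reference"`.
#' @export
pca_projection <- function(candidates, references = character(0),
                           radius = 2L, n_bits = 2048L) {
  cand <- as_smiles_vector(candidates)
  refs <- if (length(references)) as_smiles_vector(references) else character(0)
  all_smi <- c(cand, refs)
  if (length(all_smi) < 2L) stop("need at least 2 molecules", call. = FALSE)
  X <- fp_matrix(lapply(all_smi, as_symmol), radius, n_bits)
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = 2L)
  sc <- p$x
  if (ncol(sc) < 2L) sc <- cbind(sc, 0)   # degenerate rank-1 input
  data.frame(smiles = all_smi,
             set = rep(c("candidate", "reference"),
                       c(length(cand), length(refs))),
             pc1 = sc[, 1L], pc2 = sc[, 2L],
             stringsAsFactors = FALSE)
}
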