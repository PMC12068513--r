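# Open Babel glue. All canonicalisation and aromaticity perception is
# delegated to Open Babel (via ChemmineOB); everything downstream assumes the
# dialect of its canonical SMILES writer.

#' @importFrom ChemmineOB convertFormat forEachMol fingerprint_OB
NULL

# Canonicalise one or more SMILES strings with Open Babel.
# Returns a character vector; stops with the offending string on failure.
ob_canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  bad <- !nzchar(trimws(smiles))
  if (any(bad)) stop("invalid SMILES: empty string", call. = FALSE)
  out <- character(length(smiles))
  # Open Babel silently drops unparseable records, so convert one by one to
  # keep input/output alignment and be able to name the offender.
  for (i in seq_along(smiles)) {
    res <- suppressWarnings(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles[[i]], "\n"))
    )
    res <- sub("[\t ]*\n?$", "", res)
    if (!nzchar(res)) {
      stop("invalid SMILES: could not parse '", smiles[[i]], "'", call. = FALSE)
    }
    out[[i]] <- res
  }
  out
}

# Raw Open Babel ECFP bits for a SMILES (radius r -> ECFP{2r}, 4096 bits).
ob_ecfp_bits <- function(smiles, radius) {
  name <- paste0("ECFP", 2L * as.integer(radius))
  mols <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  bits <- ChemmineOB::fingerprint_OB(mols, name)
  if (is.matrix(bits)) bits <- bits[1L, ]
  as.integer(bits)
}
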