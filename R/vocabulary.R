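#' Fragment vocabulary
#'
#' A bijection between canonical fragment forms (marks stripped, attachment
#' wildcards retained) and contiguous integer IDs `0 .. N-1`. IDs double as
#' the marks placed on reactive positions: a mark is the ID of the fragment
#' that was attached there before the bond was cleaved.
#'
#' The object is environment-backed so that recursive decomposition can append
#' forms that only arise at recursion depth >= 2 (a counterpart carrying
#' inherited attachment points is not always in the single-cut vocabulary);
#' such forms receive the next free ID in discovery order, which is
#' deterministic given the input.
#'
#' @param forms character vector of canonical fragment SMILES; entries are
#'   sorted before ID assignment so vocabularies are reproducible.
#' @return an object of class `fragment_vocabulary`.
#' @export
fragment_vocabulary <- function(forms = character(0)) {
  e <- new.env(parent = emptyenv())
  e$forms <- character(0)
  e$map <- new.env(parent = emptyenv())
  v <- structure(list(e = e), class = "fragment_vocabulary")
  for (f in sort(unique(forms))) vocab_id(v, f, extend = TRUE)
  v
}

#' @rdname fragment_vocabulary
#' @param vocab a `fragment_vocabulary`.
#' @export
vocab_size <- function(vocab) length(vocab$e$forms)

#' Look up (or append) the ID of a canonical fragment form
#'
#' @param vocab a [fragment_vocabulary].
#' @param form canonical fragment SMILES with marks stripped.
#' @param extend if `TRUE`, an absent form is appended with the next free ID.
#' @return integer ID in `0 .. N-1`, or `NA` if absent and `extend = FALSE`.
#' @export
vocab_id <- function(vocab, form, extend = FALSE) {
  hit <- vocab$e$map[[form]]
  if (!is.null(hit)) return(hit)
  if (!extend) return(NA_integer_)
  id <- length(vocab$e$forms)
  vocab$e$forms <- c(vocab$e$forms, form)
  assign(form, id, envir = vocab$e$map)
  id
}

#' @rdname vocab_id
#' @param id integer ID.
#' @return `vocab_form()` returns the canonical SMILES registered under `id`.
#' @export
vocab_form <- function(vocab, id) {
  stopifnot(id >= 0L, id < vocab_size(vocab))
  vocab$e$forms[[id + 1L]]
}

#' @export
as.data.frame.fragment_vocabulary <- function(x, ...) {
  data.frame(id = seq_along(x$e$forms) - 1L, smiles = x$e$forms,
             stringsAsFactors = FALSE)
}

#' @export
print.fragment_vocabulary <- function(x, ...) {
  cat("<fragment_vocabulary> ", vocab_size(x), " entries\n", sep = "")
  df <- as.data.frame(x)
  print(utils::head(df, 10L), row.names = FALSE)
  if (nrow(df) > 10L) cat("  ... ", nrow(df) - 10L, " more\n", sep = "")
  invisible(x)
}

# JSON round trip -----------------------------------------------------------

#' Read/write a fragment vocabulary as JSON
#'
#' The on-disk format is `{"entries": [{"id": 0, "smiles": "..."}]}`.
#'
#' @param vocab a [fragment_vocabulary].
#' @param path file path.
#' @export
write_vocabulary <- function(vocab, path) {
  df <- as.data.frame(vocab)
  jsonlite::write_json(list(entries = df), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ent <- x$entries[order(x$entries$id), , drop = FALSE]
  v <- fragment_vocabulary()
  for (f in ent$smiles) vocab_id(v, f, extend = TRUE)
  v
}
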