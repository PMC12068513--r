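# One top-level YAML config governs a whole experiment; CLI flags override
# config keys, and every run writes a resolved copy next to its outputs.

default_config <- function() {
  list(
    seed = 1L,
    fingerprint = list(radius = 2L, n_bits = 2048L),
    decompose = list(size_cap = 40L, reactive_cap = 6L),
    cluster = list(k = 100L, n_bits = 512L),
    mdp = list(name = "y6", max_heavy_atoms = 100L, max_bridge_rounds = 2L),
    search = list(n_steps = 2000L, exploration = 1 / sqrt(2), window = 100L),
    reward = list(property_weight = 1, similarity_weight = 1,
                  aggregation = "max"),
    acquisition = list(n_samples = 10000L, n_top = 100L),
    al = list(stopping_rmse = 0.3, max_rounds = 3L),
    select = list(k = 5L)
  )
}

modify_list <- function(base, over) {
  for (nm in names(over)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      modify_list(base[[nm]], over[[nm]])
    } else {
      over[[nm]]
    }
  }
  base
}

#' Load an experiment configuration
#'
#' Reads a YAML file and merges it over the package defaults (missing keys
#' keep their defaults). `NULL` returns the defaults.
#'
#' @param path path to a YAML config, or `NULL`.
#' @param overrides named list merged last (e.g. parsed CLI flags).
#' @return nested list of class `symfrag_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    cfg <- modify_list(cfg, yaml::read_yaml(path))
  }
  cfg <- modify_list(cfg, overrides)
  structure(cfg, class = c("symfrag_config", "list"))
}

#' Write the resolved configuration next to run outputs
#'
#' @param config a config list from [load_config()].
#' @param path output YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# .smi / SDF input, CSV ledgers

#' Read molecules from a .smi or SDF file
#'
#' `.smi`: one record per line, optional whitespace-separated name. SDF files
#' are converted through Open Babel.
#'
#' @param path input file; format chosen by extension (`.smi`/`.smiles`
#'   vs `.sdf`/`.mol`).
#' @return character vector of canonical SMILES (names attached when given).
#' @export
read_molecules <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sdf", "mol")) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    out <- ChemmineOB::convertFormat("SDF", "CAN", txt)
    smi <- strsplit(out, "\n", fixed = TRUE)[[1]]
    smi <- sub("[\t ].*$", "", smi)
    return(smi[nzchar(smi)])
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  smi <- vapply(parts, function(p) as_symmol(p[[1]])$smiles, character(1))
  nm <- vapply(parts, function(p) if (length(p) > 1L) p[[2]] else "",
               character(1))
  if (any(nzchar(nm))) names(smi) <- nm
  smi
}

#' Write molecules to a .smi file
#'
#' @param smiles character vector (names, if any, written as a second
#'   column).
#' @param path output path.
#' @export
write_molecules <- function(smiles, path) {
  nm <- names(smiles)
  lines <- if (is.null(nm)) smiles else {
    ifelse(nzchar(nm), paste(smiles, nm, sep = "\t"), smiles)
  }
  writeLines(lines, path)
  invisible(path)
}
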