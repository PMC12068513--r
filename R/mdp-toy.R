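#' Enumerable two-level toy MDP
#'
#' A deliberately small deterministic environment for testing and
#' benchmarking the search: stage 1 chooses a monovalent core (one marked
#' position), stage 2 chooses an end-group attached at that position, giving
#' `length(cores) * length(ends)` terminal molecules that
#' [enumerate_terminals()] can list exhaustively.
#'
#' @param cores character vector of core fragments, each with exactly one
#'   marked attachment point.
#' @param ends character vector of end-group fragments, each with exactly one
#'   attachment wildcard.
#' @return a `symfrag_mdp` environment.
#' @export
toy_mdp <- function(
    cores = c("[1*]c1ccc(s1)", "[1*]c1ccc(o1)", "[1*]c1ccc([se]1)",
              "[1*]c1ccc(cc1)", "[1*]c1ccc(s1)c1ccc(s1)",
              "[1*]C=Cc1ccc(s1)", "[1*]c1ccc(cc1)c1ccc(cc1)",
              "[1*]c1cc2c(s1)cccc2", "[1*]c1ccc(nc1)", "[1*]C=Cc1ccc(o1)"),
    ends = c("*C", "*C=C", "*C=O", "*C#N", "*C=C(C#N)C#N", "*c1ccccc1",
             "*c1ccc(s1)", "*c1ccc(C#N)cc1", "*C(F)(F)F", "*C=Cc1ccccc1",
             "*N(C)C", "*OC")) {
  core_graphs <- lapply(cores,
                        function(s) parse_smiles_graph(ob_canonical_smiles(s)))
  end_graphs <- lapply(ends,
                       function(s) parse_smiles_graph(ob_canonical_smiles(s)))

  init <- function() {
    new_generation_state(NULL, "core", terminal = FALSE)
  }
  legal <- function(state) {
    switch(state$stage,
      core = lapply(seq_along(cores), function(i) {
        action_spec("choose-fragment", i, label = cores[i])
      }),
      end = lapply(seq_along(ends), function(i) {
        action_spec("choose-end-group", i, label = ends[i])
      }),
      terminal = list())
  }
  step <- function(state, action) {
    ns <- switch(state$stage,
      core = {
        stopifnot(action$kind == "choose-fragment")
        new_generation_state(core_graphs[[action$payload]], "end",
                             terminal = FALSE)
      },
      end = {
        stopifnot(action$kind == "choose-end-group")
        g <- graph_attach_at_mark(state$graph, 0L, end_graphs[[action$payload]])
        new_generation_state(g, "terminal", terminal = TRUE)
      },
      stop("terminal state", call. = FALSE))
    transition_result(ns)
  }
  term <- function(state) identical(state$stage, "terminal")
  traj <- function(state) {
    if (!term(state)) stop("state is not terminal", call. = FALSE)
    symmol_from_graph(state$graph)
  }
  key <- function(state) {
    paste(state$stage,
          if (!is.null(state$graph)) write_smiles_graph(state$graph) else "",
          sep = "|")
  }
  new_mdp("toy", init, legal, step, term, traj, key)
}
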