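# Environment contract for molecular-assembly Markov decision processes.
#
# An environment is a list of closures (class "symfrag_mdp"):
#   initial_state()                  -> generation_state
#   legal_actions(state)             -> list of action_spec (empty if terminal)
#   step(state, action)              -> transition_result
#   is_terminal(state)               -> logical
#   trajectory_molecule(state)       -> symmol (terminal states only)
#   state_key(state)                 -> character scalar
#
# Stochasticity is confined to the choice of reactive position inside step();
# it draws from R's global RNG so that searches seeded once are reproducible.

#' Generation state
#'
#' Snapshot of a partial molecule inside an assembly MDP: the molecular graph
#' with open marked positions, the stage pointer, and bookkeeping (fragments
#' already used, heavy-atom count, pi-bridge rounds).
#'
#' @param graph internal molecular graph (may be `NULL` before the first
#'   fragment is placed).
#' @param stage stage label, e.g. `"core"`, `"bridge"`, `"end"`, `"alkyl"`,
#'   `"terminal"`.
#' @param ... additional stage-specific fields.
#' @return an object of class `generation_state`.
#' @keywords internal
new_generation_state <- function(graph, stage, ...) {
  structure(list(graph = graph, stage = stage, ...),
            class = "generation_state")
}

state_open_marks <- function(state) {
  g <- state$graph
  if (is.null(g)) return(integer(0))
  iso <- g$iso[g$elem == "*"]
  sort(unique(iso[!is.na(iso)])) - 1L
}

state_heavy_atoms <- function(state) {
  if (is.null(state$graph)) 0L else graph_heavy_atoms(state$graph)
}

#' @export
print.generation_state <- function(x, ...) {
  cat("<generation_state> stage=", x$stage,
      " heavy=", state_heavy_atoms(x),
      " open marks={", paste(state_open_marks(x), collapse = ","), "}",
      if (isTRUE(x$terminal)) " [terminal]", "\n", sep = "")
  invisible(x)
}

#' Action specification
#'
#' @param kind one of `"modify-core-position"`, `"choose-cluster"`,
#'   `"choose-fragment"`, `"skip-pi-bridge"`, `"choose-end-group"`,
#'   `"choose-alkyl"`.
#' @param payload position id, cluster index, fragment id, or fragment SMILES
#'   depending on `kind`.
#' @param label optional human-readable label.
#' @return an object of class `action_spec`.
#' @export
action_spec <- function(kind, payload = NULL, label = NULL) {
  structure(list(kind = kind, payload = payload, label = label),
            class = "action_spec")
}

action_key <- function(a) paste0(a$kind, ":", paste(a$payload, collapse = ","))

#' @export
print.action_spec <- function(x, ...) {
  cat("<action> ", action_key(x),
      if (!is.null(x$label)) paste0(" (", x$label, ")"), "\n", sep = "")
  invisible(x)
}

#' Transition result
#'
#' @param next_state the resulting [new_generation_state()].
#' @param sampled_mark the reactive position mark drawn for the attachment
#'   (`NA` for deterministic steps).
#' @param probability probability of this outcome: 1 for deterministic steps,
#'   `1/k_t` when one of `k_t` unique reactive positions was sampled.
#' @return an object of class `transition_result`.
#' @keywords internal
transition_result <- function(next_state, sampled_mark = NA_integer_,
                              probability = 1) {
  structure(list(next_state = next_state, sampled_mark = sampled_mark,
                 probability = probability), class = "transition_result")
}

new_mdp <- function(name, initial_state, legal_actions, step, is_terminal,
                    trajectory_molecule, state_key) {
  structure(list(name = name, initial_state = initial_state,
                 legal_actions = legal_actions, step = step,
                 is_terminal = is_terminal,
                 trajectory_molecule = trajectory_molecule,
                 state_key = state_key),
            class = "symfrag_mdp")
}

#' @export
print.symfrag_mdp <- function(x, ...) {
  cat("<symfrag_mdp> ", x$name, "\n", sep = "")
  invisible(x)
}

#' MDP accessors
#'
#' Thin wrappers over the environment contract: `initial_state()` returns the
#' root state, `legal_actions()` the stage-appropriate actions (empty list on
#' a terminal state), `mdp_step()` applies an action (stochastic steps draw
#' the reactive position from the global RNG), `is_terminal()` tests
#' completion, and `trajectory_molecule()` returns the finished, capped,
#' canonical molecule of a terminal state.
#'
#' @param env a `symfrag_mdp` environment.
#' @param state a generation state of `env`.
#' @param action an [action_spec] from `legal_actions(env, state)`.
#' @return see above; `mdp_step()` returns a `transition_result` with fields
#'   `next_state`, `sampled_mark`, `probability`.
#' @export
initial_state <- function(env) env$initial_state()

#' @rdname initial_state
#' @export
legal_actions <- function(env, state) env$legal_actions(state)

#' @rdname initial_state
#' @export
mdp_step <- function(env, state, action) env$step(state, action)

#' @rdname initial_state
#' @export
is_terminal <- function(env, state) env$is_terminal(state)

#' @rdname initial_state
#' @export
trajectory_molecule <- function(env, state) env$trajectory_molecule(state)

#' Exhaustively enumerate the terminal molecules of a deterministic MDP
#'
#' Breadth-first traversal over all action sequences. Only valid for
#' deterministic environments (every transition probability 1); stops with an
#' error if a stochastic step is met.
#'
#' @param env a deterministic `symfrag_mdp`.
#' @param max_terminals safety cap on the number of terminals.
#' @return data.frame with columns `smiles` (canonical) and `n_actions`.
#' @export
enumerate_terminals <- function(env, max_terminals = 10000L) {
  out_smiles <- character(0)
  out_depth <- integer(0)
  queue <- list(list(state = env$initial_state(), depth = 0L))
  while (length(queue)) {
    item <- queue[[1L]]
    queue <- queue[-1L]
    if (env$is_terminal(item$state)) {
      mol <- env$trajectory_molecule(item$state)
      out_smiles <- c(out_smiles, mol$smiles)
      out_depth <- c(out_depth, item$depth)
      if (length(out_smiles) > max_terminals) {
        stop("more than ", max_terminals, " terminal states", call. = FALSE)
      }
      next
    }
    for (a in env$legal_actions(item$state)) {
      res <- env$step(item$state, a)
      if (res$probability < 1) {
        stop("enumerate_terminals requires a deterministic MDP", call. = FALSE)
      }
      queue[[length(queue) + 1L]] <- list(state = res$next_state,
                                          depth = item$depth + 1L)
    }
  }
  data.frame(smiles = out_smiles, n_actions = out_depth,
             stringsAsFactors = FALSE)
}

# shared helper: attach fragment graph at a sampled reactive position.
# `mark_base` is a monotone per-trajectory counter so fresh marks are never
# recycled after a mark has been consumed.
# Returns list(graph, sampled_mark, probability, capped, mark_base).
stochastic_attach <- function(g, frag_graph, max_heavy, mark_base = 0L) {
  iso <- g$iso[g$elem == "*"]
  marks <- sort(unique(iso[!is.na(iso)])) - 1L
  if (!length(marks)) stop("no open reactive positions", call. = FALSE)
  mark_base <- max(mark_base, marks + 1L)
  k_t <- length(marks)
  mark <- if (k_t == 1L) marks else marks[sample.int(k_t, 1L)]
  n_sites <- sum(!is.na(g$iso) & g$iso == mark + 1L & g$elem == "*")
  projected <- graph_heavy_atoms(g) + n_sites * graph_heavy_atoms(frag_graph)
  if (projected > max_heavy) {
    # attachment would exceed the size cap: hydrogen-cap everything open
    return(list(graph = graph_cap_open(g, "hydrogen"),
                sampled_mark = mark, probability = 1 / k_t, capped = TRUE,
                mark_base = mark_base))
  }
  g2 <- graph_attach_at_mark(g, mark, frag_graph, mark_base = mark_base)
  iso2 <- g2$iso[g2$elem == "*"]
  mark_base <- max(c(mark_base, iso2[!is.na(iso2)]))
  list(graph = g2, sampled_mark = mark, probability = 1 / k_t,
       capped = FALSE, mark_base = mark_base)
}
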