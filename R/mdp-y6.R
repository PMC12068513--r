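# Focused acceptor-design grammar: an editable A-D-A core with four modifiable
# ring positions, optional pi-bridges at the end-group sites, a set of
# electron-deficient end-groups, and methyl-only alkyl chains.

#' Default configuration for the focused (Y6-style) assembly grammar
#'
#' The core is an illustrative A-D-A template: four heteroaromatic ring units
#' chained around an sp3 bridge carbon that carries the alkyl sites, with the
#' two terminal rings carrying the end-group sites. The four ring units are
#' the modifiable positions `pos0 .. pos3`; each may be a thiophene, furan,
#' selenophene (heteroatom swaps) or benzene (ring-size variant) unit. The
#' libraries are configurable stand-ins: the grammar, not the specific
#' fragment set, is what the environment implements.
#'
#' Marks: end-group sites carry mark 0, alkyl sites mark 1 (serialised as
#' `[1*]` and `[2*]`).
#'
#' @param core_template `sprintf` template with four `%s` slots, one per
#'   modifiable position.
#' @param position_choices list of four character vectors of ring units.
#' @param bridges named character vector of pi-bridge fragments (two
#'   attachment wildcards each).
#' @param end_groups named character vector of terminal end-group fragments
#'   (one attachment wildcard each).
#' @param alkyls named character vector of alkyl fragments; restricted to
#'   methyl by default.
#' @param max_bridge_rounds maximum optional pi-bridge insertions (default 2).
#' @return a list of class `y6_config`.
#' @export
y6_config <- function(
    core_template = "[1*]%s%sC([2*])([2*])%s%s[1*]",
    position_choices = rep(list(c(S = "c1ccc(s1)", O = "c1ccc(o1)",
                                  Se = "c1ccc([se]1)", benzo = "c1ccc(cc1)")),
                           4L),
    bridges = c(vinylene = "*C=C*",
                thiophene = "*c1ccc(*)s1",
                furan = "*c1ccc(*)o1"),
    end_groups = c(dicyanovinyl = "*C=C(C#N)C#N",
                   cyanophenyl = "*c1ccc(C#N)cc1",
                   formyl = "*C=O",
                   nitrothienyl = "*c1ccc([N+](=O)[O-])s1"),
    alkyls = c(methyl = "*C"),
    max_bridge_rounds = 2L) {
  stopifnot(length(position_choices) == 4L, length(alkyls) >= 1L)
  structure(list(core_template = core_template,
                 position_choices = position_choices,
                 bridges = bridges, end_groups = end_groups, alkyls = alkyls,
                 max_bridge_rounds = as.integer(max_bridge_rounds)),
            class = "y6_config")
}

Y6_END_MARK <- 0L
Y6_ALKYL_MARK <- 1L

# instantiate the core for a vector of per-position choice indices
y6_core_graph <- function(config, choices) {
  units <- mapply(function(opts, i) opts[[i]], config$position_choices,
                  choices)
  smi <- do.call(sprintf, c(list(config$core_template), as.list(units)))
  parse_smiles_graph(ob_canonical_smiles(smi))
}

#' Focused (Y6-style) assembly MDP
#'
#' Stages: (1) four sequential core-position modifications, (2) up to
#' `max_bridge_rounds` optional pi-bridge insertions at the end-group sites
#' (with an explicit skip action), (3) one end-group choice attached at every
#' open end site, (4) one alkyl choice (methyl only by default) at the alkyl
#' sites. All transitions are deterministic (probability 1). Because the two
#' end sites share mark 0, bridges and end-groups are attached symmetrically
#' on both arms.
#'
#' @param config a [y6_config()].
#' @return a `symfrag_mdp` environment.
#' @export
y6_mdp <- function(config = y6_config()) {
  frag_graph <- function(smi) parse_smiles_graph(ob_canonical_smiles(smi))
  bridge_graphs <- lapply(config$bridges, frag_graph)
  end_graphs <- lapply(config$end_groups, frag_graph)
  alkyl_graphs <- lapply(config$alkyls, frag_graph)

  make_state <- function(graph, stage, pos_choices, pending, end_mark,
                         bridge_rounds, terminal = FALSE) {
    new_generation_state(graph, stage, pos_choices = pos_choices,
                         pending = pending, end_mark = end_mark,
                         bridge_rounds = bridge_rounds, terminal = terminal)
  }

  init <- function() {
    choices <- rep(1L, 4L)
    make_state(y6_core_graph(config, choices), "core", choices,
               pending = 1L, end_mark = Y6_END_MARK, bridge_rounds = 0L)
  }

  legal <- function(state) {
    switch(state$stage,
      core = {
        pos <- state$pending
        opts <- config$position_choices[[pos]]
        lapply(seq_along(opts), function(i) {
          action_spec("modify-core-position", c(pos - 1L, i),
                      label = paste0("pos", pos - 1L, "=", names(opts)[i]))
        })
      },
      bridge = {
        c(list(action_spec("skip-pi-bridge")),
          lapply(seq_along(config$bridges), function(i) {
            action_spec("choose-fragment", i,
                        label = names(config$bridges)[i])
          }))
      },
      end = lapply(seq_along(config$end_groups), function(i) {
        action_spec("choose-end-group", i,
                    label = names(config$end_groups)[i])
      }),
      alkyl = lapply(seq_along(config$alkyls), function(i) {
        action_spec("choose-alkyl", i, label = names(config$alkyls)[i])
      }),
      terminal = list())
  }

  step <- function(state, action) {
    if (state$stage == "terminal") stop("terminal state", call. = FALSE)
    ns <- switch(action$kind,
      `modify-core-position` = {
        stopifnot(state$stage == "core")
        pos <- action$payload[1L] + 1L
        stopifnot(pos == state$pending)
        choices <- state$pos_choices
        choices[pos] <- action$payload[2L]
        g <- y6_core_graph(config, choices)
        if (pos < 4L) {
          make_state(g, "core", choices, pos + 1L, Y6_END_MARK, 0L)
        } else {
          make_state(g, "bridge", choices, NA_integer_, Y6_END_MARK, 0L)
        }
      },
      `skip-pi-bridge` = {
        stopifnot(state$stage == "bridge")
        make_state(state$graph, "end", state$pos_choices, NA_integer_,
                   state$end_mark, state$bridge_rounds)
      },
      `choose-fragment` = {
        stopifnot(state$stage == "bridge")
        g <- graph_attach_at_mark(state$graph, state$end_mark,
                                  bridge_graphs[[action$payload]])
        iso <- g$iso[g$elem == "*"]
        new_mark <- max(iso[!is.na(iso)]) - 1L
        rounds <- state$bridge_rounds + 1L
        make_state(g, if (rounds < config$max_bridge_rounds) "bridge" else "end",
                   state$pos_choices, NA_integer_, new_mark, rounds)
      },
      `choose-end-group` = {
        stopifnot(state$stage == "end")
        g <- graph_attach_at_mark(state$graph, state$end_mark,
                                  end_graphs[[action$payload]])
        make_state(g, "alkyl", state$pos_choices, NA_integer_,
                   NA_integer_, state$bridge_rounds)
      },
      `choose-alkyl` = {
        stopifnot(state$stage == "alkyl")
        g <- graph_attach_at_mark(state$graph, Y6_ALKYL_MARK,
                                  alkyl_graphs[[action$payload]])
        make_state(g, "terminal", state$pos_choices, NA_integer_,
                   NA_integer_, state$bridge_rounds, terminal = TRUE)
      },
      stop("illegal action kind '", action$kind, "' in stage ", state$stage,
           call. = FALSE))
    transition_result(ns)
  }

  term <- function(state) identical(state$stage, "terminal")

  traj <- function(state) {
    if (!term(state)) stop("state is not terminal", call. = FALSE)
    symmol_from_graph(state$graph)
  }

  key <- function(state) {
    paste(state$stage, state$pending,
          if (!is.null(state$graph)) write_smiles_graph(state$graph) else "",
          sep = "|")
  }

  new_mdp("y6", init, legal, step, term, traj, key)
}
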