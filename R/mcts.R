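# UCT Monte Carlo tree search over any environment satisfying the MDP
# contract. Each iteration: selection (UCT descent through visited nodes,
# stochastic outcomes resolved by the environment), expansion (one unexpanded
# action chosen uniformly), rollout (uniform random policy to termination),
# backpropagation (scalar terminal reward added to every traversed edge).

#' Search configuration
#'
#' @param n_steps number of MCTS iterations (one terminal molecule each).
#' @param exploration UCT exploration coefficient `c`; rewards are used
#'   unnormalised, so `c` is scale-sensitive. Default `1/sqrt(2)`.
#' @param window trailing window for best-candidate extraction (default 100).
#' @param seed integer seed; every source of randomness in the search runs off
#'   it. `NULL` leaves the RNG state alone.
#' @param reward_floor reward recorded when the reward function fails on a
#'   molecule (the molecule is still logged).
#' @param transpositions `"structural"` merges tree nodes whose states have
#'   identical structural keys (same stage and identically constructed graph);
#'   `"path"` keeps strict-tree semantics (nodes keyed by action history).
#' @return a list of class `search_config`.
#' @export
search_config <- function(n_steps = 2000L, exploration = 1 / sqrt(2),
                          window = 100L, seed = NULL, reward_floor = -10,
                          transpositions = c("structural", "path")) {
  stopifnot(n_steps >= 1L, exploration >= 0, window >= 1L)
  structure(list(n_steps = as.integer(n_steps), exploration = exploration,
                 window = as.integer(window), seed = seed,
                 reward_floor = reward_floor,
                 transpositions = match.arg(transpositions)),
            class = "search_config")
}

new_tree_node <- function(actions, terminal = FALSE) {
  e <- new.env(parent = emptyenv())
  e$N <- 0L
  e$actions <- actions
  e$edge_N <- integer(length(actions))
  e$edge_W <- numeric(length(actions))
  e$children <- vector("list", length(actions))  # per edge: outcome key -> child key
  e$terminal <- terminal
  class(e) <- "tree_node"
  e
}

#' UCT action selection
#'
#' Returns the index of the action maximising
#' `Q(a) + c * sqrt(log(N_parent) / N(a))` with `Q(a) = W(a)/N(a)`. Unvisited
#' actions (`N(a) = 0`) have infinite priority and are always preferred over
#' visited ones; ties (among unvisited actions, or among equal scores) are
#' broken uniformly at random.
#'
#' @param node a tree node: any list or environment with fields `actions`
#'   (list of [action_spec]), `edge_N` (visit counts), `edge_W` (summed
#'   rewards) and `N` (parent visit count), as produced by the search or
#'   assembled by hand.
#' @param c exploration coefficient (>= 0).
#' @return the selected [action_spec]; the chosen index is in
#'   `attr(, "index")`.
#' @export
uct_select <- function(node, c = 1 / sqrt(2)) {
  n <- node$edge_N
  if (!length(n)) stop("node has no legal actions", call. = FALSE)
  unvis <- which(n == 0L)
  if (length(unvis)) {
    i <- if (length(unvis) == 1L) unvis else unvis[sample.int(length(unvis), 1L)]
  } else {
    s <- uct_scores(node$edge_W / n, n, node$N, c)
    best <- which(s >= max(s) - 1e-12)
    i <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
  }
  a <- node$actions[[i]]
  attr(a, "index") <- i
  a
}

#' @rdname uct_select
#' @param q vector of action values `Q(a)`.
#' @param n vector of action visit counts (all > 0).
#' @param n_parent parent visit count.
#' @return `uct_scores()` returns the vector of UCT scores.
#' @export
uct_scores <- function(q, n, n_parent, c = 1 / sqrt(2)) {
  q + c * sqrt(log(n_parent) / n)
}

#' Run a Monte Carlo tree search
#'
#' Performs `config$n_steps` iterations of selection / expansion / rollout /
#' backpropagation over `env`, scoring each terminal molecule with
#' `reward_fn`. A failing reward function logs the molecule with
#' `config$reward_floor` and the search continues. Fully reproducible given
#' `config$seed`.
#'
#' @param env a `symfrag_mdp` environment.
#' @param reward_fn function of a [symmol] returning a finite scalar reward
#'   (larger is better), e.g. [penalized_reward()] bound to a
#'   [reward_spec()].
#' @param config a [search_config()].
#' @return an object of class `symfrag_search`: list with `ledger`
#'   (data.frame: step, smiles, reward), `best` (best entry of the trailing
#'   window), `nodes` (the tree, an environment of tree nodes), `root_key`,
#'   `config`, `env_name`.
#' @export
run_search <- function(env, reward_fn, config = search_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  nodes <- new.env(parent = emptyenv())
  strict <- identical(config$transpositions, "path")

  # canonicalisation of recurring terminal states dominates runtime: memoise
  # by the (deterministic) structural state key
  traj_cache <- new.env(parent = emptyenv())
  terminal_molecule <- function(state) {
    k <- env$state_key(state)
    hit <- traj_cache[[k]]
    if (!is.null(hit)) return(hit)
    mol <- env$trajectory_molecule(state)
    assign(k, mol, envir = traj_cache)
    mol
  }

  node_key <- function(state, path_id) {
    if (strict) path_id else env$state_key(state)
  }
  get_node <- function(key, state) {
    nd <- nodes[[key]]
    if (is.null(nd)) {
      terminal <- env$is_terminal(state)
      nd <- new_tree_node(if (terminal) list() else env$legal_actions(state),
                          terminal)
      assign(key, nd, envir = nodes)
    }
    nd
  }

  steps <- integer(config$n_steps)
  smiles <- character(config$n_steps)
  rewards <- numeric(config$n_steps)

  root_key <- "<root>"

  for (it in seq_len(config$n_steps)) {
    state <- env$initial_state()
    key <- if (strict) root_key else env$state_key(state)
    node <- get_node(key, state)
    path <- list()
    repeat {
      if (node$terminal) break
      unvis <- which(node$edge_N == 0L)
      expanding <- length(unvis) > 0L
      if (expanding) {
        i <- if (length(unvis) == 1L) unvis
             else unvis[sample.int(length(unvis), 1L)]
      } else {
        a <- uct_select(node, config$exploration)
        i <- attr(a, "index")
      }
      res <- env$step(state, node$actions[[i]])
      path[[length(path) + 1L]] <- list(node = node, edge = i)
      state <- res$next_state
      ckey <- node_key(state, paste0(key, "/", i, "#",
                                     if (is.na(res$sampled_mark)) ""
                                     else res$sampled_mark))
      okey <- if (is.na(res$sampled_mark)) "d" else paste0("m", res$sampled_mark)
      if (is.null(node$children[[i]])) node$children[[i]] <- list()
      node$children[[i]][[okey]] <- ckey
      if (expanding) {
        get_node(ckey, state)   # add the new leaf to the tree
        # rollout: uniform random policy to termination
        while (!env$is_terminal(state)) {
          acts <- env$legal_actions(state)
          a <- acts[[sample.int(length(acts), 1L)]]
          state <- env$step(state, a)$next_state
        }
        break
      }
      key <- ckey
      node <- get_node(key, state)
    }
    mol <- terminal_molecule(state)
    r <- tryCatch(reward_fn(mol), error = function(e) {
      warning("reward failed on ", mol$smiles, ": ", conditionMessage(e),
              call. = FALSE)
      config$reward_floor
    })
    for (p in path) {
      p$node$N <- p$node$N + 1L
      p$node$edge_N[p$edge] <- p$node$edge_N[p$edge] + 1L
      p$node$edge_W[p$edge] <- p$node$edge_W[p$edge] + r
    }
    steps[it] <- it
    smiles[it] <- mol$smiles
    rewards[it] <- r
  }

  ledger <- data.frame(step = steps, smiles = smiles, reward = rewards,
                       stringsAsFactors = FALSE)
  structure(list(ledger = ledger,
                 best = best_in_window(ledger, config$window),
                 nodes = nodes, root_key = root_key, config = config,
                 env_name = env$name),
            class = "symfrag_search")
}

#' Best molecule in the trailing window of a search ledger
#'
#' @param ledger a data.frame with columns `smiles` and `reward` (e.g.
#'   `$ledger` of a [run_search()] result), or a `symfrag_search`.
#' @param window number of trailing entries considered; a window larger than
#'   the ledger uses the whole ledger.
#' @return list with `smiles`, `reward`, `step` of the reward-maximising entry
#'   among the final `window` entries.
#' @export
best_in_window <- function(ledger, window = 100L) {
  if (inherits(ledger, "symfrag_search")) ledger <- ledger$ledger
  n <- nrow(ledger)
  if (!n) stop("empty ledger", call. = FALSE)
  tail_idx <- seq.int(max(1L, n - window + 1L), n)
  best <- tail_idx[which.max(ledger$reward[tail_idx])]
  list(smiles = ledger$smiles[best], reward = ledger$reward[best],
       step = best)
}

#' @export
print.symfrag_search <- function(x, ...) {
  cat("<symfrag_search> ", x$env_name, " MDP, ", nrow(x$ledger),
      " steps\n", sep = "")
  cat("  best (last ", x$config$window, " steps): ", x$best$smiles,
      "  reward ", format(x$best$reward, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.symfrag_search <- function(object, ...) {
  led <- object$ledger
  cat("MCTS search on '", object$env_name, "' (", nrow(led), " steps, c = ",
      format(object$config$exploration, digits = 4), ")\n", sep = "")
  cat("  reward: min ", format(min(led$reward), digits = 4),
      ", mean ", format(mean(led$reward), digits = 4),
      ", max ", format(max(led$reward), digits = 4), "\n", sep = "")
  cat("  unique molecules: ", length(unique(led$smiles)), "\n", sep = "")
  cat("  best in window: ", object$best$smiles, " (reward ",
      format(object$best$reward, digits = 4), ")\n", sep = "")
  invisible(object)
}

#' @export
plot.symfrag_search <- function(x, ...) {
  led <- x$ledger
  graphics::plot(led$step, led$reward, pch = 16, cex = 0.4,
                 col = "grey60", xlab = "MCTS step", ylab = "reward", ...)
  graphics::lines(led$step, cummax(led$reward), col = "firebrick", lwd = 2)
  graphics::legend("bottomright", legend = c("terminal reward", "best so far"),
                   col = c("grey60", "firebrick"), pch = c(16, NA),
                   lty = c(NA, 1), bty = "n")
  invisible(x)
}
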