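# Open assembly grammar over a decomposed fragment pool: cluster-factorised
# fragment choices (k-means), stochastic reactive-position transitions
# (uniform over the unique open marks, P = 1/k_t), a 100-heavy-atom size cap,
# and the distinct-identities constraint (a fragment id already used in the
# trajectory is masked, so differently marked positions receive different
# fragments while identically marked positions receive the same one).

#' Configuration for the open (patent-style) assembly grammar
#'
#' @param k_clusters clusters per action hierarchy (default 100, clamped to
#'   the pool size).
#' @param max_heavy_atoms size cap; attachments that would exceed it
#'   hydrogen-cap the remaining positions and terminate (default 100).
#' @param max_bridge_rounds maximum optional pi-bridge insertions (default 2).
#' @param cluster_seed seed for the k-means cluster assignment.
#' @param radius,n_bits fingerprint parameters for clustering.
#' @return a list of class `patent_config`.
#' @export
patent_config <- function(k_clusters = 100L, max_heavy_atoms = 100L,
                          max_bridge_rounds = 2L, cluster_seed = 1L,
                          radius = 2L, n_bits = 512L) {
  structure(list(k_clusters = as.integer(k_clusters),
                 max_heavy_atoms = as.integer(max_heavy_atoms),
                 max_bridge_rounds = as.integer(max_bridge_rounds),
                 cluster_seed = as.integer(cluster_seed),
                 radius = as.integer(radius), n_bits = as.integer(n_bits)),
            class = "patent_config")
}

#' Open (patent-style) assembly MDP over a fragment pool
#'
#' Builds molecules from scratch out of decomposed fragments. Stages:
#' (1) core cluster choice then core fragment choice; (2) up to
#' `max_bridge_rounds` optional pi-bridge rounds (cluster choice then fragment
#' choice); (3) end-group rounds (cluster then fragment) iterated while open
#' reactive positions remain and the molecule stays within the heavy-atom cap.
#' Cluster choices are deterministic; every fragment attachment first samples
#' the target mark uniformly from the `k_t` unique open marks
#' (probability `1/k_t`) and then attaches one copy of the fragment at every
#' position carrying the sampled mark.
#'
#' Fragment ids already used in the trajectory are masked from later choices;
#' if masking empties every cluster, the constraint is relaxed to the least
#' recently used fragment and a warning is issued.
#'
#' @param pool a `fragment_pool` from [decompose_corpus()], or a character
#'   vector of marked fragment SMILES.
#' @param config a [patent_config()].
#' @return a `symfrag_mdp` environment.
#' @export
patent_mdp <- function(pool, config = patent_config()) {
  if (is.character(pool)) {
    pool <- data.frame(smiles = pool, count = 1L,
                       n_heavy = vapply(pool, function(s) heavy_atoms(s),
                                        integer(1)),
                       n_reactive = vapply(pool, function(s) {
                         nrow(attachment_points(s))
                       }, integer(1)),
                       stringsAsFactors = FALSE)
  }
  if (!nrow(pool)) stop("empty fragment pool", call. = FALSE)
  graphs <- lapply(pool$smiles,
                   function(s) parse_smiles_graph(ob_canonical_smiles(s)))
  roles <- list(core = which(pool$n_reactive >= 1L),
                bridge = which(pool$n_reactive >= 2L),
                end = which(pool$n_reactive >= 1L))
  clusters <- lapply(roles, function(idx) {
    if (!length(idx)) return(NULL)
    cl <- cluster_fragments(pool[idx, , drop = FALSE],
                            k_clusters = config$k_clusters,
                            seed = config$cluster_seed,
                            radius = config$radius, n_bits = config$n_bits)
    # cluster index -> pool row ids
    lapply(cl$members, function(m) idx[m])
  })

  make_state <- function(graph, stage, used, bridge_rounds, cluster = NA,
                         role = NA_character_, terminal = FALSE,
                         mark_base = 0L) {
    new_generation_state(graph, stage, used = used,
                         bridge_rounds = bridge_rounds, cluster = cluster,
                         role = role, terminal = terminal,
                         mark_base = mark_base)
  }

  init <- function() {
    make_state(NULL, "core-cluster", integer(0), 0L)
  }

  # fragment ids of a role not yet used; relaxes to the least recently used
  # id when every candidate is masked
  eligible <- function(role, used) {
    ids <- roles[[role]]
    open <- setdiff(ids, used)
    if (length(open)) return(list(ids = open, relaxed = FALSE))
    lru <- used[used %in% ids]
    if (!length(lru)) return(list(ids = integer(0), relaxed = FALSE))
    list(ids = lru[1L], relaxed = TRUE)
  }

  cluster_actions <- function(role, used, extra = list()) {
    el <- eligible(role, used)
    if (el$relaxed) {
      warning("distinct-fragment constraint relaxed for role '", role,
              "': all ", role, " fragments already used", call. = FALSE)
    }
    cl <- clusters[[role]]
    acts <- extra
    for (ci in seq_along(cl)) {
      if (any(cl[[ci]] %in% el$ids)) {
        acts[[length(acts) + 1L]] <-
          action_spec("choose-cluster", ci, label = paste0(role, "-cluster"))
      }
    }
    acts
  }

  fragment_actions <- function(role, cluster, used) {
    el <- eligible(role, used)
    ids <- intersect(clusters[[role]][[cluster]], el$ids)
    lapply(ids, function(i) {
      action_spec("choose-fragment", i, label = pool$smiles[i])
    })
  }

  legal <- function(state) {
    switch(state$stage,
      `core-cluster` = cluster_actions("core", state$used),
      `core-frag` = fragment_actions("core", state$cluster, state$used),
      `bridge-cluster` = cluster_actions("bridge", state$used,
                                         extra = list(action_spec("skip-pi-bridge"))),
      `bridge-frag` = fragment_actions("bridge", state$cluster, state$used),
      `end-cluster` = cluster_actions("end", state$used),
      `end-frag` = fragment_actions("end", state$cluster, state$used),
      terminal = list())
  }

  advance_after_attach <- function(g, used, bridge_rounds, capped,
                                   mark_base) {
    iso <- g$iso[g$elem == "*"]
    open <- any(!is.na(iso))
    if (capped || !open) {
      g <- graph_cap_open(g, "hydrogen")
      return(make_state(g, "terminal", used, bridge_rounds, terminal = TRUE,
                        mark_base = mark_base))
    }
    if (bridge_rounds < config$max_bridge_rounds) {
      make_state(g, "bridge-cluster", used, bridge_rounds,
                 mark_base = mark_base)
    } else {
      make_state(g, "end-cluster", used, bridge_rounds,
                 mark_base = mark_base)
    }
  }

  step <- function(state, action) {
    if (state$stage == "terminal") stop("terminal state", call. = FALSE)
    switch(action$kind,
      `choose-cluster` = {
        nxt <- switch(state$stage,
                      `core-cluster` = "core-frag",
                      `bridge-cluster` = "bridge-frag",
                      `end-cluster` = "end-frag",
                      stop("illegal cluster choice in stage ", state$stage,
                           call. = FALSE))
        transition_result(make_state(state$graph, nxt, state$used,
                                     state$bridge_rounds,
                                     cluster = action$payload,
                                     mark_base = state$mark_base))
      },
      `skip-pi-bridge` = {
        stopifnot(state$stage == "bridge-cluster")
        transition_result(make_state(state$graph, "end-cluster", state$used,
                                     config$max_bridge_rounds,
                                     mark_base = state$mark_base))
      },
      `choose-fragment` = {
        id <- action$payload
        used <- c(state$used, id)
        if (state$stage == "core-frag") {
          g <- graphs[[id]]
          iso <- g$iso[g$elem == "*"]
          base <- max(c(0L, iso[!is.na(iso)]))
          if (!any(!is.na(iso))) {
            return(transition_result(
              make_state(graph_cap_open(g, "hydrogen"), "terminal", used, 0L,
                         terminal = TRUE)))
          }
          return(transition_result(make_state(g, "bridge-cluster", used, 0L,
                                              mark_base = base)))
        }
        rounds <- if (state$stage == "bridge-frag") {
          state$bridge_rounds + 1L
        } else {
          state$bridge_rounds
        }
        at <- stochastic_attach(state$graph, graphs[[id]],
                                config$max_heavy_atoms,
                                mark_base = state$mark_base)
        ns <- advance_after_attach(at$graph, used, rounds, at$capped,
                                   at$mark_base)
        transition_result(ns, sampled_mark = at$sampled_mark,
                          probability = at$probability)
      },
      stop("illegal action kind '", action$kind, "' in stage ", state$stage,
           call. = FALSE))
  }

  term <- function(state) identical(state$stage, "terminal")

  traj <- function(state) {
    if (!term(state)) stop("state is not terminal", call. = FALSE)
    symmol_from_graph(state$graph)
  }

  key <- function(state) {
    paste(state$stage, state$cluster,
          if (!is.null(state$graph)) write_smiles_graph(state$graph) else "",
          paste(state$used, collapse = ","),
          sep = "|")
  }

  new_mdp("patent", init, legal, step, term, traj, key)
}
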