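# Expected-improvement acquisition and the active-learning loop used to
# collect training data for the reward predictor in the generation domain.

#' Expected improvement under a Gaussian predictive distribution
#'
#' `EI = (mu - f_star) * pnorm(z) + sigma * dnorm(z)` with
#' `z = (mu - f_star) / sigma`; the `sigma = 0` limit is
#' `max(mu - f_star, 0)`. `mu` is the predicted reward (here the negative
#' predicted bandgap), `sigma` the ensemble standard deviation, and `f_star`
#' the best predicted reward in the current candidate batch. EI is always
#' non-negative and, for `mu < f_star`, increasing in `sigma`.
#'
#' @param mu predicted reward mean(s).
#' @param sigma predictive standard deviation(s), `>= 0`.
#' @param f_star incumbent (batch-best) predicted reward.
#' @return numeric vector of expected improvements.
#' @export
expected_improvement <- function(mu, sigma, f_star) {
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  n <- max(length(mu), length(sigma), length(f_star))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  f_star <- rep_len(f_star, n)
  out <- pmax(mu - f_star, 0)
  pos <- sigma > 0
  if (any(pos)) {
    z <- (mu[pos] - f_star[pos]) / sigma[pos]
    out[pos] <- (mu[pos] - f_star[pos]) * stats::pnorm(z) +
      sigma[pos] * stats::dnorm(z)
  }
  out
}

#' Uniform random rollouts of an environment
#'
#' Follows a uniform random policy from the initial state to termination.
#'
#' @param env a `symfrag_mdp`.
#' @param n number of rollouts.
#' @return character vector of canonical SMILES (one per rollout; duplicates
#'   possible).
#' @export
random_rollouts <- function(env, n) {
  vapply(seq_len(n), function(i) {
    state <- env$initial_state()
    while (!env$is_terminal(state)) {
      acts <- env$legal_actions(state)
      state <- env$step(state, acts[[sample.int(length(acts), 1L)]])$next_state
    }
    env$trajectory_molecule(state)$smiles
  }, character(1))
}

#' Acquire a batch of candidates by expected improvement
#'
#' Samples `n_samples` random rollouts from the environment, deduplicates by
#' canonical form, scores each candidate's predicted reward
#' (`mu` = negative predicted bandgap) and uncertainty (`sigma`) with the
#' ensemble, sets the incumbent `f_star` to the batch-best `mu`, and returns
#' the `n_top` candidates with the highest expected improvement.
#'
#' @param env a `symfrag_mdp`.
#' @param ensemble a [property_predictor()] (ideally with an ensemble
#'   `std_fn`, e.g. [bootstrap_ensemble()]).
#' @param n_samples random candidates to draw (default 10000).
#' @param n_top batch size to return (default 100).
#' @param seed optional seed for the rollouts.
#' @return data.frame `(smiles, mu, sigma, ei)`, sorted by decreasing `ei`,
#'   at most `n_top` rows.
#' @export
acquire_batch <- function(env, ensemble, n_samples = 10000L, n_top = 100L,
                          seed = NULL) {
  if (n_samples < 1L) stop("n_samples must be positive", call. = FALSE)
  stopifnot(n_top <= n_samples)
  if (!is.null(seed)) set.seed(seed)
  smi <- unique(random_rollouts(env, n_samples))
  ps <- predict_with_std(ensemble, smi)
  mu <- -ps$mean
  sigma <- ps$std
  f_star <- max(mu)
  ei <- expected_improvement(mu, sigma, f_star)
  o <- order(ei, decreasing = TRUE)
  out <- data.frame(smiles = smi[o], mu = mu[o], sigma = sigma[o],
                    ei = ei[o], stringsAsFactors = FALSE)
  utils::head(out, n_top)
}

#' Ridge-ensemble trainer callback for the active-learning loop
#'
#' Returns a trainer: a function of a labelled data.frame `(smiles, bandgap)`
#' and a seed that fits a [bootstrap_ensemble()] on a training split and
#' reports the root-mean-square error on the held-out split.
#'
#' @param holdout fraction of the labelled set held out for the RMSE.
#' @param n_members ensemble size.
#' @param ... passed to [fingerprint_ridge_predictor()] via
#'   [bootstrap_ensemble()].
#' @return function `(data, seed)` returning `list(predictor, rmse)`.
#' @export
ridge_trainer <- function(holdout = 0.25, n_members = 3L, ...) {
  function(data, seed = 1L) {
    n <- nrow(data)
    stopifnot(n >= 4L)
    idx <- with_preserved_rng(seed, sample.int(n, max(2L, round(holdout * n))))
    train <- data[-idx, , drop = FALSE]
    test <- data[idx, , drop = FALSE]
    pred <- bootstrap_ensemble(train$smiles, train$bandgap,
                               n_members = n_members, seed = seed, ...)
    rmse <- sqrt(mean((predict(pred, test$smiles) - test$bandgap)^2))
    list(predictor = pred, rmse = rmse)
  }
}

#' Active-learning loop
#'
#' Alternates acquisition, labelling and re-training until the held-out RMSE
#' of the predictor reaches `stopping_rmse` or `max_rounds` is exhausted.
#' Round 1 trains on labelled random rollouts; later rounds add (1) the
#' iteration-best molecules of an [iterative_diverse_search()] driven by the
#' current predictor and (2) the top expected-improvement candidates of an
#' [acquire_batch()].
#'
#' @param env a `symfrag_mdp`.
#' @param label_oracle a [property_predictor()] supplying ground-truth labels
#'   (in production an expensive calculation; here typically
#'   [toy_conjugation_oracle()]).
#' @param trainer callback `(data, seed) -> list(predictor, rmse)`, e.g. from
#'   [ridge_trainer()].
#' @param stopping_rmse stop once the held-out RMSE is at or below this value
#'   (default 0.3 eV).
#' @param max_rounds maximum training rounds (>= 1).
#' @param n_initial random rollouts labelled for round 1.
#' @param n_samples,n_top [acquire_batch()] sizes for later rounds.
#' @param diversity_iterations,search_steps [iterative_diverse_search()] sizes
#'   for later rounds.
#' @param seed master seed.
#' @return an object of class `symfrag_al`: list with `rounds` (data.frame:
#'   round, n_labeled, rmse, stopped), `predictor` (final), `data` (all
#'   labelled molecules).
#' @export
al_loop <- function(env, label_oracle, trainer, stopping_rmse = 0.3,
                    max_rounds = 3L, n_initial = 60L, n_samples = 150L,
                    n_top = 15L, diversity_iterations = 2L,
                    search_steps = 100L, seed = 1L) {
  if (max_rounds < 1L) stop("max_rounds must be >= 1", call. = FALSE)
  set.seed(seed)
  smi <- unique(random_rollouts(env, n_initial))
  data <- data.frame(smiles = smi, bandgap = predict(label_oracle, smi),
                     stringsAsFactors = FALSE)
  rounds <- list()
  fit <- trainer(data, seed)
  rounds[[1L]] <- data.frame(round = 1L, n_labeled = nrow(data),
                             rmse = fit$rmse)
  r <- 1L
  while (fit$rmse > stopping_rmse && r < max_rounds) {
    r <- r + 1L
    spec <- reward_spec(fit$predictor)
    inv <- iterative_diverse_search(
      env, spec, n_iterations = diversity_iterations,
      config = search_config(n_steps = search_steps, seed = seed + 100L * r))
    batch <- acquire_batch(env, fit$predictor, n_samples = n_samples,
                           n_top = n_top, seed = seed + 100L * r + 1L)
    new_smi <- setdiff(unique(c(inv$smiles, batch$smiles)), data$smiles)
    if (length(new_smi)) {
      data <- rbind(data, data.frame(
        smiles = new_smi, bandgap = predict(label_oracle, new_smi),
        stringsAsFactors = FALSE))
    }
    fit <- trainer(data, seed + r)
    rounds[[r]] <- data.frame(round = r, n_labeled = nrow(data),
                              rmse = fit$rmse)
  }
  rounds <- do.call(rbind, rounds)
  rounds$stopped <- rounds$rmse <= stopping_rmse
  structure(list(rounds = rounds, predictor = fit$predictor, data = data),
            class = "symfrag_al")
}

#' @export
print.symfrag_al <- function(x, ...) {
  cat("<symfrag_al> ", nrow(x$rounds), " rounds, ", nrow(x$data),
      " labelled molecules\n", sep = "")
  print(x$rounds, row.names = FALSE)
  invisible(x)
}
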