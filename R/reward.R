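# Property predictors (pluggable contract), the diversity-penalised reward,
# and the iterative re-training loop that collects chemically diverse
# high-performing candidates.

#' Property predictor contract
#'
#' A predictor scores molecules with a scalar property (here: the optical
#' bandgap in eV, to be minimised). Any conforming object can drive the
#' reward; the quantum-chemistry or neural surrogates of a production
#' pipeline plug in through this same contract. An ensemble predictor
#' additionally reports the standard deviation across members, used as the
#' uncertainty in expected-improvement acquisition.
#'
#' @param predict_fn function taking a character vector of canonical SMILES
#'   and returning a numeric vector of property values (bandgap, eV).
#' @param std_fn optional function with the same signature returning the
#'   ensemble standard deviation; `NULL` means the uncertainty is defined
#'   as 0.
#' @param name label used in printing.
#' @return an object of class `property_predictor`.
#' @export
property_predictor <- function(predict_fn, std_fn = NULL,
                               name = "predictor") {
  structure(list(predict_fn = predict_fn, std_fn = std_fn, name = name),
            class = "property_predictor")
}

#' @export
print.property_predictor <- function(x, ...) {
  cat("<property_predictor> ", x$name,
      if (!is.null(x$std_fn)) " (ensemble)", "\n", sep = "")
  invisible(x)
}

as_smiles_vector <- function(mols) {
  if (inherits(mols, "symmol")) return(mols$smiles)
  if (is.character(mols)) {
    return(vapply(mols, function(s) as_symmol(s)$smiles, character(1),
                  USE.NAMES = FALSE))
  }
  vapply(mols, function(m) as_symmol(m)$smiles, character(1))
}

#' @export
predict.property_predictor <- function(object, newdata, ...) {
  object$predict_fn(as_smiles_vector(newdata))
}

#' Predictive mean and uncertainty of a predictor
#'
#' @param predictor a [property_predictor()].
#' @param mols molecules (SMILES, [symmol], or list thereof).
#' @return list with numeric vectors `mean` and `std` (`std` is 0 for
#'   predictors without an ensemble).
#' @export
predict_with_std <- function(predictor, mols) {
  smi <- as_smiles_vector(mols)
  m <- predictor$predict_fn(smi)
  s <- if (is.null(predictor$std_fn)) rep(0, length(m)) else predictor$std_fn(smi)
  list(mean = m, std = s)
}

# number of conjugated heavy atoms: aromatic atoms plus atoms in non-aromatic
# double or triple bonds
conjugation_count <- function(mol) {
  g <- as_symmol(mol)$graph
  multi <- g$border >= 2L & !g$barom
  length(unique(c(which(g$arom), as.vector(g$bond[multi, ]))))
}

#' Deterministic toy bandgap oracle
#'
#' A fixed, cheap stand-in for an expensive excited-state calculation, for
#' testing and demonstration: the "bandgap" decreases monotonically with the
#' number of conjugated heavy atoms, `E = 1.0 + 9 / (3 + n_conj)` eV, mimicking
#' the qualitative physics (extended conjugation red-shifts absorption).
#' With `noise_sd > 0`, i.i.d. Gaussian noise is added per call (a noisy
#' labelling oracle for active-learning tests).
#'
#' @param noise_sd standard deviation of additive Gaussian noise (eV).
#' @return a [property_predictor()].
#' @export
toy_conjugation_oracle <- function(noise_sd = 0) {
  cache <- new.env(parent = emptyenv())
  n_conj <- function(s) {
    hit <- cache[[s]]
    if (!is.null(hit)) return(hit)
    n <- conjugation_count(s)
    assign(s, n, envir = cache)
    n
  }
  property_predictor(function(smiles) {
    e <- vapply(smiles, function(s) 1.0 + 9 / (3 + n_conj(s)),
                numeric(1), USE.NAMES = FALSE)
    if (noise_sd > 0) e <- e + stats::rnorm(length(e), 0, noise_sd)
    e
  }, name = if (noise_sd > 0) {
    paste0("toy conjugation oracle (sd=", noise_sd, ")")
  } else {
    "toy conjugation oracle"
  })
}

#' Ridge regression on folded Morgan fingerprints
#'
#' A small reference implementation of the predictor contract: closed-form
#' ridge regression of the property on folded fingerprint bits.
#'
#' @param smiles training molecules.
#' @param bandgaps training labels (eV).
#' @param radius,n_bits fingerprint parameters (small `n_bits` keeps the
#'   normal equations cheap).
#' @param lambda ridge penalty.
#' @return a [property_predictor()].
#' @export
fingerprint_ridge_predictor <- function(smiles, bandgaps, radius = 2L,
                                        n_bits = 256L, lambda = 1) {
  stopifnot(length(smiles) == length(bandgaps), length(smiles) >= 2L)
  X <- cbind(1, fp_matrix(lapply(smiles, as_symmol), radius, n_bits))
  P <- diag(c(0, rep(lambda, ncol(X) - 1L)))
  beta <- solve(crossprod(X) + P, crossprod(X, bandgaps))
  property_predictor(function(smi) {
    Xn <- cbind(1, fp_matrix(lapply(smi, as_symmol), radius, n_bits))
    as.numeric(Xn %*% beta)
  }, name = sprintf("fingerprint ridge (n=%d)", length(smiles)))
}

#' Bootstrap ensemble of fingerprint-ridge predictors
#'
#' @param smiles,bandgaps training data.
#' @param n_members ensemble size.
#' @param seed resampling seed (global RNG preserved).
#' @param ... passed to [fingerprint_ridge_predictor()].
#' @return a [property_predictor()] whose `std_fn` is the across-member
#'   standard deviation (0 when `n_members = 1`).
#' @export
bootstrap_ensemble <- function(smiles, bandgaps, n_members = 5L, seed = 1L,
                               ...) {
  n <- length(smiles)
  members <- with_preserved_rng(seed, {
    lapply(seq_len(n_members), function(k) {
      idx <- sample.int(n, n, replace = TRUE)
      fingerprint_ridge_predictor(smiles[idx], bandgaps[idx], ...)
    })
  })
  member_matrix <- function(smi) {
    vapply(members, function(m) m$predict_fn(smi), numeric(length(smi)))
  }
  property_predictor(
    function(smi) {
      M <- matrix(member_matrix(smi), nrow = length(smi))
      rowMeans(M)
    },
    std_fn = function(smi) {
      M <- matrix(member_matrix(smi), nrow = length(smi))
      if (ncol(M) < 2L) return(rep(0, length(smi)))
      apply(M, 1L, stats::sd)
    },
    name = sprintf("bootstrap ridge ensemble (%d members)", n_members))
}

# ---------------------------------------------------------------------------
# diversity-penalised reward

#' Reward specification
#'
#' The reward of iteration `i` is
#' `R_i(x) = w_p * C(x) - w_s * agg_{y in Y_<i} S(x, y)`, where `C` is the
#' property reward (the negative predicted bandgap), `Y_<i` is the inventory
#' of high-performing molecules collected in earlier iterations, and `S` is
#' Tanimoto similarity over Morgan fingerprints. With an empty inventory the
#' penalty term is 0. `agg` is `max` by default (strongest diversity
#' pressure); `mean` is available.
#'
#' @param predictor a [property_predictor()] supplying the bandgap.
#' @param property_weight `w_p` > 0.
#' @param similarity_weight `w_s` >= 0.
#' @param aggregation `"max"` or `"mean"` over the inventory similarities.
#' @param inventory character vector of canonical SMILES of previous winners.
#' @param radius,n_bits fingerprint parameters for the similarity term.
#' @return an object of class `reward_spec`.
#' @export
reward_spec <- function(predictor, property_weight = 1, similarity_weight = 1,
                        aggregation = c("max", "mean"),
                        inventory = character(0), radius = 2L,
                        n_bits = 2048L) {
  stopifnot(inherits(predictor, "property_predictor"), property_weight > 0,
            similarity_weight >= 0)
  structure(list(predictor = predictor, property_weight = property_weight,
                 similarity_weight = similarity_weight,
                 aggregation = match.arg(aggregation),
                 inventory = inventory, radius = as.integer(radius),
                 n_bits = as.integer(n_bits)),
            class = "reward_spec")
}

#' Diversity-penalised reward
#'
#' @param mol a [symmol] or SMILES.
#' @param spec a [reward_spec()].
#' @return list-free scalar reward `w_p * (-bandgap) - w_s * penalty`; the
#'   components are attached as attributes `property_term` and
#'   `penalty_term`.
#' @export
penalized_reward <- function(mol, spec) {
  mol <- as_symmol(mol)
  prop <- spec$property_weight * (-predict(spec$predictor, mol))
  pen <- spec$similarity_weight * inventory_similarity(mol, spec)
  structure(prop - pen, property_term = prop, penalty_term = pen)
}

inventory_similarity <- function(mol, spec) {
  if (!length(spec$inventory)) return(0)
  fp <- morgan_fingerprint(mol, spec$radius, spec$n_bits)
  sims <- vapply(spec$inventory, function(y) {
    tanimoto(fp, morgan_fingerprint(y, spec$radius, spec$n_bits))
  }, numeric(1), USE.NAMES = FALSE)
  switch(spec$aggregation, max = max(sims), mean = mean(sims))
}

#' Iteratively re-trained diverse search
#'
#' Runs `n_iterations` fresh MCTS searches. After each, the best molecule of
#' the trailing window joins the inventory, so the next iteration's reward is
#' penalised for similarity to all previous winners: the constrained
#' optimisation becomes harder with every iteration and the winners are
#' chemically diverse.
#'
#' @param env a `symfrag_mdp` environment.
#' @param spec a [reward_spec()]; its inventory is the starting inventory
#'   (usually empty).
#' @param n_iterations number of diversity iterations.
#' @param config a [search_config()]; iteration `i` is seeded with
#'   `config$seed + i - 1` so the runs are independent but reproducible.
#' @return an object of class `symfrag_inventory`: data.frame with one row
#'   per iteration (`iteration`, `smiles`, `reward`, `property_term`,
#'   `penalty_term`, `bandgap`); the final inventory is `$smiles`.
#' @export
iterative_diverse_search <- function(env, spec, n_iterations = 5L,
                                     config = search_config()) {
  stopifnot(n_iterations >= 1L)
  rows <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    cache <- new.env(parent = emptyenv())
    reward_fn <- function(mol) {
      hit <- cache[[mol$smiles]]
      if (!is.null(hit)) return(hit)
      r <- penalized_reward(mol, spec)
      assign(mol$smiles, r, envir = cache)
      r
    }
    cfg <- config
    if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + i - 1L
    sr <- run_search(env, reward_fn, cfg)
    best <- sr$best
    r <- penalized_reward(best$smiles, spec)
    rows[[i]] <- data.frame(
      iteration = i, smiles = best$smiles, reward = as.numeric(r),
      property_term = attr(r, "property_term"),
      penalty_term = attr(r, "penalty_term"),
      bandgap = as.numeric(predict(spec$predictor, best$smiles)),
      stringsAsFactors = FALSE)
    spec$inventory <- c(spec$inventory, best$smiles)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("symfrag_inventory", "data.frame"))
}

#' @export
print.symfrag_inventory <- function(x, ...) {
  cat("<symfrag_inventory> ", nrow(x), " iterations\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.symfrag_inventory <- function(x, ...) {
  graphics::par(mar = c(4, 4, 1, 4))
  graphics::plot(x$iteration, -x$property_term, type = "b", pch = 16,
                 col = "steelblue", xlab = "iteration",
                 ylab = "weighted bandgap term (eV)", ...)
  graphics::par(new = TRUE)
  graphics::plot(x$iteration, x$penalty_term, type = "b", pch = 17,
                 col = "firebrick", axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("similarity penalty", side = 4, line = 2.5)
  invisible(x)
}
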