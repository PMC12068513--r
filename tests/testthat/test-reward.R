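# Diversity-penalised reward, expected improvement, acquisition, AL loop.

test_that("penalized reward combines property and similarity terms", {
  oracle <- toy_conjugation_oracle()
  benzene <- canonicalize("c1ccccc1")
  c_benzene <- -predict(oracle, benzene)

  spec0 <- reward_spec(oracle)                       # empty inventory
  r0 <- penalized_reward(benzene, spec0)
  expect_equal(as.numeric(r0), c_benzene)
  expect_equal(attr(r0, "penalty_term"), 0)

  # inventory containing the molecule itself: penalty is exactly w_s * 1
  spec_self <- reward_spec(oracle, inventory = benzene$smiles)
  r_self <- penalized_reward(benzene, spec_self)
  expect_equal(as.numeric(r_self), c_benzene - 1)

  # arithmetic with max aggregation and w_s = 2
  spec2 <- reward_spec(oracle, similarity_weight = 2,
                       inventory = c("c1ccncc1", "Cc1ccccc1"))
  sims <- vapply(spec2$inventory, function(y) {
    tanimoto(morgan_fingerprint(benzene), morgan_fingerprint(y))
  }, numeric(1))
  r2 <- penalized_reward(benzene, spec2)
  expect_equal(as.numeric(r2), c_benzene - 2 * max(sims))
  spec_mean <- reward_spec(oracle, similarity_weight = 2,
                           aggregation = "mean",
                           inventory = spec2$inventory)
  expect_equal(as.numeric(penalized_reward(benzene, spec_mean)),
               c_benzene - 2 * mean(sims))

  # w_s = 0 is invariant to the inventory
  spec_w0 <- reward_spec(oracle, similarity_weight = 0,
                         inventory = c("c1ccccc1", "c1ccncc1"))
  expect_equal(as.numeric(penalized_reward(benzene, spec_w0)), c_benzene)
})

test_that("expected improvement matches the closed form and its limits", {
  expect_equal(expected_improvement(0, 1, 0), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  expect_identical(expected_improvement(-1, 0, 0), 0)
  expect_identical(expected_improvement(2, 0, 0.5), 1.5)
  expect_error(expected_improvement(0, -1, 0), "non-negative")
  # sigma -> 0 limit is continuous
  expect_equal(expected_improvement(0.3, 1e-12, 0),
               expected_improvement(0.3, 0, 0), tolerance = 1e-9)
  expect_equal(expected_improvement(-0.3, 1e-12, 0), 0, tolerance = 1e-9)
  # monotone increasing in sigma below the incumbent
  sig <- seq(0.1, 3, by = 0.1)
  ei <- expected_improvement(-0.5, sig, 0)
  expect_true(all(diff(ei) > 0))
  expect_true(all(ei >= 0))
})

test_that("expected improvement agrees with a Monte-Carlo oracle", {
  set.seed(1)
  z <- stats::rnorm(2e5)
  for (mu in c(-1, 0, 1)) {
    for (sigma in c(0.2, 1)) {
      mc <- mean(pmax(mu + sigma * z, 0))
      expect_equal(expected_improvement(mu, sigma, 0), mc, tolerance = 5e-3)
    }
  }
})

test_that("iterative diverse search yields pairwise distinct winners", {
  env <- toy_mdp()
  spec <- reward_spec(toy_conjugation_oracle())
  inv <- iterative_diverse_search(env, spec, n_iterations = 3L,
                                  config = search_config(n_steps = 120L,
                                                         seed = 5L))
  expect_identical(nrow(inv), 3L)
  expect_identical(anyDuplicated(inv$smiles), 0L)
  expect_equal(inv$penalty_term[1], 0)
  expect_true(all(inv$penalty_term[-1] > 0))
  fps <- lapply(inv$smiles, morgan_fingerprint)
  for (i in 1:2) {
    for (j in (i + 1):3) expect_lt(tanimoto(fps[[i]], fps[[j]]), 1)
  }
})

test_that("acquisition ranks by expected improvement with deduplication", {
  env <- toy_mdp()
  set.seed(2)
  smi <- unique(random_rollouts(env, 40L))
  oracle <- toy_conjugation_oracle()
  ens <- bootstrap_ensemble(smi, predict(oracle, smi), n_members = 3L,
                            seed = 1L)
  batch <- acquire_batch(env, ens, n_samples = 60L, n_top = 10L, seed = 3L)
  expect_lte(nrow(batch), 10L)
  expect_identical(anyDuplicated(batch$smiles), 0L)
  expect_true(all(diff(batch$ei) <= 1e-12))
  # EI recomputed from (mu, sigma, batch f*) matches the reported ranking
  ei2 <- expected_improvement(batch$mu, batch$sigma, max(batch$mu))
  expect_equal(batch$ei, ei2, tolerance = 1e-12)
  expect_error(acquire_batch(env, ens, n_samples = 0L), "positive")
})

test_that("the active-learning loop stops on the RMSE criterion", {
  env <- toy_mdp()
  oracle <- toy_conjugation_oracle()
  # a perfectly learnable target: labels from the predictor used as oracle
  al <- al_loop(env, oracle, trainer = ridge_trainer(n_members = 2L),
                stopping_rmse = 10, max_rounds = 3L, n_initial = 30L,
                seed = 4L)
  expect_identical(nrow(al$rounds), 1L)      # trivially satisfied round 1
  expect_true(al$rounds$stopped[1])
  expect_error(al_loop(env, oracle, ridge_trainer(), max_rounds = 0L),
               "max_rounds")
})

test_that("predictors honour the contract: determinism and ensemble std", {
  oracle <- toy_conjugation_oracle()
  smi <- c("c1ccccc1", "c1ccc(s1)c1cccs1", "Cc1ccccc1")
  expect_identical(predict(oracle, smi), predict(oracle, smi))
  # more conjugation, lower toy bandgap
  expect_lt(predict(oracle, "c1ccc(s1)c1cccs1"), predict(oracle, "c1ccccc1"))

  y <- predict(oracle, smi)
  single <- bootstrap_ensemble(smi, y, n_members = 1L, seed = 1L)
  ps <- predict_with_std(single, smi)
  expect_identical(ps$std, rep(0, 3L))

  ridge <- fingerprint_ridge_predictor(smi, y, n_bits = 64L)
  expect_length(predict(ridge, smi), 3L)
  expect_true(all(is.finite(predict(ridge, smi))))
})
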