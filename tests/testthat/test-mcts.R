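# UCT selection, search behaviour, windowed extraction, tree invariants.

test_that("uct_select matches the arithmetic and prefers unvisited actions", {
  node <- list(actions = list(action_spec("a", 1), action_spec("a", 2)),
               edge_N = c(10L, 1L), edge_W = c(5, 0.4), N = 11L)
  # scores: 0.5 + sqrt(ln 11 / 10) = 0.990 vs 0.4 + sqrt(ln 11) = 1.949
  picked <- uct_select(node, c = 1)
  expect_identical(picked$payload, 2)
  expect_equal(uct_scores(c(0.5, 0.4), c(10, 1), 11, 1),
               c(0.5 + sqrt(log(11) / 10), 0.4 + sqrt(log(11))),
               tolerance = 1e-12)
  # c = 0: pure exploitation
  expect_identical(uct_select(node, c = 0)$payload, 1)
  # unvisited action always first
  node$edge_N <- c(10L, 0L)
  expect_identical(uct_select(node, c = 0)$payload, 2)
  empty <- list(actions = list(), edge_N = integer(0), edge_W = numeric(0),
                N = 0L)
  expect_error(uct_select(empty), "no legal actions")
})

test_that("uct_select equals a brute-force argmax oracle on random tuples", {
  set.seed(42)
  for (i in 1:200) {
    k <- sample(2:6, 1)
    n <- sample(1:50, k, replace = TRUE)
    w <- stats::runif(k, -5, 5) * n
    np <- sum(n)
    cc <- stats::runif(1, 0, 2)
    node <- list(actions = lapply(seq_len(k), function(j) action_spec("a", j)),
                 edge_N = n, edge_W = w, N = np)
    oracle <- which.max(w / n + cc * sqrt(log(np) / n))
    expect_identical(uct_select(node, cc)$payload, oracle)
  }
})

test_that("search is reproducible and improves on random rollouts", {
  env <- toy_mdp()
  oracle <- toy_conjugation_oracle()
  reward <- function(mol) -predict(oracle, mol)
  cfg <- search_config(n_steps = 400L, seed = 11L)
  a <- run_search(env, reward, cfg)
  b <- run_search(env, reward, cfg)
  expect_identical(a$ledger, b$ledger)

  set.seed(3)
  rnd <- random_rollouts(env, 200L)
  mean_random <- mean(-predict(oracle, rnd))
  late <- a$ledger$reward[301:400]
  expect_gt(mean(late), mean_random)     # exploitation beats random policy
})

test_that("search finds the enumerable optimum of the toy grammar", {
  env <- toy_mdp()
  oracle <- toy_conjugation_oracle()
  reward <- function(mol) -predict(oracle, mol)
  optimum <- max(-predict(oracle, enumerate_terminals(env)$smiles))
  hits <- vapply(1:3, function(s) {
    sr <- run_search(env, reward, search_config(n_steps = 1000L, seed = s))
    isTRUE(all.equal(max(sr$ledger$reward), optimum))
  }, logical(1))
  expect_true(all(hits))
})

test_that("visit counts are conserved and Q stays within backpropagated rewards", {
  env <- toy_mdp()
  oracle <- toy_conjugation_oracle()
  reward <- function(mol) -predict(oracle, mol)
  sr <- run_search(env, reward, search_config(n_steps = 300L, seed = 2L))
  rng <- range(sr$ledger$reward)
  for (key in ls(sr$nodes)) {
    nd <- sr$nodes[[key]]
    expect_identical(nd$N, sum(nd$edge_N))
    vis <- nd$edge_N > 0L
    q <- nd$edge_W[vis] / nd$edge_N[vis]
    if (length(q)) {
      expect_true(all(q >= rng[1] - 1e-12 & q <= rng[2] + 1e-12))
    }
  }
})

test_that("reward failures fall back to the configured floor without aborting", {
  env <- toy_mdp()
  flaky <- function(mol) {
    if (heavy_atoms(mol) %% 2L == 0L) stop("boom")
    -1
  }
  expect_warning(run_search(env, function(mol) stop("boom"),
                            search_config(n_steps = 1L, seed = 7L,
                                          reward_floor = -99)),
                 "reward failed")
  sr <- suppressWarnings(
    run_search(env, flaky, search_config(n_steps = 30L, seed = 1L,
                                         reward_floor = -99)))
  expect_setequal(unique(sr$ledger$reward), c(-1, -99))
})

test_that("best_in_window honours the window semantics", {
  led <- data.frame(step = 1:150,
                    smiles = sprintf("m%d", 1:150),
                    reward = c(rep(0, 50), seq(1, 0.01, length.out = 100)))
  b <- best_in_window(led, 100L)
  expect_identical(b$smiles, "m51")          # max over entries 51..150
  expect_identical(b$reward, 1)
  led$reward[10] <- 99
  expect_identical(best_in_window(led, 100L)$smiles, "m51")
  expect_identical(best_in_window(led, 1000L)$smiles, "m10")
  # direct-scan oracle on a random ledger
  set.seed(8)
  led$reward <- stats::runif(150)
  idx <- 51:150
  expect_identical(best_in_window(led, 100L)$smiles,
                   led$smiles[idx[which.max(led$reward[idx])]])
  expect_error(best_in_window(led[0, ], 10L), "empty")
})
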