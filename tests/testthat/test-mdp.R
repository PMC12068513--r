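# The two assembly grammars and fragment clustering.

state_marks <- function(s) symfrag:::state_open_marks(s)

test_that("the focused grammar initialises with four pending core positions", {
  env <- y6_mdp()
  s <- initial_state(env)
  expect_false(is_terminal(env, s))
  expect_identical(s$stage, "core")
  acts <- legal_actions(env, s)
  expect_true(all(vapply(acts, function(a) a$kind, character(1)) ==
                    "modify-core-position"))
  expect_setequal(state_marks(s), c(0L, 1L))
  # the initial state already carries the default core
  expect_identical(symfrag:::state_heavy_atoms(s), 21L)
  # two calls give identical canonical states
  s2 <- initial_state(env)
  expect_identical(env$state_key(s), env$state_key(s2))
})

test_that("focused-grammar trajectories pass core, bridge, end and alkyl stages", {
  env <- y6_mdp()
  s <- initial_state(env)
  for (i in 1:4) {
    acts <- legal_actions(env, s)
    res <- mdp_step(env, s, acts[[1]])
    expect_identical(res$probability, 1)       # deterministic grammar
    s <- res$next_state
  }
  expect_identical(s$stage, "bridge")
  kinds <- vapply(legal_actions(env, s), function(a) a$kind, character(1))
  expect_true("skip-pi-bridge" %in% kinds)
  s <- mdp_step(env, s, action_spec("skip-pi-bridge"))$next_state
  expect_identical(s$stage, "end")
  s <- mdp_step(env, s, legal_actions(env, s)[[1]])$next_state
  expect_identical(s$stage, "alkyl")
  alkyl <- legal_actions(env, s)
  expect_length(alkyl, 1L)                     # methyl only
  s <- mdp_step(env, s, alkyl[[1]])$next_state
  expect_true(is_terminal(env, s))
  expect_identical(legal_actions(env, s), list())
  mol <- trajectory_molecule(env, s)
  expect_identical(nrow(attachment_points(mol)), 0L)
  expect_error(trajectory_molecule(env, initial_state(env)), "terminal")
})

test_that("open-grammar rollouts respect cap, symmetry and bridge limits", {
  env <- patent_mdp(four_mark_pool(),
                    patent_config(k_clusters = 3L, max_heavy_atoms = 40L))
  set.seed(5)
  for (i in 1:25) {
    smi <- random_rollouts(env, 1L)
    expect_lte(heavy_atoms(smi), 40L)
  }
})

test_that("used fragments are masked from later choices", {
  pool <- four_mark_pool()
  env <- patent_mdp(pool, patent_config(k_clusters = 2L))
  s <- initial_state(env)
  s <- mdp_step(env, s, legal_actions(env, s)[[1]])$next_state  # core cluster
  core_act <- legal_actions(env, s)[[1]]
  s <- mdp_step(env, s, core_act)$next_state                    # core fragment
  expect_identical(s$used, core_act$payload)
  s <- mdp_step(env, s, action_spec("skip-pi-bridge"))$next_state
  # collect every fragment offered across all end clusters
  offered <- integer(0)
  for (ca in legal_actions(env, s)) {
    s2 <- mdp_step(env, s, ca)$next_state
    offered <- c(offered, vapply(legal_actions(env, s2),
                                 function(a) a$payload, integer(1)))
  }
  expect_false(core_act$payload %in% offered)
})

test_that("reactive-position sampling is uniform over unique marks", {
  env <- patent_mdp(four_mark_pool(), patent_config(k_clusters = 2L))
  s <- initial_state(env)
  s <- mdp_step(env, s, legal_actions(env, s)[[1]])$next_state
  s <- mdp_step(env, s, legal_actions(env, s)[[1]])$next_state  # 4-marked core
  expect_identical(length(state_marks(s)), 4L)
  s <- mdp_step(env, s, action_spec("skip-pi-bridge"))$next_state
  ca <- legal_actions(env, s)[[1]]
  s2 <- mdp_step(env, s, ca)$next_state
  fa <- legal_actions(env, s2)[[1]]
  set.seed(99)
  res1 <- mdp_step(env, s2, fa)
  expect_equal(res1$probability, 0.25)
  draws <- vapply(1:2000, function(i) mdp_step(env, s2, fa)$sampled_mark,
                  integer(1))
  tab <- table(factor(draws, levels = state_marks(s)))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("fragment clustering is deterministic, clamps k, and groups duplicates", {
  frags <- c("[1*]c1ccccc1", "[1*]c1ccc(s1)", "[1*]C")
  cl <- cluster_fragments(frags, k_clusters = 3L, seed = 1L)
  expect_identical(cl$k, 3L)
  expect_identical(sort(unique(cl$assignment)), 0:2)

  dup <- c("[1*]c1ccccc1", "[1*]c1ccccc1", "[1*]C")
  expect_message(cl2 <- cluster_fragments(dup, k_clusters = 3L, seed = 1L),
                 "clamped")
  expect_identical(cl2$assignment[1], cl2$assignment[2])

  pool <- small_pool()
  a <- cluster_fragments(pool, k_clusters = 4L, seed = 7L)
  b <- cluster_fragments(pool, k_clusters = 4L, seed = 7L)
  expect_identical(a$assignment, b$assignment)
  expect_error(cluster_fragments(character(0)), "empty")
})
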