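---
title: "Symmetry-constrained fragment generation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry-constrained fragment generation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symfrag)
```

## The design problem

Low-bandgap conjugated molecules -- non-fullerene acceptors (NFAs) for
organic photovoltaics and near-infrared photodiodes being the motivating
family -- are built in practice from a modest catalogue of aromatic building
blocks: fused electron-rich cores, conjugated pi-bridges, electron-deficient
end-groups, and solubilising alkyl chains. Molecules that have actually been
synthesised carry two kinds of information beyond their property values:
*which fragments* chemists combine, and *how symmetrically* they combine them
(an A--D--A acceptor carries the same end-group on both arms because both
arms come from the same coupling step). `symfrag` operationalises both: it
extracts fragments together with the identity of what was attached at each
reactive position, and it generates new molecules constrained to those
fragments and attachment symmetries, searching the assembly space with Monte
Carlo tree search (MCTS) against a pluggable property objective.

The package deliberately separates the *grammar* (what may be assembled, and
where) from the *objective* (how a finished molecule is scored). Anything
satisfying the predictor contract -- a function from SMILES to a scalar
property, optionally with an ensemble spread -- can drive the search; the
bundled scorers are a deterministic conjugation-count toy oracle and a
fingerprint ridge regressor, which make every example in this package run
offline in seconds. They stand in for expensive excited-state calculations
or neural surrogates, and the vignette is explicit below about what that
substitution does and does not demonstrate.

## Fragment decomposition with symmetry labels

A bond is *cleavable* when it is a single, acyclic, non-aromatic bond between
two heavy atoms at least one of which is aromatic: this captures single bonds
joining an aromatic ring to an aliphatic chain and inter-ring single bonds
between two aromatic systems, and it never opens a ring. Decomposition is a
recursive sequence of one-bond deletions forming a binary tree:

1. **Vocabulary.** Every one-bond deletion of the input molecule yields two
   fragments; their canonical forms (attachment wildcard retained, labels
   stripped) are deduplicated, sorted, and given contiguous integer IDs
   `0 .. N-1`.
2. **Recursion.** The first cleavable bond in canonical atom order is
   deleted. The new reactive position on each side is *marked* with the
   vocabulary ID of the other side's stripped form -- the identity of what
   was removed there. Both sides recurse until no cleavable bond remains;
   the uncleavable fragments are the leaves. A memo table keyed on the
   canonical marked form skips previously decomposed fragments (the result
   is identical with memoization off, which the test suite asserts).
3. **Dynamic vocabulary extension.** From recursion depth two onward a
   counterpart can carry inherited marks and be absent from the single-cut
   vocabulary; such forms are appended with the next free ID in discovery
   order, which is deterministic for a given input.

Two attachment points therefore share a mark exactly when the fragments
removed there were identical at removal time. This is the property the
generator exploits: *identically marked positions must receive identical
fragments*. Note the qualifier "at removal time": when an arm is itself
dismantled before being detached (the recursion is free to cut inside an arm
first), two geometrically equivalent positions can legitimately end up with
different marks because their counterparts differed when removed. The
invariant that is always true -- and that the acceptance checks assert -- is
the bijection between marks and removed-counterpart forms.

`reassemble()` inverts a decomposition by joining fragments whose marks
mutually reference each other's stripped forms. Because several leaves can
share a stripped form (three identical bridges, say), a locally valid join
can conflict with the original cut order, so the oracle backtracks over join
choices with failed-state memoization. Round-tripping
`reassemble(decompose(m))` against canonical equality over a 200-molecule
synthetic corpus is the package's primary correctness check.

### Serialisation of marks

Attachment points are wildcard (`*`) atoms. A mark `m` is serialised as the
isotope `m + 1` of the wildcard: `[1*]` is mark 0. The offset exists because
isotope 0 is not representable in SMILES, and isotope labels -- unlike
atom-map annotations -- survive Open Babel canonicalisation bit-exactly, so
fragment files round-trip. Unmarked wildcards are written `*`.

## The two assembly grammars

**Focused (Y6-style) grammar** (`y6_mdp()`): four sequential hierarchies --
core-position modifications at `pos0..pos3`, optional pi-bridges (with an
explicit skip action, at most two rounds), one end-group choice, one alkyl
choice. The two end sites share mark 0, so bridges and end-groups attach
symmetrically on both arms; alkyl sites carry mark 1 and default to methyl
only (alkyl chains mainly influence solubility and packing rather than
single-molecule optics, and a single alkyl keeps downstream validation
cheap; this simplification deliberately ignores aggregated-state effects).
All transitions are deterministic. The shipped core template and fragment
sets are illustrative stand-ins drawn from standard NFA chemistry
(thiophene/furan/selenophene/benzene ring units around an sp3 bridge carbon;
vinylene/thiophene/furan bridges; dicyanovinyl-type end-groups) and are
fully configurable through `y6_config()` -- the grammar, not the specific
library, is the point.

**Open (patent-style) grammar** (`patent_mdp()`): builds from an empty state
out of a decomposed fragment pool. Because the pool is wide, fragment
choices are factored into *choose a cluster, then choose a fragment within
it*, with clusters from k-means over Morgan fingerprints (`k = 100` by
default, clamped to the pool; the value is a user parameter, not a tuned
constant). Stages are: core, up to two optional pi-bridge rounds, then
end-group rounds iterated while open positions remain. Cluster choices are
deterministic; each fragment attachment first samples the target mark
uniformly from the `k_t` unique open marks (transition probability `1/k_t`)
and then attaches one copy at *every* position carrying that mark. Keeping
the reactive-position choice out of the action space halves the tree depth
and pushes the search toward solutions robust to position choice; fragment
identity matters more for optical properties than the position does.
Fragment IDs already used in a trajectory are masked from later choices, so
differently marked positions receive different identities; if masking ever
empties the action set the constraint is relaxed to the least recently used
fragment with a warning.

Numerical details worth knowing:

* **Size cap** (default 100 heavy atoms): an attachment that would exceed it
  hydrogen-caps all remaining positions and terminates. Capping (rather than
  rejecting the action) keeps every trajectory valid.
* **Fresh marks** created by an attachment are allocated above a monotone
  per-trajectory counter, so a mark value is never recycled after being
  consumed; with several identically marked sites filled at once, the
  corresponding new positions on the copies share one fresh mark and the
  symmetry constraint propagates.
* **Pool roles**: cores and end-groups may be any fragment with at least one
  reactive position; bridges need at least two. The pool filters
  (`size_cap = 40` heavy atoms, `reactive_cap = 6` positions by default) are
  configuration values chosen to keep generated molecules in a synthetically
  and computationally reasonable range.

## Monte Carlo tree search

`run_search()` is textbook UCT: selection by
`argmax_a Q(a) + c * sqrt(log N_parent / N(a))` with unvisited actions taking
infinite priority and ties broken uniformly at random; expansion picks one
unexpanded action uniformly; rollout follows a uniform random policy to
termination; the scalar terminal reward is backpropagated along every
traversed edge (`Q = W/N`, the arithmetic mean). Stochastic outcomes of one
action (the sampled mark) are separated per outcome in the tree, while the
edge statistics marginalise over them. Rewards are used unnormalised, so the
exploration coefficient is scale-sensitive; the default `c = 1/sqrt(2)` is
the usual UCT constant and a configuration value, and the default budget of
2000 iterations is where searches on the bundled problems have long
converged. Nodes are keyed by a deterministic structural state key (stage
plus the writer's SMILES of the partial graph), which merges
identically-constructed states cheaply; strict path-keyed trees are
available via `search_config(transpositions = "path")`. Every source of
randomness runs off `search_config(seed = )`, and two runs with the same
configuration produce byte-identical ledgers.

`best_in_window()` extracts the reward-maximising molecule of the trailing
100 steps -- the converged tail of a run rather than a lucky early rollout.

## Diversity-penalised iteration and acquisition

A converged policy maximises expected reward and happily rediscovers the
same optimum. To collect a *diverse* slate, `iterative_diverse_search()`
re-trains MCTS from scratch for `n` iterations with the reward

    R_i(x) = w_p * C(x) - w_s * agg_{y in Y_<i} S(x, y)

where `C` is the property reward (negative predicted bandgap), `Y_<i` the
inventory of previous iteration winners, and `S` Tanimoto similarity over
Morgan fingerprints (radius 2, 2048 bits folded from Open Babel ECFP4 -- the
community defaults, configurable). The aggregation over the inventory is
`max` by default (the strongest diversity pressure: a candidate pays for its
*closest* previous winner); `mean` is available, and `w_p = w_s = 1` unless
configured otherwise. Iteration 1 has an empty inventory and pays no
penalty; each later iteration faces a strictly harder constrained problem,
which is visible in the logged per-iteration property and penalty terms.

For active learning, `expected_improvement()` is the standard Gaussian EI,
`EI = (mu - f*) * pnorm(z) + sigma * dnorm(z)`, with `mu` the predicted
reward, `sigma` the ensemble spread, `f*` the best predicted reward *within
the current candidate batch*, and the `sigma = 0` limit handled exactly as
`max(mu - f*, 0)` (a single-model "ensemble" has `sigma = 0` by definition
and degrades gracefully to pure exploitation). `acquire_batch()` draws
random rollouts, deduplicates by canonical form, and keeps the top-EI
candidates (defaults 10000 samples, top 100). `al_loop()` alternates
acquisition (diversity winners plus top-EI), labelling by a user oracle, and
retraining, stopping at a held-out RMSE of 0.3 eV by default -- the accuracy
level at which a bandgap surrogate stops being the limiting factor -- or at
`max_rounds`.

## The synthetic fixture corpus

`generate_fixtures()` assembles molecules from a small library (aromatic
cores with 1-3 identically marked sites, divalent aromatic bridges,
monovalent end-groups) whose every junction is a cleavable bond and whose
pieces contain no internal cleavable bonds, so the exact constituent
fragments of every molecule are known. "Contrast" molecules place two
independently sampled end-groups on two differently marked sites and record
whether the ends coincide -- the discriminating case for symmetry labels.
Defaults (200 molecules at acceptance scale, symmetry degrees 2-3, half the
symmetric molecules bridged, about 30% contrast) were chosen once to cover
every grammar feature at desk-scale cost.

What the corpus does *not* emulate: fused polycyclic cores of realistic NFA
size, heteroatom-rich end-groups beyond the small built-in set,
stereochemistry, or any correlation between structure and a real measured
property. Passing tests on fixtures therefore certify the *machinery* --
decomposition, symmetry bookkeeping, grammar constraints, search mechanics,
acquisition arithmetic -- not chemical accuracy of any predictor. Likewise
the toy conjugation oracle (`E = 1 + 9/(3 + n_conj)` eV, monotone in the
count of conjugated heavy atoms) has the right qualitative physics and the
wrong everything else; results obtained with it say nothing about real
bandgaps.

## Problem sizes and degenerate inputs

The shipped checks run at deliberate desk scale: a 200-molecule fixture
corpus for round-trip/symmetry/memoization; 20 independent 2000-step
searches for toy-optimality; 10000 draws for the transition law; a million
antithetic normal draws for the EI oracle; 1000 random open-grammar
rollouts for the constraint audit. On one CPU the whole acceptance script
takes a few minutes.

Degenerate inputs are defined rather than rejected wherever a sensible
definition exists: a molecule with no cleavable bond decomposes to itself
(and its vocabulary is itself); an empty corpus yields an empty pool;
clustering clamps `k` to the number of distinct fingerprints (duplicates
always share a cluster); two empty fingerprints have Tanimoto 0 by
convention; a reward-function failure logs the molecule at a configured
floor instead of aborting the search; `k_t = 1` makes the "stochastic"
transition deterministic with probability 1.

## Known limitations

* Aromaticity and canonical forms are exactly Open Babel's model; molecules
  whose aromatic perception differs between toolkits will decompose
  accordingly. Stereochemistry is passed through but not preserved in the
  internal graph.
* Cut order dependence of marks (discussed above) means geometrically
  symmetric positions of an input molecule are not *guaranteed* identical
  marks when their arms contain internal cleavable bonds.
* The open grammar treats every pool fragment with two or more reactive
  positions as a possible bridge; chemical plausibility of a given bridge
  placement is the predictor's problem, not the grammar's.
* Search is single-threaded and tree-parallelism is out of scope, as are
  learned priors over actions; the generator is plain UCT by design.
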