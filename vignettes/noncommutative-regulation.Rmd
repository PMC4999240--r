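---
title: "Noncommutative sequential regulation: models, counting laws, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noncommutative sequential regulation: models, counting laws, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noncommnet)
```

## The problem

Biological regulators are promiscuous: a kinase phosphorylates many
substrates, a chromatin factor folds many loci. Under combinatorial (AND/OR)
logic the joint state of the regulators determines the joint state of the
targets one-to-one, so `n + m` regulators can never specify more than
`2^(n+m)` target configurations -- an information bottleneck whenever there
are more cell fates than regulators. Sequential logic escapes the
bottleneck by letting the *time order* of regulator actions matter: when
actions do not commute, distinct orderings of the same regulators drive the
network to distinct configurations. This package implements two such
noncommutative models as exact discrete dynamical systems, together with
the combinatorial theory that quantifies how much diversity they generate.

## The two models

**Ratchet network** (`ratchet_spec(n, m, l_n, l_m, T)`). Activators `K_i`
and deactivators `P_j` act on `N = choose(n, l_n) * choose(m, l_m)`
targets, each identified by the `l_n` K's and `l_m` P's it responds to.
Target states are integers in `0..T`; `K_i` increments every receptive
target (saturating at `T`), `P_j` decrements (flooring at 0); a target is
ON at state `T`. Pure-K and pure-P words commute; mixed words do not,
because of the saturation edge effects: from a target at threshold, `K P`
leaves `T - 1` but `P K` leaves `T`. The model abstracts one-pot chemistry
such as multisite phosphorylation, or summating neural inputs.

**Sequestration network** (`seq_spec(n, reduced)`). Each target is a
nonempty subset `g` of the `n` regulator pairs (its *arms*) with states
`{0} union g`. `K_i` moves 0-state targets with arm `i` into state `i`,
where they are *protected* from every action except `P_i`, which releases
them to 0. This abstracts recruitment of loci to repressive nuclear
compartments: a sequestered gene is invisible to other factors until
released. The *full* network has all `2^n - 1` subsets as targets; the
*reduced* network keeps the `2^(n-1) - 1` targets that contain index 1
(the transcribing machinery) plus at least one other arm, so a target ON in
state 1 is "expressed".

Both models are driven by *words* -- finite action sequences like
`"K1 K2 P1"`, applied left to right (`apply_word()`).

```{r}
sp <- ratchet_spec(2, 2)
connectivity_matrix(apply_word(zero_config(sp), "K1 K2 P1", sp), sp)
```

Canonical orderings (and hence all printed vectors and hash keys) are
fixed: ratchet targets lexicographic on (K-subset, P-subset), i.e.
row-major in the connectivity matrix at `l = 1`; sequestration targets by
(arm count, lexicographic arms). Regulator indices are 1-based everywhere.

## Reachability and the counting laws

`bfs_reachable()` computes the exact breadth-first closure of a start
configuration under an action alphabet, with one shortest witness word per
configuration. Configurations are encoded in a mixed radix as IEEE doubles,
which are exact integers below `2^53`; every space enumerated here is many
orders of magnitude smaller.

Three families of closed-form results are implemented and are all
cross-checked against enumeration in the test suite:

* **Lonesum correspondence.** At `T = 1`, `l = 1` the reachable ratchet
  configurations are exactly the binary matrices avoiding the 2x2 patterns
  `(1 0 / 0 1)` and `(0 1 / 1 0)` ("lonesum" matrices, equivalently:
  matrices whose row supports are nested, equivalently permutable to a
  staircase). `is_lonesum()` tests the property, `staircase_word()`
  constructs a generating word, and `poly_bernoulli(n, m)` counts them --
  e.g. 14 at `2 x 2`, 230 at `3 x 3`, which is super-exponential in
  `n + m` though below `2^(nm)`. At threshold `T = 2` the forbidden
  patterns dissolve: `t2_constructive_word()` builds, for *any* binary
  pattern, a word staging each row through intermediate 1-2 configurations,
  so all `2^(nm)` ON/OFF patterns are reachable.

* **Connected one-colorings.** In the reduced sequestration network, the
  reachable ON/OFF expression patterns are exactly the *connected*
  colorings: every ON target with three or more arms must be supported by
  an ON 2-arm target sharing one of its arms (`is_connected()`). The count
  `one_coloring_count(n)` subtracts the connectivity violations from
  `2^(2^(n-1)-1)`; the violation sum runs over the number `m` of 2-arm
  targets fixed at 0, with inner sums over arm counts `3 <= k <= n` and
  binomials `choose(m, k-1)` vanishing naturally once `k - 1 > m`. The
  inner limits matter: truncating those sums at `k = m` instead would give
  zero violations at `n = 3`; the limits used here are the ones that agree
  with exhaustive enumeration at every `n <= 5` (the test suite checks
  this), giving 1, 2, 7, 89, 16897, 780304385 for `n = 1..6`. The
  full network has no closed form; `full_network_bounds(n)` brackets its
  BFS count (94 at `n = 3` between 89 and 130).

* **Minimal-sequence recursion.** With redundant connectivity
  (`l_n, l_m > 1`), words using more than `n - l_n + 1` distinct K's or
  `m - l_m` distinct P's are redundant with shorter ones.
  `minimal_sequence_count()` implements the recursion that peels these
  classes off the poly-Bernoulli totals: the class table `a_n^j` (words
  with exactly `j` P's, for a fixed P-set) is defined by extraction from
  the `(n, j+1)` network, where the `choose(j+1, j) = j+1` placements of
  the P-set supply the normalizing division. The recursion's validity is
  certified operationally: `minimal_sequences_bruteforce()`
  independently enumerates the reachable `l = 1` configurations and
  computes, per configuration, the provably minimal regulator usage -- any
  generating word needs one K per nonzero connectivity-matrix row and one P
  per column holding a 0 in some nonzero row, and the staircase word
  attains both minima -- then filters by the caps. Recursion and census
  agree on every `(n, m, l_n, l_m)` with `n, m <= 4` (tested exhaustively).

## Orbits

Starting configurations other than all-zero split the configuration space
into *orbits* -- sets of configurations mutually accessible under a
restricted alphabet. For the sequestration model, one-step transitions
inside an orbit can always be reversed, so `sequestration_orbits()` builds
the graph of reversible one-step paths over the whole space and takes
connected components (via igraph); the component of the origin coincides
with the BFS-reachable set (2, 7, 94 configurations for full `n = 1..3`),
and isolated components exist that use every regulator pair yet never
communicate with the main orbit.

For the ratchet network, an `i, j`-orbit is anchored by a forbidden
(non-lonesum) pattern on an `i x j` sub-block whose regulators are never
used. `ratchet_orbit_count()` evaluates the closed-form recursion for the
number of such orbits; `ratchet_orbits_bruteforce()` discovers origins
independently by directed reachability from candidate origins (rest-0, with
a rest-1 variant when no K -- respectively no P -- action remains), and
`orbit_count_check()` reports both side by side. The two routes agree at
every level with a single free row or column (2, 6 and 6 orbits per block
at sizes (2,2), (2,3), (3,2)). At (3,3) they genuinely differ (174 vs 156):
the recursion accounts for the configurations generated by a smaller orbit
as a *product* of the sub-block pattern and the free-block fillings, which
cannot represent reachable states that differ only in the "arm" cells a
free-row K writes into restricted columns (for example a forbidden 2x2
block with third row `(1, 1, 0)`, reached by `K` then `P` on the free row
and column). We implement both routes faithfully and surface the
disagreement in the check's report rather than forcing either count; the
corresponding acceptance test records the discrepancy as a failure by
design.

## Operator formulation

Both models embed in a single linear-algebraic picture
(`operator_spec()`): each target contributes a block of `D*T + 1`
population states (the shared 0 plus `T` rungs along each of `D`
dimensions; ratchet: `D = 1`, variable `T`; sequestration: `D = n`,
`T = 1`). A regulator's kinetics is a conservative block rate matrix
(`build_generator()`, columns summing to zero); driving the reaction to
completion (`t -> inf`) turns it into an exact 0/1 transfer operator
(`build_limit_operator()`), sub-diagonal for K, super-diagonal for P,
identity on protected or non-responsive blocks. The operators are
constructed symbolically -- never by thresholding numerics -- and the test
suite checks them against the matrix exponential of the generators at
`g t = 50` within `1e-10`. Noncommutativity reappears as nonvanishing
commutators (`commutator()`), and `operator_equivalence_check()` verifies
on seeded random word suites that the operator pipeline and the rule-based
dynamics agree configuration-for-configuration. Ratchet networks with
`l > 1` are declared unsupported in this picture (targets then share
regulators, breaking the independent-block structure) rather than
approximated.

## Robustness to regulator loss

`recovery_analysis()` runs the deletion experiment: enumerate the full
reachable set and the set reachable without one regulator (default `K1`),
drop the configurations the impaired network still reaches exactly, and
score each lost configuration by its best similarity to any impaired
configuration. Design choices, made explicit because the source protocol
is specified only qualitatively:

* similarity is Pearson correlation on ON/OFF vectors (cosine available),
  with the degenerate zero-variance case scored 1 for identical vectors
  and 0 otherwise;
* the impaired set is length-agnostic by default; an optional
  `min_extra_len` filter restricts it to configurations whose shortest
  word is longer than in the full network, mirroring the longer-sequences
  construction;
* no numeric values are asserted against the source figures (they are
  figure-only); the tests assert the structural properties instead --
  impaired sets nest inside full sets, reachability is non-increasing in
  connectivity, and the correlation matrix and CDF regenerate bit-for-bit.

`tradeoff_curve()` tabulates reachable-count versus recovered-fraction
across `(n, l_n)` grids for export.

## Numerical and design notes

* **Exact integers in doubles.** No installed big-integer arithmetic is
  assumed; all counting uses doubles with an explicit guard that aborts
  beyond `2^53` instead of returning rounded values. Everything in scope
  fits comfortably (the largest asserted count is 780304385; poly-Bernoulli
  values are exact through `n = m = 8`). `one_coloring_count(8)` and beyond
  are therefore refused by design.
* **Determinism.** BFS layers, canonical target orders and stable
  tie-breaks (staircase rows of equal width are emitted in ascending index
  order) make every enumeration reproducible bit-for-bit; all randomized
  suites (fixtures, operator equivalence) are seed-driven.
* **Certified search in `opposite_word()`.** The constructive existence
  proof behind the reachability of connected one-colorings recurses through
  embedded sub-networks and "opposite" configurations, but leaves the
  scheduling of temporary protections under-specified for colorings whose
  2-arm supports are all ON. Rather than ship a partially specified
  construction, `opposite_word()` decides feasibility by the connectivity
  rule and then produces a shortest word by exact search with a replay
  check, so the returned word is a verified certificate. The searches
  involved are desk-scale (the reduced `n = 4` space has under 9000
  configurations); a fully constructive scheduler would be the natural
  refinement for larger `n`.
* **Capacity caps.** All exhaustive operations take explicit
  `max_states`/`max_colorings` caps (default `1e7` enumerated states) and
  fail loudly instead of thrashing.
* **Problem sizes.** The shipped tests enumerate up to the full `n = 4`
  sequestration network (37701 reachable configurations out of a
  1.5e7-state space, about a second), the `4 x 4` ratchet grid, all
  `2^15` colorings at `n = 5`, and the complete `(n, m, l_n, l_m)`
  minimal-sequence grid for `n, m <= 4`.

## What the synthetic setting does and does not show

All inputs here are generated by the models themselves -- there is no
external biological data, and the fixture generator samples uniform random
specs and words only to exercise invariants (conservation, protection,
commutativity of pure-K/pure-P words) across the parameter space. Passing
tests therefore certify the mathematics of the two idealized models, not
biological fidelity: real regulatory networks have graded expression
levels, stochastic kinetics, heterogeneous connectivity, and feedback, none
of which are modeled (continuous-time and stochastic dynamics are explicit
non-goals). The value of the package is exactness: every count, bound and
equivalence claim it makes is recomputed, not quoted.
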