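---
title: "The endosymbiosis signaling game: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The endosymbiosis signaling game: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`endogame` simulates how cellularization can stabilize cooperative
signaling between two replicating partners. This vignette records the
model, its assumptions, and the concrete numerical and design choices the
implementation makes, in the spirit of a methods section.

## The game and its outcome space

A single encounter is a two-player signaling game with one-sided
incomplete information. The sender carries a hidden nature type,
`HONEST` or `DECEPTIVE`; it emits one of two messages `M1`/`M2`; the
receiver observes only the message and selects action `A1` or `A2`. The
eight `(type, message, action)` triples are the outcomes `O1`–`O8`,
arranged so that honest types produce `O1`–`O4`, message `M1` produces
`{O1, O2, O7, O8}` and action `A1` produces `{O1, O4, O5, O8}`
(`resolve_outcome()` implements this bijection; `decompose_outcome()` its
inverse).

Payoffs `(U_S, U_R)` per outcome are configurable; the model constrains
their structure, not their magnitudes. The package ships a constructed
default (`default_payoff_table()`) that satisfies the structural
constraints the model needs, and `validate_payoff_table()` enforces them
for any user table:

* all utilities non-negative — they are reused directly as Dirichlet
  concentration parameters;
* `O1` is Pareto efficient and the *unique* joint-utility maximum, so an
  inclusive-utility replicator has a single target;
* deception tempts: `U_S(O8) > U_S(O1)` while `U_R(O8) < U_R(O2)`, so a
  trusting receiver population is invadable and `O2` ("checking") is the
  receiver's refuge.

Because any admissible table yields its own quantitative trajectories,
only the qualitative contrasts between compartments are
payoff-independent claims; every quantitative statement the package makes
about its own dynamics is recomputed by the test suite or by
`scripts/acceptance.R`.

## Agents, strategic types and the 8-endo-type resolution

Sender strategic types fix `(nature type, message)` — four types; the
nature type is a permanent component of the lineage, not redrawn each
play, which is the only reading under which senders have exactly four
scored strategic types and endo-pairs eight. Receiver types fix an action
per message — four types. A fused endo-pair holds one sender and one
receiver and replays the same triple every generation; within a fixed
pair the receiver's response to the message that is never sent is
payoff-irrelevant, so the endo strategy space collapses from 4 × 4 = 16
to the eight payoff-distinct outcome triples. This reconciles the three
stated cardinalities (4, 4, 8) and makes the endo type synonymous with
the outcome it expresses.

Decellularization must invert this projection: the released sender's type
is recovered exactly from the triple; the released receiver's action on
the played message is the triple's action, and its action on the other
message — information destroyed at fusion — is redrawn uniformly between
the two consistent receiver types. Fusing the same pair again therefore
reproduces the original endo type.

## A generation

Per generation, at each domain location, in this order:

1. **Encounters.** `min(n(S), n(R))` random sender–receiver pairs; the
   count-level implementation draws participants by multivariate
   hypergeometric sampling and their assortment with `stats::r2dtable()`
   (Patefield's algorithm), which is distributionally identical to
   uniformly matching individually labelled agents. Surplus agents sit
   out and earn zero this generation. Every endo-pair plays internally.
2. **Play.** Rewards aggregate by strategic type; endo-pairs earn the
   inclusive utility `U_S + U_R`. Outcome tallies are recorded per
   compartment *at play time* — the records describe the pre-transition
   census.
3. **Cellularization.** Each extracellular encounter fuses with
   probability α. The pair plays independently first and fuses after.
4. **Decellularization.** Each endo-pair splits with probability β, drawn
   from the *pre-fusion* census so a pair fused this generation cannot
   split in the same generation.
5. **Replication.** Each (location, class) population is resampled by a
   Dirichlet–multinomial draw (`rdirmnom()`) with size equal to the
   class's current local total and concentrations equal to the smoothed
   per-type rewards. The marginal expectation is reward-proportional,
   `n · U_v / Σ U_v` (`replication_mean()` is the closed-form oracle),
   with overdispersion relative to a plain multinomial.
6. **Mutation.** Each agent's strategy is redrawn uniformly over its own
   class's full space with probability μ (binomial thinning + uniform
   reallocation on counts).
7. **Dispersion.** Each agent moves to a uniformly chosen neighboring
   cell with probability γ. On the default 1 × 1 domain this is a no-op.

The conserved total `n(S) + n(R) + 2 n(E)` is invariant under every phase
and asserted per generation in the tests.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `total_agents` | 10,000 | conserved population size |
| `generations` | 3,000 | run length |
| `alpha` | 1e-4 | fusion probability per extracellular encounter |
| `beta` | 0.01 | fission probability per endo-pair per generation |
| `mu` | 0.01 | per-agent uniform strategy-mutation probability |
| `gamma` | 0.01 | per-agent dispersion probability |
| `domain_shape` | (1, 1) | lattice rows × cols |

These defaults are the reference experiment: a single location (which
nullifies dispersion), a fusion/fission pair of rates whose queue
stabilizes about 1% of agents inside cells, and mutation strong enough to
keep re-seeding rare strategies. Under flow balance the stationary
endo-pair count is `n_E* = alpha * N / (2 * (alpha + beta))` ≈ 49.5 at
the defaults (`stationary_endo_expectation()`); the derivation assumes an
exactly even sender/receiver split, whereas a finite run fixes the
sender–receiver imbalance at its initial binomial draw (order `sqrt(N)`),
which depresses encounter numbers — and hence the realized stationary
mean — by a fraction of a percent.

## Numerical choices

* **Smoothing floor.** Concentrations are rewards + ε with ε = 1e-6: the
  Dirichlet is undefined at zero, and the floor keeps unplayed types
  resurrectable at negligible distortion. In double precision a
  Gamma(1e-6) draw usually underflows to zero, so "negligible" is
  effectively "practically never" — acceptable, since mutation is the
  designed re-seeding channel.
* **All-zero rewards.** If *every* type of a class earned exactly zero at
  a location (typically the generation in which the first endo-pair
  appears, since it fuses after play), replication falls back to uniform
  concentrations; occurrences are counted in the run object
  (`uniform_fallbacks`).
* **Ties.** `modal_outcome()` breaks ties toward the lowest outcome
  index; `pareto_front()` uses weak domination, so identical payoff pairs
  are both on or both off the front.
* **RNG.** One global stream, seeded once per run, consumed in the fixed
  phase order above (locations ascending, classes S, R, E). Runs are
  bit-reproducible given `(config, seed)`. Per-phase substreams were
  considered and rejected to keep the reproducibility contract trivial.
* **Counts are integers** end to end; transitions operate on count
  matrices, never on agent lists, which is what makes the reference
  configuration run in seconds.

## Compartment metrics and equilibrium classification

`expression_profile()` computes each generation's fractional outcome
volume per compartment and time averages over generations with at least
one play (empty generations are excluded and counted).
`classify_equilibrium()` reduces a window's tally to two total-variation
diagnostics: `d_msg` between `P(message | HONEST)` and
`P(message | DECEPTIVE)`, and `d_act` between `P(action | M1)` and
`P(action | M2)`. Labels: SEPARATING when both ≥ 0.8, POOLING when
`d_msg` ≤ 0.2, BABBLING when `d_act` ≤ 0.2, else PARTIAL_POOLING; a
diagnostic whose conditioning event has no support is undefined, any
decision needing it is skipped, and the fallback is PARTIAL_POOLING with
a flag. Thresholds are an operational choice, configurable, and reported
alongside the raw diagnostics.

This operationalization is deliberately strict, and it has a known
limitation worth stating plainly: the conditional distributions weight a
single mutant play as heavily as the dominant strategy. Intracellularly,
mutation maintains a trickle of deceptive endo types whose message split
is interior, which bounds `d_msg` well below 1 even when the efficient
outcome accounts for nearly all plays; and under any payoff table in
which deception profits by mimicry (the model's premise), deceptive
senders pool onto the honest message, so conditional-TV "separating" is
essentially unreachable in either compartment. The stability of truthful
expression is therefore better read from the modal-outcome series and
expression profiles; the classifier's raw diagnostics are kept for
re-thresholding and for detecting regime *changes* rather than absolute
regimes.

Summary statistics discard a burn-in of 500 generations — five times the
`1/(alpha + beta)` ≈ 99-generation relaxation scale of the fusion/fission
queue — and classify windows of 100 generations, one relaxation time,
which also gives the intracellular conditional diagnostics a few dozen
minority plays per window.

## What the simulator's initializer does and does not emulate

All experiments are self-contained simulations; the initializer is the
data generator. It draws each agent's class (sender/receiver with
probability 1/2 each), strategy (uniform over the class's four types) and
location (uniform), with no endo-pairs at generation zero — a maximally
uninformed, well-mixed starting point. It does not emulate structured
founder populations, spatial clustering, unequal class abundances, or any
empirical distribution of strategies; passing tests therefore demonstrate
the model's internal dynamics from neutral initial conditions, not
inference on biological data.

## Problem sizes

Unit and property tests use populations of tens to a few hundred agents
and runs of tens of generations, where closed-form and brute-force
oracles (agent-level matching, beta-binomial frequencies, domination
scans) are exact or statistically sharp. The end-to-end checks run the
full reference configuration (10,000 agents × 3,000 generations) over
five seeds; one such run takes a few seconds on one CPU because the state
is a handful of count vectors.

## Known limitations

* The fine structure of the extracellular dynamics (episode lengths,
  mode residence fractions) depends sensitively on the payoff
  magnitudes; with the default table the chase is a short, regular limit
  cycle `O1 → O8 → O2 → O7` rather than long irregular episodes.
* One sender per cell only; multi-sender cells are out of scope.
* Decellularization is unrealistically frequent by construction: it is
  the device that keeps both compartments populated at a fixed population
  size, not a biological estimate.
* The equilibrium classifier's absolute labels are threshold-dependent
  (see above); its diagnostics, not its labels, are the robust output.
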