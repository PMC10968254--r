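# endogame

Evolutionary simulation of an endosymbiosis signaling game: how does the
cellularization of a sender–receiver pair stabilize cooperative signaling
that the free-living world cannot sustain?

The package is aimed at researchers in evolutionary game theory and
molecular evolution who want a compact, fully reproducible model of the
origin of the nuclear–mitochondrial mutualism (or any analogous
host–symbiont signaling relationship). It simulates three agent classes —
independent senders *S* (proto-mitochondria), independent receivers *R*
(proto-eukaryotes) and cellularized endo-pairs *E* — and tracks which game
outcomes each compartment expresses over evolutionary time.

## The model

**Game.** Each encounter is an information-asymmetric signaling game: the
sender has a hidden nature type (HONEST or DECEPTIVE), sends one of two
messages (M1, M2), and the receiver — observing only the message — picks
one of two actions (A1, A2). The eight (type, message, action) triples are
outcomes O1…O8 with configurable payoffs (U_S, U_R). O1 (honest signal met
by trust) is the Pareto-efficient outcome and the unique joint-utility
maximum; O8 (deception met by trust) pays the sender more than O1 at the
receiver's expense.

**Population.** Senders commit to (type, message): 4 strategic types.
Receivers commit to an action per message: 4 types. Endo-pairs replay a
fixed triple each generation: 8 types, one per outcome, scored by the
inclusive utility U_S + U_R. Each generation, at every domain location:

1. independent agents pair uniformly at random, with
   min(n(S), n(R)) encounters; every endo-pair plays internally;
2. each extracellular encounter fuses into an endo-pair with probability α
   (cellularization); each endo-pair splits with probability β;
3. each (location, class) population is resampled by a
   Dirichlet–multinomial draw whose concentrations are the per-type
   aggregate rewards, so a type's expected share next generation is
   U_v / Σ U_v (reward-proportional replicator dynamics with
   overdispersed sampling noise);
4. each agent mutates (uniform strategy redraw) with probability μ and
   disperses to a neighboring lattice cell with probability γ.

The total n(S) + n(R) + 2·n(E) is exactly conserved. Fusion and fission
form a birth–death queue whose stationary endo-pair count,
n_E\* = αN / (2(α + β)), the package also computes analytically
(`stationary_endo_expectation()`).

**Metrics.** Per-generation outcome tallies are kept separately for the
extracellular and intracellular compartments, with modal outcomes
(`modal_outcome()`), time-averaged expression profiles
(`expression_profile()`) and a signaling-equilibrium classifier
(`classify_equilibrium()`: separating / partial pooling / pooling /
babbling from total-variation diagnostics of message-vs-type and
action-vs-message dependence).

## Worked example

```r
library(endogame)
cfg <- sim_config(total_agents = 2000, generations = 1000, seed = 42)
sim <- run_simulation(cfg)
sim
#> Endosymbiosis signaling game simulation
#>   2000 agents, 1000 generations, domain 1 x 1, seed 42
#>   alpha = 1e-04, beta = 0.01, mu = 0.01, gamma = 0.01
#>   final census: n(S) = 971, n(R) = 1011, n(E) = 9
#>   intracellular modal outcome O1 in 91.7% of generations with endo plays

expression_profile(sim, burn_in = 250)
#> Outcome expression profile (time-averaged fractional volume, burn-in 250 generations)
#>                  O1    O2    O3    O4    O5    O6    O7    O8
#> extracellular 0.518 0.137 0.002 0.002 0.002 0.002 0.082 0.255
#> intracellular 0.984 0.004 0.001 0.003 0.001 0.003 0.001 0.004

stationary_endo_expectation(0.0001, 0.01, 2000)
#> Stationary agent-type prediction
#>   n(E)* = 9.901   n(S)* = n(R)* = 990.1
#>   cellularized fraction 2 n(E)*/N = 0.009901
```

The contrast in the profile is the headline phenomenon: inside cells the
Pareto-efficient outcome O1 accounts for ~98% of plays, while the
extracellular compartment cycles through an adversarial chase — episodes
of O1 are repeatedly invaded by deception (O8), answered by receiver
checking (O2/O7), after which trust recovers. The final census sits near
the analytic stationary prediction of the fusion/fission queue.

`write_results(sim, "out/")` writes `generations.csv` (one row per
generation) and `summary.json` (config echo, expression profiles, modal
and equilibrium fractions, stationarity comparison). A thin command-line
wrapper is installed at
`system.file("cli", "endogame.R", package = "endogame")` with subcommands
`run`, `validate-config` and `theory`.

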