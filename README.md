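# aimaze

An active inference agent that explores and navigates grid mazes, with
synthetic electrophysiology.

`aimaze` is for computational neuroscientists and cognitive modellers who
want a self-contained, testable implementation of discrete-state active
inference applied to spatial foraging: an agent that *learns* a maze by
being curious about it, then *plans* paths to a distal goal it cannot reach
within its short policy horizon, by following diffusion-defined subgoals.
Everything the agent does is driven by one quantity — expected free energy
— and every internal variable has a neural reading (firing rates, local
field potentials, dopamine), which the package turns into simulated
recordings.

## The model

The world is an 8×8 grid of open/closed cells. The agent's generative model
is a partially observed Markov decision process with

- hidden states `s` — the 64 locations;
- two outcome modalities: *what* (open vs closed at the current location),
  with a Dirichlet-parameterised likelihood `A ~ Dir(a)`, and *where*, a
  known identity mapping returning the veridical location;
- five actions (up, down, left, right, stay) with deterministic transition
  matrices `B^u`; moves off the boundary do nothing, and closed cells are
  physically enterable — walls live in the preferences, not the physics;
- policies `π`: all 25 two-move action sequences;
- preferences `C`, a log-probability over outcomes;
- precision `γ = 1/β`, the inverse temperature of policy selection.

Each trial has three epochs (observe, move, observe, move, observe). State
estimation relaxes depolarisations `v` toward the exact per-policy
smoothing marginals, with firing `s = softmax(v)` and a free energy that
decreases monotonically to the negative log evidence. Policies are scored
by expected free energy over the remaining epochs,

    G(π) = risk + ambiguity − novelty
    risk      = Σ_τ  ō_τ · (ln ō_τ − C)          (divergence from preferences)
    ambiguity = Σ_τ  s_τ · H,  H_j = −Σ_i Ā_ij ln Ā_ij
    novelty   = Σ_τ  ō_τ · (W s_τ),  W = ½(1/a − 1/a₀)

with `ō = Ā s` the predicted outcome and `W` the expected information gain
about the Dirichlet concentrations (exactly half the Jeffreys divergence
between the posterior and prior Dirichlet). Policy beliefs are
`π = softmax(−γG − F)`; the precision recurs on
`β = β₀ + (π_post − π_prior)·G`; and observed outcomes accumulate into the
concentrations, `a ← a + η Σ_τ o_τ ⊗ s̄_τ`.

A distal target is converted into attainable subgoals by diffusion on the
believed-open maze graph: with graph Laplacian `L` weighted by the
posterior open-probabilities, the preference over locations is

    C_where = −16·[ e·exp(L)·δ_current < e⁻³ ] + ln( e·exp(L)·δ_target )

i.e. prefer, among locations reachable in one diffusion step, those most
accessible *from the target*. Refreshing this after every trial walks the
agent down the distance gradient to the goal.

## Worked example

```r
library(aimaze)
maze <- generate_maze(8, 8, wall_density = 0.35, seed = 3)
maze
#> maze_grid: 8 x 8, 54/64 open, start=57 target=12
#> .......#
#> ...T...#
#> .......#
#> ......##
#> .....##.
#> ........
#> ....#...
#> S....#.#

# curiosity alone: 32 two-move trials on a novel maze
trace <- run_exploration(maze, n_trials = 32)
trace
#> session_trace: 32 trials, 64 moves, 1536 bins of 16.0 ms, 12 mistakes
length(unique(c(maze$start, trace$path$to)))
#> [1] 55
```

In 64 novelty-driven moves the agent covers 55 distinct cells (a uniform
random walker manages ~16): once visited, a cell's concentrations rise, its
novelty is spent, and the trajectory rarely recrosses itself. Unvisited
cells keep `P(open) = 0.5`; visited ones are learned.

```r
# planning on the familiar maze (concentrations of 128)
nav <- run_navigation(maze, "familiar", record = TRUE)
nav$metrics[c("latency", "mistakes")]
#> $latency [1] 9      # equals the BFS shortest path
#> $mistakes [1] 0
length(shortest_path(maze)) - 1
#> [1] 9

# synthetic unit types from the exploration trace
table(classify_units(trace)$epoch, classify_units(trace)$label)
#>     path place unclassified
#>   1   31     0           33
#>   2   25     4           35
#>   3    2    30           32
```

First-epoch units keep firing from a trial's start until its subgoal is
reached (path cells); final-epoch units fire only once the evidence says
the location is occupied (place cells). `lfp_and_spectrogram()`,
`dopamine_signal()` and `raster()` give the corresponding field potentials,
precision-based dopamine traces and population rasters, and
`run_goal_exploration()` / `run_familiarity_sweep()` reproduce the
goal-directed-learning and exposure-duration experiments.

A command-line interface wraps the same runs:

```sh
Rscript -e 'aimaze::aimaze_cli()' explore --gen 8x8 --seed 3 --out out/
Rscript -e 'aimaze::aimaze_cli()' navigate --maze inst/extdata/maze8.txt --out out/
```

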