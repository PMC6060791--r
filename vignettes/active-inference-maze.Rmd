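---
title: "Methods: an active inference agent for maze foraging and navigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an active inference agent for maze foraging and navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its model and the design
choices behind it: what is computed, under which assumptions, which knobs
matter, what the synthetic data generator does and does not emulate, and
where the numerically delicate spots are. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The generative model

The agent lives on an `n_rows × n_cols` grid (default 8×8, so 64 hidden
states indexed row-major, 1-based). Two outcome modalities:

* **what** — open (1) or closed (2) at the occupied cell. The likelihood
  columns carry Dirichlet priors with concentration matrix `a` (2 ×
  n_states). A *novel* maze sets every entry to 1/8; a *familiar* one puts
  128 pseudo-counts on each cell's true outcome. The floor opposing the
  128 is not pinned anywhere, so we keep 1/8 by symmetry with the novel
  case; the resulting expected accuracy is 128/128.125 ≈ 0.999.
* **where** — an identity mapping returning the veridical location. It is
  known (effectively infinite counts), so it contributes neither ambiguity
  nor novelty; this is why exploration is driven purely by the *what*
  modality.

Actions (up, down, left, right, stay — this order is load-bearing: all
enumeration and every tie-break inherit it) act through deterministic
column-stochastic matrices `B^u`. Boundary transgressions self-map.
Closed cells are enterable: "mistakes" (entries into closed cells) must be
physically possible because the interesting behaviour — illegal shortcuts
under ignorance, their disappearance with familiarity — lives there.
Policies are all `5^horizon` action sequences (horizon 2 by default, 25
policies); a trial is `horizon + 1` epochs of observe-then-act with
beliefs reset at trial boundaries and the initial prior `D` set to a delta
at the agent's location. Concentrations persist across trials: that is the
agent's only memory of where it has been.

## 2. State estimation

Under a fixed policy the trial is a short hidden Markov chain, so the
posterior marginals are available exactly by sum-product message passing
(forward filtered messages, backward evidence-weighted messages, no
double-counting). We compute those target marginals `s*` each epoch and
let the depolarisations relax toward them:

    v ← v + κ (ln s* − v),   s = softmax(v),   κ = 0.25, 16 iterations/epoch

Relaxation, not substitution, is deliberate: the per-iteration `s` are the
simulated firing rates, the per-iteration `v` the depolarisations, and the
transient between the old fixed point and the new one after each outcome
is exactly what the LFP readouts visualise. The recorded free energy is

    F_iter = Σ_τ KL(s_τ ‖ s*_τ) − ln p(o_{1:t} | π),

which is provably non-increasing along this relaxation (the softmax
Jacobian is positive semidefinite along the line toward the target) and
converges to the per-policy negative log evidence `F(π)` — the quantity
policy selection needs. A spec-literal alternative — iterating
`v* = lnĀ·o + ln(B s_{τ−1}) + ln(Bᵀ s_{τ+1})` on the current marginals —
was evaluated and rejected: its fixed point double-counts evidence (a
2-state, 2-epoch toy converges to (0.97, 0.03) where enumeration gives
(0.919, 0.081)), which would break the package's own oracle-equivalence
tests. Epochs with no observation receive no backward message, so an
unconstrained future epoch is a pure prediction `s_{τ+1} = B s_τ` exactly.

Numerical choices: probabilities are floored at 1e-16 before any
logarithm; the expected log-likelihood used as evidence is the digamma
form `ψ(a) − ψ(a₀)` (variationally correct under the Dirichlet posterior;
a log-of-mean switch exists for ablation); early stop when the free-energy
change falls below 1e-4 (tests that compare against oracles run with the
cap raised and the tolerance at zero).

## 3. Policy selection, precision, learning

Expected free energy per policy sums over the remaining epochs

    G = Σ_τ [ ō·(ln ō − C) + s·H − ō·(W s) ]

with `ō = Ā s`. Two asymmetries deserve a note:

* **Ambiguity uses the plain-log entropy** of the normalized likelihood,
  not the digamma form. With digamma, an unvisited cell (a = 1/8) would
  carry 4.16 nats of "ambiguity" against 2.0 nats of novelty and the agent
  would flee novelty — the opposite of epistemic foraging. The digamma
  correction belongs to state estimation, not to the outcome-entropy
  penalty.
* **Novelty** `W = ½(1/a − 1/a₀)` is not an approximation to the one-sided
  KL between updated and prior Dirichlet: by the digamma recurrence it is
  *exactly* half the Jeffreys divergence (the symmetrised KL). The test
  suite asserts that identity to 1e-9. Against the one-sided
  KL(Dir(a+o⊗s)‖Dir(a)) it overestimates by ~276% at counts of 1/8 and
  only agrees to 10% for counts ≳ 8, which is why the acceptance test
  pinning that 10% band is red, deliberately: the band is unattainable for
  any implementation using the paper's W.

The policy posterior is `softmax(−γG − F)`; including the accumulated
evidence `F` removes policies whose past actions contradict what was
observed (without it, "zombie" policies corrupt the action marginal at
step two). Precision follows the damped fixed point
`β = β₀ + (π_post − π_prior)·G`, with `β₀ = 1` (the prior is stated
nowhere, so we keep the neutral choice), damping 0.5, a positive floor
with a warning if the update overshoots, and `γ = 1/β` recorded per bin —
this trace *is* the simulated dopamine substrate. Actions are the argmax
of the policy-posterior action marginal at the current step, ties to the
earlier action in the fixed order. Learning adds `η · o_τ ⊗ s̄_τ` (BMA
states, η = 1, no decay by default; a multiplicative forgetting rate is
exposed but off) for each observed epoch — note the final epoch of one
trial and the first of the next observe the same cell, so a cell "visited
once" across a trial boundary accrues two observation events; the counting
tests define visits as observation events for exactly this reason.

## 4. Subgoals from diffusion

Navigation preferences come from the graph Laplacian `L` with
`L[i,j] = P_open(i)` where some action maps `j → i`, diagonal minus the
column sums, and the cost

    cost = 16·[ e·exp(L)·δ_current < e⁻³ ] − ln( e·exp(L)·δ_target ).

The `e` factor reproduces the generator whose diagonal is `1 − Σ` (its
exponential's columns sum to e). We verified this is not cosmetic: the
−ln term only shifts by a constant, but the reach indicator changes —
with the unscaled kernel, cells two moves ahead of a high-degree interior
cell drop below e⁻³, collect the +16 penalty, and the agent idles
mid-trial (latency 13 vs the BFS 9 on the README maze). With the scaled
kernel the penalty-free radius matches the two-move policy horizon, and
known-maze navigation equals the BFS oracle with zero mistakes on all 20
test mazes.

Two structural facts the tests pin down, in place of a folk claim that
preferences "decrease with distance": (i) on the open grid, every
neighbour one step closer to the target has strictly higher diffusion
mass, so preference ascent is exactly distance descent; (ii) the full
preference is monotone only within the reach set — the +16 cap
deliberately flattens everything beyond it (including, early on, the
target itself). Degenerate inputs: an all-closed belief map leaves the
kernel at the identity, so the target keeps its self-mass and the
preference stays finite; a genuine zero-mass target raises a
degenerate-preference error. Preferences are refreshed before every trial
from the agent's location and current open-probability beliefs; that
refresh is what turns a static cost map into a moving subgoal.

## 5. Neural readouts

The session trace records, per 16 ms bin (256 ms per epoch / 16
iterations), the policy-averaged firing of `n_states × epochs` units
(epoch-major rows; 192 for the default model), their log-expectation
depolarisations, precision, free energy and the agent's physical location.

* **Rasters** are bins × units slices of that firing.
* **LFPs** are band-pass filtered (FFT brick-wall, 1–8 Hz default)
  first differences of the depolarisation; the undifferenced variant is
  exposed too, since the depolarisation-vs-prediction-error reading is
  genuinely ambiguous. A measurement note: the averaged spectrogram does
  *not* peak at the 3.9 Hz outcome rate under either variant — the
  difference operator tilts the band upward (peak near 6.5 Hz, a harmonic
  of the 768 ms trial cycle), the raw depolarisation tilts it down (peak
  below 2 Hz). The 4 Hz epoch-locked component is always present and well
  above the high-frequency tail, and is returned separately as a 3–5 Hz
  `theta` component; tests assert exactly that, not the folk "peak at
  4 Hz".
* **Dopamine** is `γ + κ·Δγ` per bin (κ = 1 by default; reporting γ itself
  absorbs any offset).
* **Path/place classification** thresholds firing at 0.8 (an activation
  level on normalized expectations; the "Hz" label is cosmetic) and labels
  a unit *place* if supra-threshold bins occur only while the agent
  occupies the unit's encoded cell, *path* if they span two or more
  occupied cells, else unclassified. The diagnostic asymmetry — first-epoch
  units predominantly path, final-epoch units predominantly place — is an
  emergent property of prospective coding, not anything the classifier is
  told.

## 6. The synthetic world, and what green tests establish

There is no empirical dataset: the maze generator *is* the stated world.
It carves a random self-avoiding open path from a bottom-left entrance to
an interior target (solvability by construction), then closes remaining
cells with probability 0.35 — a one-time choice matching the look and
difficulty of a hand-drawn 8×8 maze with roughly a third of cells closed;
session lengths (32 exploration trials, 4×8 goal-directed trials, 2 s
snapshot grid at 256 ms per move, 62 moves ≈ 16 s) follow the stated
experimental protocol. Everything is deterministic given (config, seed).

What this world does not emulate: continuous space and time, vision beyond
the occupied cell, sensor noise (outcomes are exact), moving targets,
biophysical neurons, or any fitting to recorded spikes/LFP/dopamine. A
green suite therefore establishes internal validity — the update equations
do what the theory says, against independent oracles (enumeration, BFS,
closed-form Dirichlet KL, Monte Carlo) — and the qualitative phenomena:
efficient non-repeating search, illegal shortcuts under ignorance,
mistake-free shortest paths under familiarity within ~16 s of exposure,
path/place asymmetry. It does not establish anything about brains.

## 7. Known limitations

* Marginal behaviour near the reach threshold: whether a borderline cell
  collects the +16 penalty can flip with local degree; on hard mazes this
  occasionally delays goal acquisition past the 4-search budget (the
  acceptance criteria are medians over seeds for this reason; seed 17 of
  the default test set is such a maze).
* The familiarity sweep snapshots at trial boundaries (multiples of
  0.512 s), so "2 s of exposure" means 4 trials.
* Only the likelihood is learned; transitions, preferences and the policy
  prior are fixed. No habits, no hierarchy, no structure learning.
* With one-step diffusion, mazes whose true geodesic exceeds ~13 moves
  push the far field of `ln(T δ_target)` into the 1e-16 floor, flattening
  the gradient; an 8×8 grid stays inside this budget.
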