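---
title: "A discrete attractor network model of opting out in perceptual decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete attractor network model of opting out in perceptual decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wagernet)
```

## The task and the modelling idea

In the uncertain-option (post-decision wagering) task a subject judges the
net direction of a random-dot motion stimulus and, on a random half of the
trials, is later offered a third "sure" target: a guaranteed but smaller
reward that waives the risky direction decision.  The fraction of sure
choices falls with motion coherence and viewing duration, and accuracy is
higher on trials where the sure target was shown but declined — the
behavioural signatures usually read as decision confidence.

`wagernet` implements a discrete multiple-choice account of this behaviour:
a recurrent cortical network with one selective excitatory pool per option —
L and R for the two directions and S for the sure target — embedded in a
five-population winner-take-all circuit.  Opting out is nothing more than a
third competitor that enters an ongoing competition late.  Whether the sure
target wins is determined by the state of the decision pools at the moment
it appears: trials still hovering near the symmetric, undecided state are
captured by the S attractor, while trials already committed to a direction
suppress S through the shared inhibitory pool.

## The spiking network

The network has `N = 1000` leaky integrate-and-fire neurons, 80% excitatory
(three selective pools of `f·N_E = 160` neurons, one nonspecific pool of
320) and 20% inhibitory, all-to-all connected without conduction delays.
Synapses are conductance-based: external and recurrent AMPA (instantaneous
rise, 2 ms decay), NMDA (2 ms rise, 100 ms decay, saturating gating with
rate 0.5 ms⁻¹, magnesium block `1/(1 + [Mg]·exp(−0.062 V)/3.57)`) and GABA
(10 ms decay).  Within-pool excitatory weights of the selective pools are
potentiated (`w+ = 1.5`); excitatory connections from any other excitatory
pool onto a selective pool are depressed (`w− = 0.878`); every other weight
is 1.  Each neuron receives an independent 800-source Poisson background at
3 Hz per source (2.4 kHz aggregate); stimuli are additional external rate.

All parameter values are exposed through `neuron_params()`,
`synapse_params()` and `network_spec()`; the full reference set also ships
as `inst/extdata/reference_profile.yaml`.  Two parameters are not part of
the published set and deserve comment:

* **Leak conductances** (25 nS excitatory, 20 nS inhibitory, i.e. membrane
  time constants of 20/10 ms) are the standard values of the model family
  this network belongs to.  They are also forced: a scan showed the printed
  conductances only sustain a stable ~3 Hz spontaneous state in a narrow
  window around these values (24 nS already destroys it).  The mean-field
  spontaneous (≈2.5 Hz) and sure-choice (≈1 Hz decision pools) attractor
  rates validate the choice against the reported ≈3 Hz and ≈2 Hz.

* **NMDA efficacy** (`build_network(nmda_efficacy = 1.10)`).  The
  mean-field reduction describes NMDA saturation by a series ψ(ν) that
  overestimates the true event-driven average of the gating variable by
  ≈4% (measured directly against long stochastic simulations of the
  kinetics), and finite-size fluctuations at `N = 1000` preferentially
  boost the noise-driven inhibitory population.  Simulated with the literal
  kinetics the network therefore under-realises its own reduction: the
  decision-memory attractor the task depends on decays within a second.
  The efficacy factor restores the correspondence; at 1.10 the simulated
  delay-period memory rate (33.1 Hz) matches the reduction's
  decision-memory attractor (32.6 Hz) while the spontaneous state stays at
  its reference level (2.8 Hz).  The calibration brackets are sharp — at
  1.05 memory still collapses, at 1.12 the target phase already breaks the
  L/R symmetry before any evidence arrives — which is the knife-edge,
  near-bifurcation operation the model's behaviour requires.  Set the
  factor to 1 to study the uncorrected kinetics.

The integrator (in C++) uses forward Euler at `dt = 0.05` ms with exact
exponential decay of the gating variables; because weights only depend on
the (source pool, target pool) pair, recurrent input reduces to pool-level
gating sums and a step costs O(N).  External Poisson input is drawn as one
pooled count per population per step and scattered uniformly — statistically
identical to independent per-neuron generators, and reproducible from a
single per-trial seed.  Halving `dt` changes background pool rates by less
than 5%.

## The stimulation protocol

`assemble_protocol()` builds one trial: 500 ms of background, a 500 ms
target transient to L and R, the motion stimulus (`λ + Δλ` to L, `λ − Δλ`
to R; `Δλ ≥ 0`, so L is correct by convention) for 100–500 ms, a delay, and
— on free-choice trials — a sure-target input to S from 500 ms after motion
offset to the end of the trial; an 80 Hz saccade signal reaches L, R and S
during the final 100 ms, whose onset is the go cue.  The trial ends 1000 ms
after sure-target onset (the total length is not a published quantity; it is
configurable).

The target transient — two exponential decays, here 200 Hz/80 ms plus
100 Hz/450 ms — is likewise not published.  Its shape matters and was
calibrated once, against the model's own described phenomenology: the slow
component must outlast the target phase so that the network enters the
motion period from an elevated, still-symmetric state (with faster decays
the target phase itself breaks the symmetry and decisions predate the
evidence), while the peak must not commit the network before motion onset.
The sure-target input uses the same shape with a 5 Hz sustained asymptote.
Scaling it up lets S override already-formed decisions at the go cue, which
contradicts the circuit account (the winning pool inhibits S), so the scale
stays at 1 (`sure_peak_scale`).

## The mean-field reduction

`solve_fixed_point()` implements the stationary population-rate reduction:
per population, the mean `μ_x` and variance `σ_x²` of the effective
membrane potential, a self-consistent mean potential with the linearised
magnesium block, the saturating NMDA activation ψ(ν) (series truncated at
order 64 with 1e−12 early stopping, validated against a high-order
independent transcription), and the first-passage transfer function
φ(μ, σ) evaluated by 96-point Gauss–Legendre quadrature of the scaled-erfc
integrand (validated to 1e−6 relative against adaptive quadrature).  Fixed
points are found by relaxing `τ_x dν_x/dt = −ν_x + φ` with an Euler step of
0.1 ms until the per-step change falls below 1e−6 Hz; convergence under
this flow is the operational notion of stability.  Because an exactly
symmetric flow cannot reveal instability to L/R symmetry breaking,
symmetric fixed points are additionally probed with a ±0.1 Hz antisymmetric
perturbation (the same precision the basin bisection uses) and must return.

`enumerate_attractors()` classifies converged states (spontaneous /
decision_L / decision_R / decision_S / mixed, thresholds exposed as
arguments), `bifurcation_scan()` tabulates them over λ, and
`basin_boundary()` bisects basin edges along rays in the (ν_L, ν_R) plane
to 0.1 Hz.

Scanning λ with Δλ = 0 reproduces the model's four regimes in order:
spontaneous + decision attractors at very low λ, a bistable band with only
the two decision attractors, a multistable band where a stable mixed
(undecided) state coexists with them, and a monostable mixed regime.  Our
boundaries (≈4, ≈26 and ≈63 Hz on a 1 Hz grid) sit ≈4 Hz above the
originally reported 1/21/59 Hz.  The λ scale is extremely sensitive: the
stimulus rides on a 2.4 kHz background, so a uniform 4 Hz shift corresponds
to a sub-0.5% systematic difference in any single current term — the level
at which independent implementations of this reduction (quadrature, mean-
potential closure, series truncation, stability detection) genuinely
differ.  The attractor rates themselves (spontaneous ≈2.5 Hz, memory
≈33 Hz, mixed ≈25 Hz, decision-under-stimulus ≈40 Hz, sure attractor with
decision pools ≈1 Hz) agree with the reported values, and all package
presets (`λ = 15` bistable, `λ = 50` multistable) lie well inside their
regimes under both boundary sets.

## Trials, decisions, analyses

`run_ensemble()` simulates a condition grid with one seed per trial
(`base_seed + i`), classifying each trial with `classify_trial()`:
population rates in a trailing 50 ms window stepped every 5 ms; a decision
when a pool stays at or above ϑ for 50 ms (ϑ = 28 Hz at λ = 50; 24 Hz at
λ = 15; `calibrate_threshold()` re-derives ϑ for other operating points
from the under-5%-undecided criterion); the decision time measured from
motion onset; the (ν_L, ν_R) snapshot over the 50 ms before sure-target
onset (evaluated at the equivalent time on forced trials); and a
change-of-mind flag when the dominant *direction* pool at the go cue
differs from the threshold winner — an eventual takeover by S is a sure
choice, not a change of mind, following the direction-decision literature
the reported 10 ± 2% figure refers to.  The early (pre-sure-onset) choice
falls back to snapshot dominance when no threshold crossing precedes the
sure target, so every trial carries an early correct/error label for the
conditional analyses.

The analysis layer reproduces the derived statistics: `psychometrics()`
(accuracy forced vs sure-shown-but-waived, P(S), Wilson intervals),
`conditional_sure_map()` (P(S | ν_L, ν_R) on 1 Hz bins, masking bins with
fewer than 30 trials), `sure_probability_projections()` (1 − P(S) against
|ν_L − ν_R| and ν_L + ν_R with isotonic-fit residuals), `dt_split()`
(decision-time histogram in 10 ms bins, 3-bin smoothed, dip search in
[100, 1500] ms with a genuine-dip flag), `bootstrap_error_counts()`
(10000-sample bootstrap of error counts in fast vs slow trials, t-test),
`xpattern_simulated()` / `xpattern_probabilistic()` (opt-out probability
conditioned on early outcome; the probabilistic reduction satisfies the law
of total probability exactly), `reward_amount()` (P(C) + P(S)·w_S, sure
value w_S = 0.8 by default) and `rate_distributions()`.

## What the simulations do and do not show

The synthetic ensembles are generated by the model itself under the
published stimulus conditions; they emulate the structure of the
experiment (condition grids, random free/forced halves, trial counts) but
none of the biological variability outside the model — no session effects,
no lapses, no reward-history dependence, and a stimulus reduced to a
stationary rate difference.  Passing tests therefore certify that the
implementation realises this model's dynamics and statistics, not that the
model is a complete account of the recorded behaviour.  At the reduced test
scale (9 trials per condition against the reference 1000) all stochastic
checks use binomial margins; the reference scale is available through the
`psychometrics` preset.  The opt-out magnitude at zero evidence (P(S) ≈
0.2–0.3) sits below the monkeys' ≈0.6 — the input calibration preserved
the mechanism (S wins only from undecided states) rather than the
magnitude, and the decreasing patterns over evidence and duration are the
model's claim.

## Numerical choices and degenerate inputs

Rates are clamped nonnegative in the mean-field flow; non-convergence
within the step budget is flagged, never returned silently as a fixed
point.  The transfer integrand is evaluated through the scaled
complementary error function with an asymptotic branch, and deeply
subthreshold inputs short-circuit to zero rate.  Ties in the decision rule
(two pools crossing in the same 5 ms sample) resolve to the earlier
crossing sample, then to the first pool in (L, R, S) order — a measure-zero
event at these noise levels.  Zero-size selective pools, negative rates
(`λ < Δλ`), overlapping protocol phases and unknown profile keys are
rejected at construction time.
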