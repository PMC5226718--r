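# wagernet

A spiking attractor-network model of perceptual decisions with an opt-out
option, for computational neuroscientists studying decision confidence and
winner-take-all cortical circuits.

In the uncertain-option (post-decision wagering) task, a subject judges the
net direction of a random-dot motion stimulus; on a random half of trials a
third "sure" target later appears, offering a small guaranteed reward
instead of the risky decision.  `wagernet` implements a discrete
multiple-choice account of this behaviour: a five-population
conductance-based leaky integrate-and-fire network in which each option —
left, right, sure — is one selective excitatory pool in a winner-take-all
circuit, stimulated asynchronously (direction evidence first, the opt-out
target later).  The package provides:

* the **spiking network** (AMPA/NMDA/GABA conductances, NMDA saturation
  and magnesium block, structured weights `w+ = 1.5` / `w− = 0.878`, full
  connectivity, independent external Poisson drive), integrated in C++;
* its **mean-field reduction**: coupled self-consistency equations
  `ν_x = φ(μ_x, σ_x)` over population rates with the saturating NMDA
  activation ψ(ν) and a first-passage transfer function, plus fixed-point
  solving, attractor enumeration, bifurcation scans over the common
  stimulus rate λ, and basin-of-attraction bisection in the (ν_L, ν_R)
  plane;
* the **trial machinery**: the delayed three-option stimulation protocol
  (target transients, motion input `λ ± Δλ`, sure-target input, saccade
  signal), a threshold decision rule (ϑ = 28 Hz sustained for 50 ms),
  decision times, changes of mind, and reproducible trial ensembles;
* the **behavioural analyses**: psychometric tables, the conditional
  opt-out map P(S | ν_L, ν_R), decision-time bimodality and its
  fast/slow split, bootstrap error-count comparisons, the X-pattern of
  opt-out probability in correct vs error trials (simulated and in closed
  form), and reward trade-off curves `P(C) + P(S)·w_S`.

## A worked example

```r
library(wagernet)
p <- mf_params()                       # reference parameter set

solve_fixed_point(p, lambda = 0)       # resting state of the network
#> Mean-field fixed point (spontaneous)
#>           L           R           S nonspecific  inhibitory
#>       2.523       2.523       2.523       2.450       8.256
#>   residual 5.85e-05 Hz after 2036 steps

enumerate_attractors(p, lambda = 50)   # landscape during the stimulus
#> Attractor landscape: stimulus condition, lambda = 50, dlambda = 0
#>        class   nu_L   nu_R   nu_S nu_ns  nu_I  residual stable
#> 1      mixed 25.550 25.550 0.4488 6.552 18.24 8.336e-05   TRUE
#> 2 decision_L 40.462  2.304 0.8296 4.993 14.43 9.205e-05   TRUE
#> 3 decision_R  2.304 40.462 0.8296 4.993 14.43 9.205e-05   TRUE
```

At rest the selective pools sit near 2.5 Hz.  At λ = 50 Hz the network is
*multistable*: the two decision attractors (winner at 40 Hz) coexist with a
"mixed" undecided state (both pools at 25.5 Hz) whose basin slows decisions
down and keeps the circuit receptive to the late opt-out offer — the
operating regime the behaviour depends on.

```r
net <- build_network()                 # N = 1000 spiking neurons
pr <- assemble_protocol(duration = 500, lambda = 50, dlambda = 14)
trial <- simulate_trial(net, pr, seed = 7)
classify_trial(trial)[c("final_choice", "dt", "nu_L", "nu_R", "change_of_mind")]
#>   final_choice  dt  nu_L nu_R change_of_mind
#> 1            L 245 20.75  5.5          FALSE
```

This trial chose the correct direction (L receives λ + Δλ) 245 ms after
motion onset; at the moment the sure target would appear, pool L fires at
20.75 Hz and pool R at 5.5 Hz, so the trial is committed and the opt-out
would be declined.  `run_ensemble()` scales this to condition grids
(`fixture_presets()` ships smoke/bistable/multistable/full-scale presets),
and the analysis functions turn trial tables into the derived statistics.
A thin command-line front end lives at `inst/cli/wagernet.R`
(`simulate`, `meanfield`, `analyze`, `presets`).

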