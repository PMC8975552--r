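# incentivecircuit

Simulation of the *Drosophila* mushroom-body **incentive circuit**: a
twelve-neuron rate model in which six dopaminergic neurons (DANs) and six
mushroom body output neurons (MBONs) form reciprocal microcircuits that
acquire, transfer and erase olfactory memories. The package is for
computational and systems neuroscientists who want to probe how a single
dopaminergic plasticity rule produces susceptible, restrained and
long-term memories, how those memories steer approach/avoidance behaviour,
and how dopamine-receptor kinetics yield opposite associations for forward
and backward conditioning.

## The model in brief

Odour identity reaches 10 Kenyon cells (KCs) through 2 projection neurons;
a winner-take-all filter keeps the top half of the KCs active. DANs and
MBONs are bounded rectified-linear rate units, and all learning happens in
the KC→MBON weight matrix **W** under the **dopaminergic plasticity rule
(DPR)**

```
ΔW[i,j] = δ[j] · (k[i] + W[i,j] − w_rest) / τ ,   W ← max(W + ΔW, 0)
```

where `k` is the KC activity, `w_rest = 1` the resting weight, and
`δ = d·W_d2km` the signed dopaminergic factor computed from the DAN
activity `d`. Depending on `sign(δ)` and whether the KC is active, the rule
produces **depression**, **potentiation**, **recovery** (relaxation back to
rest) or **saturation** (drift away from rest). A reward-prediction-error
rule, `ΔW[i,j] = k[i]·(δ[j] − m[j] + w_rest)/τ`, is included for
comparison. At high temporal resolution the factor decomposes as
`δ(t) = D△(t) − D▽(t)` into potentiation and depression dopamine
components with fast/slow kinetics, from which ER-Ca²⁺ and cAMP proxies
and the forward/backward conditioning asymmetry follow.

On top of the circuit the package provides:

* trial schedulers for the 24-trial acquisition → extinction / unpaired /
  reversal paradigms and the classic unpaired-conditioning control,
  with off-/on-shock per-trial readouts;
* an agent-based two-odour arena (100 flies, Gaussian odour fields,
  MBON-driven attraction forces, cumulative-exposure preference indices);
* the 100-Hz second-messenger pairing model and CS/US interval sweeps;
* utilities for summarising trial-aligned imaging-style traces, generating
  synthetic traces, and running neuron silencing/activation screens scored
  by Pearson correlation against experimental effect sizes.

## Worked example

Aversive conditioning (shock paired with odour B), then read out the
susceptible attraction MBON `s_at`:

```r
library(incentivecircuit)

log <- run_experiment(build_aversive_paradigm("extinction"), seed = 1)
ts  <- extract_trial_summaries(log)
subset(ts, odour == "B" & neuron == "s_at" & phase == "acquisition")
#>  trial off_shock on_shock
#>      4     0.667    0.264
#>      6     0.264    0.000
#>      8     0.037    0.000
#>     10     0.000    0.000
#>     12     0.000    0.000
```

`s_at`'s response to the punished odour collapses from the second
acquisition trial — the susceptible memory — and the model's preference
index computed from test-phase MBON responses,
`paradigm_preference(log)`, is `1` (complete preference for the unpunished
odour A). The timing dependence of the underlying rule:

```r
backward_sweep(c(-2, 0))
#>  delta_s mean_change normalised_change
#>       -2       0.006             0.566
#>        0      -0.011            -1.000
```

A US delivered at odour onset (`delta_s = 0`) depresses the synapse
(negative mean weight change); the same US delivered 2 s *before* the
odour potentiates it — relief learning. Fly behaviour:

```r
arena <- arena_parameters()          # 100 flies, 10 repeats
log   <- run_arena_experiment("shock_a", arena, seed = 1)
median(subset(arena_preference(log), visited_both)$PI)
#> [1] -0.344
```

Flies trained with shock around odour A spend their post-training time
avoiding it (negative preference index toward A).

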