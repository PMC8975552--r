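---
title: "The incentive-circuit model: assumptions, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The incentive-circuit model: assumptions, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incentivecircuit)
```

## The model

The package simulates a deliberately small rate model of the *Drosophila*
mushroom body: 2 projection neurons (PNs) carry odour identity to 10 Kenyon
cells (KCs), and twelve extrinsic neurons — six dopaminergic neurons (DANs)
and six mushroom body output neurons (MBONs) — form three reciprocal
microcircuits per valence:

* **susceptible** MBONs (`s_at`, `s_av`) read the KC code through plastic
  synapses and are rapidly depressed by the opposite-valence *discharging*
  DANs (`d_at`, `d_av`);
* **restrained** MBONs (`r_at`, `r_av`) are inhibited by the opposite
  susceptible MBON and drive the same-valence *charging* DANs
  (`c_at`, `c_av`);
* **long-term-memory** MBONs (`m_at`, `m_av`) are potentiated by their
  charging DAN, sustain themselves through it, and drive *forgetting* DANs
  (`f_at`, `f_av`) that depress the opposite-valence long-term memory.

All connectivity except the KC→MBON synapses is fixed
(`default_parameters()`); every memory the model forms lives in the 10 × 6
KC→MBON weight matrix.

Neurons are rate units with a bounded rectified-linear activation
`bounded_relu()` on `[0, 2]`. The drive of a DAN is
`u·W_u2d + m·W_m2d + b_d`, of an MBON `k·W_k2m + m·W_m2m + b_m`, both
evaluated with the *previous* step's MBON vector (synchronous update). The
published update equations compose to a memoryless form in which the new
activity is the rectified drive divided by the time constant `tau = 3`;
`neuron_step()` implements this literal composition as the default
(`integration = "literal"`) because it is the form the model's printed
worked values satisfy, and offers the standard leaky-integrator
discretisation (`integration = "leaky"`) for users who prefer the
conventional reading. All shipped analyses use the literal form.

### Odour coding

PN codes are binary (`A` = (1,0), `B` = (0,1), both, or none). KC drive is
`cs·W_p2k` plus Gaussian noise, then a winner-take-all filter keeps the top
half of KCs (5 of 10) *with their drive values* — the code is sparse but not
binarised. Three KCs respond to both odours, which is what lets memories
generalise between odours. Numerical choices:

* the noise scale 0.001 is interpreted as a standard deviation; it is
  tie-breaking noise, three orders of magnitude below the 0.8 odour drive;
* WTA ties are broken towards the lowest KC index by a stable sort (only
  reachable at zero noise);
* KC output is clamped at zero after the filter. With no odour the drive is
  pure noise, and roughly half of the retained values would otherwise be
  negative at magnitude ~1e-3; non-negative KC activity is the constraint
  the plasticity rule relies on, so it wins. Consequently "exactly 5 active
  KCs" holds for every odour-bearing stimulus, and "at most 5" for blank
  steps.

## The dopaminergic plasticity rule

Each forward step updates the plastic weights by

```
dW[i,j] = delta[j] * (k[i] + W[i,j] - w_rest) / tau,   W' = max(W + dW, 0)
```

with `delta = d·W_d2km` the signed, per-MBON *dopaminergic factor*, and
`w_rest = 1` the resting weight. The sign of `delta` and the presence of KC
activity give four effects: depression (`delta < 0`, KC active),
potentiation (`delta > 0`, KC active), recovery towards rest
(`delta < 0`, KC silent) and saturation away from rest (`delta > 0`, KC
silent). `rpe_update()` provides the reward-prediction-error alternative
`dW[i,j] = k[i] * (delta[j] - m[j] + w_rest) / tau` under the same
non-negativity clamp, so that the two rules differ only in their update
term. Each simulated time-step runs four repeats of the
neuron-update/plasticity cycle (`forward_step(..., repeats = 4)`) to wash
out the ordering bias between value and weight updates.

## Time-resolved dopamine and backward conditioning

`dopamine_kinetics()` decomposes the dopaminergic factor into a depression
component `D_dep` and a potentiation component `D_pot`,
`delta(t) = D_pot(t) - D_dep(t)`, abstracting two receptor pathways with
different kinetics. The DAN function matrix is split by sign into a
potentiating channel `W_pos` and a depressing channel `W_neg`
(`W_pos - W_neg` reconstructs it exactly), and each channel × component
pair is a first-order low-pass filter `y <- y + (x - y)/tau`: the
depressing input drives `D_dep` through `tau_short` and `D_pot` through
`tau_long`, and symmetrically for the potentiating input.

Two constraints pinned this discretisation down. First, with
`tau_short = 1`, `tau_long = Inf` the filters must collapse so that
`D_pot - D_dep` equals the static factor `d·W_d2km` at every sample — this
is what licenses the main circuit's use of the static factor at its slow
(≥ 1 s per step) sampling, and it holds exactly for the per-channel
low-pass form (tested to 1e-9). Second, at high temporal resolution a
depressing terminal must produce a `D_dep` with a *higher peak and faster
decay* than its `D_pot`; a shared decay term for both components cannot do
this — it forces `delta(t)` to keep one sign for all time, which would make
the order of CS and US irrelevant — so the decay is applied per channel at
that channel's own rate. The constraint
`0 < 1/tau_short + 1/tau_long <= 2` (validated at construction, with
`Inf` as the sentinel for a frozen channel) is exactly the stability bound
of this one-sample Euler step.

For the 100-Hz pairing protocol the defaults are `tau_short = 60` samples
(0.6 s: the depression pathway completes its update in roughly half a
second) and `tau_long = 100` samples (1 s for the potentiation pathway).
These are the two effective timescales the model's kinetics are described
by, and they are the pair that yields the characteristic timing curve:
depression for forward pairings, potentiation peaking for a US about 1–2 s
*before* the CS, and no net change once the pulses are separated by several
seconds. A much larger `tau_long` (say 10^4 samples) lowers the
potentiation channel's peak to ~1 % of the depression channel's and washes
backward conditioning out entirely.

`run_pairing()` embeds the kinetics in the minimal susceptible motif: one
KC driven to the activation cap by a 0.5-s CS pulse (driving it merely to
`w_rest` would null the cAMP term `D_dep·(k - w_rest)`), one depressing
DAN terminal driven with gain 2 by a 0.6-s US pulse, and the MBON feeding
back −0.3 onto the DAN. The second-messenger proxies are

```
ER_Ca = -D_pot*(k - w_rest) - (D_pot - D_dep)*W,   cAMP = D_dep*(k - w_rest)
```

with all proportionality constants set to 1 — only the normalised interval
sweep is reported, so constants are immaterial. Substituting them into
`dW ~ -ER_Ca - cAMP` recovers the plasticity rule above; the per-sample
weight update is scaled by `dt = 1/sampling_hz`. Traces are padded
(`tail_s = 15`) until the kinetics have decayed below 1e-6 of their peak.

## Conditioning paradigms

`build_aversive_paradigm()` produces the 24-trial schedule: one
initialisation step, then trials of three in-trial steps with odour at
steps 2 and 3 (73 time-steps in total). Odour A is presented on odd
(1-based) trials and B on even ones; acquisition pairs the US with odour B
at in-trial step 3; the forgetting phase either omits the US (extinction),
delivers it at in-trial step 1 of A-trials (unpaired), or pairs it with A
(reversal). In the classic unpaired variant
(`build_unpaired_conditioning_paradigm()`) the acquisition B-trials become
odourless US-only trials; the US is placed at in-trial step 3, the slot it
occupies in paired trials, since the protocol does not pin the in-trial
timing of an odourless reinforcement. Per-trial readouts
(`extract_trial_summaries()`) report in-trial step 2 as the *off-shock*
and step 3 as the *on-shock* response, mirroring how imaging trials are
summarised.

## The fly arena

`run_arena_experiment()` embeds one circuit per fly (n = 100) in an
unbounded plane with odour sources at −0.6 and +0.6 m and Gaussian odour
fields (sigma = 0.3 m). A deliberate convention: the odour "density" is the
*univariate* Gaussian density evaluated at the Euclidean distance from the
source — that is the convention under which the detection threshold
`theta_CS = 0.2` gives the documented ~0.58-m detectable radius
(`detection_radius()`), comfortably larger than the 0.3-m reinforced area.
Each 100-step (1 Hz) repeat is 20 s free exploration, 30 s training
(steps 21–50) in which flies inside the reinforced area of a conditioned
source receive the US, and 50 s of extinction; positions and velocities
reset to the centre between the 10 repeats, brains persist so long-term
memory accumulates.

Within a step the order is: sense (binary odour detection at the current
position), reinforce, one circuit time-step, force, move. The attraction
force scales the unit vector towards each source by the mean of the three
attraction MBONs minus the mean of the three avoidance MBONs, weighted by
the posterior probability of being closer to that source (equal priors;
0.5/0.5 where both densities underflow; zero contribution exactly at a
source, where the unit vector is undefined). The executed velocity is the
previous *executed* velocity plus force plus per-axis N(0, 0.1) noise,
rescaled to a fixed 0.05 m/s step — carrying the unnormalised sum instead
would grow without bound and freeze the heading, so the normalised vector
is what persists. A zero pre-normalisation vector (a measure-zero event)
triggers a noise redraw.

Preference statistics follow the cumulative-exposure definition: per fly,
repeat and phase, the fraction of steps with the odour detected, summed
over repeats; `preference_index()` is the normalised difference, undefined
(and excluded) for flies that never smelled either odour, and population
summaries keep only flies that visited both odours at least once.

## What the synthetic data emulate — and what they do not

`generate_synthetic_traces()` emits trial-aligned traces with the imaging
protocol's exact geometry (100 samples at 5 Hz, odour window 25–50, shock
at sample 45, off-shock window 28–42, on-shock window 44–48) whose window
means equal a chosen ground truth plus i.i.d. Gaussian noise. They validate
the summariser's windowing and pooling arithmetic, not calcium dynamics:
there are no indicator kinetics, bleaching, motion artefacts or
fly-to-fly response correlations. Passing tests therefore certify the
bookkeeping, not fidelity to recorded traces. Similarly, the intervention
screen harness (`run_intervention_screen()`) is exercised against
synthetic screen tables with known correlation; scoring the model against
the published 92-experiment screen requires that table, which is
third-party supplementary data not shipped with the package.

## Problem sizes used by the shipped tests

The test-suite sizes are the model's own study conditions: the 73-step,
24-trial paradigms; interval sweeps over 21 offsets at 100 Hz with 15-s
decay tails; and arena runs of 100 flies × 10 repeats × 100 steps, pooled
over 5 seeds per condition for the stochastic directional checks (median
preference negative for a punished odour, positive for a rewarded one, and
weaker for sugar than for shock — the last two being small effects that
need the pooled sample). Randomised property checks (the four-effect sign
table, oracle comparisons) use 100–1000 cases under fixed seeds.

## Known limitations

* Two PNs and ten KCs cannot represent odour similarity structure beyond
  the built-in three-cell overlap; there is no gain control (no APL-like
  inhibition), no KC–KC or DAN→MBON connections.
* The literal neuron update is memoryless between steps; within-trial
  temporal structure finer than the three in-trial steps is not modelled
  outside the dedicated 100-Hz pairing module.
* The arena has no walls, no odour-plume physics and no body orientation;
  behaviour reduces to a speed-normalised drift–diffusion on the plane.
* The second-messenger model is a two-channel abstraction fitted to
  reproduce timing signs, not receptor biophysics; its proportionality
  constants are arbitrary and only normalised sweeps are meaningful.
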