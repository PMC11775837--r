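---
title: "Spiking active efficient coding: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiking active efficient coding: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science implemented by `saec`: the model
equations and their assumptions, the parameters that matter, what the
synthetic worlds do and do not emulate, the numerical and design decisions
taken where the design was genuinely open, and the known limitations of the
reduced-scale ("desk") operating point.

## 1. The model

### 1.1 Neurons

Every cell is a leaky integrate-and-fire unit. Between updates the membrane
potential leaks with time constant $\tau_m$; the threshold test subtracts
two homeostatic terms, a spike-rate-adaptation potential $V_{SRA}$
(incremented by $\eta_{SRA}$ at each spike, decaying with $\tau_{SRA}$) and
a refractory trace $\eta_{RP}\,e^{(t_s-t)/\tau_{RP}}$ armed by the last
spike at $t_s$:
$$\tilde V(t) = V\,e^{-\Delta t/\tau_m} - V_{SRA}\,e^{-\Delta t/\tau_{SRA}}
  - \eta_{RP}\,e^{(t_s-t)/\tau_{RP}} .$$
A spike is emitted when $\tilde V \ge V_\theta$, after which $V$ is reset
to $V_{reset} = -20$ mV. Synaptic transmission is instantaneous; inhibitory
input floors the potential at $V_{min} = -30$ mV ($V_{min}$ is not given in
the source material; it is exposed in the configuration).

The engine updates neurons lazily (each cell records its last-update time);
the tests verify against a clocked 1 ms pure-R oracle that lazy and clocked
updates agree to $10^{-9}$ mV.

Threshold adaptation moves $V_\theta$ by
$\eta_{TA}(S - S^*)/S^*$ (clamped at a configurable floor, default 1 mV)
where $S$ is the cell's rolling firing rate and $S^* = 0.75$ sp/s the
homeostatic target. The exact update rule and the rolling-rate estimator
live in unpublished supplementary material, so their form here is the
package's own design: $S$ is an exponential moving average over 1 ms bins
with a ~10 s memory and the threshold steps every 500 ms. *Homeostasis is
deliberately slow relative to behaviour*: with a fast homeostat (we first
used a 1 s rate memory and 50 ms steps) threshold adaptation re-equalizes
every cell's rate within seconds and thereby erases — and eventually
inverts — the activity dip that the learned inhibition carves for frequent
stimuli, which is the very signal the intrinsic reward needs. Homeostasis
stays active in all closed-loop stages but is frozen during the inhibition
stage and its measurement sweeps ("fixing the excitatory weights" is read
as fixing the whole excitatory operating point).

### 1.2 The encoder

*Simple cells* tile the retina (receptive fields of 8×8–10×10 pixels × two
polarity channels, stride equal to the field) in `n_maps` maps that share
one weight tensor. On each spike the shared tensor is updated by
exponential STDP over the presynaptic log since the previous spike and
rescaled to the L1 norm $\lambda = 4$. *Complex cells* pool 3×3–4×4
locations × all maps with per-cell weights, an all-positive step window
($\pm\tau$, inclusive bounds, $\eta_{LTP}=\eta_{LTD}=0.2$) and
$\lambda_c = 10$; normalization is their only decay.

Three inhibition schemes:

* **static**: a spiking cell subtracts $\eta_I = 15$ mV from all
  same-location cells of other maps — the decorrelation mechanism;
* **lateral**: learned inhibitory weights from the 8-neighborhood of
  locations (all maps) onto each simple cell;
* **top-down**: learned inhibitory weights from the covering complex cells
  onto each simple cell.

The plastic inhibitory weights learn with the same exponential window
(rates $\eta_{ILTP} = 0.0077$, $\eta_{ILTD} = 0.0021$) from the *received*
inhibitory spikes, and are bounded by $\lambda_{lateral} = 100$ and
$\lambda_{topdown} = 300$. Here the package deviates from a literal
always-renormalize reading: if the incoming inhibitory vector were rescaled
to $\lambda$ after *every* update, the proportional rescaling would cancel
almost all of the STDP concentration (measured: ~2 mV of restructuring per
1000 s of simulation against a 100 mV budget), and the
frequent-stimulus-suppression effect would need hours of simulated time at
the printed learning rates. The bound is therefore implemented as a *cap*
("avoid unbounded growth"): weights accumulate freely and are rescaled only
when their norm exceeds $\lambda$. Excitatory weights keep the strict
equal-norm semantics, which the tests assert.

### 1.3 Intrinsic reward

$S_t$ (simple-cell population spikes per 1 ms bin) and $E_t$ (input events
per bin) are smoothed with $\alpha = 0.75$; the reward is
$R = \gamma(\beta - S)/E$. The printed $\gamma = 5,\ \beta = 90$ belong to
the full-scale topology where the homeostatic population activity is ~8.6
spikes/ms; against the desk topology's ~0.5 spikes/ms an offset of 90 makes
the activity term — the gradient the learned inhibition shapes — invisible.
The desk profile therefore sets $\beta$ to twice the homeostatic population
activity ($2\,n_{simple} S^*/1000$) and rescales $\gamma$ to keep
$\gamma\beta$ (the reward magnitude) unchanged. A floor $\varepsilon$ on
$E$ (desk: 8 events/ms) holds the reward at zero for near-silent input.

### 1.4 Actor-critic

The value is decoded from $N_{critic} = 100$ neurons as
$V = (\nu/N)\sum_i \rho_i / E_{norm} + V_0$ with $\nu = 1000$,
$V_0 = -20$ mV and kernel rate estimates
$\kappa(t) = (e^{-t/\tau_k} - e^{-t/\nu_k})/(\tau_k - \nu_k)$
($\tau_k = 100$ ms, $\nu_k = 5$ ms; the kernel integrates to exactly 1).
$E_{norm}$ is *relative*: the smoothed event rate divided by its own ~10 s
average (floored at 0.2), so the value is insensitive to input-rate
fluctuations but keeps its scale. The value derivative is the average of
the last $N = 100$ central differences scaled by $\eta_{actor} = 80$, and
$\delta = \dot V - V/\tau_r + R$ with $\tau_r = 1$ ms.

Critic and actor neurons (50 per action) are fully connected to both
encoder layers. Initial weights are uniform with a gain chosen so the
initial population drive is independent of the representation size
(`1800 / n_sources`, which reproduces 0.15 mV at the full tracking scale);
the actor populations carry four times that budget so each group emits
enough spikes per 10 ms action interval for the winner-take-all count
comparison to resolve learned preferences. Eligibility traces decay with
$\tau_e = 250$ ms and accumulate the STDP increments at critic/actor spikes;
at each action selection the critic weights and the weights of the group
whose action was *executed over the elapsed interval* change by
$\eta\, e\, \delta$ (clamped at zero). Each actor neuron's weight vector is
renormalized to its initial L1 budget after the update: without this
constraint the exploited group's total weight inflates under TD-error noise
and locks the winner-take-all readout in regardless of state; with it,
learning reshapes each neuron's state preference instead of its
excitability. The critic is unnormalized (it must encode the value level).

Training starts with a full-exploration phase (`explore_s`): actions are
uniformly random and only the critic learns. Afterwards the schedule decays
every $\Delta_{decay} = 2$ s — exploration $\lambda_{EXP} = 0.75$, the
action interval (250 ms toward a 10 ms floor) and the learning rates
($\eta = 0.2/0.1$, decays 5%/1.66%) — exactly the printed schedule.

## 2. Synthetic worlds and the event emulator

Frames are rendered at 1 kHz and converted to events by a per-pixel
log-threshold rule (threshold 0.25, intensity floor 0.05): one event per
crossing since the pixel's last emission, multiple crossings spread
uniformly across the frame interval, optional ±0.5 ms time jitter.
Ornstein–Uhlenbeck camera jitter ($\theta = 4$/s, $\sigma = 2.5$ px)
emulates fixational eye movements and sustains event generation.

The tracking world draws a striped ball (radius 42% of the retina height)
over a *world-fixed* sparse dot texture; the texture matters: with a blank
background the event rate collapses whenever the target leaves the center,
and a reward of the form $(\beta - S)/E$ then pays the agent for expelling
the target. The stabilization world shows a bar grating behind a circular
aperture with the same texture outside. Actions are two symmetric angular
velocities; the tracking camera traverses the field in ~1 s at full
authority, the stabilization camera rotates at 180°/s. During agent
training the tracking episode also resets (uniform position) whenever the
ball leaves the field, with a 300 ms grace period.

Stage inputs follow the published protocol of repeating short recordings.
The encoder trains on a moving-bar stream whose sweep speed and bar width
re-randomize every pass (tracking) or on a rotating grating
(stabilization). The inhibition stage replays a 2 s recording in which the
stimulus moves at constant speed (8 half-fields/s — fast enough that
neighboring cells fire within the STDP windows) between successive targets
drawn from the centered normal (sd = one third of the range): the stimulus
position density is center-peaked, the stated training distribution. The
shuffled-inhibition control permutes the learned weights uniformly at
random across each whole tensor.

What the synthetic worlds do **not** emulate: sensor noise (hot pixels,
background activity), refractory/latency effects of real event pixels,
multi-object clutter, occlusion, depth. Passing tests on these worlds show
that the mechanisms interact as described, not that the system handles real
recordings; the published real-data compression factors (~116× simple,
~657× complex) are not reproducible from synthetic desk-scale input, and
the package's corresponding numbers (hundreds× to thousands×) reflect the
synthetic stimulus statistics.

## 3. Scales, problem sizes and known limitations

The `"full"` profile carries the published topologies (tracking retina
300×60, 30×6×64 simple cells; stabilization 160×160, 16×16×144). The
`"desk"` profile used by the tests and the acceptance script scales these
to 120×24 with 15×3×16 (tracking) and 64×64 with 8×8×16 (stabilization);
problem sizes are ~200 s of simulated coding, 2 s × a few thousand replays
of inhibition training, 240–300 s of closed-loop agent training, and 12–16 s
validations — all sized so a full two-task run completes in tens of minutes
on one CPU.

Desk-scale calibrations, each chosen once and for the reasons given:

* **Complex-cell threshold** = $\lambda_c/n_{maps}$ (0.625 mV at 16 maps)
  instead of the printed 3 mV. Static inhibition limits each location to
  about one spike per population volley, so the peak synchronous drive a
  complex cell can receive is about $\lambda_c/n_{maps}$; the printed value
  presumes the much denser volleys of real million-event recordings.
* **Reward offset/scale** and the **critic/actor input gain** as in §1.3
  and §1.4.
* The **history horizon** for plasticity logs is 2000 ms; STDP windows are
  truncated there (irrelevant whenever inter-spike intervals are shorter).

Known limitations at desk scale, measured rather than hypothesized:

* *Orientation selectivity does not emerge* in 16 shared-weight maps driven
  by full-field gratings (phase averaging under weight sharing; per-map
  orientation tuning stays near max/mean ≈ 1.5–2). Consequently the
  inhibition-frequency experiment in its grating-orientation variant shows
  an overall activity reduction against the shuffled control (~20%) but not
  an orientation-specific one, and the closed-loop stabilization agent has
  almost no state signal to learn from.
* *The tracking policy signal is real but thin.* After training, the TD
  error is state-action informative and the actor weights acquire the
  correct lateralized structure (the left-minus-right weight profile
  crosses zero at the field center), but the winner-take-all comparison of
  ~50-spike counts per 10 ms resolves the ~5–8% drive difference only with
  ~55–65% per-decision reliability. The resulting drift toward the target
  is slower than a strict return-within-one-second criterion demands, and
  varies between seeds. Raising actor rates to improve the counting
  statistics narrows the $[t_{s-1}, t_s]$ eligibility windows and destroys
  the state snapshots — the two requirements conflict at this scale.

## 4. Numerical choices

* Times are integer microseconds at the interface, double milliseconds in
  the engine; events within a tick are processed in `(t, y, x, polarity)`
  order for determinism.
* All randomness — weight initialization, jitter, resets, exploration,
  tie-breaks — flows through R's RNG, so `set.seed()` makes every run,
  including the C++ closed loop, bit-reproducible; checkpoints capture the
  RNG state and resume exactly.
* L1 normalization clamps negative weights to zero first; the all-zero
  vector is left unchanged; ties in the winner-take-all readout are broken
  uniformly at random.
* The log-intensity emulator keeps a per-pixel reference that advances by
  the emitted amount only, so sub-threshold changes accumulate.
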