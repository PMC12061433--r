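---
title: "A burst-gated thalamocortical ring model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A burst-gated thalamocortical ring model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(thalamoburst)
```

## The model

`thalamoburst` simulates a spiking network built from three cell classes on
an orientation ring: 90 layer-5 pyramidal-tract (L5-PT) cells modelled with
two compartments, 90 fast-spiking basket cells, and 10 matrix-thalamus
relay cells wired 9:1 to consecutive blocks of cortical cells. One lap of
the ring spans 180 degrees of stimulus orientation (2 degrees per site), so
orthogonal stimuli sit on opposite sides of the ring.

**Somatic compartments** (L5 soma, basket, thalamus) are Izhikevich
adaptive quadratic integrate-and-fire units,

$$C\dot v = k (v - v_r)(v - v_t) - u + I, \qquad
  \dot u = a\,(b (v - v_r) - u),$$

with reset $v \to c$, $u \to u + d$ at $v \ge v_\mathrm{peak}$. The L5 soma
carries two reset pairs: regular spiking (RS, $c=-65$, $d=250$) and
intrinsic bursting (IB, $c=-55$, $d=150$). Raising the reset toward
threshold while lowering the recovery jump converts isolated spikes into
clustered bursts.

**The apical compartment** of each L5 cell is a two-variable nonlinear
model of the dendritic calcium plateau potential,

$$C\dot v_d = -l (v_d - v_r) + g f(v_d) + m H(t - t_s) + u_d + I, \qquad
  \dot u_d = a (b (v_d - v_r) - u_d),$$

with the regenerative activation $f(v) = 1 / (1 + e^{-(v + 38)/6})$.
Somatic spikes send a back-propagating action potential (bAP): a square
current pulse of amplitude $m = 2600$ pA, delayed 0.5 ms and lasting 2 ms.
While $v_d$ exceeds $-30$ mV (a plateau), the somatic reset pair may switch
from RS to IB.

**Saddle-node geometry.** Treating the apical input current $I$ as a
parameter, the nullclines meet tangentially where $f'(v) = (l - b)/g$,
which for the logistic $f$ has the closed form $f(1-f) = 6(l-b)/g$. With
the default constants the tangency voltages are $-44.660$ and $-31.340$ mV
and the two saddle-node currents are $I_{B1} = 538.911$ pA (the plateau
state is born) and $I_{B2} = 647.375$ pA (the resting state vanishes).
`bifurcation_points()` implements the closed form; the test suite checks it
against a brute-force continuation oracle. The *distance to bifurcation*
of a cell is its instantaneous apical input current minus $I_{B1}$.

**Coupling gate.** Communication between the compartments is gated by a
saturating variable per cell, $\dot g_c = -g_c/\tau_c + (1 - g_c)\sum_j
\delta(t - t_j)$, driven by the spikes of the cell's matrix-thalamus
partner ($\tau_c = 800$ ms). $g_c \in [0,1]$ is used as a probability: each
somatic spike back-propagates with probability $g_c$, and at each plateau
onset the soma switches to IB resets with probability $g_c$ (one Bernoulli
draw per onset; per-step draws would make the effective switch probability
depend on the integration step). The regime reverts to RS the moment the
plateau ends, with no hysteresis.

**Synapses** are conductance-based with exact exponential decay
($\tau_\mathrm{AMPA} = \tau_{\mathrm{GABA}_A} = 6$ ms, $\tau_\mathrm{NMDA}
= 100$ ms), reversal potentials 0 / $-75$ / $-80$ mV
(excitatory/inhibitory/adaptation), an NMDA voltage gate
$((v+80)/60)^2 / (1 + ((v+80)/60)^2)$, and a hard 85 nS cap on each NMDA
conductance. Cortical weights decay with the Euclidean chord distance
between ring sites, $w_{ij} = \lambda\, e^{-\tfrac12 (d_{ij}/\sigma)^2}$,
with broad inhibition ($\sigma_{I\to E} = \sigma_{E\to I} = 2$) and narrow
excitation ($\sigma_{E\to E} = 0.5$). Thalamic wiring is block-constant:
each thalamic cell receives AMPA input (weight 4) from its 9 cortical
partners and returns AMPA + NMDA (weight 10 each) onto their apical tufts.
A slow adaptation conductance on each L5 soma (0.065 nS per spike,
$\tau = 2000$ ms, reversal $-80$ mV) is the slow process that terminates
dominance episodes.

## Calibration: what is fixed and what was tuned

All single-cell constants, time constants, reversal potentials, spatial
spreads, the NMDA gate and cap, the thalamic weights and the 9:1 loop are
fixed at their tabulated values. Two groups of parameters are not fully
determined by those tables and were calibrated once, against the stated
operating conditions — an approximately E/I-balanced asynchronous-irregular
baseline under background drive, and a winner-take-all regime with
seconds-long dominance under two competing drives:

* **External drive weights.** Background spikes arrive as Poisson trains
  (600 Hz to every L5 soma, 50 Hz to every apical tuft) but the
  conductance increment per external spike is not tabulated. The defaults
  give the L5 soma a fluctuation-driven sub-rheobase background (weight
  1.6 nS per spike; the monocular rivalry drives use 1.15 nS), a weak
  basket background (0.34) and a near-zero thalamic background (0.05 —
  the thalamic rheobase is 40 pA, so a full-weight 600 Hz background
  would pin every coupling gate at 1 and erase the suppressed-population
  decoupling that rivalry requires). Apical plateaus are driven by the
  thalamo-dendritic projection and bAP volleys rather than by the weak
  apical background.
* **Cortical synaptic amplitudes.** The printed amplitude expressions are
  internally inconsistent with the stated winner-take-all calibration: at
  face value the integrated recurrent excitation (dominated by the slow
  NMDA component) outweighs feedback inhibition several-fold, and the
  network has no competitive regime anywhere in drive space — both
  stimulated populations settle into a stable, balanced coactive state.
  The amplitudes were therefore treated as the calibration targets the
  accompanying text says they are. The working point keeps the printed
  spatial spreads and the qualitative ordering (recurrent AMPA strongest,
  broad inhibition next, E-to-I weakest) while scaling the AMPA recurrence
  and feedback-inhibition loop up until (i) a single driven population
  ignites, sustains a bursting bump, and shunts its competitor below the
  thalamic recruitment threshold, and (ii) the slow adaptation current,
  not the fast recovery variable, paces the alternation.

The calibration was done against the qualitative regime definitions, not
against any particular headline number; the reproduction statistics in the
acceptance script are computed only after the working point was frozen.

## Experiments

* `run_threshold_detection()`: 200 ms current pulses (0–350 pA) with a
  Gaussian footprint ($\sigma = 20$ sites) on the L5 somas; readout is the
  whole-ring L5 spike count in the 1000 ms window from pulse onset. The
  control arm fixes the optimal integer criterion (minimum misses + false
  alarms, smallest tie-break); perturbation arms (apical ±, thalamic −,
  constant currents) reuse it. Psychometric curves use the four-parameter
  logistic $P(x) = \gamma + (1-\gamma-\lambda)/(1+e^{-\beta(x-\alpha)})$
  fitted by bounded least squares; neurometric curves use tie-aware ROC
  AUC per intensity, normalised across conditions to span $[0,1]$.
* `run_rivalry_batch()` / `run_levelt()`: two independent Poisson drives
  (Gaussian footprints, $\sigma = 18$ sites, centres 45 sites apart) onto
  the L5 somas. Dominance is a strict $>5$ Hz difference in the smoothed
  (100 ms causal boxcar) side-population rates lasting at least 250 ms.
  Levelt proposition 2 lowers one drive 1400→1250 Hz; proposition 4 sweeps
  both 1300→1500 Hz.
* `run_rivalry_perturbation()`: constant currents (±200/400 pA) onto
  apical compartments or thalamic cells of one half-ring (asymmetric) or
  the whole ring (symmetric).
* `run_limit_cycle_probe()`: all Poisson drives replaced by their
  mean-matched constant conductance increments; a 50 ms, +200 pA somatic
  kick to one half-ring probes whether the symmetric state is surrounded
  by a stable alternating orbit. The Bernoulli gating draws remain
  stochastic — the probe removes drive noise, which is what destabilises
  the deterministic orbits.

## Numerical scheme

Forward Euler at $dt = 0.1$ ms for every membrane equation; conductances
decay by their exact exponential factor between spike events; spikes
emitted at step $k$ reach their targets at step $k+1$ (no axonal delays
are modelled); thresholds are handled by clamp-and-reset at step
boundaries. Runs are bit-reproducible from `(config, seed)`; all
randomness flows through R's RNG, so `set.seed()` fixes the run. The
per-cell trace recordings (apical input current, reset regime, coupling)
are subsampled at 1 ms.

## What the generator does and does not emulate

The synthetic drives emulate stationary Poisson background and stationary
monocular stimuli. They do not emulate stimulus onsets/offsets within a
trial, eye movements, slow non-stationarities, or cell-to-cell parameter
heterogeneity — every cell of a class is identical, so population
statistics are sharper than in real tissue. Passing tests therefore show
internal consistency of the mechanism, not quantitative agreement with any
particular cortical dataset.

## Problem sizes

Default protocols use 30 s runs; reported statistics discard a 1 s burn-in.
The packaged test-suite and the acceptance script use 10 seeds per rivalry
condition and 10 trials per detection intensity; these sizes were chosen as
the smallest batches at which the seed-to-seed spread of the headline
statistics (mean dominance duration, alternation rate) is comfortably
inside the tolerances used to evaluate them.

## Known limitations

* The integration scheme is first-order; halving $dt$ changes single-cell
  spike counts by at most a couple of spikes per second (tested), but
  exact spike times are scheme-dependent.
* The two-population dominance readout assumes the drive centres used by
  the protocols; arbitrary stimulus geometries need their own masks.
* The printed-versus-working amplitude discrepancy above means the
  absolute synaptic conductance scale should not be interpreted
  biophysically; only the operating regime is calibrated.
* The scaled-up sparse variant (thousands of neurons, Dale-respecting
  ratios) is expressible through `ring_geometry()`/`build_weights()` but
  is untested and carries no defaults.
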