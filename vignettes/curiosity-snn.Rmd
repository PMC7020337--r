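---
title: "Curiosity-based training of a conductance LIF network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curiosity-based training of a conductance LIF network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbsnn)
```

## The model

`cbsnn` trains a fully connected three-layer spiking network of
conductance-based leaky integrate-and-fire (LIF) neurons for
classification. Each neuron carries a membrane potential $V$ and an
excitatory conductance $g_E$ with discrete-time (forward Euler) dynamics

$$\tau_E \,\dot g_E = -g_E + \eta \sum_{j} w_{j,i}\,\delta_j(t), \qquad
  \tau_m \,\dot V = -(V - V_L) - \frac{g_E}{g_L}\,(V - V_E),$$

where $\delta_j(t)$ is the presynaptic spike indicator. When $V$ reaches
the threshold $V_{th}$ the neuron spikes, resets to $V_{reset}$ and is
refractory for $t_{ref}$ steps. All constants are dimensionless
(defaults: $V_L = V_{reset} = 0$, $V_{th} = 1$, $V_E = 5$, $g_L = 1$,
$\tau_m = 10$, $\tau_E = 5$, $t_{ref} = 2$) and are configurable per layer
through `neuron_params()`.

A sample is presented for a window of $T = 100$ Euler steps
($\Delta t = 1$). At step $t$ two membrane updates are blended,

$$\Delta V = \tfrac{t}{T}\,\Delta V^{FF} + \left(1 - \tfrac{t}{T}\right)
\Delta V^{ES},$$

where $\Delta V^{FF}$ is the feed-forward conductance dynamics above and
$\Delta V^{ES}$ is an equilibrium-state relaxation that nudges each
potential toward consistency with its weighted presynaptic potentials,

$$\Delta V^{ES}_i = -\eta_i\Big[\big(V_i - (\textstyle\sum_j w_{j,i} V_j
- \theta)\big) + (V_i - V_L) + \tfrac{g_E}{g_L}(V_i - V_E)\Big].$$

So the relaxation dominates early in the window and the spiking dynamics
late. During training the output layer is additionally clamped toward a
one-hot teacher signal $V_T$ every step, $dV_i = -\eta_c (V_i - V_{T,i})$,
which drives the loss $C = \sum_i (V_i - V_{T,i})^2$ down.

Weights are plastic under a bilinear STDP rule,
$\Delta w_{j,i} \propto V_j \, V'_i$: presynaptic potential times
postsynaptic potential derivative, averaged over batches of 32 samples.

## The curiosity scheduler

After every training presentation the sample's *novelty* is the cosine
distance between its output readout and its teacher,

$$NE_k = 1 - \frac{V_k \cdot V_T}{\lVert V_k\rVert\,\lVert V_T\rVert}
\in [0, 2],$$

and a sample is selected for the next selective epoch iff
$NE_k \ge NE_{th}$ (the boundary is selected). Training proceeds in four
steps: (1) `T_start` full epochs seed the novelty table; (2) subsequent
epochs train only the selected (novel) samples, re-estimating their
novelty from each presentation; (3) every `I_re` epochs the whole dataset
is reviewed once, refreshing every estimate and counteracting both
overfitting of the novel samples and forgetting of the learned ones;
(4) repeat. Defaults are `T_start = 1`, `NE_th = 0.05`, `I_re = 5`.

Computation is accounted in *sample presentations* (one presentation =
one $T$-step simulation of one sample), a hardware-independent proxy for
training time; `computation_ratio()` divides two training logs' totals.

## Design choices in the open corners

Several pieces of the method admit more than one reading; the package
fixes them as follows.

**Readout.** The readout $V_k$ is the mean output potential over the
final $\lceil T/4 \rceil$ steps of the window, sampled after the membrane
update but *before* threshold reset. Sampling post-reset silently zeroes
the readout of any strongly driven neuron (it spends most steps reset or
refractory), inverting the ranking that decoding relies on. The averaging
window is exposed as `readout_fraction`.

**Which trajectory is read out.** During training the clamped output
trajectory is the readout — novelty then measures the *residual* the
teacher still has to correct, which is proportional to how wrong the
network's own drive remains. At prediction time there is no teacher, so a
free-running output trajectory (same conductances, no clamp) supplies
$V_k$; `decode_prediction()` takes its argmax with ties to the lowest
index.

**The clamp rate is deliberately weak** (`eta_c = 0.02`). A strong clamp
(e.g. 0.5) pins the readout to the teacher within one window, collapsing
every novelty estimate to $\sim 10^{-4}$; selection then degenerates to
"nothing is ever novel". At 0.02 the residual scale makes
$NE_{th} = 0.05$ a meaningful boundary between learned cores and
boundary samples.

**The potential derivative $V'$** of the STDP rule is implemented
per projection. For the output layer it is the accumulated potential
change of the clamped trajectory minus that of the free-running one,
divided by $T$: the teacher-attributable change. It vanishes exactly when
the network already reproduces the teacher — a converged neuron stops
learning — and each extra teacher-induced spike contributes $V_{th}$ of
depolarization, so the signal acts as a rate-difference error code. A
naive "total applied change" reading was tried first and is unstable: a
frequently firing neuron accumulates roughly $V_{th}$ per spike
regardless of error, which turns the Hebbian product into positive
feedback and saturates the weights at their bounds. For the hidden layer
(no teacher, purely Hebbian) $V'$ is the net membrane displacement over
the window including reset jumps, which keeps it bounded, and the hidden
learning rate defaults to `stdp_rate / 50` so the unsupervised drift
cannot erode the representation that the supervised output layer depends
on (`stdp_rate = 8` by default).

**Threshold term of the equilibrium target.** $\theta$ defaults to a
single $V_{th}$ (`es_threshold_mode = "single"`). The alternative,
$V_{th}$ per presynaptic neuron (`"count"`), depresses the equilibrium
target by the full fan-in (on a 784-input layer, by 784), which
hyperpolarizes the layer; empirically it pins every novelty estimate
above threshold and removes the method's computation savings, so it is
available but not the default.

**Encoding.** The default encoder is the deterministic constant-drive
("current") mode: each step carries `feature * max_rate` as a graded
drive. Bernoulli rate coding (`encode_mode = "rate"`) is provided and
fully supported — every training path is reproducible under it via
per-sample seeds — but its sampling noise lowers attainable accuracy on
low-dimensional tasks, where each readout averages only a handful of
Bernoulli draws per feature, so determinism is the default.

**Teacher shape.** The teacher is one-hot (`amplitude = 1`,
`baseline = 0`). `teacher_baseline = NULL` selects a zero-mean push-pull
variant ($-1/(K-1)$ off target) that actively depresses wrong-class
potentials; it is useful when the output layer accumulates a common mode.

**Stale novelty.** Unselected samples keep their last estimate until the
next full epoch; re-evaluating them each selective epoch would cost
exactly the presentations the method is designed to save. A
`refresh_all_novelty` switch implements the other reading (those
presentations are then charged to the log).

**Batches, order, determinism.** Samples are shuffled with a per-epoch
seed derived from the master seed, and encoded with per-sample seeds that
depend only on (master seed, epoch, sample id), so the baseline trainer
and a curiosity run with `NE_th = 0` are bitwise identical — weights and
logs — which the test suite asserts. Weight deltas are averaged within a
batch and applied once per batch.

## What the synthetic generator emulates

`synth_clusters()` draws unit-variance Gaussian classes whose means sit
at the vertices of a regular simplex (pairwise distance `separation`,
default 6). A fraction `overlap_fraction` (default 0.2) of each class is
drawn near the midpoint to a neighbouring class mean — displaced 10% of
the gap toward the labelled class so the label stays weakly identifiable
— then all features are min–max normalized. These boundary samples are
the synthetic analogue of the hard, persistently novel subpopulation in
real data: after a few epochs the class cores fall below `NE_th` while
the boundary samples stay above it, which is exactly the structure the
curiosity schedule exploits.

What the generator does *not* emulate: high input dimensionality,
correlated pixel structure, label noise, or class imbalance. Passing
tests on it demonstrates the mechanics of the method — the schedule, the
accounting, the novelty dynamics, learning to a ~0.9 accuracy plateau —
not performance claims about natural images.

The study configuration used by the test suite and `scripts/acceptance.R`
is 3 classes x 200 samples in 4 dimensions, split 450/150, 20 epochs,
hidden width 30. At that scale a full strategy comparison runs in about a
minute on one core; the sizes were chosen so the whole suite stays
desk-scale while every phase of the schedule (seeding, selection,
review) is exercised several times.

## Numerical corners

* Euler integration with `dt = 1` against time constants of 5–10 keeps
  the worst-case trajectory error against the exponential closed forms
  below 5% of the amplitude; halving `dt` at least halves it (asserted).
* The conductance is floored at zero after each step, so negative
  weighted input (weights may be negative) lowers drive but cannot
  produce a negative conductance.
* A zero-norm readout has undefined cosine distance; it is assigned the
  maximal novelty 2 (an all-silent output carries no class information).
* Decoding ties break to the lowest index; with zero input the readout
  sits slightly below rest — the equilibrium threshold term $-\theta$
  pulls it down — and carries no class signal (asserted subthreshold and
  small in the tests).
* Refractory neurons are frozen at $V_{reset}$ and excluded from all
  membrane updates, including the clamp; conductances keep integrating.
* An empty selective epoch (nothing novel) trains nothing and is logged
  with `selected = 0`; it is not an error.
* Optional early stopping compares mean loss across consecutive full
  epochs (tolerance `1e-4`) and is off by default to keep run lengths
  reproducible.

## Limitations

The equilibrium-state correction is a fixed-point relaxation, not exact
credit assignment; hidden-layer learning is unsupervised and contributes
little beyond a stable random projection at these scales. Accuracy on
the synthetic task plateaus around 0.90–0.95 — the boundary samples are
genuinely ambiguous by construction. Novelty is measured against the
clamped trajectory, so its absolute scale depends on `eta_c`; if you
change `eta_c`, `NE_th` should be re-examined together with it.
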