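---
title: "Dopamine-gated plasticity during operant learning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dopamine-gated plasticity during operant learning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocplasticity)
```

## The scientific question

During appetitive operant conditioning (a rat presses a lever to obtain a
food pellet), synaptic plasticity in the medial prefrontal cortex is higher
*while the task is being learned* than *after it has been learned*.
`ocplasticity` packages two complementary ways of looking at that claim:

1. a rate-based cortico-basal-ganglia network in which a
   temporal-difference (TD) model of midbrain dopamine gates Hebbian and
   anti-Hebbian plasticity, simulated as an ensemble of model "rats"; and
2. a synthetic stand-in for the quantitative RT-PCR measurements of
   plasticity-related transcripts (BDNF, CREB, Synapsin I, CamKII) and
   immediate early genes (c-fos, c-jun, Arc) at two behavioural stages,
   analysed with the matching one-way ANOVA + Tukey HSD pipeline.

The bridge between the two is the per-trial sum of absolute synaptic
change, `sum(|dW|)`, anchored to the BDNF level of the learning-stage
group and compared with the BDNF level after learning.

## The behavioural protocol

Time advances in 100 ms steps. A trial exposes the lever (the conditioned
stimulus, CS) for a lever-out period, followed by an inter-trial interval
(ITI); a press of the correct lever (response R1 of 3) terminates the
lever-out phase and delivers a pellet one step later. Sessions have 25
trials. The default simulations compress the 60 s lever-out / 20 s ITI
trial to 60 / 20 steps so that a 100-model ensemble runs in well under five
minutes on one CPU; `oc_config(faithful = TRUE)` restores the full
600/200-step timing. Latencies are reported in steps of 0.1 s either way.

Cue-selective input units keep a short-term memory (STM) of each stimulus:
the trace is set to 1 while the stimulus is present and decays by a factor
`lambda_stm = 0.95` per step otherwise. The functional form of the STM is
not constrained beyond "decaying memory", and the exponential trace is the
standard choice.

## The network

* **PFC layer** (80 units). Unit drive is `W %*% stm + w_vta_pfc * da +
  basal_pfc`, squashed by a logistic `sigma(x) = 1/(1 + exp(-slope * x))`
  onto [0, 1] and then passed through a winner-take-all mask (ties broken
  by lowest index). Dopamine (`da`, the TD prediction error) inhibits all
  units through the clamped-negative weight `w_vta_pfc`, while the winner
  receives a D1/NMDA synergism bonus `b_winner * da * afferent` — the
  bonus scales with the unit's glutamatergic afferent drive, so a weakly
  driven unit is net-inhibited by dopamine while a strongly driven winner
  is excited. `basal_pfc` is a bias on the net drive; the default −0.15
  corresponds to a spontaneous rate `sigma(4 * -0.15) = 0.35`, i.e. PFC
  units sit well below half-activation at rest. Because the logistic maps
  zero drive to rate 0.5, low spontaneous activity requires a negative
  bias; this is a reparametrisation of "baseline firing rate", not an
  oxymoronic negative rate.
* **BG-PMC layer** (3 response units: R1 = press, R2/R3 = task-unrelated
  behaviour). Drive combines the PFC layer through plastic weights, a
  direct stimulus→response pathway whose gain is the tonic locus
  coeruleus (LC) level, the dopamine "brake" `w_vta_bg * da`, and the same
  synergism bonus. The first unit whose activity exceeds `theta_resp =
  0.75` releases its response; if no unit crosses during the lever-out
  phase a uniformly random response executes at trial end (probability 1/3
  each). An executed response's activity is held at 1 for 5 steps, and
  response STM traces feed the BG-PMC learning rule.
* **Reaction dead time.** Responses cannot be released during the first
  `t_react = 4` steps (400 ms) after CS onset — an ordinary sensorimotor
  delay. Besides realism this matters dynamically: without it, trained
  models respond at latency 0, the CS-onset dopamine burst converges to
  `gamma * V ≈ gamma`, and that burst alone would re-open Hebbian windows
  on every trial forever, replacing the observed interior plasticity peak
  with a rising plateau. With the dead time the late onset burst is
  `gamma^(t_react + 1)`, small enough that gating quiets as learning
  consolidates.
* **LC modulation.** `lc_level = lc_max * (1 - reward rate over the last
  n_lc = 40 trials)`. Early in training the direct pathway therefore
  drives exploration; as rewards accumulate the gain fades and behaviour
  must be carried by the learned PFC→BG-PMC route. The 40-trial window
  makes that hand-over gradual enough that consolidation does not relapse.
* **Optional motor noise.** `noise_sd` adds Gaussian noise to the response
  units' drives (default 0 — the shipped calibration does not need it, and
  the deterministic ratchet of reward-driven weight growth produces the
  tight acquisition-time spread that the ensemble statistics require).

## Dopamine: TD prediction error and the plasticity gate

The VTA/SNc block is a tabular TD(0) learner over a serial-compound
(tapped delay line) representation of the CS: feature *k* is active iff CS
onset occurred *k* steps ago and the trial's reward-expectation window is
still open (the window closes after the reward step, making reward
delivery the terminal transition). The prediction error is

    delta = r(t+1) + gamma * V(t+1) - V(t),      V = w . x

with `w <- w + alpha * delta * x(t)`. Dopamine bursts (`delta >
theta_hebb`) open a Hebbian gating window of `min(t_max,
ceiling(t_slope * delta))` steps — duration grows with burst amplitude —
and dips (`delta < theta_antihebb`) open a fixed 15-step anti-Hebbian
window. A new qualifying event overwrites an open window (latest event
wins); otherwise the window counts down by one step per time step.

While the gate is open, every plastic matrix updates with a first-order
momentum Hebbian rule:

    dW = mu * dW_prev + s * nu * post %o% pre,    s = +1 (Hebb) / -1 (anti)

with weights clipped to [−1, 1] after every step. Momentum buffers persist
across steps and trials. Pre/post pairings follow the wiring: stimulus STM
→ post-WTA PFC activity for the PFC afferents; post-WTA PFC activity →
response STM for the PFC→BG-PMC weights; stimulus STM → response STM for
the direct pathway. The reported plasticity read-out is
`sum(|dW|)` per trial over the PFC afferent matrix (LTP and LTD add, they
do not cancel); `include_bgpmc_in_metric = TRUE` widens it to all plastic
synapses.

## How learning unfolds, and why the plasticity curve is non-monotone

Early trials: no unit crosses threshold, forced random responses earn
reward on 1/3 of trials, each unpredicted pellet produces `delta ≈ 1`, a
full Hebbian window, and a small increment of the CS→R1 pathways. This
reward-count ratchet gives acquisition times that are tightly concentrated
across models (roughly negative-binomial), which is what lets a 100-model
ensemble pass from chance to criterion over ~50 trials. Wrong responses
after the TD value has built up produce omission dips and anti-Hebbian
pruning.

Around acquisition, rewards arrive on every trial at newly short latencies
where the TD value is still near zero: gating is maximal, PFC activity
products grow as the afferent weights strengthen, and the ensemble
plasticity trajectory climbs to its maximum shortly after the median
acquisition trial. As TD predictions converge (`alpha = 0.02` makes this
deliberately slow), reward-time prediction errors shrink, windows shorten
(`t_slope = 12` maps amplitude to duration), and the trajectory declines —
but does not collapse, because convergence is still incomplete at trial
120. That residual is the model's counterpart of the biological
observation that plasticity-related transcription at the learned stage is
reduced relative to the learning stage yet still above naive controls.

## Calibration

The two behavioural anchors are part of the study design: ensemble
performance was tuned to 65% at trial 70 and 100% at trial 120, and the
plasticity trajectory was fitted to the BDNF dynamics (the trial-70 bar is
matched to the simulated series by construction; basal transcript levels
are not model parameters, hence `scale_to_anchor()`). The shipped defaults
were found by grid/iterative search against those anchors:

| parameter | default | role |
|---|---|---|
| `gamma` | 0.81 (per 100 ms step) | discount; sets the size of the late CS-onset burst |
| `alpha` | 0.02 | TD rate; sets how fast reward-time gating quiets after acquisition |
| `theta_hebb` / `theta_antihebb` | 0.3 / −0.1 | gate thresholds |
| `t_max` / `t_slope` | 10 / 12 | window-length map `min(t_max, ceil(t_slope * delta))` |
| `nu_pfc` / `nu_bgpmc` | 0.01 / 0.0013 | Hebbian rates (PFC / BG-PMC and direct path) |
| `mu_pfc` / `mu_bgpmc` | 0.5 | momentum constants |
| `basal_pfc` | −0.15 | PFC resting bias (spontaneous rate 0.35) |
| `theta_resp` | 0.75 | response release threshold |
| `t_react` | 4 steps | sensorimotor dead time |
| `n_lc` | 40 trials | LC reward-rate window |

Under these defaults a 100-model ensemble (seeds 1–100) reaches a 10-trial
windowed performance of ≈0.67 at trial 70 and 1.00 at trial 120, the
11-trial smoothed plasticity trajectory peaks near trial 86, and its
trial-70→120 decline is ≈15–25%, bracketing the 18.9% BDNF decline. These
are the quantities `scripts/acceptance.R` recomputes; nothing in this
vignette is asserted that the test suite does not itself compute.

```{r example, eval = FALSE}
traj <- run_ensemble(oc_config(), n_models = 100, base_seed = 1)
windowed_performance(traj, 70)    # ~0.67
plasticity_peak(traj)             # ~86
scaled <- scale_to_anchor(traj, 70, 131.9)
match_report(scaled, c("50%CR" = 131.9, "100%CR" = 106.97))
```

## The synthetic expression arm

Real tissue is unavailable to a software package, so `generate_expression()`
draws replicate values from `Normal(group mean, noise_sd)` truncated at
zero, on the percent-of-cage-control scale, for 7 genes × 5 groups
(naive Control, two box controls, and the two behavioural stages) × 6
replicates. The group means are the study's printed effect sizes; BDNF's
learned-stage mean is derived from its printed 18.9% decrease
(131.9 × 0.811 = 106.97), and Arc's learned-stage increment — reported
only as significant, without a percentage — defaults to 114, in line with
the other immediate early genes, and is exposed as `arc_100cr`.

`noise_sd = 9` (percent points) is a free calibration: standard errors are
shown only graphically in the source material. At n = 6 it makes the
reported significance pattern attainable (the ~30% learning-stage
increases are detected by Tukey HSD in most replicates; the three control
groups remain statistically exchangeable). What the generator does *not*
emulate: raw Ct values, amplification efficiency, reference-gene
normalisation mechanics, inter-animal correlation, or heteroscedasticity
across groups — so passing tests certify the statistical pipeline and
effect-size bookkeeping, not qPCR chemistry.

The statistics mirror the study: per-gene one-way five-group ANOVA
followed by Tukey HSD at alpha = 0.05, with percent changes computed from
group means of normalised values. Two documented discrepancies in the
source are resolved as follows: the Methods section mentions repeated
measures ANOVA, but the groups are independent animals and every reported
F is the one-way statistic, so one-way is implemented; and the printed
degrees of freedom (4, 25) are inconsistent with 5 × 6 = 30 observations —
this package reports the true N − k = 25 only when an observation is
actually missing, otherwise 25 would be 25 = 30 − 5, which is what the
printed value happens to equal, suggesting the original denominator df was
in fact N − k with all 30 animals.

## Numerical choices and degenerate inputs

* Winner-take-all ties break to the lowest index everywhere; all
  stochastic draws flow from one seeded generator per model
  (`withr::with_seed`), and ensemble seeds are `base_seed + 0 .. n - 1`.
* Smoothing is an 11-trial centred moving average with partial edge
  windows; "performance at trial k" is the mean over a centred 10-trial
  window (single binary trials are too noisy to anchor on).
* `scale_to_anchor()` refuses a non-positive smoothed anchor value;
  `percent_of_control()` refuses a missing or non-positive control mean;
  truncated-normal draws redraw rather than clip, keeping values strictly
  positive.
* Momentum with a closed gate only decays (`dW = mu * dW_prev`), and the
  simulator skips the update entirely once the buffers are numerically
  dead, which is what makes the 100 × 125-trial ensemble cheap.

## Known limitations

* The compressed 60-step trial preserves the protocol's structure, not its
  absolute timing; `gamma` is therefore a per-step discount tied to the
  compressed clock.
* The rats' quantitative latency curve (44 s → 4 s) is not a calibration
  target; only the criterion thresholds (50–65%, 100% with latency < 5 s)
  are modelled, via `stage_criteria()`.
* Ensemble SEM bars describe across-model variability of independently
  seeded runs, not biological between-animal variance.
* The TD block uses a within-trial delay line; it cannot anticipate the CS
  itself from the trial rhythm, so the onset burst never disappears — the
  reaction dead time is what keeps it below the Hebbian threshold late in
  training.
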