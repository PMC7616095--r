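---
title: "Models and methods behind dopadist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dopadist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopadist)
```

dopadist is a simulation-plus-analysis pipeline for studying how
projection-defined midbrain dopamine populations encode events in a Pavlovian
trace-conditioning task, and how their diversity can be read as distributional
reinforcement learning. Because the recordings it was designed around are not
publicly deposited, every stage is exercised against a synthetic-data
generator with known ground truth; this vignette explains the models, the
tunable parameters, the numerical choices, and what passing the package's
tests does and does not establish about real data.

## The task generator

A session consists of `n_trials` (default 100) cue–reward pairs: a 1-s
auditory cue, reward delivered exactly 2 s after cue onset, and an
inter-trial interval (ITI) between reward and the next cue. The ITI is a
shifted exponential — flat hazard, so reward expectation does not grow within
the interval — truncated by rejection to 4–10 s. The paper-level constraint
is the support and a median of 5.4 s; the exponential rate is not stated, so
`task_config()` calibrates it by root-finding on the truncated-median
equation

$$\frac{1 - e^{-\lambda(5.4 - 4)}}{1 - e^{-\lambda(10 - 4)}} = \tfrac12,$$

giving $\lambda \approx 0.448\ \mathrm{s^{-1}}$. We define the ITI as the
span from reward delivery to the next cue onset; the anchoring is not stated
in the source methods and any consistent choice only shifts session length.

Licking and movement are generated directly at the bout level (video/EMG
scoring is out of scope): an anticipatory lick bout per trial at a fixed
latency after the cue, a consummatory bout after each reward, and spontaneous
movement bouts as a Poisson process confined to ITIs (clipped away from the
3-s post-reward consumption window by default). Overlapping bouts of one kind
are merged; lick and movement bouts may overlap each other, as in real
behavior.

Spike trains are inhomogeneous Poisson processes simulated by thinning at
1-ms resolution: a tonic rate multiplied by per-event gains over event
windows, overlapping modulations multiplying, and the effective rate floored
at zero. A Poisson model is the natural companion of the Poisson encoding
GLM; an optional absolute refractory period exists but defaults to off. The
four population templates encode only the qualitative response patterns
reported for the projection targets — DMS: cue response, no reward response,
movement-related decrease; DLS: cue and reward responses plus lick
multiplexing; VLS: no cue response, strong short-latency (40–240 ms) reward
response; NAc core: lower tonic rate, delayed lick-locked responses, and
inserted firing pauses. The magnitudes (gains 1.4–3, tonic 3.5–6 Hz, pauses
of ~1 s at 2/min for NAc core) are generator choices fixed once at values
realistic for midbrain dopamine units; no quantitative effect sizes are
available to copy. Consequently, tests that recover these templates show the
*pipeline* works at realistic effect sizes — they are not estimates of real
effect sizes.

Synthetic photometry mirrors a two-channel (activity + reference) recording
at 130 Hz: the indicator signal is the population rate convolved with a
difference-of-exponentials kernel (rise 50 ms, decay 500 ms), to which a
shared low-frequency motion artifact, independent white noise per channel, a
static fluorescence offset, and optionally an exponential bleaching trend are
added. The reference channel carries the artifact and noise but no signal.

All randomness descends from one master seed through `derive_seed()`
substreams, so any unit, channel or stage can be regenerated independently
and the full generator is a pure function of (config, seed).

## Single-unit encoding

PSTHs use 40-ms bins over −1 to +4 s around the cue. Rates are z-scored
against the mean and SD of the pooled 1-s pre-cue baseline bins of all
trials, making the pooled baseline z exactly zero by construction, then
smoothed with a 5-tap Gaussian kernel. We read the stated "half-width 70 ms"
as the FWHM of the underlying Gaussian (σ ≈ 29.7 ms ≈ 0.74 bins), the only
reading consistent with a 5-tap kernel at 40-ms bins; the kernel is
renormalized to unit sum, and at matrix edges the in-range taps are
renormalized so constants pass unchanged. Units with zero baseline SD are
flagged silent and excluded from z-scoring.

The encoding model is a Poisson GLM (log link, intercept included) of 200-ms
spike-count bins on four binary regressors. Bins tile each trial from 1 s
before its cue to 1 s before the next cue, so cue onset lies exactly on a bin
edge; a trailing partial bin is dropped. Cue and reward are coded 1 in the
two bins covering 0–400 ms from their onsets; lick and movement are coded 1
where the bin overlaps a bout by at least 75% of the bin width (the 0.15-s
boundary case counts). Multiple regressors may be active in one bin — no
exclusivity is imposed. Wald p-values classify a unit as responsive at raw
p < 0.05 (no multiplicity correction, matching the original analysis), the
dominant parameter being the significant one with the largest |β|. The
deviance goodness-of-fit p uses the χ² reference for the residual deviance;
note this reference is anticonservative when bin counts are small (mean
counts ≲ 5), which is the regime of real dopamine data — the package reports
it as defined but the calibration test runs in the moderate-count regime
where the χ² approximation holds.

Event-window quantification (0–240 ms after cue; 40–240 ms after reward)
compares the trial-averaged window rate to a shuffled baseline: the same
number of windows placed uniformly at random inside ITIs, excluding the
first second after reward, 1000 placements, two-sided percentile p with the
add-one correction. The shuffle construction is not specified in the source;
this is the package's definition.

## Tonic firing statistics

CV2 is the mean over adjacent ISI pairs of $2|I_{n+1}-I_n|/(I_{n+1}+I_n)$:
0 for regular firing, 1 in the Poisson limit. "Outside of engagement" is
implemented as each ITI minus the first 3 s after reward and the last 1 s
before the next cue; ISI statistics use only intervals within a single such
epoch.

Burst and pause detection is a robust-surprise method on ISI strings. The
cited family of methods centers log-ISIs and scores strings against a
Gaussian; implementing that literally, we found it miscalibrated on the
generator's own null — log-exponential ISIs have a heavier-than-Gaussian
short tail, so at α = 0.05 about 9% of null ISIs seed candidate bursts and no
retention threshold meets both a ≤5% null false-positive fraction and ≥90%
recovery of injected bursts. The package therefore calibrates surprise
against a robust exponential null: the tonic rate is estimated as
$\hat\lambda = \log 2 / \mathrm{median}(ISI)$ (re-estimated up to three
times excluding already-detected strings, so bursts and pauses do not
contaminate the estimate); seeds are single ISIs, or adjacent pairs, with
one-sided tail probability below α; around each seed the most surprising
substring within ±4 intervals is selected, scored by the exact gamma tail of
its summed length — the sufficient statistic for a uniform rate change over
the string — and retained at the selection-corrected threshold
$-\log_{10}(\alpha/(\mathrm{span}+1)^2)$. Bursts need ≥3 spikes, pauses ≥1
long interval; overlapping strings are pruned most-surprising-first.
Detection is invariant to uniform time rescaling. On simulated Poisson nulls
the spike-level false-positive fraction is ~3% for bursts and ~1.5% for
pauses, and 5-spike strings at 10× the tonic rate are essentially always
recovered. On real (non-Poisson, refractory) trains the exponential null is
mildly conservative for bursts.

## Population clustering

Cohort PSTHs (units × bins of smoothed mean z) are column-centered — not
variance-scaled, since all entries already share the z scale — and
decomposed by SVD; the two leading score columns, with a deterministic sign
convention (largest-|loading| positive), feed average-linkage agglomerative
clustering on Euclidean distances. The cut level is a parameter, default 4
to match the four populations; the source never states its cut. Enrichment
tables report within-cluster population fractions and each population's
modal cluster.

## Photometry processing

The chain follows the stated acquisition order exactly: 5-sample median
filter, zero-phase second-order Butterworth low-pass at 20 Hz, zero-phase
second-order high-pass at 0.001 Hz, subtraction of the best linear fit
(with intercept) of the reference channel, division by a 0.001-Hz low-pass
baseline, and per-sweep normalization to the 1-s pre-cue mean. Two numerical
choices matter:

* **Filter initialization.** A 0.001-Hz second-order filter settles over
  ~1000 s, longer than a session, so naive forward–backward filtering leaves
  large edge transients (we measured ~9% of a DC offset surviving on a 600-s
  trace). Each pass is therefore initialized at the steady state implied by
  its first sample (the standard `lfilter_zi` construction), which removes
  the transient exactly for constants and keeps it negligible for slow
  drifts. Complete removal of a bleaching *trend* is still limited by record
  length relative to the 0.001-Hz corner period (1000 s): on a 600-s trace
  ~93% of a linear trend is removed, ≥99% on a 1200-s trace.
* **Baseline positivity.** Applying the stated chain literally would divide
  by the low-pass of a zero-mean (high-passed) signal. The dF/F baseline is
  therefore computed after restoring the mean level removed by the
  high-pass, so it is strictly positive wherever the raw fluorescence was;
  a non-positive baseline is an error, not a NaN.

Whether the original "best linear fit" included an intercept is unstated; we
include one (without it, any offset difference between channels biases the
slope). The reward-response peak window is 0–1 s after delivery,
configurable, as the figure-level window is unstated.

## The distributional TD model

Each simulated neuron $i$ carries a state-value table over a deterministic
chain and updates with the TD error
$\delta_{t,i} = r_{t,i} + \gamma V_{t+1,i} - V_{t,i}$, scaled by
$\alpha_i^+$ when $\delta > 0$ and $\alpha_i^-$ when $\delta < 0$ (no update
at exactly zero). At the rewarded terminal state the reward is drawn from
the Gaussian training distribution, read as mean 5, **SD** 5 (the "N(5,5)"
notation is ambiguous; the SD reading makes the 0–20 test range span ±3 SD,
and the interpretation is configurable). The asymmetry
$\tau_i = \alpha_i^+/(\alpha_i^+ + \alpha_i^-)$ makes the reward-state value
converge to the $\tau_i$-expectile of the reward distribution; an
independent oracle computes Gaussian expectiles from closed-form partial
expectations by root finding, and the equivalence is property-tested across
τ.

Unstated environment constants are package choices: γ = 0.9, a 5-state chain
with reward at the terminal state, values initialized at 0, 10,000 training
episodes. Rewards are drawn per neuron per episode (the per-neuron subscript
on $r_{t,i}$), which leaves converged statistics unchanged versus a shared
draw. The **converged value** reported per neuron is the mean of its value
over the final 500 episodes (tail averaging): with constant learning rates
the last iterate fluctuates with SD $\approx \sigma\sqrt{\alpha/(2-\alpha)}$
— up to several reward units at α near 1 — while the tail average estimates
the stationary mean at a fraction of that variance without altering what the
update converges to. The small $O(\alpha)$ stationary bias of the asymmetric
update is visible in tests as a widened tolerance at large α.

Fitting tailors $(\alpha^+, \alpha^-)$ per neuron by grid search over
α ∈ {0.01, …, 1.00}². Each neuron draws one target from the population's
activity distribution — a Gaussian KDE (Silverman bandwidth) of
standardized reward-window responses: per-unit 40–240 ms rates minus the
pre-cue baseline rate, divided by the pooled SD across all units, a mapping
the source leaves unstated. The grid loss compares the target to the pair's
stationary expected reward-state TD error, computed analytically as
$\mu - e_{\tau}$ via the expectile relation rather than re-simulating
10⁴ grid points per neuron; ties break toward the smaller α⁺+α⁻. A
symmetric zero-mean target distribution yields mean asymmetry 0.5 exactly in
expectation (Gaussian expectiles are antisymmetric in τ); strictly positive
targets — persistent positive reward-state errors — force values below the
training mean, i.e. asymmetries below 0.5 and systematic underestimation of
test rewards. Evaluation freezes the trained values (no learning during
test, the reading most consistent with "after training, agents were tested"),
draws test rewards uniform on 0–20, and reports per-cell mean squared error.
`build_projection_agents()` fits one 50-neuron agent per population plus a
unified agent on the pooled sample.

## Orchestration and problem sizes

`run_pipeline()` chains simulate → encode → firing statistics → cluster →
photometry → TD fit/evaluate under one master seed and writes CSV/JSON
tables plus a Newick dendrogram; reports carry a content hash so identical
(config, seed) runs are verifiably identical. Configuration documents
(YAML/JSON or lists) are validated with descriptive errors naming the
offending key. The package exposes everything through functions and this
vignette rather than a shell entry point, which is the natural interface for
an analysis library.

Default problem sizes — 100-trial sessions, cohorts of 8 units per
population, 10,000 training episodes, 100×100 fitting grids, 100,000-draw
distribution checks — were chosen so a full test run and the convergence
targets complete in a few minutes on a single core while keeping Monte-Carlo
error well inside every stated tolerance.

## Known limitations

* The generator's Poisson spiking has CV2 ≈ 1; real dopamine neurons are
  more regular and refractory, so CV2 contrasts between populations are not
  emulated, and the burst detector's null calibration is conservative on
  real trains.
* Template effect sizes are stipulated, not estimated; enrichment and
  recovery rates on synthetic cohorts certify the pipeline's operating
  characteristics at those effect sizes only.
* The deviance goodness-of-fit χ² reference degrades at low per-bin counts.
* Photometry bleach removal is limited by record length relative to the
  0.001-Hz corner; sub-1000-s recordings retain a few percent of a linear
  trend.
* The TD environment is the minimal deterministic chain; no action
  selection, function approximation, or state uncertainty.
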