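---
title: "Models and methods behind lofcEncode"
author: "lofcEncode authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lofcEncode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lofcEncode)
```

# Overview

`lofcEncode` implements an analysis pipeline for single-unit spike trains
recorded in lateral orbitofrontal cortex (lOFC) during a cued-gamble task:
rats initiate a trial at a centre port, listen to Poisson click trains whose
rates convey the water volume baited at each side port, watch light flashes
whose counts convey reward probability, and after a go cue choose a side (or
opt out). The pipeline has four scientific layers:

1. **a synthetic task-and-spike generator** that emulates the trial timeline
   and plants ground-truth Poisson-GLM neurons in five response archetypes;
2. **an encoding model**: an L2-penalised Poisson GLM whose kernels are
   linear combinations of a log-raised-cosine temporal basis;
3. **clustering of response profiles** in two feature spaces (trial-averaged
   PSTHs and condition-averaged responses) with cluster-number and
   clusteredness diagnostics (gap statistic, silhouette, subsampled ARI,
   Mahalanobis separation, PAIRS);
4. **encoding and adaptation metrics**: the coefficient of partial
   determination (CPD), a sampling-based mutual information (MI),
   shuffle-corrected discriminability (d'), and trial-history regressions of
   epoch-averaged firing rates.

Everything runs end-to-end on synthetic sessions, so no recorded data are
required; an adapter (`loadDeposited()`) maps a locally downloaded copy of
the study's deposited tables onto the same containers.

# The encoding model

Spike counts $y_t$ in 50 ms bins follow a Poisson distribution with rate
$\lambda_t$,

$$\lambda_t \Delta t = \exp\Big[\sum_{s} \big(X^{(s)} * k_s\big)_t + \theta_0\Big],
\qquad k_s(\tau) = \sum_{j=1}^{M} \theta_s^{(j)} \phi_j(\tau),$$

where $X^{(s)}$ are binary (or scalar) impulse streams for the 15 task
variables — left/right clicks and flashes, left/right choice, safe/risky
choice, win/loss, previous win/loss/opt-out, previous reward rate, session
progress — each convolved causally with its kernel $k_s$ over 4 s of lag.
The basis has $M = 9$ functions: seven raised cosines on a log-time axis,
$\phi_j(\tau) = \tfrac12\cos(a\log\tau - b_j) + \tfrac12$ clipped to
$|a\log\tau - b_j|\le\pi$, plus two decaying exponentials (25 and 50 ms)
peaking in the first two lag bins. We place the cosine peaks log-linearly
between 25 ms and 2 s and set $a$ so adjacent cosines cross at half height;
the source analysis states only a "roughly log-linear placement", so the
exact peak grid is our design choice. All columns are scaled to peak at 1,
which makes a basis weight directly readable as the kernel height it
contributes.

Anchoring is part of the design: stimulus kernels start at their own event
times, choice kernels at centre-port exit, outcome kernels at side-port
entry (which is also reward delivery on wins), and history/rate/progress
kernels at trial start. All kernels are causal in lag; responses that
precede an event (e.g. pre-choice activity) are captured by anchoring the
choice-epoch kernels to the earlier centre-port exit rather than by negative
lags. No spike-history term is included.

Fitting minimises the penalised negative log-likelihood
$L = \sum_t [\lambda_t\Delta t - y_t \log \lambda_t\Delta t] +
\tfrac{\xi}{2}\lVert\theta\rVert^2$ (background unpenalised) by damped
Newton iteration to a max-gradient tolerance of $10^{-6}$; the objective is
convex, and the parameter covariance is taken as the inverse Hessian at the
optimum. The penalty $\xi$ is chosen on a refining log-spaced grid over
$[10^{-5}, 10]$ (7 points per round, 3 rounds by default; each round
brackets the previous argmin): trials are split into five partitions
balanced over the joint outcome, previous-outcome and choice contingencies;
four-fold cross-validation on the non-test partitions keeps the fold model
with the lowest validation NLL, and the $\xi$ with the lowest NLL on the
held-out test partition wins. Held-out $R^2$ compares predicted mean counts
with 250 ms boxcar-smoothed observed counts, and units must exceed
$R^2 > 0$ (and a 1 Hz mean rate) to enter the encoding metrics.

On our synthetic units the cross-validated penalty frequently sits at the
upper grid edge ($\xi = 10$): with fifteen 9-weight kernels and a few
hundred trials, the likelihood still rewards strong shrinkage of the many
noise kernels. We therefore assert only that the selected penalty leaves the
unpenalised corner in the unit tests, and note that genuinely interior
optima appear once the planted structure is strong (see
`selectModel()`'s search trace attributes).

# The synthetic generator

`generateSession()` draws, per trial: a 2.5–3 s cue period (trial start to
go cue), a 0–350 ms pre-flash interval, 20 ms flashes on a 250 ms grid (each
slot lights with probability equal to the side's reward probability, a
monotone map we chose because the published task figure is graphical),
Poisson click trains at a rate linear in volume (40 Hz at 48 µl by default),
a 0–500 ms post-flash delay, and uniform reaction (go→exit, 0.1–0.3 s) and
movement (exit→side-port, 0.2–0.5 s) times. One side is safe ($p = 1$), the
other risky ($p < 1$ from {0, 0.25, 0.5, 0.75}); volumes are drawn
independently from {6, 12, 24, 48} µl. Choices follow a logistic on the
left–right expected-value difference (slope 0.15/µl) — a configurable
convenience, not a model of the animal — opt-outs occur with probability
0.1, and wins are Bernoulli in the chosen side's probability, independent
across trials. History fields (previous outcome, mean rewarded volume over
all previous trials, normalized trial number) derive strictly from earlier
trials.

`makeArchetypes()` plants five ground-truth response families, mirroring the
canonical cluster profiles: a trial-start burst (equal kernels on every
previous-outcome condition, so the burst is history-blind), persistent
cue-period activity driven by the click streams, a **pre-choice
reward-history** unit whose previous-win kernel has both an early component
and a late (~2 s lag) component that re-emerges just before the choice, a
choice-locked transient, and a reward-locked response that is much larger
after wins. Only the third archetype distinguishes previous wins from
previous losses — it is the planted positive that the CPD/MI/d' recovery
tests must find, and the other four are planted nulls. Kernels use the
broader mid-lag cosines (hundreds of ms wide) because that matches the
width of real PSTH transients and keeps the recovery problem well
conditioned; backgrounds are drawn uniformly from 3–8 Hz with 15%
log-normal weight jitter to individuate neurons within an archetype.
Spikes are then drawn per 50 ms bin from the generative model itself
(`simulateSpikes()`), over a window slightly wider than the model window
([-2.05, 8.05] s around trial start) so that choice-aligned analyses have
coverage; run-away rates abort with an error rather than being clipped.

What the generator does *not* emulate: session non-stationarities beyond the
planted session-progress covariate, correlated noise across neurons, bursting
or refractoriness (counts are conditionally Poisson), electrode drift, and a
behaviourally realistic choice policy. Passing tests on synthetic data
therefore demonstrate the *estimators'* correctness and power under the
model's own assumptions, not robustness to these real-data features.

# Clustering and validation

PSTH clustering z-scores each neuron's trial-averaged, 250 ms-smoothed PSTH
(trial-start aligned, $[-2, 4]$ s at 50 ms — 121 bins), applies PCA, keeps
the smallest number of components explaining more than 95% of variance, and
runs k-means (50 restarts; rows are put in canonical order first so the
result is invariant to neuron ordering). Conditional clustering builds 19
features per neuron — win/loss and rewarded volume {0, 6, 12, 24, 48} µl
averaged over [0, 3] s after reward delivery, previous win/loss over
[-1, 2] s after trial start, left/right choice over [0, 1.5] s after
centre-port exit, and each side's offer expected value in log-2 bins over
[-1, 0] s before side-port entry — z-scored against the neuron's marginal
(pooled) statistics so conditions remain comparable, then PCA-reduced the
same way. Opt-out trials enter only through the reward-history features;
empty condition cells (possible in short sessions) are imputed at the
marginal mean and logged.

Cluster number uses the gap statistic (uniform reference over the
PCA-aligned box, `cluster::clusGap` with `spaceH0 = "scaledPCA"`, 5000
reference draws at full scale) with the selection rule "largest $K$ with
$\mathrm{Gap}(K) \ge \mathrm{Gap}(K-1) + 2\,\mathrm{SE}(K-1)$", falling back
to 1. Silhouette, subsampled ARI (100 draws of 90% without replacement) and
cluster-averaged Mahalanobis distances (square root of the quadratic form,
i.e. an average z-score) characterise cluster quality. PAIRS whitens the
PCA-reduced features, takes each point's mean angle to its $k$ nearest
neighbours, and compares the median against pooled standard-Gaussian
references of matched size and dimension (whitened exactly like the data); $k$ is the smallest neighbour
count whose pooled reference median angle exceeds $\pi/4$. We use signed
angles on $[0, \pi]$ with neighbours ranked by angular proximity: that
convention reproduces the published neighbour count for the conditional
space ($k = 8$ at $N = 659$, $D = 11$); a `fold` flag provides the folded
$[0, \pi/2]$ alternative. For the PSTH space ($D = 18$) no convention
reaches the published $k = 3$ — an isotropic Gaussian reference in 18
dimensions has a median nearest-neighbour angle above $\pi/4$ already at
$k = 1$, so the smallest-k rule selects 1; the acceptance suite records
this discrepancy rather than masking it.

The covariance-regime experiment plants $K = 5$ clusters (100 points each)
with means drawn from a scaled total covariance and points from a
within-cluster covariance, PCA-reduces, and records the silhouette-optimal
and gap-selected $K$ per replicate across scale factors
{0.1, 0.5, 1, 2, 3, 5}. Without the deposited covariance matrices we supply
smooth squared-exponential stand-ins (marginal variance 1 for the total,
0.1 within; correlation length 10 bins at $D = 121$) labelled synthetic
throughout: at large scales both criteria recover 5, at vanishing scale the
gap statistic collapses to 1, which is what the acceptance suite checks.
The study's data-matched regime (silhouette optimum of 2) requires the
deposited covariances and is left as a documented, failing check when the
archive is absent.

# Encoding metrics and their calibration

**CPD.** For a covariate group (reward = win/loss, reward history =
previous win/loss/opt-out, choice = left/right, clicks, flashes), the
reduced design replaces the member streams by their arithmetic mean —
event timing survives, condition identity is erased — and
$\mathrm{CPD}_t = 100\,(\mathrm{SSE}^{red}_t - \mathrm{SSE}^{full}_t) /
\mathrm{SSE}^{red}_t$ per aligned 50 ms bin, with trials weighted so each
condition contributes equally (reward/history/choice groups). CPD is
computed on the full dataset. Significance comes from 500 label shuffles
(condition labels permuted across trials; left/right streams swapped for
stimulus groups); the null mean is subtracted and non-significant bins are
zeroed before cluster averaging, and units with any raw CPD above 50% are
flagged as outliers and excluded from cluster means.

**MI.** For the trial-level groups, the conditional spiking distribution is
modelled doubly stochastically: 500 parameter vectors sampled from the
fit's normal distribution (inverse-Hessian covariance) are pushed through
the exponential link, and the implied Poisson count distributions
(truncated at 10 spikes/bin, a 200 Hz cutoff, with the excess mass pooled
into the top bin) are averaged over the trials of each condition.
$\mathrm{MI}_t = H(Y_t) - H(Y_t\,|\,X)$ is reported in bits with the
empirical stimulus entropy $H(X)$ as its upper bound. (Taking the first
term as the count entropy rather than the stimulus entropy keeps raw MI
inside $[0, H(X)]$, which the printed form of the defining equation would
violate; we read that as a typographical slip and implement the standard
definition.) Significance mirrors the CPD shuffle.

**d'.** Per bin, $d'_t = |\mu_{prevWin} - \mu_{prevLoss}| /
\sqrt{(\sigma^2_{prevWin} + \sigma^2_{prevLoss})/2}$ on smoothed
single-trial rates; because the unsigned form inflates small effects, the
mean of a 1000-fold label-shuffled null (condition counts preserved) is
subtracted, with one-sided 95% significance.

**Calibration caveat.** d' depends only on the data, and its shuffle test is
well calibrated (~5% false-positive bins on null units). CPD and MI,
however, evaluate a model whose kernels were *fitted to the same trial
labels that the shuffle permutes*: even for a covariate absent from the
generative model, the fitted noise kernels align with the true labels, so
the data statistic sits systematically above the label-shuffled null. On
planted-null units we measure ~10–20% significant bins for CPD and far
more for MI, at any penalty the cross-validated search can select. This
in-sample optimism is inherent to the published construction (full-data
CPD/MI against label shuffles without refitting); the acceptance suite
states the 5% ± 2% calibration for all three metrics and honestly fails it
for CPD and MI, while the null-subtracted *effect sizes* remain near zero
and the planted-positive archetype is still separated cleanly from the
planted nulls (the headline concurrence check requires several significant
pre-choice bins in CPD, MI and d' jointly, which de-noises the comparison).

# History and adaptation regressions

Epoch-averaged rates (post-choice: [0, 1] s after reward onset; pre-choice:
[-1, 0] s before side-port entry, configurable) are regressed per unit with
ordinary least squares: a five-trials-back win/loss history model (with a
fitted choice coefficient — the printed model omits one, which we treat as
a typographical omission), a current-vs-previous outcome model, a rewarded
volume model, and a reward-prediction-error model
($x_{rpe} = V_{reward} - p\,V_{chosen}$). Coefficients get t-tests, models
an F-test against the intercept; a unit is *adaptive* when both target
coefficients (current outcome/volume and previous outcome) are significant
at $p < 0.05$ with opposite signs, *modulated-non-adaptive* with equal
signs. Opt-out trials are excluded (their outcome coding is undefined);
opt-outs inside the five-trial history are coded 0. Cluster enrichment uses
exact Clopper–Pearson binomial 95% intervals compared across clusters.

# Numerical and design choices

- **Grids.** The model window is $[-2, 6]$ s around trial start (160 bins,
  concatenated across trials; window overlap between adjacent trials is
  accepted, as in the source analysis). Event-aligned analysis grids are
  inclusive of both endpoints (121 bins for $[-2, 4]$). Simulation covers
  $[-2.05, 8.05]$ s so edge bins and choice-aligned windows are observed;
  realigned bins without coverage are treated as missing, never as silent.
- **Smoothing.** All rate smoothing is a centred 250 ms moving average with
  symmetric shrinking windows at the edges.
- **Ties and degenerate input.** k-means restarts are seeded and rows
  canonically ordered; constant PSTH rows are dropped with a warning;
  near-singular cluster covariances get a $10^{-8}$ ridge, clusters smaller
  than dimension + 1 a pseudo-inverse with a warning; zero-variance
  held-out data, empty condition cells and zero-variance RPE raise errors.
- **Randomness.** A single seed fans out to named substreams (session,
  neurons, per-unit spikes, CV, shuffles), so any stage can be reproduced
  in isolation and a rerun with the same configuration is identical.
- **Problem sizes.** The configuration defaults carry the full-scale
  constants (500 CPD shuffles, 500 MI samples, 1000 d' shuffles, 5000 gap
  references, 10000 PAIRS references). The test-suite and acceptance runs
  use reduced sizes chosen for desk-scale runtimes: sessions of 100–400
  trials, 8–10 recovery seeds, 100–300 shuffles, 30–60 reference draws,
  and 10 regime replicates per scale; each reduction is visible in the
  corresponding test file.

# Known limitations

- CPD/MI single-bin significance is anticonservative (see the calibration
  caveat); comparisons should lean on null-subtracted effect sizes and on
  concurrence across metrics.
- The PAIRS neighbour-count rule cannot reproduce the published $k = 3$ for
  an 18-dimensional isotropic reference under any angle convention we
  examined; the conditional-space $k = 8$ reproduces exactly.
- The deposited-data adapter expects the package's own plain-text schema;
  mapping the original archive layout may need a thin conversion step, and
  every check that needs the deposit fails loudly with the DOI rather than
  silently passing.
- Spike persistence uses CSV (long tables of spike times); an HDF5 writer
  is not provided.
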