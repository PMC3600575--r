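---
title: "Single-trial correlated component analysis: model, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trial correlated component analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrcomp)
```

## The model

Let $x_n(t) \in \mathbb{R}^D$ be the multichannel EEG feature vector (here:
instantaneous band power) at epoch latency $t$ of trial $n$, and
$y_n \in \mathbb{R}$ a continuous per-trial behavioral variable such as
reaction time. The package estimates a spatial filter $w \in \mathbb{R}^D$
whose one-dimensional projection

$$z_n(t) = w^\top x_n(t)$$

maximally correlates, across trials, with the behavioral variable. Writing
$X^{(t)} = [x_1(t), \dots, x_N(t)]$ for the trial matrix at one latency, the
estimate maximizes the Pearson correlation between $X^\top w$ and $y$, whose
maximizer has the closed form

$$\hat{w} = (R_{xx} + \lambda I)^{-1} X y,$$

with $R_{xx}$ the channel covariance and $\lambda \ge 0$ an L2 (ridge)
penalty favoring spatially smooth filters. Two regularizers are built in:

* **Temporal augmentation.** Over a short window of $\Delta t$ samples the
  trial matrices are concatenated, $\tilde{X} = [X^{(t)}, \dots,
  X^{(t+\Delta t - 1)}]$, and the response is replicated once per sample
  ($\tilde{y} = 1_{\Delta t} \otimes y$). All window samples then contribute
  jointly to one correlation, and the covariance is estimated from
  $N \Delta t$ columns rather than $N$.
* **Ridge penalty.** $\lambda$ is chosen by nested cross-validation on a
  logarithmic grid scaled by the mean covariance eigenvalue (a scale-free
  parameterization; the default grid spans $10^{-3}$ to $10^{1}$ times that
  eigenvalue).

Derived quantities: the single-trial correlated component (SCC) $z_n(t)$;
the component correlation trace (CCT) $c(t) = \mathrm{cor}(z(t), y)$ per
latency; the correlated component map (trials $\times$ latency, sorted by
response); and the forward model $a = X z / (z^\top z)$, the per-channel
coupling of the component, which — unlike $w$ itself — is interpretable as a
scalp topography.

## Conventions and numerical choices

* **Centering.** Channels and response are mean-centered before the
  covariance and cross-covariance are formed; Pearson correlation presumes
  it. The covariance is normalized by the augmented column count
  $N \Delta t$.
* **Linear solves.** $(R + \lambda I) w = X y$ is solved by Cholesky
  factorization, never an explicit inverse. A near-zero pivot (numerical
  rank deficiency at $\lambda = 0$) falls back to the Moore–Penrose
  pseudoinverse with a warning.
* **Sign and scale.** The closed form always yields a nonnegative training
  correlation ($w^\top X\tilde y = \tilde y^\top X^\top (R+\lambda I)^{-1}
  X \tilde y \ge 0$). Reported weights have unit L2 norm — correlation is
  scale-free — and cross-validated projections use the same unit-norm
  convention so that held-out components from different folds share one
  scale when pooled (without this, fold-specific ridge scalings mix into
  the pooled correlation; the effect is visible in the noiseless limit).
* **Epoch sample convention.** Sample $k$ (0 at the event onset) belongs to
  the window $[t_0, t_1)$ iff $t_0 \le 1000\,k/f_s < t_1$ (half-open), so a
  $(-700, 1000)$ ms epoch at 512 Hz has 870 samples. Windows, baselines and
  scan grids all use the same convention.
* **Undefined correlations** (zero component or response variance) are
  errors or explicit `NA` markers, never silently zero.

## Spectral decomposition

Band power is obtained by convolving each channel/trial signal with complex
Morlet kernels $\phi(t) = \alpha\, e^{2\pi i f t} e^{-t^2/(2\sigma^2)}$ with
$\sigma = \mathrm{cycles}/(2\pi f)$, and squaring the magnitude. Choices:

* $\alpha$ fixes each kernel to unit L2 norm so power is comparable across
  frequencies; kernels are truncated at $3.5\sigma$.
* `cycles = 3` by default: at 10 Hz this gives $\sigma \approx 48$ ms.
  Latency scans with 60 ms windows on a 10 ms grid need temporal resolution
  on that scale; wider kernels (5–7 cycles) smear power over $\pm 100$ ms
  and blur exactly the latency structure the window scan is built to
  resolve. Users interested in finer spectral resolution can raise it.
* The frequency grid steps by 1 Hz inside each closed band; the standard
  bands are theta 5–7, alpha 8–12, beta1 16–22, beta2 23–30, gamma
  31–40 Hz.
* The band dataset collapses power by the maximum over in-band grid
  frequencies and subtracts a baseline mean per channel and latency. The
  baseline mean is computed from the collapsed tensor over a configurable
  baseline trial set (default: all trials of the dataset, since a separate
  encoding phase is not generically available).
* Latencies within $2\sigma$ of an epoch edge are flagged as contaminated,
  not dropped.
* Convolution runs either through the FFT or as a direct banded matrix
  product restricted to the requested output latencies; the two paths agree
  to machine precision and the choice is purely a speed heuristic.

## Window scan, significance, and $\tau$ selection

The scan fits the filter on every window of a grid (default 60 ms duration,
10 ms steps, 0–1000 ms post-stimulus: 95 windows). Performance per window
is the five-fold cross-validated correlation: fit on four folds (with
$\lambda$ chosen by leaving each remaining training fold out in turn —
selection never sees the held-out fold), project held-out trials, average
the component amplitude over the window samples, pool held-out pairs across
folds, and report their Pearson correlation.

Significance per window comes from a permutation test: the response is
shuffled across trials (1000 times by default) and the full cross-validation
— including $\lambda$ reselection, unless `reselect_lambda = FALSE` — is
rerun per permutation. The p-value uses the add-one estimator
$(1 + \#\{r_{null} \ge r_{obs}\})/(1 + n_{perm})$, which cannot be zero.
Benjamini–Hochberg step-up across windows controls the FDR, and the optimal
offset $\tau$ is the FDR-significant window whose correlation is the global
maximum among local maxima of the correlation profile, plateau ties broken
toward the earliest window (earliest neurophysiological onset). Absence of
any significant window is a valid outcome.

Permutations are computationally cheap because the covariance and its
Cholesky factors do not depend on the response: all permutations share one
factorization per fold and $\lambda$, and the remaining work is small
matrix products. Fold assignment and the permutation set are fixed across
windows so windows are comparable, and the entire scan is reproducible
bit-for-bit given a seed.

A practical note on dispersion: pooled cross-validated correlations are
over-dispersed relative to a plain sample correlation of the same $n$ —
fold-fitting noise and per-fold $\lambda$ selection inflate the null
standard deviation by roughly a third over the nominal Fisher
$1/\sqrt{n-3}$, so the nominal 95% Fisher band covers well below 95% of
null replicates (the test suite measures this under a seeded null Monte
Carlo). Inference should therefore rest on the permutation test, which
reproduces that dispersion under the null; Fisher bands are used only as
approximate recovery diagnostics.

## The synthetic generator

No public recordings accompany the method, so validation is end-to-end on
synthetic data with planted ground truth. Each trial is

$$x_n(t) = \sqrt{a}\; s_n(t) + \text{pink noise} + \text{white noise},$$

where $s_n(t)$ is an *ongoing* 10 Hz oscillation whose amplitude envelope
carries the planted structure: inside the planted window (240–300 ms by
default, with 50 ms cosine blends at the edges) the per-trial source power
$P_n$ is drawn jointly with reaction time from a Gaussian copula; outside
it the amplitude is a smooth, RT-independent background fluctuation
(log-sd 0.12, correlation time 100 ms) around the same median. Reaction
times are lognormal (median 600 ms, log-sd 0.2 — typical recognition-task
values) and window power lognormal with log-sd 0.3; higher power
accompanies slower responses when $\rho > 0$. The copula parameter is
calibrated so that the *raw-scale* Pearson correlation between $P_n$ and
RT equals $\rho$ (the lognormal transform would otherwise attenuate it by
one to two percent). The noise is a sum of 16 independent $1/f$-amplitude
sources mixed through smooth random spatial patterns (unit RMS per
channel) plus white sensor noise (SD 0.5).

Because the analysis operates on band power, the stored ground-truth
topography $a$ is the *power-space* coupling (a nonnegative smooth scalp
bump, unit norm) and the signal amplitude is mixed through $\sqrt{a}$; the
forward model recovered from band-power data is then directly comparable
to $a$. Three further choices matter:

* **The source is phase-locked across trials** (one random phase per
  dataset). The band power of a short burst with trial-varying phase is
  phase-dependent — the burst's negative-frequency image leaks through the
  Morlet passband — which would corrupt the planted per-trial power. With
  a common phase the leakage is a common factor across trials and the
  planted power is tracked exactly in the noiseless limit (the test suite
  asserts this limit).
* **The RT-independent background is what localizes the effect.** Windows
  that miss the planted interval measure background power, whose
  correlation with RT is zero by construction, so the correlation profile
  decays off the planted window *regardless of sensor SNR*. Without it,
  any window overlapping the (wavelet-smeared) burst would saturate near
  $\rho$ and the scan could not resolve the latency to the stated
  precision.
* **Source scale 70** (median envelope amplitude, against unit-RMS noise).
  This puts the planted window in a high band-power-SNR regime where
  measured component power tracks $P_n$ nearly losslessly, so recovered
  correlations are interpretable as estimates of $\rho$ (the effect-size
  recovery tests quantify the residual attenuation). It is an idealized
  validation regime, not a claim about typical EEG.

What passing tests on these data do **not** show: robustness to ocular and
movement artifacts, volume-conduction lead fields, multiple interacting
sources, induced (non-phase-locked) responses, non-stationary noise, or
weak-SNR regimes in which measured correlations attenuate substantially
below $\rho$. The generator is a statistical emulation of the method's
data model, not a biophysical head model.

## Validation suite and problem sizes

The test suite asserts, among others: exact agreement of the closed form
with the OLS multiple-correlation oracle at $\lambda = 0$ (100 random
designs, $10^{-8}$); that a Nelder–Mead maximizer over the unit sphere
never beats the closed form by more than $10^{-6}$ (20 designs); forward
model recovery of the planted topography (cosine $\ge 0.95$ in $\ge 90\%$
of 50 seeds at the default conditions); effect-size recovery (held-out
correlation inside the 95% Fisher interval of $\rho \in \{0.2, 0.4, 0.6\}$
at $N = 800$ in $\ge 90\%$ of runs, pooled over 50 seeds per $\rho$ since
per-$\rho$ gates at a 95% interval are dominated by binomial noise);
permutation-test
calibration (type-I error at nominal 0.05 within $[0.03, 0.07]$ over 400
null datasets of 200 trials, 200 permutations, 16 channels); and latency
localization (selected $\tau$ within $\pm 30$ ms of the planted window
start in $\ge 90\%$ of 20 seeds, full 95-window scans with 200
permutations per window). These replicate counts are the package's chosen
problem sizes; they keep the full suite to roughly ten minutes on a
single core while leaving the binomial margins of each threshold intact.

## Known limitations

* A single maximizing component per band/window; no multi-component
  extraction or deflation.
* Channel positions are abstract (a 1-D position index) for the synthetic
  spatial patterns; no scalp-surface interpolation or source localization.
* The permutation test shuffles the response vector as a whole, assuming
  exchangeable trials; serial dependence across trials would require block
  permutations.
* `fdr_select` controls the FDR across windows of one band; bands are
  treated separately, with no joint correction.
* EDF input/output covers the common 16-bit continuous case with one
  sampling rate across signals; BrainVision and EDF+ discontinuous files
  are out of scope.
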