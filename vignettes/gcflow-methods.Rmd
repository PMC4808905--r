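---
title: "Effective connectivity from pre-stimulus epochs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective connectivity from pre-stimulus epochs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gcflow infers directed ("effective") connectivity among a small set of
brain-source signals from short, trial-structured epochs, classifies
single trials by their dominant causal hub, and relates hub identity to
behavioral performance (reaction time, RT). This vignette describes the
models, the tunable parameters and their defaults, the synthetic-data
generator that the test suite uses as ground truth, and the numerical
and design choices made where the procedure left room.

## The MVAR / Granger-causality model

Each epoch is a matrix of $n$ channels by $T$ samples (defaults: six
labelled cortical regions — ACC, MCC, lSMC, rSMC, PCC, ESC — at 250 Hz,
$T = 250$, i.e. the 1-s window preceding each stimulus). After removing
the per-channel temporal mean and least-squares linear trend
(`preprocess_epoch()`), the multichannel signal is modelled as a
stationary vector autoregression of order $p$:

$$x_t = \sum_{k=1}^{p} A_k x_{t-k} + \epsilon_t, \qquad
  \epsilon_t \sim N(0, \Sigma).$$

Coefficients are estimated by ordinary least squares without an
intercept (the data are centered). Short epochs are pooled by *ensemble
fitting*: the lagged regressor blocks are built within each trial and
concatenated, so no lag ever crosses a trial boundary. The order $p$ is
chosen once per session by the multivariate BIC
$\ln\det\hat\Sigma_p + (\ln N / N)\,p\,n^2$ evaluated on a common
effective sample (all regressions start at $p_{max}+1$), with ties
broken toward the smaller order; a common order keeps single-trial
causality values comparable within a session.

Fitted models are validated three ways: Ljung–Box whiteness of each
residual channel (lags $\min(20, N/5)$, Bonferroni-combined overall p;
on ensemble fits the test runs per trial and is Fisher-combined across
trials within each channel, because a portmanteau pooled over tens of
thousands of concatenated residuals has enough power to flag the
$O(1/T)$ autocorrelation that per-trial detrending necessarily leaves
even in a correctly specified model),
a percentage-consistency score comparing the covariance structure of
one model simulation at matched length against the observed data
($100\,(1 - \|C_{sim}-C_{obs}\|_F/\|C_{obs}\|_F)$; values above ~80%
indicate the model reproduces the second-order structure), and
stability via the companion-matrix spectral radius. The consistency
simulation uses a fixed internal seed so validation reports are
reproducible.

Conditional Granger causality from source $j$ to target $i$ is the log
ratio of residual variances between the *restricted* model (all
channels except $j$) and the *unrestricted* model (all channels):

$$F_{j \to i} = \ln \frac{\operatorname{var}(\epsilon_i^{(restricted)})}
                         {\operatorname{var}(\epsilon_i^{(full)})}.$$

Both models share the same order $p$, and both variances use the same
divisor ($N-1$, the unbiased sample variance of the residuals), so the
ratio is convention-consistent and, because the restricted regressor
set is nested in the full one, non-negative up to numerical roundoff
(values within $10^{-10}$ below zero are clipped to zero and counted).
Conditioning on the remaining $n-2$ channels removes influences that
are merely mediated by third regions: in a chain
$X_3 \to X_2 \to X_1$, the pairwise magnitude $F_{3\to1}$ is positive
while the conditional one vanishes. All $n(n-1)$ ordered pairs are
computed from one pooled Gram matrix; per-entry failures (e.g. a
duplicated channel making the regression collinear) are reported as
`NA` entries rather than aborting the matrix.

## Surrogate significance and group statistics

Edge significance is assessed against a null of zero connectivity built
by phase randomization: each channel's Fourier amplitudes are kept
exactly while its phases are replaced by independent uniform draws
(conjugate-symmetric, DC and Nyquist handled so the inverse transform
is real). Randomizing each channel independently destroys cross-channel
dependence but preserves each channel's spectrum and autocorrelation.
The defaults are the protocol's constants: 2000 surrogates per session
and FDR-adjusted $\alpha = 0.01$. Each edge's p-value uses the add-one
permutation estimator $p = (1 + \#\{F^{null} \ge F^{obs}\})/(N_s+1)$,
which is bounded below by $1/(N_s+1)$ and avoids p = 0; the
Benjamini–Hochberg procedure is applied across the 30 off-diagonal
edges. The surrogate schedule is deterministic: one RNG stream seeded
from the master seed, phases drawn in a fixed chunked order, so the
entire null distribution is reproducible bit-for-bit.

Group statistics follow the same conventions as the session stage:
P(edge) is the proportion of sessions marking an edge significant, with
an inclusive consensus threshold of 0.9; paired condition differences
per edge use the exact binomial McNemar test
($p = 2 P(\mathrm{Bin}(b+c, 1/2) \le \min(b,c))$, capped at 1, p = 1 by
convention when $b+c=0$) because ten paired sessions is far too small
for the chi-square approximation, followed by BH-FDR across edges.

## Single-trial analysis

Single trials are tested with the same surrogate machinery at lighter
settings (200 surrogates, $\alpha = 0.05$ — the per-trial protocol is
not fixed by the session-level constants, so these are package defaults
and overridable). A trial's *causal hub* is the region with the highest
out-degree; any tie for the maximum, including the empty graph,
discards the trial. With 200 surrogates and BH across 30 edges, a trial
needs at least three floor-level p-values for any edge to survive,
which in practice means trials generated without coupling are almost
never falsely classified.

Hub percentages are tabulated per subject and condition. The shipped
default keeps tie-discarded trials in the denominator (percentages are
of all trials); a `denominator = "classified"` switch restricts to
classified trials, since the protocol wording supports both readings.
The feedback-by-region interaction is tested by a 2x2 within-subject
ANOVA computed directly as the squared paired-t statistic on the
per-subject double difference — algebraically identical to the
classical repeated-measures interaction F with $(1, n-1)$ df, and
cross-checked against an independent implementation in the tests.

RT comparisons aggregate to per-subject median RT per hub group before
a paired Wilcoxon signed-rank test across subjects (trials within a
subject are not exchangeable units), BH-adjusted over the family of
comparisons. RT-sorted out-degree dynamics normalize each trial's
out-degrees by the total number of significant outflow links, stack
them in ascending-RT order, and smooth with a central moving average
whose window is 10% of the trial count (step 1 trial). Edges of the
sorted axis use symmetric truncation — the window shrinks near the ends
rather than zero-padding — to avoid artificial attenuation of the
fastest and slowest trials. Per-position differences between two
regions' traces are tested with a Wilcoxon test on the raw
within-window values and BH-adjusted across positions.

## Spectral stage

Welch log-power spectra of single-channel 1-s epochs use 128-sample
Hann-windowed segments at 50% overlap (two segments per 250-sample
epoch; the overlap is not fixed by the protocol and is configurable),
zero-padded to 256 points, averaged, one-sided density scaling, and
dB conversion ($10\log_{10}$). The bin spacing is $250/256 \approx
0.977$ Hz. The reported band is 0.98–30.3 Hz with bin centers compared
at two-decimal precision; this yields **31** bins (0.98, 1.95, …,
30.27 Hz). The quoted band endpoints are mutually inconsistent with a
30-bin count at this spacing, so the implementation reports every bin
whose (rounded) center lies in the band and documents the count rather
than silently dropping an endpoint.

The RT-sorted spectral image stacks per-trial spectra in ascending-RT
order and subtracts the mean dB spectrum of the trials whose RT lies
strictly below the 10th percentile. If ties leave that set empty the
single fastest trial is used (with a warning). By construction the
baseline rows average to exactly 0 dB in every bin.

## The synthetic-data generator

No recorded source activations ship with the package, so validation
rests on a generator that emulates the study design with planted ground
truth. Regimes are stationary VAR(2) processes over the six regions;
two hub templates mirror the study's group networks: `"PCC-hub"`
(PCC sends to MCC, both SMCs and ESC; ACC to PCC and lSMC; MCC
bidirectional with PCC and ESC — 9 directed edges, PCC the out-degree
maximum) and `"MCC-hub"` (MCC bidirectional with all five other
regions), plus a `"null"` regime of independent AR(2) channels. The
coupling magnitudes are not published; the shipped defaults — 0.3 per
directed edge at lag 1, self-dynamics 0.4 (lag 1) and -0.25 (lag 2),
unit innovation variance — were chosen once as a moderate
signal-to-noise operating point that keeps every template comfortably
stationary (spectral radii 0.50, 0.73, 0.50), and are placeholders for
the unknown real effect sizes, not estimates of them. Reaction times
are lognormal (right-skewed, as empirical RT distributions are) with
per-regime medians 1.0 s (MCC-hub), 1.3 s (PCC-hub), 1.15 s (null) and
sdlog 0.3; the default condition mixtures lean PCC-ward under `"K+"`
(.255/.319/.426) and MCC-ward under `"K-"` (.349/.231/.420), mirroring
the reported hub-percentage pattern. Oscillatory components add a
sinusoid with uniform random per-trial phase (avoiding phase-locked
artifacts in Welch averaging), optionally with amplitude growing
linearly in RT to exercise the spectral stage.

Every trial records its regime and a per-trial seed, so any trial can
be re-simulated in isolation; scenario builds are bit-reproducible
under the master seed. Burn-in defaults to $10\,p\,n$ samples.
Innovations are Gaussian, matching the OLS variance-ratio framework.

What the generator does *not* emulate: volume conduction and ICA
unmixing errors, non-Gaussian or nonstationary noise, regime switching
within a trial, and 1/f background spectra. Passing tests therefore
demonstrate that the pipeline recovers what it models, not that real
recordings satisfy those assumptions.

## Problem sizes in tests and scripts

The validation suite runs at reduced but statistically meaningful
sizes chosen as package defaults for desk-scale reproduction: null
calibration uses 200 replicate single-epoch sessions at the full 2000
surrogates; planted-network recovery uses 20 sessions of 100 trials
with 500 surrogates (recovery is already exact at this scale); the
mixture-recovery study uses 2000 trials at the per-trial defaults; the
RT study uses 10 subjects x 30 trials over 3 seeds; the analysis
scripts demonstrate the full workflow at 4 subjects x 40 trials. The
oracle comparisons (closed-form bivariate causality via the discrete
Lyapunov equation, exhaustive McNemar/signed-rank/BH enumerations,
direct-DFT periodograms, direct-loop moving averages) are computed
independently of the implementation paths they check.

## Known limitations

* GC magnitudes are in-sample log variance ratios; they are biased
  upward at small $N$ (the surrogate null carries the same bias, so
  significance calibration is unaffected, but magnitudes should not be
  compared across very different $N$).
* Single-trial classification depends on the per-trial surrogate count
  and alpha; with very low counts the BH floor makes small networks
  undetectable by construction.
* The exact McNemar test is conservative for small discordance counts;
  with 10 sessions only fairly large condition effects can reach
  q < 0.05 after FDR across 30 edges.
* The consistency percentage uses a single matched-length simulation;
  it is a diagnostic, not a test statistic, and is reported without an
  enforcement threshold.
* Sessions whose trials mix several hub regimes violate the
  single-process assumption of the pooled session fit: the whiteness
  test then rejects (correctly — no one MVAR model fits all trials) and
  the session network approaches the union of the regime networks. The
  single-trial stage is the tool that resolves the mixture; the
  session stage characterizes the aggregate.
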