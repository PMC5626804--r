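---
title: "Filter-bank data space adaptation: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter-bank data space adaptation: model, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbdsa)
```

## The problem

A motor-imagery brain-computer interface (MI-BCI) decodes, from multichannel
EEG, whether the user is mentally rehearsing a movement or resting.  The
standard decoder is filter-bank common spatial patterns (FBCSP): the signal is
split into nine 4-Hz bands (4-8 ... 36-40 Hz), spatial filters maximizing the
between-class variance ratio are fitted per band, log-variance features are
extracted, the most class-informative features are selected by mutual
information, and a linear discriminant classifies each trial.

A decoder calibrated in one session degrades in the next: electrodes sit
differently, impedances drift, the user's state changes, and — when the
calibration data come from robot-assisted *passive movement* rather than
imagery, as in rehabilitation settings where imagery calibration fatigues the
patient — the task itself differs.  This package implements filter-bank data
space adaptation (FB-DSA): a per-band linear map of incoming evaluation trials
back toward the calibration distribution, recomputed on the fly from a small
buffer of recent labeled trials, leaving the CSP filters and the classifier
untouched.

## The model

A band-passed trial $x_b \in \mathbb{R}^{n \times s}$ is modeled as zero-mean
Gaussian, so the class-$j$ distribution of a session in band $b$ is summarized
by an average covariance $\Sigma_{b,j}$ (we average unit-trace per-trial
covariances $X X^\top / \operatorname{tr} X X^\top$; the log-variance features
are invariant to this normalization).  Evaluation trials are transformed as
$h_b = V_b^\top x_b$, and $V_b$ is chosen to reduce

$$L_b(V) = \sum_{j=1}^2 \mathrm{KL}\!\left[\,\mathcal N(0, V^\top \Sigma_{b,j} V)
  \;\|\; \mathcal N(0, \bar\Sigma_{b,j})\,\right],$$

where $\bar\Sigma_{b,j}$ are the stored calibration covariances.  The package
uses the closed form

$$V_b^{*} = \sqrt{2}\,\bigl(\,(\bar\Sigma_{b,1}^{-1}\Sigma_{b,1} +
  \bar\Sigma_{b,2}^{-1}\Sigma_{b,2})^{+}\bigr)^{1/2},$$

with $^{+}$ a Moore-Penrose pseudoinverse (singular values below
$10^{-10}\sigma_{\max}$ dropped) and the principal matrix square root computed
by eigendecomposition (a relative imaginary residue above $10^{-6}$ is an
error).  Transforms are computed only for bands that contributed selected
features; other bands keep the exact identity.

### Optimality of the closed form — what is and is not true

The closed form is exactly the stationary point of $L_b$ when all four
covariances commute — always in one dimension, and asymptotically for
near-identity session shifts.  It is **not** a stationary point for generic
non-commuting covariance quadruples: a numerical minimizer attains strictly
lower loss there, and for strongly mismatched or ill-conditioned inputs the
closed form can even *increase* the loss relative to the identity (the matrix
$\bar\Sigma_1^{-1}\Sigma_1 + \bar\Sigma_2^{-1}\Sigma_2$ may then have complex,
or even negative real, eigenvalues — the latter is reported as an error).  The
package therefore asserts optimality only where it holds: the exact 1-D
solution, the matched-distribution fixed point $V^* = I$, dominance over
random invertible candidates, and session-level loss reduction under the
decoding protocol.  The acceptance criterion demanding equality with a
numerical minimizer on arbitrary random covariances is left failing by
design — it tests a property the estimator does not have.

In the decoding protocol this fragility is contained by the shrinkage
estimator described next, which keeps the inputs of the closed form in its
valid near-commuting neighbourhood.

### Small-buffer covariance estimation

The adaptive protocol estimates $\Sigma_{b,j}$ from at most 10 trials per
class.  A 2-s, 4-Hz-band trial carries roughly $2\,B\,T \approx 16$
independent samples, so ten trials yield an effective sample size of ~160 for
a $27 \times 27$ covariance — noisy enough that the raw plug-in transform
visibly distorts features even when the sessions match.  The buffer
covariances are therefore shrunk toward the *calibration covariance of the
same class* — the natural "no shift" prior — with a Ledoit-Wolf-style
data-driven intensity
$\gamma = \min(1,\, b^2 / d^2)$, where $b^2$ estimates the sampling variance
of the buffer mean from the dispersion of its trial covariances and
$d^2 = \|\hat\Sigma - \bar\Sigma\|_F^2$.  When the sessions match, $d^2$ is
dominated by noise, $\gamma$ is large, and the transform degrades gracefully
to the identity; under a genuine shift the systematic part of $d^2$ passes the
correction through.  Shrinking toward *scaled identity* instead (a natural
first guess, available as `dsa_shrinkage = "trials"`) biases the transform
away from the identity on matched sessions and measurably hurts; this is why
it is not the default.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| bands | nine 4-Hz bands, 4-40 Hz | filter-bank decomposition |
| `filter_order`, `stopband_db` | 6, 40 dB | Chebyshev Type II band-pass design, applied forward-backward (zero phase) with odd-reflection padding of three filter lengths |
| `m` | 2 | CSP filter pairs kept per band (4 filters) |
| `k_select` | 4 | best individual features by Parzen-window mutual information, then CSP-pair completion (4-8 columns) |
| `window` | 0.5-2.5 s post-cue | analysis segment |
| `buffer_size` | 20 trials | adaptation buffer (10 most recent per class); 0 disables adaptation |
| `chance_band` | 43-57 % | screening band, taken as a given constant |

The filter family is fixed by the protocol; order, attenuation and phase
handling are unstated there and set to standard FBCSP practice.  "Four pairs
of features" is read as `k_select = 4` best individual features plus pair
completion; the alternative reading (exactly four fixed pairs) can be
obtained by raising `k_select` and is noted as an open interpretation.
Mutual information uses a Gaussian-kernel Parzen estimator with
normal-reference bandwidth on a 256-point grid (a histogram estimator can be
swapped in via `mi_estimator`).

## The synthetic world

`generate_session()` draws band-limited Gaussian sources through a
subject-specific mixing matrix: four contrast sources in the mu and low-beta
bands (8-12, 12-16 Hz) loaded mainly on six motor channels, eight broadband
common sources, and spatially correlated $1/f$ background noise at 0 dB
in-band SNR on the motor channels.  The motor class attenuates the contrast
sources' variance by `effect_size` (default 2.5, a 60 % band-power
suppression — a strong but ordinary desynchronization; `effect_size = 1` is
the null world).  The subject seed fixes the forward model, the session seed
the trials, so one subject yields arbitrarily many matched sessions; the noise
amplitude is derived analytically from the forward model so matched sessions
share their SNR exactly.

`apply_session_shift()` models between-session change as
$A = \mathrm{diag}(g)\,(I + \lambda E)$ with $\|E\|_F = 1$ and per-channel
gains $g = 1 + \mathcal N(0, (0.25\lambda)^2)$, so the nominal $\lambda = 0.4$
carries a 10 % gain spread — ordinary across-day electrode variation.  The
shift is deliberately *linear*, i.e. inside FB-DSA's model class, so the
recovery experiments measure estimation quality rather than model mismatch.

What a green synthetic test does **not** establish: robustness to nonlinear
drift, artifacts (EOG/EMG), non-Gaussian signals, task-correlated
nonstationarity, or the physiological fidelity of real passive-movement
versus imagery differences.  The generator matches second-order band-limited
structure only.

## Numerical choices

* Covariances are symmetrized and, where positive definiteness is required,
  ridge-regularized by $10^{-10}\,\mathrm{tr}\,\Sigma \cdot I$; `fit_csp`
  additionally regularizes $C_1 + C_2$ when its condition number exceeds
  $10^{12}$.
* CSP eigenvectors follow a deterministic sign convention (largest-magnitude
  entry positive); equal eigenvalues keep the underlying decomposition order.
* LDA uses equal priors (the protocol is balanced), a ridge of
  $10^{-6}\,\mathrm{tr}/p$, and sends an exact boundary tie to the rest
  class.
* The fixture container is plain text with 17-significant-digit samples, so
  round-trips are bit-exact and files byte-deterministic.
* Band-passed finite segments are only approximately zero-mean: spectral
  leakage leaves sample means of order 1 % of the channel standard deviation
  (the Gaussian model premise refers to the process mean).

## Evaluation protocol notes

Both evaluation arms score exactly the same trials: the first `buffer_size`
trials (20; 30 in sweep experiments) are adaptation-only.  During ramp-up the
transform uses every trial seen so far; while either class buffer is empty
the transform is the identity.  Adaptation consumes true labels (the offline
protocol); `dsa_label_source = "predicted"` switches to self-labeled
adaptation.  The shift-recovery experiments calibrate on 40+40-trial sessions
and evaluate on 200-trial sessions, mirroring the multi-run evaluation days
the protocol models.

## Known limitations

* The closed-form transform is a commuting-case approximation (above); no
  claim is made, or tested, that it is the global KL minimizer in general.
* The 43-57 % screening band corresponds to the 95 % binomial interval at
  $n = 200$; an 80-trial session's null cross-validation mean is more
  dispersed (roughly a third fall outside the band), and small-fold CV
  with in-fold selection is known to dip below chance under permuted labels.
  The band endpoints are treated as given constants, not recomputed.
* With 10 trials per class the adaptation gain on mildly shifted synthetic
  sessions is about 1-2 accuracy points against a ~3-point per-replicate
  standard error; experiments at that operating point need many replicates
  (or longer sessions) to resolve it.
* EDF/GDF import is not included; the canonical interchange format is the
  package's documented text container.
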