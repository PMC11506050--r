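---
title: "Methods: phase synchronization between infra-slow EEG and electrodermal arousal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase synchronization between infra-slow EEG and electrodermal arousal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question and the statistic

Tonic skin conductance (GSR) fluctuates at infra-slow frequencies
(0.01-0.1 Hz), and so does scalp EEG ("infra-slow activity", ISA). If central
and autonomic arousal regulation are globally organized, the *phases* of
these two oscillations should keep a stable relationship over time. This
package quantifies that relationship and compares it between two groups
(experienced meditators, "Expert", and controls, "Novice").

For one channel, one frequency band and one participant, let
$\theta_{EEG}(t)$ and $\theta_{GSR}(t)$ be the instantaneous phases of the
band-limited EEG and GSR. The core statistic is the time-averaged complex
exponential of their difference,

$$\Delta\Theta = \frac{1}{T}\sum_{t=1}^{T}
  e^{\,i\,(\theta_{EEG}(t)-\theta_{GSR}(t))} ,$$

whose modulus $PSI = |\Delta\Theta| \in [0,1]$ is the phase synchronization
index (1 = perfectly constant phase difference) and whose argument
$mPD = \arg\Delta\Theta$ is the mean phase difference. Everything downstream
is built from these two numbers:

* **Per-channel significance.** 10,000 surrogates shuffle the *time indices*
  of $\theta_{GSR}$, preserving both marginal phase distributions while
  destroying the temporal pairing. The add-one permutation p-value
  $(1+\#\{\widehat{PSI}\ge PSI\})/(1+N)$ avoids $p=0$; significance demands
  that the observed PSI strictly exceed the 95th surrogate percentile.
* **mPD-PSI coupling.** Pooling (mPD, PSI) pairs over channels and
  participants of a group, the mPD axis is split into 16 equal segments of
  $(-\pi,\pi]$; per-segment average PSI, normalized to sum to one, is treated
  as a distribution $P_{PSI}$ and scored by its KL divergence from uniform
  (natural log; empty segments contribute average 0, with $0\log 0 := 0$).
  Surrogates permute the PSI values against the fixed mPD multiset. This is
  the classic phase-amplitude modulation-index construction with mPD playing
  the role of phase and PSI of amplitude.
* **Topography.** Per channel, the participant-mean of the complex
  $\Delta\Theta_k$ gives the grand-mean phase difference (gmPD). Separately,
  functional connectivity (Pearson correlation of band-passed EEG, negatives
  clipped to zero) is averaged across a group's participants and embedded by
  a diffusion map ($\alpha = 0.5$); the first non-trivial eigenvector, scaled
  by $\lambda/(1-\lambda)$ (diffusion time 0), is the principal gradient.
  $|gmPD|$ (non-circular, unlike gmPD itself) is regressed on the gradient
  across channels by ordinary least squares.
* **Group statistics.** One-tailed Wilcoxon rank-sum tests (Expert > Novice)
  on pooled (participant x channel) PSI values per band, Benjamini-Hochberg
  FDR over bands, Cohen's d with pooled (n-1) SD, per-channel tests at
  $\alpha=0.05$, and a demographic filter that drops female participants
  older than 38 years (gender-balance / perimenopausal-GSR rationale).

Pooling participant x channel values (e.g. 12 x 64 = 768 per group and band)
ignores within-participant dependence; that is a property of the design this
package reproduces deliberately, not an oversight to be "fixed".

## Preprocessing

Per session and channel, in order:

1. **Detrend**: remove the least-squares line (slow electrode drift).
2. **Downsample to 8 Hz**: Hamming-window FIR low-pass, cutoff
   $0.4\,f_{out}$, applied forward-backward, then decimation. An FIR
   anti-alias filter is used rather than a high-order IIR because a
   Butterworth of effective order 8 at a normalized cutoff of ~0.0125 is
   numerically fragile in transfer-function form, while the linear-phase FIR
   is unconditionally stable and exactly zero-phase.
3. **Surface Laplacian (EEG only)**: spherical-spline current source density
   (Perrin-type), flexibility $m=4$, smoothing $\lambda=10^{-5}$, Legendre
   series truncated at order 50 (the conventional toolbox truncation), with
   the sum-to-zero spline constraint. The operator annihilates spatially
   constant fields and is invariant to per-sample reference offsets.
4. **Band-pass**: zero-phase (forward-backward) Hamming-window FIR. Band $b$
   spans $[f_b, f_b+0.01]$ Hz for the ten nominal frequencies
   $f_b = 0.01,\dots,0.10$ Hz; the lower-edge convention matches the usual
   "0.03~0.04 Hz" band labeling, and centered bands remain available through
   the band-edge arguments. The default transition width is 0.005 Hz, giving
   $\lceil 3.3 f_s/\Delta f\rceil \approx 5280$ taps at 8 Hz; phase analysis
   justifies the expense, since forward-backward application makes the phase
   response exactly zero.
5. **Hilbert phase**: argument of the FFT-constructed analytic signal,
   wrapped to $(-\pi,\pi]$.

One full filter length at each session edge is marked invalid and excluded
from all statistics (filter and Hilbert transients); sessions are
preprocessed independently and their valid samples concatenated before
$\Delta\Theta$, so $T$ counts valid samples only. Detrending is per session.

## The synthetic cohort generator

Real recordings for this design are not redistributable at desk scale, so the
package is validated against a generator with known ground truth. The GSR is
a sum of unit-amplitude band oscillations $\cos\phi_b(t)$, where $\phi_b$
advances at $2\pi f_b$ plus a small random walk (0.01 rad/$\sqrt{s}$), plus
white noise. EEG channel $c$ carries the same oscillations shifted by a
ground-truth lag $\delta_c$ and by von Mises phase jitter
$\varepsilon \sim vM(0,\kappa)$, plus white noise (SD 0.5 relative to unit
oscillation amplitude) and a linear drift (each channel's slope uniform in
$\pm$0.02 units/s). Because the jitter is i.i.d. von Mises, the estimated PSI
has the closed-form limit $I_1(\kappa)/I_0(\kappa)$ — the package's main
recovery surface.

Two design points deserve emphasis:

* **Jitter epochs.** A 0.01-Hz-wide band-pass averages on a ~100 s timescale,
  so per-sample i.i.d. jitter would be filtered away and every channel would
  emerge with PSI ~ 1 regardless of $\kappa$. The generator therefore redraws
  the jitter i.i.d. per *epoch* of `jitter_dt = 90` s — slow enough to
  survive the filter, frequent enough (~45 epochs across the default two
  45-minute sessions) for the coupling test to have power at small cohort
  sizes. The exact i.i.d.-per-sample regime, where the Bessel-ratio algebra
  is exact, is exposed separately as `sample_phase_pairs()` and is what the
  closed-form recovery and calibration checks use.
* **Concentration tied to lag.** The default lag map forms two spatial
  clusters ($\delta=0$ on the outer ring, $\delta=\pi$ near the vertex, a
  thin belt of intermediate lags between), and the Expert group's per-channel
  concentration is $\kappa_c = \kappa_E |\cos\delta_c|^2$ while the Novice
  group's is uniform ($\kappa_N$, exponent 0). With a single group-wide
  $\kappa$ and exact two-valued lags, pooled PSI would be independent of the
  mPD segment and the coupling statistic would have no signal at all; tying
  synchronization strength to in-phase/antiphase lags reproduces the
  empirical pattern this statistic was designed to detect (high PSI
  concentrated at mPD near 0 and $\pi$ in experts, no such tendency in
  novices) while keeping the Novice group an honest null.

Defaults emulate the study conditions: 12 + 12 participants (Expert 3 female,
Novice 10 female; ages drawn from N(39.3, 12.0) and N(45.0, 14.8) years),
64 channels at 256 Hz on a spherical-Fibonacci cap, two 45-minute sessions
(session counts and durations were not fixed by the study design, which
reported 45-90 minutes, so they are configurable), $\kappa_E = 4$,
$\kappa_N = 1$, ten bands. A fast-test mode generates directly at 8 Hz,
skipping decimation, to keep unit tests inside seconds.

**What the generator does not emulate**: volume conduction (signals are
generated directly as source-like fields, so the surface Laplacian has
nothing to deconvolve — applied to these rank-one-per-band spatial patterns
it remixes and sign-flips channels, which is why the synthetic validation
configuration disables it and the Laplacian is instead validated against an
independent dense spline solve), ocular/muscle artifacts (the emulated
analysis applies none beyond detrending), amplitude-arousal coupling (the
method is phase-only), and 1/f background spectra. Passing tests therefore
demonstrate correctness of the estimators and their calibration under the
stated phase model, not robustness to every artifact of real scalp data.

## Numerical choices

* Natural logarithm in the KL statistic; any base rescales observed and
  surrogate values identically, so p-values are base-invariant.
* Coupling significance is reported against both the 0.001 level (the level
  at which group coupling profiles are judged) and 0.05; segment
  $m$ covers $[-\pi+(m-1)\pi/8, -\pi+m\pi/8)$ with $\pi$ assigned to segment
  16.
* Rank-sum tests use exact enumeration when both groups have at most 10
  untied observations, otherwise the normal approximation with tie and
  continuity corrections (`stats::wilcox.test` in both regimes).
* The gradient's sign is arbitrary; for reporting it is oriented to
  correlate positively with $|gmPD|$, and every statistic used is
  sign-invariant.
* The spatial-null control for the $|gmPD|$-gradient regression is the
  *mean* $R^2$ over 100 channel permutations rather than a single shuffle: a
  single 16-channel permutation has roughly a 10% chance of exceeding
  $R^2 = 0.2$ by luck, whereas the null mean is stable.
* Degenerate inputs fail loudly with classed conditions: all-zero signals
  (undefined phase), duplicate electrodes (singular spline), disconnected
  connectivity graphs, rank-one affinity matrices (no non-trivial diffusion
  mode), zero-variance channels, constant gradients, and empty surrogate
  ensembles.
* All randomness flows from one master seed through named substreams, so
  identical configurations reproduce every output byte-for-byte.

## Problem sizes used in validation

The acceptance analyses run a scaled-down study — 6 + 6 participants, 16
channels, two bands (0.03 and 0.08 Hz), two 45-minute sessions at the 8-Hz
fast-test rate, 10,000 coupling surrogates — chosen so the full suite
completes on a single CPU in minutes while every qualitative contrast of the
full design (group PSI difference, expert-only coupling, expert-only
gmPD-gradient alignment) remains recoverable. Closed-form PSI recovery uses
$T = 2000$ phase samples per pair; permutation-test calibration uses 2000
random-phase pairs with 500 surrogates each.

## Known limitations

* The pooled group tests inherit the design's independence assumption across
  channels of one participant.
* EDF export quantizes to 16 bits over each channel's range; round-trip
  error is below one quantization step but not zero.
* The BDF reader covers continuous BioSemi-style files with a uniform
  sampling rate; annotations and discontinuous records are out of scope.
* Phase tensors are exchanged in memory (or as RDS at run time); no HDF5
  container is produced.
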