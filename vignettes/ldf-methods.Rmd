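---
title: "Simulating and processing laser Doppler flowmetry signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and processing laser Doppler flowmetry signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldfsim)
```

## The measurement

Laser Doppler flowmetry (LDF) points a coherent beam at perfused tissue and
detects the backscattered light on a single photodiode. Light scattered by
moving red blood cells is Doppler-shifted; beating against the unshifted
reference light it produces an AC photocurrent whose one-sided power
spectral density $P(f)$ carries the velocity distribution of the moving
scatterers. Three quantities summarise each analysis frame:

* **DC** — the mean photodetector output, proportional to total collected
  light intensity;
* **Vel** $= \sum_f f\,S(f) \big/ \sum_f S(f)$ — the first moment of the
  noise-subtracted spectrum $S(f) = \max(P(f) - N, 0)$ over the analysis
  band, in Hz, proportional to mean scatterer speed;
* **Vol** $= \Delta f \sum_f S(f) \big/ \mathrm{DC}^2$ — the DC²-normalised
  in-band spectral power, proportional to the concentration of moving
  scatterers in the probed volume.

The noise floor $N$ is the mean raw power over bins above 4 kHz, where no
physiological Doppler power is expected. The digital path uses a sampling
rate of 14336 Hz with 1024-sample frames: exactly 14 spectra per second with
a power-of-two FFT and a 14 Hz bin width, and a Nyquist frequency (7168 Hz)
above the 5 kHz maximum Doppler shift of interest. The analysis band is
bins 2–358, i.e. 28–5012 Hz: bin 1 (14 Hz) is dominated by DC leakage, and
28 Hz is the bin edge closest to the instrument's nominal 30 Hz cut-on.

Two quality flags accompany every sample. A frame passes the *spectral*
criterion when its mean raw power between 400 and 500 Hz exceeds the noise
floor — a band high enough to be clear of tissue-motion artefact and low
enough to carry genuine Doppler power whenever scatterers move. A frame is
*DC-stable* when its DC lies within 10% of the running median of the
trailing 10 s of DC history; DC jumps indicate eye or probe movement.

## Scene models and their ground truth

The synthesizer (`scene_*()`, `synthesize_record()`) generates records from
four parametric scenes, each with an analytic one-sided spectral shape:

| scene | spectrum | captures |
|---|---|---|
| `wheel` | Gaussian line at $k_{cal} v$, SD $\sigma_0 + c_b v$ | rotating solid surface; narrowband Doppler line |
| `capillary` | flat on $[0, 2 k_{cal} v]$, smoothed by a $\sigma_0$ kernel | laminar (Poiseuille) flow: scatterer speeds uniform on $[0, 2v]$ |
| `artery` | truncated exponential $e^{-f/\tau}$ | broadband arterial spectrum, power to 3–4 kHz |
| `onh` | Lorentzian (tissue, weight 0.6) + exponential (capillary blood) | optic nerve head: low-frequency, tissue-scattering dominated |

The calibration constant defaults to $k_{cal} = 651/24 \approx 27.1$
Hz/(mm/s): it equates the arterial baseline first moment (651 Hz) with the
accepted red-blood-cell speed in rat retinal arteries (24 mm/s). It is a
documented, overridable calibration, not a physical constant.

For artery and ONH scenes the free rate parameter is solved so that the
**band-limited first moment** of the shape equals a requested target. That
band-limited moment — computed by numerical quadrature at generation time,
never by the processing chain under test — is the record's embedded ground
truth `vel_true`, and all recovery tests compare pipeline output against it.
For the exponential the moment is strictly increasing in $\tau$ (from the
band's lower edge to the band midpoint in the flat limit), so bisection
applies directly. The ONH mixture needs more care: the Lorentzian's $1/f^2$
tail keeps band-limited mass long after the exponential term has decayed
below the band, so the moment is *not* monotone in the common width scale —
it has an attainable minimum near 70 Hz for the default mixture. The solver
therefore scans a cached log-grid of scales, brackets the target on the
broadest-spectrum branch and refines by root finding; targets below the
attainable minimum are clamped to it and flagged, a rare event that matters
only for extreme cohort draws.

Synthesis is by frequency-domain shaping: every record-resolution frequency
bin receives amplitude $\sqrt{2\,P(f)\,\delta f}$ and an independent uniform
phase, Hermitian symmetry is imposed and an inverse FFT returns the time
series; white detector noise (default one-sided PSD $10^{-8}$ V²/Hz) and the
scene DC level are added. This construction fixes the signal's sample
variance at exactly the target power (Parseval), makes every record a pure
function of `(scene, duration, seed)`, and its frames behave like a
stationary Gaussian process at the 1024-sample frame scale. A wheel line
narrower than the record's frequency resolution degenerates into a pure
cosine at the Doppler shift, which is the correct $\sigma_0 \to 0$ limit.

Scene defaults are chosen to match the bench data the instrument printed:
wheel modulation depth 0.232 and DC 0.359 V, capillary 0.258 and 0.338 V —
with these, the measured Vol (which equals the in-band fraction of the
modulation depth) reproduces the published constants. The in-vivo modulation
depths (artery 0.20, ONH 0.15 at DC 0.35 V) are not printed anywhere and are
set to values that give the realistic strong in-band signal-to-noise the
published spectra show; none of the validation quantities depends on them
beyond requiring adequate SNR.

## Cohorts: between-rat and within-rat variance

`cohort_params()` describes a population of rats at one site. The published
calibration anchors the marginals: artery 651 ± 76 Hz (n = 12), ONH
369 ± 138 Hz (n = 16), the ± being the between-rat SD. The within-rat
components are not printed directly; they are derived from the published
repeatability ICCs by inverting
$\mathrm{ICC} = \sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$ at each timescale
(`calibrate_variance_components()`):

* inter-session ICC 0.82 / 0.87 → `sd_session` ≈ 35.6 / 53.3 Hz,
* intra-session ICC 0.40 / 0.60 → `sd_minute` ≈ 102.8 / 120.8 Hz,
* inter-day ICC 0.79 / 0.70 → `sd_reposition` ≈ 16.3 / 72.9 Hz
  (an extra beam-repositioning offset applied on later measurement days).

Minute-scale fluctuation is modelled as an AR(1) series (lag-1 correlation
0.5 per minute — slow physiological drift rather than white noise) that is
**centred within each session**. Centring makes a session's mean target
carry only the rat, day and session components, which is what the
inter-session calibration above presumes; without it, minute-scale noise
would leak into session means and no single set of components could satisfy
the intra- and inter-session ICCs simultaneously. The centred series is
equivalently the statement that a session's target *is* its time-average.
A side effect is that the realised intra-session ICC departs modestly from
the nominal 0.40/0.60 (centring and autocorrelation shrink the effective
within-session variance); the inter-session structure, which the validation
targets, is exact.

One root seed drives everything; per-record child seeds are derived
deterministically from (rat, day, session) indices, so any slice of a cohort
can be regenerated independently and reruns are bit-identical.

## Protocols

`apply_protocol()` produces piecewise-stationary records from a timeline of
segments, each a multiplicative attenuation of the baseline target moment
(re-solving the spectral rate per segment) and of the modulation depth. Two
study protocols ship as defaults:

* **IOP clamp** (`timeline_iop_clamp()`): 2 min baseline, 4 min with
  intraocular pressure at 150 mmHg, 5 min recovery. Clamp attenuations are
  the complements of the observed mean decreases: artery 0.31 (a 69% fall —
  ocular perfusion pressure near zero), ONH 0.955 (the ONH signal barely
  responds, consistent with its tissue-scattering origin). The described
  baseline period is 2 min in the protocol text and 3 min in one figure
  caption; the package defaults to 2 min and exposes the duration.
* **Heart arrest** (`timeline_heart_arrest()`): 2 min pre-arrest, 5 min
  post-arrest; attenuations 0.19 (artery) and 0.59 (ONH). Here the
  moving-scatterer volume is attenuated by the same factor as velocity —
  circulation stops, so concentration of moving cells falls with speed; for
  the IOP clamp the volume factor stays 1. The source study does not report
  Vol during either protocol, so this is a documented modelling assumption
  that affects only SNR, not the velocity targets.

Segment lengths are rounded to whole frames so boundaries never straddle a
frame. The analysis (`run_protocol()`) drops the first 10 s of each segment
as a transition guard before averaging — the generator switches regimes
instantaneously, but a real perfusion step is not instantaneous and the
running DC median needs time to re-settle; the guard makes the estimator
indifferent to that choice.

## Numerical choices

* **Hann window, power-corrected.** Each frame is demeaned, Hann-windowed,
  and scaled so that total one-sided power times bin width equals the
  window-corrected AC variance ($\sum (w x)^2 / \sum w^2$); on bin-centred
  tones the identity is exact to floating precision. Hann was chosen to
  keep leakage from strong low-frequency content out of the 400–500 Hz QC
  band; a rectangular window sits behind a config switch.
* **Per-frame noise floor.** Estimated per frame as the mean raw power of
  bins strictly above 4 kHz; per-frame (rather than global) estimation lets
  the QC criterion respond to transient noise. A consequence worth knowing:
  spectra with genuine power above 4 kHz (broad arterial tails, Lorentzian
  tissue tails) have their floor slightly overestimated, which biases
  recovered Vel low by ~1% (artery) to ~4% (ONH). This is a property of
  the measurement definition, shared by the physical instrument, and is
  well inside every validation tolerance.
* **Clipping.** Negative post-subtraction power is clipped to zero before
  the moments, keeping Vel inside the band and Vol non-negative. At very
  low perfusion (heart-arrest segments) the surviving positive noise
  residuals add a small high-frequency mass that biases Vel slightly up,
  visible as a recovered arterial arrest decrease of ~79% against the 81%
  target — inside the 3-point validation band.
* **Degenerate spectra.** An all-zero subtracted spectrum yields Vel = 0
  with an `valid = FALSE` flag rather than an error, so traces stay aligned
  in time.
* **Tie and zero handling in the exact Wilcoxon test.** Zero differences
  are dropped, tied absolute differences get mid-ranks, and for n ≤ 25 the
  two-sided p is exact via a generating-function convolution over the
  (doubled, hence integer) rank sums — identical to full 2ⁿ enumeration but
  polynomial-time; above 25 a tie-corrected normal approximation takes
  over. With 5 paired rats and a uniform decrease this yields p = 0.0625
  (2/2⁵); published p-values of 0.04 for such designs presumably reflect a
  different approximation in the original analysis software, and the
  package reports the exact value.
* **ICC(A,1)** is computed from the explicit two-way sums of squares with
  the McGraw–Wong F-based confidence interval, and matches an independent
  reference implementation to machine precision on fixed tables.

## What the synthetic experiments do and do not show

The experiment drivers reproduce the shape of the validation study:
stepped-speed bench linearity (`run_linearity()`), cohort baselines
(`run_baseline()`), a three-session repeated-measures design with an
inter-day arm (`run_repeatability()`), and the two perfusion challenges
(`run_protocol()`). Passing them demonstrates that the processing chain
recovers known ground truth through the full signal path — synthesis,
framing, windowing, noise subtraction, moments, QC, averaging, statistics —
under the published variance structure. It does **not** certify behaviour
on real eyes: the generator has no speckle decorrelation, no eye-motion
artefact beyond a DC step, no anesthesia physiology, no fundus-image QC,
and its spectral shapes are analytic stand-ins chosen for tractable first
moments; whether ONH tissue scattering is Brownian or motion-artefact in
origin is left open by the source data, and the Lorentzian tissue term is a
modelling stand-in, not a mechanism claim.

Two quantitative honesty notes. First, the capillary scene cannot hold Vol
constant down to 0.3 mm/s: at that speed most Doppler power lies below the
28 Hz band edge, so band-limited Vol necessarily falls, and the package
asserts Vol constancy only for the wheel (whose line never leaves the
band). The published constant capillary Vol over 0.3–50 mm/s is not
reproducible under any band-limited spectral model with the printed
calibration. Second, the replicate-averaged inter-session ICC at the
study's size (6 rats, 3 sessions) centres near 0.76, not at the theoretical
0.82, because the ANOVA ICC(A,1) estimator is biased low in small samples —
a property of the estimator, not of the signal chain; at n = 30 the same
pipeline recovers the component ratio to within 0.02.

## Problem sizes

The shipped validation runs use 40-s bench records (6 speeds), 5-min
records for the 12/16-rat baseline cohorts, 200 replicate 6-rat cohorts
with 10-s sessions for the repeatability average, and 5-rat protocol runs
at the full 2/4/5-minute segment durations. These sizes keep each recovered
quantity's Monte-Carlo error an order of magnitude below its acceptance
tolerance while completing in minutes on a single core; all of them scale
up through function arguments.

```{r example}
cfg <- acquisition_config()
rec <- synthesize_record(scene_artery(651), duration = 10, seed = 1, cfg)
trace <- process_record(rec, cfg)
average_trace(trace, window = 10)
```
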