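---
title: "An SDOF time-frequency method for at-rest PPG: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An SDOF time-frequency method for at-rest PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdoftf)
```

## The physical model

A PPG sensor is held against the skin by a fixture with some contact
pressure. The tissue above the artery, the contact interface and the
sensor form a deformable stack which this package treats as a single
degree of freedom: nominal mass $m_0$, damping $c_0$ and stiffness
$k_0$, driven at its base by the arterial wall displacement $y(t)$. The
sensor reads the mass displacement $x_M(t)$:

$$ m(t)\,\ddot x_M + c(t)\,\dot x_M + k(t)\,x_M \;=\; k(t)\,y + c(t)\,\dot y . $$

At rest, body and breathing motion displace the sensor slowly —
baseline drift $x_b(t)$, band-limited below 0.7 Hz — and, because that
drift is equivalent to a time-varying contact pressure, it modulates
the stack parameters. The package couples each parameter linearly to
the drift, $m(t) = m_0(1 + \gamma_m x_b/x_s)$ and likewise for $c$ and
$k$, with one dimensionless coefficient per parameter and a
normalization amplitude $x_s$. The recorded signal is
$x_{PPG} = x_M + x_b + \text{noise}$.

With constant parameters the stack is the linear filter
$H(j\omega) = (k_0 + j c_0\omega)/(k_0 - m_0\omega^2 + j c_0\omega)$,
which `closed_form_gain()` evaluates; the simulator is verified against
it on a frequency sweep. With drift-coupled parameters the stack
becomes a slowly time-varying filter and rides *multiplicative*
distortion on every pulse harmonic.

**Choice of $m_0, c_0, k_0$.** These are not identifiable from a PPG
record, so the simulator must simply adopt physically sensible values.
The package places the stack's natural frequency at 4 Hz with damping
ratio 0.3. Two observations drive this choice: a very stiff stack
(natural frequency well above the pulse band) is nearly transparent, so
parameter modulation would produce distortion orders of magnitude
smaller than what bedside recordings show; and a resonance just above
the analyzed harmonics makes the upper harmonics distinctly more
artifact-sensitive than the fundamental, which is exactly the
phenomenology the method exploits. Both constants are exposed in
`sdof_config()`.

## The true pulse and its variability

The generator writes the pulse as $N$ heart-rate harmonics (default
$N = 3$; higher harmonics of arrhythmic pulses are too weak to track):

$$ y(t) = \sum_{i=1}^{N} A_i \cos\Theta_i(t), \qquad
   \frac{\dot\Theta_i}{2\pi} = i f_0 + s_i B_i\cos(2\pi f_r t + \alpha_i) + i\,\mathrm{PF}(t), $$

with respiratory sinus arrhythmia of amplitude $B$ at the respiration
rate $f_r$, and PF(t) an Ornstein–Uhlenbeck process (SD `pf_sd`,
correlation time `pf_corr_time`) standing for the non-harmonic
physiological drivers of heart-rate variability. Two deliberate
choices:

* **Order scaling** ($s_i = i$, the default): the respiratory frequency
  deviation of harmonic $i$ scales with its order. This is what makes
  the extracted respiration modulation grow with harmonic order in
  healthy subjects, a trend the phase metrics reproduce; it can be
  switched off.
* **Per-harmonic $B_i, \alpha_i$**: scalars give one coherent
  modulation (sinus rhythm); vectors give harmonic-wise inconsistent
  modulation, used by the AF preset.

## The analysis pipeline

1. `remove_baseline()` — the drift estimate is a cascaded (twice
   applied) zero-phase Butterworth low-pass at 0.7 Hz. The cascade
   squares the magnitude response, so pulse-band leakage into the drift
   estimate is below 0.02 % even at the slowest physiological
   fundamental, and reapplying the operation changes the result by
   less than 0.1 % over the filter-settled interior.
2. `detect_fundamental()` — smoothed Hann periodogram peak in
   0.7–3 Hz, refined by parabolic interpolation; the peak must stand
   50× above the 8–15 Hz noise floor (noise-only input fails by orders
   of magnitude, a heavily modulated arrhythmic pulse passes easily).
3. `isolate_harmonic()` — zero-phase Butterworth bandpass at
   $i f_0 \pm 0.35 f_0$. The half-width must pass the respiratory
   sidebands ($\pm f_r$ and change) while rejecting the neighbouring
   harmonic; 0.35 does both for physiological rates.
4. `hvd_track()` — Hilbert demodulation. The instant frequency is the
   low-passed (0.5 Hz) phase derivative; the instant initial phase is
   the phase residual about the segment-mean frequency,
   $\varphi_0(t) = \Phi(t) - 2\pi \bar f\,(t - t_0)$. This split makes
   $\varphi_0(t)$ carry the *integrated* respiratory modulation as a
   clean near-sinusoid of amplitude $s_i B_i/f_r$, which is why the
   phase track is the preferred carrier of the respiration signal.
   Amplitude and initial phase are then low-passed below the pulse
   fundamental (0.9 Hz) and the harmonic signal is rebuilt from the
   smoothed tracks; everything faster — residual neighbour-harmonic
   leakage, noise beating — is thereby pushed into the sensor-noise
   estimate $x_{noise} = x_0 - \sum_i x_i$, which matches the model's
   premise that noise is alleviated in the per-harmonic signals.
5. `reconstruct()` — the artifact lives almost entirely in the
   envelope, so each harmonic's envelope is replaced by its
   least-squares line ("regression line" is read as first degree; no
   higher degree is implied anywhere) and its initial phase by its
   mean. Summing gives the artifact-free pulse $x_{tf}$ (heart-rate
   variability retained); running each harmonic at its constant mean
   frequency instead gives $x_{cf}$, and $x_{tvsp} = x_{HVD} - x_{tf}$
   quantifies the multiplicative artifact.
6. `cardiac_metrics()`, `resp_metrics()`, `compute_indices()`,
   `classify_af()` — the indices and the majority-vote screening rule.

### Phase anchoring of the reconstructions

The constant of integration in $x_{tf,i} = \tilde A_i\cos(2\pi\int f_i
+ \bar\varphi_{0i})$ is chosen so that the total argument at the
segment midpoint equals the track's unwrapped analytic phase there, and
$x_{cf}$ is anchored identically. This pins both reconstructions to
$x_{HVD}$, so their residuals are artifact and noise rather than a
constant phase offset. The constant-frequency reconstruction defaults
to each harmonic's own measured mean frequency; anchoring it to the
periodogram estimate instead (the `f0_est` argument) would leak the
tiny periodogram/Hilbert mean-frequency mismatch into a spurious phase
ramp across the segment.

### Which instant parameter carries the artifact?

For a multiplicative distortion with phase component $\psi(t)$ at
artifact frequency $f_a$, the induced frequency deviation is
$f_a\,\psi$. The artifact hierarchy — envelope first, frequency
second, phase least — therefore has a timescale condition on its
second leg: within the respiratory band, frequency distortion exceeds
phase distortion when $2\pi f_a \gtrsim f_{mean}$, i.e. for
breathing-band contact motion (the canonical at-rest artifact), and
the two legs tie for very slow positional drift. Near the contact
resonance (harmonic 3 of a ~1.2 Hz pulse at the default stack) phase
sensitivity grows until it rivals the envelope's. The property tests
assert the full hierarchy on the fundamental, and envelope dominance
over frequency on every harmonic, under a breathing-dominated
artifact.

## Heart-rate and respiration indices

* $HR_i(t) = 60 f_i(t)/i$: dividing by the order makes every harmonic
  estimate the same physiological heart rate (the harmonics of one
  fundamental must agree, which is what makes their spread `SD(HR)` a
  sensitive index). HRV is the RMS deviation of a series about its own
  temporal mean — the only reference trajectory available without
  external truth.
* $HR_{\varphi i}(t)$ differentiates the respiratory-band component of
  $\varphi_{0i}(t)$, so it carries breathing-synchronous variability
  only; its RMS is the respiration-only HRV.
* Respiration rate is read as the analytic-signal frequency of the
  band-passed track (band 0.1–0.6 Hz — a default covering 6–36
  breaths/min; no narrower physiological prior is assumed), and the
  respiration modulation converts the phase envelope back to a
  frequency amplitude, $B_\varphi(t) = \mathrm{env}\cdot RR(t)$.
  $B_{\varphi i}$ is reported per harmonic *without* dividing by the
  order, so the order trend (and its loss in AF) stays visible.
* The time-domain baseline segments pulse cycles at the local minima
  preceding each steepest upstroke (derivative-peak detection with a
  $0.4/f_0$ refractory period) and computes per-cycle HR and RMSSD.
  RMSSD is taken over per-cycle heart rates in bpm; an interval-based
  variant is trivially obtained from the returned onset times.

### Screening thresholds

Thresholds are configuration, not learned parameters: the groups
separate by non-overlapping ranges, so a cut anywhere in the gap works.
Defaults in `af_thresholds()`: the `SD(HR)` cut is the geometric mean
of published group extremes for this index family (0.23 bpm vs 0.023
bpm); the respiration-only HRV cut (2 bpm) sits between the ceiling of
sinus-rhythm respiratory HRV ($60 B/\sqrt2 \le 1.7$ bpm for
$B \le 0.04$ Hz) and the AF floor; the respiration-modulation cut
(0.09 Hz) sits between the non-AF ceiling ($\approx 2B \le 0.08$ Hz
with order scaling) and the AF floor. The majority rule is the default
because the three families are redundant; `all`/`any` are available.

## The synthetic cohort: what it does and does not emulate

The presets are the package's standing study conditions
(`generate_cohort()`):

| | non-AF | AF |
|---|---|---|
| $f_0$ | U(1.0, 1.5) Hz | U(1.0, 1.8) Hz |
| $B$ | U(0.02, 0.04) Hz, coherent | U(0.05, 0.12) Hz × per-harmonic jitter U(0.6, 1.4), independent phases |
| PF | SD 0.005 Hz, τ = 5 s | SD U(0.08, 0.15) Hz, τ = 2 s |
| drift | amps 0.12/0.04, walk 0.03 | amps 0.45/0.16, walk 0.10 (≈⅓–½ of pulse amplitude) |
| coupling γ (m,c,k) | 0.05/0.10/0.15 | 0.10/0.25/0.35 |
| noise SD | 0.01 | 0.04 |

Sample sizes for the cohort experiments are 18 AF and 14 non-AF
subjects, 80 s analyzed per record at 125 Hz — the bedside-monitor
convention. Records are 85 s with the first 5 s skipped so the
integrator transient never enters analysis.

What the generator does **not** emulate: optical transduction (the PPG
is modelled as a displacement), nonlinear or intermittent contact,
in-motion artifact whose frequency enters the pulse band, true
non-harmonic AF spectra (the harmonics remain integer multiples of one
fundamental — which is why the synthetic `SD(HR)` separation rests on
artifact- and tracking-induced inconsistency and is the narrowest of
the three families), and realistic pulse morphology beyond three
harmonics. Passing tests on this cohort therefore demonstrate the
pipeline's correctness and the direction and separability of the index
families under the stated model — not clinical performance.

## Numerical choices

* **Integration**: classical fixed-step RK4 at the signal rate, forcing
  and parameter tracks linearly interpolated at half steps, $\dot y$ by
  fourth-order central differences. At 125 Hz this keeps the
  steady-state response within 0.6 % of the closed form across the
  pulse band (the acceptance sweep checks 1 %).
* **Zero-phase filtering**: all filters are forward–backward
  Butterworth (order 4 unless noted). Finite records are padded by
  autoregressive extrapolation — Burg-fitted on a 4×-decimated copy
  (AR pole radii of pulse-band oscillations are badly biased at the
  raw rate), end-anchored and spline-resampled, with a Yule–Walker and
  constant fallback. Pad lengths are generous (15 cycles of the
  cutoff for low-passes) because the forward–backward transient at
  very low normalized cutoffs dies slowly.
* **Respiratory-band operations** use an exactly zero-phase FFT-domain
  bandpass with raised-cosine edges: an IIR design at a normalized
  edge of ~1e-3 would be numerically fragile.
* **Edge trimming**: 4 s per side of every track, covering the Hilbert
  end effects and the settle regions of the 0.5/0.9 Hz smoothers; the
  segment-mean frequency is additionally estimated from the
  smoother-settled core, since a 5e-5 Hz bias would visibly tilt the
  detrended phase over 80 s.
* **Degenerate inputs**: noise-only records are rejected at fundamental
  detection; envelope collapse over more than 10 % of a track raises a
  weak-harmonic flag; cycle segmentation refuses flat signals and
  records with fewer than five detected cycles; respiratory extraction
  flags bands with no power instead of fabricating a rate.
* **Determinism**: every stochastic component (PF process, drift walk,
  sensor noise, preset draws) derives from an explicit seed;
  library code saves and restores the caller's RNG state.

## Known limitations

* The method is for at-rest recordings only; in-motion artifact shares
  the pulse band and violates the model's separation of timescales.
* $m_0, c_0, k_0$ are conventional, not identified; only their ratios
  (natural frequency, damping ratio) matter to the phenomenology.
* `SD(HR)` in the synthetic cohort reflects estimator response to
  artifact and arrhythmic modulation rather than genuinely inharmonic
  spectra, and is accordingly the index with the smallest margin.
* The WFDB writer quantizes to 16-bit integers (one part in ~32 000 of
  peak amplitude); round-trips are exact only to that quantum.

## Problem sizes used by the test-suite and acceptance script

Single records: 85 s at 125 Hz (10 625 samples), 80 s analyzed. The
cohort experiment: 32 records (18 AF / 14 non-AF), full pipeline per
record. The simulator sweep: ten 40 s constant-parameter runs. These
sizes keep the entire suite within a few minutes on one CPU while
leaving every tolerance comfortably resolvable.
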