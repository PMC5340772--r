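---
title: "Analysing hippocampal oscillations and LTP around high-frequency stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing hippocampal oscillations and LTP around high-frequency stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltposc)
```

## The analysis problem

High-frequency stimulation (HFS) of the perforant path induces long-term
potentiation (LTP) in the dentate gyrus, and the induction is accompanied by
a characteristic pattern of hippocampal network activity: transient changes
in theta (4–10 Hz) and gamma (30–100 Hz) power, and an increase in
theta–gamma phase–amplitude coupling during the tetanus. Interventions that
impair LTP — for example NMDA-receptor antagonism in rodent psychosis
models — also disturb this oscillatory signature: theta power is suppressed
during and after HFS while gamma power is spared, and theta–gamma coupling
drops in the second half of the stimulation period.

`ltposc` implements the complete analysis chain needed to quantify these
phenomena from a single-channel local field potential plus a
stimulation-event log, together with a synthetic-data generator that
produces recordings with known ground truth so that every stage can be
validated without animal data.

## Windowing and epoch extraction

The recording design defines five contiguous 100 s analysis windows:
`pre` (the baseline immediately before the first HFS train), `during`
(starting at the first train onset; ten trains of 15 pulses at 200 Hz
repeated at 10 s intervals fall inside it), and `post1`–`post3`.
`locate_windows()` derives these from the event log. Two unit conventions
appear in descriptions of this design — millisecond labels for the
post-HFS time points and 100 s recording blocks; the statistical design
("five levels of time, 100 s each") only makes sense with second-scale
blocks, so windows are implemented in seconds.

Stimulation creates large artifacts, so spectra are never computed on raw
windows. Each 100 s window is split into ten 10 s sub-windows (one per HFS
train), and from each sub-window the **earliest** 4.1 s run of artifact-free
samples is extracted (`extract_epochs()`). "Artifact-free" is not a standard
term, so it is defined operationally and configurably: a sample is flagged
when it lies inside a declared event interval ± a 50 ms guard, or when its
deviation from the median exceeds 6 robust standard deviations
(median-absolute-deviation scaled; `detect_artifacts()`). The earliest-run
rule is a deterministic tie-break, and the extraction is tested against an
exhaustive search over every candidate start.

## Spectra and band power

Power spectra use Welch averaging: Hann-tapered segments of `nfft = 2048`
samples with 50% overlap, scaled so the integrated spectrum equals the
signal variance (`power_spectrum()`). The Hann taper with segment averaging
is a deliberate choice for 4.1 s epochs — a single unwindowed FFT would
carry excessive variance. A zero-phase Butterworth band-stop with −3 dB
edges at 48.5 and 55 Hz removes mains contamination before every spectrum
(`notch_filter()`); it is applied forward–backward because the coupling
analysis downstream is phase-sensitive.

Band power is the mean bin power over half-open intervals
delta [2, 4), theta [4, 10), alpha [10, 12), beta [12, 28), gamma
[30, 100) Hz — half-open so the shared band edges are unambiguous. Per
window, band powers are averaged across the (up to ten) epochs and then
expressed as a percentage of the `pre` window's mean, separately per
subject, so the baseline row is 100% by construction
(`band_power_table()`). Averaging epoch band powers before forming the
ratio (rather than averaging spectra first) is one of two defensible
orders; both are nearly identical for stationary epochs and the epoch-mean
order makes the per-epoch values available to the statistics stage.
`theta_profile()` applies the same normalization per integer frequency
5–10 Hz (±0.5 Hz of spectrum bins) to resolve which part of the theta band
responds.

## ESC phase–amplitude coupling

The coupling estimator is the envelope-to-signal correlation (ESC): the
Pearson correlation between the low-frequency filtered signal and the
amplitude envelope of the high-frequency band. Filtering uses a complex
Morlet wavelet of width 7 cycles, implemented as a frequency-domain
Gaussian on the analytic (one-sided) spectrum (`morlet_filter()`); this is
numerically equivalent to time-domain convolution up to edge handling, and
one wavelet standard deviation (`width / (2 pi f)`) is trimmed from each
end before any correlation. Comodulograms evaluate all ordered bin pairs
of a 3–98 Hz grid in 5 Hz steps (±2 Hz bins); only pairs whose envelope
bin is faster than the signal bin are meaningful, so the rest of the
matrix holds structural `NA`s. The 48 and 53 Hz bins overlap the notch
stop-band; they are computed but flagged in the output metadata.

Significance is assessed against surrogates that destroy the
phase–envelope alignment while preserving the envelope's spectrum: for
each of 200 shuffles the envelope is cut at random points into blocks and
the blocks permuted, and the observed ESC is z-scored against the shuffle
distribution (`surrogate_normalize()`). The block length matters and was
chosen analytically, before calibration was measured, at ~8 envelope
coherence times (`8.9 / f_hi` seconds): long enough that the surrogate
spread tracks the null sampling variability of the correlation (blocks
much shorter than the envelope's autocorrelation understate the null and
inflate z), short enough that genuinely modulated envelopes lose their
alignment (a single cut-and-swap of a sinusoidally modulated envelope
merely rotates its phase, leaving surrogate correlations of the same
magnitude as the observed one — such a scheme can never flag periodic
coupling as significant). Empirical calibration under an uncoupled null is
part of the test suite.

Two score matrices are emitted deliberately. The **raw** correlation is the
quantity to compare across conditions and epochs and the statistic whose
argmax localizes coupling — it directly measures modulation strength. The
**z** matrix answers only "is this cell above chance": because Pearson
correlation is scale-invariant, spectral leakage of a modulated carrier
into neighbouring bins produces significant z there too, so the z argmax
does not localize. `theta_gamma_score()` pools all (theta-bin, gamma-bin)
pairs (theta from the full grid inside 4–10 Hz; gamma bins 33–98 Hz), and
`hfs_coupling_timecourse()` tracks the pooled score across the ten
during-HFS epochs, also expressed relative to the mean baseline score.

## Evoked potentials and LTP

Each test pulse yields a fixed-length sweep from which two measures are
taken: the fEPSP slope — the maximum of sliding 1 ms linear fits over the
initial rising phase — and the population-spike amplitude by the tangent
method, the vertical distance from the line joining the two positive peaks
flanking the spike to the spike minimum. Neither measurement geometry is
standardized in the literature beyond these conventions, so they are
implemented exactly as stated, on a lightly smoothed sweep with the
extremum values taken from short local fits (a parabola vertex at the
minimum) so the measures stay unbiased under sweep noise.

Stimulation intensity follows the input–output rule: of the tested
intensities (100–900 µA in 100 µA steps), the one whose response is
closest to 40% of the maximum is selected; ties go to the lower intensity,
and no interpolation is done because only tested intensities can be
delivered. Time courses average five sweeps per time point and are
normalized so the mean of the six baseline points (30 min at 5 min
intervals) is 100% (`ltp_timecourse()`). The recording schedule — three
post-HFS points at 5 min, 15 min intervals to 4 h, and a 24–25 h block —
is encoded as a validated default and can be overridden.
`fit_ltp_decay()` recovers `(potentiation_factor, decay_tau)` from a time
course by least squares on `100 (1 + (pf − 1) e^{−t/tau})`.

## Gated statistics

Group comparisons follow a normality-gated procedure: the
Anderson–Darling test is applied to each group's distribution, and if any
group rejects at α = 0.05 the nonparametric branch is used (Wilcoxon
tests, Kruskal–Wallis) — otherwise Student's t or (repeated-measures)
ANOVA. Post-hoc pairwise comparisons run only after a significant omnibus
with more than two levels, via Tukey HSD; on the nonparametric branch a
Tukey-type procedure on rank-transformed data is used, since "Tukey after
Kruskal–Wallis" is otherwise undefined. Two pragmatic adjustments: groups
with fewer than 8 observations route nonparametric with a `small-n` flag
(the Anderson–Darling p-value approximation is unreliable there), and
paired designs gate on the paired differences — the distribution the
paired tests actually assume, which also handles the degenerate
constant-difference case where a paired t-test is undefined.
`typeI_calibration()` pushes simulated null data through the full
gate-plus-test chain and verifies the procedure holds its nominal size;
per-frequency grids are compared cell-wise at α = 0.05 by default, with a
Benjamini–Hochberg option available via `p.adjust` on the emitted tables.

## The synthetic generator

`gen_coupled_eeg()` builds signals as theta + amplitude-modulated gamma +
1/f^α noise + mains line. Coupling is cosine amplitude modulation of the
gamma carrier by the theta phase, `gamma_amp (1 + d cos(theta_phase −
lag))`, so the envelope modulation depth equals `d` exactly — this matches
the construct ESC estimates, which is the point of the generator. Noise is
spectrally shaped Gaussian with α = 1 (a plausible LFP background), 20 µV
RMS against a 100 µV theta and 30 µV gamma; the 50 Hz line is 10 µV.
Artifacts are biphasic rectangles at 10× signal RMS, so threshold
detection is unambiguous by construction.

`gen_experiment()` assembles full 500 s scenario recordings. The presets
implement effect *directions*, not magnitudes — the source phenomenology
is reported as significance, not effect size — with per-window amplitude
multipliers: the control condition has a mild theta dip during HFS with a
rebound afterwards, a transient gamma increase, stable coupling (depth 0.7
baseline, 0.8 during HFS) and persistent LTP (`decay_tau = Inf`); the
treated conditions suppress theta to 0.6× amplitude during HFS (0.36×
power) with slow recovery, suppress delta/alpha/beta similarly, spare
gamma, halve coupling in HFS epochs 6–10 (0.7 → 0.35), and decay LTP with
τ = 240 min from a 1.5× peak — potentiation lasts roughly 4 h and is gone
at 24 h. Evoked sweeps are piecewise-stereotyped waveforms (1 ms latency,
2 ms linear rise, shouldered raised-cosine population spike, linear decay)
whose slope and tangent amplitude equal the model values exactly at zero
noise; sweep noise is multiplicative.

What the generator does **not** emulate: non-sinusoidal theta waveforms,
frequency drift, state-dependent power fluctuations, multi-channel volume
conduction, true biophysics of the tetanus. Passing tests therefore show
that the estimators recover the constructs they claim to estimate under
realistic SNR — not that real recordings satisfy the generator's
assumptions.

## Numerical choices and degenerate inputs

* Problem sizes: epochs are 4.1 s at 2 kHz; comodulograms use the full
  20-center grid (190 pairs × 200 shuffles); scenario validation uses 20
  seeded replicates per condition; statistical calibration uses 1000
  Monte-Carlo replicates. The epoch-search oracle runs at 100 Hz, where
  the exhaustive scan is cheap.
* Constant series in `esc()` return 0 with a `degenerate` attribute rather
  than `NA` or an error; zero surrogate spread returns `NA` with a flag.
* Epoch sub-windows without a 4.1 s clean run are logged and skipped;
  only a window with *no* epochs at all errors.
* `io_select_intensity()` breaks ties toward the lower intensity;
  epoch extraction breaks ties toward the earliest run.
* Seeds: every stochastic function takes an explicit seed; pipeline
  sub-stages derive their seeds from the run seed, so a run is reproducible
  byte for byte.

## Limitations

* ESC is the only coupling estimator implemented (modulation index,
  phase-locking value etc. are out of scope); the band-pass + Hilbert
  construction appears only as a test oracle.
* The repeated-measures branch handles one within-subject factor; there is
  no mixed-effects machinery.
* The comodulogram's z-scores inherit a mild anti-conservatism (~10–15%
  s.d.) for envelope bins whose coherence time approaches the surrogate
  block length; the calibration test bounds this.
* Scenario effect magnitudes are free parameters of the generator, chosen
  once as plausible values — conclusions about real effect sizes cannot be
  read off them.
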