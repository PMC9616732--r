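---
title: "Methods: encoding-sleep topography overlap analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encoding-sleep topography overlap analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spindletopo)
```

## The scientific question

During NREM sleep, spindles (transient 12–15 Hz thalamocortical
oscillations) are thought to act locally, strengthening the cortical
circuits that were engaged during prior learning. If so, a participant's
*spatial distribution* of spindle activity after learning should resemble
that participant's *spatial distribution* of learning-related cortical
engagement — and the degree of resemblance should predict how well the
memory survives sleep.

`spindletopo` implements the full analysis chain for testing this on
multichannel scalp EEG:

1. a per-participant **encoding pattern** — the channel-wise change of
   oscillatory power during a memory task relative to a memory-free
   vigilance control, collapsed over the frequency band that a group-level
   cluster test marks as significant;
2. channel-wise **detection of spindles and slow oscillations (SOs)**
   during the subsequent nap, summarized as per-channel amplitude,
   duration and density topographies;
3. the **overlap statistic** — a Spearman correlation across channels
   between the encoding topography and each sleep topography (Fisher-z for
   group statistics). Engagement shows up as a *power decrease* (negative
   values) while all sleep measures are positive, so overlap is signified
   by *negative* correlations;
4. group statistics: a 2 (event type) × 3 (characteristic)
   repeated-measures ANOVA, Holm-corrected post-hoc t tests, partial rank
   correlations among spindle characteristics, the across-participant
   correlation between overlap and memory retention, and two
   topography-shuffling permutation nulls that test whether that behaviour
   correlation depends on the participant-specific pairing.

Because the analysis is defined operationally, everything is testable
against a synthetic cohort whose ground truth is known; the package's
generator is a first-class module, not a fixture.

## Signal-processing layer

All computation assumes the fixed working rate of 200 Hz; readers reject
other rates rather than resample (preprocessing of raw acquisitions is out
of scope). Time is in seconds, intervals are half-open.

**Filtering.** Every band-pass is a 4th-order Butterworth applied forward
and backward (zero phase; the effective attenuation is the squared
magnitude response). At the SO band the normalized low edge is 0.3/100 =
0.003, where an 8-pole transfer function in expanded polynomial form is
numerically ill-conditioned; filters are therefore designed and applied as
cascaded second-order sections (analog prototype poles → band-pass
transform → bilinear transform), with odd-reflection edge padding scaled
to the low band edge (3/f1 seconds). `butter_bandpass_gain()` gives the
closed-form magnitude response used as an independent oracle in the tests.

**Envelope.** The spindle envelope is the magnitude of the FFT-based
analytic signal, then a centred 200-ms moving average. The methods
phrasing ("envelope ... based on the smoothed signal ... using the Hilbert
transform") is ambiguous about the order; smoothing a 12–15 Hz carrier
*before* the Hilbert transform would attenuate the band itself, so
rectify-then-smooth is the default and the alternative order is available
via `detection_params(envelope_order = "smooth_first")`.

## Event detection

**Spindles** (`detect_spindles()`): per channel, the 12–15 Hz envelope's
amplitude criterion is mean + 1.25·SD computed over artifact-free N2/N3
samples (pooled over stages). Maximal strictly-supra-threshold runs whose
duration lies in the *open* interval (0.5, 3) s become events. An event
must lie entirely in N2/N3 and be artifact-free from 1 s before onset to
1 s after offset. Amplitude is the envelope maximum; no merging of runs
separated by sub-threshold gaps (no merge rule is part of the method).

**Slow oscillations** (`detect_slow_oscillations()`): on the 0.3–1.25 Hz
signal, candidates are intervals between consecutive positive-to-negative
zero crossings with length in the *closed* interval [0.8, 2] s, lying in
N2/N3. Over all candidates, mean + 1.25·SD thresholds are computed for
trough-to-peak amplitude and for absolute trough depth; events must exceed
both. Amplitude is stored as |trough| so all six sleep measures are
positively scaled. A consequence of the adaptive criterion worth knowing:
a perfectly regular oscillation (all candidates identical) yields *no*
events, because nothing exceeds a mean + 1.25·(SD = 0) threshold.

**Coupling** (`spindle_so_phase()`, `split_by_coupling()`): for each
spindle, a ±2.5 s window around the envelope maximum is filtered 0.3–1.25
Hz and Hilbert-transformed; the phase at the centre sample is the event's
SO phase. Convention: 0° is the SO positive peak (up-state), ±180° the
trough — the analytic-signal phase of a cosine-like wave. The window
length (≥1.5 cycles at the slowest SO frequencies) and the zero reference
are package decisions; the method's source leaves both implicit. Events
whose SO-band envelope at the centre is below the channel's
mean + 1.25·SD NREM criterion are flagged `low_so` (a phase against no
appreciable SO activity). Per channel, the 50% of spindles with phase
closest to 0° form the "higher coupling" half (ties broken by earlier
onset; an odd event joins the higher half).

## Encoding pattern

Wake recordings are cut into 1-s Hanning-tapered epochs with 50% overlap;
squared-magnitude FFT bins 1–20 Hz (1 Hz resolution) give absolute power.
Artifact handling follows the percentile rule: for each channel × frequency
cell *independently*, epochs strictly above that cell's 95th percentile
(type-7, linear interpolation) are excluded; condition means are taken over
each cell's retained epochs. Note the unit of exclusion is the epoch
*within a cell*, not the whole epoch: excluding any epoch that is extreme
in *some* of the 58 × 20 cells would discard nearly all data, and the
per-cell reading matches a threshold defined "uniquely for each frequency
bin distribution". `pct = 100` disables rejection.

The group test (`cluster_permutation()`) is a paired cluster-based
permutation test realized as a one-sample test of the per-cell
encoding-minus-control differences against zero: per-cell t across
participants, cells with |t| above the two-sided critical value at
`cell_alpha` clustered by adjacency (neighbouring channels at the same
frequency, ±1 bin on the same channel; positive and negative cells
clustered separately), cluster mass = summed t, null = maximum |mass|
under participant-wise sign flips, p with the add-one correction. Channel
adjacency is distance-thresholded (≤1.5× the median nearest-neighbour
distance in the 2-D layout); on the built-in schematic grid this yields
the same neighbourhoods a Delaunay triangulation with long-edge pruning
would, without needing a triangulation dependency.

Each participant's topography is the *mean* power change over the
significant bins per channel (mean rather than sum keeps the scale stable
when the bin set changes). If no cluster survives, the pipeline falls back
to the full 6–20 Hz band (configurable via `fallback_band`).

## Overlap and group statistics

`topo_overlap()` computes Spearman's rho (mid-ranks; pairwise deletion of
channels with no events) and its Fisher z, clipped at |r| = 1 − 1e-6 so
perfect correlations stay finite. The 2×3 repeated-measures ANOVA is a
direct sums-of-squares decomposition with each effect tested against its
own effect-by-subject interaction, uncorrected degrees of freedom, and
partial eta squared = SS_effect/(SS_effect + SS_error); the test suite
checks it to 1e-8 against `aov()` error strata. Post-hoc families (paired
spindle-vs-SO per characteristic; one-sample spindle characteristics vs 0)
are Holm-corrected within each family of three. Partial "Spearman"
correlations are first-order partial Pearson correlations on mid-ranks.

**Permutation nulls** (`permutation_null()`): the observed statistic is
the Spearman correlation between per-participant overlap z and retention.
Each permutation uniformly shuffles one topography set (encoding *or*
spindle) across participants — identity permutations allowed — recomputes
every participant's overlap, and records the correlation. The p-value is
one-sided with the add-one correction in the *fixed a-priori* direction
(default `"less"`: stronger overlap, i.e. more negative z, accompanies
better retention). A data-driven "observed direction" tail would be
anti-conservative by construction (its null rejection rate is 2α and its p
is uniform on (0, 0.5]); with the fixed direction the null p is uniform,
which the acceptance suite verifies. A two-sided p is also returned.

**Behaviour.** The sequence-memory score correlates the retrieved object
order with the ascending true order; both are permutations, so Pearson and
Spearman coincide, and r is clipped before `atanh`. Retention is
100·post/pre on the Fisher-z scores, undefined (NA, with a warning) when
the pre-sleep score is not positive. The overlap–retention correlation
uses an exact permutation p below n = 12 and the t approximation above.

## The synthetic cohort

`synth_config()` defines the study conditions; `generate_cohort()` (or
`plant_truth()` + `generate_participant()` for streaming) emits complete
participants with full ground truth.

**Background**: Gaussian noise with a 1/(f + 0.5)^β spectrum (β = 1) plus
a small white floor, scaled to 15 µV RMS — realistic envelope statistics
so the mean + 1.25·SD criterion is meaningfully exercised. The band RMS of
this process (the Rayleigh scale of its Hilbert envelope) is available in
closed form (`background_band_sigma()`) and is the unit in which event
amplitudes are planted.

**Wake**: encoding and control recordings share the background model plus
a broadband 6–20 Hz oscillatory component (8 µV RMS); during encoding the
oscillatory amplitude on channel c is multiplied by 1 + loading(c),
loadings ≤ 0 (decrease-only). The group attenuation profile is a right
temporo-parietal bump with per-participant idiosyncrasy.

**Sleep**: a nap template (brief wake/N1 onset, N2/N3 cycles with short
REM periods) or an explicit stage vector. Events are placed on a
per-channel slot grid inside artifact-free N2/N3 with a 4-s margin, so
planted counts are exact (rate × artifact-free NREM minutes) and
within-kind spacing is guaranteed. Spindles are 13 Hz sinusoids under a
flat-topped envelope with 0.25-s raised-cosine ramps; duration (0.8–1.8 s)
is the envelope support. The flat top with steep ramps makes the planted
onset identifiable to well under the 0.25-s matching tolerance — with a
Gaussian envelope the detector's threshold-crossing time is jittered by
hundreds of milliseconds by background noise, which would make onset
agreement a property of the noise, not of the detector. SOs are single
cycles (trough then up-state peak, 0.6–1.0 Hz) flanked by half-cycle lobes
of 0.35× opposite amplitude, mimicking the slow activity that surrounds
real SO trains; the lobes pin the bounding zero crossings to the cycle
edges (otherwise background sign at the wave edges displaces the crossings
and pushes candidate durations outside [0.8, 2] s). Both waveforms are
scaled so the amplitude the detector measures on the *filtered* signal
equals the logged amplitude (the band-pass attenuation of each finite
waveform is computed once and compensated).

**Coupling**: every spindle is attached to a host SO; its envelope maximum
is placed at the SO phase drawn from von Mises(0°, κ) (Best–Fisher
sampler), with κ = 4 by default and κ = 0 giving uniform phases. If
`so_rate = 0`, spindles are planted standalone with NA phase;
`spindle_rate > so_rate` is rejected since every spindle needs its own
host.

**Planted overlap**: the spindle-amplitude topography is
exp(0.4·t) with t = w·(rank-normal scores of the encoding latent) +
√(1−w²)·noise. Because Spearman's rho between bivariate normal scores with
Pearson correlation w has expectation (6/π)·asin(w/2), choosing
w = 2·sin(π|ρ|/6) makes the *expected* encoding–spindle Spearman equal the
participant's planted overlap ρ (jittered across participants by
`overlap_noise`; calibration to ±0.05 over 200 participants is asserted in
the tests). Retention is intercept + slope·ρ + noise, clipped to (0, 150]
(defaults 60, −50, SD 15: a planted ρ of −0.6 maps to ≈90% retention).
The SO topography is independent of the encoding pattern.

**Event SNR**: `spindle_snr`/`so_snr` express the planted envelope peak /
trough depth as multiples of the background band RMS. Defaults (4/4 with
0.2 log-normal per-event jitter) give a moderately hard detection problem
(≈70–85% recall); the `high_snr` preset (5/5, jitter 0.1) is the
parameter-recovery regime.

### What the generator does and does not emulate

It reproduces the *statistical structure* the analysis assumes:
channel-selective wake power decreases, NREM-confined band-limited events
with controllable topographies, von Mises SO-phase coupling, and a
plantable overlap–behaviour link. It does not emulate: non-stationary or
bursty background (sleep depth changes, arousals), K-complexes and other
non-sinusoidal transients, volume-conduction correlation between channels
(channels are independent), slow spindles (9–12 Hz), muscle/ocular
artifacts with realistic spectra, or inter-event dependency beyond the
host-SO construction. Passing recovery tests therefore demonstrates the
pipeline's correctness and calibration under the assumed signal model, not
detector validity on real polysomnography, where threshold criteria are
known to be sensitive to background non-stationarity.

## Numerical choices and degenerate inputs

- Correlations are clipped at |r| = 1 − 1e-6 before `atanh`.
- `percentile_reject` accepts pct in (50, 100]; 100 disables rejection;
  constant cells exclude nothing (no value is strictly above the
  percentile).
- Zero-variance post-hoc contrasts return t = 0, p = 1 when the mean
  difference is 0 and t = ±Inf, p = 0 when it is a nonzero constant.
- The cluster test returns an empty (non-error) result when no cell is
  supra-threshold; p-values are bounded below by 1/(n_perm + 1).
- Detection of events near recording edges: phase windows that would cross
  an edge drop the event with a counted skip; filter edge transients are
  confined by reflection padding scaled to the band.
- All simulation and permutation functions take explicit seeds; identical
  config + seed gives byte-identical outputs (asserted on the pipeline's
  TSV bundle).

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to exercise every code path at
desk scale: detector fidelity on a 20-channel, 30-min all-NREM nap with
events planted exactly at 5× (spindles) and 4× (SOs) the background band
RMS; topography recovery on single 58-channel naps; coupling recovery
with ≈240 events at κ = 5 and 50 replicate κ = 0 naps; cluster-test
calibration on 200 replicate 12-participant cohorts at the contrast-map
level (the test's input representation) with 500 sign-flip permutations;
permutation-null calibration on 200 replicate 19-participant cohorts at
the planted-topography level; and one full-pipeline cohort (10
participants, 30 channels, 20-min naps, high-SNR preset) for end-to-end
recovery of a planted overlap of −0.6. Direction-consistency replicates
for the event-type ANOVA run at planted-topography level, where detector
sampling noise — already covered by the fidelity checks — is bypassed.

## Known limitations

- Channels are simulated independently; spatial correlation (volume
  conduction) would lower the effective number of channels in the overlap
  correlation and is not modelled.
- The detectors implement fixed-band criteria; individualized spindle
  bands and slow-spindle detection are out of scope.
- The RM-ANOVA applies no sphericity correction (by design, matching the
  reported uncorrected degrees of freedom); with 3-level factors on real
  data a Greenhouse–Geisser correction may be preferable.
- `ingest` mode expects the package's own TSV conventions and continuous
  EDF; vendor formats are not read.
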