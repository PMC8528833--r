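---
title: "Ensemble imaginary wavelet coherency and microscale network analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble imaginary wavelet coherency and microscale network analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microcoh)
```

# The problem

Transient neurophysiological events — interictal epileptiform discharges,
evoked components, brief oscillatory bursts — live on timescales of tens to
hundreds of milliseconds. Connectivity estimators built for stationary data
(multi-second Fourier coherence, correlation over long windows) blur many
brain states into one average. `microcoh` estimates time–frequency-resolved
coupling between channel pairs around annotated events and turns it into
weighted networks that can be compared across time windows, frequency
bands, and subject groups.

# Model and estimator

## Continuous wavelet transform

Each channel is decomposed with the analytic Morlet wavelet
$\psi(\tau) = \pi^{-1/4} e^{i\omega_0\tau} e^{-\tau^2/2}$ with
$\omega_0 = 6$, the conventional lowest value at which the wavelet is
numerically admissible (its spectrum is negligible at and below zero
frequency, error $\sim e^{-\omega_0^2/2} \approx 10^{-8}$). Scales are
dyadic with 12 voices per octave, $\sigma_k = s_0 2^{k/12}$, starting at
$s_0 = 2/f_s$ (two samples — the finest scale whose equivalent Fourier
frequency $f = \omega_0 / 2\pi\sigma$ stays below Nyquist). The number of
octaves is capped at $\lfloor \log_2(f_s \Delta t) \rfloor - 1$ so the
largest wavelet still fits the record. The transform is computed by FFT
with zero-padding to the next power of two at least twice the record
length, with the $L_2$ normalization $\sqrt{2\pi\sigma f_s}\,\pi^{-1/4}$;
coefficients are exactly linear in the input. Some print sources write the
Morlet prefactor as $\pi^{+1/4}$; unit energy requires $\pi^{-1/4}$, which
is what we implement.

## Ensemble coherency and its imaginary part

Coherency from a single realisation is degenerate (identically 1 without
smoothing), so two forms of averaging are combined. Within each epoch a
smoothing operator $S$ is applied to the cross- and auto-spectra; across
the $N$ event-locked epochs the smoothed spectra are summed:

$$\hat R_{ij}(\sigma,\tau) =
  \frac{\sum_{n=1}^{N} S\!\left(w_i^{(n)} \overline{w_j^{(n)}}\right)}
       {\left[\sum_n S(|w_i^{(n)}|^2)\; \sum_n S(|w_j^{(n)}|^2)\right]^{1/2}}.$$

Because every term in $S$ and in the epoch sum is a non-negative weight,
$|\hat R| \le 1$ holds by the Cauchy–Schwarz inequality (and the suite
checks it to $10^{-9}$). $|\hat R|$ is the wavelet-transform coherency
(WTC); $\mathrm{Imag}(\hat R)$ (IWTC) is insensitive to zero-lag coupling:
a source reaching two electrodes by volume conduction arrives with zero
delay, contributes only to the real axis, and vanishes from the imaginary
part. The phase $\arg \hat R$ carries the lead–lag relation; we fix the
convention so that positive $\mathrm{Imag}(\hat R_{ij})$ reads "$j$ leads
$i$" — with channels $(x, y)$ built as cosine vs sine (y delayed a quarter
cycle on the time axis but carrying the $+\pi/2$ analytic phase), the
in-silico benchmark decodes as "y leads x".

## The smoothing operator

$S$ is a unit-sum Gaussian in time whose standard deviation equals the
scale $\sigma$ (in seconds) — so smoothing always spans the same number of
oscillation cycles — followed by a unit-sum boxcar over 12 adjacent scale
bins (one octave), truncated and renormalized at the grid edges.
Renormalization (dividing by the smoothed indicator of the record) makes
constants exact fixed points and keeps non-negative fields non-negative.
Both kernel choices are package settings (`smooth_scales` in
`build_scales()`), since only the *amount* of smoothing — "twelve scales"
— is conventionally fixed, not the kernel shapes.

## Cone of influence

The wavelet envelope's e-folding time $\sqrt 2 \sigma$ is used as the
operational half wavelet length: estimates closer than that to either
record edge are invalid at that scale. Masks are symmetric and widen
monotonically with scale; significance flags are never raised outside the
COI. Events whose epoch window would cross a recording edge are skipped
(with a count), never zero-padded — padding would fabricate data that the
COI bookkeeping could not see.

## Bootstrap significance

Two processes can be mathematically coherent without being coupled.
Instead of a parametric null (e.g. red noise), the user supplies
*background epochs* that embody "no event-locked coupling" for their own
recording setup. Each of $B$ surrogate ensembles draws `N_match` epochs
with replacement **independently for the two channels**, breaking the
cross-channel pairing and thereby enforcing the independence null without
modelling the EEG spectrum. The measure (|IWTC| by default, matching the
downstream networks; WTC optionally) is recorded per bin, and analysis
bins above the $q$-quantile (default 0.95) are flagged. Thresholds are
pointwise per time–frequency bin; pooling over time within each scale is
available for small $B$. Defaults: $B = 300$; the suite's calibration
checks run $B = 99$, where the empirical flag rate under the null is
5–6 % at $q = 0.95$ (the small positive bias is the usual finite-$B$
quantile-estimation effect, shrinking as $B$ grows). No multiple-testing
correction is applied by default; a max-statistic family-wise option was
considered and deliberately left out of scope because the reference
procedure applies none.

# Network layer

## Snapshots, dynamic networks, GMC

A snapshot $G_{t,f} = (\mathcal V, E_{t,f})$ averages $|IWTC|$ over the
bins inside a time–frequency window (intersected with the COI and, when a
mask is supplied, with the significant bins); the mean sign of IWTC over
the same bins is the edge's direction score in $[-1, 1]$. A pair with no
qualifying bins — or zero mean magnitude — has no edge. Dynamic networks
divide the span $T$ into $\lceil T/w \rceil$ windows on the sample grid
(the last may be short; it is kept, not dropped). Global Microscale
Connectivity is the mean edge weight over *all* $\binom{n}{2}$ pairs,
absent edges counting as zero, so GMC is density-sensitive and comparable
across subjects with different sparsity (the mean over existing edges is
available via a flag).

## Centralities

Ten weighted measures: strength-type (degree, in-, out-degree), path-type
(harmonic closeness, in-/out-closeness, betweenness — distances
$1/\text{weight}$, so strong edges are short), spectral (eigenvector, HITS
hubs, both by power iteration to $10^{-10}$, normalized to unit maximum),
and pagerank (damping 0.85, sums to one). Harmonic closeness is used
precisely because significant-edge networks are often disconnected:
unreachable pairs contribute zero instead of poisoning the mean. The
directed view orients each edge by its direction score (ties below a
tolerance become reciprocal arcs). Shortest-path and pagerank computations
are delegated to igraph; the suite cross-checks betweenness and closeness
against exhaustive path enumeration on 100 random graphs, and the power
iterations against igraph's spectral routines.

"Characteristic centrality" asks which measures carry the most information
about a given network: the node × measure matrix is z-scored per measure
(their scales are incommensurable — pagerank sums to 1 while strength is
unbounded) and decomposed by SVD; the contribution of measure $m$ to
component $k$ is $100\,v_{mk}^2 / \sum_m v_{mk}^2$, and measures are
ranked by their PC1 contribution. Constant measures are dropped with a
warning. Ranking ties break by measure name for reproducibility.

## Layouts

The force-directed view uses Fruchterman–Reingold (attraction ∝ weight),
seeded for determinism, centred and scaled to a unit box. The layered
("dendrogram") view is explicitly heuristic: a greedy weighted
feedback-arc set breaks cycles (removed edges are *reported*, not
silently dropped), longest-path layering orients every retained edge to a
strictly deeper layer, and a few barycenter sweeps order nodes within
layers. Optimal crossing minimisation is NP-hard and out of scope.

## Group level

Subjects' snapshots are stacked into $G \in \mathbb R^{n\times m}$
(subjects × all channel pairs, absent edges 0; mismatched channel sets are
an error naming the offending subject). Grand average is the column mean.
Network modules are the right singular vectors of the **row-centered**
stack — each subject's own mean connectivity is removed, no variance
scaling — keeping $\min(3, n-1)$ components with variance fractions
$d_k^2/\sum d^2$; loading signs are fixed (largest-magnitude entry
positive) so module maps are invariant to subject order. "Identical
subjects" is detected as zero *between-subject* variance after centering
(row-centering alone never zeroes identical non-constant rows). Group
contrasts of GMC use Cohen's d with pooled SD ($n-1$ denominators), sign
= group A − group B; Hedges' g is available for small samples.

# Synthetic data

`insilico_pair()` generates the two-channel benchmark: piecewise-gated
10 Hz and 45 Hz cosines on x, the corresponding sines on y (a quarter-cycle
offset), unit amplitude, additive white noise of sd 0.05 per trial;
defaults fs = 500 Hz, 2 s, 30 trials. Where gates overlap the components
add; in the noise-free limit the output reproduces the gating equations
exactly (tested). "Noise at 0.05" is read as the white-noise standard
deviation against unit signal amplitude — the only dimensionally coherent
reading.

`ied_network_sim()` emulates event-locked discharges: independent
$1/f$-shaped background per channel, a damped-oscillation transient on a
source channel at each event, copied to destination channels with a known
lag and gain. The true directed graph is returned so pipeline tests can
score recovery. `background_epochs()` supplies independent white-noise
epochs for surrogate construction.

What these fixtures do **not** emulate: spatially correlated sensor noise,
1/f cross-channel leakage fields, non-stationary artifacts, electrode
geometry, or realistic IED waveform variability. Green tests on them
demonstrate estimator correctness and calibration under the stated
generative model — not clinical validity on real ECoG.

# Numerical choices and degenerate inputs

* FFT padding to `next_pow2(2n)` for both the CWT and the smoothing;
  kernels built in the frequency domain; edge renormalization by the
  smoothed indicator.
* Zero coherency denominators (possible with zero-variance channels) give
  $\hat R = 0$ and a `valid = FALSE` flag rather than NaN.
* WTC is clamped at 1 for display; the raw complex $\hat R$ is kept
  unclamped (float excursions are $\le 10^{-9}$).
* EDF output quantizes to 16-bit with per-channel physical scaling; the
  round-trip error is below one quantization step. Heterogeneous
  per-channel rates are an error unless a target rate for resampling is
  given. Resampling is polyphase: zero-stuffing, a zero-phase Hamming
  FIR low-pass (exact integer group-delay compensation), decimation —
  phase integrity matters because the coherency phase carries the
  direction information.
* Power iterations start uniform and tolerate disconnected graphs; an
  empty graph yields zeros for every centrality.
* Sample quantiles use R's default (type 7) interpolation.

# Problem sizes in the test suite

The suite sizes simulations so estimator properties are visible but cheap:
coherency unit tests run at fs 200 Hz, 1 s; bootstrap calibration uses
20 replicates of fs 128 Hz, 1 s, 49 scales, $B = 99$; the cohort contrast
runs ten replicate studies of 5 + 5 synthetic subjects (fs 256 Hz, ten
4.5-s-spaced events each) through the full pipeline with
$[-2, 2]$ s × $[0, 122]$ Hz windows, unmasked GMC (both masked and
unmasked are supported; the unmasked path is the cheaper default for the
cohort study and the contrast does not depend on the mask). These sizes
are package choices; all thresholds asserted in the tests are the
method-level tolerances stated alongside them.

# Ridge broadening under one-octave scale smoothing

A property of the estimator worth knowing when reading coherence maxima
off the scale axis. For two noisy but phase-locked tones, the coherence
profile across scales is not a sharp peak at the tone frequency: wherever
the tone leaks into neighbouring scales it still dominates the (tiny)
noise, and the one-octave scale boxcar then flattens the profile into a
plateau roughly an octave wide with values within $10^{-3}$ of 1. The
*location of the plateau's maximum* is therefore decided by second-order
structure. In the in-silico benchmark the x channel's gates switch at
cosine antinodes, so x carries unit-step discontinuities (at t = 0.5 and
1.1 s) whose broadband, channel-specific energy grows toward larger
scales; this depresses coherence below the tone more than above it, and
the boxcar-averaged argmax lands **4–6 voices above** the tone (≈ 56 Hz
for the 45 Hz rhythm, ≈ 14 Hz for the 10 Hz rhythm) — reproducibly across
seeds, and robustly to the time-kernel width. Disabling scale smoothing
(`smooth_scales = 1`) restores the argmax to within one voice of the tone
(44.7 / 10.6 Hz); larger noise does the same by letting the
signal-to-noise ratio dominate the profile. The package keeps the
twelve-scale default because it is the method's stated convention; when
the goal is to *read off a frequency*, use the per-scale profile or report
the plateau, not its argmax. `scripts/acceptance.R` computes exactly these
plateau argmax values so the behaviour is reproducible.

# Known limitations

* Ensemble coherency assumes epochs are realisations of the same process
  (ergodicity in place of stationarity); drifting coupling across epochs
  is averaged, not tracked.
* The surrogate null is only as good as the user's background selection;
  background epochs containing genuine coupling make the test
  conservative.
* The full surrogate sample array is held in memory
  ($B \times$ scales $\times$ times); size $B$ and the record accordingly.
* Directed centralities see one arc per pair (or reciprocal ties); truly
  asymmetric bidirectional coupling is outside the snapshot
  representation.
* Layered layouts are heuristic; interpret them next to the heatmap and
  force-directed views.
* Neuroscan input, artifact rejection, montage re-referencing, partial
  coherence and parametric (autoregressive) directionality are out of
  scope.
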