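---
title: "Movement-locked EEG analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-locked EEG analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

motoreeg implements a complete analysis chain for movement-locked
oscillatory EEG: preprocessing, surface-Laplacian current source density
(CSD), complex Morlet time-frequency decomposition, event-related spectral
perturbation (ERSP) and inter-trial coherence (ITC), debiased weighted
phase-lag-index (dwPLI) functional connectivity with weighted graph
metrics, and cluster-based permutation statistics. A synthetic two-group
cohort generator with known ground truth makes every stage verifiable by
parameter recovery at desk scale. This vignette explains the models, the
parameters that matter, and the design decisions taken where conventions
genuinely diverge.

## Data model

The unit of analysis is the response-locked epoch: a trials × channels ×
samples array with a millisecond time axis whose zero is the button press.
The reference recording configuration is a 128-channel Biosemi ABC montage
digitized at 2048 Hz and analyzed at 256 Hz over [−4500, 2500] ms epochs;
every operation is agnostic to the channel count and works on any
`eeg_layout` (labels plus unit-sphere electrode positions).

All windows — epochs, baselines, analysis intervals, frequency bands — are
half-open, `[start, end)`. This makes sample counts rate-consistent
(7 s × 2048 Hz = 14336 samples exactly) and assigns shared band edges
(4, 8, 15, 30 Hz) to exactly one band. One consequence worth stating: at
256 Hz the ±150 ms analysis window contains 77 on-grid samples (sample
times k·3.90625 ms for k = −38..38), not 0.3 s × 256 = 76.8 rounded down;
the half-open rule is applied to the actual sample grid, and since 0 ms is
on-grid the window is symmetric.

## Preprocessing

Continuous recordings are band-pass filtered at 0.5–70 Hz with 4th-order
Butterworth filters and notch-filtered at 50 Hz (constrained biquad,
Q = 45), all applied forward–backward, which doubles the effective order
and cancels the phase response exactly. The zero-phase pass uses odd
reflection padding of 3 × (filter length − 1) samples; with the long
epochs used here the startup transients never reach the analysis window.
Epoching precedes downsampling, as in the recording pipeline the package
models; resampling is FFT-based (band-limited), chosen over polyphase
filtering because it makes the output length exactly
`round(n · target/current)` and keeps 0 ms on the new grid.

Bad channels are replaced with the Perrin spherical-spline interpolant
fitted on the remaining channels. Detection is deliberately out of scope —
the caller supplies the bad-channel set — because robust automatic
detection is tied to artifact-removal pipelines (ICA and component
classifiers) that this package does not implement.

## Spherical splines and the surface Laplacian

The interpolation and Laplacian kernels are the truncated Legendre series

$$G(x) = \frac{1}{4\pi}\sum_{n=1}^{N}\frac{2n+1}{(n(n+1))^{m}}P_n(x),
\qquad
H(x) = \frac{1}{4\pi}\sum_{n=1}^{N}\frac{2n+1}{(n(n+1))^{m-1}}P_n(x),$$

with flexibility m = 4, smoothing λ = 10⁻⁵, truncation N = 10 and unit
sphere radius as defaults. N = 10 is deliberately low compared with the
N = 50 common in other implementations; it is kept as the package default
because it is the reference configuration of the toolbox this chain
models, and it is a visible config parameter. The practical effect of
N = 10 is spatial: the CSD point-spread function of a focal source has its
negative surround ring near 30–60° of arc rather than tightly around the
source; tests pin this sign structure rather than a neighbour-level claim.
Legendre polynomials are evaluated by the Bonnet recurrence; closed forms
are avoided for stability.

The CSD transform matrix is assembled once per layout —
$\mathrm{CSD} = H\,S^{-1}\big(v - c_0\mathbf{1}\big)$ with
$S = G + \lambda I$ and $c_0$ fixed by the $\sum_i c_i = 0$ constraint —
and applied to every sample as a single matrix product. Its rows sum to
zero by construction, so a spatially constant potential maps to zero
identically, and degree-1 spherical harmonics are (truncated-series)
eigenpatterns. The overall sign convention is such that a harmonic
pattern correlates positively with its CSD image; absolute scale (µV/m²
on the unit-radius head) does not affect ERSP, ITC or dwPLI, all of which
are scale-free in the relevant sense.

## Time-frequency decomposition

The decomposition is a continuous wavelet transform with the analytic
Morlet wavelet $\psi(t) = (\pi B)^{-1/2}e^{-t^2/B}e^{i2\pi Ct}$ with
B = 1 s² and C = 1 Hz ('cmor1-1'), evaluated by FFT convolution with the
one-sided (analytic) kernel $\hat\psi(sf') = e^{-\pi^2BC^2(f'/f-1)^2}$ at
scale s = C/f. Two normalization facts the tests rely on: a pure sinusoid
of amplitude A yields coefficient magnitude A at its own frequency (L1
normalization), and the coefficient phase at time t equals the sinusoid's
instantaneous phase, so the phase at the button press is read directly at
t = 0. This is a very low-Q wavelet (about one cycle per envelope
e-folding), so spectral smoothing is broad — roughly ±22% of the center
frequency at one standard deviation — which is why recovery tests read
values at the grid point nearest the planted frequency rather than
expecting a sharp peak.

The frequency grid is logarithmic, `fmin · ratio^k`, with defaults
0.32–73 Hz and ratio 1.1 (57 frequencies, the last at ≈66.5 Hz). The grid
is anchored ascending from fmin; the ratio fixes the spacing but not the
anchor, and anchoring at fmin makes the grid reproducible from the two
printed range endpoints. Zero padding is used at the epoch edges and a
cone-of-influence mask flags samples within one envelope e-folding time
(√B·C/f seconds) of either edge; with [−4500, 2500] ms epochs the ±150 ms
analysis window is clean at every grid frequency above 0.5 Hz.

## ERSP and ITC

ERSP uses the single-trial gain model: each trial's power is divided by
that same trial's mean baseline power,

$$P_k^{\%}(f,t) = \frac{|F_k(f,t)|^2}{\mu_B'(f,k)}, \qquad
\mu_B'(f,k) = \frac{1}{m}\sum_{t'\in B}|F_k(f,t')|^2,$$

and the map is $10\log_{10}\big(\tfrac{1}{n}\sum_k P_k^{\%}\big)$ dB. The
baseline window is [−3500, −3000) ms, early enough to avoid the slow
premovement potential. Because each trial is normalized by its own
baseline, the estimator is invariant to per-trial amplitude scale; trials
with exactly zero baseline power at a cell (a synthetic-data edge case)
are excluded cellwise rather than producing infinities.

ITC is the resultant length of the across-trial unit phase vectors,
$\mathrm{ITC} = |\tfrac{1}{n}\sum_k e^{i\varphi_k}|$: 0 for uniformly
random phases, 1 for perfect locking. For von Mises distributed phases
with concentration κ the population value is the Bessel ratio
$I_1(\kappa)/I_0(\kappa)$, which is what the generator's ground truth
reports and what recovery tests target. The sample ITC is upward-biased
at small n (≈1/√n under uniformity), which is why the generator offers
optional trial-count equalization between groups (off by default, since
whether the modeled study equalized is unknown). Group contrasts against
baseline use the subject's baseline-window map averaged over time and
replicated across the analysis window — an explicit interpretation of
"compared to baseline activity" that the within-group tests document.

## dwPLI connectivity and graph metrics

For each channel pair and each frequency–time cell in band × window, with
$I_k$ the imaginary part of the per-trial cross-spectrum,

$$\mathrm{dwPLI} = \frac{(\sum_k I_k)^2 - \sum_k I_k^2}
{(\sum_k |I_k|)^2 - \sum_k I_k^2},$$

defined as 0 when the denominator vanishes (all $I_k = 0$, i.e. pure
zero-lag coupling — the estimator's insensitivity to volume conduction).
Cells are computed individually and then averaged over the band × window
(per-cell-then-average, matching the description of averaging the
window's dwPLI values; a pooled-cross-spectrum variant was considered and
rejected as a different estimator). Debiasing makes small-sample values
negative on occasion; negative averaged entries are clamped to zero by
default because graph metrics require nonnegative weights, and the raw
signed matrix remains available via `clamp_negative = FALSE`.

Graph metrics follow the weighted Brain Connectivity Toolbox definitions:
node strength (row sums), global efficiency (mean inverse shortest-path
length on lengths 1/w), and weighted local efficiency

$$E_{loc}(i) = \frac{\sum_{j\ne h \in N(i)} (w_{ij}w_{ih})^{1/3} \,/\,
d_{jh}(N_i)}{k_i(k_i-1)},$$

where $d_{jh}(N_i)$ is the shortest path inside i's neighbourhood
subgraph on cube-root lengths $(1/w)^{1/3}$. The cube roots appear once,
on the weights and inside the lengths — not again on the inverse distance;
this is the toolbox's formula, and both efficiencies are validated against
brute-force Floyd–Warshall oracles on all random graphs up to 6 nodes.
Proportional thresholding keeps the round-half-up proportion of the
strongest edges (2% of 8128 possible edges on 128 channels is 162.56,
rounded to 163) with a deterministic index-order tie-break.

## Cluster-based permutation statistics

Pointwise t statistics (paired within group, pooled-variance two-sample
between groups) are thresholded at the two-sided t quantile at
cluster-α = 0.001; supra-threshold cells of the same sign are clustered by
connectivity over time (±1 sample), frequency (±1 grid step on the
logarithmic grid — spectral adjacency is not specified by the modeled
design, so nearest-grid-step is used and stated), and space (channel
adjacency = union of pairs closer than 0.4 on the unit sphere and Delaunay
triangulation edges on the azimuthal-equidistant projection; union rather
than intersection, since the combination rule is not specified). The
cluster statistic is the mass (sum of member t values); the null is the
maximum |mass| over 10,000 randomizations (sign flips of subject
differences, or group relabelings preserving group sizes), and
$p = (1 + \#\{\text{null} \ge |\text{mass}|\})/(n_{perm}+1)$ — the +1
correction keeps p positive and the test valid at finite permutation
counts. Two-sided testing splits cluster-α across tails. Scalar graph
metrics are compared with a permutation test on the absolute group-mean
difference, run exhaustively whenever the number of group assignments is
small (≤ 2·10⁵), and per band and metric without cross-band correction
(a Bonferroni option exists in the caller's hands; the modeled reporting
style is uncorrected per-band tests).

Implementation note: for both cluster tests the per-cell sums of squares
are permutation-invariant (sign flips preserve squares; relabelings
preserve the pooled total), so each permutation costs one matrix product
plus clustering of the few supra-threshold cells, which is what makes
10,000 randomizations routine and the 500-permutation calibration suites
fast.

## The synthetic cohort generator

The generator produces two groups of epoched subjects with three planted
components over 1/f^γ background noise (γ = 1 by default):

- a **phase-locked burst** (Gaussian envelope, σ = 150 ms, centered at
  0 ms so its energy falls inside the ±150 ms statistics window) whose
  per-trial phase is von Mises with group-specific κ — the ITC ground
  truth is $I_1(\kappa)/I_0(\kappa)$;
- an **induced oscillation** with uniform random phase per trial whose
  amplitude is multiplied by a group-specific gain g inside the event
  window — the ERSP ground truth is 20·log₁₀(g) dB (amplitude gain g is
  power gain g²). The default gains, 10^(−0.55/20) for the young-like and
  10^(−2.389/20) for the old-like group, are anchored to the group-mean
  ERSP values of the full study design the generator emulates;
- **lagged coupling**: a shared oscillation injected into channel pairs
  with a π/2 phase lag and group-specific amplitude, which dwPLI should
  detect while rejecting the zero-lag noise correlations.

Default cohort sizes mirror the emulated recording conditions: 22
subjects per group and 113 (young) / 88 (old) trials per subject per
hand, [−4500, 2500] ms at 256 Hz, 128 channels. Tests and the analysis
drivers pass smaller explicit configurations (4–16 channels, 16–100
trials, 2–8 subjects per group); the defaults are the study conditions,
the overrides are desk-scale problem sizes.

Background noise is mixed across channels through a smooth Gaussian
spatial kernel (chord-distance width 0.6 on the unit sphere). An earlier
design used a random orthogonal mixing matrix, but orthogonal mixing
creates spatially *rough* zero-lag correlations, which the surface
Laplacian amplifies — the opposite of volume conduction, which is smooth
and which the Laplacian and dwPLI are supposed to suppress. The Gaussian
kernel reproduces the smooth zero-lag structure that makes CSD and dwPLI
meaningful, and this is the generator's default.

Two related facts shape how recovery is tested. First, the surface
Laplacian is a spatial high-pass: a component injected *identically* on
all (or a patch of) channels is annihilated (or strongly attenuated) by
CSD. Ground-truth components therefore accept per-channel spatial weight
profiles, and spatially peaked or graded profiles are used where the CSD
path is exercised; exact ITC/ERSP recovery against theory is asserted on
the sensor-space decomposition, where the planted per-trial phases and
gains arrive unmixed. Second, what the generator does *not* emulate:
biophysical forward models, ocular/muscle artifacts (ICA cleaning is out
of scope), heavy-tailed noise, inter-subject variability in electrode
placement. Passing recovery tests therefore demonstrates estimator
correctness under the stated signal model, not robustness to real-world
artifacts.

## Problem sizes and numerical tolerances

The test suite and the analysis drivers use desk-scale configurations
chosen to finish in minutes on one core while keeping every statistical
check meaningful: cluster-test calibration runs 200 null simulations at
16 channels × 10 frequencies × 20 time points with 12 subjects and 500
permutations (family-wise false-positive rate asserted within
[0.02, 0.08] around the nominal 0.05); ITC recovery uses 100 trials × 50
seeds (within 3 standard errors of the Bessel ratio); ERSP recovery
asserts ±0.5 dB; graph metrics are checked against brute-force oracles on
1000 random graphs of up to 6 nodes; the end-to-end group contrast uses
16 channels and 8 subjects per group. Analytic identities (ITC limits,
ERSP arithmetic, dwPLI algebra, CSD on constants) are asserted at
1e-8–1e-12. The `analysis/` drivers run the same chain at 16 channels,
6 subjects per group and 60 trials, and state their outputs in
`results/`.

## Known limitations

- The EDF/BDF reader targets continuous single-record-rate files with a
  status/trigger channel (the Biosemi convention); EDF+ annotations and
  variable record layouts are not parsed.
- N = 10 series truncation gives a broader CSD point spread than N = 50
  implementations; raise `max_degree` for sharper topographies.
- Cluster p-values are Monte Carlo estimates; at 10,000 permutations the
  resolution floor is ~10⁻⁴.
- The dwPLI band matrix is O(channels² · cells · trials); at the full
  128-channel geometry use restricted grids or expect minutes per band.
- ITC group contrasts with unequal trial counts inherit the estimator's
  small-n bias; enable `equalize_trials` when that matters.
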