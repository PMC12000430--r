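---
title: "Methods: cortico-subthalamic oscillatory coupling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cortico-subthalamic oscillatory coupling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stncoupling)
```

# Scope

`stncoupling` implements a complete analysis chain for resting-state
multisite intracranial recordings in Parkinson's disease — subdural
electrocorticography (ECoG) over sensorimotor cortex together with local
field potentials from subthalamic deep-brain-stimulation leads (STN-LFP) —
across therapy conditions (OFF therapy, ON levodopa, ON STN-DBS). The chain
covers preprocessing, local oscillatory power (including spatio-spectral
decomposition), undirected and directed multivariate spectral coupling,
bispectral transmission-delay estimation, non-parametric paired permutation
statistics, and mixed-effects linkage of coupling spatial patterns to
structural and functional connectomic measures. Because clinical
recordings of this kind are not freely distributable, the package ships a
first-class synthetic-data module that generates recordings, streamline
atlases, functional volumes and cohort tables with known ground truth;
every stage is validated against that ground truth.

# Synthetic data: what it emulates, and what it does not

`sim_config()` / `simulate_sources()` / `couple_and_mix()` produce
multichannel recordings with the statistical structure the analysis
assumes:

* **Band-limited oscillatory sources.** Gaussian noise is band-filtered,
  passed through a monotone exponential transform (`nongaussianity`
  controls the exponent) and re-filtered. The transform produces the
  skewed, non-zero third-order-cumulant statistics that bispectral delay
  estimation requires. A subtlety worth knowing: a band `(lo, hi)` can
  only carry bispectral structure if it admits in-band frequency triples
  (`hi > 2 * lo`), because the bispectrum lives where `f1`, `f2` and
  `f1 + f2` all carry signal. A high-beta-like band such as 20–30 Hz is
  therefore necessarily Gaussianised by the re-filtering; delay-analysis
  simulations use a broad 5–45 Hz band instead, consistent with running
  delay estimation on broadband 3–100 Hz signals.
* **A directed, delayed cortex→STN interaction.** The STN-set source is
  the cortical source delayed by `coupling_delay` (default 25 ms, an
  indirect-pathway-like latency; delays must be whole samples) and scaled
  by `coupling_gain`, plus an independent band-limited innovation
  (`innovation_sd`, default 0.3). Both source sets are mixed into their
  channel sets through random full-rank mixing matrices; a single global
  scale factor (not per-channel normalisation) preserves mixing diversity
  so that bipolar derivations retain the source.
* **Background and nuisance components.** 1/f-shaped Gaussian noise at a
  configurable per-channel SNR (default 10 dB), common-mode 50 Hz line
  noise (default 5 µV), and optionally a periodic stimulation artifact.
* **The stimulation artifact** is a continuous-phase biphasic kernel: each
  sample's value is a pure function of `t mod P` where `P = fs/f_stim`.
  This matches hardware whose stimulator is periodic in continuous time and
  puts the artifact's power exactly on the stimulation harmonics. Pulses
  narrower than one sample (60 µs at 4000 Hz is 0.24 samples) are smeared
  to one-sample width, as acquisition anti-alias filtering would do.
  Channel gains are log-uniform on (0.5, 2).

The generator does **not** emulate biophysically realistic neural mass
dynamics, patient-specific anatomy, non-stationary bursting, movement or
muscle artifacts beyond generic amplitude transients, or cross-frequency
structure. Passing tests therefore demonstrate correctness of the
estimators under the stated statistical assumptions, not robustness to
every pathology of clinical data.

# Preprocessing

Recordings are notch-filtered at the mains frequency and all harmonics
below Nyquist, band-pass filtered at 3–150 Hz, cut into 2 s epochs,
and resampled to 500 Hz (1000 Hz for delay analysis) after zero-phase
anti-alias FIR filtering. All zero-phase filtering is implemented in the
frequency domain: the spectrum of the reflection-padded signal is
multiplied by the analytic forward-backward Butterworth amplitude response
`|H|^2 = 1/(1 + (f/fc)^(2k))`. Evaluating the response analytically is
exact at any order and cutoff, whereas high-order transfer-function
coefficients degenerate numerically at extreme normalised cutoffs; it is
also an order of magnitude faster than per-channel time-domain filtering.
Steady-state attenuation contracts (≥ 40 dB in stopbands, < 1 dB passband
ripple) refer to the record interior; any zero-phase filter rings at the
very edges of a finite record, and edges are discarded by epoching.

Artifact-laden epochs are rejected automatically by a per-channel
peak-to-peak z-score across epochs (default threshold 4.0, config-exposed),
a deterministic surrogate for visual marking. Bipolar re-referencing takes
differences of adjacent contacts within each site, cancelling common-mode
components including the recording reference exactly.

To standardise information content across recordings of unequal length,
kept epochs are resampled with replacement into fixed-size bootstrap
segments (30 epochs = 60 s per segment; 200 segments for coupling, 400 for
delay analysis). Coverage of the available epochs is reported, not
enforced: sampling with replacement cannot guarantee full coverage.

## Stimulation-artifact removal

`parrm_remove()` is a period-based template method. The exact artifact
period is estimated by maximising the variance explained by a
period-phase template over a three-stage grid around `fs/f_stim` with a
final golden-section refinement. Removal then subtracts, from each sample,
a template value obtained by averaging samples at similar period-phase
within a sliding time window (default 2 s).

Two implementation choices matter and were made after the naive variant
failed in testing:

* **Adaptive phase grid.** When the stimulator and amplifier clocks are
  near-commensurate (130 Hz at 4000 Hz is exactly 400/13 samples), the
  sampled phases cluster on a slowly drifting lattice; a fixed fine phase
  tolerance then leaves most bins holding only the sample itself, and
  template subtraction degenerates into self-subtraction. The grid
  therefore starts at `phase_tol` (0.01 samples) and widens until the 10th
  percentile of per-sample bin occupancy reaches 16 members; the template
  is evaluated at each sample's exact phase by linear interpolation
  between bin centres, and per-block templates are crossfaded for
  continuity.
* **Detection gate.** If the phase template explains less than 1% of the
  variance, nothing periodic is present and the recording is returned
  unchanged (logged). Unconditional subtraction would only inject template
  noise into clean data.

A limitation is intrinsic to all period-locked template methods: with
exactly commensurate clocks, any physiological signal on the same
super-period lattice (multiples of 10 Hz for 130 Hz at 4000 Hz) is
absorbed into the template. With realistically independent clocks (the
validation fixtures use a 5×10⁻⁵ relative skew) suppression exceeds
30 dB at the stimulation frequency with < 1 dB distortion of 10–35 Hz
band power.

# Spectral power

Power spectra use Slepian multitapers. The "5 Hz bandwidth" convention is
interpreted as the full smoothing bandwidth: half-bandwidth `W = 2.5` Hz,
`2·T·W − 1 = 9` tapers for 2 s epochs, frequency resolution
`1/T = 0.5` Hz (config-exposed, since conventions differ between tools).
Integrated power satisfies Parseval against signal variance within 5%.
Spectra are normalised to percent total power over 5–60 Hz with a 45–55 Hz
line exclusion window (the broader 5–95 Hz range is available); normalised
values sum to 100 per channel by construction. Canonical bands follow the
mu/alpha 8–12, low-beta 12–20 and high-beta 20–30 Hz definitions with
inclusive endpoints.

## Rank normalisation and spatio-spectral decomposition (SSD)

Channel counts differ between subjects and lead models, so channel sets
are reduced to fixed component counts by SVD before multivariate analysis:
bipolar cortex 4, bipolar STN 3, unipolar cortex 5, unipolar STN 3. The
projection is retained so spatial patterns can be mapped back to physical
contacts.

SSD finds spatial filters maximising band power against flanking-band
power (±1 Hz flanks, realised as the band±flank band-pass followed by a
band-stop at the band) through a generalised eigendecomposition, solved by
noise-whitening followed by a symmetric eigenproblem; a relative ridge of
1e-8 is added if the flank covariance is near-singular (logged). The flank
covariance is bandwidth-normalised (scaled by band width over total flank
width) so spectrally flat data scores an SNR eigenvalue of 1. Spatial
patterns follow the covariance-times-filter construction
`A = C_s W (WᵀC_s W)⁻¹`, absolute values, Z-scored across channels within
a component; ties in the eigenvalue ordering are broken by forcing the
largest-magnitude filter weight positive.

One design choice deserves emphasis. Covariance-based patterns are
covariant to per-channel gain, so no gain-invariance can hold without a
per-channel normalisation. Channels are standardised by their
**out-of-band residual standard deviation** (band-stop at band ± flank)
before the decomposition. An earlier variant using the flank-band SD was
abandoned: real oscillatory sources are not spectrally compact, bleed into
±1 Hz flanks, and thereby tie the scale estimate to oscillation strength,
flattening recovered patterns. The out-of-band residual estimates channel
gain from the broadband noise floor only; with it, patterns are invariant
to rescaling any channel (to ~1e-13) while recovering true mixing columns
with |r| ≈ 0.99 on ground-truth fixtures.

# Coupling

Cross-spectral densities of (rank-normalised) unipolar data are computed
per bootstrap segment with the same multitaper parameters; per-epoch CSD
tensors are computed once and averaged per segment. All coupling measures
are averaged across the 200 segments.

* **Imaginary coherency (grand average).** `C_ij = S_ij/√(S_ii S_jj)`;
  the absolute imaginary part is taken per seed–target pair and then
  averaged (the alternative order is a config flag). Being blind to
  zero-lag interactions, the measure is immune to volume conduction and
  to the shared subthalamic recording reference.
* **Maximised imaginary coherency (MIC).** Per frequency, the seed and
  target blocks are whitened by the inverse square roots of the real parts
  of their block CSDs (ridge 1e-8 if near-singular); the largest singular
  value of the imaginary part of the whitened cross-block is the coupling
  value, and the singular vectors, back-transformed and multiplied by the
  real block CSDs, give spatial patterns (absolute, Z-scored; back-mapped
  through the rank-reduction projection when one was used). The first
  singular vector is scaled so its largest-magnitude seed weight is
  positive.
* **Time-reversed Granger causality (TRGC).** A VAR (default order 60,
  config-exposed; validation fixtures use orders 8–12 appropriate to their
  low-order generating processes) is fitted to the autocovariance sequence
  obtained by inverse Fourier transform of the CSD, using Whittle's
  multivariate Levinson recursion. Frequency-resolved Granger scores in
  both directions come from the transfer function and partialised
  innovation covariance of the single full model; net = seed→target minus
  target→seed; the same net score computed after transposing the
  autocovariance sequence (time reversal) is subtracted. Statistics are
  evaluated on 3–50 Hz. Positive values mean cortex drives STN. The
  spectral route (CSD → autocovariance → VAR) was chosen over time-domain
  least squares for consistency with the undirected measures; a
  state-space estimator would be a natural extension.

On zero-lag immunity: for data whose channels are exact real-scaled
copies, the imaginary part vanishes identically and ImCoh/MIC are exactly
zero, with or without an added common-mode signal. For generic
instantaneous mixtures the measures are zero only in population;
finite-sample values are compared against an epoch-shuffled null within
the band occupied by the shared source. Outside that band observed and
null values are exchangeable, so a comparison "at all frequencies" would
fail at the nominal rate by chance. For TRGC the epoch-shuffled null is
not exchangeable at all — the statistic's sampling variance grows with
coherence, which the shuffle destroys — so zero-lag immunity is
demonstrated as (a) an order of magnitude separation from a genuinely
coupled reference at matched data size and (b) monotone shrinkage toward
zero with increasing data.

# Bispectral time-delay estimation

Per-epoch Fourier coefficients of the 1000 Hz bipolar data use a Hamming
window and a 4001-point transform, so delay estimates fall on a 1 ms grid
spanning the full ±2 s epoch length. The cross-bispectrum places the
target channel in the second frequency slot:
`B_xyx(f1,f2) = E[X(f1) Y(f2) X*(f1+f2)]`, estimated over the region where
`f1`, `f2` and `f1+f2` all lie in the broadband 3–100 Hz analysis range
(no antisymmetrisation). The delay-strength function is the inverse
Fourier transform, over `f2`, of the unit-magnitude phase difference
between the auto- and cross-bispectra (computed as
`(B_xxx/|B_xxx|)·conj(B_xyx/|B_xyx|)`, avoiding trigonometric calls),
accumulated over `f1` and Hermitian-completed so the strength function is
exactly real. For a pure delay the phase difference is linear in `f2` with
slope proportional to the delay, so the strength peaks at the true lag;
positive tau means the seed (cortex) leads. Ties at the argmax resolve
toward the smallest |tau|. The absolute normalisation of the strength
function is left arbitrary; only argmax positions and relative comparisons
are used downstream.

Per-connection confidence uses the 400 bootstrap segments: tau is computed
per segment, the 80% percentile interval (type-7 quantiles) of the segment
taus is formed, and connections whose interval contains 0 ms are flagged
invalid and excluded from tau summaries — mirroring the exclusion of
subjects with no confident connections. Band-restricted delay estimation
is deliberately out of scope: single-band estimates have too little
bispectral support to be reliable.

Local maxima of the strength function at positive lags, above the
strength at 0 ms and at least 5 ms apart (greedy by height), are grouped
into 10 ms windows — the first window being 1–9 ms, the
hyperdirect-pathway latency range, with 0 ms excluded — and counts are
normalised to percentages per connection set. Per-subject percentages are
averaged across subjects (pooling is available by flag).

# Permutation statistics

Paired contrasts use the difference in means with a sign-flip null
(conditions randomly reassigned within each subject pair). When the full
`2^n` flip set is no larger than `n_perm` it is enumerated exactly;
otherwise Monte Carlo sampling uses the +1-corrected estimator
`p = (1 + #{|perm| ≥ |obs|})/(1 + n_perm)`. The default is 100000
permutations at alpha 0.05; delay contrasts are one-sided. Frequency-wise
contrasts use cluster correction: per-bin statistics are thresholded at
the pointwise two-sided permutation alpha quantile (a config-exposed
choice, recorded in every output, since fixed-height thresholds are an
alternative), contiguous supra-threshold bins of common sign form clusters
scored by their summed statistic (mass, not extent), and cluster p-values
come from the maximum-absolute-mass null. Windowed peak-count contrasts
use Bonferroni correction. Contrasts with unequal group sizes use only
their complete pairs.

# Connectomic linkage

Structural connectivity counts streamlines passing within 5 mm of an ECoG
contact and 3 mm of an STN-LFP contact (Euclidean distance in MNI mm,
vertex proximity, inclusive boundary; segment interpolation is a dialect
the synthetic fixtures are built to be insensitive to). Functional
connectivity seeds a sphere (5 mm) at each ECoG contact in a 4D volume,
correlates the mean seed time course with every voxel, and averages the
map over indirect-pathway parcels (caudate, putamen, external pallidum,
STN). Raw correlations are used; Fisher-z transformation is a flag.

Both connectivity measures are modelled against band-averaged (low beta
12–20, high beta 20–30 Hz) MIC spatial-pattern values per contact with
`connectivity ~ pattern + medication + (1 | subject)`, fitted by REML;
medication enters as a binary fixed effect (off = 0, levodopa = 1).
Reported quantities are per-term coefficients with Satterthwaite p-values,
the conditional R² under the variance-partition definition (fixed plus
random variance over total), BIC, and the Pearson correlation of fitted
versus observed response. Alternative fixed-effect sets (STN only;
putamen + GPe + STN; putamen + GPe) support the model-comparison analyses.
Singular fits are reported with a boundary-variance flag, never silently.

# Pipeline, reproducibility and problem sizes

`run_pipeline()` orchestrates simulate → preprocess → power/SSD →
coupling → delay → statistics → connectomics with per-stage artifacts
(TSV/JSON/NIfTI/binary recordings) and a manifest of MD5 hashes; all
randomness derives from a single root seed expanded per stage, so reruns
are hash-identical. Configuration defaults follow the reference analysis
(200/400 segments, VAR order 60, 100000 permutations, 2 s epochs at
500/1000 Hz).

The shipped validation suite runs scaled-down problem sizes chosen to
exercise every code path at meaningful statistical power: delay recovery
uses 20 simulations of 120 s at 1000 Hz with 100 bootstrap segments;
direction recovery 100 runs of 80 s bivariate VAR data; pattern recovery
20 simulations of 40 × 2 s epochs; permutation calibration 500 paired
replicates and 200 cluster replicates at 1000 permutations; mixed-model
recovery 100 cohorts of 18 subjects; the end-to-end determinism demo uses
6 subjects × 2 conditions of 16 s recordings with 6 segments per stage.
`scripts/acceptance.R` recomputes the same quantities at moderately
smaller replicate counts and writes them as JSON.

# Known limitations

* Interhemispheric coupling, phase-amplitude coupling, burst dynamics and
  waveform-shape analyses are out of scope.
* The artifact-epoch rejection is an automated surrogate for visual
  inspection; its threshold is a config parameter, not a validated
  clinical criterion.
* Period-locked artifact removal absorbs physiological signal that is
  exactly commensurate with the stimulation-period lattice (see above).
* Electrode localisation is taken as given (MNI coordinates in the
  electrodes table); no imaging is performed.
* The delay sign convention assumes the designated seed set leads; reversed
  physiology appears as negative tau and is excluded from directed
  cortex→STN summaries by the tau > 0 criterion.
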