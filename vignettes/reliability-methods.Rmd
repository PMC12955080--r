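---
title: "Methods: test-retest reliability of DBS fMRI metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: test-retest reliability of DBS fMRI metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbsretest)
```

# The problem

Resting-state fMRI in patients with implanted deep brain stimulation (DBS)
hardware faces two threats that ordinary reliability studies do not: the
implant causes localized T2\*-signal loss near the leads, and stimulation
itself perturbs the signal being measured. This package quantifies how
reproducible two per-run metrics are across a test/retest pair of runs —
functional connectivity (Fisher-z correlations between parcel mean series)
and brain variability (temporal standard deviation of the parcel signal) —
separately under stimulation-OFF and stimulation-ON conditions, and
stratified by artifact involvement. Everything is exercised against a
synthetic cohort whose true reliability is known in closed form.

# The reliability model

For one subject, condition and network, the test and retest metric vectors
form an $N \times 2$ matrix whose rows are network elements (connections or
parcels). Reliability is the single-measure two-way absolute-agreement
intraclass correlation (McGraw–Wong ICC(A,1)), from the row/column/error
mean squares of the additive two-way ANOVA decomposition:

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}
  {MS_R + (k-1)\,MS_E + \tfrac{k}{N}(MS_C - MS_E)}, \qquad k = 2.$$

Assumptions and choices:

* Rows are treated as exchangeable — the network's elements are regarded as
  an approximate random sample. Spatial correlation between elements is
  real and unmodeled; this matches the estimator's standard use and is a
  known limitation (see below).
* Negative estimates are reported as-is with a flag. Truncating at zero
  would bias the downstream group contrasts toward optimism.
* A matrix with zero total variance has no defined ICC; it is flagged
  degenerate rather than forced to a number. The degeneracy test uses a
  relative tolerance of $10^4 \varepsilon$ on the total sum of squares so
  that only exactly-constant inputs trip it.
* `icc_a1()` returns a classed model object (print, summary, coef, plot
  methods); the surrounding stages are plain functions, since the package
  as a whole is a staged pipeline rather than a single estimator.

Within-visit pairings couple the two runs of a visit; between-visit
pairings enumerate every run of an earlier visit against every run of a
later one, and each pairing is kept as its own row (never averaged), so
short- and long-interval reliability can be contrasted.

# Denoising

The per-run model is confound regression **followed by** bandpass
filtering (the two-stage order is asserted by a test):

1. **Outlier frames**: framewise displacement $FD_t = \sum|\Delta trans| +
   50\,\mathrm{mm}\sum|\Delta rot|$ (backward differences, $FD_1 = 0$) above
   0.9 mm, or global-signal $|z| > 5$, flag a frame; at most 64 one-hot
   spike regressors are kept, worst-first by FD with earlier frames winning
   ties. The thresholds are configurable because the source analysis names
   only "motion-contaminated outlier volumes", not its settings; 0.9 mm and
   z = 5 are the common intermediate defaults of the toolbox family this
   models.
2. **Confound design**: per-session polynomial (order 1 — constant plus
   linear), 6 motion parameters with 6 backward-difference derivatives
   (first derivative frame set to 0), the spike columns, and the top 5
   principal components each of the demeaned white-matter and CSF voxel
   matrices (aCompCor-style). Rank-deficient columns are dropped and
   logged; a spike column can be legitimately absorbed by the motion
   derivatives when the same frame carries the excursion.
3. **Filter**: zero-phase rectangular filter in the discrete-frequency
   domain — bins with $f_{low} \le f \le f_{high}$ are kept, all others
   (including DC) zeroed. This matches the stated passband contract
   exactly, is idempotent and linear, and leaves zero column means. An IIR
   design would have none of those testable properties.
4. **Degrees of freedom**: $(n - \mathrm{rank}(X)) \cdot
   (f_{high}-f_{low})/f_{Nyq}$, floored at zero. The >30 target is enforced
   as a warning, not an error, so degenerate synthetic edge cases remain
   runnable. With the defaults (165 frames, 24 regressors, 0.01–0.10 Hz at
   TR 2.15 s) the estimate is ≈ 54.6.

The exploratory 0.01–0.25 Hz band exceeds the Nyquist frequency at TR
2.15 s (≈ 0.2326 Hz). The filter itself refuses a supra-Nyquist edge; the
pipeline caps the exploratory edge at Nyquist and records the cap in the
denoise report. Two non-steady-state volumes are assumed already removed
from the input; a `drop_initial_frames` option (0 by default, 2 for raw
scanner runs) covers the other case.

# Metrics

* Connectivity: $z_{ij} = \mathrm{atanh}(r_{ij})$ with $r$ clipped at
  $1 - 10^{-7}$ so perfectly correlated (degenerate) pairs stay finite.
* Network vectors use a pinned element order — row-major upper triangle,
  $i < j$ by ascending parcel id — so ICC inputs are reproducible across
  runs and implementations.
* Brain variability defaults to the sd over time of the parcel-mean series
  (`parcel_mean`); the alternative reading — each voxel's temporal sd
  averaged within the parcel (`voxel_mean`) — is a switch, and both are
  tested. The source text supports both readings; the parcel-mean form is
  the one consistent with its own extraction description.
* The FD convention (50 mm sphere, backward differences) is the standard
  scrubbing-literature definition; the radius is configurable. The 95th
  percentile uses linear interpolation between order statistics
  (`quantile` type 7) so motion summaries are bit-stable.

# Artifact segmentation

Otsu's threshold is computed over a 256-bin histogram of in-brain-mask
intensities by exhaustive between-class variance maximization, ties broken
toward the lower threshold (binning and tie-break pinned for bit-stable
results). The mask is `intensity < threshold` within the brain mask,
followed by removal of connected components smaller than 5 voxels
(26-connectivity) — an automated, reproducible stand-in for the manual
mask cleaning a human would do in an interactive viewer. Because Otsu
always finds *some* split, an image with no real artifact needs a guard:
when the optimum's separability (between-class over total variance,
Otsu's $\eta$) falls below 0.85 the image is declared artifact-free and
the mask is empty. A unimodal Gaussian tops out near $\eta \approx 0.64$,
while even a mild 10 %-dark bimodal image exceeds 0.9, so the guard is
far from both regimes. A parcel is "affected" on any overlap (≥ 1 voxel,
configurable), and a connection is affected when either endpoint is — the
natural reading of "all parcels containing" artifact, with the
either-endpoint rule as the package's own choice since no connection rule
is stated anywhere.

# Group contrasts

Signed-rank and rank-sum tests drop zero differences, average tied ranks,
and use exact null distributions at small n (≤ 15 non-zero pairs; combined
n ≤ 12) — full enumeration over sign patterns or group assignments of the
observed ranks, so ties are handled exactly — with tie-corrected,
continuity-corrected normal approximations beyond. Two-sided p-values are
twice the smaller tail, capped at 1. Effect sizes are Cliff's
$\delta = (\#\{x>y\} - \#\{x<y\})/(n_1 n_2)$, computed through the
rank-based Mann–Whitney identity, with a seeded percentile bootstrap CI
(10,000 replicates by default; paired designs resample pairs jointly) —
the CI method is a package choice, since none is stated for the published
intervals, and exact reproduction of those intervals is not promised.
Pearson correlations carry Fisher-z intervals
$\tanh(\mathrm{atanh}(r) \pm z_{\alpha/2}/\sqrt{n-3})$. No multiplicity
correction is applied anywhere, by design: the battery reports uncorrected
p with effect sizes and intervals as the primary quantities.

# The synthetic cohort

`generate_dataset()` emulates the study design: per subject, two runs
(test/retest, under a minute apart) in each stimulation condition, 165
frames at TR 2.15 s, optionally across several visits. Its statistical
core is the two-way variance-components model
$m_{ir} = \mu_i + s_r + e_{ir}$ with $\mu_i \sim N(0,\sigma_b^2)$ per
element, $s_r \sim N(0,\sigma_s^2)$ per run, $e_{ir} \sim
N(0,\sigma_e^2)$, giving a closed-form population reliability
$\sigma_b^2/(\sigma_b^2+\sigma_s^2+\sigma_e^2)$. Each element value is
realized as the amplitude (exact sample sd) of a band-limited 0.01–0.1 Hz
Gaussian process built on in-band frequency bins only — so the rectangular
filter is an identity on it and the raw parcel-series variability equals
the element value to machine precision. Within-network coupling
($\rho \sim U(0.3, 0.7)$ per parcel and subject, fixed across runs) gives
connectivity matrices a block structure that is stable across a subject's
runs.

Defaults, chosen once as the emulated study conditions:

| parameter | default | role |
|---|---|---|
| `sigma_row`, `sigma_session`, `sigma_noise` | 1, 0.3, 0.5 | variance components; true ICC ≈ 0.746 |
| `amp_base` | 10 | keeps amplitudes positive (truncation negligible) |
| `artifact_parcel_fraction`, `artifact_attenuation` | 0.1, 0.4 | share and depth of simulated signal loss |
| `artifact_noise_sd` | 0.5 | extra run noise on affected parcels (reduced SNR near hardware) |
| `on_modulation_sd` | 0.1 | per-parcel multiplicative stimulation gains, spatially heterogeneous ON effects |
| `motion_spike_rate` | 0.02 | transient 1.5 mm spikes, mirrored in trace and series |
| `voxels_per_parcel` | 27 | coarse 3×3×3 blocks; keeps voxel-vs-parcel distinctions at desk scale |

A master seed spawns per-subject substreams (`seed + 7919·s`), so cohorts
are bit-identical under a fixed configuration while subjects stay
independent. The phantom volume renders brain voxels at intensity 100
(sd-2 texture) with affected parcels scaled by the attenuation on a dark
exterior, so its in-brain histogram is bimodal by construction; the
two-level intensity model is a deliberate simplification — nothing is
known about the artifact's true intensity distribution, and amplitude
dropout (not geometric distortion or k-space physics) is all that is
simulated. Clinical covariates (age, target, UPDRS scores and sub-scores)
are drawn from plausible ranges purely as plumbing for the contrast
battery.

What passing tests do and do not show: the generator carries the intended
variance structure through denoising and metric extraction, so parameter
recovery validates the estimator chain — but the synthetic data have no
hemodynamic response shape, no physiological noise spectrum, no geometric
distortion, and artifact effects enter only as attenuation plus noise.
Recovery on this cohort says the code is faithful to its model, not that
real-patient ICC values are reproduced; those require the real accession
data. Two deliberate interactions are worth knowing: attenuating affected
parcels adds *stable* between-row variance to the variability channel
(raising its ICC above the closed-form truth when artifacts are enabled),
which is why the exact-recovery tests disable the artifact; and the spike
contamination is deliberately mirrored in both the motion trace and the
series so that spike regression has something real to remove.

# Problem sizes and numerical choices

The test suite and acceptance script run, as the package's own choice of
desk-scale conditions: 1,000 random matrices for the ICC oracle check
(3 ≤ N ≤ 50, k ∈ {2,3}, agreement ≤ 10⁻¹⁰), 100 replicates of a
400-element network for parameter recovery (±0.03 on the mean), 500
random histograms for the Otsu oracle, exact-test enumeration up to 10
observations, and an end-to-end cohort of 8 subjects × 2 conditions × 2
runs × 100 parcels (27 voxels each) that runs deterministically in well
under a minute. Other pinned numerics: r-clipping at $1-10^{-7}$;
percentile type 7; Otsu 256 bins with lower-tie threshold; component
filter at 5 voxels with 26-connectivity; backward differences with first
frame 0 throughout.

# Known limitations

* Element exchangeability ignores spatial autocorrelation; ICC standard
  errors (not computed here) would be optimistic, which is one reason the
  group battery leans on effect sizes rather than p-values.
* The rectangular filter has sharp spectral edges; with non-bin-aligned
  sinusoids a small leakage (< 2 % in-band loss at 0.05 Hz; < 5 % stopband
  residue at 0.20 Hz) is inherent and measured by the acceptance script.
* The separability guard makes artifact-free images yield empty masks but
  would also suppress genuinely tiny artifacts whose intensity mode blends
  into the brain's; at the simulated attenuation depths this is not a
  binding constraint.
* Degenerate and negative ICCs are retained and flagged; how (or whether)
  such values were filtered before the published group tests is unknown,
  so downstream filtering is left to the analyst.
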