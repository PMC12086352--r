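---
title: "Dissolved-phase 129Xe MRSI: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissolved-phase 129Xe MRSI: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xemrsi)
```

# The measurement

Inhaled hyperpolarized ^129^Xe dissolves from the alveolar gas into lung
tissue and plasma ("membrane") and into red blood cells, producing three
resonances: gas near 0 ppm, membrane near 197 ppm and RBC near 207-209 ppm
at a spectrometer frequency of 35.3 MHz. Because xenon follows the same
diffusion path as oxygen, the amplitude ratio RBC:M is a surrogate of
alveolar-capillary gas transfer, and the RBC resonance is sensitive to
blood oxygenation: in pigs its chemical shift *decreases* as arterial
oxygen partial pressure (paO2) rises (from 208.80 ppm at 40% inspired
oxygen to 206.81 ppm at 100%), while its linewidth broadens (71 to 80 Hz).
This package implements the complete quantitative chain for such an
experiment — on synthetic data, since the method is the deliverable:

1. a ground-truth lung phantom with a six-lobe porcine atlas
   (`generatePhantom`);
2. a simulated 3D Cartesian MRSI acquisition with a center-out spherical
   k-space pattern (`buildSphericalPattern`, `simulateAcquisition`);
3. zero-filled orthonormal Fourier reconstruction (`reconstructMRSI`) and
   point-spread-function tools (`pointSpreadFunction`);
4. prior-knowledge constrained time-domain fitting of every voxel FID
   (`fitVolume`), with Cramer-Rao lower bounds (`computeCrlb`) and SNR
   (`computeSnr`);
5. corrected quantitative maps and whole-lung summaries (`makeQuantMaps`,
   `summarizeMaps`);
6. paO2 calibration models and voxel-wise paO2 maps (`fitSlr`, `fitMlr`,
   `fitLogModel`, `predictPao2`), an exponential shift-vs-saturation
   model (`expShiftModel`) and a Hill-type oxygen-hemoglobin dissociation
   curve (`odc`);
7. ventilation defect percentage and lobe-wise regional statistics
   (`computeVdp`, `regionalSummaries`, `regionalAnova`).

# Acquisition model

The default `XeAcquisition()` encodes the protocol: 28 x 28 x 6 matrix
over a 40 x 40 x 20 cm field of view, 88 complex spectral samples at
20 kHz (zero-filled to 256, i.e. 78.125 Hz = 2.213 ppm per bin), TR
7.4 ms, a spectrally selective excitation with 10 deg flip on the
dissolved passband and 0.1 deg on the gas passband, 20 dummy scans at
30 deg (leaving cos(30)^20 = 5.6% of longitudinal magnetization in
cardiac/vascular pools), and spatial zero-filling by 2.

Two values are package choices because no protocol printout fixes them:

* **Echo time (default 0.45 ms).** Only the product exp(TE/T2*) of the
  amplitude correction depends on it; 0.45 ms approximates the second
  half of a 0.6 ms RF pulse plus receiver switching.
* **Spherical boundary rule.** The protocol states 2416 excitations but
  not the lattice-membership criterion. With centered indices
  [-N/2, N/2-1] and semi-axes N/2, plain r^2 <= 1 gives 2400 points and
  the half-voxel-offset variants 2528/1981. The shipped default
  ("inclusive-tol") is r^2 <= 1 + 1e-3, which admits the boundary shell
  at r^2 = 1765/1764 and yields exactly 2416; the next shell lies at
  r^2 = 1.0051, so the tolerance is robust. The alternatives remain
  selectable (`boundaryRule` argument).

The kz axis of the 6-plane dimension uses the same centered convention
[-3, 2] (DC at 0); this is the convention under which the 2416 count is
reproduced.

# Signal model and synthetic data

Each voxel FID is a sum over compartments

$$s(t) = \sum_k A_k \sin(\theta_k)\, e^{-TE/T_{2,k}^*}\, e^{i\phi_k}
  e^{2\pi i f_k t}\, d_k(t),$$

with $f_k$ the shift in Hz (ppm times 35.3), $d_k(t) = e^{-\pi\,lw_k t}$
for the Lorentzian gas and RBC lines, and an extra Gaussian factor
$e^{-(\pi\,lw_{G} t)^2/(4\ln 2)}$ for the Voigt membrane line. The
reported membrane linewidth is the combined Voigt FWHM via the standard
Olivero-Longbothum approximation
$f_V = 0.5346 f_L + \sqrt{0.2166 f_L^2 + f_G^2}$, because whole-lung
linewidths are conventionally quoted as a single number. The generator
fixes the Gaussian component at 40 Hz and solves the Lorentzian component
so the combined width matches the 67 Hz (40% O2) / 71 Hz (100% O2)
membrane targets; the 40 Hz split itself is a package convention — any
split reproducing the combined width is observationally equivalent at
this SNR.

**Amplitude scale.** Phantom amplitudes are stored as underlying
magnetization (corrected scale, gas = 100 a.u.); the simulated
acquisition applies sin(flip) and exp(-TE/T2*), and
`correctAmplitudes()` inverts exactly that. The corrected ratios are the
study conditions: M:Gas 0.012 at both oxygen levels, RBC:M 0.275 (40%)
and 0.330 (100%), which also reproduce the printed RBC:Gas values (0.003
and 0.004) by multiplication.

**T2^\*^ convention.** The gas compartment uses the measured gas decay
times (14.10 ms at 40%, 9.08 ms at 100%) for the exp(TE/T2*) correction;
dissolved compartments derive T2* from the Lorentzian linewidth as
1/(pi lw). Note the gas decay times are not consistent with the fitted
gas linewidth of 5-6 Hz (which would imply ~60 ms): they describe the
oxygen-dependent relaxation of the gas signal over the scan rather than
the spectroscopic linewidth. The simulator therefore uses the printed gas
*linewidth* for the FID decay and the printed decay *time* only in the
amplitude correction — both numbers are respected where each applies.

**Noise calibration.** One k-space noise SD is calibrated so the
reconstructed-voxel spectral-domain RBC SNR matches the study values (5
at 40%, 8 at 100%); see `calibrateNoiseSd` for the exact propagation
through the orthonormal transforms. The printed gas/membrane SNRs
(33-36/25-28) are *not* simultaneously reproducible with the corrected
amplitude ratios and the nominal flip-angle correction — the implied gas
SNR comes out near 20-23 — so the ratios (the quantitative endpoints)
take precedence and RBC (the peak that drives every oxygenation metric)
anchors the noise level. Membrane SNR then lands at ~25, close to print.

**Heterogeneity.** `heterogeneityConfig()` models regional structure as
additive lobe-level offsets, a deterministic linear anterior-posterior
gradient (posterior lungs are better perfused in the supine animal, and
posterior RBC shifts respond more strongly to oxygen), and within-lobe
voxel noise. No publication reports within-lobe voxel-level variance for
these metrics, so the defaults (3% relative amplitude, 0.05 ppm shift,
1 Hz linewidth at the voxel level; 5%/0.10 ppm/2 Hz at the lobe level;
0.4 ppm anterior-posterior RBC-shift span) are explicit, documented
package choices scaled by a single `scale` argument; `scale = 0` gives
the homogeneous phantom used in recovery studies.

What the generator deliberately does **not** emulate: B0 inhomogeneity,
cardiac/vascular residual signal beyond the dummy-scan arithmetic,
respiratory motion, coil sensitivity profiles, and airway gas outside
the lung. Tests passing on this phantom therefore validate the numerical
chain (sampling, reconstruction, estimation, statistics), not robustness
to those instrumental effects.

# Reconstruction

All Fourier transforms are orthonormal, so Parseval checks are
scale-free and full Cartesian sampling is inverted exactly (the
round-trip error is at machine precision, asserted below 1e-9). Sampled
FIDs are gridded (unsampled corners stay zero, exactly as implied by
zero-filled Cartesian reconstruction — no density compensation, no
iterative recovery), spatially zero-padded by the configured factor with
a sqrt(padded/native) rescale so voxel amplitudes keep the native-grid
scale, inverse-transformed per time point, then spectrally zero-filled
and transformed per voxel with the calibrated ppm axis attached.

# Spectral fitting

Fitting is in the **time domain**: with 88 samples of an ~4 ms-T2*
signal the information lives in the early FID, truncation sidelobes make
frequency-domain fits awkward, and the model is exact in time. Each
voxel solves a bounded nonlinear least-squares problem (Levenberg-
Marquardt via `minpack.lm::nls.lm`) over 11 parameters — three
amplitudes, three shifts, three Lorentzian widths, the membrane Gaussian
width, and one shared zero-order phase — with analytic complex
Jacobians. Default bounds: shifts within +/-5 ppm of the prior, gas
linewidth 1-50 Hz, dissolved 5-300 Hz, amplitudes >= 0. Optimization is
deterministic: a single start at the prior values with amplitudes and
phase initialized by one linear solve; no restarts.

The prior's starting values are first refined on the average FID
(`optimizePrior`), mirroring the usual practice of solving the
least-squares of the FID average before per-voxel fitting; bounds are
never moved, and a pure-noise average (under 20% of signal energy
explained) leaves the prior untouched with a warning flag.

**Phase correction.** A Lorentzian delayed by tau carries exactly the
constant phase 2 pi f0 tau at its own resonance, so the first-order
(dead-time) term is identified from the frequency-proportional phase
across the well-separated xenon resonances: peaks are located in the
zero-filled magnitude spectrum, their frequencies refined to sub-bin
precision by maximizing the direct DTFT magnitude (the phase of an
off-center bin is contaminated by steep lineshape phase, about
atan(offset/(lw/2))), and the delay maximizes the magnitude-weighted
phasor alignment of the peak phases. With a single detectable peak the
delay is not identifiable and is reported as zero. Residual zero-order
phase error from overlapping membrane/RBC tails is a few hundredths of a
radian; the rotation round trip itself is exact.

**CRLB.** The Fisher information is Re(J^H J)/sigma^2 at the fitted
parameters with the time-domain noise SD derived from the spectral noise
window; bounds are absolute per-parameter SDs, verified against
Monte-Carlo estimator spread within 15% at SNR 20-30. Noise itself is
measured as the SD of the real spectrum in the -250 to -150 ppm window —
far from all three resonances but, deliberately, *including* truncation
sidelobes of the strong peaks, exactly as a window-based measurement on
real data would.

# Maps, masking and the whole-lung statistic

Fitted amplitudes are corrected by exp(TE/T2*)/sin(flip) per compartment
and masked at 0.6 times the mean gas amplitude, the mean taken over
voxels with converged fits (a full-FOV mean would be dragged down by
empty background). Ratio, shift, linewidth and RBC-membrane-difference
maps are NA outside the mask; NaN flags division by zero, and flagged
voxels are excluded from all statistics.

Whole-lung summaries come in two flavours, both reported:

* voxel-map means (`summarizeMaps`), matching what a reader of the maps
  would compute;
* a **volume fit**: one fit of the masked-mean FID (`runAnimalVolume`'s
  `volumeFit`). Because averaging ~10^2-10^3 voxel FIDs of a
  spatially-varying amplitude but common spectral content raises the
  effective SNR by ~sqrt(n), this statistic is free of the small-sample
  nonlinearity bias that affects per-voxel estimates at RBC SNR 5-8
  (mean-of-voxel-ratios is a ratio of noisy quantities and inflates by
  1-3% there; the per-voxel shift mean acquires about -0.01 ppm). The
  volume fit is the default whole-lung calibration statistic, and it
  frees the per-peak phases: Monte-Carlo A/B comparison showed that at
  the volume fit's high effective SNR the shared-phase constraint
  couples gas-region noise into the RBC shift through the common phase
  term (a millippm-scale curvature bias), whereas the per-peak-phase fit
  of the same masked-mean FIDs is unbiased. Per-voxel fits keep the
  shared phase, where the constraint stabilizes low-SNR voxels.
  Replicate studies confirm the volume-fit RBC shift and RBC:M are
  unbiased within Monte-Carlo error.

# Oxygenation models

`fitSlr` calibrates RBC shift (ppm) or linewidth (Hz) against paO2
(mmHg) by ordinary least squares; the two-group means reproduce the
published rounded slopes (-0.01 ppm/mmHg, 0.04 Hz/mmHg). `predictPao2`
**always inverts the unrounded fitted coefficients** — evaluating
published rounded multiple-regression coefficients at typical shift and
linewidth values is off by thousands of mmHg, because the interaction
coefficient is printed to one significant figure while cs*lw is of order
1.5e4. Printed coefficients are kept only as rounding-validation
constants in the tests. The multiple linear model adds the linewidth and
the shift-linewidth interaction; the logarithmic model
cs = a ln(paO2) + b captures the curvature seen when hypoxic data are
included, while agreeing with the linear fit within 0.2 ppm over the
180-390 mmHg range studied.

The exponential in-vitro model delta(sO2) = alpha exp(beta sO2) + delta0
ships with the human whole-blood parameterization (9.3e-4, 8.62,
20.4 ppm; increasing) and a fitting routine for decreasing porcine data.
The dissociation curve is a Hill function sO2 = p^n/(p^n + P50^n) with
literature-sourced defaults (human P50 26.8 mmHg, n 2.7; porcine
33.0 mmHg, 2.8 — porcine blood is right-shifted). Above 150 mmHg the two
species' curves differ by under 0.02, which is why the 40%/100% oxygen
levels probe the saturated plateau of either curve.

# Regional statistics

The six-lobe porcine atlas (R1 right cranial, R2 right middle, R3 right
caudal, R4 right accessory, L1 left cranial, L2 left caudal) is carved
from the two-ellipsoid lung by cranio-caudal bands with a medial caudal
accessory region. Regional analysis aggregates lobe-level animal means —
matching the plotted per-lobe animal points of such studies — not pooled
voxels. The two-way ANOVA (region x oxygen with interaction, via `aov`)
assumes the balanced decomposition; a zero residual is flagged
degenerate, single-observation-per-cell designs raise an explicit error,
and empty cells are reported by name. The ventilation defect percentage
intersects the ventilated mask with the anatomical cavity mask before
Eq. VDP = (1 - VV/TCV) x 100, so VDP cannot go negative when ventilation
bleeds outside the cavity.

`simulateRegionalData` generates lobe-level data with configurable
region/oxygen/interaction effects in residual-SD units; the default
pattern mirrors the reported significance structure (region effects on
ratios, shifts, linewidths; oxygen effects on RBC shift, RBC linewidth
and RBC:M; interactions on M:Gas, RBC:Gas, membrane shift and RBC
linewidth; nothing on perfusion-like metrics). Effect sizes (2-3.5
residual SDs; interactions at 3.5) were chosen once so that each
metric-effect call is recovered in at least 90% of seeds at n = 4
animals.

# Problem sizes and determinism

Every stochastic stage takes an explicit seed and a fixed configuration
reproduces every output bit-for-bit (the pipeline writes an md5
manifest; two runs of the same config are byte-identical). The test
suite uses grids of 12 x 12 x 4 for exactness checks and the full
28 x 28 x 6 protocol grid for the replicated recovery studies, fitting a
random 120-voxel subsample of the masked lung per replicate — voxel
subsampling thins the volume without touching per-voxel estimates, and
100 replicates give standard errors of ~0.001 ppm on the recovered RBC
shift. Reconstruction for these studies stays on the native grid
(spatial zero-fill 1): zero-fill interpolation adds no information and
multiplies fitting cost eightfold. These sizes are the package's own
study design for its recovery claims.

# Known limitations

* The lung geometry is a stylized two-ellipsoid model; lobe boundaries
  are planar. Atlas-dependent conclusions transfer to real anatomies
  only qualitatively.
* Exactly three peaks; no baseline or macromolecule model, no
  eddy-current correction.
* The undersampled corners of k-space are zero-filled, not recovered;
  PSF sidelobes are the price, visible in `pointSpreadFunction`.
* Per-voxel estimates at RBC SNR ~5 carry percent-level nonlinearity
  bias; use the volume-fit statistics for whole-lung inference.
* The ODC parameterizations are textbook Hill fits, not per-animal
  calibrations; they matter only through sO2, which is saturated in the
  studied paO2 range.
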