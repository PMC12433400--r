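---
title: "Methods: multimodal MRI analysis of repetitive mild head injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal MRI analysis of repetitive mild head injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

rmtbiMRI implements the analysis side of a multimodal rodent MRI study of
repetitive mild traumatic brain injury (rmTBI): awake rats receive three
mild closed-head impacts and are compared to sham controls (n = 8
impacted, n = 6 sham) on blood-brain-barrier (BBB) permeability,
gray-matter microstructure, resting-state functional connectivity, and
behavior. No imaging data ship with the package; a synthetic-study
generator reproduces the statistical structure of each modality with
recorded ground truth, so every estimator can be validated end to end.

## Quantitative CBV and the permeability screen

With an intravascular iron-oxide contrast agent (ferumoxytol), positive
contrast ultrashort-echo imaging gives a quantitative cerebral blood
volume fraction per region:

$$\mathrm{qCBV} = \frac{I'_M - I_M}{I'_B - I_B},$$

the tissue intensity change after the bolus normalized by the blood-pool
change (primes denote post-contrast). The ratio is invariant to global
intensity offsets and rescaling, which is why no absolute calibration is
needed. BBB leakage is read out as the ordinary-least-squares slope of
regional qCBV over consecutive post-contrast scans, with a one-tailed
p-value (H1: slope > 0) from the t distribution on n − 2 degrees of
freedom; with the default five scans over 30 min that is 3 df, so the
parametric tail is the only practical option at this n.

Per subject, the family of regional p-values is corrected with the
two-stage adaptive (Benjamini–Krieger–Yekutieli) FDR procedure at
q = 0.1: a Benjamini–Hochberg pass at q/(1+q) estimates the number of
true nulls, and a second BH pass at the inflated level makes the
decisions. A region is called permeable only when its raw p < 0.05 *and*
it survives the adaptive FDR — both printed constraints are enforced
without guessing their precedence. The screen's sensitivity and
false-call rate are measured against the generator's leak template
(12 leak regions in 4 of 8 impacted subjects, 2 regions in 2 shams,
slope 3e-5 per s, qCBV noise SD 0.002): the acceptance script recomputes
both on every run.

Design points: regional qCBV uses the region **mean** intensity (the
median is kept as a skewness diagnostic, mean − median); the blood
reference is a dedicated atlas label averaged per scan; the number and
spacing of post-contrast scans is a free parameter (default
0, 450, ..., 1800 s).

## Diffusion microstructure

Single-shell DWI (10 non-collinear unit directions at b = 1000 s/mm²
plus one b0) is fit voxelwise by log-linear least squares on the
7-parameter design $\ln S = \ln S_0 - b\,g^T D g$ — deterministic, and
exact on noiseless data, which the tests exploit: a noiseless
simulate → fit → scalar round trip reproduces the generator's MD and FA
to better than 1e-6 relative error. ADC is reported as the tensor mean
diffusivity (λ₁+λ₂+λ₃)/3; FA uses eigenvalues clamped at zero so it
stays in [0, 1], with negative-eigenvalue voxels flagged in a QC mask.
Voxels with nonpositive signals are excluded, and per-volume exclusion
masks support motion-artifact screening.

Regional statistics follow the dot-plot granularity of the study design:
subjects are averaged within group per area, area-level values are the
observations, and each region group is tested with Kruskal–Wallis
(gate 0.05) followed by an exact Wilcoxon rank-sum post hoc. The
generator's group shifts (basal ganglia MD −10% / FA +15%, thalamus MD
−8%, cerebellum FA −10%) mirror a cytotoxic-edema pattern and give the
recovery tests a known direction of effect.

## Functional connectivity graphs

Region signals are cleaned by OLS nuisance regression (intercept, six
motion parameters, spike indicators for flagged outlier volumes, white
matter and CSF means) and a zero-phase forward–backward Butterworth
band-pass, 0.01–0.1 Hz (2nd order each direction, 4th order effective).
Pearson correlations over all N(N−1)/2 region pairs are Fisher-Z
transformed (r clipped at 1 − 1e-7); per group, each edge gets a
one-sample t against zero converted to a standard-normal deviate through
the t CDF in log space, so far tails are kept. The group-Z matrix is
thresholded at |Z| ≥ 2.3 (ties kept) and binarized; degree centrality
C_D(j) = Σᵢ A_ij, average degree 2E/N, density 2E/(N(N−1)) and average
shortest-path length (BFS; disconnected pairs excluded and counted) are
computed on that binary graph, which is the only reading consistent with
published average degrees an order of magnitude below N. At N = 171 the
pair count is exactly 14,535, and densities equal average degree/(N−1).

Modules are recovered by connected components of a union k-nearest-
neighbor graph under the distance 1 − |Z|/max|Z| — the simplest
deterministic variant of kNN clustering; it needs each true module to
hold at least k + 1 nodes. Degrees are compared between group networks
pairwise by node: a Shapiro–Wilk gate on the paired differences selects
a paired t-test (normality not rejected) or a Wilcoxon signed-rank test;
all-equal nonzero differences have zero variance, where the paired t is
undefined, and fall back to the exact sign floor 2·(1/2)ⁿ.

## The synthetic generator and what passing means

Each BOLD region signal is a shared-factor construction,
$s_r = \sqrt{c}\,f_m + \sqrt{1-c}\,e_r$, so the within-module
correlation is exactly c (default 0.4) and cross-module correlations are
zero; impacted subjects attenuate c by 0.5 in the affected region groups
(default: cerebrum, hippocampus, cerebellum, thalamus — basal ganglia
stays as a negative control). Between-animal variability enters as a
Fisher-Z jitter of c per subject and module, SD 0.1: large enough to
make the group edge t-tests honest (without it, five subjects suffice to
saturate every true edge), small enough to stay subordinate to the
group effect — comparable to test–retest variability of edge z-scores
in rodent rs-fMRI. Nuisance structure (random-walk motion, WM/CSF,
drift, spikes) is mixed in with known coefficients so the regression
step can be validated exactly. The contrast generator writes tissue
intensity $I + (\mathrm{CBV}_0 + \beta t)(I'_B - I_B)$ plus Gaussian
voxel noise, making regional qCBV linear in time by construction; DWI
signals follow the mono-exponential tensor model with Gaussian (default)
or Rician noise.

What the phantom does *not* emulate: anatomy (regions are cubic blocks),
MR physics (coils, k-space, distortion), physiological noise spectra,
registration error, or partial-volume effects. Passing tests therefore
demonstrate the correctness of the estimators and decision procedures
under the stated statistical model, not robustness to real-scanner
artifacts.

All generators derive per-modality substreams from one study seed, so a
study is internally consistent yet each modality is independently
re-runnable; identical seed and config give bit-identical outputs, and
ground truth is emitted alongside the data but never read by any
analysis function.

## Problem sizes and numerical choices

The default phantom uses a 24³ grid with 60 regions (18 thalamic, 9
hippocampal, 10 basal ganglia, 19 cerebellar areas, cerebrum, and one
blood label), 200 BOLD volumes at TR 1 s, five post-contrast scans, and
11 DWI volumes — sizes at which a full simulate-and-analyze study runs
in about a second, so the replicate-based properties (100 connectivity
studies, 20 permeability studies, 500 FDR replicates) run at desk scale.
Other numerics: atlas voxels are 0-based array indices with no world
transforms (inputs are assumed co-registered); the B1 correction divides
each slice by the mean-normalized phantom profile (minimal
multiplicative-gain model — the idempotence test pins this down);
zero-voxel regions warn rather than error so low-resolution phantoms
stay usable; Fisher-Z clipping at 1 − 1e-7 bounds z at about 8.4;
zero-variance edges in the group matrix get a flagged ±10 sentinel.

## Worked protocol quantities

The dosing and geometry calculators double as worked examples: a 50 g
impactor at 7.4 m/s carries ½mv² = 1.37 J; 200 µg/mL elemental iron is
200/55.845 = 3.58 mmol/L; a 30 mm field of view over a 180³ matrix gives
167 µm isotropic voxels, and over 96 in-plane samples 0.3125 mm
(printed 0.313).

```{r}
library(rmtbiMRI)
protocolTable()
cfg <- simConfig(seed = 1)
res <- runStudy(cfg, outDir = "study_out")
res$bbb$summary
res$connectivity$globalMetrics
```

## Limitations

The blocky atlas cannot probe registration or partial-volume behavior;
the one-tailed slope test assumes linear leakage over the scan window
(true in the generator, an approximation in vivo); kNN module detection
is sensitive to k for small modules; and the open-field central-zone
fraction is reported geometrically per arena rather than assumed to be
40%, since an 8 cm border gives 40% only for particular arena sizes.
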