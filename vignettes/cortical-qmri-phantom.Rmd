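---
title: "A synthetic fixed-hemisphere phantom for quantitative MRI of cortical demyelination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A synthetic fixed-hemisphere phantom for quantitative MRI of cortical demyelination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexqmr)
```

## Why a phantom

Quantitative post-mortem MRI studies of cortical multiple sclerosis
pathology rest on a long measurement chain: four steady-state acquisitions,
closed-form relaxometry inversions with a B1 correction, stained-slide
digitization and segmentation, histology-to-MRI registration, cortical mask
hygiene, and voxel-wise statistics. The specimen behind such a study is
unique and cannot be shared, so none of the chain can be re-verified on the
original data. `cortexqmr` rebuilds the chain on a synthetic hemisphere with
known ground truth. Everything that is a mathematical claim (the inversions
invert the forward models; erosion strips exactly one face layer; the
affine recovers itself) is then testable exactly, and everything that is a
statistical claim (group separation, correlation signs, histogram overlap)
is testable against the generating distribution.

## The phantom

**Geometry.** A white matter core wrapped in a cortical shell immersed in
formalin, on a 128^3 grid at 0.35 mm isotropic (the acquisition resolution
of the study design the defaults describe). Gyri and sulci come from a
sinusoidal radial perturbation of the pial and WM surfaces with seeded
phases — reproducible folding with a well-defined pial boundary, not an
anatomical atlas. The shell is 8 voxels (2.8 mm) thick by default, within
the 6–10-voxel band that keeps a measurable ribbon at this grid size. A
small central sphere is labeled subcortical grey matter; it is relabeled WM
for depth purposes, mirroring the usual preprocessing convention.

**Tissue parameters.** `tissue_table_default()` carries the quantitative
values measured on fixed post-mortem MS tissue at 3 T for the four pathology
classes (NAC, CL, NAWM, WM lesion): T1/T2 in ms, M0 in relative units, the
MT saturation fraction delta (MTR/100), and myelin content in % area. The
formalin row is a generator choice (T1 2200 ms, T2 800 ms, negligible MT
effect, no myelin): the embedding fluid only needs to be plausibly
long-relaxing and well separated from brain tissue, since no statistic is
computed on it.

**The myelin couplings.** Within the cortical ribbon the parameters are not
drawn independently; they are driven by myelin content through couplings
linear in relaxation *rate*:

$$1/T_1 = a_1 + k_1 m,\quad 1/T_2 = a_2 + k_2 m,\quad
\delta = a_3 + k_3 m,\quad M_0 = a_4 - k_4 m .$$

The pairs $(a_i, k_i)$ are calibrated so that $m$ at the CL myelin mean maps
exactly onto the CL row and $m$ at the NAC mean onto the NAC row
(`myelin_coupling()`); all slopes must come out positive or the generator
refuses the table. Linearity in rate makes the *time*-versus-content
relation hyperbolic — relaxation times rise steeply as myelin tends to
zero — which is exactly the regime where rank correlation beats linear
correlation, a property the statistics module tests for. WM lesions are
deliberately *not* on this coupling: their table row breaks the cortical
monotone relation (long T1 yet substantial myelin), so they draw all
parameters independently from their own row.

**The laminar gradient.** Cortex myelin increases from the pial surface to
the WM boundary. The profile is linear in fractional depth by default
(`laminar_shape = "sigmoid"` is available); a per-voxel Gaussian jitter of
SD 0.15 depth units is mixed in, and the result is standardized so the
cortex-wide mean and SD equal the NAC row. The study source does not specify
the profile shape, so linear was chosen as the minimal assumption and made
configurable. After standardization, values are clamped to [0, 100] %;
with the NAC mean near 8% and SD near 7%, clamping at zero shifts the
realized cortical mean up by a few tenths of a percentage point — visible
in stochastic summaries, absent in the deterministic mode below, and well
inside every tolerance used.

**Noise.** Magnitude images get Rician noise,
$S' = \sqrt{(S+n_1)^2 + n_2^2}$. The study design averages tens of
repetitions over a multi-day acquisition and never states an effective SNR,
so the default sigma (2 r.u., against signals of roughly 250–900 r.u. for
M0 near 3800) describes a heavily averaged acquisition: strong enough that
fitted maps are visibly noisy, weak enough that the tissue SDs remain
dominated by biology. It is a generator choice, stated here once, and not
tuned to reproduce any scanner figure.

**Deterministic mode.** `noiseless_spec()` zeroes every source of spread —
tissue SDs, laminar jitter, noise sigma. Each tissue then sits exactly at
its table mean, and because the relaxometry inversions are algebraic
inverses of the forward models, the end-to-end pipeline report must equal
the configured means to numerical precision (the suite asserts 1e-6
relative). This is the package's definition of the "noiseless phantom":
with nonzero SDs, exactness is impossible by construction, so exactness
claims always refer to this mode.

## Acquisition and inversion

The forward models are the standard steady-state expressions: SPGR
(TR 7.7 ms, TE 3.35 ms, flips 4 and 22 degrees — angles optimized for the
short relaxation times of fixed tissue), ideal on-resonance bSSFP
(TR 7.7 ms, TE 3.84 ms, flips 20 and 70 degrees), an MT-weighted SPGR pair
(25 degrees, TR 25 ms) in which saturation is a pure multiplicative
attenuation $(1-\delta)$ — MTR is semi-quantitative, and a two-pool
Bloch–McConnell model is out of scope — and a double-angle preparation pair
whose magnitudes are proportional to $\cos(\Delta B_1 \alpha)$ and
$\cos(2 \Delta B_1 \alpha)$ with $\alpha = 20$ degrees.

Inversion uses two-point closed forms rather than least squares over more
angles because the design acquires exactly two flip angles per method.
Numerical policies that matter:

* **Validity, never clamping.** DESPOT1 slopes outside (0, 1), DESPOT2
  $E_2$ outside (0, 1) (including the slope-equals-$E_1$ infinite-T2 edge),
  double-angle ratios with no cosine root in (0, 1), and nonpositive MT
  reference signals are all flagged invalid and excluded. Clamping would
  silently bias group statistics toward the clamp value.
* **B1 correction.** The fitted $\Delta B_1$ field multiplies the nominal
  flips in both DESPOT fits. The suite quantifies the necessity of the
  correction by a paired run: with the field ignored, T1 bias grows
  monotonically with the field error.
* **Banding.** The ideal bSSFP model has no off-resonance term; banding is
  handled by exclusion, not correction. With two flip angles the two-point
  model is exactly determined, so the residual rule reduces to fit validity
  plus any injected defect region carried in the simulation metadata. The
  original study's detection criterion is unstated ("carefully analyzed");
  this package's rule is a stated stand-in, and the contract tested is set
  arithmetic: downstream counts drop by exactly the excluded voxels.

## Histology

Slides are rendered at `upsample_factor = 10` (35 µm synthetic pixels
against the 0.35 mm grid) rather than true scanner resolution — a
desk-scale tradeoff that keeps rendering in memory while leaving two orders
of magnitude between pixel and voxel. Fiber strokes accumulate per
MR-resolution block until the painted fraction matches the target content
exactly at pixel quantization (error below one pixel per block), so the
render-segment-downsample round trip has a known error budget: the suite
asserts 1 percentage point per block, and 2 points for the NAWM-level
recovery that is checked end to end.

Segmentation is a normalized red-versus-blue contrast,
$(R-B)/\max(R+B,1) > \tau$ with $\tau = 0.08$: scale-invariant (so uniform
brightness changes do not move the boundary) and deliberately simple. The
original color-space algorithm is proprietary to its workflow; the contract
here is round-trip accuracy against known rendered content, not agreement
with a specific segmenter. Color jitter in the renderer is bounded so the
sign of $R-B$ is preserved — the physical counterpart is scanning slides at
the counterstain-contrast optimum, absorbed into the render model.

Down-sampling is plain block averaging (exact conservation of the global
myelin fraction on divisible grids); non-divisible grids are padded and the
partial blocks masked out of statistics rather than partially averaged.

## Registration

The phantom generates histology in register, so the affine machinery is
exercised by synthesize-and-recover: random invertible affines with
determinant magnitude in [0.5, 2] are recovered from noiseless tag points to
1e-9. Label images are resampled nearest-neighbour (no label mixing),
continuous maps bilinearly. The nonlinear in-plane refinement used on real
slides is out of scope — it is an external tool in the original workflow,
not a defined computation — so lesion-footprint claims here are only as
local as an affine allows.

## Cortical depth

Surface-based laminar analysis is replaced by a voxel-based fractional depth
field $d = D_p / (D_p + D_w)$, with $D_p$ and $D_w$ exact Euclidean
distances to the formalin and WM boundaries (compiled separable distance
transform, cross-checked against a quadratic-time oracle). Depth is 0 at the
pial surface, matching the "depth from the pial surface" convention, and the
ribbon includes cortical lesions, so implanting a lesion never changes
depth. This substitution makes depth-resolved reproductions qualitative:
surface contours at 25/50/75% depth become voxel bands
($|d - f| \le 0.05$; the 0.05 half-width is an artifact choice, with the
three default bands pairwise disjoint by construction). The expected
physiology still falls out: T1 sampled at 25% depth exceeds T1 at 75% depth,
and subpial lesions elevate superficial T1 more than deep T1.

The cortical mask is eroded by one 6-connectivity layer (0.35 mm) before any
cortical statistic, removing the partial-volume rim; the depth field itself
is computed on the uneroded ribbon.

## Statistics

Group comparisons default to Student's pooled-variance t-test (matching the
stated design) with Welch available because the table SDs differ severely
between groups; both are checked against an exhaustive permutation oracle on
small samples. Bonferroni uses a family of 5 (T1, T2, M0, MTR, myelin — the
five summary rows); the original correction family size is unstated, so
this is a package choice, configurable per call. Histograms use 64 uniform
bins over the pooled 1st–99th percentile range with explicit underflow and
overflow bins, so frequencies always sum to one; edges are recorded in the
report. Correlations are computed voxel-wise over the eroded cortical ribbon
(NAC plus CL) against the *ground-truth* myelin map — on real data this
would be the registered content map, and using truth here isolates the
statistical machinery from registration error.

One tension inherited from the source material is documented rather than
resolved: the summary table has M0 *higher* in lesions than in NAC, while
the overall M0–myelin correlation is negative. The phantom's $M_0$ coupling
($M_0 = a_4 - k_4 m$) follows the two calibration rows, which makes the
voxel-wise correlation negative; both the sign and the tension are
configuration-dependent, and the correlation tests assert signs only.

## Problem sizes and reproducibility

The defaults are the study conditions: 128^3 grid, 0.35 mm voxels, two
subpial lesions plus one focal WM lesion, B1 amplitude 0.2, noise sigma 2.
The test suite runs its stochastic checks on 48^3 phantoms (several thousand
voxels per tissue row, enough for the 2-standard-error assertions) and its
oracles on 20^3 fixtures where quadratic-time comparisons are exact; the
acceptance script uses uniform single-tissue volumes for the closed-form
recoveries, ten slide blocks for the histology round trip, and 500 voxels
per group for the group test. Every stochastic stage takes an explicit seed
derived from the phantom seed, and reports rerun byte-identically.

## Known limitations

* The folding is sinusoidal, not anatomical; thickness is constant, so
  thickness-dependent effects are absent.
* The MT model is a single multiplicative attenuation; no qMT parameters.
* bSSFP off-resonance is represented only as an injectable defect region,
  not a phase-dependent signal model.
* No reception-field bias, no partial-volume mixing at boundaries beyond
  voxel quantization, no fixation chemistry: phantom tissue classes are
  internally homogeneous apart from the laminar gradient.
* Passing tests show the *pipeline* is correct under the generating model;
  they cannot show that the generating model matches any particular
  specimen. Empirical correlation magnitudes from single-specimen data are
  explicitly not reproduction targets — only their signs and rank-vs-linear
  ordering are.
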