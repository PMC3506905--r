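# cortexqmr

Quantitative MRI characterization of cortical demyelination, rebuilt as a
tested, reproducible pipeline on a synthetic fixed-hemisphere phantom.

## The problem

Type III subpial cortical lesions in multiple sclerosis — demyelination of
the superficial cortical laminae, often spreading tangentially over several
gyri — are notoriously hard to see on MRI. Post-mortem studies attack this
by scanning a fixed hemisphere at very high resolution with *quantitative*
sequences, matching the maps against immunostained histology, and asking how
T1, T2, proton density (M0) and the magnetization transfer ratio (MTR) relate
to myelin content. The specimen in such a study is unique and unavailable,
so this package rebuilds the entire measurement chain on a synthetic phantom
with known ground truth: every processing step can then be verified exactly,
and the study's statistical machinery runs end to end on data whose answer
is known.

`cortexqmr` is aimed at people developing or validating quantitative MRI
relaxometry, MRI–histology registration, or cortical-lesion statistics, who
need a fully controlled test bed rather than scanner data.

## What it implements

* **Phantom** — a folded hemisphere (WM core, cortical shell with gyri and
  sulci, formalin bath) at 0.35 mm isotropic resolution. Tissue parameters
  come from a table of fixed post-mortem values for normal-appearing cortex
  (NAC), cortical lesions (CL), normal-appearing white matter (NAWM) and WM
  lesions. Within the cortex, myelin content m (% area) follows a
  pial-to-WM laminar gradient and drives the other parameters through
  couplings linear in relaxation *rate*,

      1/T1 = a1 + k1 m,   1/T2 = a2 + k2 m,   delta = a3 + k3 m,   M0 = a4 - k4 m,

  calibrated so the CL and NAC myelin means map exactly onto the CL and NAC
  table rows. Subpial and focal WM lesions, a smooth B1 transmit field and
  Rician noise complete the forward model.
* **Acquisition models** — steady-state SPGR (`S = M0 sin(ae)(1-E1)/(1-cos(ae)E1)`,
  `ae = dB1 * flip`, `E1 = exp(-TR/T1)`), on-resonance balanced SSFP,
  an MT-weighted SPGR pair with multiplicative saturation `(1 - delta)`, and
  a double-angle (alpha, 2 alpha) B1-mapping pair.
* **Relaxometry** — the closed-form two-point inversions: DESPOT1 (variable
  flip angle T1/M0 from SPGR at 4 and 22 degrees, TR 7.7 ms), DESPOT2 (T2
  from bSSFP at 20 and 70 degrees), MTR as the percent saturation-induced
  signal drop, the double-angle quadratic solve for dB1, and a banding
  exclusion mask for the bSSFP T2 map.
* **Histology** — synthetic chromogen-stained slides (red-brown fiber
  strokes on a light blue counterstain), segmentation by normalized
  red-vs-blue contrast, and block-average down-sampling to MR-resolution
  myelin content maps.
* **Coregistration** — least-squares tag-point 2D affine transforms,
  nearest-neighbour / bilinear resampling, coronal slab plane extraction.
* **Cortical depth** — exact 3D Euclidean distance transforms (compiled),
  6-connectivity mask erosion, a fractional depth field
  `d = Dp / (Dp + Dw)` over the cortical ribbon, and depth-band sampling.
* **Statistics** — per-tissue summaries, two-sided Student/Welch t-tests
  with Bonferroni correction, Pearson and Spearman correlations of each qMR
  parameter with myelin content, normalized histograms with overflow
  accounting, and `run_pipeline()`, which chains everything deterministically
  from a seed.

## Worked example

```r
library(cortexqmr)
spec   <- phantom_spec(grid_shape = c(64, 64, 64), seed = 1)
report <- run_pipeline(spec)
print(report)
```

```
Phantom pipeline report (seed 1 , 64x64x64 voxels)

Per-tissue summaries:
    tissue parameter        mean          sd     n
       nac        t1  207.180459  22.2504670 27529
       nac        t2   65.499640  18.4583208 27529
        cl        t1  235.226573  11.9632164  4418
        cl        t2   91.020221  12.2363708  4418
      nawm        t1  196.224781  19.0168663 16096
 wm_lesion        t1  380.275988  88.7141666  2146
 ...

CL vs NAC (Bonferroni-corrected p):
  t1      t =    81.90  p = 0 *
  t2      t =    88.82  p = 0 *
  m0      t =    42.59  p = 0 *
  mtr     t =   -58.07  p = 0 *
  myelin  t =   -79.85  p = 0 *

Correlations with myelin content (eroded cortical ribbon):
  t1    r = -0.963  rho = -0.971 (n = 31947)
  t2    r = -0.960  rho = -0.997 (n = 31947)
  m0    r = -0.555  rho = -0.547 (n = 31947)
  mtr   r =  0.765  rho =  0.763 (n = 31947)
```

Reading this: cortical-lesion voxels show longer T1 and T2, higher M0 and
lower MTR and myelin than normal-appearing cortex (every contrast decisive
at n of a few thousand voxels per group); relaxation times correlate
negatively with myelin content, with the Spearman coefficient exceeding the
Pearson one for both relaxation times — the signature of the non-linear
(rate-linear) time-versus-content relation. The fitted tissue means recover
the configured table values (e.g. NAWM T1 196 ms, WM-lesion T1 380 ms)
within noise.

The numbered scripts under `analysis/` run the same chain as a narrative
workflow — `01_simulate.R` (phantom + acquisitions), `02_fit_maps.R`
(inversion and recovery table), `03_histology.R` (slide rendering,
segmentation round trip, tag-point affine), `04_stats.R` (full report) —
writing their outputs under `results/`.

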