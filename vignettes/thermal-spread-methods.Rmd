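---
title: "Measuring lateral thermal spread from thermogram sequences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lateral thermal spread from thermogram sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermospread)
```

## The measurement problem

Bipolar electrosurgery coagulates tissue by passing RF current between two
forceps prongs. Heat conducted laterally beyond the grasped tissue — the
*lateral thermal spread* — can injure adjacent structures such as
neurovascular bundles, which is why the extent of spread under realistic
laparoscopic conditions (a CO~2~ atmosphere at 12 mmHg, 37 °C) matters
clinically. A compact radiometric thermal camera observing the tissue
surface yields a sequence of *thermograms*: images whose pixel values are
temperatures in °C.

`thermospread` implements the measurement pipeline for such recordings and,
because no public recordings exist for this experiment class, a physics-based
synthetic generator that emulates it end to end with known ground truth.

## The spread statistic

Given a sequence of frames $T_k(p)$ (°C, pixel $p$, frame $k$) and a damage
threshold $\theta$ (default 60 °C, the temperature band where protein
denaturation and cell death occur; 45 °C — hemostasis onset — and the
57–65 °C band are documented presets), the cumulative spread is

$$A = \left|\{\,p : \max_k T_k(p) > \theta\,\}\right| \cdot s^2,$$

where $s$ is the image scale in mm/pixel. Three conventions matter:

* **Strict inequality.** A pixel exactly at $\theta$ is *not* damaged;
  `area == 0` for a frame uniformly at the threshold.
* **Cumulative union over the whole sequence**, not the per-frame maximum:
  a pixel that ever experienced the damaging temperature stays counted. The
  per-frame area series is reported alongside so the per-frame reading
  remains recoverable.
* **No default smoothing.** No spatial filtering, no instrument masking.
  Because a noise-limited sensor can flicker single pixels across the
  threshold, an optional debounce (`min_frames_above`) and a
  largest-connected-component filter exist, both off by default.

The scale $s$ comes from an in-scene fiducial of known physical length
(in the physical experiment, the scalpel tip): $s = L / \lVert p_1 - p_2
\rVert$ with pixel endpoints $p_1, p_2$. Pixels are assumed square and
uniform — the optics are treated as a single scalar scale, and no automatic
fiducial detection is attempted (none is well defined for arbitrary scenes).
Calibration is explicit and per-session.

## Statistical layer

Groups (power × time settings) are summarised by median and IQR
(= Q3 − Q1). All quantiles interpolate linearly between order statistics at
position $p(n-1)$; this convention is stated because IQRs at small $n$
depend on it.

Between-group comparison uses the two-sided independent-samples Wilcoxon
rank-sum (Mann–Whitney) test. Sessions are independent tissue samples, so
the paired signed-rank variant is out of scope. For $n_1+n_2 \le 20$ the
p-value is exact: all $\binom{n_1+n_2}{n_1}$ assignments of the combined
mid-ranks are enumerated and the two-sided p is the probability of a rank
sum at least as far from its permutation mean as observed. Ties use
mid-ranks everywhere, including inside the enumeration. Larger samples use
the normal approximation with tie-corrected variance and a 0.5 continuity
correction; at $n_1=n_2=10$ the two agree to well under 0.01.

Association between the camera-derived spread and an independently
delineated necrosis area uses Spearman's rank correlation (Pearson
correlation of mid-ranks), with a constant input treated as an error rather
than silently zero. Least-squares fits report slope, intercept and $R^2$
($R^2 \equiv 0$ for constant response, a documented convention).

## The bioheat simulator

The generator's physics core solves the heat equation on a regular voxel
grid,

$$\frac{\partial T}{\partial t} = \alpha \nabla^2 T + \frac{q}{\rho c},$$

by explicit forward Euler with a 7-point Laplacian. The samples are
ex-vivo, so the Pennes perfusion sink is identically zero (re-adding it is
an extension hook). The source $q$ is uniform volumetric heating inside two
rectangular prong footprints extending a fixed deposition depth into the
tissue while the generator is active.

Key parameters, defaults and rationale:

| parameter | default | unit | rationale |
|---|---|---|---|
| block size | 30 × 30 × 20 | mm | ~3 × 3 × 2 cm ex-vivo sample |
| voxel | 0.5 | mm | resolves the 1 mm deposition depth; 2 × 2 voxels per camera pixel |
| $\alpha$ | 0.14 | mm²/s | literature muscle diffusivity |
| $\rho c$ | 3.6 × 10⁻³ | J/(mm³·K) | literature muscle heat capacity |
| ambient | 37 | °C | controlled chamber temperature |
| coupling efficiency | 0.15 | — | tuning default: fraction of generator power deposited as heat |
| deposition depth | 1 | mm | tuning default for bipolar current paths |
| prong footprint | 1 × 4, gap 2 | mm | jaw-tip contact patch of a Maryland-type forceps; chosen once so the 30 W / 2 s default peaks near tissue-carbonization temperatures with a damage area of a few tens of mm² |
| surface h | 0 | W/(mm²·K) | still CO₂ at tissue temperature; convection hook available |

Coupling efficiency and deposition depth are *tuning defaults*, never
presented as measured quantities. Phase change, vaporization,
temperature-dependent properties and denaturation feedback on the thermal
response are deliberately omitted — the analysis only thresholds at 60 °C,
and simulated peaks are reported as-is even above 100 °C. Electromagnetic
modelling of the RF circuit and any pressure dependence of heat transfer
are out of scope (chamber pressure is metadata only).

Numerical choices: the explicit scheme requires
$\Delta t \le h^2 / (6\alpha)$; violations are rejected *with the maximal
admissible step named in the error*. The insulated (zero-flux) boundary
stencil is conservative, so with no source the total excess heat
$\sum (T - T_\infty)$ is constant to rounding — one of the physics checks in
the test suite, alongside the analytic law that a Gaussian temperature bump
gains per-axis variance $2\alpha t$. The solver step must divide both the
snapshot interval and the application duration so that deposited energy and
sampling times are exact.

Ground truth from the simulated field: the damaged surface area counts
top-layer voxels whose peak-over-time temperature exceeds the threshold;
the damage depth is the center depth $(z + 0.5)\,h$ of the deepest
ever-exceeding layer (0-based $z$). Ground truth is computed from the
stored snapshots, so the snapshot interval bounds its time resolution.

## The camera model

The observation model emulates a compact 60 × 80 uncooled microbolometer
array at 10 Hz: axis-aligned block averaging of the surface layer to the
camera grid (one camera pixel integrates $b \times b$ surface voxels, with
the default 1 mm camera pixel matching the ~1 mm² effective pixel of the
physical setup), plus a systematic bias (admissible within ±2 °C), i.i.d.
Gaussian noise with the NETD (default SD 0.1 °C), saturation at the
measurement-range maximum (default 150 °C, typical for compact cameras —
well above the 60 °C threshold, so spread areas are unaffected), and
digitization to float32 (which also makes the 32-bit TIFF round trip
bit-exact). Frame times sample the stored snapshots by nearest neighbour.

Two deliberate simplifications: the mapping is orthographic (no
perspective, no lens distortion), and since the full 60 × 80 array at
1 mm/px would overhang a 30 × 30 mm block — and the measurement only
concerns the tissue — cohort rendering uses the tissue-registered
sub-window of the array (30 × 30 px at defaults).

## What the synthetic cohort does and does not establish

`generate_cohort()` reproduces the study design: four groups
({30, 60} W × {2, 4} s), 16 sessions each, per-sample lognormal
(median-1) jitter on diffusivity, coupling efficiency and contact area
(default relative SDs 0.15), an optional dropout flag emulating recording
failures, and a manifest recording every parameter. The entire cohort is a
pure function of its configuration: per-sample seeds are
`base_seed XOR index`, so dropping sessions or regenerating never shifts
another sample's realization.

A green pipeline on this cohort establishes that segmentation, calibration
and statistics *recover known ground truth through a realistic observation
model* — noise-free rendering recovers the simulated damage area within the
resolution bound (two pixel areas plus 15 %), and longer 30 W activation
reliably increases the median spread, mirroring the experiment's one clear
contrast. It does **not** establish realism of the absolute areas (the
source coupling is a tuning default), nor of the between-sample dispersion:
with ±15 % parameter jitter the simulated IQR is only ~5–15 % of the group
median, an order of magnitude tighter than physical cohorts, whose
dispersion is dominated by factors outside this physics model (tissue
composition, instrument handling, residues on the jaws). Raising the jitter
SDs widens the dispersion but weakens the time-contrast ordering; the
default keeps the contrast property sharp and leaves dispersion realism
explicitly out of reach. Likewise the absence of denaturation feedback
means simulated 60 W areas scale with power, whereas real 60 W groups did
not separate cleanly from 30 W.

## Degenerate inputs and edge behaviour

Readers reject values outside −40…400 °C as probable unit errors (°C is
the only accepted unit), ragged or non-numeric CSV cells with the file and
cell named, and sequences whose timestamps disagree with the stated frame
rate by more than 1 ms. Frame rate is required metadata — it is never
guessed. Coincident fiducial endpoints, non-positive lengths, empty
sequences, constant-input correlations and constant-x fits all raise
immediately rather than returning sentinel values; the one sentinel is the
degenerate rank-sum test (all values identical across both samples), which
reports p = 1 with a flag.

## Reproducibility bookkeeping

Every pipeline invocation writes a fresh `run_XXX` directory (never
overwriting): resolved config, manifest, per-sample results, the four
report tables, and a timing log — the log is the only file that differs
between identical reruns. Configs are JSON; a flat `key: value` sidecar
carries sequence metadata next to CSV/TIFF exports. Proprietary radiometric
containers are not parsed; the documented exchange format is a multi-page
32-bit-float TIFF (or a CSV directory) in °C.
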