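---
title: "Methods: semi-automated murine LV echocardiogram analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automated murine LV echocardiogram analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvecho)
```

# The problem

Murine echocardiography produces two kinds of left-ventricle (LV) images.
Parasternal long-axis (PLAX) **B-mode** cine loops show the whole cavity in
section over hundreds of frames; short-axis (SAX) **M-mode** sweeps sample a
single scan line through the chamber over several seconds, so the four wall
interfaces (anterior epicardium/endocardium, posterior
endocardium/epicardium) appear as bright bands oscillating at the heart
rate. Manual tracing of either is slow and operator-dependent; `lvecho`
implements a semi-automated pipeline for both, plus the phantom simulation
and validation statistics needed to qualify it against exact ground truth.

# B-mode: multi-atlas segmentation

A selected ED or ES frame is segmented by registering every entry of a
*reference library* — labelled (frame, LV mask) pairs of the same cardiac
phase — onto the target and fusing the warped labels:

1. **Preprocess.** 3×3 median filter, then 2× block-mean downsampling
   (spacing doubles). Odd trailing rows/columns are cropped.
2. **Register.** Each library frame is aligned to the target by a
   6-parameter affine (translation, rotation, anisotropic scale, shear)
   maximizing normalized mutual information,
   `NMI = (H(A)+H(B))/H(A,B)`, from a joint histogram with 32 equal-width
   bins per axis (bin edges per image, making the score invariant to linear
   intensity rescaling). The ascent is a 3-level coarse-to-fine pyramid of
   Nelder–Mead searches preceded by a deterministic translation
   initialization (dark-weighted centroid alignment refined on a coarse
   translation grid). Coarser levels use proportionally fewer histogram
   bins — a joint histogram needs several pixels per occupied bin to be
   informative. If the optimum found ever scores below the identity
   transform, the identity is kept, so a registration can never undercut
   the trivial alignment. Masks are warped with nearest-neighbour sampling
   (label integrity); frames bilinearly.
3. **Fuse.** The five registrations with the highest NMI are averaged
   pixelwise into a probability map (values on the lattice {0, 1/5, …, 1}).
   Ties in the ranking break on ascending entry id, so fusion is
   deterministic and order-invariant.
4. **Threshold.** `map ≥ 0.5` (a majority vote of five), keep the largest
   4-connected component, fill interior holes.

Every step is a pure function of its inputs, so repeat analyses of the same
frame are bit-identical — triplicate runs have zero coefficient of
variation by construction, which the test suite verifies end to end.

**Open choices made here.** The NMI variant (`(H(A)+H(B))/H(A,B)`), the
32-bin default, the 0.5 threshold, plain (unweighted) averaging of the
top-five labels, and the optimizer budget (300/200/120 Nelder–Mead
evaluations per level) are all package choices; each is exposed through
`atlas_opts()`.

# M-mode: seed-bounded dynamic-programming tracing

For each of the four walls the user supplies two seed points bracketing the
interface's depth excursion. Then:

1. **Search region** (`make_region`): the depth band between the seeds,
   padded by 10% of its height (default), full time extent. Each wall
   carries an expected gradient polarity for the transition met when moving
   deeper: entering a wall is dark-to-bright (ANT_EPI, POST_ENDO), leaving
   it bright-to-dark (ANT_ENDO, POST_EPI).
2. **Cost image** (`cost_image`): Gaussian smoothing (σ = 1 px) *along the
   depth axis only* — smoothing across time would blur the moving interface
   and bite into its excursion peaks — then the signed axial derivative,
   sign-flipped per polarity, rectified at zero and min–max normalized;
   cost = 1 − normalized gradient. A zero-gradient band yields a flat cost
   of 1 with a warning and the wall is flagged low-confidence.
3. **Optimal path** (`optimal_path`): dynamic programming finds the exact
   global minimum-cost row sequence under a smoothness constraint of at
   most 2 rows per column (unconstrained minima would allow physiologically
   impossible jumps). Ties break toward the shallower row, so the result is
   deterministic; a property test checks exact agreement with exhaustive
   enumeration on small instances. The integer path is refined to sub-pixel
   depth by a parabolic fit of the cost minimum in each column.
4. **Spectral filter** (`spectral_filter`): each trace is reduced to its
   single dominant positive-frequency component (plus baseline) by zeroing
   every other DFT bin. "Dominant" rather than literally highest frequency:
   the highest bins hold speckle jitter, the dominant bin holds the cardiac
   motion. The operation is idempotent.
5. **Phases and measurement** (`detect_phases`, `measure_walls`): the
   internal diameter LVID(t) = POST_ENDO − ANT_ENDO of the *filtered* set
   gives plateau-safe local maxima (end-diastole) and minima (end-systole).
   Dimensions are then read off the *raw* DP traces: the filtered
   single-frequency signal is ideal for locating beats but attenuates
   amplitude whenever the record holds a non-integer number of beats
   (spectral leakage — at 450 beats/min a 5 s sweep holds 37.5 cycles, the
   worst case, costing about a third of the excursion), and its beat
   positions drift against the true beats by up to a quarter cycle for the
   same reason. Each mark is therefore snapped to the raw-signal extremum
   within half a beat before LVID, LVAW and LVPW are averaged over all
   detected beats (per-beat values are kept for audit).

Manual corrections go through `edit_trace`, which splices new depths into a
trace and revalidates the ANT_EPI ≤ ANT_ENDO ≤ POST_ENDO ≤ POST_EPI
ordering; measurements are then regenerated from the stored traces.

# Endpoints

* **Method of disks** (B-mode volumes): the long axis runs from the
  midpoint of the basal chord to the farthest contour vertex; it is cut
  into 20 equal slabs (configurable) and
  `V = Σ (π/4) d_i² (L/n)` with `d_i` the boundary chord perpendicular to
  the axis at each slab centre (longest segment if the line crosses the
  boundary more than twice). Disk cross-sections are assumed circular — a
  single-plane acquisition cannot do better. On an exact half-ellipsoid
  section (L = 8 mm, D = 4 mm) the 20-disk sum is within 0.5% of the
  analytic `πLD²/6 = 67.02 µL`, with monotone convergence in the disk
  count; the mid-slab and apical cross-section areas are also reported.
* **Areas and dimensions**: shoelace polygon area; the dimension (EDD/ESD)
  is the maximal disk diameter.
* **Functional indices**: `EF = 100·(EDV−ESV)/EDV`, `SV = EDV−ESV`,
  `FS = 100·(EDD−ESD)/EDD`, `FAC = 100·(EDA−ESA)/EDA`,
  `CO = SV·HR/1000` mL/min. A missing heart rate never aborts a run — only
  CO is withheld.
* **M-mode volumes**: Teichholz conversion `V = 7.0/(2.4+D)·D³`.
* **LV mass**: cube formula
  `1.053·[(LVID;d+LVPW;d+LVAW;d)³ − LVID;d³]` mg, with the conventional
  multiplicative 0.8 reported as "corrected" mass. Both coefficients are
  arguments of `mmode_measures()`. The corrected value is defined as a
  fixed 0.8 multiple of the uncorrected one, so the two track each other
  perfectly in any correlation analysis.

# The phantom generator

`make_bmode_phantom()` renders a beating half-ellipsoid long-axis section:
cavity semi-length L, minor diameter oscillating sinusoidally at the heart
rate between its ED and ES values, a myocardial band of fixed thickness,
intensities 0.10 (blood pool), 0.85 (myocardium), 0.30 (background).
Speckle is unit-mean multiplicative gamma noise (standard deviation =
`speckle_scale`) followed by a Gaussian point-spread blur of σ = 1 px — a
minimal model reproducing the low signal-to-noise of high-frequency
ultrasound without simulating wave physics (no attenuation, refraction or
RF speckle correlation; passing tests therefore demonstrate algorithmic
correctness under calibrated noise, not clinical-grade robustness).
Defaults follow a typical acquisition protocol: 300 frames at 6.67 ms,
heart rate 450 beats/min (the middle of the 400–500 bpm window maintained
under anaesthesia), L = 8 mm, D_ED = 4 mm, D_ES = 2.8 mm (30% fractional
shortening), 0.8 mm walls, 0.08 mm pixels. ED/ES frame indices are the
argmax/argmin of cavity area over one mid-loop cycle, mirroring the
analyst's frame-selection step. The returned contours are the exactly
rendered boundaries, so any downstream error is attributable to the
algorithm, and every generator is a pure function of (spec, seed).

`make_library()` draws phantom parameters uniformly from documented ranges
(lengths 6.5–9.5 mm, ED diameters 3.2–4.8 mm, ES/ED ratios 0.60–0.80, walls
0.6–1.0 mm, heart rates 400–500 bpm, ±0.5 mm placement jitter,
speckle 0.3) — a plausible span of adult-mouse LV morphology. How much
variability a real multi-disease atlas contains cannot be known from
geometry alone, so the ranges are a user-facing argument, not a claim.

`make_mmode_phantom()` renders the four interface depths as heart-rate
sinusoids phased so LVID attains its diastolic and systolic values exactly,
walls thickening in systole, with the same speckle model; the exact
interface signals are returned as ground truth at full column resolution.

# Validation machinery

`pearson_r2` (Pearson r, r² as a percent, two-sided p with n−2 df),
`cv_percent` (100·SD/mean with the sample SD — the standard definition;
some sources print the ratio inverted, but their tabulated percentages are
consistent with SD/mean), `paired_t` (within-subjects t, df = n−1, exact
ties reported as such rather than NaN), and `leave_n_out_dice`, which
splits a library at the phantom level (seeded), segments each held-out ED
and ES frame against the remaining atlas and scores Dice overlap against
the exact mask, downsampled to the analysis grid by the same block rule the
segmenter uses.

# Problem sizes and numerical choices

The shipped experiments use sizes chosen to make the full suite quick on a
single CPU while keeping every conclusion stable across seeds: a 30-phantom
library (60 atlas entries) with a 25/5 leave-out split; 20 random M-mode
phantoms at speckle 0.3 for parameter recovery; 100 random cost grids
(≤ 6×12) for the DP-vs-enumeration property; triplicate end-to-end runs of
a 2-subject study for the determinism check. Registration operates on
half-resolution grids of about 56×80 px. Degenerate inputs are handled
explicitly: constant images give NMI = 2 against themselves by convention,
an empty post-threshold mask raises "no consensus segmentation", a constant
trace passes the spectral filter unchanged, a constant diameter signal
raises an "insufficient beats" error, and a basal chord equal to the
full diameter (circle-like contour) yields a degenerate short axis — the
disks are still computed but the geometry is the caller's responsibility.

# Known limitations

* Affine-only registration: no deformable refinement, so strongly
  non-affine shape differences between atlas and target are not captured.
* No automatic ED/ES frame detection or seed placement; both are inputs.
* Monoplane disks assume circular cross-sections.
* The similarity peak of NMI under *shared* speckle (registering an image
  against a shifted copy of itself) is a single pixel wide and is not
  findable by local search; this situation does not arise in normal
  multi-atlas use, where atlas and target carry independent speckle.
* The phantom's speckle is spatially white after a fixed PSF; real
  ultrasound speckle is correlated, depth-dependent and anisotropic.
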