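# lvecho

Semi-automated analysis of murine left-ventricle (LV) echocardiograms, for
preclinical imaging groups that need reproducible LV structure and function
endpoints at study scale.

Two pipelines form the core:

* **B-mode (parasternal long axis): multi-atlas segmentation.** Every entry
  of a reference library of manually traced (frame, LV mask) pairs is
  affinely registered to the selected end-diastolic or end-systolic frame
  with normalized mutual information, NMI = (H(A)+H(B))/H(A,B), as the
  objective; the labels of the five best-scoring registrations are averaged
  into a probability map and thresholded (majority vote) into the final
  cavity mask. LV volume follows the method of disks (modified Simpson's
  rule), V = Σᵢ (π/4) dᵢ² (L/n) with n = 20 disks along the base-to-apex
  axis.
* **M-mode (short axis): seed-bounded dynamic programming.** Two seed
  points per wall define a search band; a polarity-rectified axial-gradient
  cost image and a dynamic program trace each of the four wall interfaces
  (anterior/posterior epi- and endocardium) as the exact minimum-cost path
  under a smoothness constraint; traces are reduced to their dominant
  periodic component in the spectral domain to locate beats, and LVID, LVAW
  and LVPW at diastole/systole are averaged over all beats. Volumes use the
  Teichholz conversion V = 7.0/(2.4+D)·D³; LV mass uses the cube formula
  1.053·[(LVID;d+LVPW;d+LVAW;d)³ − LVID;d³].

Both pipelines are deterministic: repeat analyses of the same inputs are
bit-identical. The package also ships a speckle phantom simulator with
exact ground truth (beating half-ellipsoid B-mode loops, four-wall M-mode
sweeps, whole reference libraries), the validation statistics used to
qualify such tools (Dice overlap, leave-n-out experiments, Pearson r²,
triplicate coefficients of variation, paired t-tests), and a
manifest-driven batch workflow with updatable CSV reports.

## Worked example

Generate a noiseless phantom with known geometry (L = 8 mm, ED diameter
4 mm, ES diameter 2.8 mm) and derive the B-mode endpoints from its exact
contours:

```r
library(lvecho)
ph <- make_bmode_phantom(bmode_phantom_spec(speckle_scale = 0, n_frames = 30))
m  <- bmode_measures(ph$contour_ed, ph$contour_es, heart_rate = 450)
m$values
#> EDA 25.13 mm², ESA 17.59 mm², EDD 4.00 mm, ESD 2.80 mm,
#> EDV 67.03 µL, ESV 32.85 µL, EF 51.00 %, FS 30.00 %, FAC 30.00 %,
#> SV 34.19 µL, CO 15.38 mL/min
```

EDV lands within 0.02 µL of the analytic half-ellipsoid volume
πLD²/6 = 67.02 µL; FS and FAC are exactly the 30% built into the phantom
(2.8/4.0 diameter ratio). M-mode endpoints from measured wall dimensions:

```r
dims <- mmode_dimensions(4.0, 2.8, 0.8, 1.0, 0.8, 1.0)
mmode_measures(dims, heart_rate = 450)$values
#> EDV 70.00 µL, ESV 29.55 µL, EF 57.78 %, FS 30.00 %, SV 40.45 µL,
#> CO 18.20 mL/min, LV mass 117.53 mg, LV mass corr 94.03 mg
```

The full semi-automated path — phantom sweep in, dimensions out:

```r
spec <- mmode_phantom_spec(speckle_scale = 0.3)   # 5 s sweep, 450 bpm
mp   <- make_mmode_phantom(spec)
seg  <- segment_mmode(mp$image, seeds)            # 4 seed pairs, see ?seed_point_pair
seg$dims                                          # recovered within a few percent
```

A study of many subjects runs from a JSON manifest
(`run_study("study.json", "results/")`), writing per-subject masks,
contours and traces plus an aggregated `report.csv`; after manual trace or
contour edits, `regenerate_reports("results/")` rebuilds the report from
the stored segmentations. A thin command-line front end over these
functions is installed at `inst/cli/lvecho.R`.

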