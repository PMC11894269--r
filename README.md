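# monson

Digital analysis of dental occlusal curvature via Monson's sphere.

In a natural dentition the cusp tips and incisal edges do not lie in a
plane: they approximate the surface of a sphere whose centre sits
cranially — Monson's sphere, the three-dimensional combination of the
curve of Spee (sagittal) and the curve of Wilson (frontal). The
classical prosthodontic rule of thumb puts its radius at four inches
(101.6 mm), and the individual radius matters whenever the occlusal
plane has to be rebuilt: full-mouth rehabilitation, complete dentures,
orthodontic finishing.

`monson` implements the full digital workflow for estimating that
radius from intraoral-scan data, for dental researchers and
prosthodontists working with 3-D models:

* **Landmarks** — a fixed 26-point cusp-tip scheme (`Pt1`..`Pt26`: per
  side, the canine tip, 4 premolar cusps and 8 molar cusps), with CSV
  input/output and validation.
* **Sphere fitting** — the best least-squares sphere through the
  landmarks. Two estimators are provided: the algebraic (Kåsa) fit,
  which minimises Σ(‖pᵢ − c‖² − R²)² via a linear solve, and the
  geometric fit, which minimises the orthogonal-distance objective
  Σ(‖pᵢ − c‖ − R)² by damped Gauss–Newton seeded from the algebraic
  solution. The fit is fully three-dimensional: no plane constrains the
  centre.
* **Mesh landmarking** — a reproducible analogue of colour-guided cusp
  picking on an STL scan: occlusal height field, quantile threshold,
  connected regions of interest, per-region maxima with prominence and
  separation filters, and optimal one-to-one label assignment against a
  template.
* **Reliability** — two-way single-measures intraclass correlation
  coefficients, ICC(3,1) consistency and ICC(2,1) absolute agreement,
  with exact F-based 95% confidence intervals, for repeat-measurement
  designs.
* **Cohort statistics** — descriptive summaries with t-based CIs of the
  mean, the one-sample t-test against the theoretical 101.6 mm radius,
  and the two-sided Mann–Whitney U test between sexes.
* **Synthetic data** — seeded generators for landmark sets near a known
  sphere, cohorts of radii from sex-specific normals, and toy dentition
  meshes with exactly known cusp apices, so the entire pipeline is
  testable without scanner data.

## Worked example

```r
library(monson)

# a synthetic dentition: 26 cusp tips on a 77.35 mm sphere, 0.1 mm noise
truth <- synthetic_truth(radius = 77.35, noise_sd = 0.1, seed = 42)
g <- generate_landmarks(truth)
fit_sphere(g$landmarks)
#> Monson sphere fit (geometric): R = 77.445 mm, center = (0.068, -0.001, 100.136) mm
#>   26 points, rms residual 0.0901 mm, max 0.3400 mm
```

The fitted radius lands 0.095 mm from the ground truth and the 0.09 mm
rms residual reflects the injected landmark noise.

```r
# intrarater reliability of the packaged repeat measurements
tab1 <- read_repeated_radii(system.file("extdata",
  "table1_repeated_radii.csv", package = "monson"))
icc_single_measures(tab1)
#> ICC (consistency, single measures): 0.996, 95% CI (0.987, 0.998)
#>   F(14, 14) = 447.11, one-sided p 4.67e-16
```

An ICC of 0.996 means between-model differences dwarf the repeat-
measurement error: the landmark-and-fit procedure is highly repeatable.

```r
# a simulated cohort of 32 + 32 radii at the default group parameters
cohort <- generate_cohort(cohort_spec(seed = 42))
compare_cohort(cohort)
#> Monson-sphere cohort report (radii in mm)
#>   males   n=32  84.89 +/- 16.02 (median 82.54, CI 79.11-90.66)
#>   females n=32  70.13 +/- 11.07 (median 72.59, CI 66.14-74.12)
#>   total   n=64  77.51 +/- 15.55 (median 77.93, CI 73.63-81.40)
#>   male - female mean difference: 14.76 mm
#>   Mann-Whitney U = 824.0, p 2.88e-05
#>   one-sample t vs 101.6 mm: t = -12.39 (df 63), p <2e-16
```

The report mirrors a standard cohort table: males run larger than
females, and the pooled mean sits far below the classical four-inch
value.

## Command line

A thin wrapper over the same functions ships with the package:

```sh
MONSON_CLI=$(Rscript -e 'cat(system.file("cli", "monson.R", package = "monson"))')
Rscript "$MONSON_CLI" simulate --what landmarks --seed 1 --out-dir work
Rscript "$MONSON_CLI" fit work/landmarks_001.csv --out work/fit.json
Rscript "$MONSON_CLI" icc path/to/repeated_radii.csv
Rscript "$MONSON_CLI" cohort path/to/cohort.csv
Rscript "$MONSON_CLI" detect scan.stl --template template.csv --out detected.csv
```

Results are JSON (or landmark CSV for `detect`) on standard output or
`--out`; logs go to standard error.

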