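---
title: "The Monson-sphere workflow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Monson-sphere workflow: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monson)
```

# The problem

Occlusal surfaces of a natural dentition are curved in both the
sagittal plane (curve of Spee) and the frontal plane (curve of Wilson);
their three-dimensional combination is classically idealised as a
sphere — Monson's sphere — that the cusp tips approximately touch, with
a textbook radius of four inches (101.6 mm). Estimating the individual
radius from a digital scan is a small but complete analysis pipeline:
locate cusp-tip landmarks, fit a sphere by least squares, and run
reliability and cohort statistics on the fitted radii. This vignette
documents how `monson` implements each stage, which parameters matter,
and where genuine design freedom existed.

# Landmark scheme

The fixed scheme has 26 labelled points, 13 per side of the arch: the
canine cusp tip; buccal and lingual cusps of the two premolars; and
mesio-buccal, disto-buccal, mesio-lingual and disto-lingual cusps of
the two molars (`landmark_labels()`). Coordinates are millimetres in an
arbitrary right-handed frame: every downstream computation is invariant
to rigid motion of that frame, so no canonical origin is imposed. The
scheme is arch-agnostic — the geometry of sphere fitting is identical
for maxillary and mandibular landmark sets, so the labels deliberately
carry no arch attribute.

A set is *complete* with all 26 labels; fitting proceeds with any
four or more non-coplanar points, but such fits are flagged `partial`
so cohort analyses can exclude them rather than silently pooling
landmark-deficient dentitions.

# Sphere fitting

Two least-squares estimators are implemented, because "least squares
sphere" is genuinely ambiguous: the fast linear formulation and the
orthogonal-distance formulation minimise different residuals, and
which one a given legacy script used is usually unknowable. Providing
both brackets the ambiguity; at sub-millimetre landmark noise they
agree closely.

**Algebraic (Kåsa) fit.** Minimises $\sum_i (\lVert p_i - c\rVert^2 -
R^2)^2$. Substituting $\beta = (2c, R^2 - \lVert c\rVert^2)$ makes the
problem linear; it is solved by QR in closed form. The solution is the
global minimiser of the algebraic objective and is deterministic.

**Geometric fit.** Minimises the sum of squared orthogonal distances
$\sum_i (\lVert p_i - c\rVert - R)^2$ over $(c, R)$ by Levenberg-damped
Gauss–Newton, seeded from the algebraic fit. Iteration limits: 100
iterations, stop when the step norm falls below $10^{-10}$ mm or the
gradient norm below $10^{-10}$; damping starts at $10^{-3}$, halves on
an accepted step and doubles on a rejected one. Steps are accepted only
when they reduce the objective, so the returned rms residual can never
exceed that of the initialisation. Non-convergence returns the best
iterate with `converged = FALSE` rather than an error, since the
4-parameter problem is benign and the final iterate remains the best
available estimate. The default `fit_sphere()` reports the geometric
solution.

**Degeneracy.** Coplanar points do not determine a finite sphere. The
guard is the thickness ratio — smallest over largest singular value of
the centred coordinates (`coplanarity_measure()`) — with threshold
$10^{-6}$: far above double-precision noise, far below any physical
dentition (the arch layout below sits near 0.1).

# Reliability: which ICC?

Repeatability of the whole locate-and-fit procedure is quantified by a
two-way single-measures intraclass correlation on radii measured twice
per model. Two forms are implemented because reports rarely say which
was used:

* ICC(3,1), *consistency* (two-way mixed): a constant session offset
  does not reduce the coefficient. This is the package default — when
  one operator measures twice, a systematic session shift is a
  calibration artefact, not rater disagreement.
* ICC(2,1), *absolute agreement* (two-way random): a session shift
  counts against reliability.

On the packaged 15-pair repeat-measurement table the two forms differ
in the third decimal (0.9955 vs 0.9954), and only the consistency form
rounds to the published 0.996 — the acceptance test asserts both
values, documenting the matching form. Confidence intervals are the
exact F-based Shrout–Fleiss constructions (Satterthwaite degrees of
freedom for the agreement form); no bootstrap, so results are
deterministic. The p-value tests ICC = 0 via the between-subjects F
and is one-sided, the only direction of interest for a reliability
claim.

# Cohort statistics

`compare_cohort()` reproduces a standard cohort table: per-sex and
pooled mean, SD (n−1), median (midpoint of the central pair for even
n — printed medians cannot be checked without raw data, so the
convention is simply documented), and the t-based 95% CI of the mean
$\bar x \pm t_{0.975,\,n-1}\, s/\sqrt n$. Two tests accompany it, at
$\alpha = 0.05$:

* one-sample two-sided t of the pooled radii against the theoretical
  four-inch radius, with the inch fixed at exactly 25.4 mm;
* two-sided Mann–Whitney U between sexes, U computed from midranks;
  the p-value is exact by enumeration when $n_a + n_b \le 20$ with no
  ties, otherwise the normal approximation with tie and continuity
  corrections. At 32 + 32 the asymptotic path is comfortably accurate;
  the exact path exists so small-sample results are not approximation
  artefacts, and it is verified against a brute-force enumeration
  oracle in the tests. The internal grouping key is generic, so any
  binary grouping can reuse the code path.

A wholly degenerate cohort (all radii identical) yields a Mann–Whitney
p of 1 and an undefined (NA) t statistic rather than an error.

# Synthetic data: what it emulates, and what it does not

The generators make every stage testable at desk scale and define the
conditions under which the package's statistical claims are verified.

**Landmark sets.** `generate_landmarks()` places the 26 landmarks at
fixed, bilaterally symmetric angular positions (layout `"arch35"`),
projects them exactly onto a truth sphere (default radius 77.35 mm, a
typical adult mean; centre 100 mm above the occlusal table), and adds
isotropic Gaussian noise, default $\sigma = 0.1$ mm, bracketing
reported intraoral-scanner trueness. Everything is a pure function of
spec + seed.

The layout's one genuinely free choice was its angular extent, and it
is load-bearing: sphere fitting on a shallow cap is ill-conditioned in
the radius, and at a realistic arch footprint (roughly a 25° cap on a
77 mm sphere) the mean absolute radius error at $\sigma = 0.1$ mm is
about 1 mm. The `arch35` layout therefore spans a cap of half-angle
≈ 35°, where the mean absolute error drops to ≈ 0.45 mm with
negligible bias — the regime the package's recovery guarantees are
stated in. The cost is a footprint stretched beyond a typical dentition
(canine-to-canine ≈ 47 mm): the generator prioritises a well-posed
estimation geometry over anthropometric fidelity, and users fitting
real scans should expect radius uncertainty closer to the shallow-cap
figure. The synthetic data also omit every other feature of real
scans: no wear facets, no missing or restored cusps, no occlusal
contacts, no scanner artefacts. Passing recovery tests show the
estimators are correct and well-behaved under the stated noise model,
not that real dentitions are spherical.

**Cohorts.** `generate_cohort()` draws radii from sex-specific normals
(defaults: 32 males at 83.57 ± 13.12 mm, 32 females at 71.13 ± 10.59
mm), truncated at zero by redraw — at these parameters the truncation
is practically never triggered (the mean sits more than six SDs above
zero).

**Meshes.** `generate_dentition_mesh()` builds a grid surface: a flat
base band plus one paraboloid-capped bump per landmark, apex exactly at
the noiseless landmark (the grid is locally snapped so each apex is a
mesh vertex). Defaults: 0.25 mm grid step, 6 mm minimum cusp height,
bump curvature 2 mm⁻¹ — chosen so the closest cusp pair (≈ 6 mm apart)
never merges into one bump. This is a detection fixture with known
ground truth, not tooth morphology.

# Mesh cusp-tip detection

The manual workflow this replaces is a colour-guided click: render
vertex height, eyeball the "high" regions, click the top of each. The
package's analogue is explicit and reproducible
(`extract_tip_candidates()`): project vertices onto a user-supplied
occlusal axis; threshold at the upper `top_fraction` height quantile
(default 0.15); split the supra-threshold vertices into connected
components over mesh edges; take each component's height maximum as a
candidate, with prominence measured down to the component's lowest
vertex (default minimum 0.5 mm); and suppress candidates closer than
`min_separation` (default 2 mm), keeping the higher. Defaults were
calibrated once on the synthetic fixture and are user-tunable flags.
Candidates are always mesh vertices — no interpolation — so detection
is exactly reproducible. Automatic occlusal-plane estimation is out of
scope: the axis is an input, defaulting to +z, which is correct for the
synthetic meshes.

Labelling uses an optimal one-to-one minimum-total-distance assignment
(Hungarian method via `clue::solve_LSAP`) against a registered
template rather than click order, which is an artefact of the manual
workflow. Unmatched labels are reported missing and yield a partial
set.

STL input accepts both binary and ASCII encodings; coordinates are
quantized through float32 (the STL storage type) on write so the two
encodings round-trip to identical geometry, and degenerate triangles
are dropped with a count message on read.

# Numerical and testing choices

* Landmark CSV round trips are exact to well below $10^{-6}$ mm
  (coordinates written at full double precision, `%.17g`).
* Exact-sphere recovery is asserted at $10^{-9}$ relative error;
  equivariance under rotation, translation and scaling at comparable
  tolerances.
* The geometric fit is cross-checked against two independent
  optimisers (multi-restart BFGS on the objective, and
  Levenberg–Marquardt from `minpack.lm`) to $10^{-6}$ mm² in objective
  value. For the algebraic objective, parameter-space comparison with
  a black-box search is done on $|R|$ — the objective depends on R
  only through R², so sign is not identified — together with the
  stronger assertion that the closed-form solution's objective is
  never beaten.
* Simulation-based checks use 200 seeded replicates (radius recovery,
  cohort significance, effect direction); the full suite runs in
  about 15 seconds on one CPU, and the mesh fixture (≈ 170k triangles)
  is built once and shared across tests.

# Limitations

* The sphere model itself is an idealisation; residual diagnostics
  (`rms_residual`, per-point residuals in the JSON report) are the
  only flatness-of-fit evidence reported, and no alternative occlusal
  surface models (paraboloid, ellipsoid, 2-D Spee/Wilson circles) are
  fitted.
* Radius estimates from shallow arches carry substantially more
  uncertainty than the synthetic-cap figures; see the layout
  discussion above.
* Tip detection assumes clean, near-watertight meshes; real scan
  pathology (holes, spikes, soft-tissue remnants) beyond degenerate
  triangles is not handled.
* Reliability support targets the two-session single-rater design;
  k > 2 sessions compute but are not validated against published
  values, and multi-rater designs are out of scope.
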