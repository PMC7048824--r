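---
title: "Does the average nasal geometry carry the average nasal airflow?"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Does the average nasal geometry carry the average nasal airflow?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noseflow)
```

## The question

A statistical shape model (SSM) of the nasal cavity — a mean shape plus
orthogonal modes of inter-subject variation obtained by PCA over
point-to-point corresponded surface meshes — yields an *average geometry*
of the healthy nose.  Such a geometry is attractive as a standardised
substrate for aerodynamic studies, but its usefulness hinges on a
non-obvious question: because the relation between airway geometry and
airflow is nonlinear, the airflow computed *in* the average geometry need
not equal the *average of the airflows* computed in the individual
geometries.  `noseflow` builds a desk-scale, fully testable twin of that
comparison: a synthetic corpus generator with known ground truth, an SSM
fitted by PCA, a quasi-1D laminar flow model, wall-field mapping onto the
reference triangulation, and the integral measures used in rhinologic
modelling (lateral and total resistance, airflow partitioning, velocity
and wall-shear-stress summaries, cross-sectional area profiles).

## The synthetic anatomy generator

Each subject is a bilateral duct: two tubes of elliptical cross-section
around smooth centerlines, discretised as `n_stations` rings of `n_ring`
vertices per side with one fixed triangulation, so point-to-point
correspondence holds by construction.  The baseline cross-sectional-area
profile has an anterior constriction (the isthmus) at `s = 0.15` of the
normalised nostril-to-choana axis, with about 55% of the nostril area, and
a mid-cavity maximum of about twice the nostril area; the default nostril
area is 100 mm².  These magnitudes are of the order seen in adult CT-based
area profiles but are **synthetic choices, not measured data**.  The
surface is divided into 24 patches (12 per side) by longitudinal segment
and circumferential sector, mimicking the anatomically labelled subregions
used to establish correspondences on real meshes.

Inter-subject variation is low-rank plus noise: up to five smooth,
ellipse-preserving displacement fields (symmetric inflation, antisymmetric
width change — a septal-deviation surrogate — second-harmonic height and
width, vertical bow), orthonormalised by QR and applied with weights
`w_k ~ N(0, mode_sd_k^2)` plus i.i.d. per-vertex Gaussian noise.  The
default is three modes with `mode_sd = 8 * 0.65^(0:2)` mm (on unit-norm
fields, giving semi-axis perturbations of a few tenths of a millimetre to
a millimetre) and `noise_sd = 0.05` mm, i.e. noise well below the voxel
resolution of clinical CT.  The default corpus size is 25 subjects.
Mirroring across the mid-sagittal plane `x = 0` (left side at `x < 0`)
uses a precomputed vertex symmetry map, so a mirrored geometry keeps the
same triangulation; mirror augmentation doubles the corpus and forces the
fitted mean shape to be mirror-symmetric.

What the generator deliberately does **not** emulate: turbinate folds and
narrow meatus slits, real correspondence estimation (correspondence is
exact by construction), segmentation artefacts, and the nasal cycle.
Passing tests therefore demonstrate the statistical and numerical
machinery — not that the proxy reproduces the aerodynamics of real
anatomy.

One numerical choice deserves note: station semi-axes are recovered from
deformed rings by *harmonic projection* onto the known ring
parameterisation (`b = (2/R) * sum(x_j cos(theta_j))`, likewise `a` from
`z` and `sin`), which is exact for elliptical rings and unbiased under
zero-mean vertex noise.  Recovering semi-axes from coordinate extents
would instead inherit the positive bias of the maximum of the noise.

## The shape model

`nasal_ssm()` performs PCA via the SVD of the centered `n x 3V` coordinate
matrix (numerically stable for `3V >> n`), with variances
`d^2 / (n - 1)`.  Coordinates stay in millimetres — no whitening — since
raw geometric variation is the object of study.  Mode signs are fixed so
each mode's largest-magnitude component is positive.  Optional rigid
alignment (rotation and translation, no scaling) is available but off by
default, since the generator emits pre-aligned shapes; for real corpora
whose pose is arbitrary it should be switched on.  Quality-control
distances (one-directional Hausdorff and mean surface distance) use exact
point-to-triangle distances rather than vertex-to-vertex, which matters
for coarse meshes.

With all modes retained, reconstruction of any member from its weights is
exact to numerical precision, and the fitted variances equal the
eigenvalues of the realized weight sample covariance to ~1e-15 relative.
A caveat worth stating: the *sample* variance of a Gaussian mode weight
has a relative sampling SD of `sqrt(2/(n-1))` — about 10% at `n = 200` —
so fitted variance fractions agree with the generator's parametric
fractions only to within that sampling noise, however exact the
estimator.

## The flow proxy

Flow is steady, laminar, incompressible and quasi-1D.  Defaults follow
restful breathing: total flow 200 ml/s (a 6 l/min respiratory minute
volume moved in half the cycle), air density 1.18 kg/m³, dynamic
viscosity 1.86e-5 Pa·s, rigid walls, 0 Pa static pressure at the
nostrils, and a common pharynx pressure coupling the two sides.  Peak
Mach numbers are recorded and stay far below 0.01.

The viscous closure is the exact fully developed elliptical-duct law
`dp/dx = 4 mu Q (a^2 + b^2) / (pi a^3 b^3)`, which reduces to Poiseuille's
`8 mu Q / (pi r^4)` for circular sections — the analytic oracle used
throughout the tests.  It is integrated over stations by the trapezoidal
rule on centerline arc length.  Optional minor losses use the
Borda–Carnot expansion coefficient `K = (1 - A_small/A_large)^2` applied
at every inter-station transition whose area increases in the flow
direction (contraction losses default to zero).  This is the minimal
mechanism that makes resistance direction-dependent, as inertial effects
do in 3D: with losses off the model is linear (Stokes-reversible) and
inspiration and expiration resistances are identical; with losses on they
differ.  For the default single-isthmus template the large
isthmus-to-mid-cavity expansion lies in the *inspiratory* direction, so
the proxy's inspiratory resistance exceeds the expiratory one — the
asymmetry's existence, not its sign or magnitude, is the transferable
statement, since in real noses the 3D inertial mechanisms dominate.

Wall shear stress comes from the axial force balance of fully developed
flow, `tau = |dp/ds|_visc A / P`; minor-loss pressure drops are excluded
from `tau` because they model separated flow whose momentum loss does not
load the wall as developed shear.  An optional circumferential modulation
follows the elliptical boundary-gradient shape and preserves the
arc-weighted station mean; it is off by default.

The bilateral partition is solved by bisection on
`dp_left(Q) = dp_right(V - Q)` to a 1e-9 Pa mismatch (the drop is
strictly monotone in Q, so the root is unique); with losses off the
solution coincides with the two-resistor current divider.  For a
mirror-symmetric geometry the first bisection midpoint `V/2` already
balances the sides, so the airflow partitioning is exactly 50%.

## Mapping and statistics

Wall fields are mapped between meshes by nearest-neighbour vertex lookup
with deterministic lowest-index tie-breaking — the scheme that matches
scattered-data nearest interpolation on corresponded triangulations.
Vertex-wise statistics across subjects use the sample SD (`n - 1`), the
even-`n` median convention (midpoint of the central pair), and a
coefficient of variation `sd/mean` masked where `|mean|` falls below a
threshold (defaults: 1e-3 Pa for WSS, 1e-2 Pa for pressure), since
near-zero means make the CoV a low-signal ratio.  Volume-weighted
velocity percentiles and area-weighted WSS percentiles use linear
interpolation on the weighted empirical CDF; report tables round
resistances to 3 decimals, velocities and WSS to 2, and partitioning
percentages to 1, and the Tukey convention (1.5 IQR whiskers) is used for
boxplot data.  WSS surface histograms default to bin edges
`(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, Inf]` Pa — only the first bin is
canonical; the rest are configurable.

## The averaging property

The central mechanism is a Jensen-type inequality: per unit length the
viscous resistance density `(a^2 + b^2)/(a^3 b^3)` is a sum of terms
`a^p b^q` with negative exponents, each log-convex and hence convex in
`(a, b)`.  Averaging geometries therefore averages semi-axes, and each
side of the average geometry resists *at most* the average of the member
side resistances — strictly less whenever shape variance is positive.
The parallel combination of the two sides works in the opposite
direction (it is concave in the lateral resistances), so the total
resistance of the average geometry is not ordered against the cohort mean
by convexity alone.  At the default study conditions — corpora of 25
subjects, mirror augmentation, losses off — the average geometry's total
resistance falls strictly below the cohort mean in 100 of 100 seeded
corpora.  In much smaller corpora (for example 5 subjects) occasional
reversals can occur when a sampling-dominant antisymmetric mode makes
left-right asymmetry, and with it the concavity penalty, transiently
large; this is a genuine feature of the mechanism, not a numerical
artefact.

## Problem sizes and reproducibility

The default template uses 21 stations per side (a 5% grid of the
normalised axis) and 24-vertex rings (1008 vertices, 1920 triangles); the
test suite additionally uses coarse 11-station/8-ring meshes and
100-corpus ensembles, sizes chosen so the whole suite and the
acceptance script each run in well under a minute on one CPU while
leaving every property statistically resolvable.  All randomness flows
from one root seed; subject `i` draws from stream `seed + i`, so corpora
are reproducible member-by-member and `pipeline_run()` is byte-identical
across reruns of the same configuration.

## Known limitations

The quasi-1D proxy has no secondary flows, jets, or vortices, so absolute
resistances and wall shear stresses are systematically lower than 3D CFD
values for real anatomy; comparisons between the average geometry and
cohort members are meaningful, absolute magnitudes are not.  The
inspiration/expiration asymmetry is mechanism-compatible but not
magnitude-comparable.  Real corresponded meshes can be ingested (PLY with
per-face patch labels, plus station profiles as CSV) but correspondence
itself is out of scope, as are nonlinear shape statistics.
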