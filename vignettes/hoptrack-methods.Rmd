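---
title: "Methods: stereo videogrammetry and jump kinematics in hoptrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereo videogrammetry and jump kinematics in hoptrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoptrack)
```

## The problem

Comparative studies of anuran locomotion film single hops with two
high-speed cameras, digitize two body landmarks (snout and cloaca) in every
frame of both views, and reduce each hop to a handful of kinematic
variables: mean and maximum velocity, distance, height, and the body-axis
angles at take-off and landing. Those variables are then related to
size-corrected morphology and to forced-locomotion (raceway) performance,
typically contrasting cohorts such as range-core versus invasion-front
populations of an invasive species.

hoptrack implements that measurement chain end to end — camera
synchronization, calibration with quality control, triangulation, alignment
to a standard jump plane, kinematic extraction, morphometric residuals and
the comparative statistics — together with a ground-truthed synthetic-data
generator, so that every stage can be verified exactly without access to
any video.

## The forward model: ballistic hops

The generator treats the cloaca as a point mass launched from $c_0$ with
speed $v_0$ at elevation $\theta$ above horizontal:

$$c(t) = c_0 + v_0 t\,(\cos\theta\cos\phi,\ \cos\theta\sin\phi,\ \sin\theta)
  - \tfrac{1}{2} g t^2 (0, 0, 1),$$

with $g = 981\ \mathrm{cm\,s^{-2}}$ (the analysis works in cm; the constant
is physics, not data). Flight ends when the cloaca returns to take-off
height — a flat-ground assumption matching a hard bare-soil arena. The
closed forms

$$\text{range} = \frac{v_0^2 \sin 2\theta}{g}, \qquad
  \text{apex} = \frac{v_0^2 \sin^2\theta}{2g}, \qquad
  T = \frac{2 v_0 \sin\theta}{g}$$

are attached to every simulated trajectory as ground truth and anchor the
test suite.

The snout sits one body length from the cloaca along a body axis whose
elevation interpolates **linearly in time** between the planted take-off
and landing angles. Real toads pitch nonlinearly mid-flight, but no
published model of within-flight posture exists for this design; linear
interpolation is the simplest rule whose endpoint values — the only frames
the analysis reads angles from — are exact. Observed take-off angles of
real animals describe body posture, not the velocity vector, so the
generator plants the two quantities separately and either reading can be
tested.

Not modelled, deliberately: aerodynamic drag (negligible over < 1.5 m
hops), non-planar ground, multi-hop bounding sequences, and actual image
formation (landmarks arrive as pixel tables, as they do from digitization
software).

## The synthetic stereo rig

The default rig mirrors the field protocol: two cameras at 240 fps on
10 cm tripods, 20 cm apart, with a flash for synchronization and a planar
checkerboard for calibration. The cameras are pinholes (focal length
1400 px, 1920 x 1080 sensor) standing 150 cm back from the jump arena and
verged onto its centre. The field description of the tripod heads
"forming an angle of 140 degrees" cannot be the optical-axis convergence:
two axes 140 degrees apart on a 20 cm baseline would cross 3.6 cm in front
of the cameras and view disjoint scenes at working distance. The rig
therefore keeps the 140-degree figure as descriptive metadata and derives
the projection geometry from the standoff and aim point.

Landmark digitization error is isotropic Gaussian pixel noise (default sd
0.5 px when enabled; the verification rig is noiseless). At this geometry,
first-order propagation predicts a triangulation error sd of
$\sqrt{2}\, d^2 \sigma_{px} / (f\, b) \approx 0.5$–$0.7$ cm across the
jump volume, which the tests confirm by Monte Carlo. Synchronization error
is an integer frame offset of the right camera, recovered from the flash
spike positions.

## Calibration, QC and triangulation

The original workflow calibrated with a planar-checkerboard toolbox
(intrinsics + stereo extrinsics via nonlinear optimization). hoptrack
instead uses **normalized direct-linear-transform resectioning**: each
camera's 3x4 projection is estimated from pooled 3D–2D correspondences
spanning several board poses (which supplies the non-coplanar points DLT
needs), with Hartley normalization for conditioning. The observable
contract — a calibrated stereo pair mapping world cm to pixels — is
identical, the implementation is two orders of magnitude smaller, and
exactness is testable: noiseless correspondences reproduce the camera to
$\le 10^{-8}$ px. Lens distortion and bundle adjustment are out of scope.

The historical protocol suppressed calibration images showing "more than
1% inaccuracies between the left and right views" without defining the
metric. hoptrack operationalizes it: triangulate all corners of a view,
rigidly fit (Kabsch) the known board-frame corner grid onto the
reconstruction, and divide the RMS corner discrepancy by the corner-grid
width; views above `threshold = 0.01` are rejected and logged, and the
cameras are re-resected from the survivors. An epipolar-distance metric
would be a defensible alternative; it is noted but not implemented.

Triangulation is the homogeneous DLT intersection of the two viewing rays,
solved by SVD. The ratio of the third to first singular value of the 4x4
design guards reliability: identical cameras or near-parallel rays fall
below `conditioning_tol = 1e-9` and raise an error instead of returning an
arbitrary point.

Reconstruction pairs frames present in both synchronized views, requires
both landmarks in at least 90% of the frame span (configurable), linearly
interpolates gaps of at most 2 frames (flagged in the output), and rejects
longer gaps. The 2-frame rule is this package's choice; over 2/240 s a
ballistic path deviates from a chord by under 0.01 cm, so interpolation is
numerically harmless there, while longer gaps would silently smooth the
apex.

## Alignment and kinematic extraction

Trajectories from different trials live in different calibration frames.
Each hop is rigidly mapped to a standard frame: the known vertical (from
the calibration rig) to +z, the take-off cloaca to the origin, and the
horizontal heading to +x. The heading is the principal axis of the
cloaca's horizontal displacements, which minimizes the squared lateral (y)
coordinates; the sign follows the net displacement. Rigidity is exact
(orthogonal matrices), so every extracted quantity is rotation-invariant —
the tests verify to $10^{-6}$ over 200 random rigid motions. A hop with no
net horizontal displacement has no defined heading and errors out.

Take-off is the last frame before the cloaca rises more than
`epsilon = 0.1` cm above its initial height and stays up for at least 3
frames; landing is the first frame at or after the apex back within
`epsilon` of baseline. The 0.1 cm default sits well above triangulation
noise on clean data and well below any real apex.

Within the take-off–landing bracket:

* **velocity**: cloaca speed by central differences at 1/fps spacing
  (optionally a 5-frame moving average, default off); mean and max over
  the bracket. Mean velocity covers flight frames only — whether the
  historical protocol included pre-take-off frames is unknowable from the
  text, and flight-only is the reproducible choice.
* **distance**: horizontal (x) cloaca displacement take-off to landing.
* **height**: maximum cloaca elevation above the take-off baseline. The
  cloaca (not the snout) is the reference landmark for
  velocity/distance/height — it is the contact point at both ends of the
  hop; the snout alternative is one accessor away for anyone who wants it.
* **angles**: signed elevation of the cloaca-to-snout vector at the
  bracket end frames. "Angle between the xz-plane and the body vector" is
  read as elevation above the horizontal plane — the only reading
  consistent with typical values near +30 degrees at take-off and -25 at
  landing.

Frame sampling quantizes distance by at most one frame of horizontal
motion ($v/\mathrm{fps}$, about 1–1.4 cm at observed speeds) and height by
under 0.01 cm; the acceptance tolerances are set by those bounds, not the
other way round.

Analyses use one value per animal: the hop with maximum distance, ties
broken by earliest trial id.

## Cohorts: what the generator plants

`cohort_presets()` embeds the ten study cohorts (generation x invasion
category x sex/age class) with their published sample sizes, trait means
and standard errors. Each per-individual trait is drawn
$\mathcal{N}(\text{mean}, \text{se}\sqrt{n})$, so the simulated cohort
mean is distributed exactly as the published mean with its standard error
— the strongest statement a table of means and SEs supports. Consequences
worth stating plainly:

* A simulated cohort mean lands within 2 SE of the published value for
  ~95% of seeds; occasional excursions are sampling, not bugs.
* Tibiofibula length is absent from the tabulated means (though measured
  and analysed elsewhere); the presets synthesize it as 0.98 x femur with
  the femur's SE. It is a labelled synthetic assumption.
* The under-90 mm SVL juvenile classification is a field rule for animals
  too small to sex; the generator labels class by preset and does not
  truncate SVL draws at 90 mm, which would bias the planted means.

Morphology co-varies with SVL through a configurable allometric slope
(`allometry * trait_mean / svl_mean`, default `allometry = 0.6`; residual
noise is sized so marginal spreads still match the presets — full isometry
would demand more SVL-driven variance than some traits possess). Jump
kinematics are realized as ballistic parameters: distance, height and body
angles are drawn from the preset and take-off speed and elevation follow
from $\tan\theta = 4h/d$ and $v_0^2 = g d / \sin 2\theta$. Mean and
maximum velocity therefore follow from physics rather than being planted
independently — a point mass cannot have its range, apex and speed profile
all set freely, and the published velocity means are themselves summaries
of real, non-ballistic limb dynamics. Morphology and kinematics are
independent by default; `kinematic_coupling` plants an SVL–distance
correlation for exercising the regression stage, and the study simulator
couples raceway hop distance to jump distance with $\rho = 0.32$ by
default. Azimuths are drawn within ±15 degrees of the arena axis so whole
hops stay in both camera views; rotation invariance is exercised
separately.

## Statistics

* **Nested ANOVA** (`nested_anova`): fixed-effects
  $y \sim \text{category} + \text{population}(\text{category})$, both terms
  against the residual mean square — matching the large denominator df of
  the published tables (e.g. 1,83 and 5,83), which a random-population
  model would not produce. Sums of squares are Type III (the default of
  the software used historically) computed by dropping sum-contrast column
  blocks from a sigma-restricted design matrix; this coding stays full
  rank with unequal population counts per category (3 vs 4), where naive
  nested factor coding aliases. Balanced designs reproduce the classical
  nested table exactly (oracle-tested); a constant response reports
  F = 0. One population in every category collapses to one-way ANOVA; one
  population in only some categories is a nesting degeneracy and errors.
* **Category x trait interaction** (`manova_traits_interaction`): profile
  analysis — the trait matrix (typically shape residuals) is reduced to
  within-subject successive-difference contrasts and the category effect
  on them is tested multivariately (Wilks' lambda by default, Pillai
  optionally, via `stats::anova.mlm`). This is one consistent reading of
  "traits as the repeated measure"; the conventional interaction df
  $(p-1)(k-1)$ is reported alongside the F-approximation df.
* **Backward elimination** (`backward_eliminate`): full OLS fit, then
  repeatedly drop the predictor with the largest p-value at or above
  `stay_threshold = 0.05` and refit; ties drop the later column; the
  removal order is recorded. Collinear candidate sets error naming the
  offending pair. Under the null each predictor is retained at roughly the
  stay threshold, and elimination is order-invariant when p-values are
  distinct — both properties are tested by simulation.
* **Correlations** (`pearson_corr`): product-moment r with the two-sided
  t-test, requiring $n \ge 3$ and nonzero variances. No multiple-testing
  correction anywhere, matching the original analysis.

Type-I error of all four procedures is verified at 0.05 ± 0.02 under
simulated nulls (1000 replicates each), and null p-values pass
Kolmogorov–Smirnov uniformity at 2000 replicates.

## Raceway trials

A trial is an event log on a 15 m track: hops (timestamp, displacement,
cumulative position) and refusals; ten consecutive refusals terminate the
trial. Summaries report per-5 m segment times (between first crossings of
segment boundaries) and hop counts (by landing position), mean distance
per hop (final position / hops), and mean speed (final position / elapsed
time — the completed-distance convention for non-finishers, since the
historical definition for animals that never finished is unstated).
Partial final segments are reported flagged `completed = FALSE` rather
than dropped. Segment times and counts telescope to the trial totals, and
speed = mean hop distance x hop rate identically, both tested.

## Pipeline, formats, determinism

`run_pipeline()` executes calibrate → synchronize → reconstruct → align →
extract → best-jump → residuals → statistics, writing each stage's tables
before the next begins and halting with the stage name and trial id on
error (partial outputs retained). All exchange is schema-stamped CSV
(UTF-8, decimal points; locale decimal commas are rejected by name), one
logical table per file; `simulate_study()` writes a complete
ground-truthed input set, including planted QC failures on request. Every
generator is a pure function of its seed; identical seeds give identical
bytes, which the tests assert.

## Problem sizes

The verification suite runs the single-hop oracles at 240 fps (one frame
≈ 4 ms), full-size female F0 cohorts (n = 34 and 56) through the complete
stereo chain, 200 random rotations for rigidity, and 500–2000 replicates
per statistical calibration check — sizes at which every Monte-Carlo
tolerance above is meaningful while the whole suite stays interactive.

## Limitations

Passing tests demonstrate correctness of the measurement chain on data
whose generating model is known — ballistic point-mass hops, pinhole
cameras, Gaussian pixel noise, Gaussian trait distributions. They cannot
certify behaviour on real video artefacts this model omits: lens
distortion, rolling shutter, digitization outliers, non-ballistic body
dynamics, or trait distributions with skew and shared family structure.
The published field F-ratios and correlations depend on raw per-animal
data that are not embedded here; the statistical layer is validated by its
sampling properties and planted-effect recovery, not by reproducing those
field values.
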