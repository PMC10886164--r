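---
title: "Methods: population FE modelling of cementless tibial tray fixation"
author: "tibiofit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population FE modelling of cementless tibial tray fixation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

Primary fixation of a cementless tibial tray is the mechanical stability of
the implant before any bone ingrowth: it is produced by the press-fit
(interference between implant and the prepared bone cavity) and by friction
at the implant–bone interface, and it is threatened by the cyclic
tibiofemoral loads of daily activities. The quantity of interest is the
**micromotion**: the relative displacement, in the shearing direction,
between implant contact nodes and the apposed bone surface. Interface
regions moving less than roughly 112 µm are considered compatible with
osseointegration; persistent larger motion favours fibrous encapsulation.

`tibiofit` implements the full population workflow at desk scale: synthetic
patient cohorts, tibia-like geometry with CT-style density fields, automated
implant reconstruction, a nonlinear frictional press-fit FE solution under
gait and squat loading, micromotion extraction, and a linear mixed model of
micromotion on patient factors (gender, age, BMI). Because no real CT
cohort ships with the package, every input is generated by code; what the
tests demonstrate is therefore the correctness and calibration of the
*machinery* and the qualitative population contrasts, not anatomical
fidelity.

## Synthetic cohort

Patients are sampled from truncated normal distributions matched to the
published cohort summary (only means and ranges are available): age 63
(46–75) years, height 1.71 (1.55–1.99) m, BMI 26 (18–49) kg/m², weight
bounded to 52–170 kg, 63% female, and a bilateral probability reproducing
74 tibiae from 41 patients. Standard deviations default to range/4. Height
and BMI are the primary draws; weight is derived as `bmi * height^2` and
the joint draw is rejected until weight falls inside its range, so all four
constraints hold simultaneously and `bmi == weight / height^2` is exact.
The sampler is bit-reproducible under a fixed seed and restores the
caller's RNG state.

## Geometry and reconstruction

The tibia is a parametric condyle-plus-tapered-shaft solid: an asymmetric
(medially fuller) elliptical cross-section whose radius flares
metaphysially near the joint line (the plane z = 0) and tapers to a shaft,
scaled linearly with patient height, with smooth seeded shape noise and a
random pose perturbation. This is deliberately not an anatomical atlas —
the testable content of the pipeline is the mechanics and the metric, not
shape statistics. The Hounsfield field is analytic: a dense cortical shell
(default 1200 HU, 1.8 mm proximally thickening to 5 mm in the diaphysis)
blended by a sigmoid of depth over a trabecular interior (300 HU), plus
smooth spatial noise; elements sample it at their centroids.

Reconstruction mirrors the modelled surgical workflow:

* an anatomical frame from condylar and shaft landmarks (proximal–distal,
  medial–lateral, anterior–posterior; right-handed);
* an optional rigid coherent-point-drift refinement of the frame alignment
  against the canonical template surface (EM over a Gaussian mixture with
  isotropic variance; rotation from the SVD of the weighted
  cross-covariance; scale fixed at 1);
* proximal resection 8.9 mm below the articular surface and distal
  truncation 100 mm from the joint line, both orthogonal to the
  proximal–distal axis;
* tray sizing from a six-size catalog: the size maximising covered cut
  area subject to a maximum overhang of 2 mm, with the in-plane placement
  optimised by Nelder–Mead and the overhang measured as the largest signed
  distance of ≥360 footprint boundary samples outside the cut outline;
* layered structured tetrahedralization. Solids handled by the pipeline
  are star-shaped about the bore axis, so each axial level carries a
  centre node and concentric rings following the section outline; cells
  between levels are split into tetrahedra by a fixed template whose face
  diagonals agree between neighbours (conforming by construction). One
  ring is pinned exactly at the peg/bore radius so bone and implant meet
  line-to-line.

The tray carries a central fixation peg (radius 0.22 × half-width, 12 mm
long) inserted into a matching bore; the 500 µm interference acts on the
whole contacting surface, and on the peg wall it becomes the radial
press-fit that anchors the implant. Tray (4 mm) plus insert (4.9 mm)
restore the 8.9 mm resection, preserving overall tibial length.

## Materials

CT intensity maps to equivalent density through a piecewise-linear
calibration anchored at air (−1000 HU → 0), fat (−100 → 0.95) and muscle
(+40 → 1.05 g/cm³), linearly extrapolated above muscle and clamped at zero
below air. Whether the original calibration was piecewise-linear or
regression-based is not recoverable; the anchor form is the simplest map
consistent with three reference tissues and is fully configurable. Density
maps to modulus by a power law `E = 6.85 ρ²` GPa (a literature-typical
exponent), clamped to the physiological 5.0–20.5 GPa bone range. Bone is
elastic–plastic with a Von Mises yield criterion, perfectly plastic by
default, with yield stress 0.8% of the modulus (a conventional
yield-strain scaling; the source workflow specifies the criterion but not
its parameters). The tray is elastic PEEK (3.7 GPa) or titanium (109 GPa);
the insert is UHMWPE (0.974 GPa) bonded to the tray (whether the original
model re-solves the tray–insert contact is unknown; bonding is assumed).
Poisson ratios default to 0.3 (bone, titanium), 0.36 (PEEK), 0.46 (UHMWPE).

## FE contact solver

The solver is quasi-static incremental Newton on linear tetrahedra with a
penalty-regularised, single-sided node-to-face contact: implant surface
nodes (tray distal face, peg wall) are slaves against bone master faces
(resection surface, bore wall), paired in the reference configuration and
held material thereafter (small-displacement contact). The interference
enters as a surface offset measured from the as-assembled state; pressure
builds wherever the relative normal approach falls short of the current
fit, which is ramped linearly over 20 increments during the virtual
implantation (the ramp count is a package choice; only linear ramping is
prescribed). Friction is bilinear Coulomb: traction grows linearly with
relative tangential displacement up to µ·p over the slip tolerance
(default 10 µm), then stays at µ·p while the anchor slides.

Numerical choices that matter:

* **Penalty** defaults to 5000 N/mm³. The thick-walled-cylinder benchmark
  fixes the trade-off: the penalty compliance `p/k_N` must stay small
  against the interference (the benchmark itself runs at 20000 N/mm³,
  keeping that error below ~5%), while the cohort profile favours the
  softer default for conditioning.
* **Friction bound lag**: the Coulomb limit and stick stiffness use the
  pressure committed at the previous increment, decoupling friction from
  the implicit normal solve; the tangent stays symmetric and exact for the
  resulting bilinear spring. Under steady conditions the lag vanishes.
* **Stick-stiffness cap**: µN/slip_tolerance is capped at the normal
  penalty stiffness; at extreme press-fit pressures the bilinear
  breakpoint grows instead of ruining the tangent conditioning.
* **Plasticity** uses the radial-return map, vectorised over elements, and
  the consistent elastoplastic tangent with a tangent-only numerical
  hardening of 10⁻³E that keeps the operator positive definite under
  perfect plasticity (the stress update is unaffected).
* Newton iterations carry a backtracking line search on the force
  residual; the tangent is refactorised (sparse supernodal Cholesky) when
  the contact status changes materially, whenever yielding is active, or
  on slow progress, and increments are bisected on divergence.
* Convergence is declared at a force residual below `tol_rel` times the
  force scale (default 10⁻⁸; the desk cohort profile uses 10⁻⁷). At every
  converged increment the summed distal reactions balance the applied
  load; the equilibrium check in the tests runs a tighter 10⁻⁹ tolerance.

Loads: the medial and lateral tibiofemoral forces of each activity
increment are distributed over insert-top nodes within 12 mm of their
centres of pressure by inverse-distance weights, applied along the
proximal–distal axis (compressive; the source workflow does not print
force directions, so shear components are config-optional and off). The
total peaks at 1514 N scaled by bodyweight/75 kg — the reference
bodyweight is a package convention, as only proportional scaling is
prescribed. Gait cycles have 73 increments, squat 67; four cycles are run
so the implant settles numerically. Curve shapes are smooth parametric
stand-ins (two-peak stance curve for gait, single mid-flexion peak for
squat) since only the counts and the peak are prescribed; both shapes and
the medial share are overridable. The distal bone face is fixed in all
directions. Bilateral tibiae of one patient share the same
bodyweight-scaled profiles.

## Micromotion metric

Each implant contact node is projected onto the closest bone contact face
at the first increment of the tracked cycle (the fourth by default); the
correspondence is then held material and the node position is expressed in
the co-moving orthonormal frame of its face at every increment. The
per-node micromotion is the largest in-plane excursion from the
cycle-start position over the full cycle, in µm. Expressing the motion in
the face frame makes the metric exactly zero under a common rigid motion
of all bodies and invariant under rigid transforms of the entire history.
Nodes whose mean normal gap exceeds 0.5 mm (a configurable default; only
"large normal gap" is prescribed) are excluded, e.g. overhang regions.
Summaries report the peak, the 95th percentile over nodes (linear
interpolation between order statistics; the convention is a package
choice) for outlier suppression, and the tributary-area-weighted fraction
of the interface below the 112 µm osseointegration threshold. An
alternative per-increment re-projection mode is available in code; the
material-foot-point mode is the default and the tested one.

## Population study and statistics

The factorial plan crosses tibiae × {PEEK, titanium} × {gait, squat} — 296
simulations for a 74-tibia cohort. Execution shares the reconstruction per
tibia and the implantation per material, caches completed tibiae on disk
(resumable), and records failures without aborting. The mixed model is
`p95 micromotion ~ gender + age + bmi + (1 | patient)` fitted by REML
through lme4, with Wald 95% intervals and normal-approximation p-values
(the original analysis software's procedure details are unpublished; Wald
z on REML estimates is the conventional default). The random intercept per
patient absorbs the correlation of bilateral tibiae and of the four
factorial arms of one patient; pooling all arms in a single model mirrors
the finding that the BMI effect is independent of implant material, and
material/activity can be added as fixed effects. BMI rather than weight
enters the default model (both were considered in the source analysis;
BMI is the accepted body-composition covariate). Violin summaries use
kernel densities with Silverman's bandwidth.

## Problem sizes and calibration checks

The reference mesh resolution is a 2.0–2.5 mm tetrahedral edge length. All
resolutions are expressed through a single `edge_scale` multiplier so the
configuration surface is identical at any scale; the desk-scale cohort
profile runs at `edge_scale = 5` (≈10–12 mm edges, roughly 2000–3000
degrees of freedom per model), which an ordinary workstation completes for
an 8-tibia factorial (32 simulations) in a few minutes. The verification
suite anchors the mechanics independently of resolution:

* patch test: constant-strain reproduction to machine precision;
* cantilever bending: tip deflection within 5% of Euler–Bernoulli
  (56 × 14 × 14 divisions — linear tetrahedra converge slowly in bending,
  so this benchmark uses the finest mesh in the suite);
* Coulomb threshold: stick below µN with zero accumulated slip, steady
  sliding at µN within 1%;
* press-fit pressure within 15% of the plane-strain Lamé closed form
  (3–4% at the benchmark resolution);
* distal reactions balancing applied loads to 10⁻⁶ relative;
* the micromotion metric agreeing with a brute-force projection oracle to
  10⁻¹² relative on randomized synthetic histories.

Statistical calibration is checked by simulation: on synthetic cohorts
with a known BMI slope of 1.5 µm per kg/m² (n = 200 patients), the 95%
Wald interval covers the truth at the nominal rate (≥93% over 200
replicates); on null cohorts the type-I error for BMI stays within
[0.03, 0.07] over 1000 replicates.

## What passing tests do and do not show

The synthetic cohort emulates the *structure* of the study — demographics,
bilaterality, load scaling, factorial design — and the synthetic tibia the
*mechanical ingredients* of the reconstruction: a stiffness-graded bone
with a cortical shell, a resected planar interface, a press-fitted peg.
The desk-scale cohort reproduces the qualitative population findings: PEEK
trays generate larger micromotions than titanium (clearly under squat
load), micromotion grows with bodyweight (the mechanistic core of the BMI
effect, which is implemented through bodyweight-scaled forces), and the
interface stays overwhelmingly below the 112 µm threshold. Absolute
micromotion magnitudes, however, depend on anatomy, implant design and
interface detail that the synthetic geometry does not claim to reproduce;
at the desk profile they sit in the units-to-tens of µm and should be read
as scaled-down analogues, not predictions. Known limitations shared with
the modelled workflow: no viscoelastic bone, a single alignment strategy,
no ligaments or muscles, an idealized gap-free interface; specific to this
package: parametric rather than image-based anatomy, a single generic
peg-only tray design, and coarse desk-scale meshes by default.
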