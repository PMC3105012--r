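---
title: "Craniofacial morphometry with craniomorph: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Craniofacial morphometry with craniomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models
implemented, the parameters that matter and their defaults, the numerical
decisions taken where a choice was genuinely open, what the synthetic data
generator does and does not emulate, and the known limitations.

## The measurement model

The package treats the face as a deformable object observed through a
brain-stripped T1-weighted head volume on a ~1 mm lattice. All geometry
lives in world millimetres (right-handed RAS: +x right, +y anterior, +z
superior), carried by each volume's voxel-to-world affine, so grids of
different extents interoperate. Two analysis channels share one spatial
normalisation:

* a **voxel channel**: statistics on the Jacobian determinants of the
  nonlinear deformations that map the population average to each subject;
* a **landmark channel**: statistics on a fixed set of 56 facial landmarks
  carried from the average to each subject by the same deformations.

### Conventions that prevent silent errors

Every resampling operation uses the *pull-back* convention: the transform
maps target world coordinates into source world coordinates, and the output
voxel takes the trilinearly interpolated source value (zero outside the
field of view, appropriate for heads on an empty background). Displacement
fields store world-mm vectors on their own node lattice and are evaluated
anywhere by trilinear interpolation (edge-clamped outside). A field
attached to atlas geometry therefore *is* the map from atlas space to the
subject - the object needed both to resample the subject into atlas space
and to carry atlas landmarks to the subject. Affine transforms are stored
as 4x4 matrices factored `T * Rz * Ry * Rx * Shear * Scale`; the QR-based
decomposition recovers the twelve parameters exactly, which is what makes
the head-size factor (product of the three scales) well defined.

## Atlas construction

`build_atlas()` follows a sequential hierarchy: (1) rigid alignment of all
scans to a seed subject; (2) all-pairs 9-parameter registration, after
which each subject is moved by the matrix-logarithm average of the
transforms from every subject's space into its own - this scales everyone
to the population's average head and face size, and the product of the
averaged scale factors is the subject's head-size covariate; (3)
12-parameter registration to the resulting average; (4) one nonlinear
generation per schedule row, each registering every subject to the previous
generation's average and averaging the resampled scans.

Design choices worth stating explicitly:

* **Log-space transform averaging.** The geometric (matrix-logarithm) mean
  is inversion-symmetric - averaging a transform with its inverse gives the
  identity - so the average space is not biased toward any registration
  direction. The per-subject average includes the identity self-transform:
  leaving it out inflates every log-scale by `n/(n-1)`, which is invisible
  at cohort sizes in the hundreds but a 2-5% head-size error at `n = 8`.
* **Pair reuse.** Each unordered 9-parameter pair is registered once and
  the matrix inverse reused for the reverse direction; identical in exact
  arithmetic at half the cost.
* **Atlas frame.** A group-wise atlas is defined only up to the seed
  subject's linear frame. Comparisons of the model against any external
  reference (as in the validation suite) therefore align the frames with a
  12-parameter registration first; subjects themselves are compared to the
  model in its own frame.
* **Intensity averaging** is the voxel-wise mean, and each generation
  re-registers the linearly resampled originals (one interpolation), not
  previously warped copies (which would accumulate smoothing).
* **Quality control** replaces visual inspection with the normalised
  cross-correlation of each warped subject against the final model inside
  the head mask (default flag threshold 0.85). Flagged subjects are
  reported, never silently dropped.

### Linear registration

`register_linear()` maximises masked NCC over a coarse-to-fine blur pyramid
(8, 4, 2 mm FWHM by default) with Nelder-Mead over 6/9/12 parameters
(rotations and scalings taken about the target head centroid). Two details
matter in practice. The similarity is evaluated over the dilated target
head only: background voxels carry no alignment information and dilute the
correlation (including them roughly doubles the scale error). And the
simplex is restarted once from its own optimum at every level: in 9-12
dimensions Nelder-Mead is prone to degenerate simplices, and the restart
cuts recovered-scale errors from ~1% to ~0.2% on 10% planted scale
differences.

### Nonlinear registration

`register_nonlinear()` is multi-resolution block matching. Per schedule
step `(step, iterations, blur)`: both images are blurred at the stated
FWHM; control nodes sit on a lattice at the step spacing; each node's local
translation is optimised by a 3D Nelder-Mead simplex (initial edge
`step/2`, at most 50 evaluations, zero displacement kept on flat
similarity) of the local NCC over a spherical intensity window of radius
`step` (sampled at `max(1, step/2)` mm), searching within radius `3 *
step`. Defaults for the regularisation knobs are stiffness 1, weight 1,
similarity 0.3; the data-driven move is damped by `alpha =
similarity/(similarity + stiffness*weight)`.

The regulariser itself required a decision. The obvious rule - blend the
data update with the Gaussian-smoothed field, `u <- alpha*u_data +
(1-alpha)*smooth(u)` - has a biased fixed point: a displacement component
whose spatial frequency the smoother attenuates by `s` converges to
`alpha/(1 - (1-alpha)*s)` of its true amplitude, which at `alpha = 0.23`
shrinks warp-scale detail by ~40% and visibly blurs the resulting atlas.
The package instead smooths the *increment*: `u <- u +
smooth_w(alpha*(u_data - u))`, where `smooth_w` is a Gaussian over the node
lattice (sigma = one node spacing) weighted by node activity, and nodes
without usable intensity (flat target window) relax to the smoothed field.
At equilibrium the increment vanishes, so informative regions converge to
the data optimum at full amplitude while uninformative regions stay
interpolated. A step that fails to improve the masked similarity at its own
blur level is rejected and the incoming field carried forward; this keeps
the per-step similarity trace non-decreasing by construction, in the spirit
of a trust-region acceptance rule.

Fields are inverted (`invert_field()`) by per-node fixed-point iteration
`v <- -u(y + v)` (tolerance 0.05 mm, 20 iterations), with a hard error on
non-positive Jacobians.

## Voxel-wise statistics

`jacobian_map()` computes `det(I + du/dx)` with central differences
(one-sided at borders), gradients taken with respect to world coordinates.
Raw determinants (not logs) are analysed so maps read directly as
expansion/contraction; analysts preferring symmetry can transform the
returned volumes. Maps are blurred at 8 mm FWHM before masking; the face
mask keeps head voxels anterior to a coronal plane (default y = 0 mm in
the synthetic template's frame) because variation posterior to the top of
the forehead is not facial.

`fit_glm()` is ordinary least squares per voxel, validated against `lm()`
to 1e-10. The default design is intercept + sex + age + head size, with
sex coded -1/2 (male) and +1/2 (female) so positive coefficients mean
larger in females; age analyses within one sex drop the sex column.

`rft_correct()` controls family-wise error with the expected Euler
characteristic of a t field: resel counts come from discrete
voxel/edge/face/cube counting on the mask, EC densities are the standard
t-field forms in dimensions 0-3, and the peak threshold solves the EC
equation at `alpha` (capped at Bonferroni, which is sharper for very small
masks or low df). Clusters are formed at that threshold with
18-connectivity; reported p-values are EC-based peak probabilities.
Residual smoothness, when not supplied, is estimated from the variance of
normalised-residual gradients (`sqrt(4 log 2 / lambda)` per axis, geometric
mean across axes), falling back to the applied blur below 10 residual maps.
Calibration note: the Monte-Carlo validation generates its null fields on a
padded grid and crops one kernel width, because zero-padded blurring makes
boundary noise smoother than nominal and deflates the apparent error rate.

## Landmarks, anthropometrics, and the point-distribution model

The shipped template (`face_template_landmarks()`) has 56 named landmarks
- eyes (10), nose (9), lips (12), jaw/chin (10), ears (4), forehead/brow
(6), zygomatic/midface (5) - placed on the package's synthetic canonical
head; it is a synthetic reconstruction of conventional facial-landmark
coverage, not a claim about any specific cohort, and users with real data
should place their own template on their own atlas (`read_landmarks()`).
Semi-landmarks (e.g. the mid-jaw point) are stored as fixed model-space
points; their correspondence is carried entirely by the registration, so no
sliding scheme is needed.

Propagation evaluates the atlas-to-subject field at the landmark positions;
because the linear stage already removed position, orientation and size,
propagated landmarks live in a head-size-free space, the registration
analogue of Procrustes superposition. Out-of-lattice points get a per-point
flag rather than failing the set.

Anthropometric distances (eleven shipped measures) are modelled as
`distance ~ sex + age + sex:age` with age centred in months; within-sex age
slopes with 95% CIs are reported as the follow-up to interactions. The PDM
subtracts the *atlas reference* coordinates (not the sample mean) from each
subject's 168-vector before the eigendecomposition, so scores measure
deviation from the population-average face; the sample-mean offset then
appears in the scores, and `center_on = "sample_mean"` is available for
analysts who prefer centred scores. Covariance (not correlation) PCA is
used since all coordinates share millimetres. Eigenvector signs are fixed
by making the largest-magnitude loading positive.

PC simulation displaces the reference landmarks by `p * A * sqrt(lambda_k)
* v_k` for proportions `p` in 0.2-1.0; the amplitude `A` defaults to 3
score standard deviations - deliberately exaggerated so the coupled
features are visible in the warped face - and each displaced set comes with
the interpolating thin-plate spline (3D kernel `U(r) = r`, exact at control
points, affine-reproducing, minimum bending energy) to warp the atlas
volume or a mesh. Body-fat residualisation replaces each PC score by its
residual from a simple regression on total body fat before the score model
is fitted.

## The synthetic data generator

`generate_phantom()`/`generate_cohort()` emulate the pipeline's intended
input: brain-stripped heads at 1 mm isotropic resolution, 64^3 by default
so a full atlas run on 8 subjects takes minutes (the registration schedule
scales accordingly: steps 8/4/2 mm, 10/10/5 iterations, blurs 8/4/2 mm;
the full six-generation 1 mm-data schedule remains the default for real
inputs). The canonical head is an analytic function - ellipsoid with a
removed brain cavity, brightened skull shell, and nose, lip, chin, brow,
ear, orbit and zygomatic structures - so exactly warped phantoms can be
rendered with no interpolation.

Per-subject geometry composes three layers, all with exact ground truth:

* **feature displacements**: compactly supported kernels (flat plateau
  around the anchor landmarks, quartic decay) attached to seven named
  features (nose length/width, chin protrusion, jaw width, lip fullness,
  mouth width, forehead slope), so a planted delta moves its anchor
  landmarks by exactly the planted millimetres;
* **a smooth random warp**: Gaussian-blurred white-noise vector field
  (12 mm FWHM, RMS amplitude `deformation_sd`, default 1.5 mm), gradient-
  clamped to stay diffeomorphic;
* **head-size scaling**: log-normal with SD 0.03 (~3% linear), or explicit
  planted scales.

Cohort defaults are chosen once to represent an adolescent sample: ages
uniform over 144-216 months, sex Bernoulli(1/2), intensity noise SD 3
(~3% of soft tissue), and a sexual-dimorphism pattern with broader male
jaw (-4 mm), mouth (-3), chin (-2.5), nose (-2 width, -1.5 length) and
fuller female lips (+1.5), male-dominant age slopes of 0.02-0.05 mm/month,
and body fat 21 +/- 4% with +6 points in females plus 1 point per mm of
lip fullness (so body-fat residualisation has something real to absorb).
`generate_landmark_cohort()` produces landmark-level cohorts directly
(planted effects + warp + placement jitter) for statistical calibration at
hundreds of replicates.

What the phantoms do *not* emulate: MRI physics (no k-space, bias fields
only as an optional linear gradient), true tissue contrast and anatomy
(teeth, orthodontic artifacts, hair), inter-subject variation beyond the
parameterised features and smooth warps, and pathology. Passing tests on
phantoms therefore demonstrates the correctness and calibration of the
algorithms, not registration robustness on real heads.

## Numerical choices and degenerate inputs

* Trilinear interpolation everywhere; zero fill outside the source FOV;
  edge-clamped field evaluation.
* Gaussian kernels truncated at 4 sigma and renormalised (interior signals
  conserve intensity to <0.1%).
* Simplex tie-break: a node whose best move does not strictly improve the
  local similarity keeps zero displacement (minimal-deformation bias).
* Degenerate image regions (flat target window, threshold 2% of the masked
  intensity SD) are excluded from node optimisation and interpolated from
  neighbours.
* Rank-deficient designs name their collinear columns; constant residuals
  raise an explicit zero-gradient error; non-positive Jacobians block
  field inversion; empty face masks are a configuration error.
* Validation problem sizes: 64^3 phantoms, 8-subject atlases, 500-replicate
  RFT null simulations at 32^3, 200-replicate calibration of the landmark
  models at n = 60, and a 7-subject two-generation pipeline for the
  byte-level determinism check.

## Known limitations

* The nonlinear model estimates local *translations* on a node lattice
  (classic block matching), not local affines or a diffeomorphic flow;
  large-deformation template estimation is out of scope.
* RFT assumes stationary smoothness; the estimator returns a global FWHM.
  Strongly nonstationary residual fields would need a permutation
  alternative.
* Cluster-level inference reports EC-based peak p-values; cluster-extent
  p-values are not implemented.
* The atlas is built sequentially (seed, pairwise, refinements), not by
  simultaneous unbiased template estimation; seed influence is removed only
  up to the linear frame.
* Landmark accuracy in texture-free regions is limited in principle:
  intensity-driven registration cannot constrain displacement where there
  is no intensity gradient, which is visible as larger propagation errors
  for semi-landmarks far from image structure.
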