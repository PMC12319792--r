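---
title: "Longitudinal cortical surface reconstruction with cortexflow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal cortical surface reconstruction with cortexflow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cortexflow)
```

## The problem

In longitudinal neuroimaging a subject is scanned repeatedly over months or
years, and the scientific signal — for instance cortical thinning in
Alzheimer's disease, on the order of 0.1 mm per year — is far smaller than
the geometric variability a surface-reconstruction pipeline introduces when
it processes each scan independently. Two properties are needed at once:

* **accuracy** — each reconstructed white-matter (WM) and pial surface must
  follow the tissue boundaries in its own scan; and
* **spatiotemporal correspondence** — vertex `v` must denote the same
  anatomical location in every visit of every subject, so that per-vertex
  measures (thickness, curvature) can be compared across time and across
  subjects without a separate registration step.

cortexflow implements a two-stage template-deformation approach to this
problem, together with the metric suite needed to quantify both properties
and the downstream group statistics, all exercisable end to end on
synthetic cortex-like data that the package generates itself.

## Surface model and deformation network

Surfaces are closed triangle meshes $\mathcal{M} = \{V, F\}$ with fixed
connectivity: every reconstruction of every visit and subject inherits the
face array of one population template (an icosphere at desk scale), which
is what gives vertex-level correspondence by construction.

A scan is a 3D scalar volume $X$. A small convolutional encoder–decoder
(two resolution levels with a skip connection) turns $X$ into a feature
pyramid; an auxiliary per-voxel 3-class head (background / gray matter /
white matter) is attached for supervision. Reconstruction solves the
initial value problem

$$\frac{dV(t)}{dt} = f_\theta\big(t, X, V(t)\big), \qquad V(0) = T,$$

with $T$ the template vertices, integrated with an explicit Euler scheme of
5 steps of size 0.2 on $t \in [0,1]$; the reconstruction is $V(1)$. At each
step the velocity field $f_\theta$ is computed by graph-convolution blocks
over the *joint* WM+pial graph: node inputs are the trilinearly sampled
image features at the current vertex position, the normalized coordinates,
a surface indicator, the scalar time, the recurrent per-block features from
the previous step, and (in stage 2) static template features. Each block is
two rounds of neighborhood-mean message passing with linear transforms and
a leaky rectifier (slope 0.1, so rarely-active units keep a gradient); the velocity head is a linear map from the concatenated block
features, **zero-initialized** so that an untrained model is exactly the
identity deformation — a stabilizing choice that also gives the tests a
free anchor. Virtual edges connect WM vertex `v` to pial vertex `v` to let
the two surfaces coordinate and discourage crossings.

## Two stages and the within-subject template

*Stage 1* deforms the population template to each visit independently.
Because the outputs share vertex correspondence, a **within-subject
template** can be built directly in mesh space as the per-vertex mean over
the subject's visits,

$$T_i = \frac{1}{K_i + 1} \sum_{j=0}^{K_i} V_{i,j},$$

applied to *generalized vertices*: coordinates concatenated with the
$64 \times 2$ per-vertex features taken from the two graph blocks at the
final integration step, which carry geometric context beyond bare
positions. The mean is unbiased and permutation-invariant in the visit
order; all available visits always enter it (omitting later visits would
bias the template toward early anatomy). Median aggregation is implemented
as an alternative, but it is nonlinear — the flow-averaging property below
does not hold for it — and it tends to degrade consistency; it exists for
comparison, not for use.

*Stage 2* is a second deformation model of the same architecture that
starts from $T_i$ (instead of $T$) and deforms it to each visit again. Its
first-block input layer is wider (it ingests the template features), so its
weights are initialized from the trained stage-1 model *except* for that
input layer, which is freshly initialized. Temporal consistency improves
because all of a subject's visits now start from a shared, subject-specific
shape, while accuracy is maintained because the deformation to each
individual scan is unconstrained.

**Flow averaging.** The mean template can be read as the solution of the
initial value problem under the visit-averaged flow field, to first order
in the deformation magnitude. `verify_theorem1()` checks this numerically
by integrating analytic field families at decreasing scales: the gap
between mean-of-solutions and solution-of-mean vanishes identically for
fields equal across visits and for per-visit constant fields, and shrinks
(quadratically in practice) with the deformation scale for distinct
vertex-dependent fields. Note that this gap does *not* vanish with the
Euler step size at fixed deformation — the exact flows already disagree at
second order (`mean_j e^{A_j} \neq e^{\bar A}`), which is why the check is
parametrized by field scale rather than step size.

## Training

Both stages are trained jointly for WM and pial surfaces with a weighted
sum of four terms, computed on $V(1)$:

* **curvature-weighted Chamfer**: symmetric mean squared nearest-neighbor
  distance between points sampled uniformly by area from the predicted
  mesh and reference points; the reference→prediction direction is weighted
  by $1 + |\kappa|/\overline{|\kappa|}$ interpolated from the reference
  vertex curvature (normalized to mean 1, so a constant-curvature reference
  reduces to the plain Chamfer). Weights and the 100,000-point default
  follow the training recipe; desk-scale runs use fewer points.
* **edge loss**: mean squared edge length (uniform, short edges).
* **normal consistency**: mean over adjacent face pairs of
  $1 - \cos\angle(n_a, n_b)$ (smoothness).
* **voxel cross-entropy** on the auxiliary segmentation head.

Default weights are 1 / 0.1 / 0.1 / 1; they are exposed in
`loss_weights()` and were chosen on the synthetic benchmark — the original
training recipe's exact weighting lives in work this package does not
reproduce, so these defaults are non-canonical. The Chamfer target is the
final integration step only; intermediate supervision was considered and
left out to keep one clear contract per step.

Optimization is Adam (default learning rate `2e-3`, optional per-epoch
decay) with hand-derived gradients and global-norm gradient clipping at 5,
which guards the small-batch regime against occasional loss spikes. Two deliberate approximations keep the cost of an iteration
linear and are worth stating plainly:

1. **Truncated backpropagation through the flow**: each Euler step's
   velocity receives the upstream gradient $h \, \partial L / \partial
   V(1)$; the dependence of later steps on earlier coordinates and the
   feature recurrence are detached. Forward integration is exact; only the
   training signal is first-order. The parameter gradients under this
   scheme are verified against finite differences in the single-step
   setting where the truncation is exact.
2. **Sampling-measure gradients**: the Chamfer gradient flows through the
   barycentric coordinates of sampled points but not through the
   area-proportional face-selection probabilities (the standard choice in
   mesh-loss implementations).

Everything is seeded: weight initialization, point sampling, scan order,
and the synthetic data itself, so training runs are bit-reproducible on one
machine.

## Metrics

* **ASSD** — mean of point-to-surface distances over points sampled from
  both meshes, both directions. Both meshes draw from the same seed, which
  makes the metric exactly symmetric under argument exchange.
  Point-to-mesh distances are exact closest-feature computations (face
  interior, edge, or vertex) accelerated by a bounding-volume hierarchy
  that agrees with brute force to the last bit.
* **HDX** — the robust Hausdorff distance: the max over directions of the
  X-th percentile of point-to-surface distances, with the type-7
  (linear-interpolation) empirical quantile, fixed so reported values are
  reproducible bit for bit. `X = 100` is the classical Hausdorff distance.
* **SIF** — fraction of faces properly intersecting a non-adjacent face of
  the same mesh (faces sharing a vertex are excluded, which removes the
  false positives at shared edges); exact triangle–triangle tests with a
  sweep-and-prune on bounding boxes.
* **MCVar / CThVar** — per-vertex unbiased sample variance across a
  subject's visits of $|\kappa|$ (discrete mean curvature) and of bilateral
  cortical thickness, summarized per subject by the median over vertices.
  The absolute value makes MCVar invariant to the curvature sign
  convention. Thickness is the per-vertex average of the WM→pial and
  pial→WM closest-surface distances.
* **ParcF1** — parcellation labels live on the template and propagate to
  every visit by vertex identity; for each ordered visit pair, vertices are
  matched to the spatially nearest vertex of the other visit and the
  support-weighted F1 of the label pairs is averaged over all ordered
  pairs. "All ordered pairs" (rather than adjacent-only) was chosen so the
  score is invariant to visit order.

Mean curvature uses the cotangent Laplace–Beltrami operator with mixed
Voronoi areas, $\kappa = \tfrac12 \lVert \Delta x \rVert$, signed positive
where the surface bends away from the outward normal (a sphere of radius
$r$ scores $+1/r$; the sign convention is documented rather than load-
bearing, since MCVar uses $|\kappa|$). On open meshes, boundary vertices
are zeroed and flagged. The estimator converges under refinement — the
test suite checks the error on spheres strictly shrinks from subdivision
level 3 to 5.

## Group statistics

Vertex-wise longitudinal thickness is analyzed with the linear mixed-effects
model

$$\mathrm{CTh}_{i,j} = \beta_0 + \beta_1 B_i + \beta_2 W_{i,j} + \beta_3 D_i
  + b_{0,i} + b_{1,i} W_{i,j} + \varepsilon,$$

with baseline age $B_i$, time since baseline $W_{i,j}$, stable diagnosis
$D_i$, and correlated per-subject random intercept and slope (unstructured
2×2 covariance; vertices that fail to converge are refitted with
independent random effects and flagged, never dropped). Fits use `lme4`;
the reported two-tailed p-values are Wald-normal on the $t$ statistic of
$\hat\beta_3$, uncorrected by default (a Benjamini–Hochberg column is
optional), matching the common mass-univariate practice of reporting
uncorrected vertex-wise maps.

Normative scoring estimates per-vertex mean and SD in 10-year baseline-age
brackets from the *initial* scans of control subjects only (avoiding bias
toward frequently scanned individuals), scores every scan independently as
the mean per-vertex Z over unmasked vertices (the designated "unknown"
region — one parcellation label in the synthetic analogue — is excluded),
and summarizes group separation by the Mann–Whitney AUC with midranks. A
scan whose age bracket has no reference falls back to the nearest populated
bracket.

## The synthetic cohort generator

Real use consumes affinely registered T1-weighted volumes with reference
surfaces from an established pipeline. The generator replaces these with a
cohort whose every property is known:

* the outer (pial-like) surface of a subject is a sphere whose radius is
  modulated by random low-order (degree ≤ 3) spherical harmonics — smooth,
  subject-specific "bumps" (SD 0.8 mm, decaying with degree);
* the inner (WM-like) surface erodes the outer one inward **along vertex
  normals** by a smooth positive thickness field (mean 2.5 mm, spatial SD
  0.25 mm). Normal erosion makes the pair locally parallel offsets, so the
  bilateral thickness metric recovers the generating field up to faceting
  — a property the tests rely on to verify atrophy recovery;
* each visit adds a small smooth radial drift (SD 0.1 mm,
  diagnosis-independent, emulating positioning and scan variability) and
  diagnosis-dependent thinning of `atrophy_rate * time` (defaults 0.01
  mm/yr for controls, 0.10 mm/yr for the disease group — the inner surface
  moves outward while the outer shape's drift is shared between groups,
  mimicking the atrophy phenotype);
* visit counts are truncated-normal (mean 4.4, SD 1.9, minimum 2 by
  default, matching a typical longitudinal aging cohort), spacings uniform
  in 0.5–1.5 years, baseline ages uniform in 60–85 years;
* volumes are occupancy rasterizations (CSF 0, gray 0.5, white 1) with
  Gaussian noise of SD 0.1, on a 48³ grid of 1 mm voxels by default, with
  the surfaces filling roughly the central 60%;
* a parcellation is grown on the template by farthest-point seeding with
  geodesic (edge-weighted Dijkstra) nearest-seed assignment.

Rasterization classifies voxel centers by scanline parity counting with
jittered rays; it is verified exactly against an independent
integer-lattice count on spheres. Per-subject randomness derives
deterministically from one master seed, so a cohort is a pure function of
its configuration.

**What passing on this generator does and does not show.** The volumes are
piecewise-constant occupancy images, not MR physics: there is no bias
field, no partial-volume ramp, no contrast variation between scanners, and
the shapes are star-convex spheres rather than folded cortical sheets with
buried sulci. Success here demonstrates that the architecture, losses,
aggregation and metrics interact correctly and that the two-stage design
improves longitudinal consistency at desk scale — it does not certify
segmentation robustness on clinical MRI, behavior in deep sulci where
surfaces nearly touch, or hyperparameters at full cortical resolution
(~160k vertices), all of which are out of scope.

## Problem sizes and numerical choices

The package's own test and acceptance runs use deliberately small
instances: 10-subject cohorts (7 training, 1 validation, 2 held-out) with
2–4 visits on 24³ grids, icosphere level-3 meshes (642 vertices, 1280
faces), encoder channels (4, 8), 1200 Chamfer points, 6 stage-1 and 4
stage-2 epochs at learning rate `5e-3` with 0.8 per-epoch decay; the
end-to-end checks are repeated over three seeds and evaluated on the
held-out subjects. These sizes were chosen as the smallest at which the
generalization and consistency effects are stable — with fewer training
subjects, generalization to held-out anatomy degrades noticeably on some
seeds. The defaults in `deform_config()` / `synthetic_cohort_config()`
(48³ grids, channels (8, 16)) describe the intended desk-scale study
conditions.

Other numerical choices, fixed once and documented here: voxel centers sit
at integer indices in voxel space with a 4×4 affine to world mm (one
convention for training and inference); out-of-grid vertex queries clamp to
the boundary rather than erroring, since vertices may transiently exit the
grid mid-integration; integration aborts with diagnostics if any vertex
exceeds 10× the grid diameter; degenerate (zero-area) faces contribute
nothing to vertex normals and raise a warning; checkpoint files store a
fingerprint of the template connectivity and refuse to load against a
different template; curvature ties at exactly zero sign are broken toward
positive.

## Known limitations

* Training-time backpropagation is truncated across integration steps (see
  above); this is a gradient-quality, not correctness, limitation.
* The LME p-values are Wald-normal, slightly anti-conservative in very
  small cohorts; the type-I calibration test bounds the effect at the
  sizes used here.
* Median template aggregation can produce self-intersecting geometry; it
  is reported via SIF, not repaired.
* The FreeSurfer surface reader covers the binary triangle dialect
  (including the volume-geometry footer written with an identity
  transform) but not quad or ASCII variants; `.annot` atlas files are out
  of scope — parcellations enter as vertex label fields (curv/CSV).
* One hemisphere-analogue (one WM+pial pair) per model; a both-pairs mode
  would double the joint graph and is left to configuration of a future
  version.
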