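---
title: "Longitudinal fetal brain surface morphometry: models and methods"
author: "fetalmorpho"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal fetal brain surface morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalmorpho)
```

# The problem

Fetal surgery for open spina bifida (OSB) is followed by marked changes in
brain morphology: ventricles typically keep enlarging after closure, and the
cortical surface folds along an altered trajectory. Quantifying those
changes from longitudinal fetal MRI requires a chain of steps — from
segmentation label volumes to smooth surfaces, global morphometry, local
curvature markers of gyrification, longitudinal vertex correspondence, and
nonparametric group statistics on weekly rates of change. `fetalmorpho`
implements that chain as a tested, reusable pipeline, and pairs it with a
synthetic cohort generator whose growth and folding trajectories are known
by construction, so every stage can be validated without patient data.

# Measures

For each structure (unmyelinated white matter, ventricles, cerebellum) at
each timepoint:

* **Volume** $V$ (mm^3^) is the number of voxels carrying the label times
  the voxel volume (spacing^3^). This voxel-counting definition is used for
  all reported volumes; the mesh-enclosed volume is computed as a QC
  cross-check and a warning is raised when the two disagree by more than
  5%, which surfaces poorly resolved structures.
* **Surface area** $A$ (mm^2^) is the sum of triangle areas of the
  extracted, smoothed surface mesh.
* **Shape parameter** $s = V/A$ (mm). For a sphere of radius $r$,
  $s = r/3$; at fixed volume $s$ decreases as the surface folds, which
  makes it a compact global gyrification index. Note the deliberate
  asymmetry — a voxel-based numerator over a mesh-based denominator — which
  mirrors how the quantities are defined; the QC cross-check above bounds
  the inconsistency this could introduce.

Per-vertex **principal curvatures** $\kappa_1 \ge \kappa_2$ (mm^-1^) yield
the two gyrification markers:

* **curvedness** $C = \sqrt{(\kappa_1^2 + \kappa_2^2)/2}$, the magnitude of
  local bending (0 on a plane, $1/r$ on a sphere);
* **shape index**
  $SI = (2/\pi)\arctan\big((\kappa_1+\kappa_2)/(\kappa_1-\kappa_2)\big) \in [-1, 1]$,
  the local shape class: $+1$ convex dome (gyral node), $+1/2$ convex
  ridge, $0$ saddle, $-1$ concave cup (sulcal pit). Sign convention: the
  outward normal is fixed by a signed-volume test and convex regions have
  positive curvature, so gyri carry positive SI. At umbilic points
  ($\kappa_1 = \kappa_2$) SI is assigned $\mathrm{sign}(\kappa_1)$ (0 on a
  plane) rather than NaN, so summaries remain computable on near-spherical
  surfaces.

# Surface extraction

Meshes are extracted from label volumes in four steps:

1. binary mask of the label, reduced to its largest 6-connected component
   (stray islands are segmentation noise). The ventricle label is the
   exception: the lateral bodies are legitimately separate, so every
   component with at least 50 voxels is kept and geometry is reported on
   the union;
2. Gaussian softening of the binary mask (`fieldSigma`, default 0.8 voxel)
   for sub-voxel boundary placement;
3. marching-tetrahedra isosurfacing at level 0.5 on the Kuhn 6-tetrahedron
   cube subdivision, which is translation-invariant and therefore
   watertight by construction. Voxel index $(i,j,k)$ maps to world mm as
   $\mathrm{origin} + (i,j,k)\cdot\mathrm{spacing}$ (voxel-centre
   convention);
4. Taubin $\lambda|\mu$ smoothing (default 10 iterations,
   $\lambda = 0.5$, $\mu = -0.53$), a pass-band smoother that attenuates
   the voxel staircase without the shrinkage of plain Laplacian smoothing.

A mask touching the volume border signals a clipped structure and is a hard
error, not a silent crop.

The mask-softening step is a design choice worth spelling out. On a
digitized ball of radius 10 mm at 0.8 mm spacing, isosurfacing the raw
binary mask leaves a staircase whose area overshoots the analytic sphere by
27%, and 10 Taubin iterations still leave +8%; the error only falls below
2% after ~50 iterations, by which point fine anatomy would be over-smoothed.
With $\sigma = 0.8$ voxel pre-smoothing the same surface lands within 0.1%
of the analytic area and within 1% of the analytic volume after the default
10 iterations, and the enclosed-volume error decreases monotonically across
spacings 1.2/0.8/0.5 mm. The isosurface level stays at 0.5; only the field
it is applied to is softened. `fieldSigma = 0` restores the raw-mask
behaviour.

Voxelization (the inverse, used by the synthetic generator) labels a voxel
iff its centre lies inside the closed surface, by even-odd ray parity with
triangles binned per ray column; grids are padded by at least two
background voxels.

# Curvature estimation

The curvature estimator fits, at every vertex, the quadric height patch
$h(u,v) = au^2 + buv + cv^2 + du + ev$ over the 2-ring neighbourhood,
expressed in the tangent frame of the area-weighted vertex normal, and
takes the eigenvalues of the Weingarten map $I^{-1}II$ of the fitted patch.
The linear terms $(d, e)$ matter: they absorb the first-order error of the
estimated normal, which otherwise biases curvatures on irregular
triangulations. Accuracy on analytic test surfaces: sphere curvatures
within 0.6% (icosphere subdivision 4), torus principal curvatures within 3%
of the closed form at every vertex at comparable sampling density, and the
error decreases monotonically under subdivision refinement. An
angle-deficit cross-check (integrated mean curvature positivity on convex
surfaces, rigid-motion invariance to 1e-6, scaling covariance
$\kappa \to \kappa/\lambda$) guards the implementation in the test suite.

# Longitudinal correspondence

Vertex correspondence between two timepoints of one subject is computed by
joint spectral matching on the graph-Laplacian eigenmodes:

1. per-mesh spectra: the first $k = 5$ non-trivial eigenmodes of the
   cotangent-weighted Laplacian with lumped (barycentric) vertex areas,
   each normalized to unit magnitude ($k = 5$ and the unit-magnitude
   normalization follow the convention the markers are reported with; an
   unweighted graph Laplacian is available behind a flag for degenerate
   triangulations);
2. coarse geometric pairing: both vertex clouds are centred and scaled to
   unit RMS radius, then aligned by ICP restarted from the identity and
   from principal-axes candidates restricted to proper rotations
   (det = +1). The restriction matters: a near-ellipsoidal brain is almost
   mirror-symmetric, and an unconstrained axis alignment can latch onto the
   reflection, silently mapping left onto right;
3. spectral alignment: modes of B are greedily paired to modes of A by
   absolute correlation under the coarse pairing (sign flips resolved), and
   near-degenerate eigenvalue groups (relative gap < 5%) are additionally
   rotated by orthogonal Procrustes, since eigenvectors of close
   eigenvalues are only defined up to rotation;
4. dual-layered graph: the two meshes are two layers; inter-layer links
   connect nearest neighbours in the aligned, eigenvalue-scaled spectral
   coordinates (both directions), each with weight 0.1 times the mean
   intra-layer cotangent weight (exposed as `coupling`). Because intra-layer
   eigenvalues scale like $1/R^2$ for a brain-sized surface while the link
   penalty scales like a per-vertex weight over a vertex area, the lowest
   joint modes are layer-symmetric — which is exactly what makes them
   shared coordinates;
5. final map: each A-vertex takes its nearest B-vertex in the joint
   eigenvalue-scaled coordinates (each mode divided by $\sqrt{\lambda}$,
   standard spectral-matching practice); ties break to the lowest vertex
   index, and the per-vertex residual distance is reported as match
   quality.

On the synthetic surfaces this recovers the identity at 100% of vertices
for self-matching, ≥ 95% exact pairs for a rigidly moved copy, and a mean
error near one tenth of an edge length for a 6-week growth pair with
doubled folding amplitude (the generator's shared parameter grid provides
exact ground truth). Per-vertex weekly rates are then
$(f_B(\mathrm{corr}(v)) - f_A(v))/\Delta\mathrm{GA}$.

# Periods, parcellation and statistics

**Periods.** Each subject has three timepoints (before surgery, ~1 week
and ~6 weeks after). Weekly rates are computed over the immediate
(T1→T2), long-term (T2→T3) and global windows. The global rate is defined
here as $(x(T_3) - x(T_1))/(\mathrm{GA}_3 - \mathrm{GA}_1)$. The wording
"difference between the long-term and immediate periods" admits a second
reading — the literal rate difference — but reported global medians lie
between the two period rates, which is consistent with an overall T1→T3
rate and inconsistent with a difference; the literal reading is implemented
behind `global = "difference"`. Gestational ages are decimal weeks
(23 + 3 days = 23.4286): exact week-day conversion.

**Parcellation.** The cortical surface is split into frontal, parietal,
temporal and occipital lobes in both hemispheres by label transfer from a
labeled atlas surface: similarity-transform alignment (full Procrustes on
index-paired points when the meshes share a parameter grid, the ICP
alignment above otherwise) followed by nearest-neighbour label transfer.
The package's atlas is the generator's canonical surface with exact
sector-based labels; the mid-sagittal plane is fixed in parameter space so
ground-truth parcellation is available for every synthetic subject. This
replaces non-rigid registration to a real spatiotemporal fetal atlas, which
is out of scope; the interface (`parcellateLobes(mesh, atlas)`) accepts any
labeled reference surface.

**Summaries.** Subject-level curvature summaries are medians of the signed
per-vertex values, per region and whole-surface (an absolute-value variant
sits behind a flag). Whether per-vertex values should be winsorized or
smoothed before summarizing is an open sensitivity axis; raw values are
summarized.

**Statistics.** The Anderson-Darling test (case-adjusted $A^2$, sample
mean/variance) gates normality at $\alpha = 0.05$; weekly rates are
compared with the Kruskal-Wallis H test (tie-corrected, chi-square
approximation), followed by Dunn's pairwise z tests on the pooled ranking
with Holm adjustment (Bonferroni and BH are configurable). Significance is
declared at adjusted p < 0.05. Only the nonparametric branch is
implemented: rate distributions are right-skewed and every comparison of
interest runs through it. Degenerate cells (single-subject groups, empty
levels, all-identical values where H is undefined and (H, p) = (0, 1) is
returned) are handled with warnings rather than errors.

# The synthetic cohort

The generator emulates the study conditions: 29 OSB and 12 control
subjects, three timepoints each, with gestational-age schedules drawn from
the group means/SDs (OSB 23+3 / 25+6 / 31+6 weeks; controls
23+1 / 28+6 / 32+6) and 0.8 mm isotropic label volumes.

* **White matter** is a radial surface
  $r(\theta,\varphi) = R_{\mathrm{ell}}(\hat n)\,(1 + a(\mathrm{GA})\,f(\hat n))$
  on a fixed latitude/longitude grid: an ellipsoid base (semi-axes
  $1.25/1.05/0.9 \times R_w$, $R_w$ linear in GA, ~26 mm at 21 weeks
  growing 0.7 mm/week, per-subject jitter SD 0.8 mm) modulated by a fixed
  band-limited sum of ten directional sinusoids (angular frequencies 8-16,
  weights proportional to one over the square root of the frequency) with
  per-subject random phases. The shared grid makes vertices at
  different GAs correspond by index — exact longitudinal ground truth.
  Amplitude grows linearly in GA with period- and group-specific slopes
  (controls 0.012/week throughout; OSB 0.024/week in the immediate
  period, 0.008/week long-term), reproducing the reported direction of
  the folding-rate effects: OSB curvedness change exceeds controls
  immediately after surgery and falls below them long-term. The frequency
  band and slopes were chosen once so that median curvedness rises with
  gestational age despite overall head growth, as it does in vivo; the
  resulting curvedness rates are smaller in magnitude than clinical values
  because the gentle radial fold field cannot reach real sulcal
  curvatures (see Known limitations). Amplitudes
  $\ge 1$ would self-intersect and are rejected.
* **Ventricles** are two mirrored ellipsoids (axes $2.0b, b, 1.3b$); the
  atrial-diameter surrogate is the minor-axis diameter $2b$ at baseline,
  drawn per severity class with the reported class mix (4 mild : 8
  moderate : 17 severe). Total ventricular volume follows a per-subject
  global weekly rate, log-normal around the group median (2500.94 mm^3^/wk
  OSB, 708.21 control) with log-SD matched to the reported IQRs
  (0.557/0.495); the immediate-period rate is the global rate times 1.730
  (OSB) or 0.962 (control), the ratio of the corresponding reported
  medians. Subjects with severe ventriculomegaly, pACC or persistent
  hindbrain herniation carry rate multipliers (1.35/1.4/1.3); the
  multiplier distribution is renormalized by the numerically computed
  median of the resulting mixture so the programmed group median is exact
  by construction. Severe ventriculomegaly also widens the white-matter
  envelope when needed (macrocephaly), with a jitter-and-retry placement
  guard (5 attempts, then error).
* **Cerebellum** is a posterior-inferior ellipsoid growing linearly in GA.

Structures are voxelized onto one grid with the ventricles carved out of
the white-matter interior. Everything is a deterministic function of
(config, seed, subject index). Ground truth per subject includes analytic
structure volumes (ellipsoid closed forms; spherical quadrature for the
folded surface), programmed rates, folding amplitudes and phases, and the
grid correspondence.

What the generator does **not** emulate: MRI intensities, motion artifacts,
segmentation errors, anatomically realistic folding patterns (the fold
field is a stationary random sinusoid sum, not sulcus anatomy), or the
cross-sectional nature of the real control arm (synthetic controls are
longitudinal). Passing tests therefore demonstrate that the pipeline
recovers known geometry and programmed effects at matched sample sizes and
resolution — not that it reproduces any patient-data value.

# Numerical choices and problem sizes

* Eigen solves: dense LAPACK up to 1200 vertices, shift-inverted ARPACK on
  a sparse Cholesky above; eigenvector signs fixed deterministically
  (largest-magnitude entry positive).
* Nearest-neighbour searches are exact (chunked brute force); ICP runs on
  an evenly spaced subsample above 2000 vertices, the final pairing on all
  vertices.
* Default test geometry: icosphere subdivision 4 (2562 vertices), torus
  160x64, gyrified surfaces 24x48 (1106 vertices), full cohort surfaces
  32x64 (1922 vertices). The replicate studies (50 effect + 50 null
  cohorts of 41 subjects) run the ventricles-only generator with
  voxel-count volumes, which is exact for volume rates and keeps a full
  study in a few minutes on one CPU.
* The multiplier renormalization constant solves the mixture-CDF median
  equation by `uniroot` on [-10, 10] in log space.
* Provenance: every pipeline run records an MD5 hash of its configuration;
  re-running with an identical configuration is a no-op unless forced.
  Subjects failing a geometry invariant are excluded with a logged reason
  rather than aborting the cohort.

# Known limitations

* The radial surface model cannot represent overhanging (re-entrant)
  folds; real sulci at late GA can. Curvature markers remain well defined,
  but the folding geometry is simplified.
* The shape-index summary uses signed medians; mean-based or
  absolute-change summaries can behave differently on bimodal SI
  distributions and are available behind flags.
* Spectral matching assumes connected, closed surfaces; the multi-body
  ventricle surface is deliberately not a matching target.
* The statistics module implements no parametric branch and no adjustment
  for gestational-age mismatch between groups beyond the use of weekly
  rates.

# A worked mini-run

```{r mini, eval = FALSE}
cfg <- runConfig(seed = 17, nOSB = 6L, nControl = 4L,
                 structures = "ventricles", doCurvature = FALSE)
res <- runPipeline(cfg, verbose = FALSE)
subset(res$stats, parameter == "volume_mm3" & period == "global")
```

The vignette keeps this chunk unevaluated to stay light; the README shows
the identical example with the numbers it printed.
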