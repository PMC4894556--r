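---
title: "Landmark-free shape modelling of vascular surfaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-free shape modelling of vascular surfaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vesselssm)
```

This vignette documents the statistical and numerical design of
`vesselssm`: the shape representation and deformation model, the
parameters that matter and their defaults, what the synthetic cohort
generator does and does not emulate, and the choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Shape representation: currents

A triangulated surface is represented by its current: every face
contributes a Dirac functional at its barycenter carrying the
area-weighted face normal (units mm²). Two currents are compared in the
norm of a reproducing-kernel Hilbert space with the Gaussian kernel

$$ k_W(x, y) = \exp(-\lVert x-y\rVert^2/\lambda_W^2), $$

so the inner product of surfaces $S, S'$ is
$\sum_{f,g} k_W(c_f, c'_g)\, n_f \cdot n'_g$ (units mm⁴). The
representation needs no landmarks and no point correspondence; flipping
a face's orientation negates its contribution, and a closed surface has
vanishing total current — both properties are unit tests.

**Kernel convention.** We fix $\exp(-d^2/\lambda_W^2)$ — no factor 2 in
the denominator. The probed-fraction initialisation below quotes λ
values in millimetres; they are only meaningful relative to a stated
kernel convention, so the convention is part of the API contract.

**Resolution λ_W** is the spatial scale below which two shapes count as
equal. Small segmentation artefacts should stay below λ_W; anatomy of
interest (e.g. an isthmus narrowing) must be larger. Evaluation is the
direct O(F²) double sum — the reference path; the closest-point and
kernel code are vectorised, and every accelerated path is tested against
an explicit double loop at 1e-10 relative tolerance.

## 2. Deformation model and template estimation

Deformations are control-point kernel flows. Control points $q_k$ are
the template vertices subsampled at a spacing of $\lambda_V/2$ (a
Poisson-disk-style greedy pass); each carries a momentum vector
$\alpha_k$, and points move with the velocity field

$$ v(x) = \sum_k \exp(-\lVert x - q_k\rVert^2/\lambda_V^2)\, \alpha_k $$

integrated by forward Euler over `n_time_steps` (default 10) unit-time
steps, the control points flowing with the deformation. **Stiffness
λ_V** sets how local a deformation may be: large λ_V deforms the vessel
like a stiff cloth, small λ_V permits local bulges.

*Momenta are stationary in time.* The `deformation_field` container
stores the full (T, K, 3) momentum array, and `apply_deformation()`
accepts time-varying momenta, but the optimiser ties the momenta across
time steps. This keeps the parameter count at 3K, makes the initial
momenta a complete description of each subject's deformation — exactly
what the moment matrix flattens — and lets a PLS mode be visualised by
shooting a single momentum field. The cost is some expressiveness for
very large deformations; at the deformation magnitudes of a
rigidly-aligned anatomical cohort the matching residuals stay well below
the currents resolution.

Matching minimises
$J = \lVert[\varphi(S)] - [T]\rVert_W^2 + \gamma R(\alpha)$ with
$R = \sum_t \Delta t \sum_{k,l} k_V(q_k, q_l)\, \alpha_k\cdot\alpha_l$,
by gradient descent with backtracking line search. Gradients are exact
analytic reverse-mode derivatives through the Euler integration and the
currents data term; the test suite checks ten random coordinates against
central finite differences at 1e-4 relative tolerance. The default
regularity weight is γ = 0.01, which on arch-scale meshes keeps the data
term dominant (error reductions ≥ 80 % remain reachable) while
penalising momenta oscillation; reducing γ weakly decreases the data
term at the optimum, which is a property test.

**Template estimation** alternates (a) matching the current template to
every subject and (b) descending the summed cost over the template
vertex coordinates, accepting only cost decreases, so the recorded cost
trace is non-increasing. The template is initialised from the initial
reference subject; honouring the view of the template as the *average of
all currents*, an optional iteration 0 (`mean_current_init`, default on)
first regresses that surface toward the pooled cohort mean current.
Defaults: 3 outer rounds, 40 matching iterations per subject, 10
template-descent iterations; convergence when the relative cost change
falls below 1e-4. For the study-sized experiments below we use 2 outer
rounds and 25 matching iterations, which reaches matching residuals
small enough for the statistics while staying desktop-cheap. One
caveat found while calibrating that budget: severely under-converged
matching (a single pass of ~15 iterations) systematically understates
the deformation of the most extreme subject, which weakens outlier
leverage in the downstream regression — influence screening needs
converged momenta.

## 3. Kernel parameter setting

Both widths are initialised by the probed-fraction rule on the smallest
cohort surface area:
$\lambda = \sqrt{p \cdot A_{surf,min}}$, rounded to integer mm, with
defaults $p_W = 2.5\,\%$ and $p_V = 25\,\%$ — the kernel width is the
side of a square patch covering that fraction of the smallest surface.
`refine_lambdas()` then deforms the initial template toward the hardest
(smallest) subject over a grid that decreases λ_V in 1-mm steps to a
floor, then λ_W by 1 mm, returning the first pair that reduces the
baseline *maximum symmetric surface distance* by ≥ 80 % — high λ_W is
deliberately preferred (smoother templates, cheaper computation). A
perfect match is not wanted: residual detail below λ_W is treated as
segmentation noise. The matching error is symmetric (max over both
directions of vertex-to-triangle distance); a one-sided variant would
miss protrusions of whichever mesh is sampled second.

## 4. Statistics on deformations

The **moment matrix** has one row per subject: the initial momenta
flattened and whitened through the Cholesky square root of the
control-point kernel matrix, so Euclidean row inner products equal the
kernel (K_V) metric on momenta — explained-variability fractions are
therefore fractions of *metric* deformation variance, not raw-coordinate
variance.

**PLS (NIPALS PLS1)** extracts, per response, the deformation direction
of maximal covariance with the response; the per-subject score is the
**shape vector**. Size is removed before functional analyses by
deflating the BSA fit's rank-one reconstruction,
$X_{resid} = X_{orig} - XS_{BSA} XL'_{BSA}$; after deflation the BSA
scores are orthogonal to every residual column (unit test), so the
subsequent EF mode is size-free in the metric sense.

**Cook screening.** For each subject the PLS is refit on the other
n − 1 subjects and all fitted values are re-predicted;
$D_i = \sum_j(\hat y_j - \hat y_{j(i)})^2 / (p\, \mathrm{MSE})$ with
MSE the mean squared residual of the full fit and $p$ = components + 1.
The printed definition of MSE leaves its reference value ambiguous; the
mean-squared-residual reading is the standard one, and the 4 × mean flag
rule is invariant to that constant anyway. Subjects above 4 × mean(D)
are flagged. The flag set is invariant to scaling or shifting the
response (unit tests), and with one predictor the whole construction
reduces to ordinary least squares, which the tests exploit as an
independent leave-one-out oracle.

**Correlation gate.** Pearson's r when Shapiro–Wilk accepts normality of
both variables at 0.05, Kendall's τ otherwise; two-tailed p-values,
unadjusted — the analyses are exploratory and multiplicity correction
would trade Type II for Type I error asymmetrically.

**Mode visualisation.** `mode_deform_sequence()` un-whitens the PLS
weight vector back to momentum space and shoots the template along
$t \cdot \sigma_{scores} \cdot \alpha_{mode}$. We centre the
visualisation on the template itself (t = 0 returns the template
exactly) rather than adding the cohort-mean momenta: after convergence
the mean momenta are near zero by construction, and an exact identity at
t = 0 is the more useful contract.

## 5. Alignment

Rigid only — translation and rotation, never scaling: size is a
variable of interest (BSA analyses) and is removed statistically, not
geometrically. The initial reference is the subject closest to the
population centre after z-scoring gross descriptors; ICP with
vertex-to-nearest-triangle correspondence and an SVD (Kabsch) solve
aligns everyone to it, rejecting any iteration that would increase the
RMS. The Procrustes-style loop then re-aligns to successive templates
until **model compactness** stops decreasing. Compactness is defined
here as the *total* deformation variance (sum of covariance eigenvalues
of the moment rows, equivalently the mean squared deviation from the
mean row): the cited notion is a cumulative-variance-versus-modes curve,
but the loop only needs a scalar stop criterion, and total variance is
mode-count-free and monotone with it. The loop is capped at 5 iterations;
in practice one iteration suffices for rigidly perturbed cohorts.

## 6. Morphometry

The centreline is extracted by marching cross-sections: starting from
the inlet boundary-loop centroid with the loop's plane normal as initial
tangent, the mesh is sliced normal to the running tangent, the nearest
intersection loop's centroid becomes the next point, and the march
advances by `step_factor` (default 0.5) times the local equivalent
radius $\sqrt{A_{section}/\pi}$. Tangent updates are damped (0.6 new /
0.4 old) — undamped updates oscillate on coarse meshes — and the
polyline gets two binomial smoothing passes. This is deliberately *not*
a Voronoi/medial-axis centreline; it is a simple, testable contract that
is exact on tubes of circular cross-section, which is also why the
synthetic generator only sweeps circles.

Descriptors: length L_CL; tortuosity To_CL = L/chord − 1 (zero iff
straight); median curvature C_med from circumradius-reciprocals of point
triples on a ~6 mm stencil; diameters as equivalent-area circles of
sections normal to the tangent, with 5 % of arc trimmed at each end
before D_max/D_min/D_med (open-boundary sections are unreliable), and
level diameters (ascending / transverse / isthmus / descending) linearly
interpolated at configurable arc-length fractions, default
0.15 / 0.40 / 0.55 / 0.80 — the anatomical levels are image-defined in
clinical practice and not recoverable from a bare mesh, so fixed
fractions are the documented operational stand-in. Volume of an open
tube is measured after fan-capping the boundary loops; A_surf always
refers to the uncapped wall.

**Arch height A and width T.** The centreline is projected on its PCA
plane; "up" is defined by the two limb end tangents (not the endpoint
chord, which tilts when the limbs have unequal lengths). Walking from
the apex down each side, the shoulder-to-limb transition is located
where the in-plane curvature drops below 15 % of the apex curvature —
limbs are straight, arches are curved — refined to the midpoint of the
curvature drop-off ramp, on a curve resampled at uniform arc spacing so
the analysis is independent of the marching step. A is the apex
elevation above the mean transition height, T the horizontal transition
separation. For a semi-elliptic arch with straight limbs this recovers
the ellipse semi-axes; for strongly non-elliptic or very noisy arches
the transition is an operational definition, not an anatomical claim.

## 7. The synthetic cohort

`generate_arch()` sweeps circular sections along an
ascending-limb / semi-elliptic-arch / descending-limb centreline
(defaults: radius 8.5 mm, arch height 45 mm, width 60 mm, limbs
40/80 mm — total length ≈ 240 mm, in the range of adolescent
post-repair arches) with Gaussian radius bumps (dilated root ×1.15,
narrowed transverse ×0.85 and isthmus ×0.78 — the repaired-coarctation
pattern), a small lateral sinusoid (1.5 mm) and isotropic vertex jitter
(0.1 mm, about the reported operator segmentation error scale).
`generate_population()` draws BSA ~ N(1.6, 0.2) m² and EF ~ N(60, 8) %,
maps BSA to global scale (slope 0.45 per m²) and EF to
ascending-to-descending taper (0.12 per SD) and arch roundness (±10 %
of A and T per SD), with additive coupling noise (default SD 0.03).
The planted-outlier mode appends a subject that is considerably larger
(×1.5) and extremely gothic (A ×1.45, T ×0.70) while keeping its drawn
covariates — an influential observation by construction.

Everything is seeded and bit-reproducible. The generator's ground-truth
map is tested: at zero noise the clean geometry is recovered by
morphometry within 3 % (A, T, base diameter, length; marching step
factor 0.35); at default noise diameters and lengths hold to ~5 % while
A carries up to ~10 % (apex estimation interacts with the lateral
sinusoid). What the generator does **not** emulate: non-circular lumen
sections, branch vessels, wall thickness, imaging/segmentation artefact
structure, or anatomically realistic covariate distributions beyond
first-order couplings. Passing tests on this cohort therefore show that
the pipeline recovers *planted, linearly-coupled* structure at realistic
noise — not that it resolves every real-data failure mode.

Cohort experiments in the tests and the acceptance script use n = 10–12
subjects with ~380-face meshes, 10 time steps and the 2 × 25-iteration
optimiser budget; these sizes keep a full pipeline run around a minute
on one CPU while leaving the statistical conclusions unchanged at finer
resolutions.

## 8. Degenerate inputs and numerical tie-breaks

* Duplicate vertices are merged exactly (8-decimal keys); zero-area and
  duplicate faces dropped; orientation made globally consistent by
  breadth-first propagation, with a hard error on non-orientable input.
* Volume uses the divergence theorem about the mesh centroid — a distant
  origin would lose ~9 digits to cancellation.
* Reference-subject ties break to the lowest index; zero-variance
  descriptors are dropped from the z-score with a warning.
* The Cholesky whitener falls back to a jittered factorisation
  (1e-8 × mean diagonal) when control points nearly coincide.
* `refine_lambdas` treats a zero baseline distance as an immediate pass
  (matching a shape to itself has no error to reduce).
* Fold sizes in k-fold validation differ by at most one; the partition
  is drawn from the provided seed and restored RNG state afterwards.

## 9. Known limitations

* The flow is forward-Euler without a diffeomorphism guarantee; flipped
  triangles at the optimum are detected and warned about, not prevented.
* Stationary momenta trade expressiveness for parameter economy (§2).
* The marching centreline requires exactly two boundary loops and
  near-tubular topology; branching vessels are out of scope.
* A and T are operational definitions calibrated on the generator's arch
  family (§6).
* PLS is single-response; multivariate responses and PCA shape modes are
  intentionally absent.
* Statistical behaviour is demonstrated on synthetic cohorts only; no
  patient data ships with the package.
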