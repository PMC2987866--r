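---
title: "Metric identification of cryptic species: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metric identification of cryptic species: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphid)
```

`morphid` assigns unknown specimens to reference species from 2-D
anatomical landmarks and quantifies the digitization error that limits
such assignments.  This vignette is the package's own account of the
underlying models, the parameters that matter, and the choices made where
reasonable alternatives existed.

## 1. From coordinates to shape

A specimen is an ordered set of k landmark coordinates; landmark i is
assumed operationally homologous across specimens, so all information is
positional.  Size is summarized by the centroid size
CS = sqrt(sum of squared distances from each landmark to the centroid),
in pixel units unless a pixel-to-length scale factor is supplied (CS from
different imaging devices is only comparable after that conversion; the
validator warns when it is missing).

Shape is extracted by Generalized Procrustes Analysis:

1. every configuration is centered and scaled to unit CS (its *preshape*);
2. each preshape is rotated onto the current consensus by the rotation-only
   least-squares fit (SVD of the 2 x 2 cross-product; reflections are
   excluded by constraining the determinant to +1);
3. the consensus is re-estimated as the coordinate-wise mean, re-centered
   and rescaled to unit CS;
4. steps 2–3 repeat until the Frobenius change of the consensus falls
   below `tol`.

Both the rotation step and the consensus step minimize the same sum of
squared deviations, so the objective trace is non-increasing — this is
asserted in the tests on every dataset.  Defaults `tol = 1e-10`,
`max_iter = 100`; realistic datasets converge in a handful of iterations,
and non-convergence is reported as a flag rather than an error.

*Scaling convention.* Every aligned specimen is kept at unit CS ("partial
Procrustes" fitting), which keeps size and shape cleanly separated;
`scaling = "full"` additionally shrinks each specimen by the cosine of its
Procrustes angle to the consensus.  The unit-CS convention is the default
throughout and the one the shape-variable machinery assumes.

*Orientation.* A Procrustes solution is only defined up to a joint
rotation.  The fit is made deterministic by initializing from the
configuration with the lexicographically smallest digitization key and by
rotating the final solution so the consensus principal axis lies along x
with a fixed sign rule.  For shapes with rotational symmetry (e.g. regular
polygons) no intrinsic orientation exists and the canonical frame is
arbitrary — harmless, but worth knowing when comparing variable-by-variable
output across runs.

*Reflections* are never used to fit: wings are digitized on one side, and
allowing reflections would silently mask left/right digitization mistakes.
A mirrored specimen therefore shows up as a large distance, not a perfect
fit.

## 2. Distances and shape variables

With rho the Procrustes angle between two unit preshapes after optimal
rotation, the package computes the **partial** Procrustes distance
2 sin(rho/2) (the default everywhere; it is the chordal distance tangent
space approximates), the **full** distance sin(rho), and the **geodesic**
rho.  The partial distance is evaluated as the direct residual norm after
rotation rather than via sqrt(2 − 2 cos rho); the cosine route loses half
the floating-point precision near zero and would report ~1e-8 for
identical shapes.

Aligned preshapes are projected orthogonally onto the tangent plane at the
consensus.  Because centering, unit scaling and rotation alignment each
remove degrees of freedom, tangent coordinates span at most 2k − 4
dimensions — exactly 2k − 4 in practice, which the tests assert via
singular values.

**Partial warps.** The thin-plate-spline bending-energy matrix of the
consensus (kernel U(r) = r² log r², bordered by the affine terms) has
exactly k − 3 positive eigenvalues; its eigenvectors (principal warps)
provide an orthonormal basis of the non-affine subspace, and the
2-dimensional uniform (affine) component is estimated in the orthogonal
complement of the bending space within the tangent plane.  No
bending-energy weighting is applied (weight exponent alpha = 0), so the
full PW basis is an orthonormal rotation of tangent space: pairwise
distances among specimens are identical in tangent space, in full PW
space, and in full-rank RW space (tested to 1e-8/1e-10).  This is why
classification results do not depend on which of the three bases is used,
and why the choice of including the uniform component (default: included)
only matters if it is excluded.

**Relative warps** are the principal components of the PW scores
(covariance PCA, mean-centered, no eigenvalue weighting), ordered by
decreasing variance.  Centering follows standard PCA practice; as a
consequence the consensus scores zero in PW space but not exactly in RW
space (the RW object stores its centering so new rows can be projected
consistently).

**Consensus dependence.** Shape variables are only meaningful relative to
the consensus they were computed under: adding specimens changes the
consensus and every score.  `combine_shape_variables()` therefore refuses
to merge score matrices from different consensuses — this is an error, not
a warning, because silently mixing such scores is the classic way to get
nonsense out of a morphometric pipeline.

## 3. Classification

Two protocols are provided; both assign each unknown to the species at the
shortest distance, break exact ties deterministically (lexicographically
smallest species label, with the tie flagged), and flag *outliers* —
assignments whose distance to the winning group exceeds the 95th
percentile of that group's own member distances.  The outlier flag is a
concrete rule for the discrimination-versus-identification caveat: the
nearest reference group of a specimen from a species not represented in
the references is still its nearest group.

**Procrustes classification** compares each unknown with the GPA consensus
of every reference species (`nearest_consensus`) and with every individual
reference (`nearest_individual`); both distance sets are reported.  It
ignores the dispersion ellipses of the groups, which is its weakness when
groups differ in variance structure.

**Mahalanobis classification** accounts for within-group dispersion by
whitening with the pooled within-group covariance of a canonical variate
model.  The protocol is strictly *one-by-one*: for each unknown
independently, GPA over references plus that single unknown, partial warps
relative to that joint consensus, discriminant model fitted on the
reference rows exclusively, unknown projected and assigned.  Entering many
unknowns at once would let them shift the consensus and degrade the
reference discrimination, so a batch mode is deliberately absent.  Two
consequences are tested: each unknown's assignment is bit-identical
whatever the order and composition of the other unknowns, and perturbing
one unknown leaves every other unknown's fitted model and record
bit-identical.  (The model for unknown *u* necessarily depends on *u*
through the joint consensus — that is the protocol's definition, not a
leak: the *fit* uses reference rows only.)

*Rank control.* The pooled covariance must be invertible, so PW input is
first reduced to the smallest number of RW axes explaining 95% of variance,
capped at n − g − 1 (n references, g species).  A ridge option
(`ridge * trace(W)/m` added to the diagonal) exists for small-n cases;
the default is 0 because an explicit error beats a silent pseudo-inverse.

*Validation design.* Error tables ("misassigned/total (percent)" per
species plus a total row) are produced by `loo_errors()` using
leave-one-out: each reference is removed in turn and classified by the
full protocol against the rest.  Reports are labelled with the validation
design used.

## 4. Measurement error and the user effect

`repeatability_anova()` runs a one-way ANOVA per shape variable with
individuals as groups: s²_among = (MS_among − MS_within)/r, with the n₀
coefficient replacing r under unbalanced replication, and
R = s²_among / (s²_among + MS_within), truncated to [0, 1] (negative
variance-component estimates are set to zero, standard practice).
Variables are the partial-warp scores from one joint GPA over all
digitizations by default — the same space classification works in — with
raw aligned coordinates as an option.  The summary is the mean ± SD of R
across variables.

`compare_users()` computes each user's own-replicate (one-user) R and the
pooled two-user R in which the two users' digitizations are treated as
replicates of the same individuals.  A systematic one-user > two-user gap
is the signature of the user effect.  `session_scatter()` views the same
phenomenon where it hurts: in the pairwise Procrustes distances, whose
scatter around the identity line between two digitization sessions is
summarized by the RMS perpendicular deviation.

## 5. The synthetic generator

The generator produces the study conditions every test runs under:

* `make_template()` — a regular polygon or a fixed, non-symmetric
  11-point stylized wing (outline plus interior vein landmarks), unit CS.
* `simulate_species_means()` — species means displaced from the template
  along random tangent directions, rescaled so the partial Procrustes
  distance from the template equals the requested separation *exactly*
  (delta = tan(2 asin(s/2)) before renormalization).
* `simulate_specimens()` — mean + i.i.d. Gaussian coordinate noise of SD
  `sigma_shape`, then a random similarity transform (rotation uniform on
  the circle, log-scale uniform in [−0.2, 0.2], translation uniform in
  [−1, 1]²) emulating arbitrary digitizing frames.
* `apply_user_effect()` — the two-component user error model: one
  persistent per-landmark offset field per user (drawn once, SD
  `delta_persistent`) plus fresh pointing noise (SD `sigma_point`) per
  digitization, both scaled by the specimen's CS.
* `simulate_replicates()` — repeated digitizations for the repeatability
  design.

**Where the persistent offset lives.** The offset is expressed in the
*digitizing (image) frame*: parallax, display and motor habits bias the
cursor the same way in screen coordinates however the wing is oriented.
Because specimens are photographed in arbitrary orientations, a
screen-frame bias projects onto a different anatomical displacement per
specimen.  This choice was made deliberately after examining the
alternative: a bias anchored purely to the anatomy displaces all shapes
equally, cancels from pairwise distances to first order, and therefore
cannot reproduce the observed amplification of between-user scatter in
the distances — while the image-frame bias reproduces all three observed
phenomena (depressed pooled two-user repeatability, inflated two-user
classification error, inflated distance scatter).  The flip side, stated
plainly: an image-frame offset also contributes among-specimen variance,
so a one-user design with a nonzero offset reads a higher R than
`sigma_shape²/(sigma_shape² + sigma_point²)` alone would give.  Variance
calibration checks (planted R = 0.8 recovered within [0.75, 0.85]) use
`simulate_replicates()`, which has no offset component.

Directional two-user comparisons use offsets of twice the pointing noise
(delta = 2 sigma_point), with shape noise and pointing noise of equal SD
(0.01 relative to unit CS) — small enough that the tangent approximation
is exact to the tolerances tested, large enough that classification error
is neither 0 nor saturated.  The two-user *classification* contrast takes
the protocol's own perspective: references digitized by user A, unknowns
digitized either by A (one-user) or by B (two-user), which is exactly the
situation the one-user identification procedure exists to prevent.

**What the generator does not emulate.** Real digitization error is not
isotropic Gaussian per landmark: landmark quality varies (sharp vein
intersections vs diffuse points), mounting and photography introduce
non-rigid distortions, and user bias interacts with image quality.
Allometric within-species shape–size covariation is absent (specimen size
varies only through the arbitrary digitizing frame).  Passing tests on
this generator therefore demonstrate the correctness and calibration of
the machinery, not field-level error rates; published error tables from
real wing datasets depend on digitizations that are not distributed with
any paper.

## 6. Numerical choices

* GPA convergence: `tol = 1e-10` (Frobenius change of consensus),
  `max_iter = 100`; a final alignment pass after convergence makes the
  tangency constraints hold to machine precision.
* Partial Procrustes distance computed as the rotated residual norm, not
  via the angle cosine (precision near zero; see section 2).
* Bending-energy eigenvalues are declared zero below 1e-8 of the largest;
  a collinear reference is rejected by name before the solve.
* Tie-breaking in nearest-distance assignment uses a relative tolerance of
  1e-9 and is deterministic (lexicographic), with the tie flagged.
* Negative among-individual variance estimates truncate R at 0; a variable
  with no variance at all is dropped from the mean ± SD summary.
* Degenerate configurations (all landmarks coincident) return CS = 0 with
  a warning where a size is asked for, and are hard errors where a shape
  is needed.
* Seeds are mandatory in every generator; scenario sub-seeds are derived
  deterministically and kept below 2³¹.

## 7. Problem sizes used by the tests

The shipped suite runs the designs at: 100 random configurations for
similarity invariance; 50 random pairs against the exhaustive rotation
grid (step 1e-4 rad); 200 individuals x 2 replicates for variance-component
recovery; 500 specimens for consensus recovery; 30 + 30 references and 40
unknowns for the separated-species design; 44 + 44 references for the
planted-overlap leave-one-out comparison against a 10⁵-draw Monte-Carlo
oracle; and 20 seeded replicates for each directional two-user comparison.
These sizes were chosen so each estimate's sampling noise is well inside
the tolerance being asserted.

## 8. Known limitations

* 2-D landmarks only; no 3-D superimposition, semilandmarks or outline
  methods.
* Missing landmarks are not estimated; configurations must be complete.
* Allometry is not modelled or removed; shape variables are isometry-free,
  not allometry-free.
* The outlier flag is a percentile rule, not a typicality probability.
* Deformation-grid visualization is out of scope; the TPS machinery is
  used for the variable decomposition only.
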