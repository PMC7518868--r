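---
title: "Models and methods behind covgrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind covgrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covgrad)
```

covgrad studies how a parcellated cortical phenotype — cortical thickness in
millimetres, averaged within parcels of a surface atlas — is organized at the
macroscale, and how much of that organization is genetic. This vignette
explains the models, the tunable parameters, the synthetic cohort that the
package uses for validation, and the numerical choices that were genuinely
open.

## Structural covariance

Thickness is first residualized per parcel by ordinary least squares against
an intercept plus covariates. Two presets are shipped, because the covariance
and genetic analyses conventionally control different terms:

* `"covariance"`: age, sex, and global thickness (the per-subject mean across
  parcels);
* `"genetic"`: additionally age², and age × sex.

A `site` factor is appended automatically when more than one acquisition site
is present, which is how multi-site (e.g. cross-laboratory) covariance is
handled. Structural covariance is then the subjects-wise Pearson correlation
of residuals for every parcel pair. We use OLS-residual Pearson correlation
rather than a simultaneous partial-correlation fit; for linear covariates the
two are equivalent, and the residual route keeps the residual matrix
available to later stages.

Parcel values themselves come from a 10% trimmed mean over parcel vertices
(`aggregate_parcels()`): per parcel, `floor(0.1 * m)` smallest and largest of
its `m` vertex values are dropped with a stable sort, so ties never make the
result order-dependent. Subjects whose left/right mean thickness differs by
more than 0.2 cm can be excluded (`qc_hemispheric_difference()`), the quality
rule used for nonhuman cohorts where such asymmetries flag segmentation
failures.

Community structure is summarised by mean within- versus between-community
correlation, with significance per community from a permutation null that
shuffles parcel labels while preserving community sizes — the simplest
exchangeable null consistent with comparing observed networks against
"random networks". The false-discovery procedure is Benjamini–Hochberg; the
choice is a convention, not forced by the method.

## The twin AE model

For a trait $y$ with phenotypic variance $\sigma^2_p$, the AE (additive
genetic + unique environment) model gives co-twin covariance
$h^2\sigma^2_p$ for monozygotic pairs and $\tfrac12 h^2\sigma^2_p$ for
dizygotic pairs, where $h^2 = \sigma^2_g/\sigma^2_p$ is narrow-sense
heritability. `fit_univariate_ae()` maximizes the exact Gaussian pair
likelihood; because the pedigree contains only twin pairs and singletons,
the pair likelihood *is* the full pedigree likelihood, so no general
variance-component machinery is needed. The scale is profiled out
analytically, leaving a one-dimensional problem in $h^2 \in [0,1]$ solved by
grid bracketing plus golden-section refinement — deterministic and immune to
local optima. Traits are inverse-normal transformed upstream (Blom offsets,
$\Phi^{-1}((r - 3/8)/(n + 1/4))$, average ranks for ties) to protect the
Gaussian likelihood against non-normality.

The bivariate model stacks the pair vector
$(y_{i1}, y_{j1}, y_{i2}, y_{j2})$ with within-person covariance $G + E$ and
cross-twin covariance $cG$ ($c = 1$ MZ, $0.5$ DZ), where $G$ and $E$ carry
the genetic and environmental correlations $\rho_g, \rho_e$. The implied
phenotypic correlation is

$$\rho_p = \rho_g\sqrt{h^2_i h^2_j} + \rho_e\sqrt{(1-h^2_i)(1-h^2_j)},$$

and the genetic share of a phenotypic correlation is
$\rho_{ph,g}/\rho_p$ with $\rho_{ph,g} = \sqrt{h^2_i}\,\rho_g\sqrt{h^2_j}$
(`decompose_phenotypic()`). Estimation is bounded L-BFGS-B over
$(h^2_i, h^2_j, \rho_g, \rho_e)$ plus two log-scales, on sufficient
statistics (per-zygosity 4×4 cross-product matrices), so each likelihood
evaluation costs a pair of 4×4 Cholesky factorizations regardless of cohort
size. A moment-based start (Falconer heritabilities and cross-twin
cross-trait covariances) is augmented with fixed starts at
$h^2 \in \{0.1, 0.5, 0.9\}$: during development the single moment start
occasionally converged to a local optimum, and the multi-start reliably
restores the global one, so it is the default everywhere. Significance of
$\rho_g$ and $\rho_e$ comes from likelihood-ratio tests against the
respectively constrained models ($\chi^2_1$). P-values at parameter
boundaries are reported without a 50:50 mixture correction — a documented
limitation; boundary fits ($h^2 = 0$) leave $\rho_g$ undefined and are
flagged. `genetic_correlation_matrix()` runs all $p(p-1)/2$ pairs
independently (order-invariant by construction) and assembles the
$\rho_g$, $\rho_e$, $\rho_p$ matrices.

## Gradients

Any symmetric parcel matrix can be decomposed into macroscale gradients by
the standard route (`covariance_gradients()`):

1. **Row thresholding** (`threshold_rows()`): each row keeps its diagonal
   plus the top `keep_fraction * (p - 1)` off-diagonal entries by signed
   value (default 10%, the "90% cutoff"). Retention is by signed value, so
   strong negative covariances do not out-compete weak positive ones; any
   negatives that survive are handled correctly by the cosine in the next
   step. Ties break deterministically by column order. A global-threshold
   variant can be had by passing `keep_fraction = 1` and pre-masking.
2. **Normalized-angle affinity**: $1 - \arccos(\cos(r_i, r_j))/\pi$ between
   thresholded rows — 1 for parallel, 0.5 for orthogonal, 0 for
   anti-parallel profiles; always in $[0,1]$ and symmetric even though the
   thresholded matrix is not.
3. **Diffusion-map embedding** (`diffusion_embedding()`): density
   normalization $W_\alpha = D^{-\alpha} W D^{-\alpha}$ with $\alpha = 0.5$
   (the recommended compromise between geometry and sampling density),
   row normalization to a Markov operator, and its leading nontrivial right
   eigenvectors as gradients. We use diffusion time $t = 0$ with the
   multi-scale $\lambda/(1-\lambda)$ scaling, the default of the open
   gradient-mapping tools this mirrors. The eigenproblem is solved densely
   through the conjugate symmetric operator, which is exact and
   deterministic at the matrix sizes this package targets (hundreds of
   parcels); a separate sparse solver would buy nothing here.

Variance explained is reported as $\lambda_k / \sum_j \lambda_j$ over the
retained nontrivial eigenvalues. This is a declared convention — reasonable
alternatives (e.g. $\lambda^2$ ratios) exist, and reported percentages
should be read under that convention. Gradient signs are arbitrary in
principle; they are fixed either against a declared anchor map (e.g. a
planted axis or a coordinate) or, absent one, so the largest-magnitude
loading is positive.

`bin_gradient()` ranks parcels along a gradient and cuts them into bins
whose sizes differ by at most one (10 bins over 400 parcels gives exactly
40 each), averaging the source matrix within and between bins.
`align_gradients()` matches components across embeddings greedily by
maximal $|r|$, reporting sign flips — adequate for the first few
well-separated components; it is not a Procrustes alignment and is not
meant for dense subspace matching.

## Spatial inference

**Spin tests.** The null for correlating two cortical maps must preserve
spatial autocorrelation; random rotations of the spherical parcel centroids
do exactly that. `spin_permutations()` draws uniform rotations (QR of a
Gaussian matrix, sign-corrected, det +1), applies the mirrored rotation to
the right hemisphere, and reassigns each original parcel to its nearest
rotated same-hemisphere centroid, duplicates allowed — the map-resampling
variant standard for parcel data. Because permutations depend only on the
geometry they are precomputed once and reused across tests; the two-tailed
p-value is $(1 + \#\{|r_{null}| \ge |r_{obs}|\})/(B + 1)$ with $B = 1000$
rotations by default, matching the permutation count used throughout.

Parcel-level spin tests are approximate: on very smooth null maps
(Gaussian-process maps with kernel length 0.5 on the unit sphere) the
measured type-I error at nominal 0.05 is about 0.06, and the inflation
grows with map smoothness. A bijective variant
(`assignment = "bijective"`, greedy one-to-one matching) makes each null
map an exact permutation of the original values but performs markedly
*worse* (type-I ≈ 0.12 on the same maps): parcels whose rotated positions
fall in the medial wall must be matched to distant leftovers, which
destroys the null maps' smoothness and narrows the null correlation
distribution. The duplicates-allowed variant is therefore the default, and
the calibration checks estimate its rejection rate with 2000 replicates so
the estimate (standard error ≈ 0.005) can resolve the 0.03–0.07
acceptance band; each replicate draws fresh rotations, because reusing one
rotation set across replicates leaves the rejection rate conditionally
variable.

**Energy tests.** Distribution differences between two sets of parcel
values use the energy distance
$E = 2\,\overline{|a-b|} - \overline{|a-a'|} - \overline{|b-b'|}$ (scaled
by $nm/(n+m)$), with a pooled-relabelling permutation null (1000 by
default). The log-potential variant of the minimum-energy literature is
available via `potential = "log"` (with the appropriate sign convention);
the Euclidean form is the default since the choice is not dictated by the
analysis. A sample of size one contributes a zero within-sample term, with
a warning.

**Geodesics and the dual origin.** Distances are shortest paths along mesh
edges (Dijkstra with edge lengths) restricted to one hemisphere — only
ipsilateral distance is meaningful — and averaged per parcel; exact
polyhedral geodesics would change distances by a few percent at these mesh
resolutions and are out of scope. `dual_origin_association()` asks whether
a gradient follows the two ancient differentiation origins: it splits the
gradient at its median (the cut rule is a package choice; the analysis is
robust to it) and energy-tests each origin-distance field between halves,
and it correlates the gradient with each distance field under a spin test.
Both Pearson and Spearman variants are exposed since reported analyses mix
the two. `regress_distance()` removes distance and distance² from
within-hemisphere covariance by OLS, passing cross-hemisphere entries
through.

## Microstructural profiles

Intracortical surfaces are placed equivolumetrically: the Euclidean depth
fraction of surface $\alpha$ (volume fraction between the bounding
surfaces) is

$$\rho = \frac{1}{A_{out} - A_{in}}\left(-A_{in} +
\sqrt{\alpha A_{out}^2 + (1-\alpha) A_{in}^2}\right),$$

with the continuity extension $\rho = \alpha$ as $A_{out} \to A_{in}$.
Per-vertex areas are one-ring barycentric areas; on the synthetic spherical
cortex the outer surface is the mesh inflated by a nominal 2.5 mm
thickness. Twelve surfaces are sampled by default. The microstructural
profile covariance between parcels $i$ and $j$ is the partial correlation
of their depth profiles controlling the cortex-wide mean profile,

$$MPC(i,j) = \frac{r_{ij} - r_{ic}r_{jc}}
{\sqrt{(1-r_{ic}^2)(1-r_{jc}^2)}},$$

averaged over subjects (plain averaging by default; Fisher-z averaging is a
flag, as the convention is not fixed). MPC matrices implement the same
matrix interface as covariance, so the gradient pipeline runs on them
unchanged, with the same default 90% row cutoff.

Real myelin-sensitive volumes are replaced by a synthetic intensity field:
per-community polynomial depth templates (base, slope, curvature) plus
vertex-level Gaussian noise. This exercises the sampling and MPC machinery
end to end but does not emulate scanner bias fields, partial-volume
effects, or laminar discontinuities.

## The synthetic cohort

Validation needs ground truth, so the package generates it rather than
downloading anything:

* **Geometry.** An icosphere (default 70 mm radius) with a small polar cap
  along the left/right axis excluded as a medial wall (cap height 0.06);
  parcels are spherical Voronoi cells of a Fibonacci lattice restricted to
  the remaining band, split left/right at $x = 0$. Seven community labels
  come from a coarser directional partition, and two near-antipodal vertex
  sets per hemisphere serve as archicortical (superior) and paleocortical
  (inferior) origins, so the planted inferior–superior axis tracks
  paleocortex distance by construction.
* **Covariance structure.** Genetic and environmental parcel correlations
  are weighted sums of squared-exponential kernels on two orthogonal
  spherical coordinates — the posterior–anterior ($y$) and
  inferior–superior ($z$) axes — plus a parcel-unique diagonal, normalized
  to unit diagonal; each is positive semi-definite by construction and
  gets a $10^{-8}$ jitter before Cholesky. Defaults: genetic weights
  (1, 0.3), length scale 0.5 (in unit-coordinate units, i.e. roughly a
  third of a hemisphere), unique variance 0.3; the environmental structure
  is weaker and shorter-ranged (weights 0.5/0.5, length scale 0.4, unique
  variance 0.8), reflecting that unique environment is less spatially
  organized than genetic effects. Mean heritability defaults to 0.3 — the
  ballpark reported for parcel-wise thickness in large twin samples — and
  can be graded along the first axis.
* **Twin structure.** Additive values are multivariate normal with the
  genetic covariance, shared exactly between MZ co-twins and correlated 0.5
  between DZ co-twins via $a_2 = \tfrac12 a_1 + \tfrac{\sqrt3}{2}
  a_{indep}$; DZ sharing is fixed at 0.5 (no dominance or shared
  environment), matching the AE model fitted downstream. Covariates follow
  the healthy-adult twin-cohort template: age uniform on 22–37 years
  (shared within twin pairs), sex Bernoulli(½) (shared within MZ pairs),
  and an optional site intercept. Thickness is
  $2.5\,\text{mm} + \beta_{age}\,\text{age} + \beta_{sex}\,\text{sex} +
  0.25\,(a + e)$ mm with $\beta_{age} = -5\,\mu m/yr$ and $\beta_{sex} =
  20\,\mu m$ — small, realistic effects that residualization must remove.

What the generator does *not* emulate: vertex-level scanner noise,
non-Gaussian phenotypes, dominance or shared-environment components,
extended pedigrees, atlas misregistration, or folding-dependent area
variation (the synthetic sphere has near-constant curvature, so
equivolumetric and equidistant sampling differ only through the nominal
inflation). Passing tests therefore demonstrate that the estimators and the
pipeline are correct and calibrated under the stated model, not that real
cortical data meet that model.

## Problem sizes and reproducibility

The validation suite and the acceptance script run at sizes chosen to make
Monte-Carlo error small relative to the tolerances while staying desk-scale:
heritability recovery at 250+250 families × 10 replicates per level,
genetic-correlation matrices at 50 parcels × 600 families (1225 bivariate
fits), gradient recovery at 200 parcels × 1000 subjects, and 500-replicate
null calibrations for the spin and energy tests. All randomness flows
through explicit integer seeds; `run_pipeline()` derives per-stage child
seeds as `seed × 1000 + stage index` so stages are independently
reproducible, and a rerun with the same configuration is byte-identical.
Meshes are exchanged as ASCII PLY, matrices and cohorts as TSV/CSV written
with 17 significant digits (exact double round-trip), with JSON sidecars
carrying kind, settings, and seeds.
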