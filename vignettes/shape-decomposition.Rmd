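---
title: "Partitioning cranial shape variance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning cranial shape variance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniomorph)
```

This vignette is the package's own account of the statistical machinery:
the models fitted at each stage, the conventions and tolerances chosen
where several were defensible, what the synthetic-data generator does and
does not emulate, and the known limitations of the whole construction.

## The data model

A study consists of $n$ specimens (one per species), each digitised as
$p$ three-dimensional points: *fixed* landmarks with one-to-one
anatomical identity and *semilandmarks* sampled along curves (here,
dorsal profiles and tomial edges), plus a rooted ultrametric phylogeny
with the $n$ species at its tips, and per-species metadata (clade group,
diet category). Landmark files are 1-based in all on-disk formats,
matching the numbering conventions of published landmark tables. Species
names are matched across files case-insensitively with underscores
equivalent to spaces, and any mismatch is a hard error: silently dropping
a tip would corrupt the phylogenetic covariance matrix downstream.

## Superimposition

**GPA.** Each configuration is centred, scaled to unit centroid size
$CS = \sqrt{\sum_i \lVert x_i - \bar x \rVert^2}$, and rotated onto the
iteratively re-estimated consensus by the SVD (Kabsch) solution with
reflections disallowed ($\det R = +1$). Iteration stops when the
root-mean-square change of the consensus falls below $10^{-10}$
(default `max_iter = 200`; failure to converge is an error, not a
warning). Because the consensus orientation is a gauge freedom that
would otherwise depend on specimen input order, the converged solution
is rotated to a canonical frame: the principal axes of the consensus,
signs fixed by third moments (the axis with the larger skew points
positive), with a determinant correction that flips the least-skewed
axis if needed. This makes GPA order-invariant to numerical tolerance.
Finally the aligned shapes are projected orthogonally into the tangent
space at the consensus.

**Sliding.** Semilandmarks carry no identity along their curve, so each
is allowed to slide along the chord between its two neighbours (the
tangent is recomputed from current neighbour positions each pass; we do
not use TPS derivatives, which the underlying theory does not require
and which complicate nothing but the implementation). Displacements are
chosen to minimise the thin-plate-spline bending energy of the specimen
relative to the current consensus. For a 3D reference the TPS kernel is
$U(r) = -r$; the bending-energy matrix is the upper-left block of the
inverse of the bordered system $[[K, Q], [Q^\top, 0]]$, $Q = [1, X]$.
It is symmetric positive semi-definite and annihilates affine fields —
both properties are asserted in the test suite at $10^{-9}$. The
minimisation is an $m \times m$ linear solve in the $m$ tangent
coordinates; a ridge of $10^{-10}$ is added only if that system is
numerically singular (collinear curve geometry). Slide and
re-superimposition alternate for at most 5 passes or until the consensus
moves less than $10^{-6}$; within each pass the slide solves its
minimum exactly, so the recorded per-pass energy never increases from
before to after sliding. Across passes the reference itself changes, so
energies are only comparable within a pass, and that is the invariant we
state and test.

**Symmetric component.** For object-symmetric configurations each
specimen is duplicated as a mirror copy (one coordinate axis negated,
paired left/right labels swapped), originals and mirrors are jointly
superimposed, and the symmetric shape is the average of the two aligned
copies; the asymmetric remainder is discarded. The reflection axis
defaults to the axis of smallest variance of the midline landmarks in a
preliminary consensus, with a warning (and a configurable override) when
the midline variances do not single one out. Whether to slide before or
after the symmetry duplication is not dictated by theory; the package
slides first on the originals, then symmetrises, which keeps the
bending-energy reference well defined, and exposes the order through the
two functions being separate steps.

## Phylogenetic statistics

All comparative machinery rests on the Brownian covariance
$C_{ij} = $ depth of the most recent common ancestor of tips $i,j$.
Basal polytomies (including star trees) are treated as simultaneous
divergence from the root — this is required for the star-tree limit
cases below to be expressible at all. The whitening transform
$P = C^{-1/2}$ (eigen-decomposition; a non-positive eigenvalue is an
error) converts GLS problems into OLS ones.

**Kmult** is the multivariate phylogenetic signal statistic: the ratio
of the summed squared Euclidean deviations of tips from the
phylogenetic (GLS) mean to the same quantity in the whitened metric,
divided by its Brownian expectation
$(\mathrm{tr}\,C - n/(\mathbf{1}^\top C^{-1}\mathbf{1}))/(n-1)$.
Under Brownian motion on the tree its expectation is 1 (the suite
checks the mean over 200 simulations on a 50-tip tree against
$[0.9, 1.1]$); the permutation test shuffles tip identities.

**Procrustes regression.** `shape ~ logCS + diet` is fitted on the
flattened shape matrix with sequential (type I) sums of squares in the
trace form, with logCS entered first — term $R^2$ then matches the
formula's reading, and the diet $R^2$ is the gain over the allometric
model. Factors use treatment contrasts with the alphabetically first
level as reference; term-level SS, $F$ and $R^2$ are invariant to that
coding (tested). Significance comes from residual randomization (RRPP):
for each term, residuals of the reduced model holding all earlier terms
are permuted across specimens, added back to the reduced fit, and the
term's $F$ recomputed; $p = (b + 1)/(n_{\mathrm{perm}} + 1)$ where $b$
counts null values at or above the observed. The default
`n_perm = 999` plus the observed arrangement makes the attainable floor
exactly $0.001$. The PGLS variant applies $P$ to the response and the
whole design, intercept included, and permutes transformed-scale
residuals; on a star tree with equal branch lengths it reproduces the
ordinary fit to $10^{-8}$, which the suite asserts.

**Two-block phylogenetic PLS.** Both blocks are centred on the GLS mean
and whitened; the SVD of their cross-covariance yields paired axes.
Scores are the centred *untransformed* data projected on those axes, and
`rPLS` is the Pearson correlation of the paired first scores — the
statistic is invariant to rotations within either block. The null
permutes the tip rows of block 2 and recomputes the whole procedure,
GLS centring included.

## The decomposition cascade

1. **Allometry.** PGLS of shape on $\log CS$. The term $R^2$ — measured,
   like all GLS $R^2$, in the whitened metric — is the allometric
   fraction; the residuals (returned on the original coordinate scale)
   are the non-allometric shapes.
2. **Integration.** Phylogenetic PLS of the non-allometric shapes split
   into the beak and braincase blocks; ordinary least-squares regression
   of the first-dimension block-1 scores on the block-2 scores (the one
   step of the published procedure that is explicitly non-phylogenetic;
   we follow that reading literally, and the PLS scores entering it are
   already GLS-centred); PGLS of the non-allometric shape matrix on the
   fitted "prediction scores". Its residuals are the NANI shapes.
3. **Remainder.** Kmult of the NANI shapes and a PGLS of NANI on diet.

The integration fraction can be expressed against two denominators: the
non-allometric variance (the stage's own $R^2$) or the total variance of
the original shapes. The package defaults to the **total** basis, so
that allometric + integration = combined is an identity rather than an
approximation; the stagewise number is always emitted alongside for
audit, and `fraction_basis = "stagewise"` flips the convention. Because
block-2 PLS scores are GLS-centred, the prediction-score direction is
automatically orthogonal (in the whitened metric) to the transformed
intercept, and the NANI residuals are exactly orthogonal to both the
logCS and the prediction-score directions — the suite verifies this at
$10^{-8}$. A consequence worth stating: NANI shapes are GLS residuals,
so their *raw* column means are near but not exactly zero; we kept the
orthogonality property, which is the one the decomposition's logic
depends on.

## Group tests

PERMANOVA on PC scores uses the classical Euclidean decomposition
(between/within group sums of squares around centroids), which on a
Euclidean embedding is identical to the distance-matrix formulation —
the suite cross-checks pseudo-$F$ and $R^2$ against `vegan::adonis2`.
Using *all* PCs, Euclidean score distances equal tangent-space shape
distances, so PERMANOVA on full scores equals PERMANOVA on flattened
shapes (asserted to $10^{-9}$, including identical permutation
p-values). Pairwise tables Bonferroni-correct by default because at the
permutation floor this yields the characteristic adjusted floors of
$3/(n_{\mathrm{perm}}+1)$ for three groups and $6/(n_{\mathrm{perm}}+1)$
for six pairs; Holm is available by argument. Groups below a minimum
size (pipeline default 3) are excluded from pairwise clade tests — the
exclusion is driven by the metadata, never hard-coded to a taxon.

## The synthetic-data generator

Tip shape deviations are the sum of: per-coordinate Brownian motion on
the tree (rate `total_scale`, default 0.02 — a small-variation regime
relative to the unit-scale template, keeping the tangent-space
approximation honest); an allometric vector times a standardized size
trait (Brownian with SD 1 at unit depth, plus independent jitter of SD
0.05 — size in real clades is strongly phylogenetically structured, and
the jitter keeps $\log CS$ from being perfectly collinear with the tree);
a latent integration factor (Brownian on the tree, so that integration
*survives* phylogenetic correction rather than being absorbed by it)
loading equally on both landmark blocks; optional per-diet mean offsets;
and optional independent noise. Raw landmark files additionally carry
size (configurations scaled by $e^{\log CS}$) and random rigid motions,
so the full pipeline's superimposition is genuinely exercised.

**Ground truth.** The injected variance fractions are defined in the
phylogenetically whitened, GLS-centred metric — deliberately, because
that is the metric in which the PGLS stages measure $R^2$, so "recover
the injected fraction" is a well-posed estimator check rather than a
metric mismatch. Component scales are solved analytically from the
requested fractions via $\mathrm{tr}(M^\top C^{-1} M \Sigma)$ weights
($M$ the GLS-centring operator, $\Sigma$ the component's tip
covariance); effect directions are drawn once per truth object,
mutually orthogonalised, and (by default) projected onto the bilaterally
symmetric subspace of the template so the symmetric-component step does
not strip them out. Realized per-draw fractions are recorded next to the
expected ones. One practical note embedded in this design: independent
(non-Brownian) noise is *amplified* by whitening on trees with short
terminal branches — its whitened weight is
$\sigma^2\,\mathrm{tr}(C^{-1})$-like, not $\sigma^2 n$ — which is why
noise defaults to zero in the recovery fixtures and why the calibration
accounts for it explicitly when enabled.

**What passing recovery tests do and do not show.** Recovery is tested
on the generator's tangent-space shape matrices directly (the
`$aligned` route): at $n = 150$ tips the mean recovered fractions over
50 replicates sit within $\pm 0.05$ of the injected 0.30/0.25. Pushing
the same data through the *full* pipeline (GPA, sliding, symmetric
component) reproduces the structure qualitatively but shifts the
fractions by several percentage points: superimposition projects out
seven degrees of freedom, sliding moves semilandmarks, and the
symmetric averaging halves the asymmetric part of the Brownian
background while the injected (symmetrised) effects keep their full
variance. That shift is a property of the measurement process itself —
real studies face it too — and is not an estimator defect; the pipeline
smoke tests therefore assert structure, not exact fractions. The
generator makes no attempt to mimic real skull geometry, digitisation
error models, or non-Brownian evolutionary processes
(Ornstein–Uhlenbeck, early bursts); conclusions about robustness to
those are outside what the tests can certify.

## Determinism and problem sizes

Every permutation test and simulator takes an explicit integer seed.
Functions seed *locally* and restore the caller's RNG state on exit, so
wrapping them in `replicate()` cannot silently reuse one dataset — an
easy bug to write and a miserable one to notice, since the "mean over
200 replicates" it produces is actually a single draw. Identical seeds
reproduce every p-value and every on-disk fixture byte-for-byte.

The test suite's simulation sizes — 200 Brownian replicates for the
Kmult calibration on 50 tips, 50 recovery replicates at 150 tips with
the 12-point template, 999 permutations wherever a p-value floor is
asserted, the 60-point template for full-pipeline runs — were chosen so
the whole suite completes in well under a minute while keeping Monte
Carlo error comfortably inside the asserted tolerances.

## Known limitations

* The published-data acceptance test needs the deposited specimen
  bundle; without it that single test reports failure by design. All
  other claims are certified on synthetic data.
* The sliding implementation is the bending-energy criterion only;
  minimum-Procrustes-distance sliding is not offered.
* PGLS assumes pure Brownian covariance; no Pagel's lambda or OU
  transforms are fitted.
* Asymmetry is discarded, not analysed: there is no directional or
  fluctuating asymmetry decomposition.
* Plots are limited to exporting coordinates (PC scores,
  phylomorphospace points and branch segments) as CSV; rendering is left
  to the caller.
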