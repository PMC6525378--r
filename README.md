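# craniomorph

Phylogenetic decomposition of skull and beak shape variation from 3D
landmark data.

Comparative morphologists routinely ask how much of the cranial shape
variation across a clade is explained by evolutionary allometry (shape
change predicted by size), by morphological integration between modules
such as the beak and the braincase, by ecology (diet), and by phylogeny
itself. `craniomorph` implements that whole workflow for 3D
landmark + semilandmark data in a single tested R package:

* **Superimposition** — generalized Procrustes analysis (translation,
  unit-centroid-size scaling, SVD rotations with reflections disallowed,
  tangent projection), sliding of semilandmarks along their curve
  tangents to minimise thin-plate-spline bending energy, and extraction
  of the **symmetric component** of shape for object-symmetric
  configurations (each specimen averaged with its reflected, relabeled
  copy after joint superimposition).
* **Ordination** — PCA of the aligned shapes, end-member warps along PC
  axes, and phylomorphospace coordinates through maximum-likelihood
  Brownian ancestral states.
* **Phylogenetic statistics** — the Brownian covariance matrix
  `C[i,j] = depth(MRCA(i,j))`; multivariate phylogenetic signal
  *K*<sub>mult</sub> = (tr D<sub>E</sub> / tr D<sub>C</sub>) /
  [(tr C − n/(1ᵀC⁻¹1))/(n−1)], permutation-tested; Procrustes
  regression `shape ~ logCS + diet` with sequential (type I) sums of
  squares and residual-randomization permutation (RRPP), in both
  ordinary and PGLS (whitened by C^−1/2) form; and two-block
  phylogenetic partial least squares with its `rPLS` statistic.
* **The decomposition cascade** — PGLS of shape on log centroid size
  (allometric fraction); phylogenetic PLS of the residuals split into
  beak/braincase blocks, regression of the paired first scores, and a
  PGLS of the non-allometric shape on the resulting prediction scores
  (integration fraction); what remains is the non-allometric,
  non-integrated (**NANI**) shape, tested for phylogenetic signal and
  diet effects. Both fractions are reported against the total shape
  variance so they are additive.
* **Group tests** — Euclidean pairwise PERMANOVA of PC scores with
  Bonferroni (or Holm) correction and post-hoc subset reruns.
* **Synthetic data** — a generator that evolves tip shapes by Brownian
  motion on a simulated tree and injects an allometric vector, a shared
  beak–braincase latent factor, optional diet offsets and noise, with
  *known, analytically calibrated* variance fractions, so every stage of
  the pipeline is verifiable by parameter recovery without any external
  data.

## Worked example

Simulate a 150-species study with known ground truth (30% allometry,
25% integration, the rest Brownian motion on the tree) and decompose it:

```r
library(craniomorph)

tree  <- simulate_tree(150, seed = 42)
tp    <- skull_template("full")        # 20 fixed + 40 semilandmarks
truth <- synthetic_truth(tree, tp, allometric_fraction = 0.30,
                         integration_fraction = 0.25, seed = 43)
sim   <- simulate_shapes(tree, truth, seed = 44)

dec <- decompose_shape(sim$aligned, tree, tp$blocks,
                       diet = setNames(sim$metadata$diet, sim$metadata$species),
                       n_perm = 999, seed = 1)
print(dec)
#> shape variance decomposition (basis: total )
#>   allometry:     27.6%
#>   integration:   28.5%
#>   combined:      56.1%
#>   residual Kmult: 0.984 (p = 0.001)
#>   NANI ~ diet: R2 = 0.0139, p = 0.341
```

One replicate recovers the injected fractions to within sampling noise
(the test suite checks the mean over 50 replicates to ±0.05); the NANI
residuals behave as the pure Brownian background that was injected
(*K*<sub>mult</sub> ≈ 1) and show no spurious diet signal.

The same analysis runs end-to-end from files. `make_fixture()` writes a
complete dataset (landmarks, tree, sliders, symmetry pairs, metadata,
block table, config) in the plain-text formats the readers accept, and
`run_pipeline()` executes every stage — sliding, symmetric component,
PCA, *K*<sub>mult</sub>, regressions, PLS, decomposition, PERMANOVA —
and writes a JSON summary plus per-stage CSVs:

```r
make_fixture("full", "study", seed = 42)
res <- run_pipeline("study/config.json", out_dir = "study/out")
```

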