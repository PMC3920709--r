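---
title: "Surface electrostatic-potential descriptors and the QSAR stage: models, numerics, design"
author: "msepqsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface electrostatic-potential descriptors and the QSAR stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msepqsar)
```

## The model

The electrostatic potential a molecule creates around itself,

$$V(\mathbf r) = \sum_A \frac{Z_A}{|\mathbf R_A - \mathbf r|}
  - \int \frac{\rho(\mathbf r')}{|\mathbf r' - \mathbf r|}\, d\mathbf r' ,$$

is a physical observable that summarizes how the molecule is seen by an
approaching reagent, solvent molecule or receptor. Restricted to a molecular
surface — here the isodensity contour $\rho = 0.001\ e/\mathrm{bohr}^3$, the
Bader convention — its statistical structure is a compact, interpretable
descriptor set (the Politzer general-interaction-properties family):

* the surface extrema $V_{s,\max}$ and $V_{s,\min}$ (kcal/mol), read as
  hydrogen-bond-donating and -accepting propensity;
* the surface averages $\bar V_s$, $\bar V_s^+$ (over the positive region)
  and $\bar V_s^-$ (negative region);
* the average deviation $\Pi = \overline{\,|V_s - \bar V_s|\,}$, an internal
  charge-separation measure;
* the variances $\sigma^2_+$, $\sigma^2_-$ and
  $\sigma^2_{tot} = \sigma^2_+ + \sigma^2_-$, with $\sigma^2_\pm$ centred on
  $\bar V_s^\pm$;
* the balance parameter $\nu = \sigma^2_+\sigma^2_-/(\sigma^2_{tot})^2$,
  which reaches its maximum $1/4$ exactly when the two variances are equal
  (the algebraic bound $ab/(a+b)^2 \le 1/4$).

The QSAR stage regresses an inhibitory activity — here the IC$_{50}$ for
inhibition of the oxygen evolution rate in spinach chloroplasts
(mmol/dm$^3$) by fifteen substituted pyrazine-2-carboxamides — on five such
descriptors: $1/V_{s,\min}$, the LUMO energy, $\bar V_s$, $\bar V_s^+$ and
$1/V_{s,\max}$. The packaged table (`table1_path()`) carries the printed
descriptor and activity values at full precision; refitting it reproduces
the reference five-descriptor equation

$$\mathrm{IC}_{50} = -2.467 + 82.101/V_{s,\min} - 34.882\,\mathrm{LUMO}
  - 0.132\,\bar V_s + 0.139\,\bar V_s^+ + 5.569/V_{s,\max}$$

with $n = 15$, $R^2 = 0.922$, $R^2_{adj} = 0.879$, $SE = 0.095$ — values
recomputed, not assumed, by `pipeline_reproduce()`, the test suite, and
`scripts/acceptance.R`.

```{r reproduce}
m <- fit_ols(read_descriptor_table(table1_path()),
             c("inv_vs_min", "lumo", "vs_mean", "vs_plus_mean", "inv_vs_max"),
             "activity")
c(r2 = m$r2, r2_adj = m$r2_adj, se = m$se)
```

Activity is regressed untransformed, exactly as the reference equation is
written; applying that equation's printed coefficients to the printed
descriptor rows reproduces the printed predicted-activity column to better
than ±0.002, which confirms the convention.

## Pipeline and parameters

`pipeline_descriptors()` chains, per cube file: `read_cube` →
`extract_isosurface` → `sample_potential_on_surface` → `compute_descriptors`.
The parameters that matter:

* **`isovalue`** (e/bohr$^3$, default 0.001). The contour defining the
  molecular surface. Configurable for sensitivity checks; the default is the
  convention under which the descriptor set is usually reported.
* **`weighting`** (`"area"`, default, or `"uniform"`). The descriptor
  definitions are often printed as plain $1/n\sum$ point averages, but a
  plain average over mesh samples depends on how finely the mesh happens to
  be triangulated. Area weights make every statistic a surface quadrature,
  invariant under mesh refinement (a property the tests assert by splitting
  faces). `uniform` recovers the printed reading.
* **Sign tie**: samples with $V = 0$ belong to the positive partition — a
  measure-zero choice, fixed for determinism. An empty partition has an
  absent (`NA`) mean and zero variance; $\sigma^2_{tot}=0$ forces $\nu = 0$.
* **`p_enter` / `p_remove`** (0.05 / 0.10): SPSS-convention partial-F
  thresholds for `stepwise_forward()`. On the packaged table the
  single-predictor LUMO model ($R^2 = 0.054$) would not pass a 0.05 entry
  threshold, so a default stepwise run admits nothing — the published entry
  order evidently arose under other settings. Reproduction therefore goes
  through `nested_model_trace()`, which fits the published order's prefix
  models directly and does not depend on replicating any particular
  selection path.
* **LUMO** is an input scalar (hartree-scale, used exactly as tabulated):
  cube files carry no orbital energies, so the pipeline joins LUMO values
  from a sidecar table. Computing wavefunctions is out of scope.

## Numerical choices

**Isosurface extraction** uses marching tetrahedra: each grid cell is split
into the six Kuhn tetrahedra around its main diagonal, within which the
field is linear and the contour crosses each edge at most once. The
decomposition is identical across neighbouring cells, so the mesh is
watertight with no ambiguous saddle configurations to resolve (the classic
15-case cube table needs a disambiguation convention; the tetrahedral
decomposition needs none). Face centroids carry triangle areas as
quadrature weights.

Two refinement passes (configurable, `refine`) then push each vertex along
its parent edge, and each centroid along the local gradient, onto the
contour of a *second-order-corrected* interpolant (trilinear minus its
leading $u(1-u)h^2 f''/2$ bias, estimated from second differences). This
matters because the surface potential of a near-neutral molecule is a small
residual of two large cancelling terms and varies steeply across the
surface shell: at a 0.15-bohr spacing, unrefined vertex placement error
alone shifts the sampled potential of the neutral test atom by several
percent, while after refinement the mesh area of the analytic sphere is
reproduced to ~0.02% and the sampled potential is constant to well under
2%. Without refinement the mesh-area error is ~90 $h^2$ (measured
convergence order ≈ 2, asserted in the tests).

**Potential evaluation** from a density grid defaults to an Ewald-style
split of the Coulomb kernel at a range $s = 1.25\,h$:

$$\frac1d = \frac{\operatorname{erf}(d/s)}{d}
  + \frac{\operatorname{erfc}(d/s)}{d}.$$

The long-range part is smooth everywhere (finite at $d = 0$), so its
midpoint voxel sum inherits the near-spectral accuracy of lattice
quadrature on smooth integrands; the short-range part is integrated
analytically against the local density expansion,
$\pi s^2 \rho(\mathbf r) + (\pi s^4/8)\,\nabla^2\rho(\mathbf r)$, with
$\rho$ and its finite-difference Laplacian interpolated from the grid. A
plain midpoint sum (`method = "midpoint"`, with a uniform-sphere rule for
the singular voxel) is retained for comparison: its near-surface lattice
error is of order $\rho_{surf}\,h^2$, which is negligible for far-field
work but comparable to a near-neutral molecule's entire surface potential.
Voxels below $10^{-12}$ of the peak density are dropped from the sums; the
Laplacian correction is applied on orthogonal axis-aligned grids and
omitted otherwise.

All geometry is kept in bohr and potentials in hartree/e; the single
conversion to kcal/mol (× 627.5095) happens when potentials are attached to
a surface, so no quantity can be scaled twice.

**Problem sizes.** The closed-form surface checks run on a
$0.15$-bohr grid with a 4.8-bohr margin (boundary density
$< 10^{-6}$ of the isovalue); the surface-potential statistics in the tests
are evaluated on a fixed 1500-face random subset of the ~35&nbsp;000-face
mesh, which pins the mean, spread and $\Pi$ well inside the tolerances
under test while keeping the all-pairs Coulomb sums affordable. Pipeline-
level tests use tighter model atoms ($\alpha = 2$ bohr$^{-2}$) on coarser
grids, where only sign structure and schema are at stake.

## What the synthetic data does and does not emulate

The generator builds "Gaussian atoms": point nuclei of charge $Z$ inside
spherical clouds $\rho(r) = A e^{-\alpha r^2}$. Everything about them is
closed-form — the electron count $N = A(\pi/\alpha)^{3/2}$, the contour
radius $r_0 = \sqrt{\ln(A/\mathrm{iso})/\alpha}$, the potential
$V(r) = (Z - N\operatorname{erf}(\sqrt\alpha\, r))/r$ — so the cube reader,
the extractor and the potential engine are tested against independent
oracles rather than against themselves. Choosing $Z$ above, at, or below
$N$ yields cation-like, neutral and anion-like fixtures, exercising both
sign partitions of the descriptor statistics.

These model atoms are *not* DFT densities: they have no nuclear cusps, no
shell structure, no anisotropy, and a neutral one has a spherically
constant surface potential. Passing the closed-form tests therefore
demonstrates the correctness of the machinery (quadrature, meshing,
statistics), not the chemistry of real pyrazine amides — whose B3P86-level
densities are out of scope; for real molecules the package consumes cube
files produced elsewhere.

Synthetic QSAR tables draw each predictor column as an independent normal
with prescribed moments and add Gaussian noise to a known linear response.
One integer seed (default 20130415) governs all generation, restoring the
caller's RNG state afterwards. Because the columns are independent while
the real descriptor table's columns are correlated with counteracting
coefficients, tables generated with the real table's per-column moments and
the reference residual scale refit with $R^2$ somewhat *above* the
reference 0.922 (mean ≈ 0.98 over 200 seeds) — the Monte-Carlo test brackets
accordingly and this is a property of the independence assumption, not a
defect of the fit.

## Degenerate inputs and edge rules

Cube headers with a negative axis count are read as Angstrom and converted;
a negative atom count (a molecular-orbital cube) is rejected outright.
Value blocks whose length disagrees with the header are reported as
truncation, not silently padded. Grids must be at least $2^3$ with a
nonsingular axis matrix. A constant field, or an isovalue outside the
field's range, raises an empty-surface error rather than returning an
empty mesh. Query points on a nucleus (within $10^{-8}$ bohr) are an error
naming the atom. Zero-variance surfaces report $\Pi = 0$, $\nu = 0$;
zero extrema make the reciprocal transform a domain error. OLS fitting
refuses rank-deficient designs (naming the dependent columns) and designs
with $n \le p + 1$.

## Known limitations

* The all-pairs grid sums make potential sampling $O(N_{faces} \times
  N_{voxels})$; fine grids on large molecules are expensive, and no
  multipole acceleration is attempted.
* `stepwise_forward()` reproduces the SPSS convention, not any specific
  SPSS run; on data where the printed selection path conflicts with the
  stated thresholds (as here), use `nested_model_trace()`.
* Coefficient standard errors of the refit match the published ones only to
  refit tolerance, since the packaged descriptor values are printed
  (rounded) numbers.
* No cross-validation or applicability-domain analysis is provided beyond
  the predicted-vs-actual listing, mirroring the scope of the reference
  analysis.
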