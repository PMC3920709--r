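# msepqsar

Surface electrostatic-potential descriptors and QSAR regression for
molecular activity modelling.

## What this is for

Medicinal and computational chemists often summarize how a molecule "looks"
electrostatically by statistics of the molecular electrostatic potential

$$V(\mathbf r) = \sum_A \frac{Z_A}{|\mathbf R_A - \mathbf r|}
  - \int \frac{\rho(\mathbf r')}{|\mathbf r' - \mathbf r|}\, d\mathbf r'$$

evaluated on the ρ = 0.001 e/bohr³ isodensity surface: the extrema
V<sub>s,max</sub> and V<sub>s,min</sub>, the surface averages ⟨V<sub>s</sub>⟩,
⟨V<sub>s</sub>⁺⟩, ⟨V<sub>s</sub>⁻⟩, the average deviation Π, the variances
σ²₊, σ²₋, σ²<sub>tot</sub>, and the balance parameter
ν = σ²₊σ²₋/(σ²<sub>tot</sub>)² ≤ ¼. These descriptors, together with the
LUMO energy, feed quantitative structure–activity (QSAR) regressions.

`msepqsar` implements that workflow end to end in R:

* **`cube_io`** — read/write Gaussian cube volumetric files (bohr and
  Angstrom dialects) and delimited descriptor/activity tables;
* **`esp_field`** — evaluate V(r) from point nuclei plus a numerically
  integrated density grid (an Ewald-style regularized quadrature accurate
  enough for the tiny surface potentials of near-neutral species), or from
  a precomputed potential grid;
* **`surface_extract`** — marching-tetrahedra isosurface meshes with
  secant-refined vertices and area-weighted centroid sampling;
* **`surface_stats`** — the full Politzer descriptor set;
* **`qsar`** — OLS fitting (`fit_ols`), SPSS-style forward stepwise
  selection (`stepwise_forward`), nested model-summary traces
  (`nested_model_trace`), prediction;
* **`synthetic_data`** — Gaussian model atoms and seeded linear-model
  tables with closed-form oracles for every stage.

The package ships, at printed precision, the 15-compound descriptor/activity
table of a published cytotoxicity study of substituted amides of
pyrazine-2-carboxylic acid (IC₅₀ of oxygen-evolution inhibition in spinach
chloroplasts), and reproduces that study's five-descriptor regression, its
predicted-activity column, and its stepwise model-summary trace.

## Worked example

```r
library(msepqsar)

tab <- read_descriptor_table(table1_path())
m <- fit_ols(tab, c("inv_vs_min", "lumo", "vs_mean", "vs_plus_mean",
                    "inv_vs_max"), "activity")
m
#> <qsar_model> activity ~ inv_vs_min + lumo + vs_mean + vs_plus_mean + inv_vs_max
#>   intercept: -2.46646
#>   inv_vs_min         lumo      vs_mean vs_plus_mean   inv_vs_max
#>    82.079653   -34.873266    -0.132227     0.139063     5.569576
#>   n = 15, R = 0.960, R2 = 0.922, R2adj = 0.878, SE = 0.0954
```

The refit recovers the published equation: activity rises with
1/V<sub>s,min</sub> (i.e. weaker negative surface potential), falls with
LUMO and ⟨V<sub>s</sub>⟩, and R² = 0.922 with a residual standard error of
0.095 mmol/dm³ matches the published fit statistics. Fitting the published
entry order as nested prefix models reproduces the published model summary:

```r
trace <- nested_model_trace(tab, c("lumo", "inv_vs_min", "vs_plus_mean",
                                   "vs_mean", "inv_vs_max"), "activity")
model_summary_table(trace)
#>                                                 Model     R R Square Adjusted R Square Std. Error of the Estimate
#> 1                                                lumo 0.232    0.054           -0.0187                     0.2761
#> 2                                    lumo, inv_vs_min 0.675    0.455            0.3641                     0.2182
#> 3                      lumo, inv_vs_min, vs_plus_mean 0.797    0.635            0.5361                     0.1863
#> 4             lumo, inv_vs_min, vs_plus_mean, vs_mean 0.936    0.876            0.8260                     0.1141
#> 5 lumo, inv_vs_min, vs_plus_mean, vs_mean, inv_vs_max 0.960    0.922            0.8784                     0.0954
```

Applying the published coefficients themselves
(`reference_qsar_model()`) to the printed descriptor rows reproduces the
printed predicted-activity column to ±0.002:

```r
head(cbind(actual = tab$activity,
           predicted = predict(reference_qsar_model(), tab)), 4)
#>      actual predicted
#> [1,]  1.070     0.916
#> [2,]  0.244     0.178
#> [3,]  0.486     0.476
#> [4,]  0.148     0.134
```

Surface descriptors from a density cube:

```r
spec <- gaussian_atom_spec(Z = pi^1.5, A = 1, alpha = 1)  # neutral model atom
gm <- make_gaussian_molecule(spec, spacing = 0.15, padding = 4.8)
surf <- extract_isosurface(gm$grid, isovalue = 0.001)
surf <- sample_potential_on_surface(surf, esp_source(gm$grid), gm$molecule)
compute_descriptors(surf)   # constant ~0.27 kcal/mol on this sphere
```

A batch front-end (`pipeline_descriptors()`, `pipeline_fit()`,
`pipeline_reproduce()`) and a thin command-line wrapper
(`inst/cli/msepqsar.R`, subcommands `descriptors`, `fit`, `reproduce`) sit
on top of these functions. See the vignette in `vignettes/` for the model,
the numerical choices and their rationale.

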