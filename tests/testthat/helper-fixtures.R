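# Shared fixtures and independent oracles. Heavy objects are built once per
# session and cached; everything is generated in code.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, builder(), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# neutral Gaussian model atom (Z equals the integrated cloud charge) at the
# reference resolution used for the closed-form surface checks
neutral_spec <- function() gaussian_atom_spec(Z = pi^1.5, A = 1, alpha = 1)

neutral_gm <- function() {
  cached("neutral_gm_015", function()
    make_gaussian_molecule(neutral_spec(), spacing = 0.15, padding = 4.8))
}

neutral_surface <- function() {
  cached("neutral_surface_015", function()
    extract_isosurface(neutral_gm()$grid, 0.001))
}

# the neutral-atom surface with potentials evaluated on a fixed random
# subset of faces (the full all-pairs evaluation is quadratic in problem
# size; a 1500-face subset pins the surface statistics well within the
# tolerances under test)
neutral_sampled_subset <- function(n_faces = 1500L) {
  cached("neutral_subset_sampled", function() {
    gm <- neutral_gm()
    surf <- neutral_surface()
    set.seed(20130415)
    pick <- sample(nrow(surf$triangles), n_faces)
    sub <- surf
    sub$vertices <- surf$vertices
    sub$triangles <- surf$triangles[pick, , drop = FALSE]
    sub$sample_points <- surf$sample_points[pick, , drop = FALSE]
    sub$sample_weights <- surf$sample_weights[pick]
    sample_potential_on_surface(sub, esp_source(gm$grid), gm$molecule)
  })
}

# a surface object from bare samples, for testing the descriptor statistics
# in isolation
fake_surface <- function(potentials, weights = rep(1, length(potentials))) {
  structure(
    list(vertices = matrix(0, 3, 3),
         triangles = matrix(1:3, 1, 3),
         sample_points = matrix(0, length(potentials), 3),
         sample_weights = weights,
         sample_potentials = potentials),
    class = "triangulated_surface"
  )
}

# independent OLS oracle: pseudo-inverse solve via SVD, no lm anywhere
ols_pinv <- function(X, y) {
  X1 <- cbind(1, X)
  sv <- svd(X1)
  coef <- sv$v %*% ((t(sv$u) %*% y) / sv$d)
  drop(coef)
}

table1 <- function() {
  cached("table1", function() read_descriptor_table(table1_path()))
}

descriptors5 <- c("inv_vs_min", "lumo", "vs_mean", "vs_plus_mean", "inv_vs_max")
table2_order <- c("lumo", "inv_vs_min", "vs_plus_mean", "vs_mean", "inv_vs_max")
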