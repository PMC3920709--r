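test_that("the Gaussian-atom isosurface reproduces the analytic sphere", {
  spec <- neutral_spec()
  surf <- neutral_surface()
  r0 <- analytic_isosurface_radius(spec, 0.001)
  expect_equal(surface_area(surf), 4 * pi * r0^2, tolerance = 0.02)
  radii <- sqrt(rowSums(surf$sample_points^2))
  expect_lt(max(abs(radii - r0)), 0.02)
})

test_that("degenerate inputs are rejected", {
  flat <- volumetric_grid(c(0, 0, 0), diag(0.5, 3),
                          array(1e-5, c(4, 4, 4)), field_kind = "density")
  expect_error(extract_isosurface(flat, 0.001), "empty")
  expect_error(extract_isosurface(flat, -1), "positive")
  expect_error(extract_isosurface(flat, 0), "positive")
})

test_that("well-separated atoms give two components with additive area", {
  s1 <- gaussian_atom_spec(Z = 1, A = 1, alpha = 2, center = c(-4, 0, 0))
  s2 <- gaussian_atom_spec(Z = 1, A = 1, alpha = 2, center = c(4, 0, 0))
  gm2 <- make_gaussian_molecule(list(s1, s2), spacing = 0.15, padding = 3.6)
  gm1 <- make_gaussian_molecule(s1, spacing = 0.15, padding = 3.6)
  a2 <- surface_area(extract_isosurface(gm2$grid, 0.001))
  a1 <- surface_area(extract_isosurface(gm1$grid, 0.001))
  expect_equal(a2, 2 * a1, tolerance = 0.02)
  # and each sample point clusters around one of the two centres
  surf <- extract_isosurface(gm2$grid, 0.001)
  d1 <- sqrt(rowSums(sweep(surf$sample_points, 2, s1$center)^2))
  d2 <- sqrt(rowSums(sweep(surf$sample_points, 2, s2$center)^2))
  r0 <- analytic_isosurface_radius(s1, 0.001)
  expect_true(all(pmin(d1, d2) < r0 + 0.2))
})

test_that("unrefined mesh area converges at second order", {
  spec <- neutral_spec()
  r0 <- analytic_isosurface_radius(spec, 0.001)
  err <- vapply(c(0.3, 0.15), function(h) {
    gm <- make_gaussian_molecule(spec, spacing = h, padding = 4.8)
    abs(surface_area(extract_isosurface(gm$grid, 0.001, refine = 0)) /
          (4 * pi * r0^2) - 1)
  }, numeric(1))
  order <- log2(err[1] / err[2]) / log2(2)
  expect_gt(order, 1.5)
})

test_that("mesh vertices sit on the density contour", {
  gm <- neutral_gm()
  spec <- neutral_spec()
  true_density <- function(v) spec$A * exp(-spec$alpha * rowSums(v^2))
  set.seed(3)

  # refined vertices: the exact density at each vertex is the isovalue to
  # well under the leading grid-sampling error
  surf <- neutral_surface()
  pick <- sample(nrow(surf$vertices), 2000)
  expect_lt(max(abs(true_density(surf$vertices[pick, ]) - 0.001)),
            0.001 * 0.05)

  # unrefined linear edge interpolation is looser: crossings on cell
  # diagonals see the full curvature of the density between corners
  surf0 <- extract_isosurface(gm$grid, 0.001, refine = 0)
  pick0 <- sample(nrow(surf0$vertices), 2000)
  expect_lt(max(abs(true_density(surf0$vertices[pick0, ]) - 0.001)),
            0.001 * 0.25)
  # and the trilinear field itself at those vertices is closer still
  dens0 <- trilinear_interpolate(gm$grid, surf0$vertices[pick0, ])
  expect_lt(max(abs(dens0 - 0.001)), 0.001 * 0.20)
})

test_that("extraction is translation-equivariant", {
  spec <- gaussian_atom_spec(Z = 1, A = 1, alpha = 2)
  shift <- c(0.37, -1.2, 2.05)
  gm <- make_gaussian_molecule(spec, spacing = 0.3, padding = 3.6)
  spec2 <- gaussian_atom_spec(Z = 1, A = 1, alpha = 2, center = shift)
  gm2 <- make_gaussian_molecule(spec2, spacing = 0.3, padding = 3.6)
  s1 <- extract_isosurface(gm$grid, 0.001)
  s2 <- extract_isosurface(gm2$grid, 0.001)
  expect_equal(sweep(s2$vertices, 2, shift), s1$vertices, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("trilinear interpolation is exact on linear fields and at nodes", {
  ax <- seq(0, 2, by = 0.4)
  f <- function(p) 2 * p[, 1] + 3 * p[, 2] - p[, 3]
  pts <- as.matrix(expand.grid(ax, ax, ax))
  grid <- volumetric_grid(c(0, 0, 0), diag(0.4, 3),
                          array(f(pts), dim = c(6, 6, 6)),
                          field_kind = "density")
  set.seed(11)
  q <- matrix(runif(60, 0.01, 1.99), 20, 3)
  expect_equal(trilinear_interpolate(grid, q), f(q), tolerance = 1e-12)
  # grid node returns the stored value exactly
  expect_identical(trilinear_interpolate(grid, c(0.4, 0.8, 1.2)),
                   grid$values[2, 3, 4])
  expect_error(trilinear_interpolate(grid, c(2.5, 0, 0)), "outside")
})

test_that("trilinear interpolation converges at second order on smooth fields", {
  g <- function(p) exp(-rowSums(p^2))
  err_at <- function(h) {
    n <- as.integer(2 * ceiling(2 / h)) + 1L
    o <- -(n - 1) / 2 * h
    ax <- o + (seq_len(n) - 1) * h
    pts <- as.matrix(expand.grid(ax, ax, ax))
    grid <- volumetric_grid(c(o, o, o), diag(h, 3),
                            array(g(pts), dim = c(n, n, n)),
                            field_kind = "density")
    set.seed(5)
    q <- matrix(runif(300, -1.5, 1.5), 100, 3)
    max(abs(trilinear_interpolate(grid, q) - g(q)))
  }
  order <- log2(err_at(0.2) / err_at(0.1))
  expect_gt(order, 1.8)
})

test_that("surface potentials are filled in kcal/mol, zero for a zero field", {
  gm <- make_gaussian_molecule(gaussian_atom_spec(Z = 1, A = 1, alpha = 2),
                               spacing = 0.3, padding = 3.6)
  surf <- extract_isosurface(gm$grid, 0.001)
  zero_pot <- volumetric_grid(gm$grid$origin, gm$grid$axes,
                              array(0, dim = gm$grid$shape),
                              field_kind = "potential")
  out <- sample_potential_on_surface(surf, esp_source(zero_pot), gm$molecule)
  expect_equal(out$sample_potentials, rep(0, nrow(surf$sample_points)))
  expect_error(sample_potential_on_surface(
    structure(list(sample_points = NULL), class = "triangulated_surface"),
    esp_source(zero_pot), gm$molecule), "no sample points")
})

test_that("OBJ export writes one v record per vertex and f per face", {
  gm <- make_gaussian_molecule(gaussian_atom_spec(Z = 1, A = 1, alpha = 2),
                               spacing = 0.4, padding = 3.6)
  surf <- extract_isosurface(gm$grid, 0.001)
  path <- withr::local_tempfile(fileext = ".obj")
  write_obj(surf, path)
  lines <- readLines(path)
  expect_identical(sum(startsWith(lines, "v ")), nrow(surf$vertices))
  expect_identical(sum(startsWith(lines, "f ")), nrow(surf$triangles))
})
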