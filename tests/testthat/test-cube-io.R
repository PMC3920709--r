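test_that("cube files round-trip molecules and grids to 1e-12", {
  set.seed(42)
  axes <- matrix(c(0.2, 0.01, 0, 0, 0.25, 0.02, 0.01, 0, 0.3), 3, 3,
                 byrow = TRUE)
  grid <- volumetric_grid(origin = c(-1, -2, 0.5), axes = axes,
                          values = array(rnorm(5 * 6 * 7), dim = c(5, 6, 7)),
                          field_kind = "density")
  mol <- molecule(atomic_number = c(6L, 1L, 8L),
                  nuclear_charge = c(6, 1, 8),
                  position = matrix(rnorm(9), 3, 3))
  path <- withr::local_tempfile(fileext = ".cube")
  write_cube(mol, grid, path)
  back <- read_cube(path)

  expect_identical(back$molecule$atoms$atomic_number, mol$atoms$atomic_number)
  expect_equal(back$molecule$atoms$nuclear_charge, mol$atoms$nuclear_charge,
               tolerance = 1e-13)
  expect_equal(as.matrix(back$molecule$atoms[, c("x", "y", "z")]),
               as.matrix(mol$atoms[, c("x", "y", "z")]),
               tolerance = 1e-13, ignore_attr = TRUE)
  expect_identical(back$grid$shape, grid$shape)
  expect_equal(back$grid$origin, grid$origin, tolerance = 1e-13)
  expect_equal(back$grid$axes, grid$axes, tolerance = 1e-13)
  expect_equal(back$grid$values, grid$values, tolerance = 1e-13)
  expect_identical(back$grid$field_kind, "density")

  # field kind survives a round trip for potentials too
  pot <- volumetric_grid(grid$origin, axes, grid$values, field_kind = "potential")
  write_cube(mol, pot, path)
  expect_identical(read_cube(path)$grid$field_kind, "potential")
})

test_that("malformed cubes are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".cube")
  # 2 x 2 x 2 header promising 8 values but carrying 7
  writeLines(c(
    "comment", "comment",
    "    1   0.0 0.0 0.0",
    "    2   0.5 0.0 0.0",
    "    2   0.0 0.5 0.0",
    "    2   0.0 0.0 0.5",
    "    1   1.0  0.0 0.0 0.0",
    " 1.0 2.0 3.0 4.0 5.0 6.0",
    " 7.0"), path)
  expect_error(read_cube(path), "truncated.*7 values.*promises 8")

  # molecular-orbital cube flag (negative atom count)
  writeLines(c(
    "comment", "comment",
    "   -1   0.0 0.0 0.0",
    "    2   0.5 0.0 0.0",
    "    2   0.0 0.5 0.0",
    "    2   0.0 0.0 0.5",
    "    1   1.0  0.0 0.0 0.0",
    "    1",
    " 1.0 2.0 3.0 4.0 5.0 6.0 7.0 8.0"), path)
  expect_error(read_cube(path), "orbital")

  writeLines(c("comment", "comment", "  1 junk here nope"), path)
  expect_error(read_cube(path), "fewer than 7|malformed")

  expect_error(read_cube(file.path(tempdir(), "does-not-exist.cube")),
               "no such file")
  # invariant violations at construction
  expect_error(volumetric_grid(c(0, 0, 0), matrix(0, 3, 3),
                               array(0, c(2, 2, 2))), "singular")
  expect_error(volumetric_grid(c(0, 0, 0), diag(3), array(0, c(1, 2, 2))),
               ">= 2")
  expect_error(volumetric_grid(c(0, 0, 0), diag(3), rep(0, 7),
                               shape = c(2, 2, 2)), "length 7")
})

test_that("Angstrom-convention cubes are converted to bohr", {
  path <- withr::local_tempfile(fileext = ".cube")
  writeLines(c(
    "comment", "comment",
    "    1   0.0 0.0 0.0",
    "   -2   1.0 0.0 0.0",
    "    2   0.0 1.0 0.0",
    "    2   0.0 0.0 1.0",
    "    1   1.0  1.0 0.0 0.0",
    " 1.0 2.0 3.0 4.0 5.0 6.0 7.0 8.0"), path)
  out <- read_cube(path)
  b <- 1.8897261254578281
  expect_equal(out$grid$axes[1, 1], b, tolerance = 1e-12)
  expect_equal(out$molecule$atoms$x[1], b, tolerance = 1e-12)
})

test_that("a synthetic Gaussian-atom cube reads back as written", {
  gm <- make_gaussian_molecule(gaussian_atom_spec(Z = 2, A = 0.5, alpha = 2),
                               spacing = 0.5, padding = 3.6)
  path <- withr::local_tempfile(fileext = ".cube")
  write_cube(gm$molecule, gm$grid, path)
  back <- read_cube(path)
  expect_identical(nrow(back$molecule$atoms), 1L)
  expect_identical(back$grid$field_kind, "density")
  expect_identical(back$grid$shape, gm$grid$shape)
  expect_equal(back$grid$values, gm$grid$values, tolerance = 1e-13)
})

test_that("the packaged shipped cube fixture parses", {
  fx <- system.file("extdata", "gaussian_atom_synthetic.cube",
                    package = "msepqsar")
  expect_true(nzchar(fx))
  out <- read_cube(fx)
  expect_identical(nrow(out$molecule$atoms), 1L)
  expect_identical(out$grid$field_kind, "density")
})

test_that("the packaged descriptor table matches its printed values", {
  tab <- table1()
  expect_s3_class(tab, "descriptor_table")
  expect_identical(nrow(tab), 15L)
  expect_equal(tab$activity[1], 1.070)
  expect_equal(tab$inv_vs_max[1], 0.036231884058, tolerance = 1e-12)
  expect_equal(tab$lumo[11], -0.14175)
  expect_equal(tab$vs_mean[11], 5.890)
})

test_that("descriptor-table parsing enforces schema and numeric cells", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,activity,inv_vs_max", p)
  expect_error(read_descriptor_table(p), "missing required column")

  writeLines("", p)
  expect_error(read_descriptor_table(p), "")

  writeLines(c("id,activity,inv_vs_max,inv_vs_min,lumo,vs_mean,vs_plus_mean",
               "1,0.5,0.02,-0.03,-0.1,1.0,5.0",
               "2,oops,0.02,-0.03,-0.1,1.0,5.0"), p)
  expect_error(read_descriptor_table(p), "row 2")

  # round trip through the writer
  tab <- table1()
  write_descriptor_table(tab, p)
  back <- read_descriptor_table(p)
  expect_equal(back$inv_vs_min, tab$inv_vs_min, tolerance = 1e-12)
})

test_that("packaged extrema reciprocals imply the narrated Vs ranges", {
  tab <- table1()
  expect_true(all(tab$inv_vs_max > 0))
  expect_true(all(tab$inv_vs_min < 0))
  vs_max <- 1 / tab$inv_vs_max
  vs_min <- 1 / tab$inv_vs_min
  expect_true(all(vs_max >= 19.6 & vs_max <= 99.6))
  expect_true(all(vs_min >= -47.15 & vs_min <= -21.2))
})
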