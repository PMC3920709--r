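#' Read a Gaussian cube file
#'
#' Parses the standard cube layout: two comment lines; a record with the atom
#' count and grid origin; three axis records (points-per-axis and step
#' vector); one record per atom (atomic number, nuclear charge, position);
#' then the scalar values with the third grid index varying fastest. A
#' negative point count on the first axis record marks Angstrom coordinates
#' (converted to bohr on read); a negative atom count marks a molecular
#' orbital cube, which this package does not interpret and rejects.
#'
#' The field kind (density vs potential) is not part of the cube format. If
#' the first comment line contains `density` or `potential` (as written by
#' [write_cube()]) it is honoured; otherwise `field_kind` applies.
#'
#' @param path path to a cube file.
#' @param field_kind fallback field kind when the header does not declare one.
#' @return A list with components `molecule` ([molecule()]) and `grid`
#'   ([volumetric_grid()]), geometry in bohr.
#' @seealso [write_cube()]
#' @export
read_cube <- function(path, field_kind = c("density", "potential")) {
  field_kind <- match.arg(field_kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L)
    stop("malformed cube header: fewer than 7 lines in ", path, call. = FALSE)

  comment1 <- lines[1]
  if (grepl("field_kind: density", comment1, fixed = TRUE)) field_kind <- "density"
  if (grepl("field_kind: potential", comment1, fixed = TRUE)) field_kind <- "potential"

  num_fields <- function(line, at) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
    if (length(x) == 0 || anyNA(x))
      stop(sprintf("malformed cube header at %s: '%s'", at, line), call. = FALSE)
    x
  }

  hdr <- num_fields(lines[3], "atom-count/origin line")
  if (length(hdr) < 4L)
    stop("malformed cube header at atom-count/origin line: ", lines[3], call. = FALSE)
  natoms <- as.integer(hdr[1])
  if (natoms < 0L)
    stop("molecular-orbital cube (negative atom count) is not supported",
         call. = FALSE)
  if (natoms == 0L)
    stop("cube declares zero atoms; a molecule needs at least one", call. = FALSE)
  origin <- hdr[2:4]

  shape <- integer(3)
  axes <- matrix(0, 3, 3)
  for (m in 1:3) {
    ax <- num_fields(lines[3 + m], sprintf("axis record %d", m))
    if (length(ax) < 4L)
      stop(sprintf("malformed cube header at axis record %d: %s", m, lines[3 + m]),
           call. = FALSE)
    shape[m] <- as.integer(ax[1])
    axes[m, ] <- ax[2:4]
  }
  angstrom <- shape[1] < 0L
  shape <- abs(shape)

  atoms <- matrix(0, natoms, 5)
  for (a in seq_len(natoms)) {
    rec <- num_fields(lines[6 + a], sprintf("atom record %d", a))
    if (length(rec) < 5L)
      stop(sprintf("malformed cube header at atom record %d: %s", a, lines[6 + a]),
           call. = FALSE)
    atoms[a, ] <- rec[1:5]
  }

  scale <- if (angstrom) BOHR_PER_ANGSTROM else 1
  origin <- origin * scale
  axes <- axes * scale
  pos <- atoms[, 3:5, drop = FALSE] * scale

  vals <- scan(text = paste(lines[-seq_len(6 + natoms)], collapse = "\n"),
               what = double(), quiet = TRUE)
  nexp <- prod(shape)
  if (length(vals) != nexp)
    stop(sprintf("cube value block truncated or padded: read %d values, header promises %d",
                 length(vals), nexp), call. = FALSE)
  # cube order: first index slowest, third fastest -> fill (n3,n2,n1), permute
  values <- aperm(array(vals, dim = rev(shape)), 3:1)

  list(
    molecule = molecule(atomic_number = as.integer(atoms[, 1]),
                        nuclear_charge = atoms[, 2], position = pos),
    grid = volumetric_grid(origin = origin, axes = axes, values = values,
                           shape = shape, field_kind = field_kind)
  )
}

#' Write a Gaussian cube file
#'
#' Emits the bohr (positive point-count) cube dialect, with enough digits
#' that [read_cube()] round-trips geometry and values to better than 1e-12
#' relative. The field kind is recorded in the first comment line so the
#' reader can recover it.
#'
#' @param molecule a [molecule()].
#' @param grid a [volumetric_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(molecule, grid, path) {
  stopifnot(inherits(molecule, "msep_molecule"), inherits(grid, "volumetric_grid"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path, call. = FALSE))
  on.exit(close(con))

  fnum <- function(x) sprintf(" %.15E", x)
  writeLines(c(
    sprintf("msepqsar cube (field_kind: %s)", grid$field_kind),
    "all coordinates in bohr; values with third index fastest",
    paste(sprintf("%5d", nrow(molecule$atoms)),
          fnum(grid$origin[1]), fnum(grid$origin[2]), fnum(grid$origin[3])),
    vapply(1:3, function(m)
      paste(sprintf("%5d", grid$shape[m]),
            fnum(grid$axes[m, 1]), fnum(grid$axes[m, 2]), fnum(grid$axes[m, 3])),
      character(1)),
    vapply(seq_len(nrow(molecule$atoms)), function(a)
      paste(sprintf("%5d", molecule$atoms$atomic_number[a]),
            fnum(molecule$atoms$nuclear_charge[a]),
            fnum(molecule$atoms$x[a]), fnum(molecule$atoms$y[a]),
            fnum(molecule$atoms$z[a])),
      character(1))
  ), con)

  # cube value order: third index fastest
  v <- as.vector(aperm(grid$values, 3:1))
  chunks <- split(v, (seq_along(v) - 1L) %/% 6L)
  writeLines(vapply(chunks, function(ch) paste(fnum(ch), collapse = ""),
                    character(1), USE.NAMES = FALSE), con)
  invisible(path)
}

#' Read a descriptor/activity table
#'
#' Reads a comma-separated QSAR table with header-driven column lookup. The
#' required columns are `id`, `activity` (IC50, mmol/dm^3), `inv_vs_max` and
#' `inv_vs_min` (reciprocal surface-potential extrema, mol/kcal), `lumo`, and
#' `vs_mean` and `vs_plus_mean` (surface-average potentials, kcal/mol); extra
#' columns are kept. Decimal points only, no locale-dependent parsing.
#'
#' The 15-compound pyrazine-2-carboxamide table packaged with this
#' distribution is available at
#' `system.file("extdata", "table1.csv", package = "msepqsar")`.
#'
#' @param path path to a CSV file.
#' @return A `data.frame` with one row per compound, classed
#'   `descriptor_table`.
#' @export
read_descriptor_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE),
    error = function(e) stop("cannot parse descriptor table: ",
                             conditionMessage(e), call. = FALSE))
  required <- c("id", "activity", "inv_vs_max", "inv_vs_min",
                "lumo", "vs_mean", "vs_plus_mean")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("descriptor table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  numeric_cols <- setdiff(required, "id")
  for (cl in numeric_cols) {
    x <- df[[cl]]
    if (!is.numeric(x)) {
      parsed <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(parsed) & !is.na(x))
      if (length(bad) > 0)
        stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                     cl, bad[1], x[bad[1]]), call. = FALSE)
      df[[cl]] <- parsed
    }
  }
  if (nrow(df) == 0) stop("descriptor table has no rows", call. = FALSE)
  class(df) <- c("descriptor_table", "data.frame")
  df
}

#' Write a descriptor/activity table
#'
#' @param table a data frame as returned by [read_descriptor_table()] or
#'   [descriptor_row()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Path to the packaged 15-compound descriptor/activity table
#'
#' @return File path of the packaged `table1.csv` fixture.
#' @export
table1_path <- function() {
  system.file("extdata", "table1.csv", package = "msepqsar", mustWork = TRUE)
}
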