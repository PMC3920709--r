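#' Conversion factor from hartree/e to kcal/mol per e
#'
#' The single point at which electrostatic potentials leave atomic units.
#' All internal geometry is in bohr and potentials are carried in hartree/e
#' until the descriptor stage converts once to kcal/mol.
#' @export
HARTREE_TO_KCAL <- 627.5095

BOHR_PER_ANGSTROM <- 1.8897261254578281

#' Construct a molecule: point nuclei plus optional frontier-orbital energy
#'
#' A molecule is an ordered set of atoms, each a point nucleus with an
#' atomic number, a nuclear charge (in elementary charge units, normally
#' equal to the atomic number) and a position in bohr. The optional `lumo`
#' scalar carries the lowest-unoccupied-molecular-orbital energy used as an
#' electronic QSAR descriptor; it is not computed by this package.
#'
#' @param atomic_number integer vector, one entry per atom (>= 1).
#' @param nuclear_charge numeric vector of nuclear charges (> 0); defaults
#'   to `atomic_number`.
#' @param position n x 3 numeric matrix of nuclear positions, bohr.
#' @param lumo optional scalar orbital energy (hartree by convention; stored
#'   as given).
#' @param compound_id optional label.
#' @return An object of class `msep_molecule`: a list with an `atoms`
#'   data frame (`atomic_number`, `nuclear_charge`, `x`, `y`, `z`), `lumo`
#'   and `compound_id`.
#' @examples
#' molecule(1, position = matrix(0, 1, 3))
#' @export
molecule <- function(atomic_number, nuclear_charge = atomic_number,
                     position, lumo = NULL, compound_id = NULL) {
  position <- matrix(as.numeric(position), ncol = 3)
  n <- nrow(position)
  atomic_number <- as.integer(rep_len(atomic_number, n))
  nuclear_charge <- as.numeric(rep_len(nuclear_charge, n))
  if (n < 1L) stop("a molecule needs at least one atom", call. = FALSE)
  if (any(atomic_number < 1L)) stop("atomic_number must be >= 1", call. = FALSE)
  if (any(nuclear_charge <= 0)) stop("nuclear_charge must be > 0", call. = FALSE)
  structure(
    list(
      atoms = data.frame(atomic_number = atomic_number,
                         nuclear_charge = nuclear_charge,
                         x = position[, 1], y = position[, 2], z = position[, 3]),
      lumo = lumo,
      compound_id = compound_id
    ),
    class = "msep_molecule"
  )
}

#' @export
print.msep_molecule <- function(x, ...) {
  cat(sprintf("<msep_molecule> %d atom(s)%s%s\n",
              nrow(x$atoms),
              if (!is.null(x$compound_id)) paste0(", id = ", x$compound_id) else "",
              if (!is.null(x$lumo)) sprintf(", LUMO = %.5f", x$lumo) else ""))
  invisible(x)
}

atom_positions <- function(molecule) {
  as.matrix(molecule$atoms[, c("x", "y", "z")])
}

#' Construct a volumetric scalar field on a regular lattice
#'
#' Represents an electron density (e/bohr^3) or electrostatic potential
#' (hartree/e) sampled on a regular, possibly skewed, lattice: the value at
#' index `(i, j, k)` (1-based) sits at
#' `origin + (i-1) a1 + (j-1) a2 + (k-1) a3`, with `a1, a2, a3` the rows of
#' `axes`.
#'
#' @param origin numeric 3-vector, bohr.
#' @param axes 3 x 3 numeric matrix; row `m` is the step vector of axis `m`
#'   in bohr. Must be nonsingular.
#' @param values numeric array of dimension `shape`, or a vector of length
#'   `prod(shape)` in R's column-major order (first index fastest).
#' @param shape integer 3-vector; each component >= 2. Defaults to
#'   `dim(values)`.
#' @param field_kind `"density"` or `"potential"`.
#' @return An object of class `volumetric_grid`.
#' @export
volumetric_grid <- function(origin, axes, values, shape = dim(values),
                            field_kind = c("density", "potential")) {
  field_kind <- match.arg(field_kind)
  origin <- as.numeric(origin)
  axes <- matrix(as.numeric(axes), 3, 3)
  if (length(origin) != 3L) stop("origin must be a 3-vector", call. = FALSE)
  if (is.null(shape)) stop("shape missing and values has no dim", call. = FALSE)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L))
    stop("shape must be three integers, each >= 2", call. = FALSE)
  if (abs(det(axes)) < 1e-14)
    stop("axes matrix is singular", call. = FALSE)
  if (length(values) != prod(shape))
    stop(sprintf("values length %d does not match shape %s (expected %d)",
                 length(values), paste(shape, collapse = "x"), prod(shape)),
         call. = FALSE)
  values <- array(as.numeric(values), dim = shape)
  structure(
    list(origin = origin, axes = axes, shape = shape, values = values,
         field_kind = field_kind),
    class = "volumetric_grid"
  )
}

#' @export
print.volumetric_grid <- function(x, ...) {
  cat(sprintf("<volumetric_grid> %s, %d x %d x %d, origin (%.3f, %.3f, %.3f) bohr\n",
              x$field_kind, x$shape[1], x$shape[2], x$shape[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  value range [%.4g, %.4g], voxel volume %.4g bohr^3\n",
              min(x$values), max(x$values), abs(det(x$axes))))
  invisible(x)
}

#' Physical coordinates of every lattice point of a grid
#'
#' @param grid a [volumetric_grid()].
#' @return `prod(shape)` x 3 matrix in bohr, in the same (column-major)
#'   order as `as.vector(grid$values)`.
#' @keywords internal
grid_points <- function(grid) {
  n <- grid$shape
  idx <- as.matrix(expand.grid(i = seq_len(n[1]) - 1L,
                               j = seq_len(n[2]) - 1L,
                               k = seq_len(n[3]) - 1L))
  sweep(idx %*% grid$axes, 2, grid$origin, `+`)
}

voxel_volume <- function(grid) abs(det(grid$axes))

as_points_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(as.numeric(points), ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix", call. = FALSE)
  storage.mode(points) <- "double"
  points
}
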