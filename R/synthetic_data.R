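# Synthetic inputs with closed-form answers.
#
# A "Gaussian atom" is a point nucleus of charge Z sitting in a spherical
# electron cloud rho(r) = A exp(-alpha r^2). Its 0.001-contour radius and
# its electrostatic potential have closed forms, which makes superpositions
# of such atoms exact oracles for the cube reader, the isosurface extractor
# and the potential evaluator. Real DFT densities (cusps, shell structure,
# anisotropy) are emphatically not emulated.

erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Specify a spherical Gaussian model atom
#'
#' @param Z nuclear charge (elementary charges).
#' @param A density amplitude at the centre, e/bohr^3.
#' @param alpha density decay exponent, bohr^-2.
#' @param center 3-vector, bohr.
#' @return An object of class `gaussian_atom_spec`; its `n_electrons`
#'   component holds the integrated cloud charge `N = A (pi/alpha)^(3/2)`.
#' @export
gaussian_atom_spec <- function(Z, A = 1, alpha = 1, center = c(0, 0, 0)) {
  stopifnot(Z > 0, A > 0, alpha > 0, length(center) == 3)
  structure(
    list(Z = Z, A = A, alpha = alpha, center = as.numeric(center),
         n_electrons = A * (pi / alpha)^1.5),
    class = "gaussian_atom_spec"
  )
}

#' Build a molecule and density grid from Gaussian model atoms
#'
#' Evaluates the exact superposition density at the lattice points of a
#' cubic-step grid that covers all atom centres plus `padding` on every
#' side, and pairs it with the corresponding point-nucleus molecule. The
#' padding must be generous enough that the density on the grid boundary is
#' negligible relative to the default 0.001 e/bohr^3 contour (below
#' 1e-6 times it), otherwise the isosurface would be clipped; a violation
#' raises a warning, or an error when `strict = TRUE`.
#'
#' @param specs list of [gaussian_atom_spec()] (a single spec is accepted).
#' @param spacing grid step, bohr.
#' @param padding box margin beyond the atom centres, bohr.
#' @param strict escalate the boundary-leak warning to an error.
#' @return list with `molecule` and `grid` (field kind `"density"`).
#' @export
make_gaussian_molecule <- function(specs, spacing = 0.15, padding = 4.8,
                                   strict = FALSE) {
  if (inherits(specs, "gaussian_atom_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, spacing > 0, padding > 0)
  centers <- do.call(rbind, lapply(specs, `[[`, "center"))
  lo <- apply(centers, 2, min) - padding
  hi <- apply(centers, 2, max) + padding
  shape <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  axes <- diag(spacing, 3)

  xs <- lo[1] + (seq_len(shape[1]) - 1) * spacing
  ys <- lo[2] + (seq_len(shape[2]) - 1) * spacing
  zs <- lo[3] + (seq_len(shape[3]) - 1) * spacing
  vals <- array(0, dim = shape)
  for (sp in specs) {
    dx2 <- (xs - sp$center[1])^2
    dy2 <- (ys - sp$center[2])^2
    dz2 <- (zs - sp$center[3])^2
    vals <- vals + sp$A * exp(-sp$alpha * (
      outer(outer(dx2, dy2, `+`), dz2, `+`)))
  }

  boundary_max <- max(vals[1, , ], vals[shape[1], , ],
                      vals[, 1, ], vals[, shape[2], ],
                      vals[, , 1], vals[, , shape[3]])
  if (boundary_max >= 1e-6 * 0.001) {
    msg <- sprintf("density leaks through the grid boundary (max %.3g e/bohr^3); increase padding",
                   boundary_max)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }

  mol <- molecule(
    atomic_number = vapply(specs, function(s) max(1L, as.integer(round(s$Z))),
                           integer(1)),
    nuclear_charge = vapply(specs, `[[`, numeric(1), "Z"),
    position = centers
  )
  list(molecule = mol,
       grid = volumetric_grid(origin = lo, axes = axes, values = vals,
                              shape = shape, field_kind = "density"))
}

#' Closed-form isosurface radius of a Gaussian model atom
#'
#' The contour `A exp(-alpha r^2) = isovalue` sits at
#' `r0 = sqrt(log(A / isovalue) / alpha)`.
#'
#' @param spec a [gaussian_atom_spec()].
#' @param isovalue contour level, e/bohr^3; must satisfy `0 < isovalue < A`.
#' @return radius, bohr.
#' @export
analytic_isosurface_radius <- function(spec, isovalue = 0.001) {
  stopifnot(inherits(spec, "gaussian_atom_spec"))
  if (isovalue <= 0 || isovalue >= spec$A)
    stop(sprintf("isovalue must lie in (0, A = %g)", spec$A), call. = FALSE)
  sqrt(log(spec$A / isovalue) / spec$alpha)
}

#' Closed-form electrostatic potential of a Gaussian model atom
#'
#' At distance r from the centre,
#' `V(r) = Z/r - N erf(sqrt(alpha) r)/r` (hartree/e), with
#' `N = A (pi/alpha)^(3/2)` the integrated cloud charge — the potential of
#' a point nucleus screened by a spherical Gaussian charge distribution.
#'
#' @param spec a [gaussian_atom_spec()].
#' @param r distance(s) from the centre, bohr; must be > 0.
#' @return potential, hartree/e.
#' @export
analytic_esp <- function(spec, r) {
  stopifnot(inherits(spec, "gaussian_atom_spec"))
  if (any(r <= 0)) stop("r must be positive (nucleus at r = 0)", call. = FALSE)
  (spec$Z - spec$n_electrons * erf_(sqrt(spec$alpha) * r)) / r
}

#' Generate a synthetic descriptor/activity table from a known linear model
#'
#' Draws each predictor column from an independent normal distribution and
#' sets `response = intercept + sum(beta * x) + N(0, noise_sd)`. Fully
#' reproducible given the seed; the global RNG state is left untouched.
#'
#' @param n_rows number of compounds; must exceed the number of
#'   coefficients + 1.
#' @param coefficients named numeric vector of true slopes; names become
#'   predictor columns.
#' @param intercept true intercept.
#' @param predictor_means,predictor_sds per-column normal moments, recycled.
#' @param noise_sd residual standard deviation (>= 0).
#' @param response name of the response column.
#' @param seed integer seed (default 20130415).
#' @return a `descriptor_table`-classed data frame with `id`, the predictor
#'   columns, and the response.
#' @export
make_qsar_table <- function(n_rows, coefficients, intercept = 0,
                            predictor_means = 0, predictor_sds = 1,
                            noise_sd = 0, response = "activity",
                            seed = 20130415) {
  stopifnot(n_rows > length(coefficients) + 1, noise_sd >= 0,
            !is.null(names(coefficients)))
  p <- length(coefficients)
  means <- rep_len(predictor_means, p)
  sds <- rep_len(predictor_sds, p)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  X <- vapply(seq_len(p), function(j) stats::rnorm(n_rows, means[j], sds[j]),
              numeric(n_rows))
  colnames(X) <- names(coefficients)
  y <- intercept + drop(X %*% coefficients) +
    stats::rnorm(n_rows, 0, noise_sd)
  df <- data.frame(id = seq_len(n_rows), X, check.names = FALSE)
  df[[response]] <- y
  class(df) <- c("descriptor_table", "data.frame")
  df
}
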