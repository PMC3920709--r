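#' Politzer statistical descriptors of the surface electrostatic potential
#'
#' Given the electrostatic potential sampled on the molecular surface,
#' computes the general-interaction-properties descriptor set:
#' the surface extrema `Vs,max` and `Vs,min`; the surface averages `<Vs>`,
#' `<Vs+>` (over positive-potential regions) and `<Vs->` (negative regions);
#' the average deviation
#' \deqn{\Pi = \overline{|V_s(\mathbf r) - \bar V_s|};}
#' the positive, negative and total variances
#' \deqn{\sigma^2_{tot} = \sigma^2_+ + \sigma^2_-, \quad
#'   \sigma^2_\pm = \overline{(V_s^\pm - \bar V_s^\pm)^2};}
#' and the balance parameter
#' \deqn{\nu = \sigma^2_+ \sigma^2_- / (\sigma^2_{tot})^2,}
#' which attains its maximum 1/4 when the two variances are equal.
#'
#' Averages are area-weighted by default (each face centroid carries its
#' triangle area), so the statistics are quadratures over the surface and do
#' not depend on mesh density; `weighting = "uniform"` gives the plain
#' point averages instead. Samples with `V = 0` belong to the positive
#' partition. If a partition is empty its mean is `NA` and its variance 0;
#' if the total variance is 0 then `nu = 0`.
#'
#' @param surface a `triangulated_surface` with `sample_potentials` set
#'   (kcal/mol).
#' @param weighting `"area"` (default) or `"uniform"`.
#' @return An object of class `surface_descriptors`: a list with `vs_max`,
#'   `vs_min`, `vs_mean`, `vs_plus_mean`, `vs_minus_mean`, `pi`,
#'   `sigma2_plus`, `sigma2_minus`, `sigma2_tot`, `nu`, `n_samples`,
#'   `positive_area_fraction`. Potentials in kcal/mol, variances in
#'   (kcal/mol)^2, `nu` dimensionless.
#' @export
compute_descriptors <- function(surface, weighting = c("area", "uniform")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(surface, "triangulated_surface"))
  v <- surface$sample_potentials
  if (is.null(v))
    stop("surface potentials have not been sampled; call sample_potential_on_surface() first",
         call. = FALSE)
  if (length(v) < 1L) stop("surface has no samples", call. = FALSE)
  w <- if (weighting == "area") surface$sample_weights else rep(1, length(v))
  w <- w / sum(w)

  wmean <- function(x, ww) sum(ww * x) / sum(ww)
  pos <- v >= 0
  neg <- !pos

  vs_mean <- wmean(v, w)
  vs_plus_mean <- if (any(pos)) wmean(v[pos], w[pos]) else NA_real_
  vs_minus_mean <- if (any(neg)) wmean(v[neg], w[neg]) else NA_real_
  pi_val <- wmean(abs(v - vs_mean), w)
  sigma2_plus <- if (any(pos)) wmean((v[pos] - vs_plus_mean)^2, w[pos]) else 0
  sigma2_minus <- if (any(neg)) wmean((v[neg] - vs_minus_mean)^2, w[neg]) else 0
  sigma2_tot <- sigma2_plus + sigma2_minus
  nu <- if (sigma2_tot == 0) 0 else sigma2_plus * sigma2_minus / sigma2_tot^2

  structure(
    list(vs_max = max(v), vs_min = min(v), vs_mean = vs_mean,
         vs_plus_mean = vs_plus_mean, vs_minus_mean = vs_minus_mean,
         pi = pi_val, sigma2_plus = sigma2_plus, sigma2_minus = sigma2_minus,
         sigma2_tot = sigma2_tot, nu = nu,
         n_samples = length(v),
         positive_area_fraction = sum(w[pos])),
    class = "surface_descriptors"
  )
}

#' @export
print.surface_descriptors <- function(x, ...) {
  cat("<surface_descriptors> (kcal/mol)\n")
  cat(sprintf("  Vs,max %8.3f   Vs,min %8.3f   <Vs> %8.3f\n",
              x$vs_max, x$vs_min, x$vs_mean))
  cat(sprintf("  <Vs+>  %8.3f   <Vs->  %8.3f   Pi   %8.3f\n",
              x$vs_plus_mean, x$vs_minus_mean, x$pi))
  cat(sprintf("  sigma2 +%7.3f  -%7.3f  tot %8.3f   nu %6.4f\n",
              x$sigma2_plus, x$sigma2_minus, x$sigma2_tot, x$nu))
  invisible(x)
}

#' Reciprocal surface-potential extrema
#'
#' The QSAR stage regresses activity on `1/Vs,max` and `1/Vs,min`
#' (mol/kcal), the form in which the reference descriptor table prints the
#' extrema.
#'
#' @param descriptors a [compute_descriptors()] result.
#' @return named numeric vector `c(inv_vs_max =, inv_vs_min =)`, mol/kcal.
#' @export
reciprocal_transform <- function(descriptors) {
  stopifnot(inherits(descriptors, "surface_descriptors"))
  if (descriptors$vs_max == 0 || descriptors$vs_min == 0)
    stop("cannot take the reciprocal of a zero surface-potential extremum",
         call. = FALSE)
  c(inv_vs_max = 1 / descriptors$vs_max, inv_vs_min = 1 / descriptors$vs_min)
}

#' One descriptor-table row for a molecule
#'
#' Flattens a descriptor set (plus the molecule's identity and LUMO) into
#' the CSV row layout used by the pipeline: id, extrema and their
#' reciprocals, surface averages, Pi, variances, nu, lumo.
#'
#' @param descriptors a [compute_descriptors()] result.
#' @param id compound label.
#' @param lumo optional orbital-energy scalar.
#' @return one-row `data.frame`.
#' @export
descriptor_row <- function(descriptors, id = NA_character_, lumo = NA_real_) {
  inv <- reciprocal_transform(descriptors)
  data.frame(
    id = id,
    vs_max = descriptors$vs_max, vs_min = descriptors$vs_min,
    inv_vs_max = unname(inv["inv_vs_max"]), inv_vs_min = unname(inv["inv_vs_min"]),
    vs_mean = descriptors$vs_mean,
    vs_plus_mean = descriptors$vs_plus_mean,
    vs_minus_mean = descriptors$vs_minus_mean,
    pi = descriptors$pi,
    sigma2_plus = descriptors$sigma2_plus,
    sigma2_minus = descriptors$sigma2_minus,
    sigma2_tot = descriptors$sigma2_tot,
    nu = descriptors$nu,
    lumo = if (is.null(lumo)) NA_real_ else lumo,
    stringsAsFactors = FALSE
  )
}
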