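#' Fit an ordinary-least-squares QSAR model
#'
#' Multiple linear regression of an activity column on a set of descriptor
#' columns, with intercept, solved by QR through [stats::lm()]. Reports the
#' usual QSAR model-summary statistics: `r2 = 1 - SSres/SStot`,
#' `r2_adj = 1 - (1 - r2)(n - 1)/(n - p - 1)`, the residual standard error
#' `se = sqrt(SSres/(n - p - 1))`, and coefficient standard errors from the
#' unscaled covariance matrix times `se^2`.
#'
#' @param table a data frame (e.g. from [read_descriptor_table()]).
#' @param predictors character vector of predictor column names.
#' @param response response column name.
#' @return An object of class `qsar_model`: `predictor_names`,
#'   `coefficients` (named, excluding the intercept), `intercept`,
#'   `coef_std_errors` (named, including `(Intercept)`), `n`, `r`, `r2`,
#'   `r2_adj`, `se`, `fitted`, `residuals`, and the underlying `fit`.
#' @examples
#' tab <- read_descriptor_table(table1_path())
#' fit_ols(tab, c("inv_vs_min", "lumo", "vs_mean", "vs_plus_mean", "inv_vs_max"),
#'         "activity")
#' @export
fit_ols <- function(table, predictors, response) {
  table <- as.data.frame(table)
  missing <- setdiff(c(predictors, response), names(table))
  if (length(missing) > 0)
    stop("table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  n <- nrow(table)
  p <- length(predictors)
  if (p < 1L) stop("at least one predictor is required", call. = FALSE)
  if (n <= p + 1L)
    stop(sprintf("too few observations for the degrees of freedom: n = %d, predictors = %d (need n > p + 1)",
                 n, p), call. = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", predictors),
                            response = as.name(response))
  fit <- stats::lm(fml, data = table)
  if (fit$rank < p + 1L) {
    aliased <- names(which(is.na(stats::coef(fit))))
    stop("collinear design matrix; dependent column(s): ",
         paste(gsub("`", "", aliased), collapse = ", "), call. = FALSE)
  }
  # summary.lm warns on exact fits; a zero-residual model is legitimate here
  sm <- suppressWarnings(summary(fit))
  cf <- stats::coef(fit)
  names(cf) <- gsub("`", "", names(cf))
  se_cf <- sm$coefficients[, "Std. Error"]
  names(se_cf) <- gsub("`", "", names(se_cf))
  r2 <- sm$r.squared
  structure(
    list(predictor_names = predictors,
         coefficients = cf[predictors],
         intercept = unname(cf["(Intercept)"]),
         coef_std_errors = se_cf,
         n = n, r = sqrt(r2), r2 = r2, r2_adj = sm$adj.r.squared,
         se = sm$sigma,
         fitted = unname(stats::fitted(fit)),
         residuals = unname(stats::residuals(fit)),
         response = response,
         fit = fit),
    class = "qsar_model"
  )
}

#' Assemble a QSAR model from published coefficients
#'
#' Builds a `qsar_model` directly from an intercept and named coefficients,
#' without fitting — used to apply a literature equation to new descriptor
#' values. Fit statistics are absent.
#'
#' @param intercept numeric intercept.
#' @param coefficients named numeric vector; names are descriptor columns.
#' @return a `qsar_model` usable with [predict.qsar_model()].
#' @export
qsar_model <- function(intercept, coefficients) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(coefficients), !is.null(names(coefficients)))
  structure(
    list(predictor_names = names(coefficients),
         coefficients = coefficients,
         intercept = intercept,
         coef_std_errors = NULL, n = NA_integer_, r = NA_real_,
         r2 = NA_real_, r2_adj = NA_real_, se = NA_real_,
         fitted = NULL, residuals = NULL, response = NULL, fit = NULL),
    class = "qsar_model"
  )
}

#' The reference five-descriptor cytotoxicity model
#'
#' The published QSAR equation for the inhibitory activity (IC50 of oxygen
#' evolution in spinach chloroplasts, mmol/dm^3) of 15 substituted
#' pyrazine-2-carboxamides:
#'
#' `IC50 = -2.467 + 82.101/Vs,min - 34.882 LUMO - 0.132 <Vs> + 0.139 <Vs+> + 5.569/Vs,max`
#'
#' with n = 15, R^2 = 0.922, adjusted R^2 = 0.879, SE = 0.095.
#'
#' @return a `qsar_model` carrying the published coefficients.
#' @export
reference_qsar_model <- function() {
  qsar_model(
    intercept = -2.467,
    coefficients = c(inv_vs_min = 82.101, lumo = -34.882, vs_mean = -0.132,
                     vs_plus_mean = 0.139, inv_vs_max = 5.569)
  )
}

#' Predict activity from a QSAR model
#'
#' Evaluates `intercept + sum(coefficient * descriptor)` per row.
#'
#' @param object a `qsar_model`.
#' @param table data frame containing the model's predictor columns.
#' @param ... unused.
#' @return numeric vector of predicted activities.
#' @export
predict.qsar_model <- function(object, table, ...) {
  table <- as.data.frame(table)
  missing <- setdiff(object$predictor_names, names(table))
  if (length(missing) > 0)
    stop("table is missing predictor column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  X <- as.matrix(table[, object$predictor_names, drop = FALSE])
  unname(drop(object$intercept + X %*% object$coefficients[object$predictor_names]))
}

#' @export
print.qsar_model <- function(x, ...) {
  cat("<qsar_model>", x$response %||% "(published coefficients)", "~",
      paste(x$predictor_names, collapse = " + "), "\n")
  cat("  intercept:", format(x$intercept, digits = 6), "\n")
  print(round(x$coefficients, 6))
  if (!is.na(x$r2))
    cat(sprintf("  n = %d, R = %.3f, R2 = %.3f, R2adj = %.3f, SE = %.4f\n",
                x$n, x$r, x$r2, x$r2_adj, x$se))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

partial_f_p <- function(small, big, table, response) {
  # p-value for the added predictor(s): F test comparing nested OLS fits
  a <- stats::anova(small$fit, big$fit)
  a[["Pr(>F)"]][2]
}

#' Forward stepwise descriptor selection by partial-F probability
#'
#' SPSS-style stepwise multiple linear regression: at each step the
#' candidate whose partial F test (against the current model) has the
#' smallest p-value enters if `p < p_enter`; after each entry, any included
#' predictor whose partial F p-value exceeds `p_remove` is removed (worst
#' first). Ties are broken by input order. Terminates when no entry or
#' removal occurs.
#'
#' @param table data frame of descriptors and response.
#' @param candidates character vector of candidate predictor columns.
#' @param response response column name.
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10); must be >= `p_enter`.
#' @return An object of class `stepwise_trace`: a list of steps, each with
#'   `action` (`"add"` or `"remove"`), `predictor`, and the `qsar_model`
#'   after the step.
#' @export
stepwise_forward <- function(table, candidates, response,
                             p_enter = 0.05, p_remove = 0.10) {
  if (p_enter <= 0 || p_enter > p_remove || p_remove > 1)
    stop("need 0 < p_enter <= p_remove <= 1", call. = FALSE)
  steps <- list()
  included <- character(0)
  if (length(candidates) == 0)
    return(structure(list(steps = steps, response = response),
                     class = "stepwise_trace"))
  repeat {
    moved <- FALSE
    # entry phase
    pool <- setdiff(candidates, included)
    if (length(pool) > 0 && nrow(table) > length(included) + 2L) {
      pvals <- vapply(pool, function(cand) {
        big <- fit_ols(table, c(included, cand), response)
        if (length(included) == 0) {
          summary(big$fit)$coefficients[2, "Pr(>|t|)"]
        } else {
          small <- fit_ols(table, included, response)
          partial_f_p(small, big, table, response)
        }
      }, numeric(1))
      best <- which.min(pvals)  # first index on ties
      if (is.finite(pvals[best]) && pvals[best] < p_enter) {
        included <- c(included, pool[best])
        steps[[length(steps) + 1L]] <- list(
          action = "add", predictor = pool[best],
          model = fit_ols(table, included, response))
        moved <- TRUE
      }
    }
    # removal phase
    repeat {
      if (length(included) < 2L) break
      full <- fit_ols(table, included, response)
      pvals <- vapply(included, function(v) {
        small <- fit_ols(table, setdiff(included, v), response)
        partial_f_p(small, full, table, response)
      }, numeric(1))
      worst <- which.max(pvals)
      if (pvals[worst] > p_remove) {
        removed <- included[worst]
        included <- setdiff(included, removed)
        steps[[length(steps) + 1L]] <- list(
          action = "remove", predictor = removed,
          model = fit_ols(table, included, response))
        moved <- TRUE
      } else break
    }
    if (!moved) break
  }
  structure(list(steps = steps, response = response), class = "stepwise_trace")
}

#' Fit the nested prefix models of a given descriptor order
#'
#' Evaluates a model-summary trace directly from a prescribed entry order:
#' fits the k-predictor prefix model for k = 1, ..., length(order). This is
#' the canonical way to reproduce a published stepwise model summary whose
#' entry order is known, independent of any selection thresholds.
#'
#' @param table data frame of descriptors and response.
#' @param ordered_predictors predictor columns in entry order.
#' @param response response column name.
#' @return a `stepwise_trace` whose k-th step holds the k-predictor model.
#' @export
nested_model_trace <- function(table, ordered_predictors, response) {
  steps <- lapply(seq_along(ordered_predictors), function(k)
    list(action = "add", predictor = ordered_predictors[k],
         model = fit_ols(table, ordered_predictors[seq_len(k)], response)))
  structure(list(steps = steps, response = response), class = "stepwise_trace")
}

#' Model-summary table of a stepwise trace
#'
#' @param trace a `stepwise_trace`.
#' @return data frame with columns `Model`, `R`, `R Square`,
#'   `Adjusted R Square`, `Std. Error of the Estimate`.
#' @export
model_summary_table <- function(trace) {
  stopifnot(inherits(trace, "stepwise_trace"))
  rows <- lapply(trace$steps, function(s) data.frame(
    Model = paste(s$model$predictor_names, collapse = ", "),
    R = s$model$r, `R Square` = s$model$r2,
    `Adjusted R Square` = s$model$r2_adj,
    `Std. Error of the Estimate` = s$model$se,
    check.names = FALSE))
  do.call(rbind, rows)
}

#' @export
print.stepwise_trace <- function(x, ...) {
  if (length(x$steps) == 0) {
    cat("<stepwise_trace> empty\n")
    return(invisible(x))
  }
  cat("<stepwise_trace>", length(x$steps), "step(s)\n")
  print(model_summary_table(x), digits = 4)
  invisible(x)
}
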