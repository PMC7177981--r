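#' Linear model of an outcome on pivot coordinates and covariates
#'
#' Ordinary least squares of a continuous outcome (e.g. zBMI) on the D-1
#' pivot coordinates of the time-use composition plus untransformed
#' covariates. The coordinate representation makes the model well posed
#' (raw part durations would be perfectly collinear); which part is the
#' pivot only rotates the coordinate block, so fitted values, residuals,
#' R-squared and any prediction are identical across pivot choices.
#'
#' @param data a [composition_set()] carrying the outcome (and covariates).
#' @param outcome name recorded for the outcome (metadata only; the values
#'   come from `data$outcome`).
#' @param covariates character vector of covariate columns to adjust for;
#'   default all stored covariates.
#' @param pivot_part part isolated in the first coordinate.
#' @return object of class `comp_model_fit`: `basis`, `beta`, `beta_cov`,
#'   `sigma2`, `residual_df`, `n`, `r_squared`, plus the underlying `lm`.
#' @export
fit_composition_model <- function(data, outcome = "outcome",
                                  covariates = names(data$covariates),
                                  pivot_part = NULL) {
  stopifnot(inherits(data, "composition_set"))
  if (is.null(data$outcome)) stop("the composition set has no outcome", call. = FALSE)
  basis <- as_pivot_basis(colnames(data$parts), pivot_part)
  z <- pivot_coordinates(data, basis)
  df <- data.frame(.y = data$outcome, z, check.names = FALSE)
  if (length(covariates)) {
    missing_cov <- setdiff(covariates, names(data$covariates))
    if (length(missing_cov))
      stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "), call. = FALSE)
    df <- cbind(df, data$covariates[covariates])
  }
  p <- ncol(df)  # intercept + (D-1) + covariates = ncol(df) - 1 + 1
  if (nrow(df) <= p)
    stop(sprintf("insufficient data: n = %d for %d coefficients", nrow(df), p),
         call. = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    dep <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; linearly dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  structure(list(
    basis = basis,
    beta = stats::coef(fit),
    beta_cov = stats::vcov(fit),
    sigma2 = sm$sigma^2,
    residual_df = fit$df.residual,
    n = nrow(df),
    r_squared = sm$r.squared,
    outcome = outcome,
    covariates = covariates %||% character(),
    coord_names = colnames(z),
    lm = fit
  ), class = "comp_model_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.comp_model_fit <- function(x, ...) {
  cat(sprintf("<comp_model_fit: %s ~ composition (pivot '%s') + %d covariate(s), n = %d>\n",
              x$outcome, x$basis$pivot_part, length(x$covariates), x$n))
  cat(sprintf("  sigma = %.4g, R^2 = %.4f, residual df = %d\n",
              sqrt(x$sigma2), x$r_squared, x$residual_df))
  print(round(x$beta, 4))
  invisible(x)
}

#' Coefficients of the composition coordinates
#' @param fit a `comp_model_fit`.
#' @return named vector of the D-1 pivot-coordinate coefficients.
#' @export
coord_coef <- function(fit) fit$beta[fit$coord_names]

#' Covariance of the coordinate coefficients
#' @param fit a `comp_model_fit`.
#' @export
coord_vcov <- function(fit) fit$beta_cov[fit$coord_names, fit$coord_names]

#' Per-part pivot coefficient table
#'
#' Refits the model once per part with that part as the pivot and reports
#' the first coordinate's estimate, standard error, t statistic and
#' two-sided p-value — the "part vs remaining" table. All D fits are the
#' same model viewed in rotated coordinates (identical fitted values and
#' R-squared), so no multiplicity adjustment is applied across rows.
#'
#' @inheritParams fit_composition_model
#' @return data frame with columns `pivot`, `estimate`, `se`, `t`, `p`, and
#'   attribute `fits` holding the D model fits.
#' @export
pivot_table <- function(data, outcome = "outcome",
                        covariates = names(data$covariates)) {
  parts <- colnames(data$parts)
  fits <- lapply(parts, function(pp)
    fit_composition_model(data, outcome, covariates, pivot_part = pp))
  rows <- lapply(seq_along(parts), function(i) {
    f <- fits[[i]]
    est <- f$beta[["z1"]]
    se <- sqrt(f$beta_cov["z1", "z1"])
    tval <- est / se
    data.frame(pivot = paste(parts[i], "vs Remaining"),
               estimate = est, se = se, t = tval,
               p = 2 * stats::pt(abs(tval), f$residual_df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Global test of the composition-outcome association
#'
#' Nested-model F test comparing the covariates-only model with the model
#' including all D-1 pivot coordinates. Invariant to the pivot choice
#' because every pivot basis spans the same coordinate space.
#'
#' @inheritParams fit_composition_model
#' @return list with `F`, `df` (numerator, denominator) and `p`.
#' @export
global_composition_test <- function(data, outcome = "outcome",
                                    covariates = names(data$covariates)) {
  full <- fit_composition_model(data, outcome, covariates)
  df0 <- data.frame(.y = data$outcome)
  if (length(covariates)) {
    df0 <- cbind(df0, data$covariates[covariates])
    reduced <- stats::lm(.y ~ ., data = df0)
  } else {
    reduced <- stats::lm(.y ~ 1, data = df0)
  }
  an <- stats::anova(reduced, full$lm)
  list(F = an$F[2], df = c(an$Df[2], an$Res.Df[2]), p = an$`Pr(>F)`[2])
}
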