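#' Specify a time reallocation
#'
#' Describes moving a fixed duration between activity behaviours while the
#' day's total stays at 24 h. Two modes: `"one-to-one"` moves the minutes
#' between two named parts leaving everything else untouched; a
#' `"one-for-remaining"` reallocation adds the minutes to one part and takes
#' them from all the others pro rata to their reference durations.
#'
#' @param to part(s) receiving time.
#' @param from part(s) giving time; for `one-for-remaining` leave `NULL`
#'   (all remaining parts donate).
#' @param minutes duration moved, in the units of the closure total; may be
#'   negative (reallocation in the opposite direction).
#' @param mode `"one-to-one"` or `"one-for-remaining"`.
#' @return object of class `reallocation`.
#' @export
reallocation <- function(to, from = NULL, minutes,
                         mode = c("one-to-one", "one-for-remaining")) {
  mode <- match.arg(mode)
  if (mode == "one-to-one") {
    if (length(to) != 1L || length(from) != 1L)
      stop("one-to-one reallocation needs exactly one `to` and one `from` part",
           call. = FALSE)
  } else {
    if (length(to) != 1L)
      stop("one-for-remaining reallocation needs exactly one `to` part", call. = FALSE)
  }
  if (length(intersect(to, from)))
    stop("`to` and `from` parts must be disjoint", call. = FALSE)
  if (!is.numeric(minutes) || length(minutes) != 1L || !is.finite(minutes))
    stop("`minutes` must be a single finite number", call. = FALSE)
  structure(list(to = to, from = from, minutes = minutes, mode = mode),
            class = "reallocation")
}

#' Apply a reallocation to a reference composition
#'
#' Plain arithmetic on durations: the moved minutes are added to the target
#' part and removed from the donor(s), so the total is preserved exactly.
#' Any part driven to zero or below makes the reallocation infeasible.
#'
#' @param reference the starting [composition()] (typically the
#'   compositional center of the analysis sample).
#' @param spec a [reallocation()].
#' @return the reallocated [composition()].
#' @export
reallocate <- function(reference, spec) {
  reference <- as_composition(reference)
  stopifnot(inherits(spec, "reallocation"))
  nm <- names(reference)
  unknown <- setdiff(c(spec$to, spec$from), nm)
  if (length(unknown))
    stop("unknown part(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  v <- stats::setNames(as.numeric(reference), nm)
  m <- spec$minutes
  if (spec$mode == "one-to-one") {
    v[spec$to] <- v[spec$to] + m
    v[spec$from] <- v[spec$from] - m
  } else {
    donors <- setdiff(nm, spec$to)
    share <- v[donors] / sum(v[donors])
    v[spec$to] <- v[spec$to] + m
    v[donors] <- v[donors] - m * share
  }
  bad <- names(v)[v <= 0]
  if (length(bad))
    stop("infeasible reallocation: part(s) driven to zero or below: ",
         paste(bad, collapse = ", "), call. = FALSE)
  composition(v, total = comp_total(reference))
}

#' Model-based isotemporal substitution estimate
#'
#' Predicted difference in the outcome between a reallocated day and the
#' reference day, from a fitted compositional model: with `dz` the
#' difference in pivot coordinates, the estimate is `dz' beta_z`; covariate
#' terms cancel in the difference, so no covariate values are needed. The
#' standard error is `sqrt(dz' Cov(beta_z) dz)` and the confidence interval
#' uses the t distribution on the model's residual degrees of freedom.
#' Because the coordinate-to-minutes map is non-linear, adding and removing
#' the same duration generally gives estimates of different magnitude.
#'
#' @param fit a [fit_composition_model()] result.
#' @param reference starting [composition()].
#' @param spec a [reallocation()].
#' @param level confidence level in (0, 1), default 0.95.
#' @return object of class `substitution_estimate`: `reference`,
#'   `reallocated`, `delta_hat`, `se`, `ci_low`, `ci_high`, `level`.
#' @export
substitution_estimate <- function(fit, reference, spec, level = 0.95) {
  stopifnot(inherits(fit, "comp_model_fit"))
  reference <- as_composition(reference)
  if (!setequal(names(reference), fit$basis$order))
    stop("fit and reference do not share part names", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("`level` must lie in (0, 1)", call. = FALSE)
  new <- reallocate(reference, spec)
  dz <- pivot_coordinates(new, fit$basis) - pivot_coordinates(reference, fit$basis)
  bz <- coord_coef(fit)
  delta <- sum(dz * bz)
  se <- sqrt(drop(t(dz) %*% coord_vcov(fit) %*% dz))
  tq <- stats::qt((1 + level) / 2, df = fit$residual_df)
  structure(list(reference = reference, reallocated = new,
                 delta_hat = delta, se = se,
                 ci_low = delta - tq * se, ci_high = delta + tq * se,
                 level = level, spec = spec),
            class = "substitution_estimate")
}

#' @export
print.substitution_estimate <- function(x, digits = 3, ...) {
  dir <- if (x$spec$mode == "one-to-one")
    sprintf("%+g min to %s from %s", x$spec$minutes, x$spec$to, x$spec$from)
  else sprintf("%+g min to %s from remaining", x$spec$minutes, x$spec$to)
  cat(sprintf("<substitution: %s>\n  delta = %.*f  [%.*f, %.*f] (%g%% CI)\n",
              dir, digits, x$delta_hat, digits, x$ci_low, digits, x$ci_high,
              100 * x$level))
  invisible(x)
}

#' Dose-response curve for a reallocation direction
#'
#' Substitution estimates over a grid of durations in one reallocation
#' direction. The curve is exactly linear in the pivot coordinate and
#' generally non-linear (asymptotic near the simplex edge) in minutes.
#' Infeasible grid points (driving a part to zero) are dropped with a
#' warning.
#'
#' @inheritParams substitution_estimate
#' @param minutes numeric grid of durations (positive and/or negative);
#'   default -120 to 120 by 5 min.
#' @return data frame `minutes`, `delta_hat`, `se`, `ci_low`, `ci_high`.
#' @export
reallocation_curve <- function(fit, reference, spec,
                               minutes = seq(-120, 120, by = 5),
                               level = 0.95) {
  rows <- lapply(minutes, function(m) {
    s <- spec; s$minutes <- m
    est <- tryCatch(substitution_estimate(fit, reference, s, level),
                    error = function(e) NULL)
    if (is.null(est)) return(NULL)
    data.frame(minutes = m, delta_hat = est$delta_hat, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(sprintf("%d infeasible grid point(s) dropped", dropped), call. = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no feasible grid points", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Predicted-outcome surface over the three-part simplex
#'
#' Absolute model predictions on a regular barycentric grid over the simplex
#' interior, at fixed covariate values (defaults: covariate sample means
#' from the fitted model). A margin keeps the grid away from the edges,
#' where logratio predictions diverge. Output joins ternary plotting
#' coordinates.
#'
#' @param fit a [fit_composition_model()] result.
#' @param total closure total of the grid compositions.
#' @param covariate_values named list/vector of covariate values; default
#'   the means of the covariates used in the fit.
#' @param resolution grid steps per triangle edge (default 100).
#' @param margin minimum proportion per part (default 0.01).
#' @return data frame: one column per part (closure units), `predicted`,
#'   and ternary `tx`, `ty`.
#' @export
response_surface <- function(fit, total = 1440, covariate_values = NULL,
                             resolution = 100L, margin = 0.01) {
  stopifnot(inherits(fit, "comp_model_fit"))
  parts <- colnames(fit$basis$contrast)
  if (length(parts) != 3L)
    stop("response surfaces need a three-part composition", call. = FALSE)
  if (is.null(covariate_values)) {
    mf <- stats::model.frame(fit$lm)
    covariate_values <- vapply(fit$covariates, function(v) mean(mf[[v]]), numeric(1))
  }
  covariate_values <- unlist(covariate_values)[fit$covariates]
  if (length(fit$covariates) && anyNA(covariate_values))
    stop("covariate values missing for: ",
         paste(fit$covariates[is.na(covariate_values)], collapse = ", "),
         call. = FALSE)
  steps <- seq(margin, 1 - 2 * margin, length.out = resolution)
  grid <- expand.grid(p1 = steps, p2 = steps)
  grid$p3 <- 1 - grid$p1 - grid$p2
  grid <- grid[grid$p3 >= margin, , drop = FALSE]
  p <- as.matrix(grid) * total
  colnames(p) <- parts
  z <- log(p) %*% t(fit$basis$contrast)
  cov_term <- if (length(fit$covariates))
    sum(fit$beta[fit$covariates] * covariate_values) else 0
  pred <- drop(fit$beta[["(Intercept)"]] + z %*% coord_coef(fit)) + cov_term
  xy <- ternary_xy_matrix(p / total, parts)
  out <- data.frame(p, predicted = pred, tx = xy[, 1], ty = xy[, 2],
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}
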