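#' Convert a variation matrix to a clr covariance matrix
#'
#' The variation matrix `T` (pairwise logratio variances) and the clr
#' covariance are equivalent second-moment descriptions of a compositional
#' sample, related by double centering: `Sigma = -1/2 * G T G` with
#' `G = I - 11'/D`. The round trip
#' `t_jk = Sigma_jj + Sigma_kk - 2 Sigma_jk` is exact. `Sigma` has zero row
#' and column sums and must be positive semi-definite on the clr subspace
#' for `T` to be realisable.
#'
#' @param T symmetric non-negative D x D matrix with zero diagonal.
#' @return D x D clr covariance matrix.
#' @export
variation_to_clr_cov <- function(T) {
  T <- as.matrix(T)
  D <- nrow(T)
  if (ncol(T) != D || any(abs(T - t(T)) > 1e-12) || any(diag(T) != 0) || any(T < 0))
    stop("`T` must be symmetric and non-negative with a zero diagonal", call. = FALSE)
  G <- diag(D) - matrix(1 / D, D, D)
  Sigma <- -0.5 * G %*% T %*% G
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev)))
    stop("inconsistent variation matrix: implied clr covariance is not PSD",
         call. = FALSE)
  dimnames(Sigma) <- dimnames(T)
  Sigma
}

#' Recover a variation matrix from a clr covariance
#' @param Sigma clr covariance matrix.
#' @return variation matrix `T`.
#' @export
clr_cov_to_variation <- function(Sigma) {
  outer(diag(Sigma), diag(Sigma), "+") - 2 * Sigma
}

#' Default generator configuration
#'
#' Calibration of the synthetic cohort to a three-part (Sleep, SB, PA)
#' child cohort: compositional center (617.5, 553.1, 269.4) min/day,
#' logratio variances 0.13 (Sleep-SB), 0.39 (Sleep-PA) and 0.78 (SB-PA),
#' per-part "vs remaining" pivot coefficients (-0.21, 0.19, 0.02) on a zBMI
#' outcome, and covariates age ~ N(10.9, 0.3), sex ~ Bernoulli(0.5),
#' SEP ~ N(0, 1). The residual SD (1.1768) was calibrated once,
#' analytically, so the expected global composition F statistic at
#' n = 3228 is about 4; the implied coefficient standard errors
#' (0.122, 0.086, 0.050) are then consistent with a cohort of this size.
#'
#' @param n cohort size (default 3228).
#' @param center compositional center of the generated parts.
#' @param variation variation matrix (pairwise logratio variances) of the
#'   parts.
#' @param beta per-part "part vs remaining" first-pivot coefficients; must
#'   sum to zero up to numerical tolerance (they are D views of one linear
#'   functional on the simplex, which forces the constraint).
#' @param beta0 outcome intercept.
#' @param gamma named covariate coefficients.
#' @param sigma residual SD of the outcome.
#' @param covariates list describing covariate distributions
#'   (`age_mean`, `age_sd`, `sex_prevalence`, `sep_mean`, `sep_sd`).
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n = 3228,
                             center = composition(
                               c(Sleep = 617.5, SB = 553.1, PA = 269.4), 1440),
                             variation = default_variation(names(center)),
                             beta = c(Sleep = -0.21, SB = 0.19, PA = 0.02),
                             beta0 = 0,
                             gamma = c(age = 0, sex = 0, sep = 0),
                             sigma = 1.1768,
                             covariates = list(age_mean = 10.9, age_sd = 0.3,
                                               sex_prevalence = 0.5,
                                               sep_mean = 0, sep_sd = 1)) {
  center <- as_composition(center)
  D <- length(center)
  variation <- as.matrix(variation)
  if (!identical(dim(variation), c(D, D)))
    stop("`variation` must be D x D", call. = FALSE)
  if (length(beta) != D || is.null(names(beta)) ||
      !setequal(names(beta), names(center)))
    stop("`beta` must name one 'vs remaining' coefficient per part", call. = FALSE)
  if (abs(sum(beta)) > 1e-8 * max(1, max(abs(beta))))
    stop("per-part pivot coefficients must sum to zero (they are D rotated ",
         "views of a single linear effect)", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  structure(list(n = as.integer(n), center = center, variation = variation,
                 beta = beta[names(center)], beta0 = beta0, gamma = gamma,
                 sigma = sigma, covariates = covariates),
            class = "generator_config")
}

default_variation <- function(parts = c("Sleep", "SB", "PA")) {
  T <- matrix(c(0, 0.13, 0.39,
                0.13, 0, 0.78,
                0.39, 0.78, 0), 3, 3, byrow = TRUE,
              dimnames = list(parts, parts))
  T
}

#' clr coefficient vector implied by per-part pivot coefficients
#'
#' The first pivot coordinate for part l has coefficient
#' `beta_l = sqrt(D/(D-1)) * b_l` where `b` is the (sum-zero) coefficient
#' vector of the linear predictor on the clr scale; this inverts that map.
#'
#' @param beta named per-part pivot coefficients summing to zero.
#' @return named clr coefficient vector `b`.
#' @export
pivot_beta_to_clr <- function(beta) {
  D <- length(beta)
  b <- beta * sqrt((D - 1) / D)
  b - mean(b)   # remove numerical dust; exact when input sums to zero
}

#' Generate a synthetic cohort
#'
#' Draws pivot coordinates from a multivariate normal with mean at the
#' configured center and covariance implied by the configured variation
#' matrix (the logratio-normal model), back-transforms them to strictly
#' positive closed compositions, draws covariates, and builds the outcome
#' as `beta0 + b' clr(x) + gamma' covariates + N(0, sigma^2)`. With a given
#' seed the output is reproducible bit for bit.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; required so every draw is reproducible.
#' @return a [composition_set()] with covariates and outcome.
#' @export
generate_cohort <- function(config = generator_config(), seed) {
  stopifnot(inherits(config, "generator_config"))
  if (missing(seed)) stop("an explicit `seed` is required", call. = FALSE)
  set.seed(seed)
  D <- length(config$center)
  basis <- pivot_basis(names(config$center))
  Sigma <- variation_to_clr_cov(config$variation)
  Sz <- basis$contrast %*% Sigma %*% t(basis$contrast)
  mu <- pivot_coordinates(config$center, basis)
  z <- MASS::mvrnorm(config$n, mu = mu, Sigma = Sz)
  if (config$n == 1L) z <- matrix(z, nrow = 1L)
  parts <- inverse_pivot(z, basis, total = comp_total(config$center))
  cv <- config$covariates
  covariates <- data.frame(
    age = stats::rnorm(config$n, cv$age_mean, cv$age_sd),
    sex = stats::rbinom(config$n, 1L, cv$sex_prevalence),
    sep = stats::rnorm(config$n, cv$sep_mean, cv$sep_sd)
  )
  b <- pivot_beta_to_clr(config$beta)
  clr_mat <- log(parts) - rowMeans(log(parts))
  lin <- config$beta0 + drop(clr_mat %*% b) +
    drop(as.matrix(covariates) %*% config$gamma[names(covariates)])
  outcome <- lin + stats::rnorm(config$n, 0, config$sigma)
  composition_set(parts, total = comp_total(config$center),
                  covariates = covariates, outcome = outcome)
}

#' Inject rounded zeros into a cohort table
#'
#' Rounds part values below a threshold down to zero and redistributes the
#' zeroed minutes over the remaining parts of the row (as a diary would:
#' the day still sums to 24 h), to exercise zero detection and replacement.
#' Returns a plain data frame — no longer a valid composition set until the
#' zeros are replaced.
#'
#' @param data a [composition_set()].
#' @param threshold duration below which a part is recorded as zero.
#' @return data frame in cohort-CSV layout with injected zeros.
#' @export
inject_zeros <- function(data, threshold) {
  df <- as.data.frame(data)
  parts <- part_names(data)
  m <- as.matrix(df[parts])
  z <- m < threshold
  keep_row <- rowSums(!z) > 0L
  m[z] <- 0
  rs <- rowSums(m)
  m[keep_row, ] <- m[keep_row, ] * (data$total / rs[keep_row])
  df[parts] <- m
  df
}
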