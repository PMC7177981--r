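#' Compositional center (closed geometric means)
#'
#' The natural mean on the simplex: the vector of per-part geometric means,
#' closed back to the shared total. It minimises mean squared Aitchison
#' distance to the sample and is invariant to per-row rescaling.
#'
#' @param data a [composition_set()].
#' @return a [composition()].
#' @export
compositional_center <- function(data) {
  stopifnot(inherits(data, "composition_set"))
  gm <- exp(colMeans(log(data$parts)))
  closure(gm, total = data$total, names = colnames(data$parts))
}

#' Variation array of a compositional data set
#'
#' Pairwise description of a compositional sample: the upper triangle holds
#' the variances of the logratios `var(ln(x_j/x_k))` (the variation matrix),
#' the lower triangle the means `mean(ln(x_j/x_k))`, and the compositional
#' center is attached. The mean logratios equal the logratios of the center
#' exactly, an identity the object's validity relies on.
#'
#' @param data a [composition_set()] with n >= 2.
#' @return object of class `variation_array` with elements `variances`
#'   (D x D, zero diagonal), `means` (D x D, antisymmetric), `center` and `n`.
#' @export
variation_array <- function(data) {
  stopifnot(inherits(data, "composition_set"))
  n <- n_rows(data)
  if (n < 2L) stop("variances need n >= 2", call. = FALSE)
  lx <- log(data$parts)
  D <- ncol(lx)
  nm <- colnames(lx)
  vars <- matrix(0, D, D, dimnames = list(nm, nm))
  mns <- matrix(0, D, D, dimnames = list(nm, nm))
  for (j in seq_len(D)) for (k in seq_len(D)) {
    if (j == k) next
    lr <- lx[, j] - lx[, k]
    vars[j, k] <- stats::var(lr)       # denominator n - 1
    mns[j, k] <- mean(lr)
  }
  structure(list(variances = vars, means = mns,
                 center = compositional_center(data), n = n),
            class = "variation_array")
}

#' @export
print.variation_array <- function(x, digits = 2, ...) {
  cat(sprintf("<variation_array: %d parts, n = %d>\n", ncol(x$variances), x$n))
  cat("upper triangle: logratio variances; lower: logratio means; last column: center\n")
  print(round(variation_table(x), digits))
  invisible(x)
}

#' Variation array in tabular layout
#'
#' Lays the array out as commonly printed: variances above the diagonal,
#' mean logratios below it, and the center (in closure units) as a final
#' column.
#'
#' @param va a [variation_array()].
#' @return a numeric matrix with a `center` column.
#' @export
variation_table <- function(va) {
  stopifnot(inherits(va, "variation_array"))
  D <- ncol(va$variances)
  out <- matrix(NA_real_, D, D,
                dimnames = list(rownames(va$variances), colnames(va$variances)))
  out[upper.tri(out)] <- va$variances[upper.tri(out)]
  out[lower.tri(out)] <- va$means[lower.tri(out)]
  cbind(out, center = as.numeric(va$center))
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between clr vectors (equivalently between pivot
#' coordinates, by isometry): the natural relative-scale metric of the
#' simplex. It is invariant to perturbation and to rescaling of either
#' argument.
#'
#' @param x,y compositions sharing part names.
#' @return non-negative scalar.
#' @export
aitchison_distance <- function(x, y) {
  x <- as_composition(x); y <- as_composition(y)
  check_same_parts(x, y)
  sqrt(sum((clr(x) - clr(y))^2))
}

#' Normalised index of compositional change
#'
#' Aitchison distance of every row to a reference composition, scaled to
#' [0, 1]. By default the normaliser is the in-sample maximum distance (so
#' the farthest row scores exactly 1); a fixed `max_distance` can be given
#' instead to keep indices comparable across samples.
#'
#' @param data a [composition_set()].
#' @param reference reference [composition()] (e.g. an earlier wave's center).
#' @param max_distance optional positive normaliser overriding the in-sample
#'   maximum.
#' @return numeric vector of length n in [0, 1].
#' @export
change_index <- function(data, reference, max_distance = NULL) {
  stopifnot(inherits(data, "composition_set"))
  reference <- as_composition(reference)
  if (!identical(colnames(data$parts), names(reference)))
    stop("reference parts do not match the data", call. = FALSE)
  cl <- log(data$parts) - rowMeans(log(data$parts))
  cr <- clr(reference)
  d <- sqrt(rowSums(sweep(cl, 2L, cr)^2))
  mx <- if (is.null(max_distance)) max(d) else max_distance
  if (mx == 0) return(rep(0, length(d)))
  d / mx
}

#' Logratio-normal predictive region
#'
#' Fits a multivariate normal to the pivot coordinates and returns the
#' back-transformed boundary of the prediction ellipse at the given level:
#' `{z : (z - mu)' S^{-1} (z - mu) = q}` with `q` the chi-square quantile on
#' D-1 degrees of freedom. For three parts the boundary is a closed curve
#' that always stays inside the simplex (returned as a matrix of
#' compositions plus ternary coordinates).
#'
#' @param data a [composition_set()] with three parts and n > 3.
#' @param level coverage level in (0, 1); may be a vector.
#' @param n_points points per boundary curve.
#' @return data frame with columns `level`, `point`, one column per part,
#'   and ternary `tx`, `ty`.
#' @export
predictive_region <- function(data, level = c(0.75, 0.95, 0.99),
                              n_points = 200L) {
  stopifnot(inherits(data, "composition_set"))
  D <- ncol(data$parts)
  if (D != 3L)
    stop("boundary tracing supports three parts only; use pivot_coordinates() ",
         "and region_fit() for D > 3", call. = FALSE)
  if (any(level <= 0 | level >= 1)) stop("levels must lie in (0, 1)", call. = FALSE)
  if (n_rows(data) <= D) stop("need n > D observations", call. = FALSE)
  fit <- region_fit(data)
  basis <- fit$basis
  L <- t(chol(fit$cov))
  th <- seq(0, 2 * pi, length.out = n_points)
  circ <- rbind(cos(th), sin(th))
  out <- lapply(level, function(lv) {
    q <- stats::qchisq(lv, df = D - 1L)
    z <- t(fit$mean + sqrt(q) * (L %*% circ))
    parts <- inverse_pivot(z, basis, total = data$total)
    xy <- ternary_xy_matrix(parts / data$total, colnames(parts))
    data.frame(level = lv, point = seq_len(n_points), parts, tx = xy[, 1],
               ty = xy[, 2], check.names = FALSE)
  })
  do.call(rbind, out)
}

#' Fitted mean and covariance of pivot coordinates
#'
#' The logratio-normal fit underlying [predictive_region()], usable for any
#' number of parts.
#'
#' @param data a [composition_set()].
#' @param pivot_part optional pivot part (default: first stored part).
#' @return list with `mean`, `cov` (of the pivot coordinates) and `basis`.
#' @export
region_fit <- function(data, pivot_part = NULL) {
  z <- pivot_coordinates(data, pivot_part)
  S <- stats::cov(z)
  if (!all(is.finite(S)) || det(S) <= .Machine$double.eps^2)
    stop("degenerate data: singular coordinate covariance", call. = FALSE)
  list(mean = colMeans(z), cov = S,
       basis = as_pivot_basis(colnames(data$parts), pivot_part))
}

#' Ternary plot coordinates for a three-part composition
#'
#' Barycentric-to-planar map onto an equilateral triangle of unit side with
#' corners (left, right, top) given by `corner_order`:
#' `x = p_right + p_top / 2`, `y = sqrt(3)/2 * p_top`.
#'
#' @param x a three-part composition.
#' @param corner_order character vector of the three part names in
#'   (left, right, top) order; defaults to stored order.
#' @return numeric `c(x, y)`.
#' @export
ternary_xy <- function(x, corner_order = NULL) {
  x <- as_composition(x)
  if (length(x) != 3L) stop("ternary coordinates need exactly three parts", call. = FALSE)
  if (is.null(corner_order)) corner_order <- names(x)
  if (!setequal(corner_order, names(x)) || length(corner_order) != 3L)
    stop("`corner_order` must name the three parts", call. = FALSE)
  p <- as.numeric(x)[match(corner_order, names(x))] / comp_total(x)
  c(x = p[2] + p[3] / 2, y = sqrt(3) / 2 * p[3])
}

ternary_xy_matrix <- function(p, parts, corner_order = parts) {
  p <- p[, match(corner_order, parts), drop = FALSE]
  cbind(x = p[, 2] + p[, 3] / 2, y = sqrt(3) / 2 * p[, 3])
}
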