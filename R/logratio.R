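#' Centered logratio (clr) transform
#'
#' `clr_j = ln(x_j / g(x))` with `g` the geometric mean of the parts. The
#' components sum to zero by construction and are perfectly collinear, so
#' they are suited to descriptive geometry (distances, covariance structure)
#' but not to use as regression predictors.
#'
#' @param x a [composition()] or strictly positive named vector.
#' @return named numeric vector of length D summing to zero.
#' @export
clr <- function(x) {
  x <- as_composition(x)
  lx <- log(as.numeric(x))
  stats::setNames(lx - mean(lx), names(x))
}

#' Inverse clr transform
#' @param v numeric clr vector (names become part names).
#' @param total closure constant of the result.
#' @return a [composition()].
#' @export
clr_inverse <- function(v, total = 1440) {
  if (any(!is.finite(v))) stop("non-finite clr values", call. = FALSE)
  closure(exp(v), total = total, names = names(v))
}

#' Additive logratio (alr) transform
#'
#' `ln(x_j / x_ref)` for every part j other than the reference part. Simple
#' to read but not an isometry of the simplex, so it is not used as the
#' default regression representation.
#'
#' @param x a composition.
#' @param denominator_part name of the reference (denominator) part.
#' @return named numeric vector of length D-1.
#' @export
alr <- function(x, denominator_part) {
  x <- as_composition(x)
  if (!denominator_part %in% names(x))
    stop("unknown part: ", denominator_part, call. = FALSE)
  others <- setdiff(names(x), denominator_part)
  stats::setNames(log(as.numeric(x)[match(others, names(x))] /
                        as.numeric(x)[match(denominator_part, names(x))]),
                  others)
}

#' Inverse alr transform
#' @param v named alr vector.
#' @param denominator_part name of the reference part.
#' @param total closure constant.
#' @return a [composition()] with the reference part restored in last position
#'   unless the names of `v` dictate otherwise.
#' @export
alr_inverse <- function(v, denominator_part, total = 1440) {
  vals <- c(exp(v), stats::setNames(1, denominator_part))
  closure(vals, total = total)
}

#' Pivot-coordinate basis
#'
#' Builds the (D-1) x D contrast matrix of the pivot (isometric logratio)
#' representation that isolates `pivot_part` in the first coordinate: the
#' parts are reordered so the pivot comes first (remaining parts keep their
#' stored order) and coordinate k contrasts part k against the geometric mean
#' of the later parts,
#' `z_k = sqrt((D-k)/(D-k+1)) * ln(x_(k) / gm(x_(k+1..D)))`.
#' Rows are orthonormal and sum to zero, so the map from clr space is an
#' isometry.
#'
#' @param parts character vector of part names in stored order.
#' @param pivot_part the part isolated in the first coordinate; defaults to
#'   the first stored part.
#' @return object of class `pivot_basis` with elements `order` (permutation
#'   of part names), `pivot_part` and `contrast` (the matrix, columns in
#'   stored part order).
#' @export
pivot_basis <- function(parts, pivot_part = parts[[1]]) {
  if (inherits(parts, "composition") || inherits(parts, "composition_set"))
    parts <- part_names(parts)
  D <- length(parts)
  if (D < 2L) stop("need at least two parts", call. = FALSE)
  if (!pivot_part %in% parts)
    stop("unknown pivot part: ", pivot_part, call. = FALSE)
  ord <- c(pivot_part, setdiff(parts, pivot_part))
  V <- matrix(0, D - 1L, D, dimnames = list(paste0("z", seq_len(D - 1L)), ord))
  for (k in seq_len(D - 1L)) {
    a <- sqrt((D - k) / (D - k + 1))
    V[k, k] <- a
    V[k, (k + 1L):D] <- -a / (D - k)
  }
  structure(list(pivot_part = pivot_part, order = ord,
                 contrast = V[, parts, drop = FALSE]),
            class = "pivot_basis")
}

#' @export
print.pivot_basis <- function(x, ...) {
  cat(sprintf("<pivot_basis: pivot '%s', order %s>\n", x$pivot_part,
              paste(x$order, collapse = " > ")))
  print(round(x$contrast, 4))
  invisible(x)
}

#' Pivot (isometric logratio) coordinates
#'
#' The first coordinate is the normalised log of the pivot part over the
#' geometric mean of all remaining parts ("pivot vs remaining"); it depends
#' only on which part is the pivot, not on the order of the rest.
#'
#' @param x a composition, or a `composition_set` (returns an n x (D-1)
#'   matrix).
#' @param pivot_part part isolated in the first coordinate, or a
#'   [pivot_basis()].
#' @return numeric vector of length D-1 (or matrix for a set).
#' @export
pivot_coordinates <- function(x, pivot_part = NULL) {
  if (inherits(x, "composition_set")) {
    b <- as_pivot_basis(colnames(x$parts), pivot_part)
    return(log(x$parts) %*% t(b$contrast))
  }
  x <- as_composition(x)
  b <- as_pivot_basis(names(x), pivot_part)
  drop(b$contrast %*% log(as.numeric(x)))
}

as_pivot_basis <- function(parts, pivot_part) {
  if (inherits(pivot_part, "pivot_basis")) {
    if (!setequal(pivot_part$order, parts))
      stop("basis part names do not match the data", call. = FALSE)
    return(pivot_part)
  }
  if (is.null(pivot_part)) pivot_part <- parts[[1]]
  pivot_basis(parts, pivot_part)
}

#' Inverse pivot transform
#'
#' Maps a coordinate vector back to the simplex: `x = closure(exp(t(V) z))`.
#' Exact inverse of [pivot_coordinates()] up to closure.
#'
#' @param z numeric vector of length D-1 (or matrix with D-1 columns).
#' @param basis a [pivot_basis()].
#' @param total closure constant of the result.
#' @return a [composition()] (or a parts matrix for matrix input) in stored
#'   part order.
#' @export
inverse_pivot <- function(z, basis, total = 1440) {
  if (!inherits(basis, "pivot_basis")) stop("`basis` must be a pivot_basis", call. = FALSE)
  if (any(!is.finite(z))) stop("non-finite coordinates", call. = FALSE)
  if (is.matrix(z)) {
    lx <- z %*% basis$contrast
    ex <- exp(lx - apply(lx, 1L, max))   # guard overflow far from the centre
    out <- ex / rowSums(ex) * total
    colnames(out) <- colnames(basis$contrast)
    return(out)
  }
  if (length(z) != nrow(basis$contrast))
    stop("coordinate length does not match the basis", call. = FALSE)
  lx <- drop(crossprod(basis$contrast, z))
  ex <- exp(lx - max(lx))
  closure(ex, total = total, names = colnames(basis$contrast))
}
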