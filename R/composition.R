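#' Construct a composition
#'
#' A composition is a vector of strictly positive parts (e.g. minutes/day of
#' Sleep, sedentary behaviour and physical activity) carrying only relative
#' information, stored closed to a fixed total (24 h = 1440 min by default).
#'
#' @param parts named numeric vector of strictly positive part values.
#' @param total positive closure constant the parts must sum to. Defaults to
#'   the sum of `parts`, i.e. the input is taken as already closed.
#' @return an object of class `composition`: a named numeric vector with a
#'   `total` attribute.
#' @seealso [closure()] to build a composition from unclosed values.
#' @export
composition <- function(parts, total = sum(parts)) {
  if (!is.numeric(parts) || length(parts) < 2L)
    stop("a composition needs at least two numeric parts", call. = FALSE)
  nm <- names(parts)
  if (is.null(nm)) nm <- paste0("part", seq_along(parts))
  if (anyDuplicated(nm)) stop("part names must be unique", call. = FALSE)
  if (!is.numeric(total) || length(total) != 1L || !is.finite(total) || total <= 0)
    stop("`total` must be a single positive number", call. = FALSE)
  bad <- which(!is.finite(parts) | parts <= 0)
  if (length(bad))
    stop("non-positive or non-finite part(s): ", paste(nm[bad], collapse = ", "),
         " (route zeros through replace_rounded_zeros() first)", call. = FALSE)
  s <- sum(parts)
  if (abs(s - total) > 1e-9 * total)
    stop(sprintf("parts sum to %.10g, not the stated total %.10g", s, total),
         call. = FALSE)
  x <- as.numeric(parts) * (total / s)  # exact renormalisation of rounding dust
  names(x) <- nm
  structure(x, total = total, class = "composition")
}

#' Closure: rescale positive values to a fixed total
#'
#' The closure operation divides each part by the sum and multiplies by the
#' closure constant, so part ratios are unchanged (scale invariance).
#'
#' @param values numeric vector of strictly positive values, length >= 2.
#' @param total positive closure constant (default 1440 min/day).
#' @param names optional part names; taken from `values` if named.
#' @return a [composition()] summing exactly to `total`.
#' @examples
#' closure(c(Sleep = 43, SB = 38, PA = 19), total = 100)
#' @export
closure <- function(values, total = 1440, names = NULL) {
  if (!is.null(names)) base::names(values) <- names
  if (length(values) < 2L)
    stop("closure needs at least two parts", call. = FALSE)
  if (all(values == 0)) stop("degenerate input: all parts are zero", call. = FALSE)
  nm <- base::names(values)
  if (is.null(nm)) nm <- paste0("part", seq_along(values))
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    stop("non-positive part(s): ", paste(nm[bad], collapse = ", "), call. = FALSE)
  out <- values / sum(values) * total
  base::names(out) <- nm
  structure(as.numeric(out), names = nm, total = total, class = "composition")
}

#' @export
print.composition <- function(x, digits = 4, ...) {
  cat(sprintf("<composition: %d parts, total %g>\n", length(x), comp_total(x)))
  print(round(stats::setNames(as.numeric(x), names(x)), digits))
  invisible(x)
}

#' Closure total of a composition
#' @param x a `composition`.
#' @return the closure constant.
#' @export
comp_total <- function(x) attr(x, "total")

#' Part names of a composition or composition set
#' @param x a `composition` or `composition_set`.
#' @return character vector of part names.
#' @export
part_names <- function(x) UseMethod("part_names")

as_composition <- function(x, total = NULL) {
  if (inherits(x, "composition")) return(x)
  composition(x, total = if (is.null(total)) sum(x) else total)
}

check_same_parts <- function(x, p) {
  if (!identical(names(x), names(p)))
    stop("compositions do not share part names: [",
         paste(names(x), collapse = ", "), "] vs [",
         paste(names(p), collapse = ", "), "]", call. = FALSE)
}

#' Perturbation: the simplex analogue of addition
#'
#' Componentwise product of two compositions followed by closure. Perturbing
#' by the neutral element (equal parts) returns the original composition;
#' perturbing by the inverse returns the neutral element.
#'
#' @param x,p compositions with identical part names.
#' @return a `composition` with the total of `x`.
#' @export
perturb <- function(x, p) {
  x <- as_composition(x); p <- as_composition(p)
  check_same_parts(x, p)
  closure(as.numeric(x) * as.numeric(p), total = comp_total(x), names = names(x))
}

#' Powering: the simplex analogue of scalar multiplication
#'
#' Componentwise power followed by closure. `powering(x, 1)` is `x`;
#' `powering(x, 0)` is the equal-parts neutral element.
#'
#' @param x a composition.
#' @param a real exponent.
#' @return a `composition` with the total of `x`.
#' @export
powering <- function(x, a) {
  x <- as_composition(x)
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a))
  closure(as.numeric(x)^a, total = comp_total(x), names = names(x))
}

#' Neutral element of the simplex (equal parts)
#' @param part_names character vector of part names.
#' @param total closure constant.
#' @return the equal-parts `composition`.
#' @export
neutral_composition <- function(part_names, total = 1440) {
  closure(rep(1, length(part_names)), total = total, names = part_names)
}

#' Perturbation inverse of a composition
#' @param x a composition.
#' @return the composition `p` with `perturb(x, p)` equal to the neutral element.
#' @export
comp_inverse <- function(x) {
  x <- as_composition(x)
  closure(1 / as.numeric(x), total = comp_total(x), names = names(x))
}

#' Amalgamate (merge) parts of a composition
#'
#' Sums named groups of parts into single parts, e.g. merging moderate and
#' vigorous physical activity into one PA part. Ungrouped parts are carried
#' through unchanged; the total is preserved.
#'
#' @param x a composition.
#' @param groups named list: new part name -> character vector of old parts.
#' @return a `composition` over the amalgamated parts.
#' @examples
#' x <- composition(c(Sleep = 600, SB = 540, MPA = 200, VPA = 100))
#' amalgamate(x, list(PA = c("MPA", "VPA")))
#' @export
amalgamate <- function(x, groups = list()) {
  x <- as_composition(x)
  if (!length(groups)) return(x)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("every group needs a new part name", call. = FALSE)
  old <- unlist(groups, use.names = FALSE)
  unknown <- setdiff(old, names(x))
  if (length(unknown))
    stop("unknown part name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (anyDuplicated(old))
    stop("part(s) listed in more than one group: ",
         paste(unique(old[duplicated(old)]), collapse = ", "), call. = FALSE)
  kept <- setdiff(names(x), old)
  vals <- c(stats::setNames(as.numeric(x)[match(kept, names(x))], kept),
            vapply(groups, function(g) sum(as.numeric(x)[match(g, names(x))]),
                   numeric(1)))
  # preserve original ordering: each group takes the slot of its first member
  pos <- c(match(kept, names(x)),
           vapply(groups, function(g) min(match(g, names(x))), numeric(1)))
  vals <- vals[order(pos)]
  composition(vals, total = comp_total(x))
}
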