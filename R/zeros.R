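#' Detect zeros in a raw cohort table
#'
#' Zeros make logratios undefined, so they must be found and treated before
#' any compositional analysis. In diary data most zeros are "rounded" —
#' below the instrument's time resolution rather than truly absent — and are
#' candidates for replacement; an all-zero row carries no relative
#' information at all and is flagged unrecoverable.
#'
#' @param table data frame or matrix holding the raw part columns.
#' @param parts character vector of the part column names.
#' @return object of class `zero_report`: per-part zero counts, per-row zero
#'   patterns, the fraction of affected rows and indices of unrecoverable
#'   (all-zero) rows.
#' @export
detect_zeros <- function(table, parts = colnames(table)) {
  m <- as.matrix(as.data.frame(table)[, parts, drop = FALSE])
  storage.mode(m) <- "double"
  iszero <- m == 0
  rows <- which(rowSums(iszero) > 0L)
  patterns <- lapply(rows, function(i) parts[iszero[i, ]])
  structure(list(
    part_counts = colSums(iszero),
    rows = rows,
    patterns = patterns,
    fraction_affected = length(rows) / nrow(m),
    unrecoverable = which(rowSums(iszero) == ncol(m))
  ), class = "zero_report")
}

#' @export
print.zero_report <- function(x, ...) {
  cat(sprintf("<zero_report: %d affected row(s), %.1f%% of sample>\n",
              length(x$rows), 100 * x$fraction_affected))
  if (length(x$rows)) {
    cat("zeros per part:\n"); print(x$part_counts)
  }
  if (length(x$unrecoverable))
    cat("unrecoverable all-zero rows:", paste(x$unrecoverable, collapse = ", "), "\n")
  invisible(x)
}

#' Multiplicative replacement of rounded zeros
#'
#' Each zero in part j becomes `delta_j = fraction * detection_limit_j`; the
#' non-zero parts of the same row are multiplied by
#' `1 - sum(delta) / row_total`, so the row total is preserved exactly and
#' the ratios among untouched parts are unchanged (the multiplicative
#' property that makes this the standard simple treatment in compositional
#' analysis). Zero-free rows pass through untouched.
#'
#' @param table data frame or matrix with the raw part columns; rows may
#'   contain zeros but every part must be non-negative.
#' @param parts character vector of part column names.
#' @param detection_limit per-part positive detection limits (recycled if
#'   length one); for diary data typically the instrument's time resolution,
#'   e.g. 1 min.
#' @param fraction fraction of the detection limit imputed (default 0.65,
#'   common practice).
#' @param total closure total of the returned [composition_set()]; default
#'   the per-row sums (rows are assumed already closed).
#' @param ... passed to [composition_set()] (covariates, outcome, ids).
#' @return a [composition_set()] with strictly positive parts.
#' @export
replace_rounded_zeros <- function(table, parts = colnames(table),
                                  detection_limit = 1, fraction = 0.65,
                                  total = NULL, ...) {
  m <- as.matrix(as.data.frame(table)[, parts, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative part values", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  dl <- rep_len(as.numeric(detection_limit), ncol(m))
  names(dl) <- parts
  zero_parts <- parts[colSums(m == 0) > 0L]
  if (any(!is.finite(dl[zero_parts]) | dl[zero_parts] <= 0))
    stop("positive detection limits required for parts with zeros: ",
         paste(zero_parts[dl[zero_parts] <= 0], collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(m))) {
    z <- m[i, ] == 0
    if (!any(z)) next
    if (all(z)) stop(sprintf("row %d is all zero: unrecoverable", i), call. = FALSE)
    delta <- fraction * dl[z]
    rt <- sum(m[i, ])
    if (sum(delta) >= rt)
      stop(sprintf("row %d: imputed total %.3g exceeds the row total %.3g",
                   i, sum(delta), rt), call. = FALSE)
    m[i, !z] <- m[i, !z] * (1 - sum(delta) / rt)
    m[i, z] <- delta
  }
  if (is.null(total)) {
    rs <- rowSums(m)
    if (max(rs) - min(rs) > 1e-6 * max(rs))
      stop("rows have differing totals; pass `total` explicitly", call. = FALSE)
    total <- rs[1]
  }
  composition_set(m, total = total, ...)
}
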