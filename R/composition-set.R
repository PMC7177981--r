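#' Construct a cohort of compositions
#'
#' A `composition_set` holds one composition per participant (rows of a
#' strictly positive matrix, all closed to the same total) together with
#' optional covariates and a continuous outcome.
#'
#' @param parts numeric matrix or data frame, one row per participant, one
#'   column per part; all entries strictly positive.
#' @param total shared closure constant (default 1440 min/day). Rows are
#'   renormalised to it exactly; a row off by more than `tolerance`
#'   (relative) is an error.
#' @param covariates optional data frame of per-row numeric covariates.
#' @param outcome optional numeric outcome vector (one per row).
#' @param ids optional row identifiers; defaults to `1:n`.
#' @param tolerance relative tolerance on each row sum before renormalising.
#' @return an object of class `composition_set`.
#' @export
composition_set <- function(parts, total = 1440, covariates = NULL,
                            outcome = NULL, ids = NULL, tolerance = 1e-9) {
  parts <- as.matrix(parts)
  storage.mode(parts) <- "double"
  if (is.null(colnames(parts)))
    colnames(parts) <- paste0("part", seq_len(ncol(parts)))
  if (ncol(parts) < 2L) stop("need at least two parts", call. = FALSE)
  if (nrow(parts) < 1L) stop("need at least one row", call. = FALSE)
  if (any(!is.finite(parts)) || any(parts <= 0))
    stop("all part values must be strictly positive and finite; ",
         "route zeros through replace_rounded_zeros() first", call. = FALSE)
  rs <- rowSums(parts)
  off <- abs(rs - total) / total
  if (any(off > tolerance))
    stop(sprintf("%d row(s) deviate from the closure total by more than %g (max %.3g)",
                 sum(off > tolerance), tolerance, max(off)), call. = FALSE)
  parts <- parts * (total / rs)
  n <- nrow(parts)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per composition", call. = FALSE)
    if (anyNA(covariates)) stop("covariates contain missing values", call. = FALSE)
  }
  if (!is.null(outcome)) {
    outcome <- as.numeric(outcome)
    if (length(outcome) != n) stop("outcome must have one value per row", call. = FALSE)
    if (anyNA(outcome)) stop("outcome contains missing values", call. = FALSE)
  }
  if (is.null(ids)) ids <- seq_len(n)
  if (length(ids) != n) stop("ids must have one value per row", call. = FALSE)
  structure(list(parts = parts, total = total, covariates = covariates,
                 outcome = outcome, ids = ids),
            class = "composition_set")
}

#' @export
print.composition_set <- function(x, ...) {
  cat(sprintf("<composition_set: n = %d, %d parts (%s), total %g>\n",
              n_rows(x), length(part_names(x)),
              paste(part_names(x), collapse = ", "), x$total))
  if (!is.null(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  if (!is.null(x$outcome)) cat("  outcome: present\n")
  invisible(x)
}

#' Number of rows (participants) in a composition set
#' @param data a `composition_set`.
#' @export
n_rows <- function(data) nrow(data$parts)

#' @rdname part_names
#' @export
part_names.composition_set <- function(x) colnames(x$parts)

#' @export
part_names.default <- function(x) names(x)

#' Extract one row as a composition
#' @param data a `composition_set`.
#' @param i row index.
#' @return a [composition()].
#' @export
comp_row <- function(data, i) {
  composition(stats::setNames(data$parts[i, ], colnames(data$parts)),
              total = data$total)
}

#' Convert a composition set to a data frame
#'
#' Binds ids, part columns, covariates and outcome into one data frame in
#' the layout used by [read_cohort()] and [write_cohort()].
#'
#' @param x a `composition_set`.
#' @param row.names,optional,... ignored (S3 signature).
#' @export
as.data.frame.composition_set <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  out <- data.frame(id = x$ids, as.data.frame(x$parts),
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$covariates)) out <- cbind(out, x$covariates)
  if (!is.null(x$outcome)) out$outcome <- x$outcome
  rownames(out) <- NULL
  out
}
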