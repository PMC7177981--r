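#' Read and validate a cohort table
#'
#' Reads a delimited text file (header row required), checks the declared
#' part columns, filters rows that cannot enter a compositional analysis,
#' and routes rounded zeros through multiplicative replacement. Filtering
#' is reported per reason: rows with missing outcome/covariates, rows whose
#' part sum deviates from the closure total by more than
#' `closure_tolerance` (relative), and all-zero rows. Rows off by no more
#' than the tolerance are renormalised to the total (diary rounding), with
#' the count logged.
#'
#' @param path input file.
#' @param parts character vector of part column names.
#' @param total closure constant (default 1440).
#' @param outcome optional outcome column name.
#' @param covariates optional covariate column names.
#' @param id optional id column name.
#' @param sep field delimiter (default `,`).
#' @param closure_tolerance relative slack on row sums before rejection
#'   (default 0.01).
#' @param detection_limit,fraction zero-replacement settings, see
#'   [replace_rounded_zeros()].
#' @param quiet suppress log messages.
#' @return list with `data` (a [composition_set()]), `zero_report` and
#'   `log` (named counts of rows read, kept and excluded per reason).
#' @export
read_cohort <- function(path, parts, total = 1440, outcome = NULL,
                        covariates = NULL, id = NULL, sep = ",",
                        closure_tolerance = 0.01,
                        detection_limit = 1, fraction = 0.65,
                        quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c(parts, outcome, covariates, id)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  n_read <- nrow(raw)
  note <- function(...) if (!quiet) message("read_cohort: ", sprintf(...))

  for (p in parts) raw[[p]] <- as.numeric(raw[[p]])
  keep <- rep(TRUE, n_read)
  n_missing <- 0L
  if (length(c(outcome, covariates))) {
    cc <- stats::complete.cases(raw[, c(outcome, covariates), drop = FALSE])
    n_missing <- sum(!cc)
    keep <- keep & cc
  }
  pm <- as.matrix(raw[, parts, drop = FALSE])
  bad_part <- rowSums(!is.finite(pm) | pm < 0) > 0L
  n_bad_part <- sum(bad_part & keep)
  keep <- keep & !bad_part
  all_zero <- rowSums(pm != 0, na.rm = TRUE) == 0L
  n_all_zero <- sum(all_zero & keep)
  keep <- keep & !all_zero
  off <- abs(rowSums(pm) - total) / total
  n_off <- sum(off > closure_tolerance & keep, na.rm = TRUE)
  keep <- keep & off <= closure_tolerance
  n_renorm <- sum(off[keep] > 1e-9)
  if (!any(keep)) stop("no rows survive ingestion filtering", call. = FALSE)

  raw <- raw[keep, , drop = FALSE]
  pm <- pm[keep, , drop = FALSE]
  pm <- pm * (total / rowSums(pm))
  if (n_missing) note("%d row(s) excluded: missing outcome/covariates", n_missing)
  if (n_bad_part) note("%d row(s) excluded: negative or non-numeric parts", n_bad_part)
  if (n_all_zero) note("%d row(s) excluded: all parts zero", n_all_zero)
  if (n_off) note("%d row(s) excluded: off the closure total by > %g%%",
                  n_off, 100 * closure_tolerance)
  if (n_renorm) note("%d row(s) renormalised to the closure total", n_renorm)

  zr <- detect_zeros(pm, parts)
  ids <- if (is.null(id)) seq_len(nrow(pm)) else raw[[id]]
  cov_df <- if (length(covariates)) raw[, covariates, drop = FALSE] else NULL
  out_v <- if (is.null(outcome)) NULL else as.numeric(raw[[outcome]])
  if (length(zr$rows)) {
    note("%d row(s) with rounded zeros replaced (delta = %g * detection limit)",
         length(zr$rows), fraction)
    data <- replace_rounded_zeros(pm, parts, detection_limit = detection_limit,
                                  fraction = fraction, total = total,
                                  covariates = cov_df, outcome = out_v, ids = ids)
  } else {
    data <- composition_set(pm, total = total, covariates = cov_df,
                            outcome = out_v, ids = ids)
  }
  list(data = data, zero_report = zr,
       log = c(read = n_read, kept = n_rows(data), missing = n_missing,
               bad_parts = n_bad_part, all_zero = n_all_zero,
               off_total = n_off, renormalised = n_renorm,
               zero_replaced = length(zr$rows)))
}

#' Write a cohort to CSV
#' @param data a [composition_set()].
#' @param path output file.
#' @export
write_cohort <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Write a variation array in tabular layout
#'
#' Upper triangle: logratio variances; lower triangle: logratio means;
#' final column: compositional center in closure units.
#'
#' @param va a [variation_array()].
#' @param path output file.
#' @export
write_variation_array <- function(va, path) {
  tab <- variation_table(va)
  df <- data.frame(part = rownames(tab), tab, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a per-part pivot coefficient table
#' @param pt a [pivot_table()] result.
#' @param path output file.
#' @export
write_pivot_table <- function(pt, path) {
  utils::write.csv(pt, path, row.names = FALSE)
  invisible(path)
}

#' Write substitution estimates
#' @param est a `substitution_estimate` or list of them.
#' @param path output file.
#' @export
write_substitution <- function(est, path) {
  if (inherits(est, "substitution_estimate")) est <- list(est)
  rows <- lapply(est, function(e) {
    data.frame(
      to = e$spec$to, from = paste(e$spec$from %||% "remaining", collapse = "+"),
      minutes = e$spec$minutes, mode = e$spec$mode,
      t(stats::setNames(as.numeric(e$reference),
                        paste0("ref_", names(e$reference)))),
      t(stats::setNames(as.numeric(e$reallocated),
                        paste0("new_", names(e$reallocated)))),
      delta = e$delta_hat, se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
      level = e$level, check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
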