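# Cohort container and delimited-text I/O.

#' Declare which columns play which analysis roles
#'
#' A role map names the columns of a patient-level table that act as the
#' binary exposure (treatment received, X), the binary instrument (e.g. the
#' physician's previous prescription, Z), the outcome columns, the covariate
#' columns used for balance diagnostics, and the cluster identifier
#' (physician/practice) used for cluster-robust variances.
#'
#' @param exposure name of the binary exposure column.
#' @param instrument name of the binary instrument column.
#' @param outcomes character vector of outcome column names (may be empty).
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param cluster name of the cluster identifier column.
#' @param weights optional name of a positive weight column.
#' @param binary_map optional named vector/list mapping raw exposure and
#'   instrument codes to 0/1, e.g. \code{c(NRT = 0, varenicline = 1)}.
#' @return an object of class \code{column_roles}.
#' @examples
#' column_roles(exposure = "x", instrument = "z", outcomes = "y",
#'              covariates = c("age", "male"), cluster = "doc")
#' @export
column_roles <- function(exposure, instrument, outcomes = character(),
                         covariates = character(), cluster,
                         weights = NULL, binary_map = NULL) {
  roles <- list(
    exposure = as.character(exposure),
    instrument = as.character(instrument),
    outcomes = as.character(outcomes),
    covariates = as.character(covariates),
    cluster = as.character(cluster),
    weights = if (!is.null(weights)) as.character(weights) else NULL,
    binary_map = binary_map
  )
  single <- c("exposure", "instrument", "cluster")
  for (r in single) {
    if (length(roles[[r]]) != 1L || is.na(roles[[r]]) || !nzchar(roles[[r]]))
      .stop_config(sprintf("role '%s' must name exactly one column", r))
  }
  named <- c(roles$exposure, roles$instrument, roles$cluster, roles$weights)
  if (anyDuplicated(named))
    .stop_config("exposure, instrument, cluster and weights columns must be distinct")
  if (!is.null(binary_map)) {
    bm <- unlist(binary_map)
    if (is.null(names(bm)) || !all(bm %in% c(0, 1)))
      .stop_config("binary_map must be a named mapping onto values 0 and 1")
  }
  structure(roles, class = "column_roles")
}

#' Build a validated cohort table from a data frame
#'
#' Validates a patient-level table against a role map: maps raw exposure and
#' instrument codes through \code{binary_map} when given, checks that both
#' are strictly 0/1 afterwards, coerces outcome and covariate columns to
#' numeric, and drops (with a counted report, never silently) rows with a
#' missing exposure, instrument or cluster id.  Missing values in outcome or
#' covariate columns are retained; each downstream estimator performs
#' complete-case analysis on the columns it actually uses and records the N
#' used.
#'
#' @param data a data frame.
#' @param roles a \code{\link{column_roles}} object.
#' @return an object of class \code{cohort_table}: a list with elements
#'   \code{data} (the validated data frame), \code{roles}, \code{n} (rows
#'   retained) and \code{n_rejected} (rows dropped for missing
#'   exposure/instrument/cluster).
#' @export
cohort_table <- function(data, roles) {
  if (!inherits(roles, "column_roles")) roles <- do.call(column_roles, roles)
  data <- as.data.frame(data)

  needed <- c(roles$exposure, roles$instrument, roles$cluster,
              roles$outcomes, roles$covariates, roles$weights)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    .stop_config(sprintf("role column(s) not found in data: %s",
                         paste(missing_cols, collapse = ", ")))

  # map raw codes to 0/1 for exposure and instrument
  map01 <- function(col, name) {
    x <- data[[col]]
    if (!is.null(roles$binary_map)) {
      bm <- unlist(roles$binary_map)
      idx <- match(as.character(x), names(bm))
      mapped <- unname(bm[idx])
      # values absent from the map pass through (they may already be 0/1)
      x2 <- suppressWarnings(as.numeric(as.character(x)))
      x <- ifelse(is.na(idx), x2, mapped)
    } else {
      x <- suppressWarnings(as.numeric(as.character(x)))
    }
    bad <- unique(x[!is.na(x) & !(x %in% c(0, 1))])
    orig_na <- is.na(data[[col]])
    coerce_na <- is.na(x) & !orig_na
    if (length(bad) || any(coerce_na)) {
      bad_raw <- unique(c(bad, as.character(data[[col]][coerce_na])))
      .stop_validation(sprintf(
        "column '%s' (%s role) is not binary after mapping; offending values: %s",
        col, name, paste(utils::head(bad_raw, 10L), collapse = ", ")))
    }
    x
  }
  data[[roles$exposure]] <- map01(roles$exposure, "exposure")
  data[[roles$instrument]] <- map01(roles$instrument, "instrument")

  for (col in unique(c(roles$outcomes, roles$covariates))) {
    x <- data[[col]]
    if (!is.numeric(x)) {
      xn <- suppressWarnings(as.numeric(as.character(x)))
      if (any(is.na(xn) & !is.na(x)))
        .stop_validation(sprintf(
          "column '%s' contains non-numeric values and cannot be used as outcome/covariate", col))
      data[[col]] <- xn
    }
  }
  if (!is.null(roles$weights)) {
    w <- data[[roles$weights]]
    if (!is.numeric(w) || any(!is.na(w) & w <= 0))
      .stop_validation(sprintf("weights column '%s' must be positive numeric",
                               roles$weights))
  }

  keep <- !(is.na(data[[roles$exposure]]) | is.na(data[[roles$instrument]]) |
              is.na(data[[roles$cluster]]))
  n_rejected <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  rownames(data) <- NULL

  if (nrow(data) < 2L)
    .stop_validation("cohort must contain at least 2 usable rows")
  z <- data[[roles$instrument]]
  if (!any(z == 1) || !any(z == 0))
    .stop_validation("instrument must have at least one row in each arm (Z=0 and Z=1)")

  structure(list(data = data, roles = roles,
                 n = nrow(data), n_rejected = n_rejected),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d rows (%d rejected on read), %d clusters\n",
              x$n, x$n_rejected, length(unique(x$data[[x$roles$cluster]]))))
  cat(sprintf("  exposure:   %s (prevalence %.3f)\n", x$roles$exposure,
              mean(x$data[[x$roles$exposure]])))
  cat(sprintf("  instrument: %s (prevalence %.3f)\n", x$roles$instrument,
              mean(x$data[[x$roles$instrument]])))
  if (length(x$roles$outcomes))
    cat("  outcomes:  ", paste(x$roles$outcomes, collapse = ", "), "\n")
  if (length(x$roles$covariates))
    cat("  covariates:", paste(x$roles$covariates, collapse = ", "), "\n")
  invisible(x)
}

# internal column accessors
.col <- function(cohort, role) cohort$data[[cohort$roles[[role]]]]
.colname <- function(cohort, name) {
  if (!name %in% names(cohort$data))
    .stop_config(sprintf("column '%s' not present in cohort", name))
  cohort$data[[name]]
}

#' Read a delimited cohort file
#'
#' Reads a CSV/TSV file with a header row and validates it with
#' \code{\link{cohort_table}}.  Rows with missing exposure, instrument or
#' cluster values are rejected and counted in the returned object's
#' \code{n_rejected} field.
#'
#' @param path path to a delimited text file (UTF-8, header required).
#' @param roles a \code{\link{column_roles}} object.
#' @param delimiter field separator, \code{","} (default) or \code{"\t"}.
#' @return a \code{\link{cohort_table}}.
#' @export
read_cohort <- function(path, roles, delimiter = ",") {
  if (!file.exists(path)) .stop_config(sprintf("input file not found: %s", path))
  data <- utils::read.delim(path, sep = delimiter, header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            fileEncoding = "UTF-8")
  cohort_table(data, roles)
}

#' Write a cohort table to a delimited file
#'
#' @param cohort a \code{\link{cohort_table}}.
#' @param path output path.
#' @param delimiter field separator.
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path, delimiter = ",") {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.table(cohort$data, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize a balance or negative-control report to delimited text
#'
#' Writes one row per covariate (balance report) or per outcome
#' (negative-control report) with estimates, confidence-interval bounds and,
#' where applicable, p-values.  Numbers are written with full double
#' precision and round-trip to at least 12 significant digits.
#'
#' @param report a \code{balance_report}, \code{nc_report} or
#'   \code{nc_outcome_result}.
#' @param path output path.
#' @param format \code{"csv"} or \code{"tsv"}.
#' @param ... passed to the report's \code{as.data.frame} method (e.g.
#'   \code{scale_binary}).
#' @return the path, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "tsv"), ...) {
  format <- match.arg(format)
  df <- as.data.frame(report, ...)
  if (is.null(df) || nrow(df) == 0L)
    .stop_validation("refusing to write an empty report")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  sep <- if (format == "csv") "," else "\t"
  tryCatch(
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8"),
    error = function(e) .ivb_stop(sprintf("cannot write report to '%s': %s",
                                          path, conditionMessage(e)),
                                  "ivb_io_error")
  )
  invisible(path)
}
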