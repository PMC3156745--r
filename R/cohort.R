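#' Construct and validate a patient cohort
#'
#' A cohort couples a patient table (one row per patient: identifier,
#' survival time in months, event indicator, ordinal covariates) with the
#' [variable_spec()]s declaring each covariate's admissible codes.
#' Validation enforces positive survival times, a 0/1 event flag (1 = death
#' observed, 0 = censored), unique patient identifiers, and covariate values
#' drawn from their declared codes; rows with missing values in any declared
#' covariate are rejected rather than imputed, since silently imputing in a
#' cohort of this size would distort the screening correlations.
#'
#' @param data a data.frame with columns `patient_id`, `survival_time`,
#'   `event`, and one column per declared variable.
#' @param specs a named list of [variable_spec()] objects.
#' @return an object of class `cohort`: a list with elements `data` (the
#'   validated table, row order preserved) and `specs`.
#' @examples
#' specs <- list(variable_spec("T", 1:4))
#' as_cohort(data.frame(patient_id = c("a", "b"),
#'                      survival_time = c(12, 40),
#'                      event = c(1, 0), T = c(3, 1)), specs)
#' @export
as_cohort <- function(data, specs) {
  specs <- as_spec_list(specs)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (col in c("patient_id", "survival_time", "event"))
    if (!col %in% names(data))
      stop("cohort format error: missing column '", col, "'")
  for (nm in names(specs))
    if (!nm %in% names(data))
      stop("cohort format error: missing column '", nm, "' declared in the variable spec")

  data$patient_id <- as.character(data$patient_id)
  if (anyDuplicated(data$patient_id))
    stop("cohort validation error: duplicated patient_id: ",
         paste(unique(data$patient_id[duplicated(data$patient_id)]), collapse = ", "))
  if (any(!is.finite(data$survival_time)) || any(data$survival_time <= 0))
    stop("cohort validation error: survival_time must be positive for all patients")
  if (!all(data$event %in% c(0, 1)))
    stop("cohort validation error: event must be 0 (censored) or 1 (death)")

  for (nm in names(specs)) {
    v <- data[[nm]]
    if (any(is.na(v)))
      stop("cohort validation error: missing value for variable '", nm,
           "' (patient ", paste(data$patient_id[is.na(v)], collapse = ", "),
           "); rows with missing screened variables are rejected, not imputed")
    bad <- !(v %in% specs[[nm]]$values)
    if (any(bad))
      stop("cohort validation error: inadmissible value for variable '", nm,
           "' (patient ", paste(data$patient_id[bad], collapse = ", "),
           "): ", paste(unique(v[bad]), collapse = ", "),
           " not in {", paste(specs[[nm]]$values, collapse = ","), "}")
    data[[nm]] <- as.integer(v)
  }

  structure(list(data = data, specs = specs), class = "cohort")
}

#' Read a cohort from CSV plus a variable-spec file
#'
#' The CSV must carry a header row with columns `patient_id`,
#' `survival_time`, `event`, and one column per variable declared in the
#' spec file (comma-separated, `.` decimal, UTF-8).
#'
#' @param path path to the cohort CSV.
#' @param spec_path path to the JSON/YAML variable-spec file
#'   (see [read_variable_specs()]).
#' @return a validated [as_cohort()] object, row order preserved.
#' @export
read_cohort <- function(path, spec_path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  specs <- read_variable_specs(spec_path)
  data <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_cohort(data, specs)
}

#' Write a result table (or a cohort's patient table) to CSV
#'
#' @param rows a non-empty data.frame (or a `cohort`, whose patient table is
#'   written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (inherits(rows, "cohort")) rows <- rows$data
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L || ncol(rows) == 0L)
    stop("write_table: refusing to write an empty table")
  ok <- tryCatch({
    write.csv(rows, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("write_table: cannot write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  d <- x$data
  cat(sprintf("<cohort> %d patients, %d variables (%s)\n",
              nrow(d), length(x$specs), paste(names(x$specs), collapse = ", ")))
  cat(sprintf("  events: %d observed deaths, %d censored\n",
              sum(d$event == 1), sum(d$event == 0)))
  cat(sprintf("  survival time: median %.1f months (range %.1f-%.1f)\n",
              stats::median(d$survival_time), min(d$survival_time),
              max(d$survival_time)))
  invisible(x)
}

#' @export
summary.cohort <- function(object, ...) {
  d <- object$data
  grp <- assign_survival_group(d$survival_time, d$event)
  out <- list(
    n = nrow(d), n_event = sum(d$event == 1), n_censored = sum(d$event == 0),
    groups = table(grp),
    variables = lapply(object$specs, function(sp) table(factor(d[[sp$name]], levels = sp$values)))
  )
  class(out) <- "summary.cohort"
  out
}

#' @export
print.summary.cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d patients (%d deaths, %d censored)\n",
              x$n, x$n_event, x$n_censored))
  cat("Survival groups (<=12 / 12-60 / >=60 months):",
      paste(sprintf("%s=%d", names(x$groups), x$groups), collapse = "  "), "\n")
  cat("Covariate margins:\n")
  for (nm in names(x$variables)) {
    tb <- x$variables[[nm]]
    cat(sprintf("  %-7s %s\n", nm,
                paste(sprintf("%s:%d", names(tb), tb), collapse = " ")))
  }
  invisible(x)
}

# Internal: numeric covariate matrix for the named variables (column order =
# candidates), plus survival vectors.  Used on hot paths (screening, LOO).
cohort_matrix <- function(cohort, candidates) {
  stopifnot(inherits(cohort, "cohort"))
  missing <- setdiff(candidates, names(cohort$specs))
  if (length(missing))
    stop("unknown variable(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(cohort$data[candidates])
  storage.mode(X) <- "double"
  list(X = X,
       time = as.numeric(cohort$data$survival_time),
       event = as.integer(cohort$data$event),
       id = cohort$data$patient_id,
       divisors = vapply(cohort$specs[candidates], `[[`, 0L, "divisor"))
}
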