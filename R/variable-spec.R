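#' Declare an ordinal study variable
#'
#' A variable spec records the admissible integer codes of an ordinal
#' covariate (e.g. tumour size T in 1--4, nodal status N in 0--3, metastasis
#' M in 0/1, biomarker staining grades 1--4) and the scale divisor used to
#' normalise it onto \eqn{[0, 1]} before entering the composite score.  The
#' divisor is always the number of admissible codes, so variables measured on
#' different scales become comparable ("divide by two for M and H, by four
#' for the others").
#'
#' @param name variable name, matching the cohort column.
#' @param values strictly increasing integer vector of admissible codes.
#' @return an object of class `variable_spec` with elements `name`,
#'   `values` and `divisor` (`= length(values)`).
#' @examples
#' variable_spec("T", 1:4)
#' variable_spec("M", 0:1)
#' @seealso [scale_value()], [read_variable_specs()]
#' @export
variable_spec <- function(name, values) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(values) < 2L)
    stop("variable_spec '", name, "': need at least two admissible values")
  if (any(values != as.integer(values)))
    stop("variable_spec '", name, "': admissible values must be integers")
  values <- as.integer(values)
  if (any(diff(values) <= 0L))
    stop("variable_spec '", name, "': admissible values must be strictly increasing")
  structure(
    list(name = name, values = values, divisor = length(values)),
    class = "variable_spec"
  )
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s: {%s}, divisor %d\n",
              x$name, paste(x$values, collapse = ","), x$divisor))
  invisible(x)
}

#' Read variable specifications from a JSON or YAML file
#'
#' The file maps each variable name to its vector of admissible integer
#' codes, e.g. `{"T": [1,2,3,4], "M": [0,1]}`.  The format is chosen by file
#' extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param path path to a JSON or YAML file.
#' @return a named list of [variable_spec()] objects.
#' @export
read_variable_specs <- function(path) {
  if (!file.exists(path)) stop("variable spec file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml  = ,
    yaml = yaml::read_yaml(path),
    stop("unsupported variable spec format '", ext, "' (use .json, .yml or .yaml)")
  )
  if (!length(raw) || is.null(names(raw)) || any(!nzchar(names(raw))))
    stop("variable spec file must map variable names to admissible values")
  specs <- lapply(names(raw), function(nm) variable_spec(nm, unlist(raw[[nm]])))
  names(specs) <- names(raw)
  specs
}

#' Write variable specifications to JSON
#'
#' @param specs named list of [variable_spec()] objects.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_variable_specs <- function(specs, path) {
  specs <- as_spec_list(specs)
  jsonlite::write_json(lapply(specs, `[[`, "values"), path)
  invisible(path)
}

#' Default variable specifications for an NSCLC-style cohort
#'
#' Tumour size `T` (1--4), nodal status `N` (0--3), metastasis `M` (0/1),
#' histology `H` (1 = squamous cell, 2 = adenocarcinoma) and the
#' immunohistochemistry staining grades (1--4) of the five tumour-associated
#' proteins CD68, Gas6, Notch3, MMP2 and Cox2.
#'
#' @return a named list of [variable_spec()] objects.
#' @export
default_variable_specs <- function() {
  specs <- list(
    variable_spec("T", 1:4),
    variable_spec("N", 0:3),
    variable_spec("M", 0:1),
    variable_spec("H", 1:2),
    variable_spec("CD68", 1:4),
    variable_spec("Gas6", 1:4),
    variable_spec("Notch3", 1:4),
    variable_spec("MMP2", 1:4),
    variable_spec("Cox2", 1:4)
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Scale an ordinal value onto the unit interval
#'
#' Divides a covariate value by its number of possible realizations, the
#' normalisation used before values enter the composite score (M = 1 with
#' divisor 2 gives 0.5; T = 4 with divisor 4 gives 1).
#'
#' @param value integer covariate value(s), admissible for `spec`.
#' @param spec a [variable_spec()].
#' @return `value / spec$divisor`, in \eqn{[0, 1]} for the supported codings.
#' @export
scale_value <- function(value, spec) {
  stopifnot(inherits(spec, "variable_spec"))
  bad <- !(value %in% spec$values)
  if (any(bad))
    stop("value ", paste(unique(value[bad]), collapse = ", "),
         " not admissible for variable '", spec$name, "'")
  value / spec$divisor
}

# Coerce a list of specs (possibly unnamed) to a named spec list.
as_spec_list <- function(specs) {
  if (inherits(specs, "variable_spec")) specs <- list(specs)
  ok <- is.list(specs) && length(specs) &&
    all(vapply(specs, inherits, TRUE, "variable_spec"))
  if (!ok) stop("expected a list of variable_spec objects")
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}
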