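#' Define a categorical covariate schema for survey simulation
#'
#' A schema lists the categorical covariates of a survey, the ordered category
#' labels of each, which label is the reference level for dummy coding, and the
#' marginal probability of each label. The schema drives both the synthetic
#' covariate sampler ([sample_covariates()]) and the dummy coding used by the
#' model design ([design_spec()]).
#'
#' @param ... Named arguments, one per covariate. Each value is a list with
#'   elements `levels` (character vector, length >= 2), `probs` (numeric vector
#'   of marginal probabilities, same length, non-negative, summing to 1), and
#'   optionally `reference` (one of `levels`; defaults to the first level).
#'
#' @return An object of class `covariate_schema`: a named list of variable
#'   definitions, each with `levels`, `probs`, `reference`.
#'
#' @examples
#' sch <- covariate_schema(
#'   constipation = list(levels = c("no", "yes"), probs = c(0.8, 0.2)),
#'   age_band = list(
#'     levels = c("20-39", "40-59", "60+"),
#'     probs = c(0.45, 0.35, 0.20)
#'   )
#' )
#' sample_covariates(sch, n = 5, seed = 1)
#' @export
covariate_schema <- function(...) {
  vars <- list(...)
  if (length(vars) == 1L && is.null(names(vars)) && is.list(vars[[1]]) &&
      !is.null(names(vars[[1]])) && is.list(vars[[1]][[1]])) {
    # allow covariate_schema(list(a = ..., b = ...))
    vars <- vars[[1]]
  }
  if (length(vars) == 0L) {
    abort("a schema needs at least one covariate", class = "zicount_schema_error")
  }
  if (is.null(names(vars)) || any(names(vars) == "")) {
    abort("every covariate in a schema must be named", class = "zicount_schema_error")
  }
  out <- lapply(names(vars), function(nm) validate_schema_variable(nm, vars[[nm]]))
  names(out) <- names(vars)
  structure(out, class = "covariate_schema")
}

validate_schema_variable <- function(name, v) {
  if (!is.list(v) || is.null(v$levels) || is.null(v$probs)) {
    abort(
      paste0("covariate '", name, "': must be a list with `levels` and `probs`"),
      class = "zicount_schema_error"
    )
  }
  levels <- as.character(v$levels)
  probs <- as.numeric(v$probs)
  if (length(levels) < 2L) {
    abort(
      paste0("covariate '", name, "': needs at least 2 levels"),
      class = "zicount_schema_error"
    )
  }
  if (anyDuplicated(levels)) {
    abort(
      paste0("covariate '", name, "': duplicated level labels"),
      class = "zicount_schema_error"
    )
  }
  if (length(probs) != length(levels) || any(probs < 0) ||
      abs(sum(probs) - 1) > 1e-9) {
    abort(
      paste0(
        "covariate '", name,
        "': `probs` must be non-negative, match `levels` in length, and sum to 1"
      ),
      class = "zicount_schema_error"
    )
  }
  reference <- v$reference %||% levels[[1]]
  if (!reference %in% levels) {
    abort(
      paste0("covariate '", name, "': reference '", reference,
             "' is not among the levels"),
      class = "zicount_schema_error"
    )
  }
  list(levels = levels, probs = probs, reference = as.character(reference))
}

#' @export
print.covariate_schema <- function(x, ...) {
  cat("<covariate_schema> with", length(x), "variables\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(
      sprintf(
        "  %s: %s (ref: %s)\n", nm,
        paste0(v$levels, "=", format(v$probs, digits = 3), collapse = ", "),
        v$reference
      )
    )
  }
  invisible(x)
}

is_covariate_schema <- function(x) inherits(x, "covariate_schema")

#' Sample categorical covariates from a schema
#'
#' Draws `n` independent respondents; each covariate is drawn independently
#' from its stated marginal probabilities. Draws are reproducible given `seed`.
#'
#' @param schema A [covariate_schema()].
#' @param n Number of rows to draw (>= 1).
#' @param seed Integer seed; if `NULL`, the current RNG state is used.
#'
#' @return A tibble with `n` rows and one character column per covariate.
#' @export
sample_covariates <- function(schema, n, seed = NULL) {
  if (!is_covariate_schema(schema)) {
    schema <- covariate_schema(schema)
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    abort("`n` must be a single integer >= 1", class = "zicount_schema_error")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  cols <- lapply(schema, function(v) {
    v$levels[sample.int(length(v$levels), size = n, replace = TRUE, prob = v$probs)]
  })
  as_tibble(cols)
}
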