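#' Declare the design of the two model sections
#'
#' A design spec maps categorical covariates to dummy-coded design columns for
#' the count section (log link on the mean, coefficients `beta`) and, for
#' zero-inflated families, the logit section (structural-zero probability,
#' coefficients `gamma`). Dummy coding drops exactly the reference level of
#' each variable; column order is deterministic: intercept first, then each
#' variable in declared order, its non-reference levels in schema order.
#'
#' @param variables Named list describing each covariate: either a
#'   [covariate_schema()] or a list of `list(levels = ..., reference = ...)`
#'   entries (`reference` defaults to the first level).
#' @param count_terms Character vector of variable names entering the count
#'   section. Defaults to all variables.
#' @param zero_terms Character vector of variable names entering the logit
#'   (zero) section. Defaults to `count_terms`. May differ from `count_terms`.
#' @param count_intercept,zero_intercept Include an intercept in each section?
#'   Both default to `TRUE`.
#'
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(variables, count_terms = NULL, zero_terms = NULL,
                        count_intercept = TRUE, zero_intercept = TRUE) {
  if (is_covariate_schema(variables)) {
    variables <- lapply(variables, function(v) {
      list(levels = v$levels, reference = v$reference)
    })
  }
  if (is.null(names(variables)) || any(names(variables) == "")) {
    abort("`variables` must be a named list", class = "zicount_design_error")
  }
  var_names <- names(variables)
  variables <- lapply(var_names, function(nm) {
    v <- variables[[nm]]
    levels <- as.character(v$levels)
    reference <- as.character(v$reference %||% levels[[1]])
    if (length(levels) < 2L || !reference %in% levels) {
      abort(
        paste0("variable '", nm, "': needs >= 2 levels and a reference among them"),
        class = "zicount_design_error"
      )
    }
    list(levels = levels, reference = reference)
  })
  names(variables) <- var_names
  abort_if <- function(terms, which) {
    bad <- setdiff(terms, names(variables))
    if (length(bad)) {
      abort(
        paste0(which, " terms not in `variables`: ", paste(bad, collapse = ", ")),
        class = "zicount_design_error"
      )
    }
  }
  count_terms <- count_terms %||% names(variables)
  zero_terms <- zero_terms %||% count_terms
  abort_if(count_terms, "count")
  abort_if(zero_terms, "zero")
  structure(
    list(
      variables = variables,
      count_terms = count_terms,
      zero_terms = zero_terms,
      count_intercept = isTRUE(count_intercept),
      zero_intercept = isTRUE(zero_intercept)
    ),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>\n")
  cat("  count section:", if (x$count_intercept) "(Intercept) +" else "",
      paste(x$count_terms, collapse = " + "), "\n")
  cat("  zero  section:", if (x$zero_intercept) "(Intercept) +" else "",
      paste(x$zero_terms, collapse = " + "), "\n")
  invisible(x)
}

is_design_spec <- function(x) inherits(x, "design_spec")

#' Column names of one design section
#'
#' @param design A [design_spec()].
#' @param section `"count"` or `"zero"`.
#' @return Character vector of design-column names, e.g. `"(Intercept)"`,
#'   `"constipationyes"`.
#' @export
design_columns <- function(design, section = c("count", "zero")) {
  section <- match.arg(section)
  terms <- if (section == "count") design$count_terms else design$zero_terms
  intercept <- if (section == "count") design$count_intercept else design$zero_intercept
  cols <- character(0)
  if (intercept) cols <- "(Intercept)"
  for (nm in terms) {
    v <- design$variables[[nm]]
    nonref <- setdiff(v$levels, v$reference)
    cols <- c(cols, paste0(nm, nonref))
  }
  cols
}

# Dummy-coded design matrix for one section. Categorical labels are matched
# against the declared levels; unseen labels are an error naming the variable.
build_design_matrix <- function(data, design, section = c("count", "zero")) {
  section <- match.arg(section)
  terms <- if (section == "count") design$count_terms else design$zero_terms
  intercept <- if (section == "count") design$count_intercept else design$zero_intercept
  n <- nrow(data)
  blocks <- list()
  if (intercept) blocks[["(Intercept)"]] <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (nm in terms) {
    if (!nm %in% names(data)) {
      abort(paste0("data is missing design variable '", nm, "'"),
            class = "zicount_design_error")
    }
    v <- design$variables[[nm]]
    x <- as.character(data[[nm]])
    bad <- unique(x[!x %in% v$levels])
    if (length(bad)) {
      abort(
        paste0("variable '", nm, "' has labels outside its declared levels: ",
               paste(head(bad, 3), collapse = ", ")),
        class = "zicount_design_error"
      )
    }
    nonref <- setdiff(v$levels, v$reference)
    m <- vapply(nonref, function(lv) as.numeric(x == lv), numeric(n))
    if (n == 1L) m <- matrix(m, nrow = 1)
    colnames(m) <- paste0(nm, nonref)
    blocks[[nm]] <- m
  }
  X <- do.call(cbind, blocks)
  colnames(X) <- unlist(lapply(blocks, colnames), use.names = FALSE)
  X
}

# constant (non-intercept) or collinear columns make the MLE unidentified;
# report the offending column by name
check_design_rank <- function(X) {
  p <- ncol(X)
  if (p == 0L) abort("empty design matrix", class = "zicount_design_error")
  is_const <- vapply(seq_len(p), function(j) length(unique(X[, j])) == 1L, logical(1))
  bad <- which(is_const & colnames(X) != "(Intercept)")
  if (length(bad)) {
    abort(
      paste0("design column '", colnames(X)[bad[1]],
             "' is constant; drop the variable or merge levels"),
      class = "zicount_fit_error"
    )
  }
  qr_X <- qr(X)
  if (qr_X$rank < p) {
    drop <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):p]]
    abort(
      paste0("design is rank deficient; collinear column(s): ",
             paste(drop, collapse = ", ")),
      class = "zicount_fit_error"
    )
  }
  invisible(X)
}
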