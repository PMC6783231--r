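#' Two-part coefficient table in the survey-report convention
#'
#' Presents a fitted model the way zero-inflated symptom-count analyses are
#' tabulated: logit-section coefficients as odds ratios (OR = `exp(gamma)`)
#' with 95% Wald confidence intervals, count-section coefficients as betas on
#' the log-mean scale with Wald intervals, and one presentation row per
#' reference level (estimate 0, blank interval, no p-value). P-values are
#' two-sided Wald z tests.
#'
#' @param fit A converged `zicount_fit` (see [fit_count_model()]).
#' @param conf_level Confidence level of the Wald intervals. Default 0.95.
#' @param reference_rows Include the reference-level presentation rows?
#'   Default `TRUE`.
#' @param exponentiate_count Also report `exp(beta)` for count-section rows in
#'   the `transformed` column. Default `FALSE` (betas are the convention for
#'   the count section; `transformed` is `NA` there).
#'
#' @return A tibble with columns `section` (`"logit"` or `"count"`),
#'   `variable`, `level`, `estimate`, `std_error`, `ci_low`, `ci_high`,
#'   `transformed` (OR for logit rows), `p_value`.
#'
#' @examples
#' d <- simulate_survey(luts_like_preset(), n = 2000, seed = 3)
#' des <- design_spec(luts_schema(), count_terms = c("constipation", "pop"))
#' coefficient_table(fit_count_model(d, des, family = "zinb"))
#' @export
coefficient_table <- function(fit, conf_level = 0.95, reference_rows = TRUE,
                              exponentiate_count = FALSE) {
  stopifnot(inherits(fit, "zicount_fit"))
  if (!isTRUE(fit$converged)) {
    abort(
      paste0("fit did not converge (max |score| = ",
             format(fit$max_grad, digits = 3),
             "); refusing to tabulate coefficients"),
      class = "zicount_fit_error"
    )
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  td <- tidy(fit, conf_level = conf_level)
  td <- td[td$section %in% c("count", "zero"), , drop = FALSE]

  sections <- if (family_has_zero(fit$family)) c("zero", "count") else "count"
  rows <- list()
  for (sec in sections) {
    terms <- if (sec == "count") fit$design$count_terms else fit$design$zero_terms
    intercept <- if (sec == "count") fit$design$count_intercept else fit$design$zero_intercept
    label <- if (sec == "zero") "logit" else "count"
    sec_td <- td[td$section == if (sec == "zero") "zero" else "count", ]
    if (intercept) {
      r <- sec_td[sec_td$term == "(Intercept)", ]
      rows[[length(rows) + 1L]] <- present_row(label, "(Intercept)", "", r, z,
                                               sec == "zero", exponentiate_count)
    }
    for (nm in terms) {
      v <- fit$design$variables[[nm]]
      for (lv in v$levels) {
        if (lv == v$reference) {
          if (reference_rows) {
            rows[[length(rows) + 1L]] <- tibble(
              section = label, variable = nm, level = paste0(lv, " (ref)"),
              estimate = 0, std_error = NA_real_,
              ci_low = NA_real_, ci_high = NA_real_,
              transformed = if (sec == "zero") 1 else NA_real_,
              p_value = NA_real_
            )
          }
        } else {
          r <- sec_td[sec_td$term == paste0(nm, lv), ]
          rows[[length(rows) + 1L]] <- present_row(label, nm, lv, r, z,
                                                   sec == "zero", exponentiate_count)
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

present_row <- function(label, variable, level, r, z, is_logit, exp_count) {
  stopifnot(nrow(r) == 1L)
  se <- r$std.error
  fixed <- !is.na(se) && se == 0  # degenerate/fixed parameter: blank interval
  ci_low <- if (fixed) NA_real_ else r$estimate - z * se
  ci_high <- if (fixed) NA_real_ else r$estimate + z * se
  transformed <- if (is_logit || exp_count) exp(r$estimate) else NA_real_
  tibble(
    section = label, variable = variable, level = level,
    estimate = r$estimate, std_error = if (fixed) NA_real_ else se,
    ci_low = if (is_logit) exp(ci_low) else ci_low,
    ci_high = if (is_logit) exp(ci_high) else ci_high,
    transformed = transformed,
    p_value = if (fixed) NA_real_ else r$p.value
  )
}
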