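#' Overdispersion O statistic from summary moments
#'
#' Computes the overdispersion test statistic
#' \deqn{O = \sqrt{n/2}\,\left(s^2/\bar{x} - 1\right)}
#' from a sample size, mean and (unbiased, `n - 1` denominator) variance. `O`
#' is approximately standard normal under Poisson equidispersion; values at or
#' above 1.96 indicate overdispersion at the one-sided 5% level, in which case
#' the Poisson and ZIP families are inadequate for the outcome.
#'
#' @param n Sample size (>= 2).
#' @param mean Sample mean of the count outcome (> 0).
#' @param variance Unbiased sample variance of the count outcome.
#' @return The statistic `O` (a single number).
#' @examples
#' o_statistic(18992, 1.16, 2.13)
#' @export
o_statistic <- function(n, mean, variance) {
  if (n < 2) abort("`n` must be >= 2", class = "zicount_domain_error")
  if (mean <= 0) {
    abort("`mean` must be positive: O is undefined at mean 0",
          class = "zicount_domain_error")
  }
  sqrt(n / 2) * (variance / mean - 1)
}

#' Overdispersion O test on an outcome vector
#'
#' Applies [o_statistic()] to the observed outcome and reports the one-sided
#' normal p-value and the decision at the 1.96 threshold.
#'
#' @param y Either a numeric vector of non-negative integer counts or a data
#'   frame containing them.
#' @param outcome Outcome column name when `y` is a data frame. Default `"y"`.
#' @return A one-row tibble: `statistic`, `n`, `mean`, `variance`, `p_value`
#'   (one-sided upper tail), `overdispersed` (`statistic >= 1.96`).
#' @examples
#' o_test(c(0, 0, 1, 2)) # O = sqrt(2) * (11/9 - 1)
#' @export
o_test <- function(y, outcome = "y") {
  if (is.data.frame(y)) y <- check_outcome(y, outcome)
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y))) {
    abort("`y` must be non-negative integer counts", class = "zicount_domain_error")
  }
  n <- length(y)
  m <- mean(y)
  s2 <- var(y)  # unbiased, n - 1 denominator
  O <- o_statistic(n, m, s2)
  tibble(
    statistic = O, n = n, mean = m, variance = s2,
    p_value = pnorm(O, lower.tail = FALSE),
    overdispersed = O >= 1.96
  )
}

#' Vuong test for non-nested count models
#'
#' Compares two fitted models via the per-observation log-density ratio
#' `m_i = log f1(y_i) - log f2(y_i)` evaluated at the fitted parameters:
#' \deqn{V = \sqrt{n}\,\bar{m} / S_m,}
#' with `S_m` the standard deviation of the `m_i`. `V` at or above 1.96
#' favours model 1 at the one-sided 5% level; in the excess-zero workflow,
#' model 1 is the zero-inflated candidate (ZINB) and model 2 its non-inflated
#' counterpart (NB), so a large `V` signals excess zeros beyond the NB.
#' Swapping the arguments negates `V` exactly.
#'
#' @param fit1,fit2 `zicount_fit` objects fitted on the same data.
#' @return A one-row tibble: `statistic` (V), `m_mean`, `m_sd`, `n`,
#'   `p_value` (one-sided upper tail), `excess_zeros` (`V >= 1.96`),
#'   `degenerate` (`TRUE` when the two densities coincide row-wise, in which
#'   case `statistic` is `NA` — the test carries no information).
#' @examples
#' d <- simulate_survey(luts_like_preset(), n = 2000, seed = 5)
#' des <- design_spec(luts_schema(), count_terms = "constipation")
#' vuong_test(fit_count_model(d, des, family = "zinb"),
#'            fit_count_model(d, des, family = "nb"))
#' @export
vuong_test <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "zicount_fit"), inherits(fit2, "zicount_fit"))
  if (fit1$n_obs != fit2$n_obs || !isTRUE(all.equal(fit1$y, fit2$y))) {
    abort("the two fits must be on the same data", class = "zicount_domain_error")
  }
  if (fit1$family == fit2$family) {
    warn("Vuong test between two fits of the same family is degenerate")
  }
  l1 <- row_log_density(fit1)
  l2 <- row_log_density(fit2)
  bad <- which(!is.finite(l1) | !is.finite(l2))
  if (length(bad)) {
    abort(paste0("non-finite log density at row ", bad[1]),
          class = "zicount_domain_error")
  }
  m <- l1 - l2
  n <- length(m)
  m_mean <- mean(m)
  m_sd <- sd(m)
  degenerate <- !is.finite(m_sd) || m_sd < 1e-12
  V <- if (degenerate) NA_real_ else sqrt(n) * m_mean / m_sd
  if (degenerate) {
    warn("per-row densities of the two models coincide; Vuong statistic undefined")
  }
  tibble(
    statistic = V, m_mean = m_mean, m_sd = m_sd, n = n,
    p_value = if (degenerate) NA_real_ else pnorm(V, lower.tail = FALSE),
    excess_zeros = if (degenerate) NA else V >= 1.96,
    degenerate = degenerate
  )
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = -2 ln(L) + 2 a` and `BIC = -2 ln(L) + a ln(n)`, with `a` the number
#' of estimable free parameters and `n` the sample size. Smaller values mean
#' better fit.
#'
#' @param loglik Maximized log-likelihood `ln(L)`.
#' @param n_free_params Number of free parameters `a` (>= 1).
#' @param n_obs Sample size `n` (>= 1).
#' @return A list with elements `AIC` and `BIC`.
#' @examples
#' information_criteria(-100, 3, 100) # AIC 206, BIC 200 + 3 log(100)
#' @export
information_criteria <- function(loglik, n_free_params, n_obs) {
  stopifnot(n_free_params >= 1, n_obs >= 1)
  list(
    AIC = -2 * loglik + 2 * n_free_params,
    BIC = -2 * loglik + n_free_params * log(n_obs)
  )
}

#' Fit and compare the four count-model families
#'
#' Runs the full model-comparison workflow on one outcome: fits Poisson, NB,
#' ZIP and ZINB by maximum likelihood, applies the overdispersion [o_test()]
#' to the raw outcome and the [vuong_test()] (ZINB vs NB) for excess zeros,
#' tabulates log-likelihood/AIC/BIC per family, and selects the family that
#' simultaneously attains the largest log-likelihood and the smallest AIC and
#' BIC. If the three criteria disagree, no family is selected and the
#' disagreement is reported (`agreement = FALSE`); it is never silently
#' resolved.
#'
#' A family whose fit fails raises no error (unless all four fail): the
#' failure is recorded in its comparison row and the family is excluded from
#' selection.
#'
#' @param data Data frame with outcome and covariates.
#' @param design A [design_spec()].
#' @param outcome Outcome column name. Default `"y"`.
#' @param families Families to compare. Default all four.
#' @param control A [fit_control()].
#' @return A `zicount_comparison` object: `fits` (named list), `fit_stats`
#'   (tibble: family, loglik, AIC, BIC, n_free_params, converged, error),
#'   `o_test`, `vuong` (ZINB vs NB rows, when both fitted), `selected`
#'   (family name or `NA`), `agreement`, `rationale`, `n_obs`, `outcome`.
#' @examples
#' d <- simulate_survey(luts_like_preset(), n = 2000, seed = 11)
#' des <- design_spec(luts_schema(), count_terms = c("constipation", "pop"))
#' cmp <- compare_models(d, des)
#' cmp$selected
#' tidy(cmp)
#' @export
compare_models <- function(data, design, outcome = "y",
                           families = c("poisson", "nb", "zip", "zinb"),
                           control = fit_control()) {
  families <- match.arg(families, c("poisson", "nb", "zip", "zinb"),
                        several.ok = TRUE)
  fits <- list()
  errors <- setNames(rep(NA_character_, length(families)), families)
  for (fam in families) {
    res <- tryCatch(
      fit_count_model(data, design, family = fam, outcome = outcome,
                      control = control),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[[fam]] <- conditionMessage(res)
    } else {
      fits[[fam]] <- res
    }
  }
  if (!length(fits)) {
    abort(paste0("all model fits failed; first error: ", errors[[1]]),
          class = "zicount_fit_error")
  }

  fit_stats <- purrr::map_dfr(families, function(fam) {
    if (is.null(fits[[fam]])) {
      return(tibble(
        family = fam, loglik = NA_real_, AIC = NA_real_, BIC = NA_real_,
        n_free_params = NA_integer_, converged = FALSE, error = errors[[fam]]
      ))
    }
    g <- glance(fits[[fam]])
    tibble(
      family = fam, loglik = g$logLik, AIC = g$AIC, BIC = g$BIC,
      n_free_params = as.integer(g$n_free_params), converged = g$converged,
      error = NA_character_
    )
  })

  # diagnostics are reported, not load-bearing: a degenerate outcome (e.g.
  # mean zero) yields an NA row rather than aborting the comparison
  ot <- tryCatch(o_test(check_outcome(data, outcome)), error = function(e) {
    tibble(statistic = NA_real_, n = nrow(data), mean = NA_real_,
           variance = NA_real_, p_value = NA_real_, overdispersed = NA)
  })
  vg <- if (!is.null(fits$zinb) && !is.null(fits$nb)) {
    tryCatch(vuong_test(fits$zinb, fits$nb), error = function(e) NULL)
  }

  ok <- fit_stats[!is.na(fit_stats$loglik) & fit_stats$converged, ]
  selected <- NA_character_
  agreement <- FALSE
  rationale <- "no converged fits to select among"
  if (nrow(ok) > 0) {
    best_ll <- ok$family[which.max(ok$loglik)]
    best_aic <- ok$family[which.min(ok$AIC)]
    best_bic <- ok$family[which.min(ok$BIC)]
    agreement <- best_ll == best_aic && best_aic == best_bic
    if (agreement) {
      selected <- best_ll
      rationale <- paste0(
        toupper(selected),
        " attains the largest log-likelihood and the smallest AIC and BIC"
      )
    } else {
      rationale <- paste0(
        "criteria disagree: largest log-likelihood ", toupper(best_ll),
        ", smallest AIC ", toupper(best_aic), ", smallest BIC ", toupper(best_bic)
      )
    }
  }

  structure(
    list(
      fits = fits, fit_stats = fit_stats, o_test = ot, vuong = vg,
      selected = selected, agreement = agreement, rationale = rationale,
      n_obs = nrow(data), outcome = outcome
    ),
    class = "zicount_comparison"
  )
}

#' @export
print.zicount_comparison <- function(x, ...) {
  cat("<zicount_comparison> outcome:", x$outcome, " n =", x$n_obs, "\n")
  print(as.data.frame(x$fit_stats[, c("family", "loglik", "AIC", "BIC",
                                      "n_free_params", "converged")]),
        row.names = FALSE)
  cat(sprintf("  O test: %.3f (%s)\n", x$o_test$statistic,
              if (x$o_test$overdispersed) "overdispersed" else "equidispersed"))
  if (!is.null(x$vuong) && !isTRUE(x$vuong$degenerate)) {
    cat(sprintf("  Vuong (ZINB vs NB): %.3f (%s)\n", x$vuong$statistic,
                if (isTRUE(x$vuong$excess_zeros)) "excess zeros" else "no excess zeros"))
  }
  cat("  selected:", if (is.na(x$selected)) "none" else toupper(x$selected),
      "-", x$rationale, "\n")
  invisible(x)
}

#' @describeIn compare_models Tidy the per-family fit statistics (one row per
#'   family attempted).
#' @param x A `zicount_comparison`.
#' @param ... Unused.
#' @export
tidy.zicount_comparison <- function(x, ...) x$fit_stats

#' @describeIn compare_models One-row summary: selected family, agreement
#'   flag, O and Vuong statistics and decisions, sample size.
#' @export
glance.zicount_comparison <- function(x, ...) {
  tibble(
    selected = x$selected,
    agreement = x$agreement,
    o_statistic = x$o_test$statistic,
    overdispersed = x$o_test$overdispersed,
    vuong_statistic = if (!is.null(x$vuong)) x$vuong$statistic else NA_real_,
    excess_zeros = if (!is.null(x$vuong)) x$vuong$excess_zeros else NA,
    n_obs = x$n_obs
  )
}
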