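#' Control parameters for maximum-likelihood fitting
#'
#' @param maxit Iteration cap for the quasi-Newton (BFGS) stage. Default 500.
#' @param reltol Relative log-likelihood change declaring BFGS convergence.
#'   Default 1e-9.
#' @param grad_tol Max-norm of the score below which the fit is declared
#'   converged (after Newton polishing). Default 1e-5.
#' @param hess_step Relative step for the central-difference Hessian of the
#'   analytic score: the step for component j is `hess_step * max(1, |theta_j|)`.
#'   Default 1e-5.
#' @param polish_iter Maximum Newton polishing steps after BFGS. Default 25.
#' @return A list of class `zicount_control`.
#' @export
fit_control <- function(maxit = 500L, reltol = 1e-9, grad_tol = 1e-5,
                        hess_step = 1e-5, polish_iter = 25L) {
  structure(
    list(maxit = as.integer(maxit), reltol = reltol, grad_tol = grad_tol,
         hess_step = hess_step, polish_iter = as.integer(polish_iter)),
    class = "zicount_control"
  )
}

#' Fit a count regression model by maximum likelihood
#'
#' Fits one of the four families — Poisson, negative binomial (NB),
#' zero-inflated Poisson (ZIP), zero-inflated negative binomial (ZINB) — with
#' a log link on the count mean and a logit link on the structural-zero
#' probability. Optimization is quasi-Newton (BFGS with the analytic score) on
#' the unconstrained parameterization (`beta`, `gamma`, `log k`), followed by
#' Newton polishing to drive the score max-norm below `control$grad_tol`.
#' Standard errors come from the observed information: the inverse of the
#' negative numerical Hessian (central differences of the analytic score) at
#' the optimum.
#'
#' Starting values: count section from a Poisson fit; the zero-section
#' intercept from the empirical excess-zero fraction relative to the Poisson
#' fit; `k` from a method-of-moments estimate.
#'
#' @param data Data frame with the outcome and design variables.
#' @param design A [design_spec()].
#' @param family `"poisson"`, `"nb"`, `"zip"` or `"zinb"`.
#' @param outcome Outcome column name. Default `"y"`.
#' @param control A [fit_control()].
#'
#' @return A `zicount_fit` object with elements `family`, `beta`, `gamma`,
#'   `k`, `theta` (free parameters, `k` on the log scale), `loglik`, `vcov`
#'   (over the free parameters), `n_obs`, `n_free_params`, `converged`,
#'   `n_iter`, `design`. Hitting the iteration cap sets `converged = FALSE`
#'   rather than raising an error.
#'
#' @examples
#' d <- simulate_survey(luts_like_preset(), n = 800, seed = 7)
#' f <- fit_count_model(d, design_spec(luts_schema(),
#'   count_terms = "constipation"), family = "nb")
#' glance(f)
#' @export
fit_count_model <- function(data, design, family = c("poisson", "nb", "zip", "zinb"),
                            outcome = "y", control = fit_control()) {
  family <- match.arg(family)
  y <- check_outcome(data, outcome)
  n <- length(y)
  B <- build_design_matrix(data, design, "count")
  check_design_rank(B)
  G <- NULL
  if (family_has_zero(family)) {
    G <- build_design_matrix(data, design, "zero")
    check_design_rank(G)
    if (all(y == 0)) {
      abort("all outcomes are zero: the structural-zero probability is unidentified",
            class = "zicount_fit_error")
    }
  }
  layout <- param_layout(family, design)
  p <- length(layout$names)
  if (n <= p) {
    abort(paste0("n = ", n, " observations cannot identify ", p, " free parameters"),
          class = "zicount_fit_error")
  }

  theta0 <- starting_values(family, y, B, G, layout)
  nll <- nll_fun(family, y, B, G, layout)
  ngr <- ngr_fun(family, y, B, G, layout)
  opt <- optim(
    theta0, fn = nll, gr = ngr, method = "BFGS",
    control = list(maxit = control$maxit, reltol = control$reltol)
  )
  theta <- opt$par
  n_iter <- opt$counts[["function"]]

  # Newton polish: BFGS stops on relative loglik change; a few Newton steps
  # with the analytic score push the gradient max-norm to its target
  g <- -ngr(theta)
  H <- NULL
  for (i in seq_len(control$polish_iter)) {
    if (max(abs(g)) < control$grad_tol / 100) break
    H <- score_hessian(theta, family, y, B, G, layout, control$hess_step)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- theta - step
    if (nll(cand) <= nll(theta) + 1e-8) {
      theta <- cand
      g <- -ngr(theta)
      H <- NULL  # stale after the move
      n_iter <- n_iter + 1L
    } else break
  }
  if (is.null(H)) H <- score_hessian(theta, family, y, B, G, layout, control$hess_step)

  converged <- (opt$convergence %in% c(0L, 10L) || max(abs(g)) < control$grad_tol) &&
    max(abs(g)) < control$grad_tol
  loglik <- -nll(theta)
  vcov <- tryCatch(solve(-H), error = function(e) {
    matrix(NA_real_, p, p)
  })
  dimnames(vcov) <- list(layout$names, layout$names)
  # numerical asymmetry from finite differences; enforce exact symmetry
  vcov <- (vcov + t(vcov)) / 2
  pars <- unpack_params(theta, layout)
  names(theta) <- layout$names

  structure(
    list(
      family = family,
      beta = setNames(pars$beta, design_columns(design, "count")),
      gamma = if (!is.null(pars$gamma)) {
        setNames(pars$gamma, design_columns(design, "zero"))
      },
      k = pars$k,
      theta = theta,
      loglik = loglik,
      vcov = vcov,
      n_obs = n,
      n_free_params = p,
      converged = converged,
      n_iter = n_iter,
      max_grad = max(abs(g)),
      design = design,
      outcome = outcome,
      y = y, B = B, G = G
    ),
    class = "zicount_fit"
  )
}

starting_values <- function(family, y, B, G, layout) {
  # Poisson start: intercept at log(mean), slopes 0, refined by a short BFGS
  beta0 <- numeric(layout$n_beta)
  ybar <- mean(y)
  icol <- match("count_(Intercept)", layout$names[layout$beta])
  if (!is.na(icol)) beta0[icol] <- log(max(ybar, 1e-3))
  pois_layout <- list(beta = seq_along(beta0), gamma = integer(0),
                      log_k = integer(0), names = layout$names[layout$beta],
                      n_beta = layout$n_beta, n_gamma = 0L)
  pois <- optim(
    beta0, fn = nll_fun("poisson", y, B, NULL, pois_layout),
    gr = ngr_fun("poisson", y, B, NULL, pois_layout),
    method = "BFGS", control = list(maxit = 200L, reltol = 1e-8)
  )
  beta <- pois$par
  if (family == "poisson") return(beta)

  v <- var(y)
  k_mom <- if (v > ybar) ybar^2 / (v - ybar) else 100
  k_mom <- min(max(k_mom, 0.05), 1e4)
  if (family == "nb") return(c(beta, log(k_mom)))

  # zero section: intercept at the logit of the excess-zero fraction
  mu_hat <- linkinv_mu(drop(B %*% beta))
  p0_model <- mean(exp(-mu_hat))
  p0_obs <- mean(y == 0)
  excess <- (p0_obs - p0_model) / max(1 - p0_model, 1e-6)
  excess <- min(max(excess, 0.02), 0.90)
  gamma <- numeric(layout$n_gamma)
  gcol <- match("zero_(Intercept)", layout$names[layout$gamma])
  if (!is.na(gcol)) gamma[gcol] <- qlogis(excess)
  if (family == "zip") return(c(beta, gamma))
  c(beta, gamma, log(k_mom))
}

# Hessian of the log-likelihood: central differences of the analytic score,
# symmetrized; component step hess_step * max(1, |theta_j|).
score_hessian <- function(theta, family, y, B, G, layout, hess_step = 1e-5) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    h <- hess_step * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, j] <- (score_theta(tp, family, y, B, G, layout) -
                 score_theta(tm, family, y, B, G, layout)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' @export
print.zicount_fit <- function(x, ...) {
  cat("<zicount_fit> family:", toupper(x$family), "\n")
  cat(sprintf("  n = %d, free parameters = %d, logLik = %.3f\n",
              x$n_obs, x$n_free_params, x$loglik))
  cat("  converged:", x$converged, sprintf(" (max |score| = %.2e)\n", x$max_grad))
  cat("  count section:\n")
  print(round(x$beta, 4))
  if (!is.null(x$gamma)) {
    cat("  zero (logit) section:\n")
    print(round(x$gamma, 4))
  }
  if (!is.null(x$k)) cat(sprintf("  dispersion k = %.4f\n", x$k))
  invisible(x)
}

#' @export
logLik.zicount_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
coef.zicount_fit <- function(object, ...) object$theta

#' @export
vcov.zicount_fit <- function(object, ...) object$vcov

#' @export
nobs.zicount_fit <- function(object, ...) object$n_obs

# per-row fitted quantities
fitted_mu <- function(fit) linkinv_mu(drop(fit$B %*% fit$beta))
fitted_pi <- function(fit) {
  if (family_has_zero(fit$family)) linkinv_pi(drop(fit$G %*% fit$gamma))
  else rep(0, fit$n_obs)
}

# per-row log density at the fitted parameters (used by the Vuong test)
row_log_density <- function(fit) {
  log_pmf(fit$family, fit$y, fitted_mu(fit), fitted_pi(fit), fit$k)
}

#' @describeIn fit_count_model Tidy the free-parameter estimates: one row per
#'   free parameter with `section` (`count`, `zero` or `dispersion`), `term`,
#'   `estimate`, `std.error`, Wald `statistic` and `p.value`, and Wald
#'   confidence bounds. Dispersion is reported as `k` on the natural scale
#'   (delta method from the internal log scale).
#' @param x,object A `zicount_fit`.
#' @param conf_level Confidence level for Wald intervals. Default 0.95.
#' @param ... Unused.
#' @export
tidy.zicount_fit <- function(x, conf_level = 0.95, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- x$theta
  nm <- names(est)
  section <- dplyr::case_when(
    startsWith(nm, "count_") ~ "count",
    startsWith(nm, "zero_") ~ "zero",
    TRUE ~ "dispersion"
  )
  term <- sub("^(count_|zero_)", "", nm)
  out <- tibble(
    section = section, term = term, estimate = unname(est),
    std.error = unname(se)
  )
  # dispersion back to the natural scale
  disp <- out$section == "dispersion"
  if (any(disp)) {
    out$term[disp] <- "k"
    k <- exp(out$estimate[disp])
    out$std.error[disp] <- k * out$std.error[disp]
    out$estimate[disp] <- k
  }
  out$statistic <- out$estimate / out$std.error
  out$statistic[disp] <- NA_real_  # Wald z on a boundary-adjacent scale parameter
  out$p.value <- 2 * pnorm(-abs(out$statistic))
  out$conf.low <- out$estimate - z * out$std.error
  out$conf.high <- out$estimate + z * out$std.error
  out
}

#' @describeIn fit_count_model One-row model summary: family, log-likelihood,
#'   AIC, BIC, free-parameter count, dispersion, sample size, convergence.
#' @export
glance.zicount_fit <- function(x, ...) {
  ic <- information_criteria(x$loglik, x$n_free_params, x$n_obs)
  tibble(
    family = x$family,
    logLik = x$loglik,
    AIC = ic$AIC,
    BIC = ic$BIC,
    n_free_params = x$n_free_params,
    k = x$k %||% NA_real_,
    nobs = x$n_obs,
    converged = x$converged
  )
}

#' @describeIn fit_count_model Per-row fitted quantities: the fitted count
#'   mean `.mu`, structural-zero probability `.pi`, unconditional mean
#'   `.fitted = (1 - .pi) * .mu`, and the log density `.logdens` of the
#'   observed outcome.
#' @export
augment.zicount_fit <- function(x, ...) {
  mu <- fitted_mu(x)
  pi <- fitted_pi(x)
  tibble(
    y = x$y, .mu = mu, .pi = pi, .fitted = (1 - pi) * mu,
    .logdens = row_log_density(x)
  )
}
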