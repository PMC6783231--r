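#' Log probability mass of the four count families
#'
#' Evaluates `ln P(Y = y)` for the Poisson, negative binomial (NB),
#' zero-inflated Poisson (ZIP) and zero-inflated negative binomial (ZINB)
#' families. The zero-inflated families are two-part mixtures: with structural
#' probability `pi` the outcome is a zero, otherwise it is a Poisson or NB
#' draw, so
#' \deqn{P(0) = \pi + (1-\pi) f(0), \qquad P(y) = (1-\pi) f(y), \; y \ge 1,}
#' with `f` the Poisson or NB pmf. The NB is parameterized by its mean `mu`
#' and dispersion `k > 0` ("size" convention), so the variance is
#' `mu + mu^2 / k`. The `y = 0` mass is computed by log-sum-exp of
#' `{log(pi), log(1 - pi) + log f(0)}` for stability near the boundary, and
#' the NB pmf goes through log-gamma functions, never factorials.
#'
#' @param family One of `"poisson"`, `"nb"`, `"zip"`, `"zinb"`.
#' @param y Non-negative integer outcome(s).
#' @param mu Positive mean(s) of the count component.
#' @param pi Structural-zero probability in `[0, 1)`; must be 0 (default) for
#'   `poisson`/`nb`.
#' @param k Positive NB dispersion; required for `nb`/`zinb`.
#'
#' @return Numeric vector of log probabilities (recycled to common length).
#'
#' @examples
#' log_pmf("zip", y = 0, mu = 1, pi = 0.5) # log(0.5 + 0.5 * exp(-1))
#' sum(exp(log_pmf("nb", 0:1000, mu = 2, k = 1.5))) # ~1
#' @export
log_pmf <- function(family = c("poisson", "nb", "zip", "zinb"), y, mu,
                    pi = 0, k = NULL) {
  family <- match.arg(family)
  if (any(y < 0) || any(y != floor(y))) {
    abort("`y` must contain non-negative integers", class = "zicount_domain_error")
  }
  if (any(mu <= 0)) {
    abort("`mu` must be positive", class = "zicount_domain_error")
  }
  if (family %in% c("poisson", "nb")) {
    if (any(pi != 0)) {
      abort(paste0("`pi` must be 0 for family '", family, "'"),
            class = "zicount_domain_error")
    }
  } else if (any(pi < 0) || any(pi >= 1)) {
    abort("`pi` must lie in [0, 1); pi = 1 makes the likelihood degenerate",
          class = "zicount_domain_error")
  }
  uses_k <- family %in% c("nb", "zinb")
  if (uses_k && (is.null(k) || any(k <= 0))) {
    abort("`k` must be positive for NB-type families", class = "zicount_domain_error")
  }
  n <- max(length(y), length(mu), length(pi), if (uses_k) length(k) else 0L)
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  base_logf <- switch(family,
    poisson = , zip = dpois(y, lambda = mu, log = TRUE),
    nb = , zinb = dnbinom(y, size = rep_len(k, n), mu = mu, log = TRUE)
  )
  if (family %in% c("poisson", "nb")) {
    return(base_logf)
  }
  pi <- rep_len(pi, n)
  out <- log1p(-pi) + base_logf
  iz <- which(y == 0 & pi > 0)
  if (length(iz)) {
    # log(pi + (1 - pi) f(0)) via log-sum-exp
    a <- log(pi[iz])
    b <- log1p(-pi[iz]) + base_logf[iz]
    m <- pmax(a, b)
    out[iz] <- m + log(exp(a - m) + exp(b - m))
  }
  out
}

## ---- parameter packing -----------------------------------------------------
## Free parameters are stored unconstrained: (beta, gamma, log k); gamma is
## absent for poisson/nb, log k absent for poisson/zip.

family_has_zero <- function(family) family %in% c("zip", "zinb")
family_has_k <- function(family) family %in% c("nb", "zinb")

param_layout <- function(family, design) {
  cb <- design_columns(design, "count")
  cz <- if (family_has_zero(family)) design_columns(design, "zero") else character(0)
  list(
    beta = seq_along(cb),
    gamma = if (length(cz)) length(cb) + seq_along(cz) else integer(0),
    log_k = if (family_has_k(family)) length(cb) + length(cz) + 1L else integer(0),
    names = c(paste0("count_", cb), if (length(cz)) paste0("zero_", cz),
              if (family_has_k(family)) "log_k"),
    n_beta = length(cb), n_gamma = length(cz)
  )
}

unpack_params <- function(theta, layout) {
  list(
    beta = theta[layout$beta],
    gamma = if (length(layout$gamma)) theta[layout$gamma] else NULL,
    k = if (length(layout$log_k)) exp(theta[layout$log_k]) else NULL
  )
}

# linear predictors -> (mu, pi); overflow-guarded so the optimizer never sees
# NaN: eta is clamped to +-30 (exp(30) ~ 1e13, far beyond any plausible mean)
linkinv_mu <- function(eta) exp(pmin(pmax(eta, -30), 30))
linkinv_pi <- function(eta) plogis(pmin(pmax(eta, -30), 30))

#' Log-likelihood of a count model at given parameters
#'
#' Sums [log_pmf()] over the rows of `data`, with `mu_i = exp(B_i beta)` (log
#' link) and, for zero-inflated families, `pi_i = plogis(G_i gamma)` (logit
#' link), where `B` and `G` are the dummy-coded count- and zero-section design
#' matrices implied by `design`.
#'
#' @param family Model family (see [log_pmf()]).
#' @param params Named list with `beta` (count section, log-mean scale),
#'   `gamma` (zero section, log-odds scale; zero-inflated families only) and
#'   `k` (NB dispersion; NB-type families only).
#' @param design A [design_spec()].
#' @param data Data frame holding the outcome and the design variables.
#' @param outcome Name of the outcome column. Default `"y"`.
#'
#' @return A single number, the log-likelihood.
#' @export
count_loglik <- function(family, params, design, data, outcome = "y") {
  family <- match.arg(family, c("poisson", "nb", "zip", "zinb"))
  y <- check_outcome(data, outcome)
  B <- build_design_matrix(data, design, "count")
  G <- if (family_has_zero(family)) build_design_matrix(data, design, "zero")
  check_param_dims(family, params, design)
  mu <- linkinv_mu(drop(B %*% params$beta))
  pi <- if (family_has_zero(family)) linkinv_pi(drop(G %*% params$gamma)) else 0
  sum(log_pmf(family, y, mu, pi, params$k))
}

check_param_dims <- function(family, params, design) {
  nb <- length(design_columns(design, "count"))
  if (length(params$beta) != nb) {
    abort(
      paste0("`beta` has length ", length(params$beta), " but the count section has ",
             nb, " columns"),
      class = "zicount_config_error"
    )
  }
  if (family_has_zero(family)) {
    ng <- length(design_columns(design, "zero"))
    if (length(params$gamma) != ng) {
      abort(
        paste0("`gamma` has length ", length(params$gamma),
               " but the zero section has ", ng, " columns"),
        class = "zicount_config_error"
      )
    }
  }
  if (family_has_k(family) && (is.null(params$k) || params$k <= 0)) {
    abort("`k` must be a positive scalar for NB-type families",
          class = "zicount_config_error")
  }
  invisible(params)
}

check_outcome <- function(data, outcome) {
  if (!outcome %in% names(data)) {
    abort(paste0("outcome column '", outcome, "' not found in data"),
          class = "zicount_data_error")
  }
  y <- data[[outcome]]
  bad <- which(!is.finite(y) | y < 0 | y != floor(y))
  if (length(bad)) {
    abort(
      paste0("outcome '", outcome, "' must be non-negative integers; first bad row: ",
             bad[1]),
      class = "zicount_data_error"
    )
  }
  as.numeric(y)
}

## ---- internal vectorized loglik/score on prebuilt matrices -----------------
## The fitting loop avoids rebuilding design matrices at every evaluation.

nll_fun <- function(family, y, B, G, layout) {
  force(family); force(y); force(B); force(G); force(layout)
  function(theta) -loglik_theta(theta, family, y, B, G, layout)
}

ngr_fun <- function(family, y, B, G, layout) {
  force(family); force(y); force(B); force(G); force(layout)
  function(theta) -score_theta(theta, family, y, B, G, layout)
}

loglik_theta <- function(theta, family, y, B, G, layout) {
  p <- unpack_params(theta, layout)
  mu <- linkinv_mu(drop(B %*% p$beta))
  pi <- if (family_has_zero(family)) linkinv_pi(drop(G %*% p$gamma)) else 0
  ll <- sum(log_pmf(family, y, mu, pi, p$k))
  if (!is.finite(ll)) ll <- -1e10  # optimizer-safe floor; never NaN
  ll
}

# Analytic score in the unconstrained parameterization (beta, gamma, log k).
# Per-row weights below are d loglik_i / d eta; crossprod maps them onto the
# design columns.
score_theta <- function(theta, family, y, B, G, layout) {
  p <- unpack_params(theta, layout)
  mu <- linkinv_mu(drop(B %*% p$beta))
  n <- length(y)
  zi <- family_has_zero(family)
  nb_type <- family_has_k(family)
  k <- p$k
  pi <- if (zi) linkinv_pi(drop(G %*% p$gamma)) else rep(0, n)

  is0 <- y == 0
  # count component log f(y) derivatives
  if (nb_type) {
    w_count_pos <- k * (y - mu) / (k + mu)              # d log f / d eta_count
    dlogf0_deta <- -k * mu / (k + mu)                   # at y = 0
    dlogf_dlogk <- k * (digamma(y + k) - digamma(k) + log(k / (k + mu)) +
                          (mu - y) / (k + mu))
    dlogf0_dlogk <- k * (log(k / (k + mu)) + mu / (k + mu))
    logf0 <- k * log(k / (k + mu))
  } else {
    w_count_pos <- y - mu
    dlogf0_deta <- -mu
    logf0 <- -mu
  }

  if (!zi) {
    w_count <- w_count_pos
    g_beta <- drop(crossprod(B, w_count))
    if (nb_type) {
      return(c(g_beta, sum(dlogf_dlogk)))
    }
    return(g_beta)
  }

  # zero-inflated: P(0) = pi + (1 - pi) f(0)
  f0 <- exp(logf0)
  P0 <- pi + (1 - pi) * f0
  w_count <- ifelse(is0, (1 - pi) * f0 * dlogf0_deta / P0, w_count_pos)
  w_zero <- ifelse(is0, pi * (1 - pi) * (1 - f0) / P0, -pi)
  g_beta <- drop(crossprod(B, w_count))
  g_gamma <- drop(crossprod(G, w_zero))
  if (nb_type) {
    g_logk <- sum(ifelse(is0, (1 - pi) * f0 * dlogf0_dlogk / P0, dlogf_dlogk))
    return(c(g_beta, g_gamma, g_logk))
  }
  c(g_beta, g_gamma)
}

#' Score (gradient) of the log-likelihood
#'
#' Analytic gradient of [count_loglik()] with respect to the free parameters,
#' in the order count-section `beta`, zero-section `gamma` (zero-inflated
#' families), then `log(k)` (NB-type families; the dispersion is differentiated
#' on the log scale used internally for unconstrained optimization).
#'
#' @inheritParams count_loglik
#' @return Named numeric gradient vector.
#' @export
count_score <- function(family, params, design, data, outcome = "y") {
  family <- match.arg(family, c("poisson", "nb", "zip", "zinb"))
  y <- check_outcome(data, outcome)
  check_param_dims(family, params, design)
  B <- build_design_matrix(data, design, "count")
  G <- if (family_has_zero(family)) build_design_matrix(data, design, "zero")
  layout <- param_layout(family, design)
  theta <- c(params$beta, params$gamma, if (family_has_k(family)) log(params$k))
  setNames(score_theta(theta, family, y, B, G, layout), layout$names)
}
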