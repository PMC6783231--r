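# Shared fixtures and independent oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-covariate schema small enough for brute-force checks
tiny_schema <- function() {
  covariate_schema(
    exposure = list(levels = c("no", "yes"), probs = c(0.6, 0.4)),
    group = list(levels = c("a", "b", "c"), probs = c(0.5, 0.3, 0.2))
  )
}

tiny_design <- function() design_spec(tiny_schema())

tiny_zinb_config <- function(n = 200L, seed = 1L) {
  generator_config(
    tiny_schema(), family = "zinb",
    beta = c("(Intercept)" = 0.3, exposureyes = 0.4, groupb = -0.2, groupc = 0.1),
    gamma = c("(Intercept)" = -0.6, exposureyes = 0.5, groupb = 0.0, groupc = -0.3),
    dispersion = 1.5, n = n, seed = seed
  )
}

# Independent per-row log-likelihood oracle: explicit mixture arithmetic on
# probabilities (no log-scale tricks), summed in a plain loop. Deliberately
# slower and structurally different from the package's vectorized path.
oracle_loglik <- function(family, beta, gamma, k, design, data, outcome = "y") {
  B <- zicount:::build_design_matrix(data, design, "count")
  total <- 0
  for (i in seq_len(nrow(data))) {
    mu_i <- exp(sum(B[i, ] * beta))
    pi_i <- 0
    if (family %in% c("zip", "zinb")) {
      G <- zicount:::build_design_matrix(data, design, "zero")
      eta <- sum(G[i, ] * gamma)
      pi_i <- 1 / (1 + exp(-eta))
    }
    y_i <- data[[outcome]][i]
    f <- if (family %in% c("poisson", "zip")) {
      exp(-mu_i) * mu_i^y_i / factorial(y_i)
    } else {
      gamma(y_i + k) / (gamma(k) * factorial(y_i)) *
        (k / (k + mu_i))^k * (mu_i / (k + mu_i))^y_i
    }
    p <- if (y_i == 0) pi_i + (1 - pi_i) * f else (1 - pi_i) * f
    total <- total + log(p)
  }
  total
}

# central finite differences of count_loglik, elementwise
fd_score <- function(family, params, design, data, h = 1e-6) {
  pack <- c(params$beta, params$gamma,
            if (family %in% c("nb", "zinb")) log(params$k))
  nb <- length(params$beta)
  ng <- length(params$gamma)
  unpack <- function(theta) {
    list(
      beta = theta[seq_len(nb)],
      gamma = if (ng) theta[nb + seq_len(ng)] else NULL,
      k = if (family %in% c("nb", "zinb")) exp(theta[length(theta)]) else NULL
    )
  }
  vapply(seq_along(pack), function(j) {
    tp <- pack; tp[j] <- tp[j] + h
    tm <- pack; tm[j] <- tm[j] - h
    (count_loglik(family, unpack(tp), design, data) -
       count_loglik(family, unpack(tm), design, data)) / (2 * h)
  }, numeric(1))
}
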