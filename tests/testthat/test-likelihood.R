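test_that("zero inflation off reduces ZI pmfs to their base pmf", {
  y <- 0:20
  expect_equal(log_pmf("zinb", y, mu = 1.7, pi = 0, k = 2.2),
               log_pmf("nb", y, mu = 1.7, k = 2.2))
  expect_equal(log_pmf("zip", y, mu = 0.8, pi = 0),
               log_pmf("poisson", y, mu = 0.8))
})

test_that("the ZIP zero mass matches its closed form", {
  expect_equal(log_pmf("zip", 0, mu = 1, pi = 0.5),
               log(0.5 + 0.5 * exp(-1)))
  # and a non-zero count picks up the (1 - pi) factor
  expect_equal(log_pmf("zip", 3, mu = 1, pi = 0.5),
               log(0.5) + dpois(3, 1, log = TRUE))
})

test_that("pmfs are normalized for every family", {
  ys <- 0:1000
  cases <- list(
    list(family = "poisson", mu = 2),
    list(family = "nb", mu = 2, k = 1.5),
    list(family = "nb", mu = 7.5, k = 0.4),
    list(family = "zip", mu = 3, pi = 0.35),
    list(family = "zinb", mu = 2.5, pi = 0.55, k = 0.8)
  )
  for (cs in cases) {
    total <- sum(exp(log_pmf(cs$family, ys, mu = cs$mu,
                             pi = cs$pi %||% 0, k = cs$k)))
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("zero mass is strictly increasing in pi at fixed mu, k", {
  pis <- seq(0, 0.95, by = 0.05)
  p0 <- exp(log_pmf("zinb", 0, mu = 2, pi = pis, k = 1.3))
  expect_true(all(diff(p0) > 0))
})

test_that("domain violations are rejected", {
  expect_error(log_pmf("poisson", y = -1, mu = 1), class = "zicount_domain_error")
  expect_error(log_pmf("poisson", y = 1.5, mu = 1), class = "zicount_domain_error")
  expect_error(log_pmf("zip", y = 0, mu = 1, pi = 1), class = "zicount_domain_error")
  expect_error(log_pmf("nb", y = 0, mu = 1, k = -2), class = "zicount_domain_error")
  expect_error(log_pmf("nb", y = 0, mu = 1, pi = 0.2, k = 1),
               class = "zicount_domain_error")
})

test_that("log-likelihood equals the brute-force per-row oracle", {
  set.seed(2101)
  des <- tiny_design()
  for (rep in 1:20) {
    fam <- sample(c("poisson", "nb", "zip", "zinb"), 1)
    n <- sample(10:40, 1)
    cfg <- tiny_zinb_config(n = n, seed = 1000 + rep)
    d <- simulate_survey(cfg)
    beta <- rnorm(4, 0, 0.4)
    gamma <- if (fam %in% c("zip", "zinb")) rnorm(4, 0, 0.4)
    k <- if (fam %in% c("nb", "zinb")) runif(1, 0.5, 3)
    got <- count_loglik(fam, list(beta = beta, gamma = gamma, k = k), des, d)
    want <- oracle_loglik(fam, beta, gamma, k, des, d)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("family nesting limits hold for the log-likelihood", {
  cfg <- tiny_zinb_config(n = 120L, seed = 6)
  d <- simulate_survey(cfg)
  des <- tiny_design()
  beta <- c(0.2, 0.3, -0.1, 0.05)
  # ZINB with gamma -> -inf (pi -> 0) equals NB
  expect_equal(
    count_loglik("zinb", list(beta = beta, gamma = c(-40, 0, 0, 0), k = 1.4), des, d),
    count_loglik("nb", list(beta = beta, k = 1.4), des, d),
    tolerance = 1e-8
  )
  # NB as k -> infinity approaches Poisson
  expect_equal(
    count_loglik("nb", list(beta = beta, k = 1e6), des, d),
    count_loglik("poisson", list(beta = beta), des, d),
    tolerance = 1e-4
  )
  # ZINB at k -> infinity approaches ZIP at the same beta, gamma
  gam <- c(-0.5, 0.2, 0, 0.1)
  expect_equal(
    count_loglik("zinb", list(beta = beta, gamma = gam, k = 1e6), des, d),
    count_loglik("zip", list(beta = beta, gamma = gam), des, d),
    tolerance = 1e-4
  )
})

test_that("a one-row dataset reduces the log-likelihood to one pmf term", {
  d <- tibble::tibble(y = 3L, exposure = "yes", group = "b")
  des <- tiny_design()
  ll <- count_loglik("zinb", list(beta = c(0.4, 0.1, -0.2, 0),
                                  gamma = c(-1, 0.5, 0, 0), k = 2), des, d)
  mu <- exp(0.4 + 0.1 - 0.2)
  pi <- plogis(-1 + 0.5)
  expect_equal(ll, log_pmf("zinb", 3, mu, pi, 2))
})

test_that("the analytic score matches central finite differences", {
  set.seed(515)
  des <- tiny_design()
  for (fam in c("poisson", "nb", "zip", "zinb")) {
    d <- simulate_survey(tiny_zinb_config(n = 50L, seed = 99))
    params <- list(
      beta = rnorm(4, 0, 0.3),
      gamma = if (fam %in% c("zip", "zinb")) rnorm(4, 0, 0.3),
      k = if (fam %in% c("nb", "zinb")) runif(1, 0.6, 2.5)
    )
    g <- count_score(fam, params, des, d)
    fd <- fd_score(fam, params, des, d)
    expect_equal(unname(g), fd, tolerance = 1e-6)
  }
})

test_that("the poisson intercept-only score has its closed form", {
  d <- tibble::tibble(y = c(0L, 2L, 5L, 1L))
  des <- design_spec(list(dummy = list(levels = c("a", "b"))), count_terms = character(0))
  b0 <- 0.3
  g <- count_score("poisson", list(beta = b0), des, d)
  expect_equal(unname(g), sum(d$y - exp(b0)))
})

test_that("the score vanishes at a fitted optimum", {
  d <- simulate_survey(tiny_zinb_config(n = 2000L, seed = 13))
  fit <- fit_count_model(d, tiny_design(), family = "zinb")
  g <- count_score("zinb", list(beta = unname(fit$beta), gamma = unname(fit$gamma),
                                k = fit$k), tiny_design(), d)
  expect_lt(max(abs(g)), 1e-5)
})
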