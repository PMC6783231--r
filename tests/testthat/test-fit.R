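test_that("poisson intercept-only MLE is the log of the sample mean", {
  d <- tibble::tibble(y = c(0L, 1L, 3L, 2L, 4L, 2L),
                      dummy = rep(c("a", "b"), 3))
  des <- design_spec(list(dummy = list(levels = c("a", "b"))),
                     count_terms = character(0))
  fit <- fit_count_model(d, des, family = "poisson")
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), log(mean(d$y)), tolerance = 1e-8)
})

test_that("nb fit on poisson data drifts to the poisson limit", {
  sch <- covariate_schema(v = list(levels = c("a", "b"), probs = c(0.5, 0.5)))
  cfg <- generator_config(sch, "poisson",
                          beta = c("(Intercept)" = log(1.5), vb = 0.3),
                          n = 5000L, seed = 21)
  d <- simulate_survey(cfg)
  des <- design_spec(sch)
  f_nb <- fit_count_model(d, des, family = "nb")
  f_po <- fit_count_model(d, des, family = "poisson")
  expect_gt(f_nb$k, 50)
  expect_lt(abs(f_nb$loglik - f_po$loglik), 0.5)
})

test_that("zinb fitting recovers generator truth within Wald error", {
  cfg <- tiny_zinb_config(n = 8000L, seed = 456)
  d <- simulate_survey(cfg)
  fit <- fit_count_model(d, tiny_design(), family = "zinb")
  expect_true(fit$converged)
  td <- tidy(fit)
  truth <- c(cfg$beta, cfg$gamma, cfg$dispersion)
  est <- td$estimate
  se <- td$std.error
  # every true value within 4 SEs of its estimate (a loose single-replicate check)
  expect_true(all(abs(est - truth) < 4 * se))
})

test_that("fits agree with the glmmTMB reference implementation", {
  skip_if_not_installed("glmmTMB")
  skip_if_not_installed("MASS")
  d <- simulate_survey(tiny_zinb_config(n = 4000L, seed = 88))
  d$exposure <- factor(d$exposure, levels = c("no", "yes"))
  d$group <- factor(d$group, levels = c("a", "b", "c"))
  des <- tiny_design()

  f_nb <- fit_count_model(d, des, family = "nb")
  ref_nb <- MASS::glm.nb(y ~ exposure + group, data = d)
  expect_equal(f_nb$loglik, as.numeric(stats::logLik(ref_nb)), tolerance = 1e-6)
  expect_equal(unname(f_nb$beta), unname(stats::coef(ref_nb)), tolerance = 1e-4)
  expect_equal(f_nb$k, ref_nb$theta, tolerance = 1e-3)

  f_zinb <- fit_count_model(d, des, family = "zinb")
  ref <- glmmTMB::glmmTMB(y ~ exposure + group, ziformula = ~ exposure + group,
                          family = glmmTMB::nbinom2, data = d)
  expect_equal(f_zinb$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(unname(f_zinb$beta),
               unname(glmmTMB::fixef(ref)$cond), tolerance = 1e-3)
  expect_equal(unname(f_zinb$gamma),
               unname(glmmTMB::fixef(ref)$zi), tolerance = 1e-3)
  expect_equal(f_zinb$k, glmmTMB::sigma(ref), tolerance = 1e-3)
  # standard errors from the observed information agree too
  se_ref <- sqrt(diag(stats::vcov(ref)$cond))
  se_own <- tidy(f_zinb)$std.error[seq_along(se_ref)]
  expect_equal(unname(se_own), unname(se_ref), tolerance = 1e-2)
})

test_that("log-likelihoods respect family nesting on any dataset", {
  for (seed in c(1, 2)) {
    d <- simulate_survey(tiny_zinb_config(n = 1500L, seed = seed))
    des <- tiny_design()
    ll <- sapply(c("poisson", "nb", "zip", "zinb"), function(fam) {
      fit_count_model(d, des, family = fam)$loglik
    })
    slack <- 1e-6
    expect_gte(ll["zinb"], ll["nb"] - slack)
    expect_gte(ll["zinb"], ll["zip"] - slack)
    expect_gte(ll["zip"], ll["poisson"] - slack)
    expect_gte(ll["nb"], ll["poisson"] - slack)
  }
})

test_that("relabeling non-reference levels permutes rows but not the fit", {
  d <- simulate_survey(tiny_zinb_config(n = 1200L, seed = 33))
  des <- tiny_design()
  f1 <- fit_count_model(d, des, family = "zinb")
  # swap labels b <-> c (reference 'a' untouched)
  d2 <- d
  d2$group <- c(a = "a", b = "zz", c = "b")[d2$group]
  d2$group[d2$group == "zz"] <- "c"
  des2 <- design_spec(
    list(exposure = list(levels = c("no", "yes")),
         group = list(levels = c("a", "c", "b"))),
    count_terms = c("exposure", "group")
  )
  # relabel: old b -> new c, old c -> new b; design declares the same sets
  f2 <- fit_count_model(d2, des2, family = "zinb")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(sort(unname(f1$beta)), sort(unname(f2$beta)), tolerance = 1e-4)
})

test_that("degenerate designs and unidentified models raise named errors", {
  d <- simulate_survey(tiny_zinb_config(n = 300L, seed = 3))
  d$exposure <- "yes"  # constant column
  expect_error(fit_count_model(d, tiny_design(), family = "poisson"),
               "exposureyes.*constant", class = "zicount_fit_error")

  d2 <- simulate_survey(tiny_zinb_config(n = 50L, seed = 4))
  d2$y <- 0L
  expect_error(fit_count_model(d2, tiny_design(), family = "zinb"),
               "unidentified", class = "zicount_fit_error")
})

test_that("hitting the iteration cap reports non-convergence, not an error", {
  d <- simulate_survey(tiny_zinb_config(n = 2000L, seed = 14))
  fit <- fit_count_model(d, tiny_design(), family = "zinb",
                         control = fit_control(maxit = 2, polish_iter = 0))
  expect_s3_class(fit, "zicount_fit")
  expect_false(fit$converged)
  expect_error(coefficient_table(fit), "did not converge",
               class = "zicount_fit_error")
})

test_that("coefficient tables follow the OR / beta presentation convention", {
  d <- simulate_survey(tiny_zinb_config(n = 3000L, seed = 55))
  fit <- fit_count_model(d, tiny_design(), family = "zinb")
  ct <- coefficient_table(fit)
  td <- tidy(fit)

  # logit rows: transformed = exp(gamma), CI = exp(gamma -+ 1.96 se), OR scale
  r <- ct[ct$section == "logit" & ct$variable == "exposure" & ct$level == "yes", ]
  tr <- td[td$section == "zero" & td$term == "exposureyes", ]
  expect_equal(r$transformed, exp(tr$estimate))
  expect_equal(r$ci_low, exp(tr$estimate - qnorm(0.975) * tr$std.error), tolerance = 1e-6)
  expect_equal(r$ci_high, exp(tr$estimate + qnorm(0.975) * tr$std.error), tolerance = 1e-6)
  expect_lt(r$ci_low, r$ci_high)
  expect_equal(r$p_value, 2 * pnorm(-abs(tr$estimate / tr$std.error)))

  # count rows stay on the log-mean (beta) scale
  rc <- ct[ct$section == "count" & ct$variable == "exposure" & ct$level == "yes", ]
  tc <- td[td$section == "count" & td$term == "exposureyes", ]
  expect_equal(rc$estimate, tc$estimate)
  expect_equal(rc$ci_high, tc$estimate + qnorm(0.975) * tc$std.error, tolerance = 1e-6)
  expect_true(is.na(rc$transformed))

  # reference rows: estimate 0, blank interval, no p-value
  ref <- ct[ct$variable == "exposure" & grepl("ref", ct$level), ]
  expect_true(all(ref$estimate == 0))
  expect_true(all(is.na(ref$ci_low)) && all(is.na(ref$p_value)))

  # the transform at estimate 0 with se 0.1 gives OR 1.000 (0.822, 1.217)
  expect_equal(exp(c(-1.96, 1.96) * 0.1), c(0.822, 1.217), tolerance = 1e-3)
})

test_that("vcov is symmetric with non-negative diagonal; glance is consistent", {
  d <- simulate_survey(tiny_zinb_config(n = 2500L, seed = 66))
  fit <- fit_count_model(d, tiny_design(), family = "zinb")
  expect_identical(fit$vcov, t(fit$vcov))
  expect_true(all(diag(fit$vcov) >= 0))
  g <- glance(fit)
  expect_equal(g$AIC, -2 * fit$loglik + 2 * fit$n_free_params)
  expect_equal(g$BIC, -2 * fit$loglik + fit$n_free_params * log(fit$n_obs))
  expect_identical(g$n_free_params, length(fit$beta) + length(fit$gamma) + 1L)
})
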