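test_that("the O statistic matches hand evaluation of its formula", {
  # y = (0, 0, 1, 2): mean 3/4, unbiased variance 11/12
  res <- o_test(c(0, 0, 1, 2))
  expect_equal(res$statistic, sqrt(2) * (11 / 9 - 1), tolerance = 1e-12)
  expect_equal(res$statistic, 0.3143, tolerance = 1e-3)
  expect_false(res$overdispersed)

  # equidispersed vector: mean = variance = 1 -> O = 0
  res0 <- o_test(c(0L, 1L, 2L))
  expect_equal(res0$statistic, 0)
  expect_false(res0$overdispersed)

  # underdispersed all-equal-positive outcome is valid, O < 0
  resu <- o_test(rep(2L, 10))
  expect_lt(resu$statistic, 0)

  expect_error(o_test(rep(0L, 10)), "mean 0", class = "zicount_domain_error")
})

test_that("o_test on a vector agrees with o_statistic on its moments", {
  set.seed(9)
  y <- rnbinom(500, size = 1, mu = 2)
  expect_equal(o_test(y)$statistic, o_statistic(500, mean(y), var(y)))
  # data-frame-first form
  expect_equal(o_test(tibble::tibble(y = y))$statistic, o_test(y)$statistic)
})

test_that("vuong test is antisymmetric and invariant to row order", {
  d <- simulate_survey(tiny_zinb_config(n = 2500L, seed = 101))
  des <- tiny_design()
  f1 <- fit_count_model(d, des, family = "zinb")
  f2 <- fit_count_model(d, des, family = "nb")
  v12 <- vuong_test(f1, f2)
  v21 <- vuong_test(f2, f1)
  expect_equal(v12$statistic, -v21$statistic, tolerance = 1e-12)

  perm <- sample(nrow(d))
  f1p <- fit_count_model(d[perm, ], des, family = "zinb")
  f2p <- fit_count_model(d[perm, ], des, family = "nb")
  expect_equal(abs(vuong_test(f1p, f2p)$statistic), abs(v12$statistic),
               tolerance = 1e-4)
})

test_that("identical fitted densities make the vuong test degenerate", {
  d <- simulate_survey(tiny_zinb_config(n = 500L, seed = 7))
  f <- fit_count_model(d, tiny_design(), family = "nb")
  w <- testthat::capture_warnings(res <- vuong_test(f, f))
  expect_true(any(grepl("degenerate", w)))
  expect_true(res$degenerate)
  expect_true(is.na(res$statistic))
})

test_that("information criteria are the stated arithmetic", {
  ic <- information_criteria(-100, 3, 100)
  expect_equal(ic$AIC, 206)
  expect_equal(ic$BIC, 200 + 3 * log(100))
  expect_equal(ic$BIC, 213.8155, tolerance = 1e-4)
  # one inert extra parameter at unchanged loglik costs exactly 2 AIC points
  ic2 <- information_criteria(-100, 4, 100)
  expect_equal(ic2$AIC - ic$AIC, 2)
  # BIC penalizes harder than AIC whenever n > e^2
  expect_gt(information_criteria(-10, 2, 8)$BIC,
            information_criteria(-10, 2, 8)$AIC)
  expect_lt(information_criteria(-10, 2, 7)$BIC,
            information_criteria(-10, 2, 7)$AIC)
})

test_that("AIC and BIC are monotone in the log-likelihood at fixed size", {
  lls <- c(-500, -400, -300)
  aics <- vapply(lls, function(l) information_criteria(l, 5, 1000)$AIC, 0)
  bics <- vapply(lls, function(l) information_criteria(l, 5, 1000)$BIC, 0)
  expect_true(all(diff(aics) < 0) && all(diff(bics) < 0))
})

test_that("compare_models assembles a consistent report and selects ZINB on preset data", {
  d <- simulate_survey(luts_like_preset(), n = 6000, seed = 202)
  des <- design_spec(luts_schema(),
                     count_terms = c("age_band", "constipation", "pop"))
  cmp <- compare_models(d, des)
  st <- cmp$fit_stats
  expect_setequal(st$family, c("poisson", "nb", "zip", "zinb"))
  # AIC/BIC recomputable from the row's own loglik and parameter count
  expect_equal(st$AIC, -2 * st$loglik + 2 * st$n_free_params, tolerance = 1e-9)
  expect_equal(st$BIC, -2 * st$loglik + st$n_free_params * log(cmp$n_obs),
               tolerance = 1e-9)
  expect_true(cmp$o_test$overdispersed)
  expect_true(cmp$vuong$excess_zeros)
  expect_identical(cmp$selected, "zinb")
  expect_true(cmp$agreement)
  g <- glance(cmp)
  expect_identical(g$selected, "zinb")
})

test_that("criterion disagreement is reported, never silently resolved", {
  # near-poisson data: NB/ZIP gain little loglik; AIC and BIC can disagree
  # with the raw likelihood ordering, which always favours the largest family
  set.seed(404)
  d <- tibble::tibble(y = rpois(800, 1.3),
                      dummy = sample(c("a", "b"), 800, TRUE))
  des <- design_spec(list(dummy = list(levels = c("a", "b"))),
                     count_terms = character(0))
  cmp <- compare_models(d, des)
  best_ll <- cmp$fit_stats$family[which.max(cmp$fit_stats$loglik)]
  if (cmp$agreement) {
    expect_identical(cmp$selected, best_ll)
  } else {
    expect_true(is.na(cmp$selected))
    expect_match(cmp$rationale, "disagree")
  }
})

test_that("a failing family is recorded in its row, not fatal", {
  d <- simulate_survey(tiny_zinb_config(n = 400L, seed = 12))
  d$y <- 0L  # ZI families unidentified; poisson/nb still fit (boundary)
  des <- tiny_design()
  cmp <- compare_models(d, des, families = c("nb", "zinb"))
  expect_true(is.na(cmp$fit_stats$loglik[cmp$fit_stats$family == "zinb"]))
  expect_match(cmp$fit_stats$error[cmp$fit_stats$family == "zinb"], "unidentified")
})
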