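test_that("null-model baseline equals the Nelson-Aalen estimator", {
  co <- toy_cohort(c(1, 2, 2, 3, 5), c(1, 1, 0, 1, 0))
  f <- fit_cox(co, character(), ties = "breslow")
  expect_length(f$beta, 0L)
  # Nelson-Aalen by hand: 1/5 at t=1, 1/4 at t=2, 1/2 at t=3
  expect_equal(f$baseline$cumhaz, cumsum(c(1 / 5, 1 / 4, 1 / 2)))
})

test_that("one-covariate fit matches brute-force likelihood maximization", {
  co <- toy_cohort(c(1.1, 2.3, 3.7, 4.2, 5.9, 7.5), c(1, 1, 0, 1, 1, 0),
                   sex = c(1, 0, 1, 0, 1, 0))
  f <- fit_cox(co, "sex")
  opt <- stats::optimize(function(b) -brute_pl(b, co$age, co$event, co$sex),
                         c(-5, 5), tol = 1e-9)
  expect_lt(abs(unname(f$beta) - opt$minimum), 1e-6)
  expect_equal(f$loglik, -opt$objective, tolerance = 1e-9)
})

test_that("score test at beta = 0 equals the log-rank chi-square", {
  co <- random_cohort(120, seed = 31)
  st <- cox_score_test(co, matrix(co$sex, ncol = 1), ties = "breslow")
  lr <- logrank_test(co$age, co$event, co$sex)
  expect_equal(st$chisq, lr$chisq, tolerance = 1e-8)
  expect_equal(st$p, lr$p, tolerance = 1e-8)
})

test_that("Martingale residuals reproduce the hand-computed example", {
  co <- toy_cohort(c(1, 2, 3), c(1, 1, 0))
  f <- fit_cox(co, character(), ties = "breslow")
  r <- martingale_residuals(f, co)
  expect_equal(unname(r), c(2 / 3, 1 / 6, -5 / 6))
})

test_that("residual identities hold on every fitted model", {
  for (seed in 1:5) {
    co <- random_cohort(300, seed = seed)
    f <- fit_cox(co, c("sex", "pc1"), ties = "breslow")
    r <- martingale_residuals(f, co)
    expect_lt(abs(sum(r)), 1e-8)
    expect_true(all(r <= 1))
  }
  # censored subject before the first event has residual exactly 0
  co <- toy_cohort(c(0.5, 1, 2), c(0, 1, 1))
  f <- fit_cox(co, character(), ties = "breslow")
  expect_equal(unname(martingale_residuals(f, co))[1], 0)
})

test_that("Efron and Breslow agree exactly when no ties exist", {
  co <- random_cohort(150, seed = 12)
  expect_equal(anyDuplicated(co$age), 0L)
  fe <- fit_cox(co, c("sex", "pc1"), ties = "efron")
  fb <- fit_cox(co, c("sex", "pc1"), ties = "breslow")
  expect_equal(fe$beta, fb$beta, tolerance = 1e-10)
  expect_equal(fe$baseline$cumhaz, fb$baseline$cumhaz, tolerance = 1e-10)
})

test_that("fit agrees with the survival package under heavy ties", {
  skip_if_not_installed("survival")
  set.seed(8)
  n <- 400
  x <- stats::rbinom(n, 1, 0.5)
  z <- stats::rnorm(n)
  t <- ceiling(stats::rexp(n, exp(0.5 * x + 0.2 * z)) * 8) / 8
  cens <- ceiling(stats::runif(n, 0, 2) * 8) / 8
  co <- toy_cohort(pmin(t, cens), as.integer(t <= cens), sex = x, pc1 = z)
  for (tie in c("efron", "breslow")) {
    f <- fit_cox(co, c("sex", "pc1"), ties = tie)
    fs <- survival::coxph(survival::Surv(age, event) ~ sex + pc1,
                          data = co, ties = tie)
    expect_equal(unname(f$beta), unname(stats::coef(fs)), tolerance = 1e-7)
    expect_equal(unname(f$var), unname(stats::vcov(fs)), tolerance = 1e-7)
  }
})

test_that("Kaplan-Meier matches hand product-limit bookkeeping", {
  km <- kaplan_meier(c(1, 1.5, 2, 3), c(1, 0, 1, 0))
  expect_equal(km$surv, c(1, 3 / 4, 3 / 8))
  expect_equal(km$n_risk, c(4, 4, 2))
  # no events -> flat at 1
  km0 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km0$surv, 1)
  # all events at one time -> single step to 0
  km1 <- kaplan_meier(c(2, 2, 2), c(1, 1, 1))
  expect_equal(km1$surv, c(1, 0))
  expect_error(kaplan_meier(numeric(0), numeric(0), character(0)))
})

test_that("log-rank test behaves on degenerate and standard input", {
  # duplicated data in both groups -> statistic 0, p = 1
  t0 <- c(1, 2, 3, 4); e0 <- c(1, 1, 0, 1)
  lr0 <- logrank_test(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chisq, 0)
  expect_equal(lr0$p, 1)
  expect_error(logrank_test(t0, e0, rep("a", 4)), "2 groups")
  skip_if_not_installed("survival")
  co <- random_cohort(200, seed = 77)
  lr <- logrank_test(co$age, co$event, co$sex)
  sd1 <- survival::survdiff(survival::Surv(age, event) ~ sex, data = co)
  expect_equal(lr$chisq, unname(sd1$chisq), tolerance = 1e-8)
})

test_that("carrier hazard ratios are estimated with Wald intervals", {
  co <- random_cohort(400, seed = 5)
  h <- cox_carrier_hr(co, co$sex, covariates = "pc1")
  f <- fit_cox(co, cbind(carrier = co$sex, pc1 = co$pc1))
  expect_equal(unname(h$hr), exp(unname(f$beta["carrier"])))
  expect_true(h$ci[1] < h$hr && h$hr < h$ci[2])
  expect_error(cox_carrier_hr(co, rep(0, nrow(co))), "zero carriers")
  # all carriers censored before the first non-carrier event -> separation
  co2 <- toy_cohort(c(0.1, 0.2, 1, 2, 3, 4), c(0, 0, 1, 1, 1, 1))
  expect_error(cox_carrier_hr(co2, c(1, 1, 0, 0, 0, 0), covariates = character()))
})

test_that("zero-event and collinear inputs are rejected", {
  co <- toy_cohort(c(1, 2), c(0, 0))
  expect_error(fit_cox(co, character()), "zero events")
  co2 <- random_cohort(50, seed = 2)
  Z <- cbind(a = co2$pc1, b = 2 * co2$pc1)
  expect_error(fit_cox(co2, Z), "collinear")
})
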