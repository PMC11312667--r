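test_that("exact HWE test matches brute-force enumeration", {
  # independent enumeration: n=100 diploids, 5 minor alleles
  enum_hwe <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    m <- nAa + 2 * min(naa, nAA)
    m <- min(nAa + 2 * naa, nAa + 2 * nAA)
    h <- seq(m %% 2, m, by = 2)
    pr <- vapply(h, function(hh) {
      a <- (m - hh) / 2
      exp(lfactorial(n) - lfactorial(n - hh - a) - lfactorial(hh) -
            lfactorial(a) + hh * log(2) + lfactorial(m) +
            lfactorial(2 * n - m) - lfactorial(2 * n))
    }, numeric(1))
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(nAa, h)] * (1 + 1e-10)])
  }
  expect_equal(hwe_exact_test(95, 5, 0), enum_hwe(95, 5, 0), tolerance = 1e-12)
  expect_equal(hwe_exact_test(96, 3, 1), enum_hwe(96, 3, 1), tolerance = 1e-12)
  expect_gt(hwe_exact_test(25, 50, 25), 0.5)     # observed is modal
  expect_equal(hwe_exact_test(100, 0, 0), 1)     # monomorphic
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)    # gross disequilibrium
  expect_error(hwe_exact_test(0, 0, 0), "zero")
})

test_that("QC filter applies the missingness/MAF/HWE rules at their boundaries", {
  set.seed(1)
  n <- 1000
  g_ok <- stats::rbinom(n, 2, 0.3)
  g_miss <- g_ok; g_miss[1:60] <- NA              # missing rate 0.06 > 0.05
  g_edge <- g_ok; g_edge[1:50] <- NA              # missing rate 0.05, retained
  g_rare <- c(rep(1, 20), rep(0, n - 20))         # MAF 0.01 exactly, retained
  g_toorare <- c(rep(1, 10), rep(0, n - 10))      # MAF 0.005 < 0.01, removed
  g_mono <- rep(0, n)                             # MAF 0, removed
  g_hwe <- c(rep(0, 500), rep(2, 500))            # no hets, HWE p ~ 0
  G <- cbind(ok = g_ok, miss = g_miss, edge = g_edge, rare = g_rare,
             toorare = g_toorare, mono = g_mono, hwe = g_hwe)
  Gq <- qc_filter(G)
  expect_setequal(colnames(Gq), c("ok", "edge", "rare"))
  log <- attr(Gq, "qc_log")
  expect_equal(unname(log["removed_missing"]), 1)
  expect_equal(unname(log["removed_hwe"]), 1)
  # fractional dosages skip the HWE rule with a warning
  Gd <- cbind(a = stats::runif(n, 0, 2))
  expect_warning(qc_filter(Gd), "Hardy-Weinberg")
})

test_that("assoc_scan equals per-variant OLS and handles degenerate dosage", {
  set.seed(2)
  n <- 300
  y <- stats::rnorm(n)
  G <- cbind(v1 = stats::rbinom(n, 2, 0.3), v2 = stats::rbinom(n, 2, 0.1),
             v3 = rep(1, n))
  G[sample(n, 10), "v2"] <- NA
  res <- assoc_scan(y, G)
  fit <- stats::lm(y ~ G[, "v1"])
  co <- summary(fit)$coefficients
  expect_equal(res$beta[1], co[2, 1], tolerance = 1e-12)
  expect_equal(res$se[1], co[2, 2], tolerance = 1e-12)
  expect_equal(res$p[1], co[2, 4], tolerance = 1e-12)
  keep <- !is.na(G[, "v2"])
  co2 <- summary(stats::lm(y[keep] ~ G[keep, "v2"]))$coefficients
  expect_equal(res$p[2], co2[2, 4], tolerance = 1e-12)
  expect_equal(res$n[2], sum(keep))
  expect_true(is.na(res$p[3]))                     # constant dosage
  # residuals orthogonal to the centered dosage -> beta exactly 0
  g <- G[, "v1"]
  y0 <- stats::resid(stats::lm(y ~ g))
  expect_lt(abs(assoc_scan(y0, cbind(g = g))$beta), 1e-12)
  # adding a constant to all residuals leaves beta unchanged
  expect_equal(assoc_scan(y + 5, G)$beta, res$beta, tolerance = 1e-12)
})

test_that("the Martingale-residual scan is calibrated under the null", {
  cfg <- sim_config(n_subjects = 2000, seed = 19)
  sim <- simulate_cohort(cfg)
  fit <- fit_cox(sim$cohort, c("sex", paste0("pc", 1:5)))
  r <- martingale_residuals(fit, sim$cohort)
  set.seed(20)
  G <- matrix(stats::rbinom(2000 * 1500, 2, 0.25), 2000, 1500)
  res <- assoc_scan(r, G)
  alpha <- mean(res$p < 0.05)
  expect_gt(alpha, 0.05 - 3 * sqrt(0.05 * 0.95 / 1500))
  expect_lt(alpha, 0.05 + 3 * sqrt(0.05 * 0.95 / 1500))
  expect_gt(inflation_lambda(res$p), 0.93)
  expect_lt(inflation_lambda(res$p), 1.07)
})

test_that("stratified scans refit the null model within the stratum", {
  cfg <- sim_config(n_subjects = 1500, seed = 23,
                    variants = data.frame(maf = c(0.3, 0.2), log_hr = c(0, 0)))
  sim <- simulate_cohort(cfg)
  full <- {
    f <- fit_cox(sim$cohort, c("sex", paste0("pc", 1:5)))
    assoc_scan(martingale_residuals(f, sim$cohort), sim$genotypes)
  }
  all_strat <- stratified_scan(sim$cohort, sim$genotypes, "all")
  expect_equal(all_strat$beta, full$beta, tolerance = 1e-10)
  # male stratum equals a run on the male subset without the sex covariate
  males <- sim$cohort$sex == 1
  fm <- fit_cox(sim$cohort[males, ], paste0("pc", 1:5))
  manual <- assoc_scan(martingale_residuals(fm, sim$cohort[males, ]),
                       sim$genotypes[males, ])
  strat <- stratified_scan(sim$cohort, sim$genotypes, "male")
  expect_equal(strat$beta, manual$beta, tolerance = 1e-10)
  dead <- sim$cohort
  dead$event <- ifelse(dead$sex == 1, 0, dead$event)
  expect_error(stratified_scan(dead, sim$genotypes, "male"), "zero events")
})

test_that("genome-wide significance uses the standard threshold", {
  expect_equal(genome_wide_significant(c(4e-8, 5e-8, NA, 1e-3)),
               c(TRUE, FALSE, FALSE, FALSE))
})
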