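test_that("carrier collapsing follows the indicator definition", {
  G <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(NA, 0, 1), c(NA, NA, NA))
  cv <- collapse_carriers(G)
  expect_equal(cv, c(0L, 1L, 1L, 1L, 0L))      # missing counts as 0
  expect_equal(cv, as.integer(apply(G, 1, function(r) any(r > 0, na.rm = TRUE))))
  expect_error(collapse_carriers(G[, 0]), "empty")
})

test_that("burden on a single het variant reproduces assoc_scan exactly", {
  set.seed(3)
  n <- 800
  g <- as.numeric(stats::rbinom(n, 1, 0.02))
  while (sum(g) < 10) g <- as.numeric(stats::rbinom(n, 1, 0.02))
  y <- stats::rnorm(n)
  b <- burden_test(y, collapse_carriers(matrix(g, ncol = 1)))
  a <- assoc_scan(y, matrix(g, ncol = 1, dimnames = list(NULL, "v")))
  expect_equal(b$beta, a$beta, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
  expect_error(burden_test(y, rep(1, n)), "all or no")
})

test_that("single-variant SKAT equals the marginal test", {
  # with one variant the ratio-form null is the exact distribution of the
  # squared sample correlation, i.e. the OLS t-test p-value
  set.seed(9)
  n <- 150
  g <- as.numeric(stats::rbinom(n, 1, 0.06))
  y <- stats::rnorm(n) + 0.4 * g
  st <- skat_test(y, matrix(g, ncol = 1))
  pt_ols <- summary(stats::lm(y ~ g))$coefficients[2, 4]
  expect_equal(st$p, pt_ols, tolerance = 1e-5)
})

test_that("SKAT p-value agrees with a permutation oracle", {
  set.seed(21)
  n <- 50
  G <- cbind(stats::rbinom(n, 1, 0.12), stats::rbinom(n, 1, 0.15),
             stats::rbinom(n, 1, 0.10))
  y <- stats::rnorm(n) + 1.0 * rowSums(G)
  st <- skat_test(y, G)
  w <- skat_weights(variant_maf(G))
  Z <- sweep(G, 2, w, "*")
  yc <- y - mean(y)
  s2 <- sum(yc^2) / (n - 1)
  B <- 40000
  set.seed(22)
  Qp <- replicate(B, {
    S <- crossprod(Z, yc[sample.int(n)])
    sum(S^2) / s2
  })
  pperm <- mean(Qp >= st$Q)
  expect_lt(abs(st$p - pperm), 3 * sqrt(pperm * (1 - pperm) / B))
})

test_that("SKAT-O endpoints reproduce the pure component tests", {
  set.seed(4)
  n <- 300
  G <- matrix(stats::rbinom(n * 4, 1, 0.04), n, 4)
  y <- stats::rnorm(n)
  st <- skat_test(y, G)
  expect_equal(skato_test(y, G, rho_grid = 0)$p, st$p, tolerance = 1e-12)
  # rho = 1: weighted-sum burden; oracle is the OLS t-test on the
  # weighted burden score (exact ratio-form equivalence, k = 1)
  w <- skat_weights(variant_maf(G))
  score <- drop(G %*% w)
  p_oracle <- summary(stats::lm(y ~ score))$coefficients[2, 4]
  expect_equal(skato_test(y, G, rho_grid = 1)$p, p_oracle, tolerance = 1e-5)
})

test_that("the SKAT-O omnibus stays within its min-p envelope", {
  set.seed(15)
  n <- 500
  for (rep in 1:10) {
    G <- matrix(stats::rbinom(n * 5, 1, 0.015), n, 5)
    if (any(colSums(G) == 0)) next
    y <- stats::rnorm(n) + stats::rnorm(1, 0, 0.3) * rowSums(G)
    o <- skato_test(y, G)
    Tmin <- min(o$p_rho)
    expect_gte(o$p, Tmin - 1e-10)
    expect_lte(o$p, 8 * Tmin + 1e-10)
    b <- burden_test(y, collapse_carriers(G))
    s <- skat_test(y, G)
    # the min-p omnibus can exceed both components slightly (multiplicity
    # over the grid) when neither signal dominates
    expect_lte(o$p, max(b$p, s$p) + 0.05)
  }
})

test_that("SKAT outpowers burden under opposing effect directions", {
  set.seed(30)
  n <- 500
  reps <- 150
  hits <- matrix(FALSE, reps, 2)
  for (r in seq_len(reps)) {
    g1 <- stats::rbinom(n, 1, 0.05)
    g2 <- stats::rbinom(n, 1, 0.05)
    y <- stats::rnorm(n) + 0.6 * g1 - 0.6 * g2
    G <- cbind(g1, g2)
    if (sum(collapse_carriers(G)) %in% c(0, n)) next
    hits[r, 1] <- burden_test(y, collapse_carriers(G))$p < 0.05
    hits[r, 2] <- skat_test(y, G)$p < 0.05
  }
  expect_gt(mean(hits[, 2]), mean(hits[, 1]))
})

test_that("gene-wide and per-variant thresholds follow Bonferroni arithmetic", {
  expect_equal(gene_wide_threshold(1, n_methods = 1), 0.05)
  expect_equal(gene_wide_threshold(c(100, 150), n_methods = 2), 1e-4)
  # 67,568 total tests -> 7.4e-7 at two significant figures
  expect_equal(signif(gene_wide_threshold(33784, n_methods = 2), 2), 7.4e-07)
  expect_error(gene_wide_threshold(0), "zero tests")
})

test_that("per-variant Cox screen applies MAC and Bonferroni rules", {
  cfg <- sim_config(n_subjects = 3000, seed = 41,
                    genes = list(list(gene = "G1", n_variants = 6,
                                      carrier_freq = 0.004, class = "LOF",
                                      log_hr = log(3))))
  sim <- simulate_cohort(cfg)
  Gs <- sim$genes$genotypes
  Gs[, 6] <- 0; Gs[1:2, 6] <- 1          # MAC 2 -> excluded
  pv <- per_variant_cox(sim$cohort, Gs)
  expect_false("G1_v6" %in% pv$variant_id)
  expect_equal(attr(pv, "n_tested"), nrow(pv))
  expect_equal(attr(pv, "threshold"), 0.05 / nrow(pv))
  expect_true(all(pv$mac >= 3))
  expect_true(all(pv$hr > 0, na.rm = TRUE))
})

test_that("run_gene_tests assembles per-set results", {
  cfg <- sim_config(n_subjects = 2000, seed = 55,
                    genes = list(
                      list(gene = "GA", n_variants = 8, carrier_freq = 0.003,
                           class = "LOF", log_hr = 0.5),
                      list(gene = "GB", n_variants = 8, carrier_freq = 0.003,
                           class = "LOF", log_hr = 0)))
  sim <- simulate_cohort(cfg)
  fit <- fit_cox(sim$cohort, c("sex", paste0("pc", 1:5)))
  r <- martingale_residuals(fit, sim$cohort)
  sets <- build_gene_sets(sim$genes$genotypes, sim$genes$annotations, "LOF")
  out <- run_gene_tests(r, sim$genes$genotypes, sets)
  expect_setequal(out$gene, c("GA", "GB"))
  expect_true(all(out$n_carriers >= 10))
  expect_true(all(out$burden_p > 0 & out$burden_p <= 1))
  expect_true(all(out$skato_p > 0 & out$skato_p <= 1))
})
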