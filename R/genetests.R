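# Gene-based rare-variant association on the Martingale-residual
# phenotype. The burden test collapses the gene's variants into a
# binary carrier indicator (G_i = 1 iff sum_j g_ij > 0) and regresses
# the residual on it; SKAT keeps the per-variant genotypes with
# Beta(MAF; 1, 25) weights; SKAT-O combines the two over a grid of
# mixing weights rho with the one-dimensional omnibus integration.

#' Collapse a gene's variants into a carrier indicator
#'
#' `G_i = 1` iff the subject carries a minor allele at any member
#' variant (dosage sum > 0). Missing dosages count as non-carrier.
#'
#' @param G_sub subjects x member-variants dosage matrix
#' @return integer 0/1 vector, one entry per subject
#' @export
collapse_carriers <- function(G_sub) {
  if (is.null(dim(G_sub))) G_sub <- matrix(G_sub, ncol = 1L)
  if (ncol(G_sub) == 0L) stop("empty variant set")
  as.integer(rowSums(G_sub, na.rm = TRUE) > 0)
}

#' Burden test of a carrier indicator against the residual phenotype
#'
#' OLS of the Martingale residual on the 0/1 carrier indicator with an
#' intercept; two-sided t-test. For a single-variant set of
#' heterozygous carriers this reproduces [assoc_scan()] exactly.
#'
#' @param residuals Martingale residuals
#' @param carrier 0/1 carrier vector from [collapse_carriers()]
#' @return list with `beta`, `se`, `p`, `n_carriers`
#' @export
burden_test <- function(residuals, carrier) {
  y <- as.numeric(residuals)
  x <- as.numeric(carrier)
  n <- length(y)
  stopifnot(length(x) == n)
  nc <- sum(x > 0)
  if (nc == 0L || nc == n) stop("all or no subjects are carriers")
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  syy <- sum(y^2) - sum(y)^2 / n
  beta <- sxy / sxx
  rss <- syy - sxy^2 / sxx
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- beta / se
  list(beta = beta, se = se,
       p = 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE),
       n_carriers = nc)
}

#' Beta(1, 25) MAF weights for rare-variant kernels
#' @param maf per-variant minor allele frequencies
#' @param a1,a2 Beta density parameters
#' @return per-variant weights
#' @export
skat_weights <- function(maf, a1 = 1, a2 = 25) {
  stats::dbeta(maf, a1, a2)
}

# shared setup: weighted, column-centered genotypes and the score vector
skat_prep <- function(residuals, G_sub, weights = NULL) {
  if (is.null(dim(G_sub))) G_sub <- matrix(G_sub, ncol = 1L)
  y <- as.numeric(residuals)
  n <- length(y)
  stopifnot(nrow(G_sub) == n)
  G0 <- G_sub
  G0[is.na(G0)] <- 0
  if (is.null(weights)) weights <- skat_weights(variant_maf(G0))
  yc <- y - mean(y)
  s2 <- sum(yc^2) / (n - 1)
  if (s2 <= 0) stop("residual phenotype has zero variance")
  Z <- sweep(G0, 2L, weights, "*")
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  S <- drop(crossprod(Z, yc))   # equals crossprod(Zc, yc) since sum(yc) = 0
  list(Zc = Zc, S = S, s2 = s2, k = ncol(G0), n = n)
}

#' SKAT variance-component test on the residual phenotype
#'
#' `Q = (y - ybar)' G W^2 G' (y - ybar) / sigma^2` with Beta(1,25) MAF
#' weights by default; the p-value comes from the matching
#' mixture-of-chi-squares distribution via characteristic-function
#' inversion, with Liu moment-matching as fallback.
#'
#' @param residuals Martingale residuals
#' @param G_sub subjects x member-variants dosage matrix
#' @param weights optional per-variant weights (default Beta(1,25) on
#'   cohort MAF)
#' @param null `"exact"` (ratio-form null absorbing the variance
#'   estimate, see [skat_pvalue()]) or `"asymptotic"`
#' @return list with `Q`, `p`, `lambda` (mixture weights) and `method`
#' @export
skat_test <- function(residuals, G_sub, weights = NULL,
                      null = c("exact", "asymptotic")) {
  null <- match.arg(null)
  pr <- skat_prep(residuals, G_sub, weights)
  Q <- sum(pr$S^2) / pr$s2
  K <- crossprod(pr$Zc)
  lambda <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(lambda, 0) * 1e-10]
  if (!length(lambda)) {
    warning("zero-variance kernel; p set to 1")
    return(list(Q = Q, p = 1, lambda = numeric(), method = "degenerate"))
  }
  p <- skat_pvalue(Q, lambda, pr$n, null = null)
  list(Q = Q, p = as.numeric(p), lambda = lambda,
       method = attr(p, "method"))
}

# square root of R_rho = (1-rho) I + rho J (k x k), closed form a*I + b*J
rho_sqrt <- function(k, rho) {
  a <- sqrt(1 - rho)
  b <- (sqrt(1 - rho + k * rho) - a) / k
  diag(a, k) + matrix(b, k, k)
}

#' SKAT-O omnibus test over a grid of burden/SKAT mixing weights
#'
#' `Q_rho = (1 - rho) Q_SKAT + rho Q_burden` (the burden component here
#' is the weighted-sum score, the standard kernel at rho = 1). Each
#' `Q_rho` gets a mixture-of-chi-squares p-value; the omnibus p-value of
#' the minimum over the grid is computed by one-dimensional integration
#' over the shared chi-square(1) factor. A single-element grid returns
#' that component's p-value directly. If the integration fails the
#' Bonferroni bound over the grid is used (logged via the `method`
#' field).
#'
#' @inheritParams skat_test
#' @param rho_grid mixing weights in \[0,1\]
#' @return list with `p`, `rho_min` (grid point attaining the minimum
#'   p), `p_rho` (per-grid-point p-values), `method`
#' @export
skato_test <- function(residuals, G_sub,
                       rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                       weights = NULL, null = c("exact", "asymptotic")) {
  null <- match.arg(null)
  pr <- skat_prep(residuals, G_sub, weights)
  k <- pr$k
  QS <- sum(pr$S^2) / pr$s2
  QB <- sum(pr$S)^2 / pr$s2
  K <- crossprod(pr$Zc)
  p_rho <- numeric(length(rho_grid))
  Q_rho <- (1 - rho_grid) * QS + rho_grid * QB
  lam_list <- vector("list", length(rho_grid))
  for (i in seq_along(rho_grid)) {
    R2 <- rho_sqrt(k, rho_grid[i])
    lam <- eigen(R2 %*% K %*% R2, symmetric = TRUE, only.values = TRUE)$values
    lam <- lam[lam > max(lam, 0) * 1e-10]
    lam_list[[i]] <- lam
    p_rho[i] <- as.numeric(skat_pvalue(Q_rho[i], lam, pr$n, null = null))
  }
  names(p_rho) <- rho_grid
  imin <- which.min(p_rho)
  if (length(rho_grid) == 1L)
    return(list(p = p_rho[[1L]], rho_min = rho_grid[1L], p_rho = p_rho,
                method = "single-rho"))
  Tmin <- p_rho[[imin]]

  # Lee et al. decomposition: common factor along the mean genotype
  # direction, remainder as a fixed chi-square mixture
  rg <- pmin(rho_grid, 0.999)           # rho = 1 degenerates; standard cap
  zbar <- rowMeans(pr$Zc)
  zbar2 <- sum(zbar^2)
  if (zbar2 <= 0) return(list(p = Tmin, rho_min = rho_grid[imin],
                              p_rho = p_rho, method = "degenerate"))
  cof <- drop(crossprod(zbar, pr$Zc)) / zbar2
  Zi1 <- outer(zbar, cof)
  Zi2 <- pr$Zc - Zi1
  K22 <- crossprod(Zi2)
  lambda <- eigen(K22, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(lambda, 0) * 1e-10]
  if (!length(lambda)) lambda <- 1e-12
  MuQ <- sum(lambda)
  VarRemain <- 4 * sum(crossprod(Zi1) * K22)
  VarQ <- 2 * sum(lambda^2) + VarRemain
  tau <- (k^2 * rg + (1 - rg) * sum(cof^2)) * zbar2
  qmin <- vapply(seq_along(rg), function(i)
    liu_quantile(Tmin, lam_list[[i]]), numeric(1))

  sd1 <- sqrt(max(VarQ - VarRemain, 0)) / sqrt(VarQ)
  kappa_cdf <- function(m) {
    # P(kappa <= m) with the variance of the remainder term folded in
    mst <- (m - MuQ) * sd1 + MuQ
    vapply(mst, function(q) {
      if (q <= 0) return(0)
      pv <- quadform_pvalue(q, lambda, acc = 1e-5)
      1 - as.numeric(pv)
    }, numeric(1))
  }
  # the minimum over rho of (qmin - tau x)/(1 - rho) is decreasing in x;
  # tabulate the remainder CDF over its range once and interpolate, so
  # the outer quadrature does not re-invert the characteristic function
  mfun <- function(x) vapply(x, function(xx)
    min((qmin - tau * xx) / (1 - rg)), numeric(1))
  mhi <- mfun(0); mlo <- mfun(40)
  if (mhi <= 0) {
    grid_cdf <- function(m) rep(0, length(m))
  } else {
    mg <- seq(max(mlo, 0), mhi, length.out = 40L)
    cg <- cummax(pmin(pmax(kappa_cdf(mg), 0), 1))
    sf <- stats::splinefun(mg, cg, method = "monoH.FC")
    grid_cdf <- function(m)
      ifelse(m <= mg[1L], 0, pmin(pmax(sf(pmin(m, mhi)), 0), 1))
  }
  integrand <- function(x) {
    grid_cdf(mfun(x)) * stats::dchisq(x, df = 1)
  }
  val <- tryCatch(
    stats::integrate(integrand, 0, 40, subdivisions = 2000L,
                     abs.tol = 1e-12, stop.on.error = FALSE),
    error = function(e) NULL)
  if (is.null(val) || !is.finite(val$value)) {
    # Bonferroni over the grid
    return(list(p = min(1, Tmin * length(rho_grid)),
                rho_min = rho_grid[imin], p_rho = p_rho,
                method = "bonferroni"))
  }
  p <- 1 - val$value
  # the omnibus cannot beat its best component nor exceed Bonferroni
  p <- min(max(p, Tmin), Tmin * length(rho_grid), 1)
  list(p = p, rho_min = rho_grid[imin], p_rho = p_rho, method = "integration")
}

#' Run burden, SKAT and SKAT-O for a list of gene sets
#'
#' @param residuals Martingale residuals aligned with `G`
#' @param G full dosage matrix
#' @param gene_sets list from [build_gene_sets()]
#' @return data.frame with one row per gene set: `gene`, `class`,
#'   `n_variants`, `n_carriers`, `burden_beta`, `burden_p`, `skat_Q`,
#'   `skat_p`, `skato_p`, `skato_rho`
#' @export
run_gene_tests <- function(residuals, G, gene_sets) {
  rows <- lapply(gene_sets, function(gs) {
    Gs <- G[, gs$variant_ids, drop = FALSE]
    carrier <- collapse_carriers(Gs)
    b <- burden_test(residuals, carrier)
    s <- skat_test(residuals, Gs)
    o <- skato_test(residuals, Gs)
    data.frame(gene = gs$gene, class = gs$class,
               n_variants = gs$n_variants, n_carriers = gs$n_carriers,
               burden_beta = b$beta, burden_p = b$p,
               skat_Q = s$Q, skat_p = s$p,
               skato_p = o$p, skato_rho = o$rho_min,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  rows
}

#' Gene-wide Bonferroni significance threshold
#'
#' `alpha` divided by the total number of gene-level tests: genes per
#' class summed over classes, times the number of statistical methods.
#'
#' @param n_genes_per_class integer vector, genes tested in each class
#' @param n_methods number of test methods applied to each set
#' @param alpha family-wise level
#' @return the threshold
#' @export
gene_wide_threshold <- function(n_genes_per_class, n_methods = 2L,
                                alpha = 0.05) {
  total <- sum(n_genes_per_class) * n_methods
  if (total <= 0) stop("zero tests")
  alpha / total
}

#' Per-variant carrier Cox screen within a gene
#'
#' For each member variant with minor allele count at least `min_mac`,
#' fits a covariate-adjusted Cox model on that variant's carrier status
#' and reports the hazard ratio, with the Bonferroni threshold
#' `alpha / n_tested` attached.
#'
#' @param cohort cohort data.frame
#' @param G_sub dosage matrix of the gene's member variants
#' @param covariates cohort covariate columns
#' @param min_mac minimum minor allele count to test
#' @param alpha family-wise level for the attached threshold
#' @return data.frame `variant_id`, `mac`, `hr`, `ci_lower`, `ci_upper`,
#'   `p`, with attributes `threshold` and `n_tested`
#' @export
per_variant_cox <- function(cohort, G_sub,
                            covariates = c("sex", paste0("pc", 1:5)),
                            min_mac = 3L, alpha = 0.05) {
  if (is.null(dim(G_sub))) G_sub <- matrix(G_sub, ncol = 1L)
  mac <- variant_mac(G_sub)
  test <- which(mac >= min_mac)
  rows <- lapply(test, function(j) {
    g <- G_sub[, j]
    keep <- !is.na(g)
    res <- tryCatch(
      cox_carrier_hr(cohort[keep, , drop = FALSE], g[keep] > 0, covariates),
      error = function(e) NULL)
    if (is.null(res)) {
      data.frame(variant_id = colnames(G_sub)[j], mac = mac[j],
                 hr = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                 p = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(variant_id = colnames(G_sub)[j], mac = mac[j],
                 hr = res$hr, ci_lower = res$ci[1], ci_upper = res$ci[2],
                 p = res$p, stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(), mac = numeric(), hr = numeric(),
               ci_lower = numeric(), ci_upper = numeric(), p = numeric())
  rownames(out) <- NULL
  attr(out, "n_tested") <- length(test)
  attr(out, "threshold") <- if (length(test)) alpha / length(test) else NA_real_
  out
}
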