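# Common-variant QC and the Martingale-residual association scan.
# The scan is the two-stage design: a Cox null model (sex + PCs, no
# genotype) yields per-subject Martingale residuals, which are then
# regressed on dosage one variant at a time (OLS with intercept).

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test: given the allele counts, sums the
#' probabilities of all heterozygote counts no more probable than the
#' observed one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major hom, het, minor hom)
#' @return the exact p-value
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  m <- min(n_Aa + 2 * n_aa, n_Aa + 2 * n_AA)  # minor allele copies
  if (m == 0) return(1)                   # monomorphic: single outcome
  h <- seq(m %% 2, m, by = 2)             # possible het counts, same parity
  naa <- (m - h) / 2
  nAA <- n - h - naa
  logp <- lfactorial(n) - lfactorial(nAA) - lfactorial(h) - lfactorial(naa) +
    h * log(2) + lfactorial(m) + lfactorial(2 * n - m) - lfactorial(2 * n)
  pr <- exp(logp - logsumexp(logp))
  obs <- pr[match(n_Aa, h)]
  if (is.na(obs)) stop("observed heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' Quality-control filter for a genotype matrix
#'
#' Removes variants with genotype missing rate above `max_missing`,
#' minor allele frequency below `min_maf`, or exact Hardy-Weinberg
#' p-value below `hwe_alpha`. HWE needs hard calls (all dosages in
#' \{0,1,2\}); variants with fractional dosages skip the HWE rule with
#' a warning. Per-rule removal counts are attached as attribute
#' `qc_log`.
#'
#' @param G subjects x variants dosage matrix
#' @param max_missing maximum tolerated missing rate (exclusive rule:
#'   rate > threshold removes)
#' @param min_maf minimum MAF (exclusive rule: MAF < threshold removes)
#' @param hwe_alpha HWE p-value cutoff (exclusive rule: p < alpha removes)
#' @return the filtered matrix with attribute `qc_log`
#' @export
qc_filter <- function(G, max_missing = 0.05, min_maf = 0.01,
                      hwe_alpha = 1e-6) {
  miss <- variant_missing_rate(G)
  maf <- variant_maf(G)
  fail_miss <- miss > max_missing
  fail_maf <- is.na(maf) | maf < min_maf
  obs <- G[!is.na(G)]
  hard <- all(obs == round(obs))
  if (hard) {
    hwe_p <- apply(G, 2L, function(g) {
      g <- g[!is.na(g)]
      if (!length(g)) return(NA_real_)
      hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
    })
    fail_hwe <- !is.na(hwe_p) & hwe_p < hwe_alpha
  } else {
    warning("fractional dosages: Hardy-Weinberg filter skipped")
    fail_hwe <- rep(FALSE, ncol(G))
  }
  drop <- fail_miss | fail_maf | fail_hwe
  log <- c(n_input = ncol(G), removed_missing = sum(fail_miss),
           removed_maf = sum(fail_maf), removed_hwe = sum(fail_hwe),
           n_retained = sum(!drop))
  if (all(drop)) warning("no variants pass QC")
  out <- G[, !drop, drop = FALSE]
  attr(out, "qc_log") <- log
  out
}

#' Association scan of Martingale residuals on genotype dosage
#'
#' Per variant, ordinary least squares of the residual phenotype on
#' dosage with an intercept, over subjects non-missing at that variant
#' (complete-case, no imputation); two-sided t-test p-value. Covariates
#' are not re-included by default: the Cox null model already absorbed
#' them.
#'
#' @param residuals Martingale residuals aligned with the rows of `G`
#' @param G subjects x variants dosage matrix (post-QC)
#' @return data.frame with `variant_id`, `beta`, `se`, `p`, `n`, `maf`;
#'   constant-dosage variants get `p = NA`
#' @export
assoc_scan <- function(residuals, G) {
  if (length(residuals) != nrow(G))
    stop("residuals and genotype matrix are not aligned on subjects")
  y <- as.numeric(residuals)
  M <- !is.na(G)
  G0 <- G
  G0[!M] <- 0
  n <- colSums(M)
  Sx <- colSums(G0)
  Sxx <- colSums(G0^2)
  Sy <- colSums(y * M)
  Sxy <- colSums(y * G0)
  Syy <- colSums(y^2 * M)
  sxx <- Sxx - Sx^2 / n
  sxy <- Sxy - Sx * Sy / n
  syy <- Syy - Sy^2 / n
  beta <- ifelse(sxx > 0, sxy / sxx, 0)
  rss <- pmax(syy - ifelse(sxx > 0, sxy^2 / sxx, 0), 0)
  df <- n - 2
  s2 <- ifelse(df > 0, rss / df, NA_real_)
  se <- ifelse(sxx > 0, sqrt(s2 / sxx), NA_real_)
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[sxx <= 0] <- NA_real_
  data.frame(variant_id = colnames(G) %||% paste0("v", seq_len(ncol(G))),
             beta = beta, se = se, p = p, n = n, maf = variant_maf(G),
             row.names = NULL)
}

#' Sex-stratified (or whole-cohort) Martingale-residual scan
#'
#' Refits the Cox null model within the stratum -- dropping sex as a
#' covariate for single-sex strata -- recomputes residuals, and runs
#' [assoc_scan()] on the stratum's genotypes.
#'
#' @param cohort cohort data.frame
#' @param G genotype matrix aligned with the cohort rows
#' @param stratum `"all"`, `"male"` or `"female"`; sex coding in the
#'   cohort is 1 = male, 0 = female
#' @param covariates covariate columns for the null model (sex is
#'   removed automatically in sex strata)
#' @param ties Cox tie handling
#' @return data.frame as from [assoc_scan()]
#' @export
stratified_scan <- function(cohort, G, stratum = c("all", "male", "female"),
                            covariates = c("sex", paste0("pc", 1:5)),
                            ties = "efron") {
  stratum <- match.arg(stratum)
  keep <- switch(stratum,
                 all = rep(TRUE, nrow(cohort)),
                 male = cohort$sex == 1,
                 female = cohort$sex == 0)
  if (!any(keep)) stop("empty stratum: ", stratum)
  sub <- cohort[keep, , drop = FALSE]
  if (sum(sub$event) == 0) stop("stratum has zero events: ", stratum)
  covs <- covariates
  if (stratum != "all") covs <- setdiff(covs, "sex")
  if (length(covs) == 1L && stats::sd(sub[[covs]]) == 0) covs <- character()
  fit <- fit_cox(sub, covariates = covs, ties = ties)
  res <- martingale_residuals(fit, sub)
  assoc_scan(res, G[keep, , drop = FALSE])
}

#' Genomic inflation factor
#'
#' Median chi-square of the observed p-values over the null median
#' (0.456); values near 1 indicate a calibrated scan.
#'
#' @param p vector of p-values
#' @return lambda_GC
#' @export
inflation_lambda <- function(p) {
  p <- p[!is.na(p)]
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Genome-wide significance flag
#' @param p p-values
#' @param threshold genome-wide level (default 5e-8)
#' @return logical vector
#' @export
genome_wide_significant <- function(p, threshold = 5e-8) {
  !is.na(p) & p < threshold
}
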