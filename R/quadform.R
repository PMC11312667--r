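# Tail probabilities of positively weighted sums of chi-square(1)
# variables, Q ~ sum_j lambda_j X_j. Primary route: numerical inversion
# of the characteristic function (Imhof's integral, with a truncation
# point chosen from the requested absolute accuracy). Fallback:
# Liu-Tang-Zhang moment matching to a non-central chi-square, in the
# modified form that matches kurtosis when possible.

#' Tail probability of a weighted sum of chi-squares (CF inversion)
#'
#' Computes `P(Q > q)` for `Q = sum lambda_j chisq_1` by numerically
#' inverting the characteristic function. A single weight is handled
#' exactly through `pchisq`. Returns `NA` when the integration cannot
#' reach the requested accuracy; callers fall back to [liu_pvalue()].
#'
#' @param q observed statistic
#' @param lambda weights (may be negative)
#' @param acc target absolute accuracy
#' @param mult integer multiplicities of the weights (default all 1)
#' @return upper-tail probability, or NA on failure
#' @export
davies_pvalue <- function(q, lambda, acc = 1e-9, mult = NULL) {
  if (is.null(mult)) mult <- rep(1L, length(lambda))
  keep <- abs(lambda) > max(abs(lambda)) * 1e-12
  lambda <- lambda[keep]
  mult <- mult[keep]
  k <- sum(mult)
  if (k == 0L) stop("no nonzero weights")
  pos <- lambda[lambda > 0]
  neg <- lambda[lambda < 0]
  if (!length(pos)) return(if (q >= 0) 0 else
    1 - davies_pvalue(-q, -lambda, acc, mult))
  if (k == 1L && q >= 0)
    return(stats::pchisq(q / lambda, df = 1, lower.tail = FALSE))
  sc <- max(abs(lambda))
  l <- lambda / sc
  q0 <- q / sc

  # Gil-Pelaez inversion, midpoint sum with spacing Delta = 2*pi / P0.
  # The discretization error equals the probability mass wrapped in
  # from q +/- multiples of P0; both tails are bounded via Chernoff
  # bounds on the cumulant generating function.
  K_cgf <- function(s) -0.5 * colSums(mult * log1p(-2 * outer(l, s)))
  chernoff_log <- function(x, upper) {
    lim <- if (upper) 1 / (2 * max(l)) else
      if (length(neg)) -1 / (2 * min(l)) else Inf
    s <- seq(0.02, 0.98, length.out = 50) * min(lim, 50)
    if (!upper) s <- -s
    min(K_cgf(s) - s * x)
  }
  x <- sum(abs(l)) + 10
  while (chernoff_log(q0 + x, TRUE) > log(acc * 0.05) && x < 1e7) x <- x * 1.5
  if (length(neg)) {
    while (chernoff_log(q0 - x, FALSE) > log(acc * 0.05) && x < 1e7) x <- x * 1.5
  } else {
    while (q0 - x > 0 && x < 1e7) x <- x * 1.5   # images below 0 carry no mass
  }
  P0 <- x
  Delta <- 2 * pi / P0

  # truncation point U: the integrand oscillates (asymptotic half-period
  # 2*pi/|q0|, or none when q0 ~ 0) inside the monotone envelope
  # env(u) = 1/(u * prod(1+l^2 u^2)^(1/4)). Stop when either
  #  - the absolute envelope tail integral is below acc (valid once
  #    enough weights have passed their atan knee, K_eff >= 2), or
  #  - the alternating-series bound (one half-period's area) is below
  #    acc, valid once the residual atan phase drift is small
  osc <- if (abs(q0) > 1e-12) 2 * pi / abs(q0) else Inf
  tail_bound <- function(u) {
    env <- exp(-log(u) - 0.25 * sum(mult * log1p(l^2 * u^2)))
    keff <- sum(mult[abs(l) * u >= 1])
    t_abs <- if (keff >= 2) env * u * 2 / keff else Inf
    drift <- 0.5 * sum(mult * (pi / 2 - atan(abs(l) * u)))
    t_alt <- if (is.finite(osc) && drift < pi / 4) 2 * env * osc / pi else Inf
    min(t_abs, t_alt)
  }
  U <- 1
  while (tail_bound(U) > acc && U < 1e12) U <- U * 1.4
  N <- ceiling(U / Delta)
  if (N > 2e7) return(NA_real_)

  chunk <- max(1e4, floor(4e6 / k))
  total <- 0
  n0 <- 0
  while (n0 < N) {
    nn <- min(chunk, N - n0)
    u <- (n0 + seq_len(nn) - 0.5) * Delta
    lu <- outer(l, u)
    theta <- 0.5 * colSums(mult * atan(lu)) - 0.5 * q0 * u
    logrho <- 0.25 * colSums(mult * log1p(lu^2))
    total <- total + sum(sin(theta) * exp(-log(u) - logrho))
    n0 <- n0 + nn
  }
  p <- 0.5 + Delta * total / pi
  if (p < -1e-6 || p > 1 + 1e-6) return(NA_real_)
  min(max(p, 0), 1)
}

# central moments of the mixture, shared by the Liu routines
liu_params <- function(lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    df <- a^2 - 2 * delta
  } else {
    delta <- 0
    df <- 1 / s2
  }
  list(muQ = c1, sigmaQ = sqrt(2 * c2), muX = df + delta,
       sigmaX = sqrt(2 * (df + 2 * delta)), df = df, delta = delta)
}

#' Liu moment-matching tail probability
#'
#' Matches the mixture's first moments (and kurtosis where achievable)
#' to a non-central chi-square; used when characteristic-function
#' inversion fails or for very small tail areas.
#'
#' @inheritParams davies_pvalue
#' @return upper-tail probability
#' @export
liu_pvalue <- function(q, lambda) {
  pp <- liu_params(lambda)
  tstar <- (q - pp$muQ) / pp$sigmaQ
  x <- tstar * pp$sigmaX + pp$muX
  stats::pchisq(x, df = pp$df, ncp = pp$delta, lower.tail = FALSE)
}

# upper-tail quantile of the mixture by Liu matching (used for the
# SKAT-O per-rho quantiles at the minimum-p level)
liu_quantile <- function(p_upper, lambda) {
  pp <- liu_params(lambda)
  x <- stats::qchisq(p_upper, df = pp$df, ncp = pp$delta, lower.tail = FALSE)
  (x - pp$muX) / pp$sigmaX * pp$sigmaQ + pp$muQ
}

# Davies with Liu fallback; attribute "method" records which was used
quadform_pvalue <- function(q, lambda, acc = 1e-9) {
  p <- davies_pvalue(q, lambda, acc)
  method <- "davies"
  # very small tails are where the oscillatory integral loses accuracy
  if (is.na(p) || p < acc * 10) {
    p <- liu_pvalue(q, lambda)
    method <- "liu"
  }
  structure(max(p, .Machine$double.xmin), method = method)
}

#' P-value for a SKAT-type statistic on a residual phenotype
#'
#' `Q = S'S / sigma_hat^2` with `sigma_hat^2` the intercept-only
#' residual variance on `n - 1` degrees of freedom. The default
#' `"exact"` null treats the statistic as the scale-free ratio
#' `(n-1) * yc' K yc / (yc' yc)` whose distribution under a Gaussian
#' phenotype is that of a signed mixture of chi-squares -- this absorbs
#' the variability of the variance estimate, which matters at small n.
#' `"asymptotic"` uses the large-n mixture `sum lambda_j chisq_1`
#' directly. Both invert the characteristic function, falling back to
#' Liu moment matching on failure.
#'
#' @param Q observed statistic
#' @param lambda nonzero eigenvalues of the centered weighted kernel
#' @param n sample size
#' @param null `"exact"` or `"asymptotic"`
#' @param acc target accuracy of the inversion
#' @return p-value with attribute `method`
#' @export
skat_pvalue <- function(Q, lambda, n, null = c("exact", "asymptotic"),
                        acc = 1e-9) {
  null <- match.arg(null)
  if (Q <= 0) return(structure(1, method = "degenerate"))
  k <- length(lambda)
  if (null == "exact" && n - 1L > k) {
    wts <- c((n - 1) * lambda - Q, -Q)
    mlt <- c(rep(1L, k), n - 1L - k)
    p <- davies_pvalue(0, wts, acc = acc, mult = mlt)
    if (!is.na(p)) return(structure(max(p, .Machine$double.xmin),
                                    method = "davies-exact"))
  }
  quadform_pvalue(Q, lambda, acc = acc)
}
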