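# Cox proportional-hazards machinery. The model is
#   H(t | z) = H0(t) * exp(z' beta)
# fitted by Newton-Raphson maximization of the partial likelihood with
# Efron (default) or Breslow handling of tied event times. The baseline
# cumulative hazard H0 is the Breslow (or Efron-adjusted) step-function
# estimator, and Martingale residuals
#   M_i = delta_i - H0(t_i) * exp(z_i' beta)
# are the quantitative phenotype carried into the association scans.
# Time is age in years with no delayed entry.

# partial log-likelihood, gradient and (negative) Hessian at beta.
# Data must be sorted ascending in time. Returns list(ll, grad, info).
cox_pl_derivs <- function(time, status, Z, beta, ties) {
  n <- length(time)
  p <- ncol(Z)
  eta <- if (p) drop(Z %*% beta) else numeric(n)
  w <- exp(eta)
  # suffix (risk-set) sums: subject i's risk set is all j with time_j >= time_i
  S0 <- rev(cumsum(rev(w)))
  if (p) {
    wZ <- Z * w
    S1 <- apply(wZ, 2L, function(col) rev(cumsum(rev(col))))
    ZZ <- matrix(0, n, p * p)
    for (a in seq_len(p)) for (b in seq_len(p))
      ZZ[, (a - 1L) * p + b] <- Z[, a] * Z[, b] * w
    S2 <- apply(ZZ, 2L, function(col) rev(cumsum(rev(col))))
  }
  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  first_idx <- match(time, time)       # first sorted index of each time value
  ev_all <- which(status == 1)
  t_ev <- time[ev_all]
  tied_times <- unique(t_ev[duplicated(t_ev)])
  # untied events (and all events under Breslow): fully vectorized
  vec_ev <- if (ties == "breslow") ev_all else
    ev_all[!t_ev %in% tied_times]
  if (length(vec_ev)) {
    i0 <- first_idx[vec_ev]
    s0 <- S0[i0]
    ll <- ll + sum(eta[vec_ev]) - sum(log(s0))
    if (p) {
      M1 <- S1[i0, , drop = FALSE] / s0
      grad <- grad + colSums(Z[vec_ev, , drop = FALSE]) - colSums(M1)
      info <- info + matrix(colSums(S2[i0, , drop = FALSE] / s0), p, p) -
        crossprod(M1)
    }
  }
  ut <- if (ties == "breslow") numeric(0) else tied_times
  for (t0 in ut) {
    idx <- which(time == t0)
    ev <- idx[status[idx] == 1]
    d <- length(ev)
    i0 <- idx[1L]
    s0 <- S0[i0]
    s1 <- if (p) S1[i0, ] else numeric(0)
    s2 <- if (p) matrix(S2[i0, ], p, p) else matrix(0, 0, 0)
    ll <- ll + sum(eta[ev])
    if (p) grad <- grad + colSums(Z[ev, , drop = FALSE])
    {
      s0d <- sum(w[ev])
      if (p) {
        s1d <- colSums(Z[ev, , drop = FALSE] * w[ev])
        s2d <- matrix(0, p, p)
        for (a in seq_len(p)) for (b in seq_len(p))
          s2d[a, b] <- sum(Z[ev, a] * Z[ev, b] * w[ev])
      }
      for (l in seq_len(d) - 1L) {
        f <- l / d
        c0 <- s0 - f * s0d
        ll <- ll - log(c0)
        if (p) {
          c1 <- s1 - f * s1d
          c2 <- s2 - f * s2d
          m1 <- c1 / c0
          grad <- grad - m1
          info <- info + (c2 / c0 - tcrossprod(m1))
        }
      }
    }
  }
  list(ll = ll, grad = grad, info = info)
}

# baseline cumulative hazard increments at unique event times, given the
# fitted linear predictor. Breslow: d / S0; Efron: sum_l 1/(S0 - l/d * S0d).
cox_baseline <- function(time, status, eta, ties) {
  w <- exp(eta)
  S0 <- rev(cumsum(rev(w)))
  first_idx <- match(time, time)
  ev_all <- which(status == 1)
  t_ev <- time[ev_all]
  ut <- unique(t_ev)
  d_by_t <- as.integer(table(factor(t_ev, levels = ut)))
  i0 <- first_idx[ev_all[match(ut, t_ev)]]
  inc <- d_by_t / S0[i0]
  if (ties == "efron") {
    for (j in which(d_by_t > 1L)) {
      idx <- which(time == ut[j])
      ev <- idx[status[idx] == 1]
      d <- length(ev)
      s0d <- sum(w[ev])
      inc[j] <- sum(1 / (S0[i0[j]] - (seq_len(d) - 1L) / d * s0d))
    }
  }
  data.frame(time = ut, hazard = inc, cumhaz = cumsum(inc))
}

#' Fit a Cox proportional-hazards model
#'
#' Newton-Raphson maximization of the partial likelihood with
#' step-halving; convergence when the gradient max-norm drops below
#' `tol`. With no covariates the fit degenerates to the null model and
#' the baseline estimator equals the Nelson-Aalen estimator.
#'
#' @param cohort cohort data.frame (see [read_cohort()])
#' @param covariates character vector of cohort column names to adjust
#'   for (may be empty); or a numeric matrix aligned with the cohort
#' @param ties `"efron"` (default) or `"breslow"`
#' @param max_iter maximum Newton iterations
#' @param tol gradient max-norm convergence tolerance
#' @return an object of class `cox_fit`: list with `beta` (named),
#'   `var` (covariance of beta), `loglik`, `loglik_null`, `n`,
#'   `n_events`, `ties`, `baseline` (data.frame time/hazard/cumhaz) and
#'   `lp` (per-subject linear predictor, cohort order)
#' @export
fit_cox <- function(cohort, covariates = character(),
                    ties = c("efron", "breslow"),
                    max_iter = 50L, tol = 1e-8) {
  ties <- match.arg(ties)
  time <- cohort$age
  status <- cohort$event
  if (sum(status) < 1) stop("cannot fit a Cox model with zero events")
  Z <- if (is.matrix(covariates)) {
    covariates
  } else if (length(covariates)) {
    as.matrix(cohort[covariates])
  } else {
    matrix(0, length(time), 0L)
  }
  p <- ncol(Z)
  if (p) {
    sds <- apply(Z, 2L, stats::sd)
    if (any(sds == 0)) stop("constant covariate column: ",
                            paste(colnames(Z)[sds == 0], collapse = ", "))
    if (p > 1L && qr(Z)$rank < p) stop("collinear covariates")
  }
  ord <- order(time)
  ts <- time[ord]; ss <- status[ord]
  Zs <- Z[ord, , drop = FALSE]

  beta <- numeric(p)
  d0 <- cox_pl_derivs(ts, ss, Zs, beta, ties)
  loglik_null <- d0$ll
  if (p) {
    cur <- d0
    iter <- 0L
    converged <- max(abs(cur$grad)) < tol
    while (!converged && iter < max_iter) {
      iter <- iter + 1L
      step <- tryCatch(solve(cur$info, cur$grad), error = function(e)
        stop("singular information matrix in Cox fit (separation or collinearity?)"))
      new_beta <- beta + step
      new <- cox_pl_derivs(ts, ss, Zs, new_beta, ties)
      lltol <- 1e-9 * (abs(cur$ll) + 1)
      halved <- 0L
      while (new$ll < cur$ll - lltol && halved < 30L) {
        halved <- halved + 1L
        new_beta <- beta + step / 2^halved
        new <- cox_pl_derivs(ts, ss, Zs, new_beta, ties)
      }
      beta <- new_beta
      cur <- new
      converged <- max(abs(cur$grad)) < tol
    }
    if (!converged)
      stop("Cox partial likelihood did not converge in ", max_iter,
           " iterations (max |beta| = ", signif(max(abs(beta)), 3),
           "); monotone likelihood / separation is the usual cause")
    var_beta <- solve(cur$info)
    loglik <- cur$ll
  } else {
    var_beta <- matrix(0, 0, 0)
    loglik <- loglik_null
  }
  nm <- colnames(Z) %||% (if (p) paste0("x", seq_len(p)) else character())
  names(beta) <- nm
  if (p) dimnames(var_beta) <- list(nm, nm)
  eta_s <- if (p) drop(Zs %*% beta) else numeric(length(ts))
  base <- cox_baseline(ts, ss, eta_s, ties)
  lp <- if (p) drop(Z %*% beta) else numeric(length(time))
  structure(list(beta = beta, var = var_beta, loglik = loglik,
                 loglik_null = loglik_null, n = length(time),
                 n_events = sum(status), ties = ties,
                 baseline = base, lp = lp),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties): n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  if (length(x$beta)) {
    se <- sqrt(diag(x$var))
    tab <- data.frame(coef = x$beta, `exp(coef)` = exp(x$beta), se = se,
                      z = x$beta / se,
                      p = 2 * stats::pnorm(-abs(x$beta / se)),
                      check.names = FALSE)
    print(tab, digits = 4)
  } else cat("(null model, no covariates)\n")
  invisible(x)
}

#' Evaluate the baseline cumulative hazard at given times
#'
#' Right-continuous step function; times beyond the last event reuse the
#' final value.
#'
#' @param fit a `cox_fit`
#' @param times numeric vector of ages
#' @return H0 evaluated at `times`
#' @export
baseline_cumhaz <- function(fit, times) {
  bt <- fit$baseline$time
  bc <- fit$baseline$cumhaz
  idx <- findInterval(times, bt)
  c(0, bc)[idx + 1L]
}

#' Martingale residuals of a fitted Cox model
#'
#' `M_i = delta_i - H0(t_i) * exp(z_i' beta)`, with H0 evaluated
#' right-continuously at the subject's own time. Under the Breslow
#' baseline the residuals sum to zero (an estimating-equation identity)
#' and every residual is at most 1.
#'
#' @param fit a `cox_fit` produced on the same cohort
#' @param cohort the cohort the fit was produced on
#' @return numeric vector of residuals, one per subject, in cohort order
#' @export
martingale_residuals <- function(fit, cohort) {
  if (length(fit$lp) != nrow(cohort))
    stop("fit and cohort have different numbers of subjects")
  H0 <- baseline_cumhaz(fit, cohort$age)
  res <- cohort$event - H0 * exp(fit$lp)
  names(res) <- cohort$subject_id
  res
}

#' Cox partial-likelihood score test at beta = 0
#'
#' `U' I^{-1} U` evaluated at the null; for a single binary covariate
#' with no tied event times this equals the log-rank chi-square.
#'
#' @param cohort cohort data.frame
#' @param covariates covariate column names or matrix
#' @param ties tie-handling method
#' @return list with `chisq`, `df`, `p`
#' @export
cox_score_test <- function(cohort, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  Z <- if (is.matrix(covariates)) covariates else as.matrix(cohort[covariates])
  ord <- order(cohort$age)
  d <- cox_pl_derivs(cohort$age[ord], cohort$event[ord],
                     Z[ord, , drop = FALSE], numeric(ncol(Z)), ties)
  chisq <- drop(crossprod(d$grad, solve(d$info, d$grad)))
  df <- ncol(Z)
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Kaplan-Meier survival curves by group
#'
#' Product-limit estimator with at-risk bookkeeping; one curve per group
#' level, each starting at S(0) = 1.
#'
#' @param times event/censor times
#' @param events 0/1 event indicators
#' @param group group labels (single group if omitted)
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `surv`
#' @export
kaplan_meier <- function(times, events, group = NULL) {
  if (!length(times)) stop("no subjects")
  if (is.null(group)) group <- rep("all", length(times))
  stopifnot(length(times) == length(events), length(group) == length(times))
  out <- lapply(split(seq_along(times), group), function(idx) {
    if (!length(idx)) stop("empty group")
    t <- times[idx]; e <- events[idx]
    ut <- sort(unique(t[e == 1]))
    n_risk <- vapply(ut, function(t0) sum(t >= t0), numeric(1))
    n_event <- vapply(ut, function(t0) sum(t == t0 & e == 1), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    data.frame(group = group[idx[1L]],
               time = c(0, ut), n_risk = c(length(idx), n_risk),
               n_event = c(0, n_event), surv = c(1, surv))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Log-rank test across groups
#'
#' Observed-minus-expected statistic with the hypergeometric
#' variance-covariance, referred to a chi-square with (groups - 1)
#' degrees of freedom. With two groups and no tied event times this
#' equals the Cox score test on the group indicator.
#'
#' @inheritParams kaplan_meier
#' @return list with `chisq`, `df`, `p`, `observed`, `expected`
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  lev <- levels(group)
  G <- length(lev)
  if (G < 2L) stop("log-rank test needs at least 2 groups")
  if (any(tabulate(group, G) == 0L)) stop("empty group")
  ut <- sort(unique(times[events == 1]))
  O <- E <- numeric(G)
  V <- matrix(0, G, G)
  for (t0 in ut) {
    at_risk <- times >= t0
    n <- sum(at_risk)
    ng <- vapply(lev, function(l) sum(at_risk & group == l), numeric(1))
    ev <- events == 1 & times == t0
    d <- sum(ev)
    dg <- vapply(lev, function(l) sum(ev & group == l), numeric(1))
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      vmult <- d * (n - d) / (n - 1)
      V <- V + vmult * (diag(ng / n, G) - tcrossprod(ng / n))
    }
  }
  i <- seq_len(G - 1L)
  omE <- (O - E)[i]
  chisq <- if (all(abs(omE) < 1e-12)) 0 else
    drop(crossprod(omE, solve(V[i, i, drop = FALSE], omE)))
  list(chisq = chisq, df = G - 1L,
       p = stats::pchisq(chisq, G - 1L, lower.tail = FALSE),
       observed = stats::setNames(O, lev), expected = stats::setNames(E, lev))
}

#' Hazard ratio for carrier status from a covariate-adjusted Cox model
#'
#' @param cohort cohort data.frame
#' @param carrier 0/1 carrier indicator aligned with the cohort
#' @param covariates additional cohort covariate columns
#' @param conf_level Wald confidence level
#' @param ties tie-handling method
#' @return list with `hr`, `ci` (length 2), `p`, `beta`, `se`, `n_carriers`
#' @export
cox_carrier_hr <- function(cohort, carrier,
                           covariates = c("sex", paste0("pc", 1:5)),
                           conf_level = 0.95, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  carrier <- as.numeric(carrier > 0)
  if (sum(carrier) == 0) stop("zero carriers")
  Z <- cbind(carrier = carrier,
             if (length(covariates)) as.matrix(cohort[covariates]))
  fit <- fit_cox(cohort, covariates = Z, ties = ties)
  b <- fit$beta["carrier"]
  se <- sqrt(fit$var["carrier", "carrier"])
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(b), ci = exp(c(b - zq * se, b + zq * se)),
       p = 2 * stats::pnorm(-abs(b / se)),
       beta = unname(b), se = se, n_carriers = sum(carrier))
}
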