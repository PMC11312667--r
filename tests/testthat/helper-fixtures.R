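# shared fixture builders

# minimal cohort from explicit times/status; covariates default to zero
toy_cohort <- function(time, status, sex = NULL, pc1 = NULL) {
  n <- length(time)
  data.frame(subject_id = paste0("s", seq_len(n)),
             event = status, age = time,
             sex = sex %||% rep(0, n),
             pc1 = pc1 %||% rep(0, n),
             pc2 = 0, pc3 = 0, pc4 = 0, pc5 = 0,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random censored survival cohort with one binary + one continuous covariate
random_cohort <- function(n, seed, beta_x = 0.6, beta_z = 0.3) {
  set.seed(seed)
  x <- stats::rbinom(n, 1, 0.4)
  z <- stats::rnorm(n)
  t <- stats::rexp(n, exp(beta_x * x + beta_z * z))
  cens <- stats::runif(n, 0, 2)
  toy_cohort(pmin(t, cens) + 1e-3, as.integer(t <= cens), sex = x, pc1 = z)
}

# explicit partial log-likelihood for one covariate, no ties (test oracle)
brute_pl <- function(beta, time, status, x) {
  ord <- order(time)
  time <- time[ord]; status <- status[ord]; x <- x[ord]
  ll <- 0
  for (i in which(status == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
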