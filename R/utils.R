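# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log-sum-exp
#' @param x numeric vector of log-scale values
#' @return log(sum(exp(x)))
#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Truncate a positive number to a given number of significant figures
#'
#' Truncation (toward zero), not rounding: 2.994e-5 at 2 significant
#' figures is 2.9e-5. Used only for displayed thresholds; comparisons
#' always use full precision.
#'
#' @param x positive numeric
#' @param digits significant figures to keep
#' @return truncated value
#' @export
truncate_signif <- function(x, digits = 2L) {
  stopifnot(all(x > 0))
  e <- floor(log10(x))
  f <- 10^(e - digits + 1)
  floor(x / f) * f
}

# seed expansion: derive independent child seeds from one root seed,
# kept below 2^31 so they remain valid R integers
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483647)
}
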