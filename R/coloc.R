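# Bayesian colocalization of two association signals in a region from
# summary statistics, under the single-causal-variant assumption.
# Per-variant evidence is the Wakefield approximate Bayes factor
#   log ABF = 1/2 log(se^2 / (se^2 + W^2)) + 1/2 z^2 W^2 / (se^2 + W^2)
# and the five hypotheses are H0 (no association), H1/H2 (one trait
# only), H3 (two distinct causal variants), H4 (one shared causal
# variant).

#' Wakefield log approximate Bayes factor
#'
#' @param beta effect estimate
#' @param se its standard error (> 0)
#' @param W prior standard deviation of the true effect (default 0.15,
#'   the quantitative-trait convention)
#' @return log ABF (vectorized)
#' @export
log_abf <- function(beta, se, W = 0.15) {
  stopifnot(all(se > 0), W > 0)
  z <- beta / se
  r <- W^2 / (se^2 + W^2)
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

#' Colocalization posterior probabilities from two summary-stat sets
#'
#' Variants are matched on `variant_id` ("chrom:pos:ref:alt"); a variant
#' present in one trait with swapped ref/alt alleles is harmonized by
#' flipping its beta sign. Hypothesis sums use log-sum-exp throughout.
#'
#' @param trait_a,trait_b data.frames with `variant_id`, `beta`, `se`
#' @param p1,p2 prior probability a variant is causal for trait A / B
#' @param p12 prior probability a variant is causal for both
#' @param W ABF prior standard deviation
#' @return list with `pp` (named PP0..PP4 summing to 1) and `abf`
#'   (per-variant data.frame of log ABFs)
#' @export
colocalize <- function(trait_a, trait_b, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       W = 0.15) {
  a <- trait_a
  b <- trait_b
  flip_id <- function(id) {
    parts <- strsplit(id, ":", fixed = TRUE)
    vapply(parts, function(p)
      if (length(p) == 4L) paste(p[1], p[2], p[4], p[3], sep = ":") else NA_character_,
      character(1))
  }
  direct <- b$variant_id %in% a$variant_id
  swapped <- !direct & flip_id(b$variant_id) %in% a$variant_id
  if (any(swapped)) {
    b$beta[swapped] <- -b$beta[swapped]
    b$variant_id[swapped] <- flip_id(b$variant_id[swapped])
  }
  shared <- intersect(a$variant_id, b$variant_id)
  if (!length(shared)) stop("no shared variants between the two traits")
  a <- a[match(shared, a$variant_id), ]
  b <- b[match(shared, b$variant_id), ]
  la <- log_abf(a$beta, a$se, W)
  lb <- log_abf(b$beta, b$se, W)
  sa <- logsumexp(la)
  sb <- logsumexp(lb)
  sab <- logsumexp(la + lb)
  lH0 <- 0
  lH1 <- log(p1) + sa
  lH2 <- log(p2) + sb
  # sum over i != j of ABF_a[i] * ABF_b[j]
  l3 <- logdiffexp(sa + sb, sab)
  lH3 <- log(p1) + log(p2) + l3
  lH4 <- log(p12) + sab
  lall <- c(lH0, lH1, lH2, lH3, lH4)
  pp <- exp(lall - logsumexp(lall))
  names(pp) <- paste0("PP", 0:4)
  list(pp = pp,
       abf = data.frame(variant_id = shared, log_abf_a = la, log_abf_b = lb,
                        stringsAsFactors = FALSE))
}
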