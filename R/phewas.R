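# Phenome-wide association of carrier status, and the cause-of-death
# carrier-enrichment chi-square. Binary phenotypes use logistic
# regression, continuous ones OLS, each adjusted for age, sex and the
# first five principal components, per-phenotype complete-case.

#' Filter a phenotype matrix before a PheWAS
#'
#' Removes binary phenotypes with fewer than `min_cases` cases,
#' continuous phenotypes with fewer than `min_cases` non-missing
#' observations, and any phenotype whose code starts with an excluded
#' chapter prefix (default: ICD-10 chapters XIX-XXII, codes S, T, V-Y,
#' Z and U -- injuries, external causes, health-services contact and
#' special-purpose codes).
#'
#' @param phenotypes list with `values` and `meta` as from
#'   [read_phenotypes()]
#' @param min_cases case / sample-size floor
#' @param excluded_prefixes character vector of code prefixes to drop
#' @return the filtered list (same shape); idempotent
#' @export
filter_phenotypes <- function(phenotypes, min_cases = 100L,
                              excluded_prefixes = c("S", "T", "V", "W",
                                                    "X", "Y", "Z", "U")) {
  values <- phenotypes$values
  meta <- phenotypes$meta
  keep <- vapply(seq_len(nrow(meta)), function(i) {
    id <- meta$phenotype_id[i]
    code <- meta$code[i]
    if (!is.na(code) && length(excluded_prefixes) &&
        any(startsWith(toupper(code), toupper(excluded_prefixes))))
      return(FALSE)
    v <- values[[id]]
    if (meta$kind[i] == "binary") sum(v == 1, na.rm = TRUE) >= min_cases
    else sum(!is.na(v)) >= min_cases
  }, logical(1))
  meta <- meta[keep, , drop = FALSE]
  list(values = values[c("subject_id", meta$phenotype_id)], meta = meta)
}

#' Phenome-wide association scan of carrier status
#'
#' @param carrier 0/1 carrier vector aligned with the phenotype rows
#' @param phenotypes filtered list from [filter_phenotypes()]
#' @param cohort cohort data.frame aligned with the phenotype rows
#'   (source of the covariates)
#' @param covariates cohort columns used as covariates
#' @return data.frame: `phenotype_id`, `kind`, `effect` (odds ratio for
#'   binary, slope for continuous), `beta`, `se`, `p`, `n` (cases for
#'   binary); unestimable phenotypes (constant, separation) carry NA
#'   effects
#' @export
run_phewas <- function(carrier, phenotypes, cohort,
                       covariates = c("age", "sex", paste0("pc", 1:5))) {
  carrier <- as.numeric(carrier > 0)
  meta <- phenotypes$meta
  values <- phenotypes$values
  Zfull <- as.matrix(cohort[covariates])
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$phenotype_id[i]
    kind <- meta$kind[i]
    y <- values[[id]]
    ok <- !is.na(y)
    na_row <- data.frame(phenotype_id = id, kind = kind, effect = NA_real_,
                         beta = NA_real_, se = NA_real_, p = NA_real_,
                         n = sum(ok), stringsAsFactors = FALSE)
    if (length(unique(y[ok])) < 2L) {
      warning("constant phenotype: ", id)
      return(na_row)
    }
    dat <- data.frame(y = y[ok], carrier = carrier[ok], Zfull[ok, , drop = FALSE])
    if (kind == "binary") {
      fit <- suppressWarnings(stats::glm(y ~ ., data = dat,
                                         family = stats::binomial()))
      co <- summary(fit)$coefficients
      if (!"carrier" %in% rownames(co)) return(na_row)
      b <- co["carrier", "Estimate"]; se <- co["carrier", "Std. Error"]
      if (!is.finite(se) || se > 1e3 || abs(b) > 15) {    # separation
        na_row$p <- NA_real_
        return(na_row)
      }
      data.frame(phenotype_id = id, kind = kind, effect = exp(b), beta = b,
                 se = se, p = co["carrier", "Pr(>|z|)"],
                 n = sum(dat$y == 1), stringsAsFactors = FALSE)
    } else {
      fit <- stats::lm(y ~ ., data = dat)
      co <- summary(fit)$coefficients
      if (!"carrier" %in% rownames(co)) return(na_row)
      data.frame(phenotype_id = id, kind = kind,
                 effect = co["carrier", "Estimate"],
                 beta = co["carrier", "Estimate"],
                 se = co["carrier", "Std. Error"],
                 p = co["carrier", "Pr(>|t|)"], n = nrow(dat),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phenome-wide Bonferroni threshold
#'
#' `alpha / n_phenotypes`, with the display value additionally truncated
#' to two significant figures (comparisons should use the full-precision
#' value).
#'
#' @param n_phenotypes phenotypes tested
#' @param alpha family-wise level
#' @return list with `threshold` (full precision) and `display`
#'   (truncated to 2 significant figures)
#' @export
phewas_threshold <- function(n_phenotypes, alpha = 0.05) {
  stopifnot(n_phenotypes > 0)
  th <- alpha / n_phenotypes
  list(threshold = th, display = truncate_signif(th, 2L))
}

#' Carrier enrichment across outcome categories
#'
#' For each category (e.g. primary cause of death), a 1-df chi-square on
#' the 2x2 table of carrier status against membership in that category
#' versus all others; no continuity correction. A warning is raised when
#' an expected cell count falls below 5.
#'
#' @param carrier 0/1 carrier vector
#' @param category_labels category label per subject
#' @return data.frame: `category`, `n`, `n_carriers`, `chisq`, `p`
#' @export
carrier_enrichment <- function(carrier, category_labels) {
  carrier <- as.numeric(carrier > 0)
  prev <- mean(carrier)
  if (prev <= 0 || prev >= 1) stop("carrier prevalence must be in (0, 1)")
  cats <- unique(category_labels)
  if (length(cats) < 2L) stop("need at least 2 categories")
  rows <- lapply(cats, function(cat) {
    inside <- category_labels == cat
    tab <- rbind(c(sum(carrier[inside]), sum(!carrier[inside])),
                 c(sum(carrier[!inside]), sum(!carrier[!inside])))
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expd < 5)) warning("expected cell count < 5 for category ", cat)
    tst <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(category = cat, n = sum(inside),
               n_carriers = sum(carrier[inside]),
               chisq = unname(tst$statistic), p = tst$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
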