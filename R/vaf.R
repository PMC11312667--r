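# Variant allele fraction summaries per gene and variant class.
# Germline heterozygotes center near VAF = 0.5; clonal somatic variants
# picked up from blood-derived DNA sit below it (clone fraction f gives
# expected VAF f/2). A gene whose bootstrap upper confidence bound for
# the mean VAF falls below 0.5 is flagged as putatively CHIP-driven.

#' Variant allele fraction of a read-count record
#'
#' `alt_reads / depth`; records with zero depth are skipped with a
#' warning.
#'
#' @param alt_reads alternate-allele read counts
#' @param depth total read depths
#' @return numeric VAFs (entries with depth 0 dropped)
#' @export
compute_vaf <- function(alt_reads, depth) {
  stopifnot(length(alt_reads) == length(depth))
  bad <- depth <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with zero depth skipped")
    alt_reads <- alt_reads[!bad]
    depth <- depth[!bad]
  }
  if (any(alt_reads > depth)) stop("alt_reads exceeds depth")
  alt_reads / depth
}

#' Per-gene VAF summary with a bootstrap confidence interval
#'
#' Mean VAF over carriers with a percentile bootstrap 95% CI
#' (`n_boot` resamples of carriers, fixed seed); the CHIP flag fires
#' when the upper bound is below 0.5. With a single observation the CI
#' degenerates to the observation and a warning is raised.
#'
#' @param vafs per-carrier VAFs for one gene/class set
#' @param n_boot bootstrap resamples
#' @param seed RNG seed for the bootstrap
#' @param conf_level confidence level
#' @return list with `n`, `mean_vaf`, `ci` (lower, upper), `n_boot`,
#'   `chip_flag`
#' @export
gene_vaf_summary <- function(vafs, n_boot = 10000L, seed = 1L,
                             conf_level = 0.95) {
  vafs <- as.numeric(vafs)
  if (any(vafs < 0 | vafs > 1)) stop("VAFs must lie in [0, 1]")
  n <- length(vafs)
  if (n < 2L) {
    warning("fewer than 2 VAF observations; degenerate interval")
    ci <- c(vafs, vafs)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    means <- colMeans(matrix(vafs[idx], nrow = n))
    alpha <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(means, c(alpha, 1 - alpha), type = 7))
  }
  list(n = n, mean_vaf = mean(vafs), ci = ci, n_boot = n_boot,
       chip_flag = ci[2] < 0.5)
}

#' VAF summaries for every gene/class set
#'
#' Joins read counts to the variants of each gene set, restricts to
#' heterozygous carriers where dosage information is available, and
#' summarizes each set with [gene_vaf_summary()].
#'
#' @param read_counts data.frame `subject_id`, `variant_id`,
#'   `alt_reads`, `depth`
#' @param gene_sets list from [build_gene_sets()]
#' @param n_boot,seed bootstrap controls
#' @return data.frame: `gene`, `class`, `n`, `mean_vaf`, `ci_lower`,
#'   `ci_upper`, `chip_flag`
#' @export
vaf_by_gene <- function(read_counts, gene_sets, n_boot = 10000L, seed = 1L) {
  rows <- lapply(gene_sets, function(gs) {
    rc <- read_counts[read_counts$variant_id %in% gs$variant_ids, ,
                      drop = FALSE]
    if (!nrow(rc)) return(NULL)
    v <- compute_vaf(rc$alt_reads, rc$depth)
    s <- gene_vaf_summary(v, n_boot = n_boot,
                          seed = child_seed(seed, gs$gene))
    data.frame(gene = gs$gene, class = gs$class, n = s$n,
               mean_vaf = s$mean_vaf, ci_lower = s$ci[1],
               ci_upper = s$ci[2], chip_flag = s$chip_flag,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  rows
}
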