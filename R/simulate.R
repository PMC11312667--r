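# Synthetic-cohort generators. Survival ages are drawn by inverse
# transform from a Weibull baseline hazard under proportional hazards:
#   H0(t) = (t / scale)^shape,   T = scale * (-log U / exp(lp))^(1/shape)
# and censoring is administrative on the age scale: each subject gets a
# "current age" draw, and subjects whose death age exceeds it are
# recorded alive at that age (mirroring a fixed calendar censoring
# date). Defaults emulate a late-life biobank cohort: steep Weibull
# hazard (shape 10, scale 95 years) and current ages uniform on
# 55-85 years, giving roughly a 10% observed death rate.

#' Simulation configuration
#'
#' @param n_subjects cohort size
#' @param seed root RNG seed (expanded into per-stage child seeds)
#' @param weibull_shape,weibull_scale baseline-hazard Weibull parameters
#'   (scale in years)
#' @param censor_min,censor_max administrative censor ("current") age
#'   range, uniform draw
#' @param beta_sex,beta_pc log hazard ratios for sex and each of the
#'   five standard-normal PCs
#' @param variants data.frame of common-variant specs (`maf`, `log_hr`),
#'   or NULL
#' @param genes list of gene specs for [simulate_gene_burden()]: each a
#'   list with `gene`, `n_variants`, `carrier_freq` (per variant),
#'   `class`, `log_hr`
#' @param clone_fraction somatic clone fraction f in (0,1); expected
#'   somatic VAF is f/2
#' @param mean_depth mean sequencing depth (Poisson, truncated at >= 1)
#' @param coloc list with `n_variants`, `ld_r` (AR(1) parameter), `se`
#'   (per-variant standard error), `z_causal` (causal non-centrality)
#' @return a `sim_config` list
#' @export
sim_config <- function(n_subjects = 10000L, seed = 1L,
                       weibull_shape = 10, weibull_scale = 95,
                       censor_min = 55, censor_max = 85,
                       beta_sex = 0.5, beta_pc = rep(0, 5),
                       variants = NULL, genes = list(),
                       clone_fraction = 0.5, mean_depth = 30,
                       coloc = list(n_variants = 50L, ld_r = 0.5,
                                    se = 0.03, z_causal = 10)) {
  stopifnot(weibull_shape > 0, weibull_scale > 0,
            censor_min >= 0, censor_max > censor_min,
            clone_fraction > 0, clone_fraction < 1, mean_depth > 0)
  if (!is.null(variants))
    stopifnot(all(variants$maf > 0 & variants$maf < 1))
  for (g in genes) stopifnot(all(g$carrier_freq > 0 & g$carrier_freq < 1))
  structure(list(n_subjects = as.integer(n_subjects), seed = seed,
                 weibull_shape = weibull_shape,
                 weibull_scale = weibull_scale,
                 censor_min = censor_min, censor_max = censor_max,
                 beta_sex = beta_sex, beta_pc = beta_pc,
                 variants = variants, genes = genes,
                 clone_fraction = clone_fraction, mean_depth = mean_depth,
                 coloc = coloc),
            class = "sim_config")
}

#' Simulate a survival cohort with genotypes
#'
#' Hardy-Weinberg genotypes at the configured common variants, death
#' ages from the Weibull proportional-hazards model (covariate and
#' genotype log hazard ratios enter the linear predictor), and
#' administrative censoring at a per-subject current age. The returned
#' truth record stores every generative parameter.
#'
#' @param config a [sim_config()]
#' @return list with `cohort` (data.frame), `genotypes` (subjects x
#'   variants dosage matrix, NULL when no variants configured), `genes`
#'   (rare-variant architecture from [simulate_gene_burden()] when gene
#'   specs are configured; its carrier log hazard ratios enter the
#'   linear predictor) and `truth`
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$censor_max <= 0) stop("degenerate config: censoring at age 0")
  set.seed(child_seed(config$seed, "cohort"))
  n <- config$n_subjects
  sex <- stats::rbinom(n, 1L, 0.5)
  pcs <- matrix(stats::rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("pc", 1:5)))
  lp <- sex * config$beta_sex + drop(pcs %*% config$beta_pc)
  G <- NULL
  if (!is.null(config$variants) && nrow(config$variants)) {
    m <- nrow(config$variants)
    G <- vapply(seq_len(m), function(j)
      stats::rbinom(n, 2L, config$variants$maf[j]), numeric(n))
    colnames(G) <- config$variants$variant_id %||% paste0("var", seq_len(m))
    lp <- lp + drop(G %*% config$variants$log_hr)
  }
  genes <- NULL
  if (length(config$genes)) {
    genes <- simulate_gene_burden(config)
    loghr <- vapply(config$genes, function(g) g$log_hr %||% 0, numeric(1))
    lp <- lp + drop(genes$carrier %*% loghr)
  }
  set.seed(child_seed(config$seed, "survival"))
  u <- stats::runif(n)
  death_age <- config$weibull_scale *
    (-log(u) / exp(lp))^(1 / config$weibull_shape)
  censor_age <- stats::runif(n, config$censor_min, config$censor_max)
  event <- as.integer(death_age <= censor_age)
  age <- pmin(death_age, censor_age)
  cohort <- data.frame(subject_id = sprintf("S%06d", seq_len(n)),
                       event = event, age = age, sex = sex, pcs,
                       stringsAsFactors = FALSE)
  if (!is.null(G)) rownames(G) <- cohort$subject_id
  if (!is.null(genes)) rownames(genes$genotypes) <- cohort$subject_id
  list(cohort = cohort, genotypes = G, genes = genes,
       truth = list(config = config, death_age = death_age,
                    censor_age = censor_age, lp = lp))
}

#' Simulate sparse rare-variant gene architectures
#'
#' Per-variant heterozygous carriers drawn Bernoulli at the configured
#' carrier frequencies; each gene contributes a carrier-status log
#' hazard ratio that callers can feed into survival simulation. The
#' annotation table labels variants by class with AlphaMissense/REVEL
#' scores placed on both sides of the 0.7/0.75 damaging cutoffs so that
#' classification filters are exercised.
#'
#' @param config a [sim_config()] with a non-empty `genes` list
#' @return list with `genotypes` (subjects x variants 0/1 dosage),
#'   `annotations` (data.frame), `carrier` (subjects x genes indicator
#'   matrix) and `truth`
#' @export
simulate_gene_burden <- function(config) {
  stopifnot(inherits(config, "sim_config"), length(config$genes) > 0)
  set.seed(child_seed(config$seed, "genes"))
  n <- config$n_subjects
  cols <- list(); ann <- list(); carrier <- list()
  for (g in config$genes) {
    freqs <- rep_len(g$carrier_freq, g$n_variants)
    Gg <- vapply(freqs, function(f) stats::rbinom(n, 1L, f), numeric(n))
    vids <- paste0(g$gene, "_v", seq_len(g$n_variants))
    colnames(Gg) <- vids
    cols[[g$gene]] <- Gg
    carrier[[g$gene]] <- as.integer(rowSums(Gg) > 0)
    cls <- g$class %||% "LOF"
    if (cls == "LOF") {
      lof_pool <- c("stop_gained", "frameshift_variant",
                    "splice_acceptor_variant", "splice_donor_variant",
                    "start_lost", "stop_lost", "transcript_ablation",
                    "feature_elongation", "feature_truncation")
      csq <- rep_len(lof_pool, g$n_variants)
      am <- rv <- rep(NA_real_, g$n_variants)
    } else {
      csq <- rep("missense_variant", g$n_variants)
      # scores straddle the damaging cutoffs
      am <- if (cls == "AM") seq(0.70, 0.99, length.out = g$n_variants)
            else stats::runif(g$n_variants, 0, 0.69)
      rv <- if (cls == "REVEL") seq(0.75, 0.99, length.out = g$n_variants)
            else stats::runif(g$n_variants, 0, 0.74)
    }
    ann[[g$gene]] <- data.frame(variant_id = vids, gene = g$gene,
                                consequence = csq, alphamissense = am,
                                revel = rv, stringsAsFactors = FALSE)
  }
  G <- do.call(cbind, cols)
  rownames(G) <- sprintf("S%06d", seq_len(n))
  carrier <- do.call(cbind, carrier)
  list(genotypes = G, annotations = do.call(rbind, ann),
       carrier = carrier,
       truth = list(genes = config$genes, seed = config$seed))
}

#' Simulate per-carrier sequencing read counts
#'
#' Depth is Poisson(`mean_depth`) truncated at >= 1. Germline
#' heterozygotes draw alternate reads Binomial(depth, 0.5); clonal
#' somatic variants draw Binomial(depth, f/2) where f is the clone
#' fraction.
#'
#' @param n_carriers number of carrier records to draw
#' @param somatic FALSE for germline (p = 0.5), TRUE for somatic
#'   (p = f/2)
#' @param config a [sim_config()] (uses `mean_depth`, `clone_fraction`,
#'   `seed`)
#' @return data.frame: `subject_id`, `variant_id`, `alt_reads`, `depth`
#' @export
simulate_read_counts <- function(n_carriers, somatic, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mean_depth <= 0) stop("mean depth must be positive")
  set.seed(child_seed(config$seed, if (somatic) "somatic" else "germline"))
  depth <- stats::rpois(n_carriers, config$mean_depth)
  while (any(depth == 0))                     # truncate at >= 1
    depth[depth == 0] <- stats::rpois(sum(depth == 0), config$mean_depth)
  p <- if (somatic) config$clone_fraction / 2 else 0.5
  alt <- stats::rbinom(n_carriers, depth, p)
  data.frame(subject_id = sprintf("C%06d", seq_len(n_carriers)),
             variant_id = "gene_v1", alt_reads = alt, depth = depth,
             stringsAsFactors = FALSE)
}

#' Simulate a paired summary-statistic region for colocalization
#'
#' `m` variants with AR(1) linkage disequilibrium (correlation
#' `ld_r^|i-j|`). Z-scores for each trait are drawn multivariate normal
#' around `Sigma %*% ncp`, the single-causal-variant GWAS sampling
#' model; betas are `z * se`. Scenarios: `"h0"` (no causal variant),
#' `"h1"`/`"h2"` (trait A / B only), `"h3"` (distinct causal variants),
#' `"h4"` (shared causal variant).
#'
#' @param config a [sim_config()] (uses the `coloc` block and `seed`)
#' @param scenario one of `"h0"`..`"h4"`
#' @param rep_seed optional override seed for this draw
#' @return list with `trait_a`, `trait_b` (data.frames `variant_id`,
#'   `beta`, `se`) and `truth` (scenario + causal indices)
#' @export
simulate_coloc_region <- function(config, scenario = c("h4", "h0", "h1",
                                                       "h2", "h3"),
                                  rep_seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  scenario <- match.arg(scenario)
  cc <- config$coloc
  m <- cc$n_variants
  r <- cc$ld_r
  Sigma <- r^abs(outer(seq_len(m), seq_len(m), "-"))
  L <- tryCatch(chol(Sigma), error = function(e)
    stop("LD matrix is not positive definite"))
  set.seed(rep_seed %||% child_seed(config$seed, paste0("coloc_", scenario)))
  causal_a <- causal_b <- NA_integer_
  if (scenario %in% c("h1", "h4")) causal_a <- sample.int(m, 1L)
  if (scenario == "h2") causal_b <- sample.int(m, 1L)
  if (scenario == "h4") causal_b <- causal_a
  if (scenario == "h3") {
    pick <- sample.int(m, 2L)
    causal_a <- pick[1L]; causal_b <- pick[2L]
  }
  draw <- function(causal) {
    ncp <- numeric(m)
    if (!is.na(causal)) ncp[causal] <- cc$z_causal
    mu <- drop(Sigma %*% ncp)
    z <- mu + drop(crossprod(L, stats::rnorm(m)))
    data.frame(variant_id = paste0("1:", 1e6 + seq_len(m) * 1000, ":A:G"),
               beta = z * cc$se, se = rep(cc$se, m),
               stringsAsFactors = FALSE)
  }
  list(trait_a = draw(causal_a), trait_b = draw(causal_b),
       truth = list(scenario = toupper(scenario), causal_a = causal_a,
                    causal_b = causal_b))
}
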