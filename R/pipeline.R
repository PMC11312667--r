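# End-to-end orchestration: run the synthetic (or supplied) cohort
# through QC, the Martingale-residual scan, gene-based tests,
# colocalization, VAF summaries and the PheWAS, writing one TSV per
# stage plus a JSON manifest (seeds, row counts, file checksums). A
# rerun with the same config and seed reproduces byte-identical tables.

pipeline_defaults <- function() {
  list(
    out_dir = "survscan_run",
    seed = 1L,
    stages = c("simulate", "gwas", "gene_test", "coloc", "vaf"),
    n_subjects = 5000L,
    n_common_variants = 100L,
    common_maf_range = c(0.05, 0.5),
    gene_specs = list(
      list(gene = "GENE1", n_variants = 20L, carrier_freq = 0.002,
           class = "LOF", log_hr = log(2)),
      list(gene = "GENE2", n_variants = 20L, carrier_freq = 0.002,
           class = "AM", log_hr = 0)),
    qc = list(max_missing = 0.05, min_maf = 0.01, hwe_alpha = 1e-6),
    rare = list(max_maf = 0.01, min_carriers = 10L, min_mac = 3L),
    stratum = "all",
    coloc_scenario = "h4",
    n_vaf_carriers = 200L,
    somatic = TRUE
  )
}

#' Run the full analysis pipeline
#'
#' @param config list of overrides of the pipeline defaults, or a path
#'   to a YAML file holding them; see `survscan:::pipeline_defaults()`
#'   for the keys
#' @return invisibly, the manifest list; stage outputs are written under
#'   `config$out_dir`
#' @export
run_all <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "survscan",
                   version = as.character(utils::packageVersion("survscan")),
                   seed = cfg$seed, stages = cfg$stages, counts = list())
  outputs <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sc <- NULL; cohort <- NULL; G <- NULL; res <- NULL
  gene_sim <- NULL

  if ("simulate" %in% cfg$stages) {
    sc <- stage("simulate", {
      set.seed(child_seed(cfg$seed, "maf"))
      variants <- data.frame(
        variant_id = paste0("cv", seq_len(cfg$n_common_variants)),
        maf = stats::runif(cfg$n_common_variants, cfg$common_maf_range[1],
                           cfg$common_maf_range[2]),
        log_hr = 0)
      conf <- sim_config(n_subjects = cfg$n_subjects, seed = cfg$seed,
                         variants = variants, genes = cfg$gene_specs)
      simulate_cohort(conf)
    })
    gene_sim <- sc$genes
    cohort <- sc$cohort
    G <- sc$genotypes
    f <- file.path(cfg$out_dir, "cohort.tsv")
    write_cohort(cohort, f); outputs <- c(outputs, f)
    manifest$counts$subjects <- nrow(cohort)
    manifest$counts$events <- sum(cohort$event)
  } else {
    if (is.null(cfg$cohort_path)) stop("config field 'cohort_path' is required when the simulate stage is off")
    cohort <- stage("io", read_cohort(cfg$cohort_path))
    if (!is.null(cfg$genotype_path))
      G <- stage("io", read_genotypes(cfg$genotype_path,
                                      cfg$genotype_format %||% "dosage_tsv"))
  }

  residuals <- NULL
  if (any(c("gwas", "gene_test") %in% cfg$stages)) {
    fit <- stage("survfit", fit_cox(cohort, c("sex", paste0("pc", 1:5))))
    residuals <- stage("survfit", martingale_residuals(fit, cohort))
  }

  if ("gwas" %in% cfg$stages && !is.null(G)) {
    Gq <- stage("gwas", qc_filter(G, cfg$qc$max_missing, cfg$qc$min_maf,
                                  cfg$qc$hwe_alpha))
    manifest$counts$qc <- as.list(attr(Gq, "qc_log"))
    res <- stage("gwas", {
      if (cfg$stratum == "all") assoc_scan(residuals, Gq)
      else stratified_scan(cohort, Gq, cfg$stratum)
    })
    f <- file.path(cfg$out_dir, "gwas.tsv")
    write_summary_stats(res, f); outputs <- c(outputs, f)
    manifest$counts$gwas_variants <- nrow(res)
  }

  if ("gene_test" %in% cfg$stages && !is.null(gene_sim)) {
    gt <- stage("gene_test", {
      Gr <- gene_sim$genotypes
      rows <- list()
      for (cls in c("LOF", "AM", "REVEL")) {
        sets <- build_gene_sets(Gr, gene_sim$annotations, cls,
                                cfg$rare$max_maf, cfg$rare$min_carriers)
        if (length(sets))
          rows[[cls]] <- run_gene_tests(residuals, Gr, sets)
      }
      do.call(rbind, rows)
    })
    if (!is.null(gt)) {
      f <- file.path(cfg$out_dir, "gene_tests.tsv")
      write_tsv(gt, f); outputs <- c(outputs, f)
      manifest$counts$gene_sets <- nrow(gt)
    }
  }

  if ("coloc" %in% cfg$stages) {
    cl <- stage("coloc", {
      conf <- sim_config(seed = cfg$seed)
      reg <- simulate_coloc_region(conf, cfg$coloc_scenario)
      colocalize(reg$trait_a, reg$trait_b)
    })
    f <- file.path(cfg$out_dir, "coloc.tsv")
    write_tsv(as.data.frame(t(cl$pp)), f); outputs <- c(outputs, f)
  }

  if ("vaf" %in% cfg$stages) {
    vs <- stage("vaf", {
      conf <- sim_config(seed = cfg$seed)
      rc <- simulate_read_counts(cfg$n_vaf_carriers, cfg$somatic, conf)
      v <- compute_vaf(rc$alt_reads, rc$depth)
      s <- gene_vaf_summary(v, seed = child_seed(cfg$seed, "boot"))
      data.frame(gene = "gene", class = "LOF", n = s$n,
                 mean_vaf = s$mean_vaf, ci_lower = s$ci[1],
                 ci_upper = s$ci[2], chip_flag = s$chip_flag)
    })
    f <- file.path(cfg$out_dir, "vaf.tsv")
    write_tsv(vs, f); outputs <- c(outputs, f)
  }

  manifest$checksums <- as.list(tools::md5sum(outputs))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
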