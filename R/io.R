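# Reading and writing the pipeline's on-disk artifacts. All tabular files
# are plain TSV with a header row; genotypes come from VCF (hard calls via
# GT, read counts via AD/DP) or from a dosage TSV (variants as rows,
# subjects as columns).

#' Read a cohort table
#'
#' A cohort table holds one row per subject: `subject_id`, `event`
#' (0 = alive/censored, 1 = dead), `age` (age at death or last-known age,
#' in years), `sex` (0/1) and principal components `pc1`..`pc5`.
#'
#' @param path path to a TSV file with a header
#' @return a `data.frame` with validated columns
#' @export
read_cohort <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_cohort(x)
}

#' Validate a cohort table
#'
#' @param x data.frame with the cohort columns
#' @return the validated data.frame (invisibly the same object)
#' @export
validate_cohort <- function(x) {
  req <- c("subject_id", "event", "age", "sex", paste0("pc", 1:5))
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("cohort table is missing required columns: ", paste(miss, collapse = ", "))
  x$subject_id <- as.character(x$subject_id)
  bad <- which(!stats::complete.cases(x[req]))
  if (length(bad))
    stop("cohort rows with missing required fields: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  if (anyDuplicated(x$subject_id))
    stop("duplicate subject_id in cohort: ",
         x$subject_id[anyDuplicated(x$subject_id)][1L])
  if (!all(x$event %in% c(0, 1)))
    stop("event must be 0 or 1")
  nonpos <- which(x$age <= 0)
  if (length(nonpos))
    stop("non-positive age at cohort row(s): ",
         paste(utils::head(nonpos, 10L), collapse = ", "))
  x
}

#' Write a cohort table
#' @param cohort data.frame as from [read_cohort()]
#' @param path output TSV path
#' @export
write_cohort <- function(cohort, path) {
  write_tsv(cohort, path)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant annotation table
#'
#' Columns: `variant_id`, `gene`, `consequence` (Sequence Ontology style
#' term), `alphamissense`, `revel` (scores in \[0,1\] or NA).
#'
#' @param path TSV path
#' @return data.frame of annotation records
#' @export
read_annotations <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("variant_id", "gene", "consequence", "alphamissense", "revel")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("annotation table missing columns: ", paste(miss, collapse = ", "))
  for (col in c("alphamissense", "revel")) {
    v <- x[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop(col, " scores must lie in [0, 1]")
  }
  x
}

#' Read per-carrier read counts
#'
#' Columns: `subject_id`, `variant_id`, `alt_reads`, `depth`.
#'
#' @param path TSV path
#' @return data.frame of read-count records
#' @export
read_read_counts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_read_counts(x)
}

validate_read_counts <- function(x) {
  req <- c("subject_id", "variant_id", "alt_reads", "depth")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("read-count table missing columns: ", paste(miss, collapse = ", "))
  if (any(x$alt_reads < 0) || any(x$depth <= 0))
    stop("alt_reads must be >= 0 and depth > 0")
  if (any(x$alt_reads > x$depth))
    stop("alt_reads exceeds depth at row(s): ",
         paste(utils::head(which(x$alt_reads > x$depth), 10L), collapse = ", "))
  x
}

#' Read genotypes from VCF or a dosage TSV
#'
#' Hard calls are taken from the VCF `GT` field; multi-allelic sites are
#' skipped with a warning. Dosage TSVs have variants as rows and subjects
#' as columns, with a header of subject ids and a leading `variant_id`
#' column. In both cases dosages are oriented to count the minor allele:
#' when the counted allele's sample frequency exceeds 0.5 the dosage is
#' flipped to `2 - g`. Missing genotypes are `NA` and are never imputed.
#'
#' @param path input file
#' @param format `"vcf"` or `"dosage_tsv"`
#' @return a numeric subjects x variants matrix with `dimnames`
#'   (subject ids, variant ids) and attribute `read_counts` (data.frame,
#'   VCF with AD/DP only)
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_dosage(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) skipped")
  }
  keep <- which(!multi)
  ids <- paste(fix[keep, "CHROM"], fix[keep, "POS"],
               fix[keep, "REF"], fix[keep, "ALT"], sep = ":")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  # count ALT alleles in the GT string; "." -> NA
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(strsplit(g, "[/|]")[[1]] == "1")
  })
  G <- t(dos)
  colnames(G) <- ids
  G <- orient_minor_allele(G)
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP"), error = function(e) NULL)
  if (!is.null(ad)) {
    ad <- ad[keep, , drop = FALSE]
    long <- which(!is.na(ad), arr.ind = TRUE)
    if (nrow(long)) {
      alt <- vapply(ad[long], function(s) as.integer(strsplit(s, ",")[[1]][2]), 1L)
      depth <- if (!is.null(dp)) {
        as.integer(dp[keep, , drop = FALSE][long])
      } else {
        vapply(ad[long], function(s) sum(as.integer(strsplit(s, ",")[[1]])), 1L)
      }
      rc <- data.frame(subject_id = colnames(ad)[long[, 2]],
                       variant_id = ids[long[, 1]],
                       alt_reads = alt, depth = depth,
                       stringsAsFactors = FALSE)
      rc <- rc[!is.na(rc$depth) & rc$depth > 0, ]
      attr(G, "read_counts") <- rc
    }
  }
  G
}

read_genotypes_dosage <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(x)[1] != "variant_id")
    stop("dosage TSV must have a leading 'variant_id' column")
  ids <- as.character(x$variant_id)
  G <- t(as.matrix(x[, -1, drop = FALSE]))
  mode(G) <- "numeric"
  colnames(G) <- ids
  if (any(G < 0 | G > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  orient_minor_allele(G)
}

#' Orient genotype dosages to the minor allele
#'
#' Flips any variant whose counted-allele frequency (over non-missing
#' subjects) exceeds 0.5 so that downstream MAF is always <= 0.5.
#' Ties (frequency exactly 0.5) are left as-is.
#'
#' @param G subjects x variants dosage matrix
#' @return matrix with attribute `flipped` (logical per variant)
#' @export
orient_minor_allele <- function(G) {
  af <- colMeans(G, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  if (any(flip)) G[, flip] <- 2 - G[, flip, drop = FALSE]
  attr(G, "flipped") <- flip
  G
}

#' Per-variant minor allele frequency over non-missing subjects
#' @param G dosage matrix (subjects x variants)
#' @return numeric vector of MAF per variant
#' @export
variant_maf <- function(G) {
  af <- colMeans(G, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

#' Per-variant minor allele count over non-missing subjects
#' @param G dosage matrix
#' @return numeric vector of MAC per variant
#' @export
variant_mac <- function(G) {
  af <- colMeans(G, na.rm = TRUE) / 2
  cnt <- colSums(G, na.rm = TRUE)
  n2 <- 2 * colSums(!is.na(G))
  ifelse(!is.na(af) & af > 0.5, n2 - cnt, cnt)
}

#' Per-variant genotype missing rate
#' @param G dosage matrix
#' @return numeric vector of missing fractions
#' @export
variant_missing_rate <- function(G) {
  colMeans(is.na(G))
}

#' Write association summary statistics
#'
#' Fixed column order `variant_id, beta, se, p, maf, n`; p-values are
#' written in full-precision scientific notation.
#'
#' @param results data.frame with those columns
#' @param path output TSV path
#' @export
write_summary_stats <- function(results, path) {
  req <- c("variant_id", "beta", "se", "p", "maf", "n")
  miss <- setdiff(req, names(results))
  if (length(miss))
    stop("summary statistics missing columns: ", paste(miss, collapse = ", "))
  out <- results[req]
  for (col in c("beta", "se", "p", "maf"))
    out[[col]] <- formatC(out[[col]], format = "e", digits = 17)
  write_tsv(out, path)
}

#' Read association summary statistics written by [write_summary_stats()]
#' @param path TSV path
#' @return data.frame with numeric columns restored
#' @export
read_summary_stats <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("beta", "se", "p", "maf")) x[[col]] <- as.numeric(x[[col]])
  x
}

#' Read a phenotype matrix and its metadata
#'
#' @param path TSV of subjects x phenotypes with a leading `subject_id`
#'   column
#' @param meta_path TSV with columns `phenotype_id`, `kind`
#'   (`binary`/`continuous`) and `code` (e.g. an ICD-10 code, may be NA)
#' @return list with elements `values` (data.frame) and `meta` (data.frame)
#' @export
read_phenotypes <- function(path, meta_path) {
  values <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(values)[1] != "subject_id")
    stop("phenotype matrix must have a leading 'subject_id' column")
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  req <- c("phenotype_id", "kind", "code")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("phenotype metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$phenotype_id)) stop("duplicate phenotype_id in metadata")
  if (!all(meta$kind %in% c("binary", "continuous")))
    stop("phenotype kind must be 'binary' or 'continuous'")
  unknown <- setdiff(meta$phenotype_id, names(values))
  if (length(unknown))
    stop("metadata names phenotypes absent from the matrix: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  list(values = values, meta = meta)
}
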