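# Rare-variant pathogenicity classes. Three classes are tested per gene:
#   LOF   - predicted loss of function (nine consequence terms)
#   AM    - missense with AlphaMissense score >= 0.7
#   REVEL - missense with REVEL score >= 0.75
# Classes are not exclusive: a missense variant damaging by both scores
# belongs to both AM and REVEL.

# Sequence Ontology style terms accepted for LoF, normalized to lower
# case with underscores; both the bare phrase and the *_variant
# serialization common annotators emit are accepted.
.lof_terms <- c(
  "splice_acceptor", "splice_acceptor_variant",
  "splice_donor", "splice_donor_variant",
  "stop_gained", "frameshift", "frameshift_variant",
  "start_loss", "start_lost", "stop_loss", "stop_lost",
  "transcript_ablation", "feature_elongation", "feature_truncation"
)
.missense_terms <- c("missense", "missense_variant")

normalize_consequence <- function(term) {
  gsub("[ ]+", "_", tolower(trimws(term)))
}

# warn once per unknown term per session
.class_env <- new.env(parent = emptyenv())

#' Classify a variant into pathogenicity classes
#'
#' @param consequence consequence term (Sequence Ontology style)
#' @param alphamissense AlphaMissense score in \[0,1\] or NA
#' @param revel REVEL score in \[0,1\] or NA
#' @param am_cutoff AlphaMissense damaging cutoff (inclusive)
#' @param revel_cutoff REVEL damaging cutoff (inclusive)
#' @return character vector: subset of `c("LOF", "AM", "REVEL")`
#' @export
classify_variant <- function(consequence, alphamissense = NA, revel = NA,
                             am_cutoff = 0.7, revel_cutoff = 0.75) {
  term <- normalize_consequence(consequence)
  out <- character()
  if (term %in% .lof_terms) {
    out <- c(out, "LOF")
  } else if (term %in% .missense_terms) {
    if (!is.na(alphamissense) && alphamissense >= am_cutoff) out <- c(out, "AM")
    if (!is.na(revel) && revel >= revel_cutoff) out <- c(out, "REVEL")
  } else {
    if (is.null(.class_env[[term]])) {
      .class_env[[term]] <- TRUE
      warning("unknown consequence term (no class assigned): ", term)
    }
  }
  out
}

#' Classify every record of an annotation table
#'
#' @param annotations data.frame as from [read_annotations()]
#' @inheritParams classify_variant
#' @return the table with logical columns `LOF`, `AM`, `REVEL` appended
#' @export
classify_annotations <- function(annotations, am_cutoff = 0.7,
                                 revel_cutoff = 0.75) {
  cls <- lapply(seq_len(nrow(annotations)), function(i)
    classify_variant(annotations$consequence[i],
                     annotations$alphamissense[i], annotations$revel[i],
                     am_cutoff, revel_cutoff))
  annotations$LOF <- vapply(cls, function(x) "LOF" %in% x, logical(1))
  annotations$AM <- vapply(cls, function(x) "AM" %in% x, logical(1))
  annotations$REVEL <- vapply(cls, function(x) "REVEL" %in% x, logical(1))
  annotations
}

#' Assemble per-gene rare-variant sets for one class
#'
#' For each gene, collects the variants of the requested class with
#' cohort MAF below `max_maf`; sets whose carrier count (subjects with
#' dosage > 0 at any member variant) falls below `min_carriers` are
#' dropped and logged.
#'
#' @param G subjects x variants dosage matrix
#' @param annotations annotation data.frame covering the variants of `G`
#' @param class one of `"LOF"`, `"AM"`, `"REVEL"`
#' @param max_maf rare-variant MAF bound (exclusive: MAF < bound kept)
#' @param min_carriers minimum carriers for a testable set
#' @return list of gene sets, each a list with `gene`, `class`,
#'   `variant_ids`, `n_variants`, `n_carriers`; attribute `dropped`
#'   names genes excluded by the carrier gate
#' @export
build_gene_sets <- function(G, annotations, class = c("LOF", "AM", "REVEL"),
                            max_maf = 0.01, min_carriers = 10L) {
  class <- match.arg(class)
  if (!class %in% names(annotations))
    annotations <- classify_annotations(annotations)
  covered <- annotations$variant_id %in% colnames(G)
  ann <- annotations[covered & annotations[[class]], , drop = FALSE]
  maf <- variant_maf(G)
  sets <- list()
  dropped <- character()
  for (gene in unique(ann$gene)) {
    vids <- ann$variant_id[ann$gene == gene]
    vids <- vids[maf[vids] < max_maf]
    if (!length(vids)) next
    carrier <- rowSums(G[, vids, drop = FALSE] > 0, na.rm = TRUE) > 0
    ncar <- sum(carrier)
    if (ncar < min_carriers) {
      dropped <- c(dropped, gene)
      next
    }
    sets[[gene]] <- list(gene = gene, class = class, variant_ids = vids,
                         n_variants = length(vids), n_carriers = ncar)
  }
  attr(sets, "dropped") <- dropped
  sets
}

#' Overlap between AlphaMissense- and REVEL-damaging missense variants
#'
#' @param annotations annotation data.frame (classified on the fly if
#'   needed)
#' @return named numeric: `am_also_revel` (fraction of AM variants also
#'   REVEL-damaging) and `revel_also_am`; NA when a class is empty
#' @export
class_overlap <- function(annotations) {
  if (!all(c("AM", "REVEL") %in% names(annotations)))
    annotations <- classify_annotations(annotations)
  n_am <- sum(annotations$AM)
  n_rv <- sum(annotations$REVEL)
  n_both <- sum(annotations$AM & annotations$REVEL)
  c(am_also_revel = if (n_am) n_both / n_am else NA_real_,
    revel_also_am = if (n_rv) n_both / n_rv else NA_real_)
}
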