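test_that("the nine LoF consequence terms classify as LOF", {
  terms <- c("splice_acceptor_variant", "splice_donor_variant", "stop_gained",
             "frameshift_variant", "start_lost", "stop_lost",
             "transcript_ablation", "feature_elongation", "feature_truncation")
  for (term in terms)
    expect_equal(classify_variant(term), "LOF")
  # serialization variants: case, spaces
  expect_equal(classify_variant("Stop Gained"), "LOF")
  expect_equal(classify_variant("SPLICE_ACCEPTOR"), "LOF")
  # LoF terms ignore missense scores
  expect_equal(classify_variant("stop_gained", alphamissense = 0.99), "LOF")
})

test_that("missense scores are compared inclusively at 0.7 and 0.75", {
  expect_equal(classify_variant("missense_variant", alphamissense = 0.70), "AM")
  expect_equal(classify_variant("missense_variant", alphamissense = 0.699),
               character(0))
  expect_equal(classify_variant("missense_variant", revel = 0.75), "REVEL")
  expect_equal(classify_variant("missense_variant", revel = 0.749),
               character(0))
  expect_equal(classify_variant("missense_variant", alphamissense = 0.5,
                                revel = 0.80), "REVEL")
  expect_setequal(classify_variant("missense_variant", alphamissense = 0.9,
                                   revel = 0.9), c("AM", "REVEL"))
  # a synonymous variant gets no class, with a one-time warning
  expect_warning(out <- classify_variant("synonymous_variant_zz1"),
                 "unknown consequence")
  expect_length(out, 0L)
  expect_silent(classify_variant("synonymous_variant_zz1"))
})

test_that("gene sets enforce the MAF and carrier-count gates", {
  n <- 2000
  G <- matrix(0, n, 4,
              dimnames = list(NULL, c("g1_a", "g1_b", "g2_a", "g3_a")))
  G[1:6, "g1_a"] <- 1                    # 6 carriers
  G[7:10, "g1_b"] <- 1                   # +4 -> 10 carriers for gene1
  G[1:9, "g2_a"] <- 1                    # 9 carriers -> dropped
  G[1:22, "g3_a"] <- 1                   # MAF 22/4000 = 0.0055... retained
  ann <- data.frame(
    variant_id = colnames(G),
    gene = c("gene1", "gene1", "gene2", "gene3"),
    consequence = "stop_gained",
    alphamissense = NA_real_, revel = NA_real_)
  sets <- build_gene_sets(G, ann, "LOF", min_carriers = 10)
  expect_setequal(names(sets), c("gene1", "gene3"))
  expect_equal(sets$gene1$n_carriers, 10L)
  expect_true("gene2" %in% attr(sets, "dropped"))
  # a variant at MAF 0.011 fails the rare filter (strict < 0.01)
  G2 <- matrix(0, n, 1, dimnames = list(NULL, "g4_a"))
  G2[1:44, 1] <- 1                       # MAF 0.011
  ann2 <- data.frame(variant_id = "g4_a", gene = "gene4",
                     consequence = "stop_gained",
                     alphamissense = NA_real_, revel = NA_real_)
  expect_length(build_gene_sets(G2, ann2, "LOF"), 0L)
  # homozygous carriers count via dosage > 0
  G3 <- matrix(0, n, 1, dimnames = list(NULL, "g5_a"))
  G3[1:10, 1] <- 2
  ann3 <- data.frame(variant_id = "g5_a", gene = "gene5",
                     consequence = "frameshift_variant",
                     alphamissense = NA_real_, revel = NA_real_)
  expect_equal(build_gene_sets(G3, ann3, "LOF")$gene5$n_carriers, 10L)
})

test_that("a variant damaging by both scores joins both class sets", {
  n <- 2000
  G <- matrix(0, n, 1, dimnames = list(NULL, "v1"))
  G[1:12, 1] <- 1
  ann <- data.frame(variant_id = "v1", gene = "g", consequence = "missense",
                    alphamissense = 0.9, revel = 0.9)
  am <- build_gene_sets(G, ann, "AM")
  rv <- build_gene_sets(G, ann, "REVEL")
  expect_equal(am$g$variant_ids, "v1")
  expect_equal(rv$g$variant_ids, "v1")
})

test_that("class overlap fractions are exact on constructed tables", {
  # 4 AM-only, 2 REVEL-only... construct overlap 0.25 of AM, 0.60 of REVEL:
  # |AM| = 20, |REVEL| = 5 sharing disallowed; use both = 3 -> 3/12 = 0.25
  # of AM (12 total), 3/5 = 0.6 of REVEL (5 total)
  mk <- function(n, am, rv) data.frame(
    variant_id = paste0("v", seq_len(n) + stats::runif(1) * 0),
    gene = "g", consequence = "missense_variant",
    alphamissense = am, revel = rv)
  tab <- rbind(mk(9, 0.9, 0.1),     # AM only
               mk(3, 0.9, 0.9),     # both
               mk(2, 0.1, 0.9))     # REVEL only
  tab$variant_id <- paste0("v", seq_len(nrow(tab)))
  ov <- class_overlap(tab)
  expect_equal(unname(ov["am_also_revel"]), 0.25)
  expect_equal(unname(ov["revel_also_am"]), 0.60)
  # disjoint supports and identical membership
  dis <- rbind(mk(3, 0.9, 0.1), mk(3, 0.1, 0.9))
  dis$variant_id <- paste0("d", 1:6)
  expect_equal(unname(class_overlap(dis)), c(0, 0))
  same <- mk(4, 0.8, 0.8)
  same$variant_id <- paste0("s", 1:4)
  expect_equal(unname(class_overlap(same)), c(1, 1))
  none <- mk(2, 0.1, 0.1)
  none$variant_id <- paste0("n", 1:2)
  expect_true(all(is.na(class_overlap(none))))
})
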