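test_that("BLAST tabular parsing handles comments, types and bad rows", {
  path <- write_tsv_tmp(c(
    "# BLASTP 2.2",
    paste("q1", "s1", "98.0", "120", "2", "0", "1", "120", "1", "120",
          "1e-30", "250", sep = "\t")))
  hits <- parse_blast_tabular(path)
  expect_identical(nrow(hits), 1L)
  expect_equal(hits$evalue, 1e-30)
  expect_equal(hits$bit_score, 250)
  expect_identical(hits$alignment_length, 120L)

  bad <- write_tsv_tmp(paste(paste0("c", 1:11), collapse = "\t"))
  expect_error(parse_blast_tabular(bad), "line 1.*12 columns")
})

test_that("score and E-value filters are inclusive at their thresholds", {
  hits <- data.frame(bit_score = c(100, 99.9, 500, 200),
                     evalue = c(0.001, 1e-50, 0.01, 1e-10))
  kept <- filter_hits(hits)
  expect_identical(kept$bit_score, c(100, 200))
  # tightening either threshold never keeps more hits
  for (s in c(50, 100, 150, 250)) {
    k1 <- nrow(filter_hits(hits, min_score = s))
    k2 <- nrow(filter_hits(hits, min_score = s + 10))
    expect_lte(k2, k1)
  }
  for (e in c(1e-20, 1e-5, 1e-3, 1e-2)) {
    k1 <- nrow(filter_hits(hits, max_evalue = e))
    k2 <- nrow(filter_hits(hits, max_evalue = e / 10))
    expect_lte(k2, k1)
  }
})

make_hits <- function(query, subject) {
  n <- length(query)
  data.frame(query_id = query, subject_id = subject,
             percent_identity = 90, alignment_length = 100L,
             mismatches = 1L, gap_opens = 0L, q_start = 1L, q_end = 100L,
             s_start = 1L, s_end = 100L, evalue = 1e-20, bit_score = 200,
             stringsAsFactors = FALSE)
}

test_that("hit lists deduplicate, respect completeness, and drop unmapped", {
  orgs <- data.frame(organism_id = c("oA", "oB", "oC"),
                     kingdom = c("BACTERIA", "ARCHAEA", "EUKARYOTA"),
                     complete = c(TRUE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  so <- data.frame(subject_id = c("sA1", "sA2", "sB1", "sC1"),
                   organism_id = c("oA", "oA", "oB", "oC"),
                   stringsAsFactors = FALSE)
  qg <- data.frame(query_id = c("q1", "q2"), gene_id = c("g1", "g2"),
                   stringsAsFactors = FALSE)

  hits <- make_hits(c("q1", "q1", "q2", "q1"), c("sA1", "sA2", "sB1", "sC1"))
  hl <- build_hit_lists(hits, so, orgs, qg)
  expect_named(hl, c("oA", "oC"))               # oB incomplete -> omitted
  expect_identical(hl$oA$similar_genes, "g1")    # two hits deduplicated
  expect_identical(hl$oC$kingdom, "EUKARYOTA")

  with_unknown <- make_hits(c("q1", "q1"), c("sA1", "sZZ"))
  expect_warning(hl2 <- build_hit_lists(with_unknown, so, orgs, qg),
                 "1 hit\\(s\\) dropped")
  expect_named(hl2, "oA")
})

test_that("planted organisms with empty hit sets are omitted from lists", {
  cfg <- sim_config(seed = 21, n_genes = 300, test_set_sizes = c(ag = 30),
                    n_organisms_per_kingdom = c(BACTERIA = 1, ARCHAEA = 1,
                                                EUKARYOTA = 1),
                    p_incomplete_org = 0, background_hit_prob = 0,
                    n_decoy_hits = 0L,
                    mimicry_plants = data.frame(
                      organism_index = c(1, 3),
                      test_prob = c(0.5, 0.3), ref_prob = c(0.1, 0.05)))
  uni <- generate_universe(cfg)
  og <- generate_organism_domains(cfg, uni$universe, uni$sets)
  bl <- generate_blast_hits(cfg, uni$universe, uni$sets, og$od$meta)
  orgs <- og$od$meta[!duplicated(og$od$meta$organism_id), ]
  hl <- build_hit_lists(filter_hits(bl$hits), bl$subject_organism, orgs,
                        bl$query_gene)
  # only the two planted organisms generate hits; the third has none
  expect_identical(sort(names(hl)), sort(names(bl$truth$similar_counts)))
  expect_length(hl, 2L)
  for (o in names(hl))
    expect_identical(length(hl[[o]]$similar_genes),
                     bl$truth$similar_counts[[o]])
})

test_that("mimicry ORA is one family per test set and order-invariant", {
  set.seed(51)
  pool <- sprintf("g%03d", 1:200)
  test <- gene_set("t", pool[1:20])
  ref <- gene_set("r", pool[21:200])
  hl <- list(
    enriched = structure(list(organism_id = "enriched", kingdom = "BACTERIA",
                              similar_genes = pool[c(1:15, 21:30)]),
                         class = "organism_hits"),
    null_org = structure(list(organism_id = "null_org", kingdom = "ARCHAEA",
                              similar_genes = sample(pool, 40)),
                         class = "organism_hits"),
    no_overlap = structure(list(organism_id = "no_overlap",
                                kingdom = "EUKARYOTA",
                                similar_genes = "absent_gene"),
                           class = "organism_hits"))
  res <- mimicry_ora(test, ref, hl)
  expect_identical(nrow(res), 3L)
  no_ov <- res[res$category_id == "no_overlap", ]
  expect_identical(no_ov$k, 0L)
  expect_identical(no_ov$p_raw, 1)
  expect_equal(sort(res$p_adjusted), sort(bh_adjust(res$p_raw)),
               tolerance = 1e-12)
  expect_true(res[res$category_id == "enriched", "passes_filters"])

  res_perm <- mimicry_ora(test, ref, rev(hl))
  expect_identical(res, res_perm)
})
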