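small_cfg <- function(seed = 1) {
  sim_config(seed = seed, n_genes = 600,
             test_set_sizes = c(ag_one = 60, ag_two = 40),
             n_categories_per_namespace = 15,
             namespaces = c("go", "kegg"),
             n_organisms_per_kingdom = c(BACTERIA = 4, ARCHAEA = 3,
                                         EUKARYOTA = 3),
             n_domains_per_scheme = 120, domain_universality_prob = 0.4,
             seq_length = 100,
             mimicry_plants = data.frame(organism_index = 8,
                                         test_prob = 0.4, ref_prob = 0.03))
}

test_that("identical configs give byte-identical corpora", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressWarnings(simulate_corpus(small_cfg(5), d1))
  suppressWarnings(simulate_corpus(small_cfg(5), d2))
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  # a different seed changes the corpus
  d3 <- withr::local_tempdir()
  suppressWarnings(simulate_corpus(small_cfg(6), d3))
  expect_false(identical(unname(tools::md5sum(file.path(d1, "universe.tsv"))),
                         unname(tools::md5sum(file.path(d3, "universe.tsv")))))
})

test_that("configuration domain violations are rejected", {
  expect_error(generate_universe(
    sim_config(n_genes = 1000, test_set_sizes = c(a = 1200))),
    "exceeds universe size")
  expect_error(sim_config(base_annotation_prob = 1.5), "probabilities")
  expect_error(sim_config(test_set_sizes = c(10, 20)), "named")
})

test_that("null exon shift yields uniform WMW p-values", {
  ps <- vapply(1:200, function(s) {
    cfg <- sim_config(seed = s, n_genes = 300,
                      test_set_sizes = c(ag = 50),
                      exon_shift_per_set = 0)
    uni <- generate_universe(cfg)
    feat <- numeric_feature("mean_exon_length",
                            stats::setNames(uni$universe$mean_exon_length,
                                            uni$universe$gene_id))
    ref <- build_pcg_reference(uni$universe, uni$sets$ag)
    feature_wmw(uni$sets$ag, ref, feat)$p_raw
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("annotation plants produce the configured contingency", {
  # test_prob 1 and base 0: the planted category is exactly the test set
  cfg <- sim_config(seed = 3, n_genes = 400, test_set_sizes = c(ag = 50),
                    namespaces = "go", n_categories_per_namespace = 5,
                    base_annotation_prob = 0,
                    planted_categories = data.frame(
                      set_index = 1L, namespace = "go",
                      category_index = 2L, test_prob = 1))
  uni <- generate_universe(cfg)
  ann <- generate_annotations(cfg, uni$universe, uni$sets)
  expect_setequal(ann$catalogs$go$categories$go_c002, uni$sets$ag$members)
  expect_length(ann$catalogs$go$categories$go_c001, 0L)
  expect_identical(ann$truth$planted[[1]]$category_id, "go_c002")

  # no plants, base 0 -> all-null catalog
  cfg0 <- sim_config(seed = 3, n_genes = 100, test_set_sizes = c(ag = 10),
                     namespaces = "go", n_categories_per_namespace = 3,
                     base_annotation_prob = 0,
                     planted_categories = data.frame(
                       set_index = integer(), namespace = character(),
                       category_index = integer(), test_prob = numeric()))
  uni0 <- generate_universe(cfg0)
  ann0 <- generate_annotations(cfg0, uni0$universe, uni0$sets)
  expect_true(all(lengths(ann0$catalogs$go$categories) == 0L))
})

test_that("motif and universality extremes behave as configured", {
  cfg <- small_cfg()
  cfg$motif_rate_test <- 0; cfg$motif_rate_ref <- 0
  uni <- generate_universe(cfg)
  gs <- generate_sequences(cfg, uni$universe, uni$sets)
  expect_length(gs$truth$carriers, 0L)
  expect_length(build_motif_catalog(gs$sequences)$categories$ELR, 0L)

  cfg2 <- small_cfg()
  cfg2$domain_universality_prob <- 1
  cfg2$p_universal_in_org <- 1
  cfg2$p_incomplete_org <- 0
  og <- generate_organism_domains(cfg2, uni$universe, uni$sets)
  kept <- filter_organisms(og$od, 10L)
  # every domain universal -> present in every organism -> fraction 1.0
  doms <- universal_domains(kept, "BACTERIA", 1, scheme = "CATH")
  expect_length(doms, cfg2$n_domains_per_scheme)
})

test_that("features correlate with exon length and respect missingness", {
  cfg <- sim_config(seed = 17, n_genes = 2000, test_set_sizes = c(ag = 100),
                    feature_missing_prob = 0.2)
  uni <- generate_universe(cfg)
  ft <- generate_features(cfg, uni$universe, uni$sets)
  f <- ft$features$snp_synonymous
  expect_lt(length(f$values), cfg$n_genes)           # some genes missing
  len <- uni$universe$mean_exon_length[match(names(f$values),
                                             uni$universe$gene_id)]
  expect_gt(stats::cor(f$values, len, method = "spearman"), 0.5)
})
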