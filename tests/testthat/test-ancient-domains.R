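make_od <- function(meta_rows, dom_rows) {
  organism_domains(
    do.call(rbind, lapply(meta_rows, function(r)
      data.frame(organism_id = r[[1]], kingdom = r[[2]],
                 complete = as.logical(r[[3]]), scheme = r[[4]],
                 stringsAsFactors = FALSE))),
    do.call(rbind, lapply(dom_rows, function(r)
      data.frame(organism_id = r[[1]], domain_id = r[[2]],
                 stringsAsFactors = FALSE))))
}

test_that("organism retention uses inclusive domain-count and completeness", {
  doms <- c(lapply(sprintf("d%03d", 1:150), function(d) list("o150", d)),
            lapply(sprintf("d%03d", 1:149), function(d) list("o149", d)),
            lapply(sprintf("d%03d", 1:500), function(d) list("oInc", d)))
  od <- make_od(list(list("o150", "BACTERIA", TRUE, "CATH"),
                     list("o149", "BACTERIA", TRUE, "CATH"),
                     list("oInc", "BACTERIA", FALSE, "CATH")),
                doms)
  kept <- filter_organisms(od, 150L)
  expect_identical(kept$meta$organism_id, "o150")

  # monotone: raising min_domains never enlarges the retained list
  for (m in c(1L, 100L, 150L, 151L, 400L)) {
    k1 <- filter_organisms(od, m)$meta$organism_id
    k2 <- filter_organisms(od, m + 50L)$meta$organism_id
    expect_true(all(k2 %in% k1))
  }
})

test_that("universal domains use an inclusive species fraction", {
  od <- make_od(list(list("s1", "ARCHAEA", TRUE, "CATH"),
                     list("s2", "ARCHAEA", TRUE, "CATH"),
                     list("s3", "ARCHAEA", TRUE, "CATH")),
                list(list("s1", "A"), list("s1", "B"),
                     list("s2", "A"),
                     list("s3", "A"), list("s3", "C")))
  expect_identical(universal_domains(od, "ARCHAEA", 0.70), "A")

  # 10 species: present in exactly 7 -> included, 6 -> excluded
  meta <- lapply(sprintf("t%02d", 1:10),
                 function(o) list(o, "BACTERIA", TRUE, "PFAM"))
  doms <- c(lapply(sprintf("t%02d", 1:7), function(o) list(o, "d7")),
            lapply(sprintf("t%02d", 1:6), function(o) list(o, "d6")))
  od10 <- make_od(meta, doms)
  expect_identical(universal_domains(od10, "BACTERIA", 0.70), "d7")

  expect_error(universal_domains(od10, "EUKARYOTA", 0.70), "no organisms")

  # monotone shrinkage in the fraction
  prev <- NULL
  for (f in c(0.3, 0.5, 0.7, 0.9, 1)) {
    cur <- universal_domains(od10, "BACTERIA", f)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("domain-to-gene mapping unions genes and warns on unmapped domains", {
  map <- data.frame(domain_id = c("A", "A", "B"),
                    gene_id = c("g1", "g2", "g1"), stringsAsFactors = FALSE)
  us <- map_domains_to_genes("A", map, "BACTERIA", "CATH")
  expect_identical(us$gene_set$name, "UNIVERSAL_BACTERIA_CATH")
  expect_setequal(us$gene_set$members, c("g1", "g2"))

  us2 <- map_domains_to_genes(c("A", "B"),
                              data.frame(domain_id = c("A", "B"),
                                         gene_id = c("g1", "g1")),
                              "ARCHAEA", "PFAM")
  expect_identical(us2$gene_set$members, "g1")

  expect_warning(
    us3 <- map_domains_to_genes(c("A", "zz"), map, "BACTERIA", "CATH"),
    "absent from the domain-gene map")
  expect_warning(
    empty <- map_domains_to_genes(character(), map, "EUKARYOTA", "CATH"),
    "empty")
  expect_length(empty$gene_set$members, 0L)
})

test_that("six UNIVERSAL sets emerge from two schemes, fewer with warning", {
  cfg <- sim_config(seed = 13, n_genes = 400, test_set_sizes = c(ag = 50),
                    n_organisms_per_kingdom = c(BACTERIA = 5, ARCHAEA = 5,
                                                EUKARYOTA = 5),
                    p_incomplete_org = 0, n_domains_per_scheme = 120,
                    domain_universality_prob = 0.4,
                    p_universal_in_org = 1)  # universal domains in every species
  uni <- generate_universe(cfg)
  og <- generate_organism_domains(cfg, uni$universe, uni$sets)
  suppressWarnings(
    usets <- build_universal_sets(og$od, og$domain_gene, min_domains = 10L))
  expect_length(usets, 6L)
  expect_setequal(names(usets),
                  c(outer(c("UNIVERSAL_BACTERIA", "UNIVERSAL_ARCHAEA",
                            "UNIVERSAL_EUKARYOTA"),
                          c("CATH", "PFAM"), paste, sep = "_")))
  # ancient carriers land in every UNIVERSAL set
  for (us in usets)
    expect_true(all(og$truth$ancient_carriers %in% us$gene_set$members))

  one_scheme <- og$od
  one_scheme$meta <- one_scheme$meta[one_scheme$meta$scheme == "CATH", ]
  w <- testthat::capture_warnings(
    three <- build_universal_sets(one_scheme, og$domain_gene,
                                  min_domains = 10L))
  expect_true(any(grepl("fewer than two", w)))
  expect_length(three, 3L)
})

test_that("UNIVERSAL over-representation uses the full population", {
  pool <- sprintf("g%03d", 1:100)
  test <- gene_set("t", pool[1:10])
  ref <- gene_set("r", pool[11:100])
  us <- structure(list(kingdom = "BACTERIA", scheme = "CATH",
                       domains = "d1",
                       gene_set = gene_set("UNIVERSAL_BACTERIA_CATH",
                                           pool[1:10])),
                  class = "universal_set")
  res <- universal_ora(test, ref, us)
  expect_identical(unlist(res[c("N", "K", "n", "k")], use.names = FALSE),
                   c(100L, 10L, 10L, 10L))
  expect_equal(res$p_raw, 1 / choose(100, 10), tolerance = 1e-12)

  us$gene_set <- gene_set("UNIVERSAL_BACTERIA_CATH", character())
  res0 <- universal_ora(test, ref, us)
  expect_identical(res0$k, 0L)
  expect_identical(res0$p_raw, 1)
})
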