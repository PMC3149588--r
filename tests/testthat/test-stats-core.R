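test_that("hypergeometric tail matches enumeration on hand-checked cases", {
  expect_equal(hypergeom_tail(4, 10, 5, 4), 5 / 210, tolerance = 1e-12)
  expect_identical(hypergeom_tail(0, 10, 5, 4), 1)
  expect_equal(hypergeom_tail(3, 6, 3, 3), 1 / 20, tolerance = 1e-12)
  expect_error(hypergeom_tail(5, 10, 4, 4), "min")
  expect_error(hypergeom_tail(1, 10, 11, 4), "K <= N")
})

test_that("hypergeometric tail is non-increasing in k", {
  for (seed in 1:10) {
    set.seed(seed)
    N <- sample(5:60, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    p <- hypergeom_tail(0:min(n, K), N, K, n)
    expect_true(all(diff(p) <= 1e-12))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("WMW exact p-values reproduce the enumeration examples", {
  w <- wmw_test(c(3, 4, 5), c(1, 2))
  expect_equal(w$u_statistic, 6)
  expect_equal(w$p_raw, 1 / 10)
  expect_identical(w$method, "exact")

  w2 <- wmw_test(2, 1)
  expect_equal(w2$u_statistic, 1)
  expect_equal(w2$p_raw, 0.5)

  expect_warning(w3 <- wmw_test(c(1, 1), c(1, 1)), "identical")
  expect_equal(w3$u_statistic, 2)
  expect_equal(w3$p_raw, 1)

  expect_error(wmw_test(numeric(), 1), "non-empty")
})

test_that("WMW exact branch agrees with full permutation enumeration under ties", {
  set.seed(11)
  for (rep in 1:20) {
    nt <- sample(1:5, 1); nr <- sample(1:5, 1)
    x <- sample(1:4, nt, replace = TRUE)   # small alphabet forces ties
    y <- sample(1:4, nr, replace = TRUE)
    got <- suppressWarnings(wmw_test(x, y))
    expect_equal(got$p_raw, wmw_enum_oracle(x, y), tolerance = 1e-12,
                 info = sprintf("rep %d", rep))
  }
})

test_that("WMW agrees with wilcox.test on tie-free data", {
  set.seed(3)
  x <- rnorm(6); y <- rnorm(5)
  got <- wmw_test(x, y)
  ref <- stats::wilcox.test(x, y, alternative = "greater", exact = TRUE)
  expect_equal(got$u_statistic, unname(ref$statistic))
  expect_equal(got$p_raw, ref$p.value, tolerance = 1e-12)
})

test_that("exact and normal branches agree at the default crossover size", {
  # just above the default exact limit of 12, where the normal branch takes
  # over, the two branches must agree closely (no heavy ties)
  set.seed(19)
  for (rep in 1:30) {
    nt <- sample(5:8, 1); nr <- sample(5:8, 1)
    if (nt + nr < 13) nr <- 13 - nt
    x <- rnorm(nt); y <- rnorm(nr)
    exact <- wmw_test(x, y, exact_limit = 20L)$p_raw
    approx <- wmw_test(x, y, exact_limit = 0L)$p_raw
    expect_lt(abs(exact - approx), 0.01)
  }
})

test_that("BH adjustment follows the step-up formula in input order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.04, 0.01)), c(0.04, 0.02))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= 1))
})

test_that("single-category ORA computes counts on the namespace population", {
  test <- gene_set("t", c("g1", "g2"))
  ref <- gene_set("r", paste0("g", 3:10))
  all10 <- paste0("g", 1:10)
  res <- ora_test(test, ref, c("g1", "g2"), all10)
  expect_identical(unlist(res[c("N", "K", "n", "k")], use.names = FALSE),
                   c(10L, 2L, 2L, 2L))
  expect_equal(res$p_raw, 1 / 45, tolerance = 1e-12)

  res0 <- ora_test(test, ref, c("g9", "g10"), all10)
  expect_identical(res0$k, 0L)
  expect_identical(res0$p_raw, 1)

  # test genes outside the namespace drop out of n
  res_ns <- ora_test(test, ref, "g2", paste0("g", 2:10))
  expect_identical(res_ns$n, 1L)
  expect_identical(res_ns$N, 9L)

  expect_error(ora_test(test, gene_set("r2", "g1"), "g1", all10), "disjoint")
  expect_error(ora_test(test, ref, "g1", "zz"), "population")
})

test_that("result filters apply the documented boundary semantics", {
  base <- data.frame(K = 5L, k = 2L, p_adjusted = 0.01)
  cfg <- filter_config()
  expect_true(apply_filters(base, cfg, 40)$passes_filters)     # 2/40 = 5%
  base$k <- 1L
  expect_false(apply_filters(base, cfg, 40)$passes_filters)    # 2.5% < 5%
  at_alpha <- data.frame(K = 5L, k = 5L, p_adjusted = 0.05)
  expect_false(apply_filters(at_alpha, cfg, 40)$passes_filters) # strict <
  small_k <- data.frame(K = 1L, k = 1L, p_adjusted = 0.001)
  expect_false(apply_filters(small_k, cfg, 10)$passes_filters)  # K < 2
  expect_error(filter_config(alpha = 1.2), "alpha")
})

test_that("catalog-level ORA adjusts within one family and records prevalence", {
  set.seed(23)
  pool <- sprintf("g%03d", 1:300)
  test <- gene_set("t", pool[1:30])
  ref <- gene_set("r", pool[31:300])
  cats <- list(big = pool[c(1:20, 31:60)],     # strongly enriched
               null1 = sample(pool, 30),
               null2 = sample(pool, 30))
  cat_obj <- annotation_catalog("go", cats)
  res <- ora_catalog(test, ref, cat_obj)
  expect_s3_class(res, "ora_results")
  expect_identical(nrow(res), 3L)
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-15))
  expect_identical(res$namespace, rep("go", 3))
  # population restricted to annotated genes
  annotated <- unique(unlist(cats))
  expect_identical(unique(res$N), length(intersect(union(test$members,
                                                         ref$members),
                                                   annotated)))
  expect_true(res$passes_filters[res$category_id == "big"])
  # prevalence = k over annotated test genes
  n_ann_test <- length(intersect(test$members, annotated))
  expect_equal(res$prevalence, res$k / n_ann_test)
})
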