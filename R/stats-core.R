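# Core statistics: hypergeometric over-representation, one-tailed
# Wilcoxon-Mann-Whitney rank test, Benjamini-Hochberg correction, and the
# significance / category-size / prevalence result filters.

#' Upper tail of the hypergeometric distribution
#'
#' P(X >= k) where X counts annotated genes in a draw of `n` genes from a
#' population of `N` genes of which `K` are annotated. Computed with
#' survival-function arithmetic (`stats::phyper`), numerically stable far
#' into the tail.
#'
#' @param k Observed count (vectorised).
#' @param N Population size.
#' @param K Annotated genes in the population.
#' @param n Test-set size (number drawn).
#' @return P(X >= k), in \[0, 1\].
#' @export
hypergeom_tail <- function(k, N, K, n) {
  if (length(N) != 1L || length(K) != 1L || length(n) != 1L)
    stop("N, K and n must be scalars")
  vals <- c(k, N, K, n)
  if (any(is.na(vals)) || any(vals != floor(vals)))
    stop("hypergeom_tail: parameters must be non-missing integers")
  if (K < 0 || K > N || n < 0 || n > N)
    stop("hypergeom_tail: need 0 <= K <= N and 0 <= n <= N")
  if (any(k < 0) || any(k > pmin(n, K)))
    stop("hypergeom_tail: need 0 <= k <= min(n, K)")
  # P(X >= k) = P(X > k - 1)
  pmin(1, pmax(0, stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)))
}

#' Filter configuration for enrichment results
#'
#' Bundles the significance level, the minimum number of annotated genes a
#' category must have in the tested population, and the prevalence fraction
#' (minimum share of the test set carrying the annotation).
#'
#' @param alpha Significance level for the BH-adjusted p-value (strict `<`).
#' @param min_category_size Minimum `K` within the tested population (inclusive).
#' @param prevalence_fraction Minimum `k / denominator` (inclusive).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(alpha = 0.05, min_category_size = 2L,
                          prevalence_fraction = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (min_category_size < 1) stop("min_category_size must be >= 1")
  if (prevalence_fraction < 0 || prevalence_fraction > 1)
    stop("prevalence_fraction must be in [0, 1]")
  structure(list(alpha = alpha,
                 min_category_size = as.integer(min_category_size),
                 prevalence_fraction = prevalence_fraction),
            class = "filter_config")
}

#' Over-representation test for one binary category
#'
#' Tests whether category members occur in the test set more often than
#' expected under hypergeometric sampling from the population. The
#' population is `(test U reference)` intersected with `namespace_universe`
#' (the genes for which the annotation namespace is informative).
#'
#' @param test,reference Disjoint [gene_set]s.
#' @param category_members Character vector of annotated gene ids.
#' @param namespace_universe Character vector of gene ids the namespace covers.
#' @param category_id Category label carried into the result.
#' @param namespace Namespace label carried into the result.
#' @return One-row data frame with columns `set_name`, `namespace`,
#'   `category_id`, `N`, `K`, `n`, `k`, `p_raw`.
#' @export
ora_test <- function(test, reference, category_members, namespace_universe,
                     category_id = "category", namespace = "default") {
  if (length(intersect(test$members, reference$members)))
    stop("test and reference sets must be disjoint")
  population <- intersect(union(test$members, reference$members),
                          namespace_universe)
  N <- length(population)
  if (N == 0L) stop("ora_test: empty population after namespace restriction")
  in_test <- population %in% test$members
  in_cat  <- population %in% category_members
  n <- sum(in_test)
  if (n == 0L) stop("ora_test: no test-set genes in the population")
  K <- sum(in_cat)
  k <- sum(in_test & in_cat)
  data.frame(set_name = test$name, namespace = namespace,
             category_id = category_id,
             N = N, K = K, n = n, k = k,
             p_raw = hypergeom_tail(k, N, K, n),
             stringsAsFactors = FALSE)
}

#' One-tailed Wilcoxon-Mann-Whitney test for a rightward shift
#'
#' Tests whether the test values are stochastically larger than the
#' reference values. The U statistic counts (test, reference) pairs with
#' test > reference, ties at half weight. When the combined sample size is
#' at most `exact_limit` the p-value is exact: a subset-sum dynamic program
#' over doubled midranks counts, among all equally likely assignments of
#' group labels to the pooled values, those with a rank sum at least as
#' large as observed (correct under ties). Otherwise a normal approximation
#' with midranks, tie-corrected variance and continuity correction is used.
#'
#' @param test_values,ref_values Non-empty numeric vectors.
#' @param exact_limit Combined-size cutoff for the exact branch.
#' @return An object of class `wmw_result`: `n_test`, `n_ref`,
#'   `u_statistic`, `p_raw`, `method`, `direction`.
#' @export
wmw_test <- function(test_values, ref_values, exact_limit = 12L) {
  if (length(test_values) == 0L || length(ref_values) == 0L)
    stop("wmw_test: both value vectors must be non-empty")
  if (any(is.na(test_values)) || any(is.na(ref_values)))
    stop("wmw_test: missing values not allowed; drop them upstream")
  nx <- length(test_values)
  ny <- length(ref_values)
  pooled <- c(test_values, ref_values)
  r <- rank(pooled)  # midranks
  rank_sum <- sum(r[seq_len(nx)])
  u <- rank_sum - nx * (nx + 1) / 2
  if (length(unique(pooled)) == 1L) {
    warning("wmw_test: all values identical in both groups; p = 1")
    return(new_wmw_result(nx, ny, u, 1, "degenerate"))
  }
  if (nx + ny <= exact_limit) {
    p <- wmw_exact_p(r, nx)
    method <- "exact"
  } else {
    p <- wmw_normal_p(r, nx, ny, u)
    method <- "normal"
  }
  new_wmw_result(nx, ny, u, p, method)
}

new_wmw_result <- function(nx, ny, u, p, method,
                           set_name = NA_character_, feature_id = NA_character_,
                           n_missing_test = 0L, n_missing_ref = 0L) {
  structure(list(set_name = set_name, feature_id = feature_id,
                 n_test = nx, n_ref = ny, u_statistic = u,
                 p_raw = min(1, max(0, p)), method = method,
                 direction = "greater",
                 n_missing_test = n_missing_test,
                 n_missing_ref = n_missing_ref),
            class = "wmw_result")
}

#' @export
print.wmw_result <- function(x, ...) {
  cat(sprintf("<wmw_result> one-tailed (greater), %s branch\n", x$method))
  if (!is.na(x$feature_id))
    cat(sprintf("  %s vs reference, feature %s\n", x$set_name, x$feature_id))
  cat(sprintf("  n_test = %d, n_ref = %d, U = %g, p = %.6g\n",
              x$n_test, x$n_ref, x$u_statistic, x$p_raw))
  invisible(x)
}

# Exact one-sided p via DP: among all C(N, nx) subsets of the pooled
# midranks, count those whose doubled rank sum is >= the observed one.
# Doubling makes midranks integral so the DP index is exact.
wmw_exact_p <- function(r, nx) {
  w <- as.integer(round(2 * r))
  N <- length(w)
  target <- sum(sort(w, decreasing = TRUE)[seq_len(nx)])  # max attainable sum
  # dp[s + 1, t + 1] = number of subsets of size s with doubled rank sum t
  dp <- matrix(0, nrow = nx + 1L, ncol = target + 1L)
  dp[1L, 1L] <- 1
  for (wi in w) {
    smax <- nx
    for (s in seq(smax, 1L)) {
      cols <- seq_len(target + 1L - wi)
      dp[s + 1L, cols + wi] <- dp[s + 1L, cols + wi] + dp[s, cols]
    }
  }
  obs <- as.integer(round(2 * sum(r[seq_len(nx)])))
  count_ge <- sum(dp[nx + 1L, seq.int(obs + 1L, target + 1L)])
  count_ge / choose(N, nx)
}

# Normal approximation with midranks, tie-corrected variance and
# continuity correction, one-sided (greater).
wmw_normal_p <- function(r, nx, ny, u) {
  N <- nx + ny
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- (nx * ny / 12) * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u - nx * ny / 2 - 0.5) / sqrt(sigma2)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: for sorted p-values, the adjusted value at rank i
#' is `min over j >= i of p_(j) * m / j`, capped at 1, returned in the input
#' order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("bh_adjust: p-values must be in [0, 1] and non-missing")
  stats::p.adjust(p_values, method = "BH")
}

#' Apply the reporting filters to over-representation results
#'
#' Sets `passes_filters` on every result row (nothing is deleted): adjusted
#' p strictly below `alpha`, at least `min_category_size` annotated genes in
#' the tested population (`K`), and prevalence `k / prevalence_denominator`
#' of at least `prevalence_fraction` (both thresholds inclusive).
#'
#' @param results Data frame with columns `K`, `k`, `p_adjusted`.
#' @param cfg A [filter_config].
#' @param prevalence_denominator Positive integer (scalar or per-row):
#'   typically the number of test-set genes with any annotation in the
#'   namespace, or the test-set size for namespaces defined on every gene.
#' @return `results` with columns `prevalence` and `passes_filters` set.
#' @export
apply_filters <- function(results, cfg = filter_config(),
                          prevalence_denominator) {
  stopifnot(all(c("K", "k", "p_adjusted") %in% names(results)))
  if (any(prevalence_denominator < 1))
    stop("prevalence_denominator must be >= 1")
  results$prevalence <- results$k / prevalence_denominator
  results$passes_filters <- (results$p_adjusted < cfg$alpha) &
    (results$K >= cfg$min_category_size) &
    (results$prevalence >= cfg$prevalence_fraction)
  results
}

#' Over-representation analysis over a whole annotation catalog
#'
#' Runs [ora_test] for every category of a catalog against one test set and
#' reference, adjusts p-values with Benjamini-Hochberg across the catalog
#' (one family per test set x namespace run), and applies the reporting
#' filters.
#'
#' By default the population is restricted to genes carrying at least one
#' annotation in the namespace (unannotated genes are uninformative there),
#' and the prevalence denominator is the number of test-set genes with any
#' annotation. Both follow the convention of reporting categories covering
#' at least 5% of the annotated proteins of a data set; `population =
#' "full"` and `prevalence_on = "all"` switch to the unrestricted variants.
#'
#' @param test,reference Disjoint [gene_set]s.
#' @param catalog An [annotation_catalog].
#' @param cfg A [filter_config].
#' @param population `"annotated"` (default) or `"full"`.
#' @param prevalence_on `"annotated"` (default) or `"all"` test-set genes.
#' @return Data frame of class `ora_results`, one row per category, sorted
#'   by (set_name, namespace, p_adjusted, category_id).
#' @export
ora_catalog <- function(test, reference, catalog, cfg = filter_config(),
                        population = c("annotated", "full"),
                        prevalence_on = c("annotated", "all")) {
  population <- match.arg(population)
  prevalence_on <- match.arg(prevalence_on)
  stopifnot(inherits(catalog, "annotation_catalog"))
  if (length(catalog$categories) == 0L)
    return(empty_ora_results())
  annotated <- unique(unlist(catalog$categories, use.names = FALSE))
  full_pop <- union(test$members, reference$members)
  ns_universe <- if (population == "annotated") annotated else full_pop
  rows <- lapply(names(catalog$categories), function(cat_id) {
    ora_test(test, reference, catalog$categories[[cat_id]], ns_universe,
             category_id = cat_id, namespace = catalog$namespace)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- bh_adjust(res$p_raw)
  pop <- intersect(full_pop, ns_universe)
  denom <- if (prevalence_on == "annotated") {
    length(intersect(intersect(test$members, pop), annotated))
  } else {
    length(intersect(test$members, pop))
  }
  res <- apply_filters(res, cfg, max(1L, denom))
  sort_ora_results(res)
}

empty_ora_results <- function() {
  structure(data.frame(set_name = character(), namespace = character(),
                       category_id = character(), N = integer(), K = integer(),
                       n = integer(), k = integer(), p_raw = numeric(),
                       p_adjusted = numeric(), prevalence = numeric(),
                       passes_filters = logical(), stringsAsFactors = FALSE),
            class = c("ora_results", "data.frame"))
}

sort_ora_results <- function(res) {
  ord <- order(res$set_name, res$namespace, res$p_adjusted, res$category_id)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ora_results", "data.frame")
  res
}

#' @export
print.ora_results <- function(x, ...) {
  cat(sprintf("<ora_results> %d categories, %d passing filters\n",
              nrow(x), sum(x$passes_filters)))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat("  ... ", nrow(x) - 10L, " more rows\n", sep = "")
  invisible(x)
}

#' Write enrichment results as a sorted TSV
#'
#' Canonical byte-stable output: rows sorted by
#' (set_name, namespace, p_adjusted, category_id).
#'
#' @param results An `ora_results` data frame.
#' @param path Output path.
#' @export
write_ora_tsv <- function(results, path) {
  res <- sort_ora_results(as.data.frame(results))
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
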