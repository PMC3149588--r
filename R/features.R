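# Numeric per-gene features (mean exon length, SNP counts by type, somatic
# mutation counts) and per-kilobase normalized variants; rank-shift testing.

#' Create a numeric feature
#'
#' One feature is a mapping from gene identifiers to non-negative values.
#' Genes absent from the mapping are missing for that feature, not zero
#' (absence from a variant database is not evidence of zero variants).
#'
#' @param feature_id Feature name, e.g. `"snp_nonsynonymous"`.
#' @param values Named numeric vector (names are gene ids), non-negative.
#' @return An object of class `numeric_feature`.
#' @export
numeric_feature <- function(feature_id, values) {
  if (!is.character(feature_id) || length(feature_id) != 1L || !nzchar(feature_id))
    stop("feature_id must be a single non-empty string")
  values <- values[!is.na(values)]
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("feature values must be named by gene id")
  if (anyDuplicated(names(values)))
    stop("duplicate gene ids in feature '", feature_id, "'")
  if (any(values < 0))
    stop("feature '", feature_id, "' has negative values")
  structure(list(feature_id = feature_id, values = values),
            class = "numeric_feature")
}

#' @export
print.numeric_feature <- function(x, ...) {
  cat(sprintf("<numeric_feature> %s: %d genes, median %.3g\n",
              x$feature_id, length(x$values), stats::median(x$values)))
  invisible(x)
}

#' Load numeric features from TSV
#'
#' Expects a header whose first column is `gene_id`, then one column per
#' feature. Empty cells and `NA` are missing values; any other non-numeric
#' cell is an error naming its row and column. Duplicate gene rows are an
#' error.
#'
#' @param path Path to the feature TSV.
#' @return Named list of [numeric_feature] objects, one per column.
#' @export
load_feature_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (names(df)[1] != "gene_id")
    stop("feature TSV must have 'gene_id' as first column")
  if (ncol(df) < 2L) stop("feature TSV has no feature columns")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id rows in feature TSV: ",
         paste(utils::head(unique(df$gene_id[duplicated(df$gene_id)]), 3),
               collapse = ", "))
  out <- list()
  for (col in names(df)[-1]) {
    raw <- df[[col]]
    missing <- is.na(raw) | raw == "" | raw == "NA"
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!missing & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   raw[bad[1]], bad[1], col))
    vals <- num[!missing]
    names(vals) <- df$gene_id[!missing]
    out[[col]] <- numeric_feature(col, vals)
  }
  out
}

#' Normalize a count feature by mean exon length
#'
#' Converts raw per-gene counts to counts per `scale` nucleotides of mean
#' exon length (default per kilobase): `value * scale / mean_exon_length`.
#' Genes with zero exon length are dropped with a warning.
#'
#' @param feature A [numeric_feature].
#' @param universe A `gene_universe` supplying exon lengths; every feature
#'   gene must be present.
#' @param scale Length unit in nucleotides (default 1000).
#' @return A [numeric_feature] with `"_norm"` appended to the id.
#' @export
normalize_by_exon_length <- function(feature, universe, scale = 1000) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a single positive number")
  ids <- names(feature$values)
  idx <- match(ids, universe$gene_id)
  if (anyNA(idx))
    stop("feature genes missing from universe: ",
         paste(utils::head(ids[is.na(idx)], 3), collapse = ", "))
  len <- universe$mean_exon_length[idx]
  zero <- len == 0
  if (any(zero)) {
    warning(sprintf("%d genes with zero exon length dropped from '%s'",
                    sum(zero), feature$feature_id))
  }
  vals <- feature$values[!zero] * scale / len[!zero]
  numeric_feature(paste0(feature$feature_id, "_norm"), vals)
}

#' Rank-shift test of a feature between a test set and a reference
#'
#' One-tailed Wilcoxon-Mann-Whitney test of whether the feature values of
#' the test-set genes are shifted to the right of the reference-set values.
#' Genes without a value for the feature are excluded from the test (their
#' number is recorded on the result).
#'
#' @param test,reference [gene_set]s.
#' @param feature A [numeric_feature].
#' @param exact_limit Passed to [wmw_test].
#' @return A `wmw_result` with `set_name`, `feature_id` and missing-gene
#'   counts filled in.
#' @export
feature_wmw <- function(test, reference, feature, exact_limit = 12L) {
  tv <- feature$values[intersect(test$members, names(feature$values))]
  rv <- feature$values[intersect(reference$members, names(feature$values))]
  if (length(tv) == 0L)
    stop("feature_wmw: no test-set genes with values for '",
         feature$feature_id, "'")
  if (length(rv) == 0L)
    stop("feature_wmw: no reference-set genes with values for '",
         feature$feature_id, "'")
  res <- wmw_test(unname(tv), unname(rv), exact_limit = exact_limit)
  res$set_name <- test$name
  res$feature_id <- feature$feature_id
  res$n_missing_test <- length(test$members) - length(tv)
  res$n_missing_ref <- length(reference$members) - length(rv)
  res
}
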