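# Orchestration: read all inputs, build the reference sets, run every
# analysis block (numeric-feature rank tests; per-namespace binary ORA;
# UNIVERSAL ancient-domain ORA; per-organism mimicry ORA) for every test
# set against both references, and export sorted result tables plus
# set-by-category significance matrices.

#' Configuration for a full pipeline run
#'
#' Only `universe` and `gmt` are required; analysis blocks whose inputs are
#' `NULL` are skipped.
#'
#' @param universe Path to the universe TSV (`gene_id`, `mean_exon_length`).
#' @param gmt Path to the antigen-set GMT.
#' @param annotations Named character vector of annotation TSV paths, one
#'   per namespace (name = namespace label).
#' @param features Path to the wide feature TSV, or `NULL`.
#' @param fasta Path to protein FASTA for motif scanning, or `NULL`.
#' @param organisms,organism_domains,domain_genes Paths to the organism
#'   metadata, organism-domain and domain-gene TSVs, or `NULL`.
#' @param blast,subject_organisms,query_genes Paths to the BLAST tabular
#'   file and its two mapping TSVs, or `NULL`.
#' @param filter A [filter_config].
#' @param exon_threshold Strict mean-exon-length cutoff for the long-exon
#'   reference, nucleotides.
#' @param min_domains,universal_fraction Ancient-domain thresholds.
#' @param min_score,max_evalue BLAST similarity filters.
#' @param norm_scale Length unit for count normalization (nt).
#' @param references Which references to analyse: `"PCG"`, `"PCGLE"` or both.
#' @param population,prevalence_on Passed to [ora_catalog].
#' @param exact_limit Passed to [wmw_test].
#' @param out_dir Output directory for TSV tables and matrices, or `NULL`
#'   to keep results in memory only.
#' @return An object of class `run_config`.
#' @export
run_config <- function(universe, gmt,
                       annotations = NULL, features = NULL, fasta = NULL,
                       organisms = NULL, organism_domains = NULL,
                       domain_genes = NULL,
                       blast = NULL, subject_organisms = NULL,
                       query_genes = NULL,
                       filter = filter_config(),
                       exon_threshold = 3100,
                       min_domains = 150L, universal_fraction = 0.70,
                       min_score = 100, max_evalue = 0.001,
                       norm_scale = 1000,
                       references = c("PCG", "PCGLE"),
                       population = "annotated", prevalence_on = "annotated",
                       exact_limit = 12L,
                       out_dir = NULL) {
  references <- match.arg(references, c("PCG", "PCGLE"), several.ok = TRUE)
  thresholds <- c(exon_threshold, min_domains, universal_fraction,
                  min_score, norm_scale)
  if (any(thresholds <= 0) || max_evalue < 0)
    stop("thresholds must be positive")
  structure(list(universe = universe, gmt = gmt, annotations = annotations,
                 features = features, fasta = fasta,
                 organisms = organisms, organism_domains = organism_domains,
                 domain_genes = domain_genes, blast = blast,
                 subject_organisms = subject_organisms,
                 query_genes = query_genes,
                 filter = filter, exon_threshold = exon_threshold,
                 min_domains = min_domains,
                 universal_fraction = universal_fraction,
                 min_score = min_score, max_evalue = max_evalue,
                 norm_scale = norm_scale, references = references,
                 population = population, prevalence_on = prevalence_on,
                 exact_limit = exact_limit, out_dir = out_dir),
            class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run every analysis block
#'
#' For each test set (the GMT sets plus their union "ALL") and each
#' configured reference set, runs the numeric-feature rank tests, the
#' per-namespace binary over-representation analyses, the UNIVERSAL
#' ancient-domain analysis, and the per-organism mimicry analysis --
#' whichever blocks have inputs -- and builds one significance matrix per
#' block. All tables are fully sorted, so the bundle is byte-stable across
#' reruns and input row permutations.
#'
#' @param cfg A [run_config].
#' @return An object of class `enrichment_bundle`: data frames `wmw`,
#'   `ora`, `universal`, `mimicry` (NULL when skipped), a named list
#'   `matrices`, the constructed `sets` and references, and a `log` of
#'   stage counts. Written to `cfg$out_dir` when set.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log <- list()

  universe <- with_stage("read_universe", read_universe(cfg$universe))
  sets <- with_stage("read_gmt", read_gmt(cfg$gmt))
  log$n_genes <- nrow(universe)
  log$n_test_sets <- length(sets)

  all_set <- with_stage("build_refs", build_all_set(sets))
  pcg <- with_stage("build_refs", build_pcg_reference(universe, all_set))
  refs <- list()
  if ("PCG" %in% cfg$references) refs$PCG <- pcg
  if ("PCGLE" %in% cfg$references)
    refs$PCGLE <- with_stage(
      "build_refs",
      build_long_exon_reference(pcg, universe, cfg$exon_threshold))
  test_sets <- c(sets, list(all_set))
  names(test_sets) <- vapply(test_sets, `[[`, "", "name")
  test_sets <- test_sets[order(names(test_sets))]

  # ---- numeric features -------------------------------------------------
  features <- list(mean_exon_length = numeric_feature(
    "mean_exon_length",
    stats::setNames(universe$mean_exon_length, universe$gene_id)))
  if (!is.null(cfg$features)) {
    loaded <- with_stage("load_features", load_feature_tsv(cfg$features))
    for (f in names(loaded)) {
      feat <- loaded[[f]]
      keep <- names(feat$values) %in% universe$gene_id
      feat <- numeric_feature(f, feat$values[keep])
      features[[f]] <- feat
      features[[paste0(f, "_norm")]] <- with_stage(
        "normalize_features",
        normalize_by_exon_length(feat, universe, cfg$norm_scale))
    }
  }
  features <- features[order(names(features))]
  wmw_rows <- list()
  for (ref_name in names(refs)) {
    for (ts in test_sets) {
      fam <- lapply(features, function(feat) with_stage(
        "wmw", feature_wmw(ts, refs[[ref_name]], feat,
                           exact_limit = cfg$exact_limit)))
      p_adj <- bh_adjust(vapply(fam, `[[`, 0, "p_raw"))
      for (j in seq_along(fam)) {
        r <- fam[[j]]
        wmw_rows[[length(wmw_rows) + 1L]] <- data.frame(
          set_name = r$set_name, reference = ref_name,
          feature_id = r$feature_id, n_test = r$n_test, n_ref = r$n_ref,
          u_statistic = r$u_statistic, p_raw = r$p_raw,
          p_adjusted = p_adj[[j]], direction = r$direction,
          passes_filters = p_adj[[j]] < cfg$filter$alpha,
          stringsAsFactors = FALSE)
      }
    }
  }
  wmw <- do.call(rbind, wmw_rows)
  wmw <- wmw[order(wmw$set_name, wmw$reference, wmw$p_adjusted,
                   wmw$feature_id), , drop = FALSE]
  rownames(wmw) <- NULL

  # ---- binary annotation catalogs ---------------------------------------
  catalogs <- list()
  if (!is.null(cfg$annotations)) {
    for (ns in sort(names(cfg$annotations)))
      catalogs[[ns]] <- with_stage(
        "read_annotations", read_annotation_tsv(cfg$annotations[[ns]], ns))
  }
  if (!is.null(cfg$fasta)) {
    seqs <- with_stage("motif_scan", read_protein_fasta(cfg$fasta))
    mcat <- with_stage("motif_scan", build_motif_catalog(seqs))
    if ("motif" %in% names(catalogs)) {
      merged <- c(catalogs$motif$categories, mcat$categories)
      catalogs$motif <- annotation_catalog("motif", merged)
    } else catalogs$motif <- mcat
  }
  ora <- NULL
  if (length(catalogs)) {
    ora_parts <- list()
    for (ref_name in names(refs)) {
      for (ts in test_sets) {
        for (ns in sort(names(catalogs))) {
          res <- with_stage("ora", ora_catalog(
            ts, refs[[ref_name]], catalogs[[ns]], cfg$filter,
            population = cfg$population, prevalence_on = cfg$prevalence_on))
          if (nrow(res)) res$reference <- ref_name
          ora_parts[[length(ora_parts) + 1L]] <- res
        }
      }
    }
    ora <- do.call(rbind, ora_parts)
    ora <- sort_bundle_table(ora)
  }

  # ---- UNIVERSAL ancient-domain sets ------------------------------------
  universal <- NULL
  if (!is.null(cfg$organisms) && !is.null(cfg$organism_domains) &&
      !is.null(cfg$domain_genes)) {
    od <- with_stage("ancient_domains",
                     read_organism_tables(cfg$organisms, cfg$organism_domains))
    dg <- with_stage("ancient_domains", utils::read.delim(
      cfg$domain_genes, stringsAsFactors = FALSE, colClasses = "character"))
    usets <- with_stage("ancient_domains", build_universal_sets(
      od, dg, min_domains = cfg$min_domains,
      fraction = cfg$universal_fraction))
    log$n_universal_sets <- length(usets)
    cat_sets <- lapply(usets, function(u) u$gene_set$members)
    uni_parts <- list()
    for (ref_name in names(refs)) {
      for (ts in test_sets) {
        res <- with_stage("ancient_domains", ora_gene_sets(
          ts, refs[[ref_name]], cat_sets, "universal", cfg$filter))
        if (nrow(res)) res$reference <- ref_name
        uni_parts[[length(uni_parts) + 1L]] <- res
      }
    }
    universal <- sort_bundle_table(do.call(rbind, uni_parts))
  }

  # ---- molecular mimicry -------------------------------------------------
  mimicry <- NULL
  if (!is.null(cfg$blast) && !is.null(cfg$subject_organisms) &&
      !is.null(cfg$query_genes) && !is.null(cfg$organisms)) {
    hits <- with_stage("mimicry", parse_blast_tabular(cfg$blast))
    log$n_blast_hits <- nrow(hits)
    kept <- with_stage("mimicry",
                       filter_hits(hits, cfg$min_score, cfg$max_evalue))
    log$n_blast_kept <- nrow(kept)
    so <- utils::read.delim(cfg$subject_organisms, stringsAsFactors = FALSE,
                            colClasses = "character")
    qg <- utils::read.delim(cfg$query_genes, stringsAsFactors = FALSE,
                            colClasses = "character")
    org_meta <- utils::read.delim(cfg$organisms, stringsAsFactors = FALSE)
    org_meta$organism_id <- as.character(org_meta$organism_id)
    org_meta <- org_meta[!duplicated(org_meta$organism_id), , drop = FALSE]
    hl <- with_stage("mimicry", build_hit_lists(kept, so, org_meta, qg))
    log$n_organisms_with_hits <- length(hl)
    mim_parts <- list()
    for (ref_name in names(refs)) {
      for (ts in test_sets) {
        res <- with_stage("mimicry",
                          mimicry_ora(ts, refs[[ref_name]], hl, cfg$filter))
        if (nrow(res)) res$reference <- ref_name
        mim_parts[[length(mim_parts) + 1L]] <- res
      }
    }
    mimicry <- sort_bundle_table(do.call(rbind, mim_parts))
  }

  # ---- significance matrices --------------------------------------------
  matrices <- list(features = export_matrix(wmw))
  if (!is.null(ora)) {
    for (ns in sort(unique(ora$namespace)))
      matrices[[ns]] <- export_matrix(ora[ora$namespace == ns, , drop = FALSE])
  }
  if (!is.null(universal)) matrices$universal <- export_matrix(universal)
  if (!is.null(mimicry)) matrices$mimicry <- export_matrix(mimicry)

  bundle <- structure(list(wmw = wmw, ora = ora, universal = universal,
                           mimicry = mimicry, matrices = matrices,
                           sets = test_sets, references = refs, log = log),
                      class = "enrichment_bundle")
  if (!is.null(cfg$out_dir))
    with_stage("write_bundle", write_bundle(bundle, cfg$out_dir))
  bundle
}

sort_bundle_table <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(df)
  ref <- if ("reference" %in% names(df)) df$reference else ""
  ord <- order(df$set_name, ref, df$namespace, df$p_adjusted, df$category_id)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ora_results", "data.frame")
  df
}

#' Export a significance matrix from enrichment results
#'
#' Dense categories-by-sets matrix of `-log10(p_adjusted)` for results that
#' pass the filters and 0 otherwise; with two reference sets the columns
#' for each test set appear side by side (`set|PCG`, `set|PCGLE`). Row
#' order is descending maximum significance, then lexical; duplicate
#' (set, reference, category) combinations are an error.
#'
#' @param results Data frame from one analysis block with columns
#'   `set_name`, `p_adjusted`, `passes_filters`, a `category_id` or
#'   `feature_id` column, and optionally `reference`.
#' @param sets Optional explicit column (set) order.
#' @param categories Optional explicit row (category) order.
#' @return Numeric matrix, categories x set/reference columns.
#' @export
export_matrix <- function(results, sets = NULL, categories = NULL) {
  if (is.null(results) || nrow(results) == 0L)
    return(matrix(numeric(), nrow = 0, ncol = 0))
  cat_col <- if ("category_id" %in% names(results)) "category_id" else "feature_id"
  has_ref <- "reference" %in% names(results)
  col_key <- if (has_ref)
    paste(results$set_name, results$reference, sep = "|") else results$set_name
  if (anyDuplicated(paste(col_key, results[[cat_col]], sep = "\r")))
    stop("duplicate (set, category) pairs in matrix export")
  if (is.null(sets)) {
    if (has_ref) {
      combos <- unique(data.frame(s = results$set_name, r = results$reference,
                                  stringsAsFactors = FALSE))
      combos <- combos[order(combos$s, combos$r), , drop = FALSE]
      sets <- paste(combos$s, combos$r, sep = "|")
    } else sets <- sort(unique(col_key))
  }
  value <- ifelse(results$passes_filters,
                  -log10(pmax(results$p_adjusted, 1e-300)), 0)
  cats <- sort(unique(results[[cat_col]]))
  mat <- matrix(0, nrow = length(cats), ncol = length(sets),
                dimnames = list(cats, sets))
  mat[cbind(match(results[[cat_col]], cats), match(col_key, sets))] <- value
  if (is.null(categories)) {
    ord <- order(-apply(mat, 1, max), rownames(mat))
    mat <- mat[ord, , drop = FALSE]
  } else {
    mat <- mat[categories, , drop = FALSE]
  }
  mat
}

#' Write a significance matrix as TSV
#' @param mat Matrix from [export_matrix].
#' @param path Output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(category_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Write all bundle tables and matrices; on error remove everything written.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  tryCatch({
    p <- file.path(out_dir, "wmw_results.tsv")
    utils::write.table(bundle$wmw, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, p)
    for (tab in c("ora", "universal", "mimicry")) {
      if (is.null(bundle[[tab]])) next
      p <- file.path(out_dir, sprintf("%s_results.tsv", tab))
      utils::write.table(bundle[[tab]], p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, p)
    }
    for (nm in names(bundle$matrices)) {
      p <- file.path(out_dir, sprintf("matrix_%s.tsv", nm))
      write_matrix_tsv(bundle$matrices[[nm]], p)
      written <- c(written, p)
    }
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  invisible(out_dir)
}

#' @export
print.enrichment_bundle <- function(x, ...) {
  cat("<enrichment_bundle>\n")
  cat(sprintf("  %d test sets vs %s\n", length(x$sets),
              paste(names(x$references), collapse = " and ")))
  cat(sprintf("  feature rank tests: %d (%d significant)\n",
              nrow(x$wmw), sum(x$wmw$passes_filters)))
  for (tab in c("ora", "universal", "mimicry")) {
    if (is.null(x[[tab]])) next
    cat(sprintf("  %s tests: %d (%d passing filters)\n", tab,
                nrow(x[[tab]]), sum(x[[tab]]$passes_filters)))
  }
  invisible(x)
}
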