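# Molecular mimicry: BLAST tabular hits of human proteins against other
# species are filtered on score and E-value, grouped into per-organism hit
# lists of "similar" human genes, and each organism is tested for
# over-representation of the antigen sets among its similar genes.

BLAST_COLS <- c("query_id", "subject_id", "percent_identity",
                "alignment_length", "mismatches", "gap_opens",
                "q_start", "q_end", "s_start", "s_end", "evalue", "bit_score")

#' Parse a 12-column BLAST tabular file
#'
#' Standard outfmt-6 dialect: tab-separated, 12 columns, `#` comment lines
#' allowed, scientific-notation E-values accepted.
#'
#' @param path Path to the tabular file.
#' @return Data frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bit_score`.
#' @export
parse_blast_tabular <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  data_idx <- which(keep)
  if (length(data_idx) == 0L)
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 12)), BLAST_COLS))
  parts <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    stop(sprintf("BLAST tabular line %d: expected 12 columns, got %d",
                 data_idx[bad], nf[bad]))
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  df <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                   percent_identity = as.numeric(m[, 3]),
                   alignment_length = as.integer(m[, 4]),
                   mismatches = as.integer(m[, 5]),
                   gap_opens = as.integer(m[, 6]),
                   q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
                   s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
                   evalue = as.numeric(m[, 11]),
                   bit_score = as.numeric(m[, 12]),
                   stringsAsFactors = FALSE)
  if (any(df$evalue < 0) || any(df$alignment_length < 1))
    stop("BLAST tabular: negative E-value or non-positive alignment length")
  df
}

#' Filter BLAST hits on similarity score and E-value
#'
#' Keeps hits with a similarity score of at least `min_score` and an
#' E-value of at most `max_evalue` (both thresholds inclusive). The
#' similarity score is the bit score (column 12) by default; set
#' `score_column` to use another column.
#'
#' @param hits Data frame from [parse_blast_tabular].
#' @param min_score Minimum score, default 100.
#' @param max_evalue Maximum E-value, default 0.001.
#' @param score_column Column holding the similarity score.
#' @return The filtered hit data frame.
#' @export
filter_hits <- function(hits, min_score = 100, max_evalue = 0.001,
                        score_column = "bit_score") {
  if (!score_column %in% names(hits))
    stop("score column '", score_column, "' not present")
  hits[hits[[score_column]] >= min_score & hits$evalue <= max_evalue, ,
       drop = FALSE]
}

#' Group filtered hits into per-organism lists of similar human genes
#'
#' A human gene joins an organism's hit list when at least one of its
#' filtered BLAST hits falls on a subject protein of that organism. Hits to
#' organisms without a complete, published genome are dropped, as are hits
#' whose subject or query cannot be mapped (with a counted warning).
#' Organisms with no surviving hits are omitted.
#'
#' @param hits Filtered BLAST hit data frame.
#' @param subject_organism Data frame `subject_id`, `organism_id`.
#' @param organisms Organism metadata data frame with `organism_id`,
#'   `kingdom`, `complete`.
#' @param query_gene Data frame `query_id`, `gene_id`.
#' @return Named list (by organism id, sorted) of objects of class
#'   `organism_hits`: `organism_id`, `kingdom`, `similar_genes`.
#' @export
build_hit_lists <- function(hits, subject_organism, organisms, query_gene) {
  if (nrow(subject_organism) == 0L || nrow(query_gene) == 0L)
    stop("subject-organism and query-gene mappings must be non-empty")
  org <- subject_organism$organism_id[match(hits$subject_id,
                                            subject_organism$subject_id)]
  gene <- query_gene$gene_id[match(hits$query_id, query_gene$query_id)]
  unmapped <- is.na(org) | is.na(gene)
  if (any(unmapped))
    warning(sprintf("%d hit(s) dropped: subject or query without a mapping",
                    sum(unmapped)))
  org <- org[!unmapped]; gene <- gene[!unmapped]
  meta_idx <- match(org, organisms$organism_id)
  known <- !is.na(meta_idx)
  if (any(!known))
    warning(sprintf("%d hit(s) dropped: organism absent from metadata",
                    sum(!known)))
  complete <- known & as.logical(organisms$complete[meta_idx]) %in% TRUE
  org <- org[complete]; gene <- gene[complete]
  if (length(org) == 0L) return(list())
  by_org <- split(gene, org)
  out <- lapply(sort(names(by_org)), function(o) {
    structure(list(organism_id = o,
                   kingdom = organisms$kingdom[match(o, organisms$organism_id)],
                   similar_genes = sort(unique(by_org[[o]]))),
              class = "organism_hits")
  })
  stats::setNames(out, sort(names(by_org)))
}

#' @export
print.organism_hits <- function(x, ...) {
  cat(sprintf("<organism_hits> %s (%s): %d similar human genes\n",
              x$organism_id, x$kingdom, length(x$similar_genes)))
  invisible(x)
}

#' Per-organism mimicry over-representation analysis
#'
#' One over-representation test per organism (category = membership in the
#' organism's similar-gene list, full test-plus-reference population), with
#' one Benjamini-Hochberg family spanning all organisms for the test set,
#' and the reporting filters applied.
#'
#' @param test,reference Disjoint [gene_set]s.
#' @param hit_lists Named list from [build_hit_lists].
#' @param cfg A [filter_config].
#' @return An `ora_results` data frame, one row per organism.
#' @export
mimicry_ora <- function(test, reference, hit_lists, cfg = filter_config()) {
  category_sets <- lapply(hit_lists, `[[`, "similar_genes")
  ora_gene_sets(test, reference, category_sets, namespace = "mimicry",
                cfg = cfg)
}
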