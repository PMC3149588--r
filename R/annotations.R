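# Binary annotation catalogs: a namespace (GO-like, pathway-like,
# domain-like, location-like, motif) mapping categories to gene sets.

#' Create an annotation catalog
#'
#' @param namespace Namespace label, e.g. `"go"`, `"kegg"`, `"domain"`.
#' @param categories Named list; each element is a character vector of
#'   annotated gene identifiers (duplicates collapsed).
#' @return An object of class `annotation_catalog`.
#' @export
annotation_catalog <- function(namespace, categories = list()) {
  if (!is.character(namespace) || length(namespace) != 1L || !nzchar(namespace))
    stop("namespace must be a single non-empty string")
  if (length(categories)) {
    if (is.null(names(categories)) || any(!nzchar(names(categories))))
      stop("categories must be a named list")
    if (anyDuplicated(names(categories)))
      stop("duplicate category ids in namespace '", namespace, "'")
    categories <- lapply(categories, function(m) unique(as.character(m)))
  }
  structure(list(namespace = namespace, categories = categories),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  sizes <- lengths(x$categories)
  cat(sprintf("<annotation_catalog> namespace '%s': %d categories, %d annotated genes\n",
              x$namespace, length(x$categories),
              length(unique(unlist(x$categories, use.names = FALSE)))))
  if (length(sizes))
    cat(sprintf("  category sizes: min %d, median %g, max %d\n",
                min(sizes), stats::median(sizes), max(sizes)))
  invisible(x)
}

#' Read an annotation catalog from a two-column TSV
#'
#' Expects a header `gene_id<TAB>category_id`, one association per row.
#'
#' @param path Path to the annotation TSV.
#' @param namespace Namespace label for the catalog.
#' @return An [annotation_catalog].
#' @export
read_annotation_tsv <- function(path, namespace) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("gene_id", "category_id") %in% names(df)))
    stop("annotation TSV must have columns gene_id and category_id")
  if (nrow(df) == 0L) {
    warning("empty annotation TSV: ", path)
    return(annotation_catalog(namespace))
  }
  cats <- split(df$gene_id, df$category_id)
  annotation_catalog(namespace, cats[sort(names(cats))])
}

#' Write an annotation catalog to a two-column TSV
#' @param catalog An [annotation_catalog].
#' @param path Output path.
#' @export
write_annotation_tsv <- function(catalog, path) {
  cat_ids <- sort(names(catalog$categories))
  df <- data.frame(
    gene_id = unlist(lapply(cat_ids, function(cid) sort(catalog$categories[[cid]])),
                     use.names = FALSE),
    category_id = rep(cat_ids, vapply(catalog$categories[cat_ids], length, 1L)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
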