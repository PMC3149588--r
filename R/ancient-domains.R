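# "Ancient" protein domains: domains present in at least a given fraction
# of the completely sequenced species of a kingdom define UNIVERSAL gene
# sets, which antigen sets are then tested against by over-representation.

KINGDOMS <- c("BACTERIA", "ARCHAEA", "EUKARYOTA")

#' Bundle organism metadata with per-organism domain annotations
#'
#' @param meta Data frame with columns `organism_id`, `kingdom` (one of
#'   BACTERIA/ARCHAEA/EUKARYOTA), `complete` (logical: completely sequenced
#'   and published), `scheme` (domain classification scheme, e.g. CATH or
#'   PFAM).
#' @param domains Data frame with columns `organism_id`, `domain_id` and
#'   optionally `scheme` (needed when one organism is annotated under
#'   several schemes), one row per annotated domain occurrence (duplicates
#'   collapse).
#' @return An object of class `organism_domains`.
#' @export
organism_domains <- function(meta, domains) {
  need <- c("organism_id", "kingdom", "complete", "scheme")
  if (!all(need %in% names(meta)))
    stop("organism metadata needs columns: ", paste(need, collapse = ", "))
  if (!all(c("organism_id", "domain_id") %in% names(domains)))
    stop("organism-domain table needs columns organism_id and domain_id")
  if (anyDuplicated(meta[c("organism_id", "scheme")]))
    stop("duplicate (organism_id, scheme) rows in metadata")
  bad <- setdiff(unique(meta$kingdom), KINGDOMS)
  if (length(bad))
    stop("unknown kingdom(s): ", paste(bad, collapse = ", "))
  meta$complete <- as.logical(meta$complete)
  cols <- intersect(c("organism_id", "domain_id", "scheme"), names(domains))
  domains <- unique(domains[cols])
  structure(list(meta = meta, domains = domains), class = "organism_domains")
}

# Domain rows matching a metadata slice, honouring the optional scheme column.
domain_rows_for <- function(od, meta) {
  d <- od$domains
  if ("scheme" %in% names(d)) {
    keys <- paste(meta$organism_id, meta$scheme, sep = "\r")
    d[paste(d$organism_id, d$scheme, sep = "\r") %in% keys, , drop = FALSE]
  } else {
    d[d$organism_id %in% meta$organism_id, , drop = FALSE]
  }
}

#' @export
print.organism_domains <- function(x, ...) {
  cat(sprintf("<organism_domains> %d organisms (%d complete), %d domain annotations\n",
              nrow(x$meta), sum(x$meta$complete), nrow(x$domains)))
  print(table(kingdom = x$meta$kingdom, scheme = x$meta$scheme))
  invisible(x)
}

#' Read organism metadata and domain tables from TSV
#'
#' Metadata TSV: `organism_id  kingdom  complete(0/1)  scheme`; domain TSV:
#' `organism_id  domain_id`.
#'
#' @param meta_path,domains_path Paths to the two TSVs.
#' @return An [organism_domains] object.
#' @export
read_organism_tables <- function(meta_path, domains_path) {
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  meta$organism_id <- as.character(meta$organism_id)
  meta$complete <- meta$complete %in% c(1, "1", TRUE, "TRUE")
  dom <- utils::read.delim(domains_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  organism_domains(meta, dom)
}

#' Retain well-annotated, completely sequenced organisms
#'
#' Keeps organisms that are completely sequenced and annotated with at least
#' `min_domains` distinct domains (inclusive threshold).
#'
#' @param od An [organism_domains] object.
#' @param min_domains Minimum distinct domain count, default 150.
#' @return A filtered [organism_domains] object.
#' @export
filter_organisms <- function(od, min_domains = 150L) {
  stopifnot(inherits(od, "organism_domains"))
  if (min_domains < 1) stop("min_domains must be >= 1")
  d <- od$domains
  if ("scheme" %in% names(d)) {
    counts <- table(paste(d$organism_id, d$scheme, sep = "\r"))
    key <- paste(od$meta$organism_id, od$meta$scheme, sep = "\r")
  } else {
    counts <- table(d$organism_id)
    key <- od$meta$organism_id
  }
  n_dom <- as.integer(counts[key])
  n_dom[is.na(n_dom)] <- 0L
  keep <- od$meta$complete & n_dom >= min_domains
  meta <- od$meta[keep, , drop = FALSE]
  organism_domains(meta, domain_rows_for(od, meta))
}

#' Domains universal to a kingdom
#'
#' A domain is universal ("ancient") for a kingdom when it occurs in at
#' least `fraction` of that kingdom's retained species (inclusive).
#' Organisms should already have passed [filter_organisms].
#'
#' @param od An [organism_domains] object (typically filtered).
#' @param kingdom One of `"BACTERIA"`, `"ARCHAEA"`, `"EUKARYOTA"`.
#' @param fraction Minimum species fraction, default 0.70.
#' @param scheme Optional scheme restriction (e.g. `"CATH"`).
#' @return Sorted character vector of universal domain ids.
#' @export
universal_domains <- function(od, kingdom, fraction = 0.70, scheme = NULL) {
  stopifnot(inherits(od, "organism_domains"))
  kingdom <- match.arg(kingdom, KINGDOMS)
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  meta <- od$meta[od$meta$kingdom == kingdom, , drop = FALSE]
  if (!is.null(scheme)) meta <- meta[meta$scheme == scheme, , drop = FALSE]
  if (nrow(meta) == 0L)
    stop("no organisms of kingdom ", kingdom,
         if (!is.null(scheme)) paste0(" with scheme ", scheme) else "")
  dom <- unique(domain_rows_for(od, meta)[c("organism_id", "domain_id")])
  counts <- table(dom$domain_id)
  sort(names(counts)[as.integer(counts) / nrow(meta) >= fraction])
}

#' Map universal domains to their genes
#'
#' Builds one UNIVERSAL gene set: every gene carrying at least one of the
#' given domains, named `UNIVERSAL_<KINGDOM>_<SCHEME>`.
#'
#' @param domains Character vector of domain ids.
#' @param domain_gene Data frame with columns `domain_id`, `gene_id`.
#' @param kingdom,scheme Labels for the set name.
#' @return An object of class `universal_set` with elements `kingdom`,
#'   `scheme`, `domains`, `gene_set`.
#' @export
map_domains_to_genes <- function(domains, domain_gene, kingdom, scheme) {
  if (!all(c("domain_id", "gene_id") %in% names(domain_gene)))
    stop("domain-gene map needs columns domain_id and gene_id")
  if (nrow(domain_gene) == 0L) stop("domain-gene map is empty")
  kingdom <- match.arg(kingdom, KINGDOMS)
  unmapped <- setdiff(domains, domain_gene$domain_id)
  if (length(unmapped))
    warning(sprintf("%d universal domain(s) absent from the domain-gene map, skipped",
                    length(unmapped)))
  genes <- unique(domain_gene$gene_id[domain_gene$domain_id %in% domains])
  name <- sprintf("UNIVERSAL_%s_%s", kingdom, toupper(scheme))
  if (length(genes) == 0L)
    warning("UNIVERSAL set ", name, " is empty")
  structure(list(kingdom = kingdom, scheme = toupper(scheme),
                 domains = sort(domains),
                 gene_set = gene_set(name, genes,
                                     description = "genes carrying an ancient domain")),
            class = "universal_set")
}

#' @export
print.universal_set <- function(x, ...) {
  cat(sprintf("<universal_set> %s: %d domains -> %d genes\n",
              x$gene_set$name, length(x$domains), length(x$gene_set$members)))
  invisible(x)
}

#' Build all UNIVERSAL ancient-domain gene sets
#'
#' Filters organisms, extracts per-kingdom universal domains for every
#' scheme present, and maps them to genes: three kingdoms times the number
#' of schemes (six sets when CATH and PFAM are both supplied; fewer, with a
#' warning, otherwise).
#'
#' @param od An [organism_domains] object (unfiltered).
#' @param domain_gene Data frame with columns `domain_id`, `gene_id`.
#' @param min_domains Organism retention threshold, default 150.
#' @param fraction Species-fraction threshold, default 0.70.
#' @return Named list of `universal_set` objects.
#' @export
build_universal_sets <- function(od, domain_gene, min_domains = 150L,
                                 fraction = 0.70) {
  kept <- filter_organisms(od, min_domains)
  schemes <- sort(unique(kept$meta$scheme))
  if (length(schemes) < 2L)
    warning("fewer than two domain schemes present; building ",
            3L * length(schemes), " UNIVERSAL sets instead of 6")
  out <- list()
  for (scheme in schemes) {
    for (kingdom in KINGDOMS) {
      meta_k <- kept$meta[kept$meta$kingdom == kingdom &
                            kept$meta$scheme == scheme, , drop = FALSE]
      if (nrow(meta_k) == 0L) {
        warning("no retained organisms for ", kingdom, "/", scheme,
                "; UNIVERSAL set skipped")
        next
      }
      doms <- universal_domains(kept, kingdom, fraction, scheme = scheme)
      us <- map_domains_to_genes(doms, domain_gene, kingdom, scheme)
      out[[us$gene_set$name]] <- us
    }
  }
  out
}

#' Over-representation of one UNIVERSAL set in a test set
#'
#' Ancient-domain membership is defined for every gene, so the population is
#' the full test-plus-reference union (no namespace restriction).
#'
#' @param test,reference Disjoint [gene_set]s.
#' @param universal A `universal_set`.
#' @return One-row `ora_results` data frame (p_adjusted = p_raw; adjust
#'   across a family of sets with [ora_gene_sets] when testing several).
#' @export
universal_ora <- function(test, reference, universal) {
  stopifnot(inherits(universal, "universal_set"))
  res <- ora_test(test, reference, universal$gene_set$members,
                  union(test$members, reference$members),
                  category_id = universal$gene_set$name,
                  namespace = "universal")
  res$p_adjusted <- res$p_raw
  sort_ora_results(res)
}

#' Over-representation across a family of gene-set categories
#'
#' Generic driver used for UNIVERSAL sets (one family = all six sets for a
#' test set) and mimicry organisms (one family = all organisms for a test
#' set): categories are gene sets defined on the full population, p-values
#' are BH-adjusted within the family, and the reporting filters use the
#' test-set size as prevalence denominator.
#'
#' @param test,reference Disjoint [gene_set]s.
#' @param category_sets Named list of character vectors (gene ids).
#' @param namespace Namespace label.
#' @param cfg A [filter_config].
#' @return An `ora_results` data frame, one row per category.
#' @export
ora_gene_sets <- function(test, reference, category_sets,
                          namespace, cfg = filter_config()) {
  if (length(category_sets) == 0L) return(empty_ora_results())
  pop <- union(test$members, reference$members)
  rows <- lapply(names(category_sets), function(cid) {
    ora_test(test, reference, category_sets[[cid]], pop,
             category_id = cid, namespace = namespace)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- bh_adjust(res$p_raw)
  res <- apply_filters(res, cfg, res$n)
  sort_ora_results(res)
}
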