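# Gene sets, the gene universe, and construction of the reference sets
# (all protein-coding genes minus antigens; its long-exon restriction).

#' Create a gene set
#'
#' A gene set is a named collection of unique gene identifiers. Identifiers
#' are opaque strings; no symbol or Entrez resolution is attempted.
#'
#' @param name Non-empty set name.
#' @param members Character vector of gene identifiers; duplicates and empty
#'   strings are dropped.
#' @param description Optional free-text description (kept for GMT round trips).
#' @return An object of class `gene_set` with elements `name` and `members`.
#' @export
gene_set <- function(name, members = character(), description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("gene set 'name' must be a single non-empty string")
  members <- as.character(members)
  members <- unique(members[nzchar(members)])
  structure(list(name = name, members = members),
            description = description, class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$members)))
  if (length(x$members)) {
    shown <- utils::head(x$members, 6L)
    cat("  ", paste(shown, collapse = ", "),
        if (length(x$members) > 6L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Read gene sets from a GMT file
#'
#' Broad-dialect GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a line are collapsed with a warning; set order is preserved.
#'
#' @param path Path to a GMT file.
#' @return List of [gene_set] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(list())
  }
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d in %s: expected >= 3 tab-separated fields, got %d",
                   i, path, length(fields)))
    members <- fields[-(1:2)]
    if (anyDuplicated(members))
      warning(sprintf("GMT line %d (set '%s'): duplicate members collapsed",
                      i, fields[[1]]))
    out[[i]] <- gene_set(fields[[1]], members, description = fields[[2]])
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets List of [gene_set] objects.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    desc <- attr(s, "description")
    if (is.null(desc) || !nzchar(desc)) desc <- s$name
    paste(c(s$name, desc, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Create a gene universe
#'
#' The universe holds every gene the population statistics are drawn from
#' (in the motivating application, all human protein-coding genes) together
#' with the per-gene mean exon length in nucleotides.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param mean_exon_length Non-negative numeric vector, nucleotides.
#' @return A data frame of class `gene_universe`.
#' @export
gene_universe <- function(gene_id, mean_exon_length) {
  gene_id <- as.character(gene_id)
  mean_exon_length <- as.numeric(mean_exon_length)
  if (length(gene_id) < 1L) stop("universe must contain at least one gene")
  if (length(gene_id) != length(mean_exon_length))
    stop("gene_id and mean_exon_length lengths differ")
  if (any(!nzchar(gene_id))) stop("empty gene identifiers in universe")
  if (anyDuplicated(gene_id))
    stop("duplicate gene identifiers in universe: ",
         paste(utils::head(unique(gene_id[duplicated(gene_id)]), 3), collapse = ", "))
  if (any(is.na(mean_exon_length)) || any(mean_exon_length < 0))
    stop("mean_exon_length must be non-negative and non-missing")
  structure(data.frame(gene_id = gene_id,
                       mean_exon_length = mean_exon_length,
                       stringsAsFactors = FALSE),
            class = c("gene_universe", "data.frame"))
}

#' Read a gene universe from TSV
#'
#' Expects a header `gene_id<TAB>mean_exon_length`.
#'
#' @param path Path to the universe TSV.
#' @return A `gene_universe` data frame.
#' @export
read_universe <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric"))
  if (!identical(names(df)[1:2], c("gene_id", "mean_exon_length")))
    stop("universe TSV must have header 'gene_id<TAB>mean_exon_length', got: ",
         paste(names(df), collapse = ", "))
  gene_universe(df$gene_id, df$mean_exon_length)
}

#' Write a gene universe to TSV
#' @param universe A `gene_universe`.
#' @param path Output path.
#' @export
write_universe <- function(universe, path) {
  utils::write.table(as.data.frame(universe), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Union of antigen sets
#'
#' Builds the combined antigen set (named "ALL") as the union of all input
#' sets, used to find patterns common to every antigen class.
#'
#' @param sets Non-empty list of [gene_set] objects.
#' @param name Name for the union set.
#' @return A [gene_set].
#' @export
build_all_set <- function(sets, name = "ALL") {
  if (length(sets) == 0L) stop("build_all_set: need at least one input set")
  members <- unique(unlist(lapply(sets, `[[`, "members"), use.names = FALSE))
  gene_set(name, members, description = "union of all antigen sets")
}

#' Build the protein-coding-gene reference set
#'
#' The primary reference set is every gene of the universe that is not an
#' antigen: universe minus the combined antigen set. Antigen identifiers
#' absent from the universe are ignored with a warning (antigen lists often
#' predate the gene build supplying the universe).
#'
#' @param universe A `gene_universe`.
#' @param all_set The combined antigen [gene_set].
#' @param name Name for the reference set.
#' @return A [gene_set], disjoint from `all_set`.
#' @export
build_pcg_reference <- function(universe, all_set, name = "ProteinCodingGenes") {
  missing <- setdiff(all_set$members, universe$gene_id)
  if (length(missing))
    warning(sprintf("%d antigen genes absent from universe are ignored for the reference",
                    length(missing)))
  members <- setdiff(universe$gene_id, all_set$members)
  if (length(members) == 0L)
    warning("reference set is empty: every universe gene is an antigen")
  gene_set(name, members,
           description = "all universe genes excluding antigens")
}

#' Restrict a reference set to long-exon genes
#'
#' Keeps reference genes whose mean exon length is strictly greater than the
#' threshold (default 3100 nt). This length-matched reference removes the
#' exon-length bias when testing length-dependent features.
#'
#' @param pcg The protein-coding-gene reference [gene_set].
#' @param universe A `gene_universe` supplying exon lengths; every member of
#'   `pcg` must be present.
#' @param threshold Strict lower bound on mean exon length, nucleotides.
#' @param name Name for the restricted reference set.
#' @return A [gene_set], a subset of `pcg`.
#' @export
build_long_exon_reference <- function(pcg, universe, threshold = 3100,
                                      name = "ProteinCodingGenesLongerExons") {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number")
  missing <- setdiff(pcg$members, universe$gene_id)
  if (length(missing))
    stop("genes in reference set missing from universe: ",
         paste(utils::head(missing, 3), collapse = ", "))
  len <- universe$mean_exon_length[match(pcg$members, universe$gene_id)]
  gene_set(name, pcg$members[len > threshold],
           description = sprintf("reference genes with mean exon length > %g nt",
                                 threshold))
}
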