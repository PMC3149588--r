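# Sequence-derived binary annotations. The ELR (Glu-Leu-Arg) tripeptide of
# CXC chemokines is scanned exactly in-repo; predicted features such as
# Granzyme B cleavage sites or coiled-coils enter as precomputed annotation
# TSVs in the same "motif" namespace.

AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWY"

#' Scan a protein sequence for an exact short motif
#'
#' Reports all (possibly overlapping) exact occurrences of an amino-acid
#' motif, 1-based, ascending. Matching is case-insensitive; the ambiguity
#' code `X` is allowed in the sequence but never matches.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet plus `X`.
#' @param motif Amino-acid motif, length >= 1, default `"ELR"`.
#' @return Data frame with columns `position`, `matched`, `motif_id`
#'   (zero rows if no match).
#' @export
scan_tripeptide <- function(sequence, motif = "ELR") {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single string")
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) < 1L)
    stop("motif must be a non-empty string")
  seq_up <- toupper(sequence)
  motif_up <- toupper(motif)
  allowed <- c(strsplit(AA_ALPHABET, "")[[1]], "X")
  sv <- strsplit(seq_up, "")[[1]]
  bad <- which(!(sv %in% allowed))
  if (length(bad))
    stop(sprintf("illegal character '%s' at position %d (not an amino acid or X)",
                 sv[bad[1]], bad[1]))
  mv <- strsplit(motif_up, "")[[1]]
  if (any(!(mv %in% strsplit(AA_ALPHABET, "")[[1]])))
    stop("motif must use the 20-letter amino-acid alphabet")
  n <- length(sv); m <- length(mv)
  if (n < m)
    return(data.frame(position = integer(), matched = character(),
                      motif_id = character(), stringsAsFactors = FALSE))
  hit <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) hit <- hit & (sv[seq.int(j, n - m + j)] == mv[j])
  pos <- which(hit)
  data.frame(position = pos,
             matched = rep(motif_up, length(pos)),
             motif_id = rep(motif_up, length(pos)),
             stringsAsFactors = FALSE)
}

#' Build a presence/absence motif catalog from protein sequences
#'
#' Scans every sequence and collects the genes with at least one motif
#' occurrence into a binary category (presence, not count, defines the
#' category, matching the over-representation framing).
#'
#' @param sequences Named character vector of protein sequences, or a
#'   `Biostrings::AAStringSet`; names are gene identifiers and must be unique.
#' @param motif Motif to scan for, default `"ELR"`.
#' @return An [annotation_catalog] in namespace `"motif"` with one category.
#' @export
build_motif_catalog <- function(sequences, motif = "ELR") {
  if (methods::is(sequences, "AAStringSet"))
    sequences <- as.character(sequences)
  if (length(sequences) == 0L) {
    warning("no sequences supplied; empty motif catalog")
    return(annotation_catalog("motif"))
  }
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("sequences must be named by gene id")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  has_hit <- vapply(sequences,
                    function(s) nrow(scan_tripeptide(s, motif)) > 0L,
                    logical(1))
  cats <- list()
  cats[[toupper(motif)]] <- ids[has_hit]
  annotation_catalog("motif", cats)
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet` returning a named
#' character vector keyed by the first whitespace-delimited token of each
#' FASTA header.
#'
#' @param path Path to a FASTA file (wrapped or single-line).
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write protein sequences to a FASTA file
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_protein_fasta <- function(sequences, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    writeLines(paste0(">", id), con)
    s <- sequences[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
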