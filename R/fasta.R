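#' Read DNA sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a sequence-record table.
#' The full header line (without the leading `>`) is retained as the record
#' id; residues are folded to upper case. IUPAC ambiguity codes are accepted
#' and dealt with later, at k-mer extraction time.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with character columns `id` and `residues`, one row
#'   per FASTA entry (zero rows for an empty file).
#' @seealso [read_lineage()] to attach taxonomic labels, [write_fasta()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  .check_fasta_structure(path)
  set <- Biostrings::readDNAStringSet(path)
  records <- data.frame(
    id = names(set),
    residues = toupper(as.character(set)),
    stringsAsFactors = FALSE
  )
  empty <- nchar(records$residues) == 0L
  if (any(empty)) {
    stop("FASTA record with no residues: ", records$id[which(empty)[1]])
  }
  rownames(records) <- NULL
  records
}

# Light structural scan so malformed files fail with the offending line
# number rather than a low-level parser error.
.check_fasta_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(invisible(TRUE))
  }
  if (!startsWith(lines[nonblank[1]], ">")) {
    stop("malformed FASTA at line ", nonblank[1],
         ": sequence data before any '>' header")
  }
  headers <- nonblank[startsWith(lines[nonblank], ">")]
  bare <- headers[!nzchar(sub("^>\\s*", "", lines[headers]))]
  if (length(bare) > 0L) {
    stop("malformed FASTA at line ", bare[1], ": record with no header text")
  }
  invisible(TRUE)
}

#' Write sequence records to a FASTA file
#'
#' @param records A sequence-record `data.frame` with columns `id` and
#'   `residues` (as returned by [read_fasta()] or [generate_taxonomy()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  set <- Biostrings::DNAStringSet(records$residues)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a tab-delimited lineage mapping
#'
#' The mapping file has two tab-separated columns:
#' `sequence_id<TAB>phylum;class;order;family`. Ranks are separated by
#' semicolons; an empty field means the sequence is unclassified at that
#' rank (stored as `NA`).
#'
#' @param path Path to the mapping file.
#' @return A `data.frame` with columns `id`, `phylum`, `class`, `order`,
#'   `family`.
#' @export
read_lineage <- function(path) {
  if (!file.exists(path)) {
    stop("lineage file not found: ", path)
  }
  raw <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character", quote = "",
                    blank.lines.skip = TRUE)
  if (ncol(raw) != 2L) {
    stop("lineage file must have exactly two tab-separated columns, found ",
         ncol(raw))
  }
  parts <- strsplit(raw[[2]], ";", fixed = TRUE)
  lin <- vapply(seq_along(TAXONOMIC_RANKS), function(i) {
    vapply(parts, function(p) if (length(p) >= i) p[i] else "", character(1))
  }, character(nrow(raw)))
  lin <- matrix(lin, nrow = nrow(raw))
  lin[!nzchar(trimws(lin))] <- NA_character_
  out <- data.frame(id = raw[[1]], stringsAsFactors = FALSE)
  for (i in seq_along(TAXONOMIC_RANKS)) out[[TAXONOMIC_RANKS[i]]] <- lin[, i]
  out
}

#' Write a lineage mapping file
#'
#' @param records A `data.frame` with columns `id` and the four rank columns
#'   `phylum`, `class`, `order`, `family` (`NA` = unclassified).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lineage <- function(records, path) {
  stopifnot(all(c("id", TAXONOMIC_RANKS) %in% names(records)))
  lin <- as.matrix(records[TAXONOMIC_RANKS])
  lin[is.na(lin)] <- ""
  lineage <- apply(lin, 1L, paste, collapse = ";")
  write.table(data.frame(records$id, lineage),
              file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach lineage labels to sequence records
#'
#' Joins a lineage table (from [read_lineage()]) onto sequence records by
#' `id`. Records without a lineage entry get `NA` at every rank.
#'
#' @param records Sequence records (`id`, `residues`).
#' @param lineage Lineage table as returned by [read_lineage()].
#' @return `records` with the four rank columns appended.
#' @export
attach_lineage <- function(records, lineage) {
  idx <- match(records$id, lineage$id)
  for (rank in TAXONOMIC_RANKS) records[[rank]] <- lineage[[rank]][idx]
  records
}
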