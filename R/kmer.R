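#' Decompose a DNA string into overlapping k-mers
#'
#' Slides a window of fixed length `k` along the sequence and returns every
#' window in left-to-right order. Windows containing any character outside
#' `A`, `C`, `G`, `T` (i.e. IUPAC ambiguity codes such as `N`) are skipped
#' entirely: the alphabet of the bag-of-words model is strictly ACGT and
#' substituting bases would invent data. Downstream the model ignores window
#' positions (bag-of-words), but the order is preserved here so callers can
#' relate tokens to coordinates.
#'
#' @param residues A single DNA string (case-insensitive).
#' @param k Window size (positive integer, default 8).
#' @return Character vector of k-mers; empty when `k > nchar(residues)`.
#' @examples
#' extract_kmers("ACGTAC", k = 2) # 5 windows
#' extract_kmers("ACNGT", k = 2)  # windows touching N are skipped
#' @export
extract_kmers <- function(residues, k = 8L) {
  stopifnot(length(residues) == 1L, is.character(residues))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  residues <- toupper(residues)
  n <- nchar(residues)
  if (k > n) return(character(0))
  starts <- seq_len(n - k + 1L)
  windows <- substring(residues, starts, starts + k - 1L)
  if (grepl("[^ACGT]", residues)) {
    # skip every window overlapping an ambiguous position
    bad <- gregexpr("[^ACGT]", residues)[[1]]
    drop <- unique(unlist(lapply(bad, function(b) {
      max(1L, b - k + 1L):min(b, n - k + 1L)
    })))
    drop <- drop[drop >= 1L & drop <= length(windows)]
    if (length(drop)) windows <- windows[-drop]
  }
  windows
}

# Tokenize many records at once; returns a list of character-token vectors
# named by record id. Shared by build_corpus() and the hierarchical trainer
# (which re-uses one tokenization across many node corpora).
tokenize_records <- function(records, k) {
  out <- lapply(records$residues, extract_kmers, k = k)
  names(out) <- records$id
  out
}

#' Build a k-mer corpus from sequence records
#'
#' Converts each record into a bag-of-words document of k-mer tokens and
#' builds (or re-uses) the vocabulary mapping k-mer strings to integer word
#' ids. With a frozen vocabulary (test-time encoding), out-of-vocabulary
#' k-mers are silently dropped from the document, because the fitted model
#' has no topic-word estimate for unseen words; documents that end up empty
#' are flagged in the `empty` field.
#'
#' @param records Sequence records (`data.frame` with `id`, `residues`).
#' @param k Window size (default 8).
#' @param vocabulary Optional frozen vocabulary (character vector of k-mers)
#'   from a fitted model; `NULL` builds the vocabulary from `records`.
#' @return A `kmer_corpus` object: list with `documents` (integer token
#'   vectors, ids into `vocabulary`), `ids`, `vocabulary`, `k`, and `empty`
#'   (logical flags for token-less documents).
#' @export
build_corpus <- function(records, k = 8L, vocabulary = NULL) {
  tokens <- tokenize_records(records, k)
  corpus_from_tokens(tokens, k = k, vocabulary = vocabulary)
}

# Core constructor working from pre-tokenized character documents.
corpus_from_tokens <- function(tokens, k, vocabulary = NULL) {
  k <- as.integer(k)
  if (is.null(vocabulary)) {
    vocabulary <- unique(unlist(tokens, use.names = FALSE))
  }
  documents <- lapply(tokens, function(tok) {
    ids <- match(tok, vocabulary)
    ids[!is.na(ids)] # OOV k-mers dropped at encoding time
  })
  empty <- lengths(documents) == 0L
  if (length(documents) > 0L && all(empty)) {
    stop("corpus construction failed: every document is empty ",
         "(no k-mers, or all k-mers out of vocabulary)")
  }
  structure(
    list(documents = documents, ids = names(tokens),
         vocabulary = vocabulary, k = k, empty = empty),
    class = "kmer_corpus"
  )
}

#' @export
print.kmer_corpus <- function(x, ...) {
  cat("k-mer corpus: ", length(x$documents), " documents, ",
      length(x$vocabulary), " words (k = ", x$k, "), ",
      sum(lengths(x$documents)), " tokens\n", sep = "")
  if (any(x$empty)) cat("  ", sum(x$empty), " empty document(s)\n", sep = "")
  invisible(x)
}

#' Extract random fragments from sequence records
#'
#' Replaces each record's residues by one contiguous fragment of length `f`
#' whose start is uniform over all admissible positions, emulating the short
#' and ultra-short reads encountered in metagenomic surveys. Record ids are
#' suffixed with `|frag<f>` to mark provenance. Uses the current RNG state;
#' call `set.seed()` for reproducibility.
#'
#' @param records Sequence records.
#' @param f Fragment length; must not exceed any record's length.
#' @return Records with fragmented residues and suffixed ids; lineage
#'   columns, when present, are carried through.
#' @export
extract_fragment <- function(records, f) {
  f <- as.integer(f)
  len <- nchar(records$residues)
  if (any(f > len)) {
    stop("fragment length ", f, " exceeds sequence length for record ",
         records$id[which(f > len)[1]])
  }
  start <- floor(runif(nrow(records)) * (len - f + 1L)) # 0-based start
  start <- pmin(start, len - f) # guard the runif == 1 edge
  out <- records
  out$residues <- substring(records$residues, start + 1L, start + f)
  out$id <- paste0(records$id, "|frag", f)
  out
}

#' Filter a labeled dataset the way curated 16S benchmarks are filtered
#'
#' Applies, in order: (1) drop records shorter than `min_len` (full-length
#' 16S genes are about 1200-1400 bp); (2) drop records unclassified
#' (missing label) at `rank`; (3) drop every record of any taxon with fewer
#' than `min_per_taxon` members at `rank`, keeping the dataset balanced
#' enough for cross-validation. A taxon with exactly `min_per_taxon` members
#' is retained.
#'
#' @param records Labeled sequence records.
#' @param min_len Minimum sequence length (default 1200).
#' @param min_per_taxon Minimum members per taxon at `rank` (default 10).
#' @param rank Rank whose labels are checked (default `"family"`).
#' @return The filtered records (possibly zero rows).
#' @export
filter_dataset <- function(records, min_len = 1200L, min_per_taxon = 10L,
                           rank = "family") {
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  if (!rank %in% names(records)) {
    stop("records carry no '", rank, "' labels")
  }
  records <- records[nchar(records$residues) >= min_len, , drop = FALSE]
  records <- records[!is.na(records[[rank]]), , drop = FALSE]
  counts <- table(records[[rank]])
  keep <- names(counts)[counts >= min_per_taxon]
  records <- records[records[[rank]] %in% keep, , drop = FALSE]
  rownames(records) <- NULL
  records
}
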