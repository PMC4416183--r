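#' Specification of a synthetic four-rank taxonomy
#'
#' Describes a synthetic bacterial-16S-like dataset: a taxonomy tree of
#' phyla, classes, orders and families whose taxa have distinct k-mer
#' composition, created by mutating a single root sequence down the tree.
#' Counts below an internal rank are given depth-first and recycled, so a
#' scalar means "the same count under every parent".
#'
#' The defaults mirror the shape of a curated 16S benchmark: 4 phyla with
#' 1/3/4/5 classes, 3/3/7/29 orders and 26/11/29/66 families respectively
#' (132 families in all), 10 sequences per family and 1400 bp sequences —
#' full-length 16S genes are about 1200–1400 bp. Default per-rank
#' substitution rates 0.12/0.04/0.035/0.035 (phylum → family splits) plus
#' 0.005 per-sequence noise make each taxon compact relative to its
#' separation — the deepest splits contribute the least divergence, as in
#' real rRNA taxonomies — so that full-length classification lands
#' near-perfect at the top ranks while 25 bp fragments degrade visibly
#' towards the family level.
#'
#' @param n_phyla Number of phyla.
#' @param classes_per_phylum Classes under each phylum (recycled).
#' @param orders_per_class Orders under each class, depth-first (recycled).
#' @param families_per_order Families under each order, depth-first
#'   (recycled).
#' @param seqs_per_family Sequences generated per family.
#' @param seq_length Sequence length in bp (default 1400).
#' @param sub_rates Per-rank substitution rates from the parent consensus,
#'   ordered phylum, class, order, family; each in `[0, 0.75]`.
#' @param seq_noise Per-sequence substitution rate applied after the family
#'   consensus (default 0.02).
#' @param indel_rate Per-position indel rate (default 0; substitutions are
#'   sufficient to create taxon-specific k-mer signatures).
#' @return A `taxonomy_spec` list.
#' @export
taxonomy_spec <- function(n_phyla = 4L,
                          classes_per_phylum = c(1L, 3L, 4L, 5L),
                          orders_per_class = c(3L,
                                               1L, 1L, 1L,
                                               2L, 2L, 2L, 1L,
                                               6L, 6L, 6L, 6L, 5L),
                          families_per_order = c(9L, 9L, 8L,
                                                 4L, 4L, 3L,
                                                 5L, 4L, 4L, 4L, 4L, 4L, 4L,
                                                 rep(3L, 8L), rep(2L, 21L)),
                          seqs_per_family = 10L,
                          seq_length = 1400L,
                          sub_rates = c(phylum = 0.12, class = 0.04,
                                        order = 0.035, family = 0.035),
                          seq_noise = 0.005,
                          indel_rate = 0) {
  stopifnot(n_phyla >= 1L, all(classes_per_phylum >= 1L),
            all(orders_per_class >= 1L), all(families_per_order >= 1L),
            seqs_per_family >= 1L, seq_length >= 1L,
            length(sub_rates) == 4L,
            all(sub_rates >= 0), all(sub_rates <= 0.75),
            seq_noise >= 0, seq_noise <= 0.75, indel_rate >= 0)
  structure(list(n_phyla = as.integer(n_phyla),
                 classes_per_phylum = as.integer(classes_per_phylum),
                 orders_per_class = as.integer(orders_per_class),
                 families_per_order = as.integer(families_per_order),
                 seqs_per_family = as.integer(seqs_per_family),
                 seq_length = as.integer(seq_length),
                 sub_rates = sub_rates, seq_noise = seq_noise,
                 indel_rate = indel_rate),
            class = "taxonomy_spec")
}

DNA_BASES <- c("A", "C", "G", "T")

# i.i.d. substitution of a base-index vector: each position mutates to a
# uniformly chosen *different* base with probability `rate`.
mutate_seq <- function(seq_idx, rate) {
  if (rate <= 0) return(seq_idx)
  hit <- which(runif(length(seq_idx)) < rate)
  if (length(hit) > 0L) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    seq_idx[hit] <- ((seq_idx[hit] - 1L + shift) %% 4L) + 1L
  }
  seq_idx
}

apply_indels <- function(seq_idx, rate) {
  if (rate <= 0) return(seq_idx)
  n <- length(seq_idx)
  del <- runif(n) < rate / 2
  ins <- which(runif(n) < rate / 2)
  out <- seq_idx[!del]
  for (pos in rev(ins[!del[ins]])) {
    at <- sum(!del[seq_len(pos)])
    out <- append(out, sample.int(4L, 1L), after = at)
  }
  out
}

#' Generate a labeled synthetic taxonomy dataset
#'
#' A random root sequence is mutated down the rank tree: each phylum
#' consensus is a mutated copy of the root, each class consensus a mutated
#' copy of its phylum consensus, and so on; finally per-sequence noise is
#' applied to the family consensus. Sequences within a taxon therefore have
#' more similar k-mer profiles than sequences from different taxa, the
#' statistical structure the classification method assumes. Deterministic
#' under `seed`.
#'
#' @param spec A [taxonomy_spec()].
#' @param seed RNG seed (default 1).
#' @return Labeled sequence records: `data.frame` with `id`, `residues`,
#'   `phylum`, `class`, `order`, `family`.
#' @export
generate_taxonomy <- function(spec = taxonomy_spec(), seed = 1L) {
  stopifnot(inherits(spec, "taxonomy_spec"))
  set.seed(seed)
  root <- sample.int(4L, spec$seq_length, replace = TRUE)
  cpp <- rep_len(spec$classes_per_phylum, spec$n_phyla)
  n_classes <- sum(cpp)
  opc <- rep_len(spec$orders_per_class, n_classes)
  n_orders <- sum(opc)
  fpo <- rep_len(spec$families_per_order, n_orders)

  rows <- list()
  class_i <- 0L; order_i <- 0L
  for (p in seq_len(spec$n_phyla)) {
    p_name <- sprintf("P%02d", p)
    p_seq <- mutate_seq(root, spec$sub_rates[[1]])
    for (cl in seq_len(cpp[p])) {
      class_i <- class_i + 1L
      c_name <- sprintf("%s_C%02d", p_name, cl)
      c_seq <- mutate_seq(p_seq, spec$sub_rates[[2]])
      for (o in seq_len(opc[class_i])) {
        order_i <- order_i + 1L
        o_name <- sprintf("%s_O%02d", c_name, o)
        o_seq <- mutate_seq(c_seq, spec$sub_rates[[3]])
        for (f in seq_len(fpo[order_i])) {
          f_name <- sprintf("%s_F%02d", o_name, f)
          f_seq <- mutate_seq(o_seq, spec$sub_rates[[4]])
          for (s in seq_len(spec$seqs_per_family)) {
            s_seq <- mutate_seq(f_seq, spec$seq_noise)
            if (spec$indel_rate > 0) {
              s_seq <- apply_indels(s_seq, spec$indel_rate)
            }
            rows[[length(rows) + 1L]] <- data.frame(
              id = sprintf("%s_s%03d", f_name, s),
              residues = paste(DNA_BASES[s_seq], collapse = ""),
              phylum = p_name, class = c_name, order = o_name,
              family = f_name, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a corpus from the LDA generative process with known truth
#'
#' Samples documents exactly per the generative model: planted topic-word
#' distributions `phi` (rows Dirichlet-like blocks or user-supplied),
#' per-document proportions `theta ~ Dirichlet(alpha)`, then for every
#' token a topic from `theta` and a word from that topic's row of `phi`.
#' Ground truth is returned for parameter-recovery tests.
#'
#' By default `phi` has block structure: topic `t` spreads `separation`
#' extra mass uniformly over its private block of `n_words / n_topics`
#' words on top of a global uniform floor. The pairwise total variation
#' distance between any two default rows equals `separation` exactly.
#'
#' @param n_topics,n_words,n_docs,doc_len Corpus dimensions.
#' @param separation Pairwise TV distance between default `phi` rows, in
#'   `(0, 1]` (default 0.8).
#' @param phi Optional planted T x W row-stochastic matrix overriding the
#'   block construction.
#' @param alpha Planted symmetric Dirichlet concentration for `theta`
#'   (default 0.1: documents are dominated by few topics).
#' @param seed RNG seed (default 1).
#' @return List with `corpus` (a `kmer_corpus`-compatible object with
#'   synthetic word strings), `phi` (planted), `theta` (planted, D x T) and
#'   `z` (list of per-token planted topics).
#' @export
generate_planted_corpus <- function(n_topics, n_words, n_docs, doc_len,
                                    separation = 0.8, phi = NULL,
                                    alpha = 0.1, seed = 1L) {
  set.seed(seed)
  T <- as.integer(n_topics); W <- as.integer(n_words)
  if (is.null(phi)) {
    stopifnot(separation > 0, separation <= 1)
    phi <- matrix((1 - separation) / W, nrow = T, ncol = W)
    # contiguous near-even blocks, one per topic
    sizes <- tabulate(rep_len(seq_len(T), W), nbins = T)
    start <- cumsum(c(0L, sizes[-T]))
    for (t in seq_len(T)) {
      idx <- (start[t] + 1L):(start[t] + sizes[t])
      phi[t, idx] <- phi[t, idx] + separation / sizes[t]
    }
  }
  stopifnot(nrow(phi) == T, ncol(phi) == W,
            all(abs(rowSums(phi) - 1) < 1e-8))
  theta <- matrix(stats::rgamma(n_docs * T, shape = alpha), nrow = n_docs)
  theta <- theta / rowSums(theta)
  documents <- vector("list", n_docs)
  z_list <- vector("list", n_docs)
  for (d in seq_len(n_docs)) {
    z <- sample.int(T, doc_len, replace = TRUE, prob = theta[d, ])
    w <- integer(doc_len)
    for (t in unique(z)) {
      sel <- z == t
      w[sel] <- sample.int(W, sum(sel), replace = TRUE, prob = phi[t, ])
    }
    documents[[d]] <- w
    z_list[[d]] <- z
  }
  ids <- sprintf("doc%04d", seq_len(n_docs))
  names(documents) <- ids
  corpus <- structure(
    list(documents = documents, ids = ids,
         vocabulary = sprintf("w%04d", seq_len(W)),
         k = NA_integer_, empty = rep(FALSE, n_docs)),
    class = "kmer_corpus")
  list(corpus = corpus, phi = phi, theta = theta, z = z_list)
}
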