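# Independent oracles used by the tests. These deliberately re-derive
# quantities from first principles (exhaustive enumeration, literal
# formulas) rather than calling the code paths they check.

# Exact per-token posterior topic probabilities (and pairwise co-assignment
# probabilities) by exhaustive enumeration of all T^Q assignment vectors,
# weighted by the collapsed Dirichlet-multinomial joint P(w, z).
enumerate_token_posterior <- function(docs, n_words, n_topics, alpha, delta) {
  W <- n_words; T <- n_topics
  D <- length(docs)
  wid <- unlist(docs, use.names = FALSE)
  did <- rep(seq_len(D), lengths(docs))
  Q <- length(wid)
  n_assign <- T^Q
  zmat <- matrix(0L, n_assign, Q)
  logw <- numeric(n_assign)
  for (a in seq_len(n_assign)) {
    x <- a - 1L
    z <- integer(Q)
    for (q in seq_len(Q)) {
      z[q] <- x %% T + 1L
      x <- x %/% T
    }
    zmat[a, ] <- z
    n_wt <- matrix(0L, W, T)
    n_dt <- matrix(0L, D, T)
    for (q in seq_len(Q)) {
      n_wt[wid[q], z[q]] <- n_wt[wid[q], z[q]] + 1L
      n_dt[did[q], z[q]] <- n_dt[did[q], z[q]] + 1L
    }
    n_t <- colSums(n_wt)
    logw[a] <-
      sum(lgamma(n_wt + delta)) - sum(lgamma(n_t + W * delta)) +
      sum(lgamma(n_dt + alpha)) - sum(lgamma(lengths(docs) + T * alpha))
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  marg <- matrix(0, Q, T)
  co <- matrix(0, Q, Q)
  for (a in seq_len(n_assign)) {
    z <- zmat[a, ]
    marg[cbind(seq_len(Q), z)] <- marg[cbind(seq_len(Q), z)] + w[a]
    co <- co + w[a] * outer(z, z, "==")
  }
  list(marginal = marg, coassign = co, weights = w)
}

# The tiny fixed corpus used for the Gibbs-vs-exact comparison:
# 2 documents x 4 tokens, W = 4, T = 2 (2^8 assignments).
tiny_enumeration_corpus <- function() {
  documents <- list(doc1 = c(1L, 1L, 2L, 3L), doc2 = c(3L, 4L, 4L, 2L))
  structure(list(documents = documents, ids = names(documents),
                 vocabulary = c("AA", "AC", "AG", "AT"),
                 k = 2L, empty = c(FALSE, FALSE)),
            class = "kmer_corpus")
}

# Literal evaluation of the majority-vote label: for each topic, take the
# label of the member document maximising the pairwise-agreement double sum
# sum_k f(d_i, d_k); returns the set of labels attaining the maximum.
brute_force_topic_label <- function(member_labels) {
  R <- length(member_labels)
  if (R == 0L) return(character(0))
  agreement <- vapply(seq_len(R), function(i) {
    sum(member_labels[-i] == member_labels[i])
  }, numeric(1))
  unique(member_labels[agreement == max(agreement)])
}

# Four taxa over pairwise-disjoint k-mer vocabularies: each taxon uses a
# two-letter alphabet with runs capped at 3, so no k-mer (k >= 4) can be a
# homopolymer and the four vocabularies cannot overlap.
make_disjoint_taxa <- function(n_per_taxon = 20L, len = 400L) {
  pairs <- list(c("A", "C"), c("G", "T"), c("A", "G"), c("C", "T"))
  rows <- list()
  for (t in seq_along(pairs)) {
    ab <- pairs[[t]]
    for (i in seq_len(n_per_taxon)) {
      idx <- integer(len)
      run <- 0L
      prev <- 0L
      for (pos in seq_len(len)) {
        cand <- sample.int(2L, 1L)
        if (cand == prev && run >= 3L) cand <- 3L - prev
        run <- if (cand == prev) run + 1L else 1L
        prev <- cand
        idx[pos] <- cand
      }
      taxon <- paste0("T", t)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s_s%03d", taxon, i),
        residues = paste(ab[idx], collapse = ""),
        phylum = taxon, class = taxon, order = taxon, family = taxon,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Small fast taxonomy for hierarchy tests: 2 phyla x 2 classes x 2 orders
# x 2 families, short sequences, strong divergence.
small_taxonomy <- function(seed = 1L, seqs_per_family = 6L, len = 300L) {
  generate_taxonomy(taxonomy_spec(
    n_phyla = 2L, classes_per_phylum = 2L, orders_per_class = 2L,
    families_per_order = 2L, seqs_per_family = seqs_per_family,
    seq_length = len,
    sub_rates = c(phylum = 0.12, class = 0.06, order = 0.05, family = 0.05),
    seq_noise = 0.005), seed = seed)
}

# Fast LDA settings for desk-scale tests.
fast_config <- function(n_topics, seed = NULL, n_iter = 300L) {
  lda_config(n_topics, n_iter = n_iter, burn_in = n_iter %/% 2L, seed = seed)
}
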