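#' LDA configuration
#'
#' Bundles the hyperparameters and sampler settings of the latent Dirichlet
#' allocation model. The topic count `n_topics` has to be fixed a priori.
#' Defaults follow the standard collapsed-Gibbs recommendation of
#' `alpha = 50 / n_topics` for the document-topic Dirichlet and
#' `delta = 0.1` for the topic-word Dirichlet; both are smoothing
#' concentrations (> 0) and can be overridden.
#'
#' @param n_topics Number of topics `T` (>= 1).
#' @param alpha Document-topic Dirichlet concentration; default `50 / n_topics`.
#' @param delta Topic-word Dirichlet concentration; default 0.1.
#' @param n_iter Total Gibbs sweeps (default 1000).
#' @param burn_in Discarded sweeps (default `n_iter / 2`); must be < `n_iter`.
#' @param n_chains Number of independently initialised pilot chains
#'   (default 1). With more than one, each pilot runs `pilot_iter` sweeps,
#'   the state with the highest collapsed log joint is kept, and only that
#'   chain continues — a standard multi-start guard against the sampler
#'   freezing in a poor mode on strongly block-structured corpora.
#' @param pilot_iter Sweeps per pilot chain (default 100, capped at
#'   `burn_in` so pilots never eat into retained sweeps).
#' @param seed Optional RNG seed applied by [fit_lda()]; `NULL` uses the
#'   current RNG state.
#' @return An `lda_config` list.
#' @export
lda_config <- function(n_topics, alpha = 50 / n_topics, delta = 0.1,
                       n_iter = 1000L, burn_in = n_iter %/% 2L,
                       n_chains = 1L, pilot_iter = min(100L, burn_in),
                       seed = NULL) {
  n_topics <- as.integer(n_topics)
  n_iter <- as.integer(n_iter)
  burn_in <- as.integer(burn_in)
  n_chains <- as.integer(n_chains)
  pilot_iter <- as.integer(pilot_iter)
  if (is.na(n_topics) || n_topics < 1L) stop("n_topics must be >= 1")
  if (alpha <= 0 || delta <= 0) stop("alpha and delta must be > 0")
  if (burn_in < 0L || burn_in >= n_iter) stop("burn_in must be in [0, n_iter)")
  if (n_chains < 1L) stop("n_chains must be >= 1")
  if (n_chains > 1L && (pilot_iter < 1L || pilot_iter > burn_in)) {
    stop("pilot_iter must be in [1, burn_in] when n_chains > 1")
  }
  structure(list(n_topics = n_topics, alpha = alpha, delta = delta,
                 n_iter = n_iter, burn_in = burn_in, n_chains = n_chains,
                 pilot_iter = pilot_iter, seed = seed),
            class = "lda_config")
}

#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Runs a collapsed Gibbs sampler over per-token topic assignments, with the
#' topic-word distributions `phi` and document-topic proportions `theta`
#' integrated out. The full conditional for a token of word `w` in document
#' `d` is proportional to
#' `(n_wt[w,t] + delta) / (n_t[t] + W * delta) * (n_dt[d,t] + alpha)`.
#' After the run, `phi` (T x W) and `theta` (D x T) are the smoothed count
#' estimates from the final post-burn-in state; averaging states across
#' sweeps is deliberately avoided because topic-label switching between
#' sweeps would blur the estimates.
#'
#' @param corpus A `kmer_corpus` (or any list-alike with integer-token
#'   `documents` and a `vocabulary`). Every document must be non-empty.
#' @param config An [lda_config()].
#' @param track_tokens Accumulate Rao-Blackwellised per-token posterior topic
#'   probabilities over retained sweeps (returned as `token_prob`, Q x T).
#' @param track_history Record the token-assignment vector after every
#'   retained sweep (returned as `history`); only sensible at toy scale.
#' @param trace_every Record the collapsed log joint every this many sweeps
#'   (0 = off) as `log_joint_trace`.
#' @param estimator `"final"` (default): `phi` and `theta` are the smoothed
#'   counts of the final post-burn-in state; `"average"`: they are averaged
#'   over all retained sweeps, which lowers Monte-Carlo noise but assumes
#'   the chain does not switch topic labels after burn-in (safe when topics
#'   are well separated).
#' @return A `topic_model`: list with `phi`, `theta`, `config`, `vocabulary`,
#'   `k`, `ids`, and `state` (final counts `n_wt`, `n_dt`, `n_t`, assignments
#'   `z`, `doc_len`), plus any tracked extras.
#' @export
fit_lda <- function(corpus, config, track_tokens = FALSE,
                    track_history = FALSE, trace_every = 0L,
                    estimator = c("final", "average")) {
  stopifnot(inherits(config, "lda_config"))
  estimator <- match.arg(estimator)
  docs <- corpus$documents
  if (length(docs) == 0L) stop("cannot fit LDA on an empty corpus")
  if (any(lengths(docs) == 0L)) {
    stop("cannot fit LDA: empty document(s): ",
         paste(utils::head(corpus$ids[lengths(docs) == 0L], 3), collapse = ", "))
  }
  W <- length(corpus$vocabulary)
  T <- config$n_topics
  if (!is.null(config$seed)) set.seed(config$seed)
  n_chains <- if (is.null(config$n_chains)) 1L else config$n_chains
  init_z <- NULL
  remaining <- config$n_iter
  remaining_burn <- config$burn_in
  if (n_chains > 1L) {
    # multi-start: short pilot chains, keep the best collapsed log joint
    pilots <- lapply(seq_len(n_chains), function(i) {
      gibbs_fit_cpp(docs, W, T, config$alpha, config$delta,
                    config$pilot_iter, config$pilot_iter - 1L,
                    FALSE, FALSE, 0L, FALSE)
    })
    scores <- vapply(pilots, function(p) log_joint(p, config), numeric(1))
    init_z <- pilots[[which.max(scores)]]$z
    remaining <- config$n_iter - config$pilot_iter
    remaining_burn <- config$burn_in - config$pilot_iter
  }
  res <- gibbs_fit_cpp(docs, W, T, config$alpha, config$delta,
                       remaining, remaining_burn,
                       track_tokens, track_history, as.integer(trace_every),
                       estimator == "average", init_z)
  if (estimator == "average") {
    phi <- res$phi_avg
    theta <- res$theta_avg
  } else {
    phi <- t((res$n_wt + config$delta) /
               rep(res$n_t + W * config$delta, each = W))
    theta <- (res$n_dt + config$alpha) /
      (res$doc_len + T * config$alpha)
  }
  rownames(theta) <- corpus$ids
  structure(
    list(phi = phi, theta = theta, config = config,
         vocabulary = corpus$vocabulary, k = corpus$k, ids = corpus$ids,
         state = list(z = res$z, n_wt = res$n_wt, n_dt = res$n_dt,
                      n_t = res$n_t, doc_len = res$doc_len),
         token_prob = res$token_prob, history = res$history,
         log_joint_trace = res$log_joint_trace),
    class = "topic_model"
  )
}

#' @export
print.topic_model <- function(x, ...) {
  cat("LDA topic model: T = ", x$config$n_topics, ", W = ",
      length(x$vocabulary), ", D = ", nrow(x$theta),
      " (k = ", x$k, ")\n", sep = "")
  invisible(x)
}

#' Infer the topic distribution of a held-out document (fold-in)
#'
#' Runs Gibbs sampling over the document's token assignments with the
#' model's topic-word distributions held fixed, and returns the posterior
#' mean of the document-topic proportions over retained sweeps. An empty
#' document (everything out of vocabulary, or shorter than k) falls back to
#' the uniform prior mean and is flagged via the `"flagged"` attribute.
#'
#' @param model A fitted `topic_model`.
#' @param document Integer token ids (1-based into the model vocabulary), or
#'   a character vector of k-mers to be encoded against it.
#' @param n_iter Fold-in sweeps (default 200).
#' @param burn_in Discarded sweeps (default 100).
#' @return Numeric probability vector of length T summing to 1.
#' @export
infer_theta <- function(model, document, n_iter = 200L, burn_in = 100L) {
  T <- model$config$n_topics
  if (is.character(document)) {
    document <- match(document, model$vocabulary)
    document <- document[!is.na(document)]
  }
  document <- as.integer(document)
  if (length(document) > 0 &&
      (min(document) < 1L || max(document) > length(model$vocabulary))) {
    stop("document tokens outside the model vocabulary (id range 1..W)")
  }
  if (length(document) == 0L) {
    theta <- rep(1 / T, T)
    attr(theta, "flagged") <- TRUE
    return(theta)
  }
  if (T == 1L) return(1)
  theta <- gibbs_infer_cpp(document, model$phi, model$config$alpha,
                           as.integer(n_iter), as.integer(burn_in))
  as.numeric(theta / sum(theta))
}

#' Collapsed log joint probability of words and topic assignments
#'
#' Evaluates `log P(w, z | alpha, delta)` with `phi` and `theta` integrated
#' out, from the sufficient count statistics of a Gibbs state. Useful for
#' convergence monitoring; invariant under permutation of topic indices.
#'
#' @param state A Gibbs state list with `n_wt` (W x T), `n_dt` (D x T),
#'   `n_t`, `doc_len` (as found in `topic_model$state`).
#' @param config The [lda_config()] supplying `alpha` and `delta`.
#' @return A scalar log probability.
#' @export
log_joint <- function(state, config) {
  W <- nrow(state$n_wt); T <- ncol(state$n_wt); D <- nrow(state$n_dt)
  alpha <- config$alpha; delta <- config$delta
  lj <- T * (lgamma(W * delta) - W * lgamma(delta)) +
    sum(lgamma(state$n_wt + delta)) -
    sum(lgamma(state$n_t + W * delta))
  lj + D * (lgamma(T * alpha) - T * lgamma(alpha)) +
    sum(lgamma(state$n_dt + alpha)) -
    sum(lgamma(state$doc_len + T * alpha))
}

#' Total variation distance between two discrete distributions
#'
#' @param p,q Probability vectors of equal length.
#' @return `0.5 * sum(abs(p - q))`, in `[0, 1]`.
#' @export
total_variation <- function(p, q) 0.5 * sum(abs(p - q))

#' Align estimated topics with reference topics
#'
#' Finds the permutation of estimated topic rows minimising the mean total
#' variation distance to the reference rows (exhaustive search, intended for
#' small T). Used to score recovery of planted topic-word distributions,
#' where topic indices are identifiable only up to permutation.
#'
#' @param phi_est,phi_ref T x W row-stochastic matrices.
#' @return List with `perm` (reference row i is matched by estimated row
#'   `perm[i]`), `mean_tv`, and `per_topic_tv`.
#' @export
align_topics <- function(phi_est, phi_ref) {
  T <- nrow(phi_ref)
  stopifnot(nrow(phi_est) == T, ncol(phi_est) == ncol(phi_ref))
  if (T > 8L) stop("exhaustive alignment supported for T <= 8 only")
  tv <- outer(seq_len(T), seq_len(T), Vectorize(function(i, j) {
    total_variation(phi_ref[i, ], phi_est[j, ])
  }))
  perms <- .permutations(T)
  costs <- vapply(perms, function(p) mean(tv[cbind(seq_len(T), p)]),
                  numeric(1))
  best <- perms[[which.min(costs)]]
  list(perm = best, mean_tv = min(costs),
       per_topic_tv = tv[cbind(seq_len(T), best)])
}

.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(.permutations(n - 1L), function(p) {
      c(i, setdiff(seq_len(n), i)[p])
    })
  }))
}
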