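test_that("a single-topic model degenerates to smoothed word frequencies", {
  corpus <- tiny_enumeration_corpus()
  config <- lda_config(1, n_iter = 50, burn_in = 10, seed = 3)
  model <- fit_lda(corpus, config)
  expect_equal(unname(model$theta[, 1]), c(1, 1))
  # word counts: w1 x2, w2 x2, w3 x2, w4 x2 over 8 tokens
  counts <- tabulate(unlist(corpus$documents), nbins = 4)
  expect_equal(model$phi[1, ],
               (counts + config$delta) / (8 + 4 * config$delta))
})

test_that("phi and theta are strictly positive and row-stochastic", {
  g <- generate_planted_corpus(3, 30, 20, 40, separation = 0.8, seed = 2)
  for (est in c("final", "average")) {
    model <- fit_lda(g$corpus, fast_config(3, seed = 4), estimator = est)
    expect_equal(rowSums(model$phi), rep(1, 3), tolerance = 1e-9)
    expect_equal(unname(rowSums(model$theta)), rep(1, 20), tolerance = 1e-9)
    expect_true(all(model$phi > 0))
    expect_true(all(model$theta > 0))
  }
})

test_that("Gibbs count matrices stay consistent with the assignments", {
  g <- generate_planted_corpus(3, 30, 15, 25, separation = 0.8, seed = 9)
  model <- fit_lda(g$corpus, fast_config(3, seed = 1))
  st <- model$state
  Q <- sum(lengths(g$corpus$documents))
  expect_equal(sum(st$n_wt), Q)
  expect_equal(sum(st$n_dt), Q)
  expect_equal(sum(st$n_t), Q)
  # marginals agree with the final assignment vector
  expect_equal(unname(colSums(st$n_wt)), tabulate(st$z + 1L, nbins = 3))
  wid <- unlist(g$corpus$documents, use.names = FALSE)
  for (t in 0:2) {
    expect_equal(unname(st$n_wt[, t + 1]),
                 tabulate(wid[st$z == t], nbins = 30))
  }
})

test_that("fits are bitwise reproducible under a fixed seed", {
  g <- generate_planted_corpus(2, 20, 10, 30, separation = 0.8, seed = 5)
  m1 <- fit_lda(g$corpus, fast_config(2, seed = 123))
  m2 <- fit_lda(g$corpus, fast_config(2, seed = 123))
  expect_identical(m1$phi, m2$phi)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$state$z, m2$state$z)
})

test_that("Gibbs posterior matches exact enumeration on a tiny corpus", {
  corpus <- tiny_enumeration_corpus()
  alpha <- 0.5; delta <- 0.5
  exact <- enumerate_token_posterior(corpus$documents, 4, 2, alpha, delta)
  config <- lda_config(2, alpha = alpha, delta = delta,
                       n_iter = 2000, burn_in = 500, seed = 8)
  model <- fit_lda(corpus, config, track_tokens = TRUE, track_history = TRUE)
  expect_lt(max(abs(model$token_prob - exact$marginal)), 0.05)
  # permutation-invariant check: pairwise co-assignment probabilities
  hist <- model$history
  co <- matrix(0, ncol(hist), ncol(hist))
  for (s in seq_len(nrow(hist))) {
    co <- co + outer(hist[s, ], hist[s, ], "==")
  }
  co <- co / nrow(hist)
  expect_lt(max(abs(co - exact$coassign)), 0.05)
})

test_that("planted topics are recovered, and better with more documents", {
  tv <- vapply(c(50L, 200L), function(D) {
    g <- generate_planted_corpus(3, 60, D, 80, separation = 0.8,
                                 seed = 21)
    model <- fit_lda(g$corpus, lda_config(3, n_iter = 600, burn_in = 300,
                                          seed = 13))
    align_topics(model$phi, g$phi)$mean_tv
  }, numeric(1))
  expect_lt(tv[2], tv[1])
  expect_lt(tv[2], 0.15)
})

test_that("fold-in recovers the dominant topic of pure documents", {
  g <- generate_planted_corpus(4, 64, 40, 60, separation = 1, seed = 6)
  model <- fit_lda(g$corpus, fast_config(4, seed = 17))
  al <- align_topics(model$phi, g$phi)
  set.seed(30)
  for (t in 1:4) {
    # document drawn purely from planted topic t
    doc <- sample.int(64, 40, replace = TRUE, prob = g$phi[t, ])
    theta <- infer_theta(model, doc)
    expect_equal(sum(theta), 1, tolerance = 1e-9)
    expect_equal(which.max(theta), al$perm[t])
  }
})

test_that("fold-in falls back to the uniform prior for empty documents", {
  g <- generate_planted_corpus(4, 16, 6, 20, separation = 1, seed = 3)
  model <- fit_lda(g$corpus, fast_config(4, seed = 2))
  theta <- infer_theta(model, integer(0))
  expect_equal(as.numeric(theta), rep(0.25, 4))
  expect_true(attr(theta, "flagged"))
  expect_error(infer_theta(model, c(1L, 99L)), "vocabulary")
})

test_that("log joint is label-symmetric and follows the closed form", {
  g <- generate_planted_corpus(3, 25, 8, 30, separation = 0.8, seed = 12)
  model <- fit_lda(g$corpus, fast_config(3, seed = 7))
  st <- model$state
  cfg <- model$config
  lj <- log_joint(st, cfg)
  perm <- c(2L, 3L, 1L)
  st_perm <- st
  st_perm$n_wt <- st$n_wt[, perm]
  st_perm$n_dt <- st$n_dt[, perm]
  st_perm$n_t <- st$n_t[perm]
  expect_equal(log_joint(st_perm, cfg), lj)

  # doubling delta shifts the value by an amount computable in closed form
  cfg2 <- cfg; cfg2$delta <- 2 * cfg$delta
  W <- nrow(st$n_wt); T <- ncol(st$n_wt)
  shift <- T * (lgamma(W * cfg2$delta) - lgamma(W * cfg$delta)) -
    T * W * (lgamma(cfg2$delta) - lgamma(cfg$delta)) +
    sum(lgamma(st$n_wt + cfg2$delta) - lgamma(st$n_wt + cfg$delta)) -
    sum(lgamma(st$n_t + W * cfg2$delta) - lgamma(st$n_t + W * cfg$delta))
  expect_equal(log_joint(st, cfg2), lj + shift)

  # single token, single topic: log of the smoothed unigram probability
  one <- structure(list(documents = list(d = 1L), ids = "d",
                        vocabulary = c("A", "C"), k = 1L, empty = FALSE),
                   class = "kmer_corpus")
  m1 <- fit_lda(one, lda_config(1, n_iter = 5, burn_in = 1, seed = 1))
  expect_equal(log_joint(m1$state, m1$config), log(1 / 2))
})

test_that("the log joint trace rises during burn-in on separable data", {
  g <- generate_planted_corpus(3, 60, 60, 60, separation = 1, seed = 31)
  model <- fit_lda(g$corpus, lda_config(3, n_iter = 200, burn_in = 100,
                                        seed = 19), trace_every = 10)
  trace <- model$log_joint_trace
  recorded <- trace[!is.na(trace)]
  expect_gt(utils::tail(recorded, 1), recorded[1])
})

test_that("topic alignment finds the planted permutation", {
  phi <- diag(4)
  est <- phi[c(3, 1, 4, 2), ]
  al <- align_topics(est, phi)
  expect_equal(al$mean_tv, 0)
  expect_equal(al$perm, c(2L, 4L, 1L, 3L))
  expect_equal(total_variation(c(1, 0), c(0, 1)), 1)
})
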