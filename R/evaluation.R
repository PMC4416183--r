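#' Precision of a set of predictions
#'
#' Precision is `TP / (TP + FP)`: true positives are test sequences whose
#' predicted label matches the gold label; every other scored sequence —
#' including unclassified ones (`NA` predictions) — is a false positive.
#' There is no third bucket, so `TP + FP` equals the number of scored test
#' sequences and precision is a micro-accuracy. A per-taxon breakdown is
#' attached as supplementary output.
#'
#' @param predictions A `data.frame` with `id` and `predicted_label`
#'   (as from [classify()]), or with a column named by `label_col`.
#' @param gold Named character vector mapping id to the true taxon.
#' @param rank Rank being scored (annotation only).
#' @param fragment_size Fragment size scored, or `"full"` (annotation only).
#' @param label_col Column of `predictions` holding the predicted taxon.
#' @return A `precision_report` list: `rank`, `fragment_size`, `tp`, `fp`,
#'   `precision`, `n_folds`, `per_fold`, `per_taxon`.
#' @export
precision_report <- function(predictions, gold, rank = NA_character_,
                             fragment_size = "full",
                             label_col = "predicted_label") {
  if (nrow(predictions) == 0L) stop("empty prediction list")
  missing <- setdiff(predictions$id, names(gold))
  if (length(missing) > 0L) {
    stop("no gold label for prediction(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  truth <- unname(gold[predictions$id])
  pred <- predictions[[label_col]]
  if (is.null(pred)) {
    stop("predictions carry no '", label_col, "' column; for lineage ",
         "tables pass label_col = <rank>")
  }
  correct <- !is.na(pred) & pred == truth
  tp <- sum(correct)
  fp <- nrow(predictions) - tp
  per_taxon <- do.call(rbind, lapply(sort(unique(truth)), function(tx) {
    sel <- truth == tx
    data.frame(taxon = tx, n = sum(sel), tp = sum(correct[sel]),
               precision = mean(correct[sel]), stringsAsFactors = FALSE)
  }))
  structure(list(rank = rank, fragment_size = fragment_size,
                 tp = tp, fp = fp, precision = tp / (tp + fp),
                 n_folds = 1L, per_fold = tp / (tp + fp),
                 per_taxon = per_taxon),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("precision report [rank %s, size %s]: %d TP / %d FP, precision = %.4f (%d fold%s)\n",
              x$rank, as.character(x$fragment_size), x$tp, x$fp, x$precision,
              x$n_folds, if (x$n_folds == 1L) "" else "s"))
  invisible(x)
}

# Stratified fold assignment: within each taxon, members are shuffled and
# dealt round-robin, so every record is tested exactly once and small taxa
# are spread across folds. Returns an integer fold id per record.
stratified_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (tx in unique(labels)) {
    idx <- which(labels == tx)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

# Pool fold-level prediction tables into one report.
pool_reports <- function(fold_predictions, gold, rank, fragment_size) {
  all_pred <- do.call(rbind, fold_predictions)
  rep <- precision_report(all_pred, gold, rank = rank,
                          fragment_size = fragment_size)
  rep$n_folds <- length(fold_predictions)
  rep$per_fold <- vapply(fold_predictions, function(p) {
    truth <- unname(gold[p$id])
    mean(!is.na(p$predicted_label) & p$predicted_label == truth)
  }, numeric(1))
  rep
}

#' Flat cross-validated classification at one taxonomic rank
#'
#' Runs a stratified k-fold cross-validation of the single-model workflow:
#' on each fold, the training 9/10 is decomposed into k-mers, an LDA model
#' with `n_topics` topics is fitted, topics are labeled by majority vote at
#' `rank`, and the held-out 1/10 is classified. True/false positives are
#' pooled across folds. A taxon absent from some training fold triggers a
#' warning; its held-out members are necessarily scored as false positives.
#'
#' @param records Labeled sequence records.
#' @param rank Rank to classify at.
#' @param n_topics Topic count `T` for every fold's model.
#' @param k k-mer size (default 8).
#' @param alpha,delta Dirichlet concentrations (defaults `50 / n_topics`, 0.1).
#' @param n_iter,burn_in Training sweeps (defaults 1000 / 500).
#' @param n_chains Pilot chains per fold fit (default 1); see [lda_config()].
#' @param infer_iter,infer_burn_in Fold-in sweeps (defaults 200 / 100).
#' @param n_folds Number of folds (default 10).
#' @param seed RNG seed governing fold assignment and all sampling.
#' @return A `precision_report` with `per_fold` precisions.
#' @export
cross_validate <- function(records, rank, n_topics, k = 8L,
                           alpha = 50 / n_topics, delta = 0.1,
                           n_iter = 1000L, burn_in = n_iter %/% 2L,
                           n_chains = 1L,
                           infer_iter = 200L, infer_burn_in = 100L,
                           n_folds = 10L, seed = 1L) {
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  labels <- records[[rank]]
  if (is.null(labels) || anyNA(labels)) {
    stop("records must be fully labeled at rank '", rank, "'")
  }
  set.seed(seed)
  folds <- stratified_folds(labels, n_folds)
  gold <- setNames(labels, records$id)
  fold_predictions <- vector("list", n_folds)
  for (fold in seq_len(n_folds)) {
    train <- records[folds != fold, , drop = FALSE]
    test <- records[folds == fold, , drop = FALSE]
    lost <- setdiff(unique(labels), unique(train[[rank]]))
    if (length(lost) > 0L) {
      warning("taxon absent from training fold ", fold, ": ",
              paste(lost, collapse = ", "), call. = FALSE)
    }
    corpus <- build_corpus(train, k = k)
    config <- lda_config(n_topics, alpha = alpha, delta = delta,
                         n_iter = n_iter, burn_in = burn_in,
                         n_chains = n_chains,
                         pilot_iter = min(100L, burn_in))
    labeled <- label_topics(fit_lda(corpus, config),
                            setNames(train[[rank]], train$id))
    fold_predictions[[fold]] <- classify(labeled, test,
                                         n_iter = infer_iter,
                                         burn_in = infer_burn_in)
  }
  pool_reports(fold_predictions, gold, rank = rank, fragment_size = "full")
}

#' Fragment-robustness experiment over the hierarchical classifier
#'
#' For each cross-validation fold, a hierarchical classifier is trained on
#' the full-length training sequences; the held-out sequences are then
#' classified once at full length and once per requested fragment size,
#' each time replaced by a single random fragment of that size. Fragmenting
#' happens only at test time — the models never see fragments. One pooled
#' precision report per rank per size is returned.
#'
#' @param records Labeled sequence records (all four ranks).
#' @param sizes Fragment lengths in bp (default `c(400, 200, 100, 50, 40,
#'   25)`); every size must be at least `k`, otherwise no k-mer tokens are
#'   possible.
#' @param include_full Also score unfragmented test sequences (default TRUE).
#' @param k,multiplier,delta,n_iter,burn_in,n_chains,alpha Passed to
#'   [train_hierarchy()].
#' @param infer_iter,infer_burn_in Fold-in sweeps (defaults 200 / 100).
#' @param n_folds Number of folds in the partition (default 10).
#' @param folds Which folds to evaluate (default all); evaluating a subset
#'   keeps large experiments tractable while preserving the train-on-9/10
#'   design.
#' @param seed RNG seed governing folds, training, fragmenting, inference.
#' @return A `data.frame` with one row per rank per size: `rank`,
#'   `fragment_size` (`"full"` or bp), `tp`, `fp`, `precision`, `n_folds`.
#' @export
fragment_experiment <- function(records, sizes = c(400L, 200L, 100L, 50L, 40L, 25L),
                                include_full = TRUE, k = 8L, multiplier = 1L,
                                delta = 0.1, n_iter = 1000L,
                                burn_in = n_iter %/% 2L, n_chains = 4L,
                                alpha = NULL,
                                infer_iter = 200L, infer_burn_in = 100L,
                                n_folds = 10L, folds = NULL, seed = 1L) {
  sizes <- as.integer(sizes)
  if (any(sizes < k)) {
    stop("fragment size smaller than k = ", k, ": no k-mers possible")
  }
  if (any(sizes > min(nchar(records$residues)))) {
    stop("fragment size exceeds the shortest sequence length")
  }
  set.seed(seed)
  fold_id <- stratified_folds(records$family, n_folds)
  if (is.null(folds)) folds <- seq_len(n_folds)
  size_keys <- c(if (include_full) "full", as.character(sizes))
  # predictions[[size]][[rank]] accumulates per-fold tables
  predictions <- setNames(lapply(size_keys, function(s) {
    setNames(lapply(TAXONOMIC_RANKS, function(r) list()), TAXONOMIC_RANKS)
  }), size_keys)
  gold <- setNames(lapply(TAXONOMIC_RANKS, function(r) {
    setNames(records[[r]], records$id)
  }), TAXONOMIC_RANKS)
  for (fold in folds) {
    train <- records[fold_id != fold, , drop = FALSE]
    test <- records[fold_id == fold, , drop = FALSE]
    classifier <- train_hierarchy(train, k = k, multiplier = multiplier,
                                  delta = delta, n_iter = n_iter,
                                  burn_in = burn_in, n_chains = n_chains,
                                  alpha = alpha)
    for (s in size_keys) {
      test_s <- if (s == "full") test else extract_fragment(test, as.integer(s))
      test_s$id <- test$id # score against the parent record's id
      lineage <- predict_lineage(classifier, test_s,
                                 n_iter = infer_iter,
                                 burn_in = infer_burn_in)
      for (r in TAXONOMIC_RANKS) {
        predictions[[s]][[r]] <- c(predictions[[s]][[r]], list(
          data.frame(id = lineage$id, predicted_label = lineage[[r]],
                     stringsAsFactors = FALSE)))
      }
    }
  }
  out <- list()
  for (s in size_keys) {
    for (r in TAXONOMIC_RANKS) {
      rep <- pool_reports(predictions[[s]][[r]], gold[[r]],
                          rank = r, fragment_size = s)
      out[[length(out) + 1L]] <- data.frame(
        rank = r, fragment_size = s, tp = rep$tp, fp = rep$fp,
        precision = rep$precision, n_folds = length(folds),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
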