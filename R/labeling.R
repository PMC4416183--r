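#' Assign each training document to its most probable topic
#'
#' The assignment is the argmax over the document's fitted topic
#' proportions; exact ties resolve to the lowest topic index so that runs
#' are deterministic.
#'
#' @param model A fitted `topic_model`.
#' @return A `data.frame` with columns `id`, `topic` (1-based index) and
#'   `posterior` (probability mass of the winning topic).
#' @export
assign_topics <- function(model) {
  theta <- model$theta
  topic <- apply(theta, 1L, which.max) # which.max: lowest index on ties
  data.frame(id = model$ids, topic = as.integer(topic),
             posterior = theta[cbind(seq_len(nrow(theta)), topic)],
             stringsAsFactors = FALSE)
}

#' Label topics by majority vote over their assigned training sequences
#'
#' Each topic receives the modal taxonomic label among the training
#' documents whose most probable topic it is: the label that agrees with
#' the largest number of co-assigned sequences. Topics to which no document
#' is assigned stay unlabeled (`NA`). Modal ties are broken first by the
#' taxon of the tied document with the highest winning-topic posterior,
#' then alphabetically, so labeling is deterministic.
#'
#' @param model A fitted `topic_model`.
#' @param labels Named character vector mapping document id to taxon.
#' @return A `labeled_topic_model`: the model plus `topic_labels` (length T,
#'   `NA` = unlabeled) and `vote_tallies` (per-topic label counts, kept for
#'   audit).
#' @export
label_topics <- function(model, labels) {
  assignments <- assign_topics(model)
  missing <- setdiff(assignments$id, names(labels))
  if (length(missing) > 0L) {
    stop("no taxonomic label for assigned document(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  assignments$label <- unname(labels[assignments$id])
  if (anyNA(assignments$label)) {
    stop("NA taxonomic label for assigned document(s): ",
         paste(utils::head(assignments$id[is.na(assignments$label)], 3),
               collapse = ", "))
  }
  T <- model$config$n_topics
  topic_labels <- rep(NA_character_, T)
  vote_tallies <- vector("list", T)
  for (j in seq_len(T)) {
    members <- assignments[assignments$topic == j, , drop = FALSE]
    if (nrow(members) == 0L) {
      vote_tallies[[j]] <- integer(0)
      next
    }
    tally <- sort(table(members$label), decreasing = TRUE)
    vote_tallies[[j]] <- tally
    tied <- names(tally)[tally == tally[1]]
    if (length(tied) == 1L) {
      topic_labels[j] <- tied
    } else {
      contenders <- members[members$label %in% tied, , drop = FALSE]
      contenders <- contenders[order(-contenders$posterior,
                                     contenders$label), , drop = FALSE]
      topic_labels[j] <- contenders$label[1]
    }
  }
  structure(c(unclass(model),
              list(topic_labels = topic_labels,
                   vote_tallies = vote_tallies)),
            class = c("labeled_topic_model", "topic_model"))
}

#' Classify sequences by their most probable labeled topic
#'
#' Each sequence is decomposed into k-mers, encoded against the model
#' vocabulary (out-of-vocabulary k-mers dropped), folded into the model
#' with [infer_theta()], and assigned the label of its most probable topic.
#' A winning topic without a label, or a document with no usable tokens,
#' yields an unclassified prediction (`NA` label); evaluation counts these
#' as false positives rather than dropping them.
#'
#' @param labeled A `labeled_topic_model`.
#' @param records Sequence records to classify (`id`, `residues`).
#' @param n_iter,burn_in Fold-in sweeps (defaults 200 / 100).
#' @return A `data.frame` with columns `id`, `predicted_label` (`NA` =
#'   unclassified), `topic`, `confidence` (posterior mass of the winning
#'   topic; `1/T` for empty documents).
#' @export
classify <- function(labeled, records, n_iter = 200L, burn_in = 100L) {
  stopifnot(inherits(labeled, "labeled_topic_model"))
  T <- labeled$config$n_topics
  tokens <- tokenize_records(records, labeled$k)
  out <- lapply(seq_len(nrow(records)), function(i) {
    theta <- infer_theta(labeled, tokens[[i]],
                         n_iter = n_iter, burn_in = burn_in)
    if (isTRUE(attr(theta, "flagged"))) {
      return(data.frame(id = records$id[i],
                        predicted_label = NA_character_,
                        topic = NA_integer_, confidence = 1 / T,
                        stringsAsFactors = FALSE))
    }
    j <- which.max(theta)
    data.frame(id = records$id[i],
               predicted_label = labeled$topic_labels[j],
               topic = as.integer(j), confidence = theta[j],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write predictions as a tab-delimited table
#'
#' Columns: `sequence_id`, `predicted_label` (empty = unclassified),
#' `topic`, `confidence`.
#'
#' @param predictions Output of [classify()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  out <- predictions
  out$predicted_label[is.na(out$predicted_label)] <- ""
  names(out)[names(out) == "id"] <- "sequence_id"
  write.table(out, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
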