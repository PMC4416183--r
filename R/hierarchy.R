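# nodes are keyed by the parent lineage path; the root has no parent taxon
node_key <- function(path) if (nzchar(path)) path else "(root)"

#' Train one labeled topic model per parent taxon per rank
#'
#' Builds the hierarchical classifier: a root model over all records whose
#' topics are labeled with phyla, then, for each phylum, a class-level
#' model on that phylum's records, and likewise per class for orders and
#' per order for families. Each node's topic count is
#' `multiplier * (number of child categories under that parent)`; the
#' multiplier implements the rule of training with one or two topics per
#' category. A parent with a single child category gets a trivial
#' pass-through node that always predicts that child, since a topic model
#' over one category is vacuous.
#'
#' Sequences are tokenized once and re-encoded per node, so every node has
#' its own vocabulary restricted to its training subset.
#'
#' @param records Sequence records labeled at all four ranks (apply
#'   [filter_dataset()] first).
#' @param k k-mer size (default 8).
#' @param multiplier Topics per child category, 1 or 2 (default 1).
#' @param delta Topic-word Dirichlet concentration (default 0.1).
#' @param n_iter,burn_in Gibbs sweeps per node (defaults 1000 / 500).
#' @param n_chains Pilot chains per node fit (default 4): node corpora are
#'   strongly block-structured, where single chains can freeze in poor
#'   modes; see [lda_config()].
#' @param alpha Document-topic concentration; `NULL` (default) uses
#'   `50 / T` per node.
#' @param seed Optional master seed; all node fits consume the RNG stream
#'   sequentially in a fixed (sorted) node order, so a fixed seed makes the
#'   whole hierarchy reproducible.
#' @return A `hierarchical_classifier`: list with `rank_order`, `multiplier`,
#'   `k`, and `nodes`, a named list keyed by the parent lineage path
#'   (`""` for the root, `"PhylumA"`, `"PhylumA|ClassB"`, ...).
#' @export
train_hierarchy <- function(records, k = 8L, multiplier = 1L, delta = 0.1,
                            n_iter = 1000L, burn_in = n_iter %/% 2L,
                            n_chains = 4L, alpha = NULL, seed = NULL) {
  stopifnot(multiplier >= 1L)
  for (rank in TAXONOMIC_RANKS) {
    if (!rank %in% names(records) || anyNA(records[[rank]])) {
      stop("records must be labeled at every rank; missing labels at '",
           rank, "'")
    }
  }
  if (nrow(records) == 0L) stop("no training records")
  if (!is.null(seed)) set.seed(seed)
  tokens <- tokenize_records(records, k)
  nodes <- list()
  for (level in seq_along(TAXONOMIC_RANKS)) {
    rank <- TAXONOMIC_RANKS[level]
    parent_ranks <- TAXONOMIC_RANKS[seq_len(level - 1L)]
    paths <- if (level == 1L) {
      rep("", nrow(records))
    } else {
      do.call(paste, c(records[parent_ranks], sep = "|"))
    }
    for (path in sort(unique(paths))) {
      key <- node_key(path)
      in_node <- paths == path
      sub <- records[in_node, , drop = FALSE]
      children <- sort(unique(sub[[rank]]))
      if (length(children) == 1L) {
        nodes[[key]] <- list(type = "passthrough", rank = rank,
                             label = children, children = children,
                             n_train = nrow(sub))
        next
      }
      corpus <- corpus_from_tokens(tokens[in_node], k = k)
      T <- as.integer(multiplier * length(children))
      config <- lda_config(T,
                           alpha = if (is.null(alpha)) 50 / T else alpha,
                           delta = delta, n_iter = n_iter, burn_in = burn_in,
                           n_chains = n_chains,
                           pilot_iter = min(100L, burn_in))
      model <- fit_lda(corpus, config)
      labeled <- label_topics(model, setNames(sub[[rank]], sub$id))
      nodes[[key]] <- list(type = "model", rank = rank, model = labeled,
                           children = children, n_train = nrow(sub))
    }
  }
  structure(list(rank_order = TAXONOMIC_RANKS,
                 multiplier = as.integer(multiplier),
                 k = as.integer(k), nodes = nodes),
            class = "hierarchical_classifier")
}

#' @export
print.hierarchical_classifier <- function(x, ...) {
  n_model <- sum(vapply(x$nodes, function(n) n$type == "model", logical(1)))
  cat("hierarchical k-mer topic classifier: ", length(x$nodes), " nodes (",
      n_model, " topic models), k = ", x$k,
      ", topics multiplier = ", x$multiplier, "\n", sep = "")
  invisible(x)
}

#' Predict the full taxonomic lineage of sequences
#'
#' Classifies each sequence at the root model to obtain its phylum, then
#' descends into the predicted phylum's node for the class, and so on down
#' to family. An unclassified outcome at any rank (winning topic unlabeled,
#' or no usable k-mers) stops the descent and marks that and all lower
#' ranks unclassified (`NA`) — errors at upper ranks necessarily cascade.
#'
#' @param classifier A [train_hierarchy()] result.
#' @param records Sequence records to classify.
#' @param n_iter,burn_in Fold-in sweeps per node (defaults 200 / 100).
#' @param seed Optional seed for the fold-in sampler.
#' @return A `data.frame` with `id` and one predicted-taxon column per rank
#'   (`NA` = unclassified at that rank).
#' @export
predict_lineage <- function(classifier, records, n_iter = 200L,
                            burn_in = 100L, seed = NULL) {
  stopifnot(inherits(classifier, "hierarchical_classifier"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  out <- data.frame(id = records$id, stringsAsFactors = FALSE)
  for (rank in classifier$rank_order) out[[rank]] <- NA_character_
  path <- rep("", n)     # lineage path predicted so far
  alive <- rep(TRUE, n)  # descent not yet stopped
  for (rank in classifier$rank_order) {
    for (p in unique(path[alive])) {
      sel <- which(alive & path == p)
      node <- classifier$nodes[[node_key(p)]]
      if (is.null(node)) { # parent taxon unseen at training: stop descent
        alive[sel] <- FALSE
        next
      }
      if (node$type == "passthrough") {
        out[[rank]][sel] <- node$label
      } else {
        preds <- classify(node$model, records[sel, , drop = FALSE],
                          n_iter = n_iter, burn_in = burn_in)
        out[[rank]][sel] <- preds$predicted_label
      }
      dead <- sel[is.na(out[[rank]][sel])]
      alive[dead] <- FALSE
    }
    keep <- alive & !is.na(out[[rank]])
    path[keep] <- ifelse(nzchar(path[keep]),
                         paste(path[keep], out[[rank]][keep], sep = "|"),
                         out[[rank]][keep])
  }
  out
}

#' Serialize a hierarchical classifier to a directory
#'
#' Writes one serialized labeled topic model per node under `nodes/`, plus
#' a JSON `manifest.json` describing the tree (ranks, multiplier, k, node
#' paths, child categories, training sizes) with a format-version header.
#'
#' @param classifier A `hierarchical_classifier`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_classifier <- function(classifier, dir) {
  stopifnot(inherits(classifier, "hierarchical_classifier"))
  dir.create(file.path(dir, "nodes"), recursive = TRUE, showWarnings = FALSE)
  paths <- names(classifier$nodes)
  files <- sprintf("node%03d.rds", seq_along(paths))
  for (i in seq_along(paths)) {
    saveRDS(classifier$nodes[[i]], file.path(dir, "nodes", files[i]))
  }
  manifest <- list(
    format = "kmerlda-classifier",
    format_version = 1L,
    package_version = as.character(utils::packageVersion("kmerlda")),
    rank_order = classifier$rank_order,
    multiplier = classifier$multiplier,
    k = classifier$k,
    nodes = data.frame(
      path = paths, file = file.path("nodes", files),
      rank = vapply(classifier$nodes, `[[`, character(1), "rank"),
      type = vapply(classifier$nodes, `[[`, character(1), "type"),
      n_children = vapply(classifier$nodes,
                          function(n) length(n$children), integer(1)),
      n_train = vapply(classifier$nodes, `[[`, integer(1), "n_train"),
      row.names = NULL
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a serialized hierarchical classifier
#'
#' @param dir Directory written by [save_classifier()].
#' @return A `hierarchical_classifier`.
#' @export
load_classifier <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json in ", dir)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(manifest$format, "kmerlda-classifier")) {
    stop("not a kmerlda classifier directory: ", dir)
  }
  nodes <- lapply(manifest$nodes$file, function(f) {
    readRDS(file.path(dir, f))
  })
  names(nodes) <- manifest$nodes$path
  structure(list(rank_order = manifest$rank_order,
                 multiplier = as.integer(manifest$multiplier),
                 k = as.integer(manifest$k), nodes = nodes),
            class = "hierarchical_classifier")
}
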