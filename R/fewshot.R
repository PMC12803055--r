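# N-way K-shot episodic evaluation with prototypical inference: class
# prototypes are support-embedding means, queries are scored by cosine
# distance to prototypes and a softmax over negative distances.

#' Sample N-way K-shot episodes
#'
#' Each episode draws `n_way` classes without replacement from the eligible
#' classes (those with at least `k_shot + 1` cells, so a query remains),
#' `k_shot` support cells per class, and up to `query_per_class` held-out
#' query cells per class. Episodes are fully determined by `seed` and are
#' serializable (see [write_episodes()]) so multiple methods can consume
#' byte-identical support/query sets.
#'
#' @param ann A [cell_annotations()].
#' @param n_way classes per episode.
#' @param k_shot support cells per class.
#' @param n_trials number of episodes.
#' @param query_per_class cap on query cells per class (default 50).
#' @param seed integer.
#' @return list of `EpisodeSpec` lists: `episode_id`, `classes`,
#'   `support_ids`, `query_ids`, `seed`.
#' @export
sample_episodes <- function(ann, n_way = 5, k_shot = 1, n_trials = 20,
                            query_per_class = 50, seed = 0L) {
  tab <- table(ann$cell_type)
  eligible <- names(tab)[tab >= k_shot + 1]
  assert_that(length(eligible) >= n_way,
              sprintf("need >= %d classes with >= %d cells, have %d",
                      n_way, k_shot + 1, length(eligible)))
  with_seed(seed, {
    lapply(seq_len(n_trials), function(t) {
      classes <- sort(sample(eligible, n_way))
      support <- character(); query <- character()
      for (cl in classes) {
        ids <- ann$cell_ids[ann$cell_type == cl]
        ids <- sample(ids)
        support <- c(support, ids[seq_len(k_shot)])
        rest <- ids[-seq_len(k_shot)]
        query <- c(query, rest[seq_len(min(query_per_class, length(rest)))])
      }
      list(episode_id = t, classes = classes, support_ids = support,
           query_ids = query, seed = as.integer(seed))
    })
  })
}

#' Serialize episodes to JSON
#' @param episodes output of [sample_episodes()].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(episodes, path) {
  jsonlite::write_json(episodes, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read serialized episodes
#' @param path JSON file written by [write_episodes()].
#' @return list of episode specs.
#' @export
read_episodes <- function(path) {
  eps <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(eps, function(e) {
    e$episode_id <- as.integer(e$episode_id)
    e$seed <- as.integer(e$seed)
    e
  })
}

#' Prototypical prediction with cosine distance and softmax
#'
#' Prototypes are per-class means of the support embeddings. For a query
#' `z`, `d_c(z) = 1 - cos(z, p_c)` and `P(c|z) = exp(-d_c) / sum exp(-d_c')`.
#' Predicted label is the argmax, ties to the first class in level order.
#'
#' @param support_emb An [embedding_set()] of support cells.
#' @param support_labels class label per support cell.
#' @param query_emb An [embedding_set()] of query cells.
#' @return list with `predicted` (character), `probabilities` (queries x
#'   classes matrix, rows summing to 1), `prototypes` (classes x d matrix).
#' @export
prototype_predict <- function(support_emb, support_labels, query_emb) {
  S <- if (inherits(support_emb, "EmbeddingSet")) support_emb$matrix else
    as.matrix(support_emb)
  Q <- if (inherits(query_emb, "EmbeddingSet")) query_emb$matrix else
    as.matrix(query_emb)
  support_labels <- as.character(support_labels)
  assert_that(length(unique(support_labels)) >= 2,
              "support must cover >= 2 classes")
  levs <- sort(unique(support_labels))
  P <- rowsum(S, factor(support_labels, levels = levs)) /
    as.vector(table(factor(support_labels, levels = levs)))
  qn <- sqrt(rowSums(Q^2)); pn <- sqrt(rowSums(P^2))
  assert_that(all(qn > 0) && all(pn > 0),
              "zero-norm embedding: cosine distance undefined")
  cosine <- tcrossprod(Q / qn, P / pn)
  d <- 1 - cosine
  ex <- exp(-d)
  probs <- ex / rowSums(ex)
  colnames(probs) <- levs
  rownames(probs) <- rownames(Q)
  pred <- levs[apply(probs, 1, which.max)]  # which.max: first max wins ties
  list(predicted = pred, probabilities = probs, prototypes = P)
}

#' Run prototypical evaluation over a set of episodes
#'
#' @param emb An [embedding_set()] covering all support/query cells.
#' @param ann A [cell_annotations()] supplying ground-truth labels.
#' @param episodes list from [sample_episodes()].
#' @return list with `per_episode` (data.frame of per-episode metrics from
#'   [classification_report()]) and `mean` (named numeric vector of
#'   per-episode means).
#' @export
evaluate_episodes <- function(emb, ann, episodes) {
  rows <- lapply(episodes, function(ep) {
    sup <- subset_embedding(emb, ep$support_ids)
    qry <- subset_embedding(emb, ep$query_ids)
    sup_lab <- ann$cell_type[match(ep$support_ids, ann$cell_ids)]
    qry_lab <- ann$cell_type[match(ep$query_ids, ann$cell_ids)]
    out <- prototype_predict(sup, sup_lab, qry)
    ps <- prediction_set(ep$query_ids, qry_lab, out$predicted,
                         out$probabilities)
    rep_ <- classification_report(ps, top_k = min(3L, length(ep$classes)))
    c(episode_id = ep$episode_id, unlist(rep_))
  })
  per_episode <- as.data.frame(do.call(rbind, rows))
  list(per_episode = per_episode,
       mean = colMeans(per_episode[, -1, drop = FALSE]))
}
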