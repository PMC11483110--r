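# Class instances contributed by one example: the label for re/nli, one
# entry per typed span for ner (a sentence can cover several classes).
class_instances <- function(ex, task) {
  if (task$kind == "ner") {
    if (is.null(ex$spans)) character() else ex$spans$type
  } else ex$label
}

class_count_matrix <- function(dataset, task) {
  classes <- task_classes(task)
  mat <- vapply(dataset, function(ex) {
    inst <- class_instances(ex, task)
    vapply(classes, function(cl) sum(inst == cl), 0L)
  }, integer(length(classes)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(classes))
  rownames(mat) <- classes
  mat
}

greedy_ner_support <- function(dataset, task, K) {
  counts_mat <- class_count_matrix(dataset, task) # classes x sentences
  classes <- rownames(counts_mat)
  ids <- vapply(dataset, `[[`, "", "id")
  selected <- logical(length(dataset))
  cover <- stats::setNames(integer(length(classes)), classes)
  repeat {
    deficit <- pmax(K - cover, 0L)
    if (all(deficit == 0L)) break
    # most-deficient class; ties by label_set order (row order)
    target <- classes[which.max(deficit)]
    cand <- which(!selected & counts_mat[target, ] > 0L)
    if (!length(cand))
      stop_letex("class '%s' has insufficient support for K = %d", target, K)
    # among candidates, the sentence with the largest marginal gain toward
    # the current deficits; ties by example id
    gain <- vapply(cand, function(j)
      sum(pmin(counts_mat[, j], deficit)), 0)
    best <- cand[order(-gain, ids[cand])][1L]
    selected[best] <- TRUE
    cover <- cover + counts_mat[, best]
  }
  # prune: drop any sentence whose removal keeps every class at >= K,
  # visiting sentences in id order for determinism
  for (j in order(ids)) {
    if (!selected[j]) next
    if (all(cover - counts_mat[, j] >= K)) {
      selected[j] <- FALSE
      cover <- cover - counts_mat[, j]
    }
  }
  which(selected)
}

#' Sample an N-way K-shot support set and its query set
#'
#' All categories of the task are considered (N = |C|). For re/nli tasks the
#' support holds exactly K examples per class, drawn uniformly under
#' \code{seed}. For ner, where one sentence can carry instances of several
#' classes, a greedy downsampler repeatedly adds the sentence best covering
#' the currently most-deficient class until every class reaches K, then
#' prunes any sentence whose removal keeps all classes at K or above — so
#' per-class counts are at least K (the support may exceed N*K instances)
#' and no single retained sentence is redundant. The query set is every
#' remaining example; support and query ids never intersect.
#'
#' @param dataset List of examples for one task (typically the retained,
#'   explanation-augmented set).
#' @param task The task.
#' @param K Shots per class.
#' @param seed Integer seed.
#' @param explanations Optional named list of explanations; attached to
#'   support items when present.
#' @return List of class \code{letex_split} with \code{support} (list of
#'   \code{list(example, label, explanation)}), \code{query} (list of
#'   examples), \code{K}, \code{classes}.
#' @export
sample_support <- function(dataset, task, K, seed = 1, explanations = NULL) {
  if (!is_count(K)) stop_letex("K must be a count >= 1")
  classes <- task_classes(task)
  counts <- rowSums(class_count_matrix(dataset, task))
  short <- names(counts)[counts < K]
  if (length(short))
    stop_letex("class '%s' has only %d instance(s), fewer than K = %d",
               short[1L], counts[short[1L]], K)
  if (task$kind == "ner") {
    idx <- greedy_ner_support(dataset, task, K)
  } else {
    labels <- vapply(dataset, `[[`, "", "label")
    idx <- sort(unlist(lapply(seq_along(classes), function(ci) {
      members <- which(labels == classes[ci])
      perm <- with_seed(derive_seed(seed, 200L + ci),
                        sample(members, length(members)))
      perm[seq_len(K)]
    })))
  }
  support <- lapply(idx, function(i) {
    ex <- dataset[[i]]
    list(example = ex, label = gold_assertion_label(ex, task),
         explanation = explanations[[ex$id]])
  })
  structure(
    list(support = support, query = dataset[-idx], K = K, classes = classes),
    class = "letex_split"
  )
}

#' Support/query splits over a grid of shot counts
#'
#' One split per requested K under the same master seed. For re/nli the
#' per-class sampling order is drawn once, so smaller-K supports are nested
#' inside larger ones; for ner each K is downsampled independently.
#' Infeasible shot counts (a class with fewer than K instances) are skipped
#' and reported in \code{warnings} rather than failing the grid.
#'
#' @param dataset,task,seed,explanations As in \code{\link{sample_support}}.
#' @param shots Integer vector of shot counts, e.g. \code{c(16, 32, 64)}.
#' @return List with \code{splits} (named by K) and \code{warnings}
#'   (character).
#' @export
shot_grid <- function(dataset, task, shots = c(16, 32, 64), seed = 1,
                      explanations = NULL) {
  splits <- list()
  warns <- character()
  for (K in shots) {
    res <- tryCatch(
      sample_support(dataset, task, K, seed = seed,
                     explanations = explanations),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warns <- c(warns, sprintf("K = %d skipped: %s", K,
                                conditionMessage(res)))
    } else {
      splits[[as.character(K)]] <- res
    }
  }
  list(splits = splits, warnings = warns)
}

#' @export
print.letex_split <- function(x, ...) {
  cat(sprintf("<letex_split> K = %d, |S| = %d, |Q| = %d, classes: %s\n",
              x$K, length(x$support), length(x$query),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}
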