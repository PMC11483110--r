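#' Parse the label asserted by a reasoning explanation
#'
#' Looks for the closing assertion sentence \code{"So the label is <L>."}
#' (case-insensitive, trailing punctuation tolerated; the last occurrence
#' wins). If no assertion sentence is present, falls back to the last label
#' set member mentioned anywhere in the text; if none is mentioned, returns
#' \code{NA}.
#'
#' @param expl_text Explanation string.
#' @param label_set Candidate labels.
#' @return A label or \code{NA_character_}.
#' @export
extract_asserted_label <- function(expl_text, label_set) {
  if (!is.character(expl_text) || length(expl_text) != 1L || is.na(expl_text))
    return(NA_character_)
  m <- gregexpr("so the label is\\s+([^.!?\n]+)", expl_text,
                perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1L] != -1L) {
    st <- attr(m, "capture.start")[, 1L]
    len <- attr(m, "capture.length")[, 1L]
    cand <- substring(expl_text, st[length(st)],
                      st[length(st)] + len[length(len)] - 1L)
    lab <- normalize_label(cand, label_set)
    if (!is.na(lab)) return(lab)
  }
  # fallback: last label mentioned anywhere (word-boundary, case-insensitive)
  best <- NA_character_
  best_pos <- -1L
  for (lab in label_set) {
    pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", lab), "\\b")
    hits <- gregexpr(pat, expl_text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (hits[1L] != -1L && max(hits) > best_pos) {
      best_pos <- max(hits)
      best <- lab
    }
  }
  best
}

#' Convert a text-explanation pair into an entailment pair
#'
#' A reliable explanation should be entailed by the text it explains, so the
#' example text becomes the premise and the explanation the hypothesis.
#'
#' @param ex A \code{letex_example}.
#' @param expl Its \code{letex_explanation}.
#' @return One-row data.frame with columns \code{origin}, \code{premise},
#'   \code{hypothesis}, \code{weak_label}, \code{confidence}.
#' @export
nli_pair <- function(ex, expl) {
  data.frame(origin = ex$id, premise = example_text(ex),
             hypothesis = expl$text, weak_label = NA_character_,
             confidence = NA_real_, stringsAsFactors = FALSE)
}

#' Weak-label an entailment pair from the asserted label
#'
#' The deterministic supervision rule: an explanation whose asserted label
#' disagrees with the gold label — or that never states a parseable label —
#' is an evident error and is weak-labeled \code{contradiction}. Agreeing
#' pairs stay unlabeled: they are candidates the discriminator must judge,
#' not trusted positives. Manually crafted demonstrations supply the
#' entailment side of the seed set elsewhere.
#'
#' @param pair One-row pair data.frame from \code{\link{nli_pair}}.
#' @param gold Gold assertion label.
#' @param asserted Asserted label or \code{NA}.
#' @return The pair with \code{weak_label} set to \code{"contradiction"} or
#'   left \code{NA}.
#' @export
weak_label <- function(pair, gold, asserted) {
  if (is.na(asserted) || !identical(asserted, gold))
    pair$weak_label <- "contradiction"
  pair
}

# -- reference discriminator --------------------------------------------------

tokenize_lc <- function(x) {
  toks <- ws_tokens(tolower(x))
  gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
}

featurize_pairs <- function(pairs, vocab = NULL) {
  tok_list <- lapply(seq_len(nrow(pairs)), function(i) {
    h <- tokenize_lc(pairs$hypothesis[i])
    p <- tokenize_lc(pairs$premise[i])
    overlap <- if (length(h)) length(intersect(h, p)) / length(unique(h)) else 0
    list(toks = h, overlap = overlap)
  })
  if (is.null(vocab)) {
    vocab <- sort(unique(unlist(lapply(tok_list, `[[`, "toks"))))
  }
  ij <- do.call(rbind, lapply(seq_along(tok_list), function(i) {
    idx <- match(tok_list[[i]]$toks, vocab)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) return(NULL)
    tab <- table(idx)
    cbind(i = i, j = as.integer(names(tab)), x = as.numeric(tab))
  }))
  X <- Matrix::sparseMatrix(
    i = if (is.null(ij)) integer() else ij[, "i"],
    j = if (is.null(ij)) integer() else ij[, "j"],
    x = if (is.null(ij)) numeric() else ij[, "x"],
    dims = c(nrow(pairs), length(vocab) + 1L)
  )
  X[, length(vocab) + 1L] <- vapply(tok_list, `[[`, 0, "overlap")
  list(X = X, vocab = vocab)
}

#' Reference entailment discriminator
#'
#' A bag-of-words ridge-penalized logistic classifier over hypothesis
#' unigrams plus a premise-hypothesis lexical-overlap feature, fit with
#' \code{glmnet} at a fixed penalty. It implements the generic discriminator
#' contract — \code{fit(pairs)} on pairs whose \code{weak_label} is
#' \code{"entailment"}/\code{"contradiction"}, and \code{predict(pairs)}
#' returning the predicted label with the probability of that label — so a
#' transformer NLI checkpoint can be swapped in behind the same interface.
#' Both methods are deterministic given the training data.
#'
#' @param lambda Ridge penalty (fixed; no cross-validation).
#' @return An object of class \code{letex_discriminator}.
#' @export
bow_discriminator <- function(lambda = 0.01) {
  state <- new.env(parent = emptyenv())
  fit <- function(pairs) {
    labs <- pairs$weak_label
    if (any(is.na(labs)) || !all(labs %in% c("entailment", "contradiction")))
      stop_letex("discriminator training pairs must be fully weak-labeled")
    if (length(unique(labs)) < 2L)
      stop_letex("degenerate seed set: both classes are required to fit")
    feats <- featurize_pairs(pairs)
    y <- as.integer(labs == "entailment")
    state$vocab <- feats$vocab
    # glmnet warns on very small classes; fine for desk-scale seed sets
    state$model <- withCallingHandlers(
      glmnet::glmnet(feats$X, y, family = "binomial", alpha = 0,
                     lambda = lambda, standardize = FALSE),
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    invisible(NULL)
  }
  predict_fn <- function(pairs) {
    if (is.null(state$model)) stop_letex("discriminator is not fitted")
    feats <- featurize_pairs(pairs, vocab = state$vocab)
    p_ent <- as.numeric(stats::predict(state$model, newx = feats$X,
                                       type = "response"))
    label <- ifelse(p_ent >= 0.5, "entailment", "contradiction")
    data.frame(label = label,
               confidence = ifelse(p_ent >= 0.5, p_ent, 1 - p_ent),
               p_entailment = p_ent, stringsAsFactors = FALSE)
  }
  structure(list(fit = fit, predict = predict_fn, state = state),
            class = "letex_discriminator")
}

#' Confidence-thresholded self-training of the discriminator
#'
#' Fits the discriminator on the seed pairs, then for \code{iters} rounds
#' predicts the remaining unlabeled pairs, promotes those predicted
#' \code{entailment} with confidence at or above \code{threshold} into the
#' training set (as entailment), and refits. Only entailment predictions are
#' ever promoted; contradiction predictions never extend the seed negatives.
#' After the final round the fitted model partitions all input unlabeled
#' pairs into a retained (predicted entailment) and a discarded (predicted
#' contradiction) set.
#'
#' @param disc A discriminator (e.g. \code{\link{bow_discriminator}()}).
#' @param seed_pairs Weak-labeled pairs containing both classes.
#' @param unlabeled_pairs Pairs with \code{weak_label = NA}.
#' @param threshold Absolute confidence threshold in (0.5, 1).
#' @param iters Number of self-training rounds (>= 1; two to three rounds
#'   are typically enough).
#' @param top_q Optional alternative to the absolute threshold: promote the
#'   top \code{top_q} fraction of entailment-predicted pairs per round
#'   instead.
#' @return List with \code{disc} (fitted), \code{retained},
#'   \code{discarded} (disjoint data.frames partitioning
#'   \code{unlabeled_pairs}, each with \code{confidence} filled in), and
#'   \code{history} (promoted counts per round).
#' @export
self_train <- function(disc, seed_pairs, unlabeled_pairs,
                       threshold = 0.9, iters = 3, top_q = NULL) {
  if (!is_count(iters)) stop_letex("iters must be a count >= 1")
  if (is.null(top_q) && (!is_prob(threshold) || threshold <= 0.5 ||
                         threshold >= 1))
    stop_letex("threshold must lie in (0.5, 1)")
  train <- seed_pairs
  remaining <- unlabeled_pairs
  history <- integer(iters)
  disc$fit(train)
  for (it in seq_len(iters)) {
    if (nrow(remaining)) {
      pred <- disc$predict(remaining)
      is_ent <- pred$label == "entailment"
      promote <- if (is.null(top_q)) {
        is_ent & pred$confidence >= threshold
      } else {
        cut <- stats::quantile(pred$confidence[is_ent],
                               probs = 1 - top_q, names = FALSE,
                               type = 1)
        is_ent & pred$confidence >= cut
      }
      history[it] <- sum(promote)
      if (any(promote)) {
        newly <- remaining[promote, , drop = FALSE]
        newly$weak_label <- "entailment"
        train <- rbind(train, newly)
        remaining <- remaining[!promote, , drop = FALSE]
      }
    }
    disc$fit(train)
  }
  if (nrow(unlabeled_pairs)) {
    final <- disc$predict(unlabeled_pairs)
    unlabeled_pairs$confidence <- final$confidence
    keep <- final$label == "entailment"
  } else {
    keep <- logical()
  }
  list(disc = disc,
       retained = unlabeled_pairs[keep, , drop = FALSE],
       discarded = unlabeled_pairs[!keep, , drop = FALSE],
       history = history)
}

#' Filter collected explanations
#'
#' The full discrimination-and-filtering stage: every (example, explanation)
#' pair is converted to an entailment pair; evident errors (asserted label
#' missing or disagreeing with gold) are discarded outright with weak label
#' contradiction; manual demonstration explanations are weak-labeled
#' entailment; the discriminator is fit on those seeds and self-trained; and
#' the surviving candidates are partitioned by its final predictions.
#'
#' @param collected List of \code{list(example, explanation)} as produced by
#'   \code{\link{collect_explanations}}.
#' @param manual_demos Demonstration pool (entailment seeds).
#' @param task The task.
#' @param disc Discriminator (default \code{\link{bow_discriminator}()}).
#' @param threshold,iters,top_q Passed to \code{\link{self_train}}.
#' @return List with \code{retained} (list of \code{list(example,
#'   explanation)}), \code{audit} (data.frame: example id, decision, reason,
#'   confidence), and \code{disc}.
#' @export
filter_dataset <- function(collected, manual_demos, task,
                           disc = bow_discriminator(),
                           threshold = 0.9, iters = 3, top_q = NULL) {
  if (!length(collected)) stop_letex("no collected explanations to filter")
  by_id <- stats::setNames(collected,
                           vapply(collected, function(r) r$example$id, ""))
  rows <- lapply(collected, function(r) {
    pair <- nli_pair(r$example, r$explanation)
    gold <- gold_assertion_label(r$example, task)
    weak_label(pair, gold, r$explanation$asserted_label)
  })
  pairs <- do.call(rbind, rows)
  mismatched <- !is.na(pairs$weak_label)
  seed_neg <- pairs[mismatched, , drop = FALSE]
  candidates <- pairs[!mismatched, , drop = FALSE]
  seed_pos <- do.call(rbind, lapply(manual_demos, function(d) {
    p <- nli_pair(d$example, d$explanation)
    p$weak_label <- "entailment"
    p
  }))
  if (!nrow(seed_neg)) {
    # no evident error exists, so there is no contradiction supervision to
    # train on; the weak-label rule alone decides and all candidates are kept
    audit <- data.frame(example_id = candidates$origin,
                        decision = "retained", reason = "asserted_match",
                        confidence = NA_real_, stringsAsFactors = FALSE)
    retained <- lapply(candidates$origin, function(id) by_id[[id]])
    return(list(retained = retained, audit = audit, disc = disc))
  }
  st <- self_train(disc, rbind(seed_pos, seed_neg), candidates,
                   threshold = threshold, iters = iters, top_q = top_q)
  audit <- rbind(
    if (nrow(seed_neg)) data.frame(example_id = seed_neg$origin,
                                   decision = "discarded",
                                   reason = "asserted_mismatch",
                                   confidence = NA_real_,
                                   stringsAsFactors = FALSE),
    if (nrow(st$discarded)) data.frame(example_id = st$discarded$origin,
                                       decision = "discarded",
                                       reason = "discriminator",
                                       confidence = st$discarded$confidence,
                                       stringsAsFactors = FALSE),
    if (nrow(st$retained)) data.frame(example_id = st$retained$origin,
                                      decision = "retained",
                                      reason = "discriminator",
                                      confidence = st$retained$confidence,
                                      stringsAsFactors = FALSE)
  )
  retained <- lapply(st$retained$origin, function(id) by_id[[id]])
  list(retained = retained, audit = audit, disc = st$disc)
}
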