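#' Generate label and explanation predictions for a query set
#'
#' For each query item, two deterministic greedy generations are produced —
#' one under the label prefix, one under the explain prefix — and the label
#' generation is decoded into a structured prediction (span list for ner,
#' normalized label otherwise). Decoding is total: malformed generations
#' yield empty or \code{NA} decodings, never an error, and a backbone
#' failure on one item is recorded and evaluation continues.
#'
#' @param backbone A trained \code{letex_backbone}.
#' @param query List of query examples.
#' @param task The task.
#' @return List of predictions, each \code{list(example_id,
#'   generated_label_text, generated_explanation_text, decoded, error)}.
#' @export
predict_query <- function(backbone, query, task) {
  lapply(query, function(ex) {
    res <- tryCatch({
      gl <- backbone_generate(backbone, encode_input(ex, task, "label"))
      ge <- backbone_generate(backbone, encode_input(ex, task, "explain"))
      decoded <- if (task$kind == "ner") decode_ner(gl, task)
                 else normalize_label(gl, task$label_set)
      list(example_id = ex$id, generated_label_text = gl,
           generated_explanation_text = ge, decoded = decoded, error = NULL)
    }, error = function(e) {
      list(example_id = ex$id, generated_label_text = NA_character_,
           generated_explanation_text = NA_character_,
           decoded = if (task$kind == "ner")
             decode_ner(NA_character_, task) else NA_character_,
           error = conditionMessage(e))
    })
    res
  })
}

#' Is a label generation parseable?
#'
#' For re/nli a generation is parseable when it normalizes to a member of
#' the label set. For ner, where any string decodes to a (possibly empty)
#' span list, the meaningful property is well-formedness: every marker token
#' participates in a properly opened and closed region.
#'
#' @param pred One prediction from \code{\link{predict_query}}.
#' @param task The task.
#' @return Logical.
#' @export
prediction_parseable <- function(pred, task) {
  if (!is.null(pred$error)) return(FALSE)
  if (task$kind == "ner")
    markers_well_formed(pred$generated_label_text, task)
  else !is.na(pred$decoded)
}

gold_ner_key <- function(ex) {
  if (is.null(ex$spans) || !nrow(ex$spans)) return(character())
  paste(ex$spans$type, ex$spans$surface, sep = "\r")
}

multiset_overlap <- function(a, b) {
  if (!length(a) || !length(b)) return(0L)
  ta <- table(a)
  tb <- table(b)
  shared <- intersect(names(ta), names(tb))
  sum(pmin(as.integer(ta[shared]), as.integer(tb[shared])))
}

#' Micro-averaged precision, recall and F1
#'
#' True/false positives and false negatives are pooled over the whole query
#' set before computing the metrics. For ner, predictions and gold
#' annotations are matched per sentence as multisets of (type, surface)
#' pairs, i.e. at the same granularity the generation can express. For re,
#' examples are pooled over the positive relation classes: the task's
#' \code{negative_labels} (the "no relation" class) contribute no true
#' positives, predicting them on a positive example is a miss, and
#' predicting a positive class on a negative example is a false alarm.
#' F1 is 0 when P + R = 0.
#'
#' @param predictions List from \code{\link{predict_query}}.
#' @param gold List of gold examples, aligned by example id.
#' @param task The task.
#' @return List with \code{precision}, \code{recall}, \code{f1} and
#'   \code{counts} (tp, fp, fn, n).
#' @export
micro_f1 <- function(predictions, gold, task) {
  pred_ids <- vapply(predictions, `[[`, "", "example_id")
  gold_ids <- vapply(gold, `[[`, "", "id")
  if (!identical(sort(pred_ids), sort(gold_ids)))
    stop_letex("prediction and gold example ids do not match")
  gold <- gold[match(pred_ids, gold_ids)]
  tp <- fp <- fn <- 0L
  if (task$kind == "ner") {
    for (i in seq_along(predictions)) {
      dec <- predictions[[i]]$decoded
      pk <- if (is.data.frame(dec) && nrow(dec))
        paste(dec$type, dec$surface, sep = "\r") else character()
      gk <- gold_ner_key(gold[[i]])
      hit <- multiset_overlap(pk, gk)
      tp <- tp + hit
      fp <- fp + length(pk) - hit
      fn <- fn + length(gk) - hit
    }
  } else {
    positive <- setdiff(task$label_set, task$negative_labels)
    for (i in seq_along(predictions)) {
      p <- predictions[[i]]$decoded
      g <- gold[[i]]$label
      p_pos <- !is.na(p) && p %in% positive
      g_pos <- g %in% positive
      if (p_pos && g_pos && identical(p, g)) {
        tp <- tp + 1L
      } else {
        if (p_pos) fp <- fp + 1L
        if (g_pos) fn <- fn + 1L
      }
    }
  }
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall /
    (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       counts = list(tp = tp, fp = fp, fn = fn, n = length(predictions)))
}

#' Exact-match accuracy
#'
#' Fraction of query items whose decoded label equals the gold label;
#' unparseable predictions count as wrong.
#'
#' @inheritParams micro_f1
#' @return List with \code{accuracy} and \code{counts}.
#' @export
accuracy_score <- function(predictions, gold) {
  pred_ids <- vapply(predictions, `[[`, "", "example_id")
  gold_ids <- vapply(gold, `[[`, "", "id")
  if (!identical(sort(pred_ids), sort(gold_ids)))
    stop_letex("prediction and gold example ids do not match")
  gold <- gold[match(pred_ids, gold_ids)]
  correct <- vapply(seq_along(predictions), function(i) {
    p <- predictions[[i]]$decoded
    !is.na(p) && identical(p, gold[[i]]$label)
  }, NA)
  list(accuracy = mean(correct),
       counts = list(correct = sum(correct), n = length(correct)))
}

#' Evaluate a trained backbone on a query set
#'
#' Runs \code{\link{predict_query}} and computes the task's headline metric:
#' micro-averaged F1 for ner and re, accuracy for nli. Per-example
#' predictions (including the generated explanations) and the parseable
#' fraction are kept in the report for case-study inspection.
#'
#' @param backbone Trained backbone.
#' @param query Query examples.
#' @param task The task.
#' @return List of class \code{letex_eval_report}.
#' @export
evaluate_task <- function(backbone, query, task) {
  preds <- predict_query(backbone, query, task)
  metrics <- if (task$kind == "nli") {
    accuracy_score(preds, query)
  } else {
    micro_f1(preds, query, task)
  }
  parseable <- mean(vapply(preds, prediction_parseable, NA, task = task))
  structure(
    list(task = task$name, kind = task$kind, metrics = metrics,
         parseable_rate = parseable, predictions = preds),
    class = "letex_eval_report"
  )
}

#' @export
print.letex_eval_report <- function(x, ...) {
  if (x$kind == "nli") {
    cat(sprintf("<letex_eval_report> %s: accuracy = %.3f (n = %d)\n",
                x$task, x$metrics$accuracy, x$metrics$counts$n))
  } else {
    cat(sprintf(
      "<letex_eval_report> %s: P = %.3f R = %.3f F1 = %.3f (tp %d fp %d fn %d)\n",
      x$task, x$metrics$precision, x$metrics$recall, x$metrics$f1,
      x$metrics$counts$tp, x$metrics$counts$fp, x$metrics$counts$fn))
  }
  cat(sprintf("  parseable label generations: %.1f%%\n",
              100 * x$parseable_rate))
  invisible(x)
}

#' Format predictions as a markdown case study
#'
#' Renders text / generated explanation / predicted label rows for a handful
#' of query items, the layout used for qualitative error analysis.
#'
#' @param report A \code{letex_eval_report}.
#' @param query The query examples the report was computed on.
#' @param n Number of cases.
#' @return A character scalar of markdown.
#' @export
format_case_study <- function(report, query, n = 3) {
  ids <- vapply(query, `[[`, "", "id")
  take <- utils::head(seq_along(report$predictions), n)
  blocks <- vapply(take, function(i) {
    p <- report$predictions[[i]]
    ex <- query[[match(p$example_id, ids)]]
    lab <- if (is.data.frame(p$decoded)) {
      if (nrow(p$decoded))
        paste(sprintf("%s[%s]", p$decoded$surface, p$decoded$type),
              collapse = ", ") else "(no entities)"
    } else p$decoded
    paste0("**Text**: ", example_text(ex), "\n\n",
           "**Explanation**: ", p$generated_explanation_text, "\n\n",
           "**Prediction**: ", lab, "\n")
  }, "")
  paste(blocks, collapse = "\n---\n\n")
}
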