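#' Construct a labeled example
#'
#' One training or test item. The payload depends on the task kind:
#' ner examples carry typed character spans over \code{text}; re examples
#' carry a sentence with an entity pair plus a relation \code{label}; nli
#' examples carry a premise/hypothesis pair plus a \code{label}.
#'
#' Span offsets are 0-based, half-open character offsets into \code{text},
#' and each span's \code{surface} must equal the corresponding substring.
#'
#' @param id Unique example id.
#' @param task Task name (matching a \code{letex_task$name}).
#' @param text Sentence string (ner/re). May be empty for nli.
#' @param label Gold label (re/nli). Unused for ner, where span types carry
#'   the class information.
#' @param spans ner only: data.frame with columns \code{start}, \code{end},
#'   \code{type}, \code{surface}.
#' @param premise,hypothesis nli only.
#' @return An object of class \code{letex_example}.
#' @export
labeled_example <- function(id, task, text = "", label = NA_character_,
                            spans = NULL, premise = NULL, hypothesis = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_letex("example id must be a non-empty string")
  if (!is.null(spans)) {
    spans <- as.data.frame(spans, stringsAsFactors = FALSE)
    needed <- c("start", "end", "type", "surface")
    if (!all(needed %in% names(spans)))
      stop_letex("spans for example '%s' need columns %s", id,
                 paste(needed, collapse = ", "))
    spans <- spans[, needed]
  }
  structure(
    list(id = id, task = task, text = text, label = label, spans = spans,
         premise = premise, hypothesis = hypothesis),
    class = "letex_example"
  )
}

# Marker tokens reserved by the ner serialization for a task.
marker_tokens <- function(task) {
  if (task$kind != "ner") return(character())
  c(paste0(task$entity_types, "*"), paste0("*", task$entity_types))
}

#' Validate an example against its task
#'
#' Checks every structural invariant: span/surface agreement, span ordering
#' and non-overlap, label membership, and the marker-collision rule (raw ner
#' text must not already contain a reserved marker token, since silent
#' escaping would break codec round-trips).
#'
#' @param ex A \code{letex_example}.
#' @param task The matching \code{letex_task}.
#' @return \code{ex}, invisibly, or an error naming the example.
#' @export
validate_example <- function(ex, task) {
  if (!identical(ex$task, task$name))
    stop_letex("example '%s' belongs to task '%s', not '%s'",
               ex$id, ex$task, task$name)
  if (task$kind == "ner") {
    if (is.null(ex$spans)) stop_letex("ner example '%s' lacks spans", ex$id)
    sp <- ex$spans
    if (nrow(sp)) {
      if (is.unsorted(sp$start, strictly = TRUE) && nrow(sp) > 1L)
        stop_letex("spans of example '%s' are not sorted by start", ex$id)
      if (any(sp$end <= sp$start))
        stop_letex("example '%s' has an empty or inverted span", ex$id)
      if (nrow(sp) > 1L && any(sp$start[-1L] < sp$end[-nrow(sp)]))
        stop_letex("example '%s' has overlapping spans", ex$id)
      if (any(sp$end > nchar(ex$text)))
        stop_letex("example '%s' has a span beyond the text end", ex$id)
      got <- substring(ex$text, sp$start + 1L, sp$end)
      if (!identical(got, sp$surface))
        stop_letex("example '%s': span surface does not match text[start:end]",
                   ex$id)
      if (!all(sp$type %in% task$entity_types))
        stop_letex("example '%s' uses unknown entity type(s): %s", ex$id,
                   paste(setdiff(sp$type, task$entity_types), collapse = ", "))
    }
    clash <- intersect(ws_tokens(ex$text), marker_tokens(task))
    if (length(clash))
      stop_letex("example '%s' text contains reserved marker token '%s'",
                 ex$id, clash[1L])
  } else {
    if (is.na(ex$label) || !(ex$label %in% task$label_set))
      stop_letex("example '%s' has label '%s' outside the task label set",
                 ex$id, ex$label)
    if (task$kind == "nli") {
      if (is.null(ex$premise) || is.null(ex$hypothesis))
        stop_letex("nli example '%s' needs premise and hypothesis", ex$id)
    }
  }
  invisible(ex)
}

#' The plain-text form of an example
#'
#' Returns the sentence for ner/re examples and the packed
#' \code{"premise: <p> hypothesis: <h>"} sequence for nli examples. This is
#' the single textual view used by the prompt builder, the demonstration
#' embedder, and the entailment premise during filtering.
#'
#' @param ex A \code{letex_example}.
#' @return A string.
#' @export
example_text <- function(ex) {
  if (!is.null(ex$premise))
    paste0("premise: ", ex$premise, " hypothesis: ", ex$hypothesis)
  else ex$text
}

#' Gold assertion label of an example
#'
#' The single label a reasoning explanation is expected to assert in its
#' closing sentence. For re/nli this is the gold label; for ner, where a
#' sentence has no single label, it is the type of the first span, or
#' \code{"none"} for sentences without entities.
#'
#' @param ex A \code{letex_example}.
#' @param task The matching task.
#' @return A label string from \code{task$label_set}.
#' @export
gold_assertion_label <- function(ex, task) {
  if (task$kind != "ner") return(ex$label)
  if (!is.null(ex$spans) && nrow(ex$spans)) ex$spans$type[1L] else "none"
}

#' Attach a reasoning explanation to an example
#'
#' @param example_id Id of the example the explanation belongs to.
#' @param text Explanation string; by convention it ends with the assertion
#'   sentence \code{"So the label is <label>."}.
#' @param asserted_label Label named by the final assertion, or NA.
#' @param source One of \code{"manual"}, \code{"llm"}, \code{"mock"}.
#' @return An object of class \code{letex_explanation}.
#' @export
explanation <- function(example_id, text,
                        asserted_label = NA_character_,
                        source = c("manual", "llm", "mock")) {
  source <- match.arg(source)
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop_letex("explanation text for '%s' must be non-empty", example_id)
  structure(
    list(example_id = example_id, text = text,
         asserted_label = asserted_label, source = source),
    class = "letex_explanation"
  )
}

example_from_json <- function(obj, task, line = NA_integer_) {
  spans <- NULL
  if (task$kind == "ner") {
    rows <- obj$spans %||% list()
    spans <- data.frame(
      start = vapply(rows, function(s) as.integer(s$start), 0L),
      end = vapply(rows, function(s) as.integer(s$end), 0L),
      type = vapply(rows, function(s) as.character(s$type), ""),
      surface = vapply(rows, function(s) as.character(s$surface), ""),
      stringsAsFactors = FALSE
    )
  }
  labeled_example(
    id = as.character(obj$id), task = as.character(obj$task),
    text = as.character(obj$text %||% ""),
    label = as.character(obj$label %||% NA_character_),
    spans = spans,
    premise = obj$premise, hypothesis = obj$hypothesis
  )
}

#' Read a JSONL corpus
#'
#' One JSON object per line; common fields \code{id}, \code{task},
#' \code{text}; ner lines add \code{spans}, re lines \code{label}, nli lines
#' \code{premise}, \code{hypothesis}, \code{label}. Every example is
#' validated on load; malformed JSON is reported with its line number and
#' invariant violations with the offending example id.
#'
#' @param path Path to a UTF-8 JSONL file.
#' @param task The \code{letex_task} the file belongs to.
#' @return List of validated \code{letex_example} objects.
#' @export
read_jsonl <- function(path, task) {
  if (!file.exists(path)) stop_letex("no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  out <- vector("list", length(lines))
  kept <- 0L
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]]))) next
    obj <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e)
        stop_letex("%s line %d: malformed JSON (%s)", path, i,
                   conditionMessage(e))
    )
    ex <- example_from_json(obj, task, line = i)
    validate_example(ex, task)
    kept <- kept + 1L
    out[[kept]] <- ex
  }
  out[seq_len(kept)]
}

example_to_json <- function(ex, task) {
  out <- list(id = ex$id, task = ex$task, text = ex$text)
  if (task$kind == "ner") {
    out$spans <- lapply(seq_len(nrow(ex$spans)), function(i)
      as.list(ex$spans[i, c("start", "end", "type", "surface")]))
  } else if (task$kind == "re") {
    out$label <- ex$label
  } else {
    out$premise <- ex$premise
    out$hypothesis <- ex$hypothesis
    out$label <- ex$label
  }
  out
}

#' Write a JSONL corpus
#'
#' @param examples List of \code{letex_example} objects (one task).
#' @param task Their task.
#' @param path Output file path.
#' @export
write_jsonl <- function(examples, task, path) {
  lines <- vapply(examples, function(ex)
    jsonlite::toJSON(example_to_json(ex, task), auto_unbox = TRUE), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write explanations as JSONL
#'
#' @param path File path.
#' @return A named list of \code{letex_explanation} keyed by example id.
#' @export
read_explanations_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    obj <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    explanation(obj$example_id, obj$text,
                asserted_label = obj$asserted_label %||% NA_character_,
                source = obj$source %||% "manual")
  })
  names(out) <- vapply(out, `[[`, "", "example_id")
  out
}

#' @rdname read_explanations_jsonl
#' @param explanations Named list of \code{letex_explanation}.
#' @export
write_explanations_jsonl <- function(explanations, path) {
  lines <- vapply(unname(explanations), function(e) {
    obj <- list(example_id = e$example_id, text = e$text, source = e$source)
    if (!is.na(e$asserted_label)) obj$asserted_label <- e$asserted_label
    jsonlite::toJSON(obj, auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
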