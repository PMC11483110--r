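#' Define a task
#'
#' A task couples a short name (used verbatim as the text-to-text task
#' prefix), a task kind, and the closed category set the task predicts over.
#' For named-entity recognition the categories are entity types; sentences
#' without any entity are verbalized with the reserved class \code{"none"},
#' which therefore also belongs to \code{label_set}.
#'
#' @param name Short identifier, used as the task prefix. Must not contain
#'   \code{":"}.
#' @param kind One of \code{"ner"}, \code{"re"}, \code{"nli"}.
#' @param label_set Ordered character vector of label strings (the category
#'   set C). Non-empty, duplicate-free.
#' @param entity_types Character vector of entity type identifiers (ner only).
#'   Types must be lowercase identifiers without whitespace because they are
#'   spliced into the inline span markers \code{"type*"} / \code{"*type"}.
#' @param negative_labels Labels (re only) treated as the negative
#'   "no relation" class and excluded from micro-F1 pooling by default.
#' @return An object of class \code{letex_task}.
#' @export
task_spec <- function(name, kind = c("ner", "re", "nli"), label_set,
                      entity_types = character(), negative_labels = character()) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_letex("task name must be a non-empty string")
  if (grepl(":", name, fixed = TRUE))
    stop_letex("task name '%s' must not contain ':'", name)
  if (!is.character(label_set) || length(label_set) == 0L)
    stop_letex("label_set must be a non-empty character vector")
  if (anyDuplicated(label_set))
    stop_letex("label_set contains duplicates")
  if (kind == "ner") {
    if (length(entity_types) == 0L)
      stop_letex("ner task '%s' requires non-empty entity_types", name)
    bad <- entity_types[!grepl("^[a-z][a-z0-9_]*$", entity_types)]
    if (length(bad))
      stop_letex("entity types must be lowercase identifiers, got: %s",
                 paste(bad, collapse = ", "))
  }
  if (length(negative_labels) && !all(negative_labels %in% label_set))
    stop_letex("negative_labels must be a subset of label_set")
  structure(
    list(name = name, kind = kind, label_set = label_set,
         entity_types = entity_types, negative_labels = negative_labels),
    class = "letex_task"
  )
}

#' @export
print.letex_task <- function(x, ...) {
  cat(sprintf("<letex_task> %s (%s): %s\n", x$name, x$kind,
              paste(x$label_set, collapse = ", ")))
  if (x$kind == "ner")
    cat("  entity types:", paste(x$entity_types, collapse = ", "), "\n")
  invisible(x)
}

#' Classes counted when building N-way K-shot support sets
#'
#' For re/nli tasks these are the labels; for ner tasks they are the entity
#' types (a sentence contributes one class instance per typed span).
#'
#' @param task A \code{letex_task}.
#' @return Character vector of class names.
#' @export
task_classes <- function(task) {
  if (task$kind == "ner") task$entity_types else task$label_set
}

#' Read / write a task registry
#'
#' The registry is a JSON array of task objects with fields \code{name},
#' \code{kind}, \code{label_set} and optionally \code{entity_types},
#' \code{negative_labels}.
#'
#' @param path File path of the JSON registry.
#' @return \code{read_task_registry}: a named list of \code{letex_task}
#'   objects keyed by task name.
#' @export
read_task_registry <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tasks <- lapply(raw, function(t) {
    task_spec(name = t$name, kind = t$kind,
              label_set = unlist(t$label_set),
              entity_types = unlist(t$entity_types %||% list()),
              negative_labels = unlist(t$negative_labels %||% list()))
  })
  names(tasks) <- vapply(tasks, `[[`, "", "name")
  tasks
}

#' @rdname read_task_registry
#' @param tasks Named list of \code{letex_task} objects.
#' @export
write_task_registry <- function(tasks, path) {
  payload <- lapply(unname(tasks), function(t) {
    out <- list(name = t$name, kind = t$kind, label_set = t$label_set)
    if (length(t$entity_types)) out$entity_types <- t$entity_types
    if (length(t$negative_labels)) out$negative_labels <- t$negative_labels
    out
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
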