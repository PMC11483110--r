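#' Encode a model input with its task prefix
#'
#' A single text-to-text model is routed among tasks, and between label and
#' explanation generation, purely by the input prefix: \code{"<name>: "} asks
#' for the label and \code{"explain <name>: "} for the reasoning explanation.
#' The body is the sentence for ner/re and the packed premise/hypothesis
#' sequence for nli.
#'
#' @param ex A \code{letex_example}.
#' @param task Its \code{letex_task}.
#' @param role \code{"label"} or \code{"explain"}.
#' @return The prefixed input string.
#' @export
encode_input <- function(ex, task, role = c("label", "explain")) {
  role <- match.arg(role)
  if (!identical(ex$task, task$name))
    stop_letex("example '%s' does not belong to task '%s'", ex$id, task$name)
  body <- example_text(ex)
  core <- paste0(task$name, ": ", body)
  if (role == "explain") paste0("explain ", core) else core
}

#' Serialize ner spans as an inline-marker target string
#'
#' Each span of type \code{t} with surface \code{s} is rewritten in place as
#' \code{"t* s *t"}; text outside the spans is unchanged. E.g. a disease span
#' over "dihydropyrimidine dehydrogenase deficiency" becomes
#' \code{"disease* dihydropyrimidine dehydrogenase deficiency *disease"}.
#'
#' @param ex A validated ner \code{letex_example}.
#' @param task Its task.
#' @return The target string.
#' @export
encode_ner_target <- function(ex, task) {
  if (task$kind != "ner") stop_letex("encode_ner_target needs a ner task")
  sp <- ex$spans
  if (is.null(sp) || nrow(sp) == 0L) return(ex$text)
  pieces <- character(2L * nrow(sp) + 1L)
  cursor <- 0L
  for (i in seq_len(nrow(sp))) {
    pieces[2L * i - 1L] <- substring(ex$text, cursor + 1L, sp$start[i])
    pieces[2L * i] <- paste0(sp$type[i], "* ", sp$surface[i], " *", sp$type[i])
    cursor <- sp$end[i]
  }
  pieces[2L * nrow(sp) + 1L] <- substring(ex$text, cursor + 1L, nchar(ex$text))
  paste0(pieces, collapse = "")
}

# Strip clause-final punctuation glued to a token before comparing it with a
# closing marker (generation may emit "*disease." at sentence end).
strip_tail_punct <- function(tok) sub("[.,;:!?]+$", "", tok)

#' Decode marked entities from a generated string
#'
#' Total inverse of the inline-marker serialization: scans whitespace tokens
#' left to right, pairs each opening marker \code{"t*"} with the next marker
#' token, and keeps the region only when that token is the matching closer
#' \code{"*t"}. Unbalanced or crossed markers are skipped, so any input —
#' including arbitrary malformed generations — yields a (possibly empty)
#' result and never an error. Character offsets are not recoverable from a
#' generation, so matches are identified by (type, surface, occurrence):
#' \code{occurrence} 0-indexes repeats of the same (type, surface) pair.
#'
#' @param generated Any string.
#' @param task A ner \code{letex_task}; only its \code{entity_types} are
#'   recognized as markers.
#' @return data.frame with columns \code{type}, \code{surface},
#'   \code{occurrence} (0-based), possibly empty.
#' @export
decode_ner <- function(generated, task) {
  empty <- data.frame(type = character(), surface = character(),
                      occurrence = integer(), stringsAsFactors = FALSE)
  if (!is.character(generated) || length(generated) != 1L || is.na(generated))
    return(empty)
  toks <- ws_tokens(generated)
  if (!length(toks)) return(empty)
  openers <- paste0(task$entity_types, "*")
  closers <- paste0("*", task$entity_types)
  classify <- function(tok) {
    io <- match(tok, openers)
    if (!is.na(io)) return(list(role = "open", type = task$entity_types[io]))
    ic <- match(strip_tail_punct(tok), closers)
    if (!is.na(ic)) return(list(role = "close", type = task$entity_types[ic]))
    list(role = "text", type = NA_character_)
  }
  cls <- lapply(toks, classify)
  types <- character()
  surfaces <- character()
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    ci <- cls[[i]]
    if (ci$role == "open") {
      j <- i + 1L
      hit <- NA_integer_
      while (j <= n) {
        cj <- cls[[j]]
        if (cj$role != "text") {
          if (cj$role == "close" && identical(cj$type, ci$type)) hit <- j
          break
        }
        j <- j + 1L
      }
      if (!is.na(hit) && hit > i + 1L) {
        types <- c(types, ci$type)
        surfaces <- c(surfaces, paste(toks[(i + 1L):(hit - 1L)], collapse = " "))
        i <- hit + 1L
      } else {
        i <- i + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  if (!length(types)) return(empty)
  key <- paste(types, surfaces, sep = "\r")
  occurrence <- stats::ave(seq_along(key), key, FUN = seq_along) - 1L
  data.frame(type = types, surface = surfaces,
             occurrence = as.integer(occurrence), stringsAsFactors = FALSE)
}

#' Check whether a generation's markers are well formed
#'
#' TRUE when every marker token in the string participates in a well-formed
#' \code{"t* ... *t"} region — i.e. the string is a possible output of
#' \code{\link{encode_ner_target}} as far as markers are concerned.
#'
#' @inheritParams decode_ner
#' @return Logical.
#' @export
markers_well_formed <- function(generated, task) {
  toks <- ws_tokens(generated)
  if (!length(toks)) return(TRUE)
  openers <- paste0(task$entity_types, "*")
  closers <- paste0("*", task$entity_types)
  open_type <- NA_character_
  since_open <- 0L
  for (tok in toks) {
    io <- match(tok, openers)
    ic <- match(strip_tail_punct(tok), closers)
    if (!is.na(io)) {
      if (!is.na(open_type)) return(FALSE)
      open_type <- task$entity_types[io]
      since_open <- 0L
    } else if (!is.na(ic)) {
      if (is.na(open_type) || !identical(task$entity_types[ic], open_type) ||
          since_open == 0L)
        return(FALSE)
      open_type <- NA_character_
    } else if (!is.na(open_type)) {
      since_open <- since_open + 1L
    }
  }
  is.na(open_type)
}

#' Encode a training target
#'
#' For \code{role = "label"} the target is the inline-marker serialization
#' (ner) or the label verbatim (re/nli). For \code{role = "explain"} the
#' target is \code{"<label> explanation: <explanation text>"}, where the
#' explanation conventionally closes with \code{"So the label is <label>."} —
#' the model is trained to restate the label and then justify it.
#'
#' @inheritParams encode_input
#' @param expl A \code{letex_explanation}; required when
#'   \code{role = "explain"}.
#' @return The target string.
#' @export
encode_target <- function(ex, task, role = c("label", "explain"), expl = NULL) {
  role <- match.arg(role)
  label_part <- if (task$kind == "ner") encode_ner_target(ex, task) else ex$label
  if (role == "label") return(label_part)
  if (is.null(expl))
    stop_letex("role = 'explain' requires an explanation for example '%s'",
               ex$id)
  paste0(label_part, " explanation: ", expl$text)
}

#' Normalize a generated label string
#'
#' Small sequence-to-sequence models emit trailing text; normalization takes
#' the first line, trims whitespace and clause-final punctuation, and matches
#' case-insensitively against the task's label set.
#'
#' @param text Raw generated string.
#' @param label_set Character vector of canonical labels.
#' @return The canonical label, or \code{NA_character_} when nothing matches.
#' @export
normalize_label <- function(text, label_set) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    return(NA_character_)
  first <- strsplit(text, "\n", fixed = TRUE)[[1]][1] %||% ""
  first <- trimws(sub("[.,;:!?]+\\s*$", "", trimws(first)))
  hit <- match(tolower(first), tolower(label_set))
  if (is.na(hit)) NA_character_ else label_set[hit]
}
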