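#' Character trigram embedder
#'
#' Maps a string to a named count vector of lowercase character 3-grams. A
#' deterministic, dependency-light text representation for nearest-neighbour
#' demonstration selection; dense sentence encoders can be plugged in behind
#' the same \code{function(text) -> named numeric} contract.
#'
#' @param n N-gram order (default 3).
#' @return An embedder function.
#' @export
trigram_embedder <- function(n = 3L) {
  function(text) {
    text <- tolower(text)
    if (nchar(text) < n) return(stats::setNames(1, text))
    grams <- substring(text, seq_len(nchar(text) - n + 1L),
                       seq_len(nchar(text) - n + 1L) + n - 1L)
    tab <- table(grams)
    stats::setNames(as.numeric(tab), names(tab))
  }
}

cosine_named <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (!length(shared)) return(0)
  num <- sum(a[shared] * b[shared])
  num / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

#' Build the candidate demonstration pool
#'
#' Draws \code{n_demos} examples uniformly without replacement and pairs each
#' with its manually crafted explanation; these (x, r, y) triples are the
#' in-context demonstrations for explanation collection.
#'
#' @param dataset List of \code{letex_example} for one task.
#' @param manual_explanations Named list of \code{letex_explanation} keyed by
#'   example id (source \code{"manual"}).
#' @param task The task.
#' @param n_demos Pool size (e.g. 20).
#' @param seed Integer seed.
#' @return List of demonstrations, each \code{list(example, explanation,
#'   label)}.
#' @export
build_demo_pool <- function(dataset, manual_explanations, task,
                            n_demos = 20, seed = 1) {
  if (!is_count(n_demos) || n_demos > length(dataset))
    stop_letex("n_demos must be a count <= dataset size (%d)", length(dataset))
  idx <- with_seed(derive_seed(seed, 7L),
                   sample.int(length(dataset), n_demos))
  lapply(idx, function(i) {
    ex <- dataset[[i]]
    expl <- manual_explanations[[ex$id]]
    if (is.null(expl))
      stop_letex("no manual explanation for example '%s'", ex$id)
    label <- gold_assertion_label(ex, task)
    if (!identical(expl$asserted_label, label))
      stop_letex("manual explanation for '%s' asserts '%s', expected '%s'",
                 ex$id, expl$asserted_label, label)
    list(example = ex, explanation = expl, label = label)
  })
}

#' Select the nearest demonstration for a query
#'
#' Returns the pool demonstration maximizing cosine similarity between the
#' embedded query text and the embedded demonstration text (k = 1 nearest
#' neighbour); ties are broken by lowest pool index.
#'
#' @param x Query \code{letex_example}.
#' @param pool Demonstration pool from \code{\link{build_demo_pool}}.
#' @param embedder Embedder function (default \code{trigram_embedder()}).
#' @return The selected demonstration.
#' @export
knn_select <- function(x, pool, embedder = trigram_embedder()) {
  if (!length(pool)) stop_letex("demonstration pool is empty")
  qv <- embedder(example_text(x))
  sims <- vapply(pool, function(d)
    cosine_named(qv, embedder(example_text(d$example))), 0)
  pool[[which.max(sims)]]
}

default_instructions <- function() {
  list(
    ner = paste("Mark every entity in the sentence with its type and explain",
                "step by step why the marked mentions are entities."),
    re = paste("Decide the relation between the entity pair in the sentence",
               "and explain step by step how the wording supports it."),
    nli = paste("Decide whether the hypothesis is entailed by, contradicts,",
                "or is neutral to the premise, and explain step by step.")
  )
}

#' Load a chain-of-thought prompt template
#'
#' Templates live in a JSON config (not in code) so wording can be revised
#' without a package change. The file holds a \code{template} string with
#' placeholders \code{{instruction}}, \code{{demo_text}}, \code{{demo_label}},
#' \code{{demo_explanation}}, \code{{query_text}}, \code{{query_label}}, and
#' an \code{instructions} object with one entry per task kind.
#'
#' @param path Path to a template JSON; default is the template shipped with
#'   the package.
#' @return List with \code{template} and \code{instructions}.
#' @export
load_prompt_template <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("prompts", "cot_default.json", package = "letex")
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

fill_template <- function(template, values) {
  for (key in names(values)) {
    template <- gsub(paste0("{", key, "}"), values[[key]], template,
                     fixed = TRUE)
  }
  template
}

#' Assemble a chain-of-thought prompt
#'
#' The prompt shows, in order: a task instruction; the demonstration's text,
#' label, and reasoning explanation; then the query's text and gold label,
#' ending with an open \code{"Explanation:"} cue. Conditioning on both the
#' query text and its gold label steers the model toward explanations
#' consistent with the annotation. For ner the label slot holds the
#' marker-serialized target string.
#'
#' @param demo A demonstration.
#' @param x Query example.
#' @param y Query label slot (label string, or serialized ner target); if
#'   \code{NULL}, computed from the gold annotation.
#' @param task The task.
#' @param template Result of \code{\link{load_prompt_template}}.
#' @return The prompt string.
#' @export
build_cot_prompt <- function(demo, x, y = NULL, task,
                             template = load_prompt_template()) {
  label_slot <- function(ex)
    if (task$kind == "ner") encode_ner_target(ex, task) else ex$label
  if (is.null(y)) y <- label_slot(x)
  instr <- template$instructions[[task$kind]] %||%
    default_instructions()[[task$kind]]
  fill_template(template$template, list(
    instruction = instr,
    demo_text = example_text(demo$example),
    demo_label = label_slot(demo$example),
    demo_explanation = demo$explanation$text,
    query_text = example_text(x),
    query_label = y
  ))
}

#' Collect reasoning explanations for a dataset
#'
#' For every example: select the nearest demonstration, assemble the
#' chain-of-thought prompt, query the client, and parse the asserted label
#' from the response. Client failures are retried up to \code{retries} times
#' and then recorded in a skip list — a failing example never aborts the
#' batch, and output size plus skip-list size always equals input size.
#'
#' @param dataset List of examples for one task.
#' @param pool Demonstration pool.
#' @param client An \code{letex_llm_client}.
#' @param task The task.
#' @param embedder Embedder for demonstration selection.
#' @param template Prompt template.
#' @param retries Retries per example after the first failure.
#' @return List with \code{results} (list of \code{list(example,
#'   explanation)}), \code{skipped} (ids with their last error message),
#'   \code{log} (data.frame of example id, prompt, response), and, for mock
#'   clients, \code{planted} (ids of planted-wrong explanations).
#' @export
collect_explanations <- function(dataset, pool, client, task,
                                 embedder = trigram_embedder(),
                                 template = load_prompt_template(),
                                 retries = 2) {
  src <- if (identical(client$name, "mock")) "mock" else "llm"
  results <- list()
  skipped <- list()
  planted <- character()
  log_id <- character()
  log_prompt <- character()
  log_response <- character()
  for (ex in dataset) {
    demo <- knn_select(ex, pool, embedder)
    prompt <- build_cot_prompt(demo, ex, y = NULL, task = task,
                               template = template)
    response <- NULL
    last_err <- NULL
    for (attempt in seq_len(retries + 1L)) {
      response <- tryCatch(client$generate(prompt), error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      })
      if (!is.null(response)) break
    }
    if (is.null(response)) {
      skipped[[ex$id]] <- last_err %||% "unknown client failure"
      next
    }
    pre_calls <- if (src == "mock") client$state$calls else NA_integer_
    asserted <- extract_asserted_label(response, task$label_set)
    results[[length(results) + 1L]] <- list(
      example = ex,
      explanation = explanation(ex$id, response, asserted_label = asserted,
                                source = src)
    )
    if (src == "mock" && pre_calls %in% client$state$planted)
      planted <- c(planted, ex$id)
    log_id <- c(log_id, ex$id)
    log_prompt <- c(log_prompt, prompt)
    log_response <- c(log_response, response)
  }
  list(
    results = results,
    skipped = skipped,
    planted = planted,
    log = data.frame(example_id = log_id, prompt = log_prompt,
                     response = log_response, stringsAsFactors = FALSE)
  )
}
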