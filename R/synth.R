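#' Default synthetic task registry
#'
#' Three tasks emulating the structure of common biomedical benchmarks:
#' disease/gene entity recognition, a four-way drug-gene relation task with a
#' negative "none" class, and three-way clinical sentence-pair inference.
#'
#' @return Named list of \code{letex_task} objects.
#' @export
synth_tasks <- function() {
  tasks <- list(
    task_spec("synthner", "ner",
              label_set = c("disease", "gene", "none"),
              entity_types = c("disease", "gene")),
    task_spec("synthre", "re",
              label_set = c("treats", "causes", "interacts", "none"),
              negative_labels = "none"),
    task_spec("synthnli", "nli",
              label_set = c("entailment", "contradiction", "neutral"))
  )
  names(tasks) <- vapply(tasks, `[[`, "", "name")
  tasks
}

#' Configuration for the synthetic corpus generator
#'
#' @param n_per_task Examples generated per task.
#' @param tasks Named list of \code{letex_task} (default \code{synth_tasks()}).
#' @param vocab_size Number of distinct filler words; must be large enough to
#'   keep entity mentions non-overlapping (>= 20).
#' @param hallucination_rate Probability that the mock LLM asserts a wrong
#'   label, in [0, 1].
#' @param seed Master integer seed; a fixed seed yields a byte-identical
#'   corpus.
#' @return An object of class \code{letex_synth_config}.
#' @export
synth_config <- function(n_per_task = 50, tasks = synth_tasks(),
                         vocab_size = 60, hallucination_rate = 0, seed = 1) {
  if (!is_count(n_per_task)) stop_letex("n_per_task must be a count >= 1")
  if (!is_prob(hallucination_rate))
    stop_letex("hallucination_rate must be in [0, 1]")
  if (!is_count(vocab_size) || vocab_size < 20)
    stop_letex("vocab too small to honor span non-overlap (need >= 20)")
  structure(
    list(n_per_task = n_per_task, tasks = tasks, vocab_size = vocab_size,
         hallucination_rate = hallucination_rate, seed = as.integer(seed)),
    class = "letex_synth_config"
  )
}

# Pronounceable pseudo-words, deterministic in the RNG state.
make_words <- function(n, min_syl = 2, max_syl = 3, suffix = "") {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  vapply(seq_len(n), function(i) {
    k <- sample(min_syl:max_syl, 1L)
    paste0(paste0(sample(cons, k, replace = TRUE),
                  sample(vow, k, replace = TRUE), collapse = ""), suffix)
  }, "")
}

synth_lexicons <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 1L), {
    fillers <- unique(make_words(cfg$vocab_size * 2L))[seq_len(cfg$vocab_size)]
    disease <- unique(paste0(make_words(40), sample(c("itis", "oma", "osis"),
                                                    40, replace = TRUE)))
    gene <- unique(paste0(make_words(40, 1, 2),
                          sample(1:9, 40, replace = TRUE)))
    drugs <- unique(paste0(make_words(30), "ib"))
    list(fillers = fillers, disease = disease, gene = gene, drugs = drugs)
  })
}

# -- gold explanation templates ----------------------------------------------
# 2-4 sentences naming the decisive evidence and closing with the assertion
# sentence; the closing form is what extract_asserted_label parses.

assertion_sentence <- function(label) paste0("So the label is ", label, ".")

gold_explanation_text <- function(kind, info, label) {
  middle <- switch(kind,
    ner = if (identical(label, "none"))
      c("The sentence only describes the study setting.",
        "No disease or gene mention appears in it.")
    else
      c(sprintf("The sentence mentions %s.", info$first_surface),
        sprintf("This mention names a specific %s entity.", label)),
    re = c(sprintf("The sentence mentions %s and %s.", info$e1, info$e2),
           sprintf("The phrase '%s' links the two mentions directly.",
                   info$cue)),
    nli = c("The premise describes the patient's condition.",
            sprintf("The hypothesis %s.", info$rel))
  )
  extra <- "The remaining context adds no further evidence."
  body <- c(middle, "This pattern follows the annotation guideline.",
            if (info$long) extra, assertion_sentence(label))
  paste(body, collapse = " ")
}

make_ner_example <- function(i, task, lex) {
  n_spans <- sample(0:3, 1L, prob = c(0.2, 0.4, 0.3, 0.1))
  toks <- sample(lex$fillers, sample(3:5, 1L), replace = TRUE)
  ent_tok <- integer(0)
  types <- character(0)
  ents <- character(0)
  if (n_spans > 0L) {
    types <- sample(task$entity_types, n_spans, replace = TRUE)
    ents <- character(n_spans)
    for (k in seq_len(n_spans)) {
      pool <- setdiff(lex[[types[k]]], ents)
      surf <- pool[sample.int(length(pool), 1L)]
      # some disease mentions are multi-token, exercising multiword decoding
      if (types[k] == "disease" && stats::runif(1) < 0.3)
        surf <- paste(surf, "syndrome")
      ents[k] <- surf
      toks <- c(toks, surf)
      ent_tok <- c(ent_tok, length(toks))
      toks <- c(toks, sample(lex$fillers, sample(1:3, 1L), replace = TRUE))
    }
  }
  toks <- c(toks, ".")
  text <- paste(toks, collapse = " ")
  # char offset of each token in the single-space joined sentence
  offs <- cumsum(c(0L, nchar(toks) + 1L))
  if (n_spans > 0L) {
    starts <- offs[ent_tok]
    spans <- data.frame(start = starts, end = starts + nchar(ents),
                        type = types, surface = ents,
                        stringsAsFactors = FALSE)
    ord <- order(spans$start)
    spans <- spans[ord, ]
  } else {
    spans <- data.frame(start = integer(), end = integer(),
                        type = character(), surface = character(),
                        stringsAsFactors = FALSE)
  }
  ex <- labeled_example(sprintf("%s-%04d", task$name, i), task$name,
                        text = text, spans = spans)
  label <- gold_assertion_label(ex, task)
  info <- list(first_surface = if (nrow(spans)) spans$surface[1L] else "",
               long = runif(1) < 0.5)
  list(example = ex, label = label, info = info)
}

re_templates <- function() {
  # relation label is a deterministic function of the template id
  list(
    list(cue = "treats", label = "treats"),
    list(cue = "is used to treat", label = "treats"),
    list(cue = "causes", label = "causes"),
    list(cue = "induces", label = "causes"),
    list(cue = "interacts with", label = "interacts"),
    list(cue = "binds to", label = "interacts"),
    list(cue = "was mentioned alongside", label = "none"),
    list(cue = "appears in the same report as", label = "none")
  )
}

make_re_example <- function(i, task, lex) {
  tpl <- re_templates()[[sample(seq_along(re_templates()), 1L)]]
  e1 <- sample(lex$drugs, 1L)
  e2 <- sample(c(lex$disease, lex$gene), 1L)
  ctx <- paste(sample(lex$fillers, sample(1:3, 1L), replace = TRUE),
               collapse = " ")
  text <- sprintf("The drug %s %s %s in %s patients .", e1, tpl$cue, e2, ctx)
  ex <- labeled_example(sprintf("%s-%04d", task$name, i), task$name,
                        text = text, label = tpl$label)
  info <- list(e1 = e1, e2 = e2, cue = tpl$cue, long = runif(1) < 0.5)
  list(example = ex, label = tpl$label, info = info)
}

make_nli_example <- function(i, task, lex) {
  label <- sample(task$label_set, 1L)
  cond <- sample(lex$disease, 1L)
  drug <- sample(lex$drugs, 1L)
  premise <- sprintf("The patient has %s and received %s .", cond, drug)
  hyp <- switch(label,
    entailment = sprintf("The patient has %s .", cond),
    contradiction = sprintf("The patient does not have %s .", cond),
    neutral = sprintf("The patient will tolerate %s well .",
                      sample(lex$drugs, 1L))
  )
  rel <- switch(label,
    entailment = "restates a condition already stated in the premise",
    contradiction = "denies a condition stated in the premise",
    neutral = "adds information the premise neither supports nor denies"
  )
  ex <- labeled_example(sprintf("%s-%04d", task$name, i), task$name,
                        label = label, premise = premise, hypothesis = hyp)
  info <- list(rel = rel, long = runif(1) < 0.5)
  list(example = ex, label = label, info = info)
}

#' Generate a synthetic multi-task corpus with gold explanations
#'
#' Emulates the structure of few-shot biomedical benchmarks without any real
#' data: short sentences over a closed pseudo-word vocabulary, 0-3
#' non-overlapping typed spans per ner sentence drawn from type-specific
#' lexicons, relation sentences whose label is a deterministic function of a
#' cue template, and nli pairs built per label by entailment-preserving or
#' contradicting edits of the premise. Every example gets one templated gold
#' explanation ending with \code{"So the label is <label>."}.
#'
#' @param cfg A \code{\link{synth_config}}.
#' @return List with elements \code{examples} (named list per task of
#'   \code{letex_example} lists), \code{explanations} (named list of gold
#'   \code{letex_explanation} keyed by example id, source \code{"manual"}),
#'   and \code{tasks}.
#' @export
make_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "letex_synth_config"))
  lex <- synth_lexicons(cfg)
  examples <- list()
  explanations <- list()
  for (t_idx in seq_along(cfg$tasks)) {
    task <- cfg$tasks[[t_idx]]
    maker <- switch(task$kind, ner = make_ner_example, re = make_re_example,
                    nli = make_nli_example)
    items <- with_seed(derive_seed(cfg$seed, 100L + t_idx), {
      lapply(seq_len(cfg$n_per_task), function(i) maker(i, task, lex))
    })
    exs <- lapply(items, `[[`, "example")
    for (ex in exs) validate_example(ex, task)
    examples[[task$name]] <- exs
    for (it in items) {
      expl <- explanation(
        it$example$id,
        gold_explanation_text(task$kind, it$info, it$label),
        asserted_label = it$label, source = "manual"
      )
      explanations[[it$example$id]] <- expl
    }
  }
  list(examples = examples, explanations = explanations, tasks = cfg$tasks)
}

# -- mock LLM -----------------------------------------------------------------

# Faithful mock explanations imitate the in-context demonstration, as real
# few-shot generations do: the demonstration's reasoning is echoed with the
# assertion sentence rewritten to the target label. Hallucinated ones use a
# visibly different template (the token "curiously" appears only there),
# giving the entailment discriminator a learnable surface signal.
mock_explanation_text <- function(label, wrong, demo_text = NULL) {
  if (wrong) {
    paste0("Curiously, the surface pattern here is atypical for this corpus. ",
           "The mention context points elsewhere. ",
           assertion_sentence(label))
  } else if (!is.null(demo_text)) {
    body <- trimws(sub("So the label is[^.]*\\.\\s*$", "", demo_text))
    paste(body, assertion_sentence(label))
  } else {
    paste0("The sentence states the decisive evidence for this class ",
           "directly. This pattern follows the annotation guideline. ",
           assertion_sentence(label))
  }
}

#' Deterministic mock language model for explanation generation
#'
#' A test double for the explanation-collecting LLM: with probability
#' \code{1 - rate} it returns a templated explanation asserting
#' \code{gold_label}; with probability \code{rate} it asserts a uniformly
#' drawn wrong label (a planted hallucination). The planted-wrong flag is
#' returned so downstream filtering can be checked against ground truth.
#'
#' @param prompt The full prompt; when it contains a demonstration
#'   explanation (an \code{"Explanation: ..."} line), faithful generations
#'   echo its reasoning.
#' @param gold_label The gold assertion label.
#' @param label_set Full label set (>= 2 labels).
#' @param rate Hallucination probability in [0, 1].
#' @return List with \code{text}, \code{asserted_label},
#'   \code{planted_wrong}. Consumes the current RNG stream; wrap in a seeded
#'   context for determinism.
#' @export
mock_llm <- function(prompt, gold_label, label_set, rate) {
  if (length(label_set) < 2L) stop_letex("mock_llm needs >= 2 labels")
  wrong <- stats::runif(1) < rate
  label <- if (wrong) {
    pool <- setdiff(label_set, gold_label)
    pool[sample.int(length(pool), 1L)]
  } else gold_label
  demo_text <- NULL
  lines <- strsplit(prompt, "\n", fixed = TRUE)[[1]]
  expl_lines <- grep("^Explanation:\\s*\\S", lines, value = TRUE)
  if (length(expl_lines))
    demo_text <- trimws(sub("^Explanation:", "", expl_lines[[1L]]))
  list(text = mock_explanation_text(label, wrong, demo_text),
       asserted_label = label, planted_wrong = wrong)
}

#' Mock LLM client
#'
#' Wraps \code{\link{mock_llm}} behind the generic client contract
#' (\code{generate(prompt) -> string}). The gold label is recovered from the
#' prompt's query \code{"Label:"} line (for ner, the first marker type of the
#' serialized target, or \code{"none"}). Each call uses a fresh child seed of
#' \code{seed}, so a fixed corpus and seed give byte-identical output. The
#' client records every planted hallucination; retrieve them with
#' \code{\link{planted_wrong_ids}} after collection.
#'
#' @param task The \code{letex_task} the client serves.
#' @param rate Hallucination probability.
#' @param seed Integer seed.
#' @return An object of class \code{letex_llm_client}.
#' @export
mock_client <- function(task, rate = 0, seed = 1) {
  state <- new.env(parent = emptyenv())
  state$calls <- 0L
  state$planted <- character()
  parse_prompt_label <- function(prompt) {
    lines <- strsplit(prompt, "\n", fixed = TRUE)[[1]]
    lab_lines <- grep("^Label:", lines, value = TRUE)
    if (!length(lab_lines)) stop_letex("mock client found no Label: line")
    raw <- trimws(sub("^Label:", "", lab_lines[length(lab_lines)]))
    if (task$kind == "ner") {
      dec <- decode_ner(raw, task)
      if (nrow(dec)) dec$type[1L] else "none"
    } else raw
  }
  generate <- function(prompt) {
    state$calls <- state$calls + 1L
    gold <- parse_prompt_label(prompt)
    res <- with_seed(derive_seed(seed, 1000L + state$calls), {
      mock_llm(prompt, gold, task$label_set, rate)
    })
    if (res$planted_wrong)
      state$planted <- c(state$planted, state$calls)
    res$text
  }
  structure(list(name = "mock", generate = generate, state = state),
            class = "letex_llm_client")
}

#' Example ids with planted-wrong explanations
#'
#' @param collection Result of \code{\link{collect_explanations}} run with a
#'   mock client.
#' @return Character vector of example ids whose explanation asserts a
#'   planted wrong label.
#' @export
planted_wrong_ids <- function(collection) {
  collection$planted %||% character()
}

#' Shell-command LLM client
#'
#' Runs a user-supplied executable for every prompt: the prompt is written to
#' the command's stdin and the explanation read from its stdout. This is the
#' integration point for real LLM backends without bundling any API adapter.
#'
#' @param command Path to an executable.
#' @return An object of class \code{letex_llm_client}.
#' @export
command_client <- function(command) {
  generate <- function(prompt) {
    out <- suppressWarnings(system2(command, input = prompt, stdout = TRUE,
                                    stderr = FALSE))
    status <- attr(out, "status") %||% 0L
    if (status != 0L)
      stop_letex("LLM command '%s' exited with status %d", command, status)
    paste(out, collapse = "\n")
  }
  structure(list(name = "command", generate = generate),
            class = "letex_llm_client")
}

#' Write a synthetic corpus to a directory
#'
#' Writes one \code{<task>.jsonl} per task, a \code{gold_explanations.jsonl},
#' and a \code{tasks.json} registry.
#'
#' @param corpus Result of \code{\link{make_corpus}}.
#' @param dir Output directory (created if needed).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (name in names(corpus$examples)) {
    write_jsonl(corpus$examples[[name]], corpus$tasks[[name]],
                file.path(dir, paste0(name, ".jsonl")))
  }
  write_explanations_jsonl(corpus$explanations,
                           file.path(dir, "gold_explanations.jsonl"))
  write_task_registry(corpus$tasks, file.path(dir, "tasks.json"))
  invisible(dir)
}
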