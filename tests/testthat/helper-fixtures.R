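# Small in-code fixtures shared across test files.

toy_ner_task <- function() {
  task_spec("toyner", "ner", label_set = c("disease", "gene", "none"),
            entity_types = c("disease", "gene"))
}

toy_re_task <- function() {
  task_spec("i2b2", "re",
            label_set = c("TrIP", "TrWP", "TrCP", "TrAP", "TrNAP", "TeRP",
                          "TeCP", "PIP", "False"),
            negative_labels = "False")
}

toy_nli_task <- function() {
  task_spec("mednli", "nli",
            label_set = c("entailment", "contradiction", "neutral"))
}

ner_example <- function(id, text, spans) {
  labeled_example(id, "toyner", text = text, spans = spans)
}

# Build a ner example from tokens, marking the given token indices.
ner_from_tokens <- function(id, toks, ent_idx = integer(), types = character(),
                            task_name = "toyner") {
  text <- paste(toks, collapse = " ")
  offs <- cumsum(c(0L, nchar(toks) + 1L))
  spans <- data.frame(start = offs[ent_idx],
                      end = offs[ent_idx] + nchar(toks[ent_idx]),
                      type = types, surface = toks[ent_idx],
                      stringsAsFactors = FALSE)
  spans <- spans[order(spans$start), ]
  labeled_example(id, task_name, text = text, spans = spans)
}

# 12-sentence ner toy with overlapping type coverage, small enough for
# exhaustive minimal-cover search over all subsets
toy_cover_dataset <- function() {
  specs <- list(
    list(ents = c("d1", "d2"), types = c("disease", "disease")),
    list(ents = c("g1"), types = "gene"),
    list(ents = c("d3", "g2"), types = c("disease", "gene")),
    list(ents = character(), types = character()),
    list(ents = c("g3", "g4"), types = c("gene", "gene")),
    list(ents = c("d4"), types = "disease"),
    list(ents = c("d5", "g5"), types = c("disease", "gene")),
    list(ents = c("d6"), types = "disease"),
    list(ents = c("g6"), types = "gene"),
    list(ents = character(), types = character()),
    list(ents = c("d7", "g7"), types = c("disease", "gene")),
    list(ents = c("g8"), types = "gene")
  )
  lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    toks <- c("w", s$ents, "end")
    ner_from_tokens(sprintf("t%02d", i), toks,
                    ent_idx = seq_along(s$ents) + 1L, types = s$types)
  })
}

small_corpus <- function(n = 60, seed = 11, rate = 0.2) {
  make_corpus(synth_config(n_per_task = n, seed = seed,
                           hallucination_rate = rate))
}

# collect mock explanations for one synthetic task
mock_collection <- function(corpus, task_name, rate, seed,
                            n_demos = 10) {
  task <- corpus$tasks[[task_name]]
  dataset <- corpus$examples[[task_name]]
  pool <- build_demo_pool(dataset, corpus$explanations, task,
                          n_demos = n_demos, seed = seed)
  pool_ids <- vapply(pool, function(d) d$example$id, "")
  rest <- Filter(function(ex) !(ex$id %in% pool_ids), dataset)
  client <- mock_client(task, rate = rate, seed = seed)
  list(pool = pool,
       collection = collect_explanations(rest, pool, client, task),
       task = task)
}
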