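test_that("task specs enforce their invariants", {
  expect_error(task_spec("a:b", "re", "x"), "':'")
  expect_error(task_spec("t", "re", character()), "non-empty")
  expect_error(task_spec("t", "re", c("a", "a")), "duplicates")
  expect_error(task_spec("t", "ner", "x"), "entity_types")
  expect_error(task_spec("t", "ner", "x", entity_types = "Bad Type"),
               "lowercase")
  tasks <- synth_tasks()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_task_registry(tasks, tmp)
  back <- read_task_registry(tmp)
  expect_equal(names(back), names(tasks))
  expect_equal(back$synthre$negative_labels, "none")
  expect_equal(back$synthner$entity_types, c("disease", "gene"))
})

test_that("jsonl round-trips valid corpora and rejects invalid lines", {
  task <- toy_ner_task()
  exs <- list(
    ner_from_tokens("a", c("x", "fluitis", "y"), 2L, "disease"),
    ner_from_tokens("b", c("p", "q"), integer(), character()),
    ner_from_tokens("c", c("brc1", "binds", "flu"), 1L, "gene")
  )
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  write_jsonl(exs, task, tmp)
  back <- read_jsonl(tmp, task)
  expect_length(back, 3L)
  expect_equal(vapply(back, `[[`, "", "id"), c("a", "b", "c"))
  expect_equal(back[[1]]$spans$surface, "fluitis")

  # surface not matching text[start:end] is a validation error naming the id
  bad <- '{"id":"z","task":"toyner","text":"a b","spans":[{"start":0,"end":1,"type":"disease","surface":"b"}]}'
  writeLines(bad, tmp)
  expect_error(read_jsonl(tmp, task), "z")

  writeLines("not json {", tmp)
  expect_error(read_jsonl(tmp, task), "line 1")

  writeLines(character(), tmp)
  expect_length(read_jsonl(tmp, task), 0L)
})

test_that("example validation catches overlaps, bad labels, marker clashes", {
  task <- toy_ner_task()
  overlapping <- labeled_example("o", "toyner", text = "abcdef",
                                 spans = data.frame(start = c(0, 2),
                                                    end = c(4, 6),
                                                    type = "disease",
                                                    surface = c("abcd", "cdef")))
  expect_error(validate_example(overlapping, task), "overlap")
  clash <- ner_from_tokens("m", c("disease*", "x"), integer(), character())
  expect_error(validate_example(clash, task), "marker")
  re_task <- toy_re_task()
  expect_error(
    validate_example(labeled_example("r", "i2b2", text = "t", label = "nope"),
                     re_task),
    "label")
})

test_that("inputs are serialized with task and explain prefixes", {
  re_task <- toy_re_task()
  ex <- labeled_example("r1", "i2b2",
                        text = "Basilar artery stenosis with syndrome.",
                        label = "PIP")
  expect_equal(encode_input(ex, re_task, "label"),
               "i2b2: Basilar artery stenosis with syndrome.")
  expect_equal(encode_input(ex, re_task, "explain"),
               "explain i2b2: Basilar artery stenosis with syndrome.")

  nli <- labeled_example("n1", "mednli", label = "entailment",
                         premise = "A", hypothesis = "B")
  expect_equal(encode_input(nli, toy_nli_task(), "label"),
               "mednli: premise: A hypothesis: B")
})

test_that("ner target serialization matches the inline-marker scheme", {
  task <- toy_ner_task()
  text <- "Genotype and phenotype in patients with dihydropyrimidine dehydrogenase deficiency"
  surf <- "dihydropyrimidine dehydrogenase deficiency"
  st <- regexpr(surf, text, fixed = TRUE)[1] - 1L
  ex <- labeled_example("g", "toyner", text = text,
                        spans = data.frame(start = st,
                                           end = st + nchar(surf),
                                           type = "disease", surface = surf))
  expect_equal(
    encode_ner_target(ex, task),
    "Genotype and phenotype in patients with disease* dihydropyrimidine dehydrogenase deficiency *disease")

  # zero spans: unchanged text
  plain <- ner_from_tokens("p", c("a", "b"), integer(), character())
  expect_equal(encode_ner_target(plain, task), "a b")

  # adjacent spans of one type, against the character-walking oracle
  ab <- labeled_example("ab", "toyner", text = "A B C",
                        spans = data.frame(start = c(0, 4), end = c(1, 5),
                                           type = "gene",
                                           surface = c("A", "C")))
  expect_equal(encode_ner_target(ab, task), "gene* A *gene B gene* C *gene")
  expect_equal(encode_ner_target(ab, task), oracle_encode_ner(ab$text, ab$spans))
})

test_that("ner decoding inverts serialization and tolerates malformed text", {
  task <- toy_ner_task()
  dec <- decode_ner(
    "Genotype and phenotype in patients with disease* dihydropyrimidine dehydrogenase deficiency *disease",
    task)
  expect_equal(dec$type, "disease")
  expect_equal(dec$surface, "dihydropyrimidine dehydrogenase deficiency")
  expect_equal(dec$occurrence, 0L)

  expect_equal(nrow(decode_ner("no markers here", task)), 0L)

  rep2 <- decode_ner("disease* a *disease x disease* a *disease", task)
  expect_equal(rep2$occurrence, c(0L, 1L))

  # dangling and crossed markers are skipped, never an error
  expect_equal(nrow(decode_ner("disease* open forever", task)), 0L)
  crossed <- decode_ner("disease* a gene* b *disease c *gene", task)
  expect_equal(nrow(crossed), 0L)
  # trailing punctuation glued to a closer is tolerated
  glued <- decode_ner("saw disease* flu *disease.", task)
  expect_equal(glued$surface, "flu")
})

test_that("codec round-trip recovers the gold span multiset", {
  task <- synth_tasks()$synthner
  corpus <- make_corpus(synth_config(n_per_task = 150, seed = 42))
  for (ex in corpus$examples$synthner) {
    dec <- decode_ner(encode_ner_target(ex, task), task)
    expect_equal(sort(paste(dec$type, dec$surface)),
                 sort(paste(ex$spans$type, ex$spans$surface)),
                 info = ex$id)
  }
})

test_that("explain-prefix inputs equal 'explain ' plus label-prefix inputs", {
  corpus <- small_corpus(n = 20, seed = 3)
  for (name in names(corpus$examples)) {
    task <- corpus$tasks[[name]]
    for (ex in corpus$examples[[name]]) {
      expect_identical(encode_input(ex, task, "explain"),
                       paste0("explain ", encode_input(ex, task, "label")))
    }
  }
})

test_that("ner decoding is total over random marker-alphabet strings", {
  task <- toy_ner_task()
  alphabet <- c("disease*", "*disease", "gene*", "*gene", "a", "b", "x.", "")
  failures <- withr::with_seed(99, {
    sum(vapply(1:10000, function(i) {
      s <- paste(sample(alphabet, sample(0:8, 1), replace = TRUE),
                 collapse = " ")
      inherits(try(decode_ner(s, task), silent = TRUE), "try-error")
    }, NA))
  })
  expect_equal(failures, 0L)
})

test_that("targets verbalize labels and explanations per role", {
  re_task <- toy_re_task()
  ex <- labeled_example("r1", "i2b2", text = "Basilar artery stenosis.",
                        label = "PIP")
  expect_equal(encode_target(ex, re_task, "label"), "PIP")
  expl <- explanation("r1",
                      "The medical problem of the sentence. So the label is PIP.",
                      asserted_label = "PIP")
  expect_equal(
    encode_target(ex, re_task, "explain", expl),
    "PIP explanation: The medical problem of the sentence. So the label is PIP.")
  expect_error(encode_target(ex, re_task, "explain"), "explanation")

  nli <- labeled_example("n1", "mednli", label = "entailment",
                         premise = "A", hypothesis = "B")
  expect_equal(encode_target(nli, toy_nli_task(), "label"), "entailment")
})

test_that("label normalization is case-insensitive and first-line only", {
  labs <- c("TrAP", "PIP")
  expect_equal(normalize_label("trap", labs), "TrAP")
  expect_equal(normalize_label("  PIP. \nmore text", labs), "PIP")
  expect_equal(normalize_label("pip!", labs), "PIP")
  expect_true(is.na(normalize_label("nothing", labs)))
  expect_true(is.na(normalize_label(NA_character_, labs)))
})
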