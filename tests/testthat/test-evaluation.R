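fake_pred <- function(id, decoded, label_text = "x") {
  list(example_id = id, generated_label_text = label_text,
       generated_explanation_text = "e", decoded = decoded, error = NULL)
}

ner_pred <- function(id, types, surfaces) {
  occ <- stats::ave(seq_along(types), paste(types, surfaces),
                    FUN = seq_along) - 1L
  fake_pred(id, data.frame(type = types, surface = surfaces,
                           occurrence = as.integer(occ),
                           stringsAsFactors = FALSE))
}

test_that("micro F1 handles identity, partial recall, and id mismatches", {
  task <- toy_ner_task()
  gold <- list(
    ner_from_tokens("a", c("u", "flu", "v", "brc1"), c(2L, 4L),
                    c("disease", "gene")),
    ner_from_tokens("b", c("w", "malaria"), 2L, "disease")
  )
  perfect <- list(ner_pred("a", c("disease", "gene"), c("flu", "brc1")),
                  ner_pred("b", "disease", "malaria"))
  m <- micro_f1(perfect, gold, task)
  expect_equal(c(m$precision, m$recall, m$f1), c(1, 1, 1))

  # one of two gold spans found: P = 1, R = 0.5, F1 = 2/3
  gold2 <- list(ner_from_tokens("c", c("x", "flu", "y", "typhus"),
                                c(2L, 4L), c("disease", "disease")))
  part <- list(ner_pred("c", "disease", "flu"))
  m2 <- micro_f1(part, gold2, task)
  expect_equal(m2$precision, 1)
  expect_equal(m2$recall, 0.5)
  expect_equal(m2$f1, 2 / 3)

  expect_error(micro_f1(perfect, gold2, task), "ids do not match")
  # empty predictions give zero metrics, not NaN
  none <- list(ner_pred("c", character(), character()))
  m3 <- micro_f1(none, gold2, task)
  expect_equal(c(m3$precision, m3$recall, m3$f1), c(0, 0, 0))
})

test_that("ner micro F1 equals the brute-force multiset oracle on random cases", {
  task <- toy_ner_task()
  ents <- c("flu", "malaria", "brc1", "tp53", "cough")
  types <- c("disease", "gene")
  withr::with_seed(61, {
    for (case in 1:100) {
      n_sent <- sample(1:5, 1)
      gold <- list()
      preds <- list()
      gold_keys <- list()
      pred_keys <- list()
      for (s in seq_len(n_sent)) {
        id <- sprintf("s%d", s)
        ng <- sample(0:3, 1)
        gt <- sample(types, ng, replace = TRUE)
        ge <- sample(ents, ng, replace = TRUE)
        toks <- c("w0", as.vector(rbind(ge, paste0("f", seq_len(max(ng, 1))))))
        if (ng > 0) {
          gold[[s]] <- ner_from_tokens(id, toks, ent_idx = 2L * seq_len(ng),
                                       types = gt)
        } else {
          gold[[s]] <- ner_from_tokens(id, c("w0", "w1"), integer(),
                                       character())
        }
        npred <- sample(0:3, 1)
        pt <- sample(types, npred, replace = TRUE)
        pe <- sample(ents, npred, replace = TRUE)
        preds[[s]] <- ner_pred(id, pt, pe)
        gold_keys[[s]] <- paste(gold[[s]]$spans$type, gold[[s]]$spans$surface)
        pred_keys[[s]] <- paste(pt, pe)
      }
      got <- micro_f1(preds, gold, task)
      want <- oracle_micro_f1(pred_keys, gold_keys)
      expect_equal(got$precision, want$precision)
      expect_equal(got$recall, want$recall)
      expect_equal(got$f1, want$f1)
      expect_equal(unlist(got$counts[c("tp", "fp", "fn")], use.names = FALSE),
                   c(want$tp, want$fp, want$fn))
    }
  })
})

test_that("relation micro F1 pools positives only and matches its oracle", {
  task <- toy_re_task()
  positive <- setdiff(task$label_set, "False")
  withr::with_seed(62, {
    for (case in 1:100) {
      n <- sample(3:12, 1)
      ids <- sprintf("r%d", seq_len(n))
      gold_lab <- sample(task$label_set, n, replace = TRUE)
      pred_lab <- sample(c(task$label_set, NA), n, replace = TRUE)
      gold <- Map(function(id, lab)
        labeled_example(id, "i2b2", text = "t", label = lab), ids, gold_lab)
      preds <- Map(fake_pred, ids, pred_lab)
      names(gold) <- names(preds) <- NULL
      got <- micro_f1(preds, gold, task)
      want <- oracle_label_micro_f1(pred_lab, gold_lab, positive)
      expect_equal(got$precision, want$precision)
      expect_equal(got$recall, want$recall)
      expect_equal(got$f1, want$f1)
    }
  })
})

test_that("accuracy counts exact normalized matches", {
  task <- toy_nli_task()
  ids <- c("n1", "n2", "n3", "n4")
  gold <- Map(function(id, lab)
    labeled_example(id, "mednli", label = lab, premise = "p",
                    hypothesis = "h"),
    ids, c("entailment", "neutral", "contradiction", "entailment"))
  names(gold) <- NULL
  preds <- Map(fake_pred, ids,
               c("entailment", "neutral", "contradiction", "entailment"))
  names(preds) <- NULL
  expect_equal(accuracy_score(preds, gold)$accuracy, 1)
  wrong <- Map(fake_pred, ids, c("neutral", "entailment", "neutral",
                                 "contradiction"))
  names(wrong) <- NULL
  expect_equal(accuracy_score(wrong, gold)$accuracy, 0)
  mixed <- Map(fake_pred, ids, c("entailment", "neutral", "contradiction",
                                 NA))
  names(mixed) <- NULL
  expect_equal(accuracy_score(mixed, gold)$accuracy, 0.75)
})

test_that("metrics are invariant under query reordering", {
  task <- toy_ner_task()
  gold <- lapply(1:6, function(i)
    ner_from_tokens(sprintf("p%d", i), c("w", "flu"), 2L, "disease"))
  preds <- lapply(1:6, function(i)
    ner_pred(sprintf("p%d", i),
             if (i %% 2 == 0) "disease" else character(),
             if (i %% 2 == 0) "flu" else character()))
  m1 <- micro_f1(preds, gold, task)
  perm <- c(4, 1, 6, 2, 5, 3)
  m2 <- micro_f1(preds[perm], gold, task)
  expect_equal(m1, m2)
})

test_that("query prediction is total and records both generations", {
  corpus <- small_corpus(n = 60, seed = 25, rate = 0)
  task <- corpus$tasks$synthre
  split <- sample_support(corpus$examples$synthre, task, K = 6, seed = 1,
                          explanations = corpus$explanations)
  inst <- build_instances(split$support, task)
  bb <- ref_backbone(inst, seed = 1)
  res <- train_backbone(bb, inst, train_config(epochs = 15, seed = 1))
  preds <- predict_query(res$backbone, split$query, task)
  expect_length(preds, length(split$query))
  for (p in preds) {
    expect_true(is.character(p$generated_label_text))
    expect_true(is.character(p$generated_explanation_text))
  }
  report <- evaluate_task(res$backbone, split$query, task)
  expect_gte(report$parseable_rate, 0)
  expect_true(all(c("precision", "recall", "f1") %in%
                    names(report$metrics)))
  cs <- format_case_study(report, split$query, n = 2)
  expect_match(cs, "\\*\\*Explanation\\*\\*")
})
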