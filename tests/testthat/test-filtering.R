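test_that("assertion sentences are parsed case-insensitively with fallback", {
  labs <- toy_re_task()$label_set
  expect_identical(
    extract_asserted_label(
      "It does not mention the outcome. So the label is TrAP.", labs),
    "TrAP")
  expect_identical(
    extract_asserted_label("The medical problem. So the label is PIP.", labs),
    "PIP")
  expect_identical(
    extract_asserted_label("so THE LABEL IS terp", labs), "TeRP")
  # last assertion wins
  expect_identical(
    extract_asserted_label(
      "So the label is PIP. On reflection: So the label is TeRP.", labs),
    "TeRP")
  # fallback: last label mentioned anywhere
  expect_identical(
    extract_asserted_label("Could be PIP but reads more like TrCP here.",
                           labs),
    "TrCP")
  expect_true(is.na(extract_asserted_label("no label words at all", labs)))
  expect_true(is.na(extract_asserted_label(NA_character_, labs)))
})

test_that("the weak-label rule marks mismatches and absences as contradiction", {
  ex <- labeled_example("e1", "i2b2", text = "t", label = "PIP")
  base <- nli_pair(ex, explanation("e1", "x. So the label is TrAP.", "TrAP"))
  expect_identical(weak_label(base, "PIP", "TrAP")$weak_label, "contradiction")
  expect_true(is.na(weak_label(base, "PIP", "PIP")$weak_label))
  expect_identical(weak_label(base, "PIP", NA_character_)$weak_label,
                   "contradiction")
  # premise/hypothesis mapping: text is the premise, explanation the hypothesis
  expect_identical(base$premise, "t")
  expect_match(base$hypothesis, "^x\\.")
})

test_that("the discriminator contract is deterministic and rejects one-class seeds", {
  mkpair <- function(h, lab) data.frame(origin = "x", premise = "p q r",
                                        hypothesis = h, weak_label = lab,
                                        confidence = NA_real_)
  seeds <- rbind(
    mkpair("good faithful reasoning follows guideline", "entailment"),
    mkpair("good grounded reasoning follows guideline", "entailment"),
    mkpair("curiously atypical pattern elsewhere", "contradiction"),
    mkpair("curiously odd pattern elsewhere", "contradiction"))
  disc <- bow_discriminator()
  disc$fit(seeds)
  probe <- mkpair("faithful reasoning follows guideline", NA)
  p1 <- disc$predict(probe)
  p2 <- disc$predict(probe)
  expect_identical(p1, p2)
  expect_identical(p1$label, "entailment")
  expect_true(p1$confidence >= 0.5 && p1$confidence <= 1)
  bad <- bow_discriminator()
  expect_error(bad$fit(seeds[1:2, ]), "degenerate")
})

filtering_setup <- function(seed, n = 170, rate = 0.2) {
  corpus <- small_corpus(n = n, seed = seed, rate = rate)
  mc <- mock_collection(corpus, "synthre", rate = rate, seed = seed,
                        n_demos = 10)
  mc$corpus <- corpus
  mc
}

test_that("self-training at an unreachable confidence leaves the seed set unchanged", {
  mc <- filtering_setup(31)
  rows <- lapply(mc$collection$results, function(r)
    weak_label(nli_pair(r$example, r$explanation), r$example$label,
               r$explanation$asserted_label))
  pairs <- do.call(rbind, rows)
  seeds <- rbind(
    do.call(rbind, lapply(mc$pool, function(d) {
      p <- nli_pair(d$example, d$explanation)
      p$weak_label <- "entailment"
      p
    })),
    pairs[!is.na(pairs$weak_label), ])
  cands <- pairs[is.na(pairs$weak_label), ]
  st <- self_train(bow_discriminator(), seeds, cands, threshold = 0.999999,
                   iters = 1)
  expect_equal(sum(st$history), 0L)
  # partition law holds regardless
  expect_equal(nrow(st$retained) + nrow(st$discarded), nrow(cands))
  expect_length(intersect(st$retained$origin, st$discarded$origin), 0L)
})

test_that("filtering discards every planted wrong explanation by the mismatch rule", {
  mc <- filtering_setup(13, n = 170, rate = 0.2)
  filt <- filter_dataset(mc$collection$results, mc$pool, mc$task,
                         threshold = 0.9, iters = 3)
  planted <- mc$collection$planted
  expect_gt(length(planted), 0L)
  discarded <- filt$audit$example_id[filt$audit$decision == "discarded"]
  expect_true(all(planted %in% discarded))
  by_rule <- filt$audit$example_id[filt$audit$reason == "asserted_mismatch"]
  expect_setequal(planted, by_rule)
  # audit covers every collected example exactly once
  expect_setequal(filt$audit$example_id,
                  vapply(mc$collection$results, function(r) r$example$id, ""))
  # determinism of the retained/discarded partition across runs
  mc2 <- filtering_setup(13, n = 170, rate = 0.2)
  filt2 <- filter_dataset(mc2$collection$results, mc2$pool, mc2$task,
                          threshold = 0.9, iters = 3)
  expect_identical(filt$audit$decision, filt2$audit$decision)
})

test_that("boundary rates give all-retained and all-discarded filtering", {
  mc0 <- filtering_setup(17, n = 60, rate = 0)
  f0 <- filter_dataset(mc0$collection$results, mc0$pool, mc0$task)
  expect_length(f0$retained, length(mc0$collection$results))
  expect_true(all(f0$audit$decision == "retained"))

  mc1 <- filtering_setup(19, n = 60, rate = 1)
  f1 <- filter_dataset(mc1$collection$results, mc1$pool, mc1$task)
  expect_length(f1$retained, 0L)
  expect_true(all(f1$audit$decision == "discarded"))
  expect_true(all(f1$audit$reason == "asserted_mismatch"))
})

test_that("self-trained discriminator separates held-out faithful from hallucinated", {
  for (seed in c(13, 29, 57)) {
    mc <- filtering_setup(seed, n = 170, rate = 0.2)
    filt <- filter_dataset(mc$collection$results, mc$pool, mc$task,
                           threshold = 0.9, iters = 3)
    # held-out pairs from an independent corpus draw, labeled by construction
    held <- filtering_setup(seed + 1000, n = 120, rate = 0.5)
    held_pairs <- do.call(rbind, lapply(held$collection$results, function(r)
      nli_pair(r$example, r$explanation)))
    truth <- ifelse(vapply(held$collection$results, function(r)
      r$example$id, "") %in% held$collection$planted,
      "contradiction", "entailment")
    pred <- filt$disc$predict(held_pairs)
    acc <- mean(pred$label == truth)
    expect_gte(acc, 0.9)
  }
})

test_that("retained-set size is monotone non-increasing in the threshold", {
  mc <- filtering_setup(23, n = 170, rate = 0.2)
  sizes <- vapply(c(0.7, 0.8, 0.9, 0.99), function(th) {
    filt <- filter_dataset(mc$collection$results, mc$pool, mc$task,
                           threshold = th, iters = 3)
    length(filt$retained)
  }, 0L)
  expect_true(all(diff(sizes) <= 0L))
})

test_that("top-fraction promotion is available as an alternative to the threshold", {
  mc <- filtering_setup(41, n = 100, rate = 0.2)
  filt <- filter_dataset(mc$collection$results, mc$pool, mc$task,
                         iters = 2, top_q = 0.5)
  expect_equal(nrow(filt$audit), length(mc$collection$results))
})
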