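---
title: "Explanation distillation for biomedical few-shot learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explanation distillation for biomedical few-shot learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(letex)
```

## The problem

Biomedical NLP systems for named entity recognition (NER), relation
extraction (RE) and natural language inference (NLI) usually need large
expert-annotated corpora, which clinical privacy constraints and annotation
cost make scarce. In the N-way K-shot regime — all N classes of a task, K
labeled examples per class — small fine-tuned models both underperform and
offer no account of *why* they predict a label. This package implements an
explanation-distillation pipeline for that regime: reasoning explanations
for each training label are collected from a large language model, vetted
by an entailment discriminator, and distilled into a small text-to-text
model that is trained to emit the label and the justification together.

The pipeline has five stages, each exposed as ordinary R functions and
exercised end to end on synthetic data:

1. **Serialization** (`encode_input`, `encode_target`, `decode_ner`): every
   task becomes text-to-text. The input prefix `"<task>: "` requests the
   label; `"explain <task>: "` requests the explanation. NER outputs are the
   sentence with inline markers `type* surface *type`; RE/NLI outputs are
   the label verbatim; explanation targets are
   `"<label> explanation: <reasoning> So the label is <label>."`.
2. **Collection** (`build_demo_pool`, `knn_select`, `build_cot_prompt`,
   `collect_explanations`): a pool of ~20 randomly drawn examples with
   manually written explanations serves as in-context demonstrations; the
   nearest demonstration under cosine similarity of character-trigram
   vectors is inserted into a chain-of-thought prompt together with the
   query sentence *and its gold label*, and a pluggable client generates
   the explanation.
3. **Filtering** (`weak_label`, `bow_discriminator`, `self_train`,
   `filter_dataset`): each (text, explanation) pair becomes a premise-
   hypothesis pair. Explanations whose closing assertion disagrees with the
   gold label (or is unparseable) are weak-labeled *contradiction* and
   discarded outright; manual demonstrations seed the *entailment* class; a
   discriminator is fit on those seeds, self-trained on its own confident
   entailment predictions, and finally partitions the remaining candidates.
4. **Sampling** (`sample_support`, `shot_grid`): N-way K-shot support sets
   are drawn from the retained, explanation-augmented examples; the query
   set is everything else, disjoint by construction.
5. **Training and evaluation** (`build_instances`, `train_backbone`,
   `evaluate_task`): each support item contributes one label instance and
   one explanation instance; the training objective is the weighted joint
   loss; micro-averaged F1 (NER/RE) or accuracy (NLI) is computed on the
   query set.

## The joint training objective

Writing $\hat y_i$ and $\hat r_i$ for the model's label and explanation
predictions, the per-role cross-entropies are

$$L_{label} = -\tfrac{1}{N}\sum_i y_i \log \hat y_i, \qquad
  L_{expl} = -\tfrac{1}{N}\sum_i r_i \log \hat r_i,$$

and the training loss is their convex combination

$$L = \lambda\,L_{label} + (1-\lambda)\,L_{expl}.$$

Two design choices matter here. First, the per-role losses are means over
each role's own token positions, not a pooled mean, so the meaning of
$\lambda$ does not depend on explanation length or role imbalance. Second,
at the boundary $\lambda = 1$ only label instances contribute gradients, so
a $\lambda = 1$ run is bit-identical to training on the label instances
alone — this *is* the "without explanations" ablation, and the test suite
asserts the equality at machine precision. The default $\lambda = 0.5$ is a
symmetric prior over the two supervision signals; it is a config parameter
(`train_config(lambda = ...)`) and was not tuned.

## The reference backbone

The production-scale method fine-tunes a pretrained encoder-decoder
checkpoint of a few hundred million parameters. Checkpoints cannot be
assumed here, so the package ships a *reference backbone* implementing the
same contract (per-role loss, parameter update, greedy generation): a
conditional sequence model over a whitespace-token vocabulary in which the
next-token logits are linear in (a) the bag of input tokens, normalized by
bag size, (b) the previous target token, and (c) a marker-state feature
recording which entity marker is currently open. This is multinomial
logistic regression on sparse features — convex, deterministic, and
trainable full-batch with Adagrad in seconds on a laptop CPU. Tokens rather
than characters are the atoms because labels and span markers are single
tokens in the serialization; character-level modeling would need far longer
sequences for no additional desk-scale benefit. Training is full-batch (one
deterministic update per epoch), which removes batch-order randomness and
makes the $\lambda = 1$ ablation equality exact.

Greedy decoding is grammar-constrained for NER: transitions that cannot
occur in any valid inline-marker serialization are masked (a closer with no
region open, an opener or foreign closer inside a region, closing an empty
region, end-of-sequence mid-region), and a region still open at the length
cap (80 tokens) is closed — or a bare dangling opener dropped — so every
generation decodes to a well-formed span list. The empty generation is also
masked, since no valid target is empty. These constraints are standard
practice for generation-based NER; they guarantee *well-formedness*, not
correctness.

What the reference backbone can and cannot do: on the synthetic corpora it
learns label classification well (RE micro-F1 and NLI accuracy around 0.9
on query sets), but it cannot copy unseen sentences token by token, so its
NER *extraction* accuracy is near zero even though its NER outputs are
well-formed. A pretrained sequence-to-sequence adapter is the intended
production backbone; the reference implementation exists to make every
contract testable offline and to carry the loss-law and ablation
guarantees.

## The entailment discriminator

The filtering discriminator is likewise a contract. The shipped reference
is a ridge-penalized logistic classifier (`glmnet`, fixed penalty
$\lambda_{ridge} = 0.01$, no cross-validation, hence deterministic) over
hypothesis unigram counts plus one premise-hypothesis lexical-overlap
feature. Self-training runs for `iters = 3` rounds (two to three rounds are
typical for this scheme) at an absolute confidence threshold of 0.9;
because the scheme is sometimes described as keeping the "highest
confidence" predictions, a top-fraction alternative (`top_q`) is also
implemented. Only entailment-predicted pairs are ever promoted into the
training set; contradiction predictions never extend the seed negatives.
Two boundary rules are deliberate:

* an explanation that never states a parseable label is weak-labeled
  contradiction — an explanation that cannot assert its label cannot
  supervise label generation, so conservative discard is correct;
* when no evident error exists (hallucination rate 0) there is no
  contradiction supervision at all, so the weak-label rule alone decides
  and every agreeing candidate is retained rather than failing on a
  one-class seed set.

## What the synthetic generator emulates — and what it does not

`make_corpus()` generates three tasks that mirror the *structure* of common
biomedical benchmarks: short sentences over a closed pseudo-word
vocabulary; 0–3 non-overlapping typed spans per NER sentence drawn from
type-specific lexicons (some multi-token); RE sentences whose label is a
deterministic function of a cue template, with a negative "none" class
excluded from micro-F1 pooling by default; NLI pairs built per label by
entailment-preserving or contradicting edits of the premise; and a
templated 2–4 sentence gold explanation per example ending with the
assertion sentence `"So the label is <label>."`. One master seed drives
derived per-task streams, so a fixed seed reproduces the corpus byte for
byte.

The mock LLM client emulates in-context generation: with probability
$1 - r$ it echoes the demonstration's reasoning with the assertion rewritten
to the gold label (as few-shot generations imitate their demonstration's
style), and with probability $r$ — the hallucination rate — it asserts a
uniformly drawn wrong label using a visibly different template whose
signature token ("Curiously") appears nowhere else. Every planted
hallucination is recorded, giving downstream tests an exact oracle. Because
hallucinations always assert a wrong label, the weak-label mismatch rule
catches all of them by construction (recall 1.0); the discriminator's work
is measured separately on held-out pairs of both templates.

None of this emulates real biomedical vocabulary distributions, UMLS
semantics, annotation ambiguity, or hallucinations that assert the *right*
label for the wrong reason. Passing tests therefore demonstrate the
mechanics and invariants of the pipeline — codec soundness, filter recall,
sampler laws, loss laws, determinism — not clinical-grade extraction
quality.

## Numerical and degenerate-input choices

* **Tie-breaks.** Nearest-neighbour demonstration selection breaks cosine
  ties by lowest pool index; the greedy NER downsampler breaks class-deficit
  ties by label-set order and candidate ties by example id. All stages are
  deterministic given their seeds.
* **Greedy NER downsampling.** A sentence can carry several class
  instances, so exact K-per-class sampling is an NP-hard cover problem. The
  sampler repeatedly adds the sentence with the largest marginal gain
  toward the most-deficient class until every class reaches K, then prunes
  any sentence whose removal keeps all classes at K or above. The result is
  covering and 1-minimal (no single sentence is removable); the test suite
  compares it against exhaustive minimal-cover search on a 12-sentence toy.
* **Shot grids.** For flat tasks the per-class sampling order is drawn once
  per seed, so 16-shot supports nest inside 32- and 64-shot supports;
  infeasible K values are skipped with a warning record.
* **Label normalization.** Decoded labels take the first generated line,
  strip surrounding whitespace and clause-final punctuation, and match
  case-insensitively — small generative models emit trailing text.
* **Decoding totality.** `decode_ner` skips unbalanced or crossed markers
  and never raises; malformed generations yield fewer or zero spans.
  Matching is by (type, surface, occurrence) because generation loses
  character offsets.
* **Marker collisions.** Raw text already containing a reserved marker
  token is rejected at load time; round-trip soundness beats silent
  escaping.
* **Numerical guards.** Softmax is max-shifted; log-probabilities are
  clamped at 1e-12; a non-finite loss aborts training with a diagnostic.

## Problem sizes

The shipped tests and the acceptance script use corpora of 120–1000
examples per task, demonstration pools of 10–20, support sets at K = 8 or
16, and 20 training epochs — sizes chosen so the full pipeline runs in
seconds on one CPU while every class keeps comfortably more instances than
the largest K. The whole suite completes in under a minute.

## Known limitations

* The reference backbone cannot copy unseen token sequences, so NER
  extraction F1 on synthetic query sets is near zero (well-formedness is
  guaranteed, correctness is not). Production use requires a pretrained
  adapter behind the backbone contract.
* The bag-of-words discriminator judges surface vocabulary, not logic; it
  separates the synthetic templates perfectly but would not approximate
  human judgments of real explanations the way a fine-tuned NLI checkpoint
  does.
* Filtering recall of hallucinations is exact only because planted
  hallucinations always assert a wrong label; real hallucinations that
  assert the correct label evade the weak-label rule and must be caught by
  the discriminator alone.
* Nested and discontinuous entities, token-level BIO schemes, and
  document-level NER are out of scope of the serialization.
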