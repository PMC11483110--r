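# letex

Explanation-distilled few-shot learning for biomedical text mining, as a
tested end-to-end R pipeline.

## What problem this solves

Clinical and biomedical NLP tasks — disease/gene named entity recognition
(NER), clinical relation extraction (RE), and natural language inference
(NLI) — rarely come with the large expert-annotated corpora that standard
fine-tuning needs, and the models that are trained predict labels without
any justification. In the N-way K-shot regime (all N classes, K labeled
examples per class, e.g. K = 16/32/64), one remedy is to distil *reasoning
explanations* into a small generative model: collect an explanation for
every training label from a large language model via chain-of-thought
prompting, filter out hallucinated explanations with an entailment
discriminator, and fine-tune a small text-to-text model to emit the label
and its justification together.

This package implements that whole workflow for R users: the unified
text-to-text serialization of NER/RE/NLI, nearest-neighbour demonstration
selection and prompt assembly, a weak-label + self-training entailment
filter, N-way K-shot support-set sampling with greedy downsampling for
structured tasks, joint-loss training of a pluggable backbone, and
micro-F1/accuracy evaluation. A deterministic synthetic-corpus generator
and a mock LLM client make every stage runnable and testable offline.

## The model in brief

Every task is serialized as text-to-text with role-routing prefixes:
`"<task>: <sentence>"` asks for the label, `"explain <task>: <sentence>"`
for the explanation. NER labels are the sentence with inline span markers
(`... with disease* dihydropyrimidine dehydrogenase deficiency *disease`);
RE/NLI labels are emitted verbatim; explanation targets restate the label
and close with the assertion sentence `"So the label is <label>."` used by
the filter. Training minimizes the joint objective

    L = λ · L_label + (1 − λ) · L_expl,    λ ∈ [0, 1], default 0.5,

where `L_label` and `L_expl` are per-role mean cross-entropies; λ = 1 is
exactly the label-only ablation. Collected explanations are vetted by
converting each (text, explanation) pair into a premise–hypothesis pair:
evident errors (asserted label ≠ gold, or unparseable) are weak-labeled
*contradiction* and discarded; manual demonstrations seed *entailment*; a
discriminator (reference implementation: ridge logistic over bag-of-words
features) is self-trained on its confident entailment predictions and
partitions the rest.

See `vignettes/letex-methods.Rmd` for the full account, including the
reference backbone (a grammar-constrained, convex sequence model standing
behind the same contract a pretrained encoder–decoder adapter would
implement) and what the synthetic corpora do and do not emulate.

## Worked example

```r
library(letex)

res <- run_pipeline(task_name = "synthre", n = 200,
                    hallucination_rate = 0.2, K = 16,
                    lambda = 0.5, epochs = 20, seed = 1)

length(res$collection$results)   # 180 collected explanations
length(res$collection$planted)   # 43 planted hallucinations
length(res$filtered$retained)    # 137 retained after filtering
length(res$split$support)        # 64 = 16-shot x 4 relation classes
round(res$training$history$total[1], 3)  # 5.292  initial joint loss
round(res$training$final_loss, 3)        # 0.397  after 20 epochs
print(res$report)
#> <letex_eval_report> synthre: P = 0.870 R = 0.855 F1 = 0.862 (tp 47 fp 7 fn 8)
#>   parseable label generations: 100.0%
```

Reading the numbers: 200 synthetic relation sentences are generated; 20
become the demonstration pool and the remaining 180 get mock-LLM
explanations, 43 of which are planted hallucinations asserting a wrong
label. Filtering discards exactly those 43 (the weak-label rule catches
every asserted-label mismatch) and retains 137 faithful pairs. A 16-shot
support set (64 examples over the 4 relation classes) trains the reference
backbone; the joint loss falls from 5.29 to 0.40, and on the 73 held-out
query sentences the model reaches micro-F1 0.862 with every label
generation decoding to a valid label. One query prediction:

```r
res$report$predictions[[4]]$generated_label_text
#> "causes"
res$report$predictions[[1]]$generated_explanation_text
#> "treats explanation: The sentence mentions directly. This pattern follows the annotation guideline. ..."
```

The same pipeline runs for `"synthner"` and `"synthnli"`; a command-line
surface (`system.file("cli", "letex.R", package = "letex")`) exposes each
stage as `letex synth|collect|filter|sample|train|eval`.

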