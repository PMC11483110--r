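#' Run the full explanation-distillation pipeline on one task
#'
#' Convenience wrapper chaining every stage on a synthetic corpus: generate
#' examples with gold explanations, collect mock-LLM explanations via
#' chain-of-thought prompting with nearest-neighbour demonstrations, filter
#' them with the weak-label rule plus the self-trained entailment
#' discriminator, sample an N-way K-shot support set from the retained
#' examples, fine-tune the reference backbone with the joint loss, and
#' evaluate on the disjoint query set.
#'
#' @param task_name Which synthetic task to run (default \code{"synthre"}).
#' @param n Examples generated for the task.
#' @param hallucination_rate Mock-LLM hallucination probability.
#' @param K Shots per class.
#' @param lambda Loss mixing weight.
#' @param epochs Training epochs.
#' @param n_demos Demonstration pool size.
#' @param threshold,iters Filtering parameters.
#' @param seed Master seed for every stage.
#' @return List with the per-stage artifacts: \code{corpus},
#'   \code{collection}, \code{filtered}, \code{split}, \code{training},
#'   \code{report}.
#' @export
run_pipeline <- function(task_name = "synthre", n = 200,
                         hallucination_rate = 0.2, K = 16, lambda = 0.5,
                         epochs = 20, n_demos = 20, threshold = 0.9,
                         iters = 3, seed = 1) {
  cfg <- synth_config(n_per_task = n, seed = seed,
                      hallucination_rate = hallucination_rate)
  corpus <- make_corpus(cfg)
  task <- corpus$tasks[[task_name]]
  dataset <- corpus$examples[[task_name]]

  pool <- build_demo_pool(dataset, corpus$explanations, task,
                          n_demos = n_demos, seed = seed)
  pool_ids <- vapply(pool, function(d) d$example$id, "")
  to_collect <- Filter(function(ex) !(ex$id %in% pool_ids), dataset)
  client <- mock_client(task, rate = hallucination_rate,
                        seed = derive_seed(seed, 3L))
  collection <- collect_explanations(to_collect, pool, client, task)

  filtered <- filter_dataset(collection$results, pool, task,
                             threshold = threshold, iters = iters)
  retained_examples <- lapply(filtered$retained, `[[`, "example")
  retained_expl <- stats::setNames(
    lapply(filtered$retained, `[[`, "explanation"),
    vapply(retained_examples, `[[`, "", "id"))

  split <- sample_support(retained_examples, task, K, seed = seed,
                          explanations = retained_expl)
  instances <- build_instances(split$support, task)
  backbone <- ref_backbone(instances, entity_types = task$entity_types,
                           seed = seed)
  training <- train_backbone(backbone, instances,
                             train_config(lambda = lambda, epochs = epochs,
                                          seed = seed))
  report <- evaluate_task(training$backbone, split$query, task)
  list(corpus = corpus, collection = collection, filtered = filtered,
       split = split, training = training, report = report)
}
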