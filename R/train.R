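#' Build paired label/explanation training instances
#'
#' Each support triple (example, label, explanation) yields exactly two
#' sequence-to-sequence instances sharing the same body: one under the label
#' prefix with the label target (inline-marker serialization for ner, the
#' label verbatim otherwise), and one under the explain prefix whose target
#' restates the label and appends the reasoning explanation.
#'
#' @param support Support list from \code{\link{sample_support}} (each item
#'   must carry an explanation).
#' @param task The task.
#' @return data.frame with columns \code{input}, \code{target}, \code{role},
#'   \code{example_id}.
#' @export
build_instances <- function(support, task) {
  rows <- lapply(support, function(item) {
    ex <- item$example
    if (is.null(item$explanation))
      stop_letex("support item '%s' has no explanation", ex$id)
    data.frame(
      input = c(encode_input(ex, task, "label"),
                encode_input(ex, task, "explain")),
      target = c(encode_target(ex, task, "label"),
                 encode_target(ex, task, "explain", expl = item$explanation)),
      role = c("label", "explain"),
      example_id = ex$id,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Combine per-role losses into the joint training objective
#'
#' \code{total = lambda * label_loss + (1 - lambda) * expl_loss}. At
#' \code{lambda = 1} training reduces to label-only supervision (the
#' "without explanations" ablation); at \code{lambda = 0} to
#' explanation-only.
#'
#' @param label_loss,expl_loss Non-negative per-role mean cross-entropies.
#' @param lambda Mixing weight in [0, 1].
#' @return The weighted total.
#' @export
joint_loss <- function(label_loss, expl_loss, lambda) {
  if (!is_prob(lambda)) stop_letex("lambda must lie in [0, 1]")
  if (label_loss < 0 || expl_loss < 0) stop_letex("losses must be >= 0")
  lambda * label_loss + (1 - lambda) * expl_loss
}

#' Training configuration
#'
#' @param lambda Loss mixing weight in [0, 1] (default 0.5: label and
#'   explanation supervision weighted equally).
#' @param epochs Number of full passes.
#' @param learning_rate Adagrad learning rate of the reference backbone.
#' @param seed Seed for parameter initialization.
#' @param backbone Adapter name (only \code{"reference"} ships).
#' @return An object of class \code{letex_train_config}.
#' @export
train_config <- function(lambda = 0.5, epochs = 20, learning_rate = 0.5,
                         seed = 1, backbone = "reference") {
  if (!is_prob(lambda)) stop_letex("lambda must lie in [0, 1]")
  if (!is_count(epochs)) stop_letex("epochs must be a count >= 1")
  structure(
    list(lambda = lambda, epochs = epochs, learning_rate = learning_rate,
         seed = as.integer(seed), backbone = backbone),
    class = "letex_train_config"
  )
}

# -- reference backbone -------------------------------------------------------
# A small trainable conditional sequence model over a whitespace-token
# vocabulary: next-token logits are a linear function of (a) the bag of
# input tokens, (b) the previous target token, and (c) a marker-state
# feature recording which entity marker, if any, is currently open. This is
# multinomial logistic regression on sparse features, optimized full-batch
# with Adagrad - deterministic, convex, and fast enough for desk-scale
# corpora. It is a reference implementation of the backbone contract
# (loss / step / greedy generate); adapters for pretrained encoder-decoder
# checkpoints can implement the same contract.

BOS <- "<bos>"
EOS <- "<eos>"

backbone_vocab <- function(instances) {
  toks <- unique(unlist(lapply(c(instances$input, instances$target),
                               ws_tokens)))
  c(BOS, EOS, sort(toks))
}

marker_state_ids <- function(types) {
  stats::setNames(seq_along(types), types)
}

# marker state (0 = none, i = entity_types[i] open) after consuming `tok`
next_marker_state <- function(state, tok, openers, closers) {
  io <- match(tok, openers)
  if (!is.na(io)) return(io)
  if (state > 0L && identical(strip_tail_punct(tok), closers[state]))
    return(0L)
  state
}

#' Construct the reference text-to-text backbone
#'
#' @param instances Training instances (used to build the token vocabulary).
#' @param entity_types Entity types whose inline markers the decoder tracks
#'   as a state feature (empty for purely label/nli corpora).
#' @param learning_rate Adagrad learning rate.
#' @param init_sd Standard deviation of the random parameter initialization.
#' @param seed Seed for initialization.
#' @param max_len Maximum generation length in tokens.
#' @return An object of class \code{letex_backbone} (mutable environment).
#' @export
ref_backbone <- function(instances, entity_types = character(),
                         learning_rate = 0.5, init_sd = 0.01, seed = 1,
                         max_len = 80L) {
  vocab <- backbone_vocab(instances)
  V <- length(vocab)
  n_state <- length(entity_types)
  # input bag + previous token + marker state + explain-role flag + bias
  D <- V + V + n_state + 2L
  W <- with_seed(derive_seed(seed, 31L),
                 matrix(stats::rnorm(D * V, sd = init_sd), D, V))
  env <- new.env(parent = emptyenv())
  env$vocab <- vocab
  env$W <- W
  env$G <- matrix(0, D, V) # Adagrad accumulator
  env$entity_types <- entity_types
  env$openers <- paste0(entity_types, "*")
  env$closers <- paste0("*", entity_types)
  env$learning_rate <- learning_rate
  env$max_len <- as.integer(max_len)
  class(env) <- "letex_backbone"
  env
}

bag_vector_ids <- function(input, vocab) {
  ids <- match(ws_tokens(input), vocab)
  unique(ids[!is.na(ids)]) # presence features, weighted 1/|bag| in the design
}

# Expand instances into sparse teacher-forcing design matrices: one row per
# target token (including the closing EOS), one-hot targets.
backbone_design <- function(bb, instances) {
  V <- length(bb$vocab)
  n_state <- length(bb$entity_types)
  triplets_i <- list()
  triplets_j <- list()
  triplets_x <- list()
  y <- list()
  row0 <- 0L
  for (r in seq_len(nrow(instances))) {
    bag <- bag_vector_ids(instances$input[r], bb$vocab)
    bag_w <- if (length(bag)) 1 / length(bag) else 0
    is_explain <- grepl("^explain ", instances$input[r])
    tgt <- c(ws_tokens(instances$target[r]), EOS)
    tgt_ids <- match(tgt, bb$vocab)
    tgt_ids[is.na(tgt_ids)] <- match(EOS, bb$vocab)
    m <- length(tgt_ids)
    prev_ids <- c(match(BOS, bb$vocab), tgt_ids[-m])
    state <- 0L
    states <- integer(m)
    for (t in seq_len(m)) {
      states[t] <- state
      state <- next_marker_state(state, tgt[t], bb$openers, bb$closers)
    }
    for (t in seq_len(m)) {
      row <- row0 + t
      cols <- c(bag, V + prev_ids[t],
                if (states[t] > 0L) 2L * V + states[t],
                if (is_explain) 2L * V + n_state + 1L,
                2L * V + n_state + 2L)
      triplets_i[[row]] <- rep.int(row, length(cols))
      triplets_j[[row]] <- cols
      triplets_x[[row]] <- c(rep.int(bag_w, length(bag)),
                             rep.int(1, length(cols) - length(bag)))
    }
    y[[r]] <- tgt_ids
    row0 <- row0 + m
  }
  X <- Matrix::sparseMatrix(i = unlist(triplets_i), j = unlist(triplets_j),
                            x = unlist(triplets_x),
                            dims = c(row0, 2L * V + n_state + 2L))
  list(X = X, y = unlist(y), n = row0)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

role_forward <- function(bb, design) {
  P <- softmax_rows(as.matrix(design$X %*% bb$W))
  idx <- cbind(seq_len(design$n), design$y)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  list(P = P, loss = loss)
}

role_gradient <- function(design, P) {
  R <- P
  idx <- cbind(seq_len(design$n), design$y)
  R[idx] <- R[idx] - 1
  as.matrix(Matrix::crossprod(design$X, R)) / design$n
}

#' Fine-tune the backbone with the joint label/explanation objective
#'
#' Runs full-batch Adagrad for \code{cfg$epochs} epochs. At every epoch the
#' per-role mean cross-entropies are computed separately (so the mixing
#' weight's meaning does not depend on role imbalance) and combined with
#' \code{\link{joint_loss}}; the gradient is the identically weighted
#' combination of the per-role gradients. At the boundary weights only the
#' weighted role contributes to the update, which makes a \code{lambda = 1}
#' run equal, parameter for parameter, to a run on the label-role instances
#' alone.
#'
#' @param backbone A \code{letex_backbone}.
#' @param instances Instance data.frame from \code{\link{build_instances}}.
#' @param cfg A \code{\link{train_config}}.
#' @return List with \code{backbone}, \code{history} (one row per epoch:
#'   \code{label_loss}, \code{expl_loss}, \code{total}, all measured before
#'   that epoch's update), and \code{final_loss} (after the last update).
#' @export
train_backbone <- function(backbone, instances, cfg = train_config()) {
  if (!nrow(instances)) stop_letex("no training instances")
  lambda <- cfg$lambda
  roles <- unique(instances$role)
  if (lambda > 0 && lambda < 1 && !all(c("label", "explain") %in% roles))
    stop_letex("interior lambda requires both label and explain instances")
  has_label <- "label" %in% roles
  has_expl <- "explain" %in% roles
  d_label <- if (has_label)
    backbone_design(backbone, instances[instances$role == "label", ])
  d_expl <- if (has_expl)
    backbone_design(backbone, instances[instances$role == "explain", ])
  lr <- backbone$learning_rate
  history <- data.frame(epoch = seq_len(cfg$epochs), label_loss = NA_real_,
                        expl_loss = NA_real_, total = NA_real_)
  measure <- function() {
    ll <- if (has_label) role_forward(backbone, d_label) else NULL
    le <- if (has_expl) role_forward(backbone, d_expl) else NULL
    list(label = ll, expl = le,
         label_loss = if (is.null(ll)) 0 else ll$loss,
         expl_loss = if (is.null(le)) 0 else le$loss)
  }
  for (ep in seq_len(cfg$epochs)) {
    fw <- measure()
    total <- joint_loss(fw$label_loss, fw$expl_loss, lambda)
    if (!is.finite(total))
      stop_letex("non-finite loss at epoch %d (label %.4g, expl %.4g)",
                 ep, fw$label_loss, fw$expl_loss)
    history$label_loss[ep] <- fw$label_loss
    history$expl_loss[ep] <- fw$expl_loss
    history$total[ep] <- total
    grad <- NULL
    if (has_label && lambda > 0)
      grad <- lambda * role_gradient(d_label, fw$label$P)
    if (has_expl && lambda < 1) {
      ge <- (1 - lambda) * role_gradient(d_expl, fw$expl$P)
      grad <- if (is.null(grad)) ge else grad + ge
    }
    if (!is.null(grad)) {
      backbone$G <- backbone$G + grad^2
      backbone$W <- backbone$W - lr * grad / sqrt(backbone$G + 1e-8)
    }
  }
  fw <- measure()
  final_loss <- joint_loss(fw$label_loss, fw$expl_loss, lambda)
  list(backbone = backbone, history = history, final_loss = final_loss)
}

#' Grammar-constrained greedy decoding from the reference backbone
#'
#' Deterministic argmax decoding: starting from the beginning-of-sequence
#' token, repeatedly emits the highest-scoring next token given the input
#' bag, the previous token, and the current marker state, until the
#' end-of-sequence token or the length cap. When the backbone tracks entity
#' markers, transitions that cannot occur in any valid inline-marker
#' serialization are masked out — a closing marker with no region open, an
#' opener or a foreign closer inside a region, closing an empty region, or
#' ending the sequence mid-region — and a region still open at the length
#' cap is closed, so every ner generation is well formed by construction.
#'
#' @param backbone A trained \code{letex_backbone}.
#' @param input Prefixed input string.
#' @return The generated string (possibly empty).
#' @export
backbone_generate <- function(backbone, input) {
  vocab <- backbone$vocab
  V <- length(vocab)
  n_state <- length(backbone$entity_types)
  bag <- bag_vector_ids(input, vocab)
  prev <- match(BOS, vocab)
  state <- 0L
  since_open <- 0L
  eos_id <- match(EOS, vocab)
  opener_ids <- match(backbone$openers, vocab)
  closer_ids <- match(backbone$closers, vocab)
  out <- character()
  bag_w <- if (length(bag)) 1 / length(bag) else 0
  is_explain <- grepl("^explain ", input)
  for (step in seq_len(backbone$max_len)) {
    cols <- c(V + prev, if (state > 0L) 2L * V + state,
              if (is_explain) 2L * V + n_state + 1L,
              2L * V + n_state + 2L)
    logits <- colSums(backbone$W[cols, , drop = FALSE]) +
      bag_w * colSums(backbone$W[bag, , drop = FALSE])
    if (step == 1L) logits[eos_id] <- -Inf # a valid target is never empty
    if (n_state > 0L) {
      if (state == 0L) {
        logits[closer_ids[!is.na(closer_ids)]] <- -Inf
      } else {
        logits[c(opener_ids[!is.na(opener_ids)], eos_id)] <- -Inf
        drop_cl <- if (since_open == 0L) closer_ids else
          closer_ids[-state]
        logits[drop_cl[!is.na(drop_cl)]] <- -Inf
      }
    }
    nxt <- which.max(logits)
    if (nxt == eos_id) break
    tok <- vocab[nxt]
    out <- c(out, tok)
    new_state <- next_marker_state(state, tok, backbone$openers,
                                   backbone$closers)
    since_open <- if (new_state > 0L && state == 0L) 0L
                  else since_open + 1L
    state <- new_state
    prev <- nxt
  }
  if (state > 0L) {
    # region left open at the length cap: close it, or drop a bare opener
    out <- if (since_open > 0L) c(out, backbone$closers[state])
           else out[-length(out)]
  }
  paste(out, collapse = " ")
}
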