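# Independent brute-force oracles. Each is implemented differently from the
# package path it checks.

# Insert markers by walking the text character by character.
oracle_encode_ner <- function(text, spans) {
  chars <- strsplit(text, "")[[1]]
  out <- character()
  i <- 1L
  while (i <= length(chars) + 1L) {
    hit <- which(spans$start == i - 1L)
    if (length(hit)) {
      sp <- spans[hit[1L], ]
      out <- c(out, paste0(sp$type, "* ", sp$surface, " *", sp$type))
      i <- sp$end + 1L
    } else {
      if (i <= length(chars)) out <- c(out, chars[i])
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

# Exhaustive pairwise cosine over dense vectors on the union vocabulary.
oracle_knn_index <- function(query_text, pool_texts, embedder) {
  vecs <- lapply(c(query_text, pool_texts), embedder)
  keys <- sort(unique(unlist(lapply(vecs, names))))
  dense <- vapply(vecs, function(v) {
    out <- stats::setNames(numeric(length(keys)), keys)
    out[names(v)] <- v
    out
  }, numeric(length(keys)))
  q <- dense[, 1L]
  sims <- apply(dense[, -1L, drop = FALSE], 2L, function(p) {
    den <- sqrt(sum(q^2)) * sqrt(sum(p^2))
    if (den == 0) 0 else sum(q * p) / den
  })
  which.max(sims)
}

# Count-based micro F1 over (type, surface) multisets, via explicit
# per-key min/max bookkeeping.
oracle_micro_f1 <- function(pred_keys, gold_keys) {
  stopifnot(length(pred_keys) == length(gold_keys))
  tp <- fp <- fn <- 0L
  for (i in seq_along(pred_keys)) {
    all_keys <- unique(c(pred_keys[[i]], gold_keys[[i]]))
    for (k in all_keys) {
      np <- sum(pred_keys[[i]] == k)
      ng <- sum(gold_keys[[i]] == k)
      tp <- tp + min(np, ng)
      fp <- fp + max(np - ng, 0L)
      fn <- fn + max(ng - np, 0L)
    }
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1, tp = tp, fp = fp, fn = fn)
}

# Label-level micro F1 by direct counting over positive classes.
oracle_label_micro_f1 <- function(pred, gold, positive) {
  tp <- sum(!is.na(pred) & pred == gold & gold %in% positive)
  fp <- sum(!is.na(pred) & pred %in% positive & (is.na(gold) | pred != gold))
  fn <- sum(gold %in% positive & (is.na(pred) | pred != gold))
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1)
}

# Exhaustive minimal cover: smallest subset of sentences giving every class
# at least K instances. counts_mat is classes x sentences.
oracle_min_cover_size <- function(counts_mat, K) {
  n <- ncol(counts_mat)
  best <- Inf
  for (mask in seq_len(2^n) - 1L) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(members) >= best) next
    cover <- if (length(members))
      rowSums(counts_mat[, members, drop = FALSE]) else
      numeric(nrow(counts_mat))
    if (all(cover >= K)) best <- length(members)
  }
  best
}
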