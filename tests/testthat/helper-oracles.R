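# Explicit-loop oracle implementations of the model's algebra. These are
# deliberately naive (scalar loops, no matrix products beyond sum()) and
# independent of the package's vectorized code paths.

oracle_matmul <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(b))) out[i, j] <- sum(a[i, ] * b[, j])
  }
  out
}

oracle_cross_attend <- function(x_q, x_kv, wq, wk, wv) {
  d <- ncol(x_q)
  q <- oracle_matmul(x_q, wq)
  k <- oracle_matmul(x_kv, wk)
  v <- oracle_matmul(x_kv, wv)
  out <- matrix(0, nrow(x_q), d)
  for (i in seq_len(nrow(q))) {
    scores <- numeric(nrow(k))
    for (j in seq_len(nrow(k))) scores[j] <- sum(q[i, ] * k[j, ]) / sqrt(d)
    e <- exp(scores - max(scores))
    w <- e / sum(e)
    for (j in seq_len(nrow(k))) out[i, ] <- out[i, ] + w[j] * v[j, ]
  }
  out
}

oracle_embed_structured <- function(s, w1, b1, w2, b2) {
  h1 <- oracle_matmul(s, w1)
  for (i in seq_len(nrow(h1))) h1[i, ] <- h1[i, ] + b1
  h2 <- oracle_matmul(h1, w2)
  for (i in seq_len(nrow(h2))) h2[i, ] <- h2[i, ] + b2
  apply(h2, c(1, 2), function(x) max(x, 0))
}

oracle_pool_and_normalize <- function(x, gamma, beta, eps = 1e-5) {
  d <- ncol(x)
  normed <- matrix(0, nrow(x), d)
  for (i in seq_len(nrow(x))) {
    mu <- sum(x[i, ]) / d
    va <- sum((x[i, ] - mu)^2) / d
    normed[i, ] <- gamma * (x[i, ] - mu) / sqrt(va + eps) + beta
  }
  out <- numeric(d)
  for (j in seq_len(d)) out[j] <- sum(normed[, j]) / nrow(x)
  out
}

oracle_fuse_and_classify <- function(s_final, c_final, w, b, label = NULL) {
  v <- c(s_final, c_final)
  logits <- numeric(2)
  for (k in 1:2) logits[k] <- sum(v * w[, k]) + b[k]
  e <- exp(logits - max(logits))
  probs <- e / sum(e)
  out <- list(v = v, logits = logits, probs = probs)
  if (!is.null(label)) out$loss <- -log(probs[label + 1])
  out
}

# independent confusion-matrix metric reference (caret)
ref_confusion_metrics <- function(tp, tn, fp, fn) {
  m <- matrix(c(tn, fp, fn, tp), nrow = 2,
              dimnames = list(Prediction = c("0", "1"),
                              Reference = c("0", "1")))
  cm <- caret::confusionMatrix(as.table(m), positive = "1")
  c(accuracy = unname(cm$overall["Accuracy"]),
    precision = unname(cm$byClass["Precision"]),
    sensitivity = unname(cm$byClass["Sensitivity"]),
    specificity = unname(cm$byClass["Specificity"]),
    f1 = unname(cm$byClass["F1"]))
}

rand_mat <- function(n, m, scale = 1) matrix(stats::rnorm(n * m, sd = scale), n, m)
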