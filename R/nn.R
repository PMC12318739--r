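# Layer primitives with hand-written reverse-mode gradients.
#
# Every *_fwd returns list(out, cache); the matching *_bwd consumes the
# cache and the gradient of the loss w.r.t. the output and returns the
# gradient w.r.t. the input, accumulating parameter gradients into an
# environment keyed by flat parameter names.
#
# Token sequences are L x d matrices (rows are tokens). A mini-batch of
# `batch` samples travels as one stacked (batch * L) x d matrix: every
# token-wise operation (linear, layer norm, GELU, dropout, residual)
# applies unchanged to the stack in a single BLAS call, and only the
# attention modules loop over the per-sample row blocks, since attention
# must not mix tokens across samples. All arithmetic is 64-bit base R;
# correctness is checked against finite differences and explicit-loop
# oracles in the test suite.

gacc <- function(g, name, value) {
  if (is.null(g[[name]])) g[[name]] <- value else g[[name]] <- g[[name]] + value
  invisible(NULL)
}

# add a length-d bias to every row of an n x d matrix (column-major trick)
add_bias <- function(m, b) m + rep(b, each = nrow(m))

linear_fwd <- function(x, w, b) {
  list(out = add_bias(x %*% w, b), cache = list(x = x, w = w))
}

linear_bwd <- function(cache, d_out, g, w_name, b_name) {
  gacc(g, w_name, crossprod(cache$x, d_out))
  gacc(g, b_name, colSums(d_out))
  d_out %*% t(cache$w)
}

layernorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd_ <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sd_
  list(out = add_bias(xhat * rep(gamma, each = nrow(x)), beta),
       cache = list(xhat = xhat, sd = sd_, gamma = gamma))
}

layernorm_bwd <- function(cache, d_out, g, g_name, b_name) {
  xhat <- cache$xhat
  gacc(g, g_name, colSums(d_out * xhat))
  gacc(g, b_name, colSums(d_out))
  d_xhat <- d_out * rep(cache$gamma, each = nrow(d_out))
  (d_xhat - rowMeans(d_xhat) - xhat * rowMeans(d_xhat * xhat)) / cache$sd
}

gelu_fwd <- function(x) {
  phi <- stats::pnorm(x)
  list(out = x * phi, cache = list(x = x, phi = phi))
}

gelu_bwd <- function(cache, d_out) {
  d_out * (cache$phi + cache$x * stats::dnorm(cache$x))
}

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, cache = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x), ncol(x)) >= rate) / (1 - rate)
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(cache, d_out) {
  if (is.null(cache)) d_out else d_out * cache
}

# gradient of row-softmax given A = softmax(S) and dA
softmax_rows_bwd <- function(a, d_a) {
  a * (d_a - rowSums(d_a * a))
}

# row indices of sample b in a stacked (batch * l) x d matrix
block_rows <- function(b, l) ((b - 1L) * l + 1L):(b * l)

# ---- multi-head self-attention (used inside the transformer blocks) ----

mhsa_fwd <- function(x, p, prefix, n_heads, l_tokens, batch) {
  d <- ncol(x)
  dh <- d %/% n_heads
  q <- add_bias(x %*% p[[paste0(prefix, ".Wq")]], p[[paste0(prefix, ".bq")]])
  k <- add_bias(x %*% p[[paste0(prefix, ".Wk")]], p[[paste0(prefix, ".bk")]])
  v <- add_bias(x %*% p[[paste0(prefix, ".Wv")]], p[[paste0(prefix, ".bv")]])
  a_all <- array(0, dim = c(l_tokens, l_tokens, batch * n_heads))
  o <- matrix(0, nrow(x), d)
  for (b in seq_len(batch)) {
    rows <- block_rows(b, l_tokens)
    for (h in seq_len(n_heads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      a <- softmax_rows((q[rows, idx, drop = FALSE] %*%
                           t(k[rows, idx, drop = FALSE])) / sqrt(dh))
      o[rows, idx] <- a %*% v[rows, idx, drop = FALSE]
      a_all[, , (b - 1L) * n_heads + h] <- a
    }
  }
  out <- add_bias(o %*% p[[paste0(prefix, ".Wo")]], p[[paste0(prefix, ".bo")]])
  list(out = out,
       cache = list(x = x, q = q, k = k, v = v, o = o, a_all = a_all,
                    prefix = prefix, n_heads = n_heads, dh = dh,
                    l_tokens = l_tokens, batch = batch, p = p))
}

mhsa_bwd <- function(cache, d_out, g) {
  p <- cache$p; prefix <- cache$prefix
  dh <- cache$dh
  gacc(g, paste0(prefix, ".Wo"), crossprod(cache$o, d_out))
  gacc(g, paste0(prefix, ".bo"), colSums(d_out))
  d_o <- d_out %*% t(p[[paste0(prefix, ".Wo")]])
  d_q <- matrix(0, nrow(cache$q), ncol(cache$q))
  d_k <- d_q; d_v <- d_q
  for (b in seq_len(cache$batch)) {
    rows <- block_rows(b, cache$l_tokens)
    for (h in seq_len(cache$n_heads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      a <- matrix(cache$a_all[, , (b - 1L) * cache$n_heads + h],
                  cache$l_tokens, cache$l_tokens)
      d_oh <- d_o[rows, idx, drop = FALSE]
      d_a <- d_oh %*% t(cache$v[rows, idx, drop = FALSE])
      d_v[rows, idx] <- crossprod(a, d_oh)
      d_s <- softmax_rows_bwd(a, d_a) / sqrt(dh)
      d_q[rows, idx] <- d_s %*% cache$k[rows, idx, drop = FALSE]
      d_k[rows, idx] <- crossprod(d_s, cache$q[rows, idx, drop = FALSE])
    }
  }
  x <- cache$x
  gacc(g, paste0(prefix, ".Wq"), crossprod(x, d_q))
  gacc(g, paste0(prefix, ".bq"), colSums(d_q))
  gacc(g, paste0(prefix, ".Wk"), crossprod(x, d_k))
  gacc(g, paste0(prefix, ".bk"), colSums(d_k))
  gacc(g, paste0(prefix, ".Wv"), crossprod(x, d_v))
  gacc(g, paste0(prefix, ".bv"), colSums(d_v))
  d_q %*% t(p[[paste0(prefix, ".Wq")]]) +
    d_k %*% t(p[[paste0(prefix, ".Wk")]]) +
    d_v %*% t(p[[paste0(prefix, ".Wv")]])
}

# ---- pre-norm transformer encoder block ----
# x + Dropout(MHSA(LN1(x))), then + Dropout(FFN(LN2(.))) with GELU FFN

block_fwd <- function(x, p, prefix, config, training, l_tokens, batch) {
  ln1 <- layernorm_fwd(x, p[[paste0(prefix, ".ln1.g")]],
                       p[[paste0(prefix, ".ln1.b")]])
  att <- mhsa_fwd(ln1$out, p, paste0(prefix, ".attn"), config$n_heads,
                  l_tokens, batch)
  dr1 <- dropout_fwd(att$out, config$dropout, training)
  x1 <- x + dr1$out
  ln2 <- layernorm_fwd(x1, p[[paste0(prefix, ".ln2.g")]],
                       p[[paste0(prefix, ".ln2.b")]])
  f1 <- linear_fwd(ln2$out, p[[paste0(prefix, ".ffn.W1")]],
                   p[[paste0(prefix, ".ffn.b1")]])
  ge <- gelu_fwd(f1$out)
  f2 <- linear_fwd(ge$out, p[[paste0(prefix, ".ffn.W2")]],
                   p[[paste0(prefix, ".ffn.b2")]])
  dr2 <- dropout_fwd(f2$out, config$dropout, training)
  list(out = x1 + dr2$out,
       cache = list(ln1 = ln1, att = att, dr1 = dr1, ln2 = ln2,
                    f1 = f1, ge = ge, f2 = f2, dr2 = dr2, prefix = prefix))
}

block_bwd <- function(cache, d_out, g) {
  prefix <- cache$prefix
  d_f2 <- dropout_bwd(cache$dr2$cache, d_out)
  d_ge <- linear_bwd(cache$f2$cache, d_f2, g,
                     paste0(prefix, ".ffn.W2"), paste0(prefix, ".ffn.b2"))
  d_f1 <- gelu_bwd(cache$ge$cache, d_ge)
  d_ln2 <- linear_bwd(cache$f1$cache, d_f1, g,
                      paste0(prefix, ".ffn.W1"), paste0(prefix, ".ffn.b1"))
  d_x1 <- d_out + layernorm_bwd(cache$ln2$cache, d_ln2, g,
                                paste0(prefix, ".ln2.g"),
                                paste0(prefix, ".ln2.b"))
  d_att <- dropout_bwd(cache$dr1$cache, d_x1)
  d_ln1 <- mhsa_bwd(cache$att$cache, d_att, g)
  d_x1 + layernorm_bwd(cache$ln1$cache, d_ln1, g,
                       paste0(prefix, ".ln1.g"), paste0(prefix, ".ln1.b"))
}

# ---- full encoder: positional embedding, n blocks, final layer norm ----

encoder_fwd <- function(x, p, prefix, config, training, l_tokens, batch) {
  pos_name <- paste0(prefix, ".pos")
  if (config$positional) {
    x <- x + p[[pos_name]][rep(seq_len(l_tokens), batch), , drop = FALSE]
  }
  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    bl <- block_fwd(x, p, paste0(prefix, ".b", b), config, training,
                    l_tokens, batch)
    x <- bl$out
    blocks[[b]] <- bl$cache
  }
  lnf <- layernorm_fwd(x, p[[paste0(prefix, ".lnf.g")]],
                       p[[paste0(prefix, ".lnf.b")]])
  list(out = lnf$out,
       cache = list(blocks = blocks, lnf = lnf, prefix = prefix,
                    config = config, l_tokens = l_tokens, batch = batch))
}

encoder_bwd <- function(cache, d_out, g) {
  prefix <- cache$prefix
  d_x <- layernorm_bwd(cache$lnf$cache, d_out, g,
                       paste0(prefix, ".lnf.g"), paste0(prefix, ".lnf.b"))
  for (b in rev(seq_along(cache$blocks))) {
    d_x <- block_bwd(cache$blocks[[b]], d_x, g)
  }
  if (cache$config$positional) {
    d_pos <- unname(rowsum(d_x, rep(seq_len(cache$l_tokens), cache$batch),
                           reorder = TRUE))
    gacc(g, paste0(prefix, ".pos"), d_pos)
  }
  d_x
}

# ---- single-head cross-attention, scaled by the full model dimension ----
# softmax((Xq Wq)(Xkv Wk)^T / sqrt(d)) (Xkv Wv); no output projection or
# bias beyond the three projections. Query and key/value stacks may have
# different per-sample token counts.

cross_attn_fwd <- function(x_q, x_kv, p, prefix, l_q, l_kv, batch) {
  if (ncol(x_q) != ncol(x_kv)) stopf("cross-attention feature dims differ")
  d <- ncol(x_q)
  q <- x_q %*% p[[paste0(prefix, ".Wq")]]
  k <- x_kv %*% p[[paste0(prefix, ".Wk")]]
  v <- x_kv %*% p[[paste0(prefix, ".Wv")]]
  a_all <- array(0, dim = c(l_q, l_kv, batch))
  out <- matrix(0, nrow(x_q), d)
  for (b in seq_len(batch)) {
    rq <- block_rows(b, l_q); rkv <- block_rows(b, l_kv)
    a <- softmax_rows((q[rq, , drop = FALSE] %*%
                         t(k[rkv, , drop = FALSE])) / sqrt(d))
    out[rq, ] <- a %*% v[rkv, , drop = FALSE]
    a_all[, , b] <- a
  }
  list(out = out,
       cache = list(x_q = x_q, x_kv = x_kv, q = q, k = k, v = v,
                    a_all = a_all, d = d, prefix = prefix,
                    l_q = l_q, l_kv = l_kv, batch = batch, p = p))
}

cross_attn_bwd <- function(cache, d_out, g) {
  p <- cache$p; prefix <- cache$prefix
  d_q <- matrix(0, nrow(cache$q), ncol(cache$q))
  d_k <- matrix(0, nrow(cache$k), ncol(cache$k))
  d_v <- d_k
  for (b in seq_len(cache$batch)) {
    rq <- block_rows(b, cache$l_q); rkv <- block_rows(b, cache$l_kv)
    a <- matrix(cache$a_all[, , b], cache$l_q, cache$l_kv)
    d_ob <- d_out[rq, , drop = FALSE]
    d_a <- d_ob %*% t(cache$v[rkv, , drop = FALSE])
    d_v[rkv, ] <- crossprod(a, d_ob)
    d_s <- softmax_rows_bwd(a, d_a) / sqrt(cache$d)
    d_q[rq, ] <- d_s %*% cache$k[rkv, , drop = FALSE]
    d_k[rkv, ] <- crossprod(d_s, cache$q[rq, , drop = FALSE])
  }
  gacc(g, paste0(prefix, ".Wq"), crossprod(cache$x_q, d_q))
  gacc(g, paste0(prefix, ".Wk"), crossprod(cache$x_kv, d_k))
  gacc(g, paste0(prefix, ".Wv"), crossprod(cache$x_kv, d_v))
  list(d_q = d_q %*% t(p[[paste0(prefix, ".Wq")]]),
       d_kv = d_k %*% t(p[[paste0(prefix, ".Wk")]]) +
         d_v %*% t(p[[paste0(prefix, ".Wv")]]))
}

# ---- token pooling: per-token layer norm, then mean over tokens ----
# collapses each sample's l_tokens x d block to one d-vector

pool_fwd <- function(x, p, prefix, l_tokens, batch) {
  if (l_tokens == 0) stopf("cannot pool an empty token sequence")
  ln <- layernorm_fwd(x, p[[paste0(prefix, ".g")]], p[[paste0(prefix, ".b")]])
  pooled <- rowsum(ln$out, rep(seq_len(batch), each = l_tokens),
                   reorder = TRUE) / l_tokens
  list(out = pooled, cache = list(ln = ln, l_tokens = l_tokens,
                                  batch = batch, prefix = prefix))
}

pool_bwd <- function(cache, d_pooled, g) {
  d_ln <- (d_pooled / cache$l_tokens)[rep(seq_len(cache$batch),
                                          each = cache$l_tokens), ,
                                      drop = FALSE]
  layernorm_bwd(cache$ln$cache, d_ln, g,
                paste0(cache$prefix, ".g"), paste0(cache$prefix, ".b"))
}

# ---- classifier head and cross-entropy (batched) ----

head_fwd <- function(v, p) {
  list(logits = add_bias(v %*% p[["head.W"]], p[["head.b"]]),
       cache = list(v = v))
}

head_bwd <- function(cache, d_logits, g, p) {
  gacc(g, "head.W", crossprod(cache$v, d_logits))
  gacc(g, "head.b", colSums(d_logits))
  d_logits %*% t(p[["head.W"]])
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# mean cross-entropy of batch x 2 logits against labels in {0, 1}
ce_fwd <- function(logits, labels) {
  probs <- softmax_rows(logits)
  picked <- probs[cbind(seq_along(labels), labels + 1L)]
  d_logits <- probs
  d_logits[cbind(seq_along(labels), labels + 1L)] <-
    picked - 1
  list(loss = mean(-log(picked)), probs = probs,
       d_logits = d_logits / length(labels))
}
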