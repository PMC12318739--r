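#' Model configuration
#'
#' The dual cross-attention classifier encodes a 9 x 4 structured rating
#' matrix (two stacked affine maps with ReLU into 9 tokens of
#' `model_dim`) and a 32^3 nodule cube (each of the 32 axial slices mapped
#' by one shared full-slice convolution into a `model_dim` token), runs
#' each token sequence through its own stack of pre-norm transformer
#' encoder blocks, exchanges information through two independent
#' single-head cross-attention modules (image queries over structured
#' keys/values and vice versa), layer-normalizes and mean-pools each fused
#' sequence over its tokens, concatenates the two pooled vectors and
#' classifies with a single linear layer.
#'
#' @param model_dim Token embedding width (default 256).
#' @param n_blocks Transformer encoder blocks per modality (default 6).
#' @param n_heads Self-attention heads inside the encoder blocks
#'   (default 8; cross-attention is single-head by construction).
#' @param ffn_dim Feed-forward hidden width (default `4 * model_dim`).
#' @param dropout Dropout rate in the encoder blocks during training.
#' @param positional Add learnable positional embeddings to both token
#'   sequences before encoding (slice order and attribute identity are
#'   meaningful).
#' @param ablation One of `"full"`, `"structured_only"`, `"image_only"`,
#'   `"no_transformer"` (both encoders replaced by identity),
#'   `"no_cross_attention"` (encoded sequences pooled directly).
#' @param n_structured_tokens,n_slices Token counts (9 attributes,
#'   32 axial slices); fixed by the data layout.
#' @return A `noduleca_config` list.
#' @export
model_config <- function(model_dim = 256L, n_blocks = 6L, n_heads = 8L,
                         ffn_dim = 4L * model_dim, dropout = 0.1,
                         positional = TRUE, ablation = "full",
                         n_structured_tokens = 9L, n_slices = 32L) {
  ablation <- match.arg(ablation, c("full", "structured_only", "image_only",
                                    "no_transformer", "no_cross_attention"))
  if (model_dim %% n_heads != 0) {
    stopf("model_dim (%d) must be divisible by n_heads (%d)",
          model_dim, n_heads)
  }
  structure(
    list(model_dim = as.integer(model_dim), n_blocks = as.integer(n_blocks),
         n_heads = as.integer(n_heads), ffn_dim = as.integer(ffn_dim),
         dropout = dropout, positional = positional, ablation = ablation,
         n_structured_tokens = as.integer(n_structured_tokens),
         n_slices = as.integer(n_slices)),
    class = "noduleca_config"
  )
}

uses_structured <- function(config) config$ablation != "image_only"
uses_image <- function(config) config$ablation != "structured_only"
uses_cross_attention <- function(config) {
  config$ablation %in% c("full", "no_transformer")
}
uses_encoders <- function(config) config$ablation != "no_transformer"

head_input_dim <- function(config) {
  if (uses_structured(config) && uses_image(config)) 2L * config$model_dim
  else config$model_dim
}

# uniform fan-in initialization: U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_weight <- function(n_in, n_out) {
  bound <- 1 / sqrt(n_in)
  matrix(stats::runif(n_in * n_out, -bound, bound), n_in, n_out)
}

init_encoder_params <- function(p, prefix, l_tokens, config) {
  d <- config$model_dim
  if (config$positional) {
    bound <- 1 / sqrt(d)
    p[[paste0(prefix, ".pos")]] <-
      matrix(stats::runif(l_tokens * d, -bound, bound), l_tokens, d)
  }
  for (b in seq_len(config$n_blocks)) {
    bp <- paste0(prefix, ".b", b)
    for (nm in c("ln1", "ln2")) {
      p[[paste0(bp, ".", nm, ".g")]] <- rep(1, d)
      p[[paste0(bp, ".", nm, ".b")]] <- rep(0, d)
    }
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      p[[paste0(bp, ".attn.", nm)]] <- init_weight(d, d)
    }
    for (nm in c("bq", "bk", "bv", "bo")) {
      p[[paste0(bp, ".attn.", nm)]] <- rep(0, d)
    }
    p[[paste0(bp, ".ffn.W1")]] <- init_weight(d, config$ffn_dim)
    p[[paste0(bp, ".ffn.b1")]] <- rep(0, config$ffn_dim)
    p[[paste0(bp, ".ffn.W2")]] <- init_weight(config$ffn_dim, d)
    p[[paste0(bp, ".ffn.b2")]] <- rep(0, d)
  }
  p[[paste0(prefix, ".lnf.g")]] <- rep(1, d)
  p[[paste0(prefix, ".lnf.b")]] <- rep(0, d)
  p
}

#' Initialize a model
#'
#' All weights are drawn with uniform fan-in scaling under the recorded
#' seed; biases and layer-norm offsets start at zero, layer-norm gains at
#' one. Only the parameters the configured ablation actually uses are
#' created.
#'
#' @param config A [model_config()].
#' @param seed Integer seed recorded in the model.
#' @return A `noduleca_model`: list of `params`, `config`, `seed`.
#' @export
init_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "noduleca_config"))
  d <- config$model_dim
  withr::with_seed(as.integer(seed %% 2147483647), {
    p <- list()
    if (uses_structured(config)) {
      p[["str_embed.W1"]] <- init_weight(4L, 32L)
      p[["str_embed.b1"]] <- rep(0, 32L)
      p[["str_embed.W2"]] <- init_weight(32L, d)
      p[["str_embed.b2"]] <- rep(0, d)
      if (uses_encoders(config)) {
        p <- init_encoder_params(p, "enc_s", config$n_structured_tokens,
                                 config)
      }
      p[["pool_s.g"]] <- rep(1, d)
      p[["pool_s.b"]] <- rep(0, d)
    }
    if (uses_image(config)) {
      p[["vol_embed.W"]] <- init_weight(32L * 32L, d)
      p[["vol_embed.b"]] <- rep(0, d)
      if (uses_encoders(config)) {
        p <- init_encoder_params(p, "enc_c", config$n_slices, config)
      }
      p[["pool_c.g"]] <- rep(1, d)
      p[["pool_c.b"]] <- rep(0, d)
    }
    if (uses_cross_attention(config) && uses_structured(config) &&
          uses_image(config)) {
      for (side in c("ca_s", "ca_c")) {  # two independent instances
        for (nm in c("Wq", "Wk", "Wv")) {
          p[[paste0(side, ".", nm)]] <- init_weight(d, d)
        }
      }
    }
    p[["head.W"]] <- init_weight(head_input_dim(config), 2L)
    p[["head.b"]] <- rep(0, 2L)
    structure(list(params = p, config = config, seed = as.integer(seed)),
              class = "noduleca_model")
  })
}

#' @export
print.noduleca_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<noduleca_model> ablation '%s', dim %d, %d blocks, %s parameters\n",
    x$config$ablation, x$config$model_dim, x$config$n_blocks,
    format(n_par, big.mark = ",")))
  invisible(x)
}

#' Embed a structured rating matrix into token space
#'
#' Each attribute row of the 9 x 4 matrix passes through two stacked
#' affine maps (4 -> 32 -> `model_dim`) with a ReLU on the output, giving
#' nine non-negative tokens. The two maps are applied row-wise as
#' right-multiplications, the only reading consistent with the stated
#' weight shapes.
#'
#' @param s 9 x 4 numeric matrix (already rescaled to `[0, 1]`).
#' @param model A `noduleca_model` (or its parameter list).
#' @return A 9 x `model_dim` matrix of embedded tokens.
#' @export
embed_structured <- function(s, model) {
  p <- model_params(model)
  if (!is.matrix(s) || nrow(s) != 9 || ncol(s) != 4) {
    stopf("structured input must be 9 x 4")
  }
  embed_structured_fwd(s, p)$out
}

embed_structured_fwd <- function(s, p) {
  h1 <- add_bias(s %*% p[["str_embed.W1"]], p[["str_embed.b1"]])
  h2 <- add_bias(h1 %*% p[["str_embed.W2"]], p[["str_embed.b2"]])
  list(out = pmax(h2, 0), cache = list(s = s, h1 = h1, h2 = h2, p = p))
}

embed_structured_bwd <- function(cache, d_out, g) {
  p <- cache$p
  d_h2 <- d_out * (cache$h2 > 0)
  gacc(g, "str_embed.W2", crossprod(cache$h1, d_h2))
  gacc(g, "str_embed.b2", colSums(d_h2))
  d_h1 <- d_h2 %*% t(p[["str_embed.W2"]])
  gacc(g, "str_embed.W1", crossprod(cache$s, d_h1))
  gacc(g, "str_embed.b1", colSums(d_h1))
  invisible(NULL)
}

# 32 x 1024 matrix whose row z is axial slice z flattened column-major
cube_slices <- function(cube) {
  voxels <- if (inherits(cube, "nodule_cube")) cube$voxels else cube
  if (!identical(dim(voxels), c(32L, 32L, 32L))) {
    stopf("cube must be 32 x 32 x 32, got %s",
          paste(dim(voxels), collapse = " x "))
  }
  matrix(voxels, nrow = 32L, ncol = 1024L)
}

#' Embed a nodule cube into token space
#'
#' The 32^3 cube is split into its 32 axial slices; one shared
#' convolution with a full 32 x 32 kernel (stride 32, no padding) and
#' `model_dim` output channels maps each slice to a single token, so the
#' embedding is a shared linear map of the flattened slices and slice
#' order is preserved.
#'
#' @param cube A normalized `nodule_cube` or bare 32^3 array.
#' @param model A `noduleca_model`.
#' @return A 32 x `model_dim` matrix of slice tokens.
#' @export
embed_volume <- function(cube, model) {
  p <- model_params(model)
  linear_fwd(cube_slices(cube), p[["vol_embed.W"]], p[["vol_embed.b"]])$out
}

#' Cross-attend one token sequence over another
#'
#' Single-head scaled dot-product attention with queries projected from
#' one sequence and keys/values from the other:
#' `softmax((Xq Wq)(Xkv Wk)^T / sqrt(d)) (Xkv Wv)`, with `d` the model
#' dimension. The fused model calls this twice with independent weights:
#' image queries over structured keys/values, and structured queries over
#' image keys/values.
#'
#' @param query_seq L_q x d matrix supplying queries.
#' @param kv_seq L_kv x d matrix supplying keys and values.
#' @param wq,wk,wv d x d projection matrices.
#' @return An L_q x d attended sequence.
#' @export
cross_attend <- function(query_seq, kv_seq, wq, wk, wv) {
  p <- list("ca.Wq" = wq, "ca.Wk" = wk, "ca.Wv" = wv)
  cross_attn_fwd(query_seq, kv_seq, p, "ca",
                 nrow(query_seq), nrow(kv_seq), 1L)$out
}

#' Layer-normalize and mean-pool a token sequence
#'
#' Applies layer normalization per token over the feature axis (with a
#' learned gain/offset), then averages over the tokens, collapsing an
#' L x d sequence to a single d-vector.
#'
#' @param x_ca L x d matrix (an attended or encoded sequence).
#' @param gamma,beta Length-d layer-norm gain and offset (defaults 1, 0).
#' @return A length-d numeric vector.
#' @export
pool_and_normalize <- function(x_ca, gamma = rep(1, ncol(x_ca)),
                               beta = rep(0, ncol(x_ca))) {
  p <- list("pool.g" = gamma, "pool.b" = beta)
  as.numeric(pool_fwd(x_ca, p, "pool", nrow(x_ca), 1L)$out)
}

#' Fuse pooled vectors and classify
#'
#' Concatenates the structured vector first, then the image vector, into
#' a fused representation `V` and applies a single linear map to two
#' logits (benign = index 1, malignant = index 2), with softmax
#' probabilities and optional cross-entropy loss against a 0/1 label.
#'
#' @param s_final,c_final Pooled d-vectors.
#' @param w `(2 d) x 2` classifier weights; `b` length-2 bias.
#' @param label Optional true label (0 benign, 1 malignant).
#' @return List with `v`, `logits`, `probs` and (if `label` given) `loss`.
#' @export
fuse_and_classify <- function(s_final, c_final, w, b = c(0, 0),
                              label = NULL) {
  v <- c(s_final, c_final)
  logits <- as.numeric(v %*% w) + b
  probs <- softmax_vec(logits)
  out <- list(v = v, logits = logits, probs = probs)
  if (!is.null(label)) out$loss <- -log(probs[label + 1L])
  out
}

model_params <- function(model) {
  if (inherits(model, "noduleca_model")) model$params else model
}

# stack the batch's inputs: (batch * 9) x 4 ratings, (batch * 32) x 1024
# flattened slices
batch_inputs <- function(samples, config) {
  out <- list()
  if (uses_structured(config)) {
    mats <- lapply(samples, function(s) {
      if (is.null(s$ratings)) stopf("sample lacks a rating matrix")
      scale_ratings(s$ratings)
    })
    out$s <- unname(do.call(rbind, mats))
    if (!is_finite_matrix(out$s)) stopf("non-finite structured input")
  }
  if (uses_image(config)) {
    mats <- lapply(samples, function(s) {
      if (is.null(s$cube)) stopf("sample lacks a nodule cube")
      cube_slices(s$cube)
    })
    out$slices <- do.call(rbind, mats)
    if (!is_finite_matrix(out$slices)) stopf("non-finite cube input")
  }
  out
}

# Full forward pass for a mini-batch. Returns batch x 2 logits and
# probabilities plus the cache needed for the backward pass. `training`
# enables dropout. Rows never mix across samples, so a batch of size B
# produces exactly the B single-sample results.
forward_batch <- function(model, samples, training = FALSE) {
  config <- model$config
  p <- model$params
  batch <- length(samples)
  l_s <- config$n_structured_tokens
  l_c <- config$n_slices
  cache <- list(config = config, batch = batch)

  inputs <- batch_inputs(samples, config)
  s_branch <- NULL
  c_branch <- NULL

  if (uses_structured(config)) {
    emb <- embed_structured_fwd(inputs$s, p)
    cache$s_emb <- emb
    if (uses_encoders(config)) {
      enc <- encoder_fwd(emb$out, p, "enc_s", config, training, l_s, batch)
      cache$s_enc <- enc
      s_branch <- enc$out
    } else {
      s_branch <- emb$out   # identity encoder ablation
    }
  }
  if (uses_image(config)) {
    emb <- linear_fwd(inputs$slices, p[["vol_embed.W"]], p[["vol_embed.b"]])
    cache$c_emb <- emb
    if (uses_encoders(config)) {
      enc <- encoder_fwd(emb$out, p, "enc_c", config, training, l_c, batch)
      cache$c_enc <- enc
      c_branch <- enc$out
    } else {
      c_branch <- emb$out
    }
  }

  if (uses_structured(config) && uses_image(config)) {
    if (uses_cross_attention(config)) {
      # Naming follows the fusion equations: s_ca is produced by *image*
      # queries attending over structured keys/values, and c_ca by
      # structured queries over image keys/values, counterintuitive as
      # the subscripts read.
      s_ca <- cross_attn_fwd(c_branch, s_branch, p, "ca_s", l_c, l_s, batch)
      c_ca <- cross_attn_fwd(s_branch, c_branch, p, "ca_c", l_s, l_c, batch)
      cache$s_ca <- s_ca; cache$c_ca <- c_ca
      ps <- pool_fwd(s_ca$out, p, "pool_s", l_c, batch)
      pc <- pool_fwd(c_ca$out, p, "pool_c", l_s, batch)
    } else {
      ps <- pool_fwd(s_branch, p, "pool_s", l_s, batch)
      pc <- pool_fwd(c_branch, p, "pool_c", l_c, batch)
    }
    cache$pool_s <- ps; cache$pool_c <- pc
    v <- cbind(ps$out, pc$out)        # structured first
  } else if (uses_structured(config)) {
    ps <- pool_fwd(s_branch, p, "pool_s", l_s, batch)
    cache$pool_s <- ps
    v <- ps$out
  } else {
    pc <- pool_fwd(c_branch, p, "pool_c", l_c, batch)
    cache$pool_c <- pc
    v <- pc$out
  }

  hd <- head_fwd(v, p)
  cache$head <- hd
  list(logits = hd$logits, probs = softmax_rows(hd$logits), v = v,
       cache = cache)
}

# single-sample convenience wrapper around forward_batch
forward_sample <- function(model, sample, training = FALSE) {
  fwd <- forward_batch(model, list(sample), training = training)
  list(logits = fwd$logits[1, ], probs = fwd$probs[1, ], v = fwd$v[1, ],
       cache = fwd$cache)
}

# Backward pass matching forward_batch; accumulates into environment g.
backward_batch <- function(model, cache, d_logits, g) {
  config <- cache$config
  p <- model$params
  d_v <- head_bwd(cache$head$cache, d_logits, g, p)
  d <- config$model_dim

  both <- uses_structured(config) && uses_image(config)
  d_s_branch <- NULL
  d_c_branch <- NULL
  if (both) {
    d_ps <- d_v[, 1:d, drop = FALSE]
    d_pc <- d_v[, (d + 1):(2 * d), drop = FALSE]
    d_pool_s_in <- pool_bwd(cache$pool_s$cache, d_ps, g)
    d_pool_c_in <- pool_bwd(cache$pool_c$cache, d_pc, g)
    if (uses_cross_attention(config)) {
      b_s <- cross_attn_bwd(cache$s_ca$cache, d_pool_s_in, g)
      b_c <- cross_attn_bwd(cache$c_ca$cache, d_pool_c_in, g)
      d_s_branch <- b_s$d_kv + b_c$d_q
      d_c_branch <- b_s$d_q + b_c$d_kv
    } else {
      d_s_branch <- d_pool_s_in
      d_c_branch <- d_pool_c_in
    }
  } else if (uses_structured(config)) {
    d_s_branch <- pool_bwd(cache$pool_s$cache, d_v, g)
  } else {
    d_c_branch <- pool_bwd(cache$pool_c$cache, d_v, g)
  }

  if (uses_structured(config)) {
    d_emb <- if (uses_encoders(config)) {
      encoder_bwd(cache$s_enc$cache, d_s_branch, g)
    } else d_s_branch
    embed_structured_bwd(cache$s_emb$cache, d_emb, g)
  }
  if (uses_image(config)) {
    d_emb <- if (uses_encoders(config)) {
      encoder_bwd(cache$c_enc$cache, d_c_branch, g)
    } else d_c_branch
    linear_bwd(cache$c_emb$cache, d_emb, g, "vol_embed.W", "vol_embed.b")
  }
  invisible(NULL)
}

# mean loss and mean parameter gradients over a list of samples
loss_and_grads <- function(model, samples, training = TRUE) {
  g <- new.env(parent = emptyenv())
  labels <- vapply(samples, function(s) as.integer(s$label), integer(1))
  fwd <- forward_batch(model, samples, training = training)
  ce <- ce_fwd(fwd$logits, labels)
  backward_batch(model, fwd$cache, ce$d_logits, g)
  list(loss = ce$loss, grads = as.list(g))
}

#' Predict labels for a list of samples
#'
#' @param object A trained `noduleca_model`.
#' @param samples List of samples, each with `ratings` (9 x 4), `cube`
#'   and optionally `nodule_id` and `label`.
#' @param ... Unused.
#' @param chunk_size Samples per forward pass (bounds memory).
#' @return A tibble with `nodule_id`, `prob_benign`, `prob_malignant`,
#'   `pred` (0/1) and `label` when available.
#' @export
predict.noduleca_model <- function(object, samples, ..., chunk_size = 100L) {
  starts <- seq(1L, length(samples), by = chunk_size)
  rows <- purrr::map(starts, function(s) {
    chunk <- samples[s:min(s + chunk_size - 1L, length(samples))]
    fwd <- forward_batch(object, chunk, training = FALSE)
    tibble::tibble(
      nodule_id = vapply(chunk, function(x) x$nodule_id %||% NA_character_,
                         character(1)),
      prob_benign = fwd$probs[, 1], prob_malignant = fwd$probs[, 2],
      pred = max.col(fwd$probs, ties.method = "first") - 1L,
      label = vapply(chunk, function(x) {
        if (is.null(x$label)) NA_integer_ else as.integer(x$label)
      }, integer(1))
    )
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a model checkpoint
#'
#' The weights go to a single serialized file and the configuration plus
#' seed to a JSON sidecar (`<path>.json`). Loading verifies the sidecar
#' against an expected configuration when one is supplied; a mismatch is
#' an error, never a silent reinterpretation.
#'
#' @param model A `noduleca_model`.
#' @param path Checkpoint file path.
#' @return `path` invisibly (save); the model (load).
#' @export
save_model <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$params, path)
  jsonlite::write_json(
    c(unclass(model$config), list(seed = model$seed)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @param expected_config Optional [model_config()] the checkpoint must
#'   match.
#' @export
load_model <- function(path, expected_config = NULL) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  config <- do.call(model_config, sidecar[setdiff(names(sidecar), "seed")])
  if (!is.null(expected_config)) {
    stopifnot(inherits(expected_config, "noduleca_config"))
    if (!isTRUE(all.equal(unclass(config), unclass(expected_config)))) {
      stopf("checkpoint config does not match the expected config")
    }
  }
  structure(list(params = readRDS(path), config = config,
                 seed = as.integer(sidecar$seed)),
            class = "noduleca_model")
}
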