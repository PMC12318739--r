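test_that("structured embedding matches the explicit two-layer oracle", {
  withr::with_seed(11, {
    model <- init_model(model_config(model_dim = 48L, n_heads = 4L), seed = 2)
    p <- model$params
    for (i in 1:5) {
      s <- rand_mat(9, 4)
      got <- embed_structured(s, model)
      want <- oracle_embed_structured(s, p[["str_embed.W1"]],
                                      p[["str_embed.b1"]],
                                      p[["str_embed.W2"]],
                                      p[["str_embed.b2"]])
      expect_lt(max(abs(got - want)), 1e-6)
      expect_true(all(got >= 0))
    }
    # zero input with zero biases gives zero output
    expect_true(all(embed_structured(matrix(0, 9, 4), model) == 0))
    expect_error(embed_structured(matrix(0, 3, 4), model), "9 x 4")
  })
})

test_that("volume embedding is a shared per-slice linear map", {
  withr::with_seed(12, {
    model <- init_model(model_config(model_dim = 32L), seed = 3)
    cube <- array(stats::runif(32768), c(32L, 32L, 32L))
    tokens <- embed_volume(cube, model)
    expect_equal(dim(tokens), c(32L, 32L))
    # token z is bias + sum over pixels of slice z times the kernel column
    w <- model$params[["vol_embed.W"]]; b <- model$params[["vol_embed.b"]]
    for (z in c(1, 17, 32)) {
      want <- b + as.numeric(as.vector(cube[z, , ]) %*% w)
      expect_lt(max(abs(tokens[z, ] - want)), 1e-9)
    }
    # zero cube with zero bias gives zero tokens
    expect_true(all(embed_volume(array(0, c(32, 32, 32)), model) == 0))
    # shared weights: permuting slices permutes tokens identically
    perm <- sample(32)
    expect_equal(embed_volume(cube[perm, , ], model), tokens[perm, ],
                 tolerance = 1e-12)
  })
})

test_that("cross-attention matches the brute-force oracle and normalizes weights", {
  withr::with_seed(13, {
    for (i in 1:10) {
      d <- 24
      xq <- rand_mat(3, d); xkv <- rand_mat(2, d)
      wq <- rand_mat(d, d, 0.3); wk <- rand_mat(d, d, 0.3)
      wv <- rand_mat(d, d, 0.3)
      got <- cross_attend(xq, xkv, wq, wk, wv)
      want <- oracle_cross_attend(xq, xkv, wq, wk, wv)
      expect_lt(max(abs(got - want)), 1e-6)
    }
    # single key/value: softmax weight is 1, every row is that value row
    xq <- rand_mat(5, 16); xkv <- rand_mat(1, 16)
    wq <- rand_mat(16, 16); wk <- rand_mat(16, 16); wv <- rand_mat(16, 16)
    out <- cross_attend(xq, xkv, wq, wk, wv)
    expect_equal(out, matrix(rep(as.numeric(xkv %*% wv), each = 5), 5, 16),
                 tolerance = 1e-10)
    # attention rows sum to one
    a <- noduleca:::softmax_rows(rand_mat(7, 9))
    expect_equal(rowSums(a), rep(1, 7), tolerance = 1e-12)
  })
})

test_that("pooling layer-normalizes per token then averages over tokens", {
  withr::with_seed(14, {
    x <- rand_mat(4, 20)
    gamma <- stats::runif(20, 0.5, 1.5); beta <- stats::rnorm(20)
    expect_lt(max(abs(pool_and_normalize(x, gamma, beta) -
                        oracle_pool_and_normalize(x, gamma, beta))), 1e-6)
    # a single token pools to its own normalized value
    one <- rand_mat(1, 20)
    expect_equal(pool_and_normalize(one, gamma, beta),
                 oracle_pool_and_normalize(one, gamma, beta),
                 tolerance = 1e-10)
    # identical tokens repeated pool to the single-token result
    rep4 <- one[rep(1, 4), ]
    expect_equal(pool_and_normalize(rep4, gamma, beta),
                 pool_and_normalize(one, gamma, beta), tolerance = 1e-12)
  })
})

test_that("fusion concatenates structured-first and classifies with cross-entropy", {
  withr::with_seed(15, {
    s <- stats::rnorm(8); c_ <- stats::rnorm(8)
    w <- rand_mat(16, 2); b <- stats::rnorm(2)
    got <- fuse_and_classify(s, c_, w, b, label = 1L)
    want <- oracle_fuse_and_classify(s, c_, w, b, label = 1L)
    expect_equal(got$v, c(s, c_))
    expect_lt(max(abs(got$logits - want$logits)), 1e-10)
    expect_lt(abs(got$loss - want$loss), 1e-10)
    # symmetric zero case
    zero <- fuse_and_classify(rep(0, 8), rep(0, 8), matrix(0, 16, 2),
                              c(0, 0), label = 0L)
    expect_equal(zero$probs, c(0.5, 0.5))
    expect_equal(zero$loss, log(2))
    # concatenation order matters unless both halves agree
    swapped <- fuse_and_classify(c_, s, w, b)
    expect_false(isTRUE(all.equal(got$logits, swapped$logits)))
  })
})

test_that("ablations change the forward pass as specified", {
  ds <- gen_dataset(synth_config(n_samples = 2, delta = 1, seed = 31))
  sample <- ds$samples[[1]]

  full <- init_model(tiny_model_config(), seed = 5)
  out_full <- noduleca:::forward_sample(full, sample)
  expect_length(out_full$logits, 2)
  expect_length(out_full$v, 32)  # 2 * model_dim
  expect_equal(sum(out_full$probs), 1, tolerance = 1e-12)

  # identity encoders: the encoded branch equals the raw embedding
  no_tr <- init_model(tiny_model_config(ablation = "no_transformer"), seed = 5)
  fwd <- noduleca:::forward_batch(no_tr, list(sample))
  s_emb <- noduleca:::embed_structured_fwd(
    unname(scale_ratings(sample$ratings)), no_tr$params)$out
  expect_identical(fwd$cache$s_emb$out, s_emb)
  expect_null(fwd$cache$s_enc)

  # removing cross-attention changes the output on the same weights
  no_ca <- init_model(tiny_model_config(ablation = "no_cross_attention"),
                      seed = 5)
  shared <- intersect(names(no_ca$params), names(full$params))
  no_ca$params[shared] <- full$params[shared]
  out_no_ca <- noduleca:::forward_sample(no_ca, sample)
  expect_false(isTRUE(all.equal(out_full$logits, out_no_ca$logits)))

  # unimodal ablations classify from a single pooled vector
  s_only <- init_model(tiny_model_config(ablation = "structured_only"),
                       seed = 5)
  expect_length(noduleca:::forward_sample(s_only, sample)$v, 16)
  i_only <- init_model(tiny_model_config(ablation = "image_only"), seed = 5)
  expect_length(noduleca:::forward_sample(i_only, sample)$v, 16)
  expect_null(i_only$params[["str_embed.W1"]])
})

test_that("a batched forward pass reproduces single-sample results", {
  ds <- gen_dataset(synth_config(n_samples = 6, delta = 1, seed = 32))
  model <- init_model(tiny_model_config(), seed = 6)
  batch <- noduleca:::forward_batch(model, ds$samples)
  for (i in seq_along(ds$samples)) {
    single <- noduleca:::forward_sample(model, ds$samples[[i]])
    expect_lt(max(abs(batch$logits[i, ] - single$logits)), 1e-5)
  }
})

test_that("analytic gradients agree with central finite differences", {
  ds <- gen_dataset(synth_config(n_samples = 2, delta = 1, seed = 33))
  config <- model_config(model_dim = 8L, n_blocks = 1L, n_heads = 2L,
                         ffn_dim = 16L, dropout = 0)
  model <- init_model(config, seed = 7)
  # move zero-initialized biases off the ReLU kink so the loss is smooth
  # at the point being checked (minimum-ordinal ratings scale to exact
  # zeros, which would otherwise sit exactly on the kink)
  withr::with_seed(77, {
    model$params <- lapply(model$params, function(p) {
      p + stats::rnorm(length(p), sd = 0.02)
    })
  })
  lg <- noduleca:::loss_and_grads(model, ds$samples, training = FALSE)
  eps <- 1e-5
  withr::with_seed(8, {
    picks <- sample(names(lg$grads), 15)
    for (nm in picks) {
      idx <- sample(length(model$params[[nm]]), 1)
      perturbed <- function(v) {
        m2 <- model
        m2$params[[nm]][idx] <- v
        noduleca:::loss_and_grads(m2, ds$samples, training = FALSE)$loss
      }
      v0 <- model$params[[nm]][idx]
      numeric_grad <- (perturbed(v0 + eps) - perturbed(v0 - eps)) / (2 * eps)
      analytic <- lg$grads[[nm]][idx]
      rel <- abs(numeric_grad - analytic) /
        max(abs(numeric_grad), abs(analytic), 1e-8)
      expect_lt(rel, 1e-4)
    }
  })
})

test_that("checkpoints round-trip and reject mismatched configurations", {
  model <- init_model(tiny_model_config(), seed = 9)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_model(model, path)
  back <- load_model(path, expected_config = tiny_model_config())
  expect_equal(back$params, model$params)
  expect_equal(unclass(back$config), unclass(model$config))
  expect_error(load_model(path, expected_config = model_config()),
               "does not match")
})
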