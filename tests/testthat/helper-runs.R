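# Expensive training runs shared by several acceptance checks are
# computed once per test session. The study conditions are fixed here:
# 300 synthetic nodules at 50% prevalence, reduced model (2 encoder
# blocks, width 64), 10 epochs of the standard protocol.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

acceptance_dataset <- function(delta) {
  cached_run(paste0("ds", delta), gen_dataset(synth_config(
    n_samples = 300L, malignant_fraction = 0.5, delta = delta, seed = 421L)))
}

reduced_model_config <- function(ablation = "full") {
  model_config(model_dim = 64L, n_blocks = 2L, ablation = ablation)
}

acceptance_cv <- function(delta, ablation = "full") {
  cached_run(paste0("cv", delta, ablation), cross_validate(
    acceptance_dataset(delta)$samples,
    reduced_model_config(ablation),
    train_config(epochs = 10L, seed = 7L)))
}
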