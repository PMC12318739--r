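test_that("fold assignment partitions samples and preserves class balance", {
  labels <- c(rep(1L, 5), rep(0L, 5))
  fold <- make_folds(labels, n_folds = 5, seed = 1)
  expect_equal(sort(unique(fold)), 1:5)
  expect_true(all(table(fold) == 2))
  # reproducible from the seed
  expect_identical(fold, make_folds(labels, n_folds = 5, seed = 1))
  expect_false(identical(fold, make_folds(labels, n_folds = 5, seed = 2)))

  # the study's class sizes: per-fold ratio within one sample of global
  big <- c(rep(1L, 330), rep(0L, 354))
  f <- make_folds(big, n_folds = 5, seed = 3)
  per_fold_pos <- tapply(big, f, sum)
  expect_true(all(abs(per_fold_pos - 330 / 5) <= 1))
  per_fold_n <- table(f)
  expect_true(max(per_fold_n) - min(per_fold_n) <= 2)

  # non-stratified mode still partitions
  f2 <- make_folds(big, n_folds = 5, seed = 3, stratified = FALSE)
  expect_equal(length(f2), 684)
  expect_equal(sort(unique(f2)), 1:5)
  expect_error(make_folds(c(0, 1), n_folds = 5), "exceeds")
})

test_that("the metric suite implements the confusion-matrix formulas", {
  perfect <- evaluate_predictions(c(rep(1, 50), rep(0, 50)),
                                  c(rep(1, 50), rep(0, 50)))
  expect_true(all(perfect$metrics == 1))
  expect_equal(unname(perfect$confusion), c(50, 50, 0, 0))

  # hand-worked case
  ev <- evaluate_predictions(
    c(rep(1, 97), rep(0, 3), rep(1, 4), rep(0, 96)),
    c(rep(1, 100), rep(0, 100)))
  expect_equal(unname(ev$confusion["tp"]), 97)
  expect_equal(unname(ev$metrics["accuracy"]), 0.965)
  expect_equal(unname(ev$metrics["precision"]), 97 / 101, tolerance = 1e-12)
  expect_equal(unname(ev$metrics["sensitivity"]), 0.97)
  expect_equal(unname(ev$metrics["specificity"]), 0.96)
  expect_equal(unname(ev$metrics["f1"]),
               2 * (97 / 101) * 0.97 / (97 / 101 + 0.97), tolerance = 1e-12)

  # degenerate predictor: sensitivity 0, precision undefined (NA, not 0)
  degenerate <- evaluate_predictions(rep(0, 10), c(rep(1, 4), rep(0, 6)))
  expect_equal(unname(degenerate$metrics["sensitivity"]), 0)
  expect_true(is.na(degenerate$metrics["precision"]))
  expect_true(is.na(degenerate$metrics["f1"]))

  expect_error(evaluate_predictions(numeric(0), numeric(0)), "no predictions")
  expect_error(evaluate_predictions(c(0, 2), c(0, 1)), "0 .*benign")
})

test_that("metric identities hold over random confusion matrices", {
  withr::with_seed(21, {
    for (i in 1:200) {
      counts <- sample(0:80, 4, replace = TRUE)
      m <- noduleca:::metrics_from_confusion(counts[1], counts[2],
                                             counts[3], counts[4])
      pos <- counts[1] + counts[4]   # tp + fn
      neg <- counts[2] + counts[3]   # tn + fp
      if (pos > 0 && neg > 0) {
        expect_equal(unname(m["accuracy"]),
                     unname((m["sensitivity"] * pos + m["specificity"] * neg) /
                              (pos + neg)),
                     tolerance = 1e-12)
      }
      if (!is.na(m["precision"]) && !is.na(m["sensitivity"]) &&
            m["precision"] + m["sensitivity"] > 0) {
        expect_equal(unname(m["f1"]),
                     unname(2 / (1 / m["precision"] + 1 / m["sensitivity"])),
                     tolerance = 1e-12)
        if (m["precision"] == m["sensitivity"]) {
          expect_equal(unname(m["f1"]), unname(m["precision"]),
                       tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("training reduces the loss, freezes at zero learning rate, and is deterministic", {
  ds <- gen_dataset(synth_config(n_samples = 24, malignant_fraction = 0.5,
                                 delta = 1, seed = 41))
  cfg <- tiny_model_config()

  fit <- train_fold(ds$samples, cfg, train_config(epochs = 4, batch_size = 12,
                                                  seed = 2))
  expect_lt(fit$history$loss[4], fit$history$loss[1])
  expect_true(all(is.finite(fit$history$loss)))

  # lr = 0: parameters identical after an epoch
  frozen <- train_fold(ds$samples, cfg,
                       train_config(epochs = 1, batch_size = 12,
                                    learning_rate = 0, seed = 2))
  reference <- init_model(cfg, seed = noduleca:::derive_seed(2, 1))
  expect_equal(frozen$params, reference$params, tolerance = 1e-15)

  # same seed, bit-identical losses; different seed differs
  again <- train_fold(ds$samples, cfg, train_config(epochs = 4,
                                                    batch_size = 12, seed = 2))
  expect_identical(fit$history$loss, again$history$loss)
  other <- train_fold(ds$samples, cfg, train_config(epochs = 1,
                                                    batch_size = 12, seed = 3))
  expect_false(identical(fit$history$loss[1], other$history$loss[1]))

  expect_error(train_fold(list(), cfg, train_config()), "empty")
})

test_that("cross-validation tests each sample once and averages per-fold metrics", {
  ds <- gen_dataset(synth_config(n_samples = 30, malignant_fraction = 0.5,
                                 delta = 1, seed = 42))
  cv <- cross_validate(ds$samples, tiny_model_config(),
                       train_config(epochs = 2, batch_size = 24, n_folds = 5,
                                    seed = 3))
  expect_equal(nrow(cv$fold_metrics), 5)
  # every sample appears in exactly one test fold
  expect_equal(sort(cv$predictions$nodule_id),
               sort(ds$manifest$nodule_id))
  expect_equal(sum(cv$pooled_confusion), 30)
  # the headline summary is the arithmetic mean of per-fold metrics,
  # not the pooled-confusion metrics
  expect_equal(unname(cv$mean_metrics["accuracy"]),
               mean(cv$fold_metrics$accuracy))
  expect_true(all(c("accuracy", "precision", "sensitivity", "specificity",
                    "f1") %in% names(cv$mean_metrics)))

  # broom-style accessors
  long <- tidy(cv)
  expect_equal(nrow(long), 25)
  expect_equal(names(long), c("fold", "metric", "value"))
  g <- glance(cv)
  expect_equal(nrow(g), 1)
  expect_equal(g$accuracy, unname(cv$mean_metrics["accuracy"]))
  expect_s3_class(autoplot(cv), "ggplot")

  one_class <- ds$samples[vapply(ds$samples, `[[`, 0L, "label") == 1]
  expect_error(cross_validate(one_class, tiny_model_config()),
               "both classes")
})
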