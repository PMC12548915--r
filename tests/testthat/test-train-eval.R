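# Training loop, early stopping, evaluation metrics, multi-seed repetition.

local_fit <- function() {
  if (is.null(.fixtures$fit)) {
    bm <- fixture_benchmark()
    cfg <- tiny_config(dropout = 0.1, max_epochs = 5L, patience = 5L,
                       batch_size = 32L, learning_rate = 1e-3, seed = 1L)
    .fixtures$fit <- train_model(cfg, bm$examples, bm$dci_observed,
                                 bm$split_cold_drug, fixture_panel())
  }
  .fixtures$fit
}

test_that("training reduces the composite objective on a small benchmark", {
  fit <- local_fit()
  h <- fit$history
  expect_lt(h$train_total[nrow(h)], h$train_total[1])
  expect_true(all(is.finite(h$train_total)))
  expect_true(all(h$n_supervised > 0))
  expect_s3_class(fit$model, "cypdfi_model")
})

test_that("training is deterministic given the seed", {
  bm <- fixture_benchmark()
  cfg <- tiny_config(dropout = 0.1, max_epochs = 2L, batch_size = 32L,
                     learning_rate = 1e-3, seed = 9L)
  f1 <- train_model(cfg, bm$examples, bm$dci_observed, bm$split_cold_drug,
                    fixture_panel())
  f2 <- train_model(cfg, bm$examples, bm$dci_observed, bm$split_cold_drug,
                    fixture_panel())
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("early stopping respects patience and never returns a later epoch", {
  fit <- local_fit()
  expect_equal(fit$best_epoch, which.min(fit$history$val_l1))
  if (fit$stop_reason == "early_stop") {
    expect_equal(nrow(fit$history), fit$best_epoch + 5L)
  } else {
    expect_equal(fit$stop_reason, "max_epochs")
  }
  # a run that cannot improve validation loss stops early
  bm <- fixture_benchmark()
  cfg <- tiny_config(max_epochs = 30L, patience = 2L, batch_size = 32L,
                     learning_rate = 0, seed = 2L)  # frozen optimizer
  frozen <- train_model(cfg, bm$examples, bm$dci_observed, bm$split_cold_drug,
                        fixture_panel())
  expect_equal(frozen$stop_reason, "early_stop")
  expect_equal(nrow(frozen$history), frozen$best_epoch + 2L)
})

test_that("evaluation metrics match exhaustive pair counting", {
  # AUROC by brute force over all (positive, negative) pairs:
  # 3 of 4 pairs concordant -> 0.75
  scores <- c(0.9, 0.5, 0.4, 0.6)
  labels <- c(1, 1, 0, 0)
  pairs <- expand.grid(p = which(labels == 1), n = which(labels == 0))
  conc <- mean(ifelse(scores[pairs$p] > scores[pairs$n], 1,
                      ifelse(scores[pairs$p] == scores[pairs$n], 0.5, 0)))
  rep <- metrics_from_scores(scores, labels)
  expect_equal(rep$auroc, conc)
  expect_equal(rep$auroc, 0.75)

  perfect <- metrics_from_scores(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$auprc, 1)
  expect_equal(perfect$f1, 1)

  ties <- metrics_from_scores(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(ties$auroc, 0.5)

  expect_message(single <- metrics_from_scores(c(0.2, 0.6), c(1, 1)),
                 "single class")
  expect_true(is.na(single$auroc))
  expect_equal(single$recall, 0.5)  # threshold metrics still defined
})

test_that("average precision equals its step-curve definition on a hand case", {
  scores <- c(0.9, 0.7, 0.6, 0.3)
  labels <- c(1, 0, 1, 0)
  # ranked: 1, 0, 1, 0 -> AP = 1/2 * (1/1) + 1/2 * (2/3)
  rep <- metrics_from_scores(scores, labels)
  expect_equal(rep$auprc, 0.5 * 1 + 0.5 * (2 / 3))
})

test_that("multi-seed repetition aggregates mean and sample deviation", {
  bm <- fixture_benchmark()
  cfg <- tiny_config(max_epochs = 2L, batch_size = 32L, learning_rate = 1e-3)
  one <- repeat_runs(cfg, bm$examples, bm$dci_observed, bm$split_cold_drug,
                     fixture_panel(), seeds = 4L)
  expect_equal(nrow(one$per_seed), 1L)
  expect_equal(unname(one$sd), rep(0, 5))
  same <- repeat_runs(cfg, bm$examples, bm$dci_observed, bm$split_cold_drug,
                      fixture_panel(), seeds = c(4L, 4L))
  expect_equal(same$per_seed$auroc[1], same$per_seed$auroc[2])
  expect_equal(unname(same$sd["auroc"]), 0)
})

test_that("attention DCI scores are available for held-out compounds", {
  bm <- fixture_benchmark()
  fit <- local_fit()
  sc <- dci_attention_scores(fit$model, bm$drugs[1:4, ], fixture_panel())
  expect_length(sc, 4L)
  for (m in sc) {
    expect_equal(dim(m), c(2L, 5L))
    expect_true(all(m >= 0 & m <= 1))
  }
  rec <- dci_recovery_auroc(fit$model, bm$drugs, bm$dci_true, fixture_panel())
  expect_equal(rec$n_cells, 10L * nrow(bm$drugs))
  expect_true(is.finite(rec$auroc))
})

test_that("prediction is consistent between batched and single-pair paths", {
  bm <- fixture_benchmark()
  model <- tiny_model()
  ex <- bm$examples[1:3, ]
  batch_scores <- predict_pairs(model, ex, fixture_panel())
  for (k in 1:3) {
    tr <- forward_pair(model, ex$drug_smiles[k], ex$food_smiles[k],
                       fixture_panel())
    expect_equal(tr$y_hat, batch_scores[k], tolerance = 1e-9)
  }
})
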