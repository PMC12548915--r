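# Reference desk-scale benchmark protocol: train the full model and its
# alpha = 0 ablation on the default synthetic benchmark under a cold-drug
# split, and measure (a) DFI ranking quality on held-out pairs and (b) how
# well the attention-derived DCI scores recover the planted labels of
# held-out drugs.  Used by the acceptance script and the acceptance tests.

#' Desk-scale model configuration for the synthetic benchmark
#'
#' The reference configuration used on the bundled synthetic benchmark:
#' embedding width 32, and an optimization protocol rescaled to the
#' benchmark's ~3,500 training pairs (batch 256, learning rate 2e-3, weight
#' decay 1e-2, at most 18 epochs, patience 10).  All architectural settings
#' (4 heads, 10 pseudo-substructures, dropout 0.3, alpha 5) keep their
#' reference values.
#'
#' @param alpha Auxiliary loss coefficient (0 gives the ablated model).
#' @param seed Integer seed.
#' @param ... Overrides passed to [model_config()].
#' @return A [model_config()].
#' @export
benchmark_model_config <- function(alpha = 5, seed = 0L, ...) {
  args <- utils::modifyList(
    list(h = 32L, alpha = alpha, batch_size = 256L, learning_rate = 2e-3,
         weight_decay = 1e-2, max_epochs = 18L, patience = 10L, seed = seed),
    list(...))
  do.call(model_config, args)
}

#' Run the regularization-recovery benchmark
#'
#' For each seed, trains the full model (`alpha = 5`) and the ablation
#' (`alpha = 0`) on the synthetic benchmark under its cold-drug split, then
#' measures on the test partition: DFI AUROC over held-out pairs, and the
#' DCI recovery AUROC of the attention scores of held-out (test-partition)
#' drugs against the planted true labels.
#'
#' @param benchmark A benchmark from [make_benchmark()] (default benchmark
#'   when `NULL`).
#' @param seeds Integer vector of training seeds.
#' @param panel A [cyp_panel()] (bundled default when `NULL`).
#' @param verbose Print progress.
#' @param ... Overrides forwarded to [benchmark_model_config()].
#' @return List with `per_run` (data frame: seed, alpha, dfi_auroc,
#'   dci_auroc, best_epoch, epochs) and `summary` (per-alpha means).
#' @export
run_recovery_benchmark <- function(benchmark = NULL, seeds = c(0L, 1L, 2L),
                                   panel = NULL, verbose = FALSE, ...) {
  if (is.null(benchmark)) benchmark <- make_benchmark(synthetic_config())
  if (is.null(panel)) panel <- cyp_panel()
  split <- benchmark$split_cold_drug
  part <- split_partitions(split, benchmark$examples)
  test_rows <- which(part == "test")
  test_drugs <- benchmark$drugs[
    benchmark$drugs$id %in% benchmark$examples$drug_id[test_rows], ]
  rows <- list()
  for (seed in seeds) {
    for (alpha in c(5, 0)) {
      cfg <- benchmark_model_config(alpha = alpha, seed = seed, ...)
      fit <- train_model(cfg, benchmark$examples, benchmark$dci_observed,
                         split, panel)
      dfi <- evaluate_dfi(fit$model, benchmark$examples[test_rows, ], panel)
      rec <- dci_recovery_auroc(fit$model, test_drugs, benchmark$dci_true,
                                panel)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, alpha = alpha, dfi_auroc = dfi$auroc,
        dci_auroc = rec$auroc, best_epoch = fit$best_epoch,
        epochs = nrow(fit$history))
      if (verbose) {
        message(sprintf("seed %d alpha %g: DFI AUROC %.4f, DCI AUROC %.4f",
                        seed, alpha, dfi$auroc, rec$auroc))
      }
    }
  }
  per_run <- do.call(rbind, rows)
  summary <- stats::aggregate(per_run[c("dfi_auroc", "dci_auroc")],
                              by = list(alpha = per_run$alpha), FUN = mean)
  list(per_run = per_run, summary = summary)
}
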