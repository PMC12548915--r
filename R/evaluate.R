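# Evaluation: the five DFI metrics (AUROC, AUPRC, F1, precision, recall),
# multi-seed repetition with mean +/- sd aggregation, and the
# attention-recovery AUROC of DCI scores against planted labels.

.auroc <- function(scores, labels) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

# Average precision (step-wise area under the precision-recall curve),
# processing tied scores as a group.
.auprc <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  if (n_pos == 0L || n_pos == length(labels)) return(NA_real_)
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  tp <- cumsum(tp_g)
  pred <- cumsum(n_g)
  prec <- tp / pred
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate DFI predictions
#'
#' Computes AUROC, AUPRC (average precision), and F1 / precision / recall at
#' a fixed decision threshold from eval-mode scores.  With a single-class
#' evaluation set the ranking metrics are reported as `NA` with an
#' explanatory message.
#'
#' @param model A `cypdfi_model`.
#' @param examples DFI data frame with labels.
#' @param panel A [cyp_panel()].
#' @param threshold Decision threshold for F1 / precision / recall.
#' @return Object of class `metrics_report`: list of the five metrics plus
#'   `threshold`, `n`, and the raw `scores`.
#' @export
evaluate_dfi <- function(model, examples, panel, threshold = 0.5) {
  scores <- predict_pairs(model, examples, panel)
  metrics_from_scores(scores, examples$label, threshold)
}

#' @rdname evaluate_dfi
#' @param scores Numeric vector of predicted probabilities.
#' @param labels Binary labels.
#' @export
metrics_from_scores <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  auroc <- .auroc(scores, labels)
  auprc <- .auprc(scores, labels)
  if (is.na(auroc)) {
    message("evaluation set contains a single class: AUROC/AUPRC undefined")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(auroc = auroc, auprc = auprc, f1 = f1,
                 precision = precision, recall = recall,
                 threshold = threshold, n = length(labels), scores = scores),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n=%d  AUROC %.4f  AUPRC %.4f  F1 %.4f  P %.4f  R %.4f (thr %.2f)\n",
    x$n, x$auroc, x$auprc, x$f1, x$precision, x$recall, x$threshold))
  invisible(x)
}

#' Repeat training and evaluation over multiple seeds
#'
#' Trains and evaluates once per seed and aggregates each metric as mean and
#' sample (n-1) standard deviation.
#'
#' @param config A [model_config()] (its seed field is overridden per run).
#' @param examples,dci,split,panel As in [train_model()].
#' @param seeds Integer vector of seeds.
#' @param partition Which partition to evaluate (default `"test"`).
#' @return List with `per_seed` (data frame of metrics by seed), `mean`,
#'   `sd`, and `fits` (list of `cypdfi_fit`).
#' @export
repeat_runs <- function(config, examples, dci, split, panel,
                        seeds = c(0L, 1L, 2L), partition = "test") {
  stopifnot(length(seeds) >= 1L)
  part <- split_partitions(split, examples)
  eval_rows <- which(part == partition)
  stopifnot(length(eval_rows) > 0L)
  rows <- list(); fits <- list()
  for (k in seq_along(seeds)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[k])
    fit <- train_model(cfg, examples, dci, split, panel)
    rep <- evaluate_dfi(fit$model, examples[eval_rows, ], panel)
    rows[[k]] <- data.frame(
      seed = seeds[k], auroc = rep$auroc, auprc = rep$auprc, f1 = rep$f1,
      precision = rep$precision, recall = rep$recall)
    fits[[k]] <- fit
  }
  per_seed <- do.call(rbind, rows)
  metric_cols <- c("auroc", "auprc", "f1", "precision", "recall")
  agg_mean <- colMeans(per_seed[metric_cols])
  agg_sd <- if (nrow(per_seed) > 1L) {
    vapply(per_seed[metric_cols], stats::sd, numeric(1))
  } else {
    stats::setNames(rep(0, length(metric_cols)), metric_cols)
  }
  list(per_seed = per_seed, mean = agg_mean, sd = agg_sd, fits = fits)
}

#' Attention-recovery AUROC of DCI scores against reference labels
#'
#' Flattens the attention-derived DCI score of every (compound, type,
#' isoenzyme) cell that has a reference label and computes the AUROC of the
#' scores against those labels.  Used to quantify how well the regularized
#' attention recovers compound-CYP interactions for held-out compounds.
#'
#' @param model A `cypdfi_model`.
#' @param compounds Data frame with columns `id`, `smiles`.
#' @param reference Named list of 2 x 5 label matrices (entries 1/0/NA).
#' @param panel A [cyp_panel()].
#' @return List with `auroc`, `n_cells`, and the flattened `scores` and
#'   `labels`.
#' @export
dci_recovery_auroc <- function(model, compounds, reference, panel) {
  scores <- dci_attention_scores(model, compounds, panel)
  s_all <- c(); y_all <- c()
  for (id in compounds$id) {
    lab <- reference[[id]]
    if (is.null(lab)) next
    keep <- !is.na(lab)
    s_all <- c(s_all, scores[[id]][keep])
    y_all <- c(y_all, lab[keep])
  }
  list(auroc = .auroc(s_all, y_all), n_cells = length(y_all),
       scores = s_all, labels = y_all)
}
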