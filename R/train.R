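# Training loop: AdamW optimization of the composite objective with
# early stopping on validation loss, plus batched eval-mode prediction.

.adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adamw_step <- function(params, grads, st, lr, wd,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * ((st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps) +
              wd * params[[nm]])
  }
  list(params = params, st = st)
}

# Featurize the unique compounds of a DFI table once; returns a list keyed
# by compound id with $substructures and $graph, plus per-example indices.
.prepare_compounds <- function(examples) {
  ids <- c(examples$drug_id, examples$food_id)
  smiles <- c(examples$drug_smiles, examples$food_smiles)
  uniq <- !duplicated(ids)
  comp_ids <- ids[uniq]
  feats <- featurize_compounds(smiles[uniq])
  comps <- stats::setNames(feats, comp_ids)
  list(comps = comps,
       di = match(examples$drug_id, comp_ids),
       fi = match(examples$food_id, comp_ids))
}

#' Train a DFI model
#'
#' Minimizes `total = l1 + alpha * l2` with AdamW (decoupled weight decay)
#' under the configured batch size, learning rate and weight decay, for at
#' most `max_epochs` epochs with early stopping on the validation loss
#' (patience in epochs).  The monitored validation loss is the primary DFI
#' loss `l1`: the auxiliary term is a training-time regularizer, and on a
#' small cold validation partition its clipped cross-entropy is dominated by
#' a handful of saturated cells, which makes the composite loss a noisy
#' monitor.  The history records both `val_l1` and the composite
#' `val_total`.  The returned model carries the parameters of the
#' best-validation epoch.  Fully deterministic given the configuration seed
#' (initialization, batch order and dropout all draw from it).
#'
#' @param config A [model_config()].
#' @param examples DFI data frame (all partitions).
#' @param dci Named list of observed 2 x 5 DCI label matrices (compound id
#'   -> matrix); compounds absent from the list are fully unlabeled.
#' @param split A `split_spec` from [cold_split()].
#' @param panel A [cyp_panel()].
#' @param verbose Print per-epoch losses.
#' @return List of class `cypdfi_fit`: `model` (best checkpoint), `history`
#'   (per-epoch data frame), `best_epoch`, `stop_reason`.
#' @export
train_model <- function(config, examples, dci, split, panel, verbose = FALSE) {
  stopifnot(inherits(config, "model_config"), inherits(split, "split_spec"),
            inherits(panel, "cyp_panel"))
  part <- split_partitions(split, examples)
  tr_rows <- which(part == "train")
  va_rows <- which(part == "valid")
  if (length(tr_rows) == 0L || length(va_rows) == 0L) {
    stop("empty train or validation partition", call. = FALSE)
  }
  prep <- .prepare_compounds(examples)
  comp_ids <- names(prep$comps)
  dlab <- .stack_dci_labels(lapply(comp_ids, function(id) dci[[id]]))
  y <- examples$label
  L <- panel$embeddings

  model <- new_model(config)  # seeds the RNG with config$seed
  opt <- .adamw_init(model$params)
  hist <- list()
  best <- list(val = Inf, epoch = 0L, model = NULL)
  stop_reason <- "max_epochs"

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(tr_rows)
    ep_l1 <- 0; ep_l2 <- 0; ep_tot <- 0; ep_sup <- 0L; seen <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      sel <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      if (length(sel) < 2L) next  # batch-norm needs >= 2 rows
      ids <- unique(c(prep$di[sel], prep$fi[sel]))
      remap <- match(seq_along(prep$comps), ids)
      di <- remap[prep$di[sel]]; fi <- remap[prep$fi[sel]]
      fw <- .run_batch(model, prep$comps[ids], di, fi, L, training = TRUE)
      lo <- .attach_loss(model, fw, di, fi, y[sel], .dlab_subset(dlab, ids))
      if (!is.finite(lo$total$v)) {
        stop(sprintf("non-finite loss at epoch %d", epoch), call. = FALSE)
      }
      ag_backward(lo$total)
      upd <- .adamw_step(model$params, .collect_grads(fw$pw), opt,
                         config$learning_rate, config$weight_decay)
      model$params <- upd$params
      opt <- upd$st
      nb <- length(sel)
      ep_l1 <- ep_l1 + lo$l1$v * nb
      ep_l2 <- ep_l2 + lo$l2$v * nb
      ep_tot <- ep_tot + lo$total$v * nb
      ep_sup <- ep_sup + lo$n_supervised
      seen <- seen + nb
    }
    val <- .validation_loss(model, prep, va_rows, L, y, dlab)
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_l1 = ep_l1 / seen, train_l2 = ep_l2 / seen,
      train_total = ep_tot / seen, val_l1 = val$l1, val_total = val$total,
      n_supervised = ep_sup)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f (l1 %.4f, l2 %.4f)  valid l1 %.4f",
                      epoch, ep_tot / seen, ep_l1 / seen, ep_l2 / seen, val$l1))
    }
    if (val$l1 < best$val) {
      best <- list(val = val$l1, epoch = epoch, model = .copy_model(model))
    } else if (epoch - best$epoch >= config$patience) {
      stop_reason <- "early_stop"
      break
    }
  }
  structure(list(model = best$model, history = do.call(rbind, hist),
                 best_epoch = best$epoch, stop_reason = stop_reason),
            class = "cypdfi_fit")
}

.dlab_subset <- function(dlab, ids) {
  list(substrate = dlab$substrate[ids, , drop = FALSE],
       inhibition = dlab$inhibition[ids, , drop = FALSE])
}

.validation_loss <- function(model, prep, rows, L, y, dlab, chunk = 4096L) {
  tot <- 0; tot1 <- 0
  for (start in seq(1L, length(rows), by = chunk)) {
    sel <- rows[start:min(start + chunk - 1L, length(rows))]
    ids <- unique(c(prep$di[sel], prep$fi[sel]))
    remap <- match(seq_along(prep$comps), ids)
    di <- remap[prep$di[sel]]; fi <- remap[prep$fi[sel]]
    fw <- .run_batch(model, prep$comps[ids], di, fi, L, training = FALSE)
    lo <- .attach_loss(model, fw, di, fi, y[sel], .dlab_subset(dlab, ids))
    tot <- tot + lo$total$v * length(sel)
    tot1 <- tot1 + lo$l1$v * length(sel)
  }
  list(l1 = as.numeric(tot1 / length(rows)),
       total = as.numeric(tot / length(rows)))
}

#' @export
print.cypdfi_fit <- function(x, ...) {
  cat(sprintf("<cypdfi_fit> best epoch %d (val l1 %.4f), stopped by %s after %d epochs\n",
              x$best_epoch, min(x$history$val_l1), x$stop_reason,
              nrow(x$history)))
  invisible(x)
}

#' Predict DFI scores for compound pairs
#'
#' Eval-mode forward pass in chunks; deterministic for fixed parameters.
#'
#' @param model A `cypdfi_model`.
#' @param examples DFI data frame (label column ignored if present).
#' @param panel A [cyp_panel()].
#' @param chunk Pairs per forward chunk.
#' @return Numeric vector of interaction probabilities.
#' @export
predict_pairs <- function(model, examples, panel, chunk = 4096L) {
  prep <- .prepare_compounds(examples)
  out <- numeric(nrow(examples))
  for (start in seq(1L, nrow(examples), by = chunk)) {
    sel <- start:min(start + chunk - 1L, nrow(examples))
    ids <- unique(c(prep$di[sel], prep$fi[sel]))
    remap <- match(seq_along(prep$comps), ids)
    di <- remap[prep$di[sel]]; fi <- remap[prep$fi[sel]]
    fw <- .run_batch(model, prep$comps[ids], di, fi, panel$embeddings,
                     training = FALSE)
    out[sel] <- fw$yhat
  }
  out
}

#' Attention-derived DCI scores for a set of compounds
#'
#' Runs the encoders and interaction block in eval mode and returns the
#' attention-mass DCI score matrix of every compound (no pair-level
#' computation).
#'
#' @param model A `cypdfi_model`.
#' @param compounds Data frame with columns `id` and `smiles`.
#' @param panel A [cyp_panel()].
#' @return Named list: compound id -> 2 x 5 score matrix.
#' @export
dci_attention_scores <- function(model, compounds, panel) {
  feats <- featurize_compounds(compounds$smiles)
  cfg <- model$config
  tape <- ag_tape()
  pw <- .wrap_params(tape, model$params)
  bb <- .bits_batch(lapply(feats, function(f) f$substructures))
  hs <- .encode_bits(cfg, pw, bb, training = FALSE)
  he <- .encode_panel(cfg, pw, tape, panel$embeddings, training = FALSE)
  ib <- .interaction_block(cfg, pw, he, hs, bb, length(feats))
  out <- lapply(seq_along(feats), function(ci) {
    m <- rbind(substrate = ib$dci$substrate$v[ci, ],
               inhibition = ib$dci$inhibition$v[ci, ])
    colnames(m) <- CYP_ISOENZYMES
    m
  })
  names(out) <- compounds$id
  out
}
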