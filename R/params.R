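# Model configuration, parameter initialization and checkpointing.

CYP_ISOENZYMES <- c("CYP1A2", "CYP3A4", "CYP2C19", "CYP2C9", "CYP2D6")
DCI_TYPES <- c("substrate", "inhibition")
N_FP_BITS <- 1024L
CYP_EMBED_DIM <- 480L

#' Model configuration
#'
#' Hyperparameters of the DFI predictor.  Defaults follow the reference
#' training protocol: embedding width `h = 128`, `n_pseudo = 10`
#' pseudo-substructures, 4 attention heads, dropout 0.3, auxiliary loss
#' coefficient `alpha = 5`, AdamW with learning rate and weight decay 1e-4,
#' batch size 1024, at most 100 epochs with early-stopping patience 10.
#'
#' @param h Embedding width; must be divisible by `heads`.
#' @param n_pseudo Number of trainable pseudo-substructure embeddings.
#' @param heads Attention head count (head 1 = substrate, head 2 = inhibition,
#'   heads 3-4 unregularized).
#' @param dropout Dropout rate in `[0, 1)`.
#' @param alpha Auxiliary (attention-regularization) loss coefficient; 0
#'   disables the auxiliary objective (the ablated model).
#' @param batch_size,learning_rate,weight_decay,max_epochs,patience Training
#'   protocol parameters.
#' @param gin_layers Depth of the edge-attributed graph encoder.
#' @param head_hidden First hidden width of the prediction head (default
#'   `4 * h`).
#' @param seed Integer seed governing initialization, data order and dropout.
#' @return An object of class `model_config`.
#' @export
model_config <- function(h = 128L, n_pseudo = 10L, heads = 4L, dropout = 0.3,
                         alpha = 5, batch_size = 1024L, learning_rate = 1e-4,
                         weight_decay = 1e-4, max_epochs = 100L, patience = 10L,
                         gin_layers = 3L, head_hidden = 4L * h, seed = 1L) {
  h <- as.integer(h); heads <- as.integer(heads); n_pseudo <- as.integer(n_pseudo)
  stopifnot(h >= heads, h %% heads == 0L, n_pseudo >= 1L,
            dropout >= 0, dropout < 1, alpha >= 0, batch_size >= 1L,
            max_epochs >= 1L, patience >= 1L, gin_layers >= 1L)
  structure(list(h = h, n_pseudo = n_pseudo, heads = heads, dropout = dropout,
                 alpha = alpha, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 gin_layers = as.integer(gin_layers),
                 head_hidden = as.integer(head_hidden), seed = as.integer(seed)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  for (k in names(x)) cat(sprintf("  %-13s %s\n", k, format(x[[k]])))
  invisible(x)
}

.xavier <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

.gauss <- function(nin, nout, sd = 0.02) {
  matrix(stats::rnorm(nin * nout, 0, sd), nin, nout)
}

#' Initialize a DFI model
#'
#' Creates all trainable parameters: the 1024-row substructure embedding
#' table, the three encoders, the pseudo-substructure embeddings, the
#' additive multihead attention block (per-head query/key/value projections
#' and score vectors), set-normalization affines, the row-wise feedforward
#' layer, and the prediction head with its batch-normalization state.
#' Weight matrices are Xavier-uniform, biases zero, embedding tables
#' N(0, 0.02).  Drug and food compounds share every encoder parameter.
#'
#' @param config A [model_config()].
#' @return An object of class `cypdfi_model` with elements `params` (named
#'   list of matrices), `bn` (environment of batch-norm running statistics),
#'   `config`, and `vocab_version`.
#' @export
new_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  vs <- feature_vocab_sizes()
  h <- config$h; d <- h %/% config$heads
  set.seed(config$seed)
  p <- list()
  p$sub_table <- .gauss(N_FP_BITS, 2L * h)
  p$sub_W <- .xavier(2L * h, h); p$sub_b <- matrix(0, 1, h)
  p$pseudo <- .gauss(config$n_pseudo, h)
  p$cyp_W <- .xavier(CYP_EMBED_DIM, h); p$cyp_b <- matrix(0, 1, h)
  node_vocabs <- c("atomic_num", "chirality", "degree", "formal_charge",
                   "num_hs", "radical_electrons", "hybridization",
                   "aromatic", "in_ring")
  edge_vocabs <- c("bond_type", "bond_stereo", "conjugated")
  for (k in seq_along(node_vocabs)) {
    p[[paste0("gin_node_emb_", k)]] <- .gauss(vs[[node_vocabs[k]]], h)
  }
  for (l in seq_len(config$gin_layers)) {
    for (k in seq_along(edge_vocabs)) {
      p[[paste0("gin_edge_emb_", l, "_", k)]] <- .gauss(vs[[edge_vocabs[k]]], h)
    }
    p[[paste0("gin_W1_", l)]] <- .xavier(h, h)
    p[[paste0("gin_b1_", l)]] <- matrix(0, 1, h)
    p[[paste0("gin_W2_", l)]] <- .xavier(h, h)
    p[[paste0("gin_b2_", l)]] <- matrix(0, 1, h)
  }
  for (i in seq_len(config$heads)) {
    p[[paste0("att_Wq_", i)]] <- .xavier(h, d)
    p[[paste0("att_Wk_", i)]] <- .xavier(h, d)
    p[[paste0("att_Wv_", i)]] <- .xavier(h, d)
    # score vectors start at 16x the Xavier scale: additive-attention
    # logits are a product of v and a near-zero tanh at initialization, and
    # with both factors small the attention sits on a near-uniform plateau
    # whose vanishing score gradients let non-attentional shortcuts win
    # first.
    p[[paste0("att_v_", i)]] <- 16 * .xavier(d, 1L)
  }
  p$att_Wo <- .xavier(h, h); p$att_bo <- matrix(0, 1, h)
  for (nm in c("sn_q", "sn_k", "sn_o")) {
    p[[paste0(nm, "_gamma")]] <- matrix(1, 1, h)
    p[[paste0(nm, "_beta")]] <- matrix(0, 1, h)
  }
  p$rff_W1 <- .xavier(h, h); p$rff_b1 <- matrix(0, 1, h)
  p$rff_W2 <- .xavier(h, h); p$rff_b2 <- matrix(0, 1, h)
  H1 <- config$head_hidden
  p$head_W1 <- .xavier(2L * h * h, H1); p$head_b1 <- matrix(0, 1, H1)
  p$bn1_gamma <- matrix(1, 1, H1); p$bn1_beta <- matrix(0, 1, H1)
  p$head_W2 <- .xavier(H1, 2L * h); p$head_b2 <- matrix(0, 1, 2L * h)
  p$head_W3 <- .xavier(2L * h, h); p$head_b3 <- matrix(0, 1, h)
  p$bn3_gamma <- matrix(1, 1, h); p$bn3_beta <- matrix(0, 1, h)
  p$head_W4 <- .xavier(h, 1L); p$head_b4 <- matrix(0, 1, 1)
  bn <- new.env(parent = emptyenv())
  bn$bn1 <- list(mean = rep(0, H1), var = rep(1, H1))
  bn$bn3 <- list(mean = rep(0, h), var = rep(1, h))
  structure(list(params = p, bn = bn, config = config,
                 vocab_version = feature_vocab_version()),
            class = "cypdfi_model")
}

#' @export
print.cypdfi_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<cypdfi_model> h=%d heads=%d n_pseudo=%d (%s trainable values)\n",
              x$config$h, x$config$heads, x$config$n_pseudo,
              format(n_par, big.mark = ",")))
  invisible(x)
}

# Deep copy of the mutable parts of a model (parameters + batch-norm state).
.copy_model <- function(model) {
  bn <- new.env(parent = emptyenv())
  for (k in ls(model$bn)) bn[[k]] <- model$bn[[k]]
  structure(list(params = model$params, bn = bn, config = model$config,
                 vocab_version = model$vocab_version),
            class = "cypdfi_model")
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the parameters, batch-normalization running
#' statistics, configuration and featurization vocabulary version.  A
#' save/load round trip restores the model bit for bit.
#'
#' @param model A `cypdfi_model`.
#' @param path File path.
#' @return `load_checkpoint` returns the restored `cypdfi_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "cypdfi_model"))
  payload <- list(format = "cypdfi-checkpoint-1",
                  params = model$params,
                  bn = mget(ls(model$bn), envir = model$bn),
                  config = unclass(model$config),
                  vocab_version = model$vocab_version)
  saveRDS(payload, path, version = 3)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "cypdfi-checkpoint-1")) {
    stop("not a cypdfi checkpoint: ", path, call. = FALSE)
  }
  bn <- new.env(parent = emptyenv())
  for (k in names(payload$bn)) bn[[k]] <- payload$bn[[k]]
  structure(list(params = payload$params, bn = bn,
                 config = structure(payload$config, class = "model_config"),
                 vocab_version = payload$vocab_version),
            class = "cypdfi_model")
}
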