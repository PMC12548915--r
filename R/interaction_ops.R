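# Public operations of the compound-CYP interaction block: pseudo-embedding
# append, additive multihead attention, set normalization, the full multihead
# attention block (MAB), isoenzyme pooling, and attention-mass DCI scores.

#' Attention tensor
#'
#' Per-head, per-isoenzyme attention rows over the `n` real substructures
#' followed by the `n_pseudo` pseudo-substructures.  Head 1 is bound to
#' substrate-type and head 2 to inhibition-type DCI supervision; any further
#' heads are free.
#'
#' @param weights `heads x 5 x n_keys` array; every `[head, isoenzyme, ]` row
#'   sums to 1, padded key positions carry exactly 0.
#' @param n_real Number of real substructure keys (the first `n_real`
#'   positions of the third dimension).
#' @param key_labels Optional labels for the key axis (bit indices followed
#'   by pseudo labels).
#' @return An object of class `attention_tensor`.
#' @export
attention_tensor <- function(weights, n_real, key_labels = NULL) {
  stopifnot(is.array(weights), length(dim(weights)) == 3L, dim(weights)[2] == 5L,
            n_real >= 0, n_real <= dim(weights)[3])
  heads <- dim(weights)[1]
  roles <- c("substrate", "inhibition", rep("free", max(0L, heads - 2L)))[seq_len(heads)]
  structure(list(weights = weights, n = as.integer(n_real),
                 head_roles = roles, key_labels = key_labels),
            class = "attention_tensor")
}

#' @export
print.attention_tensor <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("<attention_tensor> %d heads x 5 isoenzymes x %d keys (%d real + %d pseudo)\n",
              d[1], d[3], x$n, d[3] - x$n))
  invisible(x)
}

#' Append pseudo-substructure embeddings
#'
#' Appends the globally shared trainable pseudo rows after the compound's
#' real substructure embeddings, in fixed order.  The pseudo rows act as an
#' attention sink: mass assigned to them signals absence of a compound-CYP
#' interaction.
#'
#' @param hs `n x h` matrix of real substructure embeddings.
#' @param model A `cypdfi_model`.
#' @return `(n + n_pseudo) x h` matrix.
#' @export
append_pseudo <- function(hs, model) {
  stopifnot(is.matrix(hs), nrow(hs) >= 1L, ncol(hs) == model$config$h)
  out <- rbind(hs, model$params$pseudo)
  rownames(out) <- c(rownames(hs) %||% rep("", nrow(hs)),
                     paste0("pseudo_", seq_len(model$config$n_pseudo) - 1L))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Set normalization
#'
#' Standardizes a set of vectors by the mean and variance computed jointly
#' over all elements and all features, then applies an optional per-feature
#' affine transform.  A variance floor of `eps` guards constant sets.
#'
#' @param x Matrix (rows are set elements).
#' @param gamma,beta Optional length-`ncol(x)` affine parameters (default
#'   identity).
#' @param eps Variance floor.
#' @return Matrix of the same shape.
#' @export
set_norm <- function(x, gamma = NULL, beta = NULL, eps = 1e-5) {
  stopifnot(is.matrix(x), nrow(x) >= 1L)
  m <- mean(x)
  v <- mean((x - m)^2)
  xh <- (x - m) / sqrt(v + eps)
  if (!is.null(gamma)) xh <- sweep(xh, 2L, as.vector(gamma), "*")
  if (!is.null(beta)) xh <- sweep(xh, 2L, as.vector(beta), "+")
  xh
}

# Row softmax with exact zeros at masked positions.
.masked_softmax_row <- function(s, keep) {
  out <- numeric(length(s))
  sk <- s[keep]
  e <- exp(sk - max(sk))
  out[keep] <- e / sum(e)
  out
}

#' Additive multihead cross-attention
#'
#' Per head `i`, the score between isoenzyme row `j` and key `k` is
#' `v_i' tanh(W_q,i q_j + W_k,i k_k)`; a row-wise softmax over unmasked keys
#' gives the attention weights.  Per-head value projections (width
#' `h / heads`) are attention-averaged, concatenated, and linearly projected
#' back to width `h`.
#'
#' @param q `5 x h` query matrix (isoenzymes).
#' @param kv `m x h` key/value matrix (real + pseudo substructures).
#' @param model A `cypdfi_model`.
#' @param key_mask Logical vector of length `m`; `FALSE` marks padded keys,
#'   which receive exactly zero attention.
#' @param n_real Number of real keys (defaults to `m - n_pseudo`).
#' @return List with `z` (`5 x h`) and `attention` (an [attention_tensor()]).
#' @export
additive_multihead_attention <- function(q, kv, model, key_mask = NULL,
                                         n_real = nrow(kv) - model$config$n_pseudo) {
  cfg <- model$config
  stopifnot(is.matrix(q), nrow(q) == 5L, ncol(q) == cfg$h,
            is.matrix(kv), ncol(kv) == cfg$h)
  m <- nrow(kv)
  if (is.null(key_mask)) key_mask <- rep(TRUE, m)
  stopifnot(length(key_mask) == m)
  if (!any(key_mask)) stop("all keys are masked", call. = FALSE)
  p <- model$params
  A <- array(0, dim = c(cfg$heads, 5L, m))
  zh <- vector("list", cfg$heads)
  for (i in seq_len(cfg$heads)) {
    Q <- q %*% p[[paste0("att_Wq_", i)]]
    K <- kv %*% p[[paste0("att_Wk_", i)]]
    V <- kv %*% p[[paste0("att_Wv_", i)]]
    v <- as.vector(p[[paste0("att_v_", i)]])
    zi <- matrix(0, 5L, ncol(V))
    for (j in 1:5) {
      s <- as.vector(tanh(sweep(K, 2L, Q[j, ], "+")) %*% v)
      a <- .masked_softmax_row(s, key_mask)
      A[i, j, ] <- a
      zi[j, ] <- as.vector(a %*% V)
    }
    zh[[i]] <- zi
  }
  z <- do.call(cbind, zh) %*% p$att_Wo
  z <- sweep(z, 2L, as.vector(p$att_bo), "+")
  list(z = z, attention = attention_tensor(A, n_real))
}

#' Multihead attention block (MAB)
#'
#' The Set-Transformer-style block
#' `MAB(x, y) = (x + z) + RFF(SetNorm(x + z))` with
#' `z = Multihead(SetNorm(x), SetNorm(y), SetNorm(y))` computed by additive
#' multihead attention, and `RFF(x) = GeLU(GeLU(x W1 + b1) W2 + b2)`.
#' Padded keys are excluded from key-side set normalization and carry exactly
#' zero attention.
#'
#' @param he `5 x h` isoenzyme embeddings (queries).
#' @param hs_rho `(n + n_pseudo) x h` substructure embeddings with pseudo rows
#'   appended (keys/values).
#' @inheritParams additive_multihead_attention
#' @return List with `oe` (`5 x h` attended isoenzyme embeddings) and
#'   `attention` (an [attention_tensor()]).
#' @export
mab_forward <- function(he, hs_rho, model, key_mask = NULL,
                        n_real = nrow(hs_rho) - model$config$n_pseudo) {
  cfg <- model$config
  p <- model$params
  m <- nrow(hs_rho)
  if (is.null(key_mask)) key_mask <- rep(TRUE, m)
  if (!any(key_mask)) stop("all keys are masked", call. = FALSE)
  q_sn <- set_norm(he, p$sn_q_gamma, p$sn_q_beta)
  kv_real <- hs_rho[key_mask, , drop = FALSE]
  kv_sn <- set_norm(kv_real, p$sn_k_gamma, p$sn_k_beta)
  att <- additive_multihead_attention(q_sn, kv_sn, model,
                                      n_real = sum(key_mask[seq_len(n_real)]))
  # re-insert exact zeros for masked key positions
  A <- array(0, dim = c(cfg$heads, 5L, m))
  A[, , key_mask] <- att$attention$weights
  hz <- he + att$z
  sn <- set_norm(hz, p$sn_o_gamma, p$sn_o_beta)
  gelu <- function(x) x * stats::pnorm(x)
  rff <- gelu(sweep(gelu(sweep(sn %*% p$rff_W1, 2L, as.vector(p$rff_b1), "+")) %*%
                      p$rff_W2, 2L, as.vector(p$rff_b2), "+"))
  oe <- hz + rff
  rownames(oe) <- CYP_ISOENZYMES
  list(oe = oe, attention = attention_tensor(A, n_real))
}

#' Pool attended isoenzyme embeddings
#'
#' Arithmetic mean of the five isoenzyme rows, giving the compound-integrated
#' CYP450 embedding.
#'
#' @param oe `5 x h` matrix.
#' @return Numeric vector of width h.
#' @export
pool_isoenzymes <- function(oe) {
  stopifnot(is.matrix(oe), nrow(oe) == 5L)
  colMeans(oe)
}

#' Attention-mass DCI scores
#'
#' For the substrate head (head 1) and inhibition head (head 2), the DCI
#' score of an isoenzyme is the total attention mass assigned to the real
#' substructures; the complementary mass sits on the pseudo-substructures, so
#' score + pseudo-mass = 1 for every cell.
#'
#' @param a An [attention_tensor()].
#' @return `2 x 5` matrix (rows `substrate`, `inhibition`; columns in
#'   canonical isoenzyme order) with entries in `[0, 1]`.
#' @export
dci_scores <- function(a) {
  stopifnot(inherits(a, "attention_tensor"))
  real <- seq_len(a$n)
  out <- rbind(
    substrate = apply(a$weights[1, , real, drop = FALSE], 2L, sum),
    inhibition = apply(a$weights[2, , real, drop = FALSE], 2L, sum))
  colnames(out) <- CYP_ISOENZYMES
  out
}
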