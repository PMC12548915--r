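# Cross-modality fusion and the DFI prediction head, plus the composed
# single-pair forward pass that exposes every intermediate for
# interpretation.

#' Cross-modality fusion
#'
#' Vector-wise outer product of one side's compound-integrated CYP450
#' embedding with the other side's molecular graph embedding, flattened
#' row-major (the CYP-integrated vector indexes rows), for both sides, then
#' concatenated: `flatten(hi_d o hg_f) ++ flatten(hi_f o hg_d)`.
#'
#' @param hi_d,hg_f,hi_f,hg_d Numeric vectors of width h.
#' @return Numeric vector of width `2 h^2` (drug-side block first).
#' @export
fuse <- function(hi_d, hg_f, hi_f, hg_d) {
  h <- length(hi_d)
  if (length(hg_f) != h || length(hi_f) != h || length(hg_d) != h) {
    stop("all four fusion inputs must have the same width", call. = FALSE)
  }
  c(as.vector(t(outer(hi_d, hg_f))), as.vector(t(outer(hi_f, hg_d))))
}

#' DFI prediction head
#'
#' Four stacked feedforward layers mapping the fusion embedding to an
#' interaction probability: linear/batch-norm/LeakyReLU/dropout, then
#' linear/LeakyReLU/dropout, then linear/batch-norm/LeakyReLU/dropout, then
#' linear/sigmoid.  Widths taper `2 h^2 -> head_hidden -> 2h -> h -> 1`.
#' In eval mode batch normalization uses the stored running statistics;
#' training mode requires at least two rows per batch.
#'
#' @param hf Fusion embedding: numeric vector of width `2 h^2`, or a matrix
#'   with one fusion embedding per row.
#' @param model A `cypdfi_model`.
#' @param training Use batch statistics and dropout.
#' @return Numeric vector of predicted probabilities in (0, 1).
#' @export
predict_dfi <- function(hf, model, training = FALSE) {
  cfg <- model$config
  if (!is.matrix(hf)) hf <- matrix(hf, nrow = 1L)
  stopifnot(ncol(hf) == 2L * cfg$h^2)
  tape <- ag_tape()
  pw <- .wrap_params(tape, model$params)
  logits <- .prediction_head(cfg, pw, model$bn, ag_leaf(tape, hf), training)
  as.vector(1 / (1 + exp(-logits$v)))
}

#' Full forward pass for one drug-food pair
#'
#' Runs both compounds through the shared encoders and interaction block,
#' fuses the drug-side CYP-integrated embedding with the food-side graph
#' embedding and vice versa, and applies the prediction head.  All
#' intermediates are retained for interpretation.
#'
#' @param model A `cypdfi_model`.
#' @param drug_smiles,food_smiles SMILES strings.
#' @param panel A [cyp_panel()].
#' @param training Forward in training mode (dropout, batch statistics).
#' @param drug_id,food_id Optional identifiers carried into the trace.
#' @return An object of class `cypdfi_trace`: `y_hat`, `hf`, and per-side
#'   lists (`drug`, `food`) each with `id`, `smiles`, `hs`, `hg`, `hi`,
#'   `attention` (an [attention_tensor()]) and `dci` (2 x 5 score matrix).
#' @export
forward_pair <- function(model, drug_smiles, food_smiles, panel,
                         training = FALSE, drug_id = "drug", food_id = "food") {
  stopifnot(inherits(model, "cypdfi_model"), inherits(panel, "cyp_panel"))
  feats <- tryCatch(featurize_compounds(c(drug_smiles, food_smiles)),
                    cypdfi_featurize_error = function(e) {
                      id <- if (identical(e$smiles, drug_smiles)) drug_id else food_id
                      stop(sprintf("compound '%s': %s", id, conditionMessage(e)),
                           call. = FALSE)
                    })
  smiles <- c(drug_smiles, food_smiles)
  uniq <- unique(smiles)
  comp_idx <- match(smiles, uniq)
  comps <- feats[uniq]
  fw <- .run_batch(model, comps, di = comp_idx[1], fi = comp_idx[2],
                   L = panel$embeddings, training = training)
  side <- function(ci, id, s) {
    n_c <- comps[[ci]]$substructures$n
    rows <- which(fw$ib$key_group == ci)
    A <- array(0, dim = c(model$config$heads, 5L, length(rows)))
    for (i in seq_len(model$config$heads)) {
      A[i, , ] <- t(fw$ib$A[[i]]$v[rows, , drop = FALSE])
    }
    labels <- c(as.character(comps[[ci]]$substructures$bits),
                paste0("pseudo_", seq_len(model$config$n_pseudo) - 1L))
    att <- attention_tensor(A, n_c, key_labels = labels)
    hs_rows <- which(fw$bb$comp == ci)
    hs <- fw$hs$v[hs_rows, , drop = FALSE]
    rownames(hs) <- as.character(comps[[ci]]$substructures$bits)
    dci <- rbind(substrate = fw$ib$dci$substrate$v[ci, ],
                 inhibition = fw$ib$dci$inhibition$v[ci, ])
    colnames(dci) <- CYP_ISOENZYMES
    list(id = id, smiles = comps[[ci]]$canonical, substructures = comps[[ci]]$substructures,
         hs = hs, hg = as.vector(fw$hg$v[ci, ]), hi = as.vector(fw$ib$hi$v[ci, ]),
         attention = att, dci = dci)
  }
  structure(list(
    y_hat = fw$yhat[1],
    hf = as.vector(fw$fuse$v[1, ]),
    drug = side(comp_idx[1], drug_id, drug_smiles),
    food = side(comp_idx[2], food_id, food_smiles)),
    class = "cypdfi_trace")
}

#' @export
print.cypdfi_trace <- function(x, ...) {
  cat(sprintf("<cypdfi_trace> %s + %s -> y_hat = %.4f\n",
              x$drug$id, x$food$id, x$y_hat))
  invisible(x)
}
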