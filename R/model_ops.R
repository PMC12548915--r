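# Public encoder operations.  Each wraps the batched tape machinery for a
# single input, so the standalone operations and the training path share one
# implementation.

#' Encode a compound's substructure set
#'
#' Each on bit of the fingerprint selects a trainable 2h-wide row of the
#' substructure table; rows pass through a linear layer, LeakyReLU and
#' dropout, yielding one h-vector per substructure.
#'
#' @param s A `substructure_set`.
#' @param model A `cypdfi_model`.
#' @param training Apply dropout (uses the current RNG state).
#' @return `n x h` matrix, rows named by bit index.
#' @export
encode_substructures <- function(s, model, training = FALSE) {
  stopifnot(inherits(s, "substructure_set"), inherits(model, "cypdfi_model"))
  if (s$n < 1L) stop("empty substructure set", call. = FALSE)
  tape <- ag_tape()
  pw <- .wrap_params(tape, model$params)
  out <- .encode_bits(model$config, pw, .bits_batch(list(s)), training)$v
  rownames(out) <- as.character(s$bits)
  out
}

#' Encode a compound's molecular graph
#'
#' Stacked edge-attributed GIN convolutions followed by global mean pooling
#' over atoms.
#'
#' @param g A `molecular_graph`.
#' @inheritParams encode_substructures
#' @return Numeric vector of width h.
#' @export
encode_graph <- function(g, model, training = FALSE) {
  stopifnot(inherits(g, "molecular_graph"), inherits(model, "cypdfi_model"))
  if (g$n_atoms < 1L) stop("empty molecular graph", call. = FALSE)
  tape <- ag_tape()
  pw <- .wrap_params(tape, model$params)
  as.vector(.encode_graphs(model$config, pw, .graph_batch(list(g)), 1L, training)$v)
}

#' Encode the CYP450 panel
#'
#' Maps the five 480-dimensional isoenzyme embeddings through a linear
#' layer, LeakyReLU and dropout.  The output is shared by every drug-food
#' pair in a batch.
#'
#' @param panel A [cyp_panel()].
#' @inheritParams encode_substructures
#' @return `5 x h` matrix, rows in canonical isoenzyme order.
#' @export
encode_cyp_panel <- function(panel, model, training = FALSE) {
  stopifnot(inherits(panel, "cyp_panel"), inherits(model, "cypdfi_model"))
  tape <- ag_tape()
  pw <- .wrap_params(tape, model$params)
  out <- .encode_panel(model$config, pw, tape, panel$embeddings, training)$v
  rownames(out) <- panel$isoenzymes
  out
}
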