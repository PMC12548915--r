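# Loss objectives: primary DFI binary cross-entropy, the masked
# semi-supervised auxiliary attention-regularization loss, and the composite
# objective total = l1 + alpha * l2.

#' Primary DFI loss
#'
#' Mean binary cross-entropy of predicted interaction probabilities against
#' binary labels.
#'
#' @param y_hat Numeric vector of probabilities in (0, 1).
#' @param y Binary labels (0/1), same length.
#' @param eps Clipping bound applied before the log.
#' @return Scalar loss.
#' @export
primary_loss <- function(y_hat, y, eps = 1e-7) {
  if (length(y_hat) != length(y)) {
    stop("y_hat and y must have equal length", call. = FALSE)
  }
  stopifnot(length(y) >= 1L, all(y %in% c(0, 1)))
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Auxiliary attention-regularization loss
#'
#' Binary cross-entropy of attention-mass DCI scores against DCI labels,
#' averaged over all non-missing (compound, type, isoenzyme) cells across the
#' batch.  Cells with missing labels contribute nothing (semi-supervised
#' masking); with no labeled cell at all the loss is exactly 0 and carries no
#' gradient.  Scores are clipped to `[eps, 1 - eps]` since attention mass can
#' be exactly 0 or 1.
#'
#' @param scores A single 2 x 5 DCI score matrix (from [dci_scores()]) or a
#'   list of them.
#' @param labels Matching 2 x 5 label matrix (entries 1, 0 or NA) or list of
#'   them; `NULL` entries mean fully missing.
#' @param eps Clipping bound.
#' @return List with `loss` and `n_supervised` (count of labeled cells).
#' @export
auxiliary_loss <- function(scores, labels, eps = 1e-7) {
  if (is.matrix(scores)) scores <- list(scores)
  if (is.matrix(labels) || is.null(labels)) labels <- list(labels)
  stopifnot(length(scores) == length(labels))
  s_all <- c(); y_all <- c()
  for (i in seq_along(scores)) {
    lab <- labels[[i]]
    if (is.null(lab)) next
    stopifnot(all(dim(scores[[i]]) == c(2L, 5L)), all(dim(lab) == c(2L, 5L)))
    keep <- !is.na(lab)
    s_all <- c(s_all, scores[[i]][keep])
    y_all <- c(y_all, as.numeric(lab[keep]))
  }
  n_sup <- length(y_all)
  if (n_sup == 0L) return(list(loss = 0, n_supervised = 0L))
  p <- pmin(pmax(s_all, eps), 1 - eps)
  list(loss = -mean(y_all * log(p) + (1 - y_all) * log(1 - p)),
       n_supervised = n_sup)
}

#' Composite training objective
#'
#' `total = l1 + alpha * l2`, where `alpha` controls the intensity of
#' attention regularization (`alpha = 0` is the ablated model).
#'
#' @param l1 Primary loss.
#' @param l2 Auxiliary loss.
#' @param alpha Auxiliary loss coefficient.
#' @return Scalar total loss.
#' @export
total_loss <- function(l1, l2, alpha) {
  stopifnot(l1 >= 0, l2 >= 0)
  l1 + alpha * l2
}

#' An all-missing DCI label matrix
#'
#' @return 2 x 5 matrix of NA with canonical dimnames.
#' @export
empty_dci_matrix <- function() {
  matrix(NA_real_, 2L, 5L, dimnames = list(DCI_TYPES, CYP_ISOENZYMES))
}
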