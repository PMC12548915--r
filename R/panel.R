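# The CYP450 isoenzyme panel: five isoenzymes in a fixed canonical order,
# each carrying an amino-acid sequence and/or a precomputed 480-dimensional
# language-model embedding.  The same 5 x h encoded panel is reused for every
# drug-food pair in a batch.

#' Construct the CYP450 isoenzyme panel
#'
#' The panel consists of the five isoenzymes CYP1A2, CYP3A4, CYP2C19, CYP2C9
#' and CYP2D6 (in that fixed order).  Each entry carries a 480-dimensional
#' embedding, either supplied precomputed (the output of a protein language
#' model, mean-pooled over residues) or derived deterministically from the
#' amino-acid sequence with a hashed 3-mer composition profile.  The bundled
#' default FASTA contains synthetic stand-in sequences (see the file header);
#' for production use supply the canonical UniProt sequences (P05177, P08684,
#' P33261, P11712, P10635) or a real language-model embedding table.
#'
#' @param fasta Path to a FASTA file with five sequences named after the
#'   isoenzymes.  Ignored when `embeddings` is given.
#' @param embeddings A 5 x 480 numeric matrix with rows in canonical
#'   isoenzyme order, or a path to a tab-delimited table of the same shape
#'   (first column `isoenzyme`).
#' @return An object of class `cyp_panel` with elements `isoenzymes`,
#'   `sequences` (may be `NULL`) and `embeddings` (5 x 480 matrix).
#' @export
cyp_panel <- function(fasta = NULL, embeddings = NULL) {
  seqs <- NULL
  if (!is.null(embeddings)) {
    if (is.character(embeddings)) embeddings <- read_panel_embeddings(embeddings)
    emb <- as.matrix(embeddings)
  } else {
    if (is.null(fasta)) {
      fasta <- system.file("extdata", "cyp450_panel_synthetic.fasta",
                           package = "cypdfi")
    }
    seqs <- .read_fasta(fasta)
    missing <- setdiff(CYP_ISOENZYMES, names(seqs))
    if (length(missing) > 0L) {
      stop("panel FASTA is missing isoenzyme(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    seqs <- seqs[CYP_ISOENZYMES]
    if (any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs))) {
      stop("panel sequences contain non-amino-acid letters", call. = FALSE)
    }
    emb <- t(vapply(seqs, .kmer_embedding, numeric(CYP_EMBED_DIM)))
  }
  if (!all(dim(emb) == c(5L, CYP_EMBED_DIM))) {
    stop(sprintf("panel embeddings must be 5 x %d", CYP_EMBED_DIM), call. = FALSE)
  }
  rownames(emb) <- CYP_ISOENZYMES
  structure(list(isoenzymes = CYP_ISOENZYMES, sequences = seqs,
                 embeddings = emb),
            class = "cyp_panel")
}

#' @export
print.cyp_panel <- function(x, ...) {
  cat("<cyp_panel>", paste(x$isoenzymes, collapse = ", "), "\n")
  cat(sprintf("  embeddings: 5 x %d%s\n", ncol(x$embeddings),
              if (is.null(x$sequences)) " (injected)" else " (sequence-derived)"))
  invisible(x)
}

.read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  lines <- readLines(path)
  idx <- grepl("^>", lines)
  grp <- cumsum(idx)
  headers <- sub("^>", "", sub("\\s.*$", "", lines[idx]))
  seqs <- vapply(split(lines[!idx], grp[!idx]), paste, character(1), collapse = "")
  names(seqs) <- headers
  seqs
}

# Deterministic sequence-composition embedding: counts of hashed 3-mers in
# 480 bins, standardized per sequence.  This is a lightweight, fully offline
# featurization of the panel sequences; a protein language model embedding
# table can be injected in its place through `cyp_panel(embeddings = ...)`.
.kmer_embedding <- function(seq, k = 3L, dim = CYP_EMBED_DIM) {
  chars <- utf8ToInt(seq)
  n <- length(chars) - k + 1L
  v <- numeric(dim)
  for (i in seq_len(n)) {
    hash <- 0
    for (j in 0:(k - 1L)) hash <- (hash * 131 + chars[i + j]) %% 1048573
    v[(hash %% dim) + 1L] <- v[(hash %% dim) + 1L] + 1
  }
  as.numeric(scale(v))
}

#' Read / write a panel embedding table
#'
#' Tab-delimited text with a header line; first column `isoenzyme`, followed
#' by 480 numeric columns.
#'
#' @param path File path.
#' @param embeddings 5 x 480 matrix with rownames in canonical order.
#' @export
read_panel_embeddings <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt[[1]]
  m <- m[CYP_ISOENZYMES, , drop = FALSE]
  m
}

#' @rdname read_panel_embeddings
#' @export
write_panel_embeddings <- function(embeddings, path) {
  df <- data.frame(isoenzyme = rownames(embeddings), embeddings,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
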