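# Attention-based interpretation: per-compound explanation reports with
# DCI score vectors, per-head attention matrices labeled by fingerprint bit,
# and top-attended substructures mapped back to atoms.

#' Explain a drug-food pair
#'
#' Runs one eval-mode forward pass and builds an explanation report for each
#' compound: the substrate/inhibition DCI scores per isoenzyme, the per-head
#' `5 x (n + n_pseudo)` attention matrices (columns labeled by bit index and
#' `pseudo_*`), and the top-k attended real substructures with their atom
#' sets.
#'
#' @param model A trained `cypdfi_model`.
#' @param drug_smiles,food_smiles SMILES strings.
#' @param panel A [cyp_panel()].
#' @param k Substructures to report per (head, isoenzyme).
#' @param drug_id,food_id Identifiers carried into the reports.
#' @return List with `drug` and `food` (objects of class
#'   `explanation_report`) and `y_hat`.
#' @export
explain_pair <- function(model, drug_smiles, food_smiles, panel, k = 3L,
                         drug_id = "drug", food_id = "food") {
  trace <- forward_pair(model, drug_smiles, food_smiles, panel,
                        drug_id = drug_id, food_id = food_id)
  list(drug = .explanation_report(trace$drug, model, k),
       food = .explanation_report(trace$food, model, k),
       y_hat = trace$y_hat)
}

.explanation_report <- function(side, model, k) {
  att <- side$attention
  heads <- dim(att$weights)[1]
  mats <- lapply(seq_len(heads), function(i) {
    m <- att$weights[i, , ]
    dimnames(m) <- list(CYP_ISOENZYMES, att$key_labels)
    m
  })
  names(mats) <- paste0("head", seq_len(heads), "_", att$head_roles)
  rep <- structure(list(id = side$id, smiles = side$smiles,
                        substructures = side$substructures,
                        dci = side$dci, attention = mats,
                        attention_tensor = att),
                   class = "explanation_report")
  rep$top_substructures <- top_substructures(rep, k)
  rep
}

#' Top attended substructures of an explanation report
#'
#' For each supervised head (substrate, inhibition) and isoenzyme, the `k`
#' real substructure columns with the highest attention weight, descending,
#' ties broken by ascending bit index; each with the atom set of its
#' circular environments.
#'
#' @param report An `explanation_report`.
#' @param k Number of substructures (clipped to the number of real bits).
#' @return Nested list: `report$top_substructures[[head]][[isoenzyme]]` is a
#'   data frame with columns `bit`, `weight` and a list column `atoms`.
#' @export
top_substructures <- function(report, k = 3L) {
  stopifnot(inherits(report, "explanation_report"))
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  s <- report$substructures
  n <- s$n
  atom_map <- map_bits_to_atoms(s, report$smiles, s$bits)
  out <- list()
  for (head in c("substrate", "inhibition")) {
    hidx <- match(head, c("substrate", "inhibition"))
    m <- report$attention[[hidx]]
    per_iso <- lapply(CYP_ISOENZYMES, function(iso) {
      w <- m[iso, seq_len(n)]
      bits <- s$bits
      ord <- order(-w, bits)[seq_len(min(k, n))]
      df <- data.frame(bit = bits[ord], weight = unname(w[ord]))
      df$atoms <- lapply(as.character(df$bit), function(b) atom_map[[b]])
      df
    })
    names(per_iso) <- CYP_ISOENZYMES
    out[[head]] <- per_iso
  }
  out
}

#' @export
print.explanation_report <- function(x, ...) {
  cat(sprintf("<explanation_report> %s (%s)\nDCI scores:\n", x$id, x$smiles))
  print(round(x$dci, 3))
  invisible(x)
}

#' Write an explanation to delimited text (and optional heatmaps)
#'
#' Writes, per compound: the 2 x 5 DCI score matrix, one tab-delimited
#' attention matrix per head (rows isoenzymes, columns bit indices then
#' `pseudo_*`), and the top-substructure table.  When `heatmaps = TRUE` and
#' the pheatmap package is installed, also renders PNG heatmaps of the two
#' supervised heads.
#'
#' @param explanation Result of [explain_pair()].
#' @param dir Output directory.
#' @param heatmaps Render PNG heatmaps.
#' @return Invisibly, the vector of files written.
#' @export
write_explanation <- function(explanation, dir, heatmaps = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (side in c("drug", "food")) {
    rep <- explanation[[side]]
    base <- file.path(dir, paste0(side, "_", gsub("[^A-Za-z0-9_.-]", "_", rep$id)))
    f <- paste0(base, "_dci_scores.tsv")
    utils::write.table(data.frame(type = rownames(rep$dci), rep$dci,
                                  check.names = FALSE),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    for (nm in names(rep$attention)) {
      f <- paste0(base, "_attention_", nm, ".tsv")
      utils::write.table(data.frame(isoenzyme = rownames(rep$attention[[nm]]),
                                    rep$attention[[nm]], check.names = FALSE),
                         f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }
    rows <- list()
    for (head in names(rep$top_substructures)) {
      for (iso in names(rep$top_substructures[[head]])) {
        df <- rep$top_substructures[[head]][[iso]]
        rows[[paste(head, iso)]] <- data.frame(
          head = head, isoenzyme = iso, bit = df$bit, weight = df$weight,
          atoms = vapply(df$atoms, paste, character(1), collapse = ","))
      }
    }
    f <- paste0(base, "_top_substructures.tsv")
    utils::write.table(do.call(rbind, rows), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
    if (heatmaps && requireNamespace("pheatmap", quietly = TRUE)) {
      for (hi in 1:2) {
        f <- paste0(base, "_heatmap_", names(rep$attention)[hi], ".png")
        grDevices::png(f, width = 1200, height = 400, res = 120)
        pheatmap::pheatmap(rep$attention[[hi]], cluster_rows = FALSE,
                           cluster_cols = FALSE, main = rep$id)
        grDevices::dev.off()
        files <- c(files, f)
      }
    }
  }
  invisible(files)
}
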