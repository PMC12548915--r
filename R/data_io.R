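# Reading, writing, validating and integrating DFI pair tables and DCI
# annotation tables, plus dataset statistics.
#
# DFI tables are delimited text with header columns drug_id, drug_smiles,
# food_id, food_smiles, label (binary).  DCI tables have compound_id plus ten
# label columns {cyp1a2,cyp3a4,cyp2c19,cyp2c9,cyp2d6} x {substrate,
# inhibition} with values 1, 0 or NA.

.dci_columns <- function() {
  as.vector(t(outer(tolower(CYP_ISOENZYMES), DCI_TYPES, paste, sep = "_")))
}

#' Read a DFI pair table
#'
#' Validates the schema, canonicalizes all SMILES, and collapses exact
#' duplicate pairs (same canonical drug and food) with a label-conflict
#' check.
#'
#' @param path Delimited text file (tab or comma separated, with header).
#' @return `data.frame` with columns `drug_id`, `drug_smiles`, `food_id`,
#'   `food_smiles` (canonical SMILES), `label`.
#' @export
read_dfi_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  for (cl in intersect(c("drug_id", "drug_smiles", "food_id", "food_smiles"),
                       names(dt))) {
    dt[[cl]] <- as.character(dt[[cl]])
  }
  validate_dfi_table(dt)
}

#' Validate (and canonicalize) an in-memory DFI table
#'
#' @param dt Data frame with the DFI table columns.
#' @return Validated data frame with canonical SMILES.
#' @export
validate_dfi_table <- function(dt) {
  need <- c("drug_id", "drug_smiles", "food_id", "food_smiles", "label")
  missing <- setdiff(need, names(dt))
  if (length(missing) > 0L) {
    stop("DFI table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dt <- dt[, need]
  bad <- which(!(dt$label %in% c(0, 1)))
  if (length(bad) > 0L) {
    stop(sprintf("non-binary label at row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  dt$label <- as.integer(dt$label)
  all_smiles <- unique(c(dt$drug_smiles, dt$food_smiles))
  .featurize_fill_cache(all_smiles)
  canon <- vapply(all_smiles, function(s) {
    rec <- get(s, envir = .cypdfi$cache)
    if (!isTRUE(rec$ok)) NA_character_ else rec$canonical
  }, character(1))
  if (anyNA(canon)) {
    bad_smiles <- all_smiles[is.na(canon)]
    row <- which(dt$drug_smiles %in% bad_smiles | dt$food_smiles %in% bad_smiles)[1]
    stop(sprintf("invalid SMILES '%s' at row %d", bad_smiles[1], row), call. = FALSE)
  }
  dt$drug_smiles <- unname(canon[dt$drug_smiles])
  dt$food_smiles <- unname(canon[dt$food_smiles])
  for (side in c("drug", "food")) {
    ids <- dt[[paste0(side, "_id")]]
    sm <- dt[[paste0(side, "_smiles")]]
    n_sm <- tapply(sm, ids, function(x) length(unique(x)))
    if (any(n_sm > 1L)) {
      stop(sprintf("%s id '%s' maps to multiple distinct compounds",
                   side, names(n_sm)[n_sm > 1L][1]), call. = FALSE)
    }
  }
  key <- paste(dt$drug_smiles, dt$food_smiles, sep = "\t")
  n_lab <- tapply(dt$label, key, function(x) length(unique(x)))
  if (any(n_lab > 1L)) {
    pair <- strsplit(names(n_lab)[n_lab > 1L][1], "\t")[[1]]
    stop(sprintf("conflicting labels for pair (%s, %s)", pair[1], pair[2]),
         call. = FALSE)
  }
  dt <- dt[!duplicated(key), , drop = FALSE]
  rownames(dt) <- NULL
  dt
}

#' @rdname read_dfi_table
#' @param dt DFI data frame.
#' @export
write_dfi_table <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a DCI annotation table
#'
#' @param path Delimited text with columns `compound_id` plus the ten
#'   `<isoenzyme>_<type>` label columns, values 1 / 0 / NA.
#' @return Named list: compound id -> 2 x 5 label matrix (rows `substrate`,
#'   `inhibition`; columns in canonical isoenzyme order; entries 1, 0 or NA).
#'   Compounds absent from the table are simply absent (fully missing).
#' @export
read_dci_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if ("compound_id" %in% names(dt)) dt$compound_id <- as.character(dt$compound_id)
  cols <- .dci_columns()
  unknown <- setdiff(names(dt), c("compound_id", cols))
  if (length(unknown) > 0L || !"compound_id" %in% names(dt)) {
    stop("DCI table has unexpected column(s): ",
         paste(c(unknown, setdiff("compound_id", names(dt))), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(cols, names(dt))
  if (length(missing) > 0L) {
    stop("DCI table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (cl in cols) {
    v <- dt[[cl]]
    ok <- is.na(v) | v %in% c(0, 1)
    if (!all(ok)) {
      stop(sprintf("DCI column '%s' contains value '%s' outside {1, 0, NA}",
                   cl, v[!ok][1]), call. = FALSE)
    }
  }
  out <- lapply(seq_len(nrow(dt)), function(i) {
    m <- empty_dci_matrix()
    for (ti in seq_along(DCI_TYPES)) {
      for (ji in seq_along(CYP_ISOENZYMES)) {
        m[ti, ji] <- as.numeric(dt[[paste(tolower(CYP_ISOENZYMES[ji]),
                                          DCI_TYPES[ti], sep = "_")]][i])
      }
    }
    m
  })
  names(out) <- dt$compound_id
  out
}

#' @rdname read_dci_table
#' @param dci Named list of 2 x 5 label matrices.
#' @export
write_dci_table <- function(dci, path) {
  cols <- .dci_columns()
  rows <- lapply(names(dci), function(id) {
    m <- dci[[id]]
    vals <- lapply(cols, function(cl) {
      parts <- strsplit(cl, "_")[[1]]
      m[parts[2], toupper(parts[1])]
    })
    names(vals) <- cols
    c(list(compound_id = id), vals)
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Dataset statistics
#'
#' Counts of unique drugs, unique foods, pairs, positives and negatives,
#' together with the size of the full drug x food grid and the sparsity
#' percentage `100 * n_pairs / possible_pairs`.
#'
#' @param examples DFI data frame.
#' @return Object of class `dataset_statistics`.
#' @export
dataset_statistics <- function(examples) {
  stopifnot(nrow(examples) >= 1L)
  n_drugs <- length(unique(examples$drug_id))
  n_foods <- length(unique(examples$food_id))
  n_pairs <- nrow(examples)
  n_pos <- sum(examples$label == 1L)
  possible <- as.numeric(n_drugs) * as.numeric(n_foods)
  structure(list(n_drugs = n_drugs, n_foods = n_foods, n_pairs = n_pairs,
                 n_pos = n_pos, n_neg = n_pairs - n_pos,
                 possible_pairs = possible,
                 sparsity_pct = 100 * n_pairs / possible),
            class = "dataset_statistics")
}

#' @rdname dataset_statistics
#' @param n_drugs,n_foods,n_pairs,n_pos Summary counts (for computing the
#'   derived statistics directly from a published summary table rather than
#'   from example-level data).
#' @export
dataset_statistics_from_counts <- function(n_drugs, n_foods, n_pairs, n_pos) {
  stopifnot(n_pairs >= n_pos)
  possible <- as.numeric(n_drugs) * as.numeric(n_foods)
  structure(list(n_drugs = n_drugs, n_foods = n_foods, n_pairs = n_pairs,
                 n_pos = n_pos, n_neg = n_pairs - n_pos,
                 possible_pairs = possible,
                 sparsity_pct = 100 * n_pairs / possible),
            class = "dataset_statistics")
}

#' @export
print.dataset_statistics <- function(x, ...) {
  cat(sprintf(paste0("<dataset_statistics> %d drugs x %d foods: %d pairs ",
                     "(%d pos / %d neg)\n  possible pairs %s, sparsity %.4f%%\n"),
              x$n_drugs, x$n_foods, x$n_pairs, x$n_pos, x$n_neg,
              format(x$possible_pairs, big.mark = ",", scientific = FALSE),
              x$sparsity_pct))
  invisible(x)
}

#' Per-cell DCI annotation counts
#'
#' Number of compounds with a non-missing label for each (type, isoenzyme)
#' cell.
#'
#' @param dci Named list of 2 x 5 label matrices.
#' @return 2 x 5 integer matrix.
#' @export
dci_statistics <- function(dci) {
  out <- matrix(0L, 2L, 5L, dimnames = list(DCI_TYPES, CYP_ISOENZYMES))
  for (m in dci) out <- out + !is.na(m)
  out
}

#' Integrate multiple data sources
#'
#' Unions DFI tables on canonical compound pairs, or DCI tables on compound
#' ids, with an explicit label-conflict policy.  When the sources are
#' disjoint the merged statistics are the sums of the per-source statistics.
#'
#' @param sources Named list of DFI data frames, or named list of DCI label
#'   lists (all elements must be of the same kind).
#' @param conflict `"error"` (default) fails on any label conflict between
#'   sources; `"positive_wins"` resolves conflicts in favor of the positive
#'   label.
#' @return For DFI sources: list with `merged` (data frame), `per_source`
#'   (list of `dataset_statistics`) and `statistics` (merged
#'   `dataset_statistics`).  For DCI sources: list with `merged` (label
#'   list), `per_source` and `statistics` (count matrices from
#'   [dci_statistics()]).
#' @export
integrate_sources <- function(sources, conflict = c("error", "positive_wins")) {
  conflict <- match.arg(conflict)
  stopifnot(length(sources) >= 1L)
  if (is.data.frame(sources[[1]])) {
    per <- lapply(sources, dataset_statistics)
    all_dt <- do.call(rbind, lapply(sources, function(s) {
      s[, c("drug_id", "drug_smiles", "food_id", "food_smiles", "label")]
    }))
    key <- paste(all_dt$drug_smiles, all_dt$food_smiles, sep = "\t")
    lab_range <- tapply(all_dt$label, key, function(x) length(unique(x)))
    if (any(lab_range > 1L)) {
      if (conflict == "error") {
        pair <- strsplit(names(lab_range)[lab_range > 1L][1], "\t")[[1]]
        stop(sprintf("label conflict between sources for pair (%s, %s)",
                     pair[1], pair[2]), call. = FALSE)
      }
      pos_key <- unique(key[all_dt$label == 1L])
      all_dt$label[key %in% pos_key] <- 1L
    }
    merged <- all_dt[!duplicated(key), , drop = FALSE]
    rownames(merged) <- NULL
    list(merged = merged, per_source = per,
         statistics = dataset_statistics(merged))
  } else {
    per <- lapply(sources, dci_statistics)
    merged <- list()
    for (src in sources) {
      for (id in names(src)) {
        if (is.null(merged[[id]])) {
          merged[[id]] <- src[[id]]
        } else {
          a <- merged[[id]]; b <- src[[id]]
          both <- !is.na(a) & !is.na(b) & a != b
          if (any(both)) {
            if (conflict == "error") {
              stop(sprintf("DCI label conflict between sources for compound '%s'",
                           id), call. = FALSE)
            }
            a[both] <- pmax(a[both], b[both])
          }
          take <- is.na(a) & !is.na(b)
          a[take] <- b[take]
          merged[[id]] <- a
        }
      }
    }
    list(merged = merged, per_source = per, statistics = dci_statistics(merged))
  }
}
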