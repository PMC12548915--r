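# Synthetic desk-scale benchmark generator.
#
# Emulates the statistical structure the model assumes: a compound library
# whose DCI labels are motif-determined -- each (interaction type,
# isoenzyme) cell is bound to a chemical motif with a distinctive atom
# environment (sulfonamide, nitro, trifluoromethyl, ...), and a compound is
# a true positive for a cell exactly when it carries that cell's motif.
# Motifs are planted independently per compound, which keeps the planted
# rule identifiable from a modest number of labeled cells: every motif is
# visible to the model as its own fingerprint bits, uncorrelated with the
# scaffold.  Observed drug labels are partially masked to missing; food
# labels are fully unobserved by default.  DFI labels follow a
# shared-isoenzyme rule (drug substrate + food substrate, or drug substrate
# + food inhibitor, of the same isoenzyme) plus independent label noise.

#' Synthetic benchmark configuration
#'
#' Defaults define the package's reference desk-scale study conditions:
#' 80 drugs x 60 foods (full pair grid), motif prevalence 30%, half of the
#' drug-side DCI cells masked to missing, food-side DCI labels fully
#' unobserved (mirroring the absence of food-CYP annotations in real data),
#' and 5% DFI label noise.
#'
#' @param n_drugs,n_foods Library sizes.
#' @param dci_missing_rate Probability that an observed drug DCI cell is
#'   masked to missing.
#' @param dfi_noise_rate Probability that a DFI label is flipped.
#' @param motif_prob Independent inclusion probability of each of the ten
#'   signature motifs.
#' @param anchor_bits Optional named integer vector of 10 distinct
#'   fingerprint bits (names `<type>.<isoenzyme>`); when given, true DCI
#'   labels are defined by anchor-bit presence instead of planted motifs.
#' @param observe_food_dci Observe food-side DCI labels (default `FALSE`).
#' @param seed Integer master seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 80L, n_foods = 60L,
                             dci_missing_rate = 0.5, dfi_noise_rate = 0.05,
                             motif_prob = 0.3, anchor_bits = NULL,
                             observe_food_dci = FALSE, seed = 1L) {
  stopifnot(n_drugs >= 1L, n_foods >= 1L,
            dci_missing_rate >= 0, dci_missing_rate <= 1,
            dfi_noise_rate >= 0, dfi_noise_rate <= 1,
            motif_prob > 0, motif_prob < 1)
  if (!is.null(anchor_bits)) {
    stopifnot(length(anchor_bits) == 10L, !anyDuplicated(anchor_bits))
  }
  structure(list(n_drugs = as.integer(n_drugs), n_foods = as.integer(n_foods),
                 dci_missing_rate = dci_missing_rate,
                 dfi_noise_rate = dfi_noise_rate, motif_prob = motif_prob,
                 anchor_bits = anchor_bits,
                 observe_food_dci = observe_food_dci, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Fragment grammar ------------------------------------------------------

#' Signature motifs of the synthetic benchmark
#'
#' Ten chemical motifs, one per (interaction type, isoenzyme) cell in
#' canonical order.  Each is written as a branch unit attachable inside a
#' carbon chain, and each carries atoms whose circular environments are
#' unique to the motif, so motif presence is faithfully expressed in the
#' model's fingerprint vocabulary.
#'
#' @format Named character vector (names `<type>.<isoenzyme>`).
#' @export
SYNTHETIC_MOTIFS <- c(
  "substrate.CYP1A2"   = "C(S(=O)(=O)N)",   # sulfonamide
  "substrate.CYP3A4"   = "C([N+](=O)[O-])", # nitro
  "substrate.CYP2C19"  = "C(C(F)(F)F)",     # trifluoromethyl
  "substrate.CYP2C9"   = "C(C#N)",          # nitrile
  "substrate.CYP2D6"   = "C(P(=O)(O)O)",    # phosphonate
  "inhibition.CYP1A2"  = "C(Cl)",           # chloro
  "inhibition.CYP3A4"  = "C(Br)",           # bromo
  "inhibition.CYP2C19" = "C(I)",            # iodo
  "inhibition.CYP2C9"  = "C(C(=O)NC)",      # N-methyl amide
  "inhibition.CYP2D6"  = "C(SC)")           # thioether

.syn_ring_templates <- c(
  "c1ccc(%s)cc1", "c1ccc(%s)nc1", "c1ccc(%s)o1", "c1ccc(%s)s1",
  "C1CCC(%s)CC1", "C1CCN(%s)CC1", "c1cnc(%s)cn1", "C1CCC(%s)OC1")

.syn_chain_pieces <- c("C", "CC", "CO", "CN", "CCO", "C(C)")

.syn_food_scaffolds <- c("OCC(O)(%s)CO", "CC(O)C(%s)C(=O)O", "CCC(%s)CC(=O)O",
                         "OCC(%s)CO", "CC(=O)OC(%s)C", "C(%s)CC=O",
                         "NCC(%s)C(=O)O", "CCOC(=O)C(%s)C")

# One compound: scaffold with a chain of filler pieces and the branch units
# of the planted motifs, in shuffled order.
.syn_one_smiles <- function(role, motifs_in) {
  units <- SYNTHETIC_MOTIFS[motifs_in]
  n_fill <- if (role == "drug") sample(1:3, 1L) else sample(0:1, 1L)
  units <- c(units, sample(.syn_chain_pieces, n_fill, replace = TRUE))
  chain <- paste(sample(units), collapse = "")
  if (chain == "") chain <- "C"
  template <- if (role == "drug") {
    sample(.syn_ring_templates, 1L)
  } else {
    sample(.syn_food_scaffolds, 1L)
  }
  sprintf(template, paste0(chain, "C"))
}

#' Generate a synthetic compound library
#'
#' Assembles valid SMILES from a fixed fragment grammar: a ring scaffold
#' (drugs) or a small acid/polyol/ester backbone (foods) carrying a chain of
#' filler pieces plus the branch units of the signature motifs planted in
#' that compound, each motif included independently with probability
#' `motif_prob`.  Candidates that fail featurization or duplicate an earlier
#' compound are rejected; output is deterministic in `(n, role, seed)`.
#'
#' @param n Number of compounds.
#' @param role `"drug"` or `"food"`.
#' @param seed Integer seed.
#' @param motif_prob Per-motif inclusion probability.
#' @return Data frame with columns `id`, `smiles` (canonical), `role`, and
#'   one logical column per motif cell (named as in
#'   `names(SYNTHETIC_MOTIFS)`).
#' @export
generate_compound_library <- function(n, role = c("drug", "food"), seed = 1L,
                                      motif_prob = 0.3) {
  role <- match.arg(role)
  stopifnot(n >= 1L)
  set.seed(seed)
  seen <- character(0)
  motif_rows <- list()
  attempts <- 0L
  max_attempts <- 500L * n
  while (length(seen) < n && attempts < max_attempts) {
    todo <- max(16L, n - length(seen))
    cands <- character(todo)
    motifs <- vector("list", todo)
    for (b in seq_len(todo)) {
      motifs[[b]] <- stats::runif(10L) < motif_prob
      cands[b] <- .syn_one_smiles(role, motifs[[b]])
    }
    attempts <- attempts + todo
    .featurize_fill_cache(unique(cands))
    for (b in seq_len(todo)) {
      rec <- get(cands[b], envir = .cypdfi$cache)
      if (isTRUE(rec$ok) && !(rec$canonical %in% seen)) {
        seen <- c(seen, rec$canonical)
        motif_rows[[length(seen)]] <- motifs[[b]]
        if (length(seen) == n) break
      }
    }
  }
  if (length(seen) < n) {
    stop("fragment grammar exhausted before reaching ", n,
         " unique compounds; use a smaller n", call. = FALSE)
  }
  motifs <- do.call(rbind, motif_rows)
  colnames(motifs) <- names(SYNTHETIC_MOTIFS)
  prefix <- if (role == "drug") "D" else "F"
  cbind(data.frame(id = sprintf("%s%04d", prefix, seq_len(n)), smiles = seen,
                   role = role, stringsAsFactors = FALSE),
        as.data.frame(motifs))
}

#' Empirical anchor bits of a motif-planted library
#'
#' For each motif cell, the fingerprint bit whose presence pattern across
#' the library best matches the motif's planted inclusion pattern (exact
#' match preferred, then highest agreement).  Used to verify that the
#' planted signal is faithfully expressed in the model's substructure
#' vocabulary.
#'
#' @param compounds Library data frame from [generate_compound_library()]
#'   (or the row-bound drug + food libraries).
#' @return Named integer vector (bit per motif cell) with attribute
#'   `agreement` (fraction of compounds on which bit presence equals motif
#'   presence).
#' @export
choose_anchor_bits <- function(compounds) {
  sets <- lapply(compounds$smiles, function(s) compute_substructures(s)$bits)
  n <- length(sets)
  M <- matrix(0L, n, N_FP_BITS)
  for (i in seq_len(n)) M[i, sets[[i]] + 1L] <- 1L
  cells <- names(SYNTHETIC_MOTIFS)
  bits <- integer(length(cells))
  agree <- numeric(length(cells))
  taken <- integer(0)
  for (k in seq_along(cells)) {
    target <- as.integer(compounds[[cells[k]]])
    match_frac <- colMeans(M == target)
    match_frac[taken] <- -1
    best <- which.max(match_frac)
    bits[k] <- best - 1L
    agree[k] <- match_frac[best]
    taken <- c(taken, best)
  }
  names(bits) <- cells
  attr(bits, "agreement") <- stats::setNames(agree, cells)
  bits
}

#' Plant DCI labels
#'
#' The true label of cell (type, isoenzyme) is positive exactly when the
#' compound carries that cell's motif (motif columns present in
#' `compounds`), or -- when `cfg$anchor_bits` is given -- when its
#' substructure set contains the cell's anchor bit.  The observed matrix
#' masks each drug cell to missing independently with
#' `cfg$dci_missing_rate`; food compounds are fully unobserved unless
#' `cfg$observe_food_dci` is set.
#'
#' @param compounds Library data frame (drug and food rows may be mixed).
#' @param cfg A [synthetic_config()].
#' @return List with `true` and `observed`: named lists (compound id ->
#'   2 x 5 matrix).
#' @export
plant_dci_labels <- function(compounds, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cells <- names(SYNTHETIC_MOTIFS)
  use_bits <- !is.null(cfg$anchor_bits)
  if (!use_bits && !all(cells %in% names(compounds))) {
    stop("compounds carry no motif columns and cfg$anchor_bits is NULL",
         call. = FALSE)
  }
  set.seed(cfg$seed + 101L)
  true <- list(); observed <- list()
  for (i in seq_len(nrow(compounds))) {
    m <- empty_dci_matrix()
    if (use_bits) {
      bits <- compute_substructures(compounds$smiles[i])$bits
      for (cell in cells) {
        parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
        m[parts[1], parts[2]] <- as.numeric(cfg$anchor_bits[[cell]] %in% bits)
      }
    } else {
      for (cell in cells) {
        parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
        m[parts[1], parts[2]] <- as.numeric(compounds[[cell]][i])
      }
    }
    true[[compounds$id[i]]] <- m
    obs <- m
    if (compounds$role[i] == "food" && !cfg$observe_food_dci) {
      obs[] <- NA_real_
    } else {
      mask <- matrix(stats::runif(10) < cfg$dci_missing_rate, 2L, 5L)
      obs[mask] <- NA_real_
    }
    observed[[compounds$id[i]]] <- obs
  }
  list(true = true, observed = observed)
}

#' Generate DFI labels from planted DCI structure
#'
#' The noiseless label of a (drug, food) pair is 1 exactly when some
#' isoenzyme j has (drug substrate of j AND food substrate of j) OR
#' (drug substrate of j AND food inhibitor of j); each label is then flipped
#' independently with `dfi_noise_rate`.  All `n_drugs x n_foods` pairs are
#' emitted.
#'
#' @param drugs,foods Library data frames.
#' @param true_dci Named list of true 2 x 5 matrices covering all compounds.
#' @param cfg A [synthetic_config()].
#' @return DFI data frame (columns `drug_id`, `drug_smiles`, `food_id`,
#'   `food_smiles`, `label`).
#' @export
generate_dfi_labels <- function(drugs, foods, true_dci, cfg) {
  set.seed(cfg$seed + 202L)
  grid <- expand.grid(di = seq_len(nrow(drugs)), fi = seq_len(nrow(foods)))
  lab <- integer(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    dm <- true_dci[[drugs$id[grid$di[k]]]]
    fm <- true_dci[[foods$id[grid$fi[k]]]]
    hit <- any(dm["substrate", ] == 1 &
                 (fm["substrate", ] == 1 | fm["inhibition", ] == 1))
    lab[k] <- as.integer(hit)
  }
  flip <- stats::runif(nrow(grid)) < cfg$dfi_noise_rate
  lab[flip] <- 1L - lab[flip]
  data.frame(drug_id = drugs$id[grid$di], drug_smiles = drugs$smiles[grid$di],
             food_id = foods$id[grid$fi], food_smiles = foods$smiles[grid$fi],
             label = lab, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic benchmark
#'
#' One call produces every artifact of an end-to-end run: the compound
#' libraries, planted true and observed DCI tables, the DFI pair table,
#' cold-drug and cold-food split specifications, and (optionally) the files
#' on disk plus a JSON provenance sidecar.  Fully reproducible from the
#' configuration.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (`NULL` for in-memory only).
#' @return List with `cfg`, `drugs`, `foods`, `examples`, `dci_true`,
#'   `dci_observed`, `anchor_bits` (empirical, with agreement attribute),
#'   `split_cold_drug`, `split_cold_food`, and `files` (named paths when
#'   `dir` was given).
#' @export
make_benchmark <- function(cfg = synthetic_config(), dir = NULL) {
  drugs <- generate_compound_library(cfg$n_drugs, "drug", seed = cfg$seed,
                                     motif_prob = cfg$motif_prob)
  foods <- generate_compound_library(cfg$n_foods, "food", seed = cfg$seed + 1L,
                                     motif_prob = cfg$motif_prob)
  compounds <- rbind(drugs, foods)
  dci <- plant_dci_labels(compounds, cfg)
  examples <- generate_dfi_labels(drugs, foods, dci$true, cfg)
  anchor_bits <- if (is.null(cfg$anchor_bits)) {
    choose_anchor_bits(compounds)
  } else {
    cfg$anchor_bits
  }
  split_cd <- cold_split(examples, "cold_drug", seed = cfg$seed)
  split_cf <- cold_split(examples, "cold_food", seed = cfg$seed)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(dfi = file.path(dir, "dfi.tsv"),
               dci_observed = file.path(dir, "dci_observed.tsv"),
               dci_true = file.path(dir, "dci_true.tsv"),
               split_cold_drug = file.path(dir, "split_cold_drug.tsv"),
               split_cold_food = file.path(dir, "split_cold_food.tsv"),
               provenance = file.path(dir, "provenance.json"))
    write_dfi_table(examples, files[["dfi"]])
    write_dci_table(dci$observed, files[["dci_observed"]])
    write_dci_table(dci$true, files[["dci_true"]])
    write_split_spec(split_cd, files[["split_cold_drug"]])
    write_split_spec(split_cf, files[["split_cold_food"]])
    prov <- unclass(cfg)
    prov$anchor_bits <- as.list(prov$anchor_bits)
    prov$empirical_anchor_bits <- as.list(anchor_bits)
    jsonlite::write_json(prov, files[["provenance"]], auto_unbox = TRUE,
                         pretty = TRUE)
  }
  list(cfg = cfg, drugs = drugs, foods = foods, examples = examples,
       dci_true = dci$true, dci_observed = dci$observed,
       anchor_bits = anchor_bits,
       split_cold_drug = split_cd, split_cold_food = split_cf, files = files)
}
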