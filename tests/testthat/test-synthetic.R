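# Synthetic benchmark generator: library validity, determinism, planted
# label structure, noise calibration, identifiability.

test_that("compound libraries are unique, valid and deterministic", {
  lib <- generate_compound_library(30, "drug", seed = 11)
  expect_equal(nrow(lib), 30L)
  expect_false(anyDuplicated(lib$smiles) > 0)
  expect_identical(lib$smiles, canonicalize_smiles(lib$smiles, quiet = TRUE))
  lib2 <- generate_compound_library(30, "drug", seed = 11)
  expect_identical(lib, lib2)
  lib3 <- generate_compound_library(30, "drug", seed = 12)
  expect_false(identical(lib$smiles, lib3$smiles))
  # every compound survives the full featurization pipeline
  for (s in lib$smiles[1:10]) {
    expect_gte(compute_substructures(s)$n, 1L)
    expect_gte(build_molecular_graph(s)$n_atoms, 1L)
  }
})

test_that("planted DCI labels equal motif presence and masking is calibrated", {
  bm <- fixture_benchmark()
  cells <- names(SYNTHETIC_MOTIFS)
  for (i in seq_len(nrow(bm$drugs))) {
    truth <- bm$dci_true[[bm$drugs$id[i]]]
    for (cell in cells) {
      parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
      expect_equal(truth[parts[1], parts[2]],
                   as.numeric(bm$drugs[[cell]][i]))
    }
  }
  # food observed labels fully missing by default
  expect_true(all(vapply(bm$foods$id, function(id)
    all(is.na(bm$dci_observed[[id]])), logical(1))))

  # missing rate calibration within 3 binomial standard errors
  cfg <- synthetic_config(n_drugs = 40, n_foods = 30, dci_missing_rate = 0.6,
                          seed = 21)
  lib <- rbind(generate_compound_library(40, "drug", seed = 21),
               generate_compound_library(30, "food", seed = 22))
  lib$role <- "drug"  # observe every compound for the calibration check
  planted <- plant_dci_labels(lib, cfg)
  frac <- mean(vapply(planted$observed, function(m) mean(is.na(m)), numeric(1)))
  se <- sqrt(0.6 * 0.4 / (10 * nrow(lib)))
  expect_lt(abs(frac - 0.6), 3 * se)

  # full masking
  cfg1 <- synthetic_config(dci_missing_rate = 1, seed = 3)
  planted1 <- plant_dci_labels(lib[1:5, ], cfg1)
  expect_true(all(vapply(planted1$observed, function(m) all(is.na(m)),
                         logical(1))))
})

test_that("the DFI rule fires exactly on shared-isoenzyme relations", {
  cfg <- synthetic_config(dfi_noise_rate = 0, seed = 5)
  mk <- function(sub = rep(0, 5), inh = rep(0, 5)) rbind(substrate = sub,
                                                         inhibition = inh)
  drugs <- data.frame(id = c("dA", "dB"), smiles = c("CCO", "CCN"),
                      stringsAsFactors = FALSE)
  foods <- data.frame(id = c("fA", "fB"), smiles = c("CC(=O)O", "OCC(O)CO"),
                      stringsAsFactors = FALSE)
  true_dci <- list(
    dA = mk(sub = c(1, 0, 0, 0, 0)),            # substrate of CYP1A2
    dB = mk(inh = c(1, 1, 1, 1, 1)),            # inhibitor only
    fA = mk(sub = c(1, 0, 0, 0, 0)),            # shares CYP1A2 as substrate
    fB = mk(inh = c(0, 1, 0, 0, 0)))            # inhibits CYP3A4 only
  ex <- generate_dfi_labels(drugs, foods, true_dci, cfg)
  lab <- function(d, f) ex$label[ex$drug_id == d & ex$food_id == f]
  expect_equal(lab("dA", "fA"), 1L)  # drug sub + food sub, same isoenzyme
  expect_equal(lab("dA", "fB"), 0L)  # no shared isoenzyme relation
  expect_equal(lab("dB", "fA"), 0L)  # drug is not a substrate of anything
  expect_equal(lab("dB", "fB"), 0L)
})

test_that("label noise is calibrated within 3 binomial standard errors", {
  bm <- fixture_benchmark()
  cfg0 <- bm$cfg; cfg0$dfi_noise_rate <- 0
  clean <- generate_dfi_labels(bm$drugs, bm$foods, bm$dci_true, cfg0)
  flipped <- mean(clean$label != bm$examples$label)
  p <- bm$cfg$dfi_noise_rate
  se <- sqrt(p * (1 - p) / nrow(clean))
  expect_lt(abs(flipped - p), 3 * se)
})

test_that("a rule-based reader of true DCI labels attains the noiseless ceiling", {
  cfg <- synthetic_config(n_drugs = 12, n_foods = 9, dfi_noise_rate = 0,
                          dci_missing_rate = 0, seed = 31)
  bm <- make_benchmark(cfg)
  rule_pred <- integer(nrow(bm$examples))
  for (k in seq_len(nrow(bm$examples))) {
    dm <- bm$dci_true[[bm$examples$drug_id[k]]]
    fm <- bm$dci_true[[bm$examples$food_id[k]]]
    rule_pred[k] <- as.integer(any(dm["substrate", ] == 1 &
                                     (fm["substrate", ] == 1 |
                                        fm["inhibition", ] == 1)))
  }
  expect_equal(mean(rule_pred == bm$examples$label), 1)
})

test_that("the planted signal is expressible in fingerprint space", {
  bm <- fixture_benchmark()
  expect_gte(min(attr(bm$anchor_bits, "agreement")), 0.95)
  expect_false(anyDuplicated(bm$anchor_bits) > 0)
})

test_that("benchmark artifacts round-trip through the table formats", {
  dir1 <- file.path(tempdir(), "bm1"); dir2 <- file.path(tempdir(), "bm2")
  cfg <- synthetic_config(n_drugs = 14, n_foods = 10, seed = 13)
  bm1 <- make_benchmark(cfg, dir = dir1)
  bm2 <- make_benchmark(cfg, dir = dir2)
  # byte-identical regeneration
  for (f in names(bm1$files)) {
    expect_identical(readLines(bm1$files[[f]]), readLines(bm2$files[[f]]),
                     label = paste("file", f))
  }
  # readable by the IO layer
  back <- read_dfi_table(bm1$files[["dfi"]])
  expect_equal(nrow(back), 140L)
  expect_equal(dataset_statistics(back)$possible_pairs, 140)
  dci_back <- read_dci_table(bm1$files[["dci_true"]])
  expect_equal(length(dci_back), 24L)
  sp_back <- read_split_spec(bm1$files[["split_cold_drug"]])
  expect_equal(audit_split_leakage(sp_back, back), 0L)
  unlink(c(dir1, dir2), recursive = TRUE)
})
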