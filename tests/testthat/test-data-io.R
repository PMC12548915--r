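# DFI/DCI table IO, dataset statistics, source integration, Butina
# clustering and cold splits.

make_dfi_df <- function() {
  data.frame(drug_id = c("d1", "d2", "d1"),
             drug_smiles = c("CCO", "c1ccccc1", "CCO"),
             food_id = c("f1", "f1", "f2"),
             food_smiles = c("OCC(O)CO", "OCC(O)CO", "CC(=O)O"),
             label = c(1L, 0L, 1L), stringsAsFactors = FALSE)
}

test_that("DFI tables round-trip and are validated", {
  df <- make_dfi_df()
  path <- tempfile(fileext = ".tsv")
  write_dfi_table(df, path)
  back <- read_dfi_table(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$label, df$label)
  # SMILES canonicalized on read
  expect_equal(back$drug_smiles[1], canonicalize_smiles("CCO", quiet = TRUE))

  bad <- df; bad$label[2] <- 2L
  write_dfi_table(bad, path)
  expect_error(read_dfi_table(path), "row")

  conf <- rbind(df, data.frame(drug_id = "d1", drug_smiles = "OCC",
                               food_id = "f1", food_smiles = "OCC(O)CO",
                               label = 0L))
  write_dfi_table(conf, path)
  expect_error(read_dfi_table(path), "conflicting")

  bad_smiles <- df; bad_smiles$drug_smiles[2] <- "C("
  write_dfi_table(bad_smiles, path)
  expect_error(read_dfi_table(path), "invalid SMILES")

  missing_col <- df[, -5]
  write_dfi_table(missing_col, path)
  expect_error(read_dfi_table(path), "missing column")

  # exact duplicates (even under different SMILES spellings) collapse
  dup <- rbind(df, data.frame(drug_id = "d1", drug_smiles = "OCC",
                              food_id = "f1", food_smiles = "OCC(O)CO",
                              label = 1L))
  write_dfi_table(dup, path)
  expect_equal(nrow(read_dfi_table(path)), 3L)
})

test_that("DCI tables round-trip with three-valued entries", {
  dci <- list(
    a = local({m <- empty_dci_matrix(); m["substrate", "CYP3A4"] <- 1; m}),
    b = empty_dci_matrix(),
    c = local({m <- empty_dci_matrix(); m[] <- 0; m["inhibition", "CYP1A2"] <- 1; m}))
  path <- tempfile(fileext = ".tsv")
  write_dci_table(dci, path)
  back <- read_dci_table(path)
  expect_identical(names(back), c("a", "b", "c"))
  expect_equal(back$a["substrate", "CYP3A4"], 1)
  expect_equal(sum(!is.na(back$a)), 1L)
  expect_true(all(is.na(back$b)))
  expect_equal(sum(back$c, na.rm = TRUE), 1)

  writeLines(c("compound_id\tcyp1a2_substrate", "x\tmaybe"), path)
  expect_error(read_dci_table(path), "missing column")
  cols <- c("compound_id", cypdfi:::.dci_columns())
  writeLines(c(paste(cols, collapse = "\t"),
               paste(c("x", "maybe", rep("1", 9)), collapse = "\t")), path)
  expect_error(read_dci_table(path), "maybe")
})

test_that("dataset statistics satisfy their accounting identities", {
  df <- make_dfi_df()
  st <- dataset_statistics(df)
  expect_equal(st$n_drugs, 2L)
  expect_equal(st$n_foods, 2L)
  expect_equal(st$n_pairs, st$n_pos + st$n_neg)
  expect_equal(st$possible_pairs, 4)
  expect_equal(st$sparsity_pct, 75)
  one <- dataset_statistics(df[1, ])
  expect_equal(one$possible_pairs, 1)
  expect_equal(one$sparsity_pct, 100)
})

test_that("source integration is additive on disjoint sources and idempotent", {
  df <- make_dfi_df()
  other <- data.frame(drug_id = "d3", drug_smiles = "CCN",
                      food_id = "f3", food_smiles = "CCCCC(=O)O",
                      label = 1L, stringsAsFactors = FALSE)
  got <- integrate_sources(list(a = df, b = other))
  expect_equal(got$statistics$n_pairs,
               got$per_source$a$n_pairs + got$per_source$b$n_pairs)
  expect_equal(got$statistics$n_pos,
               got$per_source$a$n_pos + got$per_source$b$n_pos)

  # merging a table with itself is the identity
  self <- integrate_sources(list(a = df, b = df))
  expect_equal(nrow(self$merged), nrow(df))
  expect_equal(self$statistics$n_pairs, 3L)

  # conflicts fail fast unless positive-wins is requested
  confl <- df; confl$label[1] <- 0L
  expect_error(integrate_sources(list(a = df, b = confl)), "conflict")
  res <- integrate_sources(list(a = df, b = confl), conflict = "positive_wins")
  expect_equal(res$merged$label[res$merged$drug_id == "d1" &
                                 res$merged$food_id == "f1"], 1L)

  # DCI sources merge cell-wise with count additivity
  d1 <- list(x = local({m <- empty_dci_matrix(); m[1, 2] <- 1; m}))
  d2 <- list(y = local({m <- empty_dci_matrix(); m[1, 2] <- 0; m}))
  merged <- integrate_sources(list(a = d1, b = d2))
  expect_equal(merged$statistics["substrate", "CYP3A4"], 2L)
  expect_equal(unname(merged$statistics["substrate", "CYP3A4"]),
               unname(merged$per_source$a["substrate", "CYP3A4"] +
                        merged$per_source$b["substrate", "CYP3A4"]))
})

test_that("Butina clustering matches an exhaustive reference on a small set", {
  smiles <- c(a = "CCO", b = "OCC", c = "c1ccccc1", d = "c1ccccc1C",
              e = "CCCCCCCC", f = "CCCCCCC", g = "CC(=O)O", h = "CCO")
  got <- butina_clusters(smiles, distance_cutoff = 0.6)

  # reference: plainly coded sphere exclusion on the same distances
  d <- tanimoto_distance_matrix(smiles)
  assigned <- rep(NA_integer_, length(smiles))
  cl <- 0L
  while (any(is.na(assigned))) {
    best <- -1L; centroid <- NA_integer_
    for (i in seq_along(smiles)) {
      if (!is.na(assigned[i])) next
      cnt <- 0L
      for (j in seq_along(smiles)) {
        if (is.na(assigned[j]) && d[i, j] <= 0.6) cnt <- cnt + 1L
      }
      if (cnt > best) { best <- cnt; centroid <- i }
    }
    cl <- cl + 1L
    for (j in seq_along(smiles)) {
      if (is.na(assigned[j]) && d[centroid, j] <= 0.6) assigned[j] <- cl
    }
  }
  expect_equal(unname(got), assigned)
  # identical compounds always share a cluster
  expect_equal(got[["a"]], got[["b"]])
  expect_equal(got[["a"]], got[["h"]])
})

test_that("compounds with no near neighbors become singletons", {
  smiles <- c(x = "CCCCCCCCCC", y = "c1ccc2ccccc2c1", z = "OC(=O)CCC(=O)O")
  d <- tanimoto_distance_matrix(smiles)
  expect_true(all(d[upper.tri(d)] > 0.2))
  got <- butina_clusters(smiles, distance_cutoff = 0.2)
  expect_equal(sort(unname(got)), 1:3)
})

test_that("cold splits confine each cold-side compound to one partition", {
  bm <- fixture_benchmark()
  for (mode in c("cold_drug", "cold_food")) {
    sp <- cold_split(bm$examples, mode, seed = 5)
    expect_equal(audit_split_leakage(sp, bm$examples), 0L)
    part <- split_partitions(sp, bm$examples)
    expect_setequal(unique(part), c("train", "valid", "test"))
    # determinism
    sp2 <- cold_split(bm$examples, mode, seed = 5)
    expect_identical(sp[names(sp) != "seed"], sp2[names(sp2) != "seed"])
  }
})

test_that("degenerate cold sides are rejected", {
  df <- data.frame(drug_id = paste0("d", 1:6),
                   drug_smiles = c("CCO", "c1ccccc1", "CCCC", "CCN",
                                   "CC(=O)O", "c1ccncc1"),
                   food_id = "f1", food_smiles = "OCC(O)CO",
                   label = rep(c(0L, 1L), 3), stringsAsFactors = FALSE)
  expect_error(cold_split(df, "cold_food"), "clusters")
})

test_that("split specifications round-trip through their text format", {
  bm <- fixture_benchmark()
  sp <- bm$split_cold_drug
  path <- tempfile(fileext = ".tsv")
  write_split_spec(sp, path)
  back <- read_split_spec(path)
  expect_identical(back$mode, sp$mode)
  expect_equal(back$cluster_of, sp$cluster_of)
  expect_equal(sort(names(back$partition_of)), sort(names(sp$partition_of)))
  expect_identical(unname(back$partition_of[names(sp$partition_of)]),
                   unname(sp$partition_of))
  expect_equal(back$fractions, sp$fractions)
  expect_identical(split_partitions(back, bm$examples),
                   split_partitions(sp, bm$examples))
})
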