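# Shared fixtures.  Everything is generated in code; heavyweight objects are
# memoized for the duration of the test run.

.fixtures <- new.env(parent = emptyenv())

# A small model configuration used across unit tests (fast, no dropout so
# eval/training arithmetic is deterministic where tests need it).
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(h = 8L, heads = 4L, n_pseudo = 3L, dropout = 0, head_hidden = 16L,
         gin_layers = 2L, batch_size = 64L, learning_rate = 1e-3,
         max_epochs = 3L, patience = 2L, seed = 42L),
    list(...))
  do.call(model_config, args)
}

tiny_model <- function(...) new_model(tiny_config(...))

fixture_panel <- function() {
  if (is.null(.fixtures$panel)) .fixtures$panel <- cyp_panel()
  .fixtures$panel
}

# A deterministic injected panel for hand-arithmetic tests.
constant_panel <- function(value = 0) {
  cyp_panel(embeddings = matrix(value, 5, 480))
}

# Small synthetic benchmark shared by data-oriented tests.
fixture_benchmark <- function() {
  if (is.null(.fixtures$benchmark)) {
    .fixtures$benchmark <- make_benchmark(
      synthetic_config(n_drugs = 14, n_foods = 10, seed = 7))
  }
  .fixtures$benchmark
}

# A hand-built substructure set (encode_substructures only reads bits and n).
fake_substructure_set <- function(bits) {
  structure(list(bits = as.integer(bits), n = length(bits),
                 atom_environments = NULL, smiles = "<synthetic>"),
            class = "substructure_set")
}

expect_rows_sum_to_one <- function(att, tol = 1e-6) {
  d <- dim(att$weights)
  for (i in seq_len(d[1])) {
    sums <- apply(att$weights[i, , , drop = FALSE], 2, sum)
    expect_equal(unname(sums), rep(1, d[2]), tolerance = tol)
  }
}
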