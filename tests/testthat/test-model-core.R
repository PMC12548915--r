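# Encoder operations: substructure-set encoder, edge-attributed graph
# encoder, CYP450 panel encoder, shared-parameter invariants.

test_that("substructure encoder applies LeakyReLU(xW + b) row-wise", {
  model <- tiny_model()
  s <- fake_substructure_set(c(3L, 7L))

  # zero map
  m0 <- model
  m0$params$sub_W[] <- 0
  m0$params$sub_b[] <- 0
  expect_equal(unname(encode_substructures(s, m0)),
               matrix(0, 2, model$config$h))

  # hand arithmetic with a small planted weight block
  mh <- model
  h <- model$config$h
  mh$params$sub_table[] <- 0
  mh$params$sub_table[4, 1] <- 1   # bit 3 -> e1
  mh$params$sub_table[8, 2] <- -2  # bit 7 -> -2 e2
  mh$params$sub_W[] <- 0
  mh$params$sub_W[1, 1] <- 1.5
  mh$params$sub_W[2, 1] <- 0.5
  mh$params$sub_b[] <- 0.25
  out <- encode_substructures(s, mh)
  # row 1: x = e1 -> pre = 1.5 e1 + 0.25; row 2: x = -2 e2 -> pre = -1 + 0.25
  lrelu <- function(x) ifelse(x >= 0, x, 0.01 * x)
  expect_equal(unname(out[1, 1]), lrelu(1.5 + 0.25))
  expect_equal(unname(out[2, 1]), lrelu(-1 + 0.25))
  expect_equal(out[1, 2:h], rep(lrelu(0.25), h - 1), ignore_attr = TRUE)

  # eval-mode determinism
  expect_identical(encode_substructures(s, model),
                   encode_substructures(s, model))
  expect_error(encode_substructures(fake_substructure_set(integer(0)), model),
               "empty")
})

test_that("graph encoder is permutation invariant and handles single atoms", {
  model <- tiny_model()
  g <- build_molecular_graph("CCO")
  # permute atom order manually
  perm <- c(3L, 1L, 2L)
  inv <- order(perm)
  gp <- g
  gp$node_features <- g$node_features[perm, ]
  gp$edges <- matrix(inv[g$edges], ncol = 2)
  gp$edge_features <- g$edge_features
  expect_equal(encode_graph(g, model), encode_graph(gp, model),
               tolerance = 1e-12)

  g1 <- build_molecular_graph("C")
  expect_length(encode_graph(g1, model), model$config$h)
  expect_true(all(is.finite(encode_graph(g1, model))))
})

test_that("graph encoder matches a hand computation of one edge-attributed GIN layer", {
  model <- tiny_model(gin_layers = 1L)
  p <- model$params
  g <- build_molecular_graph("CCO")
  # reference: plain-R recomputation from the layer definition
  emb <- function(tab, codes) t(vapply(codes, function(cd) tab[cd, ], numeric(ncol(tab))))
  x <- Reduce(`+`, lapply(1:9, function(k)
    emb(p[[paste0("gin_node_emb_", k)]], g$node_features[, k])))
  e <- Reduce(`+`, lapply(1:3, function(k)
    emb(p[[paste0("gin_edge_emb_1_", k)]], g$edge_features[, k])))
  lrelu <- function(z) ifelse(z >= 0, z, 0.01 * z)
  msg <- lrelu(x[g$edges[, 1], ] + e)
  agg <- rowsum(msg, g$edges[, 2])
  upd <- x + agg[order(as.integer(rownames(agg))), ]
  hmid <- lrelu(sweep(upd %*% p$gin_W1_1, 2, p$gin_b1_1, "+"))
  hout <- sweep(hmid %*% p$gin_W2_1, 2, p$gin_b2_1, "+")
  expect_equal(encode_graph(g, model), colMeans(hout), tolerance = 1e-10)
})

test_that("CYP450 panel encoder maps injected embeddings through the shared MLP", {
  model <- tiny_model()
  # zero map
  m0 <- model
  m0$params$cyp_W[] <- 0
  m0$params$cyp_b[] <- 0
  out0 <- encode_cyp_panel(constant_panel(0), m0)
  expect_equal(unname(out0), matrix(0, 5, model$config$h))

  # hand arithmetic on a planted weight entry
  mh <- model
  mh$params$cyp_W[] <- 0
  mh$params$cyp_W[2, 1] <- 3
  mh$params$cyp_b[] <- -0.5
  L <- matrix(0, 5, 480)
  L[, 2] <- c(1, -1, 0.5, 0, 2)
  out <- encode_cyp_panel(cyp_panel(embeddings = L), mh)
  lrelu <- function(x) ifelse(x >= 0, x, 0.01 * x)
  expect_equal(unname(out[, 1]), lrelu(3 * L[, 2] - 0.5))
  expect_equal(unname(out[, 2]), rep(lrelu(-0.5), 5))

  # the panel encoding is one shared 5 x h matrix, reused across calls
  expect_identical(encode_cyp_panel(fixture_panel(), model),
                   encode_cyp_panel(fixture_panel(), model))
  expect_error(cyp_panel(embeddings = matrix(0, 5, 100)), "480")
})

test_that("encoders are finite at default initialization on varied compounds", {
  model <- tiny_model()
  for (smi in c("C", "CCO", "c1ccc2ccccc2c1", "CC(=O)Nc1ccc(O)cc1")) {
    hs <- encode_substructures(compute_substructures(smi), model)
    hg <- encode_graph(build_molecular_graph(smi), model)
    expect_true(all(is.finite(hs)))
    expect_true(all(is.finite(hg)))
  }
})

test_that("drug and food sides share encoder parameters", {
  model <- tiny_model()
  panel <- fixture_panel()
  # same compound on both sides: per-side featurization and encodings agree
  tr <- forward_pair(model, "CCO", "CCO", panel)
  expect_identical(tr$drug$hs, tr$food$hs)
  expect_identical(tr$drug$hg, tr$food$hg)
  expect_identical(tr$drug$hi, tr$food$hi)
  # parameter identity: there is exactly one parameter set, no per-side copy
  expect_false(any(grepl("drug|food", names(model$params))))
})
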