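# Compound-CYP interaction block: pseudo append, additive multihead
# attention, set normalization, the MAB, pooling, attention-mass DCI scores.

test_that("append_pseudo concatenates the shared pseudo rows in fixed order", {
  model <- tiny_model()
  h <- model$config$h; np <- model$config$n_pseudo
  hs <- matrix(rnorm(3 * h), 3, h)
  out <- append_pseudo(hs, model)
  expect_equal(dim(out), c(3L + np, h))
  expect_equal(unname(out[4:(3 + np), ]), unname(model$params$pseudo))
  # pseudo rows are global parameters: identical for different compounds
  out2 <- append_pseudo(matrix(rnorm(5 * h), 5, h), model)
  expect_identical(unname(out[4:(3 + np), ]), unname(out2[6:(5 + np), ]))
  # default pseudo count is 10
  expect_equal(model_config()$n_pseudo, 10L)
})

test_that("set normalization standardizes jointly over elements and features", {
  x <- matrix(c(1, 3, 2, 6), 2, 2)
  out <- set_norm(x)
  expect_equal(mean(out), 0, tolerance = 1e-10)
  expect_equal(mean(out^2), 1, tolerance = 1e-4)  # eps-floored variance
  # hand computation
  m <- mean(x); v <- mean((x - m)^2)
  expect_equal(out, (x - m) / sqrt(v + 1e-5))
  # constant set centers to zero under the variance floor
  expect_equal(set_norm(matrix(5, 3, 4)), matrix(0, 3, 4))
})

test_that("additive attention rows are softmax-normalized and symmetric for equal keys", {
  model <- tiny_model()
  h <- model$config$h
  set.seed(3)
  q <- matrix(rnorm(5 * h), 5, h)
  kv_same <- matrix(rep(rnorm(h), 6), 6, h, byrow = TRUE)
  att <- additive_multihead_attention(q, kv_same, model, n_real = 3)
  expect_equal(att$attention$weights,
               array(1 / 6, dim = c(4, 5, 6)), tolerance = 1e-12)
  kv <- matrix(rnorm(6 * h), 6, h)
  att2 <- additive_multihead_attention(q, kv, model, n_real = 3)
  expect_rows_sum_to_one(att2$attention)
  expect_true(all(att2$attention$weights >= 0))
  expect_equal(dim(att2$z), c(5L, h))
})

test_that("additive attention matches the hand formula softmax(v' tanh(Wq q + Wk k))", {
  model <- tiny_model()
  h <- model$config$h
  set.seed(4)
  q <- matrix(rnorm(5 * h), 5, h)
  kv <- matrix(rnorm(2 * h), 2, h)
  att <- additive_multihead_attention(q, kv, model, n_real = 2)
  p <- model$params
  for (i in 1:4) {
    for (j in 1:5) {
      s <- vapply(1:2, function(k) {
        sum(as.vector(p[[paste0("att_v_", i)]]) *
              as.vector(tanh(q[j, ] %*% p[[paste0("att_Wq_", i)]] +
                               kv[k, ] %*% p[[paste0("att_Wk_", i)]])))
      }, numeric(1))
      expect_equal(att$attention$weights[i, j, ],
                   exp(s - max(s)) / sum(exp(s - max(s))), tolerance = 1e-10)
    }
  }
})

test_that("masked keys receive exactly zero attention and cannot all be masked", {
  model <- tiny_model()
  h <- model$config$h
  set.seed(5)
  q <- matrix(rnorm(5 * h), 5, h)
  kv <- matrix(rnorm(4 * h), 4, h)
  mask <- c(TRUE, FALSE, TRUE, TRUE)
  att <- additive_multihead_attention(q, kv, model, key_mask = mask, n_real = 4)
  expect_true(all(att$attention$weights[, , 2] == 0))
  expect_rows_sum_to_one(att$attention)
  expect_error(additive_multihead_attention(q, kv, model,
                                            key_mask = rep(FALSE, 4)),
               "all keys are masked")
})

test_that("mab_forward matches a brute-force reference on small key sets", {
  model <- tiny_model()
  h <- model$config$h; p <- model$params
  gelu <- function(x) x * pnorm(x)
  lref_setnorm <- function(x, gamma, beta) {
    m <- mean(x); v <- mean((x - m)^2)
    xh <- (x - m) / sqrt(v + 1e-5)
    out <- xh
    for (r in seq_len(nrow(x))) {
      out[r, ] <- xh[r, ] * as.vector(gamma) + as.vector(beta)
    }
    out
  }
  reference <- function(he, kv) {
    qn <- lref_setnorm(he, p$sn_q_gamma, p$sn_q_beta)
    kn <- lref_setnorm(kv, p$sn_k_gamma, p$sn_k_beta)
    zheads <- NULL
    for (i in 1:4) {
      A <- matrix(0, 5, nrow(kv))
      for (j in 1:5) {
        s <- numeric(nrow(kv))
        for (k in seq_len(nrow(kv))) {
          s[k] <- sum(as.vector(p[[paste0("att_v_", i)]]) *
                        as.vector(tanh(qn[j, ] %*% p[[paste0("att_Wq_", i)]] +
                                         kn[k, ] %*% p[[paste0("att_Wk_", i)]])))
        }
        A[j, ] <- exp(s) / sum(exp(s))
      }
      zheads <- cbind(zheads, A %*% (kn %*% p[[paste0("att_Wv_", i)]]))
    }
    z <- zheads %*% p$att_Wo
    for (r in 1:5) z[r, ] <- z[r, ] + as.vector(p$att_bo)
    hz <- he + z
    sn <- lref_setnorm(hz, p$sn_o_gamma, p$sn_o_beta)
    a1 <- gelu(sweep(sn %*% p$rff_W1, 2, p$rff_b1, "+"))
    hz + gelu(sweep(a1 %*% p$rff_W2, 2, p$rff_b2, "+"))
  }
  set.seed(6)
  for (n_keys in 2:3) {
    he <- matrix(rnorm(5 * h), 5, h)
    kv <- matrix(rnorm(n_keys * h), n_keys, h)
    got <- mab_forward(he, kv, model, n_real = n_keys - 1L)
    expect_equal(unname(got$oe), unname(reference(he, kv)), tolerance = 1e-5)
  }
})

test_that("mab_forward is permutation equivariant over keys", {
  model <- tiny_model()
  h <- model$config$h
  set.seed(7)
  he <- matrix(rnorm(5 * h), 5, h)
  hs <- matrix(rnorm(4 * h), 4, h)
  kv <- append_pseudo(hs, model)
  perm <- c(3L, 1L, 4L, 2L)
  kv_p <- rbind(hs[perm, ], model$params$pseudo)
  a <- mab_forward(he, kv, model, n_real = 4)
  b <- mab_forward(he, kv_p, model, n_real = 4)
  expect_equal(a$oe, b$oe, tolerance = 1e-10)
  expect_equal(a$attention$weights[, , perm], b$attention$weights[, , 1:4],
               tolerance = 1e-10)
  expect_equal(dim(a$oe), c(5L, h))
})

test_that("isoenzyme pooling is the arithmetic mean of the five rows", {
  r <- c(1, 2, 3)
  oe <- matrix(rep(r, each = 5), 5, 3)
  expect_equal(pool_isoenzymes(oe), r)
  expect_equal(pool_isoenzymes(matrix(0, 5, 4)), rep(0, 4))
  oe2 <- rbind(c(1, 0), c(0, 1), c(0, 0), c(0, 0), c(0, 0))
  expect_equal(pool_isoenzymes(oe2), c(0.2, 0.2))
})

test_that("DCI scores are the real-column attention mass of the supervised heads", {
  # all mass on pseudo columns -> 0; all on real -> 1; uniform -> n/(n+np)
  n <- 20L; np <- 10L
  w_pseudo <- array(0, dim = c(4, 5, n + np))
  w_pseudo[, , (n + 1):(n + np)] <- 1 / np
  expect_equal(unname(dci_scores(attention_tensor(w_pseudo, n))),
               matrix(0, 2, 5))
  w_real <- array(0, dim = c(4, 5, n + np))
  w_real[, , 1:n] <- 1 / n
  expect_equal(unname(dci_scores(attention_tensor(w_real, n))),
               matrix(1, 2, 5))
  w_unif <- array(1 / (n + np), dim = c(4, 5, n + np))
  expect_equal(unname(dci_scores(attention_tensor(w_unif, n))),
               matrix(n / (n + np), 2, 5), tolerance = 1e-12)
})

test_that("attention is independent of batch composition", {
  model <- tiny_model()
  panel <- fixture_panel()
  feats <- featurize_compounds(c("CCO", "c1ccccc1", "CC(=O)O"))
  one <- cypdfi:::.run_batch(model, feats[1], di = 1L, fi = 1L,
                             L = panel$embeddings, training = FALSE)
  all3 <- cypdfi:::.run_batch(model, feats, di = 1L, fi = 2L,
                              L = panel$embeddings, training = FALSE)
  rows1 <- which(one$ib$key_group == 1L)
  rows3 <- which(all3$ib$key_group == 1L)
  for (i in 1:4) {
    expect_equal(one$ib$A[[i]]$v[rows1, ], all3$ib$A[[i]]$v[rows3, ],
                 tolerance = 1e-9)
  }
})
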