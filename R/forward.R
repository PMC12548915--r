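# Batched forward pass.
#
# A batch is processed at two levels.  Compound-level quantities (substructure
# embeddings, graph embeddings, compound-CYP attention, integrated CYP
# embeddings, attention-derived DCI scores) are computed once per unique
# compound in the batch; pair-level quantities (cross-modality fusion and the
# prediction head) are then assembled by indexing compounds into pairs.
# Variable-size substructure sets and molecular graphs are handled with
# segment operations over index vectors rather than padding, so a compound's
# attention tensor is identical whether it is computed alone or inside any
# batch.

.wrap_params <- function(tape, params) {
  out <- lapply(params, function(v) ag_leaf(tape, v, param = TRUE))
  names(out) <- names(params)
  out
}

.collect_grads <- function(pw) {
  lapply(pw, function(nd) {
    if (is.null(nd$g)) matrix(0, nrow(nd$v), ncol(nd$v)) else nd$g
  })
}

# Stack substructure sets of a compound list into index form.
.bits_batch <- function(subs) {
  n_bits <- vapply(subs, function(s) s$n, integer(1))
  if (any(n_bits < 1L)) stop("empty substructure set", call. = FALSE)
  list(bits = unlist(lapply(subs, function(s) s$bits)) + 1L,  # 1-based rows
       comp = rep(seq_along(subs), n_bits),
       n_bits = n_bits)
}

# Stack molecular graphs of a compound list into a disjoint union.
.graph_batch <- function(graphs) {
  n_atoms <- vapply(graphs, function(g) g$n_atoms, integer(1))
  if (any(n_atoms < 1L)) stop("empty molecular graph", call. = FALSE)
  offs <- c(0L, cumsum(n_atoms))[seq_along(graphs)]
  nf <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    if (nrow(graphs[[i]]$edges) == 0L) return(NULL)
    graphs[[i]]$edges + offs[i]
  }))
  ef <- do.call(rbind, lapply(graphs, function(g) {
    if (nrow(g$edge_features) == 0L) return(NULL)
    g$edge_features
  }))
  list(node_feat = nf, node_comp = rep(seq_along(graphs), n_atoms),
       edges = edges, edge_feat = ef, n_nodes = nrow(nf))
}

# Substructure encoder over a stacked bit batch -> (total bits) x h node.
.encode_bits <- function(cfg, pw, bb, training) {
  x <- ag_rows(pw$sub_table, bb$bits)
  hmat <- ag_leakyrelu(ag_addbias(ag_mm(x, pw$sub_W), pw$sub_b))
  ag_dropout(hmat, cfg$dropout, training)
}

# Sum the per-channel categorical embeddings of a feature matrix in two tape
# operations: stack the channel tables, gather every (row, channel) code with
# per-channel offsets, and segment-sum the gathered rows back per input row.
.embed_codes <- function(tables, codes) {
  sizes <- vapply(tables, function(t) nrow(t$v), integer(1))
  offs <- c(0L, cumsum(sizes))[seq_along(tables)]
  flat <- as.vector(t(codes + rep(offs, each = nrow(codes))))
  ag_segsum(ag_rows(ag_rbind(tables), flat),
            rep(seq_len(nrow(codes)), each = length(tables)), nrow(codes))
}

# Edge-attributed GIN over a disjoint-union graph -> per-compound h node.
.encode_graphs <- function(cfg, pw, gb, n_comp, training) {
  x <- .embed_codes(lapply(1:9, function(k) pw[[paste0("gin_node_emb_", k)]]),
                    gb$node_feat)
  has_edges <- !is.null(gb$edges) && nrow(gb$edges) > 0L
  for (l in seq_len(cfg$gin_layers)) {
    if (has_edges) {
      ee <- .embed_codes(lapply(1:3, function(k)
        pw[[paste0("gin_edge_emb_", l, "_", k)]]), gb$edge_feat)
      msg <- ag_leakyrelu(ag_add(ag_rows(x, gb$edges[, 1]), ee))
      agg <- ag_segsum(msg, gb$edges[, 2], gb$n_nodes)
      upd <- ag_add(x, agg)
    } else {
      upd <- x
    }
    hmid <- ag_leakyrelu(ag_addbias(ag_mm(upd, pw[[paste0("gin_W1_", l)]]),
                                    pw[[paste0("gin_b1_", l)]]))
    x <- ag_addbias(ag_mm(hmid, pw[[paste0("gin_W2_", l)]]),
                    pw[[paste0("gin_b2_", l)]])
    if (l < cfg$gin_layers) x <- ag_leakyrelu(x)
  }
  ag_segmean(x, gb$node_comp, n_comp)
}

# CYP450 panel encoder: 5 x 480 language embeddings -> 5 x h node.
.encode_panel <- function(cfg, pw, tape, L, training) {
  x <- ag_leaf(tape, L)
  hmat <- ag_leakyrelu(ag_addbias(ag_mm(x, pw$cyp_W), pw$cyp_b))
  ag_dropout(hmat, cfg$dropout, training)
}

# Compound-CYP interaction block over the whole compound batch.
#
# Key layout: all real substructure rows first (grouped by compound via
# `bb$comp`), then n_pseudo pseudo rows per compound.  Returns the
# compound-integrated CYP embeddings, per-head attention (keys x 5 nodes),
# and the attention-mass DCI scores of the substrate and inhibition heads.
.interaction_block <- function(cfg, pw, he, hs, bb, n_comp) {
  np <- cfg$n_pseudo
  n_real <- length(bb$comp)
  key_group <- c(bb$comp, rep(seq_len(n_comp), each = np))
  is_real <- c(rep(1, n_real), rep(0, n_comp * np))
  gsplit <- split(seq_along(key_group), key_group)

  pseudo_rep <- ag_rows(pw$pseudo, rep(seq_len(np), times = n_comp))
  k_raw <- ag_rbind(list(hs, pseudo_rep))
  q_sn <- ag_setnorm(he, rep(1L, 5L), pw$sn_q_gamma, pw$sn_q_beta)
  k_sn <- ag_setnorm(k_raw, key_group, pw$sn_k_gamma, pw$sn_k_beta)

  A <- vector("list", cfg$heads)
  z_heads <- vector("list", cfg$heads)
  n_keys <- length(key_group)
  rep5 <- rep(seq_len(n_keys), times = 5L)        # keys stacked per isoenzyme
  iso_of <- rep(1:5, each = n_keys)
  # group of an (iso, key) row in iso-major (compound, iso) numbering
  zgroup <- rep(key_group, times = 5L) + n_comp * (iso_of - 1L)
  for (i in seq_len(cfg$heads)) {
    Q <- ag_mm(q_sn, pw[[paste0("att_Wq_", i)]])
    K <- ag_mm(k_sn, pw[[paste0("att_Wk_", i)]])
    V <- ag_mm(k_sn, pw[[paste0("att_Wv_", i)]])
    # additive scores for all five isoenzymes in one pass:
    # rows = (iso, key) pairs, score = v' tanh(Q[iso,] + K[key,])
    sc <- ag_mm(ag_tanh(ag_add(ag_rows(K, rep5), ag_rows(Q, iso_of))),
                pw[[paste0("att_v_", i)]])
    S <- ag_node(sc$tape, matrix(sc$v, n_keys, 5L), list(sc),
                 function(g) list(matrix(as.vector(g), ncol = 1L)))
    A[[i]] <- ag_segsoftmax(S, key_group, gsplit)
    # attention-weighted value sums for all (compound, iso) rows at once
    a_flat <- ag_node(A[[i]]$tape, matrix(A[[i]]$v, ncol = 1L), list(A[[i]]),
                      function(g) list(matrix(as.vector(g), n_keys, 5L)))
    z_heads[[i]] <- ag_segsum(ag_mulvec(ag_rows(V, rep5), a_flat),
                              zgroup, 5L * n_comp)
  }
  z_all <- ag_addbias(ag_mm(ag_cbind(z_heads), pw$att_Wo), pw$att_bo)
  comp_of_row <- rep(seq_len(n_comp), times = 5L)
  x_rep <- ag_rows(he, rep(1:5, each = n_comp))
  hz <- ag_add(x_rep, z_all)
  sn <- ag_setnorm(hz, comp_of_row, pw$sn_o_gamma, pw$sn_o_beta)
  rff <- ag_gelu(ag_addbias(ag_mm(
    ag_gelu(ag_addbias(ag_mm(sn, pw$rff_W1), pw$rff_b1)),
    pw$rff_W2), pw$rff_b2))
  oe <- ag_add(hz, rff)
  hi <- ag_segmean(oe, comp_of_row, n_comp)

  dci <- lapply(1:2, function(i) {
    ag_segsum(ag_mulconst(A[[i]], is_real), key_group, n_comp)  # n_comp x 5
  })
  names(dci) <- DCI_TYPES
  list(hi = hi, oe = oe, A = A, key_group = key_group, is_real = is_real,
       dci = dci, comp_of_row = comp_of_row)
}

# Prediction head: fusion embeddings -> logits.
.prediction_head <- function(cfg, pw, bn, fuse, training) {
  h1 <- ag_dropout(ag_leakyrelu(ag_batchnorm(
    ag_addbias(ag_mm(fuse, pw$head_W1), pw$head_b1),
    pw$bn1_gamma, pw$bn1_beta, bn, "bn1", training)), cfg$dropout, training)
  h2 <- ag_dropout(ag_leakyrelu(
    ag_addbias(ag_mm(h1, pw$head_W2), pw$head_b2)), cfg$dropout, training)
  h3 <- ag_dropout(ag_leakyrelu(ag_batchnorm(
    ag_addbias(ag_mm(h2, pw$head_W3), pw$head_b3),
    pw$bn3_gamma, pw$bn3_beta, bn, "bn3", training)), cfg$dropout, training)
  ag_addbias(ag_mm(h3, pw$head_W4), pw$head_b4)
}

# Full batched forward pass.
#
# `comps`: list of featurized compounds (elements with $substructures and
# $graph); `di`, `fi`: integer vectors indexing `comps` for the drug and food
# side of each pair; `L`: the 5 x 480 panel embedding matrix.
.run_batch <- function(model, comps, di, fi, L, training) {
  cfg <- model$config
  tape <- ag_tape()
  pw <- .wrap_params(tape, model$params)
  bb <- .bits_batch(lapply(comps, `[[`, "substructures"))
  gb <- .graph_batch(lapply(comps, `[[`, "graph"))
  n_comp <- length(comps)

  hs <- .encode_bits(cfg, pw, bb, training)
  hg <- .encode_graphs(cfg, pw, gb, n_comp, training)
  he <- .encode_panel(cfg, pw, tape, L, training)
  ib <- .interaction_block(cfg, pw, he, hs, bb, n_comp)

  hi_d <- ag_rows(ib$hi, di); hg_f <- ag_rows(hg, fi)
  hi_f <- ag_rows(ib$hi, fi); hg_d <- ag_rows(hg, di)
  fuse <- ag_cbind(list(ag_pairouter(hi_d, hg_f), ag_pairouter(hi_f, hg_d)))
  logits <- .prediction_head(cfg, pw, model$bn, fuse, training)

  list(tape = tape, pw = pw, bb = bb, hs = hs, hg = hg, he = he, ib = ib,
       fuse = fuse, logits = logits,
       yhat = 1 / (1 + exp(-as.vector(logits$v))))
}

# Stack a list of per-compound 2 x 5 label matrices (entries 1/0/NA, or NULL
# for fully missing) into C x 5 matrices per interaction type.
.stack_dci_labels <- function(dci_labels) {
  lab <- function(type) {
    t(vapply(dci_labels, function(m) {
      if (is.null(m)) rep(NA_real_, 5) else as.numeric(m[type, ])
    }, numeric(5)))
  }
  list(substrate = lab("substrate"), inhibition = lab("inhibition"))
}

# Attach the composite loss (primary + alpha * auxiliary) to a forward pass.
# `y`: binary DFI labels per pair; `dlab`: stacked label matrices from
# .stack_dci_labels(), rows aligned with `comps`.
.attach_loss <- function(model, fw, di, fi, y, dlab) {
  cfg <- model$config
  l1 <- ag_bce_logits(fw$logits, y)
  Yc <- rbind(dlab$substrate[di, , drop = FALSE],
              dlab$inhibition[di, , drop = FALSE],
              dlab$substrate[fi, , drop = FALSE],
              dlab$inhibition[fi, , drop = FALSE])
  mask <- (!is.na(Yc)) * 1
  Yc[is.na(Yc)] <- 0
  P <- ag_rbind(list(ag_rows(fw$ib$dci$substrate, di),
                     ag_rows(fw$ib$dci$inhibition, di),
                     ag_rows(fw$ib$dci$substrate, fi),
                     ag_rows(fw$ib$dci$inhibition, fi)))
  l2 <- ag_bce_probs(P, Yc, mask)
  total <- ag_add(l1, ag_scale(l2, cfg$alpha))
  list(l1 = l1, l2 = l2, total = total, n_supervised = sum(mask))
}
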