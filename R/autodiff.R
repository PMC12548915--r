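# Minimal reverse-mode automatic differentiation over dense matrices.
#
# The model in this package is small enough (a few dozen tensor operations
# per batch) that a lightweight tape is preferable to a heavyweight
# framework dependency.  Every differentiable quantity is a "node": an
# environment holding the value (always a base matrix), its parents, and a
# closure mapping the incoming gradient to per-parent gradients.
# `ag_backward()` traverses nodes in reverse creation order.
#
# Conventions: row groups passed to segment operations are integers
# 1..ngroups; gradients are accumulated into `node$g` and released as the
# sweep passes each node.  All functions are internal (`ag_` prefix).

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

ag_node <- function(tape, v, parents = list(), bw = NULL, is_param = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$parents <- parents
  nd$bw <- bw
  nd$g <- NULL
  nd$is_param <- is_param
  req <- is_param
  if (!req) {
    for (p in parents) if (p$requires) { req <- TRUE; break }
  }
  nd$requires <- req
  nd$tape <- tape
  tape$n <- nd$id <- tape$n + 1L
  tape$nodes[[nd$id]] <- nd
  nd
}

ag_leaf <- function(tape, v, param = FALSE) {
  if (!is.matrix(v)) v <- as.matrix(v)
  ag_node(tape, v, is_param = param)
}

# Backpropagate from a scalar (1x1) node.
ag_backward <- function(loss) {
  stopifnot(length(loss$v) == 1L)
  tape <- loss$tape
  loss$g <- matrix(1, 1, 1)
  for (id in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[id]]
    if (is.null(nd$g) || !nd$requires || length(nd$parents) == 0L) next
    gs <- nd$bw(nd$g)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (!p$requires || is.null(gs[[k]])) next
      p$g <- if (is.null(p$g)) gs[[k]] else p$g + gs[[k]]
    }
    nd$g <- NULL  # release memory early
  }
  invisible(NULL)
}

ag_mm <- function(a, b) {
  ag_node(a$tape, a$v %*% b$v, list(a, b), function(g) {
    list(g %*% t(b$v), crossprod(a$v, g))
  })
}

ag_add <- function(a, b) {
  ag_node(a$tape, a$v + b$v, list(a, b), function(g) list(g, g))
}

# Add a 1 x C bias node to every row of `a`.
ag_addbias <- function(a, bias) {
  ag_node(a$tape, a$v + rep(as.vector(bias$v), each = nrow(a$v)),
          list(a, bias),
          function(g) list(g, matrix(colSums(g), 1L)))
}

ag_mul <- function(a, b) {
  ag_node(a$tape, a$v * b$v, list(a, b),
          function(g) list(g * b$v, g * a$v))
}

# Multiply each column of `a` elementwise by the column-vector node `w` (n x 1).
ag_mulvec <- function(a, w) {
  wv <- as.vector(w$v)
  ag_node(a$tape, a$v * wv, list(a, w),
          function(g) list(g * wv, matrix(rowSums(g * a$v), ncol = 1L)))
}

# Multiply by a plain (non-differentiated) scalar/vector/matrix `k`.
ag_mulconst <- function(a, k) {
  ag_node(a$tape, a$v * k, list(a), function(g) list(g * k))
}

ag_scale <- function(a, s) {
  ag_node(a$tape, a$v * s, list(a), function(g) list(g * s))
}

ag_leakyrelu <- function(a, slope = 0.01) {
  m <- slope + (1 - slope) * (a$v >= 0)
  ag_node(a$tape, a$v * m, list(a), function(g) list(g * m))
}

ag_gelu <- function(a) {
  x <- a$v
  ag_node(a$tape, x * stats::pnorm(x), list(a),
          function(g) list(g * (stats::pnorm(x) + x * stats::dnorm(x))))
}

ag_tanh <- function(a) {
  y <- tanh(a$v)
  ag_node(a$tape, y, list(a), function(g) list(g * (1 - y^2)))
}

ag_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$v))
  ag_node(a$tape, y, list(a), function(g) list(g * y * (1 - y)))
}

ag_rows <- function(a, idx) {
  idx <- as.integer(idx)
  nr <- nrow(a$v)
  ag_node(a$tape, a$v[idx, , drop = FALSE], list(a), function(g) {
    acc <- rowsum(g, idx, reorder = FALSE)
    out <- matrix(0, nr, ncol(g))
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

ag_cols <- function(a, j) {
  nc <- ncol(a$v)
  ag_node(a$tape, a$v[, j, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$v), nc)
    out[, j] <- g
    list(out)
  })
}

# Sum rows of `a` within groups (group values 1..ngroups).
ag_segsum <- function(a, group, ngroups) {
  group <- as.integer(group)
  ag_node(a$tape, {
    acc <- rowsum(a$v, group)
    out <- matrix(0, ngroups, ncol(a$v))
    out[as.integer(rownames(acc)), ] <- acc
    out
  }, list(a), function(g) list(g[group, , drop = FALSE]))
}

ag_segmean <- function(a, group, ngroups) {
  group <- as.integer(group)
  cnt <- tabulate(group, nbins = ngroups)
  cnt[cnt == 0L] <- 1L
  ag_node(a$tape, {
    acc <- rowsum(a$v, group)
    out <- matrix(0, ngroups, ncol(a$v))
    out[as.integer(rownames(acc)), ] <- acc
    out / cnt
  }, list(a), function(g) list((g / cnt)[group, , drop = FALSE]))
}

# Column-wise softmax within row groups: every (group, column) cell sums to 1.
# `gsplit` is the precomputed split of row indices by group (1..ngroups, all
# present).
ag_segsoftmax <- function(a, group, gsplit) {
  x <- a$v
  group <- as.integer(group)
  mx <- matrix(0, nrow(x), ncol(x))
  for (rows in gsplit) {
    mx[rows, ] <- rep(apply(x[rows, , drop = FALSE], 2L, max), each = length(rows))
  }
  e <- exp(x - mx)
  s <- rowsum(e, group)  # sorted by group value = 1..ngroups
  av <- e / s[group, , drop = FALSE]
  ag_node(a$tape, av, list(a), function(g) {
    dot <- rowsum(av * g, group)
    list(av * (g - dot[group, , drop = FALSE]))
  })
}

# Set normalization: standardize each row group jointly over all of its
# elements and features, then apply a per-feature affine (gamma, beta 1 x C
# nodes).  Group values must be 1..ngroups, all present.
ag_setnorm <- function(a, group, gamma, beta, eps = 1e-5) {
  x <- a$v
  group <- as.integer(group)
  C <- ncol(x)
  cnt <- tabulate(group) * C
  m <- rowSums(rowsum(x, group)) / cnt
  xc <- x - m[group]
  v <- rowSums(rowsum(xc^2, group)) / cnt
  sd <- sqrt(v + eps)
  xh <- xc / sd[group]
  gv <- as.vector(gamma$v); bv <- as.vector(beta$v)
  nr <- nrow(x)
  out <- xh * rep(gv, each = nr) + rep(bv, each = nr)
  ag_node(a$tape, out, list(a, gamma, beta), function(g) {
    dxh <- g * rep(gv, each = nr)
    m1 <- rowSums(rowsum(dxh, group)) / cnt
    m2 <- rowSums(rowsum(dxh * xh, group)) / cnt
    dx <- (dxh - m1[group] - xh * m2[group]) / sd[group]
    list(dx,
         matrix(colSums(g * xh), 1L),
         matrix(colSums(g), 1L))
  })
}

# Batch normalization over rows (per-column statistics).  `state` is an
# environment holding running statistics under `key` (list with $mean, $var);
# training mode uses batch statistics and updates the running ones by side
# effect, eval mode reads the running statistics.
ag_batchnorm <- function(a, gamma, beta, state, key, training,
                         momentum = 0.1, eps = 1e-5) {
  x <- a$v
  n <- nrow(x)
  gv <- as.vector(gamma$v); bv <- as.vector(beta$v)
  if (training) {
    if (n < 2L) {
      stop("batch normalization requires batch size >= 2 in training mode",
           call. = FALSE)
    }
    mu <- colMeans(x)
    xc <- x - rep(mu, each = n)
    va <- colMeans(xc^2)
    st <- state[[key]]
    st$mean <- (1 - momentum) * st$mean + momentum * mu
    st$var <- (1 - momentum) * st$var + momentum * va * n / (n - 1)
    state[[key]] <- st
  } else {
    st <- state[[key]]
    mu <- st$mean
    va <- st$var
    xc <- x - rep(mu, each = n)
  }
  sd <- sqrt(va + eps)
  xh <- xc / rep(sd, each = n)
  out <- xh * rep(gv, each = n) + rep(bv, each = n)
  ag_node(a$tape, out, list(a, gamma, beta), function(g) {
    dxh <- g * rep(gv, each = n)
    if (training) {
      m1 <- colMeans(dxh)
      m2 <- colMeans(dxh * xh)
      dx <- (dxh - rep(m1, each = n) - xh * rep(m2, each = n)) /
        rep(sd, each = n)
    } else {
      dx <- dxh / rep(sd, each = n)
    }
    list(dx, matrix(colSums(g * xh), 1L), matrix(colSums(g), 1L))
  })
}

ag_dropout <- function(a, rate, training) {
  if (!training || rate <= 0) return(a)
  mask <- (matrix(stats::runif(length(a$v)), nrow(a$v)) >= rate) / (1 - rate)
  ag_node(a$tape, a$v * mask, list(a), function(g) list(g * mask))
}

ag_cbind <- function(lst) {
  widths <- vapply(lst, function(x) ncol(x$v), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ag_node(lst[[1]]$tape, do.call(cbind, lapply(lst, function(x) x$v)), lst,
          function(g) {
            lapply(seq_along(lst), function(k) g[, starts[k]:ends[k], drop = FALSE])
          })
}

ag_rbind <- function(lst) {
  heights <- vapply(lst, function(x) nrow(x$v), integer(1))
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  ag_node(lst[[1]]$tape, do.call(rbind, lapply(lst, function(x) x$v)), lst,
          function(g) {
            lapply(seq_along(lst), function(k) g[starts[k]:ends[k], , drop = FALSE])
          })
}

ag_sum <- function(a) {
  ag_node(a$tape, matrix(sum(a$v), 1, 1), list(a),
          function(g) list(matrix(g[1], nrow(a$v), ncol(a$v))))
}

# Mean binary cross-entropy from logits (numerically stable).
ag_bce_logits <- function(z, y) {
  zv <- as.vector(z$v)
  y <- as.vector(y)
  n <- length(zv)
  stopifnot(length(y) == n)
  val <- mean(pmax(zv, 0) - zv * y + log1p(exp(-abs(zv))))
  ag_node(z$tape, matrix(val, 1, 1), list(z), function(g) {
    p <- 1 / (1 + exp(-zv))
    list(matrix((p - y) / n * g[1], nrow(z$v), ncol(z$v)))
  })
}

# Mean binary cross-entropy of probabilities over masked entries.  `y` and
# `mask` are plain matrices shaped like `p$v`; entries with mask 0 are
# ignored.  Probabilities are clipped to [eps, 1 - eps] before the log; the
# clip blocks the gradient outside that range.
ag_bce_probs <- function(p, y, mask, eps = 1e-7) {
  pv <- p$v
  n_sup <- sum(mask)
  if (n_sup == 0) return(ag_leaf(p$tape, matrix(0, 1, 1)))
  pc <- pmin(pmax(pv, eps), 1 - eps)
  ll <- -(y * log(pc) + (1 - y) * log(1 - pc)) * mask
  val <- sum(ll) / n_sup
  inside <- (pv > eps & pv < 1 - eps) * mask
  ag_node(p$tape, matrix(val, 1, 1), list(p), function(g) {
    list(((pc - y) / (pc * (1 - pc))) * inside / n_sup * g[1])
  })
}

# Row-wise outer product: out[i, ] = flatten(a[i, ] %o% b[i, ]) with
# row-major flattening (the first argument indexes rows).
ag_pairouter <- function(a, b) {
  h1 <- ncol(a$v); h2 <- ncol(b$v)
  ri <- rep(seq_len(h1), each = h2)
  ci <- rep(seq_len(h2), times = h1)
  ag_node(a$tape, a$v[, ri, drop = FALSE] * b$v[, ci, drop = FALSE],
          list(a, b), function(g) {
            da <- matrix(0, nrow(a$v), h1)
            db <- matrix(0, nrow(b$v), h2)
            for (r in seq_len(h1)) {
              blk <- g[, ((r - 1L) * h2 + 1L):(r * h2), drop = FALSE]
              da[, r] <- rowSums(blk * b$v)
              db <- db + blk * a$v[, r]
            }
            list(da, db)
          })
}
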