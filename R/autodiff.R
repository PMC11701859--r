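#' @useDynLib fusegnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal reverse-mode automatic differentiation on matrix-valued nodes.
#
# Every node is an environment holding a value, a list of parent nodes and a
# vector-Jacobian product (vjp) closure mapping the incoming gradient to one
# gradient per parent. ad_backward() topologically sorts the graph reachable
# from a scalar loss and accumulates gradients into leaf nodes. The op set is
# exactly what the local/global networks and the composite objective need;
# every op's vjp is exercised by finite-difference tests.
# ---------------------------------------------------------------------------

.ad_counter <- new.env(parent = emptyenv())
.ad_counter$id <- 0L

ad_node <- function(value, parents = list(), vjp = NULL) {
  .ad_counter$id <- .ad_counter$id + 1L
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$vjp <- vjp
  e$grad <- NULL
  e$id <- .ad_counter$id
  class(e) <- "ad_node"
  e
}

#' Create an autodiff leaf node
#'
#' Leaf nodes hold trainable parameters (or constants) for the reverse-mode
#' tape used internally by the model. Exposed primarily for tests and
#' extension.
#'
#' @param value numeric matrix or vector (vectors become column matrices).
#' @return an `ad_node` environment.
#' @keywords internal
#' @export
ad_leaf <- function(value) {
  if (!is.matrix(value)) value <- matrix(as.numeric(value), ncol = 1L)
  ad_node(value)
}

is_ad <- function(x) inherits(x, "ad_node")

as_ad <- function(x) {
  if (is_ad(x)) return(x)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1L)
  ad_node(x)
}

#' @keywords internal
#' @export
ad_value <- function(x) if (is_ad(x)) x$value else x

#' @keywords internal
#' @export
ad_grad <- function(x) x$grad

acc_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

#' Backpropagate from a scalar node
#'
#' @param root an `ad_node` whose value is a 1x1 matrix.
#' @keywords internal
#' @export
ad_backward <- function(root) {
  stopifnot(is_ad(root), length(root$value) == 1L)
  # iterative postorder DFS
  topo <- vector("list", 256L)
  ntopo <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, idx = 0L))
  nstk <- 1L
  assign(as.character(root$id), TRUE, envir = seen)
  while (nstk > 0L) {
    fr <- stack[[nstk]]
    node <- fr$node
    if (fr$idx < length(node$parents)) {
      stack[[nstk]]$idx <- fr$idx + 1L
      p <- node$parents[[fr$idx + 1L]]
      key <- as.character(p$id)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        nstk <- nstk + 1L
        stack[[nstk]] <- list(node = p, idx = 0L)
      }
    } else {
      ntopo <- ntopo + 1L
      if (ntopo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[ntopo]] <- node
      stack[[nstk]] <- NULL
      nstk <- nstk - 1L
    }
  }
  root$grad <- matrix(1, 1L, 1L)
  for (i in seq(ntopo, 1L)) {
    node <- topo[[i]]
    if (is.null(node$vjp) || is.null(node$grad)) next
    gs <- node$vjp(node$grad)
    for (j in seq_along(node$parents)) {
      if (!is.null(gs[[j]])) acc_grad(node$parents[[j]], gs[[j]])
    }
  }
  invisible(root)
}

ad_zero_grads <- function(params) {
  walk_fn <- function(x) {
    if (is_ad(x)) x$grad <- NULL else if (is.list(x)) lapply(x, walk_fn)
    invisible(NULL)
  }
  walk_fn(params)
  invisible(params)
}

# ---- basic ops -------------------------------------------------------------

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  ad_node(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

ad_t <- function(a) {
  a <- as_ad(a)
  ad_node(t(a$value), list(a), function(g) list(t(g)))
}

# addition with limited broadcasting: equal shapes, row-vector bias (1 x k)
# against an n x k matrix, or 1 x 1 scalar against anything.
ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  red <- function(g, v) {
    if (identical(dim(g), dim(v))) return(g)
    if (length(v) == 1L) return(matrix(sum(g), 1L, 1L))
    if (nrow(v) == 1L && ncol(v) == ncol(g)) return(matrix(colSums(g), 1L))
    stop("ad_add: incompatible shapes")
  }
  val <- if (length(bv) == 1L) av + bv[1L]
         else if (length(av) == 1L) av[1L] + bv
         else if (nrow(bv) == 1L && nrow(av) > 1L) sweep(av, 2L, bv, "+")
         else if (nrow(av) == 1L && nrow(bv) > 1L) sweep(bv, 2L, av, "+")
         else av + bv
  ad_node(val, list(a, b), function(g) list(red(g, av), red(g, bv)))
}

ad_scale <- function(a, s) {
  a <- as_ad(a)
  ad_node(a$value * s, list(a), function(g) list(g * s))
}

ad_sub <- function(a, b) ad_add(a, ad_scale(as_ad(b), -1))

# elementwise product; supports equal shapes or column-vector (n x 1) against
# n x k (the vector scales rows).
ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  if (identical(dim(av), dim(bv))) {
    ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
  } else if (ncol(av) == 1L && nrow(av) == nrow(bv)) {
    v <- av[, 1L]
    ad_node(v * bv, list(a, b), function(g) {
      list(matrix(rowSums(g * bv), ncol = 1L), v * g)
    })
  } else if (ncol(bv) == 1L && nrow(bv) == nrow(av)) {
    v <- bv[, 1L]
    ad_node(v * av, list(a, b), function(g) {
      list(v * g, matrix(rowSums(g * av), ncol = 1L))
    })
  } else stop("ad_mul: incompatible shapes")
}

ad_tanh <- function(a) {
  a <- as_ad(a)
  y <- tanh(a$value)
  ad_node(y, list(a), function(g) list(g * (1 - y^2)))
}

ad_sigmoid <- function(a) {
  a <- as_ad(a)
  y <- 1 / (1 + exp(-a$value))
  ad_node(y, list(a), function(g) list(g * y * (1 - y)))
}

ad_exp <- function(a) {
  a <- as_ad(a)
  y <- exp(a$value)
  ad_node(y, list(a), function(g) list(g * y))
}

ad_pow <- function(a, k) {
  a <- as_ad(a)
  av <- a$value
  ad_node(av^k, list(a), function(g) list(g * k * av^(k - 1)))
}

ad_sum <- function(a) {
  a <- as_ad(a)
  d <- dim(a$value)
  ad_node(matrix(sum(a$value), 1L, 1L), list(a),
          function(g) list(matrix(g[1L], d[1L], d[2L])))
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(ad_value(a)))

ad_rowsums <- function(a) {
  a <- as_ad(a)
  d <- dim(a$value)
  ad_node(matrix(rowSums(a$value), ncol = 1L), list(a),
          function(g) list(matrix(g[, 1L], d[1L], d[2L])))
}

ad_colmeans <- function(a) {
  a <- as_ad(a)
  d <- dim(a$value)
  ad_node(matrix(colMeans(a$value), 1L), list(a),
          function(g) list(matrix(rep(g / d[1L], each = d[1L]), d[1L], d[2L])))
}

ad_rowmeans <- function(a) ad_scale(ad_rowsums(a), 1 / ncol(ad_value(a)))

ad_cbind <- function(nodes) {
  nodes <- lapply(nodes, as_ad)
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1L))
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ad_node(do.call(cbind, lapply(nodes, `[[`, "value")), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

ad_rows <- function(a, idx) {
  a <- as_ad(a)
  d <- dim(a$value)
  ad_node(a$value[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, d[1L], d[2L])
    out[idx, ] <- out[idx, ] + g
    list(out)
  })
}

# bijective element rearrangement: out (dims dn) with out[i] = a[idx[i]]
# (column-major positions). idx must be a permutation of seq_along(a).
ad_reorder <- function(a, idx, dn) {
  a <- as_ad(a)
  d <- dim(a$value)
  y <- matrix(a$value[idx], dn[1L], dn[2L])
  ad_node(y, list(a), function(g) {
    out <- numeric(length(g))
    out[idx] <- g
    list(matrix(out, d[1L], d[2L]))
  })
}

ad_softmax_rows <- function(a) {
  a <- as_ad(a)
  x <- a$value
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  y <- e / rowSums(e)
  ad_node(y, list(a), function(g) list(y * (g - rowSums(g * y))))
}

ad_logsoftmax_rows <- function(a) {
  a <- as_ad(a)
  x <- a$value
  m <- apply(x, 1L, max)
  lse <- m + log(rowSums(exp(x - m)))
  y <- x - lse
  p <- exp(y)
  ad_node(y, list(a), function(g) list(g - p * rowSums(g)))
}

ad_row_normalize <- function(a, eps = 1e-12) {
  a <- as_ad(a)
  x <- a$value
  nr <- pmax(sqrt(rowSums(x^2)), eps)
  y <- x / nr
  ad_node(y, list(a), function(g) list((g - y * rowSums(g * y)) / nr))
}

ad_frobenius <- function(a, eps = 1e-12) {
  a <- as_ad(a)
  x <- a$value
  nr <- sqrt(sum(x^2))
  ad_node(matrix(nr, 1L, 1L), list(a),
          function(g) list(g[1L] * x / max(nr, eps)))
}

# gradient reversal: identity forward, gradient negated and scaled backward.
ad_grl <- function(a, lambda = 1) {
  a <- as_ad(a)
  ad_node(a$value, list(a), function(g) list(-lambda * g))
}

# mean cross-entropy of 1-based integer labels against logit rows.
ad_cross_entropy <- function(logits, labels) {
  logits <- as_ad(logits)
  n <- nrow(logits$value)
  stopifnot(length(labels) == n, n >= 1L)
  ls <- ad_logsoftmax_rows(logits)
  pick <- cbind(seq_len(n), labels)
  lsv <- ls$value
  ad_node(matrix(-mean(lsv[pick]), 1L, 1L), list(ls), function(g) {
    out <- matrix(0, n, ncol(lsv))
    out[pick] <- -g[1L] / n
    list(out)
  })
}

# batch normalization over rows (one statistic per column).
# state: environment with running_mean / running_var; training toggles
# batch statistics plus running-average update.
ad_batchnorm <- function(a, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  a <- as_ad(a); gamma <- as_ad(gamma); beta <- as_ad(beta)
  x <- a$value
  n <- nrow(x)
  if (training) {
    if (n < 2L) stop("batch normalization needs a batch of >= 2 in training mode; use eval mode")
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2L, mu)^2)
    if (is.null(state$running_mean)) {
      state$running_mean <- mu
      state$running_var <- v
    } else {
      state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
      state$running_var <- (1 - momentum) * state$running_var + momentum * v
    }
  } else {
    mu <- if (is.null(state$running_mean)) rep(0, ncol(x)) else state$running_mean
    v <- if (is.null(state$running_var)) rep(1, ncol(x)) else state$running_var
  }
  sd_ <- sqrt(v + eps)
  xhat <- sweep(sweep(x, 2L, mu), 2L, sd_, "/")
  gv <- gamma$value[1L, ]
  y <- sweep(sweep(xhat, 2L, gv, "*"), 2L, beta$value[1L, ], "+")
  ad_node(y, list(a, gamma, beta), function(g) {
    dgamma <- matrix(colSums(g * xhat), 1L)
    dbeta <- matrix(colSums(g), 1L)
    if (training) {
      gg <- sweep(g, 2L, gv, "*")
      dx <- sweep(gg, 2L, colMeans(gg)) - xhat * matrix(rep(colMeans(gg * xhat), each = n), n)
      dx <- sweep(dx, 2L, sd_, "/")
    } else {
      dx <- sweep(sweep(g, 2L, gv, "*"), 2L, sd_, "/")
    }
    list(dx, dgamma, dbeta)
  })
}

# ---- fused recurrent and block ops ----------------------------------------

# bidirectional GRU over a batch of scalar sequences (rows of X). params is a
# list of leaf nodes: fwd = list(Wx, Wh, bx, bh), bwd likewise. Output is the
# concatenation of final forward and backward hidden states (N x 2h).
ad_bigru <- function(X, params, want_grad = TRUE) {
  run <- function(Xm, p) {
    gru_forward_cpp(Xm, p$Wx$value, p$Wh$value, p$bx$value[1L, ],
                    p$bh$value[1L, ], want_cache = want_grad)
  }
  Xr <- X[, rev(seq_len(ncol(X))), drop = FALSE]
  ff <- run(X, params$fwd)
  fb <- run(Xr, params$bwd)
  h <- ncol(ff$h)
  val <- cbind(ff$h, fb$h)
  if (!want_grad) return(ad_node(val))
  parents <- list(params$fwd$Wx, params$fwd$Wh, params$fwd$bx, params$fwd$bh,
                  params$bwd$Wx, params$bwd$Wh, params$bwd$bx, params$bwd$bh)
  ad_node(val, parents, function(g) {
    gf <- g[, seq_len(h), drop = FALSE]
    gb <- g[, h + seq_len(h), drop = FALSE]
    bw <- function(Xm, p, cache, gh) {
      gru_backward_cpp(Xm, p$Wx$value, p$Wh$value, p$bx$value[1L, ],
                       p$bh$value[1L, ], cache, gh)
    }
    df <- bw(X, params$fwd, ff$cache, gf)
    db <- bw(Xr, params$bwd, fb$cache, gb)
    list(df$dWx, df$dWh, matrix(df$dbx, 1L), matrix(df$dbh, 1L),
         db$dWx, db$dWh, matrix(db$dbx, 1L), matrix(db$dbh, 1L))
  })
}

# per-subject learnable adjacency: blocks of E (stacked S blocks of n rows)
# produce A_s = scale * softmax_rows(E_s E_s^T). Output stacked (S*n) x n.
ad_block_gram_softmax <- function(E, n_roi, scale = n_roi) {
  E <- as_ad(E)
  Ev <- E$value
  S <- nrow(Ev) / n_roi
  stopifnot(S == round(S))
  S <- as.integer(S)
  P_list <- vector("list", S)
  val <- matrix(0, nrow(Ev), n_roi)
  for (s in seq_len(S)) {
    rs <- (s - 1L) * n_roi + seq_len(n_roi)
    G <- tcrossprod(Ev[rs, , drop = FALSE])
    G <- G - apply(G, 1L, max)
    e <- exp(G)
    P <- e / rowSums(e)
    P_list[[s]] <- P
    val[rs, ] <- scale * P
  }
  ad_node(val, list(E), function(g) {
    dE <- matrix(0, nrow(Ev), ncol(Ev))
    for (s in seq_len(S)) {
      rs <- (s - 1L) * n_roi + seq_len(n_roi)
      P <- P_list[[s]]
      dP <- scale * g[rs, , drop = FALSE]
      dG <- P * (dP - rowSums(dP * P))
      Es <- Ev[rs, , drop = FALSE]
      dE[rs, ] <- (dG + t(dG)) %*% Es
    }
    list(dE)
  })
}

# per-subject symmetric-degree-normalized propagation:
# out_s = D^{-1/2} A_s D^{-1/2} H_s, with D the diagonal of row sums of A_s.
ad_block_gcn_prop <- function(A, H, n_roi) {
  A <- as_ad(A); H <- as_ad(H)
  Av <- A$value; Hv <- H$value
  S <- as.integer(nrow(Av) / n_roi)
  val <- matrix(0, nrow(Hv), ncol(Hv))
  cache <- vector("list", S)
  for (s in seq_len(S)) {
    rs <- (s - 1L) * n_roi + seq_len(n_roi)
    As <- Av[rs, , drop = FALSE]
    d <- rowSums(As)
    if (any(d <= 0)) stop("zero-degree node in ROI graph block ", s)
    v <- 1 / sqrt(d)
    Pn <- (v %o% v) * As
    val[rs, ] <- Pn %*% Hv[rs, , drop = FALSE]
    cache[[s]] <- list(v = v, As = As, Pn = Pn)
  }
  ad_node(val, list(A, H), function(g) {
    dA <- matrix(0, nrow(Av), ncol(Av))
    dH <- matrix(0, nrow(Hv), ncol(Hv))
    for (s in seq_len(S)) {
      rs <- (s - 1L) * n_roi + seq_len(n_roi)
      gs <- g[rs, , drop = FALSE]
      Hs <- Hv[rs, , drop = FALSE]
      cc <- cache[[s]]
      dH[rs, ] <- crossprod(cc$Pn, gs)
      dPn <- tcrossprod(gs, Hs)
      dAs <- (cc$v %o% cc$v) * dPn
      # degree pathway: v_i = d_i^{-1/2}
      dv <- rowSums(dPn * sweep(cc$As, 2L, cc$v, "*")) +
            colSums(dPn * (cc$v %o% rep(1, n_roi)) * cc$As)
      dd <- -0.5 * cc$v^3 * dv
      dAs <- dAs + matrix(dd, n_roi, n_roi)
      dA[rs, ] <- dAs
    }
    list(dA, dH)
  })
}
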