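# Global network: snowball forward against explicit arithmetic, the p-flag
# contract, weight sharing in the common block, attention fusion, and
# subject-permutation invariance of the whole global model.

test_that("snowball forward matches a hand-computed chain on a 2-node graph", {
  set.seed(1)
  W <- matrix(1, 2, 2)            # single edge between the two subjects
  L <- normalize_adjacency(W)
  X <- matrix(c(1, 0, 0.5, -1), 2, 2)
  params <- new_snowball(2L, n_layers = 1L, width = 2L, c_width = 2L,
                         out_width = 2L)
  out <- snowball_forward(L, X, params)
  W0 <- ad_value(params$Wl[[1]]); Wn <- ad_value(params$Wn)
  Wc <- ad_value(params$Wc)
  H1 <- tanh(L %*% X %*% W0)
  C <- tanh(cbind(X, H1) %*% Wn)
  raw <- C %*% Wc
  oracle <- raw / sqrt(rowSums(raw^2))
  expect_equal(out, oracle, tolerance = 1e-9)
  # p = 0 vs p = 1 differ exactly by one propagation before normalization
  out1 <- snowball_forward(L, X, params, p = 1L)
  raw1 <- L %*% raw
  expect_equal(out1, raw1 / sqrt(rowSums(raw1^2)), tolerance = 1e-9)
  # normalized rows have unit norm
  expect_lt(max(abs(sqrt(rowSums(out^2)) - 1)), 1e-9)
})

test_that("snowball layer consumes the concatenation of all previous layers", {
  set.seed(2)
  S <- 5L
  g <- build_knn_graph(matrix(rnorm(S * 3), S, 3), k = 2L, channel = "functional")
  L <- normalize_adjacency(g$weights)
  X <- matrix(rnorm(S * 4), S, 4)
  params <- new_snowball(4L, n_layers = 3L, width = 3L, c_width = 5L,
                         out_width = 4L)
  out <- snowball_forward(L, X, params)
  # explicit recomputation of the dense concatenation recursion
  Hs <- list(X)
  for (l in 1:3) {
    cc <- do.call(cbind, Hs)
    Hs[[l + 1]] <- tanh(L %*% (cc %*% ad_value(params$Wl[[l]])))
  }
  C <- tanh(do.call(cbind, Hs) %*% ad_value(params$Wn))
  raw <- C %*% ad_value(params$Wc)
  expect_equal(out, raw / sqrt(rowSums(raw^2)), tolerance = 1e-9)
})

test_that("MS-GCN channels are independent while MC-GCN shares its trunk", {
  set.seed(3)
  S <- 8L
  Xs <- list(f = matrix(rnorm(S * 6), S, 6), s = matrix(rnorm(S * 5), S, 5),
             d = matrix(rnorm(S * 4), S, 4))
  graphs <- lapply(Xs, function(X) build_knn_graph(X, k = 3L, channel = "functional"))
  cfg <- global_config(snowball_layers = 2L, snowball_width = 3L, c_width = 6L,
                       out_width = 4L, common_width = 5L)
  model <- new_global_model(c(f = 6L, s = 5L, d = 4L), eta_dim = 4L,
                            n_sites = 2L, config = cfg)
  ms <- ms_gcn(graphs, Xs, model)
  expect_named(ms, c("f", "s", "d"))
  # per-channel outputs equal direct snowball calls (composition)
  direct <- snowball_forward(graphs$f, Xs$f, model$specific$f)
  expect_equal(ms$f, direct, tolerance = 1e-12)
  # identical graphs/features with independent inits still differ
  same <- list(f = Xs$f, s = Xs$f, d = Xs$f)
  sg <- list(f = graphs$f, s = graphs$f, d = graphs$f)
  model_eq <- new_global_model(c(f = 6L, s = 6L, d = 6L), eta_dim = 4L,
                               n_sites = 2L, config = cfg)
  ms2 <- ms_gcn(sg, same, model_eq)
  expect_gt(max(abs(ms2$f - ms2$s)), 1e-4)
  # MC-GCN: identical inputs and identical projections -> identical commons
  mc <- mc_gcn(sg, same, model_eq)
  expect_named(mc$common_per_channel, c("f", "s", "d"))
  model_same_proj <- model_eq
  model_same_proj$proj$s <- model_same_proj$proj$f
  model_same_proj$proj$d <- model_same_proj$proj$f
  mc2 <- mc_gcn(sg, same, model_same_proj)
  expect_equal(mc2$common_per_channel$f, mc2$common_per_channel$s,
               tolerance = 1e-12)
  expect_equal(mc2$common, mc2$common_per_channel$f, tolerance = 1e-12)
  expect_error(mc_gcn(sg, same, model_eq, weights = c(0.5, 0.2, 0.1)),
               "sum to 1")
  expect_error(ms_gcn(graphs[c("f", "s")], Xs, model), "channel mismatch")
})

test_that("MC-GCN weight sharing routes gradients from every channel", {
  set.seed(4)
  S <- 6L
  Xs <- list(f = matrix(rnorm(S * 3), S, 3), s = matrix(rnorm(S * 3), S, 3),
             d = matrix(rnorm(S * 3), S, 3))
  L <- normalize_adjacency(build_knn_graph(Xs$f, k = 2L)$weights)
  cfg <- global_config(snowball_layers = 1L, snowball_width = 2L, c_width = 4L,
                       out_width = 3L, common_width = 3L)
  model <- new_global_model(c(f = 3L, s = 3L, d = 3L), eta_dim = 3L,
                            n_sites = 2L, config = cfg)
  shared_W <- model$shared$Wl[[1]]
  lossfn <- function() {
    ad_zero_grads(model)
    per <- lapply(c("f", "s", "d"), function(ch) {
      Xp <- linear_fwd(ad_node(Xs[[ch]]), model$proj[[ch]])
      snowball_fwd(L, Xp, model$shared, p = 0L)
    })
    ad_sum(ad_pow(Reduce(function(a, b) ad_add(a, b), per), 2))
  }
  expect_lt(fd_gradient_error(lossfn, list(shared_W)), 1e-7)
  # perturbing one channel's input changes the shared trunk's gradient
  loss <- lossfn(); ad_backward(loss)
  g1 <- ad_grad(shared_W)
  Xs$s <- Xs$s + 0.5
  loss2 <- lossfn(); ad_backward(loss2)
  expect_gt(max(abs(ad_grad(shared_W) - g1)), 1e-6)
})

test_that("m_attention produces per-node simplex weights and a faithful weighted sum", {
  set.seed(5)
  S <- 7L
  cfg <- global_config(snowball_layers = 1L, snowball_width = 2L, c_width = 4L,
                       out_width = 3L, attn_width = 2L)
  model <- new_global_model(c(f = 3L, s = 3L, d = 3L), eta_dim = 3L,
                            n_sites = 2L, config = cfg)
  emb <- list(f = matrix(rnorm(S * 3), S, 3), s = matrix(rnorm(S * 3), S, 3),
              d = matrix(rnorm(S * 3), S, 3), common = matrix(rnorm(S * 3), S, 3))
  out <- m_attention(emb, model)
  expect_equal(rowSums(out$attention), rep(1, S), tolerance = 1e-9)
  expect_true(all(out$attention > 0))
  manual <- Reduce(`+`, Map(function(e, j) out$attention[, j] * e,
                            emb, seq_along(emb)))
  expect_equal(out$fused, manual, tolerance = 1e-12)
  # identical embeddings and identical attention parameters -> equal scores
  model_tied <- model
  for (ch in names(model_tied$attn)) model_tied$attn[[ch]] <- model$attn$f
  same <- lapply(emb, function(x) emb$f)
  tied <- m_attention(same, model_tied)
  expect_equal(unname(tied$attention),
               matrix(0.25, S, 4), tolerance = 1e-12)
  expect_error(m_attention(list(f = emb$f, s = emb$s[, 1:2],
                                d = emb$d, common = emb$common), model),
               "shape mismatch")
  # scalar oracle on 1-dim embeddings with hand-set weights
  cfg1 <- global_config(snowball_layers = 1L, snowball_width = 1L, c_width = 1L,
                        out_width = 1L, attn_width = 1L)
  m1 <- new_global_model(c(f = 1L, s = 1L, d = 1L), eta_dim = 2L,
                         n_sites = 2L, config = cfg1)
  for (ch in names(m1$attn)) {
    m1$attn[[ch]]$W$value <- matrix(ch == "f")
    m1$attn[[ch]]$b$value <- matrix(0)
  }
  e1 <- list(f = matrix(2), s = matrix(1), d = matrix(-1), common = matrix(0.5))
  o1 <- m_attention(e1, m1)
  z <- c(tanh(2), 0, 0, 0)
  a <- exp(z) / sum(exp(z))
  expect_equal(drop(o1$fused), sum(a * c(2, 1, -1, 0.5)), tolerance = 1e-12)
})

test_that("classifier emits simplex probabilities matching a hand softmax", {
  cfg <- global_config(snowball_layers = 1L, out_width = 2L, clf_hidden = 2L)
  model <- new_global_model(c(f = 2L, s = 2L, d = 2L), eta_dim = 2L,
                            n_sites = 2L, config = cfg)
  model$clf$l1$W$value <- diag(2)
  model$clf$l1$b$value <- matrix(0, 1, 2)
  model$clf$l2$W$value <- diag(2)
  model$clf$l2$b$value <- matrix(0, 1, 2)
  H <- rbind(c(0.3, -0.2), c(0.3, -0.2), c(2, 1))
  out <- classify(H, model)
  expect_equal(out$probabilities[1, ], out$probabilities[2, ])
  expect_equal(rowSums(out$probabilities), rep(1, 3))
  z <- tanh(H[3, ])
  expect_equal(out$probabilities[3, ], exp(z) / sum(exp(z)), tolerance = 1e-12)
})

test_that("the global model is invariant to subject reordering", {
  set.seed(6)
  S <- 10L
  eta <- matrix(runif(S * 4), S, 4)
  Xs <- list(f = matrix(rnorm(S * 5), S, 5), s = matrix(rnorm(S * 4), S, 4),
             d = eta)
  cfg <- global_config(snowball_layers = 2L, snowball_width = 3L, c_width = 5L,
                       out_width = 4L)
  model <- new_global_model(c(f = 5L, s = 4L, d = 4L), eta_dim = 4L,
                            n_sites = 2L, config = cfg)
  Ls <- list(f = normalize_adjacency(build_knn_graph(Xs$f, 3L)$weights),
             s = normalize_adjacency(build_knn_graph(Xs$s, 3L)$weights),
             d = normalize_adjacency(build_knn_graph(eta, 3L)$weights))
  base <- global_forward(model, lapply(Ls, ad_node), lapply(Xs, ad_node))
  perm <- sample(S)
  Lp <- lapply(Ls, function(L) L[perm, perm])
  Xp <- lapply(Xs, function(X) X[perm, , drop = FALSE])
  permuted <- global_forward(model, lapply(Lp, ad_node), lapply(Xp, ad_node))
  expect_equal(ad_value(permuted$logits), ad_value(base$logits)[perm, ],
               tolerance = 1e-9)
  expect_equal(ad_value(permuted$fused), ad_value(base$fused)[perm, ],
               tolerance = 1e-9)
})
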