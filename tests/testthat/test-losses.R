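# Objective components: cross-entropy against a scalar oracle, HSIC against
# a brute-force trace, the similarity loss on Gram differences, CMD closed
# forms, the gradient-reversal contract, and additivity of the total.

test_that("classification loss matches hand-computed -sum log softmax and weighting", {
  gl <- rbind(c(2, -1), c(0.5, 0.5), c(-2, 3))
  ll <- rbind(c(1, 0), c(0, 1), c(1, 1))
  y <- c(0L, 1L, 1L)
  oracle <- function(lg) {
    p <- exp(lg - apply(lg, 1, max)); p <- p / rowSums(p)
    -mean(log(p[cbind(1:3, y + 1L)]))
  }
  out <- classification_loss(gl, ll, y, mask = 1:3, lambda_local = 0.2)
  expect_equal(out$global, oracle(gl), tolerance = 1e-10)
  expect_equal(out$local, oracle(ll), tolerance = 1e-10)
  expect_equal(out$total, oracle(gl) + 0.2 * oracle(ll), tolerance = 1e-10)
  # lambda = 0 reduces to the global loss; perfect predictions drive it to 0
  expect_equal(classification_loss(gl, ll, y, 1:3, 0)$total, oracle(gl))
  conf <- rbind(c(50, -50), c(-50, 50), c(-50, 50))
  expect_lt(classification_loss(conf, NULL, y, 1:3)$total, 1e-10)
  expect_error(classification_loss(gl, ll, y, integer(0)), "empty")
})

test_that("HSIC equals the brute-force trace formula on random instances", {
  set.seed(1)
  for (rep in 1:20) {
    m <- sample(4:8, 1)
    Hs <- matrix(rnorm(m * 3), m, 3)
    Hc <- matrix(rnorm(m * 2), m, 2)
    R <- diag(m) - matrix(1 / m, m, m)
    oracle <- sum(diag(tcrossprod(Hc) %*% R %*% tcrossprod(Hs) %*% R)) / (m - 1)^2
    expect_equal(hsic(Hs, Hc), oracle, tolerance = 1e-10)
    # taped twin produces the same value
    expect_equal(ad_value(hsic_t(ad_leaf(Hs), ad_leaf(Hc)))[1], oracle,
                 tolerance = 1e-10)
  }
})

test_that("HSIC structural properties: constants vanish, joint permutation invariant, PSD", {
  set.seed(2)
  Hs <- matrix(rnorm(12), 6, 2)
  expect_equal(hsic(Hs, matrix(1, 6, 1)), 0, tolerance = 1e-12)
  perm <- sample(6)
  Hc <- matrix(rnorm(18), 6, 3)
  expect_equal(hsic(Hs[perm, ], Hc[perm, ]), hsic(Hs, Hc), tolerance = 1e-12)
  expect_gte(hsic(Hs, Hs), 0)
  expect_gt(hsic(Hs, Hs, kernel = "gaussian"), 0)
  expect_error(hsic(Hs[1, , drop = FALSE], Hc[1, , drop = FALSE]), "m >= 2")
})

test_that("modality-specific loss sums per-channel HSIC terms", {
  set.seed(3)
  common <- matrix(rnorm(20), 10, 2)
  specific <- list(f = matrix(rnorm(30), 10, 3), s = matrix(rnorm(20), 10, 2))
  expect_equal(modality_specific_loss(specific, common),
               hsic(specific$f, common) + hsic(specific$s, common),
               tolerance = 1e-12)
  expect_equal(modality_specific_loss(specific["f"], common),
               hsic(specific$f, common), tolerance = 1e-12)
  # centered-orthogonal construction drives the linear-kernel HSIC to ~0
  m <- 6L
  a <- scale(matrix(rnorm(m), m, 1), scale = FALSE)
  b <- matrix(c(1, -1, 1, -1, 1, -1), m, 1)
  b <- scale(residuals(lm(b ~ a)), scale = FALSE)
  expect_lt(modality_specific_loss(list(x = a %*% t(c(1, 2))),
                                   b %*% t(c(2, -1))), 1e-20)
})

test_that("modality-similarity loss follows the Gram-difference form", {
  H <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2)
  commons <- list(f = H, s = H, d = H)
  expect_equal(modality_similarity_loss(commons), 0, tolerance = 1e-12)
  # 2-subject hand oracle
  f <- rbind(c(1, 0), c(0, 1)); s <- rbind(c(1, 0), c(1, 0)); d <- rbind(c(0, 1), c(1, 0))
  gram <- function(M) tcrossprod(M / sqrt(rowSums(M^2)))
  oracle <- norm(gram(f) - gram(d), "F") + norm(gram(f) - gram(s), "F") +
    norm(gram(d) - gram(s), "F")
  expect_equal(modality_similarity_loss(list(f = f, s = s, d = d)), oracle,
               tolerance = 1e-12)
  # taped twin agrees
  expect_equal(ad_value(modality_similarity_loss_t(
    list(f = ad_leaf(f), s = ad_leaf(s), d = ad_leaf(d))))[1],
    oracle, tolerance = 1e-12)
  # NOT invariant to per-row sign flips in general (inner products flip)
  f3 <- rbind(c(1, 1), c(0, 1)); f4 <- f3; f4[1, ] <- -f4[1, ]
  l3 <- modality_similarity_loss(list(f = f3, s = s, d = d))
  l4 <- modality_similarity_loss(list(f = f4, s = s, d = d))
  expect_gt(abs(l4 - l3), 1e-6)
})

test_that("site-adversarial loss sits at chance for uninformative embeddings and reverses gradients", {
  set.seed(4)
  cfg <- global_config(snowball_layers = 1L, out_width = 3L, site_hidden = 3L)
  model <- new_global_model(c(f = 3L, s = 3L, d = 3L), eta_dim = 2L,
                            n_sites = 3L, config = cfg)
  # zero the classifier so logits are constant: exact chance level
  for (lin in model$site_clf) { lin$W$value[] <- 0; lin$b$value[] <- 0 }
  H <- matrix(rnorm(30), 10, 3)
  sites <- rep(1:3, length.out = 10)
  expect_equal(site_adversarial_loss(H, sites, model), log(3), tolerance = 1e-10)
  expect_warning(site_adversarial_loss(H, rep(1L, 10), model), "vacuous")
  # grl_lambda = 0: upstream gradients from the site loss are exactly zero
  set.seed(5)
  model2 <- new_global_model(c(f = 3L, s = 3L, d = 3L), eta_dim = 2L,
                             n_sites = 3L, config = cfg)
  Hn <- ad_leaf(H)
  loss0 <- ad_cross_entropy(mlp_fwd(ad_grl(Hn, 0), model2$site_clf),
                            as.integer(factor(sites)))
  ad_backward(loss0)
  expect_equal(ad_grad(Hn), matrix(0, 10, 3))
  # backward sign is negated through the reversal: grad(-lambda) = -lambda * grad(+1)
  Hn2 <- ad_leaf(H)
  loss1 <- ad_cross_entropy(mlp_fwd(ad_grl(Hn2, 1), model2$site_clf),
                            as.integer(factor(sites)))
  ad_backward(loss1)
  Hn3 <- ad_leaf(H)
  loss2 <- ad_cross_entropy(mlp_fwd(ad_grl(Hn3, -1), model2$site_clf),
                            as.integer(factor(sites)))
  ad_backward(loss2)
  expect_equal(ad_grad(Hn2), -ad_grad(Hn3), tolerance = 1e-12)
})

test_that("CMD closed forms: zero for identical groups, mean-shift first term, symmetry", {
  set.seed(6)
  X <- matrix(rnorm(10), 5, 2)
  emb <- rbind(X, X)
  sites <- rep(1:2, each = 5)
  expect_equal(cmd_loss(emb, sites), 0, tolerance = 1e-12)
  # two 1-d sites differing only by a mean shift delta: first term delta/(b-a)
  delta <- 0.7
  x <- seq(-1, 1, length.out = 9)
  emb2 <- matrix(c(x, x + delta), ncol = 1)
  s2 <- rep(1:2, each = 9)
  rng <- range(emb2)
  v <- cmd_loss(emb2, s2, K = 1L, range = rng)
  expect_equal(v, delta / diff(rng), tolerance = 1e-12)
  # higher central moments of a shifted copy coincide: K=5 adds nothing
  expect_equal(cmd_loss(emb2, s2, K = 5L, range = rng), v, tolerance = 1e-12)
  # symmetric in site order
  set.seed(7)
  emb3 <- matrix(rnorm(24), 12, 2)
  s3 <- rep(1:2, each = 6)
  expect_equal(cmd_loss(emb3, s3), cmd_loss(emb3, rev(s3)), tolerance = 1e-12)
  expect_error(cmd_loss(emb3, factor(s3, levels = 1:3)), "empty")
  # taped twin agrees with the numeric version
  expect_equal(ad_value(cmd_loss_t(ad_leaf(emb3), s3))[1],
               cmd_loss(emb3, s3), tolerance = 1e-12)
})

test_that("total loss is the sum of its components, and gradients add", {
  comps <- list(cls = 0.4, specific = 0.02, common = 1.5, site = 1.1, cmd = 0.3)
  out <- total_loss(comps)
  expect_equal(out$domain, 1.4)
  expect_equal(out$total, 0.4 + 0.02 + 1.5 + 1.4)
  expect_equal(total_loss(list())$total, 0)
  # gradient of a composite equals the sum of component gradients
  set.seed(8)
  H <- ad_leaf(matrix(rnorm(12), 6, 2))
  sites <- rep(1:2, 3)
  other <- matrix(rnorm(12), 6, 2)
  lossfn <- function() {
    ad_zero_grads(H)
    # fixed range: the CMD scale is a constant, not differentiated through
    ad_add(hsic_t(H, ad_leaf(other)), cmd_loss_t(H, sites, range = c(-4, 4)))
  }
  expect_lt(fd_gradient_error(lossfn, list(H)), 1e-7)
})

test_that("training loss decreases over early epochs on an easy cohort", {
  co <- tiny_cohort(n_subjects = 24L, seed = 3L)
  cfg <- tiny_train_config(mode = "end_to_end", seed = 11L)
  cfg$epochs <- 10L
  fit <- train_end_to_end(co, cfg)
  tot <- fit$loss_log$total
  first <- mean(tot[1:3]); last <- mean(tot[8:10])
  expect_lt(last, first)
})
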