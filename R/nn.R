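# Parameter construction and optimization utilities shared by the local and
# global networks. Parameters are autodiff leaf nodes arranged in nested
# named lists; helpers below flatten them for the optimizer.

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

new_linear <- function(n_in, n_out) {
  list(W = ad_leaf(glorot(n_in, n_out)), b = ad_leaf(matrix(0, 1L, n_out)))
}

linear_fwd <- function(x, lin) ad_add(ad_matmul(x, lin$W), lin$b)

# two-layer perceptron with tanh hidden activation
new_mlp <- function(n_in, n_hidden, n_out) {
  list(l1 = new_linear(n_in, n_hidden), l2 = new_linear(n_hidden, n_out))
}

mlp_fwd <- function(x, mlp) linear_fwd(ad_tanh(linear_fwd(x, mlp$l1)), mlp$l2)

new_gru_dir <- function(hidden) {
  list(Wx = ad_leaf(glorot(1L, 3L * hidden)),
       Wh = ad_leaf(glorot(hidden, 3L * hidden)),
       bx = ad_leaf(matrix(0, 1L, 3L * hidden)),
       bh = ad_leaf(matrix(0, 1L, 3L * hidden)))
}

new_bigru <- function(hidden) list(fwd = new_gru_dir(hidden), bwd = new_gru_dir(hidden))

new_batchnorm <- function(width) {
  list(gamma = ad_leaf(matrix(1, 1L, width)),
       beta = ad_leaf(matrix(0, 1L, width)),
       state = new.env(parent = emptyenv()))
}

# flatten a nested parameter list into a flat list of leaf nodes
flatten_params <- function(params) {
  out <- list()
  rec <- function(x) {
    if (is_ad(x)) {
      out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) rec(el)
    }
  }
  rec(params)
  out
}

n_params <- function(params) sum(vapply(flatten_params(params),
                                        function(p) length(p$value), numeric(1L)))

# ---- Adam ------------------------------------------------------------------

adam_new <- function(params, lr = 1e-2, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  leaves <- flatten_params(params)
  list(leaves = leaves, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       t = 0L,
       m = lapply(leaves, function(p) array(0, dim(p$value))),
       v = lapply(leaves, function(p) array(0, dim(p$value))))
}

adam_step <- function(opt, lr = NULL) {
  if (is.null(lr)) lr <- opt$lr
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (i in seq_along(opt$leaves)) {
    p <- opt$leaves[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g^2
    mhat <- opt$m[[i]] / corr1
    vhat <- opt$v[[i]] / corr2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  opt
}

# stepped learning-rate schedule: halved every `period` epochs
lr_at_epoch <- function(lr0, epoch, period = 100L) lr0 * 0.5^((epoch - 1L) %/% period)
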