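# Local ROI network: a shared-weight bidirectional GRU encodes each ROI's
# BOLD sequence, a graph generator turns the embedding Gram matrix into a
# learnable row-stochastic adjacency (scaled by the number of ROIs), a
# three-layer GCN propagates Pearson-FC node features over it, and an
# attention readout yields a per-subject graph embedding plus local logits.

#' Local model configuration
#'
#' @param gru_hidden hidden width per GRU direction (embedding width is twice
#'   this).
#' @param gcn_widths output widths of the three GCN layers.
#' @param mlp_hidden hidden width of the per-layer weight MLPs and classifier.
#' @return a list of local-model hyperparameters.
#' @export
local_config <- function(gru_hidden = 32L, gcn_widths = c(64L, 32L, 16L),
                         mlp_hidden = 32L) {
  list(gru_hidden = as.integer(gru_hidden),
       gcn_widths = as.integer(gcn_widths),
       mlp_hidden = as.integer(mlp_hidden))
}

# allocate parameters for the local model
new_local_model <- function(n_rois, config = local_config()) {
  d <- 2L * config$gru_hidden
  widths <- config$gcn_widths
  ins <- c(n_rois, widths[-length(widths)])
  gcn <- lapply(seq_along(widths), function(k)
    new_mlp(ins[k], config$mlp_hidden, widths[k]))
  d_out <- widths[length(widths)]
  list(gru = new_bigru(config$gru_hidden),
       gcn = gcn,
       bn = new_batchnorm(n_rois * d_out),
       clf = new_mlp(n_rois * d_out, config$mlp_hidden, 2L),
       n_rois = as.integer(n_rois), d = d, d_out = d_out,
       config = config)
}

# index maps between stacked (S*n) x k layouts and per-subject layouts
stack_indices <- function(S, n, d) {
  g <- expand.grid(s = seq_len(S), j = seq_len(d), i = seq_len(n))
  # out position in S x (n*d), column-major; in position in (S*n) x d
  pos_out <- ((g$i - 1L) * d + g$j - 1L) * S + g$s
  pos_in <- (g$j - 1L) * S * n + (g$s - 1L) * n + g$i
  idx <- integer(S * n * d)
  idx[pos_out] <- pos_in
  idx
}

stacked_to_wide_idx <- function(S, n) {
  as.vector(outer(seq_len(S), seq_len(n), function(s, i) (s - 1L) * n + i))
}

wide_to_stacked_idx <- function(S, n) {
  as.vector(outer(seq_len(n), seq_len(S), function(i, s) (i - 1L) * S + s))
}

# taped forward pass over a stacked cohort.
# Xstack: (S*n) x t series rows; Fstack: (S*n) x n FC node features.
local_forward <- function(model, Xstack, Fstack, training = TRUE) {
  n <- model$n_rois
  S <- nrow(Xstack) / n
  stopifnot(S == round(S))
  S <- as.integer(S)
  E <- ad_bigru(Xstack, model$gru, want_grad = training)
  A <- ad_block_gram_softmax(E, n)
  H <- ad_node(Fstack)
  for (mlp in model$gcn) {
    P <- ad_block_gcn_prop(A, H, n)
    H <- ad_tanh(mlp_fwd(P, mlp))
  }
  rs <- ad_rowsums(A)
  rs_wide <- ad_reorder(rs, stacked_to_wide_idx(S, n), c(S, n))
  attn <- ad_scale(ad_softmax_rows(rs_wide), n)           # S x n, rows sum to n
  attn_st <- ad_reorder(attn, wide_to_stacked_idx(S, n), c(S * n, 1L))
  Hw <- ad_mul(attn_st, H)
  Gemb <- ad_reorder(Hw, stack_indices(S, n, model$d_out), c(S, n * model$d_out))
  z <- ad_batchnorm(Gemb, model$bn$gamma, model$bn$beta, model$bn$state,
                    training = training)
  logits <- mlp_fwd(z, model$clf)
  list(embedding = E, adjacency = A, node_states = H, attention = attn,
       graph_embedding = Gemb, logits = logits, S = S)
}

#' Encode ROI time series with the bidirectional GRU
#'
#' Each ROI's scalar sequence passes through the shared-weight bidirectional
#' gated recurrent encoder; a row of the output is the concatenation of the
#' final forward and backward hidden states.
#'
#' @param series `n_rois x t` matrix (standardized signals).
#' @param model a local model (from an internal constructor or a trained fit).
#' @return `n_rois x d` regional embedding matrix.
#' @export
encode_series <- function(series, model) {
  stopifnot(is.matrix(series))
  if (any(!is.finite(series))) stop("non-finite values in series")
  ad_value(ad_bigru(series, model$gru, want_grad = FALSE))
}

#' Generate a learnable ROI adjacency from a regional embedding
#'
#' Row-wise softmax of the embedding Gram matrix, scaled by the number of
#' ROIs, so that every row sums to `n`. Softmax uses row-max subtraction for
#' numerical stability.
#'
#' @param embedding `n x d` regional embedding.
#' @return `n x n` nonnegative adjacency with rows summing to `n`.
#' @export
generate_graph <- function(embedding) {
  stopifnot(is.matrix(embedding), all(is.finite(embedding)))
  n <- nrow(embedding)
  ad_value(ad_block_gram_softmax(ad_node(embedding), n))
}

#' One graph-convolution layer on an ROI graph
#'
#' Computes `sigma(D^{-1/2} A D^{-1/2} H W)` where `D` is the diagonal matrix
#' of row sums of `A`. `W` may be a plain matrix (single linear map) or a
#' two-layer MLP given as `list(W1, b1, W2, b2)`.
#'
#' @param H `n x h` node states.
#' @param A `n x n` adjacency with strictly positive row sums.
#' @param W weight matrix or two-layer MLP parameter list.
#' @param sigma activation function (default `tanh`).
#' @return `n x h'` matrix.
#' @export
gcn_layer <- function(H, A, W, sigma = tanh) {
  d <- rowSums(A)
  if (any(d <= 0)) stop("zero-degree node in adjacency")
  v <- 1 / sqrt(d)
  P <- ((v %o% v) * A) %*% H
  if (is.matrix(W)) return(sigma(P %*% W))
  Z <- tanh(sweep(P %*% W$W1, 2L, W$b1, "+"))
  sigma(sweep(Z %*% W$W2, 2L, W$b2, "+"))
}

#' Attention readout of an ROI graph
#'
#' ROI attention is the softmax (scaled by `n`) over ROIs of the row sums of
#' the learned adjacency; the graph embedding concatenates each ROI's state
#' scaled by its attention.
#'
#' @param H `n x d` final-layer node states.
#' @param A `n x n` learned adjacency.
#' @return list with `attention` (length-`n` vector summing to `n`) and
#'   `graph_embedding` (length `n * d` vector).
#' @export
attention_readout <- function(H, A) {
  n <- nrow(A)
  s <- rowSums(A)
  e <- exp(s - max(s))
  a <- n * e / sum(e)
  list(attention = a, graph_embedding = as.vector(t(a * H)))
}

#' Local class prediction from graph embeddings
#'
#' Batch-normalizes graph embeddings and applies the classification MLP.
#' Training mode estimates batch statistics and therefore needs a batch of at
#' least two; eval mode uses running statistics.
#'
#' @param model a local model.
#' @param embeddings subjects x (n*d) matrix of graph embeddings.
#' @param training logical.
#' @return subjects x 2 logit matrix.
#' @export
local_predict <- function(model, embeddings, training = FALSE) {
  z <- ad_batchnorm(ad_node(embeddings), model$bn$gamma, model$bn$beta,
                    model$bn$state, training = training)
  ad_value(mlp_fwd(z, model$clf))
}

# stack per-subject series/FC matrices for batched forward passes
stack_cohort <- function(series_list, fc_list) {
  Xstack <- do.call(rbind, series_list)
  Fstack <- do.call(rbind, fc_list)
  list(X = Xstack, F = Fstack)
}
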