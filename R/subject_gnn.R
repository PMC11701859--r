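# Global population network: snowball GCN blocks (densely connected graph
# convolutions that concatenate all previous layers before each propagation),
# modality-specific blocks with independent weights, a modality-common block
# with a shared trunk, softmax attention over modality embeddings, and the
# final classifier.

#' Global model configuration
#'
#' @param snowball_layers number of snowball layers (default 9).
#' @param snowball_width output width of each snowball layer.
#' @param c_width width of the collapsed concatenation (`C`).
#' @param out_width width of the per-channel output embedding.
#' @param common_width width of the shared-trunk input projections.
#' @param attn_width width of the attention logit layer.
#' @param clf_hidden classifier MLP hidden width.
#' @param site_hidden site-adversary MLP hidden width.
#' @param pae_hidden,pae_out PAE MLP widths.
#' @param p output-projection flag (`0` or `1`): with `p = 1` the collapsed
#'   representation is propagated once more through the normalized adjacency.
#' @return list of global-model hyperparameters.
#' @export
global_config <- function(snowball_layers = 9L, snowball_width = 16L,
                          c_width = 32L, out_width = 16L, common_width = 32L,
                          attn_width = 8L, clf_hidden = 16L, site_hidden = 16L,
                          pae_hidden = 16L, pae_out = 8L, p = 0L) {
  stopifnot(snowball_layers >= 1L, p %in% c(0L, 1L))
  list(snowball_layers = as.integer(snowball_layers),
       snowball_width = as.integer(snowball_width),
       c_width = as.integer(c_width), out_width = as.integer(out_width),
       common_width = as.integer(common_width),
       attn_width = as.integer(attn_width),
       clf_hidden = as.integer(clf_hidden),
       site_hidden = as.integer(site_hidden),
       pae_hidden = as.integer(pae_hidden), pae_out = as.integer(pae_out),
       p = as.integer(p))
}

# snowball parameter block: W_l per layer, W_n collapsing the concatenation,
# W_c projecting to the output embedding (bias-free, as in the update rules).
new_snowball <- function(p_in, n_layers, width, c_width, out_width) {
  Wl <- lapply(seq_len(n_layers) - 1L, function(l)
    ad_leaf(glorot(p_in + l * width, width)))
  list(Wl = Wl,
       Wn = ad_leaf(glorot(p_in + n_layers * width, c_width)),
       Wc = ad_leaf(glorot(c_width, out_width)),
       n_layers = n_layers)
}

# taped snowball forward; L and X may be ad nodes or plain matrices
snowball_fwd <- function(L, X, params, p = 0L) {
  L <- as_ad(L); X <- as_ad(X)
  Hs <- list(X)
  for (l in seq_len(params$n_layers)) {
    cc <- ad_cbind(Hs)
    # L ([H...] W) rather than (L [H...]) W: same product, far fewer flops
    Hs[[l + 1L]] <- ad_tanh(ad_matmul(L, ad_matmul(cc, params$Wl[[l]])))
  }
  C <- ad_tanh(ad_matmul(ad_cbind(Hs), params$Wn))
  out <- ad_matmul(C, params$Wc)
  if (p == 1L) out <- ad_matmul(L, out)
  ad_row_normalize(out)
}

#' Snowball GCN forward pass
#'
#' Densely connected graph convolution: layer `l+1` is
#' `tanh(L [H_0, ..., H_l] W_l)` on the symmetric-normalized adjacency with
#' self-loops `L`; all layers are concatenated, collapsed by `W_n` with tanh,
#' projected by `W_c` (premultiplied by `L` when `p = 1`) and row-normalized.
#'
#' @param graph a `subject_graph` (or a precomputed propagation matrix).
#' @param X subjects x p node-feature matrix.
#' @param params snowball parameters (see internal `new_snowball`).
#' @param p output-projection flag.
#' @return subjects x out_width embedding with unit-norm rows.
#' @export
snowball_forward <- function(graph, X, params, p = 0L) {
  L <- if (inherits(graph, "subject_graph")) normalize_adjacency(graph$weights) else graph
  ad_value(snowball_fwd(L, as.matrix(X), params, p = p))
}

# ---- full global model -----------------------------------------------------

# channels: named list with entries f, s, d, each carrying input width
new_global_model <- function(widths, eta_dim, n_sites, config = global_config()) {
  chans <- names(widths)
  specific <- lapply(widths, function(w)
    new_snowball(w, config$snowball_layers, config$snowball_width,
                 config$c_width, config$out_width))
  proj <- lapply(widths, function(w) new_linear(w, config$common_width))
  shared <- new_snowball(config$common_width, config$snowball_layers,
                         config$snowball_width, config$c_width, config$out_width)
  attn <- lapply(c(chans, "common"), function(ch)
    new_linear(config$out_width, config$attn_width))
  names(attn) <- c(chans, "common")
  list(specific = specific, proj = proj, shared = shared, attn = attn,
       clf = new_mlp(config$out_width, config$clf_hidden, 2L),
       site_clf = new_mlp(config$out_width, config$site_hidden, n_sites),
       pae = new_pae(eta_dim, config$pae_hidden, config$pae_out),
       channels = chans, n_sites = n_sites, config = config)
}

# taped forward: Ls and Xs are named lists (nodes or matrices) per channel.
global_forward <- function(model, Ls, Xs, grl_lambda = 1) {
  cfg <- model$config
  chans <- model$channels
  spec <- list()
  common <- list()
  for (ch in chans) {
    spec[[ch]] <- snowball_fwd(Ls[[ch]], Xs[[ch]], model$specific[[ch]], p = cfg$p)
    Xp <- linear_fwd(as_ad(Xs[[ch]]), model$proj[[ch]])
    common[[ch]] <- snowball_fwd(Ls[[ch]], Xp, model$shared, p = cfg$p)
  }
  w <- 1 / length(chans)     # equal modality weights summing to 1
  Hc <- Reduce(function(a, b) ad_add(a, b),
               lapply(common, function(h) ad_scale(h, w)))
  emb <- c(spec, list(common = Hc))
  scores <- lapply(names(emb), function(ch)
    ad_rowmeans(ad_tanh(linear_fwd(emb[[ch]], model$attn[[ch]]))))
  a <- ad_softmax_rows(ad_cbind(scores))           # S x n_channels
  fused <- NULL
  for (i in seq_along(emb)) {
    term <- ad_mul(ad_rows_col(a, i), emb[[i]])
    fused <- if (is.null(fused)) term else ad_add(fused, term)
  }
  logits <- mlp_fwd(fused, model$clf)
  site_logits <- mlp_fwd(ad_grl(fused, grl_lambda), model$site_clf)
  list(specific = spec, common_per_channel = common, common = Hc,
       attention = a, fused = fused, logits = logits, site_logits = site_logits)
}

# column extraction as an S x 1 node
ad_rows_col <- function(a, j) {
  a <- as_ad(a)
  d <- dim(a$value)
  ad_node(a$value[, j, drop = FALSE], list(a), function(g) {
    out <- matrix(0, d[1L], d[2L])
    out[, j] <- g
    list(out)
  })
}

#' Modality-specific embeddings (MS-GCN)
#'
#' One snowball forward per channel with independent parameters; the
#' functional channel's node features are the local graph embeddings (or
#' their concatenation with FC vectors).
#'
#' @param graphs named list of `subject_graph`s (or propagation matrices).
#' @param Xs named list of node-feature matrices, same names and row order.
#' @param model a global model.
#' @return named list of subjects x out_width embeddings.
#' @export
ms_gcn <- function(graphs, Xs, model) {
  if (!identical(sort(names(graphs)), sort(names(Xs))))
    stop("channel mismatch between graphs and features")
  out <- lapply(model$channels, function(ch) {
    L <- if (inherits(graphs[[ch]], "subject_graph"))
      normalize_adjacency(graphs[[ch]]$weights) else graphs[[ch]]
    ad_value(snowball_fwd(L, as.matrix(Xs[[ch]]), model$specific[[ch]],
                          p = model$config$p))
  })
  names(out) <- model$channels
  out
}

#' Modality-common embeddings (MC-GCN)
#'
#' Each channel is linearly projected to a common width (non-shared
#' projection) and passed through snowball layers whose trainable matrices
#' are shared across channels; the final common embedding is the weighted sum
#' of the per-channel commons with equal weights summing to 1.
#'
#' @inheritParams ms_gcn
#' @param weights per-channel weights; must sum to 1 (default equal).
#' @return list with `common_per_channel` (named list) and `common` (matrix).
#' @export
mc_gcn <- function(graphs, Xs, model, weights = NULL) {
  chans <- model$channels
  if (is.null(weights)) weights <- rep(1 / length(chans), length(chans))
  if (abs(sum(weights) - 1) > 1e-8) stop("channel weights must sum to 1")
  per <- lapply(chans, function(ch) {
    L <- if (inherits(graphs[[ch]], "subject_graph"))
      normalize_adjacency(graphs[[ch]]$weights) else graphs[[ch]]
    Xp <- linear_fwd(ad_node(as.matrix(Xs[[ch]])), model$proj[[ch]])
    ad_value(snowball_fwd(L, Xp, model$shared, p = model$config$p))
  })
  names(per) <- chans
  Hc <- Reduce(`+`, Map(`*`, per, as.list(weights)))
  list(common_per_channel = per, common = Hc)
}

#' Multimodal attention fusion
#'
#' Per channel, an attention logit `tanh(H W + b)` is reduced to a per-node
#' scalar by its mean over dimensions; softmax across channels (per node)
#' yields the attention scores, and the fused representation is the
#' score-weighted sum of the embeddings.
#'
#' @param embeddings named list of subjects x d matrices (specific channels
#'   plus the common embedding).
#' @param model a global model (provides attention parameters; names must
#'   match).
#' @return list with `fused` (subjects x d) and `attention` (subjects x
#'   channels, rows summing to 1).
#' @export
m_attention <- function(embeddings, model) {
  dims <- vapply(embeddings, dim, integer(2L))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L)
    stop("embedding shape mismatch across channels")
  scores <- lapply(names(embeddings), function(ch)
    ad_rowmeans(ad_tanh(linear_fwd(ad_node(embeddings[[ch]]), model$attn[[ch]]))))
  a <- ad_value(ad_softmax_rows(ad_cbind(scores)))
  colnames(a) <- names(embeddings)
  fused <- Reduce(`+`, Map(function(e, j) a[, j] * e,
                           embeddings, seq_along(embeddings)))
  list(fused = fused, attention = a)
}

#' Final classification from the fused embedding
#'
#' @param fused subjects x d fused embedding.
#' @param model a global model.
#' @return list with `logits` (subjects x 2) and `probabilities` (subjects x
#'   2, rows summing to 1; column 2 is the case probability).
#' @export
classify <- function(fused, model) {
  logits <- ad_value(mlp_fwd(ad_node(as.matrix(fused)), model$clf))
  probs <- softmax_rows(logits)
  list(logits = logits, probabilities = probs)
}

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}
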