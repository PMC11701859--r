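# Population (subject) graphs: functional and structural KNN graphs from
# cosine similarity of node features, and a demographic graph whose edge
# weights come from a trainable pairwise-association encoder (PAE) evaluated
# on a fixed KNN support.

#' Build a cosine-similarity KNN subject graph
#'
#' Edge weight is the cosine similarity of node feature rows; each node keeps
#' its `k` highest-similarity neighbors (ties broken by lowest index), the
#' edge set is union-symmetrized, and negative similarities are clipped to 0
#' before use as propagation weights.
#'
#' @param features subjects x p feature matrix.
#' @param k neighbors per node, `1 <= k < subjects`.
#' @param channel label for the graph (`"functional"`, `"structural"`,
#'   `"demographic"`).
#' @return object of class `subject_graph`: list with `weights` (symmetric
#'   subjects x subjects matrix, zero diagonal), `features`, `channel`, `k`.
#' @export
build_knn_graph <- function(features, k = 10L,
                            channel = c("functional", "structural", "demographic")) {
  channel <- match.arg(channel)
  features <- as.matrix(features)
  S <- nrow(features)
  stopifnot(k >= 1L, k < S)
  nrm <- sqrt(rowSums(features^2))
  if (any(nrm == 0))
    stop("zero-norm feature row for subject(s) ", paste(which(nrm == 0), collapse = ", "))
  U <- features / nrm
  sim <- tcrossprod(U)
  diag(sim) <- -Inf
  keep <- matrix(FALSE, S, S)
  for (i in seq_len(S)) {
    ord <- order(-sim[i, ], seq_len(S))   # ties: lowest index first
    keep[i, ord[seq_len(k)]] <- TRUE
  }
  keep <- keep | t(keep)                  # union symmetrization
  W <- ifelse(keep, pmax(sim, 0), 0)
  diag(W) <- 0
  structure(list(weights = W, features = features, channel = channel, k = k),
            class = "subject_graph")
}

# symmetric-normalized Laplacian-style propagation matrix with self-loops
normalize_adjacency <- function(W) {
  A <- W + diag(nrow(W))
  d <- rowSums(A)
  v <- 1 / sqrt(d)
  (v %o% v) * A
}

#' Functional node features for the population graph
#'
#' Three composition modes: `"Corr"` flattens the strict upper triangle of the
#' FC matrix, `"Emb"` uses the local model's graph embedding, `"Concat"`
#' (default, best-performing) concatenates the two.
#'
#' @param fc `n x n` FC matrix (or `NULL` in `"Emb"` mode).
#' @param local_embedding local graph-embedding vector (or `NULL` in
#'   `"Corr"` mode).
#' @param mode one of `"Corr"`, `"Emb"`, `"Concat"`.
#' @return numeric feature vector.
#' @export
functional_node_features <- function(fc, local_embedding = NULL,
                                     mode = c("Concat", "Corr", "Emb")) {
  mode <- match.arg(mode)
  if (mode %in% c("Emb", "Concat") && is.null(local_embedding))
    stop("mode ", mode, " needs a local model embedding")
  if (mode %in% c("Corr", "Concat") && is.null(fc))
    stop("mode ", mode, " needs an FC matrix")
  switch(mode,
         Corr = fc_upper(fc),
         Emb = as.numeric(local_embedding),
         Concat = c(fc_upper(fc), as.numeric(local_embedding)))
}

#' Demographic vector for the pairwise-association encoder
#'
#' Encodes each subject as (age scaled to `[0,1]` over the cohort range, sex
#' one-hot, education scaled to `[0,1]`, site one-hot).
#'
#' @param demographics tibble with `age`, `sex`, `education`, `site`.
#' @param n_sites number of sites.
#' @return subjects x (4 + n_sites) matrix.
#' @export
demographic_eta <- function(demographics, n_sites = max(demographics$site)) {
  rng01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0.5, length(x)) else (x - r[1]) / diff(r)
  }
  sex1h <- cbind(demographics$sex == 0L, demographics$sex == 1L) * 1
  site1h <- outer(demographics$site, seq_len(n_sites), `==`) * 1
  eta <- cbind(age = rng01(demographics$age), sex1h,
               education = rng01(demographics$education), site1h)
  colnames(eta) <- c("age", "sex0", "sex1", "education",
                     paste0("site", seq_len(n_sites)))
  eta
}

new_pae <- function(eta_dim, hidden = 16L, out = 8L) new_mlp(eta_dim, hidden, out)

#' Pairwise-association edge weight
#'
#' Weight between two subjects' demographic vectors:
#' `(cos(MLP(eta_i), MLP(eta_j)) + 1) / 2`, in `[0, 1]` and symmetric.
#'
#' @param eta_i,eta_j demographic vectors (same length).
#' @param pae PAE parameters (a two-layer MLP, trained jointly with the
#'   model's objective).
#' @return scalar weight in `[0, 1]`.
#' @export
pae_edge_weight <- function(eta_i, eta_j, pae) {
  M <- ad_value(mlp_fwd(ad_node(rbind(eta_i, eta_j)), pae))
  if (any(!is.finite(M))) stop("non-finite PAE output")
  n1 <- sqrt(sum(M[1, ]^2)); n2 <- sqrt(sum(M[2, ]^2))
  (sum(M[1, ] * M[2, ]) / max(n1 * n2, 1e-12) + 1) / 2
}

# taped demographic propagation matrix: PAE weights on a fixed support mask,
# self-loops added, then symmetric degree normalization.
pae_laplacian <- function(eta, pae, support) {
  M <- mlp_fwd(ad_node(eta), pae)
  U <- ad_row_normalize(M)
  C <- ad_matmul(U, ad_t(U))
  Wd <- ad_mul(ad_scale(ad_add(C, matrix(1, nrow(eta), nrow(eta))), 0.5),
               ad_node(support * 1))
  A <- ad_add(Wd, diag(nrow(eta)))
  v <- ad_pow(ad_rowsums(A), -0.5)
  ad_t(ad_mul(v, ad_t(ad_mul(v, A))))
}

#' Export a subject graph as an edge list
#'
#' @param graph a `subject_graph`.
#' @return tibble with columns `i`, `j`, `weight`, `channel` (upper-triangle
#'   edges only).
#' @export
graph_edge_list <- function(graph) {
  W <- graph$weights
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  tibble::tibble(i = idx[, 1], j = idx[, 2],
                 weight = W[idx], channel = graph$channel)
}
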