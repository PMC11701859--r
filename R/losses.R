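# The four-term training objective: weighted local+global cross-entropy,
# HSIC modality-independence, modality-similarity on normalized-embedding
# Gram matrices, and the domain loss (adversarial site classification via
# gradient reversal plus central moment discrepancy). Each exported function
# is a numeric computation on plain matrices; taped twins (suffix _t) are
# used inside the training loop and produce identical values.

#' Weighted classification loss
#'
#' Mean cross-entropy of global and (optionally) local logits on training
#' nodes, combined as `global + lambda_local * local`.
#'
#' @param global_logits subjects x 2 logit matrix.
#' @param local_logits subjects x 2 logit matrix, or `NULL`.
#' @param labels 0/1 labels.
#' @param mask indices of training nodes.
#' @param lambda_local local-loss weight (default 0.2, keeping the global
#'   term dominant).
#' @return list with `total`, `global`, `local`.
#' @export
classification_loss <- function(global_logits, local_logits, labels, mask,
                                lambda_local = 0.2) {
  if (length(mask) == 0L) stop("empty training mask")
  lg <- cross_entropy(global_logits[mask, , drop = FALSE], labels[mask])
  ll <- if (is.null(local_logits)) 0
        else cross_entropy(local_logits[mask, , drop = FALSE], labels[mask])
  list(total = lg + lambda_local * ll, global = lg, local = ll)
}

cross_entropy <- function(logits, labels01) {
  m <- apply(logits, 1L, max)
  lse <- m + log(rowSums(exp(logits - m)))
  -mean(logits[cbind(seq_len(nrow(logits)), labels01 + 1L)] - lse)
}

#' Hilbert-Schmidt independence criterion
#'
#' `HSIC(Hs, Hc) = (m-1)^{-2} tr(Kc R Ks R)` with `R = I - ee^T/m` the
#' centering matrix and Gram matrices under the chosen kernel (linear by
#' default; Gaussian with median-heuristic bandwidth optional).
#'
#' @param Hs,Hc m x a and m x b embedding matrices (same row count, `m >= 2`).
#' @param kernel `"linear"` or `"gaussian"`.
#' @param sigma Gaussian bandwidth; `NULL` uses the median heuristic.
#' @return scalar HSIC value (nonnegative up to numerical error).
#' @export
hsic <- function(Hs, Hc, kernel = c("linear", "gaussian"), sigma = NULL) {
  kernel <- match.arg(kernel)
  Hs <- as.matrix(Hs); Hc <- as.matrix(Hc)
  m <- nrow(Hs)
  if (m < 2L || nrow(Hc) != m) stop("HSIC needs matching row counts with m >= 2")
  gram <- function(H) {
    if (kernel == "linear") return(tcrossprod(H))
    D2 <- as.matrix(stats::dist(H))^2
    s <- if (is.null(sigma)) {
      med <- stats::median(D2[upper.tri(D2)])
      sqrt(max(med, 1e-12) / 2)
    } else sigma
    exp(-D2 / (2 * s^2))
  }
  Ks <- gram(Hs); Kc <- gram(Hc)
  R <- diag(m) - matrix(1 / m, m, m)
  sum(diag(Kc %*% R %*% Ks %*% R)) / (m - 1)^2
}

# taped linear-kernel HSIC
hsic_t <- function(Hs, Hc) {
  m <- nrow(ad_value(Hs))
  R <- diag(m) - matrix(1 / m, m, m)
  M1 <- ad_matmul(ad_matmul(Hc, ad_t(Hc)), R)
  M2 <- ad_matmul(ad_matmul(Hs, ad_t(Hs)), R)
  ad_scale(ad_sum(ad_mul(M1, ad_t(M2))), 1 / (m - 1)^2)
}

#' Modality-independence loss
#'
#' Sum of HSIC between each modality-specific embedding and the common
#' embedding.
#'
#' @param specific named list of specific embeddings.
#' @param common common embedding matrix.
#' @inheritParams hsic
#' @return scalar loss.
#' @export
modality_specific_loss <- function(specific, common, kernel = "linear") {
  sum(vapply(specific, function(H) hsic(H, common, kernel = kernel), numeric(1L)))
}

#' Modality-similarity loss
#'
#' Per-channel common embeddings are row-normalized, turned into Gram
#' matrices `N = H H^T`, and the Frobenius norms of pairwise Gram differences
#' are summed. The default pair list is functional-demographic,
#' functional-structural, demographic-structural (the demographic channel
#' playing the phenotypic role); `full_pairwise` sums all pairs.
#'
#' @param commons named list with entries `f`, `s`, `d`.
#' @param full_pairwise include every unordered pair.
#' @return scalar loss.
#' @export
modality_similarity_loss <- function(commons, full_pairwise = FALSE) {
  N <- lapply(commons, function(H) {
    H <- as.matrix(H)
    nr <- pmax(sqrt(rowSums(H^2)), 1e-12)
    tcrossprod(H / nr)
  })
  pairs <- if (full_pairwise) utils::combn(names(N), 2L, simplify = FALSE)
           else list(c("f", "d"), c("f", "s"), c("d", "s"))
  sum(vapply(pairs, function(pr) norm(N[[pr[1]]] - N[[pr[2]]], "F"), numeric(1L)))
}

modality_similarity_loss_t <- function(commons, full_pairwise = FALSE) {
  N <- lapply(commons, function(H) {
    Hn <- ad_row_normalize(H)
    ad_matmul(Hn, ad_t(Hn))
  })
  pairs <- if (full_pairwise) utils::combn(names(N), 2L, simplify = FALSE)
           else list(c("f", "d"), c("f", "s"), c("d", "s"))
  Reduce(function(a, b) ad_add(a, b),
         lapply(pairs, function(pr) ad_frobenius(ad_sub(N[[pr[1]]], N[[pr[2]]]))))
}

#' Site-adversarial loss
#'
#' Cross-entropy of a site-classifier perceptron consuming the fused
#' embedding through a gradient-reversal transform (identity forward,
#' gradient negated and scaled by `grl_lambda` backward). With a single site
#' the adversary is vacuous and a warning is raised.
#'
#' @param fused subjects x d fused embedding.
#' @param sites per-subject site index.
#' @param model a global model (provides the site classifier).
#' @param grl_lambda reversal strength.
#' @return scalar cross-entropy of site prediction.
#' @export
site_adversarial_loss <- function(fused, sites, model, grl_lambda = 1) {
  if (length(unique(sites)) < 2L)
    warning("single site in batch: site adversary is vacuous")
  logits <- ad_value(mlp_fwd(ad_grl(ad_node(as.matrix(fused)), grl_lambda),
                             model$site_clf))
  cross_entropy(logits, as.integer(factor(sites)) - 1L)
}

#' Central moment discrepancy between site distributions
#'
#' Standard CMD: mean difference plus central moments of orders `2..K`, each
#' scaled by the representation range `(b - a)^k`, averaged over site pairs.
#'
#' @param embeddings subjects x d matrix.
#' @param sites per-subject site index (every group nonempty).
#' @param K highest moment order (default 5).
#' @param range representation bounds `c(a, b)`; `NULL` uses the empirical
#'   range of `embeddings`.
#' @return scalar CMD, 0 for identical per-site samples.
#' @export
cmd_loss <- function(embeddings, sites, K = 5L, range = NULL) {
  X <- as.matrix(embeddings)
  groups <- split(seq_len(nrow(X)), sites)
  if (any(lengths(groups) == 0L)) stop("empty site group")
  if (is.null(range)) range <- base::range(X)
  span <- max(range[2] - range[1], 1e-12)
  orders <- if (K >= 2L) 2:K else integer(0)
  mom <- lapply(groups, function(idx) {
    Xi <- X[idx, , drop = FALSE]
    mu <- colMeans(Xi)
    cm <- lapply(orders, function(k) colMeans(sweep(Xi, 2L, mu)^k))
    list(mu = mu, cm = cm)
  })
  pairs <- utils::combn(seq_along(groups), 2L, simplify = FALSE)
  total <- 0
  for (pr in pairs) {
    a <- mom[[pr[1]]]; b <- mom[[pr[2]]]
    v <- sqrt(sum((a$mu - b$mu)^2)) / span
    for (k in orders)
      v <- v + sqrt(sum((a$cm[[k - 1]] - b$cm[[k - 1]])^2)) / span^k
    total <- total + v
  }
  total / length(pairs)
}

cmd_loss_t <- function(fused, sites, K = 5L, range = NULL) {
  X <- ad_value(fused)
  groups <- split(seq_len(nrow(X)), sites)
  # the representation range enters as a constant scale (not differentiated)
  if (is.null(range)) range <- base::range(X)
  span <- max(range[2] - range[1], 1e-12)
  orders <- if (K >= 2L) 2:K else integer(0)
  mom <- lapply(groups, function(idx) {
    Xi <- ad_rows(fused, idx)
    mu <- ad_colmeans(Xi)
    ctr <- ad_sub(Xi, mu)
    list(mu = mu, cm = lapply(orders, function(k) ad_colmeans(ad_pow(ctr, k))))
  })
  pairs <- utils::combn(seq_along(groups), 2L, simplify = FALSE)
  total <- NULL
  for (pr in pairs) {
    a <- mom[[pr[1]]]; b <- mom[[pr[2]]]
    v <- ad_scale(ad_frobenius(ad_sub(a$mu, b$mu)), 1 / span)
    for (k in orders)
      v <- ad_add(v, ad_scale(ad_frobenius(ad_sub(a$cm[[k - 1]], b$cm[[k - 1]])),
                              1 / span^k))
    total <- if (is.null(total)) v else ad_add(total, v)
  }
  ad_scale(total, 1 / length(pairs))
}

#' Total training objective
#'
#' `L = L_cls + L_specific + L_common + L_domain`, with
#' `L_domain = L_site + L_CMD`.
#'
#' @param components list with `cls`, `specific`, `common`, `site`, `cmd`
#'   (numerics; missing entries count as 0).
#' @return list with the components and `total`.
#' @export
total_loss <- function(components) {
  g <- function(nm) components[[nm]] %||% 0
  domain <- g("site") + g("cmd")
  list(cls = g("cls"), specific = g("specific"), common = g("common"),
       site = g("site"), cmd = g("cmd"), domain = domain,
       total = g("cls") + g("specific") + g("common") + domain)
}
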