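# Post-hoc interpretation: fold-averaged learned connectivity, differential
# connectivity between groups, top enhanced/diminished edges, top-degree
# regions, and mask-one-character structural importance.

#' Average learned adjacencies across folds
#'
#' Each subject's learned ROI adjacency, collected at inference from every
#' fold in which the subject was a training node, is averaged elementwise
#' into a single connectivity matrix per subject.
#'
#' @param per_fold named-or-indexed list: per subject, a list of `n x n`
#'   matrices (one per fold). A `fusegnn_eval` may be passed directly, in
#'   which case its precomputed averages are returned.
#' @return list of one `n x n` matrix per subject.
#' @export
average_learned_fc <- function(per_fold) {
  if (inherits(per_fold, "fusegnn_eval")) {
    missing <- which(vapply(per_fold$adjacency, is.null, logical(1L)))
    if (length(missing))
      stop("no learned adjacency for subject(s) ", paste(missing, collapse = ", "))
    return(per_fold$adjacency)
  }
  missing <- which(vapply(per_fold, function(x) length(x) == 0L, logical(1L)))
  if (length(missing))
    stop("no learned adjacency for subject(s) ", paste(missing, collapse = ", "))
  lapply(per_fold, function(mats) Reduce(`+`, mats) / length(mats))
}

#' Group-differential learned connectivity
#'
#' Averages per-subject connectivity matrices within each group and subtracts
#' (case minus control). The difference is symmetrized (`(M + M^T)/2`) before
#' any ranking, since learned adjacencies are row-stochastic and therefore
#' asymmetric while connectivity is treated as undirected.
#'
#' @param subject_fc list of `n x n` matrices, one per subject.
#' @param labels 0/1 group labels.
#' @return object of class `differential_fc`: list with `mean_fc_case`,
#'   `mean_fc_control`, `diff` (symmetrized case - control), `abs_diff`,
#'   `roi_labels`.
#' @export
group_differential <- function(subject_fc, labels) {
  stopifnot(length(subject_fc) == length(labels))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  avg <- function(idx) Reduce(`+`, subject_fc[idx]) / length(idx)
  mc <- avg(which(labels == 1L))
  mh <- avg(which(labels == 0L))
  d <- mc - mh
  d <- (d + t(d)) / 2
  rl <- rownames(mc) %||% roi_labels(nrow(mc))
  dimnames(d) <- list(rl, rl)
  structure(list(mean_fc_case = mc, mean_fc_control = mh,
                 diff = d, abs_diff = abs(d), roi_labels = rl),
            class = "differential_fc")
}

#' @export
print.differential_fc <- function(x, ...) {
  cat("<differential_fc>", length(x$roi_labels), "ROIs; |diff| range",
      sprintf("[%.4g, %.4g]\n", min(x$abs_diff), max(x$abs_diff)))
  invisible(x)
}

#' Top enhanced and diminished connections
#'
#' Ranks the strict upper triangle of the symmetrized differential matrix:
#' the `k` largest positive entries are the enhanced connections in cases,
#' the `k` most negative the diminished ones. Ties are broken by `(i, j)`
#' lexicographic order.
#'
#' @param diff a `differential_fc` (or a symmetric matrix).
#' @param k edges per direction.
#' @param strict error on an all-zero differential (otherwise return empty
#'   tibbles).
#' @return list of tibbles `enhanced` and `diminished` with columns `roi_a`,
#'   `roi_b`, `delta`, `rank`, `direction`.
#' @export
top_edges <- function(diff, k = 5L, strict = FALSE) {
  M <- if (inherits(diff, "differential_fc")) diff$diff else diff
  rl <- rownames(M) %||% roi_labels(nrow(M))
  ut <- which(upper.tri(M), arr.ind = TRUE)
  vals <- M[ut]
  if (k > length(vals)) stop("k exceeds the number of undirected edges")
  if (all(vals == 0)) {
    if (strict) stop("differential matrix is identically zero")
    empty <- tibble::tibble(roi_a = character(), roi_b = character(),
                            delta = numeric(), rank = integer(),
                            direction = character())
    return(list(enhanced = empty, diminished = empty))
  }
  ord_pos <- order(-vals, ut[, 1L], ut[, 2L])
  ord_neg <- order(vals, ut[, 1L], ut[, 2L])
  take <- function(ord, sign_keep, direction) {
    sel <- ord[seq_len(k)]
    keep <- if (direction == "enhanced") vals[sel] > 0 else vals[sel] < 0
    sel <- sel[keep]
    tibble::tibble(roi_a = rl[ut[sel, 1L]], roi_b = rl[ut[sel, 2L]],
                   delta = vals[sel], rank = seq_along(sel),
                   direction = direction)
  }
  list(enhanced = take(ord_pos, 1, "enhanced"),
       diminished = take(ord_neg, -1, "diminished"))
}

#' Most diagnostically informative regions
#'
#' Region degree is the row sum of the absolute differential matrix; the
#' `k` highest-degree ROIs are returned ranked.
#'
#' @param diff a `differential_fc` (or symmetric matrix, in which case its
#'   absolute value is used).
#' @param k number of regions (`<= n`).
#' @return tibble with `roi`, `degree`, `rank`.
#' @export
top_regions <- function(diff, k = 10L) {
  A <- if (inherits(diff, "differential_fc")) diff$abs_diff else abs(diff)
  stopifnot(k <= nrow(A))
  rl <- rownames(A) %||% roi_labels(nrow(A))
  deg <- rowSums(A)
  ord <- order(-deg, seq_along(deg))
  tibble::tibble(roi = rl[ord[seq_len(k)]], degree = deg[ord[seq_len(k)]],
                 rank = seq_len(k))
}

#' Structural-character importance by masking
#'
#' For each named block ("character") of the structural feature vector, the
#' corresponding model-input columns are set to zero at inference across all
#' CV folds and the pooled AUROC is recomputed; importance is the AUROC drop
#' relative to unmasked inference. Masking happens post-harmonization at the
#' model-input representation.
#'
#' @param report a `fusegnn_eval` produced with `keep_fold_models = TRUE`.
#' @param cohort the `cohort_bundle` the report was computed on.
#' @param character_partition named list of column-index blocks covering the
#'   structural vector exactly, without overlap (defaults to the cohort's
#'   ground-truth partition).
#' @param top_k how many characters to flag as most contributive.
#' @return tibble with `character`, `auroc_masked`, `auroc_drop`, `rank`,
#'   `top` (logical), sorted by decreasing drop.
#' @export
mask_character_importance <- function(report, cohort,
                                      character_partition = NULL,
                                      top_k = 5L) {
  stopifnot(inherits(report, "fusegnn_eval"))
  if (is.null(report$fold_states))
    stop("report was built without keep_fold_models = TRUE")
  if (is.null(character_partition))
    character_partition <- cohort$truth$character_blocks
  p <- ncol(cohort$struct_features)
  covered <- sort(unname(unlist(character_partition)))
  if (!identical(covered, seq_len(p)) || anyDuplicated(unlist(character_partition)))
    stop("character partition must cover the structural vector exactly, without overlap")

  # cache the expensive per-fold pieces (local inference, PAE propagation)
  # once; only the structural node features change between masks
  fold_cache <- lapply(report$fold_states, function(st) {
    feats <- prepare_features(cohort, st$config, st$train_idx)
    linf <- local_inference(st$local, feats)
    Xf <- switch(st$config$feature_mode,
                 Corr = feats$fc_vec, Emb = linf$Gemb,
                 Concat = cbind(feats$fc_vec, linf$Gemb))
    Ld <- ad_value(pae_laplacian(feats$eta, st$global$pae, st$pop$support_d))
    list(st = st, Xf = Xf, Ld = Ld, Xd = st$pop$Xd)
  })
  masked_auroc <- function(block) {
    probs <- rep(NA_real_, length(cohort$labels))
    for (fc in fold_cache) {
      st <- fc$st
      Xs <- st$pop$Xs
      if (!is.null(block)) Xs[, block] <- 0
      gout <- global_forward(st$global,
                             list(f = ad_node(st$pop$Lf), s = ad_node(st$pop$Ls),
                                  d = ad_node(fc$Ld)),
                             list(f = ad_node(fc$Xf), s = ad_node(Xs),
                                  d = ad_node(fc$Xd)),
                             grl_lambda = 0)
      pr <- softmax_rows(ad_value(gout$logits))[, 2L]
      probs[st$test_idx] <- pr[st$test_idx]
    }
    auroc_stat(cohort$labels[!is.na(probs)], probs[!is.na(probs)])
  }
  base <- masked_auroc(NULL)
  res <- purrr::map_dfr(names(character_partition), function(ch) {
    tibble::tibble(character = ch,
                   auroc_masked = masked_auroc(character_partition[[ch]]))
  })
  res |>
    dplyr::mutate(auroc_unmasked = base,
                  auroc_drop = base - .data$auroc_masked) |>
    dplyr::arrange(dplyr::desc(.data$auroc_drop),
                   .data$character) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  top = .data$rank <= top_k)
}
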