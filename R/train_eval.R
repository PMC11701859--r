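# Training loops (two-stage and end-to-end), cross-validation harnesses,
# metrics and calibration. All training is transductive full-batch node
# classification: every subject is a node of the population graphs, held-out
# labels are masked from every loss, and harmonization is fitted on training
# folds only.

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam at learning rate 1e-2
#' halved every 100 epochs, up to 800 epochs, local-loss weight 0.2, k = 10
#' population-graph neighbors and 9 snowball layers. Network widths and epoch
#' budgets are configurable for desk-scale runs.
#'
#' @param mode `"end_to_end"` (joint optimization of local and global
#'   networks under the full objective) or `"two_stage"` (local network
#'   trained alone first, then frozen).
#' @param lr initial Adam learning rate.
#' @param lr_halving_period epochs between halvings of the learning rate.
#' @param epochs global (or joint) training epochs.
#' @param epochs_local stage-1 epochs for the local network (two-stage mode).
#' @param max_epochs hard cap on `epochs`.
#' @param lambda_local weight of the local classification loss.
#' @param k_neighbors KNN parameter of the population graphs.
#' @param snowball_layers snowball depth of the global blocks.
#' @param feature_mode functional node-feature mode: `"Concat"`, `"Corr"` or
#'   `"Emb"`.
#' @param adversarial enable the gradient-reversal site adversary.
#' @param adversary_steps extra site-classifier-only updates per epoch,
#'   keeping the adversary near its optimum so the reversed gradient drives
#'   the embedding toward site confusion rather than site anti-encoding.
#' @param use_cmd enable the central-moment-discrepancy domain term.
#' @param grl_lambda gradient-reversal strength.
#' @param cmd_K highest CMD moment order.
#' @param fisher_z apply Fisher r-to-z to FC entries used as features.
#' @param harmonize fit/apply site harmonization inside training folds.
#' @param seed RNG seed for initialization and fold assignment.
#' @param local local-network widths, see [local_config()].
#' @param global global-network widths, see [global_config()].
#' @param holdout_fraction test fraction for single-split training.
#' @param patience early-stopping patience in epochs (`Inf` disables, the
#'   default).
#' @param verbose print per-epoch losses.
#' @return a `train_config` list.
#' @export
train_config <- function(mode = c("end_to_end", "two_stage"),
                         lr = 1e-2, lr_halving_period = 100L,
                         epochs = 800L, epochs_local = 100L, max_epochs = 800L,
                         lambda_local = 0.2, k_neighbors = 10L,
                         snowball_layers = 9L,
                         feature_mode = c("Concat", "Corr", "Emb"),
                         adversarial = TRUE, adversary_steps = 25L,
                         use_cmd = TRUE, grl_lambda = 1,
                         cmd_K = 5L, fisher_z = FALSE, harmonize = TRUE,
                         seed = 1L, local = local_config(),
                         global = global_config(snowball_layers = snowball_layers),
                         holdout_fraction = 0.2, patience = Inf,
                         verbose = FALSE) {
  mode <- match.arg(mode)
  feature_mode <- match.arg(feature_mode)
  stopifnot(lr > 0, epochs >= 1L, epochs_local >= 1L)
  epochs <- min(epochs, max_epochs)
  global$snowball_layers <- as.integer(snowball_layers)
  list(mode = mode, lr = lr, lr_halving_period = as.integer(lr_halving_period),
       epochs = as.integer(epochs), epochs_local = as.integer(epochs_local),
       max_epochs = as.integer(max_epochs), lambda_local = lambda_local,
       k_neighbors = as.integer(k_neighbors),
       snowball_layers = as.integer(snowball_layers),
       feature_mode = feature_mode, adversarial = adversarial,
       adversary_steps = as.integer(adversary_steps),
       use_cmd = use_cmd, grl_lambda = grl_lambda, cmd_K = as.integer(cmd_K),
       fisher_z = fisher_z, harmonize = harmonize, seed = as.integer(seed),
       local = local, global = global, holdout_fraction = holdout_fraction,
       patience = patience, verbose = verbose)
}

# ---- feature preparation ---------------------------------------------------

# windowing, standardization, FC, and fold-hygienic harmonization
prepare_features <- function(cohort, config, train_idx) {
  S <- length(cohort$series)
  width <- min(vapply(cohort$series, ncol, integer(1L)))
  series <- lapply(cohort$series, function(x)
    standardize_series(window_series(x, width)))
  fc <- lapply(series, pearson_fc, fisher_z = config$fisher_z)
  fc_vec <- t(vapply(fc, fc_upper, numeric(sum(upper.tri(fc[[1]])))))
  struct <- cohort$struct_features
  n_sites_seen <- length(unique(cohort$sites))
  covs <- cohort$demographics[, c("age", "sex")]
  if (config$harmonize && n_sites_seen > 1L) {
    cm_s <- fit_combat(struct[train_idx, , drop = FALSE],
                       cohort$sites[train_idx],
                       covariates = covs[train_idx, ])
    struct_h <- apply_combat(cm_s, struct, cohort$sites, covariates = covs)
    cm_f <- fit_combat(fc_vec[train_idx, , drop = FALSE],
                       cohort$sites[train_idx],
                       covariates = covs[train_idx, ])
    fc_vec_h <- apply_combat(cm_f, fc_vec, cohort$sites, covariates = covs)
  } else {
    struct_h <- struct
    fc_vec_h <- fc_vec
  }
  n_sites <- cohort$truth$spec$n_sites %||% max(cohort$sites)
  list(series = series, fc = fc, fc_vec = fc_vec_h, struct = struct_h,
       eta = demographic_eta(cohort$demographics, n_sites),
       labels = cohort$labels, sites = cohort$sites,
       Xstack = do.call(rbind, series), Fstack = do.call(rbind, fc),
       n_rois = nrow(series[[1]]), width = width)
}

# population graphs (fixed supports); functional features may include the
# local embedding depending on the feature mode
build_population <- function(feats, Gemb, config) {
  Xf <- switch(config$feature_mode,
               Corr = feats$fc_vec,
               Emb = Gemb,
               Concat = cbind(feats$fc_vec, Gemb))
  gf <- build_knn_graph(Xf, k = config$k_neighbors, channel = "functional")
  gs <- build_knn_graph(feats$struct, k = config$k_neighbors, channel = "structural")
  gd <- build_knn_graph(feats$eta, k = config$k_neighbors, channel = "demographic")
  support <- (gd$weights > 0) | (t(gd$weights) > 0)
  diag(support) <- FALSE
  list(Lf = normalize_adjacency(gf$weights),
       Ls = normalize_adjacency(gs$weights),
       support_d = support, Xf = Xf, Xs = feats$struct, Xd = feats$eta,
       graphs = list(f = gf, s = gs, d = gd))
}

# ---- training cores --------------------------------------------------------

train_local_stage <- function(lmodel, feats, labels01, train_idx, config) {
  params <- list(lmodel$gru, lmodel$gcn, lmodel$bn$gamma, lmodel$bn$beta, lmodel$clf)
  opt <- adam_new(params, lr = config$lr)
  log <- numeric(config$epochs_local)
  for (ep in seq_len(config$epochs_local)) {
    ad_zero_grads(params)
    out <- local_forward(lmodel, feats$Xstack, feats$Fstack, training = TRUE)
    loss <- ad_cross_entropy(ad_rows(out$logits, train_idx),
                             labels01[train_idx] + 1L)
    ad_backward(loss)
    opt <- adam_step(opt, lr = lr_at_epoch(config$lr, ep, config$lr_halving_period))
    log[ep] <- ad_value(loss)[1]
    if (config$verbose) message(sprintf("local epoch %d loss %.4f", ep, log[ep]))
  }
  log
}

local_inference <- function(lmodel, feats) {
  out <- local_forward(lmodel, feats$Xstack, feats$Fstack, training = FALSE)
  list(Gemb = ad_value(out$graph_embedding),
       A = ad_value(out$adjacency),
       logits = ad_value(out$logits),
       attention = ad_value(out$attention))
}

# taped objective for the global (or joint) phase; returns loss nodes
global_objective <- function(gmodel, lmodel, feats, pop, config, train_idx,
                             end_to_end = FALSE) {
  labels01 <- feats$labels
  if (end_to_end) {
    lout <- local_forward(lmodel, feats$Xstack, feats$Fstack, training = TRUE)
    Xf <- switch(config$feature_mode,
                 Corr = ad_node(feats$fc_vec),
                 Emb = lout$graph_embedding,
                 Concat = ad_cbind(list(ad_node(feats$fc_vec), lout$graph_embedding)))
  } else {
    lout <- NULL
    Xf <- ad_node(pop$Xf)
  }
  Ld <- pae_laplacian(feats$eta, gmodel$pae, pop$support_d)
  Ls_list <- list(f = ad_node(pop$Lf), s = ad_node(pop$Ls), d = Ld)
  Xs_list <- list(f = Xf, s = ad_node(pop$Xs), d = ad_node(pop$Xd))
  gout <- global_forward(gmodel, Ls_list, Xs_list, grl_lambda = config$grl_lambda)

  ce_g <- ad_cross_entropy(ad_rows(gout$logits, train_idx),
                           labels01[train_idx] + 1L)
  cls <- ce_g
  if (end_to_end) {
    ce_l <- ad_cross_entropy(ad_rows(lout$logits, train_idx),
                             labels01[train_idx] + 1L)
    cls <- ad_add(ce_g, ad_scale(ce_l, config$lambda_local))
  }
  spec_terms <- lapply(gout$specific, function(H) hsic_t(H, gout$common))
  l_spec <- Reduce(function(a, b) ad_add(a, b), spec_terms)
  l_common <- modality_similarity_loss_t(gout$common_per_channel)
  total <- ad_add(ad_add(cls, l_spec), l_common)
  l_site <- NULL
  if (config$adversarial && length(unique(feats$sites)) > 1L) {
    l_site <- ad_cross_entropy(gout$site_logits,
                               as.integer(factor(feats$sites)))
    total <- ad_add(total, l_site)
  }
  l_cmd <- NULL
  if (config$use_cmd && length(unique(feats$sites)) > 1L) {
    l_cmd <- cmd_loss_t(gout$fused, feats$sites, K = config$cmd_K)
    total <- ad_add(total, l_cmd)
  }
  list(total = total, cls = cls, ce_global = ce_g,
       ce_local = if (end_to_end) ce_l else NULL,
       specific = l_spec, common = l_common, site = l_site, cmd = l_cmd,
       gout = gout, lout = lout)
}

train_global_stage <- function(gmodel, lmodel, feats, pop, config, train_idx,
                               end_to_end = FALSE) {
  params <- list(gmodel$specific, gmodel$proj, gmodel$shared, gmodel$attn,
                 gmodel$clf, gmodel$site_clf, gmodel$pae)
  if (end_to_end)
    params <- c(params, list(lmodel$gru, lmodel$gcn, lmodel$bn$gamma,
                             lmodel$bn$beta, lmodel$clf))
  opt <- adam_new(params, lr = config$lr)
  adv_on <- config$adversarial && length(unique(feats$sites)) > 1L
  if (adv_on) adv_opt <- adam_new(list(gmodel$site_clf), lr = config$lr)
  site_codes <- as.integer(factor(feats$sites))
  cols <- c("epoch", "cls_global", "cls_local", "specific", "common",
            "site", "cmd", "total")
  log <- matrix(NA_real_, config$epochs, length(cols),
                dimnames = list(NULL, cols))
  best <- Inf; wait <- 0L
  gru_grad_norm <- NA_real_
  for (ep in seq_len(config$epochs)) {
    ad_zero_grads(params)
    obj <- global_objective(gmodel, lmodel, feats, pop, config, train_idx,
                            end_to_end = end_to_end)
    if (!is.finite(ad_value(obj$total)[1]))
      stop(sprintf("non-finite loss at epoch %d (components: %s)", ep,
                   paste(sprintf("%.3g", c(ad_value(obj$cls)[1],
                                           ad_value(obj$specific)[1],
                                           ad_value(obj$common)[1])),
                         collapse = ", ")))
    ad_backward(obj$total)
    if (end_to_end && ep == config$epochs) {
      g <- ad_grad(lmodel$gru$fwd$Wh)
      gru_grad_norm <- if (is.null(g)) 0 else sqrt(sum(g^2))
    }
    opt <- adam_step(opt, lr = lr_at_epoch(config$lr, ep, config$lr_halving_period))
    if (adv_on && config$adversary_steps > 0L) {
      # keep the site adversary near-optimal for the current embedding
      fused_const <- ad_node(ad_value(obj$gout$fused))
      for (k in seq_len(config$adversary_steps)) {
        ad_zero_grads(gmodel$site_clf)
        head_loss <- ad_cross_entropy(mlp_fwd(fused_const, gmodel$site_clf),
                                      site_codes)
        ad_backward(head_loss)
        adv_opt <- adam_step(adv_opt,
                             lr = lr_at_epoch(config$lr, ep, config$lr_halving_period))
      }
    }
    log[ep, ] <- c(ep, ad_value(obj$ce_global)[1],
                   if (is.null(obj$ce_local)) NA_real_ else ad_value(obj$ce_local)[1],
                   ad_value(obj$specific)[1], ad_value(obj$common)[1],
                   if (is.null(obj$site)) NA_real_ else ad_value(obj$site)[1],
                   if (is.null(obj$cmd)) NA_real_ else ad_value(obj$cmd)[1],
                   ad_value(obj$total)[1])
    if (config$verbose) message(sprintf("epoch %d total %.4f", ep, log[ep, "total"]))
    if (is.finite(config$patience)) {
      if (log[ep, "total"] < best - 1e-6) { best <- log[ep, "total"]; wait <- 0L }
      else { wait <- wait + 1L; if (wait >= config$patience) break }
    }
  }
  list(log = tibble::as_tibble(as.data.frame(log[stats::complete.cases(log[, "epoch"]), , drop = FALSE])),
       gru_grad_norm = gru_grad_norm)
}

# eval-mode forward returning probabilities, fused embedding, attention and
# the (stacked) learned local adjacency
model_inference <- function(gmodel, lmodel, feats, pop, config,
                            Xs_override = NULL) {
  linf <- local_inference(lmodel, feats)
  Xf <- switch(config$feature_mode,
               Corr = feats$fc_vec,
               Emb = linf$Gemb,
               Concat = cbind(feats$fc_vec, linf$Gemb))
  Ld <- ad_value(pae_laplacian(feats$eta, gmodel$pae, pop$support_d))
  Xs_mat <- if (is.null(Xs_override)) pop$Xs else Xs_override
  gout <- global_forward(gmodel,
                         list(f = ad_node(pop$Lf), s = ad_node(pop$Ls),
                              d = ad_node(Ld)),
                         list(f = ad_node(Xf), s = ad_node(Xs_mat),
                              d = ad_node(pop$Xd)),
                         grl_lambda = 0)
  probs <- softmax_rows(ad_value(gout$logits))
  list(probs = probs[, 2L], local = linf,
       fused = ad_value(gout$fused),
       attention = ad_value(gout$attention),
       commons = lapply(gout$common_per_channel, ad_value),
       specifics = lapply(gout$specific, ad_value),
       Ld = Ld)
}

# ---- single-split trainers -------------------------------------------------

default_split <- function(labels, sites, fraction, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  strata <- split(seq_along(labels), paste(labels, sites))
  test <- unlist(lapply(strata, function(idx)
    sample(idx, max(1L, round(length(idx) * fraction)))))
  sort(test)
}

#' Train the model on one train/test split
#'
#' `train_two_stage()` first trains the local ROI network with its local
#' classification loss alone, freezes it, computes embeddings and learned
#' adjacencies, and trains the global network with the full objective minus
#' the local term. `train_end_to_end()` optimizes all parameters jointly
#' under the complete objective, with gradients flowing from the global loss
#' into the recurrent encoder and graph generator.
#'
#' @param cohort a `cohort_bundle`.
#' @param config a [train_config()].
#' @param train_idx,test_idx subject index vectors; by default a stratified
#'   holdout split of `config$holdout_fraction` is drawn from `config$seed`.
#' @return a `fusegnn_fit`: trained models, per-epoch loss log, per-subject
#'   prediction tibble for test nodes, learned local adjacencies, attention
#'   scores and diagnostics.
#' @export
train_two_stage <- function(cohort, config = train_config(mode = "two_stage"),
                            train_idx = NULL, test_idx = NULL) {
  fit_split(cohort, config, train_idx, test_idx, end_to_end = FALSE)
}

#' @rdname train_two_stage
#' @export
train_end_to_end <- function(cohort, config = train_config(mode = "end_to_end"),
                             train_idx = NULL, test_idx = NULL) {
  fit_split(cohort, config, train_idx, test_idx, end_to_end = TRUE)
}

fit_split <- function(cohort, config, train_idx, test_idx, end_to_end) {
  S <- length(cohort$series)
  if (is.null(test_idx)) {
    test_idx <- default_split(cohort$labels, cohort$sites,
                              config$holdout_fraction, config$seed)
  }
  if (is.null(train_idx)) train_idx <- setdiff(seq_len(S), test_idx)
  stopifnot(length(intersect(train_idx, test_idx)) == 0L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  feats <- prepare_features(cohort, config, train_idx)
  lmodel <- new_local_model(feats$n_rois, config$local)
  local_log <- NULL
  if (!end_to_end) {
    local_log <- train_local_stage(lmodel, feats, feats$labels, train_idx, config)
  } else {
    # one warm pass so batch-norm statistics exist for graph construction
    invisible(local_forward(lmodel, feats$Xstack, feats$Fstack, training = TRUE))
  }
  linf0 <- local_inference(lmodel, feats)
  pop <- build_population(feats, linf0$Gemb, config)
  widths <- c(f = ncol(pop$Xf), s = ncol(pop$Xs), d = ncol(pop$Xd))
  gmodel <- new_global_model(widths, ncol(feats$eta),
                             n_sites = length(unique(feats$sites)),
                             config = config$global)
  gl <- train_global_stage(gmodel, lmodel, feats, pop, config, train_idx,
                           end_to_end = end_to_end)
  inf <- model_inference(gmodel, lmodel, feats, pop, config)
  preds <- tibble::tibble(
    subject = cohort$demographics$subject,
    site = cohort$sites,
    label = cohort$labels,
    prob = inf$probs,
    split = ifelse(seq_len(S) %in% test_idx, "test", "train")
  )
  structure(list(
    local = lmodel, global = gmodel, pop = pop, feats_cache = NULL,
    config = config, train_idx = train_idx, test_idx = test_idx,
    predictions = preds,
    metrics = compute_metrics(cohort$labels[test_idx], inf$probs[test_idx]),
    loss_log = gl$log, local_loss = local_log,
    adjacency = inf$local$A, graph_embedding = inf$local$Gemb,
    roi_attention = inf$local$attention,
    attention = inf$attention, Ld = inf$Ld,
    diagnostics = list(gru_grad_norm = gl$gru_grad_norm),
    n_rois = feats$n_rois
  ), class = "fusegnn_fit")
}

#' @export
print.fusegnn_fit <- function(x, ...) {
  cat("<fusegnn_fit> mode:", x$config$mode, "\n")
  cat("  train/test:", length(x$train_idx), "/", length(x$test_idx), "subjects\n")
  m <- x$metrics
  cat(sprintf("  test ACC %.3f AUROC %.3f F1 %.3f\n", m$acc, m$auroc, m$f1))
  invisible(x)
}

# ---- metrics ---------------------------------------------------------------

#' Classification metrics
#'
#' Accuracy, AUROC (rank statistic with tie correction), precision, recall
#' and F1 at a 0.5 threshold.
#'
#' @param labels 0/1 labels.
#' @param probs predicted case probabilities.
#' @param threshold decision threshold.
#' @return one-row tibble.
#' @export
compute_metrics <- function(labels, probs, threshold = 0.5) {
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  acc <- mean(pred == labels)
  precision <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  tibble::tibble(acc = acc, auroc = auroc_stat(labels, probs),
                 precision = precision, recall = recall, f1 = f1)
}

auroc_stat <- function(labels, probs) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(probs, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---- cross-validation ------------------------------------------------------

stratified_folds <- function(labels, sites, folds, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  assignment <- integer(length(labels))
  offset <- 0L
  for (stratum in split(seq_along(labels), paste(labels, sites))) {
    idx <- sample(stratum)
    assignment[idx] <- ((seq_along(idx) + offset - 1L) %% folds) + 1L
    offset <- offset + length(idx)
  }
  for (f in seq_len(folds)) {
    if (length(unique(labels[assignment != f])) < 2L ||
        length(unique(labels[assignment == f])) < 2L)
      stop("fold ", f, " lacks both classes; use fewer folds")
  }
  assignment
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified jointly by label and site. Each fold's training is
#' transductive (test subjects are present as graph nodes with labels
#' masked); harmonization and every parameter fit use training-fold data
#' only. Learned local adjacencies are averaged per subject over the folds
#' in which the subject was a training node, matching the interpretation
#' protocol.
#'
#' @param cohort a `cohort_bundle`.
#' @param config a [train_config()].
#' @param folds number of folds (default 10).
#' @param keep_fold_models store per-fold models and features (needed by
#'   [mask_character_importance()]).
#' @return a `fusegnn_eval` report: pooled/per-fold metrics, per-subject
#'   probability table, calibration bins, averaged learned adjacencies,
#'   attention scores, and (optionally) fold states.
#' @export
kfold_cv <- function(cohort, config = train_config(), folds = 10L,
                     keep_fold_models = TRUE) {
  stopifnot(folds >= 2L)
  assignment <- stratified_folds(cohort$labels, cohort$sites, folds, config$seed)
  run_cv(cohort, config, assignment, scheme = "kfold",
         keep_fold_models = keep_fold_models)
}

#' Leave-one-site-out cross-validation
#'
#' Each acquisition site is held out wholly once; metrics are reported per
#' site and pooled.
#'
#' @inheritParams kfold_cv
#' @return a `fusegnn_eval` report.
#' @export
loso_cv <- function(cohort, config = train_config(), keep_fold_models = FALSE) {
  sites <- cohort$sites
  if (length(unique(sites)) < 2L) stop("LOSO needs >= 2 sites")
  assignment <- as.integer(factor(sites))
  run_cv(cohort, config, assignment, scheme = "loso",
         keep_fold_models = keep_fold_models)
}

run_cv <- function(cohort, config, assignment, scheme, keep_fold_models) {
  S <- length(cohort$series)
  folds <- sort(unique(assignment))
  n <- nrow(cohort$series[[1]])
  adj_sum <- array(0, c(S, n, n))
  adj_cnt <- integer(S)
  preds <- vector("list", length(folds))
  fold_metrics <- vector("list", length(folds))
  fold_states <- if (keep_fold_models) vector("list", length(folds)) else NULL
  attn <- vector("list", length(folds))
  end_to_end <- config$mode == "end_to_end"
  for (fi in seq_along(folds)) {
    f <- folds[fi]
    test_idx <- which(assignment == f)
    train_idx <- which(assignment != f)
    cfg <- config
    cfg$seed <- config$seed + fi
    fit <- fit_split(cohort, cfg, train_idx, test_idx, end_to_end = end_to_end)
    # fold-averaged learned connectivity: inference adjacency for training
    # subjects of this fold
    for (s in train_idx) {
      rows <- (s - 1L) * n + seq_len(n)
      adj_sum[s, , ] <- adj_sum[s, , ] + fit$adjacency[rows, ]
      adj_cnt[s] <- adj_cnt[s] + 1L
    }
    preds[[fi]] <- fit$predictions[test_idx, ] |>
      dplyr::mutate(fold = f)
    fold_metrics[[fi]] <- compute_metrics(cohort$labels[test_idx],
                                          fit$predictions$prob[test_idx]) |>
      dplyr::mutate(fold = f, n_test = length(test_idx), .before = 1L)
    attn[[fi]] <- colMeans(fit$attention)
    if (keep_fold_models) {
      fold_states[[fi]] <- list(local = fit$local, global = fit$global,
                                pop = fit$pop, config = cfg,
                                train_idx = train_idx, test_idx = test_idx,
                                fold = f)
    }
  }
  predictions <- dplyr::bind_rows(preds) |>
    dplyr::select(-dplyr::any_of("split")) |>
    dplyr::arrange(.data$subject)
  pooled <- compute_metrics(predictions$label, predictions$prob)
  fold_tbl <- dplyr::bind_rows(fold_metrics)
  adjacency <- lapply(seq_len(S), function(s) {
    if (adj_cnt[s] == 0L) return(NULL)
    adj_sum[s, , ] / adj_cnt[s]
  })
  attn_mat <- do.call(rbind, attn)
  structure(list(
    scheme = scheme, predictions = predictions,
    fold_metrics = fold_tbl, pooled = pooled,
    metric_summary = summarize_folds(fold_tbl),
    calibration = calibration_curve(predictions$prob, predictions$label),
    adjacency = adjacency, adjacency_counts = adj_cnt,
    attention = attn_mat,
    labels = cohort$labels, sites = cohort$sites,
    config = config, fold_states = fold_states,
    cohort_truth = cohort$truth
  ), class = "fusegnn_eval")
}

summarize_folds <- function(fold_tbl) {
  fold_tbl |>
    tidyr::pivot_longer(cols = c("acc", "auroc", "precision", "recall", "f1"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarize(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     .groups = "drop")
}

#' @export
print.fusegnn_eval <- function(x, ...) {
  cat("<fusegnn_eval> scheme:", x$scheme, "-", nrow(x$fold_metrics), "folds,",
      nrow(x$predictions), "evaluated subjects\n")
  p <- x$pooled
  cat(sprintf("  pooled ACC %.3f AUROC %.3f precision %.3f recall %.3f F1 %.3f\n",
              p$acc, p$auroc, p$precision, p$recall, p$f1))
  invisible(x)
}

# ---- calibration and subgroup evaluation -----------------------------------

#' Calibration curve
#'
#' Equal-width bins on the predicted probability; per bin the mean
#' prediction, the observed positive fraction and the count.
#'
#' @param probabilities predicted probabilities in `[0, 1]`.
#' @param labels 0/1 labels.
#' @param n_bins number of equal-width bins.
#' @return tibble with `bin`, `lower`, `upper`, `mean_pred`, `obs_freq`,
#'   `count`.
#' @export
calibration_curve <- function(probabilities, labels, n_bins = 10L) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(findInterval(probabilities, edges, rightmost.closed = TRUE), n_bins)
  tibble::tibble(bin = seq_len(n_bins),
                 lower = edges[-length(edges)], upper = edges[-1L]) |>
    dplyr::left_join(
      tibble::tibble(bin = bin, prob = probabilities, label = labels) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarize(mean_pred = mean(.data$prob),
                         obs_freq = mean(.data$label),
                         count = dplyr::n(), .groups = "drop"),
      by = "bin") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
}

#' Recompute metrics on a subject subset
#'
#' Filters the saved probability table (e.g. one diagnostic subtype versus
#' controls) and recomputes pooled and per-fold metrics.
#'
#' @param report a `fusegnn_eval`.
#' @param subject_filter logical vector over `report$predictions` rows, or a
#'   function of the predictions tibble returning one.
#' @return a `fusegnn_eval` on the subset.
#' @export
subgroup_eval <- function(report, subject_filter) {
  stopifnot(inherits(report, "fusegnn_eval"))
  preds <- report$predictions
  keep <- if (is.function(subject_filter)) subject_filter(preds) else subject_filter
  stopifnot(is.logical(keep), length(keep) == nrow(preds))
  sub <- preds[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop("empty subgroup")
  fold_tbl <- sub |>
    dplyr::group_by(.data$fold) |>
    dplyr::group_modify(~ dplyr::mutate(compute_metrics(.x$label, .x$prob),
                                        n_test = nrow(.x))) |>
    dplyr::ungroup()
  out <- report
  out$predictions <- sub
  out$pooled <- compute_metrics(sub$label, sub$prob)
  out$fold_metrics <- fold_tbl
  out$metric_summary <- summarize_folds(fold_tbl)
  out$calibration <- calibration_curve(sub$prob, sub$label)
  out
}

#' Resampled evaluation at an imposed class ratio
#'
#' Bootstrap evaluation of the saved probability table at a fixed
#' case:control ratio (e.g. 1:4), for unbalanced-cohort validation.
#'
#' @param report a `fusegnn_eval`.
#' @param case_control_ratio length-2 numeric, cases to controls.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return tibble of metric mean/sd over replicates.
#' @export
resampled_eval <- function(report, case_control_ratio = c(1, 4), n_boot = 100L,
                           seed = 1L) {
  preds <- report$predictions
  cases <- which(preds$label == 1L)
  controls <- which(preds$label == 0L)
  n_case <- min(length(cases),
                floor(length(controls) * case_control_ratio[1] / case_control_ratio[2]))
  if (n_case < 1L) stop("not enough subjects for the requested ratio")
  n_ctrl <- round(n_case * case_control_ratio[2] / case_control_ratio[1])
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  reps <- purrr::map_dfr(seq_len(n_boot), function(b) {
    idx <- c(sample(cases, n_case), sample(controls, n_ctrl))
    compute_metrics(preds$label[idx], preds$prob[idx])
  })
  summarize_folds(dplyr::mutate(reps, fold = dplyr::row_number(), n_test = n_case + n_ctrl))
}
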