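# Harness behavior: fold construction, metric oracles, calibration,
# subgroup/resampled evaluation, determinism, wiring of gradients into the
# encoder, and the label-shuffle leak check at reduced scale.

test_that("metrics agree with independent reference implementations", {
  skip_if_not_installed("pROC")
  set.seed(1)
  for (rep in 1:5) {
    y <- rbinom(40, 1L, 0.5)
    if (length(unique(y)) < 2L) y[1:2] <- c(0L, 1L)
    p <- runif(40)
    m <- compute_metrics(y, p)
    ref <- as.numeric(suppressMessages(pROC::auc(y, p, direction = "<")))
    expect_equal(m$auroc, ref, tolerance = 1e-9)
    pred <- as.integer(p >= 0.5)
    expect_equal(m$acc, mean(pred == y), tolerance = 1e-12)
    tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
    expect_equal(m$precision, tp / (tp + fp), tolerance = 1e-12)
    expect_equal(m$recall, tp / (tp + fn), tolerance = 1e-12)
    expect_equal(m$f1, 2 * tp / (2 * tp + fp + fn), tolerance = 1e-9)
  }
})

test_that("stratified folds partition subjects with balanced case fractions", {
  co <- tiny_cohort(n_subjects = 60L)
  assignment <- stratified_folds(co$labels, co$sites, folds = 5L, seed = 2L)
  expect_length(assignment, 60L)
  expect_setequal(unique(assignment), 1:5)
  global_frac <- mean(co$labels)
  for (f in 1:5) {
    expect_lt(abs(mean(co$labels[assignment == f]) - global_frac), 0.1 + 1e-9)
  }
  # every subject exactly once in a test fold
  expect_equal(sort(unlist(lapply(1:5, function(f) which(assignment == f)))),
               1:60)
  expect_error(stratified_folds(c(rep(0L, 9), 1L), rep(1L, 10), 5L, 1L),
               "lacks both classes")
})

test_that("k-fold CV produces a complete, reproducible report", {
  co <- tiny_cohort(n_subjects = 30L)
  cfg <- tiny_train_config(mode = "two_stage", seed = 5L)
  ev <- kfold_cv(co, cfg, folds = 3L, keep_fold_models = FALSE)
  expect_s3_class(ev, "fusegnn_eval")
  expect_equal(nrow(ev$predictions), 30L)
  expect_setequal(ev$predictions$subject, co$demographics$subject)
  # metrics equal recomputation from the saved probability table
  re <- compute_metrics(ev$predictions$label, ev$predictions$prob)
  expect_equal(ev$pooled, re)
  for (f in unique(ev$fold_metrics$fold)) {
    sub <- ev$predictions[ev$predictions$fold == f, ]
    expect_equal(ev$fold_metrics$auroc[ev$fold_metrics$fold == f],
                 compute_metrics(sub$label, sub$prob)$auroc)
  }
  # determinism: a rerun reproduces the metrics exactly
  ev2 <- kfold_cv(co, cfg, folds = 3L, keep_fold_models = FALSE)
  expect_equal(ev$predictions$prob, ev2$predictions$prob, tolerance = 1e-12)
  # tidiers
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(nrow(glance(ev)), 1L)
})

test_that("LOSO holds each site out wholly and never trains on it", {
  co <- tiny_cohort(n_subjects = 30L)
  cfg <- tiny_train_config(mode = "two_stage", seed = 6L)
  ev <- suppressWarnings(loso_cv(co, cfg))
  expect_equal(nrow(ev$fold_metrics), length(unique(co$sites)))
  for (f in unique(ev$predictions$fold)) {
    held <- ev$predictions[ev$predictions$fold == f, ]
    expect_equal(unique(held$site), f)
    expect_setequal(held$subject,
                    co$demographics$subject[co$sites == f])
  }
  single <- co
  single$sites <- rep(1L, 30L)
  expect_error(loso_cv(single, cfg), ">= 2 sites")
})

test_that("calibration bins are exact on constructed predictions", {
  cal <- calibration_curve(c(1, 1, 1), c(1L, 1L, 1L), n_bins = 5L)
  expect_equal(sum(cal$count), 3L)
  expect_equal(cal$mean_pred[5], 1)
  expect_equal(cal$obs_freq[5], 1)
  # simulated perfectly calibrated probabilities stay near the diagonal
  set.seed(3)
  p <- runif(4000)
  y <- rbinom(4000, 1L, p)
  cal2 <- calibration_curve(p, y, n_bins = 10L)
  expect_equal(sum(cal2$count), 4000L)
  dev <- abs(cal2$obs_freq - cal2$mean_pred)
  expect_lt(max(dev, na.rm = TRUE), 3 * max(sqrt(0.25 / cal2$count)))
  expect_error(calibration_curve(c(-0.1, 0.5), c(0L, 1L)), "probabilities")
})

test_that("subgroup evaluation recomputes metrics and partitions confusion counts", {
  co <- tiny_cohort(n_subjects = 30L)
  cfg <- tiny_train_config(mode = "two_stage", seed = 8L)
  ev <- kfold_cv(co, cfg, folds = 3L, keep_fold_models = FALSE)
  all_sub <- subgroup_eval(ev, rep(TRUE, nrow(ev$predictions)))
  expect_equal(all_sub$pooled, ev$pooled)
  f1 <- ev$predictions$site == 1L
  s1 <- subgroup_eval(ev, f1)
  s2 <- subgroup_eval(ev, !f1)
  expect_equal(nrow(s1$predictions) + nrow(s2$predictions),
               nrow(ev$predictions))
  # disjoint filters partition the pooled confusion counts
  cm <- function(r) {
    pred <- as.integer(r$predictions$prob >= 0.5)
    table(factor(pred, 0:1), factor(r$predictions$label, 0:1))
  }
  expect_equal(cm(s1) + cm(s2), cm(ev))
  expect_equal(s1$pooled$auroc,
               auroc_stat(ev$predictions$label[f1], ev$predictions$prob[f1]))
  expect_error(subgroup_eval(ev, rep(FALSE, nrow(ev$predictions))), "empty")
  # functional filter form and resampled unbalanced evaluation
  s3 <- subgroup_eval(ev, function(p) p$site != 2L)
  expect_equal(nrow(s3$predictions), sum(ev$predictions$site != 2L))
  rs <- resampled_eval(ev, case_control_ratio = c(1, 2), n_boot = 5L, seed = 2L)
  expect_true(all(c("acc", "auroc") %in% rs$metric))
})

test_that("end-to-end training reaches the recurrent encoder and logs its config", {
  co <- tiny_cohort(n_subjects = 24L)
  cfg <- tiny_train_config(mode = "end_to_end", seed = 9L)
  cfg$epochs <- 5L
  fit <- train_end_to_end(co, cfg)
  expect_gt(fit$diagnostics$gru_grad_norm, 0)
  expect_equal(fit$config$lambda_local, 0.2)
  expect_false(any(is.na(fit$loss_log$cls_local)))
  # seed-fixed rerun reproduces metrics exactly
  fit2 <- train_end_to_end(co, cfg)
  expect_equal(fit$metrics$auroc, fit2$metrics$auroc, tolerance = 1e-12)
  expect_equal(fit$predictions$prob, fit2$predictions$prob, tolerance = 1e-12)
})

test_that("two-stage training excludes the local loss from stage 2", {
  co <- tiny_cohort(n_subjects = 24L)
  cfg <- tiny_train_config(mode = "two_stage", seed = 10L)
  fit <- train_two_stage(co, cfg)
  expect_true(all(is.na(fit$loss_log$cls_local)))
  expect_length(fit$local_loss, cfg$epochs_local)
  expect_lt(fit$local_loss[cfg$epochs_local], fit$local_loss[1] + 0.1)
})

test_that("shuffling training labels removes generalization (no leak)", {
  co <- generate_cohort(cohort_spec(n_subjects = 120L, n_rois = 12L,
                                    n_timepoints = 40L, seed = 19L,
                                    enhanced_edges = list(c(1L, 5L), c(2L, 9L)),
                                    diminished_edges = list(c(3L, 7L)),
                                    n_struct_features = 20L, n_characters = 5L,
                                    informative_characters = paste0("char_", 1:2)))
  aurocs <- vapply(1:2, function(sd) {
    cfg <- tiny_train_config(mode = "two_stage", seed = 100L + sd)
    cfg$epochs <- 12L; cfg$epochs_local <- 4L
    test_idx <- default_split(co$labels, co$sites, 0.25, cfg$seed)
    train_idx <- setdiff(seq_len(120L), test_idx)
    shuffled <- co
    old <- .Random.seed_save(); set.seed(cfg$seed)
    shuffled$labels[train_idx] <- sample(co$labels[train_idx])
    .Random.seed_restore(old)
    fit <- train_two_stage(shuffled, cfg, train_idx = train_idx,
                           test_idx = test_idx)
    # score against the TRUE held-out labels
    auroc_stat(co$labels[test_idx], fit$predictions$prob[test_idx])
  }, numeric(1L))
  expect_lt(abs(mean(aurocs) - 0.5), 0.15)
})
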