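# Shared test utilities: finite-difference gradient checking, small cohort
# builders, and a per-session cache so expensive trained models are computed
# once and reused across test blocks.

# finite-difference check of analytic gradients in a sample of coordinates;
# lossfn must rebuild the graph (and zero grads) on every call
fd_gradient_error <- function(lossfn, leaves, n_coords = 5L, eps = 1e-6) {
  loss <- lossfn()
  fusegnn::ad_backward(loss)
  grads <- lapply(leaves, fusegnn::ad_grad)
  maxerr <- 0
  for (j in seq_along(leaves)) {
    p <- leaves[[j]]
    coords <- sample(length(p$value), min(n_coords, length(p$value)))
    for (i in coords) {
      v0 <- p$value
      p$value[i] <- v0[i] + eps
      lp <- fusegnn::ad_value(lossfn())[1]
      p$value[i] <- v0[i] - eps
      lm <- fusegnn::ad_value(lossfn())[1]
      p$value <- v0
      maxerr <- max(maxerr, abs((lp - lm) / (2 * eps) - grads[[j]][i]))
    }
  }
  maxerr
}

# small multi-site cohort with planted effects, cheap enough for unit tests
tiny_cohort <- function(n_subjects = 36L, seed = 42L, ...) {
  generate_cohort(cohort_spec(
    n_subjects = n_subjects, n_rois = 10L, n_timepoints = 36L, n_sites = 2L,
    enhanced_edges = list(c(1L, 5L), c(2L, 8L)),
    diminished_edges = list(c(3L, 7L)),
    n_struct_features = 20L, n_characters = 5L,
    informative_characters = c("char_1", "char_2"),
    seed = seed, ...))
}

tiny_train_config <- function(mode = "two_stage", seed = 7L, ...) {
  train_config(
    mode = mode, epochs = 8L, epochs_local = 6L, k_neighbors = 4L,
    snowball_layers = 2L,
    local = local_config(gru_hidden = 3L, gcn_widths = c(8L, 6L, 4L),
                         mlp_hidden = 8L),
    global = global_config(snowball_layers = 2L, snowball_width = 4L,
                           c_width = 8L, out_width = 6L, common_width = 8L,
                           attn_width = 4L, pae_hidden = 8L, pae_out = 4L),
    seed = seed, ...)
}

# acceptance-scale study conditions: default generator spec at n = 300 and
# the desk-scale network/epoch configuration documented in the vignette
acceptance_cohort <- function(seed = 101L, ...) {
  generate_cohort(cohort_spec(n_subjects = 300L, seed = seed, ...))
}

acceptance_config <- function(mode = "end_to_end", seed = 1L, ...) {
  args <- list(
    mode = mode, epochs = 12L, epochs_local = 20L,
    local = local_config(gru_hidden = 8L, gcn_widths = c(32L, 16L, 8L),
                         mlp_hidden = 16L),
    global = global_config(snowball_layers = 9L, snowball_width = 8L,
                           c_width = 16L, out_width = 16L, common_width = 16L),
    seed = seed)
  dots <- list(...)
  if ("snowball_layers" %in% names(dots))
    args$global$snowball_layers <- dots$snowball_layers
  args[names(dots)] <- dots
  do.call(train_config, args)
}

# session-level cache: heavy trained objects shared across acceptance blocks
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache, inherits = FALSE)
}
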