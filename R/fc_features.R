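# Feature preparation: window alignment, signal standardization, Pearson
# functional connectivity, and empirical-Bayes location-scale site
# harmonization with train/apply separation for fold hygiene.

#' Align a BOLD series to a fixed window
#'
#' Truncates an ROI x time series to windows of a fixed width. In `"align"`
#' mode (the default, used to equalize series length across a cohort) only the
#' first full window is returned; `"augment"` mode returns every window at the
#' given step as a list.
#'
#' @param series `n_rois x t` matrix.
#' @param width window width (columns), `<= t`.
#' @param step step between window starts (augment mode).
#' @param mode `"align"` or `"augment"`.
#' @return a matrix with `width` columns, or a list of such matrices.
#' @export
window_series <- function(series, width, step = 1L, mode = c("align", "augment")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(series), step >= 1L)
  t_ <- ncol(series)
  if (width > t_)
    stop("window width ", width, " exceeds series length ", t_)
  if (mode == "align") return(series[, seq_len(width), drop = FALSE])
  starts <- seq(1L, t_ - width + 1L, by = step)
  lapply(starts, function(s) series[, s:(s + width - 1L), drop = FALSE])
}

#' Standardize ROI signals
#'
#' Z-scores each ROI row to mean 0 and unit standard deviation. (Fisher's
#' r-to-z transform, which applies to correlations rather than raw signals, is
#' available separately via `pearson_fc(..., fisher_z = TRUE)`.)
#'
#' @param series `n_rois x t` matrix.
#' @return matrix of the same shape with standardized rows.
#' @export
standardize_series <- function(series) {
  stopifnot(is.matrix(series))
  sds <- apply(series, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant ROI row(s): ", paste(which(sds == 0), collapse = ", "))
  (series - rowMeans(series)) / sds
}

#' Pearson functional connectivity matrix
#'
#' Correlates ROI BOLD signals pairwise to form the initial functional
#' connectivity matrix whose columns also serve as local-graph node features.
#'
#' @param series `n_rois x t` matrix, `t >= 3`.
#' @param fisher_z apply artanh to off-diagonal entries (clipped at
#'   `|r| <= 1 - 1e-7`).
#' @return symmetric `n x n` matrix with unit diagonal (before any `fisher_z`),
#'   ROI labels carried on dimnames.
#' @export
pearson_fc <- function(series, fisher_z = FALSE) {
  stopifnot(is.matrix(series), ncol(series) >= 3L)
  sds <- apply(series, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant ROI row(s): ", paste(which(sds == 0), collapse = ", "))
  R <- stats::cor(t(series))
  if (is.null(rownames(series))) {
    dimnames(R) <- list(roi_labels(nrow(series)), roi_labels(nrow(series)))
  }
  if (fisher_z) {
    Rc <- pmin(pmax(R, -1 + 1e-7), 1 - 1e-7)
    Z <- atanh(Rc)
    diag(Z) <- atanh(1 - 1e-7)
    dimnames(Z) <- dimnames(R)
    return(Z)
  }
  R
}

# strict upper triangle of an FC matrix as a feature vector
fc_upper <- function(fc) fc[upper.tri(fc)]

#' Fit a location-scale site harmonization model
#'
#' Empirical-Bayes harmonization of multi-site feature tables: per-feature
#' least squares estimates a grand mean, coefficients of preserved biological
#' covariates, and per-site location/scale parameters; site parameters are
#' shrunk toward site-level priors (normal prior on locations, inverse-gamma
#' on scales, moment-matched), solved by the standard conditional iteration.
#' Fitting on a training fold and applying to held-out subjects keeps fold
#' hygiene: held-out labels never enter the transform.
#'
#' @param features subjects x p numeric matrix.
#' @param sites per-subject site index (integer or factor).
#' @param covariates optional numeric matrix/data.frame of biological
#'   covariates to preserve (e.g. label, age, sex).
#' @param eb use empirical-Bayes shrinkage (otherwise raw site estimates).
#' @return an object of class `combat_model`.
#' @export
fit_combat <- function(features, sites, covariates = NULL, eb = TRUE) {
  features <- as.matrix(features)
  S <- nrow(features); p <- ncol(features)
  sites <- as.character(sites)
  lv <- sort(unique(sites))
  if (length(lv) == 1L) {
    warning("single site: harmonization model is the identity transform")
    return(structure(list(identity = TRUE, site_levels = lv, p = p),
                     class = "combat_model"))
  }
  counts <- table(factor(sites, levels = lv))
  if (any(counts < 2L)) stop("every site needs >= 2 subjects")
  B <- stats::model.matrix(~ 0 + factor(sites, levels = lv))
  colnames(B) <- lv
  Cm <- NULL
  if (!is.null(covariates)) {
    Cm <- as.matrix(as.data.frame(covariates))
    storage.mode(Cm) <- "double"
    # center covariates so site intercepts absorb the covariate-free mean
    cov_center <- colMeans(Cm)
    Cm <- sweep(Cm, 2L, cov_center)
  } else cov_center <- NULL
  D <- cbind(B, Cm)
  bh <- solve(crossprod(D), crossprod(D, features))   # (nsite+ncov) x p
  gamma_hat_ls <- bh[seq_along(lv), , drop = FALSE]
  beta_c <- if (is.null(Cm)) NULL else bh[-seq_along(lv), , drop = FALSE]
  w <- as.numeric(counts) / S
  alpha <- drop(w %*% gamma_hat_ls)                   # grand mean per feature
  fit <- D %*% bh
  sigma2 <- colMeans((features - fit)^2)
  sigma <- sqrt(pmax(sigma2, 1e-12))

  covfit <- if (is.null(Cm)) 0 else Cm %*% beta_c
  Z <- (features - matrix(alpha, S, p, byrow = TRUE) - covfit) /
    matrix(sigma, S, p, byrow = TRUE)

  gamma_hat <- matrix(0, length(lv), p, dimnames = list(lv, NULL))
  delta2_hat <- matrix(1, length(lv), p, dimnames = list(lv, NULL))
  for (i in seq_along(lv)) {
    zi <- Z[sites == lv[i], , drop = FALSE]
    gamma_hat[i, ] <- colMeans(zi)
    delta2_hat[i, ] <- apply(zi, 2L, stats::var)
  }
  delta2_hat <- pmax(delta2_hat, 1e-12)

  if (eb && p >= 2L) {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    for (i in seq_along(lv)) {
      ni <- as.numeric(counts[i])
      g <- gamma_hat[i, ]; d2 <- delta2_hat[i, ]
      gbar <- mean(g); tau2 <- stats::var(g)
      m <- mean(d2); s2 <- stats::var(d2)
      a <- (2 * s2 + m^2) / s2
      b <- (m * s2 + m^3) / s2
      zi <- Z[sites == lv[i], , drop = FALSE]
      g_old <- g; d_old <- d2
      for (it in seq_len(200L)) {
        g_new <- (ni * tau2 * g + d_old * gbar) / (ni * tau2 + d_old)
        sum2 <- colSums(sweep(zi, 2L, g_new)^2)
        d_new <- (0.5 * sum2 + b) / (ni / 2 + a - 1)
        if (max(abs(g_new - g_old), abs(d_new - d_old)) < 1e-6) {
          g_old <- g_new; d_old <- d_new
          break
        }
        g_old <- g_new; d_old <- d_new
      }
      gamma_star[i, ] <- g_old
      delta2_star[i, ] <- pmax(d_old, 1e-12)
    }
  } else {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
  }

  structure(list(identity = FALSE, site_levels = lv, p = p,
                 alpha = alpha, beta_c = beta_c, cov_center = cov_center,
                 sigma = sigma, gamma = gamma_star,
                 delta = sqrt(delta2_star), eb = eb),
            class = "combat_model")
}

#' Apply a fitted harmonization model
#'
#' Transforms features as
#' `((x - grand mean - covariate fit - site location) / site scale) * pooled sd
#'  + grand mean + covariate fit` (per feature, in standardized space), which
#' removes site location/scale effects while preserving covariate-explained
#' variance. Subjects from sites unseen at fit time pass through unchanged
#' with a warning.
#'
#' @param model a `combat_model`.
#' @param features subjects x p matrix, same features as at fit time.
#' @param sites per-subject site index.
#' @param covariates covariates matching those used at fit time (or `NULL`).
#' @return harmonized matrix, same shape as `features`.
#' @export
apply_combat <- function(model, features, sites, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  features <- as.matrix(features)
  if (ncol(features) != model$p) stop("feature dimension mismatch")
  if (isTRUE(model$identity)) return(features)
  S <- nrow(features); p <- model$p
  sites <- as.character(sites)
  if (length(sites) != S) stop("sites length mismatch")
  known <- sites %in% model$site_levels
  if (!all(known))
    warning("unseen site(s) ", paste(unique(sites[!known]), collapse = ", "),
            ": passed through unharmonized")
  if (!is.null(model$beta_c)) {
    if (is.null(covariates)) stop("model was fitted with covariates; supply them")
    Cm <- as.matrix(as.data.frame(covariates))
    storage.mode(Cm) <- "double"
    Cm <- sweep(Cm, 2L, model$cov_center)
    covfit <- Cm %*% model$beta_c
  } else covfit <- matrix(0, S, p)
  alpha <- matrix(model$alpha, S, p, byrow = TRUE)
  sigma <- matrix(model$sigma, S, p, byrow = TRUE)
  out <- features
  idx <- which(known)
  if (length(idx)) {
    si <- match(sites[idx], model$site_levels)
    Z <- (features[idx, , drop = FALSE] - alpha[idx, , drop = FALSE] -
            covfit[idx, , drop = FALSE]) / sigma[idx, , drop = FALSE]
    Zs <- (Z - model$gamma[si, , drop = FALSE]) / model$delta[si, , drop = FALSE]
    out[idx, ] <- Zs * sigma[idx, , drop = FALSE] + alpha[idx, , drop = FALSE] +
      covfit[idx, , drop = FALSE]
  }
  out
}
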