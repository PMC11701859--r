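#' Specify a synthetic multi-site case/control cohort
#'
#' Defines the generative conditions for a cohort of subjects, each carrying an
#' ROI BOLD time-series matrix, a structural (radiomics-style) feature vector,
#' and demographics, with planted case/control differences and per-site batch
#' effects. Cases differ from controls in three ways: selected ROI-ROI
#' covariance entries are strengthened (`enhanced_edges`) or weakened
#' (`diminished_edges`) by `edge_effect`; selected structural feature blocks
#' ("characters") receive a standardized mean shift of `struct_effect`; and
#' years of education differ by `demo_effect` standard deviations. Sites add
#' location/scale batch effects in the form targeted by location-scale
#' harmonization.
#'
#' ROI indices are 1-based. The `n_struct_features` columns are partitioned
#' into `n_characters` contiguous, equal-width named blocks; the blocks named
#' in `informative_characters` carry the case mean shift.
#'
#' @param n_subjects number of subjects.
#' @param n_rois number of ROIs (nodes of the local graph).
#' @param n_timepoints length of each BOLD series.
#' @param n_sites number of acquisition sites.
#' @param case_fraction fraction of subjects that are cases, in (0, 1).
#' @param enhanced_edges list of 1-based ROI index pairs whose covariance is
#'   increased by `edge_effect` in cases.
#' @param diminished_edges list of pairs decreased by `edge_effect` in cases.
#' @param edge_effect covariance delta magnitude for planted edges.
#' @param n_struct_features length of the structural feature vector.
#' @param n_characters number of equal-width feature blocks.
#' @param informative_characters character-block names carrying the case shift.
#' @param struct_effect standardized mean shift of informative blocks in cases.
#' @param site_shift_scale sd of per-site additive location effects.
#' @param site_scale_sd log-sd of per-site multiplicative scale effects.
#' @param demo_effect standardized case/control difference in education.
#' @param seed RNG seed; the bundle is a deterministic function of the spec.
#' @return an object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_subjects = 20, seed = 1)
#' bundle <- generate_cohort(spec)
#' dim(bundle$series[[1]])
#' @export
cohort_spec <- function(n_subjects,
                        n_rois = 32L,
                        n_timepoints = 120L,
                        n_sites = 3L,
                        case_fraction = 0.5,
                        enhanced_edges = list(c(1L, 5L), c(2L, 9L), c(3L, 13L),
                                              c(4L, 17L), c(6L, 21L)),
                        diminished_edges = list(c(7L, 25L), c(8L, 29L),
                                                c(10L, 22L), c(11L, 26L),
                                                c(12L, 30L)),
                        edge_effect = 0.5,
                        n_struct_features = 60L,
                        n_characters = 10L,
                        informative_characters = paste0("char_", 1:5),
                        struct_effect = 0.8,
                        site_shift_scale = 0.4,
                        site_scale_sd = 0.2,
                        demo_effect = 0.3,
                        seed = 1L) {
  stopifnot(n_subjects >= 2L, n_rois >= 2L, n_timepoints >= 3L, n_sites >= 1L,
            case_fraction > 0, case_fraction < 1,
            n_struct_features %% n_characters == 0L)
  check_pairs <- function(pairs, what) {
    for (p in pairs) {
      if (length(p) != 2L || p[1] == p[2] || any(p < 1L) || any(p > n_rois))
        stop(what, " pairs must be distinct ROI indices in [1, n_rois]")
    }
  }
  check_pairs(enhanced_edges, "enhanced")
  check_pairs(diminished_edges, "diminished")
  key <- function(pairs) vapply(pairs, function(p) paste(sort(p), collapse = "-"), "")
  if (length(intersect(key(enhanced_edges), key(diminished_edges))) > 0L)
    stop("enhanced and diminished edge sets must be disjoint")
  char_names <- paste0("char_", seq_len(n_characters))
  if (!all(informative_characters %in% char_names))
    stop("informative_characters must be drawn from ", paste(char_names, collapse = ", "))
  structure(list(
    n_subjects = as.integer(n_subjects), n_rois = as.integer(n_rois),
    n_timepoints = as.integer(n_timepoints), n_sites = as.integer(n_sites),
    case_fraction = case_fraction, enhanced_edges = enhanced_edges,
    diminished_edges = diminished_edges, edge_effect = edge_effect,
    n_struct_features = as.integer(n_struct_features),
    n_characters = as.integer(n_characters),
    character_names = char_names,
    informative_characters = informative_characters,
    struct_effect = struct_effect, site_shift_scale = site_shift_scale,
    site_scale_sd = site_scale_sd, demo_effect = demo_effect,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Signed matrix of planted connectivity differences
#'
#' Ground-truth differential connectivity implied by a cohort spec:
#' `+edge_effect` at enhanced pairs, `-edge_effect` at diminished pairs,
#' symmetric, zero elsewhere (including the diagonal).
#'
#' @param spec a [cohort_spec()].
#' @return an `n_rois` x `n_rois` signed matrix.
#' @export
planted_differential_matrix <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  M <- matrix(0, spec$n_rois, spec$n_rois)
  for (p in spec$enhanced_edges) M[p[1], p[2]] <- M[p[2], p[1]] <- spec$edge_effect
  for (p in spec$diminished_edges) M[p[1], p[2]] <- M[p[2], p[1]] <- -spec$edge_effect
  rownames(M) <- colnames(M) <- roi_labels(spec$n_rois)
  M
}

roi_labels <- function(n) sprintf("ROI%02d", seq_len(n))

# nearest positive-definite repair by eigenvalue clipping + re-symmetrization
repair_pd <- function(S, floor = 1e-6) {
  S <- (S + t(S)) / 2
  ee <- eigen(S, symmetric = TRUE)
  if (all(ee$values >= floor)) return(S)
  V <- ee$vectors
  S2 <- V %*% (pmax(ee$values, floor) * t(V))
  (S2 + t(S2)) / 2
}

# random base covariance: low-rank + diagonal, rescaled to unit diagonal
base_covariance <- function(n_rois, rank = 4L) {
  B <- matrix(stats::rnorm(n_rois * rank, sd = 0.6), n_rois, rank)
  S <- tcrossprod(B) + diag(stats::runif(n_rois, 0.5, 1.5))
  stats::cov2cor(S)
}

#' Generate a synthetic multi-site cohort
#'
#' Draws the cohort described by a [cohort_spec()]: per subject a
#' positive-definite base ROI covariance (random low-rank plus diagonal,
#' scaled to unit variances) is modified for cases by `+/- edge_effect` at the
#' planted pairs and re-projected to the nearest positive-definite matrix
#' (eigenvalue clipping at 1e-6); the BOLD series is drawn as `n_timepoints`
#' i.i.d. samples from the resulting Gaussian. Structural features follow the
#' location-scale site model `x = biological mean + gamma_site + delta_site *
#' noise`; sites also offset per-ROI signal means of the time series.
#'
#' @param spec a [cohort_spec()].
#' @param keep_covariance store each subject's true covariance (used by
#'   convergence tests; off by default to save memory).
#' @return an object of class `cohort_bundle`: list with `series` (list of
#'   `n_rois x n_timepoints` matrices), `struct_features` (subjects x features
#'   matrix), `demographics` (tibble: subject, age, sex, education, site),
#'   `labels` (0 control / 1 case), `sites`, `truth` (the spec plus planted
#'   ground truth), and optionally `covariances`.
#' @export
generate_cohort <- function(spec, keep_covariance = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  S <- spec$n_subjects
  n <- spec$n_rois
  t_ <- spec$n_timepoints

  n_cases <- round(S * spec$case_fraction)
  labels <- c(rep(1L, n_cases), rep(0L, S - n_cases))
  labels <- sample(labels)
  sites <- sample(rep_len(seq_len(spec$n_sites), S))

  # site effects
  site_roi_shift <- matrix(stats::rnorm(spec$n_sites * n, sd = spec$site_shift_scale),
                           spec$n_sites, n)
  site_feat_shift <- matrix(stats::rnorm(spec$n_sites * spec$n_struct_features,
                                         sd = spec$site_shift_scale),
                            spec$n_sites, spec$n_struct_features)
  site_feat_scale <- matrix(exp(stats::rnorm(spec$n_sites * spec$n_struct_features,
                                             sd = spec$site_scale_sd)),
                            spec$n_sites, spec$n_struct_features)

  series <- vector("list", S)
  covs <- if (keep_covariance) vector("list", S) else NULL
  for (s in seq_len(S)) {
    Sig <- base_covariance(n)
    if (labels[s] == 1L && spec$edge_effect != 0) {
      for (p in spec$enhanced_edges) {
        Sig[p[1], p[2]] <- Sig[p[1], p[2]] + spec$edge_effect
        Sig[p[2], p[1]] <- Sig[p[1], p[2]]
      }
      for (p in spec$diminished_edges) {
        Sig[p[1], p[2]] <- Sig[p[1], p[2]] - spec$edge_effect
        Sig[p[2], p[1]] <- Sig[p[1], p[2]]
      }
      Sig <- repair_pd(Sig)
      if (min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values) <= 0)
        stop("covariance not positive definite after repair for planted edges ",
             paste(vapply(c(spec$enhanced_edges, spec$diminished_edges),
                          paste, "", collapse = "-"), collapse = ", "))
    }
    if (keep_covariance) covs[[s]] <- Sig
    Z <- matrix(stats::rnorm(n * t_), n, t_)
    X <- crossprod(chol(Sig), Z)
    X <- X + site_roi_shift[sites[s], ]  # per-ROI mean offset by site
    rownames(X) <- roi_labels(n)
    series[[s]] <- X
  }

  # structural features: biological mean + site location + site scale * noise
  bio_mean <- matrix(0, S, spec$n_struct_features)
  blocks <- character_partition(spec$n_struct_features, spec$n_characters)
  for (ch in spec$informative_characters) {
    bio_mean[labels == 1L, blocks[[ch]]] <- spec$struct_effect
  }
  noise <- matrix(stats::rnorm(S * spec$n_struct_features), S)
  struct <- bio_mean + site_feat_shift[sites, ] + site_feat_scale[sites, ] * noise
  colnames(struct) <- unlist(lapply(names(blocks), function(nm)
    paste0(nm, "_f", seq_along(blocks[[nm]]))))

  age <- pmin(pmax(stats::rnorm(S, 34, 11), 18), 70)
  sex <- stats::rbinom(S, 1L, 0.6)
  education <- stats::rnorm(S, 13, 3) - ifelse(labels == 1L, spec$demo_effect * 3, 0)

  demographics <- tibble::tibble(
    subject = sprintf("S%04d", seq_len(S)),
    age = age, sex = sex, education = education, site = sites
  )
  structure(list(
    series = series,
    struct_features = struct,
    demographics = demographics,
    labels = labels,
    sites = sites,
    truth = list(spec = spec,
                 differential = planted_differential_matrix(spec),
                 informative_characters = spec$informative_characters,
                 character_blocks = blocks),
    covariances = covs
  ), class = "cohort_bundle")
}

# contiguous equal-width partition of feature indices into named blocks
character_partition <- function(n_features, n_characters) {
  w <- n_features %/% n_characters
  blocks <- lapply(seq_len(n_characters), function(i) ((i - 1L) * w + 1L):(i * w))
  names(blocks) <- paste0("char_", seq_len(n_characters))
  blocks
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  sp <- x$truth$spec
  cat("<cohort_bundle> ", sp$n_subjects, " subjects, ", sp$n_rois, " ROIs x ",
      sp$n_timepoints, " timepoints, ", sp$n_sites, " sites\n", sep = "")
  cat("  cases: ", sum(x$labels), ", controls: ", sum(x$labels == 0L), "\n", sep = "")
  cat("  planted: ", length(sp$enhanced_edges), " enhanced / ",
      length(sp$diminished_edges), " diminished edges (effect ", sp$edge_effect,
      "), ", length(sp$informative_characters), " informative characters (effect ",
      sp$struct_effect, ")\n", sep = "")
  invisible(x)
}

#' Persist / restore a cohort bundle
#'
#' Writes arrays to a compressed RDS archive plus a JSON sidecar with the
#' spec, ground truth and demographics, and a CSV of the demographics table.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return `save_cohort` returns `dir` invisibly; `load_cohort` the bundle.
#' @export
save_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(bundle[c("series", "struct_features", "labels", "sites", "covariances")],
          file.path(dir, "arrays.rds"), compress = "xz")
  sp <- bundle$truth$spec
  sidecar <- list(spec = unclass(sp),
                  demographics = bundle$demographics,
                  informative_characters = bundle$truth$informative_characters)
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(bundle$demographics, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(dir) {
  arrays <- readRDS(file.path(dir, "arrays.rds"))
  sidecar <- jsonlite::read_json(file.path(dir, "cohort.json"), simplifyVector = TRUE)
  sp <- sidecar$spec
  spec <- cohort_spec(
    n_subjects = sp$n_subjects, n_rois = sp$n_rois,
    n_timepoints = sp$n_timepoints, n_sites = sp$n_sites,
    case_fraction = sp$case_fraction,
    enhanced_edges = as_roi_pairs(sp$enhanced_edges),
    diminished_edges = as_roi_pairs(sp$diminished_edges),
    edge_effect = sp$edge_effect, n_struct_features = sp$n_struct_features,
    n_characters = sp$n_characters,
    informative_characters = sp$informative_characters,
    struct_effect = sp$struct_effect, site_shift_scale = sp$site_shift_scale,
    site_scale_sd = sp$site_scale_sd, demo_effect = sp$demo_effect,
    seed = sp$seed)
  structure(list(series = arrays$series,
                 struct_features = arrays$struct_features,
                 demographics = tibble::as_tibble(sidecar$demographics),
                 labels = arrays$labels, sites = arrays$sites,
                 truth = list(spec = spec,
                              differential = planted_differential_matrix(spec),
                              informative_characters = spec$informative_characters,
                              character_blocks = character_partition(
                                spec$n_struct_features, spec$n_characters)),
                 covariances = arrays$covariances),
            class = "cohort_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_roi_pairs <- function(x) {
  if (is.null(x) || length(x) == 0L) return(list())
  if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i) as.integer(x[i, ])))
  lapply(x, as.integer)
}
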