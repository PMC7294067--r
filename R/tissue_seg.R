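#' Gaussian-mixture EM with optional per-voxel class priors
#'
#' Standard diagonal-covariance Gaussian mixture fitted by
#' expectation-maximisation. An optional per-observation prior multiplier
#' matrix reweights class memberships in the E-step (used for the
#' T2-weighted lesion class); with fixed multipliers the EM monotonicity
#' guarantee is retained. Stops when the relative log-likelihood change
#' drops below `tol` or after `max_iter` iterations. Vanishing class
#' variances are floored at `1e-4` times the channel variance and flagged.
#'
#' @param x numeric matrix (observations x channels) or vector.
#' @param K number of classes (>= 1).
#' @param init `"kmeans"` (on a subsample of up to 10^4 observations),
#'   `"quantile"` (first-channel quantile split), or `"given"` (use
#'   `init_means` / `init_weights`).
#' @param init_means,init_weights explicit initial K x C means and mixing
#'   weights for `init = "given"`.
#' @param tol relative log-likelihood tolerance.
#' @param max_iter iteration cap.
#' @param seed integer (k-means initialisation).
#' @param prior_mult optional n x K matrix of non-negative prior multipliers.
#' @return a `mixture_model`: `means` (K x C), `vars` (K x C), `weights`,
#'   `loglik` trace, `converged`, `floored`, and `posterior` (n x K).
#' @export
fit_em_mixture <- function(x, K, init = c("kmeans", "quantile", "given"),
                           tol = 1e-6, max_iter = 100, seed = 1L,
                           prior_mult = NULL, init_means = NULL,
                           init_weights = NULL) {
  init <- match.arg(init)
  x <- as.matrix(x)
  n <- nrow(x); C <- ncol(x)
  if (K < 1) stop("K must be >= 1")
  if (K >= 2 && n < 10 * K) stop("need at least 10*K observations")
  set.seed(as.integer(seed))
  if (init == "given") {
    means <- matrix(init_means, K, C)
  } else if (init == "kmeans" && K > 1) {
    sub <- if (n > 10000) x[sample.int(n, 10000), , drop = FALSE] else x
    km <- stats::kmeans(sub, centers = K, nstart = 3, iter.max = 50)
    means <- km$centers[order(km$centers[, 1]), , drop = FALSE]
  } else {
    probs <- (seq_len(K) - 0.5) / K
    means <- sapply(seq_len(C), function(j) stats::quantile(x[, j], probs, names = FALSE))
    means <- matrix(means, nrow = K)
  }
  vars <- matrix(rep(apply(x, 2, stats::var) / K + 1e-8, each = K), K, C)
  weights <- if (!is.null(init_weights)) init_weights / sum(init_weights)
             else rep(1 / K, K)
  data_var <- apply(x, 2, stats::var) + 1e-12
  floor_var <- 1e-4 * data_var
  if (!is.null(prior_mult)) {
    prior_mult <- as.matrix(prior_mult)
    stopifnot(nrow(prior_mult) == n, ncol(prior_mult) == K, all(prior_mult >= 0))
  }
  loglik <- numeric(0)
  converged <- FALSE
  floored <- rep(FALSE, K)
  post <- NULL
  for (it in seq_len(max_iter)) {
    # E-step in log space
    logp <- matrix(0, n, K)
    for (k in seq_len(K)) {
      lk <- log(weights[k])
      for (j in seq_len(C))
        lk <- lk - 0.5 * log(2 * pi * vars[k, j]) -
          (x[, j] - means[k, j])^2 / (2 * vars[k, j])
      logp[, k] <- lk
    }
    if (!is.null(prior_mult)) logp <- logp + log(prior_mult + 1e-300)
    m <- apply(logp, 1, max)
    pe <- exp(logp - m)
    se <- rowSums(pe)
    loglik <- c(loglik, sum(m + log(se)))
    post <- pe / se
    if (it > 1) {
      rel <- abs(loglik[it] - loglik[it - 1]) /
        (abs(loglik[it - 1]) + .Machine$double.eps)
      if (rel < tol) { converged <- TRUE; break }
    }
    # M-step
    nk <- colSums(post) + 1e-12
    weights <- nk / n
    for (k in seq_len(K)) {
      for (j in seq_len(C)) {
        means[k, j] <- sum(post[, k] * x[, j]) / nk[k]
        v <- sum(post[, k] * (x[, j] - means[k, j])^2) / nk[k]
        if (v < floor_var[j]) { v <- floor_var[j]; floored[k] <- TRUE }
        vars[k, j] <- v
      }
    }
  }
  structure(list(means = means, vars = vars, weights = weights,
                 loglik = loglik, converged = converged, floored = floored,
                 posterior = post),
            class = "mixture_model")
}

#' EM tissue segmentation with a T2-weighted lesion class
#'
#' Without a T2 channel: 3-class (CSF/GM/WM) EM on the T1 intensities inside
#' the brain mask. With a T2 channel: 4-class EM on the (T1, T2) pair where
#' the lesion class's per-voxel prior is multiplied by
#' `2 * plogis(lesion_weighting * (z - 2))`, `z` the voxel's within-brain T2
#' z-score, then renormalised - lesions appear hyperintense on T2, so high-z
#' voxels are pushed towards the lesion class. The multiplier equals 1
#' everywhere when `lesion_weighting = 0` (no T2 influence). Classes are
#' identified after fitting: CSF has the lowest T1 mean; with T2, the lesion
#' class has the highest T2 mean among the rest; GM/WM follow by T1 mean.
#' Hard labels are assigned by maximum posterior.
#'
#' @param t1 `vol3d` T1 image.
#' @param brain_mask logical array.
#' @param t2 optional co-registered `vol3d` T2 image (`NULL` if absent).
#' @param lesion_weighting logistic slope of the T2 lesion prior.
#' @param seed integer.
#' @return a `tissue_segmentation`: `posteriors` (named list of arrays over
#'   `csf, gm, wm[, lesion]`), `labels` (integer array: 1 CSF, 2 GM, 3 WM,
#'   4 lesion, 0 outside mask), `lesion_mask` (empty when `t2` is `NULL`),
#'   `ventricles` (filled by [extract_ventricles()]), `model`, `spacing`.
#' @export
segment_tissues <- function(t1, brain_mask, t2 = NULL, lesion_weighting = 4,
                            seed = 1L) {
  sp <- vspacing(t1)
  if (!any(brain_mask)) stop("brain mask is empty")
  idx <- which(brain_mask)
  has_t2 <- !is.null(t2)
  if (has_t2) {
    x <- cbind(as_arr(t1)[idx], as_arr(t2)[idx])
    z2 <- (x[, 2] - mean(x[, 2])) / stats::sd(x[, 2])
    mult <- matrix(1, length(idx), 4)
    mult[, 4] <- 2 * stats::plogis(lesion_weighting * (z2 - 2))
    # initialise the three tissue classes by k-means and the lesion class
    # between GM and WM on T1 but hyperintense on T2
    set.seed(as.integer(seed))
    sub <- if (nrow(x) > 10000) x[sample.int(nrow(x), 10000), ] else x
    km <- stats::kmeans(sub, centers = 3, nstart = 3, iter.max = 50)
    cen <- km$centers[order(km$centers[, 1]), ]
    hot <- z2 > 2 & x[, 1] > mean(cen[1:2, 1])
    les0 <- if (any(hot)) colMeans(x[hot, , drop = FALSE])
            else c(mean(cen[2:3, 1]), max(x[, 2]))
    fit <- fit_em_mixture(x, K = 4, init = "given", seed = seed,
                          prior_mult = mult, init_means = rbind(cen, les0),
                          init_weights = c(km$size / sum(km$size) * 0.95, 0.05))
    # identify classes among those that survived: CSF = lowest T1 mean,
    # lesion = highest T2 mean of the rest, then GM < WM on T1
    alive <- which(fit$weights > 1e-3)
    if (length(alive) < 4) alive <- union(alive, 4L)
    csf_k <- alive[which.min(fit$means[alive, 1])]
    rest <- setdiff(alive, csf_k)
    les_k <- rest[which.max(fit$means[rest, 2])]
    gw <- setdiff(seq_len(4), c(csf_k, les_k))
    gm_k <- gw[which.min(fit$means[gw, 1])]
    wm_k <- gw[which.max(fit$means[gw, 1])]
    class_idx <- c(csf = csf_k, gm = gm_k, wm = wm_k, lesion = les_k)
  } else {
    x <- matrix(as_arr(t1)[idx], ncol = 1)
    fit <- fit_em_mixture(x, K = 3, seed = seed)
    ord_t1 <- order(fit$means[, 1])
    class_idx <- c(csf = ord_t1[1], gm = ord_t1[2], wm = ord_t1[3])
  }
  dimv <- dim(as_arr(t1))
  posteriors <- lapply(class_idx, function(k) {
    p <- array(0, dimv)
    p[idx] <- fit$posterior[, k]
    p
  })
  names(posteriors) <- names(class_idx)
  hard <- max.col(fit$posterior[, class_idx, drop = FALSE], ties.method = "first")
  labels <- array(0L, dimv)
  labels[idx] <- hard
  lesion_mask <- if (has_t2) labels == 4L else array(FALSE, dimv)
  structure(list(posteriors = posteriors, labels = labels,
                 lesion_mask = lesion_mask,
                 ventricles = list(left = NULL, right = NULL),
                 model = fit, spacing = sp, has_t2 = has_t2),
            class = "tissue_segmentation")
}

#' Extract lateral ventricles from the CSF segmentation
#'
#' CSF-labelled 26-connected components overlapping the (dilated)
#' side-specific atlas ventricle priors are assigned to that side; a
#' component overlapping both priors is split by the mid-sagittal plane.
#' The lesion mask is kept disjoint from the ventricle masks.
#'
#' @param seg a `tissue_segmentation` in atlas space.
#' @param atlas_ventricle_prior list with logical `left` and `right` atlas
#'   ventricle masks.
#' @param dilate_mm prior dilation radius (mm).
#' @return `seg` with `ventricles$left/right` filled and a logical
#'   `ventricles_flagged` if no CSF component overlapped either prior.
#' @export
extract_ventricles <- function(seg, atlas_ventricle_prior, dilate_mm = 6) {
  sp <- seg$spacing
  csf <- seg$labels == 1L
  dimv <- dim(csf)
  priors <- lapply(atlas_ventricle_prior[c("left", "right")], function(m)
    dilate_mask(m, dilate_mm, sp))
  comp <- label_components(csf, 26)
  left <- array(FALSE, dimv); right <- array(FALSE, dimv)
  found <- FALSE
  hemi_l <- hemisphere_mask(dimv, sp, "left")
  for (cc in seq_len(max(comp))) {
    cm <- comp == cc
    ol <- sum(cm & priors$left); or <- sum(cm & priors$right)
    if (ol == 0 && or == 0) next
    found <- TRUE
    if (ol > 0 && or > 0) {
      left <- left | (cm & hemi_l)
      right <- right | (cm & !hemi_l)
    } else if (ol > 0) left <- left | cm else right <- right | cm
  }
  seg$ventricles <- list(left = left, right = right)
  seg$ventricles_flagged <- !found
  seg$lesion_mask <- seg$lesion_mask & !left & !right
  seg
}

#' Structure volume table
#'
#' Volumes in ml (voxel count x voxel volume / 1000), raw and as a fraction
#' of intracranial volume (the brain-mask volume). One row per tissue class,
#' per ventricle side, per propagated structure per side, and per corpus
#' callosum segment. Absent label codes yield volume 0 with a flag.
#'
#' @param seg a `tissue_segmentation` (after [extract_ventricles()]).
#' @param structure_labels integer label volume from [finalize_labels()]
#'   (atlas codes), or `NULL`.
#' @param brain_mask logical array defining intracranial volume.
#' @param subject_id identifier copied into the table.
#' @return data.frame with columns `subject_id, structure, side, volume_ml,
#'   icv_fraction, flagged`.
#' @export
compute_volumes <- function(seg, structure_labels = NULL, brain_mask,
                            subject_id = "subject") {
  sp <- seg$spacing
  vox_ml <- prod(sp) / 1000
  icv <- sum(brain_mask) * vox_ml
  rows <- list()
  add <- function(structure, side, nvox, flagged = FALSE) {
    rows[[length(rows) + 1]] <<- data.frame(
      subject_id = subject_id, structure = structure, side = side,
      volume_ml = nvox * vox_ml,
      icv_fraction = if (icv > 0) nvox * vox_ml / icv else NA_real_,
      flagged = flagged, stringsAsFactors = FALSE)
  }
  hemi_l <- hemisphere_mask(dim(seg$labels), sp, "left")
  tiss <- c(csf = 1L, gm = 2L, wm = 3L)
  for (nm in names(tiss)) {
    m <- seg$labels == tiss[[nm]]
    add(nm, "left", sum(m & hemi_l))
    add(nm, "right", sum(m & !hemi_l))
  }
  if (seg$has_t2) {
    add("lesion", "left", sum(seg$lesion_mask & hemi_l))
    add("lesion", "right", sum(seg$lesion_mask & !hemi_l))
  } else {
    add("lesion", "left", NA_integer_, flagged = TRUE)
    add("lesion", "right", NA_integer_, flagged = TRUE)
  }
  for (side in c("left", "right")) {
    vm <- seg$ventricles[[side]]
    add("ventricle", side, if (is.null(vm)) NA_integer_ else sum(vm),
        flagged = is.null(vm))
  }
  if (!is.null(structure_labels)) {
    per_side <- c("caudate", "lenticular", "thalamus", "alic", "plic")
    for (nm in per_side) {
      for (side in c("left", "right")) {
        code <- PHANTOM_LABELS[[paste0(nm, "_", side)]]
        nv <- sum(structure_labels == code)
        add(nm, side, nv, flagged = nv == 0)
      }
    }
    for (nm in c("cc_genu", "cc_body", "cc_splenium")) {
      nv <- sum(structure_labels == PHANTOM_LABELS[[nm]])
      add(nm, "mid", nv, flagged = nv == 0)
    }
  }
  do.call(rbind, rows)
}
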