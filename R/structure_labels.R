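#' Patch-search parameters
#'
#' @param patch_size odd patch edge length in voxels (default 15, i.e.
#'   15 x 15 x 15 patches).
#' @param search_radius maximum displacement per axis in voxels (default 6).
#' @param stride spacing of the patch-centre grid in voxels (default 3;
#'   stride 1 is dense).
#' @param probability_threshold threshold on the normalised probabilistic
#'   map for the final segmentation.
#' @return a `patch_search_params` list.
#' @export
patch_search_params <- function(patch_size = 15, search_radius = 6, stride = 3,
                                probability_threshold = 0.5) {
  if (patch_size %% 2 != 1) stop("patch_size must be odd")
  if (search_radius < 0) stop("search_radius must be >= 0")
  if (stride < 1) stop("stride must be >= 1")
  if (probability_threshold <= 0 || probability_threshold > 1)
    stop("probability_threshold must be in (0, 1]")
  structure(list(patch_size = as.integer(patch_size),
                 search_radius = as.integer(search_radius),
                 stride = as.integer(stride),
                 probability_threshold = probability_threshold),
            class = "patch_search_params")
}

# displacement visit order shared by implementation and reference: increasing
# squared norm, then lexicographic on (dx, dy, dz)
displacement_order <- function(radius) {
  d <- expand.grid(dx = -radius:radius, dy = -radius:radius, dz = -radius:radius)
  d <- d[order(d$dx^2 + d$dy^2 + d$dz^2, d$dx, d$dy, d$dz), ]
  rownames(d) <- NULL
  d
}

# Chebyshev (box) dilation by `half` voxels, zero-padded
cheb_dilate <- function(mask, half) {
  out <- mask
  for (axis in 1:3) {
    acc <- out
    for (t in seq_len(half)) {
      acc <- acc | shift_axis(out, t, axis, pad = "zero", fill = FALSE) |
        shift_axis(out, -t, axis, pad = "zero", fill = FALSE)
    }
    out <- acc
  }
  out
}

structure_codes_default <- function() {
  PHANTOM_LABELS[c("caudate_left", "caudate_right", "lenticular_left",
                   "lenticular_right", "thalamus_left", "thalamus_right",
                   "alic_left", "alic_right", "plic_left", "plic_right",
                   "cc_genu", "cc_body", "cc_splenium")]
}

#' Ventricle-guided rigid alignment of atlas structure groups
#'
#' Severe tissue loss can displace the ventricles from the skull centre, so
#' deep-structure atlas labels are rigidly aligned to the *ventricles* rather
#' than the whole head: the corpus callosum group to the superior ventricle
#' surface, the deep-gray/internal-capsule group to the lateral surfaces.
#' The 6-parameter rigid transform minimises the mean distance from the
#' transformed atlas face points to the subject face points (via a distance
#' transform of the subject points), initialised at the centroid offset.
#'
#' @param atlas_labels integer atlas label `vol3d`.
#' @param subject_ventricles list with logical `left`/`right` subject
#'   ventricle masks.
#' @param structure_group `"DGM"` (lateral faces) or `"CC"` (superior face).
#' @param spacing mm per axis.
#' @return list with `matrix` (4x4 rigid, atlas world to subject world),
#'   `params`, `mean_dist_before`, `mean_dist_after`, `flagged` (TRUE with
#'   identity transform when both subject masks are empty).
#' @export
rigid_align_to_ventricles <- function(atlas_labels, subject_ventricles,
                                      structure_group = c("DGM", "CC"),
                                      spacing = vspacing(atlas_labels)) {
  structure_group <- match.arg(structure_group)
  dimv <- dim(atlas_labels)
  face_pts <- function(mask, side) {
    if (is.null(mask) || !any(mask)) return(NULL)
    if (structure_group == "CC") {
      face <- mask & !shift_axis(mask, -1, 3, pad = "zero", fill = FALSE)
    } else {
      dir <- if (side == "left") 1L else -1L  # outward lateral neighbour
      face <- mask & !shift_axis(mask, dir, 1, pad = "zero", fill = FALSE)
    }
    idx <- which(face)
    co <- coord_axes(dimv, spacing)
    ij <- arrayInd(idx, dimv)
    cbind(co[[1]][ij[, 1]], co[[2]][ij[, 2]], co[[3]][ij[, 3]])
  }
  av <- list(left = as_arr(atlas_labels) == PHANTOM_LABELS["ventricle_left"],
             right = as_arr(atlas_labels) == PHANTOM_LABELS["ventricle_right"])
  apts <- rbind(face_pts(av$left, "left"), face_pts(av$right, "right"))
  spts <- rbind(face_pts(subject_ventricles$left, "left"),
                face_pts(subject_ventricles$right, "right"))
  if (is.null(spts) || nrow(spts) == 0) {
    return(list(matrix = diag(4), params = rep(0, 6),
                mean_dist_before = NA_real_, mean_dist_after = NA_real_,
                flagged = TRUE))
  }
  smask <- subject_ventricles$left | subject_ventricles$right
  sface <- array(FALSE, dimv)
  sidx <- round(sweep(sweep(spts, 2, spacing, "/"), 2, (dimv - 1) / 2, "+")) + 1
  sface[cbind(sidx[, 1], sidx[, 2], sidx[, 3])] <- TRUE
  D <- distance_to(sface, spacing)
  W <- grid_affine(dimv, spacing)
  sample_dist <- function(pts) {
    vox <- sweep(sweep(pts, 2, W[1:3, 4], "-"), 2, spacing, "/")
    trilinear_sample(D, vox, oob = max(D[is.finite(D)]))
  }
  obj <- function(p) {
    A <- affine_from_params(c(p, rep(0, 6)))
    tp <- t(A[1:3, 1:3] %*% t(apts)) + matrix(A[1:3, 4], nrow(apts), 3, byrow = TRUE)
    mean(sample_dist(tp))
  }
  t0 <- colMeans(spts) - colMeans(apts)
  before <- obj(rep(0, 6))
  opt <- stats::optim(c(t0, 0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 800, reltol = 1e-9,
                                     parscale = c(rep(2, 3), rep(0.05, 3))))
  after <- opt$value
  p <- opt$par
  if (after > before) { p <- rep(0, 6); after <- before }
  list(matrix = affine_from_params(c(p, rep(0, 6))), params = p,
       mean_dist_before = before, mean_dist_after = after, flagged = FALSE)
}

# vectorised trilinear sampling at continuous 0-based voxel coordinates
trilinear_sample <- function(field, vox, oob = 0) {
  d <- dim(field)
  x0 <- floor(vox[, 1]); y0 <- floor(vox[, 2]); z0 <- floor(vox[, 3])
  fx <- vox[, 1] - x0; fy <- vox[, 2] - y0; fz <- vox[, 3] - z0
  ok <- x0 >= 0 & x0 + 1 <= d[1] - 1 & y0 >= 0 & y0 + 1 <= d[2] - 1 &
    z0 >= 0 & z0 + 1 <= d[3] - 1
  out <- rep(oob, nrow(vox))
  if (!any(ok)) return(out)
  b <- x0[ok] + 1 + d[1] * (y0[ok] + d[2] * z0[ok])
  dy <- d[1]; dz <- d[1] * d[2]
  fxo <- fx[ok]; fyo <- fy[ok]; fzo <- fz[ok]
  c00 <- field[b] * (1 - fxo) + field[b + 1] * fxo
  c10 <- field[b + dy] * (1 - fxo) + field[b + dy + 1] * fxo
  c01 <- field[b + dz] * (1 - fxo) + field[b + dz + 1] * fxo
  c11 <- field[b + dy + dz] * (1 - fxo) + field[b + dy + dz + 1] * fxo
  out[ok] <- (c00 * (1 - fyo) + c10 * fyo) * (1 - fzo) +
    (c01 * (1 - fyo) + c11 * fyo) * fzo
  out
}

#' CSF-masked patch-SSD label propagation
#'
#' For every stride-sampled atlas patch containing at least one voxel of a
#' structure label, the sum of squared differences against the
#' histogram-matched subject image is evaluated at every displacement within
#' the search radius. Voxel pairs where either the atlas or the (displaced)
#' subject voxel is labelled CSF are masked out of the SSD, which is
#' normalised by the number of contributing pairs - this is what makes the
#' propagation robust to periventricular tissue loss. The patch's label
#' voxels are copied to the SSD-minimising displacement (ties resolve to the
#' smallest, then lexicographically smallest, displacement); votes are
#' accumulated and divided by the per-voxel patch coverage (the maximum
#' votes a voxel could receive given the stride), clipped to `[0, 1]`.
#'
#' @param atlas_t1 `vol3d` atlas intensity image.
#' @param atlas_labels integer atlas label volume.
#' @param subject_t1 `vol3d` subject image, histogram-matched to the atlas
#'   and on the same grid.
#' @param atlas_csf,subject_csf logical CSF masks (atlas: CSF + ventricle
#'   labels; subject: the segmented CSF including ventricles).
#' @param params a [patch_search_params()].
#' @param structures integer label codes to propagate (default: deep gray,
#'   internal capsule and corpus callosum codes).
#' @return list with `maps` (named list of `[0,1]` probabilistic arrays),
#'   `displacements` (data.frame: 1-based centre indices, winning
#'   displacement, normalised SSD, pair count), `n_skipped` (patches with no
#'   unmasked pair at any displacement), `params`.
#' @export
patch_label_propagation <- function(atlas_t1, atlas_labels, subject_t1,
                                    atlas_csf, subject_csf,
                                    params = patch_search_params(),
                                    structures = structure_codes_default()) {
  dimv <- dim(as_arr(atlas_t1))
  half <- (params$patch_size - 1L) %/% 2L
  labels <- as_arr(atlas_labels)
  structures <- structures[vapply(structures, function(s) any(labels == s), logical(1))]
  if (length(structures) == 0) stop("no requested structure label present in the atlas")
  union_mask <- array(labels %in% structures, dimv)
  # ROI: structure bounding box padded by 2*half so all consumed centres have
  # complete (volume-clipped) windows
  ij <- which(union_mask, arr.ind = TRUE)
  lo <- pmax(apply(ij, 2, min) - 2L * half, 1L)
  hi <- pmin(apply(ij, 2, max) + 2L * half, dimv)
  res <- cpp_patch_ssd(as.numeric(as_arr(atlas_t1)), as.numeric(as_arr(subject_t1)),
                       as.logical(atlas_csf), as.logical(subject_csf),
                       as.integer(dimv), as.integer(lo - 1L),
                       as.integer(hi - lo + 1L), half, params$search_radius)
  m <- hi - lo + 1L
  roi_index <- function(i, j, k) (i - lo[1] + 1L) + m[1] * ((j - lo[2]) + m[2] * (k - lo[3]))

  stride_ok <- function(i) (i - 1L) %% params$stride == 0L
  # sliding (2*half+1)^3 box sum, clipped at the volume faces
  box_count <- function(a) {
    for (axis in 1:3) {
      acc <- a
      for (t in seq_len(half)) {
        acc <- acc + shift_axis(a, t, axis, pad = "zero") +
          shift_axis(a, -t, axis, pad = "zero")
      }
      a <- acc
    }
    a
  }
  shift3 <- function(a, d) {
    for (axis in 1:3) if (d[axis] != 0) a <- shift_axis(a, d[axis], axis, pad = "zero")
    a
  }
  maps <- list()
  disp_rows <- list()
  n_skipped <- 0L
  # all voting arithmetic happens on the cropped ROI block; candidate
  # centres always sit >= half voxels inside its interior faces
  rx <- lo[1]:hi[1]; ry <- lo[2]:hi[2]; rz <- lo[3]:hi[3]
  mdim <- as.integer(hi - lo + 1L)
  for (s in structures) {
    smask <- array(labels[rx, ry, rz] == s, mdim)
    cand <- cheb_dilate(smask, half)
    ci <- which(cand, arr.ind = TRUE)   # ROI-local 1-based
    keep <- stride_ok(ci[, 1] + lo[1] - 1L) & stride_ok(ci[, 2] + lo[2] - 1L) &
      stride_ok(ci[, 3] + lo[3] - 1L)
    ci <- ci[keep, , drop = FALSE]
    ridx <- ci[, 1] + mdim[1] * ((ci[, 2] - 1L) + mdim[2] * (ci[, 3] - 1L))
    ok <- !is.na(res$ssd[ridx])
    n_skipped <- n_skipped + sum(!ok)
    ci <- ci[ok, , drop = FALSE]; ridx <- ridx[ok]
    dxs <- res$dx[ridx]; dys <- res$dy[ridx]; dzs <- res$dz[ridx]
    disp_rows[[length(disp_rows) + 1]] <- data.frame(
      structure = s, cx = ci[, 1] + lo[1] - 1L, cy = ci[, 2] + lo[2] - 1L,
      cz = ci[, 3] + lo[3] - 1L, dx = dxs, dy = dys, dz = dzs,
      ssd = res$ssd[ridx], npairs = res$npairs[ridx])
    # coverage = number of centres whose window contains each voxel; votes
    # accumulated per unique winning displacement via box sums
    cind <- array(0, mdim)
    cind[ci] <- 1
    coverage <- box_count(cind)
    votes <- array(0, mdim)
    dkey <- paste(dxs, dys, dzs)
    for (key in unique(dkey)) {
      sel <- dkey == key
      d <- c(dxs[which(sel)[1]], dys[which(sel)[1]], dzs[which(sel)[1]])
      cind_d <- array(0, mdim)
      cind_d[ci[sel, , drop = FALSE]] <- 1
      votes <- votes + shift3(smask * box_count(cind_d), d)
    }
    prob_roi <- array(0, mdim)
    pos <- coverage > 0
    prob_roi[pos] <- pmin(1, votes[pos] / coverage[pos])
    prob_roi[!pos & votes > 0] <- 1
    prob <- array(0, dimv)
    prob[rx, ry, rz] <- prob_roi
    maps[[as.character(s)]] <- prob
  }
  list(maps = maps,
       displacements = if (length(disp_rows)) do.call(rbind, disp_rows) else NULL,
       n_skipped = n_skipped, params = params)
}

#' Brute-force reference for the masked patch-SSD search
#'
#' Independent exhaustive implementation used to validate
#' [patch_label_propagation()]: for each requested patch centre it extracts
#' the atlas patch directly and evaluates the normalised masked SSD at every
#' displacement by subarray indexing, with the same tie-break rule (smallest
#' squared displacement, then lexicographic). Quadratic-cost and intended
#' for small volumes only.
#'
#' @param atlas_t1,subject_t1 numeric arrays on a common grid.
#' @param atlas_csf,subject_csf logical CSF masks.
#' @param centers integer matrix (n x 3) of 1-based patch centres.
#' @param patch_size odd patch edge length.
#' @param search_radius displacement bound per axis.
#' @return data.frame with the winning `dx, dy, dz`, `ssd` and `npairs` per
#'   centre (`NA` displacement when no displacement had a valid pair).
#' @export
patch_ssd_reference <- function(atlas_t1, subject_t1, atlas_csf, subject_csf,
                                centers, patch_size = 15, search_radius = 6) {
  A <- as_arr(atlas_t1); B <- as_arr(subject_t1)
  mA <- as.logical(atlas_csf); dim(mA) <- dim(A)
  mB <- as.logical(subject_csf); dim(mB) <- dim(A)
  dimv <- dim(A)
  half <- (patch_size - 1) %/% 2
  disps <- displacement_order(search_radius)
  out <- vector("list", nrow(centers))
  for (r in seq_len(nrow(centers))) {
    cc <- centers[r, ]
    w1 <- max(1, cc[1] - half):min(dimv[1], cc[1] + half)
    w2 <- max(1, cc[2] - half):min(dimv[2], cc[2] + half)
    w3 <- max(1, cc[3] - half):min(dimv[3], cc[3] + half)
    pa <- A[w1, w2, w3]
    ma <- mA[w1, w2, w3]
    best <- Inf; bd <- c(NA, NA, NA); bn <- 0L
    for (q in seq_len(nrow(disps))) {
      d <- c(disps$dx[q], disps$dy[q], disps$dz[q])
      v1 <- w1 + d[1]; v2 <- w2 + d[2]; v3 <- w3 + d[3]
      k1 <- v1 >= 1 & v1 <= dimv[1]; k2 <- v2 >= 1 & v2 <= dimv[2]
      k3 <- v3 >= 1 & v3 <= dimv[3]
      if (!any(k1) || !any(k2) || !any(k3)) next
      pb <- B[v1[k1], v2[k2], v3[k3], drop = FALSE]
      mb <- mB[v1[k1], v2[k2], v3[k3], drop = FALSE]
      paq <- pa[k1, k2, k3, drop = FALSE]
      maq <- ma[k1, k2, k3, drop = FALSE]
      valid <- !maq & !mb
      n <- sum(valid)
      if (n == 0) next
      ssd <- sum(((paq - pb)[valid])^2) / n
      if (ssd < best) { best <- ssd; bd <- d; bn <- n }
    }
    out[[r]] <- data.frame(cx = cc[1], cy = cc[2], cz = cc[3], dx = bd[1],
                           dy = bd[2], dz = bd[3],
                           ssd = if (is.finite(best)) best else NA_real_,
                           npairs = bn)
  }
  do.call(rbind, out)
}

#' Finalise propagated structure labels
#'
#' Thresholds each probabilistic map, keeps the largest 26-connected
#' component per structure, removes lesion voxels, and resolves overlapping
#' claims by the higher probability (ties to the lower label code).
#'
#' @param prob_maps named list of `[0,1]` arrays from
#'   [patch_label_propagation()] (names are label codes).
#' @param params a [patch_search_params()] (supplies the threshold).
#' @param lesion_mask logical array of lesion voxels to exclude (or `NULL`).
#' @return integer label volume; attribute `flagged_empty` names structures
#'   with no surviving voxel.
#' @export
finalize_labels <- function(prob_maps, params = patch_search_params(),
                            lesion_mask = NULL) {
  codes <- sort(as.integer(names(prob_maps)))
  dimv <- dim(prob_maps[[1]])
  labels <- array(0L, dimv)
  bestp <- array(0, dimv)
  empty <- character(0)
  for (code in codes) {
    p <- prob_maps[[as.character(code)]]
    m <- p >= params$probability_threshold
    if (!is.null(lesion_mask)) m <- m & !lesion_mask
    if (any(m)) m <- largest_component(m, 26)
    if (!any(m)) { empty <- c(empty, as.character(code)); next }
    sel <- m & (p > bestp)
    labels[sel] <- code
    bestp[sel] <- p[sel]
  }
  attr(labels, "flagged_empty") <- empty
  labels
}

#' Geodesic propagation of cortical parcel labels
#'
#' Every GM voxel receives the parcel label of the nearest atlas-parcel
#' voxel by Euclidean distance, with no distance cap, so labels reach even
#' severely deformed or atrophied cortex. Equidistant ties resolve to the
#' lower label code.
#'
#' @param gm_mask logical cortical GM mask.
#' @param atlas_parcels integer atlas parcel volume (codes > 0).
#' @param spacing mm per axis.
#' @return integer parcellation labelling every GM voxel.
#' @export
propagate_cortical_labels <- function(gm_mask, atlas_parcels,
                                      spacing = vspacing(atlas_parcels)) {
  if (!any(gm_mask)) stop("gm_mask is empty")
  codes <- sort(unique(as.integer(atlas_parcels[atlas_parcels > 0])))
  if (length(codes) == 0) stop("atlas parcels are empty")
  dimv <- dim(gm_mask)
  out <- array(0L, dimv)
  best <- array(Inf, dimv)
  for (code in codes) {
    d <- distance_to(as_arr(atlas_parcels) == code, spacing)
    sel <- gm_mask & d < best
    out[sel] <- code
    best[sel] <- d[sel]
  }
  out
}
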