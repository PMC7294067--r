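#' Label codes of the synthetic brain phantom
#'
#' One integer code per structure. Cortical gray matter carries parcel codes
#' `100 + p` (left) and `200 + p` (right), `p = 1..8`, instead of a single GM
#' code, so that regional summaries have ground truth. The `lesion` code is a
#' ground-truth label distinct from the rendered tissue classes so that lesion
#' segmentation accuracy is scoreable.
#' @export
PHANTOM_LABELS <- c(
  background = 0L, wm = 1L, csf = 3L,
  ventricle_left = 4L, ventricle_right = 5L,
  caudate_left = 6L, caudate_right = 7L,
  lenticular_left = 8L, lenticular_right = 9L,
  thalamus_left = 10L, thalamus_right = 11L,
  alic_left = 12L, alic_right = 13L,
  plic_left = 14L, plic_right = 15L,
  cc_genu = 16L, cc_body = 17L, cc_splenium = 18L,
  lesion = 19L
)

#' Cortical parcel codes
#' @param side `"left"` or `"right"`.
#' @return integer vector of the 8 parcel codes for that hemisphere.
#' @export
parcel_codes <- function(side = c("left", "right")) {
  side <- match.arg(side)
  (if (side == "left") 100L else 200L) + 1:8
}

# map label codes to tissue classes: 0 bg, 1 wm, 2 gm, 3 csf, 4 lesion
TISSUE_CODES <- c(background = 0L, wm = 1L, gm = 2L, csf = 3L, lesion = 4L)

#' Tissue class of each phantom label
#' @param labels integer label array.
#' @return integer array of tissue codes (0 background, 1 WM, 2 GM, 3 CSF,
#'   4 lesion); deep gray structures count as GM, internal capsule and corpus
#'   callosum as WM, ventricles as CSF.
#' @export
label_tissue <- function(labels) {
  lut <- integer(300)
  lut[1 + c(1L, 12:18)] <- 1L                      # wm + IC + CC
  lut[1 + c(6:11, 101:108, 201:208)] <- 2L          # DGM + cortical parcels
  lut[1 + c(3L, 4L, 5L)] <- 3L                      # csf + ventricles
  lut[1 + 19L] <- 4L                                # lesion
  out <- lut[as.integer(labels) + 1L]
  dim(out) <- dim(labels)
  out
}

# canonical layout in normalised units (coordinate / half field of view per
# axis); right-hemisphere centres listed, left mirrored in x. Chosen so all
# structures sit strictly inside the WM compartment at any grid >= 48^3.
phantom_geometry <- function(dim, spacing) {
  half_fov <- dim * spacing / 2
  list(
    half_fov = half_fov,
    brain_semi = c(0.78, 0.88, 0.78),
    csf_rim_u = 0.05,
    gm_shell_u = 0.09,
    gm_thickness_mm = 0.09 * mean(half_fov),
    ellipsoids = list(
      ventricle = list(ctr = c(0.1875, 0, 0.0625), semi = c(0.09375, 0.25, 0.09375)),
      thalamus = list(ctr = c(0.234, -0.219, -0.0625), semi = c(0.078, 0.100, 0.078)),
      caudate = list(ctr = c(0.328, 0.140, 0.094), semi = c(0.055, 0.094, 0.055)),
      lenticular = list(ctr = c(0.420, -0.030, -0.015), semi = c(0.0625, 0.110, 0.078))
    ),
    boxes = list(
      alic = list(x = c(0.320, 0.430), y = c(-0.010, 0.160), z = c(-0.040, 0.110)),
      plic = list(x = c(0.290, 0.395), y = c(-0.215, -0.065), z = c(-0.120, 0.020))
    ),
    cc = list(xmax = 0.20, y = c(-0.375, 0.375), z = c(0.20, 0.27), split = 0.125)
  )
}

ellipsoid_mask <- function(U, ctr, semi) {
  ((U$x - ctr[1]) / semi[1])^2 + ((U$y - ctr[2]) / semi[2])^2 +
    ((U$z - ctr[3]) / semi[3])^2 <= 1
}

box_mask <- function(U, xr, yr, zr) {
  U$x >= xr[1] & U$x <= xr[2] & U$y >= yr[1] & U$y <= yr[2] &
    U$z >= zr[1] & U$z <= zr[2]
}

#' Synthetic atlas phantom
#'
#' Builds the uninjured canonical phantom: a three-compartment brain
#' (WM / cortical GM shell divided into 8 parcels per hemisphere / outer CSF
#' rim) hosting left and right lateral ventricles, caudate, lenticular
#' nucleus, thalamus (ellipsoids), anterior and posterior internal-capsule
#' limbs (boxes carved from WM), and a corpus callosum sheet superior to the
#' ventricles split into genu, body and splenium. Structures are geometric
#' primitives in a fixed layout scaled to the field of view, so every
#' downstream measure has analytic ground truth. The uninjured atlas is
#' mirror-symmetric about the mid-sagittal plane.
#'
#' @param grid_shape integer length-3, >= 48 voxels per axis.
#' @param spacing mm per axis.
#' @param seed integer; stored on the phantom (the atlas itself is
#'   deterministic).
#' @return a `labeled_phantom`: list with `labels` (integer `vol3d`),
#'   `spacing`, `injury` (an identity [injury_spec()]), `seed`, `geometry`.
#' @export
make_atlas_phantom <- function(grid_shape = c(64, 64, 64), spacing = c(2, 2, 2),
                               seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(if (length(spacing) == 1) rep(spacing, 3) else spacing)
  if (any(grid_shape < 48))
    stop("each grid axis must be >= 48 voxels to host all structures")
  geo <- phantom_geometry(grid_shape, spacing)
  co <- coord_arrays(grid_shape, spacing)
  U <- list(x = co$x / geo$half_fov[1], y = co$y / geo$half_fov[2],
            z = co$z / geo$half_fov[3])

  labels <- array(0L, grid_shape)
  brain <- ellipsoid_mask(U, c(0, 0, 0), geo$brain_semi)
  gm_outer <- ellipsoid_mask(U, c(0, 0, 0), geo$brain_semi - geo$csf_rim_u)
  wm_outer <- ellipsoid_mask(U, c(0, 0, 0), geo$brain_semi - geo$csf_rim_u - geo$gm_shell_u)
  labels[brain] <- PHANTOM_LABELS["csf"]
  # cortical parcels: hemisphere by sign(x), 8 angular sectors in (y, z)
  theta <- atan2(U$z, U$y)
  bin <- pmin(8L, pmax(1L, 1L + as.integer(floor((theta + pi) / (pi / 4)))))
  gm <- gm_outer & !wm_outer
  side_code <- ifelse(U$x > 0, 200L, 100L)
  labels[gm] <- side_code[gm] + bin[gm]
  labels[wm_outer] <- PHANTOM_LABELS["wm"]

  place_ellipsoid <- function(labels, name, ctr, semi, code) {
    m <- ellipsoid_mask(U, ctr, semi)
    if (!any(m))
      stop(sprintf("grid too small to host structure '%s'", name))
    if (any(labels[m] != PHANTOM_LABELS["wm"]))
      stop(sprintf("structure '%s' does not fit inside white matter at this grid size", name))
    labels[m] <- code
    labels
  }
  for (side in c("left", "right")) {
    sgn <- if (side == "left") -1 else 1
    for (nm in names(geo$ellipsoids)) {
      e <- geo$ellipsoids[[nm]]
      code <- PHANTOM_LABELS[[paste0(if (nm == "ventricle") "ventricle" else nm, "_", side)]]
      labels <- place_ellipsoid(labels, paste0(nm, "_", side),
                                e$ctr * c(sgn, 1, 1), e$semi, code)
    }
  }
  # corpus callosum sheet (midline, superior to the ventricles), then the
  # internal-capsule boxes; both are clipped to remaining WM
  cc <- geo$cc
  ccm <- abs(U$x) <= cc$xmax & U$y >= cc$y[1] & U$y <= cc$y[2] &
    U$z >= cc$z[1] & U$z <= cc$z[2] & labels == PHANTOM_LABELS["wm"]
  labels[ccm & U$y > cc$split] <- PHANTOM_LABELS["cc_genu"]
  labels[ccm & abs(U$y) <= cc$split] <- PHANTOM_LABELS["cc_body"]
  labels[ccm & U$y < -cc$split] <- PHANTOM_LABELS["cc_splenium"]
  for (side in c("left", "right")) {
    sgn <- if (side == "left") -1 else 1
    for (nm in names(geo$boxes)) {
      b <- geo$boxes[[nm]]
      xr <- sort(sgn * b$x)
      m <- box_mask(U, xr, b$y, b$z) & labels == PHANTOM_LABELS["wm"]
      if (!any(m))
        stop(sprintf("grid too small to host structure '%s_%s'", nm, side))
      labels[m] <- PHANTOM_LABELS[[paste0(nm, "_", side)]]
    }
  }
  expected <- setdiff(names(PHANTOM_LABELS), c("background", "lesion"))
  for (nm in expected) {
    if (!any(labels == PHANTOM_LABELS[[nm]]))
      stop(sprintf("grid too small to host structure '%s'", nm))
  }
  for (code in c(parcel_codes("left"), parcel_codes("right"))) {
    if (!any(labels == code))
      stop(sprintf("grid too small to host cortical parcel %d", code))
  }
  structure(list(labels = vol3d(labels, spacing), spacing = spacing,
                 injury = injury_spec("none"), seed = as.integer(seed),
                 geometry = geo),
            class = "labeled_phantom")
}

#' @export
print.labeled_phantom <- function(x, ...) {
  cat(sprintf("<labeled_phantom> %s voxels @ %s mm, laterality '%s', severity %.2f\n",
              paste(dim(x$labels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              x$injury$laterality, x$injury$severity))
  invisible(x)
}

#' Injury specification
#'
#' Describes the injury planted in a phantom: per-side ventricular dilation
#' (a volume ratio >= 1), periventricular lesion count and radius, and
#' cortical atrophy (fraction of cortical thickness removed). `laterality`
#' `"none"` forces all factors to identity; `"unilateral"` applies the
#' non-identity factors to `affected_side` (the brain side) only.
#'
#' @param laterality `"none"`, `"unilateral"` or `"bilateral"`.
#' @param affected_side brain hemisphere carrying the injury when unilateral.
#' @param ventricle_dilation volume ratio >= 1; scalar, or length-2
#'   `(left, right)` for bilateral injury.
#' @param lesion_count integer >= 0 per side (scalar or length 2).
#' @param lesion_radius_mm lesion sphere radius, mm.
#' @param cortical_atrophy fraction in `[0, 1)` per side (scalar or length 2).
#' @return an `injury_spec` with per-side vectors and a scalar `severity`
#'   summary.
#' @export
injury_spec <- function(laterality = c("none", "unilateral", "bilateral"),
                        affected_side = c("left", "right"),
                        ventricle_dilation = 1, lesion_count = 0L,
                        lesion_radius_mm = 5, cortical_atrophy = 0) {
  laterality <- match.arg(laterality)
  affected_side <- match.arg(affected_side)
  two <- function(v) {
    v <- if (length(v) == 1) c(left = v, right = v) else c(left = v[1], right = v[2])
    v
  }
  dil <- two(as.numeric(ventricle_dilation))
  les <- two(as.integer(lesion_count))
  atr <- two(as.numeric(cortical_atrophy))
  if (any(dil < 1)) stop("ventricle_dilation must be >= 1")
  if (any(les < 0)) stop("lesion_count must be >= 0")
  if (any(atr < 0 | atr >= 1)) stop("cortical_atrophy must be in [0, 1)")
  if (lesion_radius_mm <= 0) stop("lesion_radius_mm must be positive")
  if (laterality == "none") {
    dil[] <- 1; les[] <- 0L; atr[] <- 0
  } else if (laterality == "unilateral") {
    other <- setdiff(c("left", "right"), affected_side)
    dil[other] <- 1; les[other] <- 0L; atr[other] <- 0
    if (dil[affected_side] == 1 && les[affected_side] == 0 && atr[affected_side] == 0)
      stop("unilateral injury requires a non-identity factor on the affected side")
  } else {
    if (all(dil == 1) && all(les == 0) && all(atr == 0))
      stop("bilateral injury requires at least one non-identity factor")
  }
  severity <- sum(dil - 1) + 0.05 * sum(les) + sum(atr)
  structure(list(laterality = laterality, affected_side = affected_side,
                 ventricle_dilation = dil, lesion_count = les,
                 lesion_radius_mm = lesion_radius_mm,
                 cortical_atrophy = atr, severity = severity),
            class = "injury_spec")
}

hemisphere_mask <- function(dim, spacing, side) {
  co <- coord_arrays(dim, spacing)
  if (side == "left") co$x <= 0 else co$x > 0
}

# grow one lateral ventricle to `factor` times its volume by converting the
# nearest same-hemisphere WM voxels (distance-ordered, deterministic)
grow_ventricle <- function(labels, side, factor, spacing) {
  if (factor <= 1) return(labels)
  vcode <- PHANTOM_LABELS[[paste0("ventricle_", side)]]
  vm <- labels == vcode
  n0 <- sum(vm)
  need <- round((factor - 1) * n0)
  if (need == 0) return(labels)
  hemi <- hemisphere_mask(dim(labels), spacing, side)
  cand <- which(labels == PHANTOM_LABELS["wm"] & hemi)
  if (length(cand) < need)
    stop(sprintf("requested dilation %.2f of %s ventricle exceeds available white matter (would merge with background)", factor, side))
  d <- distance_to(vm, spacing)
  ord <- cand[order(d[cand], cand)]
  labels[ord[seq_len(need)]] <- vcode
  labels
}

# remove the outer `fraction` of cortical thickness on one side (GM -> CSF)
thin_cortex <- function(labels, side, fraction, spacing, gm_thickness_mm) {
  if (fraction <= 0) return(labels)
  wm_mask <- label_tissue(labels) == TISSUE_CODES["wm"]
  codes <- parcel_codes(side)
  gm_mask <- array(labels %in% codes, dim(labels))
  d <- distance_to(wm_mask, spacing)
  drop <- gm_mask & d > (1 - fraction) * gm_thickness_mm
  labels[drop] <- PHANTOM_LABELS["csf"]
  labels
}

#' Apply an injury to a phantom
#'
#' Ventricular dilation converts the nearest same-hemisphere WM voxels to
#' ventricle until the requested volume ratio is met; lesions are spheres
#' carved from periventricular WM (centres sampled 2-12 mm from the
#' ventricle) and carry the dedicated `lesion` ground-truth code; cortical
#' atrophy removes the outer fraction of the GM shell on the affected
#' side(s). With unilateral injury the other hemisphere is untouched.
#'
#' @param phantom a `labeled_phantom`.
#' @param injury an [injury_spec()].
#' @param seed integer driving lesion placement.
#' @return the injured `labeled_phantom` (injury and seed recorded).
#' @export
apply_injury <- function(phantom, injury, seed = 1L) {
  stopifnot(inherits(phantom, "labeled_phantom"), inherits(injury, "injury_spec"))
  if (injury$laterality == "none") {
    phantom$injury <- injury
    return(phantom)
  }
  labels <- as_arr(phantom$labels)
  storage.mode(labels) <- "integer"
  spacing <- phantom$spacing
  set.seed(as.integer(seed))
  for (side in c("left", "right")) {
    labels <- grow_ventricle(labels, side, injury$ventricle_dilation[[side]], spacing)
  }
  for (side in c("left", "right")) {
    nles <- injury$lesion_count[[side]]
    if (nles > 0) {
      vm <- labels == PHANTOM_LABELS[[paste0("ventricle_", side)]]
      d <- distance_to(vm, spacing)
      hemi <- hemisphere_mask(dim(labels), spacing, side)
      cand <- which(labels == PHANTOM_LABELS["wm"] & hemi & d >= 2 & d <= 12)
      if (length(cand) == 0)
        stop(sprintf("no periventricular white matter available for lesions on the %s", side))
      centres <- sample(cand, min(nles, length(cand)))
      co <- coord_arrays(dim(labels), spacing)
      for (cen in centres) {
        dist2 <- (co$x - co$x[cen])^2 + (co$y - co$y[cen])^2 + (co$z - co$z[cen])^2
        sph <- dist2 <= injury$lesion_radius_mm^2 & labels == PHANTOM_LABELS["wm"]
        labels[sph] <- PHANTOM_LABELS["lesion"]
      }
    }
  }
  for (side in c("left", "right")) {
    labels <- thin_cortex(labels, side, injury$cortical_atrophy[[side]], spacing,
                          phantom$geometry$gm_thickness_mm)
  }
  phantom$labels <- vol3d(labels, spacing)
  phantom$injury <- injury
  phantom$seed <- as.integer(seed)
  phantom
}

#' Rendering parameters
#'
#' Class mean intensities per tissue for the T1- and T2-like channels, a
#' smooth multiplicative bias field (`1 + amplitude * S` with `S` a
#' unit-normalised smoothed noise field), additive Gaussian noise, and a
#' partial-volume smoothing kernel (mm). Lesions must be hyperintense on T2
#' relative to WM.
#'
#' @param t1_means,t2_means named vectors over
#'   `background, wm, gm, csf, lesion` (arbitrary units >= 0).
#' @param bias_amplitude maximum fractional bias-field deviation.
#' @param bias_smoothness_mm correlation length of the bias field.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param pv_sigma_mm partial-volume Gaussian smoothing (0 disables).
#' @return a `render_params` list.
#' @export
render_params <- function(t1_means = c(background = 0, wm = 100, gm = 70, csf = 30, lesion = 60),
                          t2_means = c(background = 0, wm = 60, gm = 80, csf = 130, lesion = 140),
                          bias_amplitude = 0.15, bias_smoothness_mm = 40,
                          noise_sd = 3, pv_sigma_mm = 1) {
  nm <- c("background", "wm", "gm", "csf", "lesion")
  stopifnot(all(nm %in% names(t1_means)), all(nm %in% names(t2_means)))
  if (any(t1_means < 0) || any(t2_means < 0)) stop("class means must be >= 0")
  if (t2_means["lesion"] <= t2_means["wm"])
    stop("lesion T2 mean must strictly exceed WM T2 mean")
  if (bias_amplitude < 0 || noise_sd < 0 || pv_sigma_mm < 0)
    stop("bias_amplitude, noise_sd and pv_sigma_mm must be >= 0")
  structure(list(t1_means = t1_means[nm], t2_means = t2_means[nm],
                 bias_amplitude = bias_amplitude,
                 bias_smoothness_mm = bias_smoothness_mm,
                 noise_sd = noise_sd, pv_sigma_mm = pv_sigma_mm),
            class = "render_params")
}

# smooth random field scaled to max |S| = 1
smooth_unit_field <- function(dim, spacing, smoothness_mm) {
  raw <- array(stats::rnorm(prod(dim)), dim)
  s <- gauss_smooth3d(raw, smoothness_mm / spacing)
  s <- s - mean(s)
  m <- max(abs(s))
  if (m == 0) array(0, dim) else s / m
}

#' Render T1/T2 intensities from a phantom
#'
#' Maps tissue classes to their channel means, applies partial-volume
#' smoothing, a multiplicative bias field and additive Gaussian noise.
#' Deterministic given `seed`. The realised bias fields are attached as
#' attributes `bias` on each channel for validation.
#'
#' @param phantom a `labeled_phantom`.
#' @param params a [render_params()].
#' @param seed integer.
#' @return list with `t1` and `t2` (`vol3d`).
#' @export
render_intensities <- function(phantom, params = render_params(), seed = 1L) {
  stopifnot(inherits(phantom, "labeled_phantom"), inherits(params, "render_params"))
  tissue <- label_tissue(as_arr(phantom$labels))
  dimv <- dim(tissue)
  spacing <- phantom$spacing
  set.seed(as.integer(seed))
  render_channel <- function(means) {
    img <- array(means[tissue + 1L], dimv)
    if (params$pv_sigma_mm > 0)
      img <- gauss_smooth3d(img, params$pv_sigma_mm / spacing)
    if (params$bias_amplitude > 0) {
      field <- 1 + params$bias_amplitude *
        smooth_unit_field(dimv, spacing, params$bias_smoothness_mm)
      img <- img * field
    } else field <- array(1, dimv)
    if (params$noise_sd > 0)
      img <- img + array(stats::rnorm(prod(dimv), sd = params$noise_sd), dimv)
    out <- vol3d(img, spacing)
    attr(out, "bias") <- field
    out
  }
  list(t1 = render_channel(unname(params$t1_means)),
       t2 = render_channel(unname(params$t2_means)))
}

#' Cohort specification
#'
#' Group sizes, the planted linear effect of ground-truth structural features
#' on the motor outcome, laterality-specific interaction effects, outcome
#' noise, and rendering options. The outcome model is
#' `score = clamp(baseline + scale * (beta . z + gamma . z * 1[group] + eps), 0, 100)`
#' with `z` the cohort-standardised features and `eps ~ N(0, noise_sd)`.
#' Defaults mirror a motor-outcome study cohort: 44 controls, 37 unilateral
#' and 54 bilateral injuries, scores on a 0-100 scale, and roughly a quarter
#' of subjects lacking a T2 acquisition.
#'
#' @param n_tdc,n_unilateral,n_bilateral group sizes (>= 0, total > 0).
#' @param beta named vector of effects (in outcome-SD units per feature SD);
#'   names must match ground-truth feature columns such as
#'   `vol_ventricle_contra`. The defaults plant effects on the two injury
#'   axes the generator actually varies: ventricular enlargement and
#'   cortical thinning on the contralateral (injured) side.
#' @param gamma named vector of interaction effects applied only in
#'   `interaction_group`.
#' @param interaction_group group receiving `gamma` (`"bilateral"` or
#'   `"unilateral"`).
#' @param noise_sd outcome noise in standardised units.
#' @param baseline,scale map from standardised linear predictor to the score
#'   scale.
#' @param missing_t2_fraction fraction of subjects with no T2 volume.
#' @param grid,spacing phantom geometry.
#' @param render render T1/T2 volumes per subject (disable to simulate
#'   feature tables only).
#' @param seed integer.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_tdc = 44, n_unilateral = 37, n_bilateral = 54,
                        beta = c(vol_ventricle_contra = -0.8,
                                 ct_mean_contra = 0.8),
                        gamma = numeric(0),
                        interaction_group = "bilateral",
                        noise_sd = 1, baseline = 60, scale = 15,
                        missing_t2_fraction = 0.23,
                        grid = c(64, 64, 64), spacing = c(2, 2, 2),
                        render = TRUE, seed = 1L) {
  stopifnot(n_tdc >= 0, n_unilateral >= 0, n_bilateral >= 0)
  if (n_tdc + n_unilateral + n_bilateral == 0) stop("empty cohort")
  if (length(beta) && is.null(names(beta))) stop("beta must be named")
  if (length(gamma) && is.null(names(gamma))) stop("gamma must be named")
  structure(list(n_tdc = n_tdc, n_unilateral = n_unilateral,
                 n_bilateral = n_bilateral, beta = beta, gamma = gamma,
                 interaction_group = interaction_group, noise_sd = noise_sd,
                 baseline = baseline, scale = scale,
                 missing_t2_fraction = missing_t2_fraction, grid = grid,
                 spacing = spacing, render = render, seed = as.integer(seed)),
            class = "cohort_spec")
}

# ground-truth per-hemisphere features of a phantom, in ml and mm
phantom_truth_features <- function(phantom) {
  labels <- as_arr(phantom$labels)
  spacing <- phantom$spacing
  vox_ml <- prod(spacing) / 1000
  vol_of <- function(code) sum(labels == code) * vox_ml
  hemi_l <- hemisphere_mask(dim(labels), spacing, "left")
  tis <- label_tissue(labels)
  out <- c()
  for (side in c("left", "right")) {
    hm <- if (side == "left") hemi_l else !hemi_l
    sfx <- if (side == "left") "left" else "right"
    out[paste0("vol_ventricle_", sfx)] <- vol_of(PHANTOM_LABELS[[paste0("ventricle_", sfx)]])
    for (nm in c("thalamus", "caudate", "lenticular", "alic", "plic"))
      out[paste0("vol_", nm, "_", sfx)] <- vol_of(PHANTOM_LABELS[[paste0(nm, "_", sfx)]])
    out[paste0("vol_wm_", sfx)] <- sum(tis == TISSUE_CODES["wm"] & hm) * vox_ml
    out[paste0("vol_gm_", sfx)] <- sum(tis == TISSUE_CODES["gm"] & hm) * vox_ml
    out[paste0("vol_lesion_", sfx)] <- sum(labels == PHANTOM_LABELS["lesion"] & hm) * vox_ml
    # mean cortical thickness over the hemisphere's parcels
    gm_mask <- array(labels %in% parcel_codes(sfx), dim(labels))
    wm_mask <- tis == TISSUE_CODES["wm"]
    outer <- !(gm_mask | wm_mask | tis == TISSUE_CODES["gm"] | tis == TISSUE_CODES["lesion"])
    th <- distance_to(wm_mask, spacing) + distance_to(outer, spacing) - mean(spacing)
    out[paste0("ct_mean_", sfx)] <- mean(th[gm_mask])
  }
  for (nm in c("cc_genu", "cc_body", "cc_splenium"))
    out[paste0("vol_", nm)] <- vol_of(PHANTOM_LABELS[[nm]])
  out
}

# relabel left/right ground-truth features to ipsi/contra given the impaired
# body side (contralateral hemisphere = opposite the impaired hand = the
# injured hemisphere); TDC convention: ipsi = left, contra = right
relabel_ipsi_contra <- function(feats, body_side) {
  contra_hemi <- if (is.na(body_side)) "right" else if (body_side == "left") "right" else "left"
  ipsi_hemi <- setdiff(c("left", "right"), contra_hemi)
  nm <- names(feats)
  out_nm <- nm
  out_nm <- sub(paste0("_", contra_hemi, "$"), "_contra", out_nm)
  is_ipsi <- grepl(paste0("_", ipsi_hemi, "$"), nm)
  out_nm[is_ipsi] <- sub(paste0("_", ipsi_hemi, "$"), "_ipsi", nm[is_ipsi])
  names(feats) <- out_nm
  feats
}

#' Simulate a whole cohort with a planted structure-function effect
#'
#' Generates one phantom per subject (benign anatomical jitter for everyone,
#' plus group-specific injury for the unilateral and bilateral groups),
#' optionally renders T1/T2 volumes, computes ground-truth structural
#' features, and draws AHA and MUUL motor scores from the planted linear
#' model of [cohort_spec()]. Controls have no motor scores (they are not
#' assessed clinically) and a configurable fraction of subjects has no T2
#' volume. The exact features, coefficients and linear predictor used are
#' returned for recovery testing.
#'
#' @param spec a [cohort_spec()].
#' @return list with `subjects` (each: `phantom`, `t1`, `t2` or `NULL`,
#'   `clinical` row), `clinical` (data.frame), `features` (ground-truth
#'   ipsi/contra feature data.frame), and `truth` (planted-effect record).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- spec$n_tdc + spec$n_unilateral + spec$n_bilateral
  if (n_total == 0) stop("empty cohort")
  set.seed(spec$seed)
  atlas <- make_atlas_phantom(spec$grid, spec$spacing, seed = spec$seed)
  groups <- rep(c("tdc", "unilateral", "bilateral"),
                c(spec$n_tdc, spec$n_unilateral, spec$n_bilateral))
  rp <- render_params()
  subjects <- vector("list", n_total)
  clin <- vector("list", n_total)
  feat <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    g <- groups[i]
    # benign anatomical variation for everyone
    labels <- as_arr(atlas$labels)
    storage.mode(labels) <- "integer"
    for (side in c("left", "right"))
      labels <- grow_ventricle(labels, side, stats::runif(1, 1.0, 1.15), spec$spacing)
    for (side in c("left", "right"))
      labels <- thin_cortex(labels, side, stats::runif(1, 0, 0.08), spec$spacing,
                            atlas$geometry$gm_thickness_mm)
    ph <- atlas
    ph$labels <- vol3d(labels, spec$spacing)
    inj <- switch(g,
      tdc = injury_spec("none"),
      unilateral = injury_spec("unilateral",
        affected_side = sample(c("left", "right"), 1),
        ventricle_dilation = stats::runif(1, 1.3, 2.2),
        lesion_count = sample(0:3, 1),
        cortical_atrophy = stats::runif(1, 0, 0.3)),
      bilateral = injury_spec("bilateral",
        ventricle_dilation = stats::runif(2, 1.2, 2.0),
        lesion_count = sample(0:2, 2, replace = TRUE),
        cortical_atrophy = stats::runif(2, 0, 0.25)))
    subseed <- (spec$seed %% 1000000L) * 1000L + i
    ph <- apply_injury(ph, inj, seed = subseed)
    # impaired body side: opposite the (more) injured hemisphere
    body_side <- if (g == "tdc") NA_character_ else {
      per_side <- (inj$ventricle_dilation - 1) + 0.05 * inj$lesion_count + inj$cortical_atrophy
      injured <- if (g == "unilateral") inj$affected_side
                 else names(per_side)[which.max(per_side + stats::runif(2, 0, 1e-6))]
      setdiff(c("left", "right"), injured)
    }
    has_t2 <- stats::runif(1) >= spec$missing_t2_fraction
    imgs <- if (isTRUE(spec$render)) render_intensities(ph, rp, seed = subseed) else NULL
    f <- relabel_ipsi_contra(phantom_truth_features(ph), body_side)
    if (!has_t2) f[grepl("^vol_lesion_", names(f))] <- NA_real_
    # relabelling permutes the name order per subject; bind by name
    feat[[i]] <- f[sort(names(f))]
    clin[[i]] <- data.frame(
      subject_id = sprintf("S%03d", i), group = g,
      affected_side = body_side,
      age_years = round(stats::runif(1, 5, 17), 1),
      gender = sample(c("M", "F"), 1), has_t2 = has_t2,
      stringsAsFactors = FALSE)
    subjects[[i]] <- list(phantom = ph,
                          t1 = if (!is.null(imgs)) imgs$t1 else NULL,
                          t2 = if (!is.null(imgs) && has_t2) imgs$t2 else NULL,
                          clinical = clin[[i]])
  }
  clinical <- do.call(rbind, clin)
  features <- as.data.frame(do.call(rbind, feat))
  features$subject_id <- clinical$subject_id

  # planted outcome model over the CP subjects
  cp <- clinical$group != "tdc"
  zscore <- function(x) {
    s <- stats::sd(x[cp])
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x[cp])) / s
  }
  linpred <- rep(0, n_total)
  used <- union(names(spec$beta), names(spec$gamma))
  missing_feats <- setdiff(used, names(features))
  if (length(missing_feats))
    stop("unknown features in beta/gamma: ", paste(missing_feats, collapse = ", "))
  for (nm in names(spec$beta))
    linpred <- linpred + spec$beta[[nm]] * zscore(features[[nm]])
  ind <- as.numeric(clinical$group == spec$interaction_group)
  for (nm in names(spec$gamma))
    linpred <- linpred + spec$gamma[[nm]] * zscore(features[[nm]]) * ind
  draw_score <- function() {
    raw <- linpred + stats::rnorm(n_total, sd = spec$noise_sd)
    sc <- pmin(100, pmax(0, spec$baseline + spec$scale * raw))
    sc[!cp] <- NA_real_
    sc
  }
  clinical$AHA <- draw_score()
  clinical$MUUL <- draw_score()
  for (i in seq_len(n_total)) subjects[[i]]$clinical <- clinical[i, ]
  list(subjects = subjects, clinical = clinical, features = features,
       truth = list(beta = spec$beta, gamma = spec$gamma,
                    interaction_group = spec$interaction_group,
                    baseline = spec$baseline, scale = spec$scale,
                    noise_sd = spec$noise_sd, linpred = linpred,
                    seed = spec$seed))
}

#' Write a simulated cohort to disk
#'
#' Volumes as gzipped NIfTI-1 with spacing in the header, the clinical table
#' as TSV (`subject_id, group, affected_side, age_years, gender, AHA, MUUL`)
#' and the planted ground-truth effects as JSON.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    id <- s$clinical$subject_id
    write_volume_nifti(vol3d(as_arr(s$phantom$labels), s$phantom$spacing),
                       file.path(dir, paste0(id, "_labels.nii.gz")))
    if (!is.null(s$t1))
      write_volume_nifti(s$t1, file.path(dir, paste0(id, "_t1.nii.gz")))
    if (!is.null(s$t2))
      write_volume_nifti(s$t2, file.path(dir, paste0(id, "_t2.nii.gz")))
  }
  utils::write.table(
    cohort$clinical[, c("subject_id", "group", "affected_side", "age_years",
                        "gender", "AHA", "MUUL")],
    file.path(dir, "clinical.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  truth <- cohort$truth
  truth$linpred <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
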