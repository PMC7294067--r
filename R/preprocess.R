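#' Intensity normalisation: bias-field removal and histogram matching
#'
#' A smooth multiplicative bias field is estimated as a low-order polynomial
#' in the voxel coordinates fitted to the log-intensities of non-background
#' voxels and divided out (zero-mean in log space, so the global scale is
#' preserved). The corrected image is then histogram-matched to `reference`
#' by monotone quantile mapping over non-background voxels, which preserves
#' the rank order of intensities.
#'
#' @param volume `vol3d`, strictly positive over non-background voxels.
#' @param reference `vol3d` providing the target histogram, or `NULL` to
#'   apply bias correction only.
#' @param bias_order polynomial order of the log-bias field (0 disables bias
#'   correction).
#' @param mask,reference_mask optional logical masks restricting the
#'   histogram estimation and mapping (e.g. brain masks) instead of the
#'   background threshold.
#' @param background intensities `<= background` are treated as background
#'   and passed through unchanged; `NULL` (default) picks 5% of the 99th
#'   intensity percentile, which separates air (even with acquisition noise)
#'   from tissue.
#' @return normalised `vol3d`; the estimated multiplicative bias field is
#'   attached as attribute `bias`. All-constant input is returned unchanged
#'   with a warning.
#' @export
normalize_intensities <- function(volume, reference = NULL, bias_order = 2,
                                  background = NULL, mask = NULL,
                                  reference_mask = NULL) {
  sp <- vspacing(volume)
  v <- as_arr(volume)
  auto_bg <- function(x) 0.05 * stats::quantile(x, 0.99, names = FALSE)
  bg_thr <- if (is.null(background)) auto_bg(v) else background
  fg <- if (is.null(mask)) v > bg_thr else as.logical(mask)
  if (!any(fg) || stats::sd(v[fg]) == 0) {
    warning("all-constant input; returned unchanged")
    return(volume)
  }
  bias <- array(1, dim(v))
  if (bias_order > 0) {
    co <- coord_arrays(dim(v), sp)
    half_fov <- dim(v) * sp / 2
    full <- data.frame(x = co$x[fg] / half_fov[1], y = co$y[fg] / half_fov[2],
                       z = co$z[fg] / half_fov[3])
    fml <- stats::as.formula(paste(
      "l ~", paste0("poly(x,", bias_order, ",raw=TRUE) + poly(y,", bias_order,
                    ",raw=TRUE) + poly(z,", bias_order, ",raw=TRUE)",
                    if (bias_order >= 2) " + x:y + x:z + y:z" else "")))
    vc <- v
    # two rounds: estimate the field from bright (WM-like) voxels only,
    # where the true intensity is roughly constant, so anatomy does not
    # leak into the fit; re-select after the first correction
    for (round in 1:2) {
      q85 <- stats::quantile(vc[fg], 0.85, names = FALSE)
      idx <- which(fg & vc >= 0.85 * q85 & vc <= 1.15 * q85)
      if (length(idx) < 100) idx <- which(fg)
      if (length(idx) > 20000)
        idx <- idx[seq(1, length(idx), length.out = 20000)]
      df <- data.frame(l = log(vc[idx]), x = co$x[idx] / half_fov[1],
                       y = co$y[idx] / half_fov[2], z = co$z[idx] / half_fov[3])
      fit <- stats::lm(fml, data = df)
      logb <- stats::predict(fit, newdata = full)
      logb <- logb - mean(logb)
      bias[fg] <- bias[fg] * exp(logb)
      vc[fg] <- vc[fg] / exp(logb)
    }
    v <- vc
  }
  # monotone quantile mapping to the reference histogram
  if (!is.null(reference)) {
    ref <- as_arr(reference)
    rfg <- if (is.null(reference_mask))
      ref > (if (is.null(background)) auto_bg(ref) else background)
    else as.logical(reference_mask)
    probs <- seq(0, 1, length.out = 1001)
    qs <- stats::quantile(v[fg], probs, names = FALSE)
    qr <- stats::quantile(ref[rfg], probs, names = FALSE)
    keep <- !duplicated(qs)
    v[fg] <- stats::approx(qs[keep], qr[keep], xout = v[fg], rule = 2)$y
  }
  out <- vol3d(v, sp)
  attr(out, "bias") <- bias
  out
}

#' Perona-Malik anisotropic diffusion
#'
#' Explicit 3D scheme with exponential conductance
#' `g(|grad I|) = exp(-(|grad I| / kappa)^2)` evaluated on face-centred
#' differences, and zero-flux (Neumann) boundaries. The flux formulation
#' conserves the global mean to machine precision and obeys the discrete
#' maximum principle for `time_step <= 1/7`.
#'
#' @param volume `vol3d`.
#' @param iterations number of diffusion steps.
#' @param conductance edge threshold `kappa` (intensity units).
#' @param time_step explicit step size; must satisfy the 3D stability bound
#'   `time_step <= 1/7`.
#' @return diffused `vol3d`.
#' @export
anisotropic_diffusion <- function(volume, iterations = 5, conductance = 10,
                                  time_step = 1 / 7) {
  if (time_step > 1 / 7 + 1e-12)
    stop(sprintf("time_step %.4f exceeds the 3D explicit stability bound 1/7 = %.4f",
                 time_step, 1 / 7))
  if (conductance <= 0) stop("conductance must be positive")
  sp <- vspacing(volume)
  v <- as_arr(volume)
  for (it in seq_len(iterations)) {
    upd <- array(0, dim(v))
    for (axis in 1:3) {
      fwd <- shift_axis(v, -1, axis) - v   # I[i+1] - I[i]; replicated edge -> 0 flux
      g <- exp(-(fwd / conductance)^2)
      flux <- g * fwd
      # divergence of the face flux: flux_in - flux_out
      upd <- upd + flux - shift_axis(flux, 1, axis, pad = "zero")
    }
    v <- v + time_step * upd
  }
  vol3d(v, sp)
}

# 12-parameter affine (world -> world): translation, Euler rotation,
# log-scales, shears; rotation about the world origin (= volume centre)
affine_from_params <- function(p) {
  t <- p[1:3]; r <- p[4:6]; s <- exp(p[7:9]); h <- p[10:12]
  cx <- cos(r[1]); sx <- sin(r[1]); cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Sh <- rbind(c(1, h[1], h[2]), c(0, 1, h[3]), c(0, 0, 1))
  A3 <- Rz %*% Ry %*% Rx %*% Sh %*% diag(s)
  A <- diag(4)
  A[1:3, 1:3] <- A3
  A[1:3, 4] <- t
  A
}

#' Affine registration by multi-resolution mean-squares optimisation
#'
#' Estimates the 12-parameter affine transform (translation, rotation, scale,
#' shear in world coordinates) mapping `moving` onto `fixed` by minimising
#' the mean squared intensity difference over the fixed image's foreground,
#' coarse-to-fine with Nelder-Mead at each level. Because the atlas and
#' subject share a field of view, this alignment also normalises intracranial
#' volume: after alignment the brain bounding-box volume of phantom subjects
#' matches the atlas within about 10%.
#'
#' @param moving,fixed `vol3d` volumes with overlapping fields of view.
#' @param levels number of resolution levels (downsampling by 2 per level).
#' @param seed integer (controls the small deterministic parameter jitter
#'   used to escape flat starts).
#' @param background foreground threshold on the fixed image.
#' @return an `affine_transform`: list with `matrix` (4x4, moving world to
#'   fixed world), `inverse`, `params`, `converged`, and `resampled` (the
#'   moving image resampled onto the fixed grid).
#' @export
affine_register <- function(moving, fixed, levels = 3, seed = 1L,
                            background = 1) {
  set.seed(as.integer(seed))
  sp_m <- vspacing(moving); sp_f <- vspacing(fixed)
  p <- rep(0, 12)
  converged <- FALSE
  scale_p <- c(rep(5, 3), rep(0.1, 3), rep(0.05, 3), rep(0.05, 3))
  for (lev in rev(seq_len(levels))) {
    f <- 2^(lev - 1)
    mv <- downsample_block(moving, f); fx <- downsample_block(fixed, f)
    mv <- vol3d(mv, sp_m * f); fx <- vol3d(fx, sp_f * f)
    wsel <- which(as_arr(fx) > background)
    obj_sub <- function(active) {
      force(active)
      function(par_a) {
        par <- p
        par[active] <- par_a
        A <- affine_from_params(par)
        r <- resample_affine(mv, A, out_dim = dim(fx), out_spacing = vspacing(fx))
        mean((as_arr(r)[wsel] - as_arr(fx)[wsel])^2)
      }
    }
    # stage the search (rigid, then + scale, then full affine) and restart
    # Nelder-Mead from each incumbent; the staging tames the 12-D landscape
    stages <- if (lev == levels) list(1:6, 1:9, 1:12) else list(1:12, 1:12)
    for (active in stages) {
      opt <- stats::optim(p[active], obj_sub(active), method = "Nelder-Mead",
                          control = list(maxit = 400 * length(active),
                                         reltol = 1e-10,
                                         parscale = scale_p[active]))
      p[active] <- opt$par
      converged <- opt$convergence == 0
    }
  }
  A <- affine_from_params(p)
  if (det(A[1:3, 1:3]) <= 0)
    stop("registration produced a reflecting transform")
  res <- resample_affine(moving, A, out_dim = dim(fixed),
                         out_spacing = vspacing(fixed))
  structure(list(matrix = A, inverse = solve(A), params = p,
                 converged = converged, resampled = res),
            class = "affine_transform")
}

#' Skull-stripping parameters
#'
#' @param cog_sample_radius radius (mm) of the sphere around the
#'   intensity-weighted centre of gravity used to estimate the naive WM
#'   intensity.
#' @param naive_wm_percentile percentile of intensities inside that sphere
#'   taken as the naive WM intensity.
#' @param csf_fraction region growing accepts a voxel while its intensity
#'   exceeds `csf_fraction` times the naive WM intensity; growth stops at
#'   intradural CSF (default 0.25, i.e. the 25%-of-WM rule).
#' @param max_growth_iterations cap on geodesic dilation sweeps.
#' @return a `skull_strip_params` list.
#' @export
skull_strip_params <- function(cog_sample_radius = 25,
                               naive_wm_percentile = 0.8,
                               csf_fraction = 0.25,
                               max_growth_iterations = 200) {
  if (csf_fraction <= 0 && csf_fraction != 0) stop("csf_fraction must be in (0, 1)")
  if (csf_fraction >= 1 || csf_fraction < 0) stop("csf_fraction must be in [0, 1)")
  structure(list(cog_sample_radius = cog_sample_radius,
                 naive_wm_percentile = naive_wm_percentile,
                 csf_fraction = csf_fraction,
                 max_growth_iterations = max_growth_iterations),
            class = "skull_strip_params")
}

#' Injury-robust skull stripping
#'
#' (1) Finds the intensity-weighted centre of gravity; (2) estimates the
#' naive WM intensity as a percentile of intensities within
#' `cog_sample_radius` of it; (3) thresholds the image at +/-20% of that
#' intensity and keeps the largest component as a naive WM mask; (4) grows
#' the mask by iterative geodesic dilation, accepting a voxel while its
#' intensity exceeds `csf_fraction` times the naive WM intensity, until
#' convergence; the largest 26-connected accepted component, with interior
#' holes filled, is returned. Because acceptance depends only on intensity
#' relative to WM, large lesions remain inside the mask.
#'
#' @param t1 `vol3d` T1 image aligned to atlas space.
#' @param params a [skull_strip_params()].
#' @return logical brain mask (same shape as `t1`).
#' @export
strip_skull <- function(t1, params = skull_strip_params()) {
  sp <- vspacing(t1)
  v <- as_arr(t1)
  w <- pmax(v, 0)
  co <- coord_arrays(dim(v), sp)
  tot <- sum(w)
  if (tot == 0) stop("image has no positive intensities")
  cog <- c(sum(w * co$x), sum(w * co$y), sum(w * co$z)) / tot
  r2 <- (co$x - cog[1])^2 + (co$y - cog[2])^2 + (co$z - cog[3])^2
  inside <- r2 <= params$cog_sample_radius^2
  wm_int <- stats::quantile(v[inside], params$naive_wm_percentile, names = FALSE)
  naive <- abs(v - wm_int) <= 0.2 * wm_int
  if (!any(naive))
    stop("empty naive WM mask; run intensity normalization first")
  mask <- largest_component(naive, 26)
  thr <- params$csf_fraction * wm_int
  accept <- v > thr
  for (it in seq_len(params$max_growth_iterations)) {
    grown <- mask
    for (axis in 1:3) {
      grown <- grown | shift_axis(mask, 1, axis, pad = "zero") |
        shift_axis(mask, -1, axis, pad = "zero")
    }
    grown <- grown & accept
    if (identical(grown, mask)) break
    mask <- grown
  }
  fill_holes(largest_component(mask, 26))
}
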