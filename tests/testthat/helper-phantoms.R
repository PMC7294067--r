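# shared fixtures, all generated in code; heavy objects are memoised so the
# suite builds each of them once

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

atlas64 <- function() memo("atlas64", make_atlas_bundle(c(64, 64, 64), c(2, 2, 2)))
atlas48 <- function() memo("atlas48", make_atlas_bundle(c(48, 48, 48), c(2.5, 2.5, 2.5)))

# the standard injured phantom: unilateral left injury of moderate severity,
# rendered with noise sd = 10% of the WM-GM contrast (30) and the default
# partial-volume smoothing
standard_injury <- function() {
  injury_spec("unilateral", "left", ventricle_dilation = 1.8,
              lesion_count = 2, lesion_radius_mm = 5, cortical_atrophy = 0.2)
}

standard_injured_phantom <- function(seed) {
  ph <- apply_injury(make_atlas_phantom(), standard_injury(), seed = seed)
  im <- render_intensities(ph, render_params(), seed = seed)
  list(phantom = ph, t1 = im$t1, t2 = im$t2,
       tissue = label_tissue(ph$labels))
}

# quantification of the standard phantom for a given seed (memoised; used by
# several acceptance checks)
standard_quantification <- function(seed) {
  memo(paste0("quant", seed), {
    sc <- standard_injured_phantom(seed)
    q <- quantify_subject(sc$t1, sc$t2, atlas64(), seed = seed)
    list(scene = sc, q = q)
  })
}

# axis-aligned slab: WM below a GM slab of the requested thickness (1 mm iso)
slab_masks <- function(thickness_mm, dim = c(40, 40, 28)) {
  z <- array(rep(seq_len(dim[3]), each = dim[1] * dim[2]), dim)
  list(wm = z <= 8, gm = z > 8 & z <= 8 + thickness_mm, spacing = c(1, 1, 1))
}

# digitised ball of radius r_mm at 1 mm iso
sphere_mask <- function(r_mm, dim = c(56, 56, 56)) {
  co <- coord_arrays(dim, c(1, 1, 1))
  sqrt(co$x^2 + co$y^2 + co$z^2) <= r_mm
}

# random small scene for the patch-search oracle: smooth random intensities,
# one compact random structure label, sparse random CSF masks
random_patch_scene <- function(seed, n) {
  set.seed(seed)
  dimv <- rep(n, 3)
  A <- gauss_smooth3d(array(stats::rnorm(n^3, 50, 20), dimv), 1.5)
  B <- gauss_smooth3d(array(stats::rnorm(n^3, 50, 20), dimv), 1.5)
  labels <- array(0L, dimv)
  ctr <- sample(8:(n - 8), 3)
  co <- coord_arrays(dimv, c(1, 1, 1))
  ax <- coord_axes(dimv, c(1, 1, 1))
  blob <- (co$x - ax[[1]][ctr[1]])^2 + (co$y - ax[[2]][ctr[2]])^2 +
    (co$z - ax[[3]][ctr[3]])^2 <= stats::runif(1, 1.5, 2.5)^2
  labels[blob] <- 7L
  maskA <- array(stats::runif(n^3) < 0.08, dimv)
  maskB <- array(stats::runif(n^3) < 0.08, dimv)
  list(A = vol3d(A, c(1, 1, 1)), B = vol3d(B, c(1, 1, 1)), labels = labels,
       maskA = maskA, maskB = maskB)
}
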