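test_that("intensity normalisation is an identity on clean self-matched input", {
  ph <- make_atlas_phantom()
  im <- render_intensities(ph, render_params(bias_amplitude = 0, noise_sd = 0,
                                             pv_sigma_mm = 0), seed = 1)
  out <- normalize_intensities(im$t1, reference = im$t1, bias_order = 0)
  expect_lt(max(abs(as.numeric(out) - as.numeric(im$t1))), 1e-6)
  expect_warning(normalize_intensities(vol3d(array(0, c(8, 8, 8))), bias_order = 1),
                 "constant")
})

test_that("a planted smooth multiplicative bias field is recovered", {
  ph <- make_atlas_phantom()
  im <- render_intensities(ph, render_params(bias_amplitude = 0.3, noise_sd = 2,
                                             pv_sigma_mm = 0), seed = 7)
  out <- normalize_intensities(im$t1, bias_order = 2)
  fg <- label_tissue(ph$labels) != 0
  expect_gt(cor(attr(im$t1, "bias")[fg], attr(out, "bias")[fg]), 0.95)
  # rank order preserved by the matching step
  im2 <- render_intensities(ph, render_params(bias_amplitude = 0, noise_sd = 1,
                                              pv_sigma_mm = 0), seed = 8)
  matched <- normalize_intensities(im2$t1, reference = im$t1, bias_order = 0)
  sel <- which(label_tissue(ph$labels) != 0)[1:5000]
  expect_true(all(diff(as.numeric(matched)[sel][order(as.numeric(im2$t1)[sel])]) >= 0))
})

test_that("matching to a doubled reference doubles the class means", {
  ph <- make_atlas_phantom()
  im <- render_intensities(ph, render_params(bias_amplitude = 0, noise_sd = 1,
                                             pv_sigma_mm = 0), seed = 2)
  ref <- vol3d(array(as.numeric(im$t1) * 2, dim(im$t1)), vspacing(im$t1))
  out <- normalize_intensities(im$t1, reference = ref, bias_order = 0)
  tis <- label_tissue(ph$labels)
  for (k in 1:3) {
    expect_lt(abs(mean(out[tis == k]) / (2 * mean(im$t1[tis == k])) - 1), 0.05)
  }
})

test_that("anisotropic diffusion conserves mean, obeys the maximum principle and denoises", {
  # uniform image is a fixed point
  u <- vol3d(array(5, c(12, 12, 12)))
  expect_equal(as.numeric(anisotropic_diffusion(u, 10, 3)), as.numeric(u))
  # noisy piecewise-constant phantom: mean conserved, extrema bounded,
  # within-region variance strictly decreasing with iterations
  ph <- make_atlas_phantom()
  im <- render_intensities(ph, render_params(bias_amplitude = 0, noise_sd = 5,
                                             pv_sigma_mm = 0), seed = 3)
  tis <- label_tissue(ph$labels)
  vars <- sapply(0:3, function(it) {
    out <- if (it == 0) im$t1 else anisotropic_diffusion(im$t1, it, 10)
    mean(c(var(out[tis == 1]), var(out[tis == 2]), var(out[tis == 3])))
  })
  expect_true(all(diff(vars) < 0))
  out3 <- anisotropic_diffusion(im$t1, 3, 10)
  expect_lt(abs(mean(out3) - mean(im$t1)), 1e-6 * abs(mean(im$t1)))
  expect_gte(min(out3), min(im$t1))
  expect_lte(max(out3), max(im$t1))
  expect_error(anisotropic_diffusion(im$t1, 1, 10, time_step = 0.5), "1/7")
})

test_that("affine registration recovers identity and a known transform", {
  ph <- make_atlas_phantom(c(48, 48, 48), c(2.5, 2.5, 2.5))
  im <- render_intensities(ph, render_params(bias_amplitude = 0, noise_sd = 1,
                                             pv_sigma_mm = 1), seed = 2)
  # self-registration
  reg0 <- affine_register(im$t1, im$t1, levels = 2, seed = 1)
  expect_lt(max(abs(reg0$params[1:3])), 0.1 * 2.5)
  expect_lt(max(abs(exp(reg0$params[7:9]) - 1)), 0.005)
  # synthesise 10 deg / 1.1 scale / 5 mm shift, then recover
  true_p <- c(5, -3, 2, 10 * pi / 180, 0, 0, rep(log(1.1), 3), 0, 0, 0)
  A <- cpmorph:::affine_from_params(true_p)
  moved <- resample_affine(im$t1, solve(A))
  reg <- affine_register(moved, im$t1, levels = 3, seed = 1)
  pol <- function(M) { s <- svd(M); s$u %*% t(s$v) }
  Ra <- pol(A[1:3, 1:3]); Rb <- pol(reg$matrix[1:3, 1:3])
  ang <- acos(pmin(1, (sum(diag(t(Ra) %*% Rb)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 1)
  sa <- svd(A[1:3, 1:3])$d; sb <- svd(reg$matrix[1:3, 1:3])$d
  expect_lt(max(abs(sb / sa - 1)), 0.01)
  expect_lt(max(abs(reg$matrix[1:3, 4] - A[1:3, 4])), 1)
})

test_that("affine alignment normalises intracranial volume across head sizes", {
  ph <- make_atlas_phantom(c(48, 48, 48), c(2.5, 2.5, 2.5))
  im <- render_intensities(ph, render_params(bias_amplitude = 0, noise_sd = 1,
                                             pv_sigma_mm = 1), seed = 2)
  # a subject 1.3x the atlas ICV (isotropic 1.0914^3 = 1.3)
  s <- 1.3^(1 / 3)
  A <- cpmorph:::affine_from_params(c(0, 0, 0, 0, 0, 0, rep(log(s), 3), 0, 0, 0))
  big <- resample_affine(im$t1, A)
  reg <- affine_register(big, im$t1, levels = 3, seed = 1)
  bb_vol <- function(v) {
    m <- as.numeric(v) > 10
    dim(m) <- dim(v)
    ij <- which(m, arr.ind = TRUE)
    prod(apply(ij, 2, max) - apply(ij, 2, min) + 1)
  }
  expect_lt(abs(bb_vol(reg$resampled) / bb_vol(im$t1) - 1), 0.10)
})

test_that("skull stripping follows the naive-WM region-growing contract", {
  # CSF rim rendered at 10% of WM so growth stops at intradural CSF
  dark_csf <- render_params(
    t1_means = c(background = 0, wm = 100, gm = 70, csf = 10, lesion = 60),
    bias_amplitude = 0, noise_sd = 1, pv_sigma_mm = 0)
  ph <- make_atlas_phantom()
  im <- render_intensities(ph, dark_csf, seed = 1)
  tis <- label_tissue(ph$labels)
  truth <- tis %in% c(1, 2, 4) | as.integer(ph$labels) %in% c(4L, 5L)
  dim(truth) <- dim(tis)
  mask <- strip_skull(im$t1)
  expect_gt(dice(mask, truth), 0.95)
  expect_equal(max(label_components(mask, 26)), 1)
  # a large unilateral lesion stays inside the mask
  phl <- apply_injury(ph, injury_spec("unilateral", "left", lesion_count = 3,
                                      lesion_radius_mm = 8), seed = 2)
  iml <- render_intensities(phl, dark_csf, seed = 2)
  tisl <- label_tissue(phl$labels)
  truthl <- tisl %in% c(1, 2, 4) | as.integer(phl$labels) %in% c(4L, 5L)
  dim(truthl) <- dim(tisl)
  maskl <- strip_skull(iml$t1)
  expect_gt(dice(maskl, truthl), 0.9)
  expect_equal(sum(tisl == 4 & !maskl), 0)
  # csf_fraction -> 0 grows to the whole connected non-background region
  im0 <- render_intensities(ph, render_params(bias_amplitude = 0, noise_sd = 0,
                                              pv_sigma_mm = 0), seed = 1)
  m0 <- strip_skull(im0$t1, skull_strip_params(csf_fraction = 0))
  expect_equal(sum(m0 != (as.numeric(im0$t1) > 0)), 0)
  # monotone in csf_fraction: smaller fraction gives a superset mask
  m25 <- strip_skull(im$t1, skull_strip_params(csf_fraction = 0.25))
  m05 <- strip_skull(im$t1, skull_strip_params(csf_fraction = 0.05))
  expect_equal(sum(m25 & !m05), 0)
})
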