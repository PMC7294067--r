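test_that("atlas phantom hosts every structure, deterministically and symmetrically", {
  ph1 <- make_atlas_phantom(c(64, 64, 64), c(2, 2, 2), seed = 1)
  ph2 <- make_atlas_phantom(c(64, 64, 64), c(2, 2, 2), seed = 1)
  expect_identical(as.integer(ph1$labels), as.integer(ph2$labels))
  lab <- ph1$labels
  for (nm in setdiff(names(PHANTOM_LABELS), c("background", "lesion")))
    expect_gt(sum(lab == PHANTOM_LABELS[[nm]]), 0)
  for (code in c(parcel_codes("left"), parcel_codes("right")))
    expect_gt(sum(lab == code), 0)
  # left/right pairs are mirror symmetric in the uninjured atlas
  for (nm in c("ventricle", "caudate", "lenticular", "thalamus", "alic", "plic")) {
    l <- sum(lab == PHANTOM_LABELS[[paste0(nm, "_left")]])
    r <- sum(lab == PHANTOM_LABELS[[paste0(nm, "_right")]])
    expect_lte(abs(l - r), 1)
  }
  # one code per voxel is structural (a single integer array), and every
  # label maps to exactly one tissue class
  expect_true(all(label_tissue(lab) %in% 0:4))
  expect_error(make_atlas_phantom(c(32, 64, 64)), "48")
})

test_that("rasterised thalamus volume approximates the analytic ellipsoid", {
  ph <- make_atlas_phantom(c(96, 96, 96), c(1.5, 1.5, 1.5))
  semi_mm <- ph$geometry$ellipsoids$thalamus$semi * ph$geometry$half_fov
  analytic_vox <- 4 / 3 * pi * prod(semi_mm / 1.5)
  count <- sum(ph$labels == PHANTOM_LABELS[["thalamus_right"]])
  expect_lt(abs(count - analytic_vox) / analytic_vox, 0.10)
})

test_that("injury application follows the specification", {
  ph <- make_atlas_phantom()
  # laterality none is the identity
  ph0 <- apply_injury(ph, injury_spec("none"), seed = 1)
  expect_identical(as.integer(ph0$labels), as.integer(ph$labels))
  # unilateral dilation grows only the affected side
  inj <- injury_spec("unilateral", "left", ventricle_dilation = 2)
  ph1 <- apply_injury(ph, inj, seed = 1)
  expect_gt(sum(ph1$labels == 4), sum(ph$labels == 4))
  expect_equal(sum(ph1$labels == 5), sum(ph$labels == 5))
  # dilated volume ratio tracks the requested factor
  for (f in c(1.5, 2, 3)) {
    phf <- apply_injury(ph, injury_spec("unilateral", "left",
                                        ventricle_dilation = f), seed = 1)
    ratio <- sum(phf$labels == 4) / sum(ph$labels == 4)
    expect_lt(abs(ratio - f) / f, 0.15)
  }
  # lesions carve periventricular WM with the dedicated code
  phl <- apply_injury(ph, injury_spec("unilateral", "right", lesion_count = 2),
                      seed = 2)
  expect_gt(sum(phl$labels == PHANTOM_LABELS["lesion"]), 0)
  expect_equal(sum(phl$labels == PHANTOM_LABELS["lesion"] &
                     as.integer(ph$labels) != PHANTOM_LABELS["wm"]), 0)
  # atrophy thins the affected cortex only
  pha <- apply_injury(ph, injury_spec("unilateral", "left",
                                      cortical_atrophy = 0.4), seed = 1)
  gml <- sapply(parcel_codes("left"), function(c) sum(pha$labels == c))
  gml0 <- sapply(parcel_codes("left"), function(c) sum(ph$labels == c))
  gmr <- sapply(parcel_codes("right"), function(c) sum(pha$labels == c))
  gmr0 <- sapply(parcel_codes("right"), function(c) sum(ph$labels == c))
  expect_lt(sum(gml), sum(gml0))
  expect_equal(gmr, gmr0)
  # impossible dilation errors rather than merging with background
  expect_error(apply_injury(ph, injury_spec("unilateral", "left",
                                            ventricle_dilation = 200), seed = 1),
               "background")
})

test_that("injury severity ordering is monotone in its effects", {
  ph <- make_atlas_phantom()
  vents <- c(); wms <- c()
  for (f in c(1, 1.5, 2, 2.5)) {
    inj <- if (f == 1) injury_spec("none")
           else injury_spec("unilateral", "left", ventricle_dilation = f,
                            cortical_atrophy = (f - 1) / 5)
    phi <- apply_injury(ph, inj, seed = 1)
    vents <- c(vents, sum(phi$labels == 4))
    wms <- c(wms, sum(label_tissue(phi$labels) == 1 &
                        cpmorph:::hemisphere_mask(dim(phi$labels), phi$spacing, "left")))
  }
  expect_true(all(diff(vents) >= 0))
  expect_true(all(diff(wms) <= 0))
})

test_that("rendering reproduces class means, hyperintense lesions and bias", {
  ph <- apply_injury(make_atlas_phantom(),
                     injury_spec("unilateral", "left", lesion_count = 2), seed = 1)
  tis <- label_tissue(ph$labels)
  # noiseless limit: exactly the piecewise-constant class-mean image
  rp0 <- render_params(bias_amplitude = 0, noise_sd = 0, pv_sigma_mm = 0)
  im0 <- render_intensities(ph, rp0, seed = 1)
  expect_equal(unique(as.numeric(im0$t1[tis == 1])), 100)
  expect_equal(unique(as.numeric(im0$t1[tis == 3])), 30)
  expect_gt(mean(im0$t2[tis == 4]), mean(im0$t2[tis == 1]))
  # determinism
  im0b <- render_intensities(ph, rp0, seed = 1)
  expect_identical(as.numeric(im0$t1), as.numeric(im0b$t1))
  # WM mean under noise: sd 5 over >= 1e4 WM voxels pins the mean near 100
  rp5 <- render_params(bias_amplitude = 0, noise_sd = 5, pv_sigma_mm = 0)
  im5 <- render_intensities(ph, rp5, seed = 2)
  expect_gt(sum(tis == 1), 1e4)
  expect_true(mean(im5$t1[tis == 1]) > 98 && mean(im5$t1[tis == 1]) < 102)
  # bias field: measured WM corner-region ratio tracks the applied field
  rpb <- render_params(bias_amplitude = 0.3, noise_sd = 0, pv_sigma_mm = 0)
  imb <- render_intensities(ph, rpb, seed = 3)
  field <- attr(imb$t1, "bias")
  co <- coord_arrays(dim(field), ph$spacing)
  wm <- tis == 1
  cornerA <- wm & co$x < 0 & co$y < 0 & co$z < 0
  cornerB <- wm & co$x > 0 & co$y > 0 & co$z > 0
  measured <- mean(imb$t1[cornerA]) / mean(imb$t1[cornerB])
  predicted <- 100 * mean(field[cornerA]) / (100 * mean(field[cornerB]))
  expect_lt(abs(measured - predicted), 0.02)
  expect_true(measured > 0.7 && measured < 1.3)
})

test_that("render parameter validation enforces T2-hyperintense lesions", {
  expect_error(render_params(t2_means = c(background = 0, wm = 60, gm = 80,
                                          csf = 130, lesion = 50)),
               "exceed")
})

test_that("cohort outcomes follow the planted linear model", {
  # null model: no effects, no noise, scores sit at baseline
  co0 <- simulate_cohort(cohort_spec(n_tdc = 2, n_unilateral = 4, n_bilateral = 4,
    beta = c(vol_ventricle_contra = 0), noise_sd = 0, grid = c(48, 48, 48),
    spacing = c(2.5, 2.5, 2.5), render = FALSE, seed = 1))
  cp <- co0$clinical$group != "tdc"
  expect_equal(unique(co0$clinical$AHA[cp]), 60)
  expect_true(all(is.na(co0$clinical$AHA[!cp])))
  # single strong effect, small noise: feature-outcome correlation is strong
  co1 <- simulate_cohort(cohort_spec(n_tdc = 0, n_unilateral = 30, n_bilateral = 30,
    beta = c(vol_ventricle_contra = -1), noise_sd = 0.1, grid = c(48, 48, 48),
    spacing = c(2.5, 2.5, 2.5), render = FALSE, seed = 2))
  expect_lt(cor(co1$features$vol_ventricle_contra, co1$clinical$AHA), -0.9)
  expect_error(simulate_cohort(cohort_spec(0, 0, 0)), "empty")
})

test_that("planted interactions shift the within-group slope by gamma", {
  co <- simulate_cohort(cohort_spec(n_tdc = 0, n_unilateral = 45, n_bilateral = 45,
    beta = c(vol_ventricle_contra = -0.6), gamma = c(vol_ventricle_contra = -1),
    noise_sd = 0.3, grid = c(48, 48, 48), spacing = c(2.5, 2.5, 2.5),
    render = FALSE, seed = 3))
  cl <- co$clinical
  z <- scale(co$features$vol_ventricle_contra)[, 1]
  slope <- function(g) {
    f <- stats::lm(cl$AHA[cl$group == g] ~ z[cl$group == g])
    c(coef(f)[2], sqrt(diag(stats::vcov(f))[2]))
  }
  su <- slope("unilateral"); sb <- slope("bilateral")
  gamma_scaled <- -1 * co$truth$scale
  se <- sqrt(su[2]^2 + sb[2]^2)
  expect_lt(abs((sb[1] - su[1]) - gamma_scaled), 2 * se)
})

test_that("a configurable fraction of subjects lacks the T2 volume", {
  co <- simulate_cohort(cohort_spec(n_tdc = 0, n_unilateral = 20, n_bilateral = 20,
    missing_t2_fraction = 0.5, grid = c(48, 48, 48), spacing = c(2.5, 2.5, 2.5),
    render = FALSE, seed = 4))
  miss <- !co$clinical$has_t2
  expect_gt(sum(miss), 5)
  expect_true(all(is.na(co$features$vol_lesion_contra[miss])))
  expect_true(all(!is.na(co$features$vol_ventricle_contra)))
})
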