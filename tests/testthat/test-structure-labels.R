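test_that("patch-search parameters are validated", {
  expect_error(patch_search_params(patch_size = 14), "odd")
  expect_error(patch_search_params(search_radius = -1), "radius")
  expect_error(patch_search_params(stride = 0), "stride")
})

test_that("patch search matches the exhaustive reference on random scenes", {
  configs <- list(c(0, 1), c(2, 3), c(6, 3))
  for (i in seq_along(configs)) {
    sc <- random_patch_scene(100 + i, 26)
    radius <- configs[[i]][1]; stride <- configs[[i]][2]
    pp <- patch_label_propagation(sc$A, sc$labels, sc$B, sc$maskA, sc$maskB,
            patch_search_params(patch_size = 9, search_radius = radius,
                                stride = stride), structures = 7L)
    d <- pp$displacements
    set.seed(i)
    take <- sample(nrow(d), min(25, nrow(d)))
    ref <- patch_ssd_reference(sc$A, sc$B, sc$maskA, sc$maskB,
                               as.matrix(d[take, c("cx", "cy", "cz")]),
                               patch_size = 9, search_radius = radius)
    expect_equal(ref$dx, d$dx[take])
    expect_equal(ref$dy, d$dy[take])
    expect_equal(ref$dz, d$dz[take])
    expect_equal(ref$npairs, d$npairs[take])
    expect_equal(ref$ssd, d$ssd[take], tolerance = 1e-6)
  }
})

test_that("identity propagation reproduces atlas labels with zero displacements", {
  at <- atlas48()
  pp <- patch_label_propagation(at$t1, at$phantom$labels, at$t1,
          at$csf_mask, at$csf_mask, patch_search_params(stride = 3))
  d <- pp$displacements
  expect_true(all(d$dx == 0 & d$dy == 0 & d$dz == 0))
  expect_true(all(d$ssd < 1e-12))
  lab <- finalize_labels(pp$maps, patch_search_params(stride = 3))
  for (s in names(pp$maps)) {
    expect_identical(which(lab == as.integer(s)),
                     which(as.integer(at$phantom$labels) == as.integer(s)))
  }
})

test_that("a translated subject yields the translation as modal displacement", {
  at <- atlas48()
  dimv <- dim(at$t1)
  src <- array(as.numeric(at$t1), dimv)
  sh <- array(0, dimv)
  sh[3:dimv[1], , ] <- src[1:(dimv[1] - 2), , ]
  sh <- vol3d(sh, vspacing(at$t1))
  pp <- patch_label_propagation(at$t1, at$phantom$labels, sh,
          at$csf_mask, array(FALSE, dimv), patch_search_params(stride = 3))
  d <- pp$displacements
  modal <- names(sort(table(paste(d$dx, d$dy, d$dz)), decreasing = TRUE))[1]
  expect_equal(modal, "2 0 0")
})

test_that("intensities under the CSF masks cannot influence the result", {
  at <- atlas48()
  params <- patch_search_params(stride = 3)
  base <- patch_label_propagation(at$t1, at$phantom$labels, at$t1,
            at$csf_mask, at$csf_mask, params)
  set.seed(9)
  pert_subject <- vol3d(array(as.numeric(at$t1), dim(at$t1)), vspacing(at$t1))
  pert_subject[at$csf_mask] <- stats::runif(sum(at$csf_mask), -500, 500)
  pert_atlas <- vol3d(array(as.numeric(at$t1), dim(at$t1)), vspacing(at$t1))
  pert_atlas[at$csf_mask] <- stats::runif(sum(at$csf_mask), -500, 500)
  pert <- patch_label_propagation(pert_atlas, at$phantom$labels, pert_subject,
            at$csf_mask, at$csf_mask, params)
  expect_identical(pert$displacements, base$displacements)
  lab0 <- finalize_labels(base$maps, params)
  lab1 <- finalize_labels(pert$maps, params)
  expect_identical(lab0, lab1)
})

test_that("ventricle-guided rigid alignment recovers shifts and reduces distance", {
  at <- atlas64()
  # subject = atlas: identity within half a voxel
  self <- rigid_align_to_ventricles(at$phantom$labels, at$ventricle_priors,
                                    "DGM", at$spacing)
  expect_lt(max(abs(self$params[1:3])), 0.5 * 2)
  expect_lt(max(abs(self$params[4:6])), 0.5 * pi / 180 + 0.01)
  # atlas shifted 8 mm laterally: translation recovered within 1 mm
  dimv <- dim(at$phantom$labels)
  shift_vox <- 4   # 8 mm at 2 mm spacing
  shl <- array(FALSE, dimv); shr <- array(FALSE, dimv)
  shl[(shift_vox + 1):dimv[1], , ] <- at$ventricle_priors$left[1:(dimv[1] - shift_vox), , ]
  shr[(shift_vox + 1):dimv[1], , ] <- at$ventricle_priors$right[1:(dimv[1] - shift_vox), , ]
  rec <- rigid_align_to_ventricles(at$phantom$labels,
                                   list(left = shl, right = shr), "DGM", at$spacing)
  expect_lt(abs(rec$params[1] - 8), 1)
  expect_lt(max(abs(rec$params[2:3])), 1)
  # unilateral dilation: alignment strictly reduces the face distance
  q <- standard_quantification(1)$q
  rigi <- rigid_align_to_ventricles(at$phantom$labels, q$segmentation$ventricles,
                                    "CC", at$spacing)
  expect_lt(rigi$mean_dist_after, rigi$mean_dist_before + 1e-12)
  # both masks empty: identity with a flag
  e <- rigid_align_to_ventricles(at$phantom$labels,
                                 list(left = array(FALSE, dimv),
                                      right = array(FALSE, dimv)), "DGM", at$spacing)
  expect_true(e$flagged)
  expect_equal(e$matrix, diag(4))
})

test_that("finalisation masks lesions, keeps one component and resolves conflicts", {
  m1 <- array(0, c(10, 10, 10)); m1[2:4, 2:4, 2:4] <- 0.9; m1[8, 8, 8] <- 0.7
  m2 <- array(0, c(10, 10, 10)); m2[4:6, 2:4, 2:4] <- 0.6
  les <- array(FALSE, c(10, 10, 10)); les[2, 2, 2] <- TRUE
  lab <- finalize_labels(list(`6` = m1, `8` = m2), patch_search_params(),
                         lesion_mask = les)
  expect_equal(sum(lab == 6 & les), 0)          # lesion voxels never labelled
  expect_equal(sum(lab[8, 8, 8] == 6), 0)       # small component dropped
  expect_equal(lab[4, 3, 3], 6L)                # overlap: higher probability wins
  expect_true(all(lab[5:6, 2:4, 2:4] == 8L))
  empty <- finalize_labels(list(`6` = m1 * 0), patch_search_params())
  expect_equal(attr(empty, "flagged_empty"), "6")
})

test_that("cortical labels propagate to every GM voxel with deterministic ties", {
  at <- atlas48()
  gm <- array(as.integer(at$phantom$labels) >= 100, dim(at$phantom$labels))
  parc <- propagate_cortical_labels(gm, at$parcels, at$spacing)
  expect_identical(parc[gm], as.integer(at$phantom$labels)[gm])
  # severely atrophied cortex: still 100% labelled (no distance cap)
  pha <- apply_injury(make_atlas_phantom(c(48, 48, 48), c(2.5, 2.5, 2.5)),
                      injury_spec("bilateral", cortical_atrophy = c(0.45, 0.45)),
                      seed = 1)
  gma <- array(as.integer(pha$labels) >= 100, dim(pha$labels))
  parca <- propagate_cortical_labels(gma, at$parcels, at$spacing)
  expect_equal(sum(parca[gma] == 0), 0)
  # two-parcel toy: equidistant voxel takes the lower code
  toy <- array(0L, c(7, 3, 3)); toy[1, 2, 2] <- 5L; toy[7, 2, 2] <- 3L
  gmt <- array(TRUE, c(7, 3, 3))
  pt <- propagate_cortical_labels(gmt, vol3d(toy, c(1, 1, 1)), c(1, 1, 1))
  expect_equal(pt[4, 2, 2], 3L)
  expect_error(propagate_cortical_labels(gmt, vol3d(toy * 0L, c(1, 1, 1))),
               "empty")
})
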