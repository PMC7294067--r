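#' Atlas bundle for the pipeline
#'
#' The single synthetic atlas subject playing the registration / label-source
#' role: the uninjured phantom, its noiseless bias-free rendering (the
#' histogram-matching reference), CSF mask (CSF + ventricles), per-side
#' ventricle priors, cortical parcels and the deep-structure label codes.
#'
#' @param grid_shape,spacing atlas geometry.
#' @param seed integer.
#' @return an `atlas_bundle` list.
#' @export
make_atlas_bundle <- function(grid_shape = c(64, 64, 64), spacing = c(2, 2, 2),
                              seed = 1L) {
  phantom <- make_atlas_phantom(grid_shape, spacing, seed)
  rp <- render_params(bias_amplitude = 0, noise_sd = 0, pv_sigma_mm = 1)
  imgs <- render_intensities(phantom, rp, seed = seed)
  labels <- as_arr(phantom$labels)
  tis <- label_tissue(labels)
  parcels <- array(0L, dim(labels))
  pc <- c(parcel_codes("left"), parcel_codes("right"))
  sel <- labels %in% pc
  parcels[sel] <- labels[sel]
  structure(list(
    phantom = phantom,
    t1 = imgs$t1, t2 = imgs$t2,
    brain_mask = tis != 0L,
    csf_mask = tis == TISSUE_CODES[["csf"]],
    ventricle_priors = list(
      left = labels == PHANTOM_LABELS[["ventricle_left"]],
      right = labels == PHANTOM_LABELS[["ventricle_right"]]),
    parcels = vol3d(parcels, spacing),
    structure_codes = structure_codes_default(),
    spacing = spacing), class = "atlas_bundle")
}

#' Quantify one subject
#'
#' Full injury-robust quantification of a single subject against the atlas
#' bundle: intensity normalisation (polynomial bias removal + histogram
#' matching to the atlas), anisotropic-diffusion denoising, optional affine
#' alignment to the atlas, skull stripping, EM tissue segmentation (with the
#' T2-weighted lesion class when T2 is present), ventricle extraction,
#' ventricle-guided rigid alignment of the deep-structure atlas labels,
#' CSF-masked patch-SSD propagation and finalisation, cortical parcel
#' propagation, cortical thickness / sulcal depth / curvature, and the
#' volume and regional tables.
#'
#' @param t1 `vol3d` subject T1.
#' @param t2 `vol3d` subject T2, or `NULL`.
#' @param atlas an [make_atlas_bundle()].
#' @param subject_id identifier for the output tables.
#' @param seed integer.
#' @param register run the affine atlas alignment (disable when the subject
#'   is already on the atlas grid).
#' @param patch_params a [patch_search_params()].
#' @param diffusion_iterations,diffusion_conductance denoising steps and
#'   Perona-Malik edge threshold.
#' @return a `subject_quantification` list with the segmentation, structure
#'   labels, shape maps, `volumes` and `regional` tables.
#' @export
quantify_subject <- function(t1, t2 = NULL, atlas, subject_id = "subject",
                             seed = 1L, register = FALSE,
                             patch_params = patch_search_params(),
                             diffusion_iterations = 2,
                             diffusion_conductance = 10) {
  # bias correction + denoising; histogram matching to the atlas happens
  # brain-to-brain just before the patch comparison
  t1n <- normalize_intensities(t1, bias_order = 2)
  t1n <- anisotropic_diffusion(t1n, iterations = diffusion_iterations,
                               conductance = diffusion_conductance)
  if (register) {
    reg <- affine_register(t1n, atlas$t1, levels = 2, seed = seed)
    t1n <- reg$resampled
    if (!is.null(t2)) {
      t2 <- resample_affine(t2, reg$matrix, out_dim = dim(atlas$t1),
                            out_spacing = vspacing(atlas$t1))
    }
  } else reg <- NULL
  if (!is.null(t2)) {
    t2 <- normalize_intensities(t2, bias_order = 2)
    t2 <- anisotropic_diffusion(t2, iterations = diffusion_iterations,
                                conductance = diffusion_conductance)
  }
  brain <- strip_skull(t1n)
  seg <- segment_tissues(t1n, brain, t2 = t2, seed = seed)
  seg <- extract_ventricles(seg, atlas$ventricle_priors)
  t1m <- normalize_intensities(t1n, atlas$t1, bias_order = 0, mask = brain,
                               reference_mask = atlas$brain_mask)

  # mask both the segmented CSF and the segmented lesions out of the patch
  # comparison: both are tissue-loss signal absent from the atlas
  subject_csf <- seg$labels == 1L | seg$lesion_mask
  prop_labels <- array(0L, dim(brain))
  flagged_empty <- character(0)
  for (grp in c("DGM", "CC")) {
    codes <- if (grp == "CC")
      PHANTOM_LABELS[c("cc_genu", "cc_body", "cc_splenium")]
    else setdiff(atlas$structure_codes,
                 PHANTOM_LABELS[c("cc_genu", "cc_body", "cc_splenium")])
    rig <- rigid_align_to_ventricles(atlas$phantom$labels, seg$ventricles,
                                     structure_group = grp,
                                     spacing = atlas$spacing)
    at1 <- resample_affine(atlas$t1, rig$matrix)
    alab <- resample_affine(vol3d(as_arr(atlas$phantom$labels), atlas$spacing),
                            rig$matrix, nearest = TRUE)
    alab <- array(as.integer(round(as_arr(alab))), dim(brain))
    acsf <- array(label_tissue(alab) == TISSUE_CODES[["csf"]], dim(brain))
    prop <- patch_label_propagation(at1, alab, t1m, acsf, subject_csf,
                                    params = patch_params, structures = codes)
    lab <- finalize_labels(prop$maps, patch_params, lesion_mask = seg$lesion_mask)
    flagged_empty <- c(flagged_empty, attr(lab, "flagged_empty"))
    sel <- lab > 0L & prop_labels == 0L
    prop_labels[sel] <- lab[sel]
  }

  gm_mask <- seg$labels == 2L
  wm_mask <- (seg$labels == 3L | seg$lesion_mask | prop_labels %in%
    PHANTOM_LABELS[c("alic_left", "alic_right", "plic_left", "plic_right",
                     "cc_genu", "cc_body", "cc_splenium")]) & !gm_mask
  dim(wm_mask) <- dim(brain)
  parcellation <- propagate_cortical_labels(gm_mask, atlas$parcels,
                                            spacing = atlas$spacing)
  th <- cortical_thickness(gm_mask, wm_mask, spacing = atlas$spacing)
  tissue_brain <- gm_mask | wm_mask
  shape <- cortical_shape_maps(tissue_brain, gm_mask, spacing = atlas$spacing)
  reg_rows <- list(
    cbind(metric = "ct", summarize_by_region(th, parcellation)),
    cbind(metric = "sd", summarize_by_region(shape$sulcal_depth, parcellation)),
    cbind(metric = "curv", summarize_by_region(shape$curvature, parcellation)))
  regional <- do.call(rbind, reg_rows)
  regional$subject_id <- subject_id
  volumes <- compute_volumes(seg, prop_labels, brain, subject_id)
  structure(list(subject_id = subject_id, t1 = t1n, brain_mask = brain,
                 segmentation = seg, structure_labels = prop_labels,
                 parcellation = parcellation, thickness = th, shape = shape,
                 registration = reg, volumes = volumes, regional = regional,
                 flagged_empty = flagged_empty, qc = list(
                   n_components_brain = max(label_components(brain)),
                   skipped_patches = NA)),
            class = "subject_quantification")
}

#' Run the full pipeline on a simulated cohort
#'
#' Quantifies every subject with [quantify_subject()], assembles the
#' ipsi/contra feature table and (optionally) fits the four motor-score
#' models (AHA / MUUL, data-driven / PCA arms). Fully deterministic given
#' the cohort and `seed`.
#'
#' @param cohort result of [simulate_cohort()] (rendered).
#' @param atlas an [make_atlas_bundle()] on the cohort's grid.
#' @param seed integer.
#' @param register passed to [quantify_subject()].
#' @param fit_models fit the random-forest models (requires enough CP
#'   subjects).
#' @param patch_params a [patch_search_params()].
#' @return a `pipeline_result`: `features` (feature table), `volumes`,
#'   `regional`, `reports` (list of [fit_and_evaluate()] reports or `NULL`),
#'   `subjects` (quantifications).
#' @export
run_pipeline <- function(cohort, atlas = NULL, seed = 1L, register = FALSE,
                         fit_models = FALSE,
                         patch_params = patch_search_params()) {
  if (is.null(atlas)) {
    s1 <- cohort$subjects[[1]]
    atlas <- make_atlas_bundle(dim(s1$phantom$labels), s1$phantom$spacing,
                               seed = seed)
  }
  quants <- lapply(cohort$subjects, function(s) {
    if (is.null(s$t1)) stop("cohort was simulated without rendering")
    quantify_subject(s$t1, s$t2, atlas, subject_id = s$clinical$subject_id,
                     seed = seed, register = register,
                     patch_params = patch_params)
  })
  volumes <- do.call(rbind, lapply(quants, `[[`, "volumes"))
  regional <- do.call(rbind, lapply(quants, `[[`, "regional"))
  features <- assemble_features(volumes, regional, cohort$clinical)
  reports <- NULL
  if (fit_models) {
    reports <- list()
    for (outcome in c("AHA", "MUUL"))
      for (arm in c("data_driven", "pca"))
        reports[[paste(outcome, arm, sep = "_")]] <-
          fit_and_evaluate(features, outcome, arm, seed = seed)
  }
  structure(list(features = features, volumes = volumes, regional = regional,
                 reports = reports, subjects = quants),
            class = "pipeline_result")
}
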