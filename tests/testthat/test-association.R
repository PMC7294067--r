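# small deterministic cohorts for the association module
assoc_cohort <- function(seed, n = 45, gamma = numeric(0), beta = NULL,
                         noise_sd = 1) {
  spec <- cohort_spec(n_tdc = 0, n_unilateral = n, n_bilateral = n,
                      gamma = gamma, noise_sd = noise_sd,
                      grid = c(48, 48, 48), spacing = c(2.5, 2.5, 2.5),
                      render = FALSE, seed = seed)
  if (!is.null(beta)) spec$beta <- beta
  simulate_cohort(spec)
}

test_that("hemisphere relabelling follows the cross-laterality rule", {
  vols <- rbind(
    data.frame(subject_id = "s1", structure = "thalamus", side = "left",
               volume_ml = 7, icv_fraction = 0.007, flagged = FALSE),
    data.frame(subject_id = "s1", structure = "thalamus", side = "right",
               volume_ml = 5, icv_fraction = 0.005, flagged = FALSE),
    data.frame(subject_id = "s1", structure = "cc_genu", side = "mid",
               volume_ml = 2, icv_fraction = 0.002, flagged = FALSE))
  clin <- data.frame(subject_id = "s1", group = "unilateral",
                     affected_side = "right", age_years = 10, gender = "M",
                     AHA = 70, MUUL = 75, stringsAsFactors = FALSE)
  tab <- assemble_features(vols, NULL, clin, use_icv_fraction = FALSE)
  # right-impaired: contralateral = left hemisphere
  expect_equal(tab$vol_thalamus_contra, 7)
  expect_equal(tab$vol_thalamus_ipsi, 5)
  expect_equal(tab$vol_cc_genu, 2)
  # unilateral rows: every interaction column is exactly zero
  expect_true(all(as.numeric(tab[, startsWith(names(tab), "int_")]) == 0))
  # TDC convention: ipsi = left, contra = right
  clin_t <- clin; clin_t$group <- "tdc"; clin_t$affected_side <- NA
  clin_t$AHA <- NA; clin_t$MUUL <- NA
  tab_t <- assemble_features(vols, NULL, clin_t, use_icv_fraction = FALSE)
  expect_equal(tab_t$vol_thalamus_ipsi, 7)
  expect_equal(tab_t$vol_thalamus_contra, 5)
  # CP subject without affected_side errors
  clin_e <- clin; clin_e$affected_side <- NA
  expect_error(assemble_features(vols, NULL, clin_e), "affected_side")
})

test_that("missing lesion volumes survive assembly as NA without dropping rows", {
  co <- assoc_cohort(1, n = 12)
  tab <- assemble_truth_features(co)
  miss <- !co$clinical$has_t2
  expect_gt(sum(miss), 0)
  expect_true(all(is.na(tab$vol_lesion_contra[miss])))
  expect_equal(nrow(tab), 24)
})

test_that("data-driven selection finds a planted feature among noise", {
  hits <- 0; dup_hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 100
    X <- as.data.frame(matrix(stats::rnorm(n * 50), n,
                              dimnames = list(NULL, paste0("noise", 1:50))))
    X$planted <- stats::rnorm(n)
    X$planted_copy <- X$planted
    tab <- data.frame(subject_id = as.character(1:n),
                      group = rep(c("unilateral", "bilateral"), length.out = n),
                      age_years = stats::runif(n, 5, 17), gender = stats::rbinom(n, 1, 0.5),
                      AHA = 60 + 12 * X$planted + stats::rnorm(n, 0, 4),
                      MUUL = NA_real_, X)
    class(tab) <- c("feature_table", class(tab))
    sel <- select_features_datadriven(tab, "AHA", seed = seed)
    hits <- hits + ("planted" %in% sel$features || "planted_copy" %in% sel$features)
    dup_hits <- dup_hits + (sum(c("planted", "planted_copy") %in% sel$features) >= 1)
  }
  expect_gte(hits, 9)
  expect_gte(dup_hits, 9)
})

test_that("selection on a pure-noise outcome retains few features", {
  sizes <- sapply(1:5, function(seed) {
    set.seed(seed)
    n <- 80
    X <- as.data.frame(matrix(stats::rnorm(n * 40), n,
                              dimnames = list(NULL, paste0("f", 1:40))))
    tab <- data.frame(subject_id = as.character(1:n),
                      group = rep(c("unilateral", "bilateral"), length.out = n),
                      age_years = stats::runif(n, 5, 17), gender = stats::rbinom(n, 1, 0.5),
                      AHA = stats::rnorm(n), MUUL = NA_real_, X)
    class(tab) <- c("feature_table", class(tab))
    sel <- select_features_datadriven(tab, "AHA", seed = seed)
    if (sel$flagged) 0 else length(sel$features)
  })
  expect_lte(mean(sizes), 0.10 * 42)
})

test_that("PCA reduction satisfies its algebraic identities", {
  co <- assoc_cohort(2, n = 25)
  tab <- assemble_truth_features(co)
  red <- select_features_pca(tab, n_components = 10)
  expect_equal(sum(red$explained_ratio), 1, tolerance = 1e-10)
  expect_equal(unname(t(red$loadings) %*% red$loadings), diag(10),
               tolerance = 1e-8)
  # true rank-3 data: 3 components carry essentially all variance
  set.seed(5)
  n <- 60
  basis <- matrix(stats::rnorm(3 * 12), 3, 12)
  X <- matrix(stats::rnorm(n * 3), n, 3) %*% basis +
    matrix(stats::rnorm(n * 12, 0, 1e-5), n, 12)
  tab3 <- data.frame(subject_id = as.character(1:n),
                     group = rep(c("unilateral", "bilateral"), length.out = n),
                     age_years = 10, gender = 1, AHA = stats::rnorm(n),
                     MUUL = NA_real_, as.data.frame(X))
  class(tab3) <- c("feature_table", class(tab3))
  red3 <- select_features_pca(tab3, n_components = 3)
  expect_gt(red3$cumulative_ratio[3], 0.999)
  # requesting more components than the rank truncates with a flag
  redr <- select_features_pca(tab3, n_components = 10)
  expect_true(redr$flagged_rank || redr$n_components <= 10)
})

test_that("model evaluation is deterministic and recovers a noiseless signal", {
  co <- assoc_cohort(3, n = 60, beta = c(vol_ventricle_contra = -1), noise_sd = 0)
  tab <- assemble_truth_features(co)
  rep1 <- fit_and_evaluate(tab, "AHA", "data_driven", seed = 7)
  rep2 <- fit_and_evaluate(tab, "AHA", "data_driven", seed = 7)
  expect_identical(rep1$train_ids, rep2$train_ids)
  expect_identical(rep1$test_r, rep2$test_r)
  expect_gt(rep1$test_r, 0.95)
  # train/test indices are disjoint and exhaustive, test about 25%
  expect_length(intersect(rep1$train_ids, rep1$test_ids), 0)
  expect_equal(rep1$n_train + rep1$n_test, sum(!is.na(tab$AHA)))
  expect_lt(abs(rep1$n_test / (rep1$n_train + rep1$n_test) - 0.25), 0.05)
  small <- tab[1:10, ]
  expect_error(fit_and_evaluate(small, "AHA", "data_driven"), "5")
})

test_that("group contrasts handle nulls, effect sizes and Bonferroni arithmetic", {
  set.seed(11)
  n <- 40
  base <- data.frame(subject_id = as.character(1:(3 * n)),
                     group = rep(c("tdc", "unilateral", "bilateral"), each = n))
  # identical groups: raw p ~ 1 impossible for all, but corrected p hits 1
  base$flat <- rep(stats::rnorm(n), 3)
  gc0 <- group_contrasts(base, "flat")
  expect_true(all(gc0$p_bonferroni[gc0$feature == "flat"] == 1))
  # means 0 vs 1 at sd 1, n = 40/40: |t| lands in the expected band
  ts <- sapply(1:5, function(s) {
    set.seed(s)
    d <- base
    d$eff <- c(stats::rnorm(n, 0), stats::rnorm(n, 1), stats::rnorm(n, 0))
    gc <- group_contrasts(d, "eff")
    abs(gc$t[gc$contrast == "tdc_vs_unilateral" & gc$feature == "eff"])
  })
  expect_true(all(ts >= 3.1 & ts <= 6.3))
  # 13 features x 3 contrasts: correction factor 39
  d13 <- base
  for (i in 1:13) d13[[paste0("f", i)]] <- stats::rnorm(3 * n)
  gc13 <- group_contrasts(d13, paste0("f", 1:13))
  expect_equal(attr(gc13, "n_tests"), 39)
  expect_equal(gc13$p_bonferroni, pmin(1, gc13$p_raw * 39))
  # zero-variance feature is flagged, not an error
  dz <- base; dz$zv <- 1
  gcz <- group_contrasts(dz, "zv")
  expect_true(all(gcz$flagged))
  expect_true(all(is.na(gcz$t)))
})
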