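#' Assemble the per-subject feature table
#'
#' Joins the structural volume tables and regional shape summaries to the
#' clinical table, relabelling hemispheres relative to the impaired body
#' side: the contralateral hemisphere (opposite the impaired hand) is the
#' injured one, so for a right-impaired subject the `*_contra` columns hold
#' left-hemisphere values. Controls use the convention ipsilateral = left,
#' contralateral = right. Lesion volumes stay missing (`NA`) for subjects
#' without a T2 volume; rows are retained. Interaction columns
#' `int_<feature> = feature x 1[bilateral]` are appended for every
#' structural feature, so they are exactly zero for the unilateral group.
#'
#' @param volume_tables data.frame from [compute_volumes()] rows (all
#'   subjects; columns `subject_id, structure, side, volume_ml,
#'   icv_fraction`).
#' @param shape_tables data.frame of regional summaries with columns
#'   `subject_id, parcel, side, metric, mean`, or `NULL`.
#' @param clinical data.frame with `subject_id, group, affected_side,
#'   age_years, gender` and outcome columns `AHA, MUUL`.
#' @param use_icv_fraction take the ICV-normalised volume as the feature
#'   value (default) rather than raw ml.
#' @return a `feature_table` data.frame: one row per subject, structural
#'   columns relabelled ipsi/contra, covariates, `laterality`, interaction
#'   columns, outcomes.
#' @export
assemble_features <- function(volume_tables, shape_tables = NULL, clinical,
                              use_icv_fraction = TRUE) {
  need <- setdiff(unique(volume_tables$subject_id), clinical$subject_id)
  if (length(need))
    stop("subjects missing from the clinical table: ", paste(need, collapse = ", "))
  rows <- list()
  for (i in seq_len(nrow(clinical))) {
    cl <- clinical[i, ]
    if (cl$group != "tdc" && (is.na(cl$affected_side) || !nzchar(cl$affected_side)))
      stop(sprintf("subject %s is in a CP group but has no affected_side", cl$subject_id))
    contra_hemi <- if (cl$group == "tdc" || is.na(cl$affected_side)) "right"
      else if (cl$affected_side == "left") "right" else "left"
    ipsi_hemi <- setdiff(c("left", "right"), contra_hemi)
    vt <- volume_tables[volume_tables$subject_id == cl$subject_id, ]
    val <- if (use_icv_fraction) vt$icv_fraction else vt$volume_ml
    lat <- ifelse(vt$side == "mid", "",
                  ifelse(vt$side == contra_hemi, "_contra", "_ipsi"))
    feats <- stats::setNames(val, paste0("vol_", vt$structure, lat))
    if (!is.null(shape_tables)) {
      st <- shape_tables[shape_tables$subject_id == cl$subject_id, ]
      if (nrow(st)) {
        slat <- ifelse(st$side == contra_hemi, "contra", "ipsi")
        pn <- st$parcel %% 100
        feats <- c(feats, stats::setNames(
          st$mean, paste0(st$metric, "_p", pn, "_", slat)))
      }
    }
    rows[[i]] <- c(list(subject_id = cl$subject_id, group = cl$group,
                        age_years = cl$age_years,
                        gender = as.numeric(cl$gender == "M"),
                        AHA = cl$AHA, MUUL = cl$MUUL),
                   as.list(feats))
  }
  nm <- unique(unlist(lapply(rows, names)))
  tab <- as.data.frame(lapply(nm, function(cn)
    vapply(rows, function(r) {
      v <- r[[cn]]
      if (is.null(v)) NA else v
    }, if (cn %in% c("subject_id", "group")) character(1) else numeric(1))))
  names(tab) <- nm
  struct_cols <- setdiff(nm, c("subject_id", "group", "age_years", "gender",
                               "AHA", "MUUL"))
  bil <- as.numeric(tab$group == "bilateral")
  for (cn in struct_cols) tab[[paste0("int_", cn)]] <- tab[[cn]] * bil
  class(tab) <- c("feature_table", class(tab))
  tab
}

#' Feature table from simulated ground truth
#'
#' Builds the same table as [assemble_features()] directly from the
#' ground-truth structural features of a simulated cohort (bypassing image
#' quantification), for testing the statistical arms against the planted
#' effects.
#'
#' @param cohort result of [simulate_cohort()].
#' @return a `feature_table` data.frame.
#' @export
assemble_truth_features <- function(cohort) {
  cl <- cohort$clinical
  feats <- cohort$features[, setdiff(names(cohort$features), "subject_id"),
                           drop = FALSE]
  tab <- data.frame(subject_id = cl$subject_id, group = cl$group,
                    age_years = cl$age_years,
                    gender = as.numeric(cl$gender == "M"),
                    AHA = cl$AHA, MUUL = cl$MUUL,
                    feats, stringsAsFactors = FALSE)
  struct_cols <- setdiff(names(tab), c("subject_id", "group", "age_years",
                                       "gender", "AHA", "MUUL"))
  bil <- as.numeric(tab$group == "bilateral")
  for (cn in struct_cols) tab[[paste0("int_", cn)]] <- tab[[cn]] * bil
  class(tab) <- c("feature_table", class(tab))
  tab
}

feature_columns <- function(table, include_interactions = TRUE) {
  drop <- c("subject_id", "group", "AHA", "MUUL")
  cols <- setdiff(names(table), drop)
  if (!include_interactions) cols <- cols[!startsWith(cols, "int_")]
  cols
}

structural_columns <- function(table) {
  setdiff(feature_columns(table), c("age_years", "gender"))
}

# forest-ready design: NA -> -1 surrogate plus a missingness indicator
forest_design <- function(table, cols) {
  X <- table[, cols, drop = FALSE]
  for (cn in cols) {
    if (anyNA(X[[cn]])) {
      X[[paste0(cn, "_missing")]] <- as.numeric(is.na(X[[cn]]))
      X[[cn]][is.na(X[[cn]])] <- -1
    }
  }
  X
}

#' Data-driven feature selection by permutation importance
#'
#' Fits a random forest on the table augmented with shadow features
#' (independently permuted copies of every feature, which by construction
#' carry no signal) and retains the features whose permutation importance
#' exceeds the `importance_quantile` quantile of the shadow importances.
#' If everything is dropped, the top 5 features by importance are kept and
#' flagged.
#'
#' @param table a [assemble_features()] table (training rows).
#' @param outcome `"AHA"` or `"MUUL"`.
#' @param importance_quantile quantile of the shadow-importance null used
#'   as the retention threshold.
#' @param seed integer.
#' @param num_trees forest size.
#' @return list with `features` (retained names), `importance`,
#'   `threshold`, `flagged`.
#' @export
select_features_datadriven <- function(table, outcome = "AHA",
                                       importance_quantile = 0.99, seed = 1L,
                                       num_trees = 500) {
  rows <- !is.na(table[[outcome]])
  if (sum(rows) < 20) stop("need at least 20 rows with an outcome")
  cols <- feature_columns(table)
  X <- forest_design(table[rows, , drop = FALSE], cols)
  y <- table[[outcome]][rows]
  set.seed(as.integer(seed))
  shadow <- as.data.frame(lapply(X, sample))
  names(shadow) <- paste0("shadow_", names(X))
  dat <- cbind(X, shadow)
  dat$..y <- y
  fit <- ranger::ranger(dependent.variable.name = "..y", data = dat,
                        num.trees = num_trees, importance = "permutation",
                        seed = as.integer(seed))
  imp <- fit$variable.importance
  sh <- imp[startsWith(names(imp), "shadow_")]
  re <- imp[!startsWith(names(imp), "shadow_")]
  thr <- stats::quantile(sh, importance_quantile, names = FALSE)
  keep <- names(re)[re > thr]
  keep <- setdiff(keep, grep("_missing$", keep, value = TRUE))
  flagged <- FALSE
  if (length(keep) == 0) {
    keep <- names(sort(re, decreasing = TRUE))[seq_len(min(5, length(re)))]
    flagged <- TRUE
  }
  list(features = keep, importance = re, threshold = thr, flagged = flagged)
}

#' PCA feature reduction
#'
#' Standardises the structural measures (including the laterality
#' interaction columns), imputes missing lesion volumes by the median
#' within laterality group, and retains the top `n_components` principal
#' components. Age, gender and the laterality indicator pass through
#' unreduced. The share of variance captured is reported, not enforced.
#'
#' @param table a [assemble_features()] table.
#' @param n_components components to retain (default 10; truncated to the
#'   matrix rank, flagged when truncation occurs).
#' @return list with `scores`, `loadings`, `explained_ratio`,
#'   `cumulative_ratio`, `n_components`, `flagged_rank`, `center`, `scale`,
#'   and `project(newdata)` for applying the same reduction.
#' @export
select_features_pca <- function(table, n_components = 10) {
  cols <- structural_columns(table)
  X <- as.matrix(table[, cols, drop = FALSE])
  # median imputation within laterality group
  for (g in unique(table$group)) {
    gi <- table$group == g
    for (j in seq_len(ncol(X))) {
      mis <- gi & is.na(X[, j])
      if (any(mis)) {
        med <- stats::median(X[gi, j], na.rm = TRUE)
        if (is.na(med)) med <- stats::median(X[, j], na.rm = TRUE)
        X[mis, j] <- med
      }
    }
  }
  for (j in seq_len(ncol(X))) if (anyNA(X[, j]))
    X[is.na(X[, j]), j] <- stats::median(X[, j], na.rm = TRUE)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  pc <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  ratios <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > 1e-10)
  flagged <- n_components > rank
  k <- min(n_components, rank)
  proj <- function(newdata) {
    Xn <- as.matrix(newdata[, cols[keep], drop = FALSE])
    for (j in seq_len(ncol(Xn))) if (anyNA(Xn[, j]))
      Xn[is.na(Xn[, j]), j] <- stats::median(X[, keep, drop = FALSE][, j])
    scale(Xn, center = pc$center, scale = pc$scale) %*% pc$rotation[, seq_len(k), drop = FALSE]
  }
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained_ratio = ratios, cumulative_ratio = cumsum(ratios),
       n_components = k, flagged_rank = flagged,
       center = pc$center, scale = pc$scale, project = proj)
}

#' Fit and evaluate a random-forest motor-score model
#'
#' Controls are excluded (they carry no motor scores). The CP rows are split
#' once into 75% training / 25% test, stratified by laterality group. The
#' data-driven arm runs [select_features_datadriven()] on the training rows
#' and fits a 500-tree random forest (`mtry = sqrt(p)`) on the retained
#' features; the PCA arm fits the reduction on the training rows, projects
#' the test rows, and adds the unreduced covariates and laterality
#' indicator. Reported: training R-squared, test Pearson correlation with
#' p-value, and test RMSE.
#'
#' @param table a [assemble_features()] table.
#' @param outcome `"AHA"` or `"MUUL"`.
#' @param arm `"data_driven"` or `"pca"`.
#' @param split_fraction training fraction.
#' @param seed integer controlling the split, the selection and the forest.
#' @param num_trees forest size.
#' @param importance_quantile passed to the data-driven selection.
#' @param n_components passed to the PCA arm.
#' @return a `model_report` list: `arm`, `retained` (features or loadings),
#'   `train_r2`, `test_r`, `test_p`, `test_rmse`, `seed`, `train_ids`,
#'   `test_ids`, `n_train`, `n_test`, `hyperparams`.
#' @export
fit_and_evaluate <- function(table, outcome = "AHA",
                             arm = c("data_driven", "pca"),
                             split_fraction = 0.75, seed = 1L,
                             num_trees = 500, importance_quantile = 0.99,
                             n_components = 10) {
  arm <- match.arg(arm)
  cp <- table$group != "tdc" & !is.na(table[[outcome]])
  dat <- table[cp, , drop = FALSE]
  set.seed(as.integer(seed))
  train <- logical(nrow(dat))
  for (g in unique(dat$group)) {
    gi <- which(dat$group == g)
    ntr <- round(split_fraction * length(gi))
    train[sample(gi, ntr)] <- TRUE
  }
  if (sum(!train) < 5) stop("test set has fewer than 5 rows")
  y_tr <- dat[[outcome]][train]; y_te <- dat[[outcome]][!train]

  if (arm == "data_driven") {
    sel <- select_features_datadriven(dat[train, , drop = FALSE], outcome,
                                      importance_quantile, seed, num_trees)
    cols <- sel$features
    Xall <- forest_design(dat, feature_columns(dat))
    miss <- setdiff(cols, names(Xall))
    cols <- setdiff(cols, miss)
    X_tr <- Xall[train, cols, drop = FALSE]
    X_te <- Xall[!train, cols, drop = FALSE]
    retained <- sel$features
  } else {
    red <- select_features_pca(dat[train, , drop = FALSE], n_components)
    S_tr <- red$scores
    S_te <- red$project(dat[!train, , drop = FALSE])
    covs <- cbind(age_years = dat$age_years,
                  gender = dat$gender,
                  bilateral = as.numeric(dat$group == "bilateral"))
    X_tr <- as.data.frame(cbind(S_tr, covs[train, , drop = FALSE]))
    X_te <- as.data.frame(cbind(S_te, covs[!train, , drop = FALSE]))
    names(X_te) <- names(X_tr)
    retained <- red$loadings
  }
  dtr <- X_tr; dtr$..y <- y_tr
  fit <- ranger::ranger(dependent.variable.name = "..y", data = dtr,
                        num.trees = num_trees,
                        mtry = max(1, floor(sqrt(ncol(X_tr)))),
                        seed = as.integer(seed))
  pred_tr <- stats::predict(fit, X_tr)$predictions
  pred_te <- stats::predict(fit, X_te)$predictions
  train_r2 <- 1 - sum((y_tr - pred_tr)^2) / sum((y_tr - mean(y_tr))^2)
  ct <- if (stats::sd(pred_te) > 0)
    stats::cor.test(pred_te, y_te) else list(estimate = NA_real_, p.value = NA_real_)
  structure(list(arm = arm, retained = retained, train_r2 = train_r2,
                 test_r = unname(ct$estimate), test_p = ct$p.value,
                 test_rmse = sqrt(mean((y_te - pred_te)^2)),
                 test_actual = y_te, test_predicted = pred_te,
                 seed = as.integer(seed),
                 train_ids = dat$subject_id[train],
                 test_ids = dat$subject_id[!train],
                 n_train = sum(train), n_test = sum(!train),
                 hyperparams = list(num_trees = num_trees,
                                    mtry = max(1, floor(sqrt(ncol(X_tr)))),
                                    split_fraction = split_fraction,
                                    importance_quantile = importance_quantile,
                                    n_components = n_components)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> arm=%s  train R2=%.3f  test r=%.3f (p=%.3g)  test RMSE=%.2f  n=%d/%d\n",
              x$arm, x$train_r2, x$test_r, x$test_p, x$test_rmse,
              x$n_train, x$n_test))
  invisible(x)
}

#' Group contrasts with Bonferroni correction
#'
#' Welch two-sample t-tests for the three pairwise group contrasts
#' (TDC vs unilateral, TDC vs bilateral, unilateral vs bilateral) per
#' feature, a Shapiro-Wilk normality flag per feature per group, and
#' Bonferroni correction over all computed tests
#' (`corrected p = min(1, raw p x n_tests)`). Zero-variance features are
#' flagged with undefined t.
#'
#' @param table a [assemble_features()] table.
#' @param features character vector of feature columns to contrast.
#' @return a `group_contrast_table` data.frame: per feature and contrast,
#'   group means/sds, `t`, `p_raw`, `p_bonferroni`, normality flags, and
#'   attribute `n_tests`.
#' @export
group_contrasts <- function(table, features) {
  groups <- list(tdc = table$group == "tdc",
                 unilateral = table$group == "unilateral",
                 bilateral = table$group == "bilateral")
  for (g in names(groups)) if (sum(groups[[g]]) < 2)
    stop(sprintf("group '%s' has fewer than 2 rows", g))
  pairs <- list(c("tdc", "unilateral"), c("tdc", "bilateral"),
                c("unilateral", "bilateral"))
  rows <- list()
  for (f in features) {
    v <- table[[f]]
    stats_g <- lapply(groups, function(gi) {
      x <- v[gi & !is.na(v)]
      list(mean = mean(x), sd = stats::sd(x), n = length(x),
           normal = if (length(x) >= 3 && length(x) <= 5000 && stats::sd(x) > 0)
             stats::shapiro.test(x)$p.value > 0.05 else NA)
    })
    for (pr in pairs) {
      a <- v[groups[[pr[1]]]]; b <- v[groups[[pr[2]]]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      zerovar <- stats::sd(a) == 0 || stats::sd(b) == 0 ||
        is.na(stats::sd(a)) || is.na(stats::sd(b))
      tt <- if (!zerovar) stats::t.test(a, b) else NULL
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, contrast = paste(pr, collapse = "_vs_"),
        mean_1 = stats_g[[pr[1]]]$mean, sd_1 = stats_g[[pr[1]]]$sd,
        mean_2 = stats_g[[pr[2]]]$mean, sd_2 = stats_g[[pr[2]]]$sd,
        t = if (zerovar) NA_real_ else unname(tt$statistic),
        p_raw = if (zerovar) NA_real_ else tt$p.value,
        normal_1 = isTRUE(stats_g[[pr[1]]]$normal),
        normal_2 = isTRUE(stats_g[[pr[2]]]$normal),
        flagged = zerovar, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  n_tests <- sum(!is.na(out$p_raw))
  out$p_bonferroni <- pmin(1, out$p_raw * n_tests)
  attr(out, "n_tests") <- n_tests
  class(out) <- c("group_contrast_table", class(out))
  out
}
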