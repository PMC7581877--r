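# Stability-selected gradient-boosted classification of the two patient
# groups: repeated stratified 80/20 splits, stability selection on each
# training partition, small cross-validated hyperparameter search, a
# fold-model ensemble evaluated on the untouched test split, label
# permutation significance, and rescaled relative feature importances.

#' Machine-learning configuration
#'
#' Defaults follow the study design this package targets: 50 repeated
#' stratified 80/20 splits with 5-fold stratified cross-validation on the
#' training partition and a 1000-fold label permutation test. The boosting
#' hyperparameter grid is deliberately small (tree depth 2-3, learning
#' rate 0.05-0.1) because n is far below the number of probes.
#'
#' @param n_repeats Outer repetitions of the split/fit/evaluate cycle.
#' @param test_fraction Held-out fraction per repeat.
#' @param cv_folds Stratified cross-validation folds on the training data.
#' @param n_stability_subsamples Subsamples per stability-selection run.
#' @param stability_subsample_fraction Fraction of training samples per
#'   subsample (class-stratified, without replacement).
#' @param stability_threshold Selection-frequency threshold pi: probes
#'   selected in at least this fraction of subsamples form the stable set.
#' @param stability_colsample Fraction of probes offered to each tree of
#'   the stability-selection fits (a randomized base learner, the usual
#'   companion of subsampling in stability selection; 1 disables it).
#' @param n_permutations Label permutations for the significance test.
#' @param perm_repeats Outer repeats used per permutation (reduced from
#'   `n_repeats` for tractability).
#' @param max_depth,eta Vectors defining the hyperparameter grid.
#' @param nrounds Boosting rounds.
#' @param use_stability Run stability selection inside each repeat
#'   (default); `FALSE` trains on all probes.
#' @param ensemble `"cv_average"` (default): average the fold models'
#'   predicted probabilities on the test split; `"refit"`: one model refit
#'   on the full training partition.
#' @param seed Master seed; splits, subsamples and permutations draw from
#'   independent substreams.
#' @return A list of class `ml_config`.
#' @export
ml_config <- function(n_repeats = 50L, test_fraction = 0.2, cv_folds = 5L,
                      n_stability_subsamples = 50L,
                      stability_subsample_fraction = 0.5,
                      stability_threshold = 0.6,
                      n_permutations = 1000L, perm_repeats = 5L,
                      stability_colsample = 0.5,
                      max_depth = c(2L, 3L), eta = c(0.05, 0.1),
                      nrounds = 150L, use_stability = TRUE,
                      ensemble = c("cv_average", "refit"), seed = 1L) {
  stopifnot(n_repeats >= 1, cv_folds >= 2, n_stability_subsamples >= 1,
            test_fraction > 0, test_fraction < 1,
            stability_subsample_fraction > 0, stability_subsample_fraction < 1,
            stability_threshold > 0, stability_threshold <= 1,
            n_permutations >= 1, nrounds >= 1)
  structure(
    list(n_repeats = as.integer(n_repeats), test_fraction = test_fraction,
         cv_folds = as.integer(cv_folds),
         n_stability_subsamples = as.integer(n_stability_subsamples),
         stability_subsample_fraction = stability_subsample_fraction,
         stability_threshold = stability_threshold,
         n_permutations = as.integer(n_permutations),
         perm_repeats = as.integer(perm_repeats),
         stability_colsample = stability_colsample,
         grid = expand.grid(max_depth = as.integer(max_depth), eta = eta),
         nrounds = as.integer(nrounds),
         use_stability = use_stability,
         ensemble = match.arg(ensemble),
         seed = as.integer(seed)),
    class = "ml_config"
  )
}

# Class-stratified index draw: for each class, take floor/round(frac * n_c)
# indices without replacement. Returns the drawn indices.
stratified_indices <- function(labels, fraction, seed) {
  with_seed(seed, {
    unlist(lapply(split(seq_along(labels), labels), function(idx) {
      k <- max(1L, round(fraction * length(idx)))
      sample(idx, k)
    }), use.names = FALSE)
  })
}

# Stratified fold assignment (1..k per sample).
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (idx in split(seq_along(labels), labels)) {
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Single-thread boosted-tree fit with exact splits; deterministic given the
# data, parameters and seed. `colsample` < 1 randomizes the features
# offered per tree (used by the stability-selection phase).
fit_gbm <- function(X, y01, max_depth, eta, nrounds, colsample = 1,
                    seed = 0L) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y01)
  # column sampling draws from R's RNG in the R binding; pin it so fits are
  # reproducible regardless of the surrounding RNG state
  with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, subsample = 1,
                  colsample_bytree = colsample, tree_method = "exact",
                  seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0
  ))
}

# Total-gain importance per feature, normalized to sum to 1. Computed from
# the dumped trees rather than xgb.importance(), which errors on
# single-feature models in some xgboost builds; a model with no splits has
# all-zero importance.
gbm_importance <- function(model, feature_names) {
  out <- setNames(numeric(length(feature_names)), feature_names)
  trees <- tryCatch(xgboost::xgb.model.dt.tree(model = model),
                    error = function(e) NULL)
  if (!is.null(trees)) {
    splits <- trees[trees$Feature != "Leaf", c("Feature", "Gain")]
    if (nrow(splits)) {
      gain <- tapply(splits$Gain, splits$Feature, sum)
      gain <- gain[names(gain) %in% feature_names]
      out[names(gain)] <- gain / sum(gain)
    }
  }
  out
}

auc_score <- function(labels, scores) {
  # probability that a random "pos" sample scores higher than a random
  # "neg" sample (rank/Mann-Whitney form; ties get half credit)
  pos <- scores[labels == "pos"]
  neg <- scores[labels == "neg"]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Stability selection with gradient-boosted trees
#'
#' Repeatedly subsamples the training data (class-stratified, default 50%
#' without replacement), fits a boosted-tree classifier on each subsample,
#' and records which probes receive nonzero gain importance. A probe's
#' selection frequency is the fraction of subsamples selecting it; the
#' stable set is every probe with frequency at or above the configured
#' threshold pi.
#'
#' @param train_betas Numeric matrix, training samples x probes.
#' @param train_labels Character vector of `"neg"`/`"pos"` labels.
#' @param config An [ml_config()].
#' @param seed Seed for the subsample substreams.
#' @return A tibble `probe_id`, `frequency`, `stable` (frequency >= pi),
#'   sorted by decreasing frequency then probe id.
#' @export
stability_select <- function(train_betas, train_labels, config, seed = config$seed) {
  stopifnot(inherits(config, "ml_config"))
  if (min(table(train_labels)) < 2) {
    abort("need at least 2 samples per class for stability selection")
  }
  b <- config$n_stability_subsamples
  seeds <- derive_seeds(seed, b, salt = 3L)
  pars <- config$grid[1, ]
  counts <- setNames(numeric(ncol(train_betas)), colnames(train_betas))
  for (i in seq_len(b)) {
    idx <- stratified_indices(train_labels, config$stability_subsample_fraction,
                              seeds[i])
    model <- fit_gbm(train_betas[idx, , drop = FALSE],
                     as.numeric(train_labels[idx] == "pos"),
                     pars$max_depth, pars$eta, config$nrounds,
                     colsample = config$stability_colsample,
                     seed = seeds[i] %% 100000L)
    counts <- counts + (gbm_importance(model, colnames(train_betas)) > 0)
  }
  tibble(probe_id = names(counts), frequency = unname(counts) / b) %>%
    mutate(stable = .data$frequency >= config$stability_threshold) %>%
    arrange(desc(.data$frequency), .data$probe_id)
}

# One repeat: stratified split, optional stability selection, CV tuning,
# fold-ensemble prediction on the untouched test split.
run_one_repeat <- function(X, labels, config, seed) {
  seeds <- derive_seeds(seed, 4L, salt = 5L)
  n <- length(labels)
  for (try in 1:10) {
    train_idx <- stratified_indices(labels, 1 - config$test_fraction,
                                    seeds[1] + try - 1L)
    test_idx <- setdiff(seq_len(n), train_idx)
    if (length(unique(labels[test_idx])) == 2L) break
    inform("test split lost a class; resplitting with next seed substream")
  }
  Xtr <- X[train_idx, , drop = FALSE]
  ytr <- labels[train_idx]
  Xte <- X[test_idx, , drop = FALSE]
  yte <- labels[test_idx]

  if (config$use_stability) {
    sel <- stability_select(Xtr, ytr, config, seed = seeds[2])
    stable <- sel$probe_id[sel$stable]
    if (length(stable) == 0L) {
      inform("stable set empty; falling back to all probes for this repeat")
      stable <- colnames(X)
    }
  } else {
    sel <- tibble(probe_id = colnames(X), frequency = NA_real_, stable = NA)
    stable <- colnames(X)
  }
  Xtr_s <- Xtr[, stable, drop = FALSE]
  Xte_s <- Xte[, stable, drop = FALSE]

  folds <- stratified_folds(ytr, config$cv_folds, seeds[3])
  grid <- config$grid
  cv_auc <- vapply(seq_len(nrow(grid)), function(gi) {
    aucs <- vapply(seq_len(config$cv_folds), function(f) {
      tr <- folds != f
      model <- fit_gbm(Xtr_s[tr, , drop = FALSE],
                       as.numeric(ytr[tr] == "pos"),
                       grid$max_depth[gi], grid$eta[gi], config$nrounds)
      auc_score(ytr[!tr], stats::predict(model, Xtr_s[!tr, , drop = FALSE]))
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  best <- which.max(cv_auc)

  importance <- setNames(numeric(ncol(X)), colnames(X))
  if (config$ensemble == "cv_average") {
    preds <- matrix(0, nrow(Xte_s), config$cv_folds)
    for (f in seq_len(config$cv_folds)) {
      model <- fit_gbm(Xtr_s[folds != f, , drop = FALSE],
                       as.numeric(ytr[folds != f] == "pos"),
                       grid$max_depth[best], grid$eta[best], config$nrounds)
      preds[, f] <- stats::predict(model, Xte_s)
      imp <- gbm_importance(model, stable)
      importance[stable] <- importance[stable] + imp / config$cv_folds
    }
    score <- rowMeans(preds)
  } else {
    model <- fit_gbm(Xtr_s, as.numeric(ytr == "pos"),
                     grid$max_depth[best], grid$eta[best], config$nrounds)
    score <- stats::predict(model, Xte_s)
    importance[stable] <- gbm_importance(model, stable)
  }
  list(auc = auc_score(yte, score), selection = sel, importance = importance)
}

#' Repeated-split training and evaluation of the group classifier
#'
#' For each of `n_repeats` outer repetitions: draw a stratified
#' train/test split, run stability selection on the training partition,
#' tune the boosting hyperparameters by stratified cross-validation
#' restricted to the stable set, predict the untouched test split with the
#' averaged fold models, and record the test ROC AUC. Selection
#' frequencies and gain importances are averaged over repeats, and
#' importances rescaled so the top probe scores 100.
#'
#' @param dataset A [methyl_dataset()] (QC-filtered upstream).
#' @param config An [ml_config()].
#' @return An object of class `ml_report`: `auc_mean`, `auc_sd`, `aucs`
#'   (per repeat), `selection` (tibble `probe_id`, `frequency`),
#'   `importance` (tibble `probe_id`, `relative_importance`, `direction`),
#'   `permutation_p` (`NA` until [permutation_test()] is run), `config`.
#' @export
train_evaluate <- function(dataset, config = ml_config()) {
  stopifnot(inherits(dataset, "methyl_dataset"), inherits(config, "ml_config"))
  ord <- order(dataset$samples$sample_id)
  X <- dataset$betas[ord, , drop = FALSE]
  labels <- dataset$samples$group[ord]
  if (length(unique(labels)) != 2L) abort("both groups must be present")
  seeds <- derive_seeds(config$seed, config$n_repeats, salt = 11L)
  runs <- lapply(seq_len(config$n_repeats), function(r) {
    run_one_repeat(X, labels, config, seeds[r])
  })
  aucs <- vapply(runs, `[[`, numeric(1), "auc")
  sel_mat <- vapply(runs, function(r) {
    r$selection$frequency[match(colnames(X), r$selection$probe_id)]
  }, numeric(ncol(X)))
  selection <- tibble(
    probe_id = colnames(X),
    frequency = rowMeans(matrix(sel_mat, nrow = ncol(X)))
  ) %>% arrange(desc(.data$frequency), .data$probe_id)
  imp <- rowMeans(vapply(runs, `[[`, numeric(ncol(X)), "importance"))
  names(imp) <- colnames(X)
  importance <- if (any(imp > 0)) {
    ri <- rescale_importances(imp[imp > 0])
    dirs <- annotate_directions(dataset, ri$probe_id)
    left_join(ri, dirs, by = "probe_id")
  } else {
    tibble(probe_id = character(), relative_importance = numeric(),
           direction = character(), tie = logical())
  }
  structure(
    list(auc_mean = mean(aucs), auc_sd = sd(aucs), aucs = aucs,
         selection = selection, importance = importance,
         permutation_p = NA_real_, config = config),
    class = "ml_report"
  )
}

#' Rescale raw feature importances to a 0-100 relative scale
#'
#' `relative = 100 * raw / max(raw)`, sorted by decreasing importance with
#' ties broken lexicographically by probe id, so the top feature is always
#' exactly 100.
#'
#' @param raw Named non-negative numeric vector of raw importances.
#' @return A tibble `probe_id`, `relative_importance`.
#' @export
rescale_importances <- function(raw) {
  stopifnot(is.numeric(raw), !is.null(names(raw)))
  if (any(raw < 0)) abort("raw importances must be non-negative")
  if (length(raw) == 0L || all(raw == 0)) abort("no informative features")
  tibble(probe_id = names(raw),
         relative_importance = 100 * unname(raw) / max(raw)) %>%
    arrange(desc(.data$relative_importance), .data$probe_id)
}

#' Hyper/hypomethylation direction of probes
#'
#' Direction of the difference in median beta between the two groups:
#' `"hyper"` when the mutation-negative median exceeds the
#' mutation-positive median, `"hypo"` when it is lower. Exact ties are
#' flagged and the direction withheld (`NA`).
#'
#' @param dataset A [methyl_dataset()].
#' @param probe_ids Probes to annotate.
#' @return A tibble `probe_id`, `direction`, `tie`.
#' @export
annotate_directions <- function(dataset, probe_ids) {
  missing <- setdiff(probe_ids, colnames(dataset$betas))
  if (length(missing)) {
    abort(paste0("probe(s) not in dataset: ", paste(missing, collapse = ", ")))
  }
  B <- dataset$betas[, probe_ids, drop = FALSE]
  neg <- dataset$samples$group == "neg"
  med_neg <- apply(B[neg, , drop = FALSE], 2, median)
  med_pos <- apply(B[!neg, , drop = FALSE], 2, median)
  tibble(
    probe_id = probe_ids,
    direction = dplyr::case_when(
      med_neg > med_pos ~ "hyper",
      med_neg < med_pos ~ "hypo",
      TRUE ~ NA_character_
    ),
    tie = med_neg == med_pos
  )
}

#' Label-permutation significance of the classifier AUC
#'
#' Reshuffles the group labels (methylation profiles kept intact), reruns
#' the repeated-split evaluation at a reduced number of outer repeats per
#' permutation, and compares the permuted mean AUCs with the observed one
#' using the add-one convention:
#' `p = (1 + #\{AUC_perm >= AUC_obs\}) / (1 + n_permutations)`.
#'
#' @param dataset A [methyl_dataset()].
#' @param config An [ml_config()]; `n_permutations` and `perm_repeats`
#'   control the test.
#' @param observed_auc Observed mean AUC (e.g. `report$auc_mean`).
#' @return A list: `p` (permutation p-value), `perm_aucs`.
#' @export
permutation_test <- function(dataset, config, observed_auc) {
  stopifnot(inherits(dataset, "methyl_dataset"), inherits(config, "ml_config"))
  if (config$n_permutations < 19) abort("n_permutations must be at least 19")
  perm_config <- config
  perm_config$n_repeats <- config$perm_repeats
  seeds <- derive_seeds(config$seed, config$n_permutations, salt = 17L)
  perm_aucs <- vapply(seq_len(config$n_permutations), function(i) {
    ds <- dataset
    ds$samples$group <- with_seed(seeds[i], sample(ds$samples$group))
    perm_config$seed <- seeds[i]
    train_evaluate(ds, perm_config)$auc_mean
  }, numeric(1))
  list(
    p = (1 + sum(perm_aucs >= observed_auc)) / (1 + config$n_permutations),
    perm_aucs = perm_aucs
  )
}

#' Full classifier analysis: evaluation plus permutation significance
#'
#' Convenience wrapper running [train_evaluate()] then
#' [permutation_test()], storing the permutation p in the report.
#'
#' @inheritParams train_evaluate
#' @return An `ml_report` with `permutation_p` filled in and the permuted
#'   AUCs under `perm_aucs`.
#' @export
run_ml <- function(dataset, config = ml_config()) {
  report <- train_evaluate(dataset, config)
  perm <- permutation_test(dataset, config, report$auc_mean)
  report$permutation_p <- perm$p
  report$perm_aucs <- perm$perm_aucs
  report
}

#' @export
print.ml_report <- function(x, ...) {
  cat(sprintf("<ml_report> test AUC %.3f +/- %.3f over %d repeats\n",
              x$auc_mean, x$auc_sd, length(x$aucs)))
  if (!is.na(x$permutation_p)) {
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$permutation_p, length(x$perm_aucs)))
  }
  if (nrow(x$importance)) {
    cat("  top features:\n")
    print(head(x$importance, 5))
  }
  invisible(x)
}
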