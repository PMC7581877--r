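test_that("importance rescaling pins the top feature at 100", {
  out <- rescale_importances(c(a = 2, b = 1, c = 0.5))
  expect_equal(out$relative_importance, c(100, 50, 25))
  expect_equal(out$probe_id, c("a", "b", "c"))

  tie <- rescale_importances(c(zz = 3, aa = 3))
  expect_equal(tie$relative_importance, c(100, 100))
  expect_equal(tie$probe_id, c("aa", "zz")) # lexicographic tie-break

  expect_error(rescale_importances(c(a = 0, b = 0)), "no informative")
  # scale invariance
  set.seed(2)
  raw <- setNames(runif(10), letters[1:10])
  expect_equal(rescale_importances(raw * 7.3), rescale_importances(raw))
})

test_that("methylation direction follows the group medians", {
  cfg <- cohort_config(n_probes = 250, noise_sd_logit = 0.02, seed = 51)
  base <- generate_cohort(cfg)
  probes <- pick_mid_probes(base, 2)
  ds <- generate_cohort(cfg, spikes = list(
    spike_spec(probes[1], +0.05), spike_spec(probes[2], -0.05)
  ))
  dirs <- annotate_directions(ds, probes)
  expect_equal(dirs$direction, c("hyper", "hypo"))
  expect_false(any(dirs$tie))

  flat <- make_dataset(matrix(0.5, 6, 2))
  tie <- annotate_directions(flat, "cg00001")
  expect_true(tie$tie)
  expect_true(is.na(tie$direction))
})

test_that("a perfectly separating probe gives AUC 1 and selection frequency 1", {
  set.seed(53)
  n <- 40
  group <- rep(c("neg", "pos"), each = n / 2)
  b <- matrix(runif(n * 60, 0.3, 0.7), n, 60)
  b[, 1] <- ifelse(group == "neg", 0.85, 0.15) + rnorm(n, 0, 0.01)
  ds <- make_dataset(pmin(pmax(b, 0.01), 0.99), group = group)

  sel <- stability_select(ds$betas, group, lean_ml_config(), seed = 5)
  expect_equal(sel$frequency[sel$probe_id == colnames(ds$betas)[1]], 1)

  rep <- suppressMessages(train_evaluate(ds, lean_ml_config(seed = 5)))
  expect_equal(rep$auc_mean, 1)
  expect_equal(rep$importance$probe_id[1], colnames(ds$betas)[1])
  expect_equal(rep$importance$relative_importance[1], 100)
})

test_that("results are deterministic and invariant to sample order", {
  cfg <- cohort_config(n_group_neg = 20, n_group_pos = 16, n_probes = 250,
                       seed = 55)
  base <- generate_cohort(cfg)
  spikes <- lapply(pick_mid_probes(base, 3), spike_spec, delta_beta = 0.1)
  ds <- generate_cohort(cfg, spikes = spikes)
  mc <- lean_ml_config(seed = 9)

  r1 <- suppressMessages(train_evaluate(ds, mc))
  r2 <- suppressMessages(train_evaluate(ds, mc))
  expect_identical(r1$aucs, r2$aucs)
  expect_identical(r1$importance, r2$importance)
  expect_identical(r1$selection, r2$selection)

  perm <- sample(nrow(ds$betas))
  ds_perm <- methyl_dataset(ds$betas[perm, , drop = FALSE],
                            ds$samples[perm, ], ds$probes)
  r3 <- suppressMessages(train_evaluate(ds_perm, mc))
  expect_identical(r1$aucs, r3$aucs)
  expect_identical(r1$importance, r3$importance)
})

test_that("our AUC equals the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(57)
  labels <- sample(c("neg", "pos"), 60, replace = TRUE, prob = c(0.6, 0.4))
  scores <- runif(60) + 0.3 * (labels == "pos")
  ours <- fhmethyl:::auc_score(labels, scores)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c("neg", "pos"), direction = "<", quiet = TRUE
  )))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("noise probes rarely reach the stability threshold", {
  ok <- 0L
  for (r in 1:5) {
    set.seed(60 + r)
    n <- 60
    b <- matrix(runif(n * 1000, 0.2, 0.8), n, 1000)
    labels <- sample(rep(c("neg", "pos"), each = n / 2))
    sel <- stability_select(b |> `colnames<-`(sprintf("cg%04d", 1:1000)),
                            labels,
                            lean_ml_config(n_stability_subsamples = 20L),
                            seed = 60 + r)
    if (max(sel$frequency) < 0.6) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("the permutation p-value uses the add-one convention", {
  cfg <- cohort_config(n_group_neg = 12, n_group_pos = 12, n_probes = 250,
                       seed = 61)
  ds <- generate_cohort(cfg)
  mc <- lean_ml_config(n_repeats = 1L, n_stability_subsamples = 5L,
                       nrounds = 30L, seed = 7)
  # an observed AUC above every permuted AUC -> p = 1 / (1 + 19) = 0.05
  pt <- suppressMessages(permutation_test(ds, mc, observed_auc = 2))
  expect_equal(pt$p, 0.05)
  expect_length(pt$perm_aucs, 19L)
  # an observed AUC below every permuted AUC -> p = 1
  pt2 <- suppressMessages(permutation_test(ds, mc, observed_auc = -1))
  expect_equal(pt2$p, 1)
})

test_that("configuration invariants are enforced", {
  expect_error(ml_config(test_fraction = 1.2))
  expect_error(ml_config(stability_threshold = 0))
  expect_error(ml_config(n_repeats = 0))
  expect_equal(ml_config()$n_repeats, 50L)
  expect_equal(ml_config()$n_permutations, 1000L)
})
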