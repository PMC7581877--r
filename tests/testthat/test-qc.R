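test_that("probe exclusion applies the rules in order, once per probe", {
  b <- matrix(runif(10), 2, 5)
  ds <- make_dataset(b)
  ds$probes$probe_id <- LETTERS[1:5]
  colnames(ds$betas) <- LETTERS[1:5]
  ds$probes$cross_reactive <- c(1L, 1L, 0L, 0L, 0L)
  ds$probes$maf_cpg <- c(NA, NA, 0.02, NA, NA)
  ds$probes$maf_sbe <- c(NA, NA, NA, 0.005, NA)

  out <- suppressMessages(filter_probes(ds))
  expect_equal(out$dataset$probes$probe_id, c("D", "E"))
  expect_equal(out$report$n_retained, 2L)
  expect_equal(out$report$n_removed_cross_reactive, 2L)
  expect_equal(out$report$n_removed_snp, 1L)
  expect_equal(out$report$n_input,
               out$report$n_retained + length(out$removed_ids))

  # the MAF rule is a strict inequality: exactly 0.01 is retained
  ds$probes$cross_reactive <- 0L
  ds$probes$maf_cpg <- c(0.01, NA, 0.02, NA, NA)
  ds$probes$maf_sbe <- NA_real_
  out2 <- suppressMessages(filter_probes(ds))
  expect_true("A" %in% out2$dataset$probes$probe_id)
  expect_false("C" %in% out2$dataset$probes$probe_id)
})

test_that("filtering clean data is the identity, and filtering is idempotent", {
  set.seed(5)
  ds <- make_dataset(matrix(runif(40), 4, 10))
  out <- suppressMessages(filter_probes(ds))
  expect_equal(out$dataset$betas, ds$betas)
  expect_equal(out$report$n_retained, 10L)

  cfg <- cohort_config(n_probes = 250, seed = 6)
  noisy <- generate_cohort(cfg)
  once <- suppressMessages(filter_probes(noisy))
  twice <- suppressMessages(filter_probes(once$dataset))
  expect_equal(twice$dataset$betas, once$dataset$betas)
  expect_equal(twice$report$n_retained, once$report$n_retained)
})

test_that("sex-chromosome probes are retained by default, dropped on request", {
  ds <- make_dataset(matrix(runif(8), 2, 4))
  ds$probes$chrom <- c("chr1", "chrX", "chrY", "chr2")
  keep <- suppressMessages(filter_probes(ds))
  expect_equal(keep$report$n_retained, 4L)
  drop <- suppressMessages(filter_probes(ds, drop_sex = TRUE))
  expect_equal(drop$report$n_removed_sex, 2L)
  expect_equal(drop$dataset$probes$chrom, c("chr1", "chr2"))
})

test_that("beta/M transform matches its closed form and symmetries", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  b <- seq(0.01, 0.99, by = 0.01)
  expect_equal(beta_to_m(1 - b), -beta_to_m(b))
  expect_true(all(diff(beta_to_m(b)) > 0))
  expect_equal(m_to_beta(beta_to_m(b)), b)
})

test_that("PCA explained-variance fractions behave like eigenvalues", {
  set.seed(11)
  n <- 400
  b <- cbind(0.5 + rnorm(n, 0, 0.08), 0.5 + rnorm(n, 0, 0.04))
  b <- pmin(pmax(b, 0.01), 0.99)
  ds <- make_dataset(b)
  pca <- pca_summary(ds, k = 2)
  expect_equal(sum(pca$explained$fraction), 1)
  expect_true(all(diff(pca$explained$fraction) <= 1e-12))
  # variances 0.08^2 vs 0.04^2 -> fractions ~ (0.8, 0.2)
  expect_equal(pca$explained$fraction, c(0.8, 0.2), tolerance = 0.05)

  # duplicated sample rows only: rank-1 centered matrix
  b2 <- matrix(rep(c(0.2, 0.8, 0.2, 0.8), each = 3), nrow = 4, byrow = TRUE)
  b2 <- b2 + rep(c(0, 0.1, 0, 0.1), times = 3)[1:4] # two distinct rows
  ds2 <- make_dataset(matrix(c(rep(c(0.2, 0.3, 0.4), 2),
                               rep(c(0.6, 0.7, 0.8), 2)), 4, 3, byrow = TRUE))
  pca2 <- pca_summary(ds2, k = 2)
  expect_gt(pca2$explained$fraction[1], 0.999)

  # probe order does not change the spectrum
  perm <- sample(ncol(ds$betas))
  ds_perm <- make_dataset(ds$betas[, perm, drop = FALSE])
  expect_equal(pca_summary(ds_perm, k = 2)$explained$fraction,
               pca$explained$fraction)

  expect_error(pca_summary(ds, k = 0), "positive")
})

test_that("PC scores track the variables that drive them", {
  cfg <- cohort_config(n_probes = 250, seed = 13)
  ds <- generate_cohort(cfg)
  pca <- pca_summary(ds, k = 4)
  vars <- dplyr::bind_cols(ds$samples[, c("sample_id", "group", "age")],
                           tibble::as_tibble(ds$truth$cell_proportions))
  corr <- pca_correlate(pca, vars)
  expect_true(all(abs(corr$r) <= 1 + 1e-12))
  # granulocyte fraction dominates mixture variation -> strong loading on PC1
  gran <- corr[corr$variable == "Gran" & corr$component == 1, ]
  expect_gt(abs(gran$r), 0.5)
})
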