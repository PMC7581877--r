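test_that("two-group fit matches the hand-computed OLS solution", {
  b <- matrix(c(0.1, 0.2, 0.3, 0.4), ncol = 1)
  ds <- make_dataset(b, group = c("pos", "pos", "neg", "neg"))
  fit <- fit_dmp(ds, include_age = FALSE)
  tab <- tidy(fit)
  expect_equal(tab$beta_hat, 0.2)
  expect_equal(tab$se, sqrt(0.005))
  expect_equal(tab$t_stat, 0.2 / sqrt(0.005), tolerance = 1e-12)
  expect_equal(tab$df, 2L)
  expect_equal(tab$p_raw, 2 * pt(-0.2 / sqrt(0.005), 2), tolerance = 1e-12)
})

test_that("per-probe OLS matches brute-force normal equations to 1e-10", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 20
    b <- matrix(runif(n * 10, 0.2, 0.8), n, 10)
    group <- sample(rep(c("neg", "pos"), each = n / 2))
    age <- runif(n, 20, 80)
    ds <- make_dataset(b, group = group, age = age)
    covs <- tibble::tibble(sample_id = ds$samples$sample_id,
                           c1 = runif(n), c2 = runif(n))
    fit <- fit_dmp(ds, proportions = covs)
    # independent oracle: explicit normal equations per probe
    X <- cbind(1, as.numeric(group == "neg"), age, covs$c1, covs$c2)
    XtXi <- solve(t(X) %*% X)
    for (j in seq_len(ncol(b))) {
      beta <- XtXi %*% t(X) %*% b[, j]
      res <- b[, j] - X %*% beta
      s2 <- sum(res^2) / (n - 5)
      se <- unname(sqrt(s2 * XtXi[2, 2]))
      expect_equal(fit$table$beta_hat[j], unname(beta[2, 1]), tolerance = 1e-10)
      expect_equal(fit$table$se[j], se, tolerance = 1e-10)
      expect_equal(fit$table$t_stat[j], unname(beta[2, 1]) / se, tolerance = 1e-10)
    }
  }
})

test_that("constant probes are flagged degenerate, collinearity is an error", {
  b <- cbind(rep(0.4, 8), runif(8, 0.3, 0.7))
  ds <- make_dataset(b)
  expect_warning(fit <- fit_dmp(ds, include_age = FALSE), "degenerate")
  expect_true(fit$table$degenerate[1])
  expect_true(is.na(fit$table$t_stat[1]))
  expect_false(fit$table$degenerate[2])

  covs <- tibble::tibble(sample_id = ds$samples$sample_id,
                         dup = as.numeric(ds$samples$group == "neg"))
  expect_error(fit_dmp(ds, proportions = covs, include_age = FALSE),
               "rank deficient")
})

test_that("variance moderation agrees with the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(41)
  n <- 24
  # heteroskedastic probes so the prior df is finite
  sds <- runif(200, 0.02, 0.25)
  b <- 0.5 + matrix(rnorm(n * 200), n, 200) %*% diag(sds) / 4
  b <- pmin(pmax(b, 0.01), 0.99)
  group <- rep(c("neg", "pos"), each = n / 2)
  age <- runif(n, 20, 80)
  ds <- make_dataset(b, group = group, age = age)
  fit <- moderate_variances(fit_dmp(ds))

  X <- cbind(1, as.numeric(group == "neg"), age)
  lfit <- limma::eBayes(limma::lmFit(t(b), X))
  expect_true(is.finite(fit$eb$d0))
  expect_equal(fit$eb$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(fit$eb$s02, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(fit$table$t_mod, unname(lfit$t[, 2]), tolerance = 1e-6)
  expect_equal(fit$table$p_mod, unname(lfit$p.value[, 2]), tolerance = 1e-6)

  # homogeneous-variance data collapses to the pooled limma solution
  set.seed(42)
  b2 <- matrix(runif(n * 200, 0.2, 0.8), n, 200)
  ds2 <- make_dataset(b2, group = group, age = age)
  fit2 <- moderate_variances(fit_dmp(ds2))
  lfit2 <- limma::eBayes(limma::lmFit(t(b2), X))
  expect_equal(fit2$eb$d0, lfit2$df.prior)
  expect_equal(fit2$eb$s02, lfit2$s2.prior, tolerance = 1e-6)
  expect_equal(fit2$table$t_mod, unname(lfit2$t[, 2]), tolerance = 1e-6)
})

test_that("the variance-prior estimator recovers simulated prior parameters", {
  set.seed(43)
  d0 <- 4; s02 <- 0.01; df <- 10; n <- 1000
  sigma2 <- d0 * s02 / rchisq(n, d0)        # scaled inverse-chi-square truth
  s2 <- sigma2 * rchisq(n, df) / df          # observed residual variances
  fake <- structure(list(
    table = tibble::tibble(
      probe_id = sprintf("p%04d", 1:n), beta_hat = 1, se = sqrt(s2),
      t_stat = 1 / sqrt(s2), df = df, p_raw = 0.5, sigma2 = s2,
      degenerate = FALSE),
    df = df, n = df + 2, scale = "beta"), class = "dmp_fit")
  out <- moderate_variances(fake)
  expect_gt(out$eb$d0, d0 / 2)
  expect_lt(out$eb$d0, d0 * 2)
  expect_equal(out$eb$s02, s02, tolerance = 0.2)

  # identical variances: complete shrinkage to the pooled value
  fake$table$sigma2 <- rep(0.01, n)
  fake$table$se <- sqrt(fake$table$sigma2)
  out2 <- moderate_variances(fake)
  expect_true(is.infinite(out2$eb$d0))
  expect_equal(out2$table$df_mod[1], Inf)
})

test_that("empirical-null correction recovers the null SD within 5%", {
  for (s in c(0.8, 1.0, 1.5)) {
    set.seed(42)
    z <- rnorm(10000, 0, s)
    f <- correct_inflation(z)$fit
    expect_true(f$converged)
    expect_equal(f$sigma0, s, tolerance = 0.05)
  }
  set.seed(42)
  z1 <- rnorm(10000)
  f1 <- correct_inflation(z1)$fit
  expect_equal(f1$lambda_gc, 1, tolerance = 0.05)

  # contaminated case: tails are absorbed by the non-null components
  set.seed(1)
  zmix <- c(rnorm(9500), rnorm(500, 4, 1))
  fmix <- correct_inflation(zmix)$fit
  expect_equal(fmix$sigma0, 1, tolerance = 0.05)
  expect_lt(fmix$pi0, 1)

  # too few statistics: identity correction with a warning
  zs <- rnorm(100)
  expect_warning(out <- correct_inflation(zs), "identity")
  expect_equal(out$fit$sigma0, 1)
  expect_equal(out$z_corrected, zs)
})

test_that("corrected z-scores rescale by the fitted null", {
  set.seed(7)
  z <- rnorm(5000, 0.2, 1.3)
  out <- correct_inflation(z)
  expect_equal(out$z_corrected, (z - out$fit$mu0) / out$fit$sigma0)
  expect_equal(out$p_corrected, 2 * pnorm(-abs(out$z_corrected)),
               tolerance = 1e-12)
})

test_that("Benjamini-Hochberg matches the hand computation and is monotone", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(3)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-12))
  expect_equal(order(q[order(p)]), 1:50) # q preserves the p ordering
})

test_that("a 1.3-point spike is detected in most replicates at low noise", {
  hits <- 0L
  est <- numeric(10)
  for (r in 1:10) {
    cfg <- cohort_config(n_probes = 250, noise_sd_logit = 0.04,
                         seed = 100 + r)
    ds <- generate_cohort(cfg, spikes = spike_spec("cg00574958", -0.013))
    fl <- suppressMessages(filter_probes(ds))
    fit <- suppressWarnings(run_dmp(fl$dataset, inflation_correct = FALSE))
    row <- fit$table[fit$table$probe_id == "cg00574958", ]
    est[r] <- row$beta_hat
    if (row$q_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 6L)
  expect_lt(abs(mean(est) - (-0.013)), 0.004)
})
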