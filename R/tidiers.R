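# broom-style tidiers for the pipeline's fitted objects.

#' Tidy a per-probe differential methylation fit
#'
#' @param x A `dmp_fit` from [fit_dmp()] or [run_dmp()].
#' @param ... Unused.
#' @return The per-probe statistics tibble (one row per probe).
#' @method tidy dmp_fit
#' @export
tidy.dmp_fit <- function(x, ...) x$table

#' One-row summary of a differential methylation fit
#'
#' @param x A `dmp_fit`.
#' @param ... Unused.
#' @return A one-row tibble: probe/sample counts, modeling scale, residual
#'   df, the variance-prior parameters when moderation was run, and the
#'   empirical-null parameters when inflation correction was run.
#' @method glance dmp_fit
#' @export
glance.dmp_fit <- function(x, ...) {
  out <- tibble(
    n_probes = nrow(x$table),
    n_samples = x$n,
    n_degenerate = sum(x$table$degenerate),
    scale = x$scale,
    df_residual = x$df
  )
  if (!is.null(x$eb)) {
    out$d0 <- x$eb$d0
    out$s02 <- x$eb$s02
  }
  if (!is.null(x$inflation)) {
    out$mu0 <- x$inflation$mu0
    out$sigma0 <- x$inflation$sigma0
    out$pi0 <- x$inflation$pi0
    out$lambda_gc <- x$inflation$lambda_gc
  }
  out
}

#' Tidy an empirical-null inflation fit
#'
#' @param x An `inflation_fit` from [correct_inflation()].
#' @param ... Unused.
#' @return A one-row tibble of the null parameters.
#' @method tidy inflation_fit
#' @export
tidy.inflation_fit <- function(x, ...) {
  tibble(mu0 = x$mu0, sigma0 = x$sigma0, mu1 = x$mu1, sigma1 = x$sigma1,
         pi0 = x$pi0, lambda_gc = x$lambda_gc, converged = x$converged,
         n_iter = x$n_iter, n = x$n)
}

#' Tidy a classifier report
#'
#' @param x An `ml_report` from [train_evaluate()] or [run_ml()].
#' @param ... Unused.
#' @return A tibble of the scored probes: `probe_id`,
#'   `relative_importance`, `direction`, `tie`, `frequency` (mean
#'   stability-selection frequency).
#' @method tidy ml_report
#' @export
tidy.ml_report <- function(x, ...) {
  left_join(x$importance, x$selection, by = "probe_id")
}

#' One-row summary of a classifier report
#'
#' @param x An `ml_report`.
#' @param ... Unused.
#' @return A one-row tibble: `auc_mean`, `auc_sd`, `n_repeats`,
#'   `n_selected` (probes with nonzero aggregated importance),
#'   `permutation_p`.
#' @method glance ml_report
#' @export
glance.ml_report <- function(x, ...) {
  tibble(
    auc_mean = x$auc_mean,
    auc_sd = x$auc_sd,
    n_repeats = length(x$aucs),
    n_selected = nrow(x$importance),
    permutation_p = x$permutation_p
  )
}
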