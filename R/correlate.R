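# Correlation-based in-silico validation of methylation against
# expression or phenotype tables.

#' Correlate two paired vectors
#'
#' Pearson correlation on the raw values or Spearman correlation on
#' average ranks, with a two-sided p-value from the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Pairs with a missing value in either vector are dropped first.
#'
#' @param x,y Numeric vectors of equal length (at least 3 complete pairs).
#' @param method `"pearson"` or `"spearman"`.
#' @return A one-row tibble `r`, `p`, `n`, `method`, `degenerate`
#'   (`TRUE` when either vector has zero variance, in which case `r` and
#'   `p` are `NA`).
#' @export
#' @examples
#' correlate(1:5, c(5, 4, 3, 2, 1), method = "spearman")
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(r = NA_real_, p = NA_real_, n = n, method = method,
                  degenerate = TRUE))
  }
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- .Machine$double.xmin
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- max(2 * pt(-abs(t), n - 2), .Machine$double.xmin)
  }
  tibble(r = r, p = p, n = n, method = method, degenerate = FALSE)
}

#' Correlate probe methylation with sample-level variables
#'
#' For every (probe, variable) pair, computes both Pearson and Spearman
#' correlations of the probe's betas against the variable across samples —
#' a local replacement for database lookups of methylation-expression
#' correlations, usable with any expression or phenotype table keyed by
#' sample id.
#'
#' @param dataset A [methyl_dataset()].
#' @param table Data frame with a `sample_id` column and one or more
#'   numeric variable columns (expression, phenotypes, ...).
#' @param probe_ids Probes to test (default: all in the dataset).
#' @return A tibble: `probe_id`, `variable`, `n`, `r_pearson`, `p_pearson`,
#'   `r_spearman`, `p_spearman`, `degenerate`.
#' @export
correlate_with_table <- function(dataset, table, probe_ids = NULL) {
  stopifnot(inherits(dataset, "methyl_dataset"))
  table <- as_tibble(table)
  if (!"sample_id" %in% names(table)) abort("table must have a sample_id column")
  probe_ids <- probe_ids %||% colnames(dataset$betas)
  missing <- setdiff(probe_ids, colnames(dataset$betas))
  if (length(missing)) {
    abort(paste0("probe(s) not in dataset: ", paste(missing, collapse = ", ")))
  }
  idx <- match(dataset$samples$sample_id, table$sample_id)
  vars <- dplyr::select(table, -"sample_id")
  purrr::map_dfr(probe_ids, function(pid) {
    b <- dataset$betas[, pid]
    purrr::imap_dfr(vars, function(v, nm) {
      v <- as.numeric(v)[idx]
      pe <- correlate(b, v, "pearson")
      sp <- correlate(b, v, "spearman")
      tibble(probe_id = pid, variable = nm, n = pe$n,
             r_pearson = pe$r, p_pearson = pe$p,
             r_spearman = sp$r, p_spearman = sp$p,
             degenerate = pe$degenerate | sp$degenerate)
    })
  })
}

#' Flag biologically suggestive correlations
#'
#' A (probe, variable) pair is flagged `biologically_relevant` when its
#' p-value is below `p_threshold` and the absolute correlation coefficient
#' exceeds `r_threshold` (the absolute value is used so that negative
#' correlations of equal strength qualify). For tables carrying both
#' Pearson and Spearman columns the pair is flagged when either method
#' passes both thresholds.
#'
#' @param results A tibble from [correlate_with_table()] (columns
#'   `r_pearson`/`p_pearson`/`r_spearman`/`p_spearman`) or from
#'   [correlate()] (columns `r`/`p`).
#' @param p_threshold P-value cutoff, default 0.05 (strict `<`).
#' @param r_threshold Correlation cutoff, default 0.1 (strict `>` on
#'   `|r|`).
#' @return `results` with a logical `biologically_relevant` column.
#' @export
filter_biological <- function(results, p_threshold = 0.05, r_threshold = 0.1) {
  pass <- function(r, p) {
    !is.na(r) & !is.na(p) & p < p_threshold & abs(r) > r_threshold
  }
  if (all(c("r", "p") %in% names(results))) {
    results$biologically_relevant <- pass(results$r, results$p)
  } else if (all(c("r_pearson", "r_spearman") %in% names(results))) {
    results$biologically_relevant <-
      pass(results$r_pearson, results$p_pearson) |
      pass(results$r_spearman, results$p_spearman)
  } else {
    abort("results must carry r/p or r_pearson/p_pearson/r_spearman/p_spearman columns")
  }
  results
}
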