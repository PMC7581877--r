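# Probe exclusion, beta/M transforms and PCA-based QC summaries.

#' Exclude cross-reactive and SNP-affected probes
#'
#' Applies the standard array probe-exclusion rules: cross-reactive probes
#' are removed first; then probes with a SNP of minor-allele frequency
#' strictly greater than `maf_threshold` in the CpG dinucleotide itself or
#' at the single-base-extension position; then probes with such a SNP in
#' the probe body. Each probe is counted once, under the first rule it
#' matches; missing MAF values are treated as not exceeding the threshold.
#' Sex-chromosome probes are retained by default (the intended design is an
#' all-male cohort); set `drop_sex = TRUE` to remove them too.
#'
#' @param dataset A [methyl_dataset()].
#' @param maf_threshold MAF cutoff (strict `>`), default 0.01.
#' @param drop_sex Also remove chrX/chrY probes.
#' @return A list with `dataset` (filtered, probe order preserved),
#'   `report` (one-row tibble: `n_input`, `n_removed_cross_reactive`,
#'   `n_removed_snp`, `n_removed_snp_body`, `n_removed_sex`, `n_retained`)
#'   and `removed_ids` (named character vector, names = rule).
#' @export
filter_probes <- function(dataset, maf_threshold = 0.01, drop_sex = FALSE) {
  stopifnot(inherits(dataset, "methyl_dataset"))
  pr <- dataset$probes
  gt <- function(x) !is.na(x) & x > maf_threshold
  n_missing_maf <- sum(is.na(pr$maf_cpg) & is.na(pr$maf_sbe) & is.na(pr$maf_body))
  if (n_missing_maf > 0) {
    inform(sprintf("%d probes have no MAF annotation; treated as not exceeding the threshold",
                   n_missing_maf))
  }
  rule <- rep(NA_character_, nrow(pr))
  rule[pr$cross_reactive == 1] <- "cross_reactive"
  snp <- is.na(rule) & (gt(pr$maf_cpg) | gt(pr$maf_sbe))
  rule[snp] <- "snp_cpg_sbe"
  body <- is.na(rule) & gt(pr$maf_body)
  rule[body] <- "snp_body"
  if (drop_sex) {
    sex <- is.na(rule) & pr$chrom %in% c("chrX", "chrY", "X", "Y")
    rule[sex] <- "sex_chromosome"
  }
  keep <- is.na(rule)
  removed_ids <- setNames(pr$probe_id[!keep], rule[!keep])
  report <- tibble(
    n_input = nrow(pr),
    n_removed_cross_reactive = sum(rule == "cross_reactive", na.rm = TRUE),
    n_removed_snp = sum(rule == "snp_cpg_sbe", na.rm = TRUE),
    n_removed_snp_body = sum(rule == "snp_body", na.rm = TRUE),
    n_removed_sex = sum(rule == "sex_chromosome", na.rm = TRUE),
    n_retained = sum(keep)
  )
  list(
    dataset = subset_probes(dataset, pr$probe_id[keep]),
    report = report,
    removed_ids = removed_ids
  )
}

#' Beta-value to M-value transform
#'
#' `M = log2(beta / (1 - beta))`; the variance-stabilized scale commonly
#' used for array regression. Input is clipped to `[0.001, 0.999]` so the
#' transform stays finite.
#'
#' @param beta Numeric vector/matrix of beta values.
#' @return M-values, same shape.
#' @export
beta_to_m <- function(beta) logit2(clip_beta(beta))

#' Inverse of [beta_to_m()]
#' @param m Numeric vector/matrix of M-values.
#' @return Beta values.
#' @export
m_to_beta <- function(m) expit2(m)

#' PCA summary of a methylation dataset
#'
#' Singular-value decomposition of the probe-centered (not scaled) beta
#' matrix. Explained-variance fractions are reported over all components
#' (they sum to 1); sample scores are returned for the first `k`.
#'
#' @param dataset A [methyl_dataset()].
#' @param k Number of components to report scores for (default 8).
#' @return An object of class `methyl_pca`: list with `explained` (tibble
#'   `component`, `fraction` over all components) and `scores` (tibble
#'   `sample_id` + `PC1..PCk`).
#' @export
pca_summary <- function(dataset, k = 8L) {
  stopifnot(inherits(dataset, "methyl_dataset"))
  if (k <= 0) abort("k must be positive")
  k <- min(k, nrow(dataset$betas) - 1L, ncol(dataset$betas))
  pc <- prcomp(dataset$betas, center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(sample_id = dataset$samples$sample_id), scores)
  structure(
    list(
      explained = tibble(component = seq_along(frac), fraction = frac),
      scores = scores
    ),
    class = "methyl_pca"
  )
}

#' Correlate principal-component scores with sample-level variables
#'
#' The usual QC step of checking which known variables (group, age, cell
#' proportions, ...) track the leading components.
#'
#' @param pca A [pca_summary()] result.
#' @param vars Data frame of sample-level variables, rows aligned with the
#'   dataset's sample order (a `sample_id` column, if present, is used to
#'   align; factors/characters are coded as their integer levels).
#' @return A tibble `component`, `variable`, `r` (Pearson correlation of
#'   the score vector with the variable).
#' @export
pca_correlate <- function(pca, vars) {
  stopifnot(inherits(pca, "methyl_pca"))
  vars <- as_tibble(vars)
  if ("sample_id" %in% names(vars)) {
    vars <- vars[match(pca$scores$sample_id, vars$sample_id), , drop = FALSE]
    vars$sample_id <- NULL
  }
  num <- lapply(vars, function(v) {
    if (is.numeric(v)) v else as.numeric(factor(v))
  })
  pcs <- dplyr::select(pca$scores, -"sample_id")
  purrr::imap_dfr(num, function(v, nm) {
    tibble(
      component = seq_len(ncol(pcs)),
      variable = nm,
      r = vapply(pcs, function(s) suppressWarnings(cor(s, v)), numeric(1))
    )
  }) %>% arrange(.data$component)
}
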