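#' Methylation dataset container
#'
#' Bundles a sample-by-probe beta-value matrix with its sample sheet and
#' probe annotation. Every pipeline stage consumes and returns this
#' container (or a tibble derived from it).
#'
#' @param betas Numeric matrix, samples in rows and probes in columns, with
#'   values in `[0, 1]`. Row names are sample ids, column names probe ids.
#' @param samples Data frame with columns `sample_id`, `group`
#'   (`"neg"` for mutation-negative, `"pos"` for mutation-positive) and
#'   `age` in years. One row per row of `betas`, in the same order.
#' @param probes Data frame of probe annotation with columns `probe_id`,
#'   `chrom`, `pos` (1-based bp), `gene` (symbol or `""`), `gene_feature`,
#'   `cross_reactive` (0/1), and minor-allele frequencies `maf_cpg`,
#'   `maf_sbe`, `maf_body` in `[0, 0.5]` (`NA` when unknown). One row per
#'   column of `betas`, in the same order.
#' @param truth Optional list of hidden simulation truth (cell proportions,
#'   spikes, genotypes) attached by the synthetic generator.
#'
#' @return An object of class `methyl_dataset`: a list with elements
#'   `betas`, `samples` (tibble), `probes` (tibble) and `truth`.
#' @export
#' @examples
#' betas <- matrix(runif(12), 3, 4,
#'   dimnames = list(paste0("s", 1:3), paste0("cg", 1:4)))
#' samples <- data.frame(sample_id = paste0("s", 1:3),
#'   group = c("neg", "neg", "pos"), age = c(40, 50, 45))
#' probes <- data.frame(probe_id = paste0("cg", 1:4), chrom = "chr1",
#'   pos = 1:4 * 1000L, gene = "", gene_feature = "", cross_reactive = 0L,
#'   maf_cpg = NA_real_, maf_sbe = NA_real_, maf_body = NA_real_)
#' ds <- methyl_dataset(betas, samples, probes)
#' ds
methyl_dataset <- function(betas, samples, probes, truth = NULL) {
  samples <- as_tibble(samples)
  probes <- as_tibble(probes)
  validate_methyl_dataset(betas, samples, probes)
  structure(
    list(betas = betas, samples = samples, probes = probes, truth = truth),
    class = "methyl_dataset"
  )
}

validate_methyl_dataset <- function(betas, samples, probes) {
  if (!is.matrix(betas) || !is.numeric(betas)) {
    abort("`betas` must be a numeric matrix (samples x probes).")
  }
  if (anyNA(betas) || any(!is.finite(betas))) {
    bad <- which(!is.finite(betas), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "non-finite beta at sample '%s', probe '%s'",
      rownames(betas)[bad[1]] %||% bad[1], colnames(betas)[bad[2]] %||% bad[2]
    ))
  }
  if (any(betas < 0 | betas > 1)) {
    bad <- which(betas < 0 | betas > 1, arr.ind = TRUE)[1, , drop = TRUE]
    abort(sprintf(
      "beta value %.4g outside [0, 1] at sample '%s', probe '%s'",
      betas[bad[1], bad[2]],
      rownames(betas)[bad[1]] %||% bad[1], colnames(betas)[bad[2]] %||% bad[2]
    ))
  }
  need_s <- c("sample_id", "group", "age")
  if (!all(need_s %in% names(samples))) {
    abort(paste0("sample sheet must have columns: ", paste(need_s, collapse = ", ")))
  }
  need_p <- c("probe_id", "chrom", "pos", "gene", "gene_feature",
              "cross_reactive", "maf_cpg", "maf_sbe", "maf_body")
  if (!all(need_p %in% names(probes))) {
    abort(paste0("probe annotation must have columns: ", paste(need_p, collapse = ", ")))
  }
  if (nrow(samples) != nrow(betas)) {
    abort(sprintf("sample sheet has %d rows but beta matrix has %d samples",
                  nrow(samples), nrow(betas)))
  }
  if (nrow(probes) != ncol(betas)) {
    abort(sprintf("annotation has %d rows but beta matrix has %d probes",
                  nrow(probes), ncol(betas)))
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample ids")
  if (anyDuplicated(probes$probe_id)) abort("duplicate probe ids")
  if (!is.null(rownames(betas)) && !identical(rownames(betas), as.character(samples$sample_id))) {
    abort("beta matrix row names do not match the sample sheet order")
  }
  if (!is.null(colnames(betas)) && !identical(colnames(betas), as.character(probes$probe_id))) {
    abort("beta matrix column names do not match the annotation order")
  }
  if (!all(samples$group %in% c("neg", "pos"))) {
    abort("group labels must be 'neg' or 'pos'")
  }
  maf <- c(probes$maf_cpg, probes$maf_sbe, probes$maf_body)
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE)) {
    abort("MAF fields must lie in [0, 0.5] when present")
  }
  if (any(probes$pos < 1)) abort("probe positions must be >= 1 (1-based)")
  invisible(TRUE)
}

#' @export
print.methyl_dataset <- function(x, ...) {
  cat(sprintf(
    "<methyl_dataset> %d samples x %d probes (%d neg / %d pos)\n",
    nrow(x$betas), ncol(x$betas),
    sum(x$samples$group == "neg"), sum(x$samples$group == "pos")
  ))
  if (!is.null(x$truth)) cat("  with hidden simulation truth\n")
  invisible(x)
}

#' @export
dim.methyl_dataset <- function(x) dim(x$betas)

#' Subset a methylation dataset by probe ids
#'
#' @param dataset A [methyl_dataset()].
#' @param probe_ids Character vector of probe ids to keep (order preserved
#'   as in the dataset, not as in `probe_ids`).
#' @return A `methyl_dataset` restricted to those probes.
#' @export
subset_probes <- function(dataset, probe_ids) {
  stopifnot(inherits(dataset, "methyl_dataset"))
  keep <- dataset$probes$probe_id %in% probe_ids
  methyl_dataset(
    dataset$betas[, keep, drop = FALSE],
    dataset$samples,
    dataset$probes[keep, , drop = FALSE],
    truth = dataset$truth
  )
}
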