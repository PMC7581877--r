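# Shared fixture builders. Everything is generated in code at test time.

# Minimal hand-built dataset: betas given as a samples x probes matrix.
make_dataset <- function(betas, group = NULL, age = NULL) {
  n <- nrow(betas)
  p <- ncol(betas)
  if (is.null(rownames(betas))) rownames(betas) <- sprintf("s%03d", seq_len(n))
  if (is.null(colnames(betas))) colnames(betas) <- sprintf("cg%05d", seq_len(p))
  samples <- tibble::tibble(
    sample_id = rownames(betas),
    group = group %||% rep(c("neg", "pos"), length.out = n),
    age = age %||% seq(30, 60, length.out = n)
  )
  probes <- tibble::tibble(
    probe_id = colnames(betas), chrom = "chr1",
    pos = seq_len(p) * 1000L, gene = "", gene_feature = "",
    cross_reactive = 0L,
    maf_cpg = NA_real_, maf_sbe = NA_real_, maf_body = NA_real_
  )
  methyl_dataset(betas, samples, probes)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Background probes of a generated cohort whose mean beta is mid-range, so
# spikes of the requested size cannot push a mean outside [0, 1].
pick_mid_probes <- function(dataset, n, lo = 0.3, hi = 0.7) {
  m <- colMeans(dataset$betas)
  ids <- colnames(dataset$betas)[startsWith(colnames(dataset$betas), "cgB") &
                                   m > lo & m < hi]
  stopifnot(length(ids) >= n)
  ids[seq_len(n)]
}

# Small boosting configuration used throughout the tests; the full-size
# defaults are exercised only through their validation.
lean_ml_config <- function(n_repeats = 3L, n_stability_subsamples = 10L,
                           cv_folds = 3L, nrounds = 50L, seed = 1L, ...) {
  ml_config(
    n_repeats = n_repeats, n_stability_subsamples = n_stability_subsamples,
    cv_folds = cv_folds, max_depth = 2L, eta = 0.1, nrounds = nrounds,
    n_permutations = 19L, perm_repeats = 1L, seed = seed, ...
  )
}
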