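# Synthetic methylation-cohort generator. Emulates the data structure the
# downstream analysis assumes: two patient groups of unequal size and age,
# blood drawn as a six-leukocyte-type mixture, logit-normal probe noise,
# optional spiked group effects and SNP-artifact (trimodal) probes.

LEUKOCYTE_TYPES <- c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Gran")

#' Configuration for a synthetic two-group methylation cohort
#'
#' Defaults mirror the FH study design this package targets: 78
#' mutation-negative patients (mean age 50.7, SD 12.3 years) and 58
#' mutation-positive patients (mean age 38.1, SD 12.0 years), with blood
#' leukocyte mixtures over six cell types dominated by granulocytes.
#'
#' @param n_group_neg,n_group_pos Number of mutation-negative /
#'   mutation-positive samples.
#' @param age_mean_neg,age_sd_neg,age_mean_pos,age_sd_pos Age distribution
#'   (years) per group; draws are truncated to `[18, 90]` (adult referral
#'   cohort).
#' @param n_probes Total number of probes on the synthetic array.
#' @param cell_types Ordered labels of the six leukocyte types.
#' @param dirichlet_alpha Per-type Dirichlet concentration for the true cell
#'   proportions, in `cell_types` order. The default `(10, 10, 2, 2, 2, 30)`
#'   makes granulocytes dominant and T cells common, a realistic
#'   collinearity stress for the cell-composition covariates.
#' @param noise_sd_logit Per-observation probe noise SD on the natural-logit
#'   scale.
#' @param seed Master random seed; all randomness derives from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_group_neg = 78L,
                          n_group_pos = 58L,
                          age_mean_neg = 50.7, age_sd_neg = 12.3,
                          age_mean_pos = 38.1, age_sd_pos = 12.0,
                          n_probes = 5000L,
                          cell_types = LEUKOCYTE_TYPES,
                          dirichlet_alpha = c(10, 10, 2, 2, 2, 30),
                          noise_sd_logit = 0.15,
                          seed = 1L) {
  stopifnot(n_group_neg > 0, n_group_pos > 0, n_probes > 0,
            age_sd_neg >= 0, age_sd_pos >= 0, noise_sd_logit >= 0)
  if (length(cell_types) != 6L) abort("exactly six cell types are required")
  if (length(dirichlet_alpha) != 6L || any(dirichlet_alpha <= 0)) {
    abort("dirichlet_alpha must be six positive concentrations")
  }
  structure(
    list(
      n_group_neg = as.integer(n_group_neg),
      n_group_pos = as.integer(n_group_pos),
      age_mean_neg = age_mean_neg, age_sd_neg = age_sd_neg,
      age_mean_pos = age_mean_pos, age_sd_pos = age_sd_pos,
      n_probes = as.integer(n_probes),
      cell_types = cell_types,
      dirichlet_alpha = dirichlet_alpha,
      noise_sd_logit = noise_sd_logit,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Spiked group effect on one probe
#'
#' @param probe_id Probe to spike.
#' @param delta_beta Group effect on the beta scale, defined as
#'   mutation-negative minus mutation-positive mean methylation, in
#'   `(-1, 1)`. A 1.3-percentage-point hypomethylation is
#'   `delta_beta = -0.013`.
#' @param age_slope Optional beta change per year of age (default 0),
#'   applied to all samples as `age_slope * (age - mean(age))`.
#' @return A list of class `spike_spec`.
#' @export
spike_spec <- function(probe_id, delta_beta, age_slope = 0) {
  stopifnot(is.character(probe_id), length(probe_id) == 1L,
            abs(delta_beta) < 1)
  structure(list(probe_id = probe_id, delta_beta = delta_beta,
                 age_slope = age_slope),
            class = "spike_spec")
}

#' SNP-artifact probe specification
#'
#' Describes a probe whose apparent methylation is driven by an underlying
#' single-nucleotide polymorphism, producing two or three distinguishable
#' methylation levels (one per genotype) under Hardy-Weinberg proportions.
#'
#' @param probe_id Probe to overwrite.
#' @param maf Minor-allele frequency in `[0, 0.5]`.
#' @param level_betas Three strictly increasing beta levels, ordered
#'   homozygous-major, heterozygous, homozygous-minor.
#' @return A list of class `snp_artifact_spec`.
#' @export
snp_artifact_spec <- function(probe_id, maf, level_betas) {
  stopifnot(length(level_betas) == 3L, all(diff(level_betas) > 0),
            maf >= 0, maf <= 0.5,
            all(level_betas >= 0), all(level_betas <= 1))
  structure(list(probe_id = probe_id, maf = maf, level_betas = level_betas),
            class = "snp_artifact_spec")
}

#' Generate a synthetic leukocyte methylation reference panel
#'
#' Builds a marker-probe-by-cell-type matrix of methylation profiles for
#' reference-based deconvolution. Each marker probe discriminates one cell
#' type from the rest with a between-type beta spread of at least 0.3, so
#' the panel is identifiable (full column rank), mirroring curated blood
#' reference panels.
#'
#' @param cell_types Cell-type labels (columns).
#' @param n_marker_probes Number of marker probes (rows); must be at least
#'   the number of cell types.
#' @param seed Random seed.
#' @return An object of class `cell_reference`: list with `profiles`
#'   (markers x types matrix of betas) and `marker_probe_ids`.
#' @export
#' @examples
#' ref <- generate_cell_reference(seed = 7)
#' dim(ref$profiles)
generate_cell_reference <- function(cell_types = LEUKOCYTE_TYPES,
                                    n_marker_probes = 60L,
                                    seed = 1L) {
  k <- length(cell_types)
  if (n_marker_probes < k) {
    abort(sprintf(
      "n_marker_probes (%d) must be >= the number of cell types (%d) to guarantee a discriminating, full-rank panel",
      n_marker_probes, k
    ))
  }
  seeds <- derive_seeds(seed, 10L)
  for (attempt in seq_len(10L)) {
    profiles <- with_seed(seeds[attempt], {
      target <- rep_len(seq_len(k), n_marker_probes)
      m <- matrix(runif(n_marker_probes * k, 0.05, 0.35),
                  nrow = n_marker_probes, ncol = k)
      # one "on" type per marker: spread >= 0.7 - 0.35 = 0.35 beta
      m[cbind(seq_len(n_marker_probes), target)] <-
        runif(n_marker_probes, 0.70, 0.95)
      m
    })
    if (qr(profiles)$rank == k) {
      colnames(profiles) <- cell_types
      ids <- sprintf("cgM%05d", seq_len(n_marker_probes))
      rownames(profiles) <- ids
      return(structure(list(profiles = profiles, marker_probe_ids = ids),
                       class = "cell_reference"))
    }
  }
  abort("could not generate a full-rank cell reference after 10 attempts")
}

# Dirichlet draws via normalized gamma variates.
rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

# Synthetic probe annotation: reference marker probes, probes tiling the
# candidate-gene windows of `registry`, the registry's candidate CpG ids,
# and background probes (a small fraction carrying cross-reactive flags or
# elevated MAFs so the QC filter has work to do).
generate_probe_annotation <- function(n_probes, reference, registry, seed,
                                      probes_per_gene = 6L,
                                      frac_cross_reactive = 0.02,
                                      frac_snp = 0.03) {
  genes <- registry$gene_intervals
  tier4 <- registry$tier4_cpgs
  n_marker <- length(reference$marker_probe_ids)
  n_gene <- nrow(genes) * probes_per_gene
  n_fixed <- n_marker + n_gene + length(tier4)
  if (n_probes < n_fixed + 10L) {
    abort(sprintf(
      "n_probes = %d is too small: %d marker + %d gene-window + %d candidate-CpG probes need at least %d",
      n_probes, n_marker, n_gene, length(tier4), n_fixed + 10L
    ))
  }
  with_seed(seed, {
    marker <- tibble(
      probe_id = reference$marker_probe_ids,
      chrom = "chr21",
      pos = 9000000 + seq_len(n_marker) * 1000,
      gene = "", gene_feature = "Intergenic",
      cross_reactive = 0L,
      maf_cpg = NA_real_, maf_sbe = NA_real_, maf_body = NA_real_,
      marker = TRUE
    )
    gene_rows <- purrr::pmap_dfr(genes, function(gene, chrom, start, end) {
      tibble(
        probe_id = NA_character_, chrom = chrom,
        pos = sort(round(runif(probes_per_gene, start - 2000, end + 2000))),
        gene = gene, gene_feature = "Body", cross_reactive = 0L,
        maf_cpg = NA_real_, maf_sbe = NA_real_, maf_body = NA_real_,
        marker = FALSE
      )
    })
    gene_rows$probe_id <- sprintf("cgG%05d", seq_len(nrow(gene_rows)))
    t4_map <- registry$tier4_hosts
    t4 <- tibble(
      probe_id = tier4,
      chrom = t4_map$chrom[match(tier4, t4_map$probe_id)],
      pos = t4_map$pos[match(tier4, t4_map$probe_id)],
      gene = t4_map$gene[match(tier4, t4_map$probe_id)],
      gene_feature = "Body", cross_reactive = 0L,
      maf_cpg = NA_real_, maf_sbe = NA_real_, maf_body = NA_real_,
      marker = FALSE
    )
    n_bg <- n_probes - n_fixed
    bg <- tibble(
      probe_id = sprintf("cgB%06d", seq_len(n_bg)),
      chrom = paste0("chr", sample(1:20, n_bg, replace = TRUE)),
      pos = sample.int(2e8, n_bg, replace = TRUE),
      gene = "", gene_feature = "Intergenic",
      cross_reactive = as.integer(runif(n_bg) < frac_cross_reactive),
      maf_cpg = ifelse(runif(n_bg) < frac_snp / 3, runif(n_bg, 0.02, 0.4), NA_real_),
      maf_sbe = ifelse(runif(n_bg) < frac_snp / 3, runif(n_bg, 0.02, 0.4), NA_real_),
      maf_body = ifelse(runif(n_bg) < frac_snp / 3, runif(n_bg, 0.02, 0.4), NA_real_),
      marker = FALSE
    )
    bind_rows(marker, gene_rows, t4, bg)
  })
}

#' Generate a synthetic methylation cohort
#'
#' Draws a two-group cohort whose beta values are leukocyte-mixture means
#' plus optional spiked group/age effects and logit-normal probe noise:
#' per sample i and probe j, `mu_ij = sum_k w_ik * ref_jk` (cell-type
#' profiles for marker probes; probe baseline plus small type deviations
#' otherwise), then `beta_ij = expit(logit(mu_ij + spikes) + e_ij)` with
#' `e_ij ~ N(0, noise_sd_logit^2)`, clipped to `[0.001, 0.999]`. Spiked
#' `delta_beta` is added to the mutation-negative group's mean, so it is
#' the negative-minus-positive effect the downstream linear model
#' estimates. True cell proportions, ages, spikes and genotypes are stored
#' as hidden truth for parameter-recovery testing.
#'
#' @param config A [cohort_config()].
#' @param reference A [generate_cell_reference()] panel; its marker probes
#'   are included in the annotation (flagged `marker = TRUE`).
#' @param spikes Optional list of [spike_spec()] objects.
#' @param snp_artifacts Optional list of [snp_artifact_spec()] objects,
#'   applied via [apply_snp_artifact()].
#' @param registry A [tier_registry()] used to lay out candidate-gene probe
#'   windows in the annotation; default [default_tier_registry()].
#' @return A [methyl_dataset()] with `truth` (cell proportions, spikes,
#'   genotypes, and the reference panel used, under `truth$reference`).
#' @export
#' @examples
#' cfg <- cohort_config(n_probes = 300, seed = 11)
#' ds <- generate_cohort(cfg)
#' dim(ds)
generate_cohort <- function(config, reference = NULL, spikes = NULL,
                            snp_artifacts = NULL,
                            registry = default_tier_registry()) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(reference)) {
    reference <- generate_cell_reference(config$cell_types,
                                         seed = derive_seeds(config$seed, 1L, salt = 1L))
  }
  if (inherits(spikes, "spike_spec")) spikes <- list(spikes)
  if (inherits(snp_artifacts, "snp_artifact_spec")) snp_artifacts <- list(snp_artifacts)
  seeds <- derive_seeds(config$seed, 6L)

  probes <- generate_probe_annotation(config$n_probes, reference, registry,
                                      seed = seeds[1])
  n_probes <- nrow(probes)
  n <- config$n_group_neg + config$n_group_pos
  samples <- tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = c(rep("neg", config$n_group_neg), rep("pos", config$n_group_pos)),
    age = with_seed(seeds[2], c(
      rnorm_trunc(config$n_group_neg, config$age_mean_neg, config$age_sd_neg, 18, 90),
      rnorm_trunc(config$n_group_pos, config$age_mean_pos, config$age_sd_pos, 18, 90)
    ))
  )
  w <- with_seed(seeds[3], rdirichlet(n, config$dirichlet_alpha))
  colnames(w) <- config$cell_types
  rownames(w) <- samples$sample_id

  # Per-probe cell-type mean profiles: the reference panel for marker
  # probes; a bimodal probe baseline plus small type-specific deviations
  # for the rest (most CpGs carry mild cell-composition signal).
  profiles <- with_seed(seeds[4], {
    base <- 0.05 + 0.9 * rbeta(n_probes, 0.4, 0.4)
    dev <- matrix(rnorm(n_probes * 6L, 0, 0.02), n_probes, 6L)
    p <- pmin(pmax(base + dev, 0.01), 0.99)
    idx <- match(reference$marker_probe_ids, probes$probe_id)
    p[idx, ] <- reference$profiles
    p
  })
  mu <- w %*% t(profiles) # samples x probes mixture means

  spike_tbl <- NULL
  if (length(spikes)) {
    spike_tbl <- purrr::map_dfr(spikes, function(s) {
      tibble(probe_id = s$probe_id, delta_beta = s$delta_beta,
             age_slope = s$age_slope)
    })
    missing <- setdiff(spike_tbl$probe_id, probes$probe_id)
    if (length(missing)) {
      abort(paste0("spiked probe(s) not in annotation: ",
                   paste(missing, collapse = ", ")))
    }
    neg <- samples$group == "neg"
    age_c <- samples$age - mean(samples$age)
    for (i in seq_len(nrow(spike_tbl))) {
      j <- match(spike_tbl$probe_id[i], probes$probe_id)
      shifted <- mu[, j] + neg * spike_tbl$delta_beta[i] +
        spike_tbl$age_slope[i] * age_c
      if (any(shifted < 0 | shifted > 1)) {
        abort(sprintf(
          "spike on probe '%s' pushes a mean beta outside [0, 1] (range %.3f..%.3f)",
          spike_tbl$probe_id[i], min(shifted), max(shifted)
        ))
      }
      mu[, j] <- shifted
    }
  }

  betas <- with_seed(seeds[5], {
    e <- matrix(rnorm(length(mu), 0, config$noise_sd_logit), nrow(mu), ncol(mu))
    clip_beta(expit(logit(clip_beta(mu)) + e))
  })
  rownames(betas) <- samples$sample_id
  colnames(betas) <- probes$probe_id

  truth <- list(
    cell_proportions = w,
    spikes = spike_tbl,
    genotypes = NULL,
    noise_sd_logit = config$noise_sd_logit,
    reference = reference
  )
  ds <- methyl_dataset(betas, samples, probes, truth = truth)
  if (length(snp_artifacts)) {
    art_seeds <- derive_seeds(config$seed, length(snp_artifacts), salt = 9L)
    for (i in seq_along(snp_artifacts)) {
      ds <- apply_snp_artifact(ds, snp_artifacts[[i]], seed = art_seeds[i])
    }
  }
  ds
}

#' Overwrite one probe with a SNP-driven trimodal methylation pattern
#'
#' Assigns each sample a genotype by Hardy-Weinberg draws at the given
#' minor-allele frequency (`(1-p)^2`, `2p(1-p)`, `p^2`) and replaces the
#' probe's betas with the genotype's level plus logit-scale noise.
#'
#' @param dataset A [methyl_dataset()].
#' @param spec A [snp_artifact_spec()].
#' @param seed Random seed.
#' @param noise_sd_logit Noise SD around the genotype level (logit scale).
#' @return The modified dataset; genotypes (minor-allele counts) are
#'   recorded under `truth$genotypes[[probe_id]]`.
#' @export
apply_snp_artifact <- function(dataset, spec, seed = 1L,
                               noise_sd_logit = 0.1) {
  stopifnot(inherits(dataset, "methyl_dataset"),
            inherits(spec, "snp_artifact_spec"))
  j <- match(spec$probe_id, dataset$probes$probe_id)
  if (is.na(j)) abort(sprintf("probe '%s' not present in dataset", spec$probe_id))
  n <- nrow(dataset$betas)
  p <- spec$maf
  geno <- with_seed(seed, {
    sample(0:2, n, replace = TRUE,
           prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
  })
  levels <- clip_beta(spec$level_betas)
  betas_j <- with_seed(seed + 1L, {
    clip_beta(expit(logit(levels[geno + 1L]) + rnorm(n, 0, noise_sd_logit)))
  })
  dataset$betas[, j] <- betas_j
  truth <- dataset$truth %||% list()
  truth$genotypes <- c(truth$genotypes,
                       setNames(list(geno), spec$probe_id))
  dataset$truth <- truth
  dataset
}
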