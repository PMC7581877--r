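test_that("flanking windows are inclusive at both boundaries", {
  ann <- tibble::tibble(
    probe_id = paste0("p", 1:4), chrom = "chr1",
    pos = c(96999L, 97000L, 108000L, 108001L),
    gene = "", gene_feature = "", cross_reactive = 0L,
    maf_cpg = NA_real_, maf_sbe = NA_real_, maf_body = NA_real_
  )
  reg <- tier_registry(
    tier3_genes = "GENEX", tier4_cpgs = character(0),
    gene_intervals = tibble::tibble(gene = "GENEX", chrom = "chr1",
                                    start = 100000L, end = 105000L)
  )
  sel <- suppressWarnings(select_tier_probes(ann, reg, "tier3", flank_bp = 3000))
  expect_equal(sel, c("p2", "p3")) # positions 97000 and 108000 only

  # the left edge clamps at 1
  reg2 <- tier_registry("GENEY", character(0),
                        tibble::tibble(gene = "GENEY", chrom = "chr1",
                                       start = 1000L, end = 2000L))
  ann2 <- ann
  ann2$pos <- c(1L, 500L, 5000L, 5001L)
  sel2 <- select_tier_probes(ann2, reg2, "tier3", flank_bp = 3000)
  expect_equal(sel2, c("p1", "p2", "p3"))

  expect_error(select_tier_probes(ann, reg, "tier9"), "unknown tier")
})

test_that("tier selection matches an independent interval-enumeration oracle", {
  cfg <- cohort_config(n_probes = 300, seed = 33)
  ds <- generate_cohort(cfg)
  reg <- default_tier_registry()
  for (tier in c("tier1", "tier2", "tier3")) {
    genes <- reg[[paste0(tier, "_genes")]]
    expected <- ds$probes$probe_id[purrr::map_lgl(seq_len(nrow(ds$probes)), function(i) {
      any(purrr::map_lgl(genes, function(g) {
        iv <- reg$gene_intervals[reg$gene_intervals$gene == g, ]
        nrow(iv) == 1 && ds$probes$chrom[i] == iv$chrom &&
          ds$probes$pos[i] >= max(iv$start - 3000, 1) &&
          ds$probes$pos[i] <= iv$end + 3000
      }))
    })]
    expect_equal(select_tier_probes(ds$probes, reg, tier), expected)
  }
  # tier 4 is an exact id match
  expect_equal(select_tier_probes(ds$probes, reg, "tier4"),
               intersect(ds$probes$probe_id, reg$tier4_cpgs))
  expect_equal(select_tier_probes(ds$probes, reg, 4),
               select_tier_probes(ds$probes, reg, "tier4"))
})

test_that("growing the flank never shrinks a tier probe set", {
  cfg <- cohort_config(n_probes = 300, seed = 34)
  ds <- generate_cohort(cfg)
  reg <- default_tier_registry()
  for (flank in list(c(0, 3000), c(3000, 10000))) {
    a <- select_tier_probes(ds$probes, reg, "tier2", flank[1])
    b <- select_tier_probes(ds$probes, reg, "tier2", flank[2])
    expect_true(all(a %in% b))
  }
})

test_that("a missing tier-4 CpG warns and yields an empty selection", {
  cfg <- cohort_config(n_probes = 300, seed = 35)
  ds <- generate_cohort(cfg)
  reg <- tier_registry(
    tier3_genes = character(0), tier4_cpgs = "cg99999999",
    gene_intervals = default_tier_registry()$gene_intervals
  )
  expect_warning(sel <- select_tier_probes(ds$probes, reg, "tier4"),
                 "cg99999999")
  expect_length(sel, 0L)
})

test_that("a targeted candidate-CpG spike is the only tier discovery", {
  cfg <- cohort_config(n_probes = 300, noise_sd_logit = 0.05, seed = 37)
  ds <- generate_cohort(cfg, spikes = spike_spec("cg00574958", -0.05))
  fl <- suppressMessages(filter_probes(ds))
  props <- estimate_cell_proportions(fl$dataset, ds$truth$reference)
  tiers <- suppressWarnings(
    run_candidate_analysis(fl$dataset, props, fdr_scope = "tier")
  )
  hits <- tiers[tiers$q_value < 0.05, ]
  expect_equal(hits$probe_id, "cg00574958")
  expect_equal(hits$tier, "tier4")
  expect_lt(hits$beta_hat, 0)

  # tier tables are row subsets of the single genome-wide fit
  fit <- attr(tiers, "dmp_fit")
  merged <- dplyr::left_join(
    dplyr::select(tiers, "tier", "probe_id", "beta_hat", "t_mod"),
    dplyr::select(fit$table, "probe_id", gw_beta = "beta_hat", gw_t = "t_mod"),
    by = "probe_id"
  )
  expect_equal(merged$beta_hat, merged$gw_beta)
  expect_equal(merged$t_mod, merged$gw_t)
})

test_that("a no-spike cohort yields no tier discoveries", {
  disc <- integer(5)
  for (r in 1:5) {
    cfg <- cohort_config(n_probes = 300, seed = 200 + r)
    ds <- generate_cohort(cfg)
    fl <- suppressMessages(filter_probes(ds))
    props <- estimate_cell_proportions(fl$dataset, ds$truth$reference)
    tiers <- suppressWarnings(run_candidate_analysis(fl$dataset, props))
    disc[r] <- sum(tiers$q_value < 0.05)
  }
  expect_gte(sum(disc == 0L), 4L)
})
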