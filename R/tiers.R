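# Candidate-gene tiers: registry of gene lists / CpG lists, flanking-window
# probe selection, and the tiered differential-methylation analysis.

TIER1_GENES <- c("LDLR", "APOB", "PCSK9")
TIER2_GENES <- c("LDLRAP", "STAP1", "ABCG5", "ABCG8", "APOE", "LIPA")

#' Candidate-tier registry
#'
#' The four tiers of candidate loci, graded by strength of evidence for a
#' role in LDL-cholesterol metabolism: tier 1 the major FH genes
#' (`LDLR, APOB, PCSK9`), tier 2 the minor FH genes
#' (`LDLRAP, STAP1, ABCG5, ABCG8, APOE, LIPA`), tier 3 a configurable list
#' of GWAS lipid genes, and tier 4 a configurable list of individual CpG
#' ids previously associated with LDL-C/total cholesterol.
#'
#' @param tier3_genes Character vector of tier-3 gene symbols.
#' @param tier4_cpgs Character vector of tier-4 CpG ids.
#' @param gene_intervals Tibble `gene`, `chrom`, `start`, `end` (1-based,
#'   both ends inclusive) covering every tier 1-3 gene; genes without an
#'   interval are skipped with a warning at selection time.
#' @param tier4_hosts Optional tibble `probe_id`, `chrom`, `pos`, `gene`
#'   giving array coordinates for the tier-4 CpGs (used by the synthetic
#'   annotation generator).
#' @return A list of class `tier_registry`.
#' @seealso [default_tier_registry()]
#' @export
tier_registry <- function(tier3_genes, tier4_cpgs, gene_intervals,
                          tier4_hosts = NULL) {
  gene_intervals <- as_tibble(gene_intervals)
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(gene_intervals)),
            all(gene_intervals$start <= gene_intervals$end))
  structure(
    list(
      tier1_genes = TIER1_GENES,
      tier2_genes = TIER2_GENES,
      tier3_genes = tier3_genes,
      tier4_cpgs = tier4_cpgs,
      gene_intervals = gene_intervals,
      tier4_hosts = tier4_hosts
    ),
    class = "tier_registry"
  )
}

#' Default candidate-tier registry
#'
#' Ships approximate hg19 intervals for the tier-1/2 FH genes, a small
#' example tier-3 list of well-established GWAS lipid genes, and an example
#' tier-4 list of CpG sites reported to associate with LDL-C or total
#' cholesterol (cg00574958 in *CPT1A*, two *ABCG1* sites, one *SREBF1*
#' site). Tier 3 and 4 are configuration, not algorithm: replace them with
#' your own lists via [tier_registry()].
#'
#' @return A `tier_registry`.
#' @export
default_tier_registry <- function() {
  gene_intervals <- tibble::tribble(
    ~gene, ~chrom, ~start, ~end,
    "LDLR",   "chr19", 11200038L,  11244506L,
    "APOB",   "chr2",  21224301L,  21266945L,
    "PCSK9",  "chr1",  55505221L,  55530525L,
    "LDLRAP", "chr1",  25870071L,  25895377L,
    "STAP1",  "chr4",  68424700L,  68473310L,
    "ABCG5",  "chr2",  44039611L,  44065973L,
    "ABCG8",  "chr2",  44066103L,  44105605L,
    "APOE",   "chr19", 45409039L,  45412650L,
    "LIPA",   "chr10", 90973325L,  91011654L,
    "SORT1",  "chr1",  109852192L, 109940563L,
    "HMGCR",  "chr5",  74632154L,  74657929L,
    "ABCA1",  "chr9",  107543283L, 107690518L,
    "CETP",   "chr16", 56995762L,  57017757L,
    "LPL",    "chr8",  19796764L,  19824770L,
    "CPT1A",  "chr11", 68522088L,  68611881L,
    "ABCG1",  "chr21", 43619799L,  43717354L,
    "SREBF1", "chr17", 17714662L,  17740325L
  )
  tier4_hosts <- tibble::tribble(
    ~probe_id, ~chrom, ~pos, ~gene,
    "cg00574958", "chr11", 68607622L, "CPT1A",
    "cg06500161", "chr21", 43656587L, "ABCG1",
    "cg27243685", "chr21", 43642366L, "ABCG1",
    "cg11024682", "chr17", 17730094L, "SREBF1"
  )
  tier_registry(
    tier3_genes = c("SORT1", "HMGCR", "ABCA1", "CETP", "LPL"),
    tier4_cpgs = tier4_hosts$probe_id,
    gene_intervals = gene_intervals,
    tier4_hosts = tier4_hosts
  )
}

#' Select the probes belonging to a candidate tier
#'
#' For gene tiers (1-3), selects every probe on the gene's chromosome with
#' position inside the gene interval extended by `flank_bp` base pairs on
#' either side (both endpoints inclusive; the left edge is clamped at 1).
#' For tier 4, matches CpG ids exactly.
#'
#' @param annotation Probe annotation tibble (`probe_id`, `chrom`, `pos`).
#' @param registry A [tier_registry()].
#' @param tier `"tier1"`..`"tier4"` (or 1..4).
#' @param flank_bp Flanking window, default 3000 bp.
#' @return Character vector of probe ids, in annotation order.
#' @export
select_tier_probes <- function(annotation, registry, tier, flank_bp = 3000) {
  stopifnot(inherits(registry, "tier_registry"))
  tier <- if (is.numeric(tier)) paste0("tier", tier) else tier
  if (!tier %in% c("tier1", "tier2", "tier3", "tier4")) {
    abort(sprintf("unknown tier label '%s'", tier))
  }
  annotation <- as_tibble(annotation)
  if (tier == "tier4") {
    ids <- annotation$probe_id[annotation$probe_id %in% registry$tier4_cpgs]
    missing <- setdiff(registry$tier4_cpgs, ids)
    if (length(missing)) {
      warn(paste0("tier-4 CpG(s) absent from annotation: ",
                  paste(missing, collapse = ", ")))
    }
    return(ids)
  }
  genes <- registry[[paste0(tier, "_genes")]]
  iv <- registry$gene_intervals
  sel <- rep(FALSE, nrow(annotation))
  for (gene in genes) {
    row <- iv[iv$gene == gene, ]
    if (nrow(row) == 0L) {
      warn(sprintf("no interval for gene '%s'; skipped", gene))
      next
    }
    lo <- max(row$start[1] - flank_bp, 1)
    hi <- row$end[1] + flank_bp
    sel <- sel | (annotation$chrom == row$chrom[1] &
                    annotation$pos >= lo & annotation$pos <= hi)
  }
  annotation$probe_id[sel]
}

#' Tiered candidate differential-methylation analysis
#'
#' Runs a single genome-wide per-probe fit ([run_dmp()]: OLS + variance
#' moderation + empirical-null correction), then for each tier subsets the
#' selected probes and applies Benjamini-Hochberg FDR. By default the FDR
#' is computed within each tier's probe set (`fdr_scope = "tier"`); with
#' `fdr_scope = "genome"` the genome-wide q-values are carried over.
#'
#' @inheritParams fit_dmp
#' @param registry A [tier_registry()].
#' @param flank_bp Flanking window for gene tiers (default 3000 bp).
#' @param fdr_scope `"tier"` (default) or `"genome"`.
#' @return A tibble: `tier`, then the per-probe statistics of the
#'   genome-wide fit plus `q_value` per the chosen scope, sorted by
#'   `q_value` within tier. The genome-wide `dmp_fit` is attached as
#'   attribute `"dmp_fit"`; the FDR scope as attribute `"fdr_scope"`.
#' @export
run_candidate_analysis <- function(dataset, proportions = NULL,
                                   registry = default_tier_registry(),
                                   flank_bp = 3000,
                                   fdr_scope = c("tier", "genome"),
                                   scale = c("beta", "m")) {
  fdr_scope <- match.arg(fdr_scope)
  fit <- run_dmp(dataset, proportions, scale = scale)
  tabs <- purrr::map_dfr(paste0("tier", 1:4), function(tier) {
    ids <- select_tier_probes(dataset$probes, registry, tier, flank_bp)
    sub <- fit$table[fit$table$probe_id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warn(sprintf("%s contains no probes after selection", tier))
      return(tibble())
    }
    if (fdr_scope == "tier") sub$q_value <- bh_fdr(sub$p_corrected)
    dplyr::bind_cols(tibble(tier = tier), sub) %>% arrange(.data$q_value)
  })
  attr(tabs, "dmp_fit") <- fit
  attr(tabs, "fdr_scope") <- fdr_scope
  tabs
}
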