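# Readers/writers for the pipeline's tabular artifacts and the bundled
# top-feature fixture.

#' Write a methylation dataset to a directory of TSV files
#'
#' Writes `betas.tsv` (probes x samples, probe id as row key), `samples.tsv`
#' (`sample_id`, `group`, `age`), `probes.tsv` (the annotation) and, when
#' the dataset carries simulation truth, `truth.json`.
#'
#' @param dataset A [methyl_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_methyl_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "methyl_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bet <- tibble(probe_id = colnames(dataset$betas)) %>%
    dplyr::bind_cols(as_tibble(t(dataset$betas)))
  readr::write_tsv(bet, file.path(dir, "betas.tsv"))
  readr::write_tsv(dataset$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(dataset$probes, file.path(dir, "probes.tsv"), na = "")
  if (!is.null(dataset$truth)) {
    jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a methylation dataset from a directory of TSV files
#'
#' Counterpart of [write_methyl_dataset()]. Validates shape consistency,
#' duplicate ids and the `[0, 1]` beta range; any violation is a descriptive
#' error naming the offending probe/sample.
#'
#' @param dir Directory containing `betas.tsv`, `samples.tsv`, `probes.tsv`
#'   and optionally `truth.json`.
#' @return A [methyl_dataset()].
#' @export
read_methyl_dataset <- function(dir) {
  paths <- file.path(dir, c("betas.tsv", "samples.tsv", "probes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("missing dataset file(s): ", paste(missing, collapse = ", ")))
  }
  bet <- readr::read_tsv(paths[1], show_col_types = FALSE)
  samples <- readr::read_tsv(paths[2], show_col_types = FALSE)
  probes <- readr::read_tsv(paths[3], show_col_types = FALSE,
                            col_types = readr::cols(
                              gene = readr::col_character(),
                              gene_feature = readr::col_character(),
                              cross_reactive = readr::col_integer(),
                              maf_cpg = readr::col_double(),
                              maf_sbe = readr::col_double(),
                              maf_body = readr::col_double()))
  probes$gene[is.na(probes$gene)] <- ""
  probes$gene_feature[is.na(probes$gene_feature)] <- ""
  if (names(bet)[1] != "probe_id") abort("betas.tsv must have a 'probe_id' first column")
  mat <- as.matrix(bet[, -1, drop = FALSE])
  if (!is.numeric(mat)) abort("betas.tsv contains non-numeric cells")
  rn <- bet$probe_id
  betas <- t(mat)
  colnames(betas) <- rn
  if (!setequal(rownames(betas), samples$sample_id) ||
      nrow(betas) != nrow(samples)) {
    abort(sprintf(
      "sample mismatch between betas.tsv (%s) and samples.tsv (%s)",
      paste(head(rownames(betas)), collapse = ","),
      paste(head(samples$sample_id), collapse = ",")
    ))
  }
  betas <- betas[as.character(samples$sample_id), , drop = FALSE]
  if (!setequal(colnames(betas), probes$probe_id) || ncol(betas) != nrow(probes)) {
    abort("probe mismatch between betas.tsv and probes.tsv")
  }
  betas <- betas[, as.character(probes$probe_id), drop = FALSE]
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  methyl_dataset(betas, samples, probes, truth = truth)
}

#' Bundled top-20 CpG feature panel
#'
#' Loads the package's example table of the 20 CpG sites with the highest
#' relative feature importance from a published familial-hypercholesterolemia
#' blood methylation case study (mutation-negative vs mutation-positive
#' patients, hg19 coordinates). `direction` is `"hyper"`/`"hypo"`: higher or
#' lower median beta in the mutation-negative group; `relative_importance`
#' is rescaled so the top feature equals 100.
#'
#' @return A tibble with 20 rows and columns `rank`, `probe_id`, `gene`,
#'   `chrom`, `pos`, `gene_feature`, `direction`, `relative_importance`.
#' @export
#' @examples
#' top <- fh_top20_features()
#' summarize_top_features(top)
fh_top20_features <- function() {
  path <- system.file("extdata", "top20_features_fh_study.tsv",
                      package = "fhmethyl", mustWork = TRUE)
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           rank = readr::col_integer(),
                           probe_id = readr::col_character(),
                           gene = readr::col_character(),
                           chrom = readr::col_character(),
                           pos = readr::col_double(),
                           gene_feature = readr::col_character(),
                           direction = readr::col_character(),
                           relative_importance = readr::col_double()
                         ))
  tab$gene[is.na(tab$gene)] <- ""
  stopifnot(nrow(tab) == 20L, identical(tab$rank, 1:20),
            max(tab$relative_importance) == 100)
  tab
}

#' Summarise a top-feature table
#'
#' @param table A tibble as returned by [fh_top20_features()] or built from
#'   an [ml_report] (columns `gene`, `direction`, `relative_importance`).
#' @return A one-row tibble: `pct_hyper` (percent of rows hypermethylated in
#'   the mutation-negative group), `n_hypo`, `n_without_gene` (rows with no
#'   gene annotation), `max_importance`.
#' @export
summarize_top_features <- function(table) {
  if (nrow(table) == 0L) abort("top-feature table is empty")
  bad <- setdiff(unique(table$direction), c("hyper", "hypo"))
  if (length(bad)) {
    abort(paste0("unknown direction value(s): ", paste(bad, collapse = ", ")))
  }
  gene <- table$gene
  gene[is.na(gene)] <- ""
  tibble(
    pct_hyper = 100 * sum(table$direction == "hyper") / nrow(table),
    n_hypo = sum(table$direction == "hypo"),
    n_without_gene = sum(gene == ""),
    max_importance = max(table$relative_importance)
  )
}
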