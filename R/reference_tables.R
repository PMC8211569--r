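#' Shipped pan-cancer reference tables
#'
#' Small plain-text tables shipped with the package, transcribed from a
#' published pan-cancer glucose-metabolism screen, for use as worked
#' examples and printed-table screening inputs:
#'
#' * `tcga_cohort_sizes()` — the 12 TCGA cohorts with their normal and
#'   cancer sample counts;
#' * `pan_cancer_log2fc_grid()` — the reported gene-by-cohort normalized
#'   log2 fold-change grid for the ten consistently trending
#'   glucose-metabolism genes (`NA` where a gene was unavailable in a
#'   cohort);
#' * `pan_cancer_consistent_pairs()` — the five reported gene pairs with
#'   a consistent correlation-change category across all 12 cohorts.
#'
#' Printed grids carry no p-values, so differential screens over them
#' waive the p criterion (see [screen_differential()]).
#'
#' @return A tibble (see each description).
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
tcga_cohort_sizes <- function() {
  read_cohort_manifest(
    system.file("extdata", "tcga_cohort_sizes.tsv", package = "coexscreen",
                mustWork = TRUE))
}

#' @rdname reference_tables
#' @export
pan_cancer_log2fc_grid <- function() {
  readr::read_tsv(
    system.file("extdata", "pan_cancer_log2fc_grid.tsv",
                package = "coexscreen", mustWork = TRUE),
    col_types = readr::cols(gene = "c", .default = "d"), progress = FALSE)
}

#' @rdname reference_tables
#' @export
pan_cancer_consistent_pairs <- function() {
  readr::read_tsv(
    system.file("extdata", "pan_cancer_consistent_pairs.tsv",
                package = "coexscreen", mustWork = TRUE),
    col_types = "ccc", progress = FALSE)
}
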