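# In-code fixtures shared across test files.

# Expression tibble from a named list of gene -> numeric sample vector.
make_expr <- function(rows, sample_ids = NULL) {
  n <- length(rows[[1]])
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(n))
  tb <- tibble::tibble(gene = names(rows))
  m <- do.call(rbind, rows)
  colnames(m) <- sample_ids
  dplyr::bind_cols(tb, tibble::as_tibble(m))
}

# Tiny two-arm cohort with fully controlled values.
make_pair <- function(normal_rows, cancer_rows, cancer_type = "TST") {
  nor <- make_expr(normal_rows,
                   sprintf("N%d", seq_along(normal_rows[[1]])))
  can <- make_expr(cancer_rows,
                   sprintf("T%d", seq_along(cancer_rows[[1]])))
  structure(list(cancer_type = cancer_type, normal = nor, cancer = can),
            class = "cohort_pair")
}

# Write a classic-format BioGRID tab file from a data frame with columns
# sym_a, sym_b (and optionally org_a, org_b, system).
write_biogrid_fixture <- function(df, path) {
  if (!"org_a" %in% names(df)) df$org_a <- 9606
  if (!"org_b" %in% names(df)) df$org_b <- 9606
  if (!"system" %in% names(df)) df$system <- "Two-hybrid"
  lines <- c(
    "#BioGRID interactions (test fixture)",
    paste("INTERACTOR_A", "INTERACTOR_B", "OFFICIAL_SYMBOL_A",
          "OFFICIAL_SYMBOL_B", "EXPERIMENTAL_SYSTEM",
          "ORGANISM_A_ID", "ORGANISM_B_ID", sep = "\t"),
    sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s",
            paste0("id_", df$sym_a), paste0("id_", df$sym_b),
            df$sym_a, df$sym_b, df$system, df$org_a, df$org_b))
  writeLines(lines, path)
  path
}

# A small multi-cohort synthetic spec that runs in well under a second.
# With few cohorts the consistency intersection is weak, so per-arm sample
# sizes are kept large enough that background pairs rarely align.
small_spec <- function(seed = 42, k = 4, n_normal = 40, n_cancer = 80) {
  synthetic_spec(
    n_genes = 30,
    cancer_types = sprintf("C%02d", seq_len(k)),
    n_normal = n_normal, n_cancer = n_cancer,
    planted_degs = tibble::tibble(gene = c("G001", "G002"),
                                  log2fc = c(-3, 2)),
    planted_pairs = tibble::tibble(
      gene_a = c("G003", "G005"), gene_b = c("G004", "G006"),
      r_normal = c(0.95, -0.95), r_cancer = c(0.25, -0.25)),
    seed = seed)
}
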