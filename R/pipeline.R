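#' Read and validate a run configuration
#'
#' The pipeline is driven by one declarative YAML file.  Recognised keys:
#'
#' * `cohorts`: list of entries with `cancer_type`, `expression` (TSV
#'   path) and `groups` (group-map path) — required;
#' * `gene_list`: optional path restricting the screen to a gene panel;
#' * `fc_cutoff` (default 1), `p_cutoff` (0.05): differential cut-offs;
#' * `sign_tau` (0.1), `delta_min` (0.1), `transform` (`log2p1`):
#'   correlation-screen settings;
#' * `min_normal`, `min_cancer` (10, 10): cohort admission thresholds;
#' * `pseudocount` (1e-3): fold-change stabilizer;
#' * `biogrid`: optional interaction file for the subnetwork stage;
#' * `out_dir`: output directory — required;
#' * `plots`: write dot plots (default `TRUE`).
#'
#' Every referenced path is checked before any computation runs.
#'
#' @param path YAML config path, or a list with the same fields.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
    yaml::read_yaml(path)
  }
  if (is.null(cfg$cohorts) || !length(cfg$cohorts)) {
    stop("config must list at least one cohort", call. = FALSE)
  }
  if (is.null(cfg$out_dir)) stop("config must set out_dir", call. = FALSE)
  defaults <- list(fc_cutoff = 1, p_cutoff = 0.05, sign_tau = 0.1,
                   delta_min = 0.1, transform = "log2p1",
                   min_normal = 10, min_cancer = 10, pseudocount = 1e-3,
                   plots = TRUE)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  stopifnot(cfg$fc_cutoff >= 0, cfg$p_cutoff > 0, cfg$p_cutoff <= 1)
  for (co in cfg$cohorts) {
    for (k in c("cancer_type", "expression", "groups")) {
      if (is.null(co[[k]])) {
        stop("cohort entry missing field '", k, "'", call. = FALSE)
      }
    }
    for (k in c("expression", "groups")) {
      if (!file.exists(co[[k]])) {
        stop("cohort ", co$cancer_type, ": path does not exist: ", co[[k]],
             call. = FALSE)
      }
    }
  }
  for (k in c("gene_list", "biogrid")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      stop(k, " path does not exist: ", cfg[[k]], call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the full screening pipeline
#'
#' Executes cohort loading, the differential-expression screens, the
#' correlation-change consistency screen and (when a BioGRID file is
#' configured) the PPI subnetwork stage, writing every stage table, the
#' plots and a Markdown summary report into `out_dir`.  The report echoes
#' every threshold and convention in effect.  Deterministic: re-running on
#' identical inputs rewrites identical tables.
#'
#' @param config A config path or list accepted by [read_run_config()].
#' @return A `coex_screen` object (list of all stage results) with
#'   [generics::tidy()] and [generics::glance()] methods.
#' @export
run_screen <- function(config) {
  cfg <- read_run_config(config)
  scfg <- screen_config(cfg$sign_tau, cfg$delta_min, cfg$transform)
  gene_list <- if (!is.null(cfg$gene_list)) read_gene_list(cfg$gene_list)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  pairs <- list()
  absent <- list()
  for (co in cfg$cohorts) {
    expr <- read_expression_table(co$expression)
    groups <- read_group_map(co$groups)
    if (!is.null(gene_list)) {
      expr <- restrict_to_gene_list(expr, gene_list)
      absent[[co$cancer_type]] <- absent_genes(expr)
    }
    pairs[[co$cancer_type]] <-
      build_cohort_pair(expr, groups, co$cancer_type,
                        min_normal = cfg$min_normal,
                        min_cancer = cfg$min_cancer)
  }

  manifest <- summarize_cohorts(pairs)
  totals <- cohort_totals(manifest)

  genes <- if (!is.null(gene_list)) gene_list else pairs[[1]]$normal$gene
  deg_records <- purrr::map_dfr(pairs, deg_table, genes = genes,
                                pseudocount = cfg$pseudocount)
  trend <- screen_trend(deg_records)
  differential <- screen_differential(deg_records,
                                      fc_cutoff = cfg$fc_cutoff,
                                      p_cutoff = cfg$p_cutoff)
  pair_records <- purrr::map_dfr(pairs, pair_change_table, cfg = scfg)
  hits <- screen_consistent_pairs(pair_records, require_all = TRUE)

  ppi_res <- NULL
  if (!is.null(cfg$biogrid)) {
    seeds <- unique(c(hits$gene_a, hits$gene_b))
    if (length(seeds)) {
      g <- parse_biogrid_tab(cfg$biogrid)
      ppi_res <- tryCatch(
        direct_neighborhood(g, seeds, reference_list = gene_list),
        error = function(e) {
          warning("ppi stage skipped: ", conditionMessage(e))
          NULL
        })
    }
  }

  out <- cfg$out_dir
  write_cohort_manifest(manifest, file.path(out, "cohort_manifest.tsv"))
  readr::write_tsv(deg_records, file.path(out, "deg_records.tsv"),
                   progress = FALSE)
  readr::write_tsv(log2fc_grid(deg_records),
                   file.path(out, "log2fc_grid.tsv"), progress = FALSE)
  readr::write_tsv(trend, file.path(out, "trend_screen.tsv"),
                   progress = FALSE)
  readr::write_tsv(differential, file.path(out, "differential_screen.tsv"),
                   progress = FALSE)
  readr::write_tsv(pair_records, file.path(out, "pair_records.tsv"),
                   progress = FALSE)
  readr::write_tsv(hits, file.path(out, "consistent_pairs.tsv"),
                   progress = FALSE)
  readr::write_tsv(format_hit_table(hits),
                   file.path(out, "consistent_pairs_labelled.tsv"),
                   progress = FALSE)
  if (!is.null(ppi_res)) {
    write_degree_report(ppi_res, file.path(out, "ppi_degrees.tsv"))
    export_graph(ppi_res$subgraph, file.path(out, "ppi_subnetwork.sif"),
                 "sif")
    export_graph(ppi_res$subgraph, file.path(out, "ppi_subnetwork.graphml"),
                 "graphml")
  }
  if (isTRUE(cfg$plots)) {
    for (p in pairs) {
      render_corr_dotplot(
        correlation_matrix(p$normal, scfg$transform),
        correlation_matrix(p$cancer, scfg$transform),
        file.path(out, paste0("corr_dots_", p$cancer_type, ".png")))
    }
  }

  res <- structure(
    list(config = cfg, manifest = manifest, totals = totals,
         deg_records = deg_records, trend = trend,
         differential = differential, pair_records = pair_records,
         hits = hits, ppi = ppi_res, absent_genes = absent),
    class = "coex_screen")
  writeLines(screen_report(res), file.path(out, "report.md"))
  res
}

screen_report <- function(res) {
  cfg <- res$config
  diff_hits <- dplyr::filter(res$differential, .data$hit)
  p_waived <- isTRUE(attr(res$differential, "p_waived"))
  lines <- c(
    "# Co-expression screen report", "",
    sprintf("Package coexscreen %s",
            as.character(utils::packageVersion("coexscreen"))),
    "",
    "## Cohorts", "",
    sprintf("- %d cohorts; %d normal and %d cancer samples in total",
            nrow(res$manifest), res$totals$total_normal,
            res$totals$total_cancer),
    "",
    "## Settings", "",
    sprintf("- fc_cutoff = %g, p_cutoff = %g (per-cohort, unadjusted)",
            cfg$fc_cutoff, cfg$p_cutoff),
    sprintf("- sign_tau = %g, delta_min = %g, transform = %s",
            cfg$sign_tau, cfg$delta_min, cfg$transform),
    sprintf("- pseudocount = %g; cohort admission: >= %d normal, >= %d cancer",
            cfg$pseudocount, cfg$min_normal, cfg$min_cancer),
    if (p_waived)
      "- NOTE: p-value criterion waived for records without p-values",
    "",
    "## Results", "",
    sprintf("- trend-consistent genes: %d of %d",
            sum(res$trend$trend_consistent), nrow(res$trend)),
    sprintf("- differential in all available cohorts: %d (%s)",
            nrow(diff_hits),
            if (nrow(diff_hits)) paste(diff_hits$gene, collapse = ", ")
            else "none"),
    sprintf("- consistent correlation-change pairs: %d", nrow(res$hits)))
  if (nrow(res$hits)) {
    ht <- format_hit_table(res$hits)
    lines <- c(lines, "",
               paste0("  - ", ht$gene_pair, ": ", ht$change))
  }
  if (!is.null(res$ppi)) {
    s <- res$ppi$summary
    lines <- c(lines, "", "## PPI subnetwork", "",
               sprintf("- %d seed genes found; %d direct interactions; %d partners (%s in the reference list)",
                       s$n_seeds_found, s$n_direct_interactions,
                       s$n_partners,
                       ifelse(is.na(s$n_partners_in_reference_list), "NA",
                              s$n_partners_in_reference_list)))
  }
  lines[!is.na(lines)]
}

#' @export
print.coex_screen <- function(x, ...) {
  cat(screen_report(x), sep = "\n")
  invisible(x)
}
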