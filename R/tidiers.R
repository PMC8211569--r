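#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pipeline result
#'
#' Returns the consistency-screen hit list — the pipeline's headline
#' result — as a tibble, one row per gene pair with its change category.
#'
#' @param x A `coex_screen` from [run_screen()].
#' @param ... Unused.
#' @return A tibble: `gene_a`, `gene_b`, `category`, `n_cohorts_defined`.
#' @export
tidy.coex_screen <- function(x, ...) {
  x$hits
}

#' Glance at a pipeline result
#'
#' @param x A `coex_screen` from [run_screen()].
#' @param ... Unused.
#' @return One-row tibble summarising the run: cohort and sample counts,
#'   screen hit counts and the thresholds in effect.
#' @export
glance.coex_screen <- function(x, ...) {
  tibble::tibble(
    n_cohorts = nrow(x$manifest),
    total_normal = x$totals$total_normal,
    total_cancer = x$totals$total_cancer,
    n_genes = nrow(x$trend),
    n_trend_consistent = sum(x$trend$trend_consistent),
    n_differential_hits = sum(x$differential$hit),
    n_consistent_pairs = nrow(x$hits),
    fc_cutoff = x$config$fc_cutoff,
    p_cutoff = x$config$p_cutoff,
    sign_tau = x$config$sign_tau,
    delta_min = x$config$delta_min,
    transform = x$config$transform)
}

#' @rdname tidy.coex_screen
#' @param object A `coex_screen`.
#' @export
autoplot.coex_screen <- function(object, ...) {
  plot_log2fc_grid(object$deg_records)
}
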