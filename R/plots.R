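corr_mat_tidy <- function(cm, condition) {
  tibble::tibble(
    gene_a = rep(cm$gene_ids, times = length(cm$gene_ids)),
    gene_b = rep(cm$gene_ids, each = length(cm$gene_ids)),
    r = as.vector(cm$r),
    defined = as.vector(cm$defined),
    condition = condition)
}

#' Correlation dot-matrix plot
#'
#' Renders one or two correlation matrices in the dot-matrix style used
#' for pan-cohort correlation figures: one dot per gene pair, blue for
#' positive and red for negative correlations, dot area proportional to
#' |r|, undefined cells left blank.  With both arms supplied the panels
#' appear side by side.
#'
#' @param cm_normal `corr_mat` for the normal arm.
#' @param cm_cancer Optional `corr_mat` for the cancer arm (same genes).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_corr_dots <- function(cm_normal, cm_cancer = NULL, title = NULL) {
  stopifnot(inherits(cm_normal, "corr_mat"))
  df <- corr_mat_tidy(cm_normal, "normal")
  if (!is.null(cm_cancer)) {
    if (!identical(cm_normal$gene_ids, cm_cancer$gene_ids)) {
      stop("the two correlation matrices cover different gene sets",
           call. = FALSE)
    }
    df <- dplyr::bind_rows(df, corr_mat_tidy(cm_cancer, "cancer"))
    df$condition <- factor(df$condition, levels = c("normal", "cancer"))
  }
  df <- dplyr::filter(df, .data$defined)
  lv <- cm_normal$gene_ids
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$gene_b, levels = lv),
    y = factor(.data$gene_a, levels = rev(lv)),
    size = abs(.data$r),
    colour = .data$r > 0)) +
    ggplot2::geom_point() +
    ggplot2::scale_size_area(max_size = 3, limits = c(0, 1), name = "|r|") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166AC",
                                            `FALSE` = "#B2182B"),
                                 labels = c(`TRUE` = "positive",
                                            `FALSE` = "negative"),
                                 name = "sign") +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (!is.null(cm_cancer)) p <- p + ggplot2::facet_wrap(~condition)
  p
}

#' @export
#' @rdname plot_corr_dots
#' @param object A `corr_mat`.
#' @param ... Unused.
autoplot.corr_mat <- function(object, ...) {
  plot_corr_dots(object)
}

#' Render a side-by-side correlation dot plot to a file
#'
#' @param cm_normal,cm_cancer `corr_mat` objects on the same gene set.
#' @param out Output path; the device is inferred from the extension
#'   (png, pdf, svg, ...).
#' @param width,height Device size in inches.
#' @return `out`, invisibly.
#' @export
render_corr_dotplot <- function(cm_normal, cm_cancer, out,
                                width = 10, height = 5) {
  p <- plot_corr_dots(cm_normal, cm_cancer)
  ggplot2::ggsave(out, p, width = width, height = height, dpi = 150)
  invisible(out)
}

#' Fold-change overview plot
#'
#' Heat-style tile plot of the gene-by-cohort log2 fold-change grid, the
#' layout used when reporting cross-cohort expression trends.
#'
#' @param records Per-gene per-cohort records (`gene`, `cancer_type`,
#'   `log2fc`, `available`).
#' @return A ggplot object.
#' @export
plot_log2fc_grid <- function(records) {
  df <- dplyr::filter(records, .data$available)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cancer_type, y = .data$gene,
                                   fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  name = "log2FC") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}
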