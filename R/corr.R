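#' Screen configuration for correlation-change classification
#'
#' The six-category classifier needs two thresholds the underlying idea
#' leaves open: `sign_tau`, the dead-zone half-width inside which a
#' correlation counts as neither positive nor negative, and `delta_min`,
#' the minimum absolute change `|r_normal - r_cancer|` required to call
#' any change at all.  Both default to 0.1; every pipeline report echoes
#' the values used.
#'
#' @param sign_tau Dead-zone half-width, `0 <= sign_tau < 1`.
#' @param delta_min Minimum change, `0 <= delta_min < 2`.
#' @param transform Expression transform applied before Pearson
#'   correlation: `"log2p1"` (log2(x + 1), default — FPKM-like values are
#'   heavy-tailed) or `"none"`.
#' @return A `screen_config` list.
#' @export
screen_config <- function(sign_tau = 0.1, delta_min = 0.1,
                          transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  stopifnot(sign_tau >= 0, sign_tau < 1, delta_min >= 0, delta_min < 2)
  structure(list(sign_tau = sign_tau, delta_min = delta_min,
                 transform = transform),
            class = "screen_config")
}

#' The six correlation-change categories
#'
#' @return Character vector of the six category codes, in the order
#'   positive-start then negative-start.
#' @export
change_categories <- function() {
  c("pos_more_pos", "pos_less_pos", "pos_to_neg",
    "neg_more_neg", "neg_less_neg", "neg_to_pos")
}

#' Human-readable labels for change categories
#'
#' Maps category codes to the arrow-style labels used in reports, e.g.
#' `pos_less_pos` to `"Positive -> Less positive"`.
#'
#' @param category Character vector of category codes.
#' @return Character vector of labels.
#' @export
category_label <- function(category) {
  lab <- c(pos_more_pos = "Positive → More positive",
           pos_less_pos = "Positive → Less positive",
           pos_to_neg   = "Positive → Negative",
           neg_more_neg = "Negative → More negative",
           neg_less_neg = "Negative → Less negative",
           neg_to_pos   = "Negative → Positive",
           null_change  = "No change",
           undefined    = "Undefined")
  unname(lab[category])
}

#' Pearson correlation matrix of an expression table
#'
#' Computes the genes-by-genes Pearson correlation matrix over samples,
#' optionally after a log2(x + 1) transform.  Genes with zero variance
#' across samples yield undefined correlations: their rows/columns are
#' `NA` and flagged in the `defined` mask.
#'
#' @param expr Expression tibble (`gene` + numeric sample columns).
#' @param transform `"log2p1"` or `"none"`.
#' @return A `corr_mat` object: list with `gene_ids`, `r` (symmetric
#'   matrix, `NA` where undefined), `n_samples`, and `defined` (symmetric
#'   logical mask).
#' @export
correlation_matrix <- function(expr, transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  validate_expression(expr)
  vals <- as.matrix(expr[-1])
  if (ncol(vals) < 3L) {
    stop("correlation requires at least 3 samples, got ", ncol(vals),
         call. = FALSE)
  }
  if (transform == "log2p1") vals <- log2(vals + 1)
  x <- t(vals)                       # samples x genes, as cor() expects
  sds <- apply(x, 2L, stats::sd)
  ok <- sds > 0
  r <- matrix(NA_real_, ncol(x), ncol(x))
  if (any(ok)) r[ok, ok] <- stats::cor(x[, ok, drop = FALSE])
  r[ok, ok] <- (r[ok, ok] + t(r[ok, ok])) / 2
  defined <- outer(ok, ok, `&`)
  diag(r)[ok] <- 1
  dimnames(r) <- dimnames(defined) <- list(expr$gene, expr$gene)
  structure(list(gene_ids = expr$gene, r = r,
                 n_samples = ncol(vals), defined = defined),
            class = "corr_mat")
}

#' @export
print.corr_mat <- function(x, ...) {
  cat(sprintf("<corr_mat: %d genes, %d samples, %d undefined entries>\n",
              length(x$gene_ids), x$n_samples, sum(!x$defined)))
  invisible(x)
}

#' Classify the change of one correlation between conditions
#'
#' Assigns each (r_normal, r_cancer) pair to one of the six change
#' categories, or `undefined` / `null_change`:
#' * the starting sign is decided with a dead zone — positive iff
#'   `r_normal > sign_tau`, negative iff `r_normal < -sign_tau`,
#'   otherwise `undefined`;
#' * changes smaller than `delta_min` in absolute value are `null_change`;
#' * a positive start strengthens to `pos_more_pos` when `r_cancer >
#'   r_normal`, crosses to `pos_to_neg` when `r_cancer < -sign_tau`, and
#'   weakens to `pos_less_pos` otherwise; negative starts mirror this.
#'
#' A boundary value `r_cancer == ±sign_tau` counts as weakening, not as a
#' sign crossing.  Vectorized over `r_normal` / `r_cancer`.
#'
#' @param r_normal,r_cancer Correlations in `[-1, 1]`.
#' @param cfg A [screen_config()].
#' @return Character vector of category codes.
#' @export
classify_change <- function(r_normal, r_cancer, cfg = screen_config()) {
  if (anyNA(r_normal) || anyNA(r_cancer)) {
    stop("undefined input correlation; filter undefined pairs first",
         call. = FALSE)
  }
  stopifnot(all(abs(r_normal) <= 1), all(abs(r_cancer) <= 1))
  tau <- cfg$sign_tau
  dmin <- cfg$delta_min
  start_pos <- r_normal > tau
  start_neg <- r_normal < -tau
  no_change <- abs(r_normal - r_cancer) < dmin
  dplyr::case_when(
    !start_pos & !start_neg          ~ "undefined",
    no_change                        ~ "null_change",
    start_pos & r_cancer > r_normal  ~ "pos_more_pos",
    start_pos & r_cancer < -tau      ~ "pos_to_neg",
    start_pos                        ~ "pos_less_pos",
    start_neg & r_cancer < r_normal  ~ "neg_more_neg",
    start_neg & r_cancer > tau       ~ "neg_to_pos",
    TRUE                             ~ "neg_less_neg")
}

#' Per-cohort gene-pair correlation-change records
#'
#' Computes the normal-arm and cancer-arm correlation matrices of a cohort
#' and classifies every unordered gene pair.  Pairs are stored with
#' `gene_a < gene_b` lexicographically; pairs undefined in either arm get
#' category `"undefined"` with `NA` correlations.
#'
#' @param pair A `cohort_pair`.
#' @param cfg A [screen_config()].
#' @return Tibble: `gene_a`, `gene_b`, `cancer_type`, `r_normal`,
#'   `r_cancer`, `category`.
#' @export
pair_change_table <- function(pair, cfg = screen_config()) {
  stopifnot(inherits(pair, "cohort_pair"))
  cm_n <- correlation_matrix(pair$normal, transform = cfg$transform)
  cm_c <- correlation_matrix(pair$cancer, transform = cfg$transform)
  g <- cm_n$gene_ids
  idx <- which(upper.tri(cm_n$r), arr.ind = TRUE)
  a <- g[idx[, 1]]
  b <- g[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  rn <- cm_n$r[idx]
  rc <- cm_c$r[idx]
  def <- cm_n$defined[idx] & cm_c$defined[idx]
  cat_out <- rep("undefined", length(rn))
  if (any(def)) {
    cat_out[def] <- classify_change(rn[def], rc[def], cfg)
  }
  tibble::tibble(gene_a = a, gene_b = b, cancer_type = pair$cancer_type,
                 r_normal = ifelse(def, rn, NA_real_),
                 r_cancer = ifelse(def, rc, NA_real_),
                 category = cat_out) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Cross-cohort consistency screen for correlation changes
#'
#' A gene pair is a hit when its change category is identical — and one of
#' the six real change categories — in every cohort where the pair is
#' defined.  With `require_all` (default) the pair must additionally be
#' defined in every cohort present in `records`, mirroring an
#' "across all cohorts" intersection.
#'
#' @param records Stacked [pair_change_table()] outputs across cohorts.
#' @param require_all Require definition in every cohort.
#' @return Tibble of hits: `gene_a`, `gene_b`, `category`,
#'   `n_cohorts_defined`; sorted by `gene_a` then `gene_b`.
#' @export
screen_consistent_pairs <- function(records, require_all = TRUE) {
  stopifnot(all(c("gene_a", "gene_b", "cancer_type", "category")
                %in% names(records)))
  k_total <- dplyr::n_distinct(records$cancer_type)
  real <- change_categories()
  records |>
    dplyr::filter(.data$category != "undefined") |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(
      n_cohorts_defined = dplyr::n(),
      consistent = dplyr::n_distinct(.data$category) == 1L,
      category = .data$category[1],
      .groups = "drop") |>
    dplyr::filter(.data$consistent,
                  .data$category %in% real,
                  !require_all | .data$n_cohorts_defined == k_total) |>
    dplyr::select("gene_a", "gene_b", "category", "n_cohorts_defined") |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Format a consistency hit list for reporting
#'
#' Renders hits the way pan-cancer reports print them: one row per pair
#' with an en-dash pair label and the arrow-style category label.
#'
#' @param hits Tibble from [screen_consistent_pairs()].
#' @return Tibble with `gene_pair` and `change` columns.
#' @export
format_hit_table <- function(hits) {
  tibble::tibble(
    gene_pair = paste(hits$gene_a, "–", hits$gene_b),
    change = category_label(hits$category))
}

#' Fisher z-test for the difference of two correlations
#'
#' Two-sample test of H0 "the two population correlations are equal",
#' using the variance-stabilizing transform `atanh(r)`:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal p-value.  Offered as an optional significance filter
#' on correlation changes; the consistency screen itself applies none by
#' default.
#'
#' @param r1,r2 Sample correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes (>= 4).
#' @return Named list with `z` and `p_value`; `z = 0`, `p = 1` when
#'   `r1 == r2`.
#' @export
fisher_z_difference <- function(r1, n1, r2, n2) {
  stopifnot(n1 >= 4, n2 >= 4)
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("|r| must be < 1 for the Fisher z transform", call. = FALSE)
  }
  if (r1 == r2) return(list(z = 0, p_value = 1))
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}
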