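#' Library-size normalization by median column sum
#'
#' Scales every sample column so that its sum equals the median of the
#' original column sums.  The median of an even number of sums is the
#' arithmetic mean of the two middle values.  Log2 fold-changes downstream
#' are computed on these normalized values, which is what "normalized
#' log2 fold-change" means throughout the package.
#'
#' @param expr Expression tibble (`gene` + numeric sample columns).
#' @return The rescaled expression tibble; all column sums equal within
#'   1e-9 relative tolerance.
#' @export
normalize_library <- function(expr) {
  validate_expression(expr)
  vals <- as.matrix(expr[-1])
  cs <- colSums(vals)
  if (any(cs == 0)) {
    stop("all-zero sample column(s): ",
         paste(names(expr)[-1][cs == 0], collapse = ", "), call. = FALSE)
  }
  target <- stats::median(cs)
  out <- expr
  out[-1] <- sweep(vals, 2L, target / cs, `*`)
  out
}

#' Normalized log2 fold-change of one gene in a cohort
#'
#' `log2((mean_cancer + pseudocount) / (mean_normal + pseudocount))` on
#' library-normalized values.  Positive values mean upregulated in cancer.
#' The pseudocount keeps the ratio defined at zero means; its default of
#' 1e-3 is small relative to typical FPKM so large fold-changes are not
#' compressed.
#'
#' @param pair A `cohort_pair`.
#' @param gene Gene symbol.
#' @param pseudocount Positive stabilizer added to both means.
#' @param normalize Apply [normalize_library()] to each arm first.
#' @return A single number, or `NA_real_` when the gene is absent from the
#'   cohort (absence is recorded, not an error, at this level).
#' @export
compute_log2fc <- function(pair, gene, pseudocount = 1e-3, normalize = TRUE) {
  stopifnot(inherits(pair, "cohort_pair"), pseudocount > 0)
  if (!(gene %in% pair$normal$gene)) return(NA_real_)
  nor <- pair$normal
  can <- pair$cancer
  if (normalize) {
    nor <- normalize_library(nor)
    can <- normalize_library(can)
  }
  m_n <- mean(as.numeric(nor[nor$gene == gene, -1]))
  m_c <- mean(as.numeric(can[can$gene == gene, -1]))
  log2((m_c + pseudocount) / (m_n + pseudocount))
}

#' Two-group Poisson likelihood-ratio test
#'
#' Tests H0 "both groups share one Poisson mean" against H1 "each group has
#' its own mean" on rounded nonnegative values.  The statistic is
#' `2 * (l1 - l0)` where each `l` is the Poisson log-likelihood maximized
#' at the group mean(s); the p-value comes from the chi-square distribution
#' with 1 degree of freedom.  When both groups are all zero the test is
#' degenerate: statistic 0, p-value 1, flagged via the `degenerate`
#' attribute.
#'
#' @param x_a,x_b Nonnegative numeric vectors (values are rounded to
#'   integers before the likelihood is evaluated).
#' @return Named list with `statistic` (>= 0) and `p_value`.
#' @export
lrt_two_group <- function(x_a, x_b) {
  if (!length(x_a) || !length(x_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (any(x_a < 0) || any(x_b < 0)) {
    stop("expression values must be nonnegative", call. = FALSE)
  }
  a <- round(x_a)
  b <- round(x_b)
  s_a <- sum(a); n_a <- length(a)
  s_b <- sum(b); n_b <- length(b)
  degenerate <- (s_a + s_b) == 0
  # x*log(mu) terms with 0*log(0) := 0; the factorial terms cancel in the
  # ratio and are omitted.
  ll <- function(s, n, mu) if (mu == 0) 0 else s * log(mu) - n * mu
  mu0 <- (s_a + s_b) / (n_a + n_b)
  l0 <- ll(s_a + s_b, n_a + n_b, mu0)
  l1 <- ll(s_a, n_a, s_a / n_a) + ll(s_b, n_b, s_b / n_b)
  stat <- max(0, 2 * (l1 - l0))
  out <- list(statistic = stat,
              p_value = if (degenerate) 1 else
                stats::pchisq(stat, df = 1, lower.tail = FALSE))
  attr(out, "degenerate") <- degenerate
  out
}

#' Per-cohort differential-expression table
#'
#' Computes, for every gene of a cohort (or a supplied subset), the
#' normalized log2 fold-change and the two-group Poisson LRT p-value.
#'
#' @param pair A `cohort_pair`.
#' @param genes Genes to score; defaults to every gene in the cohort.
#'   Genes absent from the cohort yield rows with `available = FALSE`.
#' @param pseudocount Passed to [compute_log2fc()].
#' @return Tibble with columns `gene`, `cancer_type`, `log2fc`, `p_value`,
#'   `available`.
#' @export
deg_table <- function(pair, genes = NULL, pseudocount = 1e-3) {
  stopifnot(inherits(pair, "cohort_pair"))
  if (is.null(genes)) genes <- pair$normal$gene
  nor <- normalize_library(pair$normal)
  can <- normalize_library(pair$cancer)
  m_nor <- as.matrix(nor[-1])
  m_can <- as.matrix(can[-1])
  rownames(m_nor) <- nor$gene
  rownames(m_can) <- can$gene
  purrr::map_dfr(genes, function(g) {
    if (!(g %in% nor$gene)) {
      return(tibble::tibble(gene = g, cancer_type = pair$cancer_type,
                            log2fc = NA_real_, p_value = NA_real_,
                            available = FALSE))
    }
    xn <- m_nor[g, ]
    xc <- m_can[g, ]
    lfc <- log2((mean(xc) + pseudocount) / (mean(xn) + pseudocount))
    lrt <- lrt_two_group(xn, xc)
    tibble::tibble(gene = g, cancer_type = pair$cancer_type,
                   log2fc = lfc, p_value = lrt$p_value, available = TRUE)
  })
}

#' Cross-cohort trend screen
#'
#' A gene is trend-consistent when its log2 fold-changes are strictly
#' positive in every cohort where it is available (direction `up`) or
#' strictly negative in every such cohort (direction `down`).  A zero
#' fold-change counts as neither direction.  Cohorts where the gene is
#' unavailable are ignored; genes available in no cohort are dropped with
#' a report entry in the `excluded` attribute.
#'
#' @param records Tibble of per-gene per-cohort records with columns
#'   `gene`, `cancer_type`, `log2fc`, `available` (e.g. stacked
#'   [deg_table()] outputs).
#' @return Tibble with one row per gene: `gene`, `n_available`,
#'   `direction` (`"up"`, `"down"` or `"mixed"`), `trend_consistent`.
#' @export
screen_trend <- function(records) {
  stopifnot(all(c("gene", "cancer_type", "log2fc", "available")
                %in% names(records)))
  res <- records |>
    dplyr::filter(.data$available) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_available = dplyr::n(),
      direction = dplyr::case_when(
        all(.data$log2fc > 0) ~ "up",
        all(.data$log2fc < 0) ~ "down",
        TRUE ~ "mixed"),
      .groups = "drop") |>
    dplyr::mutate(trend_consistent = .data$direction %in% c("up", "down")) |>
    dplyr::arrange(.data$gene)
  excluded <- setdiff(unique(records$gene), res$gene)
  attr(res, "excluded") <- excluded
  res
}

#' Cross-cohort differential screen
#'
#' A gene passes one cohort when it is available there, `|log2fc| >=
#' fc_cutoff`, and `p_value < p_cutoff`.  Records with `p_value = NA`
#' (screens of printed fold-change tables, which carry no p-values) treat
#' the p criterion as satisfied; this waiver is recorded in the
#' `p_waived` attribute.
#'
#' @param records As in [screen_trend()], plus a `p_value` column.
#' @param fc_cutoff Absolute log2 fold-change cut-off (default 1).
#' @param p_cutoff P-value cut-off (default 0.05).
#' @param require_all When `TRUE` (default) a gene is a hit only if it
#'   passes every cohort in which it is available.
#' @param adjust Multiple-testing adjustment applied to p-values within
#'   each cohort before thresholding: `"none"` (default, mirroring raw
#'   per-cohort screening) or `"BH"`.
#' @return Tibble per gene: `gene`, `n_available`, `n_cohorts_differential`,
#'   `hit`; sorted by `n_cohorts_differential` descending then symbol.
#' @export
screen_differential <- function(records, fc_cutoff = 1, p_cutoff = 0.05,
                                require_all = TRUE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(fc_cutoff >= 0, p_cutoff > 0, p_cutoff <= 1)
  avail <- dplyr::filter(records, .data$available)
  if (adjust == "BH") {
    avail <- avail |>
      dplyr::group_by(.data$cancer_type) |>
      dplyr::mutate(p_value = stats::p.adjust(.data$p_value, "BH")) |>
      dplyr::ungroup()
  }
  p_waived <- anyNA(avail$p_value)
  res <- avail |>
    dplyr::mutate(pass = abs(.data$log2fc) >= fc_cutoff &
                    (is.na(.data$p_value) | .data$p_value < p_cutoff)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_available = dplyr::n(),
                     n_cohorts_differential = sum(.data$pass),
                     .groups = "drop") |>
    dplyr::mutate(hit = if (require_all)
      .data$n_cohorts_differential == .data$n_available else
        .data$n_cohorts_differential > 0) |>
    dplyr::arrange(dplyr::desc(.data$n_cohorts_differential), .data$gene)
  attr(res, "p_waived") <- p_waived
  res
}

#' Reshape per-cohort records into a gene-by-cohort fold-change grid
#'
#' Produces the wide layout used for reporting: one row per gene, one
#' column per cohort, `NA` where a gene is unavailable.
#'
#' @param records Per-gene per-cohort tibble (`gene`, `cancer_type`,
#'   `log2fc`, `available`).
#' @return Wide tibble, genes in rows.
#' @export
log2fc_grid <- function(records) {
  records |>
    dplyr::mutate(log2fc = ifelse(.data$available, .data$log2fc, NA_real_)) |>
    dplyr::select("gene", "cancer_type", "log2fc") |>
    tidyr::pivot_wider(names_from = "cancer_type", values_from = "log2fc") |>
    dplyr::arrange(.data$gene)
}

#' Melt a gene-by-cohort fold-change grid into per-cohort records
#'
#' The inverse of [log2fc_grid()]: turns a printed-style wide table (one
#' row per gene, one numeric column per cohort, `NA` marking unavailable
#' entries) into the long record layout the screens consume.  P-values are
#' set to `NA` — printed grids carry none — so [screen_differential()]
#' waives the p criterion on these records.
#'
#' @param grid Wide tibble with a `gene` column and one column per cohort.
#' @return Long tibble: `gene`, `cancer_type`, `log2fc`, `p_value`,
#'   `available`.
#' @export
grid_to_records <- function(grid) {
  stopifnot("gene" %in% names(grid))
  grid |>
    tidyr::pivot_longer(-"gene", names_to = "cancer_type",
                        values_to = "log2fc") |>
    dplyr::mutate(p_value = NA_real_, available = !is.na(.data$log2fc))
}
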