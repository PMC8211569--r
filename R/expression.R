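#' Read a genes-by-samples expression table
#'
#' Reads a tab-separated expression table whose first column (`gene`) holds
#' gene symbols and whose remaining columns hold nonnegative expression
#' values (FPKM-like units), one column per sample.  The table is validated
#' on read: every cell must be numeric, finite and nonnegative, and gene and
#' sample identifiers must be unique.  Missing-value markers (`NA`, `.`,
#' empty cells) are errors — missingness is modelled at the cohort level
#' (a gene absent from a cohort), never at the cell level.
#'
#' @param path Path to a UTF-8 TSV file.  The header row is `gene` followed
#'   by sample identifiers.
#' @return A tibble with a character `gene` column followed by one numeric
#'   column per sample.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "HK1\t1.5\t2", "PFKM\t0\t3.25"), tf)
#' read_expression_table(tf)
read_expression_table <- function(path) {
  if (!file.exists(path)) {
    stop("expression table not found: ", path, call. = FALSE)
  }
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  dup_h <- unique(hdr[-1][duplicated(hdr[-1])])
  if (length(dup_h)) {
    stop("duplicate sample id(s): ", paste(dup_h, collapse = ", "),
         call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  if (ncol(raw) < 2L) {
    stop("expression table needs a gene column plus at least one sample column",
         call. = FALSE)
  }
  names(raw)[1] <- "gene"
  expr <- raw
  for (j in seq(2L, ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- is.na(v)
    if (any(bad)) {
      stop("non-numeric or missing cell in column '", names(raw)[j],
           "' (e.g. value '", raw[[j]][which(bad)[1]], "' for gene ",
           raw$gene[which(bad)[1]], ")", call. = FALSE)
    }
    expr[[j]] <- v
  }
  validate_expression(expr)
  expr
}

#' Write an expression table
#'
#' Writes the TSV dialect read by [read_expression_table()].  Numeric values
#' are written with the shortest representation that round-trips, so
#' read / write / read preserves values bit-exactly.
#'
#' @param expr Expression tibble (`gene` column + numeric sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  validate_expression(expr)
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' @keywords internal
validate_expression <- function(expr) {
  stopifnot(is.data.frame(expr))
  if (!identical(names(expr)[1], "gene")) {
    stop("first column must be 'gene'", call. = FALSE)
  }
  dup_g <- unique(expr$gene[duplicated(expr$gene)])
  if (length(dup_g)) {
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "),
         call. = FALSE)
  }
  samp <- names(expr)[-1]
  dup_s <- unique(samp[duplicated(samp)])
  if (length(dup_s)) {
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(expr[-1])
  if (!is.numeric(vals)) stop("sample columns must be numeric", call. = FALSE)
  if (any(!is.finite(vals))) {
    stop("expression values must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (any(vals < 0)) {
    i <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop("negative expression value for gene ", expr$gene[i[1]],
         ", sample ", samp[i[2]], call. = FALSE)
  }
  invisible(expr)
}

#' Read a gene list
#'
#' One symbol per line; blank lines and `#` comments are ignored.  Matching
#' elsewhere in the package is by exact, case-sensitive symbol string.
#'
#' @param path Path to a plain-text gene list.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path, call. = FALSE)
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (!length(x)) stop("gene list is empty: ", path, call. = FALSE)
  x
}

#' Read a sample-to-group map
#'
#' Two-column TSV `sample_id<TAB>group` with groups `normal` or `cancer`.
#'
#' @param path Path to the map file.
#' @return Named character vector: names are sample ids, values the groups.
#' @export
read_group_map <- function(path) {
  if (!file.exists(path)) stop("group map not found: ", path, call. = FALSE)
  tb <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (ncol(tb) != 2L) stop("group map must have two columns", call. = FALSE)
  names(tb) <- c("sample_id", "group")
  bad <- setdiff(unique(tb$group), c("normal", "cancer"))
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(tb$group, tb$sample_id)
}

#' Restrict an expression table to a gene list
#'
#' Keeps the genes appearing in `genes`, in gene-list order.  Symbols absent
#' from the table are reported via the `absent` attribute (and a message),
#' never fabricated.
#'
#' @param expr Expression tibble.
#' @param genes Character vector of gene symbols (case-sensitive).
#' @return The restricted tibble, with attribute `absent` listing the
#'   symbols from `genes` not present in `expr`.
#' @export
restrict_to_gene_list <- function(expr, genes) {
  validate_expression(expr)
  if (!length(genes)) stop("gene list must be non-empty", call. = FALSE)
  keep <- genes[genes %in% expr$gene]
  absent <- setdiff(genes, expr$gene)
  if (!length(keep)) {
    stop("none of the ", length(genes),
         " listed genes are present in the expression table", call. = FALSE)
  }
  out <- expr[match(keep, expr$gene), , drop = FALSE]
  attr(out, "absent") <- absent
  out
}

#' Absent-gene report from a restricted table
#'
#' @param expr A tibble returned by [restrict_to_gene_list()].
#' @return Character vector of symbols that were requested but absent.
#' @export
absent_genes <- function(expr) {
  a <- attr(expr, "absent")
  if (is.null(a)) character() else a
}

#' Split an expression table into a paired normal/cancer cohort
#'
#' Splits the samples of one cohort's expression table by the supplied
#' group map and applies the cohort admission check: a cohort is admitted
#' only when it has at least `min_normal` normal and `min_cancer` cancer
#' samples (defaults 10 and 10).
#'
#' @param expr Expression tibble for the cohort (all samples).
#' @param groups Named character vector mapping every sample id to
#'   `"normal"` or `"cancer"` (see [read_group_map()]).
#' @param cancer_type Short cohort code, e.g. `"BRCA"`.
#' @param min_normal,min_cancer Minimum per-arm sample counts.
#' @return A `cohort_pair` object: a list with elements `cancer_type`,
#'   `normal` and `cancer` (expression tibbles sharing the same genes).
#' @export
build_cohort_pair <- function(expr, groups, cancer_type,
                              min_normal = 10, min_cancer = 10) {
  validate_expression(expr)
  samp <- names(expr)[-1]
  unmapped <- setdiff(samp, names(groups))
  if (length(unmapped)) {
    stop("sample id(s) missing from group map: ",
         paste(utils::head(unmapped, 5), collapse = ", "), call. = FALSE)
  }
  g <- groups[samp]
  n_n <- sum(g == "normal")
  n_c <- sum(g == "cancer")
  if (n_n < min_normal || n_c < min_cancer) {
    stop(sprintf(
      "cohort %s fails the admission check: %d normal (min %d), %d cancer (min %d)",
      cancer_type, n_n, min_normal, n_c, min_cancer), call. = FALSE)
  }
  pair <- structure(
    list(cancer_type = cancer_type,
         normal = expr[c("gene", samp[g == "normal"])],
         cancer = expr[c("gene", samp[g == "cancer"])]),
    class = "cohort_pair")
  pair
}

#' @export
print.cohort_pair <- function(x, ...) {
  cat(sprintf("<cohort_pair %s: %d genes, %d normal / %d cancer samples>\n",
              x$cancer_type, nrow(x$normal),
              ncol(x$normal) - 1L, ncol(x$cancer) - 1L))
  invisible(x)
}

#' Summarize a set of cohorts into a manifest
#'
#' @param pairs List of `cohort_pair` objects.
#' @return A tibble with columns `cancer_type`, `n_normal`, `n_cancer`,
#'   one row per cohort.  Use [cohort_totals()] for the grand totals.
#' @export
summarize_cohorts <- function(pairs) {
  if (!length(pairs)) stop("no cohorts supplied", call. = FALSE)
  purrr::map_dfr(pairs, function(p) {
    tibble::tibble(cancer_type = p$cancer_type,
                   n_normal = ncol(p$normal) - 1L,
                   n_cancer = ncol(p$cancer) - 1L)
  })
}

#' Grand totals of a cohort manifest
#'
#' @param manifest A manifest tibble with `n_normal` and `n_cancer` columns
#'   (from [summarize_cohorts()] or [read_cohort_manifest()]).
#' @return One-row tibble with `total_normal` and `total_cancer`.
#' @export
cohort_totals <- function(manifest) {
  stopifnot(all(c("n_normal", "n_cancer") %in% names(manifest)))
  tibble::tibble(total_normal = sum(manifest$n_normal),
                 total_cancer = sum(manifest$n_cancer))
}

#' Read / write a cohort manifest TSV
#'
#' Columns: `cancer_type`, optional `description`, `n_normal`, `n_cancer`.
#'
#' @param path Manifest path.
#' @return For the reader, a manifest tibble.
#' @export
read_cohort_manifest <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(tb)[1] <- "cancer_type"
  stopifnot(all(c("n_normal", "n_cancer") %in% names(tb)))
  if (anyDuplicated(tb$cancer_type)) {
    stop("duplicate cancer_type in manifest", call. = FALSE)
  }
  if (any(tb$n_normal < 0) || any(tb$n_cancer < 0)) {
    stop("negative sample count in manifest", call. = FALSE)
  }
  tb
}

#' @rdname read_cohort_manifest
#' @param manifest Manifest tibble.
#' @export
write_cohort_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path, progress = FALSE)
  invisible(path)
}
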