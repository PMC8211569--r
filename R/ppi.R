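#' Parse a BioGRID tab-format interaction file
#'
#' Reads the tab-delimited BioGRID organism interaction format (classic
#' `.tab` with `OFFICIAL_SYMBOL_A`/`OFFICIAL_SYMBOL_B` columns, or the
#' tab2/tab3 variants with `Official Symbol Interactor A`/`B`) into an
#' undirected simple graph keyed by official gene symbol.  Multiple
#' evidence lines for one pair collapse to one edge; self-interactions and
#' rows with empty symbols are dropped and counted in the parse report.
#'
#' @param path Path to the interaction file.  Comment lines before the
#'   header (classic files open with `#` lines) are skipped.
#' @param organism_filter Optional NCBI taxon id; when given, only rows
#'   where both interactors carry this organism id are kept (requires the
#'   organism id columns to be present).
#' @param experimental_system Optional filter on the experimental-system
#'   column (e.g. `"Two-hybrid"`); default keeps everything, physical and
#'   genetic alike.
#' @return A `ppi_graph`: an igraph object with a logical `seed` vertex
#'   attribute (all `FALSE` until [direct_neighborhood()] marks seeds) and
#'   a `parse_report` attribute counting dropped duplicates, self-loops
#'   and empty-symbol rows.
#' @export
parse_biogrid_tab <- function(path, organism_filter = NULL,
                              experimental_system = NULL) {
  if (!file.exists(path)) stop("BioGRID file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty BioGRID file: ", path, call. = FALSE)
  # classic .tab files start with comment lines; the header is the first
  # line that names the interactor-symbol columns
  hdr_idx <- which(grepl("OFFICIAL_SYMBOL_A|Official Symbol Interactor A",
                         lines))[1]
  if (is.na(hdr_idx)) {
    stop("malformed BioGRID file: no official-symbol header found",
         call. = FALSE)
  }
  header <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]]
  header <- sub("^#", "", header)
  col_a <- which(header %in% c("OFFICIAL_SYMBOL_A",
                               "Official Symbol Interactor A"))[1]
  col_b <- which(header %in% c("OFFICIAL_SYMBOL_B",
                               "Official Symbol Interactor B"))[1]
  if (is.na(col_a) || is.na(col_b)) {
    stop("malformed BioGRID header: missing official-symbol columns",
         call. = FALSE)
  }
  body <- lines[-seq_len(hdr_idx)]
  body <- body[nzchar(body)]
  if (!length(body)) {
    warning("BioGRID file has no interaction rows")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    igraph::V(g)$seed <- logical(0)
    return(structure(g, parse_report = list(
      n_rows = 0L, n_self = 0L, n_duplicate = 0L, n_empty_symbol = 0L),
      class = c("ppi_graph", class(g))))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  sym_a <- vapply(fields, function(f) if (length(f) >= col_a) f[col_a] else "",
                  character(1))
  sym_b <- vapply(fields, function(f) if (length(f) >= col_b) f[col_b] else "",
                  character(1))
  keep <- rep(TRUE, length(body))
  if (!is.null(organism_filter)) {
    org_cols <- which(header %in% c("ORGANISM_A_ID", "ORGANISM_B_ID",
                                    "Organism Interactor A",
                                    "Organism Interactor B",
                                    "Organism ID Interactor A",
                                    "Organism ID Interactor B"))
    if (length(org_cols) < 2) {
      stop("organism filter requested but no organism id columns present",
           call. = FALSE)
    }
    for (oc in org_cols) {
      v <- vapply(fields, function(f) if (length(f) >= oc) f[oc] else "",
                  character(1))
      keep <- keep & v == as.character(organism_filter)
    }
  }
  if (!is.null(experimental_system)) {
    es_col <- which(header %in% c("EXPERIMENTAL_SYSTEM",
                                  "Experimental System"))[1]
    if (is.na(es_col)) {
      stop("experimental-system filter requested but column not present",
           call. = FALSE)
    }
    v <- vapply(fields, function(f) if (length(f) >= es_col) f[es_col] else "",
                character(1))
    keep <- keep & v %in% experimental_system
  }
  sym_a <- sym_a[keep]
  sym_b <- sym_b[keep]
  empty <- sym_a == "" | sym_b == "" | sym_a == "-" | sym_b == "-"
  n_empty <- sum(empty)
  sym_a <- sym_a[!empty]
  sym_b <- sym_b[!empty]
  self <- sym_a == sym_b
  n_self <- sum(self)
  sym_a <- sym_a[!self]
  sym_b <- sym_b[!self]
  # canonical unordered order, then dedup evidence lines
  lo <- pmin(sym_a, sym_b)
  hi <- pmax(sym_a, sym_b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  lo <- lo[!dup]; hi <- hi[!dup]
  verts <- sort(unique(c(lo, hi)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  igraph::V(g)$seed <- FALSE
  structure(g,
            parse_report = list(n_rows = sum(keep), n_self = n_self,
                                n_duplicate = n_dup,
                                n_empty_symbol = n_empty),
            class = c("ppi_graph", class(g)))
}

#' Parse report of a BioGRID import
#'
#' @param g A `ppi_graph` from [parse_biogrid_tab()].
#' @return List with counts of kept rows and of dropped self-loops,
#'   duplicate evidence lines and empty-symbol rows.
#' @export
parse_report <- function(g) attr(g, "parse_report")

#' Direct-interaction neighborhood of a seed gene set
#'
#' Extracts the subgraph induced by the seed genes and their direct
#' interaction partners, keeping only edges incident to at least one seed.
#' Reports the number of distinct seed-incident interactions (an edge
#' between two seeds counts once) and, optionally, how many of the non-seed
#' partners appear in a reference gene list (e.g. a pathway panel).
#'
#' @param g A `ppi_graph` (or any undirected igraph keyed by symbol).
#' @param seeds Character vector of seed gene symbols.
#' @param reference_list Optional character vector of symbols against
#'   which partners are counted.
#' @return List with `subgraph` (igraph, `seed` vertex attribute set),
#'   `degrees` (tibble: `gene`, `is_seed`, `degree` — degree within the
#'   seed-incident subgraph), and `summary` (one-row tibble:
#'   `n_seeds_found`, `n_direct_interactions`, `n_partners`,
#'   `n_partners_in_reference_list`).
#' @export
direct_neighborhood <- function(g, seeds, reference_list = NULL) {
  stopifnot(length(seeds) > 0)
  seeds <- unique(seeds)
  present <- intersect(seeds, igraph::V(g)$name)
  if (!length(present)) {
    stop("none of the seed genes are present in the interaction graph",
         call. = FALSE)
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  inc <- el[, 1] %in% present | el[, 2] %in% present
  el_inc <- el[inc, , drop = FALSE]
  n_direct <- nrow(el_inc)
  partners <- setdiff(unique(c(el_inc[, 1], el_inc[, 2])), present)
  sub_verts <- c(sort(present), sort(partners))
  sub <- igraph::subgraph_from_edges(
    g, which(inc), delete.vertices = FALSE)
  sub <- igraph::induced_subgraph(sub, sub_verts)
  igraph::V(sub)$seed <- igraph::V(sub)$name %in% present
  deg <- igraph::degree(sub)
  degrees <- tibble::tibble(gene = names(deg),
                            is_seed = names(deg) %in% present,
                            degree = as.integer(deg)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$gene)
  n_ref <- if (is.null(reference_list)) NA_integer_ else
    length(intersect(partners, reference_list))
  list(subgraph = sub,
       degrees = degrees,
       summary = tibble::tibble(
         n_seeds_found = length(present),
         n_direct_interactions = n_direct,
         n_partners = length(partners),
         n_partners_in_reference_list = n_ref))
}

#' Export an interaction graph
#'
#' Writes SIF (`A pp B`, one line per edge; isolated nodes as single-field
#' lines) or GraphML with a boolean `seed` node attribute.  A GraphML
#' round-trip through [import_graphml()] reproduces nodes, edges and seed
#' flags exactly.
#'
#' @param g An igraph object (vertex attribute `seed` optional).
#' @param out Output path.
#' @param format `"sif"` or `"graphml"`.
#' @return `out`, invisibly.
#' @export
export_graph <- function(g, out, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (is.null(igraph::V(g)$seed)) igraph::V(g)$seed <- FALSE
  if (format == "sif") {
    el <- igraph::as_edgelist(g, names = TRUE)
    lines <- if (nrow(el)) paste(el[, 1], "pp", el[, 2]) else character()
    iso <- setdiff(igraph::V(g)$name, unique(c(el[, 1], el[, 2])))
    writeLines(c(lines, iso), out)
  } else {
    # GraphML booleans round-trip more portably as 0/1 integers
    g2 <- g
    igraph::V(g2)$seed <- as.integer(igraph::V(g2)$seed)
    igraph::write_graph(g2, out, format = "graphml")
  }
  invisible(out)
}

#' @rdname export_graph
#' @param path GraphML file written by [export_graph()].
#' @export
import_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  igraph::V(g)$seed <- as.logical(as.integer(igraph::V(g)$seed))
  g
}

#' Degree report of a neighborhood extraction
#'
#' @param nb Result of [direct_neighborhood()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_degree_report <- function(nb, path) {
  readr::write_tsv(nb$degrees, path, progress = FALSE)
  invisible(path)
}
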