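#' Read and write the pipeline's tab-separated file dialects
#'
#' All tables travel as plain TSV with a header row. The expression dialect
#' has features in rows, samples in columns, and the feature id in the first
#' column (`probe_id` or `target_id`). Numeric values are written with
#' `%.10g` so that identical matrices serialize to identical bytes.
#'
#' @param path file path.
#' @param level,scale passed to [expr_matrix()] when reading.
#' @return `read_expression_tsv` returns an [expr_matrix]; the other readers
#'   return data frames (see the individual descriptions).
#' @name io_tsv
NULL

fmt_num <- function(x) {
  out <- sprintf("%.10g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv_raw <- function(df, path) {
  is_num <- vapply(df, is.numeric, logical(1))
  df[is_num] <- lapply(df[is_num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_raw <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop(path, ": missing required column(s): ",
           paste(missing, collapse = ", "))
  }
  df
}

#' @rdname io_tsv
#' @param x an [expr_matrix] (or bare matrix) to serialize.
#' @export
write_expression_tsv <- function(x, path) {
  m <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  id_col <- if (inherits(x, "expr_matrix") && x$level == "target")
    "target_id" else "probe_id"
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  names(df)[1] <- id_col
  write_tsv_raw(df, path)
}

#' @rdname io_tsv
#' @export
read_expression_tsv <- function(path, level = c("probe", "target"),
                                scale = c("raw", "glog2")) {
  df <- read_tsv_raw(path)
  if (ncol(df) < 2) stop(path, ": expression TSV needs id + >=1 sample column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  expr_matrix(m, level = match.arg(level), scale = match.arg(scale))
}

#' @rdname io_tsv
#' @description `read_probe_annotation_tsv` reads columns `probe_id`,
#'   `target_id` (and optional `species`).
#' @export
read_probe_annotation_tsv <- function(path)
  read_tsv_raw(path, c("probe_id", "target_id"))

#' @rdname io_tsv
#' @description `read_metadata_tsv` reads `sample_id`, `class` and optional
#'   `myc_fraction` (a proportion in `[0,1]`).
#' @export
read_metadata_tsv <- function(path)
  read_tsv_raw(path, c("sample_id", "class"))

#' @rdname io_tsv
#' @description `read_nucleus_tsv` reads `slide_id`, `nucleus_id`,
#'   `intensity`, `is_reference`.
#' @export
read_nucleus_tsv <- function(path) {
  df <- read_tsv_raw(path, c("slide_id", "nucleus_id", "intensity",
                             "is_reference"))
  df$is_reference <- as.logical(df$is_reference)
  df
}

#' @rdname io_tsv
#' @description `read_target_tsv` reads the miRNA-target table (`mirna`,
#'   `gene`, `evidence` with evidence in strong/weak).
#' @export
read_target_tsv <- function(path) {
  df <- read_tsv_raw(path, c("mirna", "gene", "evidence"))
  bad <- setdiff(unique(df$evidence), c("strong", "weak"))
  if (length(bad))
    stop(path, ": evidence must be 'strong' or 'weak', found: ",
         paste(bad, collapse = ", "))
  df
}

#' @rdname io_tsv
#' @description `read_go_tsv` reads gene-to-GO-term annotation (`gene`,
#'   `go_id`, GO ids of the form GO:NNNNNNN).
#' @export
read_go_tsv <- function(path) {
  df <- read_tsv_raw(path, c("gene", "go_id"))
  bad <- !grepl("^GO:[0-9]{7}$", df$go_id)
  if (any(bad))
    stop(path, ": malformed GO id(s): ",
         paste(unique(df$go_id[bad]), collapse = ", "))
  df
}

#' @rdname io_tsv
#' @description `read_interactome` reads an undirected protein graph from a
#'   2-column edge TSV (`a`, `b`; header optional names) or a SIF file
#'   (`A interaction B` whitespace-separated). Self-loops and duplicate
#'   edges are dropped.
#' @param format `"tsv"` or `"sif"`; guessed from the extension by default.
#' @export
read_interactome <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    bad <- vapply(parts, length, integer(1)) < 3
    if (any(bad)) stop(path, ": SIF lines need 'A interaction B'")
    edges <- t(vapply(parts, function(p) c(p[1], p[3]), character(2)))
  } else {
    df <- read_tsv_raw(path)
    if (ncol(df) < 2) stop(path, ": edge TSV needs two columns")
    edges <- as.matrix(df[, 1:2])
  }
  make_interactome(edges[, 1], edges[, 2])
}

#' @rdname io_tsv
#' @param sig_path two-column signature TSV with columns `list` (up/down) and
#'   `mirna_id`, or a GMT-like file whose set names end in `_UP` / `_DOWN`.
#' @export
read_signature_file <- function(sig_path) {
  first <- readLines(sig_path, n = 1)
  if (grepl("^list\t", first) || grepl("\tmirna_id", first)) {
    df <- read_tsv_raw(sig_path, c("list", "mirna_id"))
    up <- df$mirna_id[df$list == "up"]
    down <- df$mirna_id[df$list == "down"]
  } else {
    lines <- strsplit(readLines(sig_path), "\t")
    up <- character(); down <- character()
    for (ln in lines) {
      if (length(ln) < 3) next
      ids <- ln[-(1:2)]
      if (grepl("_UP$", ln[1], ignore.case = TRUE)) up <- c(up, ids)
      if (grepl("_DOWN$", ln[1], ignore.case = TRUE)) down <- c(down, ids)
    }
  }
  myc_signature(up = up, down = down, name = basename(sig_path))
}

#' @rdname io_tsv
#' @param g an igraph object as produced by [make_interactome()] or
#'   [shortest_path_union()].
#' @export
write_sif <- function(g, path) {
  e <- igraph::as_edgelist(g)
  type <- igraph::edge_attr(g, "type")
  if (is.null(type)) type <- rep("ppi", nrow(e))
  writeLines(paste(e[, 1], type, e[, 2]), path)
  invisible(path)
}
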