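#' Expression matrix container
#'
#' A light container for a features-by-samples intensity matrix together with
#' the two pieces of state the pipeline must track: the summarization level
#' (individual array probes vs collapsed miRNA targets) and the intensity
#' scale (raw non-negative intensities vs glog2-transformed values).
#'
#' @param values numeric matrix, features in rows, samples in columns; must
#'   carry unique rownames (feature ids) and colnames (sample ids).
#' @param level `"probe"` or `"target"`.
#' @param scale `"raw"` or `"glog2"`. Raw values must be non-negative and
#'   glog2 values must be finite.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `level` and `scale`.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
#' expr_matrix(m, level = "probe", scale = "raw")
#' @export
expr_matrix <- function(values, level = c("probe", "target"),
                        scale = c("raw", "glog2")) {
  level <- match.arg(level)
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (scale == "raw" && any(values < 0, na.rm = TRUE))
    stop("raw-scale intensities must be >= 0")
  if (scale == "glog2" && any(!is.finite(values)))
    stop("glog2-scale values must all be finite")
  structure(list(values = values, level = level, scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d %s(s) x %d sample(s), %s scale\n",
              nrow(x$values), x$level, ncol(x$values), x$scale))
  cat("value range:",
      paste(signif(range(x$values, na.rm = TRUE), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
as.matrix.expr_matrix <- function(x, ...) x$values

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Accept either an expr_matrix of the required level/scale or a bare matrix
# (taken on trust); returns the numeric matrix.
as_expr_values <- function(x, level = NULL, scale = NULL,
                           what = deparse(substitute(x))) {
  if (inherits(x, "expr_matrix")) {
    if (!is.null(level) && x$level != level)
      stop(what, " must be ", level, "-level (got ", x$level, ")")
    if (!is.null(scale) && x$scale != scale)
      stop(what, " must be on the ", scale, " scale (got ", x$scale, ")")
    return(x$values)
  }
  m <- as.matrix(x)
  if (is.null(rownames(m)))
    rownames(m) <- paste0("f", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}
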