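#' Per-target one-way ANOVA across sample classes
#'
#' Fixed-effects one-way ANOVA of each target's glog2 profile on the class
#' labels, vectorized over targets. Degenerate targets with zero between-
#' and within-group variance get F = 0, p = 1.
#'
#' @param x target-level glog2 [expr_matrix] (or bare matrix).
#' @param labels class label per sample (length = number of columns); every
#'   class must have >= 2 samples.
#' @return data frame `target`, `statistic` (F), `p`, one row per target,
#'   in matrix row order.
#' @export
test_multigroup <- function(x, labels) {
  m <- as_expr_values(x, scale = NULL)
  labels <- as.character(labels)
  if (length(labels) != ncol(m))
    stop("labels length must equal number of samples")
  counts <- table(labels)
  if (length(counts) < 2) stop("need >= 2 classes")
  if (any(counts < 2))
    stop("class with < 2 samples: ",
         paste(names(counts)[counts < 2], collapse = ", "))

  n <- ncol(m)
  k <- length(counts)
  groups <- split(seq_len(n), labels)
  grand <- rowMeans(m)
  ss_between <- 0
  ss_within <- 0
  for (idx in groups) {
    gm <- rowMeans(m[, idx, drop = FALSE])
    ss_between <- ss_between + length(idx) * (gm - grand)^2
    ss_within <- ss_within +
      rowSums((m[, idx, drop = FALSE] - gm)^2)
  }
  df1 <- k - 1
  df2 <- n - k
  f <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  degen <- ss_between == 0
  f[degen] <- 0
  p[degen] <- 1
  data.frame(target = rownames(m), statistic = unname(f), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Per-target Welch two-sample t-test
#'
#' Two-sided Welch (unequal-variance) t-test of each target between the two
#' classes present in `labels`, vectorized over targets. The sign of t
#' follows `mean(group2) - mean(group1)` with groups ordered by label.
#'
#' @inheritParams test_multigroup
#' @return data frame `target`, `statistic` (t), `p`.
#' @export
test_twogroup <- function(x, labels) {
  m <- as_expr_values(x, scale = NULL)
  labels <- as.character(labels)
  if (length(labels) != ncol(m))
    stop("labels length must equal number of samples")
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("need exactly 2 classes, got ", length(lev))
  i1 <- which(labels == lev[1]); i2 <- which(labels == lev[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop("both classes need >= 2 samples")

  m1 <- rowMeans(m[, i1, drop = FALSE])
  m2 <- rowMeans(m[, i2, drop = FALSE])
  v1 <- apply(m[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(m[, i2, drop = FALSE], 1, stats::var)
  n1 <- length(i1); n2 <- length(i2)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # zero spread in both groups: t = 0, p = 1 when the means agree too
  degen <- se2 == 0 & m1 == m2
  tstat[degen] <- 0
  p[degen] <- 1
  p[se2 == 0 & m1 != m2] <- 0
  data.frame(target = rownames(m), statistic = unname(tstat),
             p = unname(p), stringsAsFactors = FALSE)
}

#' Storey q-values
#'
#' False-discovery-rate q-values by the Storey procedure with a fixed
#' tuning parameter lambda: the null proportion is estimated as
#' `pi0 = min(1, #(p > lambda) / ((1 - lambda) m))`, and for p-values
#' sorted ascending `q(m) = pi0 p(m)`,
#' `q(i) = min(q(i+1), pi0 p(i) m / i)`. Results are returned in the input
#' order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param lambda tuning parameter for the pi0 estimate (default 0.5).
#' @return list with `q` (vector, input order) and `pi0`.
#' @examples
#' estimate_qvalues(c(0.001, 0.5, 0.9, 0.95))
#' @export
estimate_qvalues <- function(p, lambda = 0.5) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  # guard: with no p above lambda the raw estimate degenerates to 0 and
  # would zero out every q-value; count at least one
  pi0 <- min(1, max(1, sum(p > lambda)) / ((1 - lambda) * m))
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  q[m] <- pi0 * ps[m]
  if (m > 1)
    for (i in (m - 1):1)
      q[i] <- min(q[i + 1], pi0 * ps[i] * m / i)
  out <- numeric(m)
  out[ord] <- q
  list(q = out, pi0 = pi0)
}

#' Maximum pairwise fold change between class means
#'
#' On the glog2 scale the fold change between two classes is
#' `2^(difference of class means)`; across more than two classes the
#' reported value is the maximum pairwise ratio,
#' `2^(max class mean - min class mean)`, so FC >= 1 always. With exactly
#' two classes a `direction` column gives the sign of
#' `mean(group2) - mean(group1)` (groups in sorted label order): `"up"`
#' means higher in group 2.
#'
#' @inheritParams test_multigroup
#' @return data frame `target`, `fc`, group mean columns (one per class,
#'   named `mean_<class>`), and `direction` for the two-class case.
#' @export
fold_change <- function(x, labels) {
  m <- as_expr_values(x, scale = "glog2")
  labels <- as.character(labels)
  if (length(labels) != ncol(m))
    stop("labels length must equal number of samples")
  lev <- sort(unique(labels))
  means <- vapply(lev, function(g)
    rowMeans(m[, labels == g, drop = FALSE]), numeric(nrow(m)))
  means <- matrix(means, nrow = nrow(m),
                  dimnames = list(rownames(m), lev))
  fc <- 2^(apply(means, 1, max) - apply(means, 1, min))
  out <- data.frame(target = rownames(m), fc = unname(fc),
                    stringsAsFactors = FALSE)
  for (g in lev) out[[paste0("mean_", g)]] <- unname(means[, g])
  if (length(lev) == 2) {
    d <- means[, 2] - means[, 1]
    out$direction <- ifelse(d >= 0, "up", "down")
  }
  out
}

#' Run a differential-expression comparison and assemble the result table
#'
#' Convenience wrapper combining the test ([test_multigroup()] for > 2
#' classes, [test_twogroup()] for 2), [estimate_qvalues()] and
#' [fold_change()] into one table.
#'
#' @inheritParams test_multigroup
#' @return data frame `target`, `statistic`, `p`, `q`, `fc`, group means
#'   and (two-class only) `direction`; attribute `pi0` carries the null
#'   proportion estimate.
#' @export
differential_expression <- function(x, labels) {
  labels <- as.character(labels)
  k <- length(unique(labels))
  tests <- if (k == 2) test_twogroup(x, labels) else test_multigroup(x, labels)
  qv <- estimate_qvalues(tests$p)
  fc <- fold_change(x, labels)
  out <- cbind(tests, q = qv$q, fc[, -1, drop = FALSE])
  attr(out, "pi0") <- qv$pi0
  out
}

#' Select a signature at FDR and fold-change thresholds
#'
#' Keeps targets with `q <= fdr_threshold` and `fc > fc_threshold`, sorted
#' by q ascending with ties broken by target id. The study's operating
#' points were FDR 0.5% with FC > 1.5 for the five-class comparison and
#' FDR 2% with FC > 1.5 for the tumor-vs-reactive-node comparison.
#'
#' @param results table from [differential_expression()] (needs columns
#'   `target`, `q`, `fc`).
#' @param fdr_threshold q-value cutoff (proportion).
#' @param fc_threshold linear fold-change cutoff (strict `>`).
#' @return the selected rows of `results`, re-sorted.
#' @export
select_signature <- function(results, fdr_threshold = 0.005,
                             fc_threshold = 1.5) {
  need <- c("target", "q", "fc")
  if (!all(need %in% names(results)))
    stop("results needs columns: ", paste(need, collapse = ", "))
  keep <- results$q <= fdr_threshold & results$fc > fc_threshold
  sel <- results[keep, , drop = FALSE]
  sel[order(sel$q, sel$target), , drop = FALSE]
}

#' Hierarchical clustering with the 1 - Pearson correlation distance
#'
#' Agglomerative clustering of features (rows) or samples (columns) using
#' `d = 1 - r` where r is the Pearson correlation between profiles, and
#' complete linkage. Items are pre-sorted by id so the leaf order is
#' deterministic for a given matrix regardless of input column/row order.
#'
#' @inheritParams test_multigroup
#' @param axis `"samples"` (cluster columns) or `"features"` (cluster rows).
#' @return object of class `mir_hclust`: list with the `hclust` tree
#'   (`tree`), `axis`, the distance object (`dist`) and `leaf_order`
#'   (item ids in dendrogram order).
#' @export
hierarchical_cluster <- function(x, axis = c("samples", "features")) {
  axis <- match.arg(axis)
  m <- as_expr_values(x, scale = NULL)
  if (axis == "samples") m <- t(m)
  m <- m[order(rownames(m)), , drop = FALSE]
  if (nrow(m) < 2) stop("need >= 2 items to cluster")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance item(s): ",
         paste(rownames(m)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(t(m)))
  tree <- stats::hclust(d, method = "complete")
  structure(list(tree = tree, axis = axis, dist = d,
                 leaf_order = tree$labels[tree$order]),
            class = "mir_hclust")
}

#' @export
print.mir_hclust <- function(x, ...) {
  cat(sprintf("<mir_hclust> %d %s, 1 - Pearson distance, complete linkage\n",
              length(x$leaf_order), x$axis))
  invisible(x)
}

#' @export
plot.mir_hclust <- function(x, ...) {
  plot(x$tree, xlab = x$axis, sub = "", main = "1 - Pearson, complete", ...)
  invisible(x)
}

#' Export a clustering tree as newick
#'
#' @param clust a `mir_hclust` from [hierarchical_cluster()].
#' @param path output file.
#' @export
write_dendrogram_newick <- function(clust, path) {
  ape::write.tree(ape::as.phylo(clust$tree), file = path)
  invisible(path)
}

#' Heatmap of a signature with a class annotation strip
#'
#' Draws a basic expression heatmap (features x samples, both ordered by
#' 1 - Pearson complete-linkage trees) with a per-sample class color strip
#' along the top, echoing the usual signature-heatmap layout.
#'
#' @inheritParams test_multigroup
#' @param labels class per sample, used for the annotation strip.
#' @export
plot_signature_heatmap <- function(x, labels) {
  m <- as_expr_values(x, scale = NULL)
  co <- hierarchical_cluster(m, "samples")$leaf_order
  ro <- hierarchical_cluster(m, "features")$leaf_order
  m <- m[ro, co]
  labels <- as.character(labels)[match(co, colnames(as_expr_values(x)))]
  classes <- sort(unique(labels))
  pal <- grDevices::hcl.colors(max(3, length(classes)), "Dark 3")
  old <- graphics::par(mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old))
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = "samples", ylab = "features", axes = FALSE)
  graphics::points(seq_len(ncol(m)), rep(nrow(m) + 0.75, ncol(m)),
                   pch = 15, col = pal[match(labels, classes)], xpd = NA)
  graphics::legend("topright", legend = classes, fill = pal, cex = 0.7,
                   bty = "n")
  invisible(NULL)
}
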