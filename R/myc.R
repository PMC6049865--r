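#' Normalize miRNA identifiers
#'
#' Lowercases ids and strips a leading species prefix ("hsa-"). Star forms
#' and arm suffixes ("*", "-5p", "-3p") are biologically distinct mature
#' species and are kept as-is.
#'
#' @param ids character vector of miRNA ids.
#' @return normalized character vector.
#' @examples
#' normalize_mirna_id(c("hsa-miR-17-5p", "MIR-126*"))
#' @export
normalize_mirna_id <- function(ids) {
  out <- tolower(ids)
  sub("^hsa-", "", out)
}

#' MYC signature container
#'
#' @param up,down character vectors of miRNA ids up-/down-regulated by MYC;
#'   both non-empty and disjoint after [normalize_mirna_id()].
#' @param name label for the signature.
#' @return object of class `myc_signature` (list `up`, `down`, `name`).
#' @export
myc_signature <- function(up, down, name = "custom") {
  up <- unique(normalize_mirna_id(up))
  down <- unique(normalize_mirna_id(down))
  if (length(up) == 0 || length(down) == 0)
    stop("both up and down lists must be non-empty")
  both <- intersect(up, down)
  if (length(both))
    stop("ids in both lists: ", paste(both, collapse = ", "))
  structure(list(up = up, down = down, name = name),
            class = "myc_signature")
}

#' @export
print.myc_signature <- function(x, ...) {
  cat(sprintf("<myc_signature> '%s': %d up, %d down\n",
              x$name, length(x$up), length(x$down)))
  invisible(x)
}

#' The default MYC-regulated miRNA signature
#'
#' MYC transcriptionally activates the miR-17-92 polycistron (and, through
#' its paralog clusters miR-106b-25 and miR-106a-363, the paralogous mature
#' species) and represses a well-characterized set including the let-7 and
#' miR-30 families, the miR-29 family, miR-26a/b, miR-34a, miR-146a,
#' miR-150 and miR-195.
#'
#' @param include_paralogs include the paralog-cluster members miR-106a,
#'   miR-106b, miR-20b, miR-93 and miR-25 in the up list (default TRUE).
#' @return a [myc_signature].
#' @export
default_myc_signature <- function(include_paralogs = TRUE) {
  up <- c("miR-17-5p", "miR-17-3p", "miR-18a", "miR-19a", "miR-19b",
          "miR-20a", "miR-92")
  if (include_paralogs)
    up <- c(up, "miR-106a", "miR-106b", "miR-20b", "miR-93", "miR-25")
  down <- c(paste0("let-7", letters[1:7]),
            paste0("miR-30", c("a", "b", "c", "d", "e")),
            paste0("miR-29", c("a", "b", "c")),
            "miR-26a", "miR-26b", "miR-34a", "miR-146a", "miR-150",
            "miR-195")
  myc_signature(up, down,
                name = if (include_paralogs) "myc_default+paralogs"
                       else "myc_default")
}

#' The M parameter: a per-sample MYC-activity score
#'
#' For each sample, M is the unweighted mean glog2 level of the
#' MYC-upregulated signature miRNAs found in the matrix minus the mean
#' level of the MYC-downregulated ones. M is invariant to adding a constant
#' to a sample's whole column, so array-wide shifts do not move it.
#'
#' @param x target-level glog2 [expr_matrix].
#' @param signature a [myc_signature] (default [default_myc_signature()]).
#' @param min_found minimum number of signature members that must be
#'   present in the matrix, per list (default 3).
#' @return data frame `sample_id`, `up_mean`, `down_mean`, `m`, with
#'   attributes `n_up_found`, `n_down_found`, `unmatched` (ids not found).
#' @export
m_parameter <- function(x, signature = default_myc_signature(),
                        min_found = 3) {
  m <- as_expr_values(x, scale = "glog2")
  ids <- normalize_mirna_id(rownames(m))
  up_idx <- which(ids %in% signature$up)
  down_idx <- which(ids %in% signature$down)
  if (length(up_idx) < min_found || length(down_idx) < min_found)
    stop(sprintf(
      "need >= %d matches per list; matched up: {%s}; matched down: {%s}",
      min_found, paste(ids[up_idx], collapse = ", "),
      paste(ids[down_idx], collapse = ", ")))
  up_mean <- colMeans(m[up_idx, , drop = FALSE])
  down_mean <- colMeans(m[down_idx, , drop = FALSE])
  out <- data.frame(sample_id = colnames(m), up_mean = unname(up_mean),
                    down_mean = unname(down_mean),
                    m = unname(up_mean - down_mean),
                    stringsAsFactors = FALSE)
  attr(out, "n_up_found") <- length(up_idx)
  attr(out, "n_down_found") <- length(down_idx)
  attr(out, "unmatched") <- setdiff(c(signature$up, signature$down), ids)
  out
}

# Spearman rho with average ranks plus a two-sided p-value: t approximation
# for n >= exact_below, exact permutation enumeration under that.
spearman_test <- function(xv, yv, exact_below = 8) {
  n <- length(xv)
  rx <- rank(xv); ry <- rank(yv)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(c(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rx, ry)
  if (n >= exact_below) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
    p <- min(p, 1)
  } else {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  }
  c(rho = rho, p = p)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Correlate miRNA levels with MYC-positive cell fractions
#'
#' The discovery screen behind the volcano analysis: every feature (probe
#' by default, mirroring a per-probe screen; collapsed targets work too) is
#' correlated with the per-sample immunohistochemical MYC-positive fraction
#' by Spearman's rho with average ranks. Two-sided p-values use the
#' t approximation for n >= 8 pairs and exact permutation enumeration
#' below; q-values come from [estimate_qvalues()]. Each feature is flagged
#' against the known MYC signature so novel candidates can be told apart.
#'
#' @param x probe- or target-level glog2 [expr_matrix].
#' @param myc_fractions named numeric vector (names = sample ids) of
#'   MYC-positive fractions in `[0, 1]`, or percentages in `[0, 100]`.
#' @param signature a [myc_signature] used for flagging.
#' @param min_n minimum complete pairs per feature (default 8); features
#'   with fewer are skipped with a warning.
#' @return data frame `feature`, `rho`, `p`, `q`, `n`, `known_myc_flag`
#'   (up/down/none).
#' @export
correlate_with_myc <- function(x, myc_fractions,
                               signature = default_myc_signature(),
                               min_n = 8) {
  m <- as_expr_values(x, scale = NULL)
  if (is.null(names(myc_fractions)))
    stop("myc_fractions must be named by sample id")
  common <- intersect(colnames(m), names(myc_fractions))
  if (length(common) < min_n)
    stop("fewer than min_n samples with both expression and MYC fraction")
  m <- m[, common, drop = FALSE]
  fr <- myc_fractions[common]

  res <- t(apply(m, 1, function(row) {
    ok <- is.finite(row) & is.finite(fr)
    if (sum(ok) < min_n) return(c(NA_real_, NA_real_, sum(ok)))
    c(spearman_test(row[ok], fr[ok]), sum(ok))
  }))
  skipped <- rownames(m)[is.na(res[, 1])]
  if (length(skipped))
    warning("skipped (fewer than min_n pairs or constant ranks): ",
            paste(skipped, collapse = ", "))
  keep <- !is.na(res[, 1])
  qv <- rep(NA_real_, nrow(m))
  if (any(keep)) qv[keep] <- estimate_qvalues(res[keep, 2])$q
  ids <- normalize_mirna_id(rownames(m))
  flag <- rep("none", nrow(m))
  flag[ids %in% signature$up] <- "up"
  flag[ids %in% signature$down] <- "down"
  data.frame(feature = rownames(m), rho = unname(res[, 1]),
             p = unname(res[, 2]), q = qv, n = as.integer(res[, 3]),
             known_myc_flag = flag, stringsAsFactors = FALSE)
}

#' Partition a correlation screen into volcano arms
#'
#' Splits significant features (`p < p_cut`) by correlation sign into a
#' positive and a negative arm; features significant but not in the known
#' MYC signature are reported as novel candidates.
#'
#' @param records output of [correlate_with_myc()].
#' @param p_cut raw p-value cutoff (default 0.001).
#' @return list with data frames `positive`, `negative`, `novel`, each
#'   sorted by p ascending.
#' @export
volcano_table <- function(records, p_cut = 0.001) {
  if (nrow(records) == 0) stop("records must be non-empty")
  sig <- records[!is.na(records$p) & records$p < p_cut, , drop = FALSE]
  sig <- sig[order(sig$p, sig$feature), , drop = FALSE]
  list(positive = sig[sig$rho > 0, , drop = FALSE],
       negative = sig[sig$rho < 0, , drop = FALSE],
       novel = sig[sig$known_myc_flag == "none", , drop = FALSE])
}

#' Volcano plot of the MYC correlation screen
#'
#' x = Spearman rho, y = -log10 p; known MYC-signature features are
#' highlighted by their up/down flag.
#'
#' @inheritParams volcano_table
#' @export
plot_volcano <- function(records, p_cut = 0.001) {
  ok <- !is.na(records$p)
  col <- c(none = "grey50", up = "dodgerblue3", down = "firebrick3")
  plot(records$rho[ok], -log10(records$p[ok]),
       col = col[records$known_myc_flag[ok]], pch = 16, cex = 0.6,
       xlab = "Spearman rho (miRNA vs MYC+ fraction)",
       ylab = expression(-log[10] ~ p), xlim = c(-1, 1))
  graphics::abline(h = -log10(p_cut), lty = 2)
  graphics::legend("topleft", legend = names(col), col = col, pch = 16,
                   bty = "n", cex = 0.8)
  invisible(NULL)
}
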