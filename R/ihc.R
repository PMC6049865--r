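#' Positivity threshold from reference slides
#'
#' The staining threshold is anchored on reference slides (reactive lymph
#' nodes with low-frequency nuclear stain): it is set just under the level
#' that leaves a fixed share of reference nuclei negative — concretely, the
#' nearest-rank quantile of the pooled reference intensities at
#' `negative_fraction` (default 95%), with a nucleus called positive iff
#' its intensity is strictly greater than the threshold. By construction at
#' most `(1 - negative_fraction) + 1/n` of reference nuclei come out
#' positive.
#'
#' @param reference data frame in the nucleus-table dialect (needs column
#'   `intensity`; rows are pooled across reference slides) or a numeric
#'   vector of reference intensities. At least 100 nuclei.
#' @param negative_fraction share of reference nuclei to keep negative
#'   (default 0.95).
#' @return the numeric threshold.
#' @examples
#' set_threshold(1:100)   # 95
#' @export
set_threshold <- function(reference, negative_fraction = 0.95) {
  x <- if (is.data.frame(reference)) reference$intensity else reference
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("empty reference")
  if (length(x) < 100)
    stop("need >= 100 reference nuclei, got ", length(x))
  if (negative_fraction <= 0 || negative_fraction >= 1)
    stop("negative_fraction must be in (0, 1)")
  k <- ceiling(negative_fraction * length(x))
  sort(x)[k]
}

#' MYC-positive fraction of a slide
#'
#' Counts sample nuclei with intensity strictly above the threshold and
#' reports the positive percentage (the paper-scale readout: MYC-positive
#' nuclei per counted nuclei, nominally 10,000 per slide). Because the
#' rank threshold deliberately calls `1 - negative_fraction` of truly
#' negative nuclei positive, the raw percentage over-estimates small true
#' fractions by about `(1 - f)(1 - negative_fraction)`; the returned
#' `percent_positive_adjusted` divides out that known operating
#' characteristic, `f_hat = (p_hat - (1 - nf)) / nf`, clipped to [0, 100],
#' and is the better estimate of the underlying positive fraction.
#'
#' @param sample data frame with columns `slide_id` and `intensity` (or a
#'   numeric vector, treated as one slide).
#' @param threshold from [set_threshold()].
#' @param negative_fraction the value used when the threshold was set;
#'   feeds the adjusted estimate (default 0.95).
#' @return object of class `ihc_result`: data frame per slide with
#'   `slide_id`, `threshold`, `n_nuclei`, `n_positive`, `percent_positive`,
#'   `percent_positive_adjusted`.
#' @export
positive_fraction <- function(sample, threshold, negative_fraction = 0.95) {
  if (!is.data.frame(sample))
    sample <- data.frame(slide_id = "slide", intensity = sample)
  if (nrow(sample) == 0) stop("no nuclei")
  slides <- split(sample$intensity, sample$slide_id)
  nf <- negative_fraction
  rows <- lapply(names(slides), function(sl) {
    x <- slides[[sl]]
    n <- length(x)
    np <- sum(x > threshold)
    pct <- 100 * np / n
    adj <- 100 * min(1, max(0, (np / n - (1 - nf)) / nf))
    data.frame(slide_id = sl, threshold = threshold, n_nuclei = n,
               n_positive = np, percent_positive = pct,
               percent_positive_adjusted = adj, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ihc_result", "data.frame")
  out
}

#' @export
print.ihc_result <- function(x, ...) {
  cat(sprintf("<ihc_result> %d slide(s), threshold %.4g\n",
              nrow(x), x$threshold[1]))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Quantify a whole nucleus table
#'
#' Convenience wrapper: pools `is_reference` slides to set the threshold,
#' then scores every non-reference slide.
#'
#' @param nuclei nucleus table (`slide_id`, `nucleus_id`, `intensity`,
#'   `is_reference`).
#' @inheritParams set_threshold
#' @return an `ihc_result` for the non-reference slides.
#' @export
ihc_quantify <- function(nuclei, negative_fraction = 0.95) {
  if (!any(nuclei$is_reference))
    stop("no reference slide present")
  thr <- set_threshold(nuclei[nuclei$is_reference, , drop = FALSE],
                       negative_fraction)
  positive_fraction(nuclei[!nuclei$is_reference, , drop = FALSE], thr,
                    negative_fraction)
}
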