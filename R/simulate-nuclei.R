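#' Simulate nucleus-intensity tables for IHC quantification
#'
#' Emulates the output of automated positive-cell counting: reference
#' nuclei (reactive-node background staining) follow a log-normal law; the
#' sample slide's nuclei are a mixture of that background (probability
#' `1 - true_positive_fraction`) and a positively stained population whose
#' log-intensity is shifted upward by `separation` (probability
#' `true_positive_fraction`). The generating truth is recorded per nucleus.
#'
#' @param n_reference number of reference nuclei (pooled reference slides).
#' @param n_sample number of sample nuclei (> 0; the study counted 10,000
#'   per slide).
#' @param true_positive_fraction proportion of truly positive sample nuclei
#'   in `[0, 1]`.
#' @param separation upward shift of positive nuclei on the log-intensity
#'   scale (> 0); in units of `sdlog`, a shift of `4 * sdlog` makes the
#'   populations nearly disjoint.
#' @param seed integer seed.
#' @param meanlog,sdlog background log-normal parameters (defaults 4 and
#'   0.25).
#' @return list with `nuclei` (nucleus table: `slide_id`, `nucleus_id`,
#'   `intensity`, `is_reference`) and `truth` (`true_positive_fraction`,
#'   per-nucleus `is_positive`, `sdlog`).
#' @export
simulate_nuclei <- function(n_reference = 10000, n_sample = 10000,
                            true_positive_fraction = 0.1,
                            separation = 1, seed = 1L,
                            meanlog = 4, sdlog = 0.25) {
  if (n_sample <= 0) stop("n_sample must be > 0")
  if (true_positive_fraction < 0 || true_positive_fraction > 1)
    stop("true_positive_fraction must be in [0, 1]")
  if (separation <= 0) stop("separation must be > 0")
  set.seed(as.integer(seed))
  ref <- stats::rlnorm(n_reference, meanlog, sdlog)
  is_pos <- stats::runif(n_sample) < true_positive_fraction
  smp <- stats::rlnorm(n_sample,
                       meanlog + ifelse(is_pos, separation, 0), sdlog)
  nuclei <- data.frame(
    slide_id = c(rep("reference", n_reference), rep("sample", n_sample)),
    nucleus_id = c(sprintf("ref_%05d", seq_len(n_reference)),
                   sprintf("smp_%05d", seq_len(n_sample))),
    intensity = c(ref, smp),
    is_reference = c(rep(TRUE, n_reference), rep(FALSE, n_sample)),
    stringsAsFactors = FALSE)
  list(nuclei = nuclei,
       truth = list(true_positive_fraction = true_positive_fraction,
                    is_positive = is_pos, sdlog = sdlog))
}
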