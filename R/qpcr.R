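#' Comparative-method (delta-delta Ct) relative quantification
#'
#' Computes per-sample relative quantities from qPCR cycle-threshold values
#' by the comparative method: for each sample,
#' `dCt = Ct(target) - mean(Ct(references))`, then
#' `ddCt = dCt(sample) - dCt(calibrator)` and `RQ = 2^(-ddCt)`. With the
#' small-RNA references used for miRNA assays (e.g. RNU44 and U47) the
#' reference Ct entering dCt is their plain average.
#'
#' @param ct_table data frame with columns `sample_id`, `assay_id`, `ct`.
#' @param target_assay assay id to quantify.
#' @param reference_assays character vector of reference assay ids
#'   (default `c("RNU44", "U47")`).
#' @param calibrator sample id whose RQ is defined as 1.
#' @return data frame `sample_id`, `dct`, `ddct`, `rq`, sorted by sample id.
#' @examples
#' ct <- expand.grid(sample_id = c("a", "b"),
#'                   assay_id = c("miR-21", "RNU44", "U47"))
#' ct$ct <- c(25, 24, 20, 20, 22, 22)
#' qpcr_relative_expression(ct, "miR-21", c("RNU44", "U47"), calibrator = "a")
#' @export
qpcr_relative_expression <- function(ct_table, target_assay,
                                     reference_assays = c("RNU44", "U47"),
                                     calibrator) {
  need <- c("sample_id", "assay_id", "ct")
  if (!all(need %in% names(ct_table)))
    stop("ct_table needs columns: ", paste(need, collapse = ", "))
  samples <- unique(as.character(ct_table$sample_id))
  if (!calibrator %in% samples)
    stop("calibrator sample not found: ", calibrator)

  get_ct <- function(s, a) {
    v <- ct_table$ct[ct_table$sample_id == s & ct_table$assay_id == a]
    if (length(v) == 0 || any(is.na(v)))
      stop("missing Ct for sample '", s, "', assay '", a, "'")
    mean(v)  # technical replicates averaged
  }
  dct <- vapply(samples, function(s) {
    refs <- vapply(reference_assays, function(a) get_ct(s, a), numeric(1))
    get_ct(s, target_assay) - mean(refs)
  }, numeric(1))
  ddct <- dct - dct[[calibrator]]
  out <- data.frame(sample_id = samples, dct = unname(dct),
                    ddct = unname(ddct), rq = 2^(-unname(ddct)),
                    stringsAsFactors = FALSE)
  out[order(out$sample_id), , drop = FALSE]
}
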