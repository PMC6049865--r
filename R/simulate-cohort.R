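#' Configuration for the synthetic lymphoma cohort
#'
#' The generator emulates the statistical structure of a mixed non-Hodgkin
#' B-cell lymphoma miRNA-profiling study: five lymphoma classes (BL, DLBCL,
#' PMBL, MCL, FL) plus reactive lymph nodes (LN); multiple array probes per
#' miRNA target (on average 4.3); a latent per-sample MYC activity
#' `a_s` on [0, 1] whose class means are ordered BL highest and MCL/FL/LN
#' lowest; a MYC signature whose up members gain `+beta * a_s` and down
#' members `-beta * a_s` glog2 units; optionally planted class-
#' discriminating targets and planted MYC-correlated "novel" targets; and
#' an immunohistochemical MYC-positive fraction that is a noisy logistic of
#' `a_s`.
#'
#' @param class_sizes named integer vector of samples per class (defaults
#'   to BL 12, DLBCL 13, PMBL 8, MCL 17, FL 26, LN 11).
#' @param n_targets total number of miRNA targets (default 300).
#' @param probes_per_target_mean mean probes per target; per-target counts
#'   are 1 + Poisson(mean - 1) (default 4.3).
#' @param myc_activity_params data frame `class`, `mean`, `sd` of the
#'   truncated-normal latent activity per class; means must be in [0, 1].
#' @param beta MYC effect size, glog2 units per unit activity (default 1).
#' @param signature [myc_signature] realized in the cohort (its member ids
#'   become target ids); default [default_myc_signature()].
#' @param n_planted_de number of class-discriminating targets (default 0).
#' @param de_offset glog2 offset of planted DE targets (default 1.25).
#' @param de_classes classes receiving the DE offset; default one class
#'   drawn at random per planted target.
#' @param n_planted_corr number of planted MYC-correlated novel targets
#'   (default 0).
#' @param corr_effect glog2 units per unit activity for planted correlated
#'   targets (default 1.8, tuned for a true Spearman around 0.7 under the
#'   default noise).
#' @param noise_sd residual biological sd at target level, glog2 units
#'   (default 0.5).
#' @param probe_offset_sd sd of fixed per-probe additive offsets (default
#'   0.3), giving median polish real work.
#' @param array_effect_sd sd of the per-array log-normal multiplicative
#'   factor on the raw scale (default 0.15).
#' @param background additive raw-scale offset (default 50).
#' @param raw_noise_sd additive raw-scale measurement noise sd (default 10).
#' @param baseline_mean,baseline_sd glog2 baseline level distribution of
#'   expressed targets (defaults 8 and 1.5).
#' @param unexpressed_prop proportion of the non-signature, non-planted
#'   targets that are essentially unexpressed (baseline glog2 of
#'   `unexpressed_level`), as on real arrays where many miRNAs sit at
#'   background; this near-background probe mass is what anchors the
#'   calibration's background-quantile estimate (default 0.3).
#' @param unexpressed_level glog2 baseline of unexpressed targets
#'   (default 2).
#' @param myc_fraction_noise_sd additive noise on the logistic MYC-positive
#'   fraction (default 0.05).
#' @param seed integer seed; the same config and seed give byte-identical
#'   output.
#' @return object of class `cohort_config` (validated list).
#' @export
cohort_config <- function(class_sizes = c(BL = 12, DLBCL = 13, PMBL = 8,
                                          MCL = 17, FL = 26, LN = 11),
                          n_targets = 300,
                          probes_per_target_mean = 4.3,
                          myc_activity_params = default_activity_params(),
                          beta = 1.0,
                          signature = default_myc_signature(),
                          n_planted_de = 0,
                          de_offset = 1.25,
                          de_classes = NULL,
                          n_planted_corr = 0,
                          corr_effect = 1.8,
                          noise_sd = 0.5,
                          probe_offset_sd = 0.3,
                          array_effect_sd = 0.15,
                          background = 50,
                          raw_noise_sd = 10,
                          baseline_mean = 8,
                          baseline_sd = 1.5,
                          unexpressed_prop = 0.3,
                          unexpressed_level = 2,
                          myc_fraction_noise_sd = 0.05,
                          seed = 1L) {
  if (is.null(names(class_sizes)) || any(!nzchar(names(class_sizes))))
    stop("class_sizes must be named")
  if (any(class_sizes < 1)) stop("all class sizes must be >= 1")
  if (n_targets < 1) stop("n_targets must be >= 1")
  if (probes_per_target_mean < 1)
    stop("probes_per_target_mean must be >= 1")
  ap <- myc_activity_params
  if (!all(c("class", "mean", "sd") %in% names(ap)))
    stop("myc_activity_params needs columns class, mean, sd")
  if (any(ap$mean < 0 | ap$mean > 1))
    stop("activity means must lie in [0, 1]")
  missing_cls <- setdiff(names(class_sizes), ap$class)
  if (length(missing_cls))
    stop("no activity parameters for class(es): ",
         paste(missing_cls, collapse = ", "))
  if (!is.null(de_classes)) {
    bad <- setdiff(unlist(de_classes), names(class_sizes))
    if (length(bad))
      stop("invalid class label in de_classes: ",
           paste(bad, collapse = ", "))
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  structure(list(class_sizes = class_sizes, n_targets = n_targets,
                 probes_per_target_mean = probes_per_target_mean,
                 myc_activity_params = ap, beta = beta,
                 signature = signature, n_planted_de = n_planted_de,
                 de_offset = de_offset, de_classes = de_classes,
                 n_planted_corr = n_planted_corr,
                 corr_effect = corr_effect, noise_sd = noise_sd,
                 probe_offset_sd = probe_offset_sd,
                 array_effect_sd = array_effect_sd,
                 background = background, raw_noise_sd = raw_noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 unexpressed_prop = unexpressed_prop,
                 unexpressed_level = unexpressed_level,
                 myc_fraction_noise_sd = myc_fraction_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default per-class latent MYC-activity parameters
#'
#' Class means are ordered BL > DLBCL (wide spread, matching its large
#' observed MYC-positivity range) > PMBL > LN > FL > MCL, with the bottom
#' three close together.
#'
#' @return data frame `class`, `mean`, `sd`.
#' @export
default_activity_params <- function() {
  data.frame(class = c("BL", "DLBCL", "PMBL", "LN", "FL", "MCL"),
             mean = c(0.90, 0.60, 0.52, 0.30, 0.25, 0.17),
             sd = c(0.06, 0.18, 0.15, 0.10, 0.14, 0.12),
             stringsAsFactors = FALSE)
}

rtruncnorm01 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0 | x > 1))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a synthetic lymphoma cohort
#'
#' Target-level truth per target g and sample s is
#' `t_gs = baseline_g + DE offset + signed beta * a_s + N(0, noise_sd)`;
#' each probe of a target measures
#' `raw = (2^(t + probe offset) + background) * array_factor + noise`,
#' clipped at 0. The MYC-positive fraction per sample is a noisy logistic
#' of `a_s`, clipped to [0, 1]. MYC-signature member ids are used verbatim
#' as target ids so the scoring stage finds them; all other targets get
#' synthetic ids (`mir-syn-NNN`).
#'
#' @param config a [cohort_config()].
#' @return list with `raw` (probe-level raw [expr_matrix]), `annotation`
#'   (`probe_id`, `target_id`, `species`), `metadata` (`sample_id`,
#'   `class`, `myc_fraction`), and `truth` (per-sample `a_s`, planted DE
#'   targets with directions/classes, planted correlated targets, signature
#'   targets, per-target baselines).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  cs <- config$class_sizes
  classes <- rep(names(cs), cs)
  n_s <- length(classes)
  sample_ids <- sprintf("%s_%02d", classes,
                        unlist(lapply(cs, seq_len)))

  ap <- config$myc_activity_params
  a_s <- numeric(n_s)
  for (cl in names(cs)) {
    idx <- which(classes == cl)
    row <- ap[ap$class == cl, ]
    a_s[idx] <- rtruncnorm01(length(idx), row$mean, row$sd)
  }
  names(a_s) <- sample_ids

  # --- target universe -------------------------------------------------
  sig <- config$signature
  sig_ids <- c(sig$up, sig$down)
  n_sig <- length(sig_ids)
  if (config$n_targets < n_sig + config$n_planted_de + config$n_planted_corr)
    stop("n_targets too small for signature + planted targets")
  n_other <- config$n_targets - n_sig
  other_ids <- sprintf("mir-syn-%03d", seq_len(n_other))
  target_ids <- c(sig_ids, other_ids)

  sig_dir <- c(rep(1, length(sig$up)), rep(-1, length(sig$down)),
               rep(0, n_other))
  names(sig_dir) <- target_ids

  planted_corr <- if (config$n_planted_corr > 0)
    other_ids[seq_len(config$n_planted_corr)] else character(0)
  de_pool <- setdiff(other_ids, planted_corr)
  planted_de <- if (config$n_planted_de > 0)
    de_pool[seq_len(config$n_planted_de)] else character(0)

  de_dir <- sample(c(-1, 1), length(planted_de), replace = TRUE)
  de_cls <- if (is.null(config$de_classes))
    lapply(seq_along(planted_de),
           function(i) sample(names(cs), 1))
  else rep(config$de_classes, length.out = length(planted_de))

  baseline <- stats::rnorm(config$n_targets, config$baseline_mean,
                           config$baseline_sd)
  names(baseline) <- target_ids
  # a share of the null targets sits at background, as on real arrays
  null_ids <- setdiff(other_ids, c(planted_de, planted_corr))
  n_unexpr <- round(config$unexpressed_prop * length(null_ids))
  if (n_unexpr > 0) {
    unexpr <- sample(null_ids, n_unexpr)
    baseline[unexpr] <- stats::rnorm(n_unexpr, config$unexpressed_level,
                                     0.3)
  }

  # --- target-level truth ----------------------------------------------
  truth_mat <- matrix(baseline, config$n_targets, n_s,
                      dimnames = list(target_ids, sample_ids))
  truth_mat <- truth_mat +
    config$beta * outer(sig_dir, a_s)
  for (i in seq_along(planted_de)) {
    cols <- classes %in% de_cls[[i]]
    truth_mat[planted_de[i], cols] <-
      truth_mat[planted_de[i], cols] + de_dir[i] * config$de_offset
  }
  if (length(planted_corr))
    truth_mat[planted_corr, ] <- truth_mat[planted_corr, , drop = FALSE] +
      config$corr_effect * matrix(a_s, length(planted_corr), n_s,
                                  byrow = TRUE)
  truth_mat <- truth_mat +
    matrix(stats::rnorm(length(truth_mat), 0, config$noise_sd),
           nrow(truth_mat))

  # --- probe layer ------------------------------------------------------
  n_probes_per <- 1L + stats::rpois(config$n_targets,
                                    config$probes_per_target_mean - 1)
  probe_target <- rep(target_ids, n_probes_per)
  probe_ids <- sprintf("probe_%04d", seq_along(probe_target))
  probe_offset <- stats::rnorm(length(probe_ids), 0,
                               config$probe_offset_sd)
  array_factor <- exp(stats::rnorm(n_s, 0, config$array_effect_sd))

  glog_true <- truth_mat[probe_target, , drop = FALSE] + probe_offset
  raw <- sweep(2^glog_true + config$background, 2, array_factor, "*") +
    matrix(stats::rnorm(length(glog_true), 0, config$raw_noise_sd),
           nrow(glog_true))
  raw <- pmax(raw, 0)
  dimnames(raw) <- list(probe_ids, sample_ids)

  myc_fraction <- stats::plogis(6 * (a_s - 0.5)) +
    stats::rnorm(n_s, 0, config$myc_fraction_noise_sd)
  myc_fraction <- pmin(pmax(myc_fraction, 0), 1)

  annotation <- data.frame(probe_id = probe_ids, target_id = probe_target,
                           species = "hsa", stringsAsFactors = FALSE)
  metadata <- data.frame(sample_id = sample_ids, class = classes,
                         myc_fraction = unname(myc_fraction),
                         stringsAsFactors = FALSE)
  truth <- list(a_s = a_s,
                planted_de = data.frame(
                  target = planted_de,
                  direction = if (length(planted_de))
                    ifelse(de_dir > 0, "up", "down") else character(0),
                  classes = vapply(de_cls, paste, "", collapse = ","),
                  stringsAsFactors = FALSE),
                planted_corr = planted_corr,
                signature_up = sig$up, signature_down = sig$down,
                baseline = baseline,
                myc_fraction_true = stats::plogis(6 * (a_s - 0.5)))
  list(raw = expr_matrix(raw, "probe", "raw"), annotation = annotation,
       metadata = metadata, truth = truth)
}
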