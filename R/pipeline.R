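#' Derive a per-stage child seed from the global pipeline seed
#'
#' A stable polynomial hash of the stage name is folded into the global
#' seed modulo 2^31 - 1, so toggling one stage on or off never shifts the
#' randomness any other stage sees.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer child seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  as.integer((h + as.numeric(seed)) %% m)
}

#' Pipeline configuration
#'
#' Collects the thresholds, stage toggles and seed for [run_pipeline()].
#' Threshold defaults follow the study's operating points: five-class
#' signature at FDR 0.5% and fold change > 1.5; two-class (tumor vs
#' reactive node) signature at FDR 2% and fold change > 1.5; volcano
#' significance at raw p < 0.001; IHC negative fraction 95%; 7 hub
#' proteins.
#'
#' @param outdir output directory (created if needed).
#' @param seed global integer seed.
#' @param cohort a [cohort_config()] for the simulate stage; its seed is
#'   overridden by the stage seed derived from `seed`.
#' @param stages named logical vector toggling stages on/off; names among
#'   simulate, normalize, collapse, de, cluster, myc_score, myc_correlate,
#'   ihc, network.
#' @param fdr_multigroup,fdr_twogroup,fc_threshold,volcano_p_cut,
#'   ihc_negative_fraction,hub_k thresholds (see description).
#' @param signature [myc_signature] for the scoring stages.
#' @param two_group_classes the two classes compared in the two-group
#'   stage (default BL vs LN).
#' @param ihc_nuclei_per_slide nuclei per simulated slide (default 2000).
#' @param include_ln include reactive-node samples in the MYC correlation
#'   screen (default TRUE).
#' @param paths named list of input paths used when `simulate` is off;
#'   needs `expression`, `annotation`, `metadata`, and for the ihc/network
#'   stages `nuclei`, `interactome`, `targets`, `go`, `de_mirnas`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            seed = 1L,
                            cohort = cohort_config(n_planted_corr = 5),
                            stages = NULL,
                            fdr_multigroup = 0.005,
                            fdr_twogroup = 0.02,
                            fc_threshold = 1.5,
                            volcano_p_cut = 0.001,
                            ihc_negative_fraction = 0.95,
                            hub_k = 7,
                            signature = default_myc_signature(),
                            two_group_classes = c("BL", "LN"),
                            ihc_nuclei_per_slide = 2000,
                            include_ln = TRUE,
                            paths = list()) {
  all_stages <- c(simulate = TRUE, normalize = TRUE, collapse = TRUE,
                  de = TRUE, cluster = TRUE, myc_score = TRUE,
                  myc_correlate = TRUE, ihc = TRUE, network = TRUE)
  if (!is.null(stages)) {
    bad <- setdiff(names(stages), names(all_stages))
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
    all_stages[names(stages)] <- stages
  }
  stopifnot(fdr_multigroup > 0, fdr_multigroup < 1,
            fdr_twogroup > 0, fdr_twogroup < 1, fc_threshold >= 1,
            volcano_p_cut > 0, volcano_p_cut < 1,
            ihc_negative_fraction > 0, ihc_negative_fraction < 1,
            hub_k >= 1)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 cohort = cohort, stages = all_stages,
                 fdr_multigroup = fdr_multigroup,
                 fdr_twogroup = fdr_twogroup,
                 fc_threshold = fc_threshold,
                 volcano_p_cut = volcano_p_cut,
                 ihc_negative_fraction = ihc_negative_fraction,
                 hub_k = hub_k, signature = signature,
                 two_group_classes = two_group_classes,
                 ihc_nuclei_per_slide = ihc_nuclei_per_slide,
                 include_ln = include_ln, paths = paths),
            class = "pipeline_config")
}

log_msg <- function(verbose, ...) {
  if (verbose) message("[mirlymph] ", ...)
}

#' Validate pipeline input files
#'
#' Checks the TSV dialects, id cross-references (probes vs annotation,
#' samples vs metadata, seeds vs interactome) and value ranges. Any
#' blocking issue stops [run_pipeline()] unless `force = TRUE` there.
#'
#' @param paths named list of file paths; recognized names: `expression`,
#'   `annotation`, `metadata`, `nuclei`, `targets`, `go`, `interactome`.
#'   Absent entries are skipped.
#' @return data frame `severity` ("blocking"/"warning"), `where`,
#'   `message`; zero rows means clean.
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  add <- function(severity, where, msg)
    issues[[length(issues) + 1]] <<- data.frame(
      severity = severity, where = where, message = msg,
      stringsAsFactors = FALSE)
  try_read <- function(name, reader) {
    p <- paths[[name]]
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) stop("unreadable file: ", p)
    tryCatch(reader(p), error = function(e) {
      add("blocking", name, conditionMessage(e))
      NULL
    })
  }
  expr <- try_read("expression",
                   function(p) read_expression_tsv(p, "probe", "raw"))
  ann <- try_read("annotation", read_probe_annotation_tsv)
  meta <- try_read("metadata", read_metadata_tsv)
  nuc <- try_read("nuclei", read_nucleus_tsv)
  tg <- try_read("targets", read_target_tsv)
  go <- try_read("go", read_go_tsv)
  net <- try_read("interactome", read_interactome)

  if (!is.null(expr) && !is.null(ann)) {
    orphan <- setdiff(rownames(expr$values), ann$probe_id)
    if (length(orphan))
      add("blocking", "annotation",
          paste("probe(s) in matrix but not annotated:",
                paste(utils::head(orphan, 5), collapse = ", ")))
  }
  if (!is.null(expr) && !is.null(meta)) {
    unmet <- setdiff(colnames(expr$values), meta$sample_id)
    if (length(unmet))
      add("blocking", "metadata",
          paste("sample(s) without metadata:",
                paste(utils::head(unmet, 5), collapse = ", ")))
  }
  if (!is.null(meta) && "myc_fraction" %in% names(meta)) {
    bad <- meta$myc_fraction < 0 | meta$myc_fraction > 1
    if (any(bad, na.rm = TRUE))
      add("blocking", "metadata",
          paste("myc_fraction outside [0, 1] for:",
                paste(utils::head(meta$sample_id[bad], 5), collapse = ", ")))
  }
  if (!is.null(nuc)) {
    if (!any(nuc$is_reference))
      add("blocking", "nuclei", "no reference slide present")
    if (any(!is.finite(nuc$intensity)))
      add("blocking", "nuclei", "non-finite intensities")
  }
  if (!is.null(tg) && !is.null(net)) {
    known <- igraph::V(net)$name
    strong_genes <- unique(tg$gene[tg$evidence == "strong"])
    if (!any(strong_genes %in% known))
      add("warning", "targets",
          "no strong-evidence target gene occurs in the interactome")
  }
  if (length(issues) == 0)
    return(data.frame(severity = character(0), where = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Run the analysis pipeline end to end
#'
#' Executes (optionally) simulate, then normalize, collapse, differential
#' expression (five-class and two-class), clustering, M-parameter scoring,
#' the MYC correlation screen, IHC quantification and network inference,
#' writing each stage's outputs as TSV/JSON under `config$outdir` plus a
#' run manifest and a summary. All randomness derives from the single
#' config seed via [stage_seed()], so identical config + seed reproduces
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param verbose log progress to stderr (default FALSE).
#' @param force run even when [validate_inputs()] reports blocking issues.
#' @return (invisibly) a list with the summary, per-stage results and the
#'   manifest of written files.
#' @export
run_pipeline <- function(config, verbose = FALSE, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$outdir, name)
  st <- config$stages
  written <- character(0)
  emit <- function(writer, obj, name) {
    writer(obj, out(name))
    written <<- c(written, name)
  }
  results <- list()
  run_stage <- function(name, fn) {
    log_msg(verbose, "stage: ", name)
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- simulate --------------------------------------------------------
  if (st[["simulate"]]) {
    sim <- run_stage("simulate", function() {
      cfg <- config$cohort
      cfg$seed <- stage_seed(config$seed, "simulate")
      simulate_cohort(cfg)
    })
    results$sim <- sim
    emit(write_expression_tsv, sim$raw, "expression_raw.tsv")
    emit(write_tsv_raw, sim$annotation, "probe_annotation.tsv")
    emit(write_tsv_raw, sim$metadata, "metadata.tsv")
    jsonlite::write_json(
      list(a_s = as.list(sim$truth$a_s),
           planted_de = sim$truth$planted_de,
           planted_corr = sim$truth$planted_corr),
      out("ground_truth.json"), auto_unbox = TRUE, digits = NA)
    written <- c(written, "ground_truth.json")
    expr_raw <- sim$raw; ann <- sim$annotation; meta <- sim$metadata
  } else {
    p <- config$paths
    issues <- validate_inputs(p)
    blocking <- issues[issues$severity == "blocking", , drop = FALSE]
    if (nrow(blocking) && !force)
      stop("blocking validation issue(s):\n",
           paste(blocking$where, blocking$message, sep = ": ",
                 collapse = "\n"))
    expr_raw <- read_expression_tsv(p$expression, "probe", "raw")
    ann <- read_probe_annotation_tsv(p$annotation)
    meta <- read_metadata_tsv(p$metadata)
  }

  # ---- normalize / collapse -------------------------------------------
  norm <- NULL; targets_expr <- NULL
  if (st[["normalize"]]) {
    norm <- run_stage("normalize", function() glog_normalize(expr_raw))
    emit(write_expression_tsv, norm$normalized, "expression_glog2.tsv")
  }
  if (st[["collapse"]]) {
    if (is.null(norm)) stop("collapse stage requires normalize stage")
    targets_expr <- run_stage("collapse", function()
      collapse_probes(norm$normalized, ann))
    emit(write_expression_tsv, targets_expr, "expression_targets.tsv")
  }

  classes <- meta$class[match(colnames(expr_raw$values), meta$sample_id)]
  lymphoma <- classes != "LN"

  # ---- differential expression ----------------------------------------
  if (st[["de"]]) {
    if (is.null(targets_expr)) stop("de stage requires collapse stage")
    de <- run_stage("de", function() {
      tm <- targets_expr$values
      multi <- differential_expression(
        tm[, lymphoma, drop = FALSE], classes[lymphoma])
      two_keep <- classes %in% config$two_group_classes
      two <- differential_expression(
        tm[, two_keep, drop = FALSE], classes[two_keep])
      list(multi = multi, two = two,
           sig_multi = select_signature(multi, config$fdr_multigroup,
                                        config$fc_threshold),
           sig_two = select_signature(two, config$fdr_twogroup,
                                      config$fc_threshold))
    })
    results$de <- de
    emit(write_tsv_raw, de$multi, "de_multigroup.tsv")
    emit(write_tsv_raw, de$two, "de_twogroup.tsv")
    emit(write_tsv_raw, de$sig_multi, "signature_multigroup.tsv")
    emit(write_tsv_raw, de$sig_two, "signature_twogroup.tsv")
  }

  # ---- clustering ------------------------------------------------------
  if (st[["cluster"]]) {
    if (is.null(targets_expr)) stop("cluster stage requires collapse stage")
    cl <- run_stage("cluster", function()
      hierarchical_cluster(targets_expr, "samples"))
    results$cluster <- cl
    emit(write_dendrogram_newick, cl, "samples_dendrogram.nwk")
  }

  # ---- M parameter -----------------------------------------------------
  if (st[["myc_score"]]) {
    if (is.null(targets_expr))
      stop("myc_score stage requires collapse stage")
    mp <- run_stage("myc_score", function()
      m_parameter(targets_expr, config$signature))
    mp$class <- meta$class[match(mp$sample_id, meta$sample_id)]
    results$m_parameter <- mp
    emit(write_tsv_raw, mp, "m_parameter.tsv")
  }

  # ---- MYC correlation screen -----------------------------------------
  if (st[["myc_correlate"]]) {
    if (is.null(norm)) stop("myc_correlate stage requires normalize stage")
    if (!"myc_fraction" %in% names(meta))
      stop("metadata lacks myc_fraction")
    scr <- run_stage("myc_correlate", function() {
      keep <- if (config$include_ln) rep(TRUE, length(classes)) else lymphoma
      fr <- stats::setNames(meta$myc_fraction, meta$sample_id)
      recs <- correlate_with_myc(
        expr_matrix(norm$normalized$values[, keep, drop = FALSE],
                    "probe", "glog2"),
        fr, config$signature)
      list(records = recs,
           volcano = volcano_table(recs, config$volcano_p_cut))
    })
    results$screen <- scr
    emit(write_tsv_raw, scr$records, "myc_correlation.tsv")
    emit(write_tsv_raw, scr$volcano$novel, "myc_novel_candidates.tsv")
  }

  # ---- IHC -------------------------------------------------------------
  if (st[["ihc"]]) {
    ihc <- run_stage("ihc", function() {
      if (st[["simulate"]]) {
        # one slide per class at the class-typical true fraction
        ap <- config$cohort$myc_activity_params
        nuc <- NULL
        for (i in seq_len(nrow(ap))) {
          f <- stats::plogis(6 * (ap$mean[i] - 0.5))
          sm <- simulate_nuclei(
            n_reference = config$ihc_nuclei_per_slide,
            n_sample = config$ihc_nuclei_per_slide,
            true_positive_fraction = f, separation = 1,
            seed = stage_seed(config$seed, paste0("ihc_", ap$class[i])))
          tab <- sm$nuclei
          tab$slide_id[!tab$is_reference] <- ap$class[i]
          nuc <- rbind(nuc, if (i == 1) tab
                       else tab[!tab$is_reference, , drop = FALSE])
        }
        nuc
      } else read_nucleus_tsv(config$paths$nuclei)
    })
    ihc_res <- ihc_quantify(ihc, config$ihc_negative_fraction)
    results$ihc <- ihc_res
    emit(write_tsv_raw, as.data.frame(ihc_res), "ihc_results.tsv")
  }

  # ---- network ---------------------------------------------------------
  if (st[["network"]]) {
    net <- run_stage("network", function() {
      if (st[["simulate"]]) {
        sim_net <- simulate_interactome(
          seed = stage_seed(config$seed, "network"))
        list(graph = sim_net$graph, targets = sim_net$targets,
             go = sim_net$go, de_mirnas = sim_net$de_mirnas)
      } else {
        p <- config$paths
        list(graph = read_interactome(p$interactome),
             targets = read_target_tsv(p$targets),
             go = read_go_tsv(p$go),
             de_mirnas = readLines(p$de_mirnas))
      }
    })
    seeds <- filter_targets(net$targets, net$de_mirnas, net$go)
    sub <- shortest_path_union(net$graph, seeds)
    hubnet <- overlay_mirnas(sub, net$targets,
                             data.frame(target = net$de_mirnas,
                                        stringsAsFactors = FALSE),
                             k = config$hub_k)
    results$network <- hubnet
    emit(write_tsv_raw, hubnet$hubs, "hubs.tsv")
    emit(write_sif, hubnet$graph, "hub_network.sif")
    emit(write_hub_network_graphml, hubnet, "hub_network.graphml")
  }

  # ---- summary + manifest ---------------------------------------------
  summary <- list(
    n_samples = nrow(meta),
    class_counts = as.list(table(meta$class)),
    signature_sizes = if (!is.null(results$de))
      list(multigroup = nrow(results$de$sig_multi),
           twogroup = nrow(results$de$sig_two)) else NULL,
    m_by_class = if (!is.null(results$m_parameter))
      lapply(split(results$m_parameter$m, results$m_parameter$class),
             stats::median) else NULL,
    hubs = if (!is.null(results$network)) results$network$hubs$protein
           else NULL,
    n_connected_mirnas = if (!is.null(results$network))
      results$network$n_connected_mirnas else NULL)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(seed = config$seed,
                   stages = as.list(st),
                   thresholds = list(
                     fdr_multigroup = config$fdr_multigroup,
                     fdr_twogroup = config$fdr_twogroup,
                     fc = config$fc_threshold,
                     volcano_p_cut = config$volcano_p_cut,
                     ihc_negative_fraction = config$ihc_negative_fraction,
                     hub_k = config$hub_k),
                   outputs = c(written, "summary.json"))
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg(verbose, "done: ", length(written) + 2, " files in ",
          config$outdir)
  invisible(list(summary = summary, results = results,
                 manifest = manifest))
}
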