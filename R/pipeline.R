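# End-to-end pipeline: simulate (or load) -> classify -> spectra + FGA ->
# combined clustering with reference-group assignment -> survival.
#
# Every stage is a pure function of its inputs and the config (given the
# seed); outputs are written under the run directory and summarised in a
# single JSON report.

#' Pipeline configuration
#'
#' @param simulate a \code{\link{cohort_config}} to generate inputs, or NULL
#'   to read them from \code{paths}.
#' @param paths named list of input files (\code{samples}, \code{snv},
#'   \code{seg}, \code{survival}) when not simulating.
#' @param out output directory.
#' @param pole_whitelist POLE pathogenicity whitelist.
#' @param linkage clustering linkage.
#' @param k number of clusters to cut (NULL = number of reference groups).
#' @param mode distance mode: combined / mutational / scna.
#' @param horizon survival read-out in months.
#' @param stage_subset stages kept for the survival comparison.
#' @param resume skip stages whose outputs already exist.
#' @param verbose log to console as well as to the run log file.
#' @return config list.
#' @export
pipeline_config <- function(simulate = cohort_config(), paths = NULL,
                            out = tempfile("mcec_run_"),
                            pole_whitelist = default_pole_whitelist(),
                            linkage = "complete", k = NULL,
                            mode = "combined", horizon = 60,
                            stage_subset = c("I", "IA", "IB"),
                            resume = FALSE, verbose = TRUE) {
  if (is.null(simulate) && is.null(paths)) {
    stop_mcec("either a simulate block or input paths must be given")
  }
  if (!is.null(paths)) {
    need <- c("samples", "snv", "seg", "survival")
    miss <- setdiff(need, names(paths))
    if (length(miss)) stop_mcec("paths lacks entries: ", paste(miss, collapse = ", "))
    for (p in unlist(paths[need])) {
      if (!file.exists(p)) stop_mcec("input file not found: ", p)
    }
  }
  list(simulate = simulate, paths = paths, out = out,
       pole_whitelist = pole_whitelist, linkage = linkage, k = k, mode = mode,
       horizon = horizon, stage_subset = stage_subset, resume = resume,
       verbose = verbose)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate or load the cohort; (2) classify every sample and
#' tabulate the cohort; (3) build 96-channel catalogs and per-sample FGA;
#' (4) cluster on the combined distance and assign multiple-classifier
#' queries to single-classifier reference groups, with an association test
#' on the co-assignment table; (5) Kaplan-Meier / log-rank survival
#' comparison of query groups against the single-classifier p53abn group.
#'
#' @param config from \code{\link{pipeline_config}}.
#' @return report list (also written as \code{summary.json} in the run
#'   directory).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (config$verbose) message(msg)
  }
  stage <- function(name, outputs, fun) {
    if (config$resume && all(file.exists(file.path(config$out, outputs)))) {
      logf("stage %s: outputs present, skipped (resume)", name)
      return(NULL)
    }
    logf("stage %s: start", name)
    tryCatch(fun(), error = function(e) {
      stop_mcec(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  tsv <- function(df, name) {
    utils::write.table(df, file.path(config$out, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  ## stage 1: inputs
  if (!is.null(config$simulate)) {
    stage("simulate", "samples.tsv", function() {
      cohort <- generate_cohort(config$simulate)
      write_cohort(cohort, config$out)
      logf("simulated %d samples (seed %d)", nrow(cohort$samples), config$simulate$seed)
    })
    samples <- read_sample_sheet(file.path(config$out, "samples.tsv"))
    snv <- read_snv_table(file.path(config$out, "snv.tsv"))
    seg <- read_seg(file.path(config$out, "segments.seg"))
    surv <- read_survival_table(file.path(config$out, "survival.tsv"))
  } else {
    samples <- read_sample_sheet(config$paths$samples)
    snv <- read_snv_table(config$paths$snv)
    seg <- read_seg(config$paths$seg)
    surv <- read_survival_table(config$paths$survival)
  }

  ## stage 2: classification
  results <- classify_cohort(samples, config$pole_whitelist)
  cls <- classification_table(results)
  summary_tab <- tabulate_cohort(results)
  stage("classify", "classification.tsv", function() {
    tsv(cls, "classification.tsv")
    jsonlite::write_json(summary_tab, file.path(config$out, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    logf("classified %d samples, %d multiple-classifier",
         summary_tab$n, summary_tab$n_multiple_classifier)
  })

  ## stage 3: genomic descriptors
  catalogs <- build_catalog_matrix(snv)
  fga <- fga_by_sample(seg)
  stage("descriptors", c("catalogs.tsv", "fga.tsv"), function() {
    write_catalog_tsv(catalogs, file.path(config$out, "catalogs.tsv"))
    tsv(data.frame(sample_id = names(fga), fga = unname(fga)), "fga.tsv")
  })

  ## stage 4: clustering + co-assignment
  is_multi <- grepl("-", cls$raw_classifier_set, fixed = TRUE)
  single <- cls[!is_multi & cls$resolved_class %in% c("POLEmut", "MMRd", "p53abn"), ]
  reference_labels <- stats::setNames(single$resolved_class, single$sample_id)
  query_ids <- cls$sample_id[is_multi]
  cluster_report <- NULL
  if (length(query_ids) > 0 && length(unique(reference_labels)) >= 2) {
    keep <- c(names(reference_labels), query_ids)
    dm <- build_distance_matrix(catalogs[keep, , drop = FALSE], fga[keep],
                                mode = config$mode)
    assignments <- assign_groups(dm, reference_labels, query_ids,
                                 k = config$k, linkage = config$linkage)
    # driver class of each query = highest-priority member of its raw set
    driver <- vapply(strsplit(cls$raw_classifier_set[is_multi], "-"), function(s) {
      if ("POLEmut" %in% s) "POLEmut" else if ("MMRd" %in% s) "MMRd" else s[1]
    }, character(1))
    names(driver) <- query_ids
    coas <- coassignment_table(assignments, driver)
    assoc <- if (nrow(coas) >= 2 && ncol(coas) >= 2) association_test(coas) else NULL
    agree <- mean(assignments$assigned_group == driver[assignments$sample_id])
    stage("cluster", "assignments.tsv", function() {
      tsv(assignments, "assignments.tsv")
      hc <- hierarchical_cluster(dm, config$linkage)
      write_dendrogram_newick(hc, file.path(config$out, "dendrogram.nwk"))
      utils::write.table(as.data.frame(as.table(dm)),
                         file.path(config$out, "distance_matrix.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      logf("assigned %d queries; driver co-assignment %.1f%%",
           length(query_ids), 100 * agree)
    })
    cluster_report <- list(
      n_reference = length(reference_labels), n_query = length(query_ids),
      coassignment = as.data.frame(as.table(coas)),
      driver_coassignment_rate = agree,
      association = assoc)
  }

  ## stage 5: survival
  surv_report <- NULL
  if (length(unique(surv$group)) >= 2) {
    ref_grp <- if ("p53abn" %in% surv$group) "p53abn" else NULL
    ss <- survival_summary(surv, horizon = config$horizon,
                           subset_stage = config$stage_subset,
                           reference_group = ref_grp)
    fu <- reverse_km_followup(surv)
    stage("survival", "survival_by_group.tsv", function() {
      tsv(ss$by_group, "survival_by_group.tsv")
      logf("survival: %d groups, log-rank p = %.3g",
           nrow(ss$by_group), if (!is.null(ss$logrank)) ss$logrank$p_value else NA)
    })
    surv_report <- list(horizon = config$horizon, by_group = ss$by_group,
                        logrank = ss$logrank, pairwise = ss$pairwise,
                        median_followup = fu$median)
  }

  report <- list(
    n_samples = nrow(samples),
    cohort = summary_tab,
    clustering = cluster_report,
    survival = surv_report,
    parameters = list(linkage = config$linkage, mode = config$mode,
                      k = config$k, horizon = config$horizon))
  jsonlite::write_json(report, file.path(config$out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  logf("pipeline complete; summary.json written")
  invisible(report)
}
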