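#' Pipeline configuration
#'
#' Bundles the screen design with the analysis settings of the full
#' two-stage pipeline: the primary-screen hit count `k_hits`, the curated
#' exclusion list, the viability analysis window, the deltaAA tolerance
#' `tau` and elimination threshold `min_lines`, the activity-area baseline,
#' and the mandatory master seed.
#'
#' @param design a [screen_config()]; its series is used for the
#'   confirmation/3D stage while the primary stage always uses the 5-point
#'   primary series.
#' @param seed integer master seed (mandatory: every stochastic stage
#'   derives from it).
#' @param k_hits number of primary hits to carry forward.
#' @param exclusions curated exclusion list (character vector or
#'   data.frame drug/reason), may be `NULL`.
#' @param window viability analysis window, hours.
#' @param tau deltaAA decreased-inhibition tolerance.
#' @param min_lines spheroid-filter elimination threshold.
#' @param baseline no-effect baseline for activity areas.
#' @param k_leads top compounds (by summed activity area) reported as
#'   leads.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = screen_config(), seed,
                            k_hits = 20L, exclusions = NULL,
                            window = 72, tau = 0.1, min_lines = 3L,
                            baseline = 1, k_leads = 3L) {
  if (missing(seed) || !is_count(seed)) {
    abort_invalid("pipeline_config requires an integer seed")
  }
  stopifnot(inherits(design, "screen_config"))
  if (!is_count(k_hits) || k_hits < 1) abort_invalid("k_hits must be >= 1")
  if (window <= 0) abort_invalid("window must be > 0")
  if (tau < 0) abort_invalid("tau must be >= 0")
  structure(list(design = design, seed = as.integer(seed),
                 k_hits = as.integer(k_hits), exclusions = exclusions,
                 window = window, tau = tau, min_lines = as.integer(min_lines),
                 baseline = baseline, k_leads = as.integer(k_leads)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Structured text configuration for batch runs; keys mirror the arguments
#' of [pipeline_config()] and [screen_config()] (design settings nested
#' under `design:`). A seed is mandatory.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_invalid("no such file: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) abort_invalid("config must set a seed")
  dargs <- y$design
  if (!is.null(dargs$series) && is.character(dargs$series)) {
    dargs$series <- concentration_series(dargs$series)
  }
  design <- do.call(screen_config, if (is.null(dargs)) list() else dargs)
  args <- y[setdiff(names(y), "design")]
  do.call(pipeline_config, c(list(design = design), args))
}

#' Run the full two-stage screening pipeline
#'
#' Executes the complete funnel on synthetic data from one master seed:
#'
#' 1. sample one ground truth for all drugs, lines and conditions;
#' 2. primary screen — monolayer, 5-point primary series, single
#'    replicate; endpoint viable counts at 72 h normalized to same-plate
#'    controls; per-curve AUC; hits = `k_hits` drugs with lowest mean and
#'    most consistent across-line AUC;
#' 3. curation — remove the user-supplied exclusion list;
#' 4. confirmation / 3D screen — 2D and 3D, the design's concentration
#'    series in triplicate; time-resolved dead-fraction viability over the
#'    analysis window; activity areas and 4PL fits; deltaAA per drug x
#'    line; eliminate drugs decreased in >= `min_lines` lines;
#' 5. rank retained drugs by summed 2D activity area; top `k_leads` are
#'    the lead candidates; assemble the funnel report.
#'
#' Every stage derives its RNG stream from the master seed, so a rerun of
#' the same configuration reproduces all outputs exactly. With `outdir`,
#' every stage's table is persisted as CSV and a plain-text log records
#' stage parameters and row counts.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory for stage CSVs and the log.
#' @return list with the truth, stage tables (primary_viability,
#'   primary_metrics, primary_summary, confirm_viability, confirm_metrics,
#'   delta, decisions, ranking) and the `funnel_report` in `$report`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", paste0(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  note("pipeline start: seed ", config$seed, ", ", length(design$drugs),
       " drugs, ", length(design$lines), " lines, noise ", design$noise)
  truth <- sample_truth(design, config$seed)
  validate_truth(truth)

  # -- stage 1: primary screen (2D, 5-point series, singlicate, endpoint)
  primary_design <- design
  primary_design$series <- as.numeric(concentration_series("primary5"))
  primary_design$conditions <- "2D"
  primary_design$replicates <- 1L
  layout_p <- build_layout(primary_design)
  ts_p <- simulate_timeseries(truth, layout_p, times = design$times,
                              noise = design$noise, sigma = design$sigma,
                              seed = config$seed + 1L)
  viab_p <- wells_to_endpoint_viability(ts_p, endpoint_h = config$window)
  curves_p <- build_curves(viab_p)
  metrics_p <- curve_metrics(curves_p, baseline = config$baseline, fit = FALSE)
  summary_p <- summarize_across_lines(metrics_p)
  hits <- select_primary_hits(summary_p, k = min(config$k_hits, nrow(summary_p)))
  note("primary screen: ", nrow(layout_p), " wells, ", length(hits), " hits")

  # -- stage 2: curation
  priority <- apply_curation(hits, config$exclusions)
  note("curation: ", length(hits) - length(priority), " excluded, ",
       length(priority), " priority drugs")

  # -- stage 3: confirmation screen in 2D and 3D
  confirm_design <- design
  confirm_design$drugs <- priority
  confirm_design$conditions <- c("2D", "3D")
  layout_c <- build_layout(confirm_design)
  ts_c <- simulate_timeseries(truth, layout_c, times = design$times,
                              noise = design$noise, sigma = design$sigma,
                              seed = config$seed + 2L)
  viab_c <- wells_to_viability(ts_c, window = config$window)
  curves_c <- build_curves(viab_c)
  metrics_c <- curve_metrics(curves_c, baseline = config$baseline, fit = TRUE)
  note("confirmation screen: ", nrow(layout_c), " wells, ",
       sum(metrics_c$converged), "/", nrow(metrics_c), " curves fit")

  # -- stage 4: deltaAA spheroid filter
  delta <- delta_aa_records(metrics_c, tau = config$tau)
  decisions <- decide_drugs(delta, min_lines = config$min_lines)
  eliminated <- decisions$drug[decisions$eliminated]
  note("spheroid filter (tau ", config$tau, ", min_lines ", config$min_lines,
       "): ", length(eliminated), " eliminated")

  # -- stage 5: ranking and report
  summary_c2d <- summarize_across_lines(metrics_c[metrics_c$condition == "2D", ])
  retained <- setdiff(priority, eliminated)
  ranking <- rank_by_sum_aa(summary_c2d[summary_c2d$drug %in% retained, ])
  leads <- head(ranking$drug, config$k_leads)
  report <- build_funnel_report(screened = design$drugs, hits = hits,
                                priority = priority, eliminated_3d = eliminated,
                                leads = leads)
  note("funnel: ", report$n_screened, " screened -> ", report$n_primary_hits,
       " hits -> ", report$n_priority, " priority -> ", report$n_retained,
       " retained -> ", report$n_leads, " leads")

  out <- list(config = config, truth = truth,
              primary_viability = viab_p, primary_metrics = metrics_p,
              primary_summary = summary_p,
              confirm_viability = viab_c, confirm_metrics = metrics_c,
              delta = delta, decisions = decisions, ranking = ranking,
              report = report, log = log_lines)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_truth_csv(truth, file.path(outdir, "ground_truth.csv"))
    write_viability_csv(viab_p, file.path(outdir, "primary_viability.csv"))
    write_table_csv(metrics_p, file.path(outdir, "primary_metrics.csv"))
    write_table_csv(summary_p, file.path(outdir, "primary_summary.csv"))
    write_viability_csv(viab_c, file.path(outdir, "confirmation_viability.csv"))
    write_table_csv(metrics_c, file.path(outdir, "confirmation_metrics.csv"))
    write_table_csv(delta, file.path(outdir, "delta_aa.csv"))
    write_table_csv(decisions, file.path(outdir, "filter_decisions.csv"))
    write_table_csv(ranking, file.path(outdir, "ranking.csv"))
    writeLines(c(log_lines,
                 paste("funnel:", report$n_screened, "screened;",
                       report$n_primary_hits, "hits;", report$n_priority,
                       "priority;", report$n_eliminated_3d, "eliminated;",
                       report$n_retained, "retained")),
               file.path(outdir, "pipeline.log"))
  }
  out
}
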