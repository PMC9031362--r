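#' Select primary-screen hits by low mean AUC and low AUC spread
#'
#' Orders drugs ascending by mean across-line AUC (strongest inhibition
#' first), breaking ties by the across-line AUC standard deviation (most
#' consistent first) and then drug id. With `k`, the top k drugs are
#' returned; with thresholds, all drugs passing `mean_auc <= auc_max` and
#' `sd_auc <= sd_max`. With `per_line_max`, a drug additionally must keep
#' every per-line AUC at or below that bound.
#'
#' @param summaries per-drug summaries ([summarize_across_lines()]).
#' @param k number of hits to select (top-k mode).
#' @param auc_max,sd_max threshold mode: bounds on mean and sd of AUC.
#' @param per_line_max optional bound on each line's AUC; requires a
#'   `metrics` table.
#' @param metrics per-curve metrics, needed for `per_line_max`.
#' @return character vector of hit drug ids, in selection order.
#' @export
select_primary_hits <- function(summaries, k = NULL, auc_max = NULL, sd_max = NULL,
                                per_line_max = NULL, metrics = NULL) {
  if (nrow(summaries) < 1) abort_invalid("need >= 1 drug summary")
  o <- order(summaries$mean_auc, summaries$sd_auc, summaries$drug)
  ranked <- summaries[o, , drop = FALSE]
  if (!is.null(per_line_max)) {
    if (is.null(metrics)) abort_invalid("per_line_max requires the metrics table")
    worst <- tapply(metrics$auc, metrics$drug, max)
    ranked <- ranked[as.numeric(worst[ranked$drug]) <= per_line_max, , drop = FALSE]
  }
  if (!is.null(k)) {
    if (!is_count(k) || k < 1) abort_invalid("k must be a positive integer")
    return(head(ranked$drug, k))
  }
  if (is.null(auc_max) && is.null(sd_max)) {
    abort_invalid("give k or at least one of auc_max / sd_max")
  }
  keep <- rep(TRUE, nrow(ranked))
  if (!is.null(auc_max)) keep <- keep & ranked$mean_auc <= auc_max
  if (!is.null(sd_max)) keep <- keep & ranked$sd_auc <= sd_max
  ranked$drug[keep]
}

#' Apply a curated exclusion list to the hit list
#'
#' Curation (target redundancy, clinical availability, known futility) is a
#' judgment call supplied as data, not computed: this removes the excluded
#' drugs from the hit list, preserving order. Exclusions that are not hits
#' are reported with a warning and ignored.
#'
#' @param hits character vector of hit drug ids.
#' @param exclusions character vector of drug ids, or a data.frame with
#'   columns `drug` and optionally `reason`; see
#'   `system.file("extdata", "example_exclusions.csv", package = "spheroscreen")`
#'   for the expected file format.
#' @return the priority drug list; exclusion reasons (when given) are
#'   attached as the `reasons` attribute.
#' @export
apply_curation <- function(hits, exclusions = NULL) {
  if (is.null(exclusions) || NROW(exclusions) == 0) return(hits)
  if (is.data.frame(exclusions)) {
    if (!"drug" %in% names(exclusions)) abort_invalid("exclusions need a drug column")
    excl <- exclusions$drug
    reasons <- if ("reason" %in% names(exclusions)) {
      setNames(exclusions$reason, exclusions$drug)
    } else NULL
  } else {
    excl <- as.character(exclusions)
    reasons <- NULL
  }
  unknown <- setdiff(excl, hits)
  if (length(unknown) > 0) {
    warning("ignoring exclusions that are not hits: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    excl <- intersect(excl, hits)
  }
  out <- setdiff(hits, excl)
  if (!is.null(reasons)) attr(out, "reasons") <- reasons[intersect(excl, names(reasons))]
  out
}

#' Assemble the screen funnel report
#'
#' Collects the stage-by-stage drug lists of the screening funnel —
#' screened, primary hits, curated priority set, 3D-eliminated, retained —
#' checks their consistency, and derives all counts from the lists
#' (never supplied independently): `n_priority = n_hits - n_excluded` and
#' `n_retained = n_priority - n_eliminated`.
#'
#' @param screened all screened drug ids.
#' @param hits primary-screen hits (subset of screened).
#' @param priority post-curation priority drugs (subset of hits).
#' @param eliminated_3d drugs removed by the spheroid filter (subset of
#'   priority).
#' @param leads optional final lead candidates (subset of retained).
#' @return object of class `funnel_report` with counts and stage lists.
#' @export
build_funnel_report <- function(screened, hits = character(0),
                                priority = hits, eliminated_3d = character(0),
                                leads = character(0)) {
  chk <- function(sub, sup, what) {
    if (!all(sub %in% sup)) {
      abort_data(what, " not a subset of the previous stage: ",
                 paste(setdiff(sub, sup), collapse = ", "))
    }
    if (anyDuplicated(sub)) abort_data("duplicate drugs in ", what)
  }
  if (anyDuplicated(screened)) abort_data("duplicate drugs in screened list")
  chk(hits, screened, "hits")
  chk(priority, hits, "priority")
  chk(eliminated_3d, priority, "eliminated_3d")
  retained <- setdiff(priority, eliminated_3d)
  chk(leads, retained, "leads")
  excluded <- setdiff(hits, priority)
  structure(list(
    n_screened = length(screened),
    n_primary_hits = length(hits),
    n_excluded_by_curation = length(excluded),
    n_priority = length(priority),
    n_eliminated_3d = length(eliminated_3d),
    n_retained = length(retained),
    n_leads = length(leads),
    screened = screened, hits = hits, excluded = excluded,
    priority = priority, eliminated_3d = eliminated_3d,
    retained = retained, leads = leads
  ), class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Screening funnel:\n")
  cat(sprintf("  screened:            %5d\n", x$n_screened))
  cat(sprintf("  primary hits:        %5d\n", x$n_primary_hits))
  cat(sprintf("  excluded (curation): %5d\n", x$n_excluded_by_curation))
  cat(sprintf("  priority:            %5d\n", x$n_priority))
  cat(sprintf("  eliminated (3D):     %5d\n", x$n_eliminated_3d))
  cat(sprintf("  retained:            %5d\n", x$n_retained))
  if (x$n_leads > 0) {
    cat(sprintf("  leads:               %5d  (%s)\n", x$n_leads,
                paste(x$leads, collapse = ", ")))
  }
  invisible(x)
}
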