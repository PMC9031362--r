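#' Dead-cell fraction over a well time series
#'
#' Per timepoint, the fraction of counted nuclei that are dead:
#' \eqn{f_t = D_t / (L_t + D_t)}. Timepoints where no cells were counted
#' (live + dead = 0) carry no information and are returned as `NA`.
#'
#' @param live,dead non-negative integer count vectors of equal length.
#' @return numeric vector of fractions in [0, 1], `NA` where counts are empty.
#' @export
dead_fraction_series <- function(live, dead) {
  if (length(live) != length(dead)) abort_invalid("live and dead must have equal length")
  if (any(live < 0) || any(dead < 0)) abort_invalid("counts must be non-negative")
  tot <- live + dead
  if (all(tot == 0)) abort("all timepoints have zero cells", class = "spheroscreen_empty_series")
  ifelse(tot > 0, dead / tot, NA_real_)
}

#' Time-resolved viability statistic for one well
#'
#' The viability of a well is one minus the highest dead-cell fraction
#' observed at any timepoint within the analysis window (default the first
#' 72 h after treatment): \eqn{V = 1 - \max\{f_t : 0 \le t \le w\}}.
#' The baseline (t = 0) point is included; timepoints after the window are
#' ignored, as are empty timepoints.
#'
#' @param time_h timepoints in hours, ascending, starting at 0.
#' @param live,dead counts per timepoint.
#' @param window analysis window in hours.
#' @return viability fraction in [0, 1].
#' @export
viability_from_timeseries <- function(time_h, live, dead, window = 72) {
  if (length(time_h) != length(live)) abort_invalid("time and count lengths differ")
  keep <- time_h <= window
  if (!any(keep)) abort_invalid("no timepoint within the analysis window")
  f <- dead_fraction_series(live[keep], dead[keep])
  if (all(is.na(f))) abort("all in-window timepoints have zero cells",
                           class = "spheroscreen_empty_series")
  1 - max(f, na.rm = TRUE)
}

#' Endpoint viability normalized to same-plate controls
#'
#' Viable-count viability used by the primary screen: the well's viable
#' (stain-negative) cell count divided by the mean viable count of the
#' vehicle-control wells on the same plate. Values above 1 indicate growth
#' beyond control and are allowed.
#'
#' @param live_count viable cells in the treated well.
#' @param control_live_counts viable cells in the plate's control wells.
#' @return non-negative viability ratio.
#' @export
endpoint_viability <- function(live_count, control_live_counts) {
  if (length(control_live_counts) == 0 || mean(control_live_counts) <= 0) {
    abort_invalid("control counts must be non-empty with positive mean")
  }
  if (any(live_count < 0)) abort_invalid("live_count must be non-negative")
  live_count / mean(control_live_counts)
}

#' Per-well viability table from simulated or imported time series
#'
#' Applies [viability_from_timeseries()] to every treated well of a
#' long-format time-series table, producing viability points ready for
#' [build_curves()].
#'
#' @param ts long-format data.frame as written by [simulate_timeseries()].
#' @param window analysis window in hours.
#' @return data.frame drug, line, condition, conc_M, replicate, viability.
#' @export
wells_to_viability <- function(ts, window = 72) {
  need <- c("plate", "row", "col", "line", "drug", "condition",
            "conc_M", "replicate", "time_h", "live", "dead")
  if (!all(need %in% names(ts))) abort_invalid("time-series table missing columns")
  ts <- ts[ts$drug != "CONTROL" & ts$time_h <= window, ]
  wkey <- paste(ts$plate, ts$row, ts$col, sep = "\r")
  tot <- ts$live + ts$dead
  f <- ifelse(tot > 0, ts$dead / tot, NA_real_)
  fmax <- tapply(f, wkey, max, na.rm = TRUE)
  first <- !duplicated(wkey)
  out <- data.frame(drug = ts$drug[first], line = ts$line[first],
                    condition = ts$condition[first], conc_M = ts$conc_M[first],
                    replicate = ts$replicate[first],
                    viability = 1 - as.numeric(fmax[wkey[first]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-well endpoint viability table (primary-screen style)
#'
#' Takes the live count of each treated well at the latest timepoint not
#' exceeding `endpoint_h` and normalizes it to the mean control live count
#' on the same plate at that timepoint.
#'
#' @param ts long-format time-series data.frame.
#' @param endpoint_h assay endpoint in hours post-treatment.
#' @return data.frame drug, line, condition, conc_M, replicate, viability.
#' @export
wells_to_endpoint_viability <- function(ts, endpoint_h = 72) {
  in_win <- ts$time_h <= endpoint_h
  if (!any(in_win)) abort_invalid("no timepoint at or before the endpoint")
  t_end <- max(ts$time_h[in_win])
  snap <- ts[ts$time_h == t_end, ]
  ctrl <- snap[snap$drug == "CONTROL", ]
  if (nrow(ctrl) == 0) abort_invalid("no control wells in time series")
  ctrl_mean <- tapply(ctrl$live, ctrl$plate, mean)
  trt <- snap[snap$drug != "CONTROL", ]
  cm <- as.numeric(ctrl_mean[trt$plate])
  if (anyNA(cm) || any(cm <= 0)) abort_invalid("some plates lack usable control wells")
  if (any(trt$live < 0)) abort_invalid("live counts must be non-negative")
  data.frame(drug = trt$drug, line = trt$line, condition = trt$condition,
             conc_M = trt$conc_M, replicate = trt$replicate,
             viability = trt$live / cm,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble dose-response curves from viability points
#'
#' Groups viability points by drug x line x condition, averages replicates
#' at each concentration, and sorts concentrations ascending. Per-replicate
#' values are retained in the `replicates` attribute-free long form via the
#' `n_rep` column count; conflicting duplicates (same key, concentration and
#' replicate index) are rejected.
#'
#' @param points data.frame with columns drug, line, condition, conc_M,
#'   replicate, viability.
#' @return data.frame of class `dose_curves`: drug, line, condition, conc_M
#'   (ascending within curve), viability (replicate mean), n_rep.
#' @export
build_curves <- function(points) {
  need <- c("drug", "line", "condition", "conc_M", "replicate", "viability")
  if (!all(need %in% names(points))) abort_invalid("viability points missing columns")
  if (any(points$viability < 0, na.rm = TRUE)) abort_invalid("viability must be >= 0")
  points <- points[!is.na(points$viability), ]
  full_key <- paste(points$drug, points$line, points$condition,
                    points$conc_M, points$replicate)
  if (anyDuplicated(full_key)) {
    abort_data("duplicate (drug, line, condition, concentration, replicate) rows")
  }
  agg <- aggregate(viability ~ drug + line + condition + conc_M, data = points, FUN = mean)
  n <- aggregate(cbind(n_rep = viability) ~ drug + line + condition + conc_M,
                 data = points, FUN = length)
  out <- merge(agg, n, by = c("drug", "line", "condition", "conc_M"))
  out <- out[order(out$drug, out$line, out$condition, out$conc_M), ]
  rownames(out) <- NULL
  class(out) <- c("dose_curves", "data.frame")
  out
}
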