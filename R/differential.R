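#' deltaAA: monolayer-vs-spheroid activity residual
#'
#' When a drug behaves identically in monolayer (2D) and spheroid (3D)
#' culture its observed activity areas fall on the y = x reference line;
#' deltaAA is the residual from that line, \eqn{\Delta AA = AA_{3D} -
#' AA_{2D}}. Positive values indicate higher activity in spheroids,
#' negative values higher activity in monolayers. A drug x line is flagged
#' `decreased` (decreased inhibition in spheroids) when the residual falls
#' below `-tau`.
#'
#' @param aa_2d,aa_3d observed activity areas (dimensionless, >= 0);
#'   vectorized.
#' @param tau decreased-inhibition tolerance in normalized AA units.
#' @return data.frame aa_2d, aa_3d, delta_aa, decreased.
#' @export
delta_aa <- function(aa_2d, aa_3d, tau = 0.1) {
  if (any(aa_2d < 0) || any(aa_3d < 0)) abort_invalid("activity areas must be >= 0")
  if (tau < 0) abort_invalid("tau must be >= 0")
  d <- aa_3d - aa_2d
  data.frame(aa_2d = aa_2d, aa_3d = aa_3d, delta_aa = d, decreased = d < -tau)
}

#' Per drug x line deltaAA records from a metrics table
#'
#' Pairs the 2D and 3D observed activity areas of every drug x line in a
#' [curve_metrics()] table and computes the deltaAA residual and
#' decreased-inhibition flag.
#'
#' @param metrics per-curve metrics containing both conditions.
#' @param tau decreased-inhibition tolerance.
#' @return data.frame: drug, line, aa_2d, aa_3d, delta_aa, decreased.
#' @export
delta_aa_records <- function(metrics, tau = 0.1) {
  need <- c("drug", "line", "condition", "aa_obs")
  if (!all(need %in% names(metrics))) abort_invalid("metrics table missing columns")
  m2 <- metrics[metrics$condition == "2D", ]
  m3 <- metrics[metrics$condition == "3D", ]
  if (nrow(m2) == 0 || nrow(m3) == 0) abort_invalid("need both 2D and 3D metrics")
  if (anyDuplicated(paste(m2$drug, m2$line)) || anyDuplicated(paste(m3$drug, m3$line))) {
    abort_data("duplicate drug x line rows within a condition")
  }
  j <- match(paste(m2$drug, m2$line), paste(m3$drug, m3$line))
  if (anyNA(j)) abort_data("2D rows without matching 3D rows")
  rec <- delta_aa(m2$aa_obs, m3$aa_obs[j], tau = tau)
  out <- cbind(data.frame(drug = m2$drug, line = m2$line, stringsAsFactors = FALSE), rec)
  out <- out[order(out$drug, out$line), ]
  rownames(out) <- NULL
  out
}

#' Eliminate drugs with decreased spheroid inhibition in most lines
#'
#' A drug is eliminated when it shows decreased inhibition (deltaAA below
#' `-tau`) in at least `min_lines` of the tested spheroid lines — by
#' default 3 of the 4 — and retained otherwise.
#'
#' @param records deltaAA records for one or more drugs
#'   ([delta_aa_records()]).
#' @param min_lines elimination threshold on the number of decreased lines.
#' @return data.frame: drug, n_lines_decreased, n_lines_total, eliminated,
#'   retained.
#' @export
decide_drugs <- function(records, min_lines = 3) {
  need <- c("drug", "line", "decreased")
  if (!all(need %in% names(records))) abort_invalid("records missing columns")
  if (nrow(records) == 0) abort_invalid("need >= 1 record")
  if (anyDuplicated(paste(records$drug, records$line))) {
    abort_data("duplicate line records for a drug")
  }
  if (!is_count(min_lines) || min_lines < 1) abort_invalid("min_lines must be >= 1")
  rows <- split(seq_len(nrow(records)), records$drug)
  out <- do.call(rbind, lapply(rows, function(i) {
    ndec <- sum(records$decreased[i])
    data.frame(drug = records$drug[i[1]],
               n_lines_decreased = ndec, n_lines_total = length(i),
               eliminated = ndec >= min_lines, retained = ndec < min_lines,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$drug), ]
  rownames(out) <- NULL
  out
}

#' Rank drugs by total observed activity area
#'
#' Orders drugs by the sum of observed activity areas across cell lines,
#' descending (most active first); ties break lexicographically by drug id
#' for determinism. Used to pick the top compounds of a screen.
#'
#' @param summaries per-drug summaries with a `sum_aa` column
#'   ([summarize_across_lines()]).
#' @param k optionally return only the top k drugs.
#' @return the summaries, reordered, with a `rank` column.
#' @export
rank_by_sum_aa <- function(summaries, k = NULL) {
  if (!all(c("drug", "sum_aa") %in% names(summaries))) {
    abort_invalid("summaries need drug and sum_aa columns")
  }
  o <- order(-summaries$sum_aa, summaries$drug)
  out <- summaries[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(k)) {
    if (!is_count(k) || k < 1) abort_invalid("k must be a positive integer")
    out <- head(out, k)
  }
  rownames(out) <- NULL
  out
}
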