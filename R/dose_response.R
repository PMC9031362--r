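#' Fit a four-parameter log-logistic dose-response model
#'
#' Bounded least-squares fit of
#' \eqn{E(c) = E_{inf} + (E_0 - E_{inf})/(1 + (c/EC_{50})^h)} to observed
#' viability versus concentration, optimized in log10-concentration space
#' with Levenberg-Marquardt ([minpack.lm::nls.lm]). Initial values follow
#' standard practice: `e0` from the maximum response, `einf` from the
#' minimum, the EC50 from the concentration nearest the half-range
#' crossing, Hill slope 1.
#'
#' Curves whose response range is below `flat_tol` are reported unfit
#' (`converged = FALSE`) rather than forced through the optimizer — these
#' are the "no curve could be generated" cells of a screening heatmap — as
#' are optimizer failures and fits whose bottom exceeds their top.
#'
#' @param conc concentrations in mol/L (>= 4 distinct values).
#' @param response observed viability at each concentration.
#' @param flat_tol minimum response range for a fit to be attempted.
#' @param lower,upper bounds on (e0, einf, log10 ec50, hill); defaults allow
#'   e0/einf in [0, 1.2], hill in [0.1, 10], and ec50 within 100x of the
#'   tested range. The top asymptote is kept near 1 because responses are
#'   normalized viability: values above ~1 reflect noise or growth beyond
#'   control, not pharmacology, and an unconstrained top trades off against
#'   the midpoint on shallow curves.
#' @param maxiter,ftol optimizer control.
#' @return object of class `fit4pl`: list(e0, einf, ec50, hill, converged,
#'   rss, n).
#' @export
fit_4pl <- function(conc, response, flat_tol = 0.1,
                    lower = NULL, upper = NULL,
                    maxiter = 200, ftol = 1e-12) {
  if (length(conc) != length(response)) abort_invalid("conc and response lengths differ")
  keep <- is.finite(conc) & is.finite(response) & conc > 0
  conc <- conc[keep]; response <- response[keep]
  if (length(unique(conc)) < 4) abort_invalid("4PL fit needs >= 4 concentrations")

  unfit <- structure(list(e0 = NA_real_, einf = NA_real_, ec50 = NA_real_,
                          hill = NA_real_, converged = FALSE,
                          rss = NA_real_, n = length(response)),
                     class = "fit4pl")
  if (diff(range(response)) < flat_tol) return(unfit)

  x <- log10(conc)
  if (is.null(lower)) lower <- c(0, 0, min(x) - 2, 0.1)
  if (is.null(upper)) upper <- c(1.2, 1.2, max(x) + 2, 10)

  e0_0 <- min(max(response), upper[1])
  einf_0 <- max(min(response), lower[2])
  half <- (e0_0 + einf_0) / 2
  m0 <- x[which.min(abs(response - half))]
  start <- c(e0_0, einf_0, clamp(m0, lower[3], upper[3]), 1)

  resid_fn <- function(p) {
    response - (p[2] + (p[1] - p[2]) / (1 + 10^(p[4] * (x - p[3]))))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ftol = ftol, ptol = ftol)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(unfit)
  p <- fit$par
  if (p[2] > p[1]) return(unfit)       # rising "inhibition" curve: not reportable
  structure(list(e0 = p[1], einf = p[2], ec50 = 10^p[3], hill = p[4],
                 converged = TRUE, rss = sum(fit$fvec^2), n = length(response)),
            class = "fit4pl")
}

#' @export
print.fit4pl <- function(x, ...) {
  if (!x$converged) {
    cat("4PL fit: not converged (flat or unfittable curve),", x$n, "points\n")
  } else {
    cat(sprintf("4PL fit: E0 = %.3f, Einf = %.3f, EC50 = %.3g M, Hill = %.2f (rss %.3g, n %d)\n",
                x$e0, x$einf, x$ec50, x$hill, x$rss, x$n))
  }
  invisible(x)
}

#' Predict viability from a converged 4PL fit
#'
#' @param fit a converged [fit_4pl()] result.
#' @param conc concentration(s), mol/L, > 0.
#' @return predicted viability.
#' @export
predict_4pl <- function(fit, conc) {
  stopifnot(inherits(fit, "fit4pl"))
  if (!isTRUE(fit$converged)) abort_state("cannot predict from an unconverged 4PL fit")
  if (any(conc <= 0)) abort_invalid("concentration must be > 0")
  four_pl(conc, fit$e0, fit$einf, fit$ec50, fit$hill)
}

#' Absolute IC50 of a converged 4PL fit
#'
#' The concentration at which predicted viability crosses 0.5 (50% of
#' control), solved in closed form:
#' \eqn{IC_{50} = EC_{50}\,[(E_0 - 0.5)/(0.5 - E_{inf})]^{1/h}}.
#' Unlike the relative EC50 (the curve midpoint), the absolute IC50 exists
#' only when 0.5 lies strictly between the asymptotes; otherwise `NA`.
#'
#' @param fit a converged [fit_4pl()] result.
#' @return concentration in mol/L, or `NA_real_` when viability never
#'   crosses 0.5.
#' @export
ic50_absolute <- function(fit) {
  stopifnot(inherits(fit, "fit4pl"))
  if (!isTRUE(fit$converged)) abort_state("cannot compute IC50 from an unconverged fit")
  if (!(fit$einf < 0.5 && fit$e0 > 0.5)) return(NA_real_)
  fit$ec50 * ((fit$e0 - 0.5) / (0.5 - fit$einf))^(1 / fit$hill)
}

# shared trapezoid over log10 concentration, normalized by the log10 span
trapz_log10 <- function(conc, y) {
  o <- order(conc)
  x <- log10(conc[o]); y <- y[o]
  span <- x[length(x)] - x[1]
  if (span <= 0) abort_invalid("concentrations must span a positive log range")
  sum(diff(x) * (head(y, -1) + y[-1]) / 2) / span
}

#' Observed activity area of a dose-response curve
#'
#' The fit-independent efficacy metric: the trapezoidal area, in
#' log10-concentration space, of the response deficit below a no-effect
#' baseline, normalized by the tested log-concentration span:
#' \deqn{AA_{obs} = \frac{1}{x_n - x_1}\int \max(0,\, b - y(x))\, dx,
#'   \quad x = \log_{10} c.}
#' 0 means no observed activity; 1 means complete loss of viability at
#' every tested concentration (baseline 1). Because it integrates the data
#' directly it needs no curve fit and is comparable across series lengths.
#'
#' @param conc concentrations in mol/L (>= 2 distinct values, any order).
#' @param response observed viability per concentration.
#' @param baseline no-effect reference level.
#' @return dimensionless area >= 0.
#' @export
aa_observed <- function(conc, response, baseline = 1) {
  if (length(conc) != length(response)) abort_invalid("conc and response lengths differ")
  if (length(conc) < 2) abort_invalid("activity area needs >= 2 points")
  if (any(conc <= 0)) abort_invalid("concentrations must be > 0")
  trapz_log10(conc, pmax(0, baseline - response))
}

#' Normalized area under a dose-response curve
#'
#' Trapezoidal area under the observed viability, over log10 concentration,
#' normalized by the tested span: a flat full-viability curve scores 1 and
#' a complete kill at all concentrations scores 0. Lower AUC means stronger
#' inhibition — the inverse orientation of [aa_observed()]; when all
#' responses lie in [0, 1] the two sum to 1 on the same grid.
#'
#' @inheritParams aa_observed
#' @return dimensionless area >= 0.
#' @export
auc_observed <- function(conc, response) {
  if (length(conc) != length(response)) abort_invalid("conc and response lengths differ")
  if (length(conc) < 2) abort_invalid("AUC needs >= 2 points")
  if (any(conc <= 0)) abort_invalid("concentrations must be > 0")
  if (any(response < 0)) abort_invalid("responses must be >= 0")
  trapz_log10(conc, response)
}

#' Per-curve activity metrics and 4PL fits
#'
#' Computes, for every drug x line x condition curve, the normalized AUC,
#' the observed activity area, and (optionally) the 4PL fit parameters with
#' the absolute IC50.
#'
#' @param curves a [build_curves()] result.
#' @param baseline no-effect baseline for the activity area.
#' @param fit also fit the 4PL model (needs >= 4 concentrations per curve).
#' @param ... passed to [fit_4pl()].
#' @return data.frame: drug, line, condition, n_conc, auc, aa_obs and, when
#'   `fit = TRUE`, e0, einf, ec50_M, hill, ic50_abs_M, converged.
#' @export
curve_metrics <- function(curves, baseline = 1, fit = TRUE, ...) {
  if (!all(c("drug", "line", "condition", "conc_M", "viability") %in% names(curves))) {
    abort_invalid("curves table missing columns")
  }
  key <- paste(curves$drug, curves$line, curves$condition, sep = "\r")
  rows <- split(seq_len(nrow(curves)), key)
  recs <- lapply(rows, function(i) {
    cc <- curves$conc_M[i]; y <- curves$viability[i]
    rec <- data.frame(drug = curves$drug[i[1]], line = curves$line[i[1]],
                      condition = curves$condition[i[1]], n_conc = length(i),
                      auc = auc_observed(cc, y),
                      aa_obs = aa_observed(cc, y, baseline = baseline),
                      stringsAsFactors = FALSE)
    if (fit) {
      f <- if (length(unique(cc)) >= 4) fit_4pl(cc, y, ...) else
        structure(list(e0 = NA_real_, einf = NA_real_, ec50 = NA_real_,
                       hill = NA_real_, converged = FALSE, rss = NA_real_,
                       n = length(i)), class = "fit4pl")
      rec$e0 <- f$e0; rec$einf <- f$einf; rec$ec50_M <- f$ec50
      rec$hill <- f$hill
      rec$ic50_abs_M <- if (f$converged) ic50_absolute(f) else NA_real_
      rec$converged <- f$converged
    }
    rec
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$drug, out$line, out$condition), ]
  rownames(out) <- NULL
  out
}

#' Across-line summary of a drug's activity
#'
#' For each drug (within one condition), the mean and sample standard
#' deviation of its per-line AUC — the primary screen's hit-selection
#' statistics — and the sum of per-line observed activity areas, the
#' potency-ranking statistic. A single-line summary reports sd 0 with an
#' `insufficient_replication` flag rather than failing.
#'
#' @param metrics per-curve metrics (one condition; see [curve_metrics()]).
#' @return data.frame: drug, n_lines, mean_auc, sd_auc, sum_aa,
#'   insufficient_replication.
#' @export
summarize_across_lines <- function(metrics) {
  if (nrow(metrics) == 0) abort_invalid("no metrics to summarize")
  if (length(unique(metrics$condition)) > 1) {
    abort_invalid("summarize one condition at a time")
  }
  if (anyDuplicated(paste(metrics$drug, metrics$line))) {
    abort_data("duplicate drug x line rows")
  }
  rows <- split(seq_len(nrow(metrics)), metrics$drug)
  out <- do.call(rbind, lapply(rows, function(i) {
    data.frame(drug = metrics$drug[i[1]], n_lines = length(i),
               mean_auc = mean(metrics$auc[i]),
               sd_auc = if (length(i) > 1) sd(metrics$auc[i]) else 0,
               sum_aa = sum(metrics$aa_obs[i]),
               insufficient_replication = length(i) < 2,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$drug), ]
  rownames(out) <- NULL
  out
}
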