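#' Screen design configuration
#'
#' Collects the design of a synthetic screen: cell lines with their seeding
#' densities and growth rates, drug identifiers, the concentration series,
#' replication, culture conditions, and the ground-truth sampling settings
#' (penetrance-limited drug count and effect sizes, inert-drug fraction,
#' parameter ranges) together with the kinetic and noise settings used when
#' counts are simulated.
#'
#' Defaults emulate a four-line anaplastic thyroid carcinoma screen:
#' lines THJ-11T/16T/29T seeded at 600 cells/well and THJ-21T at 900,
#' exponential growth at 0.03/h (~23 h doubling), maximal drug-induced death
#' rate 0.05/h, imaging every 6 h for 5 days, and Poisson count noise.
#'
#' @param lines character vector of cell-line ids.
#' @param drugs character vector of drug ids.
#' @param series descending molar concentration series
#'   (see [concentration_series()]).
#' @param replicates technical replicates per drug x concentration.
#' @param conditions culture conditions, subset of `c("2D", "3D")`.
#' @param seed_density named integer vector, cells/well per line.
#' @param growth_rate per-hour exponential growth rate; scalar, or named by
#'   line, or a data.frame with columns line, condition, growth_rate.
#' @param d_max maximal drug-induced death rate (per hour) at full effect.
#' @param n_penetrance number of penetrance-limited drugs to plant.
#' @param min_lines minimum number of lines carrying the 3D potency shift in
#'   each planted drug.
#' @param p_range range of the 3D EC50 shift factor (log-uniform draw).
#' @param einf_lift additive lift of the 3D bottom asymptote for planted
#'   drugs (0 disables).
#' @param inert_fraction fraction of drugs with no effect at any tested
#'   concentration.
#' @param einf_range,hill_range uniform / log-uniform draw ranges for the
#'   bottom asymptote and Hill slope of active drugs.
#' @param times imaging timepoints, hours post-treatment (must start at 0).
#' @param noise count noise model: `"poisson"`, `"gaussian"` (multiplicative,
#'   sd `sigma`), or `"none"`.
#' @param sigma multiplicative noise sd for the gaussian model.
#' @param controls_per_plate vehicle-control wells placed on every plate.
#' @return a list of class `screen_config`.
#' @export
screen_config <- function(lines = c("THJ-11T", "THJ-16T", "THJ-21T", "THJ-29T"),
                          drugs = sprintf("drug%03d", seq_len(40)),
                          series = concentration_series("confirmation10"),
                          replicates = 3L,
                          conditions = c("2D", "3D"),
                          seed_density = NULL,
                          growth_rate = 0.03,
                          d_max = 0.05,
                          n_penetrance = 7L,
                          min_lines = 3L,
                          p_range = c(3, 30),
                          einf_lift = 0,
                          inert_fraction = 0.5,
                          einf_range = c(0, 0.6),
                          hill_range = c(0.5, 3),
                          times = seq(0, 120, by = 6),
                          noise = c("poisson", "gaussian", "none"),
                          sigma = 0.05,
                          controls_per_plate = 12L) {
  if (length(lines) < 1) abort_invalid("config needs >= 1 cell line")
  if (length(drugs) < 1) abort_invalid("config needs >= 1 drug")
  if (anyDuplicated(lines)) abort_invalid("duplicate line ids")
  if (anyDuplicated(drugs)) abort_invalid("duplicate drug ids")
  validate_series(series)
  conditions <- match.arg(conditions, c("2D", "3D"), several.ok = TRUE)
  if (!is_count(replicates) || replicates < 1) abort_invalid("replicates must be >= 1")
  if (is.null(seed_density)) {
    seed_density <- setNames(ifelse(lines == "THJ-21T", 900L, 600L), lines)
  }
  if (is.null(names(seed_density))) {
    seed_density <- setNames(rep_len(seed_density, length(lines)), lines)
  }
  if (!all(lines %in% names(seed_density))) abort_invalid("seed_density must cover every line")
  if (any(seed_density[lines] <= 0)) abort_invalid("seed densities must be positive")
  growth <- normalize_growth(growth_rate, lines, conditions)
  if (d_max < 0) abort_invalid("d_max must be >= 0")
  if (!is_count(n_penetrance) || n_penetrance < 0 || n_penetrance > length(drugs)) {
    abort_invalid("n_penetrance must be an integer in [0, number of drugs]")
  }
  if (!is_count(min_lines) || min_lines < 1 || min_lines > length(lines)) {
    abort_invalid("min_lines must be in [1, number of lines]")
  }
  if (length(p_range) != 2 || any(p_range <= 1) || p_range[1] > p_range[2]) {
    abort_invalid("p_range must be an increasing pair with values > 1")
  }
  if (inert_fraction < 0 || inert_fraction > 1) {
    abort_invalid("inert_fraction must be in [0, 1]")
  }
  if (times[1] != 0 || length(times) < 2 || any(diff(times) <= 0)) {
    abort_invalid("times must start at 0 and be strictly increasing, length >= 2")
  }
  noise <- match.arg(noise)
  if (sigma < 0) abort_invalid("sigma must be >= 0")
  if (!is_count(controls_per_plate) || controls_per_plate < 1) {
    abort_invalid("controls_per_plate must be >= 1")
  }
  structure(list(
    lines = lines, drugs = drugs, series = as.numeric(series),
    replicates = as.integer(replicates), conditions = conditions,
    seed_density = seed_density, growth = growth, d_max = d_max,
    n_penetrance = as.integer(n_penetrance), min_lines = as.integer(min_lines),
    p_range = p_range, einf_lift = einf_lift, inert_fraction = inert_fraction,
    einf_range = einf_range, hill_range = hill_range,
    times = times, noise = noise, sigma = sigma,
    controls_per_plate = as.integer(controls_per_plate)
  ), class = "screen_config")
}

# expand growth specification to a (line, condition) table
normalize_growth <- function(growth_rate, lines, conditions) {
  if (is.data.frame(growth_rate)) {
    need <- c("line", "condition", "growth_rate")
    if (!all(need %in% names(growth_rate))) {
      abort_invalid("growth_rate data.frame needs columns line, condition, growth_rate")
    }
    g <- growth_rate[growth_rate$line %in% lines & growth_rate$condition %in% conditions, need]
  } else {
    per_line <- if (!is.null(names(growth_rate))) {
      if (!all(lines %in% names(growth_rate))) abort_invalid("named growth_rate must cover every line")
      growth_rate[lines]
    } else {
      rep_len(growth_rate, length(lines))
    }
    g <- expand.grid(line = lines, condition = conditions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$growth_rate <- per_line[match(g$line, lines)]
  }
  if (any(g$growth_rate <= 0)) abort_invalid("growth rates must be > 0")
  if (nrow(unique(g[c("line", "condition")])) !=
      length(lines) * length(conditions)) {
    abort_invalid("growth_rate must cover every line x condition")
  }
  rownames(g) <- NULL
  g
}

#' @export
print.screen_config <- function(x, ...) {
  cat("Screen design:\n")
  cat("  lines:      ", paste(x$lines, collapse = ", "), "\n")
  cat("  drugs:      ", length(x$drugs), "\n")
  cat("  series:     ", length(x$series), "concentrations,",
      format(max(x$series), digits = 3), "to",
      format(min(x$series), digits = 3), "mol/L\n")
  cat("  conditions: ", paste(x$conditions, collapse = ", "),
      " x", x$replicates, "replicate(s)\n")
  cat("  planted penetrance-limited drugs:", x$n_penetrance,
      sprintf("(shift in >= %d lines)\n", x$min_lines))
  cat("  noise:      ", x$noise,
      if (x$noise == "gaussian") sprintf("(sigma = %g)", x$sigma), "\n")
  invisible(x)
}
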