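#' Four-parameter log-logistic response surface
#'
#' \deqn{E(c) = E_{inf} + (E_0 - E_{inf}) / (1 + (c/EC_{50})^h)}
#' the standard sigmoidal dose-response model: `e0` is the response as
#' c -> 0, `einf` the response at saturating drug, `ec50` the midpoint and
#' `hill` the slope. Vectorized over `conc`.
#'
#' @param conc concentration(s), mol/L; `conc = 0` returns `e0`.
#' @param e0,einf,ec50,hill model parameters.
#' @return response value(s) on the viability scale.
#' @export
four_pl <- function(conc, e0, einf, ec50, hill) {
  einf + (e0 - einf) / (1 + (conc / ec50)^hill)
}

#' Simulate time-resolved live/dead counts for a plate layout
#'
#' Generates per-well time series under a two-compartment birth-death model:
#' live cells grow exponentially at the line's rate g and die at a
#' concentration-dependent rate \eqn{d(c) = d_{max} (1 - E(c))}, where E(c)
#' is the drug's ground-truth 4PL viability surface; dead cells accumulate
#' the dying cells without removal:
#' \deqn{dL/dt = (g - d)L, \quad dD/dt = dL.}
#' The deterministic expectation has the closed form
#' \eqn{L(t) = n_0 e^{(g-d)t}}, \eqn{D(t) = n_0 d (e^{(g-d)t}-1)/(g-d)}
#' (or \eqn{n_0 d t} when g = d). Control wells (c = 0) have d = 0 and show
#' pure growth. Integer counts are drawn around the expectation from the
#' configured noise model; each well uses an RNG substream derived by
#' hashing its (plate, row, column) key with the master seed, so draws do
#' not depend on layout order and identical seeds reproduce the screen
#' byte-for-byte.
#'
#' @param truth a [sample_truth()] result.
#' @param layout a [build_layout()] result (or compatible data.frame).
#' @param times imaging timepoints in hours, starting at 0.
#' @param noise `"poisson"` (counts ~ Poisson(expectation)), `"gaussian"`
#'   (expectation x (1 + N(0, sigma)), rounded, floored at 0) or `"none"`
#'   (rounded expectation).
#' @param sigma sd of the gaussian multiplicative noise.
#' @param seed integer master seed for the noise draws.
#' @return data.frame in long format: plate, row, col, line, drug,
#'   condition, conc_M, replicate, time_h, live, dead.
#' @export
simulate_timeseries <- function(truth, layout,
                                times = seq(0, 120, by = 6),
                                noise = c("poisson", "gaussian", "none"),
                                sigma = 0.05, seed = 1L) {
  stopifnot(inherits(truth, "screen_truth"))
  noise <- match.arg(noise)
  if (times[1] != 0 || any(diff(times) <= 0)) {
    abort_invalid("times must start at 0 and increase strictly")
  }
  validate_layout(layout)

  treated <- layout$drug != "CONTROL"
  pkey <- paste(layout$drug, layout$line, layout$condition)
  tkey <- paste(truth$params$drug, truth$params$line, truth$params$condition)
  it <- match(pkey, tkey)
  if (any(treated & is.na(it))) {
    abort("no ground truth for: ",
          paste(unique(pkey[treated & is.na(it)]), collapse = "; "),
          class = "spheroscreen_key_error")
  }
  lkey <- paste(layout$line, layout$condition)
  gkey <- paste(truth$lines$line, truth$lines$condition)
  il <- match(lkey, gkey)
  if (anyNA(il)) abort("no line profile for: ",
                       paste(unique(lkey[is.na(il)]), collapse = "; "),
                       class = "spheroscreen_key_error")
  g <- truth$lines$growth_rate[il]
  n0 <- truth$lines$seed_density[il]

  eff <- rep(1, nrow(layout))          # viability surface E(c); controls: 1
  eff[treated] <- four_pl(layout$conc_M[treated],
                          truth$params$e0[it[treated]],
                          truth$params$einf[it[treated]],
                          truth$params$ec50_M[it[treated]],
                          truth$params$hill[it[treated]])
  d <- truth$d_max * (1 - eff)

  nt <- length(times)
  r <- g - d
  # closed-form expectations, wells x times
  ert <- exp(outer(r, times))
  L <- n0 * ert
  D <- matrix(0, nrow(layout), nt)
  nz <- abs(r) > 1e-12
  if (any(nz)) D[nz, ] <- (n0[nz] * d[nz] / r[nz]) * (ert[nz, , drop = FALSE] - 1)
  if (any(!nz)) D[!nz, ] <- outer(n0[!nz] * d[!nz], times)

  if (noise != "none") {
    seeds <- substream_seed(seed, paste(layout$plate, layout$row, layout$col))
    for (w in seq_len(nrow(layout))) {
      set.seed(seeds[w])
      if (noise == "poisson") {
        L[w, ] <- rpois(nt, L[w, ])
        D[w, ] <- rpois(nt, D[w, ])
      } else {
        L[w, ] <- pmax(0, round(L[w, ] * (1 + rnorm(nt, 0, sigma))))
        D[w, ] <- pmax(0, round(D[w, ] * (1 + rnorm(nt, 0, sigma))))
      }
    }
  } else {
    L <- round(L); D <- round(D)
  }

  out <- layout[rep(seq_len(nrow(layout)), each = nt),
                c("plate", "row", "col", "line", "drug", "condition",
                  "conc_M", "replicate"), drop = FALSE]
  out$time_h <- rep(times, nrow(layout))
  out$live <- as.integer(t(L))
  out$dead <- as.integer(t(D))
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Deterministic expectation of the kinetic count model
#'
#' Closed-form expected live/dead counts for one well of the birth-death
#' model used by [simulate_timeseries()]; exposed for inspection and
#' model checking.
#'
#' @param n0 seeded cell count.
#' @param g growth rate per hour.
#' @param d death rate per hour.
#' @param times timepoints in hours.
#' @return data.frame time_h, live, dead (continuous expectations).
#' @export
expected_counts <- function(n0, g, d, times) {
  r <- g - d
  ert <- exp(r * times)
  dead <- if (abs(r) > 1e-12) n0 * d * (ert - 1) / r else n0 * d * times
  data.frame(time_h = times, live = n0 * ert, dead = dead)
}
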