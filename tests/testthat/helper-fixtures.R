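# shared fixtures: a small screen design, independent oracles

tiny_config <- function(...) {
  args <- list(lines = c("L1", "L2"),
               drugs = c("dA", "dB", "dC"),
               series = concentration_series("primary5"),
               replicates = 2L,
               n_penetrance = 1L, min_lines = 2L,
               inert_fraction = 0, noise = "none",
               times = seq(0, 72, by = 12))
  over <- list(...)
  do.call(screen_config, c(over, args[setdiff(names(args), names(over))]))
}

# independent trapezoid oracle over log10 concentration (pracma, not the
# package's own integrator)
oracle_area <- function(conc, y) {
  o <- order(conc)
  x <- log10(conc[o])
  pracma::trapz(x, y[o]) / (max(x) - min(x))
}

# full-screen helper: simulate a confirmation-style 2D/3D screen and run the
# deltaAA elimination, returning decisions plus the planted truth
run_filter_screen <- function(seed, n_drugs = 40, n_penetrance = 7L,
                              p_range = c(10, 30), tau = 0.1, min_lines = 3L,
                              noise = "gaussian", sigma = 0.05) {
  cfg <- screen_config(drugs = sprintf("drug%03d", seq_len(n_drugs)),
                       n_penetrance = n_penetrance, p_range = p_range,
                       noise = noise, sigma = sigma)
  truth <- sample_truth(cfg, seed)
  layout <- build_layout(cfg)
  ts <- simulate_timeseries(truth, layout, times = cfg$times,
                            noise = noise, sigma = sigma, seed = seed + 1000L)
  viab <- wells_to_viability(ts, window = 72)
  metrics <- curve_metrics(build_curves(viab), fit = FALSE)
  decisions <- decide_drugs(delta_aa_records(metrics, tau = tau),
                            min_lines = min_lines)
  list(truth = truth, decisions = decisions,
       planted = truth$drugs$drug[truth$drugs$penetrance_limited],
       eliminated = decisions$drug[decisions$eliminated])
}
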