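test_that("4PL midpoint, asymptotes, and closed-form predictions hold", {
  conc <- concentration_series("confirmation10")
  y <- four_pl(conc, 1, 0.2, 1e-7, 1.3)
  f <- fit_4pl(conc, y)
  expect_true(f$converged)
  expect_equal(predict_4pl(f, f$ec50), (f$e0 + f$einf) / 2)
  expect_equal(predict_4pl(f, 1e-15), f$e0, tolerance = 1e-6)
  expect_equal(predict_4pl(f, 1e3), f$einf, tolerance = 1e-6)
  expect_equal(four_pl(1e-7, 1, 0, 1e-7, 1), 0.5)
})

test_that("noiseless 4PL curves recover their generating parameters", {
  conc <- concentration_series("confirmation10")
  y <- four_pl(conc, 1, 0.2, 1e-7, 1)
  f <- fit_4pl(conc, y)
  expect_true(f$converged)
  expect_equal(f$e0, 1, tolerance = 1e-4)
  expect_equal(f$einf, 0.2, tolerance = 1e-4)
  expect_equal(f$ec50, 1e-7, tolerance = 1e-4)
  expect_equal(f$hill, 1, tolerance = 1e-4)
})

test_that("flat or degenerate curves are reported unfit", {
  conc <- concentration_series("confirmation10")
  flat <- fit_4pl(conc, rep(1, 10))
  expect_false(flat$converged)
  expect_error(predict_4pl(flat, 1e-7), class = "spheroscreen_invalid_state")
  expect_error(ic50_absolute(flat), class = "spheroscreen_invalid_state")
  expect_error(fit_4pl(conc[1:3], c(1, 0.5, 0)), ">= 4")
})

test_that("absolute IC50 solves E(c) = 0.5 in closed form", {
  mk <- function(e0, einf, ec50, hill) {
    structure(list(e0 = e0, einf = einf, ec50 = ec50, hill = hill,
                   converged = TRUE, rss = 0, n = 10), class = "fit4pl")
  }
  expect_equal(ic50_absolute(mk(1, 0, 1e-7, 1)), 1e-7)
  expect_equal(ic50_absolute(mk(1, 0, 1e-7, 2)), 1e-7)
  expect_true(is.na(ic50_absolute(mk(1, 0.6, 1e-7, 1))))
  # numeric cross-check: predicted viability at the IC50 is 0.5
  f <- mk(0.95, 0.1, 3e-8, 1.7)
  expect_equal(predict_4pl(f, ic50_absolute(f)), 0.5)
})

test_that("activity areas match the independent trapezoid oracle", {
  p5 <- concentration_series("primary5")
  y <- c(0.2, 0.3, 0.5, 0.8, 0.9)          # responses at descending conc
  expect_equal(aa_observed(p5, y), oracle_area(p5, pmax(0, 1 - y)))
  expect_equal(auc_observed(p5, y), oracle_area(p5, y))

  expect_equal(aa_observed(p5, rep(1, 5)), 0)
  expect_equal(aa_observed(p5, rep(0, 5)), 1)
  expect_equal(auc_observed(p5, rep(1, 5)), 1)
  expect_equal(auc_observed(p5, rep(0, 5)), 0)
  expect_error(aa_observed(p5[1], 1), ">= 2")

  set.seed(12)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    conc <- sort(10^runif(n, -9, -4))
    y <- runif(n, 0, 1.3)
    expect_equal(aa_observed(conc, y), oracle_area(conc, pmax(0, 1 - y)),
                 tolerance = 1e-12)
    expect_equal(auc_observed(conc, y), oracle_area(conc, y), tolerance = 1e-12)
  }
})

test_that("aa and auc are complementary and monotone in the responses", {
  set.seed(13)
  p5 <- concentration_series("primary5")
  for (i in 1:50) {
    y <- runif(5)
    expect_equal(aa_observed(p5, y) + auc_observed(p5, y), 1, tolerance = 1e-12)
    # lowering one response never decreases aa nor increases auc
    j <- sample(5, 1)
    y2 <- y; y2[j] <- y2[j] * runif(1)
    expect_gte(aa_observed(p5, y2), aa_observed(p5, y))
    expect_lte(auc_observed(p5, y2), auc_observed(p5, y))
  }
})

test_that("across-line summaries give mean/sd AUC and summed activity area", {
  m <- data.frame(drug = rep(c("a", "b"), each = 4),
                  line = rep(sprintf("L%d", 1:4), 2), condition = "2D",
                  auc = c(0.5, 0.5, 0.5, 0.5, 0.2, 0.4, 0.6, 0.8),
                  aa_obs = c(0.2, 0.3, 0.1, 0.4, 0.5, 0.5, 0.5, 0.5))
  s <- summarize_across_lines(m)
  expect_equal(s$mean_auc[s$drug == "a"], 0.5)
  expect_equal(s$sd_auc[s$drug == "a"], 0)
  expect_equal(s$sum_aa[s$drug == "a"], 1.0)
  expect_equal(s$sd_auc[s$drug == "b"], sd(c(0.2, 0.4, 0.6, 0.8)))
  expect_false(any(s$insufficient_replication))

  one <- summarize_across_lines(m[1, ])
  expect_equal(one$sd_auc, 0)
  expect_true(one$insufficient_replication)
  expect_error(summarize_across_lines(m[0, ]), "summarize")
})

test_that("curve metrics table carries areas and fits per curve", {
  cfg <- tiny_config(series = concentration_series("confirmation10"))
  tr <- sample_truth(cfg, 21L)
  ts <- simulate_timeseries(tr, build_layout(cfg), times = cfg$times,
                            noise = "none", seed = 1L)
  m <- curve_metrics(build_curves(wells_to_viability(ts)), fit = TRUE)
  expect_equal(nrow(m), 3 * 2 * 2)           # drugs x lines x conditions
  expect_true(all(m$aa_obs >= 0 & m$auc >= 0))
  expect_equal(m$aa_obs + m$auc, rep(1, nrow(m)), tolerance = 1e-12)
  expect_true(any(m$converged))
})
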