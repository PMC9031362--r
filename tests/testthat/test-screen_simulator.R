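test_that("named concentration series match their printed designs", {
  p5 <- concentration_series("primary5")
  expect_equal(as.numeric(p5), c(5.14e-6, 1.09e-6, 1.56e-7, 3.08e-8, 6.2e-9))

  c10 <- concentration_series("confirmation10")
  expect_length(c10, 10)
  expect_equal(c10[1], 2e-5)
  expect_equal(c10[10], 2e-8)
  # log-spaced across three decades: constant adjacent ratio 1000^(1/9)
  ratios <- c10[-10] / c10[-1]
  expect_equal(ratios, rep(1000^(1 / 9), 9), tolerance = 1e-12)
  # cross-check against direct log-space computation
  expect_equal(as.numeric(c10), 10^seq(log10(2e-5), log10(2e-8), length.out = 10))
})

test_that("custom series are log-spaced and validated", {
  s <- concentration_series("custom", top = 1e-5, bottom = 1e-8, n = 4)
  expect_equal(as.numeric(s), 10^seq(-5, -8, length.out = 4))
  expect_error(concentration_series("custom", top = 1e-8, bottom = 1e-5, n = 4),
               "top must exceed")
  expect_error(concentration_series("custom", top = 1e-5, bottom = -1, n = 4),
               "positive")
  expect_error(concentration_series("custom", top = 1e-5, bottom = 1e-8, n = 1),
               ">= 2")
})

test_that("layouts are valid, deterministic, and carry same-plate controls", {
  cfg <- screen_config(lines = "L1", drugs = "d1",
                       series = concentration_series("primary5"),
                       replicates = 1L, conditions = c("2D", "3D"),
                       n_penetrance = 0L, min_lines = 1L,
                       controls_per_plate = 2L)
  lay <- build_layout(cfg)
  expect_identical(lay, build_layout(cfg))
  expect_equal(sum(lay$drug != "CONTROL"), 10)       # 5 conc x 1 rep x 2 cond
  expect_gte(sum(lay$drug == "CONTROL"), 2)
  expect_false(anyDuplicated(paste(lay$plate, lay$row, lay$col)) > 0)
  expect_true(all(lay$conc_M[lay$drug == "CONTROL"] == 0))
  # every treated well's plate also hosts control wells
  ctrl_plates <- unique(lay$plate[lay$drug == "CONTROL"])
  expect_true(all(lay$plate %in% ctrl_plates))

  expect_error(screen_config(drugs = character(0)), ">= 1 drug")
  big <- screen_config(drugs = sprintf("d%d", 1:50),
                       series = concentration_series("confirmation10"),
                       replicates = 3L, n_penetrance = 0L)
  expect_error(build_layout(big, allow_multiple_plates = FALSE),
               class = "spheroscreen_capacity_error")
  expect_silent(validate_layout(build_layout(big)))
})

test_that("sampled truth honours penetrance structure and seeding contract", {
  cfg <- screen_config(n_penetrance = 7L, min_lines = 3L, p_range = c(3, 30))
  tr <- sample_truth(cfg, 11L)
  expect_identical(tr$params, sample_truth(cfg, 11L)$params)
  expect_false(identical(tr$params$ec50_M, sample_truth(cfg, 12L)$params$ec50_M))
  expect_silent(validate_truth(tr))
  expect_equal(sum(tr$drugs$penetrance_limited), 7)
  # flagged drugs carry a 3D EC50 shift > 1 in at least min_lines lines
  p2 <- tr$params[tr$params$condition == "2D", ]
  p3 <- tr$params[tr$params$condition == "3D", ]
  j <- match(paste(p2$drug, p2$line), paste(p3$drug, p3$line))
  shift <- p3$ec50_M[j] / p2$ec50_M
  for (d in tr$drugs$drug[tr$drugs$penetrance_limited]) {
    expect_gte(sum(shift[p2$drug == d] > 1), 3)
  }
  # unflagged drugs are identical across conditions
  unflagged <- tr$drugs$drug[!tr$drugs$penetrance_limited]
  expect_true(all(shift[p2$drug %in% unflagged] == 1))

  tr0 <- sample_truth(screen_config(n_penetrance = 0L), 5L)
  expect_equal(sum(tr0$drugs$penetrance_limited), 0)
  expect_equal(tr0$params[tr0$params$condition == "2D", c("e0", "einf", "ec50_M", "hill")],
               tr0$params[tr0$params$condition == "3D", c("e0", "einf", "ec50_M", "hill")],
               ignore_attr = TRUE)
  expect_error(screen_config(n_penetrance = 99L), "n_penetrance")
})

test_that("noiseless kinetics follow the closed-form birth-death model", {
  cfg <- tiny_config()
  tr <- sample_truth(cfg, 3L)
  lay <- build_layout(cfg)
  ts <- simulate_timeseries(tr, lay, times = cfg$times, noise = "none", seed = 1L)

  # control wells: pure exponential growth, no deaths
  ctrl <- ts[ts$drug == "CONTROL", ]
  expect_true(all(ctrl$dead == 0))
  g <- tr$lines$growth_rate[match(paste(ctrl$line, ctrl$condition),
                                  paste(tr$lines$line, tr$lines$condition))]
  n0 <- tr$lines$seed_density[match(paste(ctrl$line, ctrl$condition),
                                    paste(tr$lines$line, tr$lines$condition))]
  expect_equal(ctrl$live, as.integer(round(n0 * exp(g * ctrl$time_h))))

  # conservation: d/dt (L + D) = g L >= 0 -> total never decreases
  key <- paste(ts$plate, ts$row, ts$col)
  for (w in split(seq_len(nrow(ts)), key)) {
    tot <- ts$live[w] + ts$dead[w]
    expect_true(all(diff(tot[order(ts$time_h[w])]) >= 0))
  }

  # saturating concentration with Einf = 0: dead fraction approaches 1
  tr$params$einf <- 0
  hot <- lay[lay$drug != "CONTROL", ][1, , drop = FALSE]
  hot$conc_M <- 1e6 * max(tr$params$ec50_M)
  hot_ts <- simulate_timeseries(tr, hot, times = seq(0, 240, 24),
                                noise = "none", seed = 1L)
  f_end <- with(hot_ts[hot_ts$time_h == 240, ], dead / (live + dead))
  expect_gt(f_end, 0.95)
})

test_that("higher concentration never increases the noiseless final live count", {
  cfg <- tiny_config()
  tr <- sample_truth(cfg, 8L)
  lay <- build_layout(cfg)
  ts <- simulate_timeseries(tr, lay, times = cfg$times, noise = "none", seed = 1L)
  fin <- ts[ts$time_h == max(ts$time_h) & ts$drug != "CONTROL" & ts$replicate == 1, ]
  for (grp in split(fin, paste(fin$drug, fin$line, fin$condition))) {
    expect_true(all(diff(grp$live[order(grp$conc_M)]) <= 0))
  }
})

test_that("simulated counts are deterministic per seed and unbiased around the expectation", {
  cfg <- tiny_config(noise = "poisson")
  tr <- sample_truth(cfg, 4L)
  lay <- build_layout(cfg)
  a <- simulate_timeseries(tr, lay, times = cfg$times, noise = "poisson", seed = 9L)
  expect_identical(a, simulate_timeseries(tr, lay, times = cfg$times,
                                          noise = "poisson", seed = 9L))
  b <- simulate_timeseries(tr, lay, times = cfg$times, noise = "poisson", seed = 10L)
  expect_false(identical(a$live, b$live))

  # substreams keyed by well identity: draws survive layout reordering
  shuf <- lay[rev(seq_len(nrow(lay))), ]
  a2 <- simulate_timeseries(tr, shuf, times = cfg$times, noise = "poisson", seed = 9L)
  a2 <- a2[order(match(paste(a2$plate, a2$row, a2$col, a2$time_h),
                       paste(a$plate, a$row, a$col, a$time_h))), ]
  expect_equal(a2$live, a$live)
  expect_equal(a2$dead, a$dead)

  # Monte-Carlo: mean count across seeds within 3 SE of the closed form
  one_ctrl <- lay[lay$drug == "CONTROL", ][1, , drop = FALSE]
  gi <- match(paste(one_ctrl$line, one_ctrl$condition),
              paste(tr$lines$line, tr$lines$condition))
  expec <- expected_counts(tr$lines$seed_density[gi], tr$lines$growth_rate[gi],
                           0, cfg$times)
  draws <- sapply(1:100, function(s) {
    simulate_timeseries(tr, one_ctrl, times = cfg$times,
                        noise = "poisson", seed = s)$live
  })
  se <- sqrt(expec$live / 100)               # Poisson variance = mean
  expect_true(all(abs(rowMeans(draws) - expec$live) <= 3 * se + 1e-9))

  # unknown drug x line x condition -> key error
  bad <- lay[lay$drug != "CONTROL", ][1, , drop = FALSE]
  bad$drug <- "nonexistent"
  expect_error(simulate_timeseries(tr, bad, times = cfg$times, seed = 1L),
               class = "spheroscreen_key_error")
})
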