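test_that("rendering matches its construction rules", {
  none <- render_well(random_nuclei(0, 64, 64, seed = 1), 64, 64)
  expect_true(all(none$red == 0) && all(none$green == 0))

  one <- data.frame(x = 32, y = 20, radius = 6, label = "live")
  img <- render_well(one, 64, 64, amplitude = 500)
  expect_equal(which(img$red == max(img$red), arr.ind = TRUE)[1, ],
               c(row = 21, col = 33))           # (x=32, y=20), 0-based
  expect_true(all(img$green == 0))

  dead <- data.frame(x = 32, y = 32, radius = 6, label = "dead")
  img2 <- render_well(dead, 64, 64, amplitude = 500, green_amplitude = 400)
  expect_gt(max(img2$green), 300)
  expect_error(render_well(data.frame(x = 999, y = 1, radius = 5, label = "live"),
                           64, 64), "bounds")
})

test_that("max projection equals the per-pixel maximum oracle", {
  set.seed(2)
  stack <- lapply(1:4, function(i) {
    structure(list(red = matrix(runif(64), 8), green = matrix(runif(64), 8)),
              pixel_size = 1, class = "well_image")
  })
  proj <- max_project(stack)
  # direct-loop oracle
  for (ch in c("red", "green")) {
    oracle <- matrix(0, 8, 8)
    for (r in 1:8) for (c in 1:8) {
      oracle[r, c] <- max(vapply(stack, function(s) s[[ch]][r, c], numeric(1)))
    }
    expect_equal(proj[[ch]], oracle)
  }
  # identity on a single slice, idempotence on the projection
  expect_equal(max_project(stack[1]), stack[[1]], ignore_attr = TRUE)
  expect_equal(max_project(list(proj)), proj)
  # disjoint nuclei from two slices both survive projection
  a <- render_well(data.frame(x = 10, y = 10, radius = 4, label = "live"), 48, 48)
  b <- render_well(data.frame(x = 35, y = 35, radius = 4, label = "live"), 48, 48)
  expect_equal(count_well(list(a, b))$n_total, 2)

  expect_error(max_project(list()), "non-empty")
  bad <- list(a, structure(list(red = matrix(0, 2, 2), green = matrix(0, 2, 2)),
                           class = "well_image"))
  expect_error(max_project(bad), "shape")
})

test_that("segmentation finds well-separated nuclei and ignores blank images", {
  blank <- matrix(0, 128, 128)
  expect_equal(segment_nuclei(blank)$n, 0)

  tr <- random_nuclei(50, 512, 512, radius = 6, dead_fraction = 0, seed = 4)
  img <- render_well(tr, 512, 512, amplitude = 1000, noise_sd = 50, seed = 9)
  seg <- segment_nuclei(img)
  expect_gte(seg$n, 49); expect_lte(seg$n, 51)
  expect_true(all(seg$regions$area >= 20))
  # centroids land near the planted centers
  d2 <- outer(seg$regions$x, tr$x, `-`)^2 + outer(seg$regions$y, tr$y, `-`)^2
  expect_lt(max(sqrt(apply(d2, 2, min))), 2)

  # two nuclei closer than one radius merge into at most 2 regions
  close <- data.frame(x = c(60, 64), y = c(60, 60), radius = c(6, 6),
                      label = c("live", "live"))
  seg2 <- segment_nuclei(render_well(close, 128, 128))
  expect_lte(seg2$n, 2)
})

test_that("live/dead calls follow the green-overlap rule exactly", {
  tr <- random_nuclei(50, 512, 512, radius = 6, dead_fraction = 0.4, seed = 10)
  img <- render_well(tr, 512, 512)
  cr <- count_well(img)
  expect_equal(cr$n_total, 50)
  expect_equal(cr$n_dead, sum(tr$label == "dead"))
  expect_equal(cr$n_live + cr$n_dead, cr$n_total)

  # all-zero green channel: everything lives
  seg <- segment_nuclei(img)
  allz <- classify_live_dead(seg, matrix(0, 512, 512))
  expect_equal(allz$n_dead, 0)
  expect_equal(allz$n_live, allz$n_total)

  # threshold 0: any green signal marks a nucleus dead
  t0 <- classify_live_dead(seg, img$green, threshold = 0)
  expect_equal(t0$n_dead, sum(tr$label == "dead"))

  expect_error(classify_live_dead(seg, matrix(0, 2, 2)), "geometry")
})

test_that("two-channel TIFF round-trips through disk", {
  tr <- random_nuclei(8, 96, 96, radius = 5, dead_fraction = 0.5, seed = 6)
  img <- render_well(tr, 96, 96, amplitude = 900)
  path <- tempfile(fileext = ".tif")
  write_well_tiff(img, path)
  back <- read_well_tiff(path)
  expect_equal(back$red, round(img$red), tolerance = 1e-3)
  cr <- count_well(back)
  expect_equal(cr$n_total, 8)
  expect_equal(cr$n_dead, sum(tr$label == "dead"))
})
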