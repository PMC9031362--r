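#' Synthetic nucleus ground truth for a well image
#'
#' Places `n` nuclei uniformly at random in a `width` x `height` image,
#' enforcing a minimum center-to-center distance by dart-throwing, and
#' labels a fraction of them dead. Used to build counting fixtures with
#' known answers.
#'
#' @param n number of nuclei.
#' @param width,height image size in pixels.
#' @param radius nucleus radius in pixels (scalar or length n).
#' @param dead_fraction fraction of nuclei labelled dead.
#' @param min_dist minimum center distance (default 4 x radius, which keeps
#'   nuclei well separated for exact-recovery fixtures).
#' @param margin keep-out border in pixels.
#' @param seed integer seed.
#' @return data.frame of class `nuclei_truth`: x, y (0-based pixel
#'   coordinates, x = column), radius, label ("live"/"dead").
#' @export
random_nuclei <- function(n, width = 512, height = 512, radius = 6,
                          dead_fraction = 0.3, min_dist = 4 * max(radius),
                          margin = 3 * max(radius), seed = 1L) {
  if (!is_count(n) || n < 0) abort_invalid("n must be a non-negative integer")
  with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    while (length(xs) < n) {
      x <- runif(1, margin, width - 1 - margin)
      y <- runif(1, margin, height - 1 - margin)
      if (length(xs) == 0 || all((xs - x)^2 + (ys - y)^2 >= min_dist^2)) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
      tries <- tries + 1L
      if (tries > 200L * n + 1000L) {
        abort_invalid("could not place ", n, " nuclei at min_dist ", min_dist)
      }
    }
    lab <- rep("live", n)
    if (n > 0 && dead_fraction > 0) {
      lab[sample(n, round(dead_fraction * n))] <- "dead"
    }
    structure(data.frame(x = xs, y = ys, radius = rep_len(radius, n),
                         label = lab, stringsAsFactors = FALSE),
              class = c("nuclei_truth", "data.frame"))
  })
}

#' Render a two-channel well image from nucleus ground truth
#'
#' Draws each nucleus as an isotropic 2D Gaussian blob (sd = radius/2) of
#' peak `amplitude` in the red (nuclear marker) channel; dead nuclei are
#' additionally drawn in the green (dead-cell stain) channel at
#' `green_amplitude`. Optional additive Gaussian background noise
#' (sd `noise_sd`, floored at 0) is applied to both channels.
#'
#' @param truth a [random_nuclei()]-style data.frame (x, y, radius, label).
#' @param width,height image size in pixels.
#' @param amplitude red-channel peak intensity per nucleus.
#' @param green_amplitude green-channel peak intensity for dead nuclei.
#' @param noise_sd additive background noise sd (0 = noiseless).
#' @param pixel_size physical pixel size, um/pixel (metadata only).
#' @param seed integer seed for the noise.
#' @return object of class `well_image`: list(red, green) intensity
#'   matrices (rows = y, columns = x) with attribute `pixel_size`.
#' @export
render_well <- function(truth, width = 512, height = 512,
                        amplitude = 1000, green_amplitude = 800,
                        noise_sd = 0, pixel_size = 1, seed = 1L) {
  if (nrow(truth) > 0 &&
      (any(truth$x < 0 | truth$x > width - 1 | truth$y < 0 | truth$y > height - 1))) {
    abort_invalid("nucleus center outside image bounds")
  }
  red <- matrix(0, nrow = height, ncol = width)
  green <- matrix(0, nrow = height, ncol = width)
  for (i in seq_len(nrow(truth))) {
    s <- truth$radius[i] / 2
    r0 <- ceiling(4 * s)
    xr <- max(0, floor(truth$x[i] - r0)):min(width - 1, ceiling(truth$x[i] + r0))
    yr <- max(0, floor(truth$y[i] - r0)):min(height - 1, ceiling(truth$y[i] + r0))
    blob <- amplitude *
      exp(-(outer((yr - truth$y[i])^2, (xr - truth$x[i])^2, "+")) / (2 * s^2))
    red[yr + 1, xr + 1] <- red[yr + 1, xr + 1] + blob
    if (truth$label[i] == "dead") {
      green[yr + 1, xr + 1] <- green[yr + 1, xr + 1] +
        blob * (green_amplitude / amplitude)
    }
  }
  if (noise_sd > 0) {
    with_seed(seed, {
      red <- red + matrix(rnorm(length(red), 0, noise_sd), nrow(red))
      green <- green + matrix(rnorm(length(green), 0, noise_sd), nrow(green))
    })
    red[red < 0] <- 0
    green[green < 0] <- 0
  }
  structure(list(red = red, green = green),
            pixel_size = pixel_size, class = "well_image")
}

#' Maximum-intensity projection of a z-stack
#'
#' Collapses a z-stack of two-channel slices to a single image by taking
#' the per-pixel, per-channel maximum across slices — the standard
#' reduction applied to spheroid stacks before nuclei are counted.
#'
#' @param stack non-empty list of `well_image` slices of identical shape.
#' @return a single `well_image`.
#' @export
max_project <- function(stack) {
  if (!is.list(stack) || length(stack) == 0 || inherits(stack, "well_image")) {
    abort_invalid("stack must be a non-empty list of well_image slices")
  }
  dims <- lapply(stack, function(s) dim(s$red))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    abort_invalid("slices must share one shape")
  }
  structure(list(red = Reduce(pmax, lapply(stack, `[[`, "red")),
                 green = Reduce(pmax, lapply(stack, `[[`, "green"))),
            pixel_size = attr(stack[[1]], "pixel_size"), class = "well_image")
}

#' Segment nuclei in the red (nuclear marker) channel
#'
#' Gaussian smoothing, global Otsu threshold, connected-component
#' labelling, and an optional marker-based split of touching nuclei via a
#' watershed on the distance transform; components below `min_area` are
#' discarded. A blank (signal-free) image yields zero regions.
#'
#' @param image a `well_image`, or a red-channel intensity matrix.
#' @param smooth_sigma Gaussian smoothing sd in pixels.
#' @param min_area minimum region area in pixels squared.
#' @param split split touching nuclei with a distance-transform watershed.
#' @return object of class `nuclei_segmentation`: list(labels
#'   (integer matrix, 0 = background), n, regions (data.frame label, area,
#'   x, y centroids in 0-based pixels)).
#' @export
segment_nuclei <- function(image, smooth_sigma = 2, min_area = 20, split = FALSE) {
  red <- if (inherits(image, "well_image")) image$red else image
  if (!is.matrix(red) || any(!is.finite(red)) || any(red < 0)) {
    abort_invalid("red channel must be a finite non-negative matrix")
  }
  empty <- function() {
    structure(list(labels = matrix(0L, nrow(red), ncol(red)), n = 0L,
                   regions = data.frame(label = integer(0), area = numeric(0),
                                        x = numeric(0), y = numeric(0))),
              class = "nuclei_segmentation")
  }
  rng <- range(red)
  if (diff(rng) <= 0) return(empty())   # flat image: nothing to segment

  # EBImage works on [0,1] images in (x, y) order; transpose in and out
  img <- EBImage::Image(t((red - rng[1]) / diff(rng)))
  sm <- EBImage::gblur(img, sigma = smooth_sigma)
  thr <- EBImage::otsu(sm, range = c(0, 1))
  mask <- sm > thr
  if (sum(mask) == 0) return(empty())
  labs <- if (split) {
    EBImage::watershed(EBImage::distmap(mask), tolerance = 1)
  } else {
    EBImage::bwlabel(mask)
  }
  lm <- t(EBImage::imageData(labs))     # back to (row = y, col = x)
  storage.mode(lm) <- "integer"

  areas <- tabulate(lm[lm > 0])
  keep <- which(areas >= min_area)
  if (length(keep) == 0) return(empty())
  relabel <- integer(length(areas)); relabel[keep] <- seq_along(keep)
  lm[lm > 0] <- relabel[lm[lm > 0]]

  idx <- which(lm > 0, arr.ind = TRUE)
  lab <- lm[lm > 0]
  regions <- data.frame(label = seq_along(keep), area = as.numeric(areas[keep]),
                        x = as.numeric(tapply(idx[, 2] - 1, lab, mean)),
                        y = as.numeric(tapply(idx[, 1] - 1, lab, mean)))
  structure(list(labels = lm, n = length(keep), regions = regions),
            class = "nuclei_segmentation")
}

#' Classify segmented nuclei as live or dead from the green channel
#'
#' A nucleus is called dead when the mean intensity of the dead-cell stain
#' (green) channel within its segmented footprint exceeds `threshold` —
#' i.e. its red-channel nucleus has overlapping green signal; otherwise it
#' is live. The default threshold is estimated from the image itself as
#' background mean + 3 x background sd, with background taken outside all
#' nuclei.
#'
#' @param seg a [segment_nuclei()] result.
#' @param green green-channel intensity matrix of the same geometry.
#' @param threshold mean-green cutoff; `NULL` for the background-derived
#'   default.
#' @return object of class `count_result`: list(n_total, n_live, n_dead,
#'   nuclei (data.frame label, x, y, area, mean_green, label_class)).
#' @export
classify_live_dead <- function(seg, green, threshold = NULL) {
  stopifnot(inherits(seg, "nuclei_segmentation"))
  if (!is.matrix(green) || !all(dim(green) == dim(seg$labels))) {
    abort_invalid("green channel geometry does not match the segmentation")
  }
  if (seg$n == 0) {
    return(structure(list(n_total = 0L, n_live = 0L, n_dead = 0L,
                          nuclei = data.frame(label = integer(0), x = numeric(0),
                                              y = numeric(0), area = numeric(0),
                                              mean_green = numeric(0),
                                              label_class = character(0))),
                     class = "count_result"))
  }
  inside <- seg$labels > 0
  if (is.null(threshold)) {
    bg <- green[!inside]
    threshold <- if (length(bg) > 1) mean(bg) + 3 * sd(bg) else 0
  }
  mg <- as.numeric(tapply(green[inside], seg$labels[inside], mean))
  dead <- mg > threshold
  nuclei <- cbind(seg$regions,
                  data.frame(mean_green = mg,
                             label_class = ifelse(dead, "dead", "live")))
  structure(list(n_total = seg$n, n_live = sum(!dead), n_dead = sum(dead),
                 nuclei = nuclei, threshold = threshold),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("Counted %d nuclei: %d live, %d dead (green threshold %.3g)\n",
              x$n_total, x$n_live, x$n_dead, x$threshold))
  invisible(x)
}

#' Count viable cells in a well image
#'
#' Full counting pipeline for one well: optional maximum projection of a
#' z-stack, nucleus segmentation on the red channel, and the live/dead
#' call — viable cells are nuclei without overlapping green (dead-cell
#' stain) signal.
#'
#' @param image a `well_image`, or a list of them (z-stack, projected
#'   first).
#' @param ... passed to [segment_nuclei()].
#' @param threshold green-channel cutoff for [classify_live_dead()].
#' @return a `count_result`.
#' @export
count_well <- function(image, ..., threshold = NULL) {
  if (!inherits(image, "well_image")) image <- max_project(image)
  seg <- segment_nuclei(image, ...)
  classify_live_dead(seg, image$green, threshold = threshold)
}

#' Write / read a two-channel well image as TIFF
#'
#' Stores the red and green channels as two 16-bit pages of one TIFF file,
#' the native convention of microscope exports: intensities are written as
#' counts on the 0..65535 scale (values above are clipped) and restored on
#' read. Intensities are therefore quantized to integer gray levels.
#'
#' @param image a `well_image`.
#' @param path TIFF file path.
#' @return `write_well_tiff` the path, invisibly; `read_well_tiff` a
#'   `well_image`.
#' @export
write_well_tiff <- function(image, path) {
  stopifnot(inherits(image, "well_image"))
  enc <- function(ch) pmin(round(ch), 65535) / 65535
  tiff::writeTIFF(list(enc(image$red), enc(image$green)), path,
                  bits.per.sample = 16, reduce = FALSE)
  invisible(path)
}

#' @rdname write_well_tiff
#' @export
read_well_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) abort_invalid("expected a two-page (red, green) TIFF")
  structure(list(red = pages[[1]] * 65535, green = pages[[2]] * 65535),
            pixel_size = 1, class = "well_image")
}
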