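#' Sample ground-truth drug-response parameters for a synthetic screen
#'
#' Draws, for every drug x line x condition, the four-parameter log-logistic
#' response surface (top `e0`, bottom `einf`, midpoint `ec50_M`, slope
#' `hill`) that generates the simulated counts, plus the per-drug
#' spheroid-penetrance labels that downstream filter tests try to recover.
#'
#' Active drugs draw `einf` uniformly in `einf_range`, `hill` log-uniformly
#' in `hill_range`, and EC50 log-uniformly within the tested concentration
#' range; per-line heterogeneity is added as a x10^N(0, 0.15) EC50 factor
#' and a small `einf` perturbation. A configured fraction of drugs is inert
#' (flat response at full viability), mirroring the long tail of a primary
#' screen in which most compounds do nothing. `n_penetrance` drugs are
#' flagged penetrance-limited: in a random subset of at least `min_lines`
#' lines their 3D EC50 is right-shifted by a factor p drawn log-uniformly
#' from `p_range` (optionally with an `einf` lift), leaving 2D untouched.
#' Flagged drugs draw their 2D EC50 at least a decade below the top tested
#' concentration so the planted potency loss is observable in-range.
#'
#' @param config a [screen_config()].
#' @param seed integer master seed; identical seeds give identical truths.
#' @return object of class `screen_truth`: list with `params` (data.frame
#'   drug, line, condition, e0, einf, ec50_M, hill), `drugs` (data.frame
#'   drug, penetrance_limited, inert, n_lines_shifted), `lines` (growth and
#'   seeding per line x condition), `d_max`, and the seed.
#' @export
sample_truth <- function(config, seed) {
  stopifnot(inherits(config, "screen_config"))
  if (!is_count(seed)) abort_invalid("seed must be a single integer")
  n_drug <- length(config$drugs)
  n_line <- length(config$lines)
  cmin <- min(config$series); cmax <- max(config$series)

  with_seed(seed, {
    flagged <- if (config$n_penetrance > 0) {
      sort(sample(config$drugs, config$n_penetrance))
    } else character(0)
    pool <- setdiff(config$drugs, flagged)
    n_inert <- min(length(pool), round(config$inert_fraction * n_drug))
    inert <- if (n_inert > 0) sort(sample(pool, n_inert)) else character(0)

    per_drug <- data.frame(drug = config$drugs, stringsAsFactors = FALSE)
    per_drug$penetrance_limited <- per_drug$drug %in% flagged
    per_drug$inert <- per_drug$drug %in% inert
    per_drug$einf <- runif(n_drug, config$einf_range[1], config$einf_range[2])
    per_drug$hill <- rlogunif(n_drug, config$hill_range[1], config$hill_range[2])
    # planted drugs keep their midpoint >= 1 decade below the top tested
    # concentration so the 3D shift has observable 2D activity to remove
    per_drug$ec50 <- ifelse(per_drug$penetrance_limited,
                            rlogunif(n_drug, cmin, cmax / 10),
                            rlogunif(n_drug, cmin, cmax))

    base <- expand.grid(line = config$lines, drug = config$drugs,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    base <- base[, c("drug", "line")]
    i <- match(base$drug, per_drug$drug)
    base$e0 <- 1
    base$einf <- clamp(per_drug$einf[i] + rnorm(nrow(base), 0, 0.05), 0, 0.95)
    base$ec50_M <- per_drug$ec50[i] * 10^rnorm(nrow(base), 0, 0.15)
    base$hill <- per_drug$hill[i]
    inert_row <- per_drug$inert[i]
    base$einf[inert_row] <- 1          # flat: E(c) = 1 everywhere
    base$ec50_M[inert_row] <- sqrt(cmin * cmax)
    base$hill[inert_row] <- 1

    # 3D penetrance shift: choose affected lines per flagged drug
    n_lines_shifted <- setNames(integer(n_drug), config$drugs)
    shift <- setNames(rep(1, nrow(base)), paste(base$drug, base$line))
    lift <- setNames(rep(0, nrow(base)), paste(base$drug, base$line))
    for (d in flagged) {
      k <- if (config$min_lines >= n_line) n_line else
        sample(seq(config$min_lines, n_line), 1)
      affected <- sample(config$lines, k)
      n_lines_shifted[d] <- k
      key <- paste(d, affected)
      shift[key] <- rlogunif(k, config$p_range[1], config$p_range[2])
      lift[key] <- config$einf_lift
    }

    make_cond <- function(cond) {
      out <- base
      out$condition <- cond
      if (cond == "3D") {
        key <- paste(out$drug, out$line)
        out$ec50_M <- out$ec50_M * shift[key]
        out$einf <- pmin(out$e0, out$einf + lift[key])
      }
      out[, c("drug", "line", "condition", "e0", "einf", "ec50_M", "hill")]
    }
    params <- do.call(rbind, lapply(config$conditions, make_cond))
    rownames(params) <- NULL
    per_drug$n_lines_shifted <- n_lines_shifted[per_drug$drug]

    lines <- merge(config$growth,
                   data.frame(line = config$lines,
                              seed_density = as.numeric(config$seed_density[config$lines])),
                   by = "line")

    structure(list(params = params,
                   drugs = per_drug[, c("drug", "penetrance_limited", "inert",
                                        "n_lines_shifted")],
                   lines = lines, d_max = config$d_max, seed = as.integer(seed)),
              class = "screen_truth")
  })
}

validate_truth <- function(truth) {
  p <- truth$params
  if (any(p$einf < 0 | p$einf > p$e0)) abort_data("truth violates 0 <= Einf <= E0")
  if (any(p$ec50_M <= 0) || any(p$hill <= 0)) abort_data("truth needs ec50 > 0, hill > 0")
  invisible(truth)
}

#' @export
print.screen_truth <- function(x, ...) {
  cat("Ground truth for", length(unique(x$params$drug)), "drugs x",
      length(unique(x$params$line)), "lines x",
      length(unique(x$params$condition)), "condition(s)\n")
  cat("  penetrance-limited:", sum(x$drugs$penetrance_limited),
      "  inert:", sum(x$drugs$inert), "  seed:", x$seed, "\n")
  invisible(x)
}
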