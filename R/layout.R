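#' Deterministic 384-well plate layout for a screen design
#'
#' Assigns every drug x concentration x replicate of each cell line and
#' culture condition to a well of a 384-well plate (16 rows x 24 columns).
#' Each line x condition gets its own plate series; every plate carries
#' `controls_per_plate` vehicle-control wells (drug `"CONTROL"`,
#' concentration 0) at its start, so each drug shares a plate with controls
#' of its own line and condition. The layout is a pure function of the
#' config: the same design always yields byte-identical layouts.
#'
#' @param config a [screen_config()].
#' @param allow_multiple_plates spill to additional plates when a line x
#'   condition exceeds one plate; if `FALSE`, overflowing designs error.
#' @return data.frame with columns plate, row, col, line, drug, condition,
#'   conc_M, replicate. Control wells have drug `"CONTROL"`, conc_M 0.
#' @export
build_layout <- function(config, allow_multiple_plates = TRUE) {
  stopifnot(inherits(config, "screen_config"))
  rows <- LETTERS[1:16]
  n_wells <- 384L
  usable <- n_wells - config$controls_per_plate
  treated_per_group <- length(config$drugs) * length(config$series) * config$replicates
  n_plates <- ceiling(treated_per_group / usable)
  if (n_plates > 1 && !allow_multiple_plates) {
    abort("design needs ", treated_per_group + config$controls_per_plate,
          " wells per line x condition but a plate holds ", n_wells,
          class = "spheroscreen_capacity_error")
  }

  # treated wells for one line x condition, in fixed drug/conc/replicate order
  treated <- expand.grid(replicate = seq_len(config$replicates),
                         conc_M = config$series,
                         drug = config$drugs,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  treated <- treated[, c("drug", "conc_M", "replicate")]

  one_group <- function(line, condition) {
    plate_of <- rep(seq_len(n_plates), each = usable, length.out = nrow(treated))
    pieces <- lapply(seq_len(n_plates), function(p) {
      trt <- treated[plate_of == p, , drop = FALSE]
      ctrl <- data.frame(drug = "CONTROL", conc_M = 0,
                         replicate = seq_len(config$controls_per_plate))
      block <- rbind(ctrl, trt)
      idx <- seq_len(nrow(block)) - 1L   # row-major fill: A1, A2, ...
      data.frame(plate = sprintf("%s_%s_p%02d", line, condition, p),
                 row = rows[idx %/% 24L + 1L],
                 col = idx %% 24L + 1L,
                 line = line, drug = block$drug, condition = condition,
                 conc_M = block$conc_M, replicate = block$replicate,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  }

  groups <- expand.grid(line = config$lines, condition = config$conditions,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- do.call(rbind, Map(one_group, groups$line, groups$condition))
  rownames(out) <- NULL
  class(out) <- c("plate_layout", "data.frame")
  out
}

validate_layout <- function(layout) {
  key <- paste(layout$plate, layout$row, layout$col)
  if (anyDuplicated(key)) abort_data("duplicate wells in layout")
  if (any(layout$conc_M[layout$drug == "CONTROL"] != 0)) {
    abort_data("control wells must have concentration 0")
  }
  if (any(layout$conc_M[layout$drug != "CONTROL"] <= 0)) {
    abort_data("treated wells must have positive concentration")
  }
  invisible(layout)
}
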