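#' Read and write the pipeline's CSV schemas
#'
#' Long-format CSVs bind the pipeline stages together: the time-series
#' table (`plate,row,col,line,drug,condition,conc_M,replicate,time_h,live,dead`),
#' the viability-point table
#' (`drug,line,condition,conc_M,replicate,viability`), the ground-truth
#' table, and the per-curve metrics table. Readers validate the header,
#' coerce types, and report malformed rows by line number; rows with
#' missing viability are skipped with a warning.
#'
#' @param points,ts,truth,df table to write.
#' @param path CSV file path.
#' @name screen_io
NULL

check_schema <- function(df, need, path) {
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort("file ", path, " is missing columns: ", paste(missing, collapse = ", "),
          class = "spheroscreen_schema_error")
  }
}

#' @rdname screen_io
#' @export
write_viability_csv <- function(points, path) {
  need <- c("drug", "line", "condition", "conc_M", "replicate", "viability")
  check_schema(points, need, path)
  write.csv(points[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_viability_csv <- function(path) {
  if (!file.exists(path)) abort_invalid("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "line", "condition", "conc_M", "replicate", "viability")
  check_schema(df, need, path)
  viab <- suppressWarnings(as.numeric(df$viability))
  conc <- suppressWarnings(as.numeric(df$conc_M))
  bad <- which(is.na(viab) | is.na(conc))
  if (length(bad) > 0) {
    warning("skipping ", length(bad), " malformed/missing row(s) at line(s) ",
            paste(head(bad + 1L, 10), collapse = ", "),
            if (length(bad) > 10) ", ..." else "", " of ", path, call. = FALSE)
    df <- df[-bad, , drop = FALSE]
    viab <- viab[-bad]; conc <- conc[-bad]
  }
  df$viability <- viab
  df$conc_M <- conc
  df$replicate <- as.integer(df$replicate)
  rownames(df) <- NULL
  df[, need]
}

#' @rdname screen_io
#' @export
write_timeseries_csv <- function(ts, path) {
  need <- c("plate", "row", "col", "line", "drug", "condition",
            "conc_M", "replicate", "time_h", "live", "dead")
  check_schema(ts, need, path)
  write.csv(ts[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) abort_invalid("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate", "row", "col", "line", "drug", "condition",
            "conc_M", "replicate", "time_h", "live", "dead")
  check_schema(df, need, path)
  for (col in c("conc_M", "time_h")) df[[col]] <- as.numeric(df[[col]])
  for (col in c("replicate", "live", "dead", "col")) df[[col]] <- as.integer(df[[col]])
  df[, need]
}

#' @rdname screen_io
#' @export
write_truth_csv <- function(truth, path) {
  stopifnot(inherits(truth, "screen_truth"))
  p <- truth$params
  i <- match(p$drug, truth$drugs$drug)
  p$penetrance_limited <- truth$drugs$penetrance_limited[i]
  p$inert <- truth$drugs$inert[i]
  write.csv(p, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
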