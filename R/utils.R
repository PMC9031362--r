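#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rpois runif sd setNames aggregate
#' @importFrom utils read.csv write.csv head
NULL

# stop with a consistent error style; all validation errors go through here
abort <- function(..., class = "spheroscreen_error") {
  stop(errorCondition(paste0(...), class = c(class, "spheroscreen_error")))
}

abort_invalid <- function(...) abort(..., class = "spheroscreen_invalid_argument")
abort_state   <- function(...) abort(..., class = "spheroscreen_invalid_state")
abort_data    <- function(...) abort(..., class = "spheroscreen_data_integrity")

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched.
with_seed <- function(seed, code) {
  if (!is_count(seed)) abort_invalid("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stable 31-bit string hash (Horner scheme). Used to derive per-well RNG
# substreams so that draws depend on well identity, not layout order.
hash31 <- function(keys) {
  vapply(keys, function(k) {
    h <- 0
    for (ch in utf8ToInt(k)) h <- (h * 31 + ch) %% 2147483563
    h
  }, numeric(1), USE.NAMES = FALSE)
}

substream_seed <- function(master_seed, keys) {
  as.integer((hash31(keys) + as.numeric(master_seed) * 7919) %% 2147483563)
}

# log-uniform draw
rlogunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
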