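## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed without disturbing the
#' caller's random-number stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Derive a per-stream child seed from one global seed
#'
#' One user-facing seed is expanded into independent substreams (one per
#' simulator stage) so that stages can be regenerated in isolation without
#' perturbing each other's draws. The mapping is a fixed affine hash into
#' the 32-bit signed-integer range.
#'
#' @param seed Integer master seed.
#' @param stream One of `"transcriptome"`, `"counts"`, `"hdx"`, `"binding"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed,
                           stream = c("transcriptome", "counts", "hdx",
                                      "binding")) {
  stream <- match.arg(stream)
  offset <- c(transcriptome = 101L, counts = 202L, hdx = 303L,
              binding = 404L)[[stream]]
  as.integer((abs(as.numeric(seed)) * 7919 + offset) %% 2147483646) + 1L
}

## Weighted mode with ties broken toward the smallest value.
weighted_mode_min <- function(values, weights) {
  stopifnot(length(values) == length(weights), length(values) > 0L)
  agg <- tapply(weights, values, sum)
  vals <- as.numeric(names(agg))
  best <- vals[agg == max(agg)]
  min(best)
}

## Centered moving average of width `window` applied within each maximal
## run of non-NA values; partial windows at run edges use the available
## values only. `window` must be odd; 1 disables smoothing.
smooth_runs <- function(x, window) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  if (window == 1L || length(x) == 0L) return(x)
  half <- (window - 1L) %/% 2L
  out <- x
  ok <- !is.na(x)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    for (i in i0:i1) {
      lo <- max(i0, i - half); hi <- min(i1, i + half)
      out[i] <- mean(x[lo:hi])
    }
  }
  out
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single number in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

check_range <- function(x, name, integer = TRUE) {
  if (!is.numeric(x) || length(x) != 2L || anyNA(x) || x[1] > x[2])
    stop(sprintf("`%s` must be a non-empty interval c(lo, hi)", name),
         call. = FALSE)
  if (integer && any(x < 0))
    stop(sprintf("`%s` must be non-negative", name), call. = FALSE)
  invisible(x)
}

sample_range <- function(n, range) {
  if (range[1] == range[2]) rep.int(as.integer(range[1]), n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}
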