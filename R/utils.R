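# Internal helpers: interval algebra on 0-based half-open integer intervals,
# seeded evaluation, and input validation.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Merge possibly-overlapping intervals (matrix/data.frame with start, end;
# 0-based half-open). Returns a data.frame sorted by start. Touching
# intervals ([a,b) and [b,c)) are merged.
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# Gaps between sorted non-overlapping intervals, within [span_start, span_end).
interval_gaps <- function(merged, span_start, span_end) {
  bounds_s <- c(span_start, merged$end)
  bounds_e <- c(merged$start, span_end)
  keep <- bounds_e > bounds_s
  data.frame(start = bounds_s[keep], end = bounds_e[keep])
}

# Overlap width of [s1,e1) with [s2,e2); vectorized.
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    stop(sprintf("`%s` out of range", name), call. = FALSE)
  invisible(x)
}

input_error <- function(msg) {
  stop(errorCondition(msg, class = c("snhg_input_error", "error")))
}
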