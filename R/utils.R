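# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards (no global side effects).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(expr)
}

rms <- function(x) {
  if (length(x) == 0) return(0)
  sqrt(mean(x^2))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# piecewise-constant lookup: schedule is a 2-column structure (t_start, value),
# t_start non-decreasing; returns value in force at each time in `t`.
schedule_at <- function(schedule, t) {
  sch <- as.matrix(schedule)
  idx <- findInterval(t, sch[, 1])
  idx[idx < 1] <- 1L
  sch[idx, 2]
}

as_schedule <- function(x, duration_s, what = "schedule") {
  if (is.null(dim(x))) x <- matrix(c(0, x[1]), nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != 2) stopf("%s must have two columns (t_start, value)", what)
  if (is.unsorted(x[, 1])) stopf("%s times must be non-decreasing", what)
  if (any(x[, 1] < 0) || any(x[, 1] > duration_s))
    stopf("%s times must lie within [0, duration_s]", what)
  x
}
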