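#' Piecewise-quadratic coupling schedule
#'
#' A schedule gives a coupling strength as a function of time:
#' `value(t) = a * t^2 + b * t + c` on each segment `[t_start, t_end)`.
#' Segments must be contiguous (each segment starts where the previous one
#' ends) and ordered. Evaluations before the first segment use the first
#' segment's polynomial and evaluations at or after the last segment's end
#' use the last segment's; negative evaluations are clamped to zero when the
#' schedule is used as a coupling strength.
#'
#' @param segments a data frame with columns `t_start`, `t_end`, `a`, `b`,
#'   `c` (seconds and polynomial coefficients).
#' @return An object of class `schedule` (a tibble of segments).
#' @examples
#' # constant 0.6 for 100 s then linear decay
#' schedule(data.frame(t_start = c(0, 100), t_end = c(100, 200),
#'                     a = 0, b = c(0, -0.006), c = c(0.6, 1.2)))
#' @export
schedule <- function(segments) {
  segments <- tibble::as_tibble(segments)
  req <- c("t_start", "t_end", "a", "b", "c")
  if (!all(req %in% names(segments))) {
    stop("segments must have columns t_start, t_end, a, b, c", call. = FALSE)
  }
  segments <- segments[req]
  if (nrow(segments) < 1L) stop("schedule needs >= 1 segment", call. = FALSE)
  if (any(segments$t_end <= segments$t_start)) {
    stop("each segment must have t_end > t_start", call. = FALSE)
  }
  if (nrow(segments) > 1L) {
    gaps <- segments$t_start[-1] - segments$t_end[-nrow(segments)]
    if (any(abs(gaps) > 1e-9)) {
      stop("segments must be contiguous and non-overlapping", call. = FALSE)
    }
  }
  structure(segments, class = c("schedule", class(segments)))
}

#' Constant schedule helper
#'
#' @param value constant coupling value.
#' @param t_end end of validity (default unbounded).
#' @return A one-segment [schedule()].
#' @export
constant_schedule <- function(value, t_end = Inf) {
  schedule(data.frame(t_start = 0, t_end = t_end, a = 0, b = 0, c = value))
}

#' @export
print.schedule <- function(x, ...) {
  cat("<schedule> ", nrow(x), " segment(s)\n", sep = "")
  print(tibble::as_tibble(unclass(x)))
  invisible(x)
}

is_schedule <- function(x) inherits(x, "schedule")

#' Evaluate a schedule
#'
#' @param sched a [schedule()] or a single numeric constant.
#' @param t time(s), seconds.
#' @param clamp clamp negative evaluations to zero (the default, matching the
#'   schedule's use as a coupling strength).
#' @return Numeric vector of evaluated values.
#' @export
schedule_value <- function(sched, t, clamp = TRUE) {
  if (is.numeric(sched) && length(sched) == 1L) {
    v <- rep_len(sched, length(t))
  } else {
    stopifnot(is_schedule(sched))
    idx <- vapply(t, function(ti) {
      k <- which(ti < sched$t_end)
      if (length(k) == 0L) nrow(sched) else k[1]
    }, integer(1))
    v <- sched$a[idx] * t^2 + sched$b[idx] * t + sched$c[idx]
  }
  if (clamp) v <- pmax(v, 0)
  v
}

#' Interior breakpoints of a schedule
#' @param sched a [schedule()] or numeric constant.
#' @return Numeric vector of segment boundaries (possibly empty).
#' @export
schedule_breakpoints <- function(sched) {
  if (!is_schedule(sched)) return(numeric(0))
  bp <- sched$t_start[-1]
  bp[is.finite(bp)]
}

# coupling -> segment matrix for the C++ core (columns t0, t1, a, b, c)
sched_matrix <- function(x) {
  if (is_schedule(x)) {
    cbind(t_start = as.numeric(x$t_start), t_end = as.numeric(x$t_end),
          a = as.numeric(x$a), b = as.numeric(x$b), c = as.numeric(x$c))
  } else {
    stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
    matrix(c(0, Inf, 0, 0, x), nrow = 1,
           dimnames = list(NULL, c("t_start", "t_end", "a", "b", "c")))
  }
}
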