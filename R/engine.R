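#' @title Discrete-event kernel: event calendar
#'
#' @description
#' A minimal binary-heap event calendar ordered lexicographically by
#' `(time, seq)`, where `seq` is a monotone insertion counter.  Events with
#' equal times are therefore dispatched in insertion (FIFO) order, which is
#' what makes replications replayable: two runs with the same master seed
#' produce byte-identical event logs.
#'
#' Times are simulated seconds from session start (session start = 0).
#'
#' @param init initial storage size; the calendar grows by doubling.
#' @return an event calendar (an environment of class `event_calendar`).
#' @export
new_calendar <- function(init = 64L) {
  cal <- new.env(parent = emptyenv())
  cal$time <- numeric(init)
  cal$seq <- integer(init)
  cal$kind <- character(init)
  cal$pid <- integer(init)
  cal$res <- integer(init)
  cal$n <- 0L
  cal$counter <- 0L
  class(cal) <- "event_calendar"
  cal
}

#' Number of pending events
#' @param cal an event calendar.
#' @return integer count of events not yet dispatched.
#' @export
cal_size <- function(cal) cal$n

# strict (time, seq) heap order
.cal_before <- function(cal, i, j) {
  cal$time[i] < cal$time[j] ||
    (cal$time[i] == cal$time[j] && cal$seq[i] < cal$seq[j])
}

.cal_swap <- function(cal, i, j) {
  ij <- c(i, j); ji <- c(j, i)
  cal$time[ij] <- cal$time[ji]
  cal$seq[ij] <- cal$seq[ji]
  cal$kind[ij] <- cal$kind[ji]
  cal$pid[ij] <- cal$pid[ji]
  cal$res[ij] <- cal$res[ji]
}

#' Schedule an event
#'
#' Inserts an event into the calendar.  Scheduling strictly in the past
#' (before `clock`) is an error; scheduling exactly at the current clock is
#' allowed and the event is dispatched on the next step.
#'
#' @param cal an event calendar.
#' @param time event time in simulated seconds (must be `>= clock`).
#' @param kind event label, e.g. `"arrival"` or `"consult_end"`.
#' @param pid integer id of the subject patient (`NA` for markers).
#' @param res integer id of the resource involved (`NA` if none).
#' @param clock current simulation clock (default 0).
#' @return (invisibly) the insertion sequence number.
#' @export
schedule <- function(cal, time, kind, pid = NA_integer_, res = NA_integer_,
                     clock = 0) {
  if (!is.finite(time) || time < 0)
    stop("event time must be a nonnegative number, got ", time)
  if (time < clock)
    stop(sprintf(
      "cannot schedule event '%s' at t=%.6g: clock is already at t=%.6g",
      kind, time, clock))
  n <- cal$n + 1L
  if (n > length(cal$time)) {
    grow <- 2L * length(cal$time)
    length(cal$time) <- grow
    length(cal$seq) <- grow
    length(cal$kind) <- grow
    length(cal$pid) <- grow
    length(cal$res) <- grow
  }
  cal$counter <- cal$counter + 1L
  cal$time[n] <- time
  cal$seq[n] <- cal$counter
  cal$kind[n] <- kind
  cal$pid[n] <- as.integer(pid)
  cal$res[n] <- as.integer(res)
  cal$n <- n
  i <- n
  while (i > 1L) {
    p <- i %/% 2L
    if (.cal_before(cal, i, p)) {
      .cal_swap(cal, i, p)
      i <- p
    } else break
  }
  invisible(cal$counter)
}

#' Pop the next event
#'
#' Removes and returns the pending event with the smallest `(time, seq)`.
#'
#' @param cal an event calendar.
#' @return a list with elements `time`, `seq`, `kind`, `pid`, `res`, or
#'   `NULL` if the calendar is empty.
#' @export
next_event <- function(cal) {
  n <- cal$n
  if (n == 0L) return(NULL)
  out <- list(time = cal$time[1L], seq = cal$seq[1L], kind = cal$kind[1L],
              pid = cal$pid[1L], res = cal$res[1L])
  .cal_swap(cal, 1L, n)
  cal$n <- n - 1L
  n <- n - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L
    m <- i
    if (l <= n && .cal_before(cal, l, m)) m <- l
    if (r <= n && .cal_before(cal, r, m)) m <- r
    if (m == i) break
    .cal_swap(cal, i, m)
    i <- m
  }
  out
}

# ---------------------------------------------------------------------------
# Named random substreams
# ---------------------------------------------------------------------------

#' Names of the clinic's random substreams
#'
#' One independent stream per stochastic element, so that a change consuming
#' draws from one element (say, a different consultation-time mean) never
#' reshuffles the realizations of another (say, walk-in arrival times).
#' This is what makes common-random-numbers policy comparison sharp.
#'
#' @return character vector of stream names.
#' @export
clinic_streams <- function() {
  c("walkin_arrivals", "lateness", "no_show", "special",
    "consult", "exam_decision", "exam_duration",
    "registration", "pharmacy")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Create named, independent random streams
#'
#' Builds one independent L'Ecuyer-CMRG substream per named stochastic
#' element, all derived from a single master seed.  The same master seed
#' yields byte-identical draw sequences on every stream, and drawing from
#' one stream never perturbs another.
#'
#' @param master_seed integer master seed.
#' @param streams character vector of stream names
#'   (default [clinic_streams()]).
#' @return an object of class `random_streams`.
#' @export
random_streams <- function(master_seed, streams = clinic_streams()) {
  if (length(master_seed) != 1L || !is.finite(master_seed))
    stop("master_seed must be a single finite integer")
  rs <- new.env(parent = emptyenv())
  rs$master_seed <- as.integer(master_seed)
  rs$states <- new.env(parent = emptyenv())
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(rs$master_seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  for (nm in streams) {
    s <- parallel::nextRNGStream(s)
    assign(nm, s, envir = rs$states)
  }
  class(rs) <- "random_streams"
  rs
}

#' Evaluate a drawing expression on one substream
#'
#' Temporarily installs the substream's generator state, evaluates `fn()`,
#' stores the advanced state back, and restores the caller's RNG state.
#'
#' @param rs a [random_streams()] object.
#' @param stream stream name.
#' @param fn a zero-argument function performing the draws.
#' @return the value of `fn()`.
#' @export
rs_eval <- function(rs, stream, fn) {
  st <- get0(stream, envir = rs$states, inherits = FALSE)
  if (is.null(st))
    stop("unknown random stream: '", stream, "'")
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  assign(".Random.seed", st, envir = globalenv())
  val <- fn()
  assign(stream, get(".Random.seed", envir = globalenv(), inherits = FALSE),
         envir = rs$states)
  val
}

#' Draw service durations from a configured family
#'
#' Durations are parameterized by mean and coefficient of variation (CV).
#' `lognormal` matches both moments (right-skewed clinical service times);
#' `exponential` uses the mean only (CV fixed at 1); `fixed` is degenerate.
#' A nonpositive mean yields zeros (a disabled station).
#'
#' @param rs a [random_streams()] object.
#' @param stream stream name to draw from.
#' @param n number of draws.
#' @param mean mean duration in seconds (scalar or length-`n`).
#' @param cv coefficient of variation (lognormal only).
#' @param family `"lognormal"`, `"exponential"` or `"fixed"`.
#' @return numeric vector of `n` nonnegative durations.
#' @export
draw_duration <- function(rs, stream, n, mean, cv = 0.5,
                          family = c("lognormal", "exponential", "fixed")) {
  family <- match.arg(family)
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  mean <- rep_len(as.numeric(mean), n)
  out <- numeric(n)
  pos <- mean > 0
  if (!any(pos)) return(out)
  m <- mean[pos]
  k <- sum(pos)
  out[pos] <- switch(family,
    fixed = m,
    exponential = rs_eval(rs, stream, function() rexp(k, rate = 1) * m),
    lognormal = {
      sdlog <- sqrt(log1p(cv^2))
      meanlog <- log(m) - sdlog^2 / 2
      rs_eval(rs, stream, function() rlnorm(k, meanlog, sdlog))
    })
  out
}

#' Write an event log to CSV
#'
#' Stable column order `(time_s, seq, kind, patient_id, resource_id,
#' detail)` with a header row; `detail` carries the dispatching policy name
#' on `consult_start` rows.
#'
#' @param log event-log data frame from [simulate_session()].
#' @param path output file path.
#' @return (invisibly) `path`.
#' @export
write_event_log <- function(log, path) {
  cols <- c("time_s", "seq", "kind", "patient_id", "resource_id", "detail")
  stopifnot(all(cols %in% names(log)))
  utils::write.csv(log[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
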