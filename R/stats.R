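#' Parse an h:mm:ss duration
#'
#' @param text character vector of `"h:mm:ss"` strings with minutes and
#'   seconds in `00..59` (hours unbounded).
#' @return numeric vector of seconds.
#' @examples
#' hms_to_seconds("2:00:59")  # 7259
#' @export
hms_to_seconds <- function(text) {
  ok <- grepl("^[0-9]+:[0-5][0-9]:[0-5][0-9]$", text)
  if (any(!ok))
    stop("malformed h:mm:ss duration: '", text[which(!ok)[1]], "'")
  parts <- do.call(rbind, strsplit(text, ":", fixed = TRUE))
  3600 * as.numeric(parts[, 1]) + 60 * as.numeric(parts[, 2]) +
    as.numeric(parts[, 3])
}

#' Format seconds as h:mm:ss
#' @param s numeric vector of nonnegative seconds.
#' @return character vector of `"h:mm:ss"` strings.
#' @export
seconds_to_hms <- function(s) {
  s <- round(s)
  sprintf("%d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

#' Waiting-time improvement percentage
#'
#' `100 * (before - after) / before`, rounded to two decimals, as printed
#' in per-session improvement tables.
#'
#' @param before,after waiting times in seconds; `before` must be > 0.
#' @return percentage, two decimals.
#' @examples
#' improvement_pct(7259, 4902)  # 32.47
#' @export
improvement_pct <- function(before, after) {
  if (any(before <= 0)) stop("'before' must be > 0")
  round(100 * (before - after) / before, 2)
}

#' Absolute percent difference between simulated and collected values
#'
#' `100 * |simulated - collected| / collected`, the validation discrepancy
#' measure used when comparing simulated session statistics with collected
#' clinic data.
#'
#' @param simulated,collected numeric; `collected` must be nonzero.
#' @return percentage.
#' @export
percent_difference <- function(simulated, collected) {
  if (any(collected == 0)) stop("'collected' must be nonzero")
  100 * abs(simulated - collected) / abs(collected)
}

#' Student-t confidence interval for replication means
#'
#' The standard terminating-simulation interval
#' `mean(x) +/- t(1 - alpha/2, n - 1) * s / sqrt(n)`.
#' Zero-variance samples give a degenerate interval of width zero.
#'
#' @param x numeric vector of per-replication means (length >= 2).
#' @param alpha significance level (default 0.05 for a 95% interval).
#' @return named numeric `c(mean, lower, upper)`.
#' @export
summarize_replications <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 2L)
    stop("need at least 2 replications for a confidence interval, got ", n)
  m <- mean(x)
  s <- stats::sd(x)
  hw <- if (s == 0) 0 else stats::qt(1 - alpha / 2, n - 1L) * s / sqrt(n)
  c(mean = m, lower = m - hw, upper = m + hw)
}

#' Per-session replication statistics
#'
#' Bundles per-replication means of waiting time, throughput time and
#' doctor utilization into point estimates with 95% Student-t intervals.
#'
#' @param session_id session identifier.
#' @param policy policy name used for the replications.
#' @param rep_means data frame with columns `waiting`, `throughput`,
#'   `utilization`, one row per replication.
#' @param alpha significance level (default 0.05).
#' @return an object of class `session_stats`.
#' @export
session_stats <- function(session_id, policy, rep_means, alpha = 0.05) {
  stopifnot(all(c("waiting", "throughput", "utilization") %in%
                  names(rep_means)))
  w <- summarize_replications(rep_means$waiting, alpha)
  th <- summarize_replications(rep_means$throughput, alpha)
  u <- summarize_replications(rep_means$utilization, alpha)
  structure(list(
    session_id = session_id, policy = policy,
    n_reps = nrow(rep_means), alpha = alpha,
    rep_means = rep_means,
    mean_waiting = unname(w["mean"]),
    ci_waiting = unname(w[c("lower", "upper")]),
    mean_throughput = unname(th["mean"]),
    ci_throughput = unname(th[c("lower", "upper")]),
    mean_utilization = unname(u["mean"]),
    ci_utilization = unname(u[c("lower", "upper")])),
    class = "session_stats")
}

#' @export
print.session_stats <- function(x, ...) {
  cat(sprintf("<session_stats> session %s | policy %s | %d replications\n",
              x$session_id, x$policy, x$n_reps))
  cat(sprintf("  waiting     %7.2f min  [%.2f, %.2f]\n",
              x$mean_waiting / 60, x$ci_waiting[1] / 60,
              x$ci_waiting[2] / 60))
  cat(sprintf("  throughput  %7.2f min  [%.2f, %.2f]\n",
              x$mean_throughput / 60, x$ci_throughput[1] / 60,
              x$ci_throughput[2] / 60))
  cat(sprintf("  utilization %7.2f %%    [%.2f, %.2f]\n",
              100 * x$mean_utilization, 100 * x$ci_utilization[1],
              100 * x$ci_utilization[2]))
  invisible(x)
}

#' @export
summary.session_stats <- function(object, ...) {
  data.frame(
    session_id = object$session_id, policy = object$policy,
    n_reps = object$n_reps,
    mean_waiting_min = object$mean_waiting / 60,
    ci_waiting_lo = object$ci_waiting[1] / 60,
    ci_waiting_hi = object$ci_waiting[2] / 60,
    mean_throughput_min = object$mean_throughput / 60,
    ci_throughput_lo = object$ci_throughput[1] / 60,
    ci_throughput_hi = object$ci_throughput[2] / 60,
    mean_utilization_pct = 100 * object$mean_utilization,
    ci_utilization_lo = 100 * object$ci_utilization[1],
    ci_utilization_hi = 100 * object$ci_utilization[2])
}

#' @export
plot.session_stats <- function(x, ...) {
  graphics::hist(x$rep_means$waiting / 60, col = "grey85",
                 main = sprintf("Session %s (%s): replication mean waits",
                                x$session_id, x$policy),
                 xlab = "mean waiting time per replication (min)", ...)
  graphics::abline(v = x$mean_waiting / 60, lwd = 2)
  graphics::abline(v = x$ci_waiting / 60, lty = 2)
  invisible(x)
}

#' Paired t-test on per-session waiting times
#'
#' Differences are `before - after`; the statistic is
#' `t = mean(d) / (s_d / sqrt(n))` on `n - 1` degrees of freedom, with a
#' one-tail p-value in the direction "waiting decreased"
#' (`mean(d) > 0`).  Per-session improvement percentages and minute totals
#' accompany the test.
#'
#' @param before,after equal-length numeric vectors of per-session mean
#'   waiting times in seconds (length >= 2).
#' @param session_ids optional session labels.
#' @return an object of class `clinic_comparison`: paired differences,
#'   `mean_difference` (s), `dof`, `t_value`, `one_tail_p`, per-session
#'   `improvement_pct`, and before/after totals in minutes.
#' @export
paired_t <- function(before, after, session_ids = seq_along(before)) {
  if (length(before) != length(after))
    stop("before and after must have equal length (got ", length(before),
         " and ", length(after), ")")
  n <- length(before)
  if (n < 2L) stop("need at least 2 paired sessions, got ", n)
  d <- before - after
  sd_d <- stats::sd(d)
  if (sd_d == 0)
    stop("paired differences have zero variance; the t statistic is ",
         "undefined")
  t_value <- mean(d) / (sd_d / sqrt(n))
  structure(list(
    session_ids = session_ids,
    before_s = before, after_s = after, differences_s = d,
    mean_difference = mean(d),
    dof = n - 1L,
    t_value = t_value,
    one_tail_p = stats::pt(t_value, df = n - 1L, lower.tail = FALSE),
    improvement_pct = improvement_pct(before, after),
    total_before_min = sum(before) / 60,
    total_after_min = sum(after) / 60),
    class = "clinic_comparison")
}

#' @export
print.clinic_comparison <- function(x, ...) {
  cat("<clinic_comparison> paired t-test on per-session mean waiting time\n")
  tab <- data.frame(session = x$session_ids,
                    before = seconds_to_hms(x$before_s),
                    after = seconds_to_hms(x$after_s),
                    reduction_min = sprintf("%.2f", x$differences_s / 60),
                    improvement_pct = sprintf("%.2f", x$improvement_pct))
  print(tab, row.names = FALSE)
  cat(sprintf("  totals: before %.2f min, after %.2f min (overall %.2f%%)\n",
              x$total_before_min, x$total_after_min,
              improvement_pct(sum(x$before_s), sum(x$after_s))))
  cat(sprintf("  mean difference %.1f s | dof %d | t = %.3f | one-tail p %s\n",
              x$mean_difference, x$dof, x$t_value,
              format.pval(x$one_tail_p, digits = 3)))
  invisible(x)
}

#' The packaged before/after waiting-time table
#'
#' Twelve consultation sessions with the observed ("before") and
#' post-change ("after") mean waiting times as h:mm:ss strings, the
#' improvement percentage as printed in the source table, and the
#' slightly different improvement percentage and reduction (minutes)
#' quoted in the source's discussion (session 10 differs between the
#' two).
#'
#' @return data frame with columns `session`, `before_hms`, `after_hms`,
#'   `printed_improvement_pct`, `discussion_improvement_pct`,
#'   `discussion_reduction_min`.
#' @export
clinic_table2 <- function() {
  path <- system.file("extdata", "table2.csv", package = "clinicflow",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Fraction of process time spent waiting
#'
#' Given mean waiting and mean service time, the share of the total
#' process time spent in queues: `100 * wait / (wait + service)`.
#'
#' @param wait_min mean waiting time in minutes.
#' @param service_min mean service time in minutes.
#' @return percentage.
#' @export
waiting_fraction <- function(wait_min, service_min) {
  100 * wait_min / (wait_min + service_min)
}
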