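#' Configure one consultation session
#'
#' A consultation session is one bounded clinic block staffed by one doctor
#' team; the study department runs 12 per week.  The configuration carries
#' everything the simulator needs: operating window, scheduled-patient
#' appointment grid, walk-in arrival intensity, behavioural rates (late,
#' no-show, special, examination), service-time distributions, move times,
#' and station capacities.
#'
#' All times are simulated seconds with session start at 0.  Rates are
#' fractions in `[0, 1]`.  Arrival intensity is patients per hour, either a
#' single constant or a piecewise-constant profile (a data frame with
#' columns `from`, `to` in seconds and `rate` in patients/hour).
#'
#' @param session_id integer 1..12.
#' @param team `"sports"`, `"trauma"` or `"hand_and_foot"`.
#' @param duration session length in seconds (registration closes then;
#'   patients already checked in are served to completion).
#' @param n_scheduled number of appointment slots.
#' @param appointment_grid appointment times in seconds; default evenly
#'   spaced over the session (`template = "even"`), or the front-loaded
#'   Bailey-Welch template (`template = "bailey_welch"`: two patients at
#'   time zero, the rest evenly spaced).
#' @param template appointment template used when `appointment_grid` is
#'   `NULL`.
#' @param walkin_rate constant walk-in intensity, patients/hour.
#' @param walkin_profile optional piecewise-constant intensity profile
#'   overriding `walkin_rate`.
#' @param late_rate fraction of scheduled patients arriving after their
#'   appointment (plus grace).
#' @param lateness_mean mean lateness delay in seconds (exponential).
#' @param grace_s grace period in seconds before a scheduled arrival counts
#'   as late (default 0: late means any arrival after the appointment).
#' @param no_show_rate fraction of scheduled patients who never arrive.
#' @param special_rate fraction of patients with first priority (over 85
#'   years of age, strictly, or a special condition).
#' @param exam_rate probability a first consultation sends the patient to
#'   the examination center.
#' @param reg_mean,reg_cv,reg_dist registration service time (seconds).
#' @param consult_mean,consult_cv,consult_dist consultation time (seconds).
#' @param consult_mean_by_class optional named vector
#'   `c(walk_in = , scheduled = )` of class-specific consultation means,
#'   overriding `consult_mean`.
#' @param exam_mean,exam_cv,exam_dist examination time (seconds).
#' @param pharmacy_mean,pharmacy_cv,pharmacy_dist pharmacy time (seconds).
#' @param move_s move time between clinic zones (seconds); counted in
#'   throughput, never in waiting.
#' @param n_doctors doctors consulting in parallel in this session.
#' @param reg_capacity registration clerks.
#' @param exam_capacity examination-center slots available to the session
#'   (the center is shared with other departments, hence small).
#' @param pharmacy_capacity pharmacy counters.
#' @param walkin_rate_scale,consult_mean_scale calibration knobs: scale
#'   factors applied multiplicatively to the walk-in intensity and to the
#'   consultation mean(s).
#' @return an object of class `session_config` (a list).
#' @seealso [default_sessions()], [generate_arrivals()], [calibrate()]
#' @export
session_config <- function(session_id = 1L,
                           team = c("sports", "trauma", "hand_and_foot"),
                           duration = 4 * 3600,
                           n_scheduled = 12L,
                           appointment_grid = NULL,
                           template = c("even", "bailey_welch"),
                           walkin_rate = 3,
                           walkin_profile = NULL,
                           late_rate = 0.2,
                           lateness_mean = 900,
                           grace_s = 0,
                           no_show_rate = 0.1,
                           special_rate = 0.05,
                           exam_rate = 0.3,
                           reg_mean = 120, reg_cv = 1, reg_dist = "exponential",
                           consult_mean = 480, consult_cv = 0.5,
                           consult_dist = "lognormal",
                           consult_mean_by_class = NULL,
                           exam_mean = 600, exam_cv = 0.5,
                           exam_dist = "lognormal",
                           pharmacy_mean = 120, pharmacy_cv = 1,
                           pharmacy_dist = "exponential",
                           move_s = 60,
                           n_doctors = 1L,
                           reg_capacity = 2L,
                           exam_capacity = 3L,
                           pharmacy_capacity = 2L,
                           walkin_rate_scale = 1,
                           consult_mean_scale = 1) {
  team <- match.arg(team)
  template <- match.arg(template)
  if (is.null(appointment_grid))
    appointment_grid <- appointment_template(n_scheduled, duration, template)
  cfg <- list(
    session_id = as.integer(session_id), team = team,
    duration = as.numeric(duration),
    n_scheduled = length(appointment_grid),
    appointment_grid = as.numeric(appointment_grid),
    walkin_rate = walkin_rate, walkin_profile = walkin_profile,
    late_rate = late_rate, lateness_mean = lateness_mean, grace_s = grace_s,
    no_show_rate = no_show_rate, special_rate = special_rate,
    exam_rate = exam_rate,
    reg_mean = reg_mean, reg_cv = reg_cv, reg_dist = reg_dist,
    consult_mean = consult_mean, consult_cv = consult_cv,
    consult_dist = consult_dist,
    consult_mean_by_class = consult_mean_by_class,
    exam_mean = exam_mean, exam_cv = exam_cv, exam_dist = exam_dist,
    pharmacy_mean = pharmacy_mean, pharmacy_cv = pharmacy_cv,
    pharmacy_dist = pharmacy_dist,
    move_s = move_s,
    n_doctors = as.integer(n_doctors),
    reg_capacity = as.integer(reg_capacity),
    exam_capacity = as.integer(exam_capacity),
    pharmacy_capacity = as.integer(pharmacy_capacity),
    walkin_rate_scale = walkin_rate_scale,
    consult_mean_scale = consult_mean_scale)
  class(cfg) <- "session_config"
  problems <- validate_session_config(cfg)
  if (length(problems))
    stop("invalid session configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  cfg
}

#' Appointment templates
#'
#' `"even"` spaces `n` appointments evenly over the session starting at 0;
#' `"bailey_welch"` books two patients at the session start and spaces the
#' remainder evenly (the classic single-block/individual rule).
#'
#' @param n number of appointments.
#' @param duration session length in seconds.
#' @param template `"even"` or `"bailey_welch"`.
#' @return numeric vector of appointment times (seconds), nondecreasing.
#' @export
appointment_template <- function(n, duration,
                                 template = c("even", "bailey_welch")) {
  template <- match.arg(template)
  n <- as.integer(n)
  if (n <= 0L) return(numeric(0))
  even <- seq(0, duration, length.out = n + 1L)[seq_len(n)]
  switch(template,
    even = even,
    bailey_welch = {
      if (n == 1L) return(0)
      rest <- seq(0, duration, length.out = n)[seq_len(n - 1L)]
      sort(c(0, rest))
    })
}

#' Validate a session configuration
#'
#' @param cfg a `session_config`.
#' @return character vector of violated invariants (empty when valid).
#' @export
validate_session_config <- function(cfg) {
  p <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) p[[length(p) + 1L]] <<- msg
  chk(is.numeric(cfg$duration) && cfg$duration > 0,
      "duration must be > 0 seconds")
  for (r in c("late_rate", "no_show_rate", "special_rate", "exam_rate"))
    chk(is.numeric(cfg[[r]]) && cfg[[r]] >= 0 && cfg[[r]] <= 1,
        paste0(r, " must lie in [0, 1]"))
  for (m in c("reg_mean", "consult_mean", "exam_mean", "pharmacy_mean"))
    chk(is.numeric(cfg[[m]]) && cfg[[m]] >= 0,
        paste0(m, " must be >= 0"))
  chk(cfg$lateness_mean >= 0, "lateness_mean must be >= 0")
  chk(cfg$move_s >= 0, "move_s must be >= 0")
  chk(all(cfg$appointment_grid >= 0 & cfg$appointment_grid <= cfg$duration),
      "appointment_grid must lie within the session bounds")
  chk(!is.unsorted(cfg$appointment_grid),
      "appointment_grid must be nondecreasing")
  chk(cfg$n_doctors >= 1L, "n_doctors must be >= 1")
  for (cp in c("reg_capacity", "exam_capacity", "pharmacy_capacity"))
    chk(cfg[[cp]] >= 1L, paste0(cp, " must be >= 1"))
  chk(cfg$walkin_rate >= 0, "walkin_rate must be >= 0")
  if (!is.null(cfg$walkin_profile)) {
    wp <- cfg$walkin_profile
    chk(is.data.frame(wp) && all(c("from", "to", "rate") %in% names(wp)),
        "walkin_profile needs columns from, to, rate")
    if (is.data.frame(wp) && all(c("from", "to", "rate") %in% names(wp))) {
      chk(all(wp$rate >= 0), "walkin_profile rates must be >= 0")
      chk(all(wp$to > wp$from), "walkin_profile intervals must have to > from")
    }
  }
  if (!is.null(cfg$consult_mean_by_class))
    chk(all(c("walk_in", "scheduled") %in% names(cfg$consult_mean_by_class)) &&
          all(cfg$consult_mean_by_class > 0),
        "consult_mean_by_class needs positive walk_in and scheduled entries")
  chk(cfg$walkin_rate_scale > 0, "walkin_rate_scale must be > 0")
  chk(cfg$consult_mean_scale > 0, "consult_mean_scale must be > 0")
  chk(cfg$team %in% c("sports", "trauma", "hand_and_foot"),
      "team must be sports, trauma or hand_and_foot")
  p
}

# piecewise-constant intensity (patients/hour) at time t (seconds)
.profile_rate <- function(cfg, t) {
  if (is.null(cfg$walkin_profile)) return(rep(cfg$walkin_rate, length(t)))
  wp <- cfg$walkin_profile
  out <- numeric(length(t))
  for (i in seq_len(nrow(wp)))
    out[t >= wp$from[i] & t < wp$to[i]] <- wp$rate[i]
  out
}

#' Generate one session's patient population
#'
#' Scheduled patients are placed on the appointment grid and independently
#' marked no-show or late (late arrival = appointment + exponential delay);
#' walk-ins are drawn from a nonhomogeneous Poisson process by thinning the
#' intensity profile.  Registration numbers are assigned odd to walk-ins
#' (in arrival order) and even to scheduled patients (in appointment
#' order).  Special status (age over 85, strictly, or a special condition)
#' is drawn at `special_rate`.
#'
#' All per-patient stochastic attributes, including service durations and
#' the examination decision, are pre-drawn here from their named
#' substreams in a canonical patient order, so that a queue-policy change
#' (which consumes no draws) leaves every realization untouched.
#'
#' @param cfg a [session_config()].
#' @param rs a [random_streams()] object.
#' @return a data frame, one row per generated patient, with identity,
#'   arrival and pre-drawn service attributes.
#' @export
generate_arrivals <- function(cfg, rs) {
  horizon <- cfg$duration
  # --- scheduled patients, appointment order ---------------------------
  ns <- cfg$n_scheduled
  appt <- cfg$appointment_grid
  no_show <- rs_eval(rs, "no_show", function() runif(ns)) < cfg$no_show_rate
  u_late <- rs_eval(rs, "lateness", function() runif(ns))
  delay <- rs_eval(rs, "lateness", function() rexp(ns, rate = 1)) *
    cfg$lateness_mean
  late <- u_late < cfg$late_rate
  s_arr <- ifelse(late, appt + cfg$grace_s + delay, appt)
  # --- walk-ins: NHPP by thinning --------------------------------------
  lam_max <- if (is.null(cfg$walkin_profile)) cfg$walkin_rate
             else max(cfg$walkin_profile$rate)
  lam_max <- lam_max * cfg$walkin_rate_scale
  w_arr <- numeric(0)
  if (lam_max > 0) {
    w_arr <- rs_eval(rs, "walkin_arrivals", function() {
      t <- 0; acc <- numeric(0)
      rate_s <- lam_max / 3600
      repeat {
        t <- t + rexp(1, rate_s)
        if (t >= horizon) break
        keep <- runif(1) < (.profile_rate(cfg, t) * cfg$walkin_rate_scale /
                              lam_max)
        if (keep) acc[length(acc) + 1L] <- t
      }
      acc
    })
  }
  nw <- length(w_arr)
  n <- ns + nw
  ptype <- c(rep("scheduled", ns), rep("walk_in", nw))
  appointment_s <- c(appt, rep(NA_real_, nw))
  arrival_s <- c(s_arr, w_arr)
  late <- c(late, rep(FALSE, nw))
  no_show <- c(no_show, rep(FALSE, nw))
  reg_number <- integer(n)
  reg_number[seq_len(ns)] <- 2L * seq_len(ns)               # even
  if (nw) reg_number[ns + order(w_arr)] <- 2L * seq_len(nw) - 1L  # odd
  # --- special flags and ages ------------------------------------------
  u_sp <- rs_eval(rs, "special", function() runif(2L * max(n, 1L)))
  special <- u_sp[seq_len(n)] < cfg$special_rate
  u_age <- u_sp[max(n, 1L) + seq_len(n)]
  # special patients split between over-85 and special-condition cases
  age <- ifelse(special & u_age < 0.5,
                86 + round(9 * u_age * 2),
                20 + round(64 * u_age))
  # --- pre-drawn service attributes ------------------------------------
  cm <- if (!is.null(cfg$consult_mean_by_class)) {
    unname(cfg$consult_mean_by_class[ptype])
  } else rep(cfg$consult_mean, n)
  cm <- cm * cfg$consult_mean_scale
  reg_dur <- draw_duration(rs, "registration", n, cfg$reg_mean,
                           cfg$reg_cv, cfg$reg_dist)
  consult_dur1 <- draw_duration(rs, "consult", n, cm, cfg$consult_cv,
                                cfg$consult_dist)
  consult_dur2 <- draw_duration(rs, "consult", n, cm, cfg$consult_cv,
                                cfg$consult_dist)
  needs_exam <- rs_eval(rs, "exam_decision", function() runif(n)) <
    cfg$exam_rate
  exam_dur <- draw_duration(rs, "exam_duration", n, cfg$exam_mean,
                            cfg$exam_cv, cfg$exam_dist)
  pharm_dur <- draw_duration(rs, "pharmacy", n, cfg$pharmacy_mean,
                             cfg$pharmacy_cv, cfg$pharmacy_dist)
  out <- data.frame(
    patient_id = seq_len(n),
    ptype = ptype,
    special = special,
    age = age,
    appointment_s = appointment_s,
    arrival_s = arrival_s,
    late = late,
    no_show = no_show,
    reg_number = reg_number,
    reg_dur = reg_dur,
    consult_dur1 = consult_dur1,
    consult_dur2 = consult_dur2,
    needs_exam = needs_exam,
    exam_dur = exam_dur,
    pharm_dur = pharm_dur,
    stringsAsFactors = FALSE)
  out
}

#' The department's 12 weekly consultation sessions
#'
#' Returns the default weekly roster: five sports-team sessions, four
#' trauma-team sessions and three hand-and-foot-team sessions.  Per-session
#' arrival rates and patient counts are not publicly available for the
#' study department, so these parameters are package defaults: they anchor
#' the mean consultation process to roughly the observed 14-minute total
#' service time and are sized so that baseline simulated mean waits fall
#' in the observed 63-151 minute range across sessions.  Every field is
#' overridable through [session_config()].
#'
#' @return list of 12 [session_config()] objects.
#' @export
default_sessions <- function() {
  teams <- c(rep("sports", 5), rep("trauma", 4), rep("hand_and_foot", 3))
  # heavier sessions (more demand) mimic the observed spread of mean waits
  n_sched <- c(25L, 26L, 20L, 19L, 20L, 24L, 21L, 27L, 20L, 25L, 27L, 21L)
  w_rate <- c(6.25, 6.5, 5, 4.75, 5, 6, 5.25, 6.75, 5, 6.25, 6.75, 5.25)
  lapply(seq_len(12L), function(i)
    session_config(session_id = i, team = teams[i],
                   duration = 4 * 3600,
                   n_scheduled = n_sched[i],
                   walkin_rate = w_rate[i],
                   consult_mean = 480, exam_mean = 600,
                   reg_mean = 120, pharmacy_mean = 120))
}

#' Calibrate a session to a target mean waiting time
#'
#' Adjusts one monotone knob (the walk-in intensity scale or the
#' consultation-mean scale) by bisection on `[0.1, 10]` until the simulated
#' mean waiting time over `reps` replications is within a relative
#' tolerance of the target.  Common random numbers (a fixed seed) make the
#' simulated response a deterministic, nondecreasing function of the knob,
#' so bisection converges; at most 40 steps are taken.
#'
#' This plays the role that a model-building data month plays in practice:
#' tuning the unobserved load parameter until the simulated clinic matches
#' an observed mean wait.
#'
#' @param cfg a [session_config()].
#' @param target_mean_wait target mean waiting time in seconds.
#' @param knob `"walkin_rate_scale"` or `"consult_mean_scale"`.
#' @param tol relative tolerance (default 0.02).
#' @param reps replications per evaluation (default 20).
#' @param seed master seed for the common random numbers.
#' @param policy queue discipline used during calibration.
#' @return the calibrated `session_config`, with an attribute
#'   `"calibration"` carrying the fitted scale, achieved mean wait and
#'   number of bisection steps.
#' @export
calibrate <- function(cfg, target_mean_wait,
                      knob = c("walkin_rate_scale", "consult_mean_scale"),
                      tol = 0.02, reps = 20L, seed = 1L,
                      policy = policy_spec("baseline_alternating")) {
  knob <- match.arg(knob)
  if (tol <= 0) stop("tol must be > 0")
  if (target_mean_wait <= 0) stop("target_mean_wait must be > 0")
  f <- function(scale) {
    cfg[[knob]] <- scale
    st <- evaluate_policy(cfg, policy, reps = reps, seed = seed)
    st$mean_waiting
  }
  lo <- 0.1; hi <- 10
  flo <- f(lo); fhi <- f(hi)
  if (target_mean_wait < flo || target_mean_wait > fhi)
    stop(sprintf(paste0(
      "target mean wait %.1f s unreachable with knob '%s' in [0.1, 10]: ",
      "achieved %.1f s at 0.1 and %.1f s at 10"),
      target_mean_wait, knob, flo, fhi))
  best <- NULL
  for (i in seq_len(40L)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (is.null(best) || abs(fm - target_mean_wait) < abs(best$achieved -
                                                          target_mean_wait))
      best <- list(scale = mid, achieved = fm, steps = i)
    if (abs(fm - target_mean_wait) / target_mean_wait <= tol) {
      best <- list(scale = mid, achieved = fm, steps = i)
      break
    }
    if (fm < target_mean_wait) lo <- mid else hi <- mid
  }
  if (abs(best$achieved - target_mean_wait) / target_mean_wait > tol)
    stop(sprintf(
      "calibration did not reach target %.1f s within tol %.3g (best %.1f s)",
      target_mean_wait, tol, best$achieved))
  cfg[[knob]] <- best$scale
  attr(cfg, "calibration") <- best
  cfg
}
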