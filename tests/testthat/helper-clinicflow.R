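# shared fixtures and independent oracles, all built in code

# M/M/1-reducible clinic: walk-ins only, exponential consultations, no
# registration / examination / pharmacy delay, no move time
mm1_config <- function(lambda_per_h = 6, consult_mean = 480,
                       duration = 8 * 3600) {
  session_config(n_scheduled = 0L, walkin_rate = lambda_per_h,
                 duration = duration,
                 reg_mean = 0, pharmacy_mean = 0, move_s = 0,
                 exam_rate = 0, late_rate = 0, no_show_rate = 0,
                 special_rate = 0,
                 consult_mean = consult_mean, consult_dist = "exponential")
}

# independent terminating M/M/1 oracle: Lindley recursion over a Poisson
# arrival stream on [0, T]; returns the per-customer mean queue wait of one
# replication (NA if no arrivals)
lindley_mm1 <- function(lambda, mu, T) {
  t <- 0; arr <- numeric(0)
  repeat {
    t <- t + rexp(1, lambda)
    if (t >= T) break
    arr[length(arr) + 1L] <- t
  }
  n <- length(arr)
  if (n == 0L) return(NA_real_)
  S <- rexp(n, mu)
  W <- numeric(n)
  if (n > 1L) for (i in 2:n)
    W[i] <- max(0, W[i - 1L] + S[i - 1L] - (arr[i] - arr[i - 1L]))
  mean(W)
}

# hand-built patient populations for deterministic flow tests
make_patients <- function(arrival, ptype, consult = 300, consult2 = consult,
                          special = FALSE, late = FALSE, no_show = FALSE,
                          appointment = NA_real_, reg = 0, exam = FALSE,
                          exam_dur = 0, pharm = 0) {
  n <- length(arrival)
  data.frame(
    patient_id = seq_len(n),
    ptype = rep_len(ptype, n),
    special = rep_len(special, n),
    age = rep_len(40, n),
    appointment_s = rep_len(appointment, n),
    arrival_s = arrival,
    late = rep_len(late, n),
    no_show = rep_len(no_show, n),
    reg_number = seq_len(n),
    reg_dur = rep_len(reg, n),
    consult_dur1 = rep_len(consult, n),
    consult_dur2 = rep_len(consult2, n),
    needs_exam = rep_len(exam, n),
    exam_dur = rep_len(exam_dur, n),
    pharm_dur = rep_len(pharm, n),
    stringsAsFactors = FALSE)
}

# randomized small sessions for rule-property sweeps
random_scenario <- function(i) {
  set.seed(1000L + i)
  session_config(
    session_id = 1L,
    duration = 2 * 3600,
    n_scheduled = sample(4:10, 1),
    walkin_rate = runif(1, 2, 7),
    late_rate = runif(1, 0, 0.5),
    lateness_mean = runif(1, 300, 1800),
    no_show_rate = runif(1, 0, 0.3),
    special_rate = runif(1, 0, 0.3),
    exam_rate = runif(1, 0, 0.5),
    reg_mean = runif(1, 0, 240),
    consult_mean = runif(1, 180, 600),
    exam_mean = runif(1, 120, 900),
    pharmacy_mean = runif(1, 0, 240),
    move_s = sample(c(0, 30, 60), 1),
    n_doctors = sample(1:2, 1, prob = c(0.8, 0.2)))
}

.path_cols <- c("arrival_s", "reg_start", "reg_end", "queue_join",
                "consult1_start", "consult1_end", "exam_queue_join",
                "exam_start", "exam_end", "return_join", "consult2_start",
                "consult2_end", "pharmacy_queue_join", "pharmacy_start",
                "pharmacy_end", "departure")

trail_monotone_ok <- function(sim) {
  m <- as.matrix(sim$trail[, .path_cols])
  for (r in seq_len(nrow(m))) {
    v <- m[r, ]; v <- v[!is.na(v)]
    if (is.unsorted(v)) return(FALSE)
  }
  TRUE
}

conservation_ok <- function(sim) {
  cn <- sim$counts
  cn["generated"] == cn["departed"] + cn["no_show"] + cn["dropped_at_close"]
}

# no first-visit dispatch of a non-special patient while a special patient
# is waiting (in the waiting room or returned from examination)
special_priority_ok <- function(sim) {
  tr <- sim$trail
  sp <- which(tr$special)
  if (!length(sp)) return(TRUE)
  t1 <- tr$consult1_start
  for (p in which(!tr$special & !is.na(t1))) {
    t <- t1[p]
    w1 <- tr$queue_join[sp] < t & (is.na(t1[sp]) | t1[sp] > t)
    wr <- !is.na(tr$return_join[sp]) & tr$return_join[sp] < t &
      (is.na(tr$consult2_start[sp]) | tr$consult2_start[sp] > t)
    if (any(w1, na.rm = TRUE) || any(wr, na.rm = TRUE)) return(FALSE)
  }
  TRUE
}

# every late (non-special) patient either had >= 3 dispatches between
# check-in and service, or was served by the non-idling fallback with no
# other eligible patient waiting
late_rule_ok <- function(sim) {
  log <- sim$log; tr <- sim$trail
  cs <- log[log$kind == "consult_start", ]
  lc <- log[log$kind == "late_checkin", ]
  blocked_at <- function(q, upto_seq) {
    sq <- lc$seq[lc$patient_id == q]
    if (!length(sq)) return(FALSE)
    sum(cs$seq > sq[1] & cs$seq < upto_seq) < 3L
  }
  for (p in which(tr$late & !tr$special & tr$status == "departed")) {
    sq_ci <- lc$seq[lc$patient_id == p][1]
    t <- tr$consult1_start[p]
    own <- cs$seq[cs$patient_id == p & cs$time_s == t][1]
    if (is.na(own)) return(FALSE)
    k <- sum(cs$seq > sq_ci & cs$seq < own)
    if (k >= 3L) next
    for (q in seq_len(nrow(tr))[-p]) {
      w1 <- !is.na(tr$queue_join[q]) && tr$queue_join[q] < t &&
        (is.na(tr$consult1_start[q]) || tr$consult1_start[q] > t)
      wr <- !is.na(tr$return_join[q]) && tr$return_join[q] < t &&
        (is.na(tr$consult2_start[q]) || tr$consult2_start[q] > t)
      if (!w1 && !wr) next
      eligible <- TRUE
      if (w1 && tr$late[q] && !tr$special[q] && blocked_at(q, own))
        eligible <- FALSE
      if (eligible) return(FALSE)
    }
  }
  TRUE
}

# whenever the alternation-preferred class has an eligible waiting patient,
# a plain (non-special, first-visit) dispatch must take that class
alternation_ok <- function(sim) {
  log <- sim$log; tr <- sim$trail
  cs <- log[log$kind == "consult_start", ]
  lc <- log[log$kind == "late_checkin", ]
  last <- "none"
  for (i in seq_len(nrow(cs))) {
    p <- cs$patient_id[i]; t <- cs$time_s[i]
    visit2 <- !is.na(tr$consult2_start[p]) && tr$consult2_start[p] == t &&
      !(tr$consult1_start[p] == t)  # distinguish zero-duration edge
    if (tr$special[p] || visit2) next
    cls <- tr$ptype[p]
    pref <- if (last == "walk_in") "scheduled" else "walk_in"
    if (cls != pref) {
      # only legal when the preferred class had no eligible waiting patient
      cand <- which(tr$ptype == pref & !tr$special)
      elig <- FALSE
      for (q in cand) {
        if (is.na(tr$queue_join[q]) || tr$queue_join[q] >= t) next
        if (!is.na(tr$consult1_start[q]) && tr$consult1_start[q] <= t) next
        if (tr$late[q]) {
          sq <- lc$seq[lc$patient_id == q][1]
          if (!is.na(sq) && sum(cs$seq > sq & cs$seq < cs$seq[i]) < 3L) next
        }
        elig <- TRUE; break
      }
      if (elig) return(FALSE)
    }
    last <- cls
  }
  TRUE
}
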