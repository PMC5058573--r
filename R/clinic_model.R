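#' Simulate one terminating consultation session
#'
#' Runs the full patient flow of the mixed-registration clinic as a
#' discrete-event simulation: walk-in patients queue at the registration
#' counter and then join the waiting room; scheduled patients go directly
#' to the waiting room; an idle doctor receives the next patient from the
#' queue discipline in `policy`; after a first consultation the patient
#' may be sent to the examination center (probability `exam_rate`) and
#' then returns to the same doctor's queue as a returning patient; every
#' consulted patient finally passes the pharmacy and departs.
#'
#' The run is terminating: the clinic starts empty, admissions stop at
#' `cfg$duration`, and every patient already checked in is served to
#' completion (the clock drains past the session end if needed).
#' Scheduled patients whose late arrival falls after the session end are
#' dropped at close; no-shows are never admitted.
#'
#' @param cfg a [session_config()].
#' @param policy a [policy_spec()].
#' @param seed master seed (ignored when `streams` is given).
#' @param streams a [random_streams()] object; same streams imply a
#'   byte-identical event log.
#' @param patients optional pre-generated population from
#'   [generate_arrivals()]; by default generated from `streams`.
#' @param keep_log keep the full event log (set `FALSE` in tight
#'   replication loops).
#' @return an object of class `clinic_session`: a list with the patient
#'   `trail` (one row per patient, every timestamp plus derived waiting
#'   and throughput seconds), the event `log`, per-doctor busy intervals
#'   and `utilization`, conservation `counts`, and a per-run `summary`.
#' @export
simulate_session <- function(cfg, policy = policy_spec("baseline_alternating"),
                             seed = 1L, streams = NULL, patients = NULL,
                             keep_log = TRUE) {
  if (is.null(streams)) streams <- random_streams(as.integer(seed))
  if (is.null(patients)) patients <- generate_arrivals(cfg, streams)
  if (anyDuplicated(patients$patient_id))
    stop("duplicate admission of patient id ",
         patients$patient_id[duplicated(patients$patient_id)][1])
  n <- nrow(patients)
  until <- cfg$duration
  move <- cfg$move_s

  arrival <- patients$arrival_s
  walkin <- patients$ptype == "walk_in"
  special <- patients$special
  late <- patients$late
  no_show <- patients$no_show
  reg_dur <- patients$reg_dur
  cdur1 <- patients$consult_dur1
  cdur2 <- patients$consult_dur2
  needs_exam <- patients$needs_exam
  exam_dur <- patients$exam_dur
  pharm_dur <- patients$pharm_dur

  ecm <- if (!is.null(cfg$consult_mean_by_class))
    cfg$consult_mean_by_class * cfg$consult_mean_scale
  else c(walk_in = cfg$consult_mean, scheduled = cfg$consult_mean) *
    cfg$consult_mean_scale

  na <- rep(NA_real_, n)
  reg_start <- na; reg_end <- na; queue_join <- na
  c1_start <- na; c1_end <- na
  exq_join <- na; ex_start <- na; ex_end <- na; ret_join <- na
  c2_start <- na; c2_end <- na
  phq_join <- na; ph_start <- na; ph_end <- na; depart <- na
  admitted <- logical(n); dropped <- logical(n)

  # stations: simple FIFO queues with head pointers
  reg_q <- integer(8L); reg_len <- 0L; reg_head <- 1L; reg_busy <- 0L
  ex_q <- integer(8L); ex_len <- 0L; ex_head <- 1L; ex_busy <- 0L
  ph_q <- integer(8L); ph_len <- 0L; ph_head <- 1L; ph_busy <- 0L

  D <- cfg$n_doctors
  doc_busy <- logical(D); doc_cstart <- numeric(D)
  bi_doc <- integer(64L); bi_start <- numeric(64L); bi_end <- numeric(64L)
  bi_n <- 0L

  qs <- new_queue_state(n)
  cal <- new_calendar(max(2L * n, 16L))

  # event log (grown by doubling)
  lg_cap <- max(8L * n, 64L)
  lg_t <- numeric(lg_cap); lg_kind <- character(lg_cap)
  lg_pid <- integer(lg_cap); lg_res <- integer(lg_cap)
  lg_detail <- character(lg_cap); lg_n <- 0L
  log_ev <- function(t, kind, pid = NA_integer_, res = NA_integer_,
                     detail = "") {
    m <- lg_n + 1L
    if (m > length(lg_t)) {
      g <- 2L * length(lg_t)
      length(lg_t) <<- g; length(lg_kind) <<- g
      length(lg_pid) <<- g; length(lg_res) <<- g; length(lg_detail) <<- g
    }
    lg_t[m] <<- t; lg_kind[m] <<- kind
    lg_pid[m] <<- as.integer(pid); lg_res[m] <<- as.integer(res)
    lg_detail[m] <<- detail
    lg_n <<- m
  }

  push_q <- function(qname, pid) {
    # qname in reg/ex/ph; returns nothing, mutates enclosing vectors
    len <- get(paste0(qname, "_len")) + 1L
    v <- get(paste0(qname, "_q"))
    if (len > length(v)) length(v) <- 2L * length(v)
    v[len] <- pid
    assign(paste0(qname, "_q"), v, inherits = TRUE)
    assign(paste0(qname, "_len"), len, inherits = TRUE)
  }
  pop_q <- function(qname) {
    h <- get(paste0(qname, "_head")); len <- get(paste0(qname, "_len"))
    if (h > len) return(NA_integer_)
    pid <- get(paste0(qname, "_q"))[h]
    assign(paste0(qname, "_head"), h + 1L, inherits = TRUE)
    pid
  }

  clock <- 0

  try_reg <- function() {
    while (reg_busy < cfg$reg_capacity) {
      pid <- pop_q("reg")
      if (is.na(pid)) break
      reg_busy <<- reg_busy + 1L
      reg_start[pid] <<- clock
      log_ev(clock, "registration_start", pid)
      schedule(cal, clock + reg_dur[pid], "registration_done", pid,
               clock = clock)
    }
  }
  try_exam <- function() {
    while (ex_busy < cfg$exam_capacity) {
      pid <- pop_q("ex")
      if (is.na(pid)) break
      ex_busy <<- ex_busy + 1L
      ex_start[pid] <<- clock
      log_ev(clock, "exam_start", pid)
      schedule(cal, clock + exam_dur[pid], "exam_done", pid, clock = clock)
    }
  }
  try_pharm <- function() {
    while (ph_busy < cfg$pharmacy_capacity) {
      pid <- pop_q("ph")
      if (is.na(pid)) break
      ph_busy <<- ph_busy + 1L
      ph_start[pid] <<- clock
      log_ev(clock, "pharmacy_start", pid)
      schedule(cal, clock + pharm_dur[pid], "pharmacy_done", pid,
               clock = clock)
    }
  }
  try_dispatch <- function() {
    repeat {
      d <- which(!doc_busy)
      if (!length(d)) break
      d <- d[1L]
      pid <- next_patient(qs, policy, clock, expected_consult = ecm)
      if (is.na(pid)) break
      if (doc_busy[d]) stop("internal: consult dispatched to a busy doctor")
      visit1 <- is.na(c1_start[pid])
      if (visit1) c1_start[pid] <<- clock else c2_start[pid] <<- clock
      log_ev(clock, "consult_start", pid, d, policy$name)
      doc_busy[d] <<- TRUE
      doc_cstart[d] <<- clock
      dur <- if (visit1) cdur1[pid] else cdur2[pid]
      schedule(cal, clock + dur, "consult_end", pid, d, clock = clock)
    }
  }
  join_consult <- function(pid, returning = FALSE) {
    if (returning) ret_join[pid] <<- clock else queue_join[pid] <<- clock
    class <- if (special[pid]) "special"
             else if (returning) "returning"
             else if (walkin[pid]) "walk_in" else "scheduled"
    blocked <- !returning && !special[pid] && late[pid]
    qs_add(qs, pid, class, clock, late_blocked = blocked)
    try_dispatch()
  }

  # feed arrivals to the calendar lazily (they are known and sorted), so
  # the heap stays small regardless of session size
  dropped[!no_show & arrival >= until] <- TRUE
  arr_ids <- which(!no_show & arrival < until)
  arr_ids <- arr_ids[order(arrival[arr_ids], arr_ids)]
  arr_next <- 1L
  feed_arrival <- function() {
    if (arr_next <= length(arr_ids)) {
      i <- arr_ids[arr_next]
      arr_next <<- arr_next + 1L
      schedule(cal, arrival[i], "arrival", i, clock = clock)
    }
  }
  feed_arrival()
  schedule(cal, until, "session_end")
  log_ev(0, "session_start")

  repeat {
    ev <- next_event(cal)
    if (is.null(ev)) break
    if (ev$time < clock) stop("internal: clock moved backwards")
    clock <- ev$time
    pid <- ev$pid
    switch(ev$kind,
      arrival = {
        if (admitted[pid]) stop("duplicate admission of patient id ", pid)
        admitted[pid] <- TRUE
        feed_arrival()
        log_ev(clock, "arrival", pid)
        if (walkin[pid]) {
          push_q("reg", pid)
          try_reg()
        } else {
          if (late[pid]) log_ev(clock, "late_checkin", pid)
          join_consult(pid)
        }
      },
      registration_done = {
        reg_busy <- reg_busy - 1L
        reg_end[pid] <- clock
        log_ev(clock, "registration_done", pid)
        join_consult(pid)
        try_reg()
      },
      consult_end = {
        d <- ev$res
        doc_busy[d] <- FALSE
        bi_n <- bi_n + 1L
        if (bi_n > length(bi_doc)) {
          g <- 2L * length(bi_doc)
          length(bi_doc) <- g; length(bi_start) <- g; length(bi_end) <- g
        }
        bi_doc[bi_n] <- d; bi_start[bi_n] <- doc_cstart[d]
        bi_end[bi_n] <- clock
        log_ev(clock, "consult_end", pid, d)
        first <- is.na(c1_end[pid])
        if (first) {
          c1_end[pid] <- clock
          if (needs_exam[pid]) {
            schedule(cal, clock + move, "exam_arrive", pid, clock = clock)
          } else {
            schedule(cal, clock + move, "pharmacy_arrive", pid, clock = clock)
          }
        } else {
          c2_end[pid] <- clock
          schedule(cal, clock + move, "pharmacy_arrive", pid, clock = clock)
        }
        try_dispatch()
      },
      exam_arrive = {
        exq_join[pid] <- clock
        push_q("ex", pid)
        try_exam()
      },
      exam_done = {
        ex_busy <- ex_busy - 1L
        ex_end[pid] <- clock
        log_ev(clock, "exam_done", pid)
        schedule(cal, clock + move, "return_join", pid, clock = clock)
        try_exam()
      },
      return_join = {
        join_consult(pid, returning = TRUE)
      },
      pharmacy_arrive = {
        phq_join[pid] <- clock
        push_q("ph", pid)
        try_pharm()
      },
      pharmacy_done = {
        ph_busy <- ph_busy - 1L
        ph_end[pid] <- clock
        log_ev(clock, "pharmacy_done", pid)
        depart[pid] <- clock
        log_ev(clock, "departure", pid)
        try_pharm()
      },
      session_end = {
        log_ev(clock, "session_end")
      },
      stop("internal: unknown event kind '", ev$kind, "'"))
  }

  z <- function(x) ifelse(is.na(x), 0, x)
  wait_s <- z(reg_start - arrival) * walkin +
    z(c1_start - queue_join) +
    z(ex_start - exq_join) +
    z(c2_start - ret_join) +
    z(ph_start - phq_join)
  examined <- !is.na(ex_start)
  service_s <- z(reg_end - reg_start) + z(c1_end - c1_start) +
    z(c2_end - c2_start) + z(ex_end - ex_start) + z(ph_end - ph_start)
  move_s_tot <- move * (1 + 2 * examined) * !is.na(depart)
  throughput_s <- depart - arrival
  status <- ifelse(no_show, "no_show",
            ifelse(dropped, "dropped_at_close", "departed"))
  wait_s[status != "departed"] <- NA_real_

  trail <- data.frame(
    patient_id = patients$patient_id, ptype = patients$ptype,
    special = special, age = patients$age, late = late,
    reg_number = patients$reg_number, status = status,
    appointment_s = patients$appointment_s, arrival_s = arrival,
    reg_start = reg_start, reg_end = reg_end, queue_join = queue_join,
    consult1_start = c1_start, consult1_end = c1_end,
    exam_queue_join = exq_join, exam_start = ex_start, exam_end = ex_end,
    return_join = ret_join,
    consult2_start = c2_start, consult2_end = c2_end,
    pharmacy_queue_join = phq_join, pharmacy_start = ph_start,
    pharmacy_end = ph_end, departure = depart,
    waiting_s = wait_s, service_s = service_s, move_s = move_s_tot,
    throughput_s = throughput_s,
    stringsAsFactors = FALSE)

  busy <- data.frame(doctor = bi_doc[seq_len(bi_n)],
                     start = bi_start[seq_len(bi_n)],
                     end = bi_end[seq_len(bi_n)])
  util <- vapply(seq_len(D), function(d) {
    b <- busy[busy$doctor == d, , drop = FALSE]
    horizon <- max(until, if (nrow(b)) max(b$end) else 0)
    utilization(b, horizon)
  }, numeric(1))

  dep <- status == "departed"
  counts <- c(generated = n, departed = sum(dep), no_show = sum(no_show),
              dropped_at_close = sum(dropped))

  log <- NULL
  if (keep_log) {
    idx <- seq_len(lg_n)
    log <- data.frame(time_s = lg_t[idx], seq = idx, kind = lg_kind[idx],
                      patient_id = lg_pid[idx], resource_id = lg_res[idx],
                      detail = lg_detail[idx], stringsAsFactors = FALSE)
  }

  structure(list(
    config = cfg, policy = policy, trail = trail, log = log,
    doctors = list(busy = busy, utilization = util),
    counts = counts,
    summary = list(
      mean_waiting = if (any(dep)) mean(wait_s[dep]) else NA_real_,
      mean_throughput = if (any(dep)) mean(throughput_s[dep]) else NA_real_,
      mean_utilization = mean(util))),
    class = "clinic_session")
}

#' Total in-queue time of a departed patient
#'
#' The sum of all in-queue intervals (registration queue, consultation
#' queue on each visit, examination queue, pharmacy queue), excluding
#' service and move time.  For every departed patient,
#' `throughput = waiting + service + move`.
#'
#' @param session a [simulate_session()] result.
#' @param patient_id integer patient id.
#' @return waiting time in seconds.
#' @export
waiting_time <- function(session, patient_id) {
  row <- session$trail[session$trail$patient_id == patient_id, ,
                       drop = FALSE]
  if (!nrow(row)) stop("unknown patient id ", patient_id)
  if (row$status != "departed")
    stop("patient ", patient_id, " has not departed (status: ", row$status,
         "); waiting time is undefined")
  row$waiting_s
}

#' Doctor utilization
#'
#' Fraction of the session a doctor spends in consultation: the sum of
#' busy-interval lengths divided by the session duration.  When the
#' session drains past its scheduled end, the overrun extends the
#' denominator, keeping the value in `[0, 1]`.
#'
#' @param busy data frame of busy intervals with columns `start`, `end`.
#' @param session_duration denominator in seconds (> 0).
#' @return fraction in `[0, 1]`.
#' @export
utilization <- function(busy, session_duration) {
  if (session_duration <= 0)
    stop("session_duration must be > 0")
  if (!nrow(busy)) return(0)
  sum(busy$end - busy$start) / session_duration
}

#' @export
print.clinic_session <- function(x, ...) {
  cat("<clinic_session> session", x$config$session_id,
      "| policy:", x$policy$name, "\n")
  cat(sprintf("  patients: %d generated, %d departed, %d no-show, %d dropped\n",
              x$counts["generated"], x$counts["departed"],
              x$counts["no_show"], x$counts["dropped_at_close"]))
  cat(sprintf("  mean waiting %.1f min | mean throughput %.1f min | utilization %.1f%%\n",
              x$summary$mean_waiting / 60, x$summary$mean_throughput / 60,
              100 * x$summary$mean_utilization))
  invisible(x)
}

#' Write a patient trail to CSV
#'
#' One row per patient with every timestamp plus derived waiting and
#' throughput seconds.
#'
#' @param session a [simulate_session()] result.
#' @param path output file path.
#' @return (invisibly) `path`.
#' @export
write_patient_trail <- function(session, path) {
  utils::write.csv(session$trail, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
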