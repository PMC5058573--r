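#' Specify a queue discipline
#'
#' The registered disciplines are:
#' \describe{
#'   \item{`baseline_alternating`}{the department's house rule: one walk-in
#'     patient, then one scheduled patient, alternating; non-idling when
#'     the preferred class queue is empty.}
#'   \item{`fifo`}{strict first-come-first-served by waiting-room join
#'     time, ignoring registration-number parity.}
#'   \item{`sps_first`}{shortest-expected-consultation-first: the class
#'     with the smaller expected consultation mean is served first (the
#'     SPT-style rule reported to perform best in mixed-registration
#'     clinics); expectations, not realized durations, are used since a
#'     realized duration is unknown before dispatch.}
#'   \item{`block_interval`}{serve the classes in alternating blocks of
#'     `block_size` patients instead of one-by-one.}
#' }
#'
#' Three house rules are invariant under every discipline: special
#' patients (over 85, strictly, or with a special condition) always have
#' first priority; patients returning from examination are served before
#' new patients but after special patients; and a late scheduled patient
#' is ineligible until three subsequent patients have been seen.
#'
#' @param name discipline name.
#' @param ... discipline parameters (`block_size` for `block_interval`,
#'   default 2).
#' @return an object of class `policy_spec`.
#' @export
policy_spec <- function(name = c("baseline_alternating", "fifo",
                                 "sps_first", "block_interval"), ...) {
  name <- match.arg(name)
  params <- list(...)
  if (name == "block_interval" && is.null(params$block_size))
    params$block_size <- 2L
  structure(list(name = name, params = params), class = "policy_spec")
}

#' @export
print.policy_spec <- function(x, ...) {
  cat("<policy:", x$name)
  if (length(x$params))
    cat(" | ", paste(names(x$params), unlist(x$params), sep = "=",
                     collapse = ", "))
  cat(">\n")
  invisible(x)
}

#' Create an empty partitioned waiting room
#'
#' The waiting room is partitioned into four FIFO queues (special,
#' returning, walk-in, scheduled) plus the alternation pointer
#' (`last_served`) and the late-postponement trackers.  A patient appears
#' in exactly one queue.
#'
#' @param n upper bound on patient ids (storage hint).
#' @return an object of class `queue_state`.
#' @export
new_queue_state <- function(n = 64L) {
  qs <- new.env(parent = emptyenv())
  n <- max(as.integer(n), 1L)
  for (q in c("special", "returning", "walk_in", "scheduled")) {
    qs[[q]] <- integer(8L)
    qs[[paste0(q, "_len")]] <- 0L
    qs[[paste0(q, "_head")]] <- 1L
  }
  qs$removed <- logical(n)
  qs$late_blocked <- logical(n)
  qs$late_count <- integer(n)
  qs$join_time <- numeric(n)
  qs$late_active <- integer(0)
  qs$last_served <- "none"
  qs$block_class <- "walk_in"
  qs$block_count <- 0L
  class(qs) <- "queue_state"
  qs
}

.qs_grow <- function(qs, pid) {
  m <- length(qs$removed)
  if (pid > m) {
    m2 <- max(2L * m, pid)
    length(qs$removed) <- m2; qs$removed[is.na(qs$removed)] <- FALSE
    length(qs$late_blocked) <- m2
    qs$late_blocked[is.na(qs$late_blocked)] <- FALSE
    length(qs$late_count) <- m2; qs$late_count[is.na(qs$late_count)] <- 0L
    length(qs$join_time) <- m2
  }
}

#' Enqueue a waiting patient
#'
#' @param qs a [new_queue_state()].
#' @param pid integer patient id.
#' @param class one of `"special"`, `"returning"`, `"walk_in"`,
#'   `"scheduled"`.
#' @param join_time waiting-room join time in seconds.
#' @param late_blocked `TRUE` for a late scheduled patient, who becomes
#'   eligible only after three subsequent dispatches.
#' @return (invisibly) `qs`.
#' @export
qs_add <- function(qs, pid, class, join_time = 0, late_blocked = FALSE) {
  stopifnot(class %in% c("special", "returning", "walk_in", "scheduled"))
  .qs_grow(qs, pid)
  len <- qs[[paste0(class, "_len")]] + 1L
  if (len > length(qs[[class]]))
    length(qs[[class]]) <- 2L * length(qs[[class]])
  v <- qs[[class]]; v[len] <- pid; qs[[class]] <- v
  qs[[paste0(class, "_len")]] <- len
  qs$join_time[pid] <- join_time
  qs$removed[pid] <- FALSE
  if (late_blocked) {
    qs$late_blocked[pid] <- TRUE
    qs$late_count[pid] <- 0L
    qs$late_active <- c(qs$late_active, pid)
  }
  invisible(qs)
}

#' Number of waiting patients
#' @param qs a queue state.
#' @return integer count over the four class queues.
#' @export
qs_size <- function(qs) {
  tot <- 0L
  for (q in c("special", "returning", "walk_in", "scheduled")) {
    v <- qs[[q]]; len <- qs[[paste0(q, "_len")]]
    h <- qs[[paste0(q, "_head")]]
    if (h <= len) tot <- tot + sum(!qs$removed[v[h:len]])
  }
  tot
}

# first eligible pid in a class queue, advancing the head past removals;
# returns NA if none
.q_first <- function(qs, class, skip_late = TRUE) {
  v <- qs[[class]]
  len <- qs[[paste0(class, "_len")]]
  h <- qs[[paste0(class, "_head")]]
  while (h <= len && qs$removed[v[h]]) h <- h + 1L
  qs[[paste0(class, "_head")]] <- h
  i <- h
  while (i <= len) {
    pid <- v[i]
    if (!qs$removed[pid] && !(skip_late && qs$late_blocked[pid]))
      return(pid)
    i <- i + 1L
  }
  NA_integer_
}

.other_class <- function(class) {
  if (class == "walk_in") "scheduled" else "walk_in"
}

#' Dispatch the next patient to an idle doctor
#'
#' Selection order: (1) head of the special queue; else (2) head of the
#' returning queue; else (3) a walk-in or scheduled patient chosen by the
#' discipline in `policy`.  Late-blocked patients are skipped (they keep
#' their FIFO position); every dispatch, of any class, advances all active
#' late trackers by one, and a tracker reaching 3 makes its patient
#' eligible.  The alternation pointer is updated only when a walk-in or
#' scheduled patient is dispatched.
#'
#' Non-idling guarantee: if the only waiting patients are late-blocked,
#' the first of them is served anyway — with nobody else in the room the
#' "following three patients" will never materialize, and an idle doctor
#' facing a waiting patient is not clinic practice.
#'
#' @param qs a [new_queue_state()].
#' @param policy a [policy_spec()].
#' @param clock current time in seconds (recorded only).
#' @param expected_consult named vector `c(walk_in = , scheduled = )` of
#'   expected consultation means in seconds (used by `sps_first`).
#' @return the dispatched patient id, or `NA` if no patient is eligible.
#' @export
next_patient <- function(qs, policy = policy_spec("baseline_alternating"),
                         clock = 0, expected_consult = NULL) {
  pid <- .q_first(qs, "special", skip_late = FALSE)
  picked_class <- "special"
  if (is.na(pid)) {
    pid <- .q_first(qs, "returning", skip_late = FALSE)
    picked_class <- "returning"
  }
  if (is.na(pid)) {
    sel <- switch(policy$name,
      baseline_alternating = {
        pref <- if (qs$last_served == "walk_in") "scheduled" else "walk_in"
        p <- .q_first(qs, pref)
        if (is.na(p)) {
          pref <- .other_class(pref)
          p <- .q_first(qs, pref)
        }
        list(pid = p, class = pref)
      },
      fifo = {
        pw <- .q_first(qs, "walk_in")
        ps <- .q_first(qs, "scheduled")
        if (is.na(pw) && is.na(ps)) list(pid = NA_integer_, class = "walk_in")
        else if (is.na(ps) || (!is.na(pw) &&
                 qs$join_time[pw] <= qs$join_time[ps]))
          list(pid = pw, class = "walk_in")
        else list(pid = ps, class = "scheduled")
      },
      sps_first = {
        ec <- expected_consult
        if (is.null(ec)) ec <- c(walk_in = 1, scheduled = 1)
        first <- if (ec[["walk_in"]] <= ec[["scheduled"]]) "walk_in"
                 else "scheduled"
        p <- .q_first(qs, first)
        if (is.na(p)) {
          first <- .other_class(first)
          p <- .q_first(qs, first)
        }
        list(pid = p, class = first)
      },
      block_interval = {
        k <- policy$params$block_size
        cls <- qs$block_class
        p <- .q_first(qs, cls)
        if (qs$block_count >= k || is.na(p)) {
          other <- .other_class(cls)
          po <- .q_first(qs, other)
          if (!is.na(po)) {
            cls <- other; p <- po
            qs$block_count <- 0L
          }
        }
        if (!is.na(p)) {
          qs$block_class <- cls
          qs$block_count <- qs$block_count + 1L
        }
        list(pid = p, class = cls)
      },
      stop("unregistered policy: ", policy$name))
    pid <- sel$pid
    picked_class <- sel$class
    if (is.na(pid)) {
      # non-idling fallback: only late-blocked patients remain waiting, so
      # "the following three patients" will never be seen; serve the first
      # blocked patient instead of idling the doctor
      pid <- .q_first(qs, "scheduled", skip_late = FALSE)
      picked_class <- "scheduled"
    }
  }
  if (is.na(pid)) return(NA_integer_)
  if (qs$late_blocked[pid]) {
    qs$late_blocked[pid] <- FALSE
    qs$late_active <- qs$late_active[qs$late_active != pid]
  }
  qs$removed[pid] <- TRUE
  if (picked_class %in% c("walk_in", "scheduled"))
    qs$last_served <- picked_class
  # advance every active late tracker; at 3 the patient becomes eligible
  if (length(qs$late_active)) {
    keep <- logical(length(qs$late_active))
    for (i in seq_along(qs$late_active)) {
      p <- qs$late_active[i]
      qs$late_count[p] <- qs$late_count[p] + 1L
      if (qs$late_count[p] >= 3L) qs$late_blocked[p] <- FALSE
      else keep[i] <- TRUE
    }
    qs$late_active <- qs$late_active[keep]
  }
  pid
}

# deterministic per-replication seed, independent of the policy, < 2^31
.rep_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 48271 + r * 16807) %% 2147483647 + 1)
}

#' Evaluate a queue discipline over independent replications
#'
#' Runs `reps` independent terminating replications of one session under
#' the given discipline and summarizes per-replication mean waiting time,
#' throughput time and doctor utilization with 95% Student-t confidence
#' intervals.  Replication `r` uses a seed derived only from
#' `(seed, r)`, never from the policy, so evaluations of different
#' policies at the same seed share identical arrival and service
#' realizations (common random numbers).
#'
#' @param cfg a [session_config()].
#' @param policy a [policy_spec()].
#' @param reps number of replications (>= 2; a confidence interval is
#'   undefined otherwise).
#' @param seed master seed.
#' @return an object of class `session_stats`.
#' @export
evaluate_policy <- function(cfg, policy = policy_spec("baseline_alternating"),
                            reps = 20L, seed = 1L) {
  reps <- as.integer(reps)
  if (reps < 2L)
    stop("reps must be >= 2: a confidence interval is undefined for one ",
         "replication")
  w <- numeric(reps); th <- numeric(reps); u <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_session(cfg, policy,
                            streams = random_streams(.rep_seed(seed, r)),
                            keep_log = FALSE)
    w[r] <- sim$summary$mean_waiting
    th[r] <- sim$summary$mean_throughput
    u[r] <- sim$summary$mean_utilization
  }
  session_stats(cfg$session_id, policy$name,
                data.frame(waiting = w, throughput = th, utilization = u))
}

#' Search a candidate set of disciplines for one session
#'
#' Evaluates each candidate under common random numbers (the same master
#' seed, hence identical arrival and service realizations) and returns the
#' candidate minimizing mean waiting time; ties go to the earlier
#' candidate in the list.
#'
#' @param cfg a [session_config()].
#' @param candidates nonempty list of [policy_spec()] objects.
#' @param reps replications per candidate.
#' @param seed master seed shared by all candidates.
#' @return a list with elements `policy` (the winner), `stats` (its
#'   [session_stats()]) and `all` (every candidate's stats, named by
#'   policy).
#' @export
policy_search <- function(cfg,
                          candidates = list(
                            policy_spec("baseline_alternating"),
                            policy_spec("fifo"),
                            policy_spec("sps_first"),
                            policy_spec("block_interval")),
                          reps = 20L, seed = 1L) {
  if (!length(candidates)) stop("candidates must be nonempty")
  stats <- lapply(candidates, function(p)
    evaluate_policy(cfg, p, reps = reps, seed = seed))
  means <- vapply(stats, function(s) s$mean_waiting, numeric(1))
  best <- which.min(means)  # which.min takes the first on ties
  names(stats) <- vapply(candidates, function(p) p$name, character(1))
  list(policy = candidates[[best]], stats = stats[[best]], all = stats)
}
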