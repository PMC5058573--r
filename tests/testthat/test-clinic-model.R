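cfg0 <- session_config(move_s = 0, reg_mean = 0, pharmacy_mean = 0,
                       exam_rate = 0, special_rate = 0, late_rate = 0,
                       no_show_rate = 0)

test_that("admission paths set waiting-room join times as specified", {
  # walk-in arriving at t=600 with registration d=90 and a free clerk
  pts <- make_patients(600, "walk_in", consult = 100, reg = 90)
  sim <- simulate_session(cfg0, patients = pts,
                          streams = random_streams(1L))
  expect_equal(sim$trail$queue_join, 600 + 90)
  expect_equal(sim$trail$reg_start, 600)
  # on-time scheduled patient joins directly, no registration timestamps
  pts <- make_patients(900, "scheduled", consult = 100, appointment = 900)
  sim <- simulate_session(cfg0, patients = pts,
                          streams = random_streams(1L))
  expect_equal(sim$trail$queue_join, 900)
  expect_true(is.na(sim$trail$reg_start))
  # no-show is never admitted and carries no timestamps
  pts <- make_patients(c(0, 600), "scheduled", consult = 100,
                       no_show = c(FALSE, TRUE))
  sim <- simulate_session(cfg0, patients = pts,
                          streams = random_streams(1L))
  expect_equal(sim$trail$status, c("departed", "no_show"))
  expect_true(is.na(sim$trail$queue_join[2]))
  expect_equal(unname(sim$counts["no_show"]), 1L)
})

test_that("a patient with zero work departs at the arrival instant", {
  pts <- make_patients(1000, "walk_in", consult = 0)
  sim <- simulate_session(cfg0, patients = pts,
                          streams = random_streams(1L))
  expect_equal(sim$trail$departure, 1000)
  expect_equal(sim$trail$waiting_s, 0)
  expect_equal(sim$trail$throughput_s, 0)
})

test_that("an empty session logs only the session markers", {
  cfg <- session_config(n_scheduled = 0, walkin_rate = 0)
  sim <- simulate_session(cfg, seed = 1)
  expect_equal(sim$log$kind, c("session_start", "session_end"))
  expect_equal(unname(sim$counts["generated"]), 0L)
})

test_that("examination re-entry follows the configured decision", {
  base <- function(rate) session_config(move_s = 0, exam_rate = rate,
                                        special_rate = 0, late_rate = 0,
                                        no_show_rate = 0)
  s0 <- simulate_session(base(0), seed = 2)
  expect_true(all(is.na(s0$trail$consult2_start)))
  s1 <- simulate_session(base(1), seed = 2)
  dep <- s1$trail$status == "departed"
  expect_true(all(!is.na(s1$trail$consult2_start[dep])))
  expect_true(all(!is.na(s1$trail$exam_start[dep])))
  # examined patients get exactly two consultation visits, no chains
  expect_true(all(s1$trail$exam_end[dep] <= s1$trail$consult2_start[dep]))
})

test_that("examined fraction matches the binomial oracle", {
  cfg <- session_config(n_scheduled = 10000, duration = 10000 * 60,
                        walkin_rate = 0, exam_rate = 0.3)
  pts <- generate_arrivals(cfg, random_streams(31L))
  phat <- mean(pts$needs_exam)
  expect_lt(abs(phat - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("tandem service arithmetic: second of two twins waits one consult", {
  pts <- make_patients(c(0, 0), "walk_in", consult = 300)
  sim <- simulate_session(cfg0, patients = pts,
                          streams = random_streams(1L))
  expect_equal(sort(sim$trail$waiting_s), c(0, 300))
})

test_that("throughput decomposes into waiting + service + move", {
  for (seed in c(3, 9, 27)) {
    sim <- simulate_session(session_config(), seed = seed)
    tr <- sim$trail[sim$trail$status == "departed", ]
    expect_equal(tr$throughput_s, tr$waiting_s + tr$service_s + tr$move_s,
                 tolerance = 1e-9)
  }
})

test_that("waiting_time accessor guards undeparted patients", {
  pts <- make_patients(c(0, 100), "scheduled", consult = 50,
                       no_show = c(FALSE, TRUE))
  sim <- simulate_session(cfg0, patients = pts,
                          streams = random_streams(1L))
  expect_equal(waiting_time(sim, 1), 0)
  expect_error(waiting_time(sim, 2), "has not departed")
  expect_error(waiting_time(sim, 99), "unknown patient")
})

test_that("utilization is busy time over (possibly drained) session length", {
  busy <- data.frame(start = 0, end = 110.59 * 60)
  expect_equal(utilization(busy, 120 * 60), 0.9216, tolerance = 1e-4)
  expect_equal(utilization(busy[0, ], 100), 0)
  expect_error(utilization(busy, 0), "> 0")
  # full-session back-to-back work gives exactly 1
  pts <- make_patients(c(0, 0), "walk_in", consult = 7200)
  cfg <- session_config(move_s = 0, duration = 4 * 3600)
  sim <- simulate_session(cfg, patients = pts,
                          streams = random_streams(1L))
  expect_equal(sim$doctors$utilization, 1)
})

test_that("duplicate admission is rejected", {
  pts <- make_patients(c(100, 100), "scheduled", consult = 50)
  pts$patient_id <- c(1L, 1L)
  expect_error(
    simulate_session(cfg0, patients = pts, streams = random_streams(1L)),
    "duplicate admission")
})

test_that("late arrivals beyond closing are dropped, the rest drain", {
  pts <- make_patients(c(1000, 5 * 3600), "scheduled", consult = 200,
                       appointment = c(1000, 3 * 3600),
                       late = c(FALSE, TRUE))
  sim <- simulate_session(cfg0, patients = pts,
                          streams = random_streams(1L))
  expect_equal(sim$trail$status, c("departed", "dropped_at_close"))
  expect_equal(unname(sim$counts["dropped_at_close"]), 1L)
  # a patient checked in before close is served past the session end
  cfg <- session_config(move_s = 0, duration = 3600)
  pts <- make_patients(c(3500, 3550), "scheduled", consult = 400)
  sim <- simulate_session(cfg, patients = pts,
                          streams = random_streams(1L))
  expect_equal(sim$trail$status, c("departed", "departed"))
  expect_gt(max(sim$trail$departure), 3600)
})

test_that("time-average queue length is consistent with Little's law", {
  # open single-server queue at rho = 0.8, ~1e4 customers
  cfg <- session_config(n_scheduled = 0, walkin_rate = 200,
                        duration = 50 * 3600, reg_mean = 0,
                        pharmacy_mean = 0, move_s = 0, exam_rate = 0,
                        late_rate = 0, no_show_rate = 0, special_rate = 0,
                        consult_mean = 3600 / 250,
                        consult_dist = "exponential")
  sim <- simulate_session(cfg, seed = 77, keep_log = FALSE)
  tr <- sim$trail
  n <- nrow(tr)
  expect_gt(n, 8000)
  # reconstruct the queue-length trajectory from joins and service starts
  ev <- rbind(data.frame(t = tr$queue_join, d = 1),
              data.frame(t = tr$consult1_start, d = -1))
  ev <- ev[order(ev$t), ]
  horizon <- max(ev$t)
  L_bar <- sum(cumsum(ev$d)[-nrow(ev)] * diff(ev$t)) / horizon
  lambda <- 200 / 3600
  W_bar <- mean(tr$waiting_s)
  expect_equal(L_bar, lambda * W_bar, tolerance = 0.15)
})
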