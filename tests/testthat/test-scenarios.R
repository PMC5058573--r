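test_that("configuration invariants are validated with explicit messages", {
  expect_error(session_config(late_rate = 1.4), "late_rate")
  expect_error(session_config(duration = 0), "duration")
  expect_error(session_config(n_doctors = 0), "n_doctors")
  err <- expect_error(session_config(late_rate = -1, no_show_rate = 2))
  expect_match(conditionMessage(err), "late_rate")
  expect_match(conditionMessage(err), "no_show_rate")
  expect_silent(session_config())
})

test_that("appointment templates space patients as documented", {
  # 10 patients over 3 hours, evenly -> every 18 minutes
  g <- appointment_template(10, 3 * 3600, "even")
  expect_equal(diff(g), rep(18 * 60, 9))
  expect_equal(g[1], 0)
  bw <- appointment_template(6, 3 * 3600, "bailey_welch")
  expect_equal(sum(bw == 0), 2L)   # two patients booked at the start
  expect_length(bw, 6L)
})

test_that("zero walk-in intensity yields only scheduled patients", {
  cfg <- session_config(walkin_rate = 0, n_scheduled = 8)
  pts <- generate_arrivals(cfg, random_streams(3L))
  expect_true(all(pts$ptype == "scheduled"))
  expect_equal(nrow(pts), 8L)
})

test_that("registration numbers carry walk-in/scheduled parity", {
  for (seed in 1:20) {
    pts <- generate_arrivals(session_config(), random_streams(seed))
    expect_true(all(pts$reg_number[pts$ptype == "walk_in"] %% 2 == 1))
    expect_true(all(pts$reg_number[pts$ptype == "scheduled"] %% 2 == 0))
    expect_false(anyDuplicated(pts$reg_number[pts$ptype == "walk_in"]) > 0)
  }
})

test_that("homogeneous walk-in counts match the Poisson oracle", {
  # lambda = 6/h over 2 h: mean count 12; 2000 seeds, 3-sigma band
  cfg <- session_config(n_scheduled = 0, walkin_rate = 6,
                        duration = 2 * 3600)
  counts <- vapply(1:2000, function(s)
    nrow(generate_arrivals(cfg, random_streams(s))), numeric(1))
  expect_lt(abs(mean(counts) - 12), 3 * sqrt(12 / 2000))
  expect_equal(var(counts), 12, tolerance = 0.15)  # Poisson dispersion
})

test_that("thinned nonhomogeneous arrivals honor the intensity profile", {
  prof <- data.frame(from = c(0, 3600), to = c(3600, 7200), rate = c(0, 12))
  cfg <- session_config(n_scheduled = 0, walkin_profile = prof,
                        walkin_rate = 0, duration = 7200)
  pts <- generate_arrivals(cfg, random_streams(17L))
  expect_true(all(pts$arrival_s >= 3600))
  counts <- vapply(1:400, function(s)
    nrow(generate_arrivals(cfg, random_streams(s))), numeric(1))
  expect_lt(abs(mean(counts) - 12), 3 * sqrt(12 / 400))
})

test_that("constant-profile window counts pass a Poisson goodness-of-fit", {
  cfg <- session_config(n_scheduled = 0, walkin_rate = 6,
                        duration = 500 * 3600)
  arr <- generate_arrivals(cfg, random_streams(29L))$arrival_s
  win <- floor(arr / 1800)  # 30-min windows, Poisson(3)
  counts <- tabulate(win + 1L, nbins = 1000L)
  lam <- mean(counts)
  bins <- 0:8
  obs <- vapply(bins, function(k)
    if (k < 8) sum(counts == k) else sum(counts >= 8), numeric(1))
  pr <- c(dpois(0:7, lam), ppois(7, lam, lower.tail = FALSE))
  stat <- sum((obs - 1000 * pr)^2 / (1000 * pr))
  pval <- pchisq(stat, df = length(bins) - 2L, lower.tail = FALSE)
  expect_gt(pval, 0.01)
  # successive windows uncorrelated
  expect_lt(abs(cor(counts[-1000], counts[-1])), 0.1)
})

test_that("the weekly roster has 12 valid sessions with 5/4/3 teams", {
  ss <- default_sessions()
  expect_length(ss, 12L)
  teams <- vapply(ss, function(s) s$team, character(1))
  expect_equal(unname(table(teams)[c("sports", "trauma", "hand_and_foot")]),
               c(5L, 4L, 3L), ignore_attr = TRUE)
  for (s in ss) expect_length(validate_session_config(s), 0L)
  expect_equal(vapply(ss, function(s) s$session_id, integer(1)), 1:12)
})

test_that("policy changes leave arrival realizations untouched", {
  cfg <- session_config()
  rs1 <- random_streams(5L)
  rs2 <- random_streams(5L)
  # consume draws another component might take between replications
  rs_eval(rs2, "consult", function() runif(500))
  p1 <- generate_arrivals(cfg, rs1)
  p2 <- generate_arrivals(cfg, rs2)
  expect_identical(p1$arrival_s, p2$arrival_s)
  expect_identical(p1$no_show, p2$no_show)
  # and whole-run comparison: different policies, same seed, same patients
  s_base <- simulate_session(cfg, policy_spec("baseline_alternating"),
                             seed = 5)
  s_fifo <- simulate_session(cfg, policy_spec("fifo"), seed = 5)
  expect_identical(s_base$trail$arrival_s, s_fifo$trail$arrival_s)
  expect_identical(s_base$trail$consult_dur1, s_fifo$trail$consult_dur1)
})

test_that("calibration reaches a session's own mean wait at scale ~ 1", {
  cfg <- session_config(n_scheduled = 8, walkin_rate = 3,
                        duration = 2 * 3600)
  target <- evaluate_policy(cfg, reps = 8, seed = 4)$mean_waiting
  out <- calibrate(cfg, target, knob = "consult_mean_scale", tol = 0.02,
                   reps = 8, seed = 4)
  cal <- attr(out, "calibration")
  expect_lt(abs(cal$achieved - target) / target, 0.02)
  expect_lt(abs(cal$scale - 1), 0.15)
})

test_that("simulated mean wait is monotone in both calibration knobs", {
  cfg <- session_config(n_scheduled = 8, walkin_rate = 3,
                        duration = 2 * 3600)
  f <- function(knob, s) {
    cfg[[knob]] <- s
    evaluate_policy(cfg, reps = 10, seed = 6)$mean_waiting
  }
  for (knob in c("walkin_rate_scale", "consult_mean_scale")) {
    w <- vapply(c(0.6, 1, 1.6), function(s) f(knob, s), numeric(1))
    expect_false(is.unsorted(w))
  }
})

test_that("unreachable calibration targets report the achieved bracket", {
  cfg <- session_config(n_scheduled = 4, walkin_rate = 1,
                        duration = 2 * 3600)
  err <- expect_error(
    calibrate(cfg, 1e7, knob = "consult_mean_scale", reps = 4, seed = 2))
  expect_match(conditionMessage(err), "unreachable")
  expect_match(conditionMessage(err), "achieved")
})
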