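# clinicflow

`clinicflow` is a discrete-event simulator of a mixed-registration
orthopedic outpatient clinic — the common Asian-hospital setting in which
walk-in patients (who must register on arrival and receive odd queue
numbers) and scheduled patients (who go straight to the waiting room and
receive even numbers) share the same consultation sessions.  Long waits
are endemic in such clinics: a patient typically spends around 14 minutes
being served and well over an hour and a half in queues, so waiting
accounts for almost 90% of the total process time.

The package is written for healthcare operations analysts who want to
evaluate queue-discipline and scheduling changes *before* implementing
them.  It models:

- patient flow through registration, waiting room, consultation,
  examination center (with re-entry to the same doctor) and pharmacy;
- the clinic's house rules: first priority for *special* patients (over
  85 years of age, strictly, or with a special condition), walk-in /
  scheduled alternation (one of each, in turn), and postponement of late
  scheduled arrivals until three subsequent patients have been seen;
- behavioural inputs: no-shows, lateness, nonhomogeneous Poisson walk-in
  arrivals, right-skewed service times;
- alternative disciplines behind one dispatch interface (`fifo`,
  `sps_first` — shortest-expected-consultation-first, `block_interval`)
  and a per-session policy search under common random numbers.

## The statistics at its core

Sessions are *terminating* simulations: the clinic starts empty, stops
admitting at closing time, and drains.  Output analysis is the standard
replication method: for per-replication means `X_1, ..., X_n`, the
session estimate is `X̄ ± t(1-α/2, n-1) · s/√n` at `α = 0.05`.

Before/after comparisons across the 12 weekly consultation sessions use
the paired t-test on per-session mean waits `d_i = before_i − after_i`:

    t = d̄ / (s_d / √n),  dof = n − 1,

with a one-tail p-value in the direction "waiting decreased".  Policy
comparisons reuse identical random streams across candidates (common
random numbers), so observed differences are attributable to the policy,
not to noise.  A single-doctor reduction of the model (Poisson walk-ins,
exponential consultations, no other stations) is validated against the
M/M/1 closed form `Wq = λ / (μ(μ − λ))`.

## Worked example

```r
library(clinicflow)

cfg <- default_sessions()[[1]]            # session 1 of the weekly roster
st  <- evaluate_policy(cfg, reps = 20, seed = 1)
st
#> <session_stats> session 1 | policy baseline_alternating | 20 replications
#>   waiting      119.24 min  [104.90, 133.58]
#>   throughput   136.86 min  [122.07, 151.66]
#>   utilization   98.40 %    [97.79, 99.01]
```

The session waits about two hours on average under the baseline
alternating discipline, with a 95% confidence interval from 20
independent replications; the doctor is busy nearly the whole session.

```r
t2  <- clinic_table2()                    # packaged before/after table
res <- paired_t(hms_to_seconds(t2$before_hms),
                hms_to_seconds(t2$after_hms), t2$session)
res
#>   totals: before 1246.38 min, after 847.22 min (overall 32.03%)
#>   mean difference 1995.8 s | dof 11 | t = 8.405 | one-tail p 2.04e-06
```

The packaged 12-session table shows a 32% overall waiting-time reduction;
the paired t-test (t = 8.4 on 11 degrees of freedom) confirms the
reduction is systematic, not a few lucky sessions.

```r
policy_search(cfg, reps = 10, seed = 1)$policy$name
#> [1] "sps_first"
```

For this session mix the shortest-expected-consultation-first rule wins
the candidate search.

A command-line wrapper is installed as `exec/clinicflow` with subcommands
`run`, `compare`, `tables`, `calibrate` and `policy-search`; scenarios are
YAML documents (see `read_scenario()`).

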