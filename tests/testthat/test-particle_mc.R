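test_that("no binding events occur when the sensor is inert", {
  cfg <- ref_config(k_on = 0)
  log <- suppressWarnings(
    simulate_ions(cfg, mc_config(dt = 5e-5, n_trials = 10, horizon = 0.05,
                                 seed = 1)))
  expect_equal(nrow(log$events), 0L)
})

test_that("ions remain confined for the whole run", {
  ## the core traps any post-reflection escape as an error; a clean run
  ## with a large step relative to the shell exercises the reflections
  cfg <- ref_config(cd = 280)
  expect_silent(simulate_ions(cfg, mc_config(dt = 5e-4, n_trials = 5,
                                             horizon = 0.5, seed = 2)))
})

test_that("sensor-bound interval durations are exponential with mean 1/k_off", {
  cfg <- ref_config(cd = 5)
  log <- suppressWarnings(
    simulate_ions(cfg, mc_config(dt = 2e-5, n_trials = 4000,
                                 horizon = 1, seed = 3)))
  iv <- bound_intervals(log)
  expect_gt(length(iv), 150)
  se <- sd(iv) / sqrt(length(iv))
  expect_lt(abs(mean(iv) - 1 / 15.7), 3 * se)
  ## printed reference: ~0.06 ms
  expect_equal(mean(iv), 0.0637, tolerance = 0.15)
})

test_that("empirical first-passage CDF matches the absorbing analytic curve", {
  cfg <- ref_config(k_on = Inf, k_off = 0)
  log <- simulate_ions(cfg, mc_config(dt = 2e-5, n_trials = 4000,
                                      horizon = 1, seed = 4))
  f <- empirical_fpt(log)
  tg <- 10^seq(-2.5, 0, length.out = 30)
  ana <- invert_numeric(cfg, tg)
  emp <- vapply(tg, function(x) sum(f$fpt <= x) / log$n_trials, numeric(1))
  expect_lt(max(abs(emp - ana)), 0.02)
})

test_that("discretization error in the first-passage CDF shrinks with dt", {
  cfg <- ref_config(k_on = Inf, k_off = 0)
  ks <- vapply(c(8e-5, 2e-5), function(dt) {
    log <- suppressWarnings(
      simulate_ions(cfg, mc_config(dt = dt, n_trials = 3000,
                                   horizon = 0.5, seed = 8)))
    f <- empirical_fpt(log)
    tg <- 10^seq(-2.5, log10(0.5), length.out = 25)
    max(abs(vapply(tg, function(x) sum(f$fpt <= x) / log$n_trials,
                   numeric(1)) - invert_numeric(cfg, tg)))
  }, numeric(1))
  expect_lt(ks[2], ks[1] + 0.01)   # finer step is no worse within noise
  expect_lt(ks[2], 0.025)
})

test_that("single-trial event log gives an indicator step function", {
  ev <- data.frame(trial = 1L, time_ms = 0.3, event = "bind")
  log <- structure(list(events = ev, n_trials = 1L, horizon = 1,
                        config = NULL), class = "mc_event_log")
  cv <- estimate_occupancy(log, c(0.1, 0.2, 0.5, 0.9))
  expect_equal(cv$values, c(0, 0, 1, 1))
  empty <- structure(list(events = ev[0, ], n_trials = 3L, horizon = 1,
                          config = NULL), class = "mc_event_log")
  expect_equal(estimate_occupancy(empty, c(0.1, 0.5))$values, c(0, 0))
})

test_that("multi-ion occupancy with unlimited capacity matches independence", {
  ## N ions released together; the MC mean bound count divided through the
  ## independence formula must agree within Monte Carlo error
  cfg <- ref_config(cd = 5)
  N <- 10
  ent <- lapply(1:300, function(j)
    structure(list(trial = j, times = rep(0, N), r = NULL),
              class = "ion_entry_sequence"))
  log <- suppressWarnings(
    simulate_ions(cfg, mc_config(dt = 2e-5, n_trials = 300,
                                 horizon = 0.08, seed = 5), ent))
  tg <- c(0.005, 0.01, 0.02, 0.05)
  emp <- estimate_occupancy(log, tg)
  ana <- N * occupancy_single(cfg, tg)$values   # mean bound count
  expect_true(all(abs(emp$values - ana) < 3.5 * emp$sem))
})

test_that("the large-step warning fires and the log exports to CSV", {
  cfg <- ref_config()
  expect_warning(simulate_ions(cfg, mc_config(dt = 5e-4, n_trials = 2,
                                              horizon = 0.01, seed = 6)),
                 "rms step")
  log <- simulate_ions(cfg, mc_config(dt = 2e-5, n_trials = 50,
                                      horizon = 0.05, seed = 7))
  f <- tempfile(fileext = ".csv")
  write_event_log_csv(log, f)
  d <- read.csv(f)
  expect_named(d, c("trial", "time_ms", "event"))
  unlink(f)
})

test_that("fixed seeds reproduce event logs exactly", {
  cfg <- ref_config(cd = 5)
  mk <- function() simulate_ions(cfg, mc_config(dt = 5e-5, n_trials = 50,
                                                horizon = 0.1, seed = 99))
  expect_identical(suppressWarnings(mk())$events,
                   suppressWarnings(mk())$events)
})
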