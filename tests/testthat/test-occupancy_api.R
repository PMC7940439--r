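test_that("steady state follows the closed form and its limits", {
  expect_equal(steady_state(ref_config(k_off = 0)), 1)
  expect_equal(steady_state(ref_config(k_on = 0)), 0)
  ## adding a buffer scales the odds by (1 + k_0i/k_i0): EFB gives 41
  p0 <- steady_state(ref_config())
  p1 <- steady_state(ref_config(buffers = list(buffer_preset("EFB"))))
  odds0 <- (1 - p0) / p0
  odds1 <- (1 - p1) / p1
  expect_equal(odds1 / odds0, 41, tolerance = 1e-12)
})

test_that("occupancy curve metrics reproduce published reference values", {
  ## peaks 0.027 -> 0.001 and times 6.1 -> 47.5 us across the CD range,
  ## peak 0.012 near 10 us at the reference distance
  m5 <- curve_metrics(occupancy_single(ref_config(cd = 5)))
  expect_equal(m5$peak, 0.027, tolerance = 0.1)
  expect_equal(m5$time_to_peak_us, 6.1, tolerance = 0.1)
  m95 <- curve_metrics(occupancy_single(ref_config(cd = 95)))
  expect_equal(m95$peak, 0.001, tolerance = 0.4)
  expect_equal(m95$time_to_peak_us, 47.5, tolerance = 0.1)
  m15 <- curve_metrics(occupancy_single(ref_config()))
  expect_equal(m15$peak, 0.012, tolerance = 0.1)
  expect_equal(m15$time_to_peak_us, 10, tolerance = 0.1)
})

test_that("peak occupancy decreases with coupling distance", {
  peaks <- vapply(c(5, 15, 45, 95), function(cd)
    curve_metrics(occupancy_single(ref_config(cd = cd),
                                   default_time_grid(300)))$peak, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("peak occupancy decreases with buffer concentration", {
  tg <- default_time_grid(300)
  peaks <- vapply(c(0, 2, 4), function(conc) {
    bufs <- if (conc == 0) list() else
      list(buffer_spec("EFB", 0, 100, conc, 10))
    max(occupancy_single(ref_config(buffers = bufs), tg)$values)
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("zero-rate sensor yields the identically zero curve", {
  v <- occupancy_single(ref_config(k_on = 0), default_time_grid(50))$values
  expect_equal(v, rep(0, 50))
})

test_that("multi-ion transform follows the independence formula", {
  P <- occupancy_single(ref_config(), default_time_grid(100))
  expect_equal(occupancy_at_least_one(P, 1)$values, P$values)
  fake <- occusens:::.new_curve(c(1, 2), c(0.5, 0), NULL, "test")
  expect_equal(occupancy_at_least_one(fake, 2)$values, c(0.75, 0))
  edge <- occusens:::.new_curve(c(1, 2), c(0, 1), NULL, "test")
  expect_equal(occupancy_at_least_one(edge, 7)$values, c(0, 1))
})

test_that("at-least-n occupancy is the binomial tail and reduces at n = 1", {
  P <- occupancy_single(ref_config(cd = 5), default_time_grid(120))
  N <- 200
  expect_equal(occupancy_at_least_n(P, N, 1)$values,
               occupancy_at_least_one(P, N)$values)
  fake <- occusens:::.new_curve(1, 0.5, NULL, "test")
  expect_equal(occupancy_at_least_n(fake, 2, 2)$values, 0.25)
  zero <- occusens:::.new_curve(1, 0, NULL, "test")
  expect_equal(occupancy_at_least_n(zero, 1000, 5)$values, 0)
  expect_error(occupancy_at_least_n(P, 3, 4), "n <= N")
  ## exact-k binomial terms sum to one at every time point
  pv <- P$values[40]
  expect_equal(sum(dbinom(0:N, N, pv)), 1, tolerance = 1e-12)
})

test_that("small expected-count limit: P_N ~ N P when N P << 1", {
  P <- occupancy_single(ref_config(cd = 95), default_time_grid(100))
  N <- 5
  pn <- occupancy_at_least_one(P, N)$values
  np <- N * P$values
  expect_true(all(abs(pn - np) <= np^2 + 1e-15))
})

test_that("curve metrics handle flat and synthetic shapes", {
  flat <- occusens:::.new_curve(10^seq(-2, 2, length.out = 50),
                                rep(0.3, 50), NULL, "test")
  m <- curve_metrics(flat)
  expect_equal(m$peak, 0.3)
  expect_true(is.na(m$fwhm_us))
  ## Gaussian bump in log-time with known FWHM
  tg <- 10^seq(-2, 2, length.out = 2000)
  center <- 1; sig <- 0.3
  gv <- exp(-(tg - center)^2 / (2 * sig^2))
  gc <- occusens:::.new_curve(tg, gv, NULL, "test")
  mg <- curve_metrics(gc)
  expect_equal(mg$peak, 1, tolerance = 1e-4)
  expect_equal(mg$fwhm_us, 2 * sqrt(2 * log(2)) * sig * 1e3, tolerance = 1e-2)
})

test_that("deviation time detects where two curves depart", {
  tg <- seq(0.01, 1, length.out = 500)
  a <- occusens:::.new_curve(tg, tg, NULL, "test")
  b <- occusens:::.new_curve(tg, tg + pmax(0, tg - 0.5)^2 * 10, NULL, "test")
  m <- curve_metrics(b, reference = a, deviation_tol = 0.01)
  expect_gt(m$t_c_us, 500)  # departs after 0.5 ms
  expect_true(is.na(curve_metrics(a, reference = a)$t_c_us))
})

test_that("error metrics: identical, offset and Gaussian-pair cases", {
  tg <- 10^seq(-2, 2, length.out = 800)
  mk <- function(w) occusens:::.new_curve(
    tg, exp(-(tg - 5)^2 / (2 * (w / 2.3548)^2)), NULL, "test")
  a <- mk(2)
  expect_equal(unlist(curve_error_metrics(a, a)), c(mae = 0, fwhm_error_percent = 0))
  b <- occusens:::.new_curve(tg, a$values + 0.1, NULL, "test")
  expect_equal(curve_error_metrics(b, a)$mae, 0.1, tolerance = 1e-12)
  wide <- mk(3)
  expect_equal(curve_error_metrics(a, wide)$fwhm_error_percent,
               100 * abs(2 - 3) / 3, tolerance = 0.02)
})

test_that("curves round-trip through CSV", {
  P <- occupancy_single(ref_config(), default_time_grid(40))
  f <- tempfile(fileext = ".csv")
  write_curve_csv(P, f)
  Q <- read_curve_csv(f)
  expect_equal(Q$times, P$times)
  expect_equal(Q$values, P$values)
  unlink(f)
})
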