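test_that("zero calcium leaves the sensor in the unbound state", {
  ca <- ca_transient(c(0, 5), c(0, 0))
  tr <- integrate_release(release_params(), ca, times = seq(0, 5, 0.1))
  expect_equal(tr$V0, rep(1, nrow(tr)), tolerance = 1e-12)
  expect_equal(tr$F, rep(0, nrow(tr)), tolerance = 1e-12)
})

test_that("constant calcium without fusion relaxes to detailed balance", {
  pars <- release_params(gamma = 0)
  caval <- 0.02
  ca <- ca_transient(c(0, 50), c(caval, caval))
  tr <- integrate_release(pars, ca, times = seq(0, 50, 0.5))
  last <- as.numeric(tr[nrow(tr), paste0("V", 0:5)])
  for (i in 0:4) {
    expected <- (5 - i) * pars$k_on * caval /
      ((i + 1) * pars$k_off * pars$b^i)
    expect_equal(last[i + 2] / last[i + 1], expected, tolerance = 1e-6)
  }
})

test_that("non-cooperative limit gives the binomial state distribution", {
  pars <- release_params(b = 1, gamma = 0)
  caval <- 0.05
  ca <- ca_transient(c(0, 30), c(caval, caval))
  tr <- integrate_release(pars, ca, times = seq(0, 30, 0.5))
  p <- pars$k_on * caval / (pars$k_on * caval + pars$k_off)
  expect_equal(as.numeric(tr[nrow(tr), paste0("V", 0:5)]),
               dbinom(0:5, 5, p), tolerance = 1e-6)
})

test_that("frozen-rate trajectory matches the matrix-exponential oracle", {
  pars <- release_params()
  caval <- 0.03
  ca <- ca_transient(c(0, 2), c(caval, caval))
  tt <- seq(0, 2, 0.05)
  tr <- integrate_release(pars, ca, times = tt)
  ## independent oracle: generator of the 7-state linear system
  kon <- pars$k_on * caval
  A <- matrix(0, 7, 7)
  fwd <- (5:1) * kon
  bwd <- (1:5) * pars$k_off * pars$b^(0:4)
  for (i in 1:5) {
    A[i, i] <- A[i, i] - fwd[i]
    A[i + 1, i] <- A[i + 1, i] + fwd[i]
    A[i + 1, i + 1] <- A[i + 1, i + 1] - bwd[i]
    A[i, i + 1] <- A[i, i + 1] + bwd[i]
  }
  A[6, 6] <- A[6, 6] - pars$gamma
  A[7, 6] <- pars$gamma
  y0 <- c(1, rep(0, 6))
  for (k in c(10, 25, 41)) {
    ref <- as.numeric(Matrix::expm(A * tt[k]) %*% y0)
    expect_equal(as.numeric(tr[k, 2:8]), ref, tolerance = 1e-8)
  }
})

test_that("probability is conserved to 1e-12 along the trajectory", {
  ca <- gaussian_ca_transient(0.08, fwhm = 0.5, center = 1, t_end = 8)
  tr <- integrate_release(release_params(), ca)
  expect_lt(max(abs(rowSums(tr[, 2:8]) - 1)), 1e-12)
})

test_that("removing unbinding can only increase fusion", {
  ca <- gaussian_ca_transient(0.04, fwhm = 0.5, center = 1, t_end = 10)
  ctrl <- integrate_release(release_params(), ca)
  ko <- integrate_release(release_params(), ca, knockout_koff = TRUE)
  expect_gte(ko$F[nrow(ko)], ctrl$F[nrow(ctrl)])
  m <- release_metrics(ko, reference = ctrl)
  expect_gte(m$prob_ratio, 1)
})

test_that("knockout gain grows as the transient weakens", {
  ratio <- vapply(c(0.08, 0.04, 0.02), function(a) {
    ca <- gaussian_ca_transient(a, fwhm = 0.5, center = 1, t_end = 10)
    ctrl <- integrate_release(release_params(), ca)
    ko <- integrate_release(release_params(), ca, knockout_koff = TRUE)
    release_metrics(ko, reference = ctrl)$prob_ratio
  }, numeric(1))
  expect_true(all(diff(ratio) > 0))
  expect_true(all(ratio > 1))
})

test_that("release probability is monotone in transient amplitude", {
  F_end <- vapply(c(0.01, 0.03, 0.09), function(a) {
    ca <- gaussian_ca_transient(a, fwhm = 0.5, center = 1, t_end = 8)
    tr <- integrate_release(release_params(), ca)
    tr$F[nrow(tr)]
  }, numeric(1))
  expect_true(all(diff(F_end) > 0))
})

test_that("Euler compatibility mode agrees with the adaptive integrator", {
  ca <- gaussian_ca_transient(0.03, fwhm = 0.5, center = 1, t_end = 6)
  tt <- seq(0, 6, 0.1)
  ad <- integrate_release(release_params(), ca, times = tt)
  eu <- integrate_release(release_params(), ca, times = tt, method = "euler",
                          dt = 2e-5)
  expect_lt(max(abs(ad$F - eu$F)), 1e-4)
  expect_error(integrate_release(release_params(), ca, times = tt,
                                 method = "euler", dt = 0.5),
               "too large")
})

test_that("transients round-trip through CSV and reject bad input", {
  ca <- gaussian_ca_transient(0.05, t_end = 5, n = 101)
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_ms = ca$times, ca_mM = ca$ca), f, row.names = FALSE)
  ca2 <- read_ca_transient(f)
  expect_equal(ca2$ca, ca$ca)
  unlink(f)
  expect_error(ca_transient(c(0, 1), c(0.1, -0.2)), "negative")
})
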