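test_that("zero binding rate gives certain survival, S0~ = 1/p", {
  cfg <- ref_config(k_on = 0)
  for (p in c(0.5, 3, 40)) {
    s <- solve_survival(cfg, p, c(10, 100, 300))
    expect_equal(Re(s$S0), rep(1 / p, 3))
  }
})

test_that("binding is certain in the bounded domain: psi1~(p -> 0) -> 1", {
  cfg <- ref_config()
  for (r in c(10, 20, 150)) {
    psi1 <- 1 - 1e-9 * Re(solve_survival(cfg, 1e-9, r)$S0)
    expect_equal(psi1, 1, tolerance = 1e-5)
  }
})

test_that("Laplace solution matches the finite-difference boundary-value oracle", {
  ## frozen oracle values from fd_survival_oracle(config, p = 1, r = 20)
  ## (ghost-node centred scheme + Richardson extrapolation)
  cases <- list(
    list(bufs = list(), expect = 0.975978524573),
    list(bufs = list(buffer_preset("EFB")), expect = 0.986252973388),
    list(bufs = list(buffer_preset("ATP")), expect = 0.982583493726)
  )
  for (cs in cases) {
    cfg <- ref_config(buffers = cs$bufs)
    expect_equal(Re(solve_survival(cfg, 1, 20)$S0), cs$expect,
                 tolerance = 1e-8)
  }
  ## live oracle run for the no-buffer case guards the frozen values
  cfg <- ref_config()
  ora <- fd_survival_oracle(cfg, 1, 20)
  expect_equal(Re(solve_survival(cfg, 1, 20)$S0), ora, tolerance = 1e-8)
})

test_that("p S0~ is a probability transform: bounded in [0, 1] on the real axis", {
  configs <- list(ref_config(), ref_config(buffers = list(buffer_preset("EFB"))),
                  ref_config(buffers = list(buffer_preset("ATP"),
                                            buffer_preset("EGTA"))))
  for (cfg in configs) for (p in 10^seq(-3, 5, by = 1)) {
    v <- p * Re(solve_survival(cfg, p, 20)$S0)
    expect_gte(v, 0)
    expect_lte(v, 1 + 1e-12)
  }
})

test_that("p S0~ -> 1 as p -> infinity (initial condition)", {
  cfg <- ref_config(buffers = list(buffer_preset("ATP")))
  expect_equal(Re(1e8 * solve_survival(cfg, 1e8, 20)$S0), 1, tolerance = 1e-3)
})

test_that("buffers with zero exchange rate reduce to the no-buffer solution", {
  cfg0 <- ref_config()
  null_buf <- buffer_spec("null", D = 0.1, k_on_i = 0, c_i = 1, k_i0 = 3)
  cfg1 <- ref_config(buffers = list(null_buf))
  for (p in c(0.3, 5, 200)) {
    expect_equal(Re(solve_survival(cfg1, p, 20)$S0),
                 Re(solve_survival(cfg0, p, 20)$S0), tolerance = 1e-12)
  }
})

test_that("fixed-buffer elimination agrees with the mobile path as D -> 0", {
  ## the eigenmode machinery cannot hold D = 0, so convergence of a
  ## slow-buffer sequence onto the algebraic elimination is the check
  fixed <- ref_config(buffers = list(buffer_preset("EFB")))
  target <- Re(solve_survival(fixed, 2, 20)$S0)
  err <- vapply(c(1e-3, 1e-4, 1e-5), function(Dum) {
    cc <- ref_config(buffers = list(
      buffer_spec("slow", D = Dum, k_on_i = 100, c_i = 4, k_i0 = 10)))
    abs(Re(solve_survival(cc, 2, 20)$S0) - target)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-5)
  expect_gt(err[1] / err[3], 20)   # roughly linear convergence in D
})

test_that("renewal identity links occupancy and survival transforms", {
  cfg <- ref_config()
  p <- 2.5
  oc <- occupancy_laplace(cfg, p)
  s <- solve_survival(cfg, p, c(cfg$geometry$r, cfg$geometry$rho))
  psi1 <- 1 - p * s$S0[1]
  psi <- 1 - p * s$S0[2]
  expect_equal(oc$P, psi1 / (p + cfg$sensor$k_off * (1 - psi)))
  ## k_off = 0: occupancy transform is the first-passage CDF transform
  cfg0 <- ref_config(k_off = 0)
  oc0 <- occupancy_laplace(cfg0, p)
  expect_equal(oc0$P, oc0$psi1 / p)
  ## k_on = 0: no binding at all
  expect_equal(Mod(occupancy_laplace(ref_config(k_on = 0), p)$P), 0)
})

test_that("p P~ tends to the closed-form steady state as p -> 0", {
  for (cfg in list(ref_config(),
                   ref_config(buffers = list(buffer_preset("ATP"))))) {
    ## Richardson extrapolation in p removes the leading O(p) term
    v1 <- Re(1e-6 * occupancy_laplace(cfg, 1e-6)$P)
    v2 <- Re(5e-7 * occupancy_laplace(cfg, 5e-7)$P)
    expect_equal(2 * v2 - v1, steady_state(cfg), tolerance = 1e-6)
  }
})

test_that("p P~ is bounded as a probability transform for real p", {
  cfg <- ref_config(buffers = list(buffer_preset("EFB")))
  for (p in 10^seq(-2, 4)) {
    v <- p * Re(occupancy_laplace(cfg, p)$P)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("solution is purely radial (no angular arguments exist)", {
  expect_false(any(c("theta", "phi_angle") %in% names(formals(solve_survival))))
  expect_named(formals(solve_survival), c("config", "p", "r"))
})
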