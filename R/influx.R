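## Calcium entry: deterministic fixtures and stochastic channel gating.

## charge of Ca2+ is 2e; 1 pA of Ca2+ current carries this many ions per ms
PA_TO_IONS_PER_MS <- 1e-12 / (2 * 1.602176634e-19) / 1e3

#' Gaussian-profile instantaneous-entry fixture
#'
#' Draws `N` ion entry times from a Gaussian time course of given full
#' width at half maximum, the shape over which a single channel opening
#' delivers its ions during an action potential; negative draws are
#' redrawn (truncation at zero).
#'
#' @param N Number of ions.
#' @param fwhm FWHM of the entry-time distribution in ms (default 0.3).
#' @param center Centre of the Gaussian in ms (default 0.5).
#' @param seed Optional integer seed for reproducibility.
#' @return An `"ion_entry_sequence"`: list with sorted `times` (ms) and
#'   `trial = 1`.
#' @export
gaussian_flux_fixture <- function(N, fwhm = 0.3, center = 0.5, seed = NULL) {
  stopifnot(N >= 1, fwhm > 0)
  if (!is.null(seed)) set.seed(seed)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  times <- rnorm(N, center, sigma)
  while (any(times < 0)) {
    bad <- times < 0
    times[bad] <- rnorm(sum(bad), center, sigma)
  }
  structure(list(trial = 1L, times = sort(times), r = NULL),
            class = "ion_entry_sequence")
}

#' Hodgkin-Huxley-type calcium channel gating model
#'
#' Sequential chain with three closed states and one open state
#' (`C1 -> C2 -> C3 -> O`, forward rates `3a(V), 2a(V), a(V)`, backward
#' `b(V), 2b(V), 3b(V)`), exponential voltage dependence of the gate rates
#' `a(V) = a0 exp(V/Va)` and `b(V) = b0 exp(-V/Vb)`, and an ohmic
#' open-channel current `i(V) = g (V - E_rev)` (inward for `V < E_rev`).
#' The default parameters are calibrated so that the reference action
#' potential opens the channel in about 30% of trials, the unitary
#' current reaches 0.3 pA, and the trial-averaged current lasts about
#' 250 us at half maximum; see [calibrate_channel()].
#'
#' @param a0,Va Forward gate rate at 0 mV (ms^-1) and its e-fold slope (mV).
#' @param b0,Vb Backward gate rate at 0 mV (ms^-1) and its e-fold slope (mV).
#' @param g Single-channel conductance in pA/mV (i.e. nS).
#' @param E_rev Apparent reversal potential in mV.
#' @return A `"gating_model"` object with rate functions `alpha(V)`,
#'   `beta(V)` and current `current(V)` in pA (negative = inward).
#' @export
gating_model <- function(a0 = 1.55, Va = 49.14, b0 = 1.25, Vb = 51.4,
                         g = 0.00261, E_rev = 45) {
  stopifnot(a0 >= 0, b0 >= 0, Va > 0, Vb > 0, g >= 0)
  m <- list(a0 = a0, Va = Va, b0 = b0, Vb = Vb, g = g, E_rev = E_rev,
            n_closed = 3L)
  m$alpha <- function(V) a0 * exp(V / Va)
  m$beta <- function(V) b0 * exp(-V / Vb)
  m$current <- function(V) ifelse(V < E_rev, g * (V - E_rev), 0)  # pA
  structure(m, class = "gating_model")
}

#' Gaussian action-potential waveform
#'
#' A convenient smooth depolarization `V(t) = v_rest + amp *
#' exp(-(t - t_peak)^2 / (2 sigma^2))` standing in for an axonal action
#' potential.
#'
#' @param amp Peak depolarization above rest in mV (default 110).
#' @param v_rest Resting potential in mV (default -70).
#' @param t_peak Time of the peak in ms (default 0.5).
#' @param fwhm Full width at half maximum in ms (default 0.4).
#' @return A function of time (ms) returning membrane potential (mV).
#' @export
ap_waveform <- function(amp = 110, v_rest = -70, t_peak = 0.5, fwhm = 0.4) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  function(t) v_rest + amp * exp(-(t - t_peak)^2 / (2 * sigma^2))
}

#' Stochastic simulation of calcium influx through a single channel
#'
#' Exact-jump (thinning) simulation of the sequential gating chain under a
#' time-varying voltage, with ion entries drawn, while the channel is open,
#' from an inhomogeneous Poisson process whose intensity is the open-channel
#' current converted to ions/ms (charge 2e per ion).
#'
#' @param ap Function of time (ms) returning voltage (mV).
#' @param model A [gating_model()].
#' @param t_end End of the simulation window in ms (default 3).
#' @param n_trials Number of independent trials (default 1000).
#' @param dt Grid step for the returned open/current traces in ms
#'   (default 1e-3).
#' @param seed Optional integer seed.
#' @return A list with `entries` (list of `"ion_entry_sequence"`, one per
#'   trial), `open_prob` (fraction of trials with at least one opening),
#'   `t` (trace grid), `open_trace` (probability the channel is open),
#'   `current_trace` (mean current in pA, negative inward), and
#'   `mean_ions` (mean entries per trial).
#' @export
simulate_channel <- function(ap, model, t_end = 3, n_trials = 1000,
                             dt = 1e-3, seed = NULL) {
  stopifnot(inherits(model, "gating_model"), dt <= 1e-3 + 1e-12)
  if (!is.null(seed)) set.seed(seed)
  tg <- seq(0, t_end, by = dt)
  V <- ap(tg)
  if (any(!is.finite(V))) stop("simulate_channel: waveform returned non-finite voltage")
  al <- model$alpha(V); be <- model$beta(V)
  if (any(al < 0) || any(be < 0))
    stop("simulate_channel: rate function returned a negative rate")
  Vfun <- approxfun(tg, V, rule = 2)
  ## piecewise-constant thinning bounds on coarse segments
  seg_w <- 0.05
  seg_edges <- seq(0, t_end + seg_w, by = seg_w)
  seg_of <- function(t) pmin(findInterval(t, seg_edges), length(seg_edges) - 1L)
  seg_bound <- vapply(seq_len(length(seg_edges) - 1L), function(i) {
    sel <- tg >= seg_edges[i] - dt & tg <= seg_edges[i + 1] + dt
    if (!any(sel)) return(0)
    3 * max(al[sel], be[sel]) * 1.05
  }, numeric(1))
  ## cumulative ion intensity for inverse-CDF sampling while open
  lam <- abs(model$current(V)) * PA_TO_IONS_PER_MS       # ions/ms
  cumlam <- c(0, cumsum((lam[-1] + lam[-length(lam)]) / 2 * dt))
  Cfun <- approxfun(tg, cumlam, rule = 2)
  Cinv <- approxfun(cumlam, tg, rule = 2, ties = "ordered")
  open_cnt <- numeric(length(tg))
  cur_sum <- numeric(length(tg))
  entries <- vector("list", n_trials)
  opened <- logical(n_trials)
  for (j in seq_len(n_trials)) {
    s <- 0L                       # activated gates; 3 = open
    t <- 0
    open_iv <- NULL
    t_open <- NA_real_
    repeat {
      B <- seg_bound[seg_of(t)]
      if (B <= 0) { t <- seg_edges[seg_of(t) + 1L]; if (t >= t_end) break; next }
      t_next <- t + rexp(1, B)
      seg_end <- seg_edges[seg_of(t) + 1L]
      if (t_next > seg_end) { t <- seg_end; if (t >= t_end) break; next }
      t <- t_next
      if (t >= t_end) break
      v <- Vfun(t)
      kf <- if (s < 3L) (3L - s) * model$alpha(v) else 0
      kb <- s * model$beta(v)
      u <- runif(1) * B
      if (u < kf) {
        s <- s + 1L
        if (s == 3L) t_open <- t
      } else if (u < kf + kb) {
        if (s == 3L) open_iv <- rbind(open_iv, c(t_open, t))
        s <- s - 1L
      }
    }
    if (s == 3L) open_iv <- rbind(open_iv, c(t_open, t_end))
    ions <- numeric(0)
    if (!is.null(open_iv)) {
      opened[j] <- TRUE
      for (k in seq_len(nrow(open_iv))) {
        i1 <- max(1L, ceiling(open_iv[k, 1] / dt) + 1L)
        i2 <- min(length(tg), floor(open_iv[k, 2] / dt) + 1L)
        if (i2 >= i1) {
          open_cnt[i1:i2] <- open_cnt[i1:i2] + 1
          cur_sum[i1:i2] <- cur_sum[i1:i2] + model$current(V[i1:i2])
        }
        ## inhomogeneous Poisson entries while open, by inverting the
        ## integrated intensity (preserves the expected count exactly)
        Lab <- Cfun(open_iv[k, 2]) - Cfun(open_iv[k, 1])
        if (Lab > 0) {
          nk <- stats::rpois(1, Lab)
          if (nk > 0)
            ions <- c(ions, Cinv(Cfun(open_iv[k, 1]) + runif(nk) * Lab))
        }
      }
    }
    entries[[j]] <- structure(list(trial = j, times = sort(ions), r = NULL),
                              class = "ion_entry_sequence")
  }
  list(entries = entries, open_prob = mean(opened), t = tg,
       open_trace = open_cnt / n_trials, current_trace = cur_sum / n_trials,
       mean_ions = mean(vapply(entries, function(e) length(e$times),
                               numeric(1))))
}

#' Calibrate the channel model against summary targets
#'
#' Rescales the forward-rate amplitude `a0` so that the per-trial opening
#' probability matches `target_po`, then rescales the conductance so the
#' peak of the mean open-channel current matches `target_peak_pa`; the
#' resulting current FWHM is reported for comparison against
#' `target_fwhm_us`. Uses short pilot simulations, so supply a seed for
#' reproducibility.
#'
#' @param model Starting [gating_model()].
#' @param ap Waveform function (default [ap_waveform()]).
#' @param target_po Target opening probability (default 0.3).
#' @param target_peak_pa Target unitary current magnitude in pA (0.3).
#' @param target_fwhm_us Reference current FWHM in us (250), reported only.
#' @param n_trials Pilot trials per iteration (default 2000).
#' @param seed Integer seed.
#' @return A list with the calibrated `model`, achieved `open_prob`,
#'   `peak_pa`, `fwhm_us`.
#' @export
calibrate_channel <- function(model = gating_model(), ap = ap_waveform(),
                              target_po = 0.3, target_peak_pa = 0.3,
                              target_fwhm_us = 250,
                              n_trials = 2000, seed = 1) {
  fac <- 1
  for (it in 1:6) {
    m <- gating_model(a0 = model$a0 * fac, Va = model$Va, b0 = model$b0,
                      Vb = model$Vb, g = model$g, E_rev = model$E_rev)
    sim <- simulate_channel(ap, m, n_trials = n_trials, seed = seed + it)
    po <- sim$open_prob
    if (abs(po - target_po) < 0.01) break
    ## opening hazard is roughly proportional to a0 near threshold
    fac <- fac * min(max(target_po / max(po, 1e-3), 0.33), 3)
  }
  ## unitary current maximum over the waveform is deterministic in g
  Vr <- ap(seq(0, 3, by = 1e-3))
  pk_unit <- max(abs(m$current(Vr)))
  g_new <- m$g * target_peak_pa / pk_unit
  m <- gating_model(a0 = m$a0, Va = m$Va, b0 = m$b0, Vb = m$Vb,
                    g = g_new, E_rev = m$E_rev)
  sim <- simulate_channel(ap, m, n_trials = n_trials, seed = seed + 99)
  cur <- abs(sim$current_trace)
  fwhm <- {
    half <- max(cur) / 2
    ab <- cur >= half
    if (any(ab)) (sim$t[max(which(ab))] - sim$t[min(which(ab))]) * 1e3
    else NA_real_
  }
  list(model = m, open_prob = sim$open_prob,
       peak_pa = max(abs(m$current(Vr))), mean_peak_pa = max(cur),
       fwhm_us = fwhm)
}

#' Interpolator for a single-ion occupancy curve
#'
#' Wraps an `"occ_curve"` into a fast vectorized function of elapsed time:
#' zero for non-positive elapsed times, linear interpolation in log-time on
#' the curve's grid, constant at the steady level beyond the grid.
#'
#' @param P An `"occ_curve"`.
#' @return A function `f(elapsed_ms)`.
#' @export
occupancy_interpolator <- function(P) {
  stopifnot(inherits(P, "occ_curve"))
  lf <- approxfun(log(P$times), P$values, rule = 2)
  t0 <- P$times[1]; v0 <- P$values[1]
  function(dt_ms) {
    out <- numeric(length(dt_ms))
    pos <- dt_ms > 0
    ## below the grid start, scale the first value linearly toward 0
    small <- pos & dt_ms < t0
    out[small] <- v0 * dt_ms[small] / t0
    big <- pos & !small
    out[big] <- lf(log(dt_ms[big]))
    out
  }
}

#' Per-trial occupancy from an ion entry sequence
#'
#' Poisson-binomial complement product over the ions of one trial:
#' `P_trial(t) = 1 - prod_i (1 - P(t - t_i))`, where `P` is the single-ion
#' occupancy as a function of elapsed time and ions that have not yet
#' entered contribute zero.
#'
#' @param entries An `"ion_entry_sequence"`.
#' @param P_fun Function of elapsed time (ms), e.g. from
#'   [occupancy_interpolator()].
#' @param times Evaluation grid in ms.
#' @return An `"occ_curve"`.
#' @export
occupancy_trial <- function(entries, P_fun, times) {
  stopifnot(inherits(entries, "ion_entry_sequence"))
  if (!length(entries$times))
    return(.new_curve(times, rep(0, length(times)), NULL, "trial"))
  el <- outer(times, entries$times, `-`)
  Pm <- matrix(P_fun(as.vector(el)), nrow = length(times))
  vals <- 1 - exp(rowSums(log1p(-Pm)))
  .new_curve(times, vals, NULL, "trial")
}

#' Trial-averaged occupancy for stochastic influx
#'
#' Average of [occupancy_trial()] over a set of entry-time sequences (for
#' instance the trials of [simulate_channel()]).
#'
#' @param trials List of `"ion_entry_sequence"` objects.
#' @param P_fun Single-ion occupancy function of elapsed time.
#' @param times Evaluation grid in ms.
#' @param keep_trials Return the per-trial matrix as attribute
#'   `"trial_matrix"` (default FALSE).
#' @return An `"occ_curve"` with SEM across trials in `$sem`.
#' @export
occupancy_ap <- function(trials, P_fun, times, keep_trials = FALSE) {
  stopifnot(length(trials) >= 1)
  mat <- vapply(trials, function(e) occupancy_trial(e, P_fun, times)$values,
                numeric(length(times)))
  mat <- matrix(mat, nrow = length(times))
  vals <- rowMeans(mat)
  sem <- if (ncol(mat) > 1) apply(mat, 1, sd) / sqrt(ncol(mat)) else
    rep(NA_real_, length(times))
  cv <- .new_curve(times, vals, NULL, "ap_average", sem = sem)
  if (keep_trials) attr(cv, "trial_matrix") <- mat
  cv
}
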