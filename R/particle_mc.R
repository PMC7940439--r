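## Particle-based Brownian-dynamics validator.

#' Monte Carlo simulation settings
#'
#' @param dt Time step in ms (default 5e-6, i.e. 5 ns).
#' @param n_trials Number of independent trials.
#' @param horizon Simulated time span per trial in ms.
#' @param seed Optional integer seed (applied by [simulate_ions()]).
#' @param sensor_capacity `"unlimited"`, `"single_site"`, or a positive
#'   integer giving the number of simultaneously occupiable sites.
#' @param burnin Initial time span (ms) excluded from the per-state
#'   residence-time accounting (equilibrium measurements only; default 0).
#' @param interaction_range Contact radius for particle-surface reactions
#'   in nm (default 5, matching the sensor radius).
#' @return An `"mc_config"` object.
#' @export
mc_config <- function(dt = 5e-6, n_trials = 1000, horizon = 1,
                      seed = NULL, sensor_capacity = "unlimited",
                      interaction_range = 5, burnin = 0) {
  stopifnot(dt > 0, n_trials >= 1, horizon > 0)
  cap <- if (identical(sensor_capacity, "unlimited")) 0L
  else if (identical(sensor_capacity, "single_site")) 1L
  else as.integer(sensor_capacity)
  if (cap < 0) stop("mc_config: invalid sensor_capacity")
  structure(list(dt = dt, n_trials = n_trials, horizon = horizon,
                 seed = seed, capacity = cap,
                 interaction_range = interaction_range, burnin = burnin),
            class = "mc_config")
}

#' Brownian-dynamics simulation of ion binding to the sensor
#'
#' Simulates every ion of every trial as an independent Brownian particle
#' (switching to the buffer-bound diffusivity while captured by a buffer),
#' with specular reflection at the outer hemisphere and the membrane
#' plane, Robin-consistent partial absorption at the sensor surface, and
#' exponential unbinding. Buffers are the same continuous reactive media
#' as in the analytical model: per-ion Markov state switching, not
#' explicit buffer particles.
#'
#' @param config An [model_config()] object.
#' @param mc An [mc_config()] object.
#' @param entries Either `NULL` (one ion per trial released at time 0 from
#'   the configured source position) or a list of `"ion_entry_sequence"`
#'   objects, one per trial.
#' @return An `"mc_event_log"`: list with `events` (data.frame `trial`,
#'   `time_ms`, `event` in `bind`/`unbind`), `state_time` (per-trial time
#'   spent free / in each buffer state), `n_trials`, `horizon`, and the
#'   two configs.
#' @export
simulate_ions <- function(config, mc, entries = NULL) {
  stopifnot(inherits(config, "occ_config"), inherits(mc, "mc_config"))
  g <- config$geometry
  step_rms <- sqrt(2 * config$D0 * mc$dt)
  if (step_rms > g$cd / 5)
    warning(sprintf(paste0("simulate_ions: rms step %.2g nm exceeds CD/5 ",
                           "= %.2g nm; reduce dt"), step_rms, g$cd / 5))
  if (is.null(entries)) {
    ion_trial <- seq_len(mc$n_trials) - 1L
    ion_entry <- rep(0, mc$n_trials)
    ion_r <- rep(g$r, mc$n_trials)
  } else {
    stopifnot(all(vapply(entries, inherits, logical(1), "ion_entry_sequence")))
    n <- vapply(entries, function(e) length(e$times), integer(1))
    ion_trial <- rep(seq_along(entries) - 1L, n)
    ion_entry <- unlist(lapply(entries, `[[`, "times"), use.names = FALSE)
    ion_r <- unlist(lapply(entries, function(e)
      if (is.null(e$r)) rep(g$r, length(e$times)) else e$r),
      use.names = FALSE)
    if (is.null(ion_entry)) ion_entry <- numeric(0)
    if (is.null(ion_r)) ion_r <- numeric(0)
  }
  if (length(ion_r) && any(ion_r <= g$rho | ion_r > g$R))
    stop("simulate_ions: entry positions must satisfy rho < r <= R")
  if (!is.null(mc$seed)) set.seed(mc$seed)
  absorb <- is.infinite(config$k_on_vol)
  kappa <- if (absorb) 0 else config$kappa
  M <- length(config$buffers)
  res <- .mc_core(R = g$R, rho = g$rho, D0 = config$D0,
                  kappa = kappa, absorb = absorb,
                  koff = config$sensor$k_off,
                  bufD = vapply(config$buffers, `[[`, numeric(1), "D"),
                  buf_k0i = vapply(config$buffers, `[[`, numeric(1), "k_0i"),
                  buf_ki0 = vapply(config$buffers, `[[`, numeric(1), "k_i0"),
                  ion_trial = as.integer(ion_trial),
                  ion_entry = as.numeric(ion_entry),
                  ion_r = as.numeric(ion_r),
                  dt = mc$dt, horizon = mc$horizon,
                  capacity = mc$capacity, burnin = mc$burnin)
  events <- data.frame(trial = res$trial, time_ms = res$time,
                       event = c("bind", "unbind")[res$code])
  events <- events[order(events$trial, events$time_ms), , drop = FALSE]
  rownames(events) <- NULL
  st <- res$state_time
  colnames(st) <- c("free", vapply(config$buffers, `[[`, character(1), "name"))
  n_eff <- if (is.null(entries)) mc$n_trials else length(entries)
  structure(list(events = events, state_time = st,
                 n_trials = n_eff, horizon = mc$horizon,
                 config = config, mc = mc), class = "mc_event_log")
}

#' Empirical occupancy curve from a Monte Carlo event log
#'
#' Per trial, the number of currently bound ions is a step function jumping
#' at the recorded bind/unbind times; the estimate is its average across
#' trials with the standard error of the mean.
#'
#' @param log An `"mc_event_log"`.
#' @param times Evaluation grid in ms.
#' @return An `"occ_curve"` with `provenance = "mc"` and per-time SEM.
#' @export
estimate_occupancy <- function(log, times) {
  stopifnot(inherits(log, "mc_event_log"))
  nt <- log$n_trials
  counts <- matrix(0, length(times), nt)
  ev <- log$events
  if (nrow(ev)) {
    sgn <- ifelse(ev$event == "bind", 1, -1)
    for (tr in unique(ev$trial)) {
      sel <- ev$trial == tr
      tt <- ev$time_ms[sel]; ss <- sgn[sel]
      counts[, tr] <- vapply(times, function(x) sum(ss[tt <= x]), numeric(1))
    }
  }
  vals <- rowMeans(counts)
  sem <- if (nt > 1) apply(counts, 1, sd) / sqrt(nt) else rep(NA_real_, length(times))
  .new_curve(times, vals, log$config, provenance = "mc", sem = sem)
}

#' First-binding times from a Monte Carlo event log
#'
#' @param log An `"mc_event_log"`.
#' @return A list with `fpt` (first bind time per trial that bound, ms),
#'   `censored` (number of trials with no binding before the horizon), and
#'   `horizon`.
#' @export
empirical_fpt <- function(log) {
  stopifnot(inherits(log, "mc_event_log"))
  binds <- log$events[log$events$event == "bind", ]
  fpt <- tapply(binds$time_ms, binds$trial, min)
  list(fpt = as.numeric(fpt),
       censored = log$n_trials - length(fpt),
       horizon = log$horizon)
}

#' Durations of sensor-bound intervals
#'
#' Pairs each bind event with the following unbind of the same trial;
#' open-ended intervals at the horizon are dropped. For a single-site
#' sensor these are exact residence times with mean `1/k_off`.
#'
#' @param log An `"mc_event_log"`.
#' @return Numeric vector of bound durations in ms.
#' @export
bound_intervals <- function(log) {
  stopifnot(inherits(log, "mc_event_log"))
  out <- numeric(0)
  ev <- log$events
  for (tr in unique(ev$trial)) {
    e <- ev[ev$trial == tr, ]
    tb <- e$time_ms[e$event == "bind"]
    tu <- e$time_ms[e$event == "unbind"]
    n <- min(length(tb), length(tu))
    if (n) out <- c(out, tu[seq_len(n)] - tb[seq_len(n)])
  }
  out
}

#' Export a Monte Carlo event log as CSV
#'
#' @param log An `"mc_event_log"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log_csv <- function(log, path) {
  write.csv(log$events, path, row.names = FALSE)
  invisible(path)
}
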