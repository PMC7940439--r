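## Five-state cooperative calcium sensor driving vesicle fusion.
##
## V0 <-> V1 <-> ... <-> V5 -> F with forward rates (5-i) k_on [Ca](t)
## from V_i and backward rates (i+1) k_off b^i from V_{i+1}; the
## cooperativity factor b < 1 slows successive unbinding steps, and the
## fully occupied state fuses irreversibly with rate gamma.

#' Parameters of the five-site release sensor
#'
#' @param k_on Per-site forward rate constant in mM^-1 ms^-1 (default 127).
#' @param k_off Base backward rate in ms^-1 (default 15.7).
#' @param b Cooperativity factor in (0, 1] (default 0.25).
#' @param gamma Fusion rate from the fully bound state in ms^-1 (default 6).
#' @return A `"release_params"` object.
#' @export
release_params <- function(k_on = 127, k_off = 15.7, b = 0.25, gamma = 6) {
  stopifnot(k_on >= 0, k_off >= 0, b > 0, b <= 1, gamma >= 0)
  structure(list(k_on = k_on, k_off = k_off, b = b, gamma = gamma),
            class = "release_params")
}

#' Calcium concentration transient
#'
#' Piecewise-linear free-calcium time course driving the release sensor,
#' either supplied directly or read from a two-column CSV
#' (`time_ms`, `ca_mM`).
#'
#' @param times Times in ms (sorted).
#' @param ca Free calcium in mM (non-negative).
#' @return A `"ca_transient"` object with an interpolating function `$fun`.
#' @export
ca_transient <- function(times, ca) {
  stopifnot(length(times) == length(ca), !is.unsorted(times))
  if (any(ca < 0)) stop("ca_transient: negative concentrations")
  structure(list(times = times, ca = ca,
                 fun = approxfun(times, ca, rule = 2)),
            class = "ca_transient")
}

#' @rdname ca_transient
#' @param path CSV file with columns `time_ms` and `ca_mM`.
#' @export
read_ca_transient <- function(path) {
  d <- read.csv(path)
  ca_transient(d$time_ms, d$ca_mM)
}

#' Synthetic Gaussian calcium transient
#'
#' A localized free-calcium pulse of given peak amplitude and FWHM,
#' emulating the shape of an action-potential-driven microdomain
#' transient.
#'
#' @param amp_mM Peak amplitude in mM.
#' @param fwhm Full width at half maximum in ms (default 0.5).
#' @param center Peak time in ms (default 1).
#' @param t_end End of the transient window in ms (default 10).
#' @param n Grid points (default 2001).
#' @return A `"ca_transient"`.
#' @export
gaussian_ca_transient <- function(amp_mM, fwhm = 0.5, center = 1,
                                  t_end = 10, n = 2001) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  tt <- seq(0, t_end, length.out = n)
  ca_transient(tt, amp_mM * exp(-(tt - center)^2 / (2 * sigma^2)))
}

## time-derivative of the 7-component state (V0..V5, F)
.release_rhs <- function(t, y, parms) {
  ca <- parms$cafun(t)
  kon <- parms$k_on * ca
  fwd <- (5:1) * kon                       # V_i -> V_{i+1}, i = 0..4
  bwd <- (1:5) * parms$k_off * parms$b^(0:4) # V_{i+1} -> V_i
  if (parms$knockout) bwd[] <- 0
  V <- y[1:6]
  dV <- numeric(6)
  flux <- fwd * V[1:5] - bwd * V[2:6]      # net i -> i+1
  dV[1] <- -flux[1]
  dV[2:5] <- flux[1:4] - flux[2:5]
  dV[6] <- flux[5] - parms$gamma * V[6]
  dF <- parms$gamma * V[6]
  list(c(dV, dF))
}

#' Integrate the five-state release model over a calcium transient
#'
#' Linear time-varying ODE system integrated with an adaptive
#' embedded-error stepper (`deSolve::ode`, `"ode45"`); a fixed-step forward
#' Euler compatibility mode is available. Conservation of total
#' probability is enforced to 1e-12 by construction and checked.
#'
#' @param params A [release_params()] object.
#' @param ca A `"ca_transient"`.
#' @param times Output times in ms (default: the transient's grid).
#' @param knockout_koff If TRUE all backward (unbinding) rates are zeroed.
#' @param method `"adaptive"` (default) or `"euler"`.
#' @param dt Fixed step for the Euler mode in ms (default 1e-4); an error
#'   is raised if it does not resolve the fastest rate.
#' @return A `"release_trajectory"`: data.frame with `time`, `V0`..`V5`,
#'   `F`, and `rate` (the fusion rate `gamma V5`).
#' @export
integrate_release <- function(params, ca, times = NULL,
                              knockout_koff = FALSE,
                              method = c("adaptive", "euler"), dt = 1e-4) {
  stopifnot(inherits(params, "release_params"), inherits(ca, "ca_transient"))
  method <- match.arg(method)
  if (is.null(times)) times <- ca$times
  parms <- list(k_on = params$k_on, k_off = params$k_off, b = params$b,
                gamma = params$gamma, knockout = knockout_koff,
                cafun = ca$fun)
  y0 <- c(1, 0, 0, 0, 0, 0, 0)
  if (method == "euler") {
    max_rate <- max(5 * params$k_on * max(ca$ca), 5 * params$k_off,
                    params$gamma)
    if (dt * max_rate >= 0.1)
      stop(sprintf(paste0("integrate_release: dt = %g too large for fastest ",
                          "rate %g ms^-1 (need dt * rate < 0.1)"),
                   dt, max_rate))
    grid <- seq(min(times), max(times), by = dt)
    Y <- matrix(0, length(grid), 7)
    Y[1, ] <- y0
    y <- y0
    for (i in seq_len(length(grid) - 1)) {
      y <- y + dt * .release_rhs(grid[i], y, parms)[[1]]
      Y[i + 1, ] <- y
    }
    out <- cbind(time = grid, Y)
    out <- out[findInterval(times, grid), , drop = FALSE]
    out[, 1] <- times
  } else {
    out <- deSolve::ode(y = y0, times = times, func = .release_rhs,
                        parms = parms, method = "ode45",
                        rtol = 1e-10, atol = 1e-12)
  }
  df <- as.data.frame(out)
  names(df) <- c("time", paste0("V", 0:5), "F")
  err <- max(abs(rowSums(df[, -1]) - 1))
  if (err > 1e-8)
    warning(sprintf("integrate_release: conservation violated by %g", err))
  df$rate <- params$gamma * df$V5
  class(df) <- c("release_trajectory", class(df))
  df
}

#' Summary metrics of a release trajectory
#'
#' @param traj A `"release_trajectory"`.
#' @param reference Optional reference trajectory for ratio metrics.
#' @return A list with `release_prob` (final fused fraction), `peak_rate`
#'   (ms^-1), `rate_fwhm_ms`, and, given a reference, `prob_ratio` and
#'   `fwhm_change_percent`.
#' @export
release_metrics <- function(traj, reference = NULL) {
  stopifnot(inherits(traj, "release_trajectory"))
  pk <- max(traj$rate)
  fwhm <- if (pk > 0) {
    w <- .fwhm(traj$time, traj$rate, pk / 2)
    if (is.na(w)) NA_real_ else w / 1e3    # .fwhm returns us
  } else NA_real_
  out <- list(release_prob = traj$F[nrow(traj)], peak_rate = pk,
              rate_fwhm_ms = fwhm)
  if (!is.null(reference)) {
    ref <- release_metrics(reference)
    out$prob_ratio <- out$release_prob / ref$release_prob
    out$fwhm_change_percent <-
      if (is.na(fwhm) || is.na(ref$rate_fwhm_ms)) NA_real_
      else 100 * (fwhm - ref$rate_fwhm_ms) / ref$rate_fwhm_ms
  }
  out
}

#' Write a release trajectory to CSV
#'
#' @param traj A `"release_trajectory"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_release_csv <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
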