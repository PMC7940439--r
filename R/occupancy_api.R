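## User-facing occupancy curves and their metrics.

#' Default logarithmic time grid
#'
#' 600 log-spaced points over 1e-4 ms to 1e3 ms (0.1 us to 1 s), the range
#' over which the occupancy probability develops from the diffusive arrival
#' transient to its steady state.
#'
#' @param n Number of points (default 600).
#' @param t_min,t_max Grid limits in ms.
#' @return Numeric vector of times in ms.
#' @export
default_time_grid <- function(n = 600, t_min = 1e-4, t_max = 1e3)
  10^seq(log10(t_min), log10(t_max), length.out = n)

.new_curve <- function(times, values, config, provenance,
                       sem = NULL, extra = list()) {
  stopifnot(length(times) == length(values), all(diff(times) > 0))
  structure(c(list(times = times, values = values, config = config,
                   provenance = provenance, sem = sem), extra),
            class = "occ_curve")
}

#' @export
print.occ_curve <- function(x, ...) {
  cat(sprintf("<occ_curve> %d points on [%g, %g] ms (%s)\n",
              length(x$times), min(x$times), max(x$times), x$provenance))
  m <- curve_metrics(x)
  cat(sprintf("  peak %.4g at %.4g us; steady state %.4g\n",
              m$peak, m$time_to_peak_us, m$steady_state %||% NA))
  invisible(x)
}

#' Single-ion occupancy curve P(t, r)
#'
#' Probability that a single calcium ion released at the source position is
#' bound to the sensor at each time of the grid. The `"auto"` backend uses
#' the exact residue series for buffer-free configurations and fixed-Talbot
#' numerical inversion otherwise; both explicit backends remain available
#' for cross-validation.
#'
#' @param config An [model_config()] object.
#' @param times Time grid in ms (default [default_time_grid()]).
#' @param backend `"auto"`, `"series"` or `"numeric"`.
#' @return An `"occ_curve"` object with fields `times`, `values`.
#' @export
occupancy_single <- function(config, times = default_time_grid(),
                             backend = c("auto", "series", "numeric")) {
  backend <- match.arg(backend)
  vals <- .occupancy_eval(config, times, backend = backend)
  .new_curve(times, vals, config, provenance = backend)
}

#' Occupancy by at least one of N simultaneously released ions
#'
#' Under the unlimited-binding-capacity assumption the N single-ion binding
#' events are independent, so `P_N = 1 - (1 - P)^N` pointwise. Saturation
#' of a real sensor makes this an upper-bound approximation at high
#' occupancy (see the particle simulator for the saturable counterpart).
#'
#' @param P An `"occ_curve"` (single-ion occupancy).
#' @param N Number of ions released at time zero.
#' @return An `"occ_curve"`.
#' @export
occupancy_at_least_one <- function(P, N) {
  stopifnot(inherits(P, "occ_curve"), N >= 1)
  .new_curve(P$times, 1 - (1 - P$values)^N, P$config,
             provenance = paste0(P$provenance, ":at_least_one(N=", N, ")"))
}

#' Occupancy by at least n of N simultaneously released ions
#'
#' Binomial-tail transform `P_{N,n} = 1 - sum_{k<n} C(N,k) P^k (1-P)^(N-k)`,
#' evaluated through the stable binomial CDF. Reduces exactly to
#' [occupancy_at_least_one()] at `n = 1`.
#'
#' @param P An `"occ_curve"`.
#' @param N Total ions released.
#' @param n Minimum number simultaneously bound.
#' @return An `"occ_curve"`.
#' @export
occupancy_at_least_n <- function(P, N, n) {
  stopifnot(inherits(P, "occ_curve"))
  if (!(n >= 1 && n <= N)) stop("occupancy_at_least_n: need 1 <= n <= N")
  vals <- pbinom(n - 1, size = N, prob = P$values, lower.tail = FALSE)
  .new_curve(P$times, vals, P$config,
             provenance = paste0(P$provenance, ":at_least_n(N=", N,
                                 ",n=", n, ")"))
}

## quadratic refinement of an interior grid maximum in log10-time
.refine_peak <- function(times, values) {
  i <- which.max(values)
  if (i == 1L || i == length(values))
    return(list(peak = values[i], t_peak = times[i], interior = FALSE))
  x <- log10(times[(i - 1):(i + 1)])
  y <- values[(i - 1):(i + 1)]
  d1 <- (y[3] - y[1]) / 2
  d2 <- y[3] - 2 * y[2] + y[1]
  if (d2 >= 0) return(list(peak = y[2], t_peak = times[i], interior = TRUE))
  h <- x[2] - x[1]
  s <- max(min(-d1 / d2, 1), -1)    # vertex offset in grid-spacing units
  list(peak = y[2] - d1^2 / (2 * d2),
       t_peak = 10^(x[2] + s * h), interior = TRUE)
}

#' Summary metrics of an occupancy curve
#'
#' Peak and time-to-peak (quadratic refinement around the grid maximum in
#' log-time), full width at half maximum (linear interpolation of the
#' half-peak crossings, measured from baseline zero), steady state (last
#' grid value, or the closed form when the curve carries a configuration),
#' and, given a reference curve, the deviation time `t_c`: the first time
#' at which the curve departs from the reference by more than
#' `deviation_tol` of the reference maximum.
#'
#' @param P An `"occ_curve"`.
#' @param reference Optional `"occ_curve"` on the same grid for `t_c`.
#' @param deviation_tol Relative deviation threshold (default 0.01).
#' @return A list with `peak`, `time_to_peak_us`, `fwhm_us` (NA when the
#'   curve has no interior maximum above its tail), `steady_state`, and
#'   `t_c_us` (NA without a reference or deviation).
#' @export
curve_metrics <- function(P, reference = NULL, deviation_tol = 0.01) {
  stopifnot(inherits(P, "occ_curve"))
  pk <- .refine_peak(P$times, P$values)
  ss <- if (!is.null(P$config)) tryCatch(steady_state(P$config),
                                         error = function(e) NULL)
  if (is.null(ss)) ss <- P$values[length(P$values)]
  fwhm <- NA_real_
  if (pk$interior && pk$peak > 2 * max(ss, 0) && pk$peak > 0) {
    half <- pk$peak / 2
    fwhm <- .fwhm(P$times, P$values, half)
  }
  t_c <- NA_real_
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "occ_curve"))
    ref <- approxfun(reference$times, reference$values, rule = 2)(P$times)
    dev <- abs(P$values - ref) / max(ref)
    i <- which(dev > deviation_tol)
    if (length(i)) t_c <- P$times[i[1]] * 1e3
  }
  list(peak = pk$peak, time_to_peak_us = pk$t_peak * 1e3,
       fwhm_us = fwhm, steady_state = ss, t_c_us = t_c)
}

## width between the first upward and last downward crossing of `level`
.fwhm <- function(times, values, level) {
  above <- values >= level
  if (!any(above)) return(NA_real_)
  i1 <- which(above)[1]
  i2 <- which(above)[sum(above)]
  t_lo <- if (i1 == 1L) times[1] else {
    f <- (level - values[i1 - 1]) / (values[i1] - values[i1 - 1])
    times[i1 - 1] + f * (times[i1] - times[i1 - 1])
  }
  t_hi <- if (i2 == length(values)) return(NA_real_) else {
    f <- (level - values[i2]) / (values[i2 + 1] - values[i2])
    times[i2] + f * (times[i2 + 1] - times[i2])
  }
  (t_hi - t_lo) * 1e3                    # us
}

#' Discrepancy metrics between two occupancy curves
#'
#' Mean absolute difference and relative FWHM error, the two summary
#' statistics used to compare analytical and Monte Carlo curves. Curve `b`
#' is linearly resampled onto the grid of `a`.
#'
#' @param a,b `"occ_curve"` objects.
#' @return A list with `mae` and `fwhm_error_percent`
#'   (`100 |FWHM_a - FWHM_b| / FWHM_b`; NA if either width is undefined).
#' @export
curve_error_metrics <- function(a, b) {
  stopifnot(inherits(a, "occ_curve"), inherits(b, "occ_curve"))
  bv <- approxfun(b$times, b$values, rule = 2)(a$times)
  mae <- mean(abs(a$values - bv))
  fa <- curve_metrics(a)$fwhm_us
  fb <- curve_metrics(b)$fwhm_us
  fe <- if (is.na(fa) || is.na(fb)) NA_real_ else 100 * abs(fa - fb) / fb
  list(mae = mae, fwhm_error_percent = fe)
}

#' Write an occupancy curve to CSV
#'
#' Two columns, `t_ms` and `P`, in deterministic order.
#'
#' @param P An `"occ_curve"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(P, path) {
  stopifnot(inherits(P, "occ_curve"))
  write.csv(data.frame(t_ms = P$times, P = P$values), path, row.names = FALSE)
  invisible(path)
}

#' Read an occupancy curve from CSV
#'
#' @param path CSV with columns `t_ms` and `P`.
#' @return An `"occ_curve"` with `provenance = "file"`.
#' @export
read_curve_csv <- function(path) {
  d <- read.csv(path)
  .new_curve(d$t_ms, d$P, config = NULL, provenance = "file")
}
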