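#' @useDynLib occusens, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approxfun dbinom optimize pbinom quantile rexp rnorm
#'   runif sd setNames uniroot
#' @importFrom utils modifyList read.csv write.csv
"_PACKAGE"

## Internal unit system: nm, ms, mM.  Avogadro's constant is carried
## explicitly so that bimolecular rate constants quoted in mM^-1 ms^-1 can
## be converted to a per-ion reactive volume in nm^3/ms:
##   1 mM = 1e-3 mol/L, 1 L = 1e24 nm^3  =>  1 mM^-1 = 1e27/N_A nm^3.
AVOGADRO <- 6.02214076e23
MM_INV_MS_TO_NM3_MS <- 1e27 / AVOGADRO

#' Unit conversion constant for bimolecular rate constants
#'
#' Returns the factor converting a rate constant in mM^-1 ms^-1 into a
#' per-ion reactive volume rate in nm^3 ms^-1 (equal to 1e27 / N_A).
#'
#' @return A length-one numeric.
#' @export
kon_unit_factor <- function() MM_INV_MS_TO_NM3_MS

#' Geometry of the active zone
#'
#' The simulation compartment is a reflecting hemisphere of radius `R`
#' containing a partially absorbing hemispherical sensor of radius `rho` at
#' its centre; the calcium source sits on the membrane at radial position
#' `r`, i.e. at coupling distance `r - rho` from the sensor surface. By
#' mirror symmetry in the membrane plane all first-passage quantities are
#' computed in the full spherical shell `rho < |x| < R`.
#'
#' @param R Outer (bouton) radius in nm.
#' @param rho Sensor radius in nm.
#' @param r Radial position of the calcium source in nm. Exactly one of `r`
#'   or `cd` must be given.
#' @param cd Coupling distance `r - rho` in nm (alternative to `r`).
#' @return An object of class `"occ_geometry"` with fields `R`, `rho`, `r`,
#'   and derived `cd`.
#' @export
geometry <- function(R = 300, rho = 5, r = NULL, cd = NULL) {
  if (is.null(r) && is.null(cd)) cd <- 15
  if (!is.null(r) && !is.null(cd) && abs((r - rho) - cd) > 1e-9)
    stop("geometry: both 'r' and 'cd' given but inconsistent")
  if (is.null(r)) r <- rho + cd
  if (!(is.numeric(R) && R > 0)) stop("geometry: 'R' must be positive")
  if (!(rho > 0)) stop("geometry: 'rho' must be positive")
  if (!(rho < r)) stop("geometry: need rho < r (source outside the sensor)")
  if (!(r <= R)) stop("geometry: need r <= R (source inside the bouton)")
  structure(list(R = R, rho = rho, r = r, cd = r - rho),
            class = "occ_geometry")
}

#' Sensor binding kinetics
#'
#' Forward and backward rate constants of the single-site sensor, plus the
#' convention used to spread the intrinsic `k_on` over the sensor surface
#' when forming the Robin (partially absorbing) boundary constant.
#'
#' The `"sphere"` convention divides `k_on` by the full spherical area
#' `4*pi*rho^2` (the form in which the radiation boundary condition is
#' conventionally written for an interaction sphere); `"hemisphere"` divides
#' by the exposed hemispherical area `2*pi*rho^2`, doubling the surface
#' reactivity. See the methods vignette for why both are offered and how
#' they map onto published reference values.
#'
#' @param k_on Forward rate constant in mM^-1 ms^-1 (default `5 * 127`).
#' @param k_off Backward rate constant in ms^-1 (default 15.7).
#' @param area_convention `"sphere"` (default) or `"hemisphere"`. `k_on`
#'   may be `Inf` for a perfectly absorbing sensor.
#' @return An object of class `"occ_sensor"`.
#' @export
sensor_kinetics <- function(k_on = 5 * 127, k_off = 15.7,
                            area_convention = c("sphere", "hemisphere")) {
  area_convention <- match.arg(area_convention)
  if (!(is.numeric(k_on) && k_on >= 0)) stop("sensor_kinetics: 'k_on' must be >= 0")
  if (!(is.numeric(k_off) && is.finite(k_off) && k_off >= 0))
    stop("sensor_kinetics: 'k_off' must be finite and >= 0")
  structure(list(k_on = k_on, k_off = k_off,
                 area_convention = area_convention),
            class = "occ_sensor")
}

#' Calcium buffer specification
#'
#' A buffer is modelled as a continuous homogeneous reactive medium in its
#' linear (low-occupancy) regime: a free ion switches into the buffer-bound
#' state with rate `k_0i = k_on_i * c_i` and back with rate `k_i0`, and
#' while bound diffuses with coefficient `D` (`D = 0` for a fixed buffer).
#' Buffer-bound ions cannot bind the sensor.
#'
#' @param name Label (e.g. `"EFB"`, `"ATP"`, `"EGTA"`).
#' @param D Bound-state diffusion coefficient in um^2/ms (converted to
#'   nm^2/ms internally).
#' @param k_on_i Forward rate constant in mM^-1 ms^-1.
#' @param c_i Total buffer concentration in mM.
#' @param k_i0 Unbinding rate in ms^-1.
#' @return An object of class `"occ_buffer"` with the derived binding rate
#'   `k_0i` in ms^-1.
#' @export
buffer_spec <- function(name, D, k_on_i, c_i, k_i0) {
  vals <- c(D = D, k_on_i = k_on_i, c_i = c_i, k_i0 = k_i0)
  bad <- names(vals)[!is.finite(vals) | vals < 0]
  if (length(bad))
    stop("buffer_spec: field(s) ", paste(bad, collapse = ", "),
         " must be finite and >= 0")
  structure(list(name = as.character(name), D = D * 1e6, # um^2/ms -> nm^2/ms
                 k_on_i = k_on_i, c_i = c_i,
                 k_0i = k_on_i * c_i, k_i0 = k_i0),
            class = "occ_buffer")
}

## Reference buffer rows (diffusion coefficients in um^2/ms).
.buffer_presets <- list(
  EFB  = list(name = "EFB",  D = 0,    k_on_i = 100,  c_i = 4,   k_i0 = 10),
  ATP  = list(name = "ATP",  D = 0.2,  k_on_i = 100,  c_i = 0.2, k_i0 = 10),
  EGTA = list(name = "EGTA", D = 0.22, k_on_i = 10.5, c_i = 10,  k_i0 = 0.000735)
)

#' Reference buffer presets
#'
#' Ready-made [buffer_spec()] objects for the endogenous fixed buffer
#' (EFB, 4 mM), ATP (0.2 mM) and EGTA (10 mM) with their standard kinetic
#' constants.
#'
#' @param name One of `"EFB"`, `"ATP"`, `"EGTA"`.
#' @return An `"occ_buffer"` object.
#' @export
buffer_preset <- function(name = c("EFB", "ATP", "EGTA")) {
  name <- match.arg(name)
  do.call(buffer_spec, .buffer_presets[[name]])
}

#' Full diffusion-reaction model configuration
#'
#' Bundles the geometry, sensor kinetics, free-calcium diffusion coefficient
#' and buffer table into one validated object in internal units (nm, ms,
#' mM). All downstream computations take this object.
#'
#' @param geometry An [geometry()] object.
#' @param sensor A [sensor_kinetics()] object.
#' @param D0 Free-calcium diffusion coefficient in um^2/ms (default 0.22).
#' @param buffers List of [buffer_spec()] objects (possibly empty).
#' @return An object of class `"occ_config"`. The stored `D0` is in nm^2/ms;
#'   `k_on_vol` is the per-ion reactive volume rate in nm^3/ms and `kappa`
#'   the Robin constant in nm/ms under the chosen area convention.
#' @export
model_config <- function(geometry = occusens::geometry(),
                         sensor = sensor_kinetics(),
                         D0 = 0.22, buffers = list()) {
  stopifnot(inherits(geometry, "occ_geometry"), inherits(sensor, "occ_sensor"))
  if (!(is.numeric(D0) && D0 > 0)) stop("model_config: 'D0' must be positive")
  if (!is.list(buffers) || (length(buffers) &&
      !all(vapply(buffers, inherits, logical(1), "occ_buffer"))))
    stop("model_config: 'buffers' must be a list of buffer_spec objects")
  D0nm <- D0 * 1e6
  area <- if (sensor$area_convention == "hemisphere") 2 else 4
  k_on_vol <- sensor$k_on * MM_INV_MS_TO_NM3_MS        # nm^3/ms (Inf allowed)
  kappa <- k_on_vol / (area * pi * geometry$rho^2)      # nm/ms
  structure(list(geometry = geometry, sensor = sensor,
                 D0 = D0nm, buffers = buffers,
                 k_on_vol = k_on_vol, kappa = kappa, N_A = AVOGADRO),
            class = "occ_config")
}

#' @export
print.occ_config <- function(x, ...) {
  g <- x$geometry
  cat("<occ_config>\n")
  cat(sprintf("  geometry : R = %g nm, rho = %g nm, r = %g nm (CD %g nm)\n",
              g$R, g$rho, g$r, g$cd))
  cat(sprintf("  sensor   : k_on = %g mM^-1 ms^-1, k_off = %g ms^-1 (%s)\n",
              x$sensor$k_on, x$sensor$k_off, x$sensor$area_convention))
  cat(sprintf("  D0       : %g um^2/ms\n", x$D0 / 1e6))
  if (length(x$buffers)) {
    for (b in x$buffers)
      cat(sprintf("  buffer %-5s: D = %g um^2/ms, k_0i = %g ms^-1, k_i0 = %g ms^-1\n",
                  b$name, b$D / 1e6, b$k_0i, b$k_i0))
  } else cat("  buffers  : none\n")
  invisible(x)
}

#' Load a model configuration from a YAML/JSON document
#'
#' Reads a structured document with keys `R`, `rho`, and `r` or `CD` (nm),
#' `D0` (um^2/ms), `k_on` (mM^-1 ms^-1), `k_off` (ms^-1), optional
#' `area_convention`, and an optional `buffers` list of records with keys
#' `name`, `D`, `k_on`, `c`, `k_off`. Missing fields fall back to the
#' reference parameter set. A bundled document reproducing the full
#' reference table ships as
#' `system.file("extdata", "reference_config.yaml", package = "occusens")`.
#'
#' @param source Path to a YAML (or JSON) file, or a named list already
#'   parsed from one.
#' @return An `"occ_config"` object.
#' @export
load_config <- function(source) {
  doc <- if (is.character(source)) yaml::read_yaml(source) else source
  if (!is.list(doc)) stop("load_config: source must be a file path or a list")
  geo <- geometry(R = doc[["R"]] %||% 300, rho = doc[["rho"]] %||% 5,
                  r = doc[["r"]],
                  cd = if (is.null(doc[["r"]])) doc[["CD"]] %||% doc[["cd"]] %||% 15)
  sen <- sensor_kinetics(k_on = doc$k_on %||% (5 * 127),
                         k_off = doc$k_off %||% 15.7,
                         area_convention = doc$area_convention %||% "sphere")
  bufs <- lapply(doc$buffers %||% list(), function(b) {
    if (is.character(b) && length(b) == 1L) return(buffer_preset(b))
    buffer_spec(name = b$name %||% "buffer", D = b$D,
                k_on_i = b$k_on, c_i = b$c, k_i0 = b$k_off)
  })
  model_config(geometry = geo, sensor = sen, D0 = doc$D0 %||% 0.22,
               buffers = bufs)
}

#' Serialize a model configuration back to a document list
#'
#' Inverse of [load_config()]: returns a plain named list (units as in the
#' input document: um^2/ms for diffusion coefficients) that round-trips
#' through [load_config()] to an identical configuration.
#'
#' @param config An `"occ_config"` object.
#' @return A named list suitable for `yaml::write_yaml()`.
#' @export
config_to_document <- function(config) {
  stopifnot(inherits(config, "occ_config"))
  list(R = config$geometry$R, rho = config$geometry$rho, r = config$geometry$r,
       D0 = config$D0 / 1e6,
       k_on = config$sensor$k_on, k_off = config$sensor$k_off,
       area_convention = config$sensor$area_convention,
       buffers = lapply(config$buffers, function(b)
         list(name = b$name, D = b$D / 1e6, k_on = b$k_on_i,
              c = b$c_i, k_off = b$k_i0)))
}

#' Dimensionless groups of the no-buffer problem
#'
#' The exact residue representation of the occupancy probability is indexed
#' by three dimensionless parameters: the shell aspect ratio
#' `beta = (R - rho)/rho`, the reduced unbinding rate
#' `lambda = k_off rho^2 / D0`, and the reduced surface reactivity
#' `mu = kappa rho / D0` (equivalently `k_on / (a pi rho D0 N_A)` with
#' `a = 4` or `2` by area convention).
#'
#' @param config An `"occ_config"` object.
#' @return A list with fields `beta`, `lambda`, `mu`.
#' @export
dimensionless_groups <- function(config) {
  stopifnot(inherits(config, "occ_config"))
  g <- config$geometry
  list(beta = (g$R - g$rho) / g$rho,
       lambda = config$sensor$k_off * g$rho^2 / config$D0,
       mu = config$kappa * g$rho / config$D0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
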