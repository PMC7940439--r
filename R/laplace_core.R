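## Laplace-domain solution of the switching-diffusion survival problem.
##
## In the Laplace variable p the backward equations for the survival
## probabilities S_i(t, r) of an ion in state i (0 = free, i >= 1 =
## bound to buffer i) become a coupled radial ODE system on (rho, R):
##
##   D_i Lap S~_i = (p S~_i - 1) - sum_j k_ij (S~_j - S~_i)
##
## with Neumann conditions at R for all states, Neumann at rho for
## buffer-bound states, and a Robin (radiation) condition at rho for the
## free state.  Writing S~ = 1/p + v, the constant part solves the source
## term exactly and v satisfies the homogeneous system D Lap v = B(p) v.
## Fixed buffers (D_i = 0) are eliminated algebraically, giving the free
## state a p-dependent effective exchange rate; mobile buffers are carried
## as extra field components and the coupling matrix is diagonalized per p.
## Each eigenmode q_m^2 contributes two spherical-Helmholtz radial modes,
## kept in overflow-safe scaled form exp(-q(r-rho))/r and exp(q(r-R))/r.

## Split buffers into mobile / fixed; returns index bookkeeping.
.split_buffers <- function(config) {
  D <- vapply(config$buffers, `[[`, numeric(1), "D")
  list(mobile = config$buffers[D > 0], fixed = config$buffers[D == 0])
}

## Per-p boundary solve. Returns an object with everything needed to
## evaluate any S~_i at any radius, or the scalar boundary determinant.
.laplace_modes <- function(config, p) {
  g <- config$geometry
  rho <- g$rho; R <- g$R; D0 <- config$D0
  sp <- .split_buffers(config)
  mob <- sp$mobile; fix <- sp$fixed
  K <- length(mob); n <- K + 1L

  ## effective exchange added to the free state by eliminated fixed buffers
  fix_rate <- if (length(fix))
    sum(vapply(fix, function(b) b$k_0i * p / (p + b$k_i0), complex(1)))
  else 0 + 0i

  B <- matrix(0 + 0i, n, n)
  B[1, 1] <- p + sum(vapply(mob, `[[`, numeric(1), "k_0i")) + fix_rate
  Ds <- c(D0, vapply(mob, `[[`, numeric(1), "D"))
  if (K) for (m in seq_len(K)) {
    B[1, m + 1] <- -mob[[m]]$k_0i
    B[m + 1, 1] <- -mob[[m]]$k_i0
    B[m + 1, m + 1] <- p + mob[[m]]$k_i0
  }
  A <- B / Ds
  if (n == 1L) {
    qs <- sqrt(A[1, 1]); V <- matrix(1 + 0i, 1, 1)
  } else {
    ev <- eigen(A)
    qs <- sqrt(ev$values)
    V <- ev$vectors
  }
  qs[Re(qs) < 0] <- -qs[Re(qs) < 0]   # decaying mode first

  ## radial basis kept well-conditioned over the whole q range:
  ## f1 decays away from the inner sphere; f2 is a scaled sinh that tends
  ## to (r - rho)/r as q -> 0 instead of collapsing onto f1
  f1 <- function(q, r) exp(-q * (r - rho)) / r
  df1 <- function(q, r) (-q - 1 / r) * f1(q, r)
  f2 <- function(q, r) {
    if (abs(q) * (R - rho) < 1e-4) {
      ## series of sinh(q(r-rho))/(q r) * exp(-q(R-rho)) for tiny q
      x <- q * (r - rho)
      (r - rho) / r * (1 + x^2 / 6) * exp(-q * (R - rho))
    } else
      (exp(-q * (R - r)) - exp(-q * (R + r - 2 * rho))) / (2 * q * r)
  }
  df2 <- function(q, r)
    (exp(-q * (R - r)) + exp(-q * (R + r - 2 * rho))) / (2 * r) -
      f2(q, r) / r

  M <- matrix(0 + 0i, 2L * n, 2L * n)
  rhs <- rep(0 + 0i, 2L * n)
  row <- 0L
  for (i in seq_len(n)) {               # Neumann at R, every state
    row <- row + 1L
    for (m in seq_len(n)) {
      M[row, m] <- V[i, m] * df1(qs[m], R)
      M[row, n + m] <- V[i, m] * df2(qs[m], R)
    }
  }
  row <- row + 1L                       # sensor condition, free state
  if (is.infinite(config$k_on_vol)) {   # Dirichlet: S~_0(rho) = 0
    for (m in seq_len(n)) {
      M[row, m] <- V[1, m] * f1(qs[m], rho)
      M[row, n + m] <- V[1, m] * f2(qs[m], rho)
    }
    rhs[row] <- -1 / p
  } else {                              # Robin: D0 dS/dr = kappa S at rho
    kap <- config$kappa
    for (m in seq_len(n)) {
      M[row, m] <- D0 * V[1, m] * df1(qs[m], rho) - kap * V[1, m] * f1(qs[m], rho)
      M[row, n + m] <- D0 * V[1, m] * df2(qs[m], rho) - kap * V[1, m] * f2(qs[m], rho)
    }
    rhs[row] <- kap / p
  }
  if (K) for (i in 2L:n) {              # Neumann at rho, mobile buffers
    row <- row + 1L
    for (m in seq_len(n)) {
      M[row, m] <- V[i, m] * df1(qs[m], rho)
      M[row, n + m] <- V[i, m] * df2(qs[m], rho)
    }
  }
  list(M = M, rhs = rhs, V = V, qs = qs, n = n,
       f1 = f1, f2 = f2, fix = fix, p = p)
}

## Solve the boundary system; error on a numerically singular system.
.laplace_coeffs <- function(modes) {
  x <- tryCatch(solve(modes$M, modes$rhs), error = function(e)
    stop("solve_survival: boundary linear system is numerically degenerate (",
         conditionMessage(e), ")", call. = FALSE))
  x
}

#' Laplace-transformed survival probabilities
#'
#' Solves the radial switching-diffusion boundary-value problem exactly at
#' a (possibly complex) Laplace rate `p` and returns the transformed
#' survival probability of a free-state ion started at radius `r`, together
#' with the buffer-state components.
#'
#' @param config An [model_config()] object.
#' @param p Laplace variable in ms^-1; complex values are allowed.
#' @param r Radius (nm), `rho <= r <= R`; may be a vector.
#' @return A list with `p`, `r`, `S0` (complex vector along `r`), and `Si`
#'   (complex matrix, one column per buffer, ordered as `config$buffers`).
#' @export
solve_survival <- function(config, p, r) {
  stopifnot(inherits(config, "occ_config"))
  g <- config$geometry
  if (any(r < g$rho - 1e-9 | r > g$R + 1e-9))
    stop("solve_survival: r must lie in [rho, R]")
  if (config$k_on_vol == 0 && !is.infinite(config$k_on_vol)) {
    ## no absorption anywhere: survival is identically one
    S0 <- rep(1 / p, length(r))
    Si <- matrix(1 / p, length(r), length(config$buffers))
    return(list(p = p, r = r, S0 = S0, Si = Si))
  }
  modes <- .laplace_modes(config, as.complex(p))
  x <- .laplace_coeffs(modes)
  n <- modes$n
  eval_state <- function(i, rr) {
    v <- 1 / modes$p
    for (m in seq_len(n))
      v <- v + modes$V[i, m] *
        (x[m] * modes$f1(modes$qs[m], rr) + x[n + m] * modes$f2(modes$qs[m], rr))
    v
  }
  S0 <- vapply(r, function(rr) eval_state(1L, rr), complex(1))
  ## reassemble full buffer-state table in the original buffer order
  sp <- .split_buffers(config)
  Si <- matrix(0 + 0i, length(r), length(config$buffers))
  if (length(config$buffers)) {
    Dvals <- vapply(config$buffers, `[[`, numeric(1), "D")
    imob <- 0L
    for (j in seq_along(config$buffers)) {
      if (Dvals[j] > 0) {
        imob <- imob + 1L
        Si[, j] <- vapply(r, function(rr) eval_state(1L + imob, rr), complex(1))
      } else {
        b <- config$buffers[[j]]
        Si[, j] <- (1 + b$k_i0 * S0) / (modes$p + b$k_i0)
      }
    }
  }
  list(p = p, r = r, S0 = S0, Si = Si)
}

## Internal: S~_0 at both the requested radius and the sensor surface with
## a single boundary solve (used by the occupancy transform and inversion).
.s0_pair <- function(config, p, r) {
  g <- config$geometry
  if (config$k_on_vol == 0 && !is.infinite(config$k_on_vol))
    return(c(1 / p, 1 / p))
  modes <- .laplace_modes(config, as.complex(p))
  x <- .laplace_coeffs(modes)
  n <- modes$n
  ev <- function(rr) {
    v <- 1 / modes$p
    for (m in seq_len(n))
      v <- v + modes$V[1, m] *
        (x[m] * modes$f1(modes$qs[m], rr) + x[n + m] * modes$f2(modes$qs[m], rr))
    v
  }
  c(ev(r), ev(g$rho))
}

#' Laplace-transformed occupancy probability
#'
#' Combines the first-binding density `psi1~(p, r) = 1 - p S0~(p, r)`, the
#' re-binding density `psi~(p) = psi1~(p, rho)`, and the exponential
#' residence time on the sensor through the renewal identity
#' `P~(p, r) = psi1~(p, r) / (p + k_off (1 - psi~(p)))`.
#'
#' @inheritParams solve_survival
#' @param r Single radius (nm); defaults to the configured source position.
#' @return A list with `p`, `r`, `P` (complex), `psi1`, `psi`.
#' @export
occupancy_laplace <- function(config, p, r = config$geometry$r) {
  stopifnot(inherits(config, "occ_config"), length(r) == 1L)
  s <- .s0_pair(config, p, r)
  psi1 <- 1 - p * s[1]
  psi <- 1 - p * s[2]
  P <- psi1 / (p + config$sensor$k_off * (1 - psi))
  list(p = p, r = r, P = P, psi1 = psi1, psi = psi)
}

## Real-arithmetic variant of the boundary system for real (negative) p,
## used by the pole search: all eigenvalues of the coupling matrix are
## real there, and a real radial basis (cos/sin for oscillatory modes,
## exp/scaled-sinh for decaying ones) keeps the boundary determinant a
## real, sign-scannable function of p.
.real_modes <- function(config, p) {
  g <- config$geometry
  rho <- g$rho; R <- g$R; D0 <- config$D0
  sp <- .split_buffers(config)
  mob <- sp$mobile; fix <- sp$fixed
  K <- length(mob); n <- K + 1L
  fix_rate <- if (length(fix))
    sum(vapply(fix, function(b) b$k_0i * p / (p + b$k_i0), numeric(1)))
  else 0
  B <- matrix(0, n, n)
  B[1, 1] <- p + sum(vapply(mob, `[[`, numeric(1), "k_0i")) + fix_rate
  Ds <- c(D0, vapply(mob, `[[`, numeric(1), "D"))
  if (K) for (m in seq_len(K)) {
    B[1, m + 1] <- -mob[[m]]$k_0i
    B[m + 1, 1] <- -mob[[m]]$k_i0
    B[m + 1, m + 1] <- p + mob[[m]]$k_i0
  }
  A <- B / Ds
  if (n == 1L) { q2s <- A[1, 1]; V <- matrix(1, 1, 1) } else {
    ev <- eigen(A)
    if (is.complex(ev$values))
      stop("solve_survival: complex relaxation eigenvalues on the real axis")
    q2s <- ev$values; V <- ev$vectors
  }
  ## real radial basis per mode, continuous across q2 = 0
  phi <- function(q2, r, deriv = FALSE) {
    if (q2 > 1e-12) {
      q <- sqrt(q2)
      p1 <- exp(-q * (r - rho)) / r
      p2 <- (exp(-q * (R - r)) - exp(-q * (R + r - 2 * rho))) / (2 * q * r)
      if (!deriv) return(c(p1, p2))
      c((-q - 1 / r) * p1,
        (exp(-q * (R - r)) + exp(-q * (R + r - 2 * rho))) / (2 * r) - p2 / r)
    } else if (q2 < -1e-12) {
      w <- sqrt(-q2)
      x <- w * (r - rho)
      p1 <- cos(x) / r
      p2 <- sin(x) / (w * r)
      if (!deriv) return(c(p1, p2))
      c(-w * sin(x) / r - p1 / r, cos(x) / r - p2 / r)
    } else {
      p1 <- 1 / r; p2 <- (r - rho) / r
      if (!deriv) return(c(p1, p2))
      c(-1 / r^2, rho / r^2)
    }
  }
  M <- matrix(0, 2L * n, 2L * n)
  rhs <- numeric(2L * n)
  row <- 0L
  for (i in seq_len(n)) {
    row <- row + 1L
    for (m in seq_len(n)) {
      d <- phi(q2s[m], R, deriv = TRUE)
      M[row, m] <- V[i, m] * d[1]
      M[row, n + m] <- V[i, m] * d[2]
    }
  }
  row <- row + 1L
  kap <- config$kappa
  for (m in seq_len(n)) {
    d <- phi(q2s[m], rho, deriv = TRUE)
    f <- phi(q2s[m], rho)
    if (is.infinite(config$k_on_vol)) {
      M[row, m] <- V[1, m] * f[1]
      M[row, n + m] <- V[1, m] * f[2]
    } else {
      M[row, m] <- D0 * V[1, m] * d[1] - kap * V[1, m] * f[1]
      M[row, n + m] <- D0 * V[1, m] * d[2] - kap * V[1, m] * f[2]
    }
  }
  rhs[row] <- if (is.infinite(config$k_on_vol)) -1 / p else kap / p
  if (K) for (i in 2L:n) {
    row <- row + 1L
    for (m in seq_len(n)) {
      d <- phi(q2s[m], rho, deriv = TRUE)
      M[row, m] <- V[i, m] * d[1]
      M[row, n + m] <- V[i, m] * d[2]
    }
  }
  list(M = M, rhs = rhs, V = V, q2s = q2s, n = n, phi = phi, p = p)
}
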