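## Shared fixtures and independent oracles for the test suite.

ref_config <- function(cd = 15, R = 300, k_on = 5 * 127, k_off = 15.7,
                       buffers = list(), area = "sphere") {
  model_config(geometry = geometry(R = R, cd = cd),
               sensor = sensor_kinetics(k_on = k_on, k_off = k_off,
                                        area_convention = area),
               buffers = buffers)
}

## Independent finite-difference boundary-value oracle for the
## Laplace-domain survival system: second-order central differences on a
## uniform radial grid, with the full coupled (M+1)-state system assembled
## as one sparse linear problem (fixed buffers enter as algebraic rows).
## Richardson extrapolation of two grids upgrades the result to ~4th order.
fd_survival_oracle <- function(config, p, r_eval, n_grid = 2361) {
  solve_once <- function(N) {
    g <- config$geometry
    rho <- g$rho; R <- g$R; D0 <- config$D0
    h <- (R - rho) / (N - 1)
    rg <- seq(rho, R, length.out = N)
    M <- length(config$buffers)
    nst <- M + 1L
    Ds <- c(D0, vapply(config$buffers, `[[`, numeric(1), "D"))
    k0i <- vapply(config$buffers, `[[`, numeric(1), "k_0i")
    ki0 <- vapply(config$buffers, `[[`, numeric(1), "k_i0")
    idx <- function(i, j) (i - 1L) * N + j     # state i (1-based), grid j
    trip <- list(i = integer(0), j = integer(0), x = numeric(0))
    rhs <- numeric(nst * N)
    add <- function(i, j, x) {
      trip$i <<- c(trip$i, i); trip$j <<- c(trip$j, j); trip$x <<- c(trip$x, x)
    }
    for (i in seq_len(nst)) {
      D <- Ds[i]
      for (j in seq_len(N)) {
        row <- idx(i, j)
        if (D == 0) {
          ## algebraic fixed-buffer row: (p + ki0) S_i - ki0 S_0 = 1
          add(row, idx(i, j), p + ki0[i - 1L])
          add(row, idx(1L, j), -ki0[i - 1L])
          rhs[row] <- 1
          next
        }
        rj <- rg[j]
        cm <- D * (1 / h^2 - 1 / (h * rj))   # S_{j-1}
        cp <- D * (1 / h^2 + 1 / (h * rj))   # S_{j+1}
        add_exchange <- function(row, j) {
          if (i == 1L && M > 0) {
            add(row, idx(1L, j), -sum(k0i))
            for (m in seq_len(M)) add(row, idx(m + 1L, j), k0i[m])
          } else if (i > 1L) {
            add(row, idx(i, j), -ki0[i - 1L])
            add(row, idx(1L, j), ki0[i - 1L])
          }
        }
        if (j == 1L) {
          ## ghost node eliminated through the sensor boundary condition
          ## (keeps the scheme fully centred, so errors are pure h^2/h^4)
          if (i == 1L && is.infinite(config$k_on_vol)) {
            add(row, idx(i, 1L), 1); rhs[row] <- 0
          } else {
            kap <- if (i == 1L) config$kappa else 0
            ## Robin: D (S_2 - S_g)/(2h) = kap S_1 => S_g = S_2 - 2h kap S_1 / D
            add(row, idx(i, 1L), -2 * D / h^2 - p - cm * 2 * h * kap / D)
            add(row, idx(i, 2L), cp + cm)
            add_exchange(row, 1L)
            rhs[row] <- -1
          }
        } else if (j == N) {
          ## outer Neumann: ghost S_{N+1} = S_{N-1}
          add(row, idx(i, N - 1L), cm + cp)
          add(row, idx(i, N), -2 * D / h^2 - p)
          add_exchange(row, N)
          rhs[row] <- -1
        } else {
          add(row, idx(i, j - 1L), cm)
          add(row, idx(i, j), -2 * D / h^2 - p)
          add(row, idx(i, j + 1L), cp)
          add_exchange(row, j)
          rhs[row] <- -1
        }
      }
    }
    A <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                              dims = c(nst * N, nst * N))
    sol <- as.numeric(Matrix::solve(A, rhs))
    spline(rg, sol[seq_len(N)], xout = r_eval)$y
  }
  s1 <- solve_once(n_grid)
  s2 <- solve_once(2L * n_grid - 1L)   # exact step halving for Richardson
  (4 * s2 - s1) / 3
}

## Brute-force dense-scan root oracle for the no-buffer spectrum equation.
dense_root_oracle <- function(groups, upper, n_scan = 1e6) {
  f <- occusens:::.root_fn(groups)
  a <- seq(upper / n_scan, upper, length.out = n_scan)
  fv <- f(a)
  i <- which(sign(fv[-1]) != sign(fv[-n_scan]))
  vapply(i, function(k)
    uniroot(f, c(a[k], a[k + 1]), tol = 1e-15)$root, numeric(1))
}
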