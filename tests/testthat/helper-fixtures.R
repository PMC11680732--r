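# shared fixtures, memoized so expensive simulations run once per session
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

default_scheme <- function() memo("scheme", sat_scheme())

striatum_zspec <- function() {
  memo("striatum_z", simulate_zspectrum(striatum_system(), default_scheme()))
}

# noise floor threshold consistent with sigma, for multistart early exit
rss_floor <- function(sigma, n = 51) max(1e-10, (n + 3 * sqrt(2 * n)) * sigma^2)

# independent super-Lorentzian quadrature oracle (adaptive integration,
# no shared code with the package's Gauss-Legendre implementation)
sl_oracle <- function(delta_hz, t2_s) {
  f <- function(th) {
    u <- 3 * cos(th)^2 - 1
    sqrt(2 / pi) * sin(th) * (t2_s / abs(u)) *
      exp(-2 * (2 * pi * delta_hz * t2_s / u)^2)
  }
  stats::integrate(f, 0, pi / 2, subdivisions = 10000L,
                   rel.tol = 1e-12)$value
}

# independent two-pool Bloch-McConnell matrix (water + one Lorentzian pool),
# hand-built for steady-state oracles; state (xw, yw, zw, xs, ys, zs)
two_pool_matrix <- function(delta_s_ppm, kex_hz, f_s, t1_s, t2w_s, t2s_s,
                            offset_ppm, b1_ut, larmor_mhz = 499.9) {
  w1 <- 2 * pi * 42.577 * b1_ut
  dww <- 2 * pi * (0 - offset_ppm) * larmor_mhz
  dws <- 2 * pi * (delta_s_ppm - offset_ppm) * larmor_mhz
  k <- kex_hz; fk <- f_s * kex_hz
  r1 <- 1 / t1_s; r2w <- 1 / t2w_s; r2s <- 1 / t2s_s
  A <- matrix(0, 6, 6)
  A[1, ] <- c(-r2w - fk, dww, 0, k, 0, 0)
  A[2, ] <- c(-dww, -r2w - fk, w1, 0, k, 0)
  A[3, ] <- c(0, -w1, -r1 - fk, 0, 0, k)
  A[4, ] <- c(fk, 0, 0, -r2s - k, dws, 0)
  A[5, ] <- c(0, fk, 0, -dws, -r2s - k, w1)
  A[6, ] <- c(0, 0, fk, 0, -w1, -r1 - k)
  b <- c(0, 0, r1 * 1, 0, 0, r1 * f_s)
  list(A = A, b = b)
}
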