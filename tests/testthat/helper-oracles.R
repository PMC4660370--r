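# Independent oracles used to check the package implementations. These are
# deliberately naive (closed forms, brute-force sums, generic root finding)
# and share no code with the functions under test.

# Brute-force Debye double sum over all bead pairs (O(N^2), exact sinc).
oracle_debye <- function(centers, radii, q, weights = 1) {
  n <- nrow(centers)
  radii <- rep_len(radii, n)
  weights <- rep_len(weights, n)
  V <- 4 / 3 * pi * radii^3
  amp <- function(x) ifelse(x < 1e-8, 1, 3 * (sin(x) - x * cos(x)) / x^3)
  D <- as.matrix(dist(centers))
  vapply(q, function(qq) {
    f <- weights * V * amp(qq * radii)
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      x <- qq * D[i, j]
      s <- s + f[i] * f[j] * (if (x < 1e-8) 1 else sin(x) / x)
    }
    s
  }, numeric(1))
}

# Closed-form pair-distance distribution of a homogeneous sphere of radius R
# (unnormalized): p(r) = r^2 (1 - 3u/2 + u^3/2), u = r / (2R), 0 <= r <= 2R.
oracle_sphere_pofr <- function(r, R) {
  u <- r / (2 * R)
  p <- r^2 * (1 - 1.5 * u + 0.5 * u^3)
  p[u > 1] <- 0
  p
}

# Exact sphere form-factor intensity, I0 at q -> 0.
oracle_sphere_curve <- function(q, R, I0 = 100) {
  x <- q * R
  I0 * (3 * (sin(x) - x * cos(x)) / x^3)^2
}

# Independent single-site ITC heats: the same continuous-dilution
# concentrations, but the equilibrium is solved numerically for the free
# ligand with uniroot instead of the closed-form quadratic.
oracle_itc_heats <- function(protocol, n, Ka, dH) {
  V0 <- protocol$cell_volume_uL
  cum <- c(0, cumsum(protocol$injection_volumes_uL))
  f <- exp(-cum / V0)
  Mt <- protocol$cell_conc_uM * 1e-6 * f
  Xt <- protocol$syringe_conc_uM * 1e-6 * (1 - f)
  bound <- mapply(function(M, X) {
    if (X <= 0) return(0)
    g <- function(xf) xf + n * M * Ka * xf / (1 + Ka * xf) - X
    gp <- function(xf) 1 + n * M * Ka / (1 + Ka * xf)^2
    xf <- uniroot(g, c(0, X), tol = 1e-15)$root
    for (i in 1:4) xf <- xf - g(xf) / gp(xf)   # polish to machine precision
    n * M * Ka * xf / (1 + Ka * xf)
  }, Mt, Xt)
  Q <- bound * V0 * 1e-6 * dH * 1e9
  dV <- protocol$injection_volumes_uL
  i <- seq_along(dV) + 1L
  Q[i] - Q[i - 1L] + (dV / V0) * (Q[i] + Q[i - 1L]) / 2
}

# Default truth sets used across the kinetics tests (inhibition constants in
# uM; alpha/beta dimensionless).
kin_truths <- list(
  GMP = list(mechanism = "competitive", Vmax = 1, Km = 51, Ki = 600),
  GDP = list(mechanism = "mixed", Vmax = 1, Km = 51, Ki = 210,
             alpha = 6.5, beta = 0.033),
  GTP = list(mechanism = "mixed", Vmax = 1, Km = 51, Ki = 160,
             alpha = 4.1, beta = 0.24))

itc_truths <- list(
  apo = list(n = 1, Kd_uM = 1.7, dH = -26.4),
  GTP = list(n = 1, Kd_uM = 26, dH = -55.0),
  GDP = list(n = 1, Kd_uM = 63, dH = -30.9))
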