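# Shared fixtures and independent oracles. Expensive lineshape tables are
# built lazily once per test run.

.fixture_env <- new.env(parent = emptyenv())

# overdamped-only bath, 100 cm^-1 reorganization, moderately fast
shared_lt <- function() {
  if (is.null(.fixture_env$lt)) {
    .fixture_env$lt <- lineshape_function(
      spectral_density(lambda_c = 100, gamma_c = 53), temperature = 300)
  }
  .fixture_env$lt
}

# slow environmental bath for Stokes-shift checks (slow-modulation limit)
shared_lt_slow <- function() {
  if (is.null(.fixture_env$lt_slow)) {
    .fixture_env$lt_slow <- lineshape_function(
      spectral_density(lambda_c = 200, gamma_c = 5), temperature = 300)
  }
  .fixture_env$lt_slow
}

rand_system <- function(n, seed, with_centers = TRUE) {
  set.seed(seed)
  sites <- lapply(seq_len(n), function(i) {
    pigment_site(paste0("s", i),
                 energy = runif(1, 14500, 16500),
                 dipole = rnorm(3),
                 center = if (with_centers) runif(3, 0, 30) else rep(NA_real_, 3))
  })
  v <- matrix(rnorm(n * n, 0, 60), n, n)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  build_system(sites, v)
}

# independent dihedral oracle: projection onto the plane normal to the
# central bond (textbook formula, no shared code with torsion())
oracle_dihedral <- function(p) {
  b1 <- p[1, ] - p[2, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  b2n <- b2 / sqrt(sum(b2^2))
  v <- b1 - sum(b1 * b2n) * b2n     # component of a->1 bond normal to axis
  w <- b3 - sum(b3 * b2n) * b2n
  x <- sum(v * w)
  y <- sum(.cross_oracle(b2n, v) * w)
  -atan2(y, x) * 180 / pi
}
.cross_oracle <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# direct half-Fourier monomer absorption oracle (independent of the
# spectra code path; same grid/window contract)
oracle_monomer_od <- function(energy, dipole2, lt, grid) {
  u <- 2 * pi * 2.99792458e-5
  tg <- lt$t
  win <- rep(1, length(tg))
  t0 <- max(tg) * 0.8
  i <- tg > t0
  win[i] <- 0.5 * (1 + cos(pi * (tg[i] - t0) / (max(tg) - t0)))
  dt <- diff(tg)
  wts <- c(dt[1] / 2, (dt[-1] + dt[-length(dt)]) / 2, dt[length(dt)] / 2)
  s <- dipole2 * exp(-1i * u * energy * tg - lt$g) * wts * win
  vapply(grid, function(nu) {
    Re(sum(exp(1i * u * nu * tg) * s)) / pi
  }, numeric(1))
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y)), tol)
}
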