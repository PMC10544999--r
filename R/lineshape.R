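#' Lineshape function g(t) from a spectral density
#'
#' Computes the second-order cumulant lineshape function
#' \deqn{g(t) = \frac{1}{\pi}\int_0^\infty d\omega \frac{J(\omega)}{\omega^2}
#'   \left[\coth\!\left(\frac{\hbar\omega}{2k_BT}\right)(1-\cos\omega t)
#'   + i(\sin\omega t - \omega t)\right]}
#' together with its first two time derivatives (the second derivative is
#' the bath correlation function).  Frequencies are in cm^-1, times in fs;
#' g is dimensionless (phases use 2 pi c omega t).
#'
#' The overdamped-Brownian-oscillator part is evaluated in closed form
#' (exponential plus Matsubara series -- its slowly decaying 1/omega
#' spectral tail makes the correlation function hostile to quadrature),
#' while the discrete-mode part, whose integrands fall off as fast powers
#' of omega, is integrated by trapezoid on a grid fine enough to resolve
#' both the narrowest mode and the fastest oscillation at the largest
#' requested time.  The secular linear term -i lambda t uses the
#' closed-form reorganization energy, so the long-time slope of Im g is
#' exact.
#'
#' @param sd A [spectral_density()].
#' @param temperature Temperature in Kelvin (> 0).
#' @param t_grid Time grid in fs, starting at 0, strictly increasing.
#'   Default 0 to 3000 fs at 1 fs.
#' @return Object of class `lineshape_table` with fields `t` (fs), `g`,
#'   `gdot` (fs^-1), `gddot` (fs^-2) (complex), `lambda` (cm^-1),
#'   `temperature` (K) and `sd`.
#' @export
#' @examples
#' sd <- spectral_density(lambda_c = 100, gamma_c = 50)
#' lt <- lineshape_function(sd, 300, seq(0, 500, by = 1))
#' lt$g[1]  # exactly 0
lineshape_function <- function(sd, temperature = 300,
                               t_grid = seq(0, 3000, by = 1)) {
  stopifnot(inherits(sd, "spectral_density"))
  stopifnot(is.numeric(temperature), temperature > 0)
  t_grid <- as.numeric(t_grid)
  if (t_grid[1] != 0 || any(diff(t_grid) <= 0)) {
    stop("t_grid must start at 0 and be strictly increasing")
  }
  kT <- kT_cm1(temperature)
  lambda <- reorganization_energy(sd)
  tmax <- max(t_grid)
  u <- CM1_TO_RADFS
  nt <- length(t_grid)
  g <- complex(length.out = nt)
  gdot <- complex(length.out = nt)
  gddot <- complex(length.out = nt)

  ## --- overdamped Brownian oscillator: closed form with Matsubara series
  if (sd$lambda_c > 0) {
    gam <- sd$gamma_c
    nu <- 2 * pi * kT * seq_len(200)          # Matsubara frequencies, cm^-1
    if (any(abs(nu - gam) < 1e-6)) gam <- gam * (1 + 1e-9)
    ## per-exponential amplitudes c_j (cm^-2) and decay rates r_j (cm^-1):
    ## C(t) = u^2 sum_j c_j exp(-u r_j t)
    cj <- c(sd$lambda_c * gam * complex(real = 1 / tan(gam / (2 * kT)),
                                        imaginary = -1),
            4 * sd$lambda_c * gam * kT * nu / (nu^2 - gam^2) + 0i)
    rj <- c(gam, nu)
    for (j in seq_along(rj)) {
      a <- u * rj[j]
      e <- exp(-a * t_grid)
      g <- g + u^2 * cj[j] * (e + a * t_grid - 1) / a^2
      gdot <- gdot + u^2 * cj[j] * (1 - e) / a
      gddot <- gddot + u^2 * cj[j] * e
    }
    ## the series already carries its exact secular part: the asymptotic
    ## Im slope is u * sum(Im(cj)/rj) = -u * lambda_c identically
  }

  ## --- discrete modes: quadrature (integrands decay fast in omega)
  if (nrow(sd$modes)) {
    modes_sd <- spectral_density(lambda_c = 0, gamma_c = sd$gamma_c,
                                 modes = sd$modes)
    gamma_min <- min(sd$modes$gamma_cm1)
    w_hi <- max(sd$modes$omega_cm1 + 20 * sd$modes$gamma_cm1, 4 * kT, 500)
    dw <- min(gamma_min / 10, (2 * pi / (u * max(tmax, 1))) / 8)
    dw <- max(dw, w_hi / 40000)  # cap the grid size
    w <- c(seq(dw, w_hi, by = dw), w_hi * 1.15^(1:40))
    J <- evaluate_J(modes_sd, w)
    pref <- J / (pi * w^2)
    cth <- 1 / tanh(w / (2 * kT))
    wts_full <- .trap_weights(c(0, w))
    w0wt <- wts_full[1]
    wt <- wts_full[-1]
    ## omega -> 0 limit of the integrand is finite (slope J'(0) survives)
    Jp0 <- sum(2 * sd$modes$S * sd$modes$gamma_cm1 / sd$modes$omega_cm1)
    ## normalize the quadrature so the modes' reorganization energy is
    ## exact: g'(0) then vanishes identically and the secular slope is
    ## consistent with the closed-form lambda
    lam_modes <- sum(sd$modes$S * sd$modes$omega_cm1)
    lam_quad <- (sum(wt * J / w) + w0wt * Jp0) / pi
    scl <- lam_modes / lam_quad
    a_re <- scl * wt * pref * cth
    a_im <- scl * wt * pref
    w0wt <- scl * w0wt
    block <- 1024L
    for (i0 in seq(1L, nt, by = block)) {
      idx <- i0:min(i0 + block - 1L, nt)
      ph <- outer(w * u, t_grid[idx])        # nw x nb phase matrix
      cph <- cos(ph); sph <- sin(ph)
      tb <- t_grid[idx]
      g[idx] <- g[idx] + complex(
        real = colSums(a_re * (1 - cph)) + w0wt * Jp0 * kT * u^2 * tb^2 / pi,
        imaginary = colSums(a_im * sph) + w0wt * Jp0 * u * tb / pi)
      gdot[idx] <- gdot[idx] + complex(
        real = colSums(a_re * (w * u) * sph) + w0wt * 2 * Jp0 * kT * u^2 * tb / pi,
        imaginary = colSums(a_im * (w * u) * cph) + w0wt * Jp0 * u / pi)
      gddot[idx] <- gddot[idx] + complex(
        real = colSums(a_re * (w * u)^2 * cph) + w0wt * 2 * Jp0 * kT * u^2 / pi,
        imaginary = -colSums(a_im * (w * u)^2 * sph))
    }
    ## the mode quadrature contains sin(wt), not sin(wt) - wt: add the
    ## modes' secular term from the closed-form mode reorganization
    g <- g - 1i * u * lam_modes * t_grid
    gdot <- gdot - 1i * u * lam_modes
  }
  structure(list(t = t_grid, g = g, gdot = gdot, gddot = gddot,
                 lambda = lambda, temperature = temperature, sd = sd),
            class = "lineshape_table")
}

#' @export
print.lineshape_table <- function(x, ...) {
  cat(sprintf("lineshape_table: %d times to %g fs, lambda = %g cm^-1, T = %g K\n",
              length(x$t), max(x$t), x$lambda, x$temperature))
  invisible(x)
}

.trap_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}

#' Cumulative trapezoid integral
#'
#' @param y Values on grid `x` (numeric or complex).
#' @param x Strictly increasing grid.
#' @return Vector of the same length: the running integral of `y` from the
#'   start of `x`.
#' @keywords internal
cumtrapz <- function(y, x) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

#' Half-Fourier transform of a time-domain response
#'
#' Computes `Re (1/pi) int_0^T e^{i 2 pi c nu t} S(t) W(t) dt` on a
#' wavenumber grid, where W is a raised-cosine window over the final
#' `tail_fraction` of the record that suppresses truncation ringing.
#'
#' @param response Complex vector S(t) on `t_grid`.
#' @param t_grid Time grid in fs (from 0).
#' @param wavenumber_grid Output grid in cm^-1.
#' @param tail_fraction Fraction of the record tapered (default 0.2).
#' @return Numeric vector of spectral intensity (arbitrary units).
#' @export
half_fourier_spectrum <- function(response, t_grid, wavenumber_grid,
                                  tail_fraction = 0.2) {
  stopifnot(length(response) == length(t_grid))
  win <- cosine_tail_window(t_grid, tail_fraction)
  wts <- .trap_weights(t_grid) * win
  s <- response * wts
  u <- CM1_TO_RADFS
  out <- numeric(length(wavenumber_grid))
  block <- 2048L
  for (i0 in seq(1L, length(wavenumber_grid), by = block)) {
    idx <- i0:min(i0 + block - 1L, length(wavenumber_grid))
    ph <- outer(wavenumber_grid[idx] * u, t_grid)   # nb x nt
    out[idx] <- cos(ph) %*% Re(s) - sin(ph) %*% Im(s)
  }
  out / pi
}

#' Raised-cosine tail window
#'
#' @inheritParams half_fourier_spectrum
#' @return Numeric weights in `[0, 1]`.
#' @export
cosine_tail_window <- function(t_grid, tail_fraction = 0.2) {
  tmax <- max(t_grid)
  t0 <- tmax * (1 - tail_fraction)
  w <- rep(1, length(t_grid))
  i <- t_grid > t0
  w[i] <- 0.5 * (1 + cos(pi * (t_grid[i] - t0) / (tmax - t0)))
  w
}
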