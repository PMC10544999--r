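#' Modified Redfield relaxation rates
#'
#' Population transfer rates between exciton states in modified Redfield
#' theory: diagonal exciton-bath fluctuations are treated to all orders via
#' the lineshape tensors, off-diagonal fluctuations to second order.  With
#' purely site-diagonal, mutually uncorrelated baths, every lineshape
#' tensor g_{abcd} reduces to sum_n C_na C_nb C_nc C_nd g_n(t), fully
#' symmetric in its indices, and the standard rate expression takes the
#' form (initial state k relaxed on its own surface, final state k')
#' \deqn{k_{k'\leftarrow k} = 2\,\mathrm{Re}\int_0^\infty dt\,
#'  e^{i(\omega_k-\omega_{k'})t + 2i(\lambda_{kkk'k'}-\lambda_{kkkk})t}
#'  e^{-g_{kkkk}-g_{k'k'k'k'}+2g_{kkk'k'}}
#'  \left\{\ddot g_{kkk'k'} - \left[\dot g_{kkkk'}-\dot g_{kk'k'k'}
#'   + 2i\lambda_{kkkk'}\right]^2\right\}}
#' integrated on the lineshape-table time grid with a cosine tail window.
#' In the weak-coupling localized limit this reduces to the Foerster
#' donor-emission/acceptor-absorption overlap rate.
#'
#' @param states An `exciton_states`.
#' @param system The `exciton_system`.
#' @param lineshapes One shared [lineshape_function()] table or a list with
#'   one table per site (shared time grid).
#' @param tail_tol Convergence guard: the modulus of the integrand at the
#'   end of the grid must fall below `tail_tol` times its maximum,
#'   otherwise the time grid is declared too short and an error is raised
#'   (never silently truncated).  The default 0.05 tolerates picosecond
#'   ringing of weakly damped vibronic coherences, which the cosine tail
#'   window suppresses in the quadrature.
#' @return N x N rate matrix in fs^-1; entry `[k', k]` is the rate from
#'   state k to state k', the diagonal holds minus the total depopulation
#'   rate of each column's state (so lifetimes are `-1/diag`).
#' @export
modified_redfield_rates <- function(states, system, lineshapes, tail_tol = 0.05) {
  sl <- .site_lineshapes(system, lineshapes)
  coef <- states$coefficients
  nk <- length(states$energies)
  tg <- sl$tables[[1]]$t
  u <- CM1_TO_RADFS
  rates <- matrix(0, nk, nk)
  if (nk == 1L) return(rates)
  win <- cosine_tail_window(tg)
  wts <- .trap_weights(tg)
  for (k in seq_len(nk)) {
    for (kp in seq_len(nk)) {
      if (kp == k) next
      g_kk <- .tensor_series(coef, sl$group, sl$tables, "g", k, k, k, k)
      g_pp <- .tensor_series(coef, sl$group, sl$tables, "g", kp, kp, kp, kp)
      g_kp <- .tensor_series(coef, sl$group, sl$tables, "g", k, k, kp, kp)
      gd3k <- .tensor_series(coef, sl$group, sl$tables, "gdot", k, k, k, kp)
      gd3p <- .tensor_series(coef, sl$group, sl$tables, "gdot", k, kp, kp, kp)
      gdd_kp <- .tensor_series(coef, sl$group, sl$tables, "gddot", k, k, kp, kp)
      lam_kk <- .tensor_lambda(coef, sl$group, sl$tables, k, k, k, k)
      lam_kp <- .tensor_lambda(coef, sl$group, sl$tables, k, k, kp, kp)
      lam_3k <- .tensor_lambda(coef, sl$group, sl$tables, k, k, k, kp)
      if (all(g_kp == 0) && all(gd3p == 0) && all(gd3k == 0)) next
      ## initial state k relaxes on its own surface: donor-emission phase
      phase <- 1i * u * (states$energies[k] - states$energies[kp] +
                           2 * (lam_kp - lam_kk)) * tg
      env <- exp(phase - g_kk - g_pp + 2 * g_kp)
      brack <- gd3k - gd3p + 2i * u * lam_3k
      integrand <- env * (gdd_kp - brack^2)
      m <- abs(integrand)
      if (max(m) > 0 && m[length(m)] > tail_tol * max(m)) {
        stop(sprintf(
          "modified Redfield integrand not decayed at t = %g fs (tail %.2g of max); extend the time grid",
          max(tg), m[length(m)] / max(m)))
      }
      val <- 2 * Re(sum(wts * win * integrand))
      rates[kp, k] <- max(val, 0)
    }
  }
  diag(rates) <- -colSums(rates)
  rates
}

#' Exciton state lifetimes
#'
#' @param rates Rate matrix from [modified_redfield_rates()].
#' @return Per-state depopulation lifetimes in fs (`Inf` for stable states).
#' @export
state_lifetimes <- function(rates) {
  dep <- -diag(rates)
  ifelse(dep > 0, 1 / dep, Inf)
}
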