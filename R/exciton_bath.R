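#' Internal: per-site lineshape bookkeeping
#'
#' Spectra and rate routines accept either one `lineshape_table` shared by
#' all sites (the default modelling choice: one bath per pigment type, here
#' collapsed to one per system) or a list with one table per site.  Site
#' fluctuations are assumed mutually uncorrelated, so every exciton-basis
#' bath tensor is a coefficient-weighted sum of site lineshape functions:
#' g_{abcd}(t) = sum_n C_na C_nb C_nc C_nd g_n(t).
#'
#' @keywords internal
#' @noRd
.site_lineshapes <- function(system, lineshapes) {
  n <- n_sites(system)
  if (inherits(lineshapes, "lineshape_table")) {
    return(list(tables = list(lineshapes), group = rep(1L, n)))
  }
  stopifnot(is.list(lineshapes), length(lineshapes) == n)
  ok <- vapply(lineshapes, inherits, logical(1), "lineshape_table")
  if (!all(ok)) stop("lineshapes must be lineshape_table objects (one per site)")
  t0 <- lineshapes[[1]]$t
  for (lt in lineshapes) {
    if (length(lt$t) != length(t0) || any(lt$t != t0)) {
      stop("all site lineshape tables must share one time grid")
    }
  }
  ## group identical tables to avoid recomputation
  group <- integer(n)
  tables <- list()
  for (i in seq_len(n)) {
    hit <- 0L
    for (j in seq_along(tables)) {
      if (identical(tables[[j]], lineshapes[[i]])) { hit <- j; break }
    }
    if (hit == 0L) { tables[[length(tables) + 1L]] <- lineshapes[[i]]; hit <- length(tables) }
    group[i] <- hit
  }
  list(tables = tables, group = group)
}

## weight sum_n-in-group C_na C_nb C_nc C_nd for one group g
.tensor_weight <- function(coef, group, g, a, b, c, d) {
  idx <- which(group == g)
  sum(coef[idx, a] * coef[idx, b] * coef[idx, c] * coef[idx, d])
}

## exciton-basis tensor time series: sum over groups of weight * series
.tensor_series <- function(coef, group, tables, field, a, b, c, d) {
  out <- 0
  for (g in seq_along(tables)) {
    w <- .tensor_weight(coef, group, g, a, b, c, d)
    if (w != 0) out <- out + w * tables[[g]][[field]]
  }
  out
}

## exciton-basis reorganization tensor (cm^-1)
.tensor_lambda <- function(coef, group, tables, a, b, c, d) {
  out <- 0
  for (g in seq_along(tables)) {
    w <- .tensor_weight(coef, group, g, a, b, c, d)
    if (w != 0) out <- out + w * tables[[g]]$lambda
  }
  out
}

#' Exciton-state diagonal lineshape and reorganization
#'
#' g_k(t) = sum_n C_nk^4 g_n(t) and lambda_k = sum_n C_nk^4 lambda_n: the
#' effective lineshape of exciton state k in the secular (modified
#' Redfield) picture.  Exchange narrowing appears as the participation
#' ratio scaling of lambda_k.
#'
#' @param states An `exciton_states`.
#' @param system The `exciton_system`.
#' @param lineshapes One shared `lineshape_table` or a list of one per site.
#' @return List with `g` (list of complex vectors per state), `lambda`
#'   (cm^-1 per state), `t` (fs).
#' @export
exciton_lineshapes <- function(states, system, lineshapes) {
  sl <- .site_lineshapes(system, lineshapes)
  nk <- length(states$energies)
  coef <- states$coefficients
  g <- vector("list", nk)
  lam <- numeric(nk)
  for (k in seq_len(nk)) {
    g[[k]] <- .tensor_series(coef, sl$group, sl$tables, "g", k, k, k, k)
    lam[k] <- .tensor_lambda(coef, sl$group, sl$tables, k, k, k, k)
  }
  list(g = g, lambda = lam, t = sl$tables[[1]]$t)
}
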