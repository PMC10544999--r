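#' Homogeneous optical spectra of an exciton system
#'
#' Absorption (OD), circular dichroism (CD) and fluorescence (FLU) from
#' one of two lineshape theories:
#'
#' * `"modified_redfield"` -- secular: each exciton state k
#'   contributes a stick at its energy broadened by its own lineshape
#'   g_k(t) = sum_n C_nk^4 g_n(t) and by lifetime damping
#'   exp(-t/2tau_k) from the modified Redfield depopulation rates.
#' * `"cumulant"` -- full-cumulant-expansion style: second-order matrix
#'   cumulant in the
#'   exciton basis.  The full matrix K(t) of twice-integrated bath
#'   correlations (diagonal: dephasing and reorganization shifts;
#'   off-diagonal and k''-sums: non-Markovian lifetime kernel and
#'   non-secular mixing) is exponentiated at every time,
#'   U(t) = e^{-i Omega t} e^{-K(t)}, and contracted with dipole or
#'   rotational-strength weights.
#'
#' Both theories reduce exactly to the monomer response
#' Re int e^{i(omega - epsilon)t - g(t)} dt for N = 1, and to a sum of
#' monomer responses when all couplings vanish.
#'
#' Intensities are reported in arbitrary units (no omega prefactor), so
#' integrated OD equals pi times the total dipole strength and is
#' conserved between coupled and uncoupled calculations.
#'
#' @param states `exciton_states` from [diagonalize()].
#' @param system The matching `exciton_system`.
#' @param lineshapes One shared [lineshape_function()] table or a list of
#'   one per site.
#' @param rates Optional rate matrix from [modified_redfield_rates()]
#'   (used for lifetime damping in the modified Redfield theory; computed
#'   on the fly when `NULL` and N > 1).
#' @param theory `"modified_redfield"` or `"cumulant"`.
#' @param wavenumber_grid Output grid in cm^-1 (default: span of exciton
#'   energies widened by 2500 cm^-1, 2 cm^-1 step).
#' @param temperature Temperature in K for fluorescence Boltzmann weights
#'   (default: the lineshape-table temperature).
#' @return A `spectrum_result`: list with `wavenumber` (cm^-1),
#'   `intensity`, `kind` (od/cd/flu) and `meta`.
#' @name spectra
NULL

.default_grid <- function(states) {
  r <- range(states$energies)
  seq(floor(r[1] - 2500), ceiling(r[2] + 2500), by = 2)
}

.spectrum_result <- function(wavenumber, intensity, kind, meta = list()) {
  if (any(diff(wavenumber) <= 0)) stop("wavenumber grid must be strictly increasing")
  if (kind %in% c("od", "flu")) {
    neg <- min(intensity)
    if (neg < -1e-6 * max(abs(intensity))) {
      stop(sprintf("negative %s intensity beyond numerical tolerance (%.3g)", kind, neg))
    }
    intensity <- pmax(intensity, 0)
  }
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 kind = kind, meta = meta),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  pk <- x$wavenumber[which.max(abs(x$intensity))]
  cat(sprintf("spectrum_result [%s]: %d points, %g..%g cm^-1, |peak| at %g cm^-1\n",
              x$kind, length(x$wavenumber), min(x$wavenumber), max(x$wavenumber), pk))
  invisible(x)
}

## ---- secular (modified Redfield) response -------------------------------

.secular_response <- function(states, exls, weights, damping = NULL,
                              emission = FALSE) {
  tg <- exls$t
  u <- CM1_TO_RADFS
  S <- complex(length.out = length(tg))
  for (k in seq_along(states$energies)) {
    if (weights[k] == 0) next
    gk <- exls$g[[k]]
    if (emission) {
      ph <- -1i * u * (states$energies[k] - 2 * exls$lambda[k]) * tg
      resp <- exp(ph - Conj(gk))
    } else {
      resp <- exp(-1i * u * states$energies[k] * tg - gk)
    }
    if (!is.null(damping)) resp <- resp * exp(-damping[k] * tg / 2)
    S <- S + weights[k] * resp
  }
  S
}

## ---- matrix cumulant (full-cumulant-expansion style) response -----------

## oscillatory integrals of the bath correlation expressed through g alone:
##   f(w,t) = int_0^t C(s) e^{iws} ds
##   h(w,t) = int_0^t (t-s) C(s) e^{iws} ds,  h(0,t) = g(t) exactly
.osc_integrals <- function(lt, omegas) {
  tg <- lt$t
  g <- lt$g
  gdot <- lt$gdot
  res <- vector("list", length(omegas))
  for (i in seq_along(omegas)) {
    w <- omegas[i]
    if (w == 0) {
      res[[i]] <- list(f = gdot, h = g)
    } else {
      e <- exp(1i * w * tg)
      A <- cumtrapz(e * g, tg)
      B <- cumtrapz(tg * e * g, tg)
      f <- gdot * e - 1i * w * e * g - w^2 * A
      h <- e * g - 2i * w * A - w^2 * (tg * A - B)
      res[[i]] <- list(f = f, h = h)
    }
  }
  res
}

.cumulant_propagator <- function(states, system, lineshapes) {
  sl <- .site_lineshapes(system, lineshapes)
  coef <- states$coefficients
  nk <- length(states$energies)
  tg <- sl$tables[[1]]$t
  nt <- length(tg)
  u <- CM1_TO_RADFS
  om <- u * states$energies                      # rad/fs
  ## all pairwise frequency differences w_ab = om_a - om_b
  wmat <- outer(om, om, `-`)
  wkey <- signif(as.vector(wmat), 12)
  uw <- unique(wkey)
  widx <- matrix(match(wkey, uw), nk, nk)
  ## oscillatory integrals per lineshape group and unique frequency
  osc <- lapply(sl$tables, .osc_integrals, omegas = uw)
  ## K_{kk'}(t) assembled as nt x nk x nk
  K <- array(0i, dim = c(nt, nk, nk))
  for (g in seq_along(sl$tables)) {
    idx <- which(sl$group == g)
    cg <- coef[idx, , drop = FALSE]
    for (k in seq_len(nk)) {
      for (kp in seq_len(nk)) {
        wkkp <- wmat[k, kp]
        acc <- complex(length.out = nt)
        for (kpp in seq_len(nk)) {
          P <- sum(cg[, k] * cg[, kpp]^2 * cg[, kp])
          if (P == 0) next
          if (k == kp) {
            acc <- acc + P * osc[[g]][[widx[k, kpp]]]$h
          } else {
            fa <- osc[[g]][[widx[kp, kpp]]]$f
            fb <- osc[[g]][[widx[k, kpp]]]$f
            acc <- acc + P * (exp(1i * wkkp * tg) * fa - fb) / (1i * wkkp)
          }
        }
        K[, k, kp] <- K[, k, kp] + acc
      }
    }
  }
  list(t = tg, om = om, K = K, nk = nk)
}

## complex matrix exponential by scaling-and-squaring Taylor series
.expm_complex <- function(m) {
  nrm <- max(colSums(abs(m)))
  s <- max(0L, ceiling(log2(max(nrm, .Machine$double.eps) / 0.5)))
  a <- m / 2^s
  n <- nrow(m)
  res <- diag(1 + 0i, n)
  term <- diag(1 + 0i, n)
  for (j in 1:16) {
    term <- term %*% a / j
    res <- res + term
  }
  for (j in seq_len(s)) res <- res %*% res
  res
}

.cumulant_responses <- function(prop, weight_list) {
  nt <- length(prop$t)
  nk <- prop$nk
  nw <- length(weight_list)
  out <- lapply(weight_list, function(w) complex(length.out = nt))
  if (nk == 1L) {
    ## scalar path keeps the monomer limit exact
    base <- exp(-1i * prop$om[1] * prop$t - prop$K[, 1, 1])
    for (j in seq_len(nw)) out[[j]] <- weight_list[[j]][1, 1] * base
    return(out)
  }
  for (i in seq_len(nt)) {
    U <- .expm_complex(-matrix(prop$K[i, , ], nk, nk))
    U <- exp(-1i * prop$om * prop$t[i]) * U   # row scaling = e^{-i Omega t} U
    for (j in seq_len(nw)) out[[j]][i] <- sum(weight_list[[j]] * U)
  }
  out
}

.cumulant_response <- function(prop, weight_matrix) {
  .cumulant_responses(prop, list(weight_matrix))[[1]]
}

## ---- public spectra -----------------------------------------------------

#' @rdname spectra
#' @export
absorption_spectrum <- function(states, system, lineshapes, rates = NULL,
                                theory = c("modified_redfield", "cumulant"),
                                wavenumber_grid = NULL) {
  theory <- match.arg(theory)
  if (is.null(wavenumber_grid)) wavenumber_grid <- .default_grid(states)
  D <- dipole_strengths(states, system)
  if (theory == "modified_redfield") {
    exls <- exciton_lineshapes(states, system, lineshapes)
    damping <- NULL
    if (length(states$energies) > 1L) {
      if (is.null(rates)) rates <- modified_redfield_rates(states, system, lineshapes)
      damping <- -diag(rates)
    }
    S <- .secular_response(states, exls, D, damping)
    tg <- exls$t
  } else {
    prop <- .cumulant_propagator(states, system, lineshapes)
    M <- tcrossprod_dipoles(states, system)
    S <- .cumulant_response(prop, M)
    tg <- prop$t
  }
  inten <- half_fourier_spectrum(S, tg, wavenumber_grid)
  .spectrum_result(wavenumber_grid, inten, "od",
                   list(theory = theory))
}

## dipole weight matrix M_{kk'} = mu_k . mu_k'
tcrossprod_dipoles <- function(states, system) {
  muk <- exciton_dipoles(states, system)
  tcrossprod(muk)
}

#' @rdname spectra
#' @export
cd_spectrum <- function(states, system, lineshapes, rates = NULL,
                        theory = c("modified_redfield", "cumulant"),
                        wavenumber_grid = NULL) {
  theory <- match.arg(theory)
  if (is.null(wavenumber_grid)) wavenumber_grid <- .default_grid(states)
  if (theory == "modified_redfield") {
    R <- rotational_strengths(states, system)
    exls <- exciton_lineshapes(states, system, lineshapes)
    damping <- NULL
    if (length(states$energies) > 1L) {
      if (is.null(rates)) rates <- modified_redfield_rates(states, system, lineshapes)
      damping <- -diag(rates)
    }
    S <- .secular_response(states, exls, R, damping)
    tg <- exls$t
  } else {
    prop <- .cumulant_propagator(states, system, lineshapes)
    W <- rotational_strength_matrix(states, system)
    S <- .cumulant_response(prop, W)
    tg <- prop$t
  }
  inten <- half_fourier_spectrum(S, tg, wavenumber_grid)
  .spectrum_result(wavenumber_grid, inten, "cd", list(theory = theory))
}

#' @rdname spectra
#' @export
fluorescence_spectrum <- function(states, system, lineshapes,
                                  temperature = NULL,
                                  wavenumber_grid = NULL) {
  if (is.null(wavenumber_grid)) wavenumber_grid <- .default_grid(states)
  exls <- exciton_lineshapes(states, system, lineshapes)
  if (is.null(temperature)) {
    sl <- .site_lineshapes(system, lineshapes)
    temperature <- sl$tables[[1]]$temperature
  }
  if (temperature <= 0) stop("temperature must be > 0")
  D <- dipole_strengths(states, system)
  e <- states$energies
  pop <- exp(-(e - min(e)) / kT_cm1(temperature))
  pop <- pop / sum(pop)
  S <- .secular_response(states, exls, pop * D, emission = TRUE)
  inten <- half_fourier_spectrum(S, exls$t, wavenumber_grid)
  .spectrum_result(wavenumber_grid, inten, "flu",
                   list(temperature = temperature))
}

#' Boltzmann populations of exciton states
#'
#' @param states An `exciton_states`.
#' @param temperature Temperature in Kelvin.
#' @return Normalized populations.
#' @export
boltzmann_populations <- function(states, temperature) {
  if (temperature <= 0) stop("temperature must be > 0")
  e <- states$energies
  p <- exp(-(e - min(e)) / kT_cm1(temperature))
  p / sum(p)
}

#' Write spectra as CSV
#'
#' One file with columns `wavenumber_cm1, od, cd, flu` and `#`-prefixed
#' metadata header lines.
#'
#' @param path Output file.
#' @param od,cd,flu `spectrum_result` objects on one shared grid (any may
#'   be `NULL`).
#' @param meta Named list of scalar metadata for the header.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(path, od = NULL, cd = NULL, flu = NULL,
                              meta = list()) {
  specs <- Filter(Negate(is.null), list(od = od, cd = cd, flu = flu))
  if (!length(specs)) stop("no spectra supplied")
  grid <- specs[[1]]$wavenumber
  for (s in specs) stopifnot(identical(s$wavenumber, grid))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  }
  df <- data.frame(wavenumber_cm1 = grid)
  for (nm in names(specs)) df[[nm]] <- specs[[nm]]$intensity
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read spectra CSV written by [write_spectra_csv()]
#'
#' @param path File path.
#' @return Data frame with attribute `meta` (named character vector).
#' @export
read_spectra_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- character(0)
  if (length(hdr)) {
    kv <- sub("^# ", "", lines[hdr])
    meta <- stats::setNames(sub("^[^:]+: ", "", kv), sub(":.*$", "", kv))
  }
  df <- utils::read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                     collapse = "\n"))
  attr(df, "meta") <- meta
  df
}
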