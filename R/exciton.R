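#' Pigment sites
#'
#' A pigment site is one bilin chromophore characterized by its uncoupled
#' excitation ("site") energy, electric transition dipole and spatial center.
#' Site labels follow the field convention of naming pigments by bilin type
#' and cysteine attachment residue, e.g. `"DBV_50/61B"` or `"PCB_82D"`.
#'
#' @param site_id Unique label for the pigment.
#' @param energy Site energy in cm^-1 (must be > 0 for physical inputs).
#' @param dipole Numeric length-3 transition dipole in Debye.
#' @param center Numeric length-3 pigment center in Angstrom (optional,
#'   needed only for rotational strengths).
#' @param bilin_type One of `"PCB"`, `"DBV"`, `"MBV"`, `"PEB"` or `NA`.
#' @param chain Chain label (optional).
#' @return An object of class `pigment_site`.
#' @export
#' @examples
#' pigment_site("DBV_50/61B", 16000, dipole = c(12, 0, 0))
pigment_site <- function(site_id, energy, dipole = c(0, 0, 0),
                         center = c(NA_real_, NA_real_, NA_real_),
                         bilin_type = NA_character_, chain = NA_character_) {
  stopifnot(is.character(site_id), length(site_id) == 1L, nzchar(site_id))
  stopifnot(is.numeric(energy), length(energy) == 1L, is.finite(energy), energy > 0)
  dipole <- as.numeric(dipole)
  center <- as.numeric(center)
  stopifnot(length(dipole) == 3L, all(is.finite(dipole)))
  stopifnot(length(center) == 3L)
  if (!is.na(bilin_type)) {
    bilin_type <- match.arg(bilin_type, c("PCB", "DBV", "MBV", "PEB"))
  }
  structure(
    list(site_id = site_id, energy = energy, dipole = dipole,
         center = center, bilin_type = bilin_type, chain = chain),
    class = "pigment_site")
}

#' Build a Frenkel exciton system
#'
#' Assembles the one-exciton Hamiltonian H of a multichromophoric system:
#' site energies on the diagonal and electronic couplings V_nm on the
#' off-diagonal, all in cm^-1.  The coupling matrix must be symmetric;
#' small numerical asymmetries (max |V_nm - V_mn| < 1e-6 cm^-1) are
#' symmetrized, anything larger is rejected.
#'
#' @param sites A list of [pigment_site()] objects.
#' @param couplings N x N numeric coupling matrix in cm^-1. The diagonal is
#'   ignored and stored as exactly zero. A single site may pass a 1 x 1
#'   matrix, `NULL`, or `0`.
#' @return An object of class `exciton_system` with elements `sites` and
#'   `couplings`.
#' @export
#' @examples
#' s <- list(pigment_site("a", 15000), pigment_site("b", 15000))
#' sys <- build_system(s, matrix(c(0, 238, 238, 0), 2))
#' hamiltonian(sys)
build_system <- function(sites, couplings = NULL) {
  stopifnot(is.list(sites), length(sites) >= 1L)
  sites <- lapply(sites, function(s) {
    if (!inherits(s, "pigment_site")) stop("all sites must be pigment_site objects")
    s
  })
  n <- length(sites)
  ids <- vapply(sites, `[[`, character(1), "site_id")
  if (anyDuplicated(ids)) {
    stop("duplicate site_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (is.null(couplings)) couplings <- matrix(0, n, n)
  if (length(couplings) == 1L && n == 1L) couplings <- matrix(as.numeric(couplings), 1, 1)
  couplings <- as.matrix(couplings)
  if (!is.numeric(couplings) || nrow(couplings) != n || ncol(couplings) != n) {
    stop("couplings must be a ", n, " x ", n, " numeric matrix")
  }
  asym <- max(abs(couplings - t(couplings)))
  if (asym >= 1e-6) {
    stop(sprintf("coupling matrix not symmetric (max asymmetry %.3g cm^-1)", asym))
  }
  couplings <- (couplings + t(couplings)) / 2
  diag(couplings) <- 0
  dimnames(couplings) <- list(ids, ids)
  structure(list(sites = sites, couplings = couplings), class = "exciton_system")
}

#' @export
print.exciton_system <- function(x, ...) {
  n <- length(x$sites)
  cat(sprintf("exciton_system with %d pigment site%s\n", n, if (n == 1L) "" else "s"))
  e <- site_energies(x)
  cat("  site energies (cm^-1): ", paste(format(e, digits = 6), collapse = ", "), "\n")
  offd <- x$couplings[upper.tri(x$couplings)]
  if (length(offd)) {
    cat(sprintf("  couplings: max |V| = %.3g cm^-1\n", max(abs(offd))))
  }
  invisible(x)
}

#' Site-level accessors
#'
#' @param system An `exciton_system`.
#' @return `site_energies`: numeric vector of site energies (cm^-1);
#'   `site_dipoles`: N x 3 matrix in Debye; `site_centers`: N x 3 matrix in
#'   Angstrom; `hamiltonian`: the full N x N Hamiltonian in cm^-1;
#'   `n_sites`: integer.
#' @export
site_energies <- function(system) {
  vapply(system$sites, `[[`, numeric(1), "energy")
}

#' @rdname site_energies
#' @export
site_dipoles <- function(system) {
  do.call(rbind, lapply(system$sites, `[[`, "dipole"))
}

#' @rdname site_energies
#' @export
site_centers <- function(system) {
  do.call(rbind, lapply(system$sites, `[[`, "center"))
}

#' @rdname site_energies
#' @export
hamiltonian <- function(system) {
  h <- system$couplings
  diag(h) <- site_energies(system)
  h
}

#' @rdname site_energies
#' @export
n_sites <- function(system) length(system$sites)

#' Diagonalize an exciton system
#'
#' Solves H C = C diag(e) for the exciton states k: eigen-energies in
#' ascending order, with degenerate blocks ordered by descending dipole
#' strength, and the sign of each eigenvector fixed so that its
#' largest-magnitude coefficient is positive.  Also attaches dipole
#' strengths, rotational strengths (when centers are available) and inverse
#' participation ratios.
#'
#' @param system An `exciton_system`.
#' @return Object of class `exciton_states` with fields `energies` (cm^-1,
#'   ascending), `coefficients` (N x N, columns are states, orthonormal),
#'   `dipole_strengths` (Debye^2), `rotational_strengths` (Debye^2 Angstrom,
#'   unit prefactor convention, `NA` if centers missing), `participation`
#'   (inverse participation ratio, in `[1, N]`).
#' @export
#' @examples
#' s <- list(pigment_site("a", 15000, c(1, 0, 0)), pigment_site("b", 15500, c(1, 0, 0)))
#' st <- diagonalize(build_system(s, matrix(c(0, 100, 100, 0), 2)))
#' st$energies  # 15250 -/+ sqrt(250^2 + 100^2)
diagonalize <- function(system) {
  stopifnot(inherits(system, "exciton_system"))
  h <- hamiltonian(system)
  eig <- eigen(h, symmetric = TRUE)
  ord <- order(eig$values)  # eigen() returns descending for symmetric
  energies <- eig$values[ord]
  coef <- eig$vectors[, ord, drop = FALSE]
  ## sign convention: largest-magnitude coefficient positive
  for (k in seq_len(ncol(coef))) {
    i <- which.max(abs(coef[, k]))
    if (coef[i, k] < 0) coef[, k] <- -coef[, k]
  }
  st <- structure(
    list(energies = energies, coefficients = coef,
         dipole_strengths = NULL, rotational_strengths = NULL,
         participation = NULL),
    class = "exciton_states")
  st$dipole_strengths <- dipole_strengths(st, system)
  ## degenerate ties: reorder by descending dipole strength within blocks
  st <- .break_degenerate_ties(st)
  st$rotational_strengths <- tryCatch(rotational_strengths(st, system),
                                      error = function(e) rep(NA_real_, length(energies)))
  st$participation <- participation_ratio(st)
  st
}

.break_degenerate_ties <- function(states, tol = 1e-9) {
  e <- states$energies
  n <- length(e)
  if (n < 2L) return(states)
  grp <- cumsum(c(TRUE, diff(e) > tol * max(1, abs(e[-n]))))
  ord <- seq_len(n)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) > 1L) {
      ord[idx] <- idx[order(states$dipole_strengths[idx], decreasing = TRUE)]
    }
  }
  states$energies <- states$energies[ord]
  states$coefficients <- states$coefficients[, ord, drop = FALSE]
  states$dipole_strengths <- states$dipole_strengths[ord]
  states
}

#' @export
print.exciton_states <- function(x, ...) {
  cat(sprintf("exciton_states: %d states\n", length(x$energies)))
  df <- data.frame(energy_cm1 = x$energies,
                   dipole_strength_D2 = x$dipole_strengths,
                   rotational_strength = x$rotational_strengths,
                   ipr = x$participation)
  print(df, digits = 6)
  invisible(x)
}

#' Exciton dipole strengths
#'
#' Contracts site transition dipoles with the exciton coefficients,
#' mu_k = sum_n C_nk mu_n, and returns D_k = |mu_k|^2 in Debye^2.  The sum
#' over states equals the sum of squared site dipoles (oscillator-strength
#' sum rule).
#'
#' @param states An `exciton_states` object.
#' @param system The `exciton_system` it came from.
#' @return Numeric vector of per-state dipole strengths.
#' @export
dipole_strengths <- function(states, system) {
  mu <- site_dipoles(system)                 # N x 3
  muk <- crossprod(states$coefficients, mu)  # N_states x 3
  rowSums(muk^2)
}

#' Exciton transition dipoles
#'
#' @inheritParams dipole_strengths
#' @return N_states x 3 matrix of exciton transition dipoles in Debye.
#' @export
exciton_dipoles <- function(states, system) {
  crossprod(states$coefficients, site_dipoles(system))
}

#' Exciton rotational strengths
#'
#' Rotational strengths in the point-dipole exciton approximation with a
#' unit prefactor:
#' R_k = sum_{n<m} C_nk C_mk (r_n - r_m) . (mu_n x mu_m),
#' in Debye^2 Angstrom.  CD spectra built from these are in arbitrary units;
#' the excitonic sum rule sum_k R_k = 0 holds exactly.
#'
#' @inheritParams dipole_strengths
#' @return Numeric vector of per-state rotational strengths.
#' @export
rotational_strengths <- function(states, system) {
  r <- site_centers(system)
  if (anyNA(r)) stop("pigment centers are required for rotational strengths")
  mu <- site_dipoles(system)
  n <- nrow(mu)
  coef <- states$coefficients
  R <- numeric(ncol(coef))
  if (n < 2L) return(R)
  ## precompute pair terms t_nm = (r_n - r_m) . (mu_n x mu_m)
  for (nn in seq_len(n - 1L)) {
    for (mm in (nn + 1L):n) {
      cr <- c(mu[nn, 2] * mu[mm, 3] - mu[nn, 3] * mu[mm, 2],
              mu[nn, 3] * mu[mm, 1] - mu[nn, 1] * mu[mm, 3],
              mu[nn, 1] * mu[mm, 2] - mu[nn, 2] * mu[mm, 1])
      tnm <- sum((r[nn, ] - r[mm, ]) * cr)
      R <- R + coef[nn, ] * coef[mm, ] * tnm
    }
  }
  R
}

#' Cross-state rotational strength matrix
#'
#' Generalization of [rotational_strengths()] used by the non-secular
#' cumulant theory: W_{kk'} = (1/2) sum_{n != m} C_nk C_mk' (r_n - r_m) .
#' (mu_n x mu_m).  Its diagonal equals R_k.
#'
#' @inheritParams dipole_strengths
#' @return N_states x N_states numeric matrix.
#' @export
rotational_strength_matrix <- function(states, system) {
  r <- site_centers(system)
  if (anyNA(r)) stop("pigment centers are required for rotational strengths")
  mu <- site_dipoles(system)
  n <- nrow(mu)
  coef <- states$coefficients
  W <- matrix(0, ncol(coef), ncol(coef))
  if (n < 2L) return(W)
  for (nn in seq_len(n)) {
    for (mm in seq_len(n)) {
      if (nn == mm) next
      cr <- c(mu[nn, 2] * mu[mm, 3] - mu[nn, 3] * mu[mm, 2],
              mu[nn, 3] * mu[mm, 1] - mu[nn, 1] * mu[mm, 3],
              mu[nn, 1] * mu[mm, 2] - mu[nn, 2] * mu[mm, 1])
      tnm <- sum((r[nn, ] - r[mm, ]) * cr)
      W <- W + 0.5 * tnm * tcrossprod(coef[nn, ], coef[mm, ])
    }
  }
  W
}

#' Delocalization length of exciton states
#'
#' Inverse participation ratio IPR_k = 1 / sum_n C_nk^4, the effective
#' number of pigments a state is delocalized over.  1 for a fully localized
#' state, N for uniform delocalization.
#'
#' @param states An `exciton_states` object.
#' @return Numeric vector bounded in `[1, N]`.
#' @export
participation_ratio <- function(states) {
  1 / colSums(states$coefficients^4)
}
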