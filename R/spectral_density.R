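#' Spectral density of electronic-vibrational coupling
#'
#' The bath spectral density J(omega) has a continuous part modelling slow
#' environmental motions -- an overdamped Brownian oscillator (OBO) with
#' reorganization energy `lambda_c` and inverse correlation time `gamma_c`
#' -- plus a set of damped discrete intramolecular modes, each with
#' frequency `omega_j`, Huang-Rhys factor `S_j` (so its reorganization
#' energy is `S_j * omega_j`) and damping `gamma_j`.  All parameters in
#' cm^-1 (S dimensionless).
#'
#' @param lambda_c OBO reorganization energy, cm^-1 (>= 0).
#' @param gamma_c OBO inverse correlation time, cm^-1 (> 0).
#' @param modes Data frame (possibly empty) with columns `omega_cm1`, `S`,
#'   `gamma_cm1`.
#' @return Object of class `spectral_density`.
#' @export
#' @examples
#' sd <- spectral_density(lambda_c = 100, gamma_c = 50)
#' reorganization_energy(sd)
spectral_density <- function(lambda_c = 0, gamma_c = 50, modes = NULL) {
  stopifnot(is.numeric(lambda_c), lambda_c >= 0, is.numeric(gamma_c), gamma_c > 0)
  if (is.null(modes)) {
    modes <- data.frame(omega_cm1 = numeric(0), S = numeric(0), gamma_cm1 = numeric(0))
  }
  modes <- as.data.frame(modes)
  if (nrow(modes)) {
    stopifnot(all(c("omega_cm1", "S") %in% names(modes)))
    if (is.null(modes$gamma_cm1)) modes$gamma_cm1 <- 10
    stopifnot(all(modes$omega_cm1 > 0), all(modes$S >= 0), all(modes$gamma_cm1 > 0))
  }
  structure(list(lambda_c = lambda_c, gamma_c = gamma_c, modes = modes),
            class = "spectral_density")
}

#' @export
print.spectral_density <- function(x, ...) {
  cat(sprintf("spectral_density: OBO lambda = %g cm^-1, gamma = %g cm^-1; %d discrete mode(s); total lambda = %g cm^-1\n",
              x$lambda_c, x$gamma_c, nrow(x$modes), reorganization_energy(x)))
  invisible(x)
}

#' Evaluate J(omega)
#'
#' J(omega) = 2 lambda_c gamma_c omega / (omega^2 + gamma_c^2) for the OBO
#' part, plus a multimode-Brownian-oscillator term
#' 2 lambda_j omega_j^2 gamma_j omega / ((omega^2 - omega_j^2)^2 +
#' gamma_j^2 omega^2) per discrete mode, with lambda_j = S_j omega_j.  Each
#' term integrates to its reorganization energy: (1/pi) int J/omega domega
#' = lambda.
#'
#' @param sd A `spectral_density`.
#' @param omega_grid Non-negative wavenumber grid, cm^-1.
#' @return Numeric vector J(omega) in cm^-1.
#' @export
evaluate_J <- function(sd, omega_grid) {
  stopifnot(inherits(sd, "spectral_density"))
  omega_grid <- as.numeric(omega_grid)
  if (any(omega_grid < 0)) stop("omega grid must be non-negative")
  J <- 2 * sd$lambda_c * sd$gamma_c * omega_grid / (omega_grid^2 + sd$gamma_c^2)
  if (nrow(sd$modes)) {
    for (j in seq_len(nrow(sd$modes))) {
      wj <- sd$modes$omega_cm1[j]
      lj <- sd$modes$S[j] * wj
      gj <- sd$modes$gamma_cm1[j]
      J <- J + 2 * lj * wj^2 * gj * omega_grid /
        ((omega_grid^2 - wj^2)^2 + gj^2 * omega_grid^2)
    }
  }
  J
}

#' Total reorganization energy
#'
#' Closed form lambda = lambda_c + sum_j S_j omega_j, which equals
#' (1/pi) int_0^inf J(omega)/omega domega for the forms used here.
#'
#' @param sd A `spectral_density`.
#' @return lambda in cm^-1.
#' @export
reorganization_energy <- function(sd) {
  stopifnot(inherits(sd, "spectral_density"))
  sd$lambda_c + sum(sd$modes$S * sd$modes$omega_cm1)
}

#' Calibrate the OBO part against a target Stokes shift
#'
#' For linear coupling the Stokes shift equals twice the total
#' reorganization energy, 2 (lambda_c + sum_j S_j omega_j).  Given the
#' discrete-mode list (whose reorganization is fixed by the intramolecular
#' model) this solves for the continuous lambda_c reproducing a target
#' Stokes shift.
#'
#' @param target_stokes Target Stokes shift in cm^-1.
#' @param modes Data frame of discrete modes (as in [spectral_density()]),
#'   or `NULL`.
#' @return lambda_c in cm^-1; errors if the target is infeasible
#'   (would require negative lambda_c).
#' @export
#' @examples
#' stokes_calibrate(400)                    # 200
#' stokes_calibrate(400, data.frame(omega_cm1 = 600, S = 0.25))  # 50
stokes_calibrate <- function(target_stokes, modes = NULL) {
  stopifnot(is.numeric(target_stokes), target_stokes >= 0)
  lambda_v <- if (is.null(modes) || !nrow(as.data.frame(modes))) 0 else {
    m <- as.data.frame(modes); sum(m$S * m$omega_cm1)
  }
  lambda_c <- target_stokes / 2 - lambda_v
  if (lambda_c < 0) {
    stop(sprintf(
      "infeasible Stokes target: %g cm^-1 < 2 x vibronic reorganization (%g cm^-1)",
      target_stokes, 2 * lambda_v))
  }
  lambda_c
}

#' Read/write a spectral-density JSON config
#'
#' Schema: `{lambda_c_cm1, gamma_c_cm1, modes: [{omega_cm1, S, gamma_cm1}]}`.
#'
#' @param path File path.
#' @param sd A `spectral_density` (writer).
#' @return The reader returns a `spectral_density`.
#' @export
read_spectral_density <- function(path) {
  obj <- jsonlite::fromJSON(path)
  modes <- if (!is.null(obj$modes) && length(obj$modes)) as.data.frame(obj$modes) else NULL
  spectral_density(lambda_c = obj$lambda_c_cm1 %||% 0,
                   gamma_c = obj$gamma_c_cm1 %||% 50,
                   modes = modes)
}

#' @rdname read_spectral_density
#' @export
write_spectral_density <- function(sd, path) {
  stopifnot(inherits(sd, "spectral_density"))
  obj <- list(lambda_c_cm1 = sd$lambda_c, gamma_c_cm1 = sd$gamma_c,
              modes = sd$modes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
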