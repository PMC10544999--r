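#' Frame ensembles of site energies
#'
#' A frame ensemble holds per-pigment site energies sampled along a
#' molecular-dynamics protocol.  Long format: one row per sample with
#' columns `protocol` (one of `"MD"`, `"Crystal-OPT"`, `"MD-OPT"`,
#' `"MD-BOMD"`), `pigment_id`, `frame` (starting-frame index), `snapshot`
#' (within-trajectory snapshot index; `NA` for per-frame protocols such as
#' MD-OPT) and `energy_cm1`.  The reference sampling design is 34 starting
#' frames, and for the dual-MD protocol 25 snapshots per frame, i.e. 850
#' samples per pigment.
#'
#' @param data Data frame with the columns above.
#' @return Object of class `frame_ensemble` (a validated data frame).
#' @export
frame_ensemble <- function(data) {
  data <- as.data.frame(data)
  need <- c("protocol", "pigment_id", "frame", "energy_cm1")
  if (!all(need %in% names(data))) {
    stop("frame ensemble needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(data$snapshot)) data$snapshot <- NA_integer_
  ok <- data$protocol %in% c("MD", "Crystal-OPT", "MD-OPT", "MD-BOMD")
  if (!all(ok)) stop("unknown protocol: ", paste(unique(data$protocol[!ok]), collapse = ", "))
  stopifnot(is.numeric(data$energy_cm1), all(is.finite(data$energy_cm1)))
  ## consistent pigment set across frames, per protocol
  for (p in unique(data$protocol)) {
    d <- data[data$protocol == p, ]
    tab <- table(d$pigment_id, d$frame)
    if (length(tab) && length(unique(as.vector(tab))) > 1L) {
      stop("ragged ensemble: pigment/frame counts differ within protocol ", p)
    }
  }
  class(data) <- c("frame_ensemble", "data.frame")
  data
}

#' @rdname frame_ensemble
#' @param path CSV file with columns `protocol, pigment_id, frame, snapshot,
#'   energy_cm1` (snapshot blank for per-frame protocols).
#' @export
read_frame_ensemble <- function(path) {
  frame_ensemble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname frame_ensemble
#' @param ensemble A `frame_ensemble`.
#' @export
write_frame_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "frame_ensemble"))
  utils::write.csv(as.data.frame(ensemble), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-pigment ensemble statistics
#'
#' Mean and sample (n-1) standard deviation of site energies per pigment,
#' pooling all samples of the requested protocol (nested MD-BOMD samples
#' are flattened, e.g. 34 x 25 = 850 values).
#'
#' @param ensemble A [frame_ensemble()].
#' @param protocol Protocol to summarize (default: all present, one block
#'   each).
#' @return Data frame with columns `pigment_id, protocol, mean_cm1, sd_cm1,
#'   n`.
#' @export
ensemble_site_statistics <- function(ensemble, protocol = NULL) {
  stopifnot(inherits(ensemble, "frame_ensemble"))
  d <- as.data.frame(ensemble)
  if (!is.null(protocol)) d <- d[d$protocol %in% protocol, ]
  if (!nrow(d)) stop("no samples for requested protocol")
  out <- do.call(rbind, lapply(split(d, list(d$protocol, d$pigment_id), drop = TRUE),
    function(g) data.frame(pigment_id = g$pigment_id[1], protocol = g$protocol[1],
                           mean_cm1 = mean(g$energy_cm1),
                           sd_cm1 = stats::sd(g$energy_cm1),
                           n = nrow(g))))
  rownames(out) <- NULL
  out[order(out$protocol, out$pigment_id), ]
}

#' Static disorder estimated from per-frame optimizations
#'
#' The spread of site energies across independently optimized MD frames:
#' the sample standard deviation over the (34) per-frame energies of each
#' pigment.  This estimator sees the slow, frozen-on-the-optical-timescale
#' part of the energy-gap fluctuations.
#'
#' @param ensemble A `frame_ensemble` containing `MD-OPT` samples.
#' @return Named numeric vector of per-pigment sigma in cm^-1.
#' @export
disorder_from_opt <- function(ensemble) {
  stopifnot(inherits(ensemble, "frame_ensemble"))
  d <- as.data.frame(ensemble)
  d <- d[d$protocol == "MD-OPT", ]
  if (!nrow(d)) stop("ensemble has no MD-OPT samples")
  vapply(split(d$energy_cm1, d$pigment_id), stats::sd, numeric(1))
}

#' Static disorder estimated from short-trajectory means
#'
#' For the dual-MD protocol the per-trajectory mean over the (25) snapshots
#' of each starting frame is formed first, and the standard deviation is
#' taken across the (34) per-trajectory means.  Because each mean retains
#' a residual fast-fluctuation variance of sigma_fast^2/25, this estimator
#' is biased upward: it converges to
#' sqrt(sigma_slow^2 + sigma_fast^2 / n_snapshots) for decorrelated
#' snapshots -- short quantum trajectories necessarily overestimate static
#' disorder.
#'
#' @param ensemble A `frame_ensemble` containing `MD-BOMD` samples.
#' @return Named numeric vector of per-pigment sigma in cm^-1.
#' @export
disorder_from_bomd <- function(ensemble) {
  stopifnot(inherits(ensemble, "frame_ensemble"))
  d <- as.data.frame(ensemble)
  d <- d[d$protocol == "MD-BOMD", ]
  if (!nrow(d)) stop("ensemble has no MD-BOMD samples")
  vapply(split(d, d$pigment_id), function(g) {
    means <- tapply(g$energy_cm1, g$frame, mean)
    stats::sd(means)
  }, numeric(1))
}

#' Disorder model and static-disorder realizations
#'
#' Static disorder is modelled as independent Gaussian perturbations of
#' the site energies (couplings untouched) with per-site standard
#' deviation sigma; spectra are then averaged over realizations.  The
#' fitted value used for the reference antenna simulations is a common
#' sigma = 100 cm^-1.
#'
#' @param sigma Per-site sigma in cm^-1 (scalar recycled, or one per site).
#' @param n_realizations Number of Monte-Carlo realizations (>= 1).
#' @param seed Integer RNG seed.
#' @return Object of class `disorder_model`.
#' @export
disorder_model <- function(sigma = 100, n_realizations = 2000, seed = 1L) {
  stopifnot(all(sigma >= 0), n_realizations >= 1)
  structure(list(sigma = sigma, n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed)),
            class = "disorder_model")
}

#' @rdname disorder_model
#' @param system An `exciton_system`.
#' @param model A `disorder_model`.
#' @return `sample_realizations`: list of `exciton_system`s of length
#'   `n_realizations`, reproducible under the model seed.
#' @export
sample_realizations <- function(system, model) {
  stopifnot(inherits(system, "exciton_system"), inherits(model, "disorder_model"))
  n <- n_sites(system)
  sigma <- rep_len(model$sigma, n)
  e0 <- site_energies(system)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(model$seed)
  lapply(seq_len(model$n_realizations), function(r) {
    de <- stats::rnorm(n, 0, sigma)
    sites <- system$sites
    for (i in seq_len(n)) sites[[i]]$energy <- e0[i] + de[i]
    build_system(sites, system$couplings)
  })
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Disorder-averaged spectra
#'
#' Averages OD/CD/FLU over Gaussian site-energy realizations.  Averaging
#' is performed on the time-domain response functions (the Fourier
#' transform is linear), which makes 2000-realization monomer averages
#' cheap; for a monomer the result equals the homogeneous spectrum
#' convolved with a Gaussian of width sigma, up to Monte-Carlo error.
#'
#' @param system An `exciton_system`.
#' @param model A [disorder_model()].
#' @param lineshapes Shared `lineshape_table` or list per site.
#' @param theory `"modified_redfield"` or `"cumulant"`.
#' @param kinds Character subset of `c("od", "cd", "flu")`.
#' @param wavenumber_grid Output grid in cm^-1.
#' @param temperature Temperature for fluorescence (default from tables).
#' @return Named list of `spectrum_result`s (one per requested kind).
#' @export
disorder_averaged_spectrum <- function(system, model, lineshapes,
                                       theory = c("modified_redfield", "cumulant"),
                                       kinds = c("od", "cd", "flu"),
                                       wavenumber_grid = NULL,
                                       temperature = NULL) {
  theory <- match.arg(theory)
  kinds <- match.arg(kinds, several.ok = TRUE)
  realizations <- sample_realizations(system, model)
  sl <- .site_lineshapes(system, lineshapes)
  tg <- sl$tables[[1]]$t
  if (is.null(temperature)) temperature <- sl$tables[[1]]$temperature
  if (is.null(wavenumber_grid)) {
    st0 <- diagonalize(system)
    pad <- 2500 + 4 * max(rep_len(model$sigma, n_sites(system)))
    r <- range(st0$energies)
    wavenumber_grid <- seq(floor(r[1] - pad), ceiling(r[2] + pad), by = 2)
  }
  acc <- stats::setNames(vector("list", length(kinds)), kinds)
  for (k in kinds) acc[[k]] <- complex(length.out = length(tg))
  for (r in realizations) {
    st <- diagonalize(r)
    if (theory == "modified_redfield") {
      exls <- exciton_lineshapes(st, r, lineshapes)
      damping <- NULL
      if (n_sites(r) > 1L && any(c("od", "cd") %in% kinds)) {
        rates <- modified_redfield_rates(st, r, lineshapes)
        damping <- -diag(rates)
      }
      if ("od" %in% kinds) {
        acc$od <- acc$od + .secular_response(st, exls, dipole_strengths(st, r), damping)
      }
      if ("cd" %in% kinds) {
        acc$cd <- acc$cd + .secular_response(st, exls, rotational_strengths(st, r), damping)
      }
    } else {
      prop <- .cumulant_propagator(st, r, lineshapes)
      wl <- list()
      if ("od" %in% kinds) wl$od <- tcrossprod_dipoles(st, r)
      if ("cd" %in% kinds) wl$cd <- rotational_strength_matrix(st, r)
      if (length(wl)) {
        resp <- .cumulant_responses(prop, wl)
        for (nm in names(wl)) acc[[nm]] <- acc[[nm]] + resp[[nm]]
      }
    }
    if ("flu" %in% kinds) {
      exls_f <- exciton_lineshapes(st, r, lineshapes)
      pop <- boltzmann_populations(st, temperature)
      acc$flu <- acc$flu +
        .secular_response(st, exls_f, pop * dipole_strengths(st, r), emission = TRUE)
    }
  }
  out <- list()
  for (k in kinds) {
    inten <- half_fourier_spectrum(acc[[k]] / length(realizations), tg, wavenumber_grid)
    out[[k]] <- .spectrum_result(wavenumber_grid, inten, k,
                                 list(theory = theory, sigma = model$sigma,
                                      n_realizations = model$n_realizations,
                                      seed = model$seed))
  }
  out
}

#' Peak detection in a spectrum
#'
#' Local maxima after smoothing with a fixed-width Gaussian kernel,
#' keeping peaks above a fraction of the global maximum.  A deterministic
#' stand-in for visual band assignment.
#'
#' @param spectrum A `spectrum_result` (or list with `wavenumber`,
#'   `intensity`).
#' @param kernel_cm1 Gaussian smoothing sigma in cm^-1 (default 30).
#' @param min_fraction Intensity threshold relative to the global maximum
#'   (default 0.05).
#' @return Numeric vector of peak positions in cm^-1, ascending.
#' @export
find_peaks <- function(spectrum, kernel_cm1 = 30, min_fraction = 0.05) {
  x <- spectrum$wavenumber
  y <- spectrum$intensity
  dx <- stats::median(diff(x))
  half <- max(1L, ceiling(3 * kernel_cm1 / dx))
  kern <- stats::dnorm(seq(-half, half) * dx, sd = kernel_cm1)
  kern <- kern / sum(kern)
  ypad <- c(rep(y[1], half), y, rep(y[length(y)], half))
  ys <- stats::filter(ypad, kern, sides = 2)[(half + 1):(half + length(y))]
  n <- length(ys)
  i <- which(ys[2:(n - 1)] > ys[1:(n - 2)] & ys[2:(n - 1)] >= ys[3:n]) + 1L
  i <- i[ys[i] >= min_fraction * max(ys)]
  sort(x[i])
}

#' Fit a uniform spectral shift
#'
#' Finds the single rigid wavenumber shift that best aligns the simulated
#' band positions with reference band positions, in the least-squares
#' sense: the optimal shift is the mean of the per-peak offsets
#' (reference - simulated), after pairing peaks in ascending order.
#'
#' @param simulated A `spectrum_result`.
#' @param reference_peaks Reference band positions in cm^-1.
#' @param ... Passed to [find_peaks()].
#' @return List with `shift_cm1`, `simulated_peaks`, `residual_cm1`.
#' @export
fit_uniform_shift <- function(simulated, reference_peaks, ...) {
  pk <- find_peaks(simulated, ...)
  reference_peaks <- sort(as.numeric(reference_peaks))
  if (length(pk) != length(reference_peaks)) {
    stop(sprintf("peak count mismatch: %d simulated vs %d reference",
                 length(pk), length(reference_peaks)))
  }
  off <- reference_peaks - pk
  shift <- mean(off)
  list(shift_cm1 = shift, simulated_peaks = pk,
       residual_cm1 = sqrt(mean((off - shift)^2)))
}

#' Apply a rigid shift to a spectrum
#'
#' @param spectrum A `spectrum_result`.
#' @param shift_cm1 Shift added to the wavenumber axis.
#' @return Shifted `spectrum_result`.
#' @export
shift_spectrum <- function(spectrum, shift_cm1) {
  spectrum$wavenumber <- spectrum$wavenumber + shift_cm1
  spectrum$meta$shift_cm1 <- (spectrum$meta$shift_cm1 %||% 0) + shift_cm1
  spectrum
}
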