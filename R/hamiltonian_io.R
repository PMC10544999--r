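#' Read and write exciton Hamiltonian files
#'
#' The JSON schema has a `sites` array with per-pigment records
#' `{id, type, energy_cm1, dipole_D, center_A, chain}` and a `couplings_cm1`
#' field holding the symmetric coupling matrix (row-major, in cm^-1).  The
#' CSV alternative is a pair of files: a sites table and a square coupling
#' table.
#'
#' @param path File to read or write.
#' @param system An `exciton_system`.
#' @return `read_hamiltonian_json` returns an `exciton_system`;
#'   the writers return `path` invisibly.
#' @name hamiltonian_io
NULL

#' @rdname hamiltonian_io
#' @export
read_hamiltonian_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (is.null(obj$sites)) stop("Hamiltonian JSON lacks a 'sites' array: ", path)
  sites <- lapply(obj$sites, function(s) {
    pigment_site(
      site_id = s$id,
      energy = s$energy_cm1,
      dipole = if (!is.null(s$dipole_D)) unlist(s$dipole_D) else c(0, 0, 0),
      center = if (!is.null(s$center_A)) unlist(s$center_A) else rep(NA_real_, 3),
      bilin_type = if (!is.null(s$type)) s$type else NA_character_,
      chain = if (!is.null(s$chain)) s$chain else NA_character_)
  })
  n <- length(sites)
  v <- unlist(obj$couplings_cm1)
  if (is.null(v)) v <- rep(0, n * n)
  if (length(v) != n * n) stop("couplings_cm1 must hold ", n * n, " values")
  build_system(sites, matrix(v, n, n, byrow = TRUE))
}

#' @rdname hamiltonian_io
#' @export
write_hamiltonian_json <- function(system, path) {
  stopifnot(inherits(system, "exciton_system"))
  sites <- lapply(system$sites, function(s) {
    list(id = s$site_id, type = s$bilin_type, energy_cm1 = s$energy,
         dipole_D = s$dipole, center_A = s$center, chain = s$chain)
  })
  obj <- list(sites = sites,
              couplings_cm1 = lapply(seq_len(n_sites(system)),
                                     function(i) system$couplings[i, ]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname hamiltonian_io
#' @param sites_csv,couplings_csv Paths of the sites table and the square
#'   coupling table.
#' @export
read_hamiltonian_csv <- function(sites_csv, couplings_csv) {
  tab <- utils::read.csv(sites_csv, stringsAsFactors = FALSE)
  need <- c("id", "energy_cm1")
  if (!all(need %in% names(tab))) stop("sites CSV must have columns id, energy_cm1")
  sites <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    getv <- function(cols) if (all(cols %in% names(tab))) as.numeric(row[cols]) else NULL
    pigment_site(
      site_id = row$id, energy = row$energy_cm1,
      dipole = getv(c("mu_x", "mu_y", "mu_z")) %||% c(0, 0, 0),
      center = getv(c("x", "y", "z")) %||% rep(NA_real_, 3),
      bilin_type = if ("type" %in% names(tab)) row$type else NA_character_,
      chain = if ("chain" %in% names(tab)) row$chain else NA_character_)
  })
  cm <- as.matrix(utils::read.csv(couplings_csv, header = FALSE))
  storage.mode(cm) <- "double"
  build_system(sites, cm)
}

#' @rdname hamiltonian_io
#' @export
write_hamiltonian_csv <- function(system, sites_csv, couplings_csv) {
  stopifnot(inherits(system, "exciton_system"))
  mu <- site_dipoles(system)
  ce <- site_centers(system)
  tab <- data.frame(
    id = vapply(system$sites, `[[`, character(1), "site_id"),
    type = vapply(system$sites, function(s) as.character(s$bilin_type), character(1)),
    chain = vapply(system$sites, function(s) as.character(s$chain), character(1)),
    energy_cm1 = site_energies(system),
    mu_x = mu[, 1], mu_y = mu[, 2], mu_z = mu[, 3],
    x = ce[, 1], y = ce[, 2], z = ce[, 3])
  utils::write.csv(tab, sites_csv, row.names = FALSE)
  utils::write.table(system$couplings, couplings_csv, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(sites_csv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
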