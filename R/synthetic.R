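#' Ornstein-Uhlenbeck parameters for synthetic site-energy ensembles
#'
#' The generator emulates the statistical structure of the dual-MD
#' sampling protocol: per starting frame a frozen baseline drawn from a
#' Gaussian of width `sigma_slow` (protein conformations sampled at long
#' intervals, effectively independent), and within each frame an
#' Ornstein-Uhlenbeck path with stationary standard deviation
#' `sigma_fast` and correlation time `tau_c`, sampled every
#' `spacing_fs` fs (fast intramolecular motions).
#'
#' @param mean Mean site energy, cm^-1.
#' @param sigma_slow Inter-frame (static) sd, cm^-1.
#' @param sigma_fast Intra-trajectory (fast) stationary sd, cm^-1.
#' @param tau_c OU correlation time, fs (> 0).
#' @param spacing_fs Snapshot spacing, fs (default 20: 500 fs of usable
#'   trajectory over 25 snapshots).
#' @return Object of class `ou_params`.
#' @export
ou_params <- function(mean, sigma_slow, sigma_fast, tau_c = 5, spacing_fs = 20) {
  stopifnot(sigma_slow >= 0, sigma_fast >= 0, tau_c > 0, spacing_fs > 0)
  structure(list(mean = mean, sigma_slow = sigma_slow, sigma_fast = sigma_fast,
                 tau_c = tau_c, spacing_fs = spacing_fs),
            class = "ou_params")
}

#' Generate a nested synthetic site-energy ensemble
#'
#' Draws, per pigment, `n_frames` frame baselines and an exact-conditional
#' OU path of `n_snapshots` per frame (no Euler discretization error, so
#' the lag-k snapshot autocorrelation is exactly exp(-k dt / tau_c) in
#' expectation).  Returns both protocol views in one [frame_ensemble()]:
#' `MD-OPT` rows are the frame baselines, `MD-BOMD` rows are all
#' frame x snapshot samples (34 x 25 = 850 per pigment at the default
#' design).
#'
#' @param params Named list of [ou_params()], one per pigment.
#' @param n_frames,n_snapshots Sampling design (defaults 34 and 25).
#' @param seed Integer seed.
#' @return A `frame_ensemble` with both MD-OPT and MD-BOMD rows.
#' @export
gen_site_energy_ensemble <- function(params, n_frames = 34, n_snapshots = 25,
                                     seed = 1L) {
  stopifnot(is.list(params), length(params) >= 1, !is.null(names(params)))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  rows <- list()
  for (pg in names(params)) {
    p <- params[[pg]]
    stopifnot(inherits(p, "ou_params"))
    base <- p$mean + stats::rnorm(n_frames, 0, p$sigma_slow)
    phi <- exp(-p$spacing_fs / p$tau_c)
    for (f in seq_len(n_frames)) {
      x <- numeric(n_snapshots)
      x[1] <- stats::rnorm(1, 0, p$sigma_fast)
      if (n_snapshots > 1) {
        innov <- stats::rnorm(n_snapshots - 1, 0, p$sigma_fast * sqrt(1 - phi^2))
        for (k in 2:n_snapshots) x[k] <- phi * x[k - 1] + innov[k - 1]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        protocol = "MD-BOMD", pigment_id = pg, frame = f,
        snapshot = seq_len(n_snapshots), energy_cm1 = base[f] + x)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      protocol = "MD-OPT", pigment_id = pg, frame = seq_len(n_frames),
      snapshot = NA_integer_, energy_cm1 = base)
  }
  frame_ensemble(do.call(rbind, rows))
}

#' Build a toy bilin geometry with prescribed torsions
#'
#' Constructs a bonded chain carrying the topology's atom names so that
#' each requested torsion is realized exactly by the corresponding atom
#' quadruple (bond length 1.4 A, bond angles 120 degrees, unconstrained
#' linker dihedrals anti).  Useful as a synthetic fixture for the torsion
#' machinery; it is a stand-in chain, not a chemically complete bilin.
#'
#' @param torsions Numeric vector of requested torsions in degrees, one
#'   per topology entry (6 for CYC/MBV, 4 for DBV).
#' @param ligand Ligand residue name (`"CYC"`, `"MBV"`, `"DBV"`).
#' @param chain,resid Placement metadata.
#' @param topology Topology from [bilin_topology()].
#' @param linker_dihedral Dihedral (degrees) assigned to chain slots not
#'   constrained by a torsion request (default 180, extended).
#' @return A `structure_model` holding the single ligand.
#' @export
gen_bilin_geometry <- function(torsions, ligand = "CYC", chain = "B",
                               resid = 101L, topology = bilin_topology(),
                               linker_dihedral = 180) {
  topo <- topology[[ligand]]
  if (is.null(topo)) stop("unknown ligand: ", ligand)
  if (length(torsions) != length(topo)) {
    stop("need ", length(topo), " torsions for ", ligand)
  }
  if (!all(is.finite(torsions))) stop("torsions must be finite")
  ## chain of atom names: merge quadruples on their maximal prefix/suffix
  ## overlap (3 within a methine bridge, 1 across bridges)
  atoms <- topo[[1]]
  for (q in topo[-1]) {
    o <- 0L
    for (j in 3:1) {
      if (identical(q[1:j], atoms[(length(atoms) - j + 1):length(atoms)])) {
        o <- j
        break
      }
    }
    atoms <- c(atoms, q[(o + 1):4])
  }
  if (anyDuplicated(atoms)) stop("topology quadruples do not form a simple chain")
  ## dihedral slot of each quadruple within the chain
  slot <- vapply(topo, function(q) match(q[1], atoms), integer(1))
  nd <- length(atoms) - 3L
  dihedrals <- rep(linker_dihedral, nd)
  dihedrals[slot] <- torsions
  xyz <- .build_chain(length(atoms), bond = 1.4, angle = 120, dihedrals = dihedrals)
  ## clash guard: non-bonded pairs must stay apart
  dmat <- as.matrix(stats::dist(xyz))
  nb <- which(abs(row(dmat) - col(dmat)) > 2 & upper.tri(dmat), arr.ind = TRUE)
  if (length(nb) && min(dmat[nb]) < 0.8 * 1.4) {
    stop("infeasible torsion set: generated chain clashes")
  }
  structure_model(data.frame(
    chain = chain, resid = resid, resname = ligand, atom = atoms,
    element = substr(atoms, 1, 1),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

## natural-extension chain builder: fixed bond/angle, given dihedrals
.build_chain <- function(n, bond, angle, dihedrals) {
  stopifnot(n >= 4, length(dihedrals) == n - 3L)
  xyz <- matrix(0, n, 3)
  xyz[2, ] <- c(bond, 0, 0)
  th <- (180 - angle) * pi / 180
  xyz[3, ] <- xyz[2, ] + bond * c(cos(pi - th), sin(pi - th), 0)
  for (i in 4:n) {
    xyz[i, ] <- .nerf(xyz[i - 3, ], xyz[i - 2, ], xyz[i - 1, ],
                      bond, angle, dihedrals[i - 3])
  }
  xyz
}

## place D given A,B,C with |CD| = bond, angle(BCD), dihedral(ABCD)
.nerf <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180
  phi <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(phi), -sin(th) * sin(phi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Two-site exciton fixtures
#'
#' Ready-made dimers for lineshape and CD tests.  Reference coupling
#' values: 238 cm^-1 for a strongly coupled central bilin pair in a
#' closed antenna, attenuated to 16 cm^-1 in the open quaternary
#' structure.
#'
#' @param gap Site-energy gap in cm^-1 (energies `15000 +/- gap/2`).
#' @param V Electronic coupling in cm^-1.
#' @param geometry `"parallel"` (dipoles along x, H-type), `"chiral"`
#'   (perpendicular dipoles offset along z, nonzero CD couplet) or
#'   `"custom"`.
#' @param dipoles,centers For `geometry = "custom"`: 2 x 3 matrices.
#' @param mean_energy Center of the site-energy pair, cm^-1.
#' @return An `exciton_system`.
#' @export
gen_dimer_fixture <- function(gap = 0, V = 238,
                              geometry = c("parallel", "chiral", "custom"),
                              dipoles = NULL, centers = NULL,
                              mean_energy = 15000) {
  geometry <- match.arg(geometry)
  if (geometry == "parallel") {
    dipoles <- rbind(c(1, 0, 0), c(1, 0, 0))
    centers <- rbind(c(0, 0, 0), c(0, 0, 10))
  } else if (geometry == "chiral") {
    dipoles <- rbind(c(1, 0, 0), c(0, 1, 0))
    centers <- rbind(c(0, 0, 0), c(0, 0, 10))
  } else {
    stopifnot(!is.null(dipoles), !is.null(centers))
  }
  sites <- list(
    pigment_site("site_1", mean_energy + gap / 2, dipoles[1, ], centers[1, ]),
    pigment_site("site_2", mean_energy - gap / 2, dipoles[2, ], centers[2, ]))
  build_system(sites, matrix(c(0, V, V, 0), 2))
}

#' Synthetic eight-pigment antenna Hamiltonian
#'
#' A deterministic stand-in for a closed (PC645-like) or open (PC612-like)
#' phycocyanin Hamiltonian: eight bilins on two protomers with a central
#' DBV pair coupled at 238 cm^-1 (closed) or 16 cm^-1 (open), weak
#' peripheral couplings, realistic dipole magnitudes (~13 Debye) and an
#' energy ladder spanning ~700 cm^-1.  Couplings, energies and geometry
#' are invented (synthetic), chosen only to be of the magnitudes typical
#' for these complexes.
#'
#' @param kind `"closed"` or `"open"`.
#' @return An `exciton_system` of 8 sites.
#' @export
gen_antenna_fixture <- function(kind = c("closed", "open")) {
  kind <- match.arg(kind)
  central_V <- if (kind == "closed") 238 else 16
  types <- if (kind == "closed") {
    c("DBV", "DBV", "MBV", "MBV", "PCB", "PCB", "PCB", "PCB")
  } else {
    c("DBV", "DBV", "PCB", "PCB", "PCB", "PCB", "PCB", "PCB")
  }
  ids <- c("DBV_50/61B", "DBV_50/61D",
           if (kind == "closed") c("MBV_19A", "MBV_19C") else c("PCB_20A", "PCB_20C"),
           "PCB_82B", "PCB_82D", "PCB_158B", "PCB_158D")
  energies <- c(16050, 16090, 15690, 15720, 15480, 15510, 15380, 15410)
  ## two pseudo-protomers facing each other
  centers <- rbind(
    c(0, 0, 0), c(5, 0, 3),          # central pair
    c(-18, 10, 5), c(23, -10, 8),    # alpha-chain pigments
    c(-12, -14, -6), c(17, 14, -9),  # beta82
    c(-25, -5, 12), c(30, 5, 15))    # beta158
  dirs <- rbind(
    c(1, 0.2, 0), c(0.2, 1, 0.1), c(0.8, -0.5, 0.3), c(-0.6, 0.7, 0.4),
    c(0.3, 0.9, -0.3), c(0.9, -0.3, 0.3), c(0.5, 0.5, 0.7), c(-0.4, 0.8, -0.4))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  mu <- 13 * dirs
  sites <- lapply(1:8, function(i) {
    pigment_site(ids[i], energies[i], mu[i, ], centers[i, ],
                 bilin_type = types[i],
                 chain = substr(ids[i], nchar(ids[i]), nchar(ids[i])))
  })
  V <- matrix(0, 8, 8)
  V[1, 2] <- central_V
  weak <- rbind(c(1, 3, 24), c(2, 4, -21), c(1, 5, 15), c(2, 6, -14),
                c(3, 7, 9), c(4, 8, -11), c(5, 7, 18), c(6, 8, 17),
                c(3, 5, -7), c(4, 6, 6), c(7, 8, 4))
  for (r in seq_len(nrow(weak))) V[weak[r, 1], weak[r, 2]] <- weak[r, 3]
  V <- V + t(V)
  build_system(sites, V)
}

#' Synthetic phycocyanin-like structures
#'
#' Builds a small synthetic two-protomer complex: four chains (A, C =
#' alpha; B, D = beta) of C-alpha helices plus bilin ligand chains, with
#' the open form's pigment complement (6 phycocyanobilins as residue name
#' CYC + 2 DBV) or the closed form's (4 CYC + 2 DBV + 2 MBV).  The second
#' protomer (chains C + D) can be rotated about the x axis relative to the
#' first to emulate the open-vs-closed quaternary difference.
#'
#' @param kind `"open"` (6 CYC + 2 DBV) or `"closed"` (4 CYC + 2 DBV +
#'   2 MBV).
#' @param protomer_rotation_deg Rotation of protomer 2 about the x axis
#'   (default 0).
#' @return A `structure_model`.
#' @export
gen_phycocyanin_structure <- function(kind = c("open", "closed"),
                                      protomer_rotation_deg = 0) {
  kind <- match.arg(kind)
  helix <- function(n, chain, resid0, offset) {
    t <- seq_len(n)
    data.frame(chain = chain, resid = resid0 + t - 1L, resname = "ALA",
               atom = "CA", element = "C",
               x = 2.3 * cos(t * 100 * pi / 180) + offset[1],
               y = 2.3 * sin(t * 100 * pi / 180) + offset[2],
               z = 1.5 * t + offset[3])
  }
  ## protomer 1: alpha chain A + beta chain B (beta longer, like the
  ## conserved beta subunits)
  p1 <- rbind(helix(25, "A", 1L, c(0, 0, 0)), helix(40, "B", 1L, c(8, 3, -5)))
  p2 <- rbind(helix(25, "C", 1L, c(0, 18, 0)), helix(40, "D", 1L, c(8, 21, -5)))
  lig <- function(ligname, chain, resid, torsions, shift) {
    g <- gen_bilin_geometry(torsions, ligand = ligname, chain = chain, resid = resid)
    a <- g$atoms
    a$x <- a$x + shift[1]; a$y <- a$y + shift[2]; a$z <- a$z + shift[3]
    a
  }
  tau6 <- c(180, 30, 180, 180, -35, 180)
  tau4 <- c(183, 32, 172, 182)
  ligands <- if (kind == "open") {
    rbind(lig("DBV", "B", 150L, tau4, c(4, 6, 10)),
          lig("DBV", "D", 150L, tau4, c(4, 24, 10)),
          lig("CYC", "A", 120L, tau6, c(-6, -4, 8)),
          lig("CYC", "C", 120L, tau6, c(-6, 14, 8)),
          lig("CYC", "B", 160L, tau6, c(12, 8, 20)),
          lig("CYC", "D", 160L, tau6, c(12, 26, 20)),
          lig("CYC", "B", 170L, tau6, c(-2, 10, 30)),
          lig("CYC", "D", 170L, tau6, c(-2, 28, 30)))
  } else {
    rbind(lig("DBV", "B", 150L, tau4, c(4, 6, 10)),
          lig("DBV", "D", 150L, tau4, c(4, 24, 10)),
          lig("MBV", "A", 119L, tau6, c(-6, -4, 8)),
          lig("MBV", "C", 119L, tau6, c(-6, 14, 8)),
          lig("CYC", "B", 160L, tau6, c(12, 8, 20)),
          lig("CYC", "D", 160L, tau6, c(12, 26, 20)),
          lig("CYC", "B", 170L, tau6, c(-2, 10, 30)),
          lig("CYC", "D", 170L, tau6, c(-2, 28, 30)))
  }
  atoms <- rbind(p1, p2, ligands)
  if (protomer_rotation_deg != 0) {
    th <- protomer_rotation_deg * pi / 180
    R <- matrix(c(1, 0, 0,
                  0, cos(th), -sin(th),
                  0, sin(th), cos(th)), 3, 3, byrow = TRUE)
    i2 <- atoms$chain %in% c("C", "D")
    xyz <- as.matrix(atoms[i2, c("x", "y", "z")])
    ctr <- colMeans(xyz)
    atoms[i2, c("x", "y", "z")] <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, "+")
  }
  structure_model(atoms)
}

#' Jittered trajectory frames for a structure
#'
#' Adds isotropic Gaussian noise per atom and frame, optionally composing
#' each frame with a random rigid-body motion (which RMSF must be blind
#' to after superposition).
#'
#' @param model A `structure_model` (frame 1 is the template).
#' @param n_frames Number of frames to generate.
#' @param jitter_sd Per-axis displacement sd in Angstrom.
#' @param rigid Add random rigid rotations/translations per frame.
#' @param seed Integer seed.
#' @return A `structure_model` with `n_frames` frames.
#' @export
gen_trajectory_frames <- function(model, n_frames = 50, jitter_sd = 0.3,
                                  rigid = FALSE, seed = 1L) {
  stopifnot(inherits(model, "structure_model"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  base <- model$frames[[1]]
  frames <- lapply(seq_len(n_frames), function(f) {
    x <- base + matrix(stats::rnorm(length(base), 0, jitter_sd), nrow(base), 3)
    if (rigid) {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      th <- stats::runif(1, 0, 2 * pi)
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
                  byrow = TRUE)
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
      x <- sweep(x %*% t(R), 2, stats::rnorm(3, 0, 20), "+")
    }
    x
  })
  structure_model(model$atoms, frames)
}
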