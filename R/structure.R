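#' Read a PDB structure
#'
#' Minimal fixed-width reader for ATOM/HETATM records, with multi-MODEL
#' files interpreted as trajectory frames sharing the first model's atom
#' ordering.  Coordinates in Angstrom.
#'
#' @param path PDB file.
#' @return Object of class `structure_model`: a list with `atoms` (data
#'   frame: `chain, resid, resname, atom, element, x, y, z` for the first
#'   model) and `frames` (list of N_atoms x 3 coordinate matrices, one per
#'   MODEL; length 1 for single-model files).
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  is_endmdl <- startsWith(rec, "ENDMDL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines)) else model_id[model_id == 0L] <- 1L
  ai <- which(is_atom)
  al <- lines[ai]
  parse_num <- function(s, what, lineno) {
    v <- suppressWarnings(as.numeric(s))
    bad <- is.na(v)
    if (any(bad)) {
      stop(sprintf("malformed %s in PDB record at line %d: '%s'",
                   what, lineno[bad][1], trimws(s[bad][1])))
    }
    v
  }
  atoms <- data.frame(
    record = trimws(substr(al, 1, 6)),
    atom = trimws(substr(al, 13, 16)),
    resname = trimws(substr(al, 18, 20)),
    chain = trimws(substr(al, 22, 22)),
    resid = as.integer(parse_num(substr(al, 23, 26), "residue number", ai)),
    x = parse_num(substr(al, 31, 38), "x coordinate", ai),
    y = parse_num(substr(al, 39, 46), "y coordinate", ai),
    z = parse_num(substr(al, 47, 54), "z coordinate", ai),
    element = trimws(substr(al, 77, 78)),
    stringsAsFactors = FALSE)
  m <- model_id[ai]
  first <- atoms[m == min(m), , drop = FALSE]
  frames <- lapply(sort(unique(m)), function(mm) {
    a <- atoms[m == mm, , drop = FALSE]
    if (nrow(a) != nrow(first)) {
      stop("MODEL blocks differ in atom count; frames must share atom ordering")
    }
    as.matrix(a[, c("x", "y", "z")])
  })
  structure_model(first[, setdiff(names(first), "record")], frames)
}

#' Construct a structure model
#'
#' @param atoms Data frame with columns `chain, resid, resname, atom,
#'   element, x, y, z`.
#' @param frames Optional list of coordinate matrices (defaults to the
#'   single frame in `atoms`).
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms, frames = NULL) {
  atoms <- as.data.frame(atoms)
  need <- c("chain", "resid", "resname", "atom", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  if (is.null(atoms$element)) atoms$element <- substr(atoms$atom, 1, 1)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(frames)) frames <- list(xyz)
  for (f in frames) {
    stopifnot(is.matrix(f), nrow(f) == nrow(atoms), ncol(f) == 3, all(is.finite(f)))
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, frames = frames), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d frame(s), chains %s\n",
              nrow(x$atoms), length(x$frames),
              paste(sort(unique(x$atoms$chain)), collapse = "")))
  lig <- ligand_counts(x)
  if (length(lig)) {
    cat("  ligands:", paste(sprintf("%s x %d", names(lig), lig), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a structure model as PDB
#'
#' @param model A `structure_model`.
#' @param path Output file; multiple frames are written as MODEL blocks.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  std_aa <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
              "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
  rec <- ifelse(a$resname %in% std_aa, "ATOM  ", "HETATM")
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(model$frames) > 1L
  for (f in seq_along(model$frames)) {
    if (multi) writeLines(sprintf("MODEL %8d", f), con)
    xyz <- model$frames[[f]]
    ln <- sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  rec, seq_len(nrow(a)),
                  ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
                  "", a$resname, a$chain, a$resid, "",
                  xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element)
    writeLines(ln, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Ligand (heteroresidue) counts
#'
#' Counts non-water, non-standard-amino-acid residues by residue name --
#' e.g. an open-structure phycocyanin carries 6 CYC (phycocyanobilin) and
#' 2 DBV, a closed one 4 CYC + 2 DBV + 2 MBV.
#'
#' @param model A `structure_model`.
#' @return Named integer vector of residue-name counts.
#' @export
ligand_counts <- function(model) {
  a <- model$atoms
  std_aa <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
              "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
              "HOH","WAT")
  lig <- a[!(a$resname %in% std_aa), , drop = FALSE]
  if (!nrow(lig)) return(integer(0))
  key <- unique(paste(lig$chain, lig$resid, lig$resname))
  tab <- table(vapply(strsplit(key, " "), `[`, character(1), 3))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Select atom indices
#'
#' @param model A `structure_model`.
#' @param chain,resname,atom Optional filters (vectors allowed).
#' @param resid Optional residue numbers.
#' @return Integer atom indices.
#' @export
select_atoms <- function(model, chain = NULL, resname = NULL, atom = NULL,
                         resid = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(atom)) keep <- keep & a$atom %in% atom
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  which(keep)
}

## ---- torsions -----------------------------------------------------------

#' Dihedral angle of four atoms
#'
#' IUPAC dihedral of the ordered quadruple, mapped to the branch
#' (-90, 270] degrees.  Near-anti torsions of conjugated tetrapyrroles are
#' reported around 180 without wrapping to -180 (crystal values such as
#' 190 or 203 stay continuous).
#'
#' @param xyz 4 x 3 coordinate matrix (rows: the bonded chain a-b-c-d), or
#'   a `structure_model` plus `quadruple` indices.
#' @param quadruple When `xyz` is a `structure_model`: four distinct atom
#'   indices.
#' @param frame Frame index (default 1).
#' @return Angle in degrees in (-90, 270].
#' @export
torsion <- function(xyz, quadruple = NULL, frame = 1L) {
  if (inherits(xyz, "structure_model")) {
    stopifnot(length(quadruple) == 4L, !anyDuplicated(quadruple))
    xyz <- xyz$frames[[frame]][quadruple, , drop = FALSE]
  }
  stopifnot(is.matrix(xyz), nrow(xyz) == 4L, ncol(xyz) == 3L)
  b1 <- xyz[2, ] - xyz[1, ]
  b2 <- xyz[3, ] - xyz[2, ]
  b3 <- xyz[4, ] - xyz[3, ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("collinear atom triple: dihedral undefined")
  }
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  to_branch(ang)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Map an angle to the reporting branch (-90, 270]
#'
#' @param angle Angle(s) in degrees.
#' @return Equivalent angle(s) in (-90, 270].
#' @export
to_branch <- function(angle) {
  a <- (angle + 90) %% 360 - 90
  a[a <= -90] <- a[a <= -90] + 360  # guard exact boundary
  a
}

#' Circular mean and standard deviation in degrees
#'
#' Mean direction from the resultant of unit vectors; SD from circular
#' variance, sd = sqrt(-2 log Rbar) mapped to degrees.  The mean is
#' reported in the (-90, 270] branch so that ensembles straddling the
#' +/-180 cut average correctly (e.g. \{179, -179\} -> 180, not 0).
#'
#' @param angles Angles in degrees.
#' @return List with `mean` and `sd` (degrees).
#' @export
circular_stats <- function(angles) {
  th <- angles * pi / 180
  s <- mean(sin(th)); c <- mean(cos(th))
  rbar <- sqrt(s^2 + c^2)
  m <- atan2(s, c) * 180 / pi
  sd <- if (rbar >= 1) 0 else sqrt(-2 * log(rbar)) * 180 / pi
  list(mean = to_branch(m), sd = sd)
}

#' Bilin torsion topology
#'
#' The conjugated region of a bilin is characterized by six torsions (four
#' for DBV, whose C--D methine bridge is saturated): each methine bridge
#' contributes the two dihedrals about its two inter-ring bonds.  With the
#' standard tetrapyrrole atom names (rings A-D with nitrogens NA-ND, ring
#' carbons C1A..C4A etc., bridge carbons CHB/CHC/CHD), the default
#' quadruples are, per bridge X-Y with bridge carbon CH?:
#' (N_X, C4X, CH?, C1Y) and (C4X, CH?, C1Y, N_Y).  The table ships as an
#' editable JSON config so alternative atom-name conventions can be
#' swapped in.
#'
#' @param path Optional path to a topology JSON
#'   (`{ligand: {tau1: [a,b,c,d], ...}}`); default: the packaged table for
#'   CYC (phycocyanobilin), DBV and MBV.
#' @return Named list: per ligand residue name, a named list of atom-name
#'   quadruples.
#' @export
bilin_topology <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bilin_torsion_topology.json",
                        package = "phycoexciton")
  }
  topo <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(topo, function(lig) lapply(lig, as.character))
}

#' Torsion series and circular statistics for a bilin
#'
#' Measures the topology-defined torsions of one ligand residue across all
#' frames and summarizes each with circular mean and SD.
#'
#' @param model A `structure_model` (frames = trajectory).
#' @param chain,resid Chain and residue number of the ligand.
#' @param topology Topology list from [bilin_topology()]; the entry
#'   matching the ligand's residue name is used.
#' @return Object of class `torsion_series`: list with `pigment`, `angles`
#'   (frames x torsions matrix, degrees, branch (-90, 270]), `mean`, `sd`.
#' @export
torsion_stats <- function(model, chain, resid, topology = bilin_topology()) {
  stopifnot(inherits(model, "structure_model"))
  sel <- select_atoms(model, chain = chain, resid = resid)
  if (!length(sel)) stop("no atoms for chain ", chain, " resid ", resid)
  resname <- unique(model$atoms$resname[sel])
  if (length(resname) != 1L) stop("selection spans several residues")
  topo <- topology[[resname]]
  if (is.null(topo)) stop("no torsion topology for ligand ", resname)
  names_here <- model$atoms$atom[sel]
  quads <- lapply(topo, function(q) {
    idx <- match(q, names_here)
    if (anyNA(idx)) {
      stop("ligand ", resname, " is missing atom(s): ",
           paste(q[is.na(idx)], collapse = ", "))
    }
    sel[idx]
  })
  nf <- length(model$frames)
  ang <- matrix(NA_real_, nf, length(quads),
                dimnames = list(NULL, names(quads)))
  for (f in seq_len(nf)) {
    for (j in seq_along(quads)) {
      ang[f, j] <- torsion(model, quads[[j]], frame = f)
    }
  }
  st <- apply(ang, 2, circular_stats)
  structure(list(pigment = sprintf("%s_%d%s", resname, resid, chain),
                 angles = ang,
                 mean = vapply(st, `[[`, numeric(1), "mean"),
                 sd = vapply(st, `[[`, numeric(1), "sd")),
            class = "torsion_series")
}

#' @export
print.torsion_series <- function(x, ...) {
  cat("torsion_series for", x$pigment, sprintf("(%d frame(s))\n", nrow(x$angles)))
  print(data.frame(tau = colnames(x$angles),
                   mean_deg = round(x$mean), sd_deg = round(x$sd, 1)))
  invisible(x)
}

## ---- superposition, RMSF, rotation --------------------------------------

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping `mobile` onto `target`.
#'
#' @param mobile,target N x 3 coordinate matrices (matched rows).
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3;
#'   apply as `sweep(mobile %*% R, 2, t, "+")`), `rmsd`.
#' @export
kabsch <- function(mobile, target) {
  stopifnot(nrow(mobile) == nrow(target), ncol(mobile) == 3, ncol(target) == 3)
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm)
  B <- sweep(target, 2, ct)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$v %*% t(s$u)))
  Rm <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fit <- A %*% Rm
  rmsd <- sqrt(mean(rowSums((fit - B)^2)))
  list(rotation = Rm, translation = ct - cm %*% Rm, rmsd = rmsd)
}

.apply_fit <- function(xyz, fit) sweep(xyz %*% fit$rotation, 2, fit$translation, "+")

#' Per-residue RMSF over trajectory frames
#'
#' Each frame is superposed (least squares, on the selection) onto a
#' running mean structure -- starting from the first frame and iterating
#' the mean twice -- and the root-mean-square fluctuation of every
#' selected atom about the converged mean is averaged per residue.
#' Invariant under rigid-body motion of whole frames.
#'
#' @param model A `structure_model` with at least 2 frames.
#' @param selection Atom indices used for both fitting and reporting;
#'   default: all CA atoms.
#' @return Data frame `chain, resid, rmsf_A`.
#' @export
rmsf <- function(model, selection = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (length(model$frames) < 2L) stop("RMSF needs at least 2 frames")
  if (is.null(selection)) selection <- select_atoms(model, atom = "CA")
  if (!length(selection)) stop("empty selection")
  frames <- lapply(model$frames, function(f) f[selection, , drop = FALSE])
  ref <- frames[[1]]
  for (iter in 1:3) {
    fitted <- lapply(frames, function(f) .apply_fit(f, kabsch(f, ref)))
    ref <- Reduce(`+`, fitted) / length(fitted)
  }
  fitted <- lapply(frames, function(f) .apply_fit(f, kabsch(f, ref)))
  dev2 <- Reduce(`+`, lapply(fitted, function(f) rowSums((f - ref)^2))) / length(fitted)
  atom_rmsf <- sqrt(dev2)
  a <- model$atoms[selection, , drop = FALSE]
  key <- paste(a$chain, a$resid)
  out <- do.call(rbind, lapply(split(seq_along(key), factor(key, unique(key))),
    function(i) data.frame(chain = a$chain[i[1]], resid = a$resid[i[1]],
                           rmsf_A = mean(atom_rmsf[i]))))
  rownames(out) <- NULL
  out
}

#' Rotation angle of a 3 x 3 rotation matrix
#'
#' @param R Rotation matrix.
#' @return Angle in degrees in `[0, 180]`, from the matrix trace.
#' @export
rotation_angle <- function(R) {
  tr <- sum(diag(R))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

#' Relative rotation of two alpha-beta protomers
#'
#' Quantifies open-vs-closed quaternary structure: both structures are
#' superposed on their first protomer selection, then the best-fit
#' rotation relating the second protomers is extracted and its angle
#' returned.  An open complex is related to a closed reference by a
#' rotation of roughly 73 degrees of one protomer.
#'
#' @param model A `structure_model`.
#' @param reference Reference `structure_model` (e.g. the closed form).
#' @param protomer1,protomer2 Atom indices of the two protomers in
#'   `model`.
#' @param ref_protomer1,ref_protomer2 Matching indices in `reference`
#'   (defaults: same as `protomer1`/`protomer2`; index counts must match
#'   pairwise).
#' @return Rotation angle in degrees.
#' @export
protomer_rotation_angle <- function(model, reference, protomer1, protomer2,
                                    ref_protomer1 = protomer1,
                                    ref_protomer2 = protomer2) {
  stopifnot(inherits(model, "structure_model"), inherits(reference, "structure_model"))
  if (length(protomer1) != length(ref_protomer1) ||
      length(protomer2) != length(ref_protomer2)) {
    stop("protomer selections do not map 1:1 between model and reference")
  }
  x <- model$frames[[1]]
  y <- reference$frames[[1]]
  ## align the whole model on protomer 1
  fit1 <- kabsch(x[protomer1, , drop = FALSE], y[ref_protomer1, , drop = FALSE])
  x2 <- .apply_fit(x[protomer2, , drop = FALSE], fit1)
  fit2 <- kabsch(x2, y[ref_protomer2, , drop = FALSE])
  rotation_angle(fit2$rotation)
}
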