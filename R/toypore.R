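#' @include AllClasses.R pore.R rotamer.R
NULL

# idealized tryptophan residue built from internal coordinates (bond lengths
# in Angstrom, angles/torsions in degrees); chi1 = N-CA-CB-CG,
# chi2 = CA-CB-CG-CD1; the indole ring is kept planar
.trp_template <- function(chi1 = -60, chi2 = 90) {
  N <- c(1.458, 0, 0)
  CA <- c(0, 0, 0)
  C <- 1.525 * c(cos(111.2 * pi / 180), sin(111.2 * pi / 180), 0)
  # CB direction from the two backbone bond angles, lower-z branch
  ux <- cos(110.5 * pi / 180)
  chat <- .unit(C)
  uy <- (cos(110.1 * pi / 180) - chat[1] * ux) / chat[2]
  uz <- -sqrt(max(0, 1 - ux^2 - uy^2))
  CB <- 1.530 * c(ux, uy, uz)
  O <- .place_atom(N, CA, C, 1.231, 120.5, 180)
  CG <- .place_atom(N, CA, CB, 1.498, 113.7, chi1)
  CD1 <- .place_atom(CA, CB, CG, 1.365, 126.9, chi2)
  CD2 <- .place_atom(CA, CB, CG, 1.433, 126.7, chi2 + 180)
  NE1 <- .place_atom(CB, CG, CD1, 1.374, 110.1, 180)
  CE2 <- .place_atom(CG, CD1, NE1, 1.370, 109.0, 0)
  CE3 <- .place_atom(CD1, CG, CD2, 1.398, 133.9, 180)
  CZ2 <- .place_atom(CD1, NE1, CE2, 1.394, 130.4, 180)
  CZ3 <- .place_atom(CG, CD2, CE3, 1.382, 118.7, 180)
  CH2 <- .place_atom(CD2, CE3, CZ3, 1.400, 121.2, 0)
  xyz <- rbind(N, CA, C, O, CB, CG, CD1, CD2, NE1, CE2, CE3, CZ2, CZ3, CH2)
  data.frame(atom = rownames(xyz),
             element = substr(rownames(xyz), 1, 1),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

.ring_atoms <- function(R, n, z, chain = "A", resno_start = 1) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  data.frame(atom = "C", resname = "RNG", resno = resno_start + seq_len(n) - 1,
             chain = chain, x = R * cos(ang), y = R * sin(ang), z = z,
             element = "C", stringsAsFactors = FALSE)
}

#' Synthetic channel structures with known pore geometry
#'
#' Deterministic toy structures used as geometry fixtures:
#' \describe{
#'   \item{ring}{n carbon atoms on a circle of radius R in the z = 0 plane;
#'     analytic pore radius at the plane is R - vdw(C).}
#'   \item{cylinder}{identical stacked rings: a constant-radius pore.}
#'   \item{hourglass}{stacked rings with radius R0 + curvature * z^2: the
#'     analytic waist R0 - vdw(C) sits at z = 0.}
#'   \item{tetramer_gate}{four idealized tryptophan residues (full backbone +
#'     indole side chain) in exact C4 symmetry around the z axis, side chains
#'     facing the axis; the CA ring radius is solved so the facing-rotamer
#'     inter-subunit side-chain distance equals \code{facing_distance}. A
#'     synthetic stand-in for a tetrameric channel gate, not a real
#'     structure.}
#' }
#'
#' @param kind one of "ring", "cylinder", "hourglass", "tetramer_gate".
#' @param R ring radius in Angstrom (ring/cylinder).
#' @param n atoms per ring.
#' @param n_rings number of stacked rings (cylinder/hourglass).
#' @param spacing ring spacing in Angstrom along z.
#' @param R0 waist radius in Angstrom (hourglass).
#' @param curvature quadratic flare in 1/Angstrom (hourglass).
#' @param facing_distance target facing-rotamer inter-subunit distance in
#'   Angstrom (tetramer_gate; default 3.1).
#' @param resno residue number given to the gate tryptophans (default 583).
#' @param jitter_sd optional Gaussian coordinate jitter in Angstrom.
#' @param seed integer seed (used only when jitter_sd > 0).
#' @param file optional path; when given the structure is also written as PDB.
#' @return a [ChannelStructure-class] (with declared rotational symmetry).
#' @export
makeToyPore <- function(kind = c("ring", "cylinder", "hourglass", "tetramer_gate"),
                        R = 5, n = 12, n_rings = 5, spacing = 2,
                        R0 = 3, curvature = 0.05,
                        facing_distance = 3.1, resno = 583,
                        jitter_sd = 0, seed = 1L, file = NULL) {
  kind <- match.arg(kind)
  axis <- list(point = c(0, 0, 0), direction = c(0, 0, 1))
  if (kind == "ring") {
    at <- .ring_atoms(R, n, 0)
    sym <- list(order = n, axis = axis)
  } else if (kind == "cylinder") {
    zs <- (seq_len(n_rings) - (n_rings + 1) / 2) * spacing
    at <- do.call(rbind, lapply(seq_along(zs), function(i)
      .ring_atoms(R, n, zs[i], resno_start = (i - 1) * n + 1)))
    sym <- list(order = n, axis = axis)
  } else if (kind == "hourglass") {
    zs <- (seq_len(n_rings) - (n_rings + 1) / 2) * spacing
    at <- do.call(rbind, lapply(seq_along(zs), function(i)
      .ring_atoms(R0 + curvature * zs[i]^2, n, zs[i],
                  resno_start = (i - 1) * n + 1)))
    sym <- list(order = n, axis = axis)
  } else {
    at <- .tetramer_gate_atoms(facing_distance, resno)
    sym <- list(order = 4, axis = axis)
  }
  if (jitter_sd > 0) {
    jit <- withr::with_seed(as.integer(seed),
                            stats::rnorm(3 * nrow(at), 0, jitter_sd))
    at$x <- at$x + jit[seq_len(nrow(at))]
    at$y <- at$y + jit[nrow(at) + seq_len(nrow(at))]
    at$z <- at$z + jit[2 * nrow(at) + seq_len(nrow(at))]
  }
  s <- channelStructure(at, symmetry = sym)
  if (!is.null(file)) writePDBStructure(s, file)
  s
}

# place one oriented Trp per chain, CA on a ring of radius r_ca, side chains
# toward the axis, in exact C4 symmetry
.tetramer_chain_atoms <- function(r_ca, resno) {
  fac <- trpRotamers()
  tpl <- .trp_template(chi1 = fac$chi1[fac$class == "facing"],
                       chi2 = fac$chi2[fac$class == "facing"])
  xyz <- as.matrix(tpl[, c("x", "y", "z")])
  side <- !(tpl$atom %in% c(.backbone_atoms, "CB"))
  v <- .unit(colMeans(xyz[side, , drop = FALSE]))   # CA is at the origin
  # rotate so the side-chain centroid direction points along -x (toward axis)
  t <- c(-1, 0, 0)
  ax <- .cross3(v, t)
  if (sqrt(sum(ax^2)) < 1e-12) {
    Rm <- if (sum(v * t) > 0) diag(3) else diag(c(-1, 1, -1))
  } else {
    ang <- acos(max(-1, min(1, sum(v * t)))) * 180 / pi
    K <- .unit(ax)
    th <- ang * pi / 180
    Km <- matrix(c(0, K[3], -K[2], -K[3], 0, K[1], K[2], -K[1], 0), 3, 3)
    Rm <- diag(3) + sin(th) * Km + (1 - cos(th)) * (Km %*% Km)
  }
  xyz <- xyz %*% t(Rm)
  xyz[, 1] <- xyz[, 1] + r_ca
  chains <- c("A", "B", "C", "D")
  do.call(rbind, lapply(0:3, function(k) {
    th <- k * pi / 2
    Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    p <- xyz %*% t(Rz)
    data.frame(atom = tpl$atom, resname = "TRP", resno = resno,
               chain = chains[k + 1], x = p[, 1], y = p[, 2], z = p[, 3],
               element = tpl$element, stringsAsFactors = FALSE)
  }))
}

.tetramer_gate_atoms <- function(facing_distance, resno) {
  d_at <- function(r_ca) {
    s <- channelStructure(.tetramer_chain_atoms(r_ca, resno))
    facingDistance(s, resno) - facing_distance
  }
  # facing distance grows monotonically with the CA ring radius
  r <- stats::uniroot(d_at, lower = 4, upper = 40, tol = 1e-6)$root
  gate <- .tetramer_chain_atoms(r, resno)
  # cylindrical wall scaffold so the axis is the only passage: C4-symmetric
  # ring stack just outside the CA ring
  zs <- seq(-8, 8, by = 1)
  wall <- do.call(rbind, lapply(seq_along(zs), function(i) {
    w <- .ring_atoms(r + 2.5, 28, zs[i], chain = "W",
                     resno_start = 900 + (i - 1) * 28)
    w
  }))
  rbind(gate, wall)
}

#' Apply a rigid-body transform to a structure
#'
#' @param structure a [ChannelStructure-class].
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation length-3 shift in Angstrom.
#' @return the transformed [ChannelStructure-class]; a declared symmetry axis
#'   is transformed along.
#' @export
rigidTransform <- function(structure, rotation = diag(3),
                           translation = c(0, 0, 0)) {
  at <- structure@atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(rotation)
  at$x <- xyz[, 1] + translation[1]
  at$y <- xyz[, 2] + translation[2]
  at$z <- xyz[, 3] + translation[3]
  sym <- structure@symmetry
  if (length(sym) && !is.null(sym$axis)) {
    sym$axis$point <- as.numeric(rotation %*% sym$axis$point + translation)
    sym$axis$direction <- as.numeric(rotation %*% sym$axis$direction)
  }
  new("ChannelStructure", atoms = at, symmetry = sym)
}

#' Drop a declared symmetry so the axis is re-estimated from coordinates
#'
#' @param structure a [ChannelStructure-class].
#' @return the structure without symmetry annotation.
#' @export
clearSymmetry <- function(structure) {
  new("ChannelStructure", atoms = structure@atoms, symmetry = list())
}
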