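#' @include AllClasses.R pore.R
NULL

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# signed dihedral a-b-c-d in degrees (IUPAC convention)
.dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, .unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# rotate points about the line through `origin` with unit direction `axis`
# by `angle` degrees (right-hand rule)
.rotate_about <- function(points, origin, axis, angle) {
  u <- .unit(axis)
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(points, 2, origin) %*% t(R), 2, origin, "+")
}

# place a new atom bonded to c, with bond length D, angle b-c-new (degrees)
# and torsion a-b-c-new (degrees): the NeRF construction
.place_atom <- function(a, b, c, D, angle, torsion) {
  th <- angle * pi / 180; ph <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d2 <- D * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

.get_atom <- function(at, chain, resno, name) {
  i <- which(at$chain == chain & at$resno == resno & at$atom == name)
  if (length(i) == 0)
    stop(sprintf("atom %s missing in residue %d chain %s", name, resno, chain),
         call. = FALSE)
  as.numeric(at[i[1], c("x", "y", "z")])
}

#' Measure side-chain dihedrals chi1 and chi2
#'
#' chi1 = N-CA-CB-CG; chi2 = CA-CB-CG-CD1 (degrees, IUPAC sign convention).
#'
#' @param structure a [ChannelStructure-class].
#' @param resno residue number.
#' @param chain chain id.
#' @return named numeric c(chi1, chi2) in degrees.
#' @export
measureChi <- function(structure, resno, chain) {
  at <- structure@atoms
  N <- .get_atom(at, chain, resno, "N")
  CA <- .get_atom(at, chain, resno, "CA")
  CB <- .get_atom(at, chain, resno, "CB")
  CG <- .get_atom(at, chain, resno, "CG")
  CD1 <- .get_atom(at, chain, resno, "CD1")
  c(chi1 = .dihedral(N, CA, CB, CG), chi2 = .dihedral(CA, CB, CG, CD1))
}

#' Set a side-chain rotamer symmetrically across subunits
#'
#' Rigidly rotates the side chain beyond CB so that the dihedrals
#' N-CA-CB-CG = chi1 and CA-CB-CG-CD1 = chi2 take the requested values,
#' identically in every listed chain. Bond lengths and bond angles are
#' preserved (pure rigid rotations about the CA-CB and CB-CG axes); a
#' C4-symmetric structure stays C4-symmetric.
#'
#' @param structure a [ChannelStructure-class].
#' @param resno residue number present in all listed chains.
#' @param chains chain ids to modify.
#' @param chi1,chi2 target dihedrals in degrees.
#' @return the modified [ChannelStructure-class].
#' @export
setSymmetricRotamer <- function(structure, resno, chains, chi1, chi2) {
  stopifnot(is(structure, "ChannelStructure"))
  at <- structure@atoms
  for (ch in chains) {
    ridx <- which(at$chain == ch & at$resno == resno)
    if (length(ridx) == 0)
      stop(sprintf("residue %d not found in chain %s", resno, ch), call. = FALSE)
    names_r <- at$atom[ridx]
    beyond_cb <- ridx[!(names_r %in% c(.backbone_atoms, "CB"))]
    if (length(beyond_cb) == 0)
      stop(sprintf("no side-chain atoms beyond CB in residue %d chain %s",
                   resno, ch), call. = FALSE)
    N <- .get_atom(at, ch, resno, "N")
    CA <- .get_atom(at, ch, resno, "CA")
    CB <- .get_atom(at, ch, resno, "CB")
    CG <- .get_atom(at, ch, resno, "CG")
    # chi1: rotate everything beyond CB about the CA->CB axis
    cur1 <- .dihedral(N, CA, CB, CG)
    pts <- as.matrix(at[beyond_cb, c("x", "y", "z")])
    pts <- .rotate_about(pts, CB, CA - CB, chi1 - cur1)
    at[beyond_cb, c("x", "y", "z")] <- pts
    # chi2: rotate everything beyond CG about the CB->CG axis
    CG <- .get_atom(at, ch, resno, "CG")
    CD1 <- .get_atom(at, ch, resno, "CD1")
    beyond_cg <- beyond_cb[at$atom[beyond_cb] != "CG"]
    cur2 <- .dihedral(CA, CB, CG, CD1)
    pts <- as.matrix(at[beyond_cg, c("x", "y", "z")])
    pts <- .rotate_about(pts, CG, CB - CG, chi2 - cur2)
    at[beyond_cg, c("x", "y", "z")] <- pts
  }
  new("ChannelStructure", atoms = at, symmetry = structure@symmetry)
}

#' Built-in tryptophan rotamer classes
#'
#' The three canonical chi1 wells (-60, 60, 180 degrees) with representative
#' chi2 values, labelled by the orientation the side chain takes in the
#' synthetic tetramer gate fixture: facing the pore axis, pointing up, or
#' pointing down. Users studying a real structure should supply their own
#' (chi1, chi2) list.
#'
#' @return data.frame with columns class, chi1, chi2 (degrees).
#' @export
trpRotamers <- function() {
  data.frame(class = c("facing", "up", "down"),
             chi1 = c(-60, 180, 60),
             chi2 = c(90, -90, 90),
             stringsAsFactors = FALSE)
}
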