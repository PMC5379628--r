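#' @include AllClasses.R
NULL

# Bondi van der Waals radii (Angstrom)
.bondi <- c(H = 1.20, HE = 1.40, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
            NE = 1.54, SI = 2.10, P = 1.80, S = 1.80, CL = 1.75, AR = 1.88,
            BR = 1.85, KR = 2.02, I = 1.98, XE = 2.16, ZN = 1.39, CA = 2.31,
            `NA` = 2.27, K = 2.75, MG = 1.73)

#' Van der Waals radius by element (Bondi table)
#'
#' @param element character element symbols.
#' @param table named radius table in Angstrom; defaults to the Bondi set.
#' @return radii in Angstrom; unknown elements get 1.70 A with a warning.
#' @export
vdwRadius <- function(element, table = .bondi) {
  el <- toupper(trimws(element))
  r <- unname(table[el])
  if (anyNA(r)) {
    warning(sprintf("unknown element(s) %s: using 1.70 A",
                    paste(unique(el[is.na(r)]), collapse = ", ")))
    r[is.na(r)] <- 1.70
  }
  r
}

#' Construct a ChannelStructure from an atom table
#'
#' @param atoms data.frame with at least \code{atom}, \code{resname},
#'   \code{resno}, \code{chain}, \code{x}, \code{y}, \code{z}; \code{element}
#'   is derived from the atom name and \code{vdw} from the Bondi table when
#'   absent.
#' @param symmetry optional list(order =, axis = list(point, direction)).
#' @param vdw_table named vdW radius table.
#' @return a [ChannelStructure-class].
#' @export
channelStructure <- function(atoms, symmetry = list(), vdw_table = .bondi) {
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$element))
    atoms$element <- .element_from_name(atoms$atom)
  if (is.null(atoms$vdw))
    atoms$vdw <- vdwRadius(atoms$element, vdw_table)
  new("ChannelStructure", atoms = atoms, symmetry = symmetry)
}

# derive an element symbol from a PDB atom name (hydrogens aside, the first
# non-digit character is the element for standard protein atoms)
.element_from_name <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  two <- toupper(substr(nm, 1, 2))
  el <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"),
               two, toupper(substr(nm, 1, 1)))
  el
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), keeps the highest-occupancy
#' alternate location (A on ties), skips waters by default, and assigns van
#' der Waals radii per element from the Bondi table (unknown elements get
#' 1.70 A with a warning). Hydrogens absent from the input are simply absent:
#' no united-atom radius inflation is applied.
#'
#' @param path PDB file path.
#' @param keep_water retain water molecules (default FALSE).
#' @param symmetry optional declared symmetry, list(order =, axis =).
#' @param vdw_table named vdW radius table.
#' @return a [ChannelStructure-class].
#' @export
readPDBStructure <- function(path, keep_water = FALSE, symmetry = list(),
                             vdw_table = .bondi) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0) stop("structure contains no atoms", call. = FALSE)
  if (!keep_water)
    at <- at[!at$resid %in% c("HOH", "WAT", "DOD", "SOL", "TIP", "TIP3"), ]
  if (nrow(at) == 0) stop("structure is empty after removing waters", call. = FALSE)
  # altloc: keep the highest occupancy per atom site; ties go to the
  # alphabetically first altloc (A)
  alt <- at$alt; alt[is.na(alt)] <- ""
  occ <- at$o; occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  at <- at[ord, ][!duplicated(key[ord]), ]
  at <- at[order(at$eleno), ]
  el <- trimws(at$elesy)
  el[is.na(el) | el == ""] <- .element_from_name(at$elety[is.na(el) | el == ""])
  atoms <- data.frame(
    serial = at$eleno, atom = trimws(at$elety), resname = trimws(at$resid),
    resno = at$resno, chain = as.character(at$chain),
    x = at$x, y = at$y, z = at$z,
    element = toupper(el), stringsAsFactors = FALSE
  )
  atoms$vdw <- vdwRadius(atoms$element, vdw_table)
  new("ChannelStructure", atoms = atoms, symmetry = symmetry)
}

#' Write a ChannelStructure to a PDB file
#'
#' @param structure a [ChannelStructure-class].
#' @param path output PDB path.
#' @return the path, invisibly.
#' @export
writePDBStructure <- function(structure, path) {
  at <- structure@atoms
  bio3d::write.pdb(file = path,
                   eleno = at$serial, elety = at$atom, resid = at$resname,
                   chain = at$chain, resno = at$resno,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   elesy = at$element)
  invisible(path)
}

.coords <- function(structure) as.matrix(structure@atoms[, c("x", "y", "z")])

.unit <- function(v) v / sqrt(sum(v^2))

# variance of the radial (perpendicular) distances of points to the line
# (point = centroid, direction = u)
.lateral_spread <- function(xyz, centroid, u) {
  rel <- sweep(xyz, 2, centroid)
  along <- rel %*% u
  perp2 <- rowSums(rel^2) - along^2
  stats::var(sqrt(pmax(perp2, 0)))
}

#' Pore axis of a channel structure
#'
#' The conduction axis: the line through the centroid of the selected atoms
#' whose direction minimizes the spread (variance) of their radial distances
#' — pore-lining atoms form a roughly cylindrical shell around the true axis.
#' When the structure declares a rotational symmetry axis, that axis is
#' returned directly.
#'
#' @param structure a [ChannelStructure-class].
#' @param selection logical or integer index into the atom table (default all).
#' @return list with \code{point} (centroid) and unit \code{direction}.
#' @export
poreAxis <- function(structure, selection = NULL) {
  stopifnot(is(structure, "ChannelStructure"))
  sym <- structure@symmetry
  if (length(sym) && !is.null(sym$axis))
    return(list(point = as.numeric(sym$axis$point),
                direction = .unit(as.numeric(sym$axis$direction))))
  xyz <- .coords(structure)
  if (!is.null(selection)) xyz <- xyz[selection, , drop = FALSE]
  if (nrow(xyz) < 3) stop("axis estimation needs at least 3 atoms", call. = FALSE)
  centroid <- colMeans(xyz)
  ev <- eigen(stats::cov(xyz), symmetric = TRUE)$vectors
  angles_of <- function(u) c(acos(max(-1, min(1, u[3]))), atan2(u[2], u[1]))
  obj <- function(p) {
    u <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
    .lateral_spread(xyz, centroid, u)
  }
  best <- NULL
  for (j in 1:3) {
    p0 <- angles_of(ev[, j])
    fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  u <- c(sin(best$par[1]) * cos(best$par[2]),
         sin(best$par[1]) * sin(best$par[2]), cos(best$par[1]))
  if (u[3] < 0) u <- -u     # canonical orientation
  list(point = as.numeric(centroid), direction = .unit(u))
}

# orthonormal frame completing the axis direction
.axis_frame <- function(direction) {
  u <- .unit(direction)
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(a - sum(a * u) * u)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(u = u, e1 = e1, e2 = e2)
}

# clearance of a lateral probe position: min over atoms of
# (distance to atom centre - vdw radius)
.clearance <- function(px, py, z, ax, ay, az, vdw) {
  d <- sqrt((ax - px)^2 + (ay - py)^2 + (az - z)^2) - vdw
  min(d)
}

#' HOLE-style pore radius profile
#'
#' At each axial position z the largest probe sphere is found by maximizing,
#' over lateral offsets within \code{lateral_bound} of the axis, the clearance
#' min_a(|p - x_a| - vdw_a). A coarse lateral grid (\code{grid_step}) locates
#' the optimum, which is then refined by a local simplex search. Slabs with no
#' atoms in reach report the lateral bound as radius with the \code{open}
#' flag set.
#'
#' @param structure a [ChannelStructure-class].
#' @param axis list(point, direction); computed by [poreAxis()] when missing.
#' @param z_range length-2 axial range in Angstrom (default: atom extent).
#' @param z_step axial sampling step in Angstrom (default 0.25).
#' @param lateral_bound maximum lateral probe offset in Angstrom (default 10).
#' @param grid_step coarse lateral grid step in Angstrom (default 0.25).
#' @return a [PoreProfile-class].
#' @export
radiusProfile <- function(structure, axis = NULL, z_range = NULL,
                          z_step = 0.25, lateral_bound = 10,
                          grid_step = 0.25) {
  stopifnot(is(structure, "ChannelStructure"))
  if (z_step <= 0) stop("z_step must be > 0", call. = FALSE)
  if (lateral_bound <= 0) stop("lateral_bound must be > 0", call. = FALSE)
  if (is.null(axis)) axis <- poreAxis(structure)
  fr <- .axis_frame(axis$direction)
  xyz <- sweep(.coords(structure), 2, axis$point)
  az <- drop(xyz %*% fr$u)
  ax <- drop(xyz %*% fr$e1)
  ay <- drop(xyz %*% fr$e2)
  vdw <- structure@atoms$vdw
  if (is.null(z_range)) z_range <- range(az)
  zs <- seq(z_range[1], z_range[2], by = z_step)
  # lateral candidate grid within the bound
  g <- seq(-lateral_bound, lateral_bound, by = grid_step)
  gx <- rep(g, times = length(g)); gy <- rep(g, each = length(g))
  keep <- gx^2 + gy^2 <= lateral_bound^2
  gx <- gx[keep]; gy <- gy[keep]
  max_vdw <- max(vdw)
  radius <- numeric(length(zs)); open <- logical(length(zs))
  for (i in seq_along(zs)) {
    z <- zs[i]
    slab <- abs(az - z) <= 2 * lateral_bound + max_vdw
    if (!any(slab)) { radius[i] <- lateral_bound; open[i] <- TRUE; next }
    sx <- ax[slab]; sy <- ay[slab]; sz <- az[slab]; sv <- vdw[slab]
    # vectorized coarse scan
    dz2 <- (sz - z)^2
    cl <- vapply(seq_along(gx), function(j)
      min(sqrt((sx - gx[j])^2 + (sy - gy[j])^2 + dz2) - sv), numeric(1))
    jbest <- which.max(cl)
    # local refinement with a bound penalty
    ref <- stats::optim(c(gx[jbest], gy[jbest]), function(p) {
      if (p[1]^2 + p[2]^2 > lateral_bound^2) return(1e6)
      -.clearance(p[1], p[2], z, sx, sy, sz, sv)
    }, method = "Nelder-Mead", control = list(maxit = 300, reltol = 1e-10))
    r <- max(cl[jbest], -ref$value)
    if (r >= lateral_bound) { radius[i] <- lateral_bound; open[i] <- TRUE }
    else { radius[i] <- max(0, r); open[i] <- FALSE }
  }
  new("PoreProfile", z = zs, radius = radius, open = open,
      axis = list(point = axis$point, direction = fr$u))
}

#' Narrowest point of a pore profile
#'
#' @param profile a [PoreProfile-class].
#' @param z_window optional length-2 axial window in Angstrom.
#' @return list with \code{z}, \code{radius} and \code{diameter} (Angstrom);
#'   ties are broken toward the smallest z.
#' @export
minConstriction <- function(profile, z_window = NULL) {
  stopifnot(is(profile, "PoreProfile"))
  sel <- if (is.null(z_window)) rep(TRUE, length(profile@z))
         else profile@z >= z_window[1] & profile@z <= z_window[2]
  if (!any(sel)) stop("window contains no profile samples", call. = FALSE)
  z <- profile@z[sel]; r <- profile@radius[sel]
  i <- which.min(r)   # first minimum = smallest z on ties
  list(z = z[i], radius = r[i], diameter = 2 * r[i])
}

# backbone names never counted as side chain
.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

#' Minimum distance between gate side chains of opposing subunits
#'
#' Finds the chains carrying the residue, identifies opposing subunit pairs
#' (chains whose side-chain centroids sit on opposite sides of the pore axis;
#' with only two chains, that pair), and returns the minimum atom-atom
#' distance between their selected side-chain atoms.
#'
#' @param structure a [ChannelStructure-class].
#' @param resno residue number (source-file numbering).
#' @param atoms character atom names to consider; default: all side-chain
#'   atoms beyond CB.
#' @param chains optional chain subset.
#' @return minimum inter-subunit distance in Angstrom.
#' @export
facingDistance <- function(structure, resno, atoms = NULL, chains = NULL) {
  at <- structure@atoms
  sel <- at$resno == resno
  if (!is.null(chains)) sel <- sel & at$chain %in% chains
  if (is.null(atoms)) {
    sel <- sel & !(at$atom %in% c(.backbone_atoms, "CB"))
  } else {
    sel <- sel & at$atom %in% atoms
  }
  at <- at[sel, , drop = FALSE]
  chs <- unique(at$chain)
  if (length(chs) < 2)
    stop("residue must be present (with side-chain atoms) in at least 2 chains",
         call. = FALSE)
  cent <- t(vapply(chs, function(ch)
    colMeans(as.matrix(at[at$chain == ch, c("x", "y", "z")])), numeric(3)))
  mid <- colMeans(cent)
  dirs <- sweep(cent, 2, mid)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pairs <- utils::combn(length(chs), 2)
  opp <- apply(pairs, 2, function(p) sum(dirs[p[1], ] * dirs[p[2], ]))
  use <- if (length(chs) == 2) 1L else {
    w <- which(opp < cos(135 * pi / 180))
    if (length(w)) w else which.min(opp)   # most anti-parallel pair(s)
  }
  dmin <- Inf
  for (j in use) {
    p <- pairs[, j]
    a <- as.matrix(at[at$chain == chs[p[1]], c("x", "y", "z")])
    b <- as.matrix(at[at$chain == chs[p[2]], c("x", "y", "z")])
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    dmin <- min(dmin, sqrt(max(0, min(d2))))
  }
  dmin
}

#' Effective gate aperture between opposed side chains
#'
#' The free diameter left between two opposed side-chain surfaces:
#' aperture = max(0, d - 2 r_eff), where d is the centre-to-centre facing
#' distance and r_eff the effective surface radius of the side-chain atoms.
#' The default r_eff = 1.15 A maps the wild-type facing distance of 3.1 A to
#' the 0.8 A passage size; it is a calibration constant, configurable.
#'
#' @param d facing distance in Angstrom (>= 0).
#' @param r_eff effective side-chain surface radius in Angstrom (default 1.15).
#' @return aperture in Angstrom (clamped at 0).
#' @export
gateAperture <- function(d, r_eff = 1.15) {
  if (any(d < 0) || any(r_eff < 0))
    stop("d and r_eff must be >= 0", call. = FALSE)
  pmax(0, d - 2 * r_eff)
}

#' Ion permeation feasibility of a gate aperture
#'
#' An ion passes when the aperture is at least the dehydrated ion diameter
#' (the boundary counts as permeable). The default diameter 0.99 A is that of
#' dehydrated Ca2+.
#'
#' @param aperture gate aperture in Angstrom (>= 0).
#' @param ion_diameter dehydrated ion diameter in Angstrom (default 0.99).
#' @return "permeable" or "blocked" (vectorized over aperture).
#' @export
permeationFeasibility <- function(aperture, ion_diameter = 0.99) {
  if (any(aperture < 0) || any(ion_diameter < 0))
    stop("aperture and ion_diameter must be >= 0", call. = FALSE)
  ifelse(aperture >= ion_diameter, "permeable", "blocked")
}

#' Gate geometry of one symmetric rotamer configuration
#'
#' Applies a symmetric side-chain rotamer to the gate residue, measures the
#' inter-subunit facing distance, and classifies permeation.
#'
#' @param structure a [ChannelStructure-class].
#' @param resno gate residue number.
#' @param chi1,chi2 target dihedrals in degrees.
#' @param chains chains to modify (default: all carrying the residue).
#' @param r_eff effective surface radius in Angstrom (see [gateAperture()]).
#' @param ion_diameter dehydrated ion diameter in Angstrom.
#' @return a [GateGeometry-class].
#' @export
assessGate <- function(structure, resno, chi1, chi2, chains = NULL,
                       r_eff = 1.15, ion_diameter = 0.99) {
  if (is.null(chains))
    chains <- unique(structure@atoms$chain[structure@atoms$resno == resno])
  rot <- setSymmetricRotamer(structure, resno, chains, chi1, chi2)
  d <- facingDistance(rot, resno, chains = chains)
  ap <- gateAperture(d, r_eff)
  new("GateGeometry", residue = resno, chi1 = chi1, chi2 = chi2,
      facingDistance = d, aperture = ap,
      verdict = permeationFeasibility(ap, ion_diameter))
}

#' Sweep the gate residue over a rotamer table
#'
#' @param structure a [ChannelStructure-class].
#' @param resno gate residue number.
#' @param rotamers data.frame with columns \code{class}, \code{chi1},
#'   \code{chi2} (degrees); default [trpRotamers()].
#' @param chains chains to modify.
#' @param r_eff,ion_diameter see [assessGate()].
#' @return data.frame: class, chi1, chi2, facing_d_A, aperture_A, verdict.
#' @export
rotamerSweep <- function(structure, resno, rotamers = trpRotamers(),
                         chains = NULL, r_eff = 1.15, ion_diameter = 0.99) {
  res <- lapply(seq_len(nrow(rotamers)), function(i) {
    gg <- assessGate(structure, resno, rotamers$chi1[i], rotamers$chi2[i],
                     chains = chains, r_eff = r_eff,
                     ion_diameter = ion_diameter)
    data.frame(class = rotamers$class[i], chi1 = gg@chi1, chi2 = gg@chi2,
               facing_d_A = gg@facingDistance, aperture_A = gg@aperture,
               verdict = gg@verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
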