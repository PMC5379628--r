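test_that("PDB round-trip preserves coordinates to file precision", {
  ring <- makeToyPore("ring", R = 5, n = 12)
  f <- tempfile(fileext = ".pdb")
  writePDBStructure(ring, f)
  back <- readPDBStructure(f)
  expect_equal(nrow(atomTable(back)), nrow(atomTable(ring)))
  expect_equal(as.matrix(atomTable(back)[, c("x", "y", "z")]),
               as.matrix(atomTable(ring)[, c("x", "y", "z")]),
               tolerance = 1.1e-3, ignore_attr = TRUE)
  expect_equal(atomTable(back)$vdw, rep(1.70, 12))   # Bondi carbon
})

test_that("PDB parsing honors altloc occupancy and skips waters", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA ATRP A 583       1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BTRP A 583       2.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CB ATRP A 583       3.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CB BTRP A 583       4.000   0.000   0.000  0.50 10.00           C",
    "ATOM      5  N   GLY A 584       5.000   1.000   0.000  1.00 10.00           N",
    "HETATM    6  O   HOH A 701       9.000   9.000   9.000  1.00 10.00           O",
    "END"), f)
  s <- readPDBStructure(f)
  at <- atomTable(s)
  expect_equal(nrow(at), 3L)                        # water dropped
  expect_equal(at$x[at$atom == "CA"], 2.0)          # higher occupancy B
  expect_equal(at$x[at$atom == "CB"], 3.0)          # tie -> altloc A
  expect_equal(at$vdw[at$atom == "N"], 1.55)        # Bondi nitrogen
  expect_error(readPDBStructure(tempfile()), "not found")
})

test_that("unknown elements fall back to 1.70 A with a warning", {
  expect_warning(r <- vdwRadius(c("C", "XX")), "unknown element")
  expect_equal(r, c(1.70, 1.70))
  expect_equal(vdwRadius(c("N", "O", "S")), c(1.55, 1.52, 1.80))
})

test_that("pore axis is recovered for rings, stacks and rigid motions", {
  ring <- clearSymmetry(makeToyPore("ring", R = 5, n = 12))
  ax <- poreAxis(ring)
  expect_equal(abs(ax$direction[3]), 1, tolerance = 1e-6)
  expect_equal(ax$point, c(0, 0, 0), tolerance = 1e-9)
  # translation equivariance
  shifted <- rigidTransform(ring, translation = c(10, 0, 0))
  ax2 <- poreAxis(shifted)
  expect_equal(ax2$point, c(10, 0, 0), tolerance = 1e-9)
  expect_equal(abs(ax2$direction[3]), 1, tolerance = 1e-6)
  # two stacked rings: matches the brute-force least-spread direction
  two <- clearSymmetry(makeToyPore("cylinder", R = 5, n = 10, n_rings = 2,
                                   spacing = 4))
  th <- 0.5
  Rx <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  rot <- rigidTransform(two, Rx, c(1, 2, 3))
  u_fit <- poreAxis(rot)$direction
  u_brute <- brute_force_axis_direction(
    as.matrix(atomTable(rot)[, c("x", "y", "z")]))
  expect_gt(abs(sum(u_fit * u_brute)), 0.999)
  expect_error(poreAxis(ring, selection = 1:2), "at least 3")
})

test_that("radius profile matches brute-force grid search on fixtures", {
  ring <- makeToyPore("ring", R = 5, n = 12)
  p <- radiusProfile(ring, z_range = c(-1, 1), z_step = 0.5, lateral_bound = 4)
  expect_equal(p@radius[p@z == 0], 3.3, tolerance = 0.01)
  for (z in c(-1, 0, 0.5))
    expect_equal(p@radius[p@z == z],
                 brute_force_radius(ring, z, 4), tolerance = 0.05)

  cyl <- makeToyPore("cylinder", R = 5, n = 14, n_rings = 9, spacing = 0.5)
  pc <- radiusProfile(cyl, z_range = c(-1.5, 1.5), z_step = 0.25,
                      lateral_bound = 4)
  expect_lt(diff(range(pc@radius)), 0.02)          # near-constant along z
  expect_equal(min(pc@radius), 3.3, tolerance = 0.01)

  hg <- makeToyPore("hourglass", R0 = 3, curvature = 0.1, n_rings = 13,
                    spacing = 1, n = 16)
  ph <- radiusProfile(hg, z_range = c(-4, 4), z_step = 0.25,
                      lateral_bound = 2.5)
  mc <- minConstriction(ph)
  expect_equal(mc$z, 0)                            # analytic waist position
  expect_equal(mc$radius, 3 - 1.7, tolerance = 0.02)
  expect_equal(mc$diameter, 2 * mc$radius)
  for (z in c(-2, 0, 1))
    expect_equal(ph@radius[ph@z == z],
                 brute_force_radius(hg, z, 2.5), tolerance = 0.05)
})

test_that("radius profile respects vdW inflation and rigid motions", {
  ring <- makeToyPore("ring", R = 5, n = 12)
  p0 <- radiusProfile(ring, z_range = c(0, 0), lateral_bound = 4)
  inflated <- ring
  at <- atomTable(inflated); at$vdw <- at$vdw + 0.3
  inflated <- new("ChannelStructure", atoms = at, symmetry = inflated@symmetry)
  p1 <- radiusProfile(inflated, z_range = c(0, 0), lateral_bound = 4)
  expect_equal(p1@radius, p0@radius - 0.3, tolerance = 1e-6)
  # rigid rotation/translation with recomputed axis leaves the profile intact
  th <- 0.8
  Rx <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  cyl <- clearSymmetry(makeToyPore("cylinder", R = 5, n = 14, n_rings = 9,
                                   spacing = 0.5))
  moved <- rigidTransform(cyl, Rx, c(4, -2, 7))
  pa <- radiusProfile(cyl, z_range = c(-1, 1), z_step = 0.5, lateral_bound = 4)
  pb <- radiusProfile(moved, z_range = c(-1, 1), z_step = 0.5, lateral_bound = 4)
  expect_equal(pb@radius, pa@radius, tolerance = 1e-3)
  # empty slab reports the lateral bound with the open flag
  po <- radiusProfile(ring, z_range = c(30, 30), lateral_bound = 4)
  expect_true(po@open[1])
  expect_equal(po@radius[1], 4)
})

test_that("constriction minimum breaks ties toward the smallest z", {
  prof <- new("PoreProfile", z = c(-2, -1, 0, 1), radius = c(3, 1, 1, 2),
              open = rep(FALSE, 4), axis = list())
  mc <- minConstriction(prof)
  expect_equal(mc$z, -1)
  expect_equal(mc$diameter, 2)
  expect_equal(minConstriction(prof, c(0, 1))$z, 0)
  expect_error(minConstriction(prof, c(5, 6)), "no profile samples")
})

test_that("symmetric rotamer setting is exact, rigid and C4-preserving", {
  s <- makeToyPore("tetramer_gate")
  # identity: setting the current chi leaves coordinates unchanged
  cur <- measureChi(s, 583, "A")
  s_id <- setSymmetricRotamer(s, 583, LETTERS[1:4], cur[["chi1"]], cur[["chi2"]])
  expect_equal(as.matrix(atomTable(s_id)[, c("x", "y", "z")]),
               as.matrix(atomTable(s)[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
  # requested dihedrals are realized in every chain
  s2 <- setSymmetricRotamer(s, 583, LETTERS[1:4], 170, -75)
  for (ch in LETTERS[1:4])
    expect_equal(unname(measureChi(s2, 583, ch)), c(170, -75), tolerance = 1e-6)
  # bond lengths preserved (rigid rotations only)
  blen <- function(st, ch, a1, a2) {
    at <- atomTable(st); at <- at[at$chain == ch & at$resno == 583, ]
    p <- function(nm) as.numeric(at[at$atom == nm, c("x", "y", "z")])
    sqrt(sum((p(a1) - p(a2))^2))
  }
  for (b in list(c("CB", "CG"), c("CG", "CD1"), c("NE1", "CE2"), c("CZ3", "CH2")))
    expect_equal(blen(s2, "A", b[1], b[2]), blen(s, "A", b[1], b[2]),
                 tolerance = 1e-9)
  # C4 symmetry: chain A rotated by 90 degrees matches chain B
  atA <- atomTable(s2); atA <- atA[atA$chain == "A" & atA$resno == 583, ]
  atB <- atomTable(s2); atB <- atB[atB$chain == "B" & atB$resno == 583, ]
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  expect_equal(as.matrix(atA[, c("x", "y", "z")]) %*% t(Rz),
               as.matrix(atB[, c("x", "y", "z")]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(setSymmetricRotamer(s, 999, "A", 0, 0), "not found")
})

test_that("facing distance measures opposing subunits", {
  # two single-atom 'side chains' constructed 3.1 A apart
  at <- data.frame(atom = "CG", resname = "TRP", resno = 1,
                   chain = c("A", "B"),
                   x = c(-1.55, 1.55), y = 0, z = 0, element = "C")
  s2 <- channelStructure(at)
  expect_equal(facingDistance(s2, 1), 3.1, tolerance = 1e-9)

  s <- makeToyPore("tetramer_gate")
  # both diagonals of the symmetric tetramer agree and match the exhaustive scan
  dAC <- brute_force_pair_min(s, 583, "A", "C")
  dBD <- brute_force_pair_min(s, 583, "B", "D")
  expect_equal(dAC, dBD, tolerance = 1e-9)
  expect_equal(facingDistance(s, 583), min(dAC, dBD), tolerance = 1e-9)
  # perturbed (non-symmetric) tetramer still matches the pair scan
  sj <- makeToyPore("tetramer_gate", jitter_sd = 0.05, seed = 8)
  expect_equal(facingDistance(sj, 583),
               min(brute_force_pair_min(sj, 583, "A", "C"),
                   brute_force_pair_min(sj, 583, "B", "D")),
               tolerance = 1e-9)
  expect_error(facingDistance(s, 583, chains = "A"), "at least 2 chains")
})

test_that("gate aperture and permeation rule follow the calibrated mapping", {
  expect_equal(gateAperture(3.1), 0.8, tolerance = 1e-12)
  expect_equal(gateAperture(4, 0), 4)
  expect_equal(gateAperture(2.3, 1.15), 0)          # clamped at zero
  expect_error(gateAperture(-1), ">= 0")
  expect_identical(permeationFeasibility(0.8), "blocked")
  expect_identical(permeationFeasibility(0.99), "permeable")  # boundary rule
  expect_identical(permeationFeasibility(22.4 - 2.3), "permeable")
  # monotonicity: aperture non-decreasing in distance, verdict in aperture
  d <- seq(0, 6, by = 0.5)
  expect_true(all(diff(gateAperture(d)) >= 0))
  v <- permeationFeasibility(gateAperture(d))
  expect_true(all(diff(v == "permeable") >= 0))
})

test_that("rotamer sweep orders the gate constriction radii", {
  s <- makeToyPore("tetramer_gate")
  sweep_tab <- rotamerSweep(s, 583)
  expect_identical(sweep_tab$verdict[sweep_tab$class == "facing"], "blocked")
  expect_true(all(sweep_tab$verdict[sweep_tab$class != "facing"] == "permeable"))
  expect_equal(sweep_tab$aperture_A[sweep_tab$class == "facing"], 0.8,
               tolerance = 0.01)
  # constriction radii strictly ordered, the facing-in rotamer narrowest
  radii <- vapply(seq_len(nrow(sweep_tab)), function(i) {
    st <- setSymmetricRotamer(s, 583, LETTERS[1:4],
                              sweep_tab$chi1[i], sweep_tab$chi2[i])
    minConstriction(radiusProfile(st, z_range = c(-6, 6), z_step = 0.5,
                                  lateral_bound = 10))$radius
  }, numeric(1))
  names(radii) <- sweep_tab$class
  expect_equal(unname(which.min(radii)), 1L)       # facing is narrowest
  expect_true(all(diff(sort(radii)) > 0.1))        # strictly distinct
})

test_that("toy tetramer is generated at the requested facing distance", {
  s4 <- makeToyPore("tetramer_gate", facing_distance = 4.2)
  expect_equal(facingDistance(s4, 583), 4.2, tolerance = 1e-4)
  # round-trips through PDB
  f <- tempfile(fileext = ".pdb")
  makeToyPore("tetramer_gate", file = f)
  s <- readPDBStructure(f)
  expect_equal(facingDistance(s, 583), 3.1, tolerance = 2e-3)
  expect_error(makeToyPore("doughnut"), "arg")
})
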