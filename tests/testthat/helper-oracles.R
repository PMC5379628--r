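# Independent oracles and shared fixtures for the test suite.

# canonical rate sets (k_oc, k_co, k_21, k_12) used across property tests
rate_sets <- list(
  classic = c(100, 50, 20, 10),
  wt_like = c(100, 80, 30, 15),
  mutant_like = c(200, 50, 70.8, 10)
)

model_from <- function(rs, amp = 5.5) buildThreeState(rs[1], rs[2], rs[3], rs[4], amp)

# phase-type closed-sojourn sampler by explicit embedded-chain walk
# (independent of the package's spectral machinery): enter at C2, hop between
# C2 and C1 until the jump to O
sample_closed_dwells <- function(rates, n, seed) {
  k_co <- rates[2]; k_21 <- rates[3]; k_12 <- rates[4]
  withr::with_seed(seed, {
    out <- numeric(n)
    for (i in seq_len(n)) {
      t <- 0; s <- 2L
      repeat {
        if (s == 2L) {
          t <- t + stats::rexp(1, k_co + k_21)
          if (stats::runif(1) < k_co / (k_co + k_21)) break
          s <- 3L
        } else {
          t <- t + stats::rexp(1, k_12)
          s <- 2L
        }
      }
      out[i] <- t
    }
    out
  })
}

# Monte-Carlo standard error of a segmented statistic: value per independent
# segment, returned as list(mean, se)
segment_mc <- function(values) {
  list(mean = colMeans(values), se = apply(values, 2, stats::sd) / sqrt(nrow(values)))
}

# brute-force inscribed-probe radius at one axial position: dense lateral grid
brute_force_radius <- function(structure, z, lateral_bound, step = 0.05,
                               axis = list(point = c(0, 0, 0),
                                           direction = c(0, 0, 1))) {
  at <- atomTable(structure)
  u <- axis$direction / sqrt(sum(axis$direction^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  xyz <- sweep(as.matrix(at[, c("x", "y", "z")]), 2, axis$point)
  az <- drop(xyz %*% u); ax <- drop(xyz %*% e1); ay <- drop(xyz %*% e2)
  g <- seq(-lateral_bound, lateral_bound, by = step)
  best <- -Inf
  dz2 <- (az - z)^2
  for (px in g) for (py in g) {
    if (px^2 + py^2 > lateral_bound^2) next
    cl <- min(sqrt((ax - px)^2 + (ay - py)^2 + dz2) - at$vdw)
    if (cl > best) best <- cl
  }
  max(0, min(best, lateral_bound))
}

# exhaustive atom-pair scan between two chains of a residue
brute_force_pair_min <- function(structure, resno, chain1, chain2) {
  at <- atomTable(structure)
  sel <- at$resno == resno &
    !(at$atom %in% c("N", "CA", "C", "O", "OXT", "CB"))
  a <- at[sel & at$chain == chain1, c("x", "y", "z")]
  b <- at[sel & at$chain == chain2, c("x", "y", "z")]
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
  best
}

# brute-force direction search minimizing the radial-spread objective
brute_force_axis_direction <- function(xyz, n_grid = 60) {
  centroid <- colMeans(xyz)
  best <- NULL; best_v <- Inf
  for (th in seq(0, pi, length.out = n_grid))
    for (ph in seq(0, 2 * pi, length.out = 2 * n_grid)) {
      u <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      rel <- sweep(xyz, 2, centroid)
      along <- rel %*% u
      v <- stats::var(sqrt(pmax(rowSums(rel^2) - along^2, 0)))
      if (v < best_v) { best_v <- v; best <- u }
    }
  if (best[3] < 0) best <- -best
  best
}
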