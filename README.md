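# gatekin

Single-channel gating kinetics and pore geometry of tetrameric cation
channels.

`gatekin` is an R package for electrophysiologists and structural biologists
studying how an intracellular gate controls ion permeation in TRPV-family
channels (the motivating system is TRPV5, whose lower gate is formed by a
ring of tryptophan side chains below a glycine hinge). It covers both sides
of that question:

* **Kinetics** — the channel is modelled as a three-state continuous-time
  Markov chain

  ```
  O  <=>  C2  <=>  C1
     k_oc    k_21
     k_co    k_12
  ```

  with an open state O, a pre-open closed state C2 and a long-lived closed
  state C1 (no direct O–C1 transition). The stationary open probability is

  ```
  Po = 1 / (1 + k_oc/k_co + k_oc*k_21 / (k_co*k_12))
  ```

  open dwell times are exponential with tau_O = 1/k_oc (the closing rate
  constant is k_oc), and closed sojourns — entered at C2 — follow the
  biexponential phase-type density of the closed sub-generator. The package
  simulates such channels exactly (Gillespie), renders realistic
  cell-attached sweeps (5.5 pA openings at −80 mV, Gaussian noise, 5 kHz
  low-pass, 100 µs sampling), idealizes noisy traces by the half-amplitude
  threshold with an imposed dead time, and recovers the four rates by
  maximum likelihood on left-truncated dwell distributions. Amplitude
  histograms are fitted with Gaussian mixtures; whole-cell voltage-step
  recordings are reduced to I–V curves, %I_max normalization,
  EGTA-sensitive currents and current densities.

* **Pore geometry** — for tetrameric structures (PDB input) the package
  computes HOLE-style pore radius profiles by inscribed-probe optimization,
  rotates gate side chains into symmetric rotamers (exact chi1/chi2
  dihedrals, rigid beyond-CB rotations), measures the facing distance
  between opposed side chains, converts it to an effective gate aperture
  `max(0, d − 2*r_eff)` (default r_eff = 1.15 Å maps a 3.1 Å tryptophan
  facing distance to a 0.8 Å aperture), and classifies permeation against
  the dehydrated Ca²⁺ diameter of 0.99 Å.

## Worked example

```r
library(gatekin)

wt <- wildtypeModel()            # (k_oc, k_co, k_21, k_12) = (100, 80, 30, 15) s^-1
analyticOpenProbability(wt)
#> [1] 0.2105263

## ten 10-s cell-attached sweeps at -80 mV, idealized and fitted
sweeps <- lapply(1:10, function(i)
  renderTrace(simulateStates(wt, 10, seed = i), wt, seed = 100 + i))
res <- analyzeSweeps(sweeps)
res$fit
#> Three-state gating fit (O <-> C2 <-> C1):
#>   k_oc = 97.79, k_co = 80.53, k_21 = 30.12, k_12 = 14.93 s^-1
#>   tau_O = 10.23 ms, tau_C2 = 9.037 ms, tau_C1 = 66.99 ms
#>   closing rate = 97.79 s^-1, implied Po = 0.2144, logLik = 12564.09
res$activity
#> ActivityStats: Po = 0.2126 (NPo = 0.2126, 1 channel(s))
#>   mean open amplitude 5.5 pA over 100 s

## synthetic tetramer gate: sweep the tryptophan rotamers
gate <- makeToyPore("tetramer_gate")
rotamerSweep(gate, 583)
#>    class chi1 chi2 facing_d_A aperture_A   verdict
#> 1 facing  -60   90   3.100000   0.800000   blocked
#> 2     up  180  -90   8.865444   6.565444 permeable
#> 3   down   60   90  12.040348   9.740348 permeable
```

The fitted rates land within a few percent of the generating values, the
empirical open probability matches the analytic 0.21, and the rotamer sweep
shows the permeation logic of the gate: with the side chains facing each
other the 0.8 Å aperture is below the 0.99 Å dehydrated Ca²⁺ diameter
(blocked); the up/down rotamers open a multi-Ångström passage.

A command-line wrapper for the common steps lives at
`inst/cli/gatekin.R` (subcommands `simulate`, `idealize`, `fit-dwells`,
`fit-model`, `iv`, `pore`, `rotamer`).

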