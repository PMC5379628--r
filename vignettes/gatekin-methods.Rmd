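---
title: "Models and methods behind gatekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gatekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatekin)
```

`gatekin` packages two analyses that are usually done with separate,
partly closed-source tools: maximum-likelihood inference of single-channel
gating kinetics from patch-clamp records, and pore-geometry characterization
of tetrameric channel structures. This vignette explains the models, the
defaults, and the numerical decisions, so that results can be interpreted —
and distrusted — for the right reasons.

## The gating model

The channel is a continuous-time Markov chain on three states,
O &harr; C2 &harr; C1: an open state `O`, a *pre-open* closed state `C2`
adjacent to it, and a deeper closed state `C1` reachable only through `C2`.
The generator is the chain matrix built by `buildThreeState(k_oc, k_co,
k_21, k_12)`; all rates are in s⁻¹ and must be strictly positive (a zero
rate would disconnect the chain). The linear topology is an assumption:
dwell-time data alone cannot distinguish all three-state wirings, and the
package deliberately does not fit an O&harr;C1 shortcut.

Consequences used throughout:

* stationary occupancy `pi` solves `pi Q = 0`; the open probability is
  `Po = 1/(1 + k_oc/k_co + k_oc k_21/(k_co k_12))`;
* open dwells are exponential, `tau_O = 1/k_oc`; the *closing rate
  constant* reported by the package is defined as this exit rate from the
  open state, `k_oc = 1/tau_O` (a per-channel kinetic quantity, not a
  macroscopic relaxation rate);
* closed sojourns always begin in `C2` (it is the only closed state
  connected to `O`), so their density is the phase-type density of the
  2×2 closed sub-generator — a mixture of exactly two exponentials. This is
  why dwell-time histograms of such a channel need one open and two closed
  exponential components, and why `analyticDwellMixture()` computes the
  closed time constants from the eigenvalues of
  `[[-(k_co+k_21), k_21], [k_12, -k_12]]`.

Rates scale trivially: multiplying all four rates by `c > 0` leaves `Po`
unchanged and divides every time constant by `c`. The unit convention is
seconds internally and milliseconds in printed summaries, which avoids unit
drift inside the likelihoods.

### Reference parameter sets

Two bundled models anchor the simulations. `wildtypeModel()` uses
`(k_oc, k_co, k_21, k_12) = (100, 80, 30, 15)` s⁻¹ with a 5.5 pA open
amplitude: `Po = 0.2105`, `tau_O = 10` ms, closed time constants
≈ 95 and 8.7 ms — millisecond-scale gating with an open probability around
21 %, typical of a healthy wild-type-like channel at −80 mV.
`hingeMutantModel()` uses `(200, 50, 70.8, 10)` s⁻¹ at 4.8 pA:
`Po = 0.030`, a channel that closes faster and spends long stretches in the
deep closed state, emulating a gating-impaired glycine-hinge mutant. These
values were fixed once, when the generator was designed, as realistic
parameterizations of those two regimes; every dwell constant comfortably
exceeds the 0.2 ms dead time, which is the regime in which truncation-only
missed-event handling is adequate (see below).

## The synthetic-data generator

`simulateStates()` is an exact Gillespie realization: exponential holding
times at each state's total exit rate, jumps by the embedded chain, the
final dwell truncated at the sweep end and flagged so that fits can censor
it. `renderTrace()` turns a path into a recording the way an acquisition
chain would: piecewise-constant current (`closed_level` plus one
`open_amplitude` per open channel), sampled at `dt` (default 100 µs),
plus white Gaussian noise (default sd 0.5 pA), then low-pass filtered.
`superposeChannels()` sums 1–3 independent channels over a shared noise
draw, producing the integer amplitude staircase seen in multi-channel
patches. Default sweeps are 10 s at −80 mV.

The filter is a Gaussian FIR whose time-domain sigma is chosen so the −3 dB
point matches the requested cutoff (`sigma_t = 0.1325/f_c`; 5 kHz default).
Hardware Bessel filters differ in phase response and stop-band rolloff; the
Gaussian is an explicit approximation chosen for determinism. What the
generator does **not** emulate: 1/f and seal-leak noise, baseline drift,
capacitive transients, conductance sublevels, or voltage-dependent rates.
Tests passing on this generator therefore demonstrate correctness of the
estimators under idealized recording physics, not robustness to every
artifact of real patches.

Every stochastic operation takes an integer `seed` and is bit-reproducible
given it; multi-channel and multi-sweep helpers derive per-component
sub-seeds deterministically (a fixed affine map modulo 2³¹−1).

## Idealization

`halfAmplitudeIdealize()` uses the standard half-amplitude threshold:
with baseline `b` (estimated as the mode of the all-points histogram via a
kernel density — valid when the channel is closed most of the time) and
open amplitude `A`, thresholds at `b + (k − 1/2)A` assign each sample an
integer open level. A hidden-Markov idealizer would be statistically more
efficient at low signal-to-noise, but the threshold method is deterministic,
transparent, and exactly testable against the generator path; it is the
package's choice, with model-based idealization left as an extension point.

The **dead time** (default `2*dt` = 0.2 ms at the 100 µs sampling) encodes
the resolution limit of the filtered recording. `imposeDeadTime()` merges
every event shorter than the dead time into the preceding resolved event
(a too-short leading stretch is absorbed forward), coalescing same-level
neighbours, in a single forward pass; the operation is idempotent. The same
rule applied to the latent simulation path (`idealizeFromPath()`) provides
the ground-truth event list against which threshold idealization is tested.

## Dwell-time likelihoods

All fits treat dwells as left-truncated at the dead time `d`: events shorter
than `d` are unobservable, so densities are renormalized on `[d, Inf)`.
This is the entire missed-event correction. It is transparent and exactly
testable, but it ignores the *concatenation* bias (a missed gap fuses two
dwells); when time constants approach the dead time the fitted rates are
increasingly biased. At the bundled parameter sets (shortest tau ≈ 8.7 ms
vs `d` = 0.2 ms) the full-pipeline bias is within a few percent; no exact
missed-event correction is attempted.

`fitExpMixture()` maximizes the truncated mixture likelihood over log time
constants and logit weights (quasi-Newton, deterministic multi-start from
quantile-spaced and geometrically spread initializations; `k = 1` is closed
form, `tau = mean − d`). Ties and degeneracies: identical durations raise a
warning for `k = 1` and an error for `k > 1`; numerically coincident
components are collapsed with a warning. `selectNComponents()` fits
`k = 1..k_max` and selects by BIC (default) or a forward likelihood-ratio
test at alpha = 0.05 with 2 df per extra component; candidates with fewer
than 10 dwells per component are not fitted, and a sample too small for any
`k > 1` is forced to `k = 1` with a warning.

`fitThreeState()` is the joint MLE. The open class is closed-form. The
closed class maximizes the phase-type likelihood over
`(k_co, k_21, k_12)` on the log scale, multi-started from a moment map of a
two-exponential mixture fit (`k_co = f(0)`, `k_12 = lambda_1 lambda_2 /
k_co`, `k_21 = lambda_1 + lambda_2 − k_co − k_12`) plus fixed spread
variants. Two numerical decisions matter here:

* the sub-generator eigenvalues are computed with the cancellation-free
  quadratic (`l2 = (tr − s)/2`, `l1 = det/l2`), and the truncation
  normalizer is integrated **from the same spectral coefficients** as the
  density, so the conditional density integrates to one even where the
  coefficients carry rounding error — otherwise the optimizer can invent
  spurious likelihood in extreme corners of parameter space;
* log-rates are confined to ±14 (about 8·10⁻⁷ to 1.2·10⁶ s⁻¹), a generous
  physical box that keeps the search away from those corners.

Closed dwells that are truly single-exponential leave the model
unidentifiable along a ridge; the fit then reports whatever point on the
ridge the optimizer reached and warns that the model has collapsed to two
states (detected as `k_21` at its lower bound or a vanishing implied
mixture weight). Edge dwells are censored by default in all fits. Pooled
fits across sweeps are the default workflow (`analyzeSweeps()`); per-record
fitting is available by calling the fitters on single records.

## Amplitude analysis

`fitAmplitudeGaussians()` is a univariate EM with deterministic
initialization: component means at equally spaced sample quantiles, a
common initial sd, uniform weights; at most 500 iterations, relative
log-likelihood tolerance 1e-8, non-convergence is an error. The component
nearest the baseline is tagged "closed" and the open amplitude is the open
mean minus the closed mean. The unit test cross-checks means and
log-likelihood against an independent mixture fitter (`mclust`) on the same
data.

## Whole-cell processing

Steady-state current is the mean over a window, by default the final 25 %
of each step (the protocol's steps are long relative to activation, and the
window is configurable because the choice is a convention). `buildIV()`
assembles one point per command voltage; `normalizePercentImax()` rescales
by the signed current at the −100 mV reference so inward-rectifying curves
read +100 at the reference; `egtaSensitive()` subtracts the nominally
divalent-free curve from the EGTA-containing one pointwise on a matching
voltage grid; `currentDensity()` divides by capacitance. Series-resistance
compensation, capacitance transients and junction potentials are hardware
concerns, out of scope. The synthetic step generator produces a
Boltzmann-weighted driving-force curve (inward-rectifying, reversal +30 mV)
— adequate for exercising the arithmetic, not a biophysical model of the
conductance.

## Pore geometry

`radiusProfile()` re-implements the inscribed-probe idea of HOLE: at each
axial position `z`, maximize over lateral offsets `p` (within
`lateral_bound`) the clearance `min_a(|p − x_a| − vdw_a)`. The lateral
optimum is located on a coarse grid (0.25 Å default) and refined by a local
simplex search; profiles agree with a brute-force 0.05 Å grid within
0.05 Å on the analytic fixtures. Choose `lateral_bound` smaller than the
radius of the surrounding wall: an over-generous bound lets the probe
escape through gaps between atoms, which is a property of the structure,
not a bug in the profiler — slabs with no atoms in reach are reported at
the bound with an `open` flag. Radii come from the Bondi van der Waals set
(configurable); hydrogens absent from the input are simply absent, with no
united-atom inflation. `minConstriction()` returns the profile minimum,
ties broken toward the smallest z.

The pore axis is the line through the selection centroid whose direction
minimizes the *variance* of the atoms' radial distances. For pore-lining
atoms — a roughly cylindrical shell — this is the natural objective; the
more common least-squares line (maximal-variance principal axis) would pick
an in-plane direction for a flat ring of atoms. A declared rotational
symmetry short-circuits the estimate.

`setSymmetricRotamer()` sets chi1 (N–CA–CB–CG) and chi2 (CA–CB–CG–CD1) by
rigid rotations of everything beyond CB about the CA–CB and CB–CG axes:
bond lengths and angles are exactly preserved, and a C4-symmetric input
stays C4-symmetric. No repacking or energy minimization is attempted — the
rotamers are geometric hypotheses, not refined conformations.
`facingDistance()` measures the minimum side-chain atom distance between
*opposing* subunits (chains whose side-chain centroids are anti-parallel
across the pore; the diagonal pairs of a tetramer), since the gate-forming
contact is across the pore, not between neighbours.

The **gate aperture** is `max(0, d − 2 r_eff)`. The default effective
surface radius `r_eff = 1.15 Å` is a calibration: it maps a 3.1 Å
tryptophan facing distance to a 0.8 Å aperture, the published mapping for
the facing-in gate conformation. It is smaller than a carbon vdW radius
because the relevant surfaces are the flat faces of the indole rings; no
claim of equivalence with any particular probe convention is made, and the
constant is configurable. Permeation is classified by comparing the
aperture with the dehydrated ion diameter (Ca²⁺: 0.99 Å), the boundary
counting as permeable.

### The tetramer-gate fixture

`makeToyPore("tetramer_gate")` builds a *synthetic* stand-in for a channel
gate: four idealized tryptophans (internal-coordinate template, planar
indole) in exact C4 symmetry with side chains facing the axis, surrounded
by a cylindrical wall of scaffold atoms so that the axis is the only
passage. The CA ring radius is solved at construction time so that the
facing rotamer's inter-subunit distance equals the requested
`facing_distance` (default 3.1 Å — the gate condition the package is
designed to analyze). The built-in rotamer table uses the three canonical
chi1 wells (−60°, 60°, 180°); the class labels (*facing*, *up*, *down*)
describe the side-chain orientation in this fixture's frame, and users
studying a real structure should pass their own (chi1, chi2) list. The
fixture is constructed geometry: it validates the measurement chain, not
any particular channel.

## Problem sizes and verification

The test suite regenerates everything it needs: Gillespie runs of ~10⁵
dwell events per rate set for the analytic–simulation comparisons
(occupancy within 3 Monte-Carlo standard errors, closed-dwell
Kolmogorov–Smirnov p > 0.01); twenty independent 30-sweep (10 s each)
wild-type-like experiments through the full
simulate–render–idealize–fit pipeline, requiring all four rates within
20 % and open probability within ±0.03 in at least 18 of 20 seeds;
component selection on 2·10⁴ dwells per class over 20 seeds; the
wild-type vs hinge-mutant open-probability ordering in 20 of 20 seeds;
and the geometry fixtures above. `scripts/acceptance.R` reruns the same
computations from scratch and writes the headline numbers as JSON. One test
requires the published TRPV1 coordinates (PDB 3j5p) to benchmark the lower
gate constriction; the file is not redistributable inside the package and
must be supplied locally, so that test fails cleanly when it is absent.

## Known limitations

* Truncation-only missed-event handling (no concatenation correction).
* The three-state topology is assumed, not selected from data.
* The threshold idealizer degrades below ~3 sd of amplitude-to-noise;
  no drift or sublevel handling.
* The Gaussian filter approximates, not reproduces, a Bessel chain.
* The pore profiler treats atoms as hard spheres on a fixed frame — no
  flexibility, electrostatics or solvation; rotamer sweeps are rigid.
* The interpretation of `r_eff` and hence the absolute aperture is a
  calibration, robust for comparisons between rotamers but not an
  independent measurement of passage size.
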