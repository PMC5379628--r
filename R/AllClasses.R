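#' @import methods
NULL

#' Continuous-time Markov gating model
#'
#' A labelled continuous-time Markov chain describing single-channel gating.
#' States are partitioned into an open and a closed conductance class; the
#' channel passes \code{openAmplitude} pA of current per simultaneously open
#' channel on top of \code{closedLevel}.
#'
#' @slot stateLabels character vector of state names (e.g. \code{c("O","C2","C1")}).
#' @slot stateClass character vector, one of \code{"open"}/\code{"closed"} per state.
#' @slot generator square rate matrix Q in s^-1; rows sum to zero, off-diagonal
#'   entries non-negative, and the chain must be irreducible.
#' @slot openAmplitude single-channel current increment in pA.
#' @slot closedLevel baseline current in pA (conventionally 0).
#'
#' @seealso [buildThreeState()], [stationaryDistribution()],
#'   [analyticOpenProbability()], [simulateStates()]
#' @export
setClass("RateModel",
  representation(
    stateLabels = "character",
    stateClass = "character",
    generator = "matrix",
    openAmplitude = "numeric",
    closedLevel = "numeric"
  ),
  prototype(closedLevel = 0)
)

setValidity("RateModel", function(object) {
  Q <- object@generator
  n <- length(object@stateLabels)
  msg <- character()
  if (nrow(Q) != n || ncol(Q) != n)
    msg <- c(msg, "generator must be square with one row per state label")
  if (length(object@stateClass) != n)
    msg <- c(msg, "stateClass must have one entry per state")
  if (!all(object@stateClass %in% c("open", "closed")))
    msg <- c(msg, "stateClass entries must be 'open' or 'closed'")
  if (length(msg) == 0) {
    offdiag <- Q; diag(offdiag) <- 0
    if (any(offdiag < 0))
      msg <- c(msg, "off-diagonal rates must be >= 0")
    if (any(abs(rowSums(Q)) > 1e-9))
      msg <- c(msg, "generator rows must sum to 0 (within 1e-9)")
    if (!any(object@stateClass == "open") || !any(object@stateClass == "closed"))
      msg <- c(msg, "model needs at least one open and one closed state")
    if (length(msg) == 0 && !.is_irreducible(Q))
      msg <- c(msg, "rate matrix is reducible: all states must communicate")
    if (length(object@openAmplitude) != 1 || !is.finite(object@openAmplitude))
      msg <- c(msg, "openAmplitude must be a single finite number")
  }
  if (length(msg)) msg else TRUE
})

# strong connectivity of the directed graph of positive rates
.is_irreducible <- function(Q) {
  n <- nrow(Q)
  A <- (Q > 0); diag(A) <- TRUE
  R <- A
  for (i in seq_len(ceiling(log2(max(n, 2))) + 1)) R <- (R %*% R) > 0
  all(R)
}

#' Latent gating path from exact stochastic simulation
#'
#' An alternating sequence of (state, dwell duration) pairs produced by
#' [simulateStates()]. The final dwell is truncated at the sweep end and
#' flagged so downstream fitting can censor it.
#'
#' @slot states integer state indices into the model's \code{stateLabels}.
#' @slot durations dwell durations in seconds (all > 0).
#' @slot startTime sweep start time in seconds.
#' @slot seed integer seed used for the realization.
#' @slot truncatedLast logical; TRUE when the last dwell was cut at sweep end.
#' @export
setClass("StateSequence",
  representation(
    states = "integer",
    durations = "numeric",
    startTime = "numeric",
    seed = "integer",
    truncatedLast = "logical"
  ),
  prototype(startTime = 0, truncatedLast = TRUE)
)

setValidity("StateSequence", function(object) {
  msg <- character()
  if (length(object@states) != length(object@durations))
    msg <- c(msg, "states and durations must have equal length")
  if (any(object@durations <= 0))
    msg <- c(msg, "all dwell durations must be > 0")
  if (length(object@states) > 1 &&
      any(diff(object@states) == 0))
    msg <- c(msg, "consecutive entries must be in different states")
  if (length(msg)) msg else TRUE
})

#' Uniformly sampled current record
#'
#' A patch-clamp current trace: current samples in pA at a fixed sampling
#' interval, plus acquisition metadata (holding potential, filter cutoff,
#' number of channels in the patch, seed).
#'
#' @slot dt sampling interval in seconds (100 us for single-channel work).
#' @slot samples current in pA.
#' @slot meta named list: \code{holding_mV}, \code{filter_Hz} (NA if unfiltered),
#'   \code{n_channels}, \code{seed}, optionally \code{noise_sd}.
#' @export
setClass("CurrentTrace",
  representation(dt = "numeric", samples = "numeric", meta = "list")
)

setValidity("CurrentTrace", function(object) {
  msg <- character()
  if (length(object@dt) != 1 || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number")
  if (any(!is.finite(object@samples)))
    msg <- c(msg, "all samples must be finite")
  nch <- object@meta$n_channels
  if (!is.null(nch) && nch < 1)
    msg <- c(msg, "meta$n_channels must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Exponential dwell-time mixture
#'
#' The distribution of dwell durations in one conductance class, as a mixture
#' of exponential components with time constants \code{tau} (seconds, strictly
#' decreasing) and non-negative \code{weights} summing to one.
#'
#' @slot conductanceClass "open" or "closed".
#' @slot tau time constants in seconds, strictly decreasing.
#' @slot weights component fractions summing to 1.
#' @export
setClass("DwellMixture",
  representation(conductanceClass = "character", tau = "numeric", weights = "numeric")
)

setValidity("DwellMixture", function(object) {
  msg <- character()
  if (!object@conductanceClass %in% c("open", "closed"))
    msg <- c(msg, "conductanceClass must be 'open' or 'closed'")
  if (any(object@tau <= 0)) msg <- c(msg, "time constants must be > 0")
  if (length(object@tau) > 1 && any(diff(object@tau) >= 0))
    msg <- c(msg, "time constants must be strictly decreasing")
  if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "weights must be >= 0 and sum to 1 (within 1e-9)")
  if (length(object@tau) != length(object@weights))
    msg <- c(msg, "tau and weights must have equal length")
  if (length(msg)) msg else TRUE
})

#' Fitted dwell-time mixture
#'
#' A [DwellMixture-class] estimated by maximum likelihood from observed dwell
#' durations left-truncated at the dead time.
#'
#' @slot nEvents number of dwells used in the fit.
#' @slot deadTime left-truncation point in seconds.
#' @slot logLik maximized log-likelihood.
#' @export
setClass("DwellMixtureFit",
  contains = "DwellMixture",
  representation(nEvents = "integer", deadTime = "numeric", logLik = "numeric")
)

setValidity("DwellMixtureFit", function(object) {
  if (object@nEvents < 2L * length(object@tau))
    "nEvents must be at least twice the number of components" else TRUE
})

#' All-points amplitude histogram
#'
#' @slot binEdges strictly increasing bin edges in pA.
#' @slot counts per-bin sample counts (>= 0).
#' @export
setClass("AmplitudeHistogram",
  representation(binEdges = "numeric", counts = "numeric")
)

setValidity("AmplitudeHistogram", function(object) {
  msg <- character()
  if (any(diff(object@binEdges) <= 0))
    msg <- c(msg, "bin edges must be strictly increasing")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (length(object@counts) != length(object@binEdges) - 1)
    msg <- c(msg, "counts must have length(binEdges) - 1")
  if (length(msg)) msg else TRUE
})

#' Gaussian mixture fit of an amplitude histogram
#'
#' Expectation-maximization fit of current sample amplitudes; the component
#' with mean nearest the baseline is tagged as the closed level, all others as
#' open levels.
#'
#' @slot means component means in pA.
#' @slot sds component standard deviations in pA (> 0).
#' @slot weights mixing fractions summing to 1.
#' @slot classMap character, "open"/"closed" per component (exactly one closed).
#' @slot logLik maximized log-likelihood.
#' @slot histogram the [AmplitudeHistogram-class] the fit summarizes.
#' @export
setClass("GaussianMixtureFit",
  representation(
    means = "numeric", sds = "numeric", weights = "numeric",
    classMap = "character", logLik = "numeric", histogram = "AmplitudeHistogram"
  )
)

setValidity("GaussianMixtureFit", function(object) {
  msg <- character()
  if (abs(sum(object@weights) - 1) > 1e-6) msg <- c(msg, "weights must sum to 1")
  if (any(object@sds <= 0)) msg <- c(msg, "sds must be > 0")
  if (sum(object@classMap == "closed") != 1)
    msg <- c(msg, "exactly one component must map to the closed baseline")
  if (length(msg)) msg else TRUE
})

#' Idealized single-channel record
#'
#' The event list produced by threshold idealization of a current trace:
#' alternating conductance levels (0 = all closed, k = k channels open) with
#' durations no shorter than the dead time.
#'
#' @slot events data.frame with columns \code{level} (integer open-channel
#'   count), \code{class} ("open"/"closed"), \code{start_s}, \code{duration_s},
#'   \code{mean_pA}.
#' @slot deadTime imposed resolution limit in seconds.
#' @slot meta acquisition metadata inherited from the source trace.
#' @export
setClass("IdealizedRecord",
  representation(events = "data.frame", deadTime = "numeric", meta = "list")
)

setValidity("IdealizedRecord", function(object) {
  ev <- object@events
  msg <- character()
  need <- c("level", "class", "start_s", "duration_s", "mean_pA")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  if (nrow(ev) > 1 && any(diff(ev$level) == 0))
    msg <- c(msg, "consecutive events must differ in level")
  if (object@deadTime > 0 && nrow(ev) > 1 &&
      any(ev$duration_s < object@deadTime - 1e-12))
    msg <- c(msg, "all event durations must be >= deadTime")
  if (length(msg)) msg else TRUE
})

#' Per-record channel activity statistics
#'
#' @slot Po open probability per channel (0..1).
#' @slot NPo time-averaged number of simultaneously open channels.
#' @slot nChannels channel count used for normalization.
#' @slot meanOpenAmplitude mean single-channel open amplitude in pA.
#' @slot duration record duration in seconds.
#' @export
setClass("ActivityStats",
  representation(
    Po = "numeric", NPo = "numeric", nChannels = "numeric",
    meanOpenAmplitude = "numeric", duration = "numeric"
  )
)

setValidity("ActivityStats", function(object) {
  msg <- character()
  if (object@Po < 0 || object@Po > 1) msg <- c(msg, "Po must lie in [0, 1]")
  if (abs(object@NPo - object@Po * object@nChannels) > 1e-9)
    msg <- c(msg, "NPo must equal Po * nChannels")
  if (length(msg)) msg else TRUE
})

#' Maximum-likelihood fit of the three-state gating model
#'
#' Joint fit of the O <-> C2 <-> C1 scheme to open and closed dwell times:
#' the four transition rates, the derived per-state time constants, the
#' closing rate constant (the exit rate from the open state, 1/tau_O), and
#' the open probability implied by the fitted rates.
#'
#' @slot rates named numeric: \code{k_oc}, \code{k_co}, \code{k_21}, \code{k_12} in s^-1.
#' @slot tau named numeric: \code{tau_O}, \code{tau_C2}, \code{tau_C1} in seconds.
#' @slot closingRate exit rate from the open state, s^-1 (= k_oc).
#' @slot Po open probability implied by the fitted rates.
#' @slot logLik maximized joint log-likelihood.
#' @slot convergence list with optimizer diagnostics (code, n starts, messages).
#' @export
setClass("ThreeStateFit",
  representation(
    rates = "numeric", tau = "numeric", closingRate = "numeric",
    Po = "numeric", logLik = "numeric", convergence = "list"
  )
)

setValidity("ThreeStateFit", function(object) {
  msg <- character()
  if (any(object@rates <= 0)) msg <- c(msg, "all rates must be > 0")
  if (abs(object@closingRate - object@rates[["k_oc"]]) > 1e-9)
    msg <- c(msg, "closingRate must equal k_oc")
  if (object@Po < 0 || object@Po > 1) msg <- c(msg, "derived Po must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Voltage-step protocol recording
#'
#' One whole-cell recording: a trace per command voltage, with the holding
#' potential and the bath solution tag (nominally divalent-free or
#' divalent-free with EGTA).
#'
#' @slot voltages command voltages in mV (unique).
#' @slot traces list of [CurrentTrace-class], one per voltage, sharing dt.
#' @slot holding_mV holding potential in mV.
#' @slot solution "nDVF" or "DVF".
#' @export
setClass("StepProtocolRecording",
  representation(
    voltages = "numeric", traces = "list",
    holding_mV = "numeric", solution = "character"
  )
)

setValidity("StepProtocolRecording", function(object) {
  msg <- character()
  if (anyDuplicated(object@voltages)) msg <- c(msg, "command voltages must be unique")
  if (length(object@traces) != length(object@voltages))
    msg <- c(msg, "one trace per voltage required")
  dts <- vapply(object@traces, function(tr) tr@dt, numeric(1))
  if (length(dts) && diff(range(dts)) > 1e-12)
    msg <- c(msg, "all traces must share the sampling interval")
  if (!object@solution %in% c("nDVF", "DVF"))
    msg <- c(msg, "solution must be 'nDVF' or 'DVF'")
  if (length(msg)) msg else TRUE
})

#' Current-voltage relationship
#'
#' @slot voltage command voltages in mV, strictly increasing.
#' @slot current current in pA, or percent of the reference current when
#'   \code{normalized}.
#' @slot normalized logical flag.
#' @slot referenceV reference voltage in mV used for normalization (NA if raw).
#' @export
setClass("IVCurve",
  representation(
    voltage = "numeric", current = "numeric",
    normalized = "logical", referenceV = "numeric"
  ),
  prototype(normalized = FALSE, referenceV = NA_real_)
)

setValidity("IVCurve", function(object) {
  msg <- character()
  if (any(diff(object@voltage) <= 0))
    msg <- c(msg, "voltages must be strictly increasing")
  if (length(object@voltage) != length(object@current))
    msg <- c(msg, "voltage and current must have equal length")
  if (isTRUE(object@normalized) && !is.na(object@referenceV)) {
    i <- match(object@referenceV, object@voltage)
    if (!is.na(i) && abs(object@current[i] - 100) > 1e-6)
      msg <- c(msg, "normalized curve must be 100 at the reference voltage")
  }
  if (length(msg)) msg else TRUE
})

#' Atomic structure of a (tetrameric) channel
#'
#' A flat atom table parsed from a PDB file (or built synthetically), with
#' van der Waals radii assigned per element from the Bondi table, plus an
#' optional declared rotational symmetry.
#'
#' @slot atoms data.frame with columns \code{serial}, \code{atom}, \code{resname},
#'   \code{resno}, \code{chain}, \code{x}, \code{y}, \code{z} (Angstrom),
#'   \code{element}, \code{vdw} (Angstrom).
#' @slot symmetry list with \code{order} (rotational order, e.g. 4) and
#'   \code{axis} (list of \code{point}, \code{direction}), or empty list.
#' @export
setClass("ChannelStructure",
  representation(atoms = "data.frame", symmetry = "list"),
  prototype(symmetry = list())
)

setValidity("ChannelStructure", function(object) {
  at <- object@atoms
  need <- c("serial", "atom", "resname", "resno", "chain",
            "x", "y", "z", "element", "vdw")
  if (!all(need %in% names(at)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(at) == 0) msg <- c(msg, "structure must contain at least one atom")
  if (any(!is.finite(c(at$x, at$y, at$z)))) msg <- c(msg, "coordinates must be finite")
  if (any(at$vdw <= 0)) msg <- c(msg, "vdW radii must be > 0")
  if (length(msg)) msg else TRUE
})

#' Pore radius profile along the conduction axis
#'
#' The radius of the largest probe sphere that fits at each axial position,
#' obtained by maximizing the clearance min_a(|p - x_a| - vdw_a) over lateral
#' probe positions (a HOLE-style inscribed-sphere profile).
#'
#' @slot z axial coordinates in Angstrom, strictly increasing.
#' @slot radius pore radii in Angstrom (>= 0).
#' @slot open logical per sample: TRUE where no atoms constrain the probe and
#'   the radius is the lateral search bound.
#' @slot axis list of \code{point} and \code{direction} defining the axis.
#' @export
setClass("PoreProfile",
  representation(z = "numeric", radius = "numeric", open = "logical", axis = "list")
)

setValidity("PoreProfile", function(object) {
  msg <- character()
  if (any(diff(object@z) <= 0)) msg <- c(msg, "z must be strictly increasing")
  if (any(object@radius < 0)) msg <- c(msg, "radii must be >= 0")
  if (length(object@z) != length(object@radius))
    msg <- c(msg, "z and radius must have equal length")
  if (length(msg)) msg else TRUE
})

#' Gate residue rotamer geometry
#'
#' The aperture left between opposed gate side chains in one symmetric rotamer
#' configuration, and the resulting permeation verdict for a dehydrated ion.
#'
#' @slot residue residue number of the gate (source-file numbering).
#' @slot chi1,chi2 side-chain dihedrals in degrees.
#' @slot facingDistance minimum inter-subunit side-chain distance d in Angstrom.
#' @slot aperture effective free diameter, max(0, d - 2 r_eff), Angstrom.
#' @slot verdict "permeable" or "blocked".
#' @export
setClass("GateGeometry",
  representation(
    residue = "numeric", chi1 = "numeric", chi2 = "numeric",
    facingDistance = "numeric", aperture = "numeric", verdict = "character"
  )
)

setValidity("GateGeometry", function(object) {
  msg <- character()
  if (object@aperture > object@facingDistance + 1e-9)
    msg <- c(msg, "aperture cannot exceed the facing distance")
  if (!object@verdict %in% c("permeable", "blocked"))
    msg <- c(msg, "verdict must be 'permeable' or 'blocked'")
  if (length(msg)) msg else TRUE
})
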