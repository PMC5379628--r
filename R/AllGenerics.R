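#' @include AllClasses.R
NULL

#' Accessors for gatekin objects
#'
#' Small accessor generics so user code never reaches into slots directly.
#'
#' @param object a gatekin S4 object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("generatorMatrix", function(object) standardGeneric("generatorMatrix"))
#' @rdname accessors
#' @export
setMethod("generatorMatrix", "RateModel", function(object) object@generator)

#' @rdname accessors
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setMethod("stateLabels", "RateModel", function(object) object@stateLabels)

#' @rdname accessors
#' @export
setGeneric("stateClasses", function(object) standardGeneric("stateClasses"))
#' @rdname accessors
#' @export
setMethod("stateClasses", "RateModel", function(object) object@stateClass)

#' @rdname accessors
#' @export
setGeneric("openAmplitude", function(object) standardGeneric("openAmplitude"))
#' @rdname accessors
#' @export
setMethod("openAmplitude", "RateModel", function(object) object@openAmplitude)
#' @rdname accessors
#' @export
setMethod("openAmplitude", "ActivityStats", function(object) object@meanOpenAmplitude)

#' @rdname accessors
#' @export
setGeneric("samplingInterval", function(object) standardGeneric("samplingInterval"))
#' @rdname accessors
#' @export
setMethod("samplingInterval", "CurrentTrace", function(object) object@dt)

#' @rdname accessors
#' @export
setGeneric("traceSamples", function(object) standardGeneric("traceSamples"))
#' @rdname accessors
#' @export
setMethod("traceSamples", "CurrentTrace", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("traceMeta", function(object) standardGeneric("traceMeta"))
#' @rdname accessors
#' @export
setMethod("traceMeta", "CurrentTrace", function(object) object@meta)

#' Sample times of a trace
#'
#' Sample midpoint times in seconds: sample i represents \code{(i - 1/2) * dt}.
#'
#' @param object a [CurrentTrace-class].
#' @return numeric vector of times in seconds.
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))
#' @rdname traceTimes
#' @export
setMethod("traceTimes", "CurrentTrace", function(object)
  (seq_along(object@samples) - 0.5) * object@dt)

#' @rdname accessors
#' @export
setGeneric("dwellEvents", function(object) standardGeneric("dwellEvents"))
#' @rdname accessors
#' @export
setMethod("dwellEvents", "IdealizedRecord", function(object) object@events)

#' @rdname accessors
#' @export
setGeneric("deadTime", function(object) standardGeneric("deadTime"))
#' @rdname accessors
#' @export
setMethod("deadTime", "IdealizedRecord", function(object) object@deadTime)
#' @rdname accessors
#' @export
setMethod("deadTime", "DwellMixtureFit", function(object) object@deadTime)

#' @rdname accessors
#' @export
setGeneric("timeConstants", function(object) standardGeneric("timeConstants"))
#' @rdname accessors
#' @export
setMethod("timeConstants", "DwellMixture", function(object) object@tau)
#' @rdname accessors
#' @export
setMethod("timeConstants", "ThreeStateFit", function(object) object@tau)

#' @rdname accessors
#' @export
setGeneric("mixtureWeights", function(object) standardGeneric("mixtureWeights"))
#' @rdname accessors
#' @export
setMethod("mixtureWeights", "DwellMixture", function(object) object@weights)
#' @rdname accessors
#' @export
setMethod("mixtureWeights", "GaussianMixtureFit", function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("fittedRates", function(object) standardGeneric("fittedRates"))
#' @rdname accessors
#' @export
setMethod("fittedRates", "ThreeStateFit", function(object) object@rates)

#' @rdname accessors
#' @export
setGeneric("closingRate", function(object) standardGeneric("closingRate"))
#' @rdname accessors
#' @export
setMethod("closingRate", "ThreeStateFit", function(object) object@closingRate)

#' @rdname accessors
#' @export
setGeneric("openProbability", function(object) standardGeneric("openProbability"))
#' @rdname accessors
#' @export
setMethod("openProbability", "ActivityStats", function(object) object@Po)
#' @rdname accessors
#' @export
setMethod("openProbability", "ThreeStateFit", function(object) object@Po)

#' @rdname accessors
#' @export
setGeneric("logLikelihood", function(object) standardGeneric("logLikelihood"))
#' @rdname accessors
#' @export
setMethod("logLikelihood", "DwellMixtureFit", function(object) object@logLik)
#' @rdname accessors
#' @export
setMethod("logLikelihood", "ThreeStateFit", function(object) object@logLik)
#' @rdname accessors
#' @export
setMethod("logLikelihood", "GaussianMixtureFit", function(object) object@logLik)

#' @rdname accessors
#' @export
setGeneric("atomTable", function(object) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setMethod("atomTable", "ChannelStructure", function(object) object@atoms)

#' @rdname accessors
#' @export
setGeneric("axialCoords", function(object) standardGeneric("axialCoords"))
#' @rdname accessors
#' @export
setMethod("axialCoords", "PoreProfile", function(object) object@z)

#' @rdname accessors
#' @export
setGeneric("poreRadii", function(object) standardGeneric("poreRadii"))
#' @rdname accessors
#' @export
setMethod("poreRadii", "PoreProfile", function(object) object@radius)

#' Coerce an IVCurve to a data.frame
#'
#' @param x an [IVCurve-class].
#' @param ... unused.
#' @return data.frame with \code{V_mV} and \code{I_pA} (or \code{pct_Imax}).
#' @export
setMethod("as.data.frame", "IVCurve", function(x, ...) {
  d <- data.frame(V_mV = x@voltage)
  d[[if (isTRUE(x@normalized)) "pct_Imax" else "I_pA"]] <- x@current
  d
})

setMethod("show", "RateModel", function(object) {
  cat(sprintf("RateModel with %d states: %s\n", length(object@stateLabels),
              paste(sprintf("%s(%s)", object@stateLabels,
                            substr(object@stateClass, 1, 1)), collapse = " ")))
  cat("Generator Q (s^-1):\n")
  Q <- object@generator
  dimnames(Q) <- list(object@stateLabels, object@stateLabels)
  print(signif(Q, 4))
  cat(sprintf("Open amplitude: %.3g pA (closed level %.3g pA)\n",
              object@openAmplitude, object@closedLevel))
})

setMethod("show", "CurrentTrace", function(object) {
  n <- length(object@samples)
  cat(sprintf("CurrentTrace: %d samples, dt = %.3g s (%.4g s total)\n",
              n, object@dt, n * object@dt))
  m <- object@meta
  cat(sprintf("  holding %s mV | filter %s Hz | %s channel(s)\n",
              format(m$holding_mV %||% NA), format(m$filter_Hz %||% NA),
              format(m$n_channels %||% 1)))
})

setMethod("show", "StateSequence", function(object) {
  cat(sprintf("StateSequence: %d dwells over %.4g s (seed %d%s)\n",
              length(object@states), sum(object@durations), object@seed,
              if (isTRUE(object@truncatedLast)) ", last dwell truncated" else ""))
})

setMethod("show", "DwellMixture", function(object) {
  cat(sprintf("%s-dwell exponential mixture (%d component%s):\n",
              object@conductanceClass, length(object@tau),
              if (length(object@tau) > 1) "s" else ""))
  for (i in seq_along(object@tau))
    cat(sprintf("  tau = %.4g ms, weight = %.3f\n",
                1000 * object@tau[i], object@weights[i]))
})

setMethod("show", "DwellMixtureFit", function(object) {
  callNextMethod()
  cat(sprintf("  n = %d dwells, dead time %.3g ms, logLik = %.2f\n",
              object@nEvents, 1000 * object@deadTime, object@logLik))
})

setMethod("show", "GaussianMixtureFit", function(object) {
  cat(sprintf("Gaussian amplitude mixture (%d components), logLik = %.2f\n",
              length(object@means), object@logLik))
  for (i in order(object@means))
    cat(sprintf("  %-6s mean = %7.3f pA, sd = %.3f pA, weight = %.3f\n",
                object@classMap[i], object@means[i], object@sds[i],
                object@weights[i]))
})

setMethod("show", "IdealizedRecord", function(object) {
  ev <- object@events
  cat(sprintf("IdealizedRecord: %d events over %.4g s (dead time %.3g ms)\n",
              nrow(ev), sum(ev$duration_s), 1000 * object@deadTime))
  cat(sprintf("  %d open / %d closed events, max level %d\n",
              sum(ev$class == "open"), sum(ev$class == "closed"),
              max(ev$level)))
})

setMethod("show", "ActivityStats", function(object) {
  cat(sprintf("ActivityStats: Po = %.4f (NPo = %.4f, %g channel(s))\n",
              object@Po, object@NPo, object@nChannels))
  cat(sprintf("  mean open amplitude %.3g pA over %.4g s\n",
              object@meanOpenAmplitude, object@duration))
})

setMethod("show", "ThreeStateFit", function(object) {
  cat("Three-state gating fit (O <-> C2 <-> C1):\n")
  r <- object@rates
  cat(sprintf("  k_oc = %.4g, k_co = %.4g, k_21 = %.4g, k_12 = %.4g s^-1\n",
              r[["k_oc"]], r[["k_co"]], r[["k_21"]], r[["k_12"]]))
  tau <- object@tau
  cat(sprintf("  tau_O = %.4g ms, tau_C2 = %.4g ms, tau_C1 = %.4g ms\n",
              1000 * tau[["tau_O"]], 1000 * tau[["tau_C2"]], 1000 * tau[["tau_C1"]]))
  cat(sprintf("  closing rate = %.4g s^-1, implied Po = %.4f, logLik = %.2f\n",
              object@closingRate, object@Po, object@logLik))
})

setMethod("show", "StepProtocolRecording", function(object) {
  cat(sprintf("StepProtocolRecording (%s): %d steps, %g..%g mV from %g mV holding\n",
              object@solution, length(object@voltages), min(object@voltages),
              max(object@voltages), object@holding_mV))
})

setMethod("show", "IVCurve", function(object) {
  cat(sprintf("IVCurve: %d points, %g..%g mV%s\n",
              length(object@voltage), min(object@voltage), max(object@voltage),
              if (isTRUE(object@normalized))
                sprintf(" (%%Imax, ref %g mV)", object@referenceV) else ""))
  print(utils::head(as.data.frame(object), 5))
})

setMethod("show", "ChannelStructure", function(object) {
  at <- object@atoms
  cat(sprintf("ChannelStructure: %d atoms, %d chain(s) [%s], %d residue(s)\n",
              nrow(at), length(unique(at$chain)),
              paste(unique(at$chain), collapse = ","),
              nrow(unique(at[, c("chain", "resno")]))))
  if (length(object@symmetry))
    cat(sprintf("  declared C%d symmetry\n", object@symmetry$order))
})

setMethod("show", "PoreProfile", function(object) {
  i <- which.min(object@radius)
  cat(sprintf("PoreProfile: %d samples, z in [%.2f, %.2f] A\n",
              length(object@z), min(object@z), max(object@z)))
  cat(sprintf("  minimum radius %.3f A at z = %.2f A\n",
              object@radius[i], object@z[i]))
})

setMethod("show", "GateGeometry", function(object) {
  cat(sprintf(
    "GateGeometry: residue %g, chi1 = %g, chi2 = %g deg\n  facing distance %.3g A, aperture %.3g A -> %s\n",
    object@residue, object@chi1, object@chi2,
    object@facingDistance, object@aperture, object@verdict))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
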