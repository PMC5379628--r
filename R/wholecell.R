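#' @include AllClasses.R
NULL

#' Mean current over a steady-state window
#'
#' @param trace a [CurrentTrace-class].
#' @param window numeric length-2, (t0, t1) in seconds within the trace;
#'   by default the final 25 percent of the step.
#' @return mean current in pA.
#' @export
measureStepCurrent <- function(trace, window = NULL) {
  stopifnot(is(trace, "CurrentTrace"))
  total <- length(trace@samples) * trace@dt
  if (is.null(window)) window <- c(0.75 * total, total)
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be (t0, t1) with t1 > t0", call. = FALSE)
  if (window[1] < 0 || window[2] > total + trace@dt / 2)
    stop("window must lie within the trace", call. = FALSE)
  t <- traceTimes(trace)
  sel <- t >= window[1] & t <= window[2]
  if (!any(sel)) stop("window contains no samples", call. = FALSE)
  mean(trace@samples[sel])
}

#' Build an I-V curve from a voltage-step recording
#'
#' One point per command voltage: the steady-state mean current of that step.
#'
#' @param recording a [StepProtocolRecording-class] with >= 2 steps.
#' @param window steady-state window passed to [measureStepCurrent()].
#' @return an [IVCurve-class] ordered by voltage.
#' @export
buildIV <- function(recording, window = NULL) {
  stopifnot(is(recording, "StepProtocolRecording"))
  if (length(recording@voltages) < 2)
    stop("need at least 2 voltage steps", call. = FALSE)
  I <- vapply(recording@traces, measureStepCurrent, numeric(1), window = window)
  ord <- order(recording@voltages)
  new("IVCurve", voltage = recording@voltages[ord], current = I[ord],
      normalized = FALSE, referenceV = NA_real_)
}

#' Normalize an I-V curve to percent of the reference current
#'
#' Each current is replaced by 100 * I(V) / I(V_ref); by convention the
#' reference is the -100 mV step, so the inward-rectifying curve reads 100 at
#' -100 mV. The signed ratio is used, so inward (negative) currents plot
#' positive against an inward reference.
#'
#' @param iv an [IVCurve-class].
#' @param V_ref reference voltage in mV, present in the curve (default -100).
#' @return normalized [IVCurve-class]; idempotent.
#' @export
normalizePercentImax <- function(iv, V_ref = -100) {
  stopifnot(is(iv, "IVCurve"))
  i <- match(V_ref, iv@voltage)
  if (is.na(i))
    stop(sprintf("reference voltage %g mV is not in the curve", V_ref), call. = FALSE)
  if (iv@current[i] == 0)
    stop("current at the reference voltage is zero", call. = FALSE)
  new("IVCurve", voltage = iv@voltage,
      current = 100 * iv@current / iv@current[i],
      normalized = TRUE, referenceV = V_ref)
}

#' EGTA-sensitive current
#'
#' Pointwise difference between the divalent-free (DVF, with EGTA) and the
#' nominally divalent-free (nDVF) I-V curves on the same voltage grid.
#'
#' @param iv_DVF,iv_nDVF [IVCurve-class] objects on matching voltage grids.
#' @return difference [IVCurve-class] (DVF - nDVF).
#' @export
egtaSensitive <- function(iv_DVF, iv_nDVF) {
  stopifnot(is(iv_DVF, "IVCurve"), is(iv_nDVF, "IVCurve"))
  if (length(iv_DVF@voltage) != length(iv_nDVF@voltage) ||
      any(abs(iv_DVF@voltage - iv_nDVF@voltage) > 1e-9))
    stop("voltage grids do not match", call. = FALSE)
  new("IVCurve", voltage = iv_DVF@voltage,
      current = iv_DVF@current - iv_nDVF@current,
      normalized = FALSE, referenceV = NA_real_)
}

#' Current density
#'
#' @param I current in pA.
#' @param capacitance cell capacitance in pF (> 0).
#' @return current density in pA/pF.
#' @export
currentDensity <- function(I, capacitance) {
  if (any(capacitance <= 0)) stop("capacitance must be > 0", call. = FALSE)
  I / capacitance
}

#' Synthetic whole-cell voltage-step recording
#'
#' Generates an inward-rectifying step recording of the kind seen in
#' divalent-free Na+ recordings: steady-state current follows a Boltzmann-
#' weighted driving force I(V) = g (V - E_rev) / (1 + exp((V - V_half) / s)),
#' rendered as constant steps plus Gaussian noise. Used as the synthetic test
#' bed for the I-V pipeline; it does not model capacitance transients or
#' series-resistance artifacts.
#'
#' @param voltages command voltages in mV (default -100 to +40 in 20 mV steps).
#' @param g conductance scale in pA/mV.
#' @param E_rev reversal potential in mV.
#' @param V_half,slope rectification midpoint and slope in mV.
#' @param duration step length in seconds.
#' @param dt sampling interval in seconds (200 us, the whole-cell setting).
#' @param noise_sd sample noise in pA.
#' @param solution "nDVF" or "DVF".
#' @param holding_mV holding potential in mV.
#' @param seed integer seed.
#' @return a [StepProtocolRecording-class].
#' @export
simulateStepRecording <- function(voltages = seq(-100, 40, by = 20),
                                  g = 10, E_rev = 30, V_half = -20, slope = 15,
                                  duration = 0.4, dt = 2e-4, noise_sd = 5,
                                  solution = c("DVF", "nDVF"),
                                  holding_mV = 20, seed = 1L) {
  solution <- match.arg(solution)
  seed <- as.integer(seed)
  n <- floor(duration / dt)
  traces <- lapply(seq_along(voltages), function(i) {
    V <- voltages[i]
    I <- g * (V - E_rev) / (1 + exp((V - V_half) / slope))
    x <- rep(I, n)
    if (noise_sd > 0)
      x <- x + withr::with_seed(.child_seed(seed, i), stats::rnorm(n, 0, noise_sd))
    new("CurrentTrace", dt = dt, samples = x,
        meta = list(holding_mV = holding_mV, filter_Hz = 3600,
                    n_channels = 1L, seed = seed, command_mV = V))
  })
  new("StepProtocolRecording", voltages = voltages, traces = traces,
      holding_mV = holding_mV, solution = solution)
}
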