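#' @include AllClasses.R
NULL

#' Build the linear three-state gating model O <-> C2 <-> C1
#'
#' Constructs the gating scheme with an open state O, a pre-open closed state
#' C2 adjacent to it, and a long-lived closed state C1 reached only through
#' C2. There is no direct O <-> C1 transition.
#'
#' @param k_oc closing rate O -> C2 in s^-1 (the closing rate constant).
#' @param k_co opening rate C2 -> O in s^-1.
#' @param k_21 rate C2 -> C1 in s^-1.
#' @param k_12 rate C1 -> C2 in s^-1.
#' @param open_amplitude single-channel current in pA added per open channel
#'   (default 5.5 pA, the wild-type amplitude at -80 mV).
#' @param closed_level baseline current in pA.
#' @return a [RateModel-class] with states O, C2, C1.
#' @examples
#' m <- buildThreeState(100, 50, 20, 10, 5.5)
#' generatorMatrix(m)
#' analyticOpenProbability(m)
#' @export
buildThreeState <- function(k_oc, k_co, k_21, k_12, open_amplitude = 5.5,
                            closed_level = 0) {
  rates <- c(k_oc = k_oc, k_co = k_co, k_21 = k_21, k_12 = k_12)
  for (nm in names(rates)) {
    r <- rates[[nm]]
    if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r <= 0)
      stop(sprintf("%s must be > 0 (got %s)", nm, format(r)), call. = FALSE)
  }
  if (!is.finite(open_amplitude))
    stop("open_amplitude must be finite", call. = FALSE)
  Q <- matrix(0, 3, 3)
  Q[1, 2] <- k_oc   # O  -> C2
  Q[2, 1] <- k_co   # C2 -> O
  Q[2, 3] <- k_21   # C2 -> C1
  Q[3, 2] <- k_12   # C1 -> C2
  diag(Q) <- -rowSums(Q)
  new("RateModel",
      stateLabels = c("O", "C2", "C1"),
      stateClass = c("open", "closed", "closed"),
      generator = Q,
      openAmplitude = open_amplitude,
      closedLevel = closed_level)
}

#' Stationary distribution of a gating model
#'
#' Solves pi Q = 0 with sum(pi) = 1 by linear algebra.
#'
#' @param model a [RateModel-class].
#' @return numeric occupancy vector named by state, all entries > 0.
#' @examples
#' stationaryDistribution(buildThreeState(100, 50, 20, 10))  # (1, 2, 4)/7
#' @export
stationaryDistribution <- function(model) {
  stopifnot(is(model, "RateModel"))
  Q <- model@generator
  n <- nrow(Q)
  # append the normalization row to t(Q) and solve the least-squares system
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_hat <- drop(qr.solve(A, b))
  if (any(pi_hat <= 0))
    stop("stationary distribution has non-positive entries; chain may be reducible",
         call. = FALSE)
  pi_hat <- pi_hat / sum(pi_hat)
  names(pi_hat) <- model@stateLabels
  pi_hat
}

#' Analytic open probability of a gating model
#'
#' Sum of the stationary occupancy over open-class states. For the linear
#' three-state chain this equals
#' \deqn{P_o = \frac{1}{1 + k_{oc}/k_{co} + k_{oc} k_{21} / (k_{co} k_{12})}.}
#'
#' @param model a [RateModel-class].
#' @return open probability in [0, 1].
#' @export
analyticOpenProbability <- function(model) {
  pi_hat <- stationaryDistribution(model)
  sum(pi_hat[model@stateClass == "open"])
}

#' Analytic dwell-time mixture of one conductance class
#'
#' Dwell durations in a conductance class follow a phase-type distribution
#' governed by the class sub-generator; its density is a mixture of
#' exponentials with rates equal to the eigenvalue magnitudes of the negated
#' sub-generator. The entry distribution into the class is the stationary
#' transition flux from the other class, so for the three-state chain closed
#' sojourns always start in the pre-open state C2 and the closed dwell
#' distribution is biexponential, while open dwells are single-exponential
#' with tau_O = 1/k_oc.
#'
#' @param model a [RateModel-class].
#' @param class "open" or "closed".
#' @return a [DwellMixture-class] with strictly decreasing time constants.
#' @examples
#' analyticDwellMixture(buildThreeState(100, 50, 20, 10), "closed")
#' @export
analyticDwellMixture <- function(model, class = c("open", "closed")) {
  class <- match.arg(class)
  stopifnot(is(model, "RateModel"))
  idx <- which(model@stateClass == class)
  if (length(idx) == 0)
    stop(sprintf("model has no states of class '%s'", class), call. = FALSE)
  other <- which(model@stateClass != class)
  Q <- model@generator
  Qcc <- Q[idx, idx, drop = FALSE]
  # entry distribution: stationary flux from the complementary class
  pi_hat <- stationaryDistribution(model)
  flux <- as.vector(pi_hat[other] %*% Q[other, idx, drop = FALSE])
  phi <- flux / sum(flux)
  # exit rate vector out of the class
  r <- -as.vector(Qcc %*% rep(1, length(idx)))
  eg <- eigen(Qcc)
  lambda <- Re(eg$values)            # real & negative for gating sub-generators
  V <- Re(eg$vectors)
  ci <- as.vector(phi %*% V) * as.vector(solve(V, r))
  tau <- -1 / lambda
  w <- ci * tau
  ord <- order(tau, decreasing = TRUE)
  tau <- tau[ord]; w <- w[ord]
  keep <- w > 1e-12                  # drop numerically void components
  tau <- tau[keep]; w <- w[keep]
  w <- w / sum(w)
  new("DwellMixture", conductanceClass = class, tau = tau, weights = w)
}

#' Density / distribution of an exponential dwell mixture
#'
#' @param mix a [DwellMixture-class].
#' @param t durations in seconds.
#' @return density (\code{dDwellMixture}) or CDF (\code{pDwellMixture}) at t.
#' @export
dDwellMixture <- function(mix, t) {
  drop(vapply(t, function(ti)
    sum(mix@weights / mix@tau * exp(-ti / mix@tau)), numeric(1)))
}

#' @rdname dDwellMixture
#' @export
pDwellMixture <- function(mix, t) {
  drop(vapply(t, function(ti)
    sum(mix@weights * (1 - exp(-ti / mix@tau))), numeric(1)))
}

#' Exact stochastic simulation of the gating path
#'
#' Gillespie realization of the continuous-time Markov chain: exponential
#' dwells at each state's total exit rate, jumps by the embedded chain. The
#' final dwell is truncated at the requested duration and flagged.
#'
#' @param model a [RateModel-class].
#' @param duration sweep length in seconds (> 0).
#' @param seed integer seed; the same (model, duration, seed) gives a
#'   bit-identical path.
#' @param start_state optional starting state index; by default drawn from the
#'   stationary distribution.
#' @return a [StateSequence-class].
#' @export
simulateStates <- function(model, duration, seed, start_state = NULL) {
  stopifnot(is(model, "RateModel"))
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  seed <- as.integer(seed)
  Q <- model@generator
  n <- nrow(Q)
  exit <- -diag(Q)
  P <- Q / exit; diag(P) <- 0       # embedded jump chain
  withr::with_seed(seed, {
    s0 <- if (is.null(start_state))
      sample.int(n, 1, prob = stationaryDistribution(model)) else as.integer(start_state)
    # grow in blocks: expected number of events plus slack
    block <- max(64L, ceiling(duration * sum(stationaryDistribution(model) * exit) * 1.25) + 32L)
    states <- integer(0); durs <- numeric(0)
    total <- 0; cur <- s0
    while (total < duration) {
      bs <- integer(block); bd <- numeric(block)
      for (i in seq_len(block)) {
        bs[i] <- cur
        bd[i] <- stats::rexp(1, exit[cur])
        cur <- sample.int(n, 1, prob = P[cur, ])
      }
      states <- c(states, bs); durs <- c(durs, bd)
      total <- total + sum(bd)
    }
    cum <- cumsum(durs)
    k <- which(cum >= duration)[1]
    states <- states[seq_len(k)]; durs <- durs[seq_len(k)]
    durs[k] <- duration - if (k > 1) cum[k - 1] else 0
    if (durs[k] <= 0) { states <- states[-k]; durs <- durs[-k] }
  })
  new("StateSequence", states = states, durations = durs,
      startTime = 0, seed = seed, truncatedLast = TRUE)
}

#' Open-level indicator sampled on a uniform grid
#'
#' @keywords internal
.sequence_levels <- function(seq, model, dt, n_samples) {
  t_mid <- (seq_len(n_samples) - 0.5) * dt
  ends <- cumsum(seq@durations)
  idx <- findInterval(t_mid, c(0, ends), rightmost.closed = TRUE)
  idx[idx > length(seq@states)] <- length(seq@states)
  as.integer(model@stateClass[seq@states[idx]] == "open")
}

#' Gaussian low-pass FIR kernel emulating the recording filter
#'
#' The time-domain sigma is chosen so the -3 dB point of the Gaussian
#' frequency response matches the cutoff: sigma_t = 0.1325 / f_c. This is an
#' approximation to the hardware Bessel filter used during acquisition.
#'
#' @keywords internal
.gaussian_kernel <- function(filter_cutoff, dt) {
  sigma <- 0.1325 / filter_cutoff / dt   # in samples
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k / sum(k)
}

.apply_filter <- function(x, filter_cutoff, dt) {
  if (is.null(filter_cutoff) || is.na(filter_cutoff)) return(x)
  if (filter_cutoff <= 0) stop("filter_cutoff must be > 0", call. = FALSE)
  k <- .gaussian_kernel(filter_cutoff, dt)
  half <- (length(k) - 1) / 2
  # replicate edges so the filtered trace has no NA border
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  out <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(out[(half + 1):(half + length(x))])
}

#' Render a gating path as a noisy, filtered current trace
#'
#' Converts a latent state path to a piecewise-constant current (closed level
#' plus one open amplitude per open channel), samples it at dt, adds white
#' Gaussian noise, and low-pass filters with a Gaussian FIR approximating the
#' acquisition filter.
#'
#' @param seq a [StateSequence-class].
#' @param model the [RateModel-class] that generated it.
#' @param dt sampling interval in seconds (default 100 us, the single-channel
#'   acquisition setting).
#' @param noise_sd white noise standard deviation in pA, added before filtering.
#' @param filter_cutoff low-pass cutoff in Hz (default 5 kHz); NA disables.
#' @param seed integer seed for the noise draw.
#' @param holding_mV holding potential recorded into the metadata.
#' @return a [CurrentTrace-class].
#' @export
renderTrace <- function(seq, model, dt = 1e-4, noise_sd = 0.5,
                        filter_cutoff = 5000, seed = seq@seed,
                        holding_mV = -80) {
  stopifnot(is(seq, "StateSequence"), is(model, "RateModel"))
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  n <- floor(sum(seq@durations) / dt + 1e-9)
  lev <- .sequence_levels(seq, model, dt, n)
  x <- model@closedLevel + model@openAmplitude * lev
  if (noise_sd > 0)
    x <- x + withr::with_seed(as.integer(seed), stats::rnorm(n, 0, noise_sd))
  x <- .apply_filter(x, filter_cutoff, dt)
  new("CurrentTrace", dt = dt, samples = x,
      meta = list(holding_mV = holding_mV,
                  filter_Hz = if (is.null(filter_cutoff)) NA_real_ else as.numeric(filter_cutoff),
                  n_channels = 1L, seed = as.integer(seed),
                  noise_sd = noise_sd))
}

#' Simulate a patch containing several independent channels
#'
#' Sums n independent single-channel gating paths into one trace sharing a
#' single noise draw; before noise the trace takes levels in
#' \{0, A, 2A, ..., nA\} above baseline.
#'
#' @param n number of channels in the patch (>= 1).
#' @param model a [RateModel-class].
#' @param duration sweep length in seconds.
#' @param dt sampling interval in seconds.
#' @param noise_sd white noise sd in pA.
#' @param filter_cutoff low-pass cutoff in Hz; NA disables.
#' @param seed integer master seed; per-channel paths and the noise use
#'   deterministic sub-seeds derived from it.
#' @param holding_mV holding potential in mV.
#' @return a [CurrentTrace-class] with \code{meta$n_channels = n}.
#' @export
superposeChannels <- function(n, model, duration, dt = 1e-4, noise_sd = 0.5,
                              filter_cutoff = 5000, seed = 1L,
                              holding_mV = -80) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  seed <- as.integer(seed)
  ns <- floor(duration / dt + 1e-9)
  lev <- integer(ns)
  for (i in seq_len(n)) {
    seq_i <- simulateStates(model, duration, seed = .child_seed(seed, i))
    lev <- lev + .sequence_levels(seq_i, model, dt, ns)
  }
  x <- model@closedLevel + model@openAmplitude * lev
  if (noise_sd > 0)
    x <- x + withr::with_seed(.child_seed(seed, 0L), stats::rnorm(ns, 0, noise_sd))
  x <- .apply_filter(x, filter_cutoff, dt)
  new("CurrentTrace", dt = dt, samples = x,
      meta = list(holding_mV = holding_mV,
                  filter_Hz = if (is.null(filter_cutoff)) NA_real_ else as.numeric(filter_cutoff),
                  n_channels = n, seed = seed, noise_sd = noise_sd))
}

# deterministic sub-seed derivation, kept within 32-bit integer range
.child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + 104729 * (i + 1)) %% 2147483647)
}

#' Open-time fraction of a latent path
#'
#' @param seq a [StateSequence-class].
#' @param model its [RateModel-class].
#' @return fraction of total time spent in open-class states.
#' @export
openTimeFraction <- function(seq, model) {
  open <- model@stateClass[seq@states] == "open"
  sum(seq@durations[open]) / sum(seq@durations)
}

#' Occupancy of each state along a latent path
#'
#' @param seq a [StateSequence-class].
#' @param model its [RateModel-class].
#' @return named time-fraction vector over states.
#' @export
stateOccupancy <- function(seq, model) {
  occ <- vapply(seq_along(model@stateLabels), function(s)
    sum(seq@durations[seq@states == s]), numeric(1))
  stats::setNames(occ / sum(occ), model@stateLabels)
}

#' Dwell durations of a latent path by conductance class
#'
#' Merges consecutive dwells of the same class (e.g. C2 -> C1 -> C2 counts as
#' one closed sojourn) and returns the class sojourn durations, optionally
#' dropping the truncated edge sojourns.
#'
#' @param seq a [StateSequence-class].
#' @param model its [RateModel-class].
#' @param class "open" or "closed".
#' @param censor_edges drop the first and last sojourn (default TRUE).
#' @return numeric durations in seconds.
#' @export
pathDwells <- function(seq, model, class = c("open", "closed"),
                       censor_edges = TRUE) {
  class <- match.arg(class)
  cls <- model@stateClass[seq@states]
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  durs <- vapply(seq_along(r$values), function(i)
    sum(seq@durations[starts[i]:ends[i]]), numeric(1))
  keep <- r$values == class
  if (censor_edges) {
    keep[1] <- FALSE
    keep[length(keep)] <- FALSE
  }
  durs[keep]
}

#' Default wild-type-like and hinge-mutant-like gating models
#'
#' Reference parameterizations of the three-state scheme used throughout the
#' package: a wild-type-like channel with open probability ~0.21 and 5.5 pA
#' amplitude, and a glycine-hinge-mutant-like channel with open probability
#' 0.03 and 4.8 pA amplitude. Time constants are in the millisecond range
#' typical of cell-attached recordings at -80 mV.
#'
#' @return a [RateModel-class].
#' @examples
#' analyticOpenProbability(wildtypeModel())   # ~0.21
#' analyticOpenProbability(hingeMutantModel())  # 0.03
#' @export
wildtypeModel <- function() buildThreeState(100, 80, 30, 15, open_amplitude = 5.5)

#' @rdname wildtypeModel
#' @export
hingeMutantModel <- function() buildThreeState(200, 50, 70.8, 10, open_amplitude = 4.8)
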