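#' @include AllClasses.R
NULL

#' Extract dwell durations of one conductance class
#'
#' @param record an [IdealizedRecord-class] (alternating events).
#' @param class "open" or "closed".
#' @param censor_edges drop the first and last event of the record (their
#'   durations are truncated by the sweep boundaries); default TRUE.
#' @return numeric durations in seconds.
#' @export
extractDwells <- function(record, class = c("open", "closed"),
                          censor_edges = TRUE) {
  class <- match.arg(class)
  stopifnot(is(record, "IdealizedRecord"))
  ev <- record@events
  if (nrow(ev) == 0) stop("record contains no events", call. = FALSE)
  keep <- ev$class == class
  if (censor_edges) {
    keep[1] <- FALSE
    keep[nrow(ev)] <- FALSE
  }
  ev$duration_s[keep]
}

# log-density and log-survival of a left-truncated exponential mixture
.mix_loglik <- function(t, tau, w, dead_time) {
  dens <- vapply(seq_along(tau), function(j)
    w[j] / tau[j] * exp(-t / tau[j]), numeric(length(t)))
  dens <- matrix(dens, nrow = length(t))
  f <- rowSums(dens)
  S <- sum(w * exp(-dead_time / tau))
  if (any(f <= 0) || S <= 0) return(-Inf)
  sum(log(f)) - length(t) * log(S)
}

.softmax <- function(eta) {
  e <- exp(c(eta, 0) - max(eta, 0))
  e / sum(e)
}

#' Fit a left-truncated exponential mixture to dwell times
#'
#' Maximum-likelihood fit of a k-component exponential mixture to dwell
#' durations, left-truncated at the dead time (the density is renormalized on
#' \[dead_time, Inf)), which is how unresolvable short events are accounted
#' for. For k = 1 the estimator is closed-form (tau = mean - dead_time); for
#' k >= 2 a quasi-Newton optimizer on log time constants and logit weights is
#' run from a deterministic set of starts.
#'
#' @param durations dwell times in seconds, all >= dead_time.
#' @param k number of exponential components (>= 1, and <= n/2).
#' @param dead_time left-truncation point in seconds (default 0).
#' @param class conductance class label stored in the result.
#' @return a [DwellMixtureFit-class] with time constants in decreasing order.
#' @export
fitExpMixture <- function(durations, k, dead_time = 0,
                          class = c("closed", "open")) {
  class <- match.arg(class)
  t <- as.numeric(durations)
  n <- length(t)
  if (!is.numeric(k) || k < 1) stop("k must be >= 1", call. = FALSE)
  k <- as.integer(k)
  if (k > n / 2)
    stop(sprintf("k = %d components cannot be fitted to %d dwells (need n >= 2k)",
                 k, n), call. = FALSE)
  if (any(t < dead_time - 1e-12))
    stop("all durations must be >= dead_time", call. = FALSE)
  if (stats::sd(t) == 0) {
    if (k > 1) stop("degenerate input: all dwell durations are equal", call. = FALSE)
    warning("all dwell durations are equal; tau estimate is degenerate")
  }
  if (k == 1) {
    tau <- mean(t) - dead_time
    if (tau <= 0) stop("mean duration does not exceed the dead time", call. = FALSE)
    ll <- .mix_loglik(t, tau, 1, dead_time)
    return(new("DwellMixtureFit", conductanceClass = class,
               tau = tau, weights = 1, nEvents = as.integer(n),
               deadTime = dead_time, logLik = ll))
  }
  # deterministic starts: quantile-split means plus spread variants
  m <- mean(t) - dead_time
  qs <- as.numeric(stats::quantile(t, probs = seq(0.15, 0.95, length.out = k)))
  starts <- list(
    pmax(qs - dead_time, m / 50),
    m * 4^(seq_len(k) - k / 2 - 0.5),
    m * 10^(seq_len(k) - (k + 1) / 2)
  )
  obj <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 50)) return(1e10)
    tau <- exp(par[seq_len(k)])
    w <- .softmax(par[(k + 1):(2 * k - 1)])
    v <- -.mix_loglik(t, tau, w, dead_time)
    if (!is.finite(v)) 1e10 else v
  }
  best <- NULL
  for (s in starts) {
    par0 <- c(log(s), rep(0, k - 1))
    fit <- tryCatch(
      stats::optim(par0, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || !is.finite(best$value))
    stop("exponential mixture fit did not converge from any start", call. = FALSE)
  tau <- exp(best$par[seq_len(k)])
  w <- .softmax(best$par[(k + 1):(2 * k - 1)])
  ord <- order(tau, decreasing = TRUE)
  tau <- tau[ord]; w <- w[ord]
  # collapse numerically identical components so the decreasing-tau invariant holds
  if (any(diff(tau) > -1e-10 * tau[-length(tau)])) {
    grp <- cumsum(c(TRUE, -diff(tau) > 1e-10 * tau[-length(tau)]))
    tau <- vapply(split(seq_along(tau), grp), function(i)
      sum(w[i] * tau[i]) / sum(w[i]), numeric(1))
    w <- vapply(split(w, grp), sum, numeric(1))
    warning("mixture components collapsed to a common time constant")
  }
  new("DwellMixtureFit", conductanceClass = class,
      tau = as.numeric(tau), weights = as.numeric(w / sum(w)),
      nEvents = as.integer(n), deadTime = dead_time,
      logLik = -best$value)
}

#' Choose the number of exponential dwell components
#'
#' Fits mixtures with k = 1..k_max components and selects among them by BIC
#' (default) or by a forward likelihood-ratio test at alpha = 0.05 (2 df per
#' extra component). With fewer than 10 dwells per candidate component the
#' candidate is not fitted; if that forces k = 1 a warning is raised.
#'
#' @param durations dwell times in seconds.
#' @param k_max largest component count to consider (>= 1).
#' @param criterion "bic" or "lrt".
#' @param dead_time left-truncation point in seconds.
#' @param class conductance class label.
#' @return list with \code{k} (chosen count), \code{fits} (one
#'   [DwellMixtureFit-class] per candidate), and \code{bic} values.
#' @export
selectNComponents <- function(durations, k_max, criterion = c("bic", "lrt"),
                              dead_time = 0, class = c("closed", "open")) {
  criterion <- match.arg(criterion)
  class <- match.arg(class)
  if (k_max < 1) stop("k_max must be >= 1", call. = FALSE)
  n <- length(durations)
  k_feasible <- max(1L, min(as.integer(k_max), floor(n / 10)))
  if (k_feasible < k_max)
    warning(sprintf("only %d dwells: restricting candidate components to k <= %d",
                    n, k_feasible))
  fits <- lapply(seq_len(k_feasible), function(k)
    tryCatch(fitExpMixture(durations, k, dead_time, class),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no mixture size could be fitted", call. = FALSE)
  ll <- vapply(fits, function(f) if (is.null(f)) -Inf else f@logLik, numeric(1))
  p <- 2 * seq_len(k_feasible) - 1
  bic <- -2 * ll + p * log(n)
  if (criterion == "bic") {
    k_hat <- which.min(bic)
  } else {
    k_hat <- 1L
    while (k_hat < k_feasible && ok[k_hat + 1] &&
           stats::pchisq(2 * (ll[k_hat + 1] - ll[k_hat]), df = 2,
                         lower.tail = FALSE) < 0.05) {
      k_hat <- k_hat + 1L
    }
  }
  list(k = as.integer(k_hat), fits = fits, bic = bic, logLik = ll)
}

#' Open probability and activity statistics of an idealized record
#'
#' NPo is the time-averaged number of simultaneously open channels,
#' sum(level_k * duration_k) / T; Po = NPo / n_channels.
#'
#' @param record an [IdealizedRecord-class].
#' @param n_channels number of channels in the patch; defaults to the largest
#'   observed open level.
#' @return an [ActivityStats-class].
#' @export
empiricalOpenProbability <- function(record, n_channels = NULL) {
  stopifnot(is(record, "IdealizedRecord"))
  ev <- record@events
  total <- sum(ev$duration_s)
  if (total <= 0) stop("record spans no time", call. = FALSE)
  max_lev <- max(ev$level)
  if (is.null(n_channels)) n_channels <- max(max_lev, 1L)
  if (max_lev > n_channels)
    stop(sprintf("observed level %d exceeds n_channels = %d", max_lev, n_channels),
         call. = FALSE)
  NPo <- sum(ev$level * ev$duration_s) / total
  open <- ev$level > 0
  amp <- if (any(open)) {
    baseline <- if (any(!open))
      sum(ev$mean_pA[!open] * ev$duration_s[!open]) / sum(ev$duration_s[!open]) else 0
    sum((ev$mean_pA[open] - baseline) / ev$level[open] * ev$duration_s[open]) /
      sum(ev$duration_s[open])
  } else NA_real_
  new("ActivityStats", Po = NPo / n_channels, NPo = NPo,
      nChannels = as.numeric(n_channels), meanOpenAmplitude = amp,
      duration = total)
}

# closed-sojourn log-likelihood for the three-state chain, entry at C2,
# left-truncated at the dead time; biexponential via the 2x2 sub-generator
.closed_loglik_3state <- function(t, k_co, k_21, k_12, dead_time) {
  a <- -(k_co + k_21)
  tr <- a - k_12
  det <- k_co * k_12
  disc <- tr * tr - 4 * det
  if (disc < 0) disc <- 0
  s <- sqrt(disc)
  l2 <- (tr - s) / 2          # fast eigenvalue, no cancellation for tr < 0
  l1 <- det / l2              # slow eigenvalue via the product (stable)
  if (l1 >= 0 || abs(l1 - l2) < 1e-12 * abs(l1)) return(-Inf)
  dl <- l1 - l2
  # f(t) = k_co * [exp(Qcc t)]_{C2,C2} = c1 exp(l1 t) + c2 exp(l2 t);
  # the truncation normalizer is integrated from the same coefficients so the
  # conditional density is exactly normalized even when the spectral
  # coefficients carry rounding error
  c1 <- k_co * (a - l2) / dl
  c2 <- -k_co * (a - l1) / dl
  f <- c1 * exp(l1 * t) + c2 * exp(l2 * t)
  S <- -c1 / l1 * exp(l1 * dead_time) - c2 / l2 * exp(l2 * dead_time)
  if (any(f <= 0) || S <= 0) return(-Inf)
  sum(log(f)) - length(t) * log(S)
}

#' Joint maximum-likelihood fit of the three-state gating model
#'
#' Fits the O <-> C2 <-> C1 scheme to idealized dwell times. Open dwells are
#' exponential with rate k_oc (left-truncated at the dead time, so
#' k_oc = 1 / (mean open dwell - dead_time) in closed form). Closed sojourns
#' start in the pre-open state C2 and follow the biexponential phase-type
#' density of the 2x2 closed sub-generator; (k_co, k_21, k_12) are estimated
#' by a quasi-Newton optimizer on log rates, started from moment-matched
#' two-exponential mixture fits plus deterministic perturbations.
#'
#' Missed events are handled by left truncation only; no exact missed-event
#' correction is applied, so rates whose time constants approach the dead
#' time are increasingly biased.
#'
#' @param open_dwells open durations in seconds (all >= dead_time).
#' @param closed_dwells closed durations in seconds (all >= dead_time).
#' @param dead_time resolution limit in seconds.
#' @param init optional named vector of starting rates
#'   (k_oc, k_co, k_21, k_12) in s^-1.
#' @param n_starts number of deterministic optimizer starts (default 5).
#' @return a [ThreeStateFit-class].
#' @export
fitThreeState <- function(open_dwells, closed_dwells, dead_time = 0,
                          init = NULL, n_starts = 5) {
  to <- as.numeric(open_dwells); tc <- as.numeric(closed_dwells)
  if (length(to) < 50 || length(tc) < 50)
    warning(sprintf("few dwells (open %d, closed %d); at least 50 per class recommended",
                    length(to), length(tc)))
  if (any(c(to, tc) < dead_time - 1e-12))
    stop("all dwells must be >= dead_time", call. = FALSE)
  # open state: closed-form truncated-exponential MLE
  tau_O <- mean(to) - dead_time
  if (tau_O <= 0) stop("mean open dwell does not exceed the dead time", call. = FALSE)
  k_oc <- 1 / tau_O
  ll_open <- length(to) * log(k_oc) - k_oc * sum(to - dead_time)

  # starts for the closed sub-model
  starts <- list()
  if (!is.null(init)) {
    starts[[1]] <- log(init[c("k_co", "k_21", "k_12")])
  } else {
    mm <- tryCatch(fitExpMixture(tc, 2, dead_time, "closed"), error = function(e) NULL)
    if (!is.null(mm) && length(mm@tau) == 2) {
      lam <- 1 / mm@tau
      k_co0 <- sum(mm@weights / mm@tau)          # f(0) = k_co
      k_120 <- lam[1] * lam[2] / k_co0
      k_210 <- sum(lam) - k_co0 - k_120
      if (all(c(k_co0, k_210, k_120) > 0))
        starts[[length(starts) + 1]] <- log(c(k_co0, k_210, k_120))
    }
    m1 <- 1 / (mean(tc) - dead_time)
    base <- c(m1 * 2, m1, m1 / 4)
    for (f in c(1, 0.3, 3, 0.1)[seq_len(max(1, n_starts - length(starts)))])
      starts[[length(starts) + 1]] <- log(base * f)
  }
  obj <- function(par) {
    # rates confined to a generous physical box (8e-7 .. 1.2e6 s^-1)
    if (any(!is.finite(par)) || any(abs(par) > 14)) return(1e10)
    r <- exp(par)
    v <- -.closed_loglik_3state(tc, r[1], r[2], r[3], dead_time)
    if (!is.finite(v)) 1e10 else v
  }
  best <- NULL
  msgs <- character()
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-10)),
      error = function(e) { msgs <<- c(msgs, conditionMessage(e)); NULL })
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop(paste(c("three-state fit failed from all starts", msgs), collapse = "; "),
         call. = FALSE)
  r <- exp(best$par)
  k_co <- r[1]; k_21 <- r[2]; k_12 <- r[3]
  rates <- c(k_oc = k_oc, k_co = k_co, k_21 = k_21, k_12 = k_12)
  # non-identifiability: the implied closed mixture degenerates to a single
  # exponential either when k_21 hits its lower bound or when one mixture
  # weight vanishes along the flat ridge
  mix_w <- tryCatch(mixtureWeights(analyticDwellMixture(
    buildThreeState(k_oc, k_co, k_21, k_12), "closed")), error = function(e) 1)
  if (k_21 < 1e-3 * k_co || length(mix_w) < 2 || min(mix_w) < 0.01)
    warning("closed dwells are effectively single-exponential (k_21 at its lower bound or vanishing mixture weight); the model collapses to two states")
  Po <- 1 / (1 + k_oc / k_co + k_oc * k_21 / (k_co * k_12))
  new("ThreeStateFit",
      rates = rates,
      tau = c(tau_O = 1 / k_oc, tau_C2 = 1 / (k_co + k_21), tau_C1 = 1 / k_12),
      closingRate = k_oc,
      Po = Po,
      logLik = ll_open - best$value,
      convergence = list(code = best$convergence, n_starts = length(starts),
                         n_open = length(to), n_closed = length(tc),
                         messages = msgs))
}

#' End-to-end kinetic analysis of rendered sweeps
#'
#' Convenience pipeline mirroring the experimental workflow: idealize each
#' sweep by the half-amplitude threshold, pool dwells across sweeps, fit the
#' three-state model, and summarize activity.
#'
#' @param traces list of [CurrentTrace-class] sweeps from one patch.
#' @param open_amplitude single-channel current step in pA; when missing it is
#'   estimated from a two-component Gaussian amplitude fit of the first sweep.
#' @param dead_time resolution limit in seconds (default 2 * dt).
#' @return list with \code{fit} ([ThreeStateFit-class]), \code{activity}
#'   (pooled [ActivityStats-class]), \code{records} (idealized sweeps), and
#'   \code{amplitude} (the open amplitude used, pA).
#' @export
analyzeSweeps <- function(traces, open_amplitude = NULL, dead_time = NULL) {
  stopifnot(length(traces) >= 1)
  dt <- traces[[1]]@dt
  if (is.null(dead_time)) dead_time <- 2 * dt
  if (is.null(open_amplitude)) {
    gm <- fitAmplitudeGaussians(traces[[1]], k = 2)
    open_amplitude <- fittedOpenAmplitude(gm)
  }
  records <- lapply(traces, function(tr)
    halfAmplitudeIdealize(tr, open_amplitude = open_amplitude,
                          dead_time = dead_time))
  open_d <- unlist(lapply(records, extractDwells, class = "open"))
  closed_d <- unlist(lapply(records, extractDwells, class = "closed"))
  fit <- fitThreeState(open_d, closed_d, dead_time = dead_time)
  # pooled activity: duration-weighted across sweeps
  stats_list <- lapply(records, empiricalOpenProbability, n_channels = 1)
  durs <- vapply(stats_list, function(s) s@duration, numeric(1))
  Po <- sum(vapply(stats_list, function(s) s@Po, numeric(1)) * durs) / sum(durs)
  amps <- vapply(stats_list, function(s) s@meanOpenAmplitude, numeric(1))
  amp <- stats::weighted.mean(amps, durs, na.rm = TRUE)
  activity <- new("ActivityStats", Po = Po, NPo = Po, nChannels = 1,
                  meanOpenAmplitude = amp, duration = sum(durs))
  list(fit = fit, activity = activity, records = records,
       amplitude = open_amplitude)
}
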