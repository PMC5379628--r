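#' @include AllClasses.R
NULL

#' Estimate the baseline (closed) current level
#'
#' The baseline is the mode of the all-points amplitude histogram, estimated
#' by a kernel density over the samples. For records with open probability
#' below 0.5 the dominant peak is the closed level.
#'
#' @param trace a [CurrentTrace-class] with at least 1000 samples.
#' @return baseline current in pA.
#' @export
estimateBaseline <- function(trace) {
  stopifnot(is(trace, "CurrentTrace"))
  x <- trace@samples
  if (length(x) < 1000)
    stop("baseline estimation needs at least 1000 samples", call. = FALSE)
  if (stats::sd(x) == 0) return(x[1])
  d <- stats::density(x, n = 2048)
  d$x[which.max(d$y)]
}

#' All-points amplitude histogram of a trace
#'
#' @param trace a [CurrentTrace-class].
#' @param binwidth bin width in pA; by default the Freedman-Diaconis choice.
#' @return an [AmplitudeHistogram-class].
#' @export
amplitudeHistogram <- function(trace, binwidth = NULL) {
  x <- trace@samples
  if (is.null(binwidth)) {
    binwidth <- 2 * stats::IQR(x) / length(x)^(1 / 3)
    if (binwidth <= 0) binwidth <- max(diff(range(x)) / 50, 1e-3)
  }
  edges <- seq(min(x) - binwidth, max(x) + binwidth, by = binwidth)
  if (edges[length(edges)] < max(x)) edges <- c(edges, edges[length(edges)] + binwidth)
  h <- graphics::hist(x, breaks = edges, plot = FALSE)
  new("AmplitudeHistogram", binEdges = h$breaks, counts = h$counts)
}

#' Fit Gaussian components to the amplitude distribution
#'
#' Expectation-maximization fit of a k-component univariate Gaussian mixture
#' to the sample amplitudes, reproducing the amplitude-histogram analysis of
#' single-channel records. Initialization is deterministic: component means at
#' equally spaced sample quantiles, common initial sd, uniform weights. The
#' component with mean nearest the baseline is tagged "closed"; the open
#' amplitude is the open-component mean minus the closed mean.
#'
#' @param trace a [CurrentTrace-class].
#' @param k number of components (>= 1); use 2 for a one-channel patch.
#' @param max_iter maximum EM iterations (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @return a [GaussianMixtureFit-class] carrying the amplitude histogram.
#' @export
fitAmplitudeGaussians <- function(trace, k, max_iter = 500, tol = 1e-8) {
  stopifnot(is(trace, "CurrentTrace"))
  if (!is.numeric(k) || k < 1) stop("k must be >= 1", call. = FALSE)
  k <- as.integer(k)
  x <- trace@samples
  n <- length(x)
  mu <- as.numeric(stats::quantile(x, probs = (seq_len(k)) / (k + 1), names = FALSE))
  sd0 <- stats::sd(x) / max(k, 2)
  if (sd0 == 0) sd0 <- 1e-6
  sig <- rep(sd0, k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sig[j]), numeric(n))
    dens <- matrix(dens, nrow = n)
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sig <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
    sig[sig < 1e-8] <- 1e-8
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE; break
    }
    ll_old <- ll
  }
  if (!converged && k > 1)
    stop(sprintf(
      "EM did not converge after %d iterations (last logLik %.6g, rel change %.3g)",
      max_iter, ll, abs(ll - ll_old) / abs(ll_old)), call. = FALSE)
  baseline <- estimateBaseline(trace)
  cls <- rep("open", k)
  cls[which.min(abs(mu - baseline))] <- "closed"
  new("GaussianMixtureFit",
      means = mu, sds = sig, weights = w, classMap = cls,
      logLik = ll, histogram = amplitudeHistogram(trace))
}

#' Open amplitude implied by a Gaussian mixture fit
#'
#' Difference between the open component nearest the baseline and the closed
#' component: the single-channel current step in pA.
#'
#' @param fit a [GaussianMixtureFit-class] with at least one open component.
#' @return open amplitude in pA.
#' @export
fittedOpenAmplitude <- function(fit) {
  stopifnot(is(fit, "GaussianMixtureFit"))
  closed <- fit@means[fit@classMap == "closed"]
  open <- fit@means[fit@classMap == "open"]
  if (length(open) == 0) stop("fit has no open component", call. = FALSE)
  open[which.min(abs(open - closed))] - closed
}

#' Half-amplitude threshold idealization
#'
#' Converts a current trace into an alternating event list by thresholding at
#' half the open amplitude above baseline; for a patch with n channels,
#' thresholds sit at (k - 1/2) * A for k = 1..n and each sample is assigned an
#' integer open-level count. Events shorter than the dead time are then merged
#' into their neighbours ([imposeDeadTime()]).
#'
#' @param trace a [CurrentTrace-class].
#' @param baseline closed current level in pA; estimated from the trace when
#'   missing.
#' @param open_amplitude single-channel current step in pA (non-zero).
#' @param dead_time resolution limit in seconds (default 2 * dt).
#' @param n_channels maximum open level; defaults to the trace metadata.
#' @return an [IdealizedRecord-class].
#' @export
halfAmplitudeIdealize <- function(trace, baseline = NULL, open_amplitude,
                                  dead_time = NULL, n_channels = NULL) {
  stopifnot(is(trace, "CurrentTrace"))
  if (open_amplitude == 0) stop("open_amplitude must be non-zero", call. = FALSE)
  if (is.null(baseline)) baseline <- estimateBaseline(trace)
  if (is.null(dead_time)) dead_time <- 2 * trace@dt
  if (dead_time < 0) stop("dead_time must be >= 0", call. = FALSE)
  if (is.null(n_channels)) n_channels <- trace@meta$n_channels %||% 1L
  x <- trace@samples
  lev <- floor((x - baseline) / open_amplitude + 0.5)
  lev <- pmin(pmax(lev, 0L), n_channels)
  r <- rle(as.integer(lev))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mean_pA <- vapply(seq_along(starts), function(i)
    mean(x[starts[i]:ends[i]]), numeric(1))
  ev <- data.frame(
    level = r$values,
    class = ifelse(r$values > 0, "open", "closed"),
    start_s = (starts - 1L) * trace@dt,
    duration_s = r$lengths * trace@dt,
    mean_pA = mean_pA,
    stringsAsFactors = FALSE
  )
  rec <- new("IdealizedRecord", events = ev, deadTime = 0, meta = trace@meta)
  imposeDeadTime(rec, dead_time)
}

#' Impose a dead time on an idealized record
#'
#' Events shorter than the dead time are unresolvable at the recording
#' bandwidth: each is merged into the preceding event (duration added, mean
#' amplitude duration-weighted), then same-level neighbours are coalesced.
#' A too-short first event is absorbed into the following one. The operation
#' is idempotent.
#'
#' @param record an [IdealizedRecord-class].
#' @param dead_time resolution limit in seconds (>= 0).
#' @return an [IdealizedRecord-class] whose events all last >= dead_time
#'   (unless only a single event remains).
#' @export
imposeDeadTime <- function(record, dead_time) {
  stopifnot(is(record, "IdealizedRecord"))
  if (dead_time < 0) stop("dead_time must be >= 0", call. = FALSE)
  ev <- .merge_dead_time(record@events, dead_time)
  rownames(ev) <- NULL
  new("IdealizedRecord", events = ev, deadTime = dead_time, meta = record@meta)
}

# single forward pass over the event vectors: events shorter than the dead
# time are absorbed into the preceding resolved event (a too-short leading
# stretch into the following one), same-level neighbours coalesce, and mean
# amplitudes are duration-weighted
.merge_dead_time <- function(ev, dead_time) {
  n <- nrow(ev)
  if (n == 0) return(ev)
  lev <- ev$level; dur <- ev$duration_s; start <- ev$start_s
  charge <- ev$mean_pA * ev$duration_s
  out_lev <- integer(n); out_dur <- numeric(n)
  out_start <- numeric(n); out_chg <- numeric(n)
  m <- 0L                       # committed output events
  pend_dur <- 0; pend_chg <- 0; pend_start <- NA_real_  # unresolved prefix
  eps <- 1e-12
  for (i in seq_len(n)) {
    d <- dur[i]; l <- lev[i]; ch <- charge[i]
    if (m == 0L) {
      if (d < dead_time - eps) {          # leading stretch too short
        if (is.na(pend_start)) pend_start <- start[i]
        pend_dur <- pend_dur + d; pend_chg <- pend_chg + ch
        next
      }
      m <- 1L
      out_lev[1] <- l
      out_start[1] <- if (is.na(pend_start)) start[i] else pend_start
      out_dur[1] <- d + pend_dur
      out_chg[1] <- ch + pend_chg
      next
    }
    if (d < dead_time - eps || l == out_lev[m]) {
      # absorb into the preceding event (keeps its level)
      out_dur[m] <- out_dur[m] + d
      out_chg[m] <- out_chg[m] + ch
    } else {
      m <- m + 1L
      out_lev[m] <- l; out_dur[m] <- d
      out_start[m] <- start[i]; out_chg[m] <- ch
    }
  }
  if (m == 0L) {                          # everything was sub-resolution
    m <- 1L
    out_lev[1] <- lev[n]; out_dur[1] <- pend_dur
    out_start[1] <- pend_start; out_chg[1] <- pend_chg
  }
  data.frame(
    level = out_lev[seq_len(m)],
    class = ifelse(out_lev[seq_len(m)] > 0, "open", "closed"),
    start_s = out_start[seq_len(m)],
    duration_s = out_dur[seq_len(m)],
    mean_pA = out_chg[seq_len(m)] / out_dur[seq_len(m)],
    stringsAsFactors = FALSE
  )
}

# merge runs of equal level, duration-weighting the mean amplitude
.coalesce_events <- function(ev) {
  if (nrow(ev) < 2) return(ev)
  grp <- cumsum(c(1L, diff(ev$level) != 0))
  if (max(grp) == nrow(ev)) return(ev)
  out <- do.call(rbind, lapply(split(ev, grp), function(g) {
    data.frame(level = g$level[1], class = g$class[1],
               start_s = g$start_s[1], duration_s = sum(g$duration_s),
               mean_pA = sum(g$mean_pA * g$duration_s) / sum(g$duration_s),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Idealized record of a latent gating path (ground truth)
#'
#' Produces the event list a perfect detector would report for a simulated
#' path: class sojourns of the latent path, with the dead time imposed. Used
#' as the oracle when validating threshold idealization.
#'
#' @param seq a [StateSequence-class].
#' @param model its [RateModel-class].
#' @param dead_time resolution limit in seconds.
#' @return an [IdealizedRecord-class].
#' @export
idealizeFromPath <- function(seq, model, dead_time = 0) {
  cls <- model@stateClass[seq@states]
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  durs <- vapply(seq_along(starts), function(i)
    sum(seq@durations[starts[i]:ends[i]]), numeric(1))
  start_s <- cumsum(c(0, durs[-length(durs)]))
  lev <- as.integer(r$values == "open")
  ev <- data.frame(
    level = lev, class = r$values, start_s = start_s, duration_s = durs,
    mean_pA = model@closedLevel + model@openAmplitude * lev,
    stringsAsFactors = FALSE
  )
  rec <- new("IdealizedRecord", events = ev, deadTime = 0,
             meta = list(n_channels = 1L, seed = seq@seed))
  imposeDeadTime(rec, dead_time)
}
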