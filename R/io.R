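#' @include AllClasses.R
NULL

#' Write / read a current trace as CSV with a JSON metadata sidecar
#'
#' The trace goes to a two-column CSV (\code{time_s,current_pA}); acquisition
#' metadata (dt, holding potential, filter cutoff, channel count, seed) goes
#' to \code{<name>.meta.json} next to it.
#'
#' @param trace a [CurrentTrace-class].
#' @param path CSV output path.
#' @return the path, invisibly.
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "CurrentTrace"))
  utils::write.csv(
    data.frame(time_s = traceTimes(trace), current_pA = trace@samples),
    path, row.names = FALSE)
  meta <- trace@meta
  meta$dt <- trace@dt
  jsonlite::write_json(meta, .meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.meta_path <- function(path) paste0(sub("\\.csv$", "", path), ".meta.json")

#' @rdname writeTrace
#' @param path CSV path written by [writeTrace()].
#' @export
readTrace <- function(path) {
  d <- utils::read.csv(path)
  mp <- .meta_path(path)
  meta <- if (file.exists(mp)) jsonlite::read_json(mp, simplifyVector = TRUE)
          else list()
  dt <- meta$dt %||% stats::median(diff(d$time_s))
  meta$dt <- NULL
  if (!is.null(meta$n_channels)) meta$n_channels <- as.integer(meta$n_channels)
  new("CurrentTrace", dt = dt, samples = d$current_pA, meta = as.list(meta))
}

#' Write / read a gating model as JSON
#'
#' @param model a [RateModel-class].
#' @param path JSON path.
#' @return the path, invisibly (write) or a [RateModel-class] (read).
#' @export
writeRateModel <- function(model, path) {
  stopifnot(is(model, "RateModel"))
  jsonlite::write_json(list(
    state_labels = model@stateLabels,
    state_class = model@stateClass,
    generator = model@generator,
    open_amplitude = model@openAmplitude,
    closed_level = model@closedLevel
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRateModel
#' @export
readRateModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("RateModel", stateLabels = j$state_labels, stateClass = j$state_class,
      generator = as.matrix(j$generator),
      openAmplitude = j$open_amplitude, closedLevel = j$closed_level %||% 0)
}

#' Write / read an idealized event list as CSV
#'
#' Columns: \code{class,level,start_s,duration_s,mean_pA}.
#'
#' @param record an [IdealizedRecord-class].
#' @param path CSV path.
#' @param dead_time dead time in seconds to record on read.
#' @return the path, invisibly (write) or an [IdealizedRecord-class] (read).
#' @export
writeEvents <- function(record, path) {
  stopifnot(is(record, "IdealizedRecord"))
  ev <- record@events[, c("class", "level", "start_s", "duration_s", "mean_pA")]
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path, dead_time = 0) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  new("IdealizedRecord",
      events = ev[, c("level", "class", "start_s", "duration_s", "mean_pA")],
      deadTime = dead_time, meta = list())
}

#' Write an I-V curve or pore profile as CSV
#'
#' @param x an [IVCurve-class] or [PoreProfile-class].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeIV <- function(x, path) {
  stopifnot(is(x, "IVCurve"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeIV
#' @export
writeProfile <- function(x, path) {
  stopifnot(is(x, "PoreProfile"))
  utils::write.csv(data.frame(z_A = x@z, radius_A = x@radius), path,
                   row.names = FALSE)
  invisible(path)
}
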