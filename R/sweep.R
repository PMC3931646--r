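#' @include AllClasses.R
NULL

#' Construct a Sweep
#'
#' @param time time base, ms
#' @param voltage command voltage, mV
#' @param current recorded current, pA
#' @param meta named list of condition metadata
#' @return a \linkS4class{Sweep}
#' @examples
#' Sweep(1:5, rep(-60, 5), rnorm(5), list(ligand = "cGMP"))
#' @export
Sweep <- function(time, voltage, current, meta = list()) {
  new("Sweep", time = as.numeric(time), voltage = as.numeric(voltage),
      current = as.numeric(current), meta = meta)
}

#' Construct a RecordingSet
#'
#' @param sweeps list of \linkS4class{Sweep} objects
#' @param meta shared metadata list
#' @return a \linkS4class{RecordingSet}
#' @export
RecordingSet <- function(sweeps = list(), meta = list()) {
  new("RecordingSet", sweeps = sweeps, meta = meta)
}

#' @describeIn Sweep sample times (ms)
#' @param x a Sweep
#' @export
sweepTime <- function(x) x@time

#' @describeIn Sweep command voltage (mV)
#' @export
sweepVoltage <- function(x) x@voltage

#' @describeIn Sweep current (pA)
#' @export
sweepCurrent <- function(x) x@current

#' @describeIn Sweep metadata list
#' @export
sweepMeta <- function(x) x@meta

#' @rdname RecordingSet
#' @param x a RecordingSet
#' @export
setMethod("length", "RecordingSet", function(x) length(x@sweeps))

#' @rdname RecordingSet
#' @param i sweep index
#' @export
setMethod("[[", "RecordingSet", function(x, i) x@sweeps[[i]])

#' Sweeps of a RecordingSet as a plain list
#' @param x a \linkS4class{RecordingSet}
#' @return list of \linkS4class{Sweep}
#' @export
sweepList <- function(x) x@sweeps

#' Select sweeps by metadata
#'
#' Filters the sweeps of a set on exact equality of metadata fields
#' (e.g. \code{concentration_uM = 0, voltage_mV = -60}).
#'
#' @param x a \linkS4class{RecordingSet}
#' @param ... named metadata values to match
#' @return a \linkS4class{RecordingSet} with the matching sweeps
#' @export
filterSweeps <- function(x, ...) {
  want <- list(...)
  keep <- vapply(x@sweeps, function(s) {
    all(vapply(names(want), function(k) {
      isTRUE(!is.null(s@meta[[k]]) && s@meta[[k]] == want[[k]])
    }, logical(1)))
  }, logical(1))
  RecordingSet(x@sweeps[keep], x@meta)
}

setMethod("show", "Sweep", function(object) {
  m <- object@meta
  lab <- if (length(m))
    paste(names(m), vapply(m, function(v) paste(format(v), collapse = ","),
                           character(1)),
          sep = "=", collapse = " ")
  else "(no metadata)"
  cat(sprintf("Sweep: %d samples, %.4g-%.4g ms, V in [%.4g, %.4g] mV\n  %s\n",
              length(object@time), min(object@time), max(object@time),
              min(object@voltage), max(object@voltage), lab))
})

setMethod("show", "RecordingSet", function(object) {
  cat(sprintf("RecordingSet of %d sweep(s)\n", length(object@sweeps)))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})
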