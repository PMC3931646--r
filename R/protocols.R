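#' @include AllClasses.R
NULL

#' Voltage-step protocol
#'
#' Defaults reproduce the characterization protocol: 300-ms pulses in
#' 10-mV steps between -80 and +80 mV.
#'
#' @param levels command voltages, mV
#' @param duration step duration, ms
#' @param sampleInterval sampling interval, ms
#' @return a \linkS4class{VoltageProtocol}
#' @examples
#' stepProtocol()
#' stepProtocol(levels = -60, duration = 300)
#' @export
stepProtocol <- function(levels = seq(-80, 80, by = 10),
                         duration = 300, sampleInterval = 1) {
  new("VoltageProtocol", kind = "step", levels = as.numeric(levels),
      duration = duration, vertices = numeric(), rate = NA_real_,
      sampleInterval = sampleInterval)
}

#' Voltage-ramp protocol
#'
#' Defaults reproduce the reversal-potential protocol: a ramp from
#' -20 mV to +20 mV and back to -20 mV.
#'
#' @param vertices ramp vertex voltages, mV
#' @param rate slew rate, mV/ms
#' @param sampleInterval sampling interval, ms
#' @return a \linkS4class{VoltageProtocol}
#' @examples
#' rampProtocol()
#' @export
rampProtocol <- function(vertices = c(-20, 20, -20),
                         rate = 0.16, sampleInterval = 1) {
  new("VoltageProtocol", kind = "ramp", levels = numeric(),
      duration = NA_real_, vertices = as.numeric(vertices), rate = rate,
      sampleInterval = sampleInterval)
}

#' Gaussian-noise and leak model
#'
#' @param sd baseline noise standard deviation, pA
#' @param leakConductance ohmic leak conductance, nS
#' @param leakReversal leak reversal potential, mV
#' @param seed RNG seed (NA leaves the RNG stream untouched)
#' @return a \linkS4class{NoiseModel}
#' @examples
#' noiseModel(sd = 2, seed = 1)
#' noiseModel()           # noiseless, leak-free
#' @export
noiseModel <- function(sd = 0, leakConductance = 0, leakReversal = 0,
                       seed = NA_integer_) {
  new("NoiseModel", sd = sd, leakConductance = leakConductance,
      leakReversal = leakReversal, seed = as.numeric(seed))
}

## time/voltage samples for one step level or a full ramp
.protocolTrace <- function(protocol, level = NULL) {
  dt <- protocol@sampleInterval
  if (protocol@kind == "step") {
    stopifnot(!is.null(level))
    tt <- seq(dt, protocol@duration, by = dt)
    list(time = tt, voltage = rep(level, length(tt)))
  } else {
    v <- protocol@vertices
    seg <- abs(diff(v)) / protocol@rate            # ms per segment
    tEnd <- cumsum(seg)
    tt <- seq(dt, sum(seg), by = dt)
    volt <- numeric(length(tt))
    t0 <- 0
    for (i in seq_along(seg)) {
      idx <- tt > t0 & tt <= tEnd[i] + 1e-12
      volt[idx] <- v[i] + (v[i + 1] - v[i]) * (tt[idx] - t0) / seg[i]
      t0 <- tEnd[i]
    }
    list(time = tt, voltage = volt)
  }
}

setMethod("show", "VoltageProtocol", function(object) {
  if (object@kind == "step")
    cat(sprintf("VoltageProtocol: %d step(s) of %g ms (%g to %g mV), dt = %g ms\n",
                length(object@levels), object@duration,
                min(object@levels), max(object@levels),
                object@sampleInterval))
  else
    cat(sprintf("VoltageProtocol: ramp %s mV at %g mV/ms, dt = %g ms\n",
                paste(object@vertices, collapse = " -> "), object@rate,
                object@sampleInterval))
})
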