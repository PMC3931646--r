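#' @include channelParams.R protocols.R sweep.R ghk.R
NULL

## Normalized open-channel I-V used by the simulator: the Na+/Ca2+ GHK
## current sum, times a multiplicative voltage-asymmetry factor exp(-bV)
## solved in closed form so that |I(-60)|/|I(+60)| equals the requested
## rectification ratio (rectification is an empirical observation, no
## mechanism is assumed). The factor is positive so the zero crossing
## stays at the GHK reversal potential exactly.
.unitaryIV <- function(params, pair, model = activityModel()) {
  r <- params@pCaOverPNa
  base <- function(V) ghkNetCurrent(V, pair, r, model)
  beta <- log(params@rectificationRatio * abs(base(60)) / abs(base(-60))) / 120
  ## scale so the slope conductance at 0 mV equals the unitary
  ## conductance (pS -> pA/mV is a factor 1e-3)
  slope0 <- (base(1e-3) - base(-1e-3)) / 2e-3
  scale <- params@unitaryConductance / 1000 / slope0
  function(V) scale * base(V) * exp(-beta * V)
}

.applyNoise <- function(current, voltage, noise) {
  leak <- noise@leakConductance * (voltage - noise@leakReversal)
  eps <- if (noise@sd > 0) stats::rnorm(length(current), 0, noise@sd) else 0
  current + leak + eps
}

#' Simulate a ligand dose-response recording set
#'
#' Generates one voltage-step sweep per (concentration, level)
#' combination plus a zero-ligand baseline sweep per level. The expected
#' steady-state channel current is
#' nChannels * openProbability(c) * unitaryIV(V); cAMP open probability
#' is scaled by the cAMP efficacy; an optional diltiazem condition
#' multiplies the open-channel current by (1 - blockFraction),
#' concentration-independent as the block is characterized at a single
#' blocker concentration. Leak and Gaussian noise are added per the
#' \linkS4class{NoiseModel}. No activation kinetics are modeled: each
#' step is at gating steady state throughout.
#'
#' @param params \linkS4class{ChannelParams} ground truth
#' @param protocol a step \linkS4class{VoltageProtocol}
#' @param ligand "cGMP" or "cAMP"
#' @param concentrations ligand concentrations, uM (all > 0)
#' @param noise a \linkS4class{NoiseModel}
#' @param blocker "none" or "diltiazem"
#' @param pair bath/electrode \linkS4class{SolutionPair}
#' @param model \linkS4class{ActivityModel} for the unitary I-V
#' @return a \linkS4class{RecordingSet}; sweep metadata carry ligand,
#'   concentration_uM, blocker, voltage_mV, temperature_K
#' @examples
#' rs <- simulateDoseResponse(presetChannelParams("cA3"),
#'                            stepProtocol(levels = -60),
#'                            concentrations = c(1, 3, 10, 30, 100))
#' length(rs)
#' @export
simulateDoseResponse <- function(params, protocol = stepProtocol(),
                                 ligand = c("cGMP", "cAMP"),
                                 concentrations,
                                 noise = noiseModel(),
                                 blocker = c("none", "diltiazem"),
                                 pair = standardSolutions(0),
                                 model = activityModel()) {
  ligand <- match.arg(ligand)
  blocker <- match.arg(blocker)
  stopifnot(is(params, "ChannelParams"), is(protocol, "VoltageProtocol"))
  if (protocol@kind != "step")
    stop("dose-response simulation requires a step protocol")
  if (!length(concentrations)) stop("empty concentration list")
  if (any(!is.finite(concentrations) | concentrations <= 0))
    stop("concentrations must be positive")
  if (is.finite(noise@seed)) set.seed(noise@seed)
  iUnit <- .unitaryIV(params, pair, model)
  k05 <- if (ligand == "cGMP") params@k05cGMP else params@k05cAMP
  nh <- if (ligand == "cGMP") params@nhcGMP else params@nhcAMP
  eff <- if (ligand == "cGMP") 1 else params@campEfficacy
  blockF <- if (blocker == "diltiazem") params@blockFractionDiltiazem else 0
  sweeps <- list()
  for (conc in c(0, sort(concentrations))) {
    po <- if (conc > 0) openProbability(conc, k05, nh, eff) else 0
    for (lev in protocol@levels) {
      tr <- .protocolTrace(protocol, lev)
      ich <- params@nChannels * po * iUnit(lev) * (1 - blockF)
      cur <- .applyNoise(rep(ich, length(tr$time)), tr$voltage, noise)
      sweeps[[length(sweeps) + 1]] <- Sweep(
        tr$time, tr$voltage, cur,
        list(ligand = if (conc > 0) ligand else "none",
             concentration_uM = conc, blocker = blocker,
             voltage_mV = lev, temperature_K = pair@temperature,
             net = FALSE))
    }
  }
  RecordingSet(sweeps, meta = list(params = params, ligand = ligand,
                                   blocker = blocker, seed = noise@seed))
}

#' Simulate a control/test voltage-ramp pair
#'
#' Generates one up-and-down ramp sweep in the Ca2+-free control
#' solutions and one in the test solutions (Ca2+ added on one side), at
#' a fixed activating cGMP concentration. The noiseless test recording
#' crosses zero channel current exactly at the reversal potential
#' returned by \code{\link{ghkReversal}} for the ground-truth
#' P_Ca/P_Na, which closes the loop with the downstream
#' \code{\link{estimateReversal}} + \code{\link{permeabilityRatioFromShift}}
#' analysis.
#'
#' @param params \linkS4class{ChannelParams}
#' @param ramp a ramp \linkS4class{VoltageProtocol} with ascending and
#'   descending limbs
#' @param control,test \linkS4class{SolutionPair}s (equal temperature)
#' @param noise a \linkS4class{NoiseModel}
#' @param conc activating cGMP concentration, uM
#' @param model \linkS4class{ActivityModel}
#' @return list with \linkS4class{Sweep} elements \code{control},
#'   \code{test}
#' @examples
#' pr <- simulateRampPair(presetChannelParams("cA3+hB3"),
#'                        control = standardSolutions(0),
#'                        test = standardSolutions(1))
#' @export
simulateRampPair <- function(params, ramp = rampProtocol(),
                             control = standardSolutions(0),
                             test = standardSolutions(1),
                             noise = noiseModel(), conc = 200,
                             model = activityModel()) {
  stopifnot(is(params, "ChannelParams"), is(ramp, "VoltageProtocol"))
  if (ramp@kind != "ramp") stop("a ramp protocol is required")
  if (length(ramp@vertices) < 3)
    stop("ramp must have ascending and descending limbs")
  if (abs(control@temperature - test@temperature) > 1e-9)
    stop("control and test solutions declare different temperatures")
  if (is.finite(noise@seed)) set.seed(noise@seed)
  po <- openProbability(conc, params@k05cGMP, params@nhcGMP)
  one <- function(pair, label) {
    iUnit <- .unitaryIV(params, pair, model)
    tr <- .protocolTrace(ramp)
    cur <- .applyNoise(params@nChannels * po * iUnit(tr$voltage),
                       tr$voltage, noise)
    Sweep(tr$time, tr$voltage, cur,
          list(ligand = "cGMP", concentration_uM = conc,
               solution = label, temperature_K = pair@temperature,
               net = FALSE))
  }
  list(control = one(control, "control"), test = one(test, "test"))
}

#' Simulate a minimal characterization set for one patch
#'
#' Four steady-state sweeps at one voltage: zero-ligand baseline,
#' saturating cGMP, saturating cAMP, and saturating cGMP plus
#' diltiazem. This is the raw material of the efficacy/block patch
#' classification.
#'
#' @param params \linkS4class{ChannelParams}
#' @param voltage step level, mV
#' @param noise a \linkS4class{NoiseModel}
#' @param satCGMP,satCAMP saturating concentrations, uM
#' @param duration step duration, ms
#' @return a \linkS4class{RecordingSet} of 4 sweeps
#' @seealso \code{\link{patchMetrics}}
#' @export
simulatePatchSet <- function(params, voltage = -60,
                             noise = noiseModel(),
                             satCGMP = 500, satCAMP = 10000,
                             duration = 300) {
  proto <- stepProtocol(levels = voltage, duration = duration)
  a <- simulateDoseResponse(params, proto, "cGMP", satCGMP, noise)
  b <- simulateDoseResponse(params, proto, "cAMP", satCAMP,
                            noiseModel(noise@sd, noise@leakConductance,
                                       noise@leakReversal))
  d <- simulateDoseResponse(params, proto, "cGMP", satCGMP,
                            noiseModel(noise@sd, noise@leakConductance,
                                       noise@leakReversal),
                            blocker = "diltiazem")
  RecordingSet(c(sweepList(a), sweepList(b)[-1], sweepList(d)[-1]),
               meta = list(params = params, seed = noise@seed))
}
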