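#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Electrophysiology containers
## ---------------------------------------------------------------------------

#' ChannelParams: ground-truth gating and permeation parameters
#'
#' Parameter bundle describing a (simulated) CNG channel population:
#' Hill activation constants for cGMP and cAMP, the cAMP efficacy
#' (fraction of the maximal cGMP-activated current reached at saturating
#' cAMP), the fraction of open-channel current blocked by L-cis-diltiazem,
#' the relative Ca2+/Na+ permeability, and the inward rectification ratio
#' |I(-60 mV)| / |I(+60 mV)|.
#'
#' @slot nChannels number of channels in the patch
#' @slot unitaryConductance single-channel conductance, pS
#' @slot k05cGMP,k05cAMP half-activating ligand concentration, uM
#' @slot nhcGMP,nhcAMP Hill coefficients (dimensionless)
#' @slot campEfficacy I_cAMP/I_cGMP at saturation, in [0, 1]
#' @slot blockFractionDiltiazem fraction of current blocked, in [0, 1]
#' @slot pCaOverPNa relative Ca2+/Na+ permeability, >= 0
#' @slot rectificationRatio |I(-60)|/|I(+60)|, > 0
#' @seealso \code{\link{ChannelParams}}, \code{\link{presetChannelParams}}
#' @export
setClass("ChannelParams", representation(
  nChannels = "numeric",
  unitaryConductance = "numeric",
  k05cGMP = "numeric",
  nhcGMP = "numeric",
  k05cAMP = "numeric",
  nhcAMP = "numeric",
  campEfficacy = "numeric",
  blockFractionDiltiazem = "numeric",
  pCaOverPNa = "numeric",
  rectificationRatio = "numeric"
))

setValidity("ChannelParams", function(object) {
  msg <- character()
  pos <- c(nChannels = object@nChannels,
           unitaryConductance = object@unitaryConductance,
           k05cGMP = object@k05cGMP, nhcGMP = object@nhcGMP,
           k05cAMP = object@k05cAMP, nhcAMP = object@nhcAMP,
           rectificationRatio = object@rectificationRatio)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    msg <- c(msg, paste0("strictly positive value required for: ",
                         paste(bad, collapse = ", ")))
  frac <- c(campEfficacy = object@campEfficacy,
            blockFractionDiltiazem = object@blockFractionDiltiazem)
  bad <- names(frac)[!is.finite(frac) | frac < 0 | frac > 1]
  if (length(bad))
    msg <- c(msg, paste0("fraction in [0, 1] required for: ",
                         paste(bad, collapse = ", ")))
  if (!is.finite(object@pCaOverPNa) || object@pCaOverPNa < 0)
    msg <- c(msg, "pCaOverPNa must be >= 0")
  if (length(msg)) msg else TRUE
})

#' VoltageProtocol: a step or ramp command-voltage protocol
#'
#' @slot kind "step" or "ramp"
#' @slot levels step command levels, mV (step protocols)
#' @slot duration step duration, ms
#' @slot vertices ramp vertex voltages, mV (ramp protocols)
#' @slot rate ramp slew rate, mV/ms
#' @slot sampleInterval sampling interval, ms
#' @seealso \code{\link{stepProtocol}}, \code{\link{rampProtocol}}
#' @export
setClass("VoltageProtocol", representation(
  kind = "character",
  levels = "numeric",
  duration = "numeric",
  vertices = "numeric",
  rate = "numeric",
  sampleInterval = "numeric"
))

setValidity("VoltageProtocol", function(object) {
  msg <- character()
  if (!object@kind %in% c("step", "ramp"))
    msg <- c(msg, "kind must be 'step' or 'ramp'")
  if (!is.finite(object@sampleInterval) || object@sampleInterval <= 0)
    msg <- c(msg, "sampleInterval must be positive")
  if (object@kind == "step") {
    if (!length(object@levels))
      msg <- c(msg, "step protocol needs at least one level")
    if (any(abs(object@levels) > 200))
      msg <- c(msg, "step levels must lie within +/- 200 mV")
    if (!is.finite(object@duration) || object@duration <= 0)
      msg <- c(msg, "step duration must be positive")
  } else {
    if (length(object@vertices) < 2)
      msg <- c(msg, "ramp protocol needs at least two vertices")
    if (any(abs(object@vertices) > 200))
      msg <- c(msg, "ramp vertices must lie within +/- 200 mV")
    if (!is.finite(object@rate) || object@rate <= 0)
      msg <- c(msg, "ramp rate must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' NoiseModel: recording baseline noise and leak
#'
#' Gaussian baseline noise plus an ohmic leak conductance. The leak is a
#' stand-in for the un-subtracted bath current; real recordings only
#' constrain it through the zero-ligand subtraction step.
#'
#' @slot sd baseline noise standard deviation, pA
#' @slot leakConductance leak conductance, nS
#' @slot leakReversal leak reversal potential, mV
#' @slot seed RNG seed (NA for no reseeding)
#' @seealso \code{\link{noiseModel}}
#' @export
setClass("NoiseModel", representation(
  sd = "numeric",
  leakConductance = "numeric",
  leakReversal = "numeric",
  seed = "numeric"
))

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (!is.finite(object@sd) || object@sd < 0)
    msg <- c(msg, "noise sd must be >= 0")
  if (!is.finite(object@leakConductance) || object@leakConductance < 0)
    msg <- c(msg, "leak conductance must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Sweep: one voltage-protocol trace
#'
#' @slot time time base, ms (strictly increasing)
#' @slot voltage command voltage, mV
#' @slot current recorded current, pA
#' @slot meta named list of condition metadata (ligand, concentration_uM,
#'   blocker, voltage_mV for step sweeps, solution IDs, temperature_K, ...)
#' @seealso \code{\link{Sweep}}
#' @export
setClass("Sweep", representation(
  time = "numeric",
  voltage = "numeric",
  current = "numeric",
  meta = "list"
))

setValidity("Sweep", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@voltage) != n || length(object@current) != n)
    msg <- c(msg, "time, voltage and current must have equal length")
  if (n > 1 && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' RecordingSet: a collection of sweeps from one patch
#'
#' @slot sweeps list of \linkS4class{Sweep} objects
#' @slot meta named list of shared metadata (ground-truth parameters for
#'   simulated sets, seed, protocol description)
#' @export
setClass("RecordingSet", representation(
  sweeps = "list",
  meta = "list"
))

setValidity("RecordingSet", function(object) {
  if (!all(vapply(object@sweeps, is, logical(1), class2 = "Sweep")))
    return("all elements of sweeps must be Sweep objects")
  TRUE
})

#' HillFit: least-squares fit of the Hill activation equation
#'
#' Model: I(c) = Imax * c^N / (c^N + K05^N).
#'
#' @slot imax fitted (or fixed) maximal current, pA
#' @slot k05 half-activating concentration, uM
#' @slot nh Hill coefficient
#' @slot se named standard errors (imax, k05, nh; NA where fixed)
#' @slot rss residual sum of squares
#' @slot converged logical convergence flag
#' @slot imaxFixed logical: was Imax constrained?
#' @slot data the fitted (concentration, current) table
#' @seealso \code{\link{fitHill}}
#' @export
setClass("HillFit", representation(
  imax = "numeric",
  k05 = "numeric",
  nh = "numeric",
  se = "numeric",
  rss = "numeric",
  converged = "logical",
  imaxFixed = "logical",
  data = "data.frame"
))

setValidity("HillFit", function(object) {
  msg <- character()
  if (!is.finite(object@k05) || object@k05 <= 0)
    msg <- c(msg, "k05 must be positive")
  if (!is.finite(object@nh) || object@nh <= 0)
    msg <- c(msg, "nh must be positive")
  if (!is.finite(object@imax))
    msg <- c(msg, "imax must be finite")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Solutions / permeability
## ---------------------------------------------------------------------------

#' IonSolution: an ionic composition
#'
#' @slot species species names (e.g. "Na", "Ca", "Cl")
#' @slot conc molar concentrations, mM
#' @slot valence signed ionic valences
#' @seealso \code{\link{IonSolution}}
#' @export
setClass("IonSolution", representation(
  species = "character",
  conc = "numeric",
  valence = "numeric"
))

setValidity("IonSolution", function(object) {
  msg <- character()
  n <- length(object@species)
  if (length(object@conc) != n || length(object@valence) != n)
    msg <- c(msg, "species, conc and valence must have equal length")
  if (any(!is.finite(object@conc) | object@conc < 0))
    msg <- c(msg, "concentrations must be >= 0")
  if (anyDuplicated(object@species))
    msg <- c(msg, "duplicated species")
  if (length(msg)) msg else TRUE
})

#' SolutionPair: intracellular and extracellular compositions
#'
#' In the inside-out patch configuration the bath faces the intracellular
#' side of the membrane and the electrode the extracellular side.
#'
#' @slot inner intracellular (bath) \linkS4class{IonSolution}
#' @slot outer extracellular (electrode) \linkS4class{IonSolution}
#' @slot temperature absolute temperature, K
#' @slot pH bath pH (recorded, not used in the GHK sum)
#' @seealso \code{\link{SolutionPair}}, \code{\link{standardSolutions}}
#' @export
setClass("SolutionPair", representation(
  inner = "IonSolution",
  outer = "IonSolution",
  temperature = "numeric",
  pH = "numeric"
))

setValidity("SolutionPair", function(object) {
  if (!is.finite(object@temperature) ||
      object@temperature < 273 || object@temperature > 320)
    return("temperature must lie in [273, 320] K")
  TRUE
})

#' ActivityModel: single-ion activity coefficients
#'
#' Either the Davies equation evaluated at the solution's ionic strength
#' (mode "davies") or a fixed per-species gamma table (mode "fixed").
#'
#' @slot mode "davies" or "fixed"
#' @slot gamma named activity coefficients (fixed mode), each in (0, 1]
#' @seealso \code{\link{activityModel}}, \code{\link{solutionActivities}}
#' @export
setClass("ActivityModel", representation(
  mode = "character",
  gamma = "numeric"
))

setValidity("ActivityModel", function(object) {
  msg <- character()
  if (!object@mode %in% c("davies", "fixed"))
    msg <- c(msg, "mode must be 'davies' or 'fixed'")
  if (object@mode == "fixed") {
    if (!length(object@gamma) || is.null(names(object@gamma)))
      msg <- c(msg, "fixed mode requires a named gamma table")
    if (any(!is.finite(object@gamma) | object@gamma <= 0 | object@gamma > 1))
      msg <- c(msg, "gamma values must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' PermeabilityResult: a GHK permeability-ratio inference
#'
#' @slot erevControl,erevTest reversal potentials, mV
#' @slot shift erevTest - erevControl, mV
#' @slot ratio inferred P_Ca/P_Na (>= 0)
#' @slot gamma named list of activity coefficients used (inner, outer sides)
#' @slot diagnostics solver diagnostics (bracket, iterations, residual)
#' @export
setClass("PermeabilityResult", representation(
  erevControl = "numeric",
  erevTest = "numeric",
  shift = "numeric",
  ratio = "numeric",
  gamma = "list",
  diagnostics = "list"
))

setValidity("PermeabilityResult", function(object) {
  msg <- character()
  if (!is.finite(object@ratio) || object@ratio < 0)
    msg <- c(msg, "ratio must be >= 0")
  if (is.finite(object@shift) &&
      abs(object@shift - (object@erevTest - object@erevControl)) > 1e-9)
    msg <- c(msg, "shift must equal erevTest - erevControl")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Structure containers
## ---------------------------------------------------------------------------

#' StructureEnsemble: a multi-frame coordinate set
#'
#' Thin container over a bio3d-style atom table and frame-by-3N coordinate
#' matrix, as read from (or written to) a multi-MODEL PDB file.
#'
#' @slot atoms data.frame with columns chain, resno, resid, elety
#' @slot xyz numeric matrix, one row per frame, columns x1,y1,z1,x2,...
#' @slot midplaneZ membrane midplane position, Angstrom (NA if undeclared)
#' @seealso \code{\link{generateBundleEnsemble}}, \code{\link{loadEnsemble}}
#' @export
setClass("StructureEnsemble", representation(
  atoms = "data.frame",
  xyz = "matrix",
  midplaneZ = "numeric"
))

setValidity("StructureEnsemble", function(object) {
  msg <- character()
  if (nrow(object@xyz) < 1)
    msg <- c(msg, "ensemble must contain at least one frame")
  if (ncol(object@xyz) != 3L * nrow(object@atoms))
    msg <- c(msg, "xyz must have 3 columns per atom")
  need <- c("chain", "resno", "resid", "elety")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must carry columns:",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' DistanceMap: time-averaged acidic-basic charge-atom distances
#'
#' One matrix per chain (pairing "within-chain") or a single matrix over
#' all sites (pairing "all"); rows are acidic sites (D/E), columns basic
#' sites (K/R), entries mean Euclidean distance in Angstrom over the
#' averaging window.
#'
#' @slot maps named list of distance matrices
#' @slot pairing "within-chain" or "all"
#' @slot frames integer indices of the frames averaged
#' @slot nFrames number of frames averaged
#' @slot sites the ChargedSite table used
#' @seealso \code{\link{meanDistanceMap}}
#' @export
setClass("DistanceMap", representation(
  maps = "list",
  pairing = "character",
  frames = "integer",
  nFrames = "integer",
  sites = "data.frame"
))

setValidity("DistanceMap", function(object) {
  msg <- character()
  if (!object@pairing %in% c("within-chain", "all"))
    msg <- c(msg, "pairing must be 'within-chain' or 'all'")
  if (any(vapply(object@maps, function(m) any(m < 0), logical(1))))
    msg <- c(msg, "distances must be >= 0")
  if (object@nFrames != length(object@frames))
    msg <- c(msg, "nFrames must equal length(frames)")
  if (length(msg)) msg else TRUE
})
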