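#' @include solutions.R constants.R
NULL

## GHK constant-field flux of one species, in normalized units
## (permeability set to 1, F^2/RT scale dropped; only zeros and ratios of
## these fluxes are ever used). u = z E / kT is the reduced voltage.
## flux = z * kT * q(u) * (aIn - aOut * exp(-u)),  q(u) = u / (1 - e^-u)
.ghkFlux <- function(E, z, aIn, aOut, kT) {
  u <- z * E / kT
  q <- ifelse(abs(u) < 1e-6, 1 + u / 2 + u^2 / 12, u / (1 - exp(-u)))
  z * kT * q * (aIn - aOut * exp(-u))
}

#' Net GHK current carried by Na+ and Ca2+ (normalized units)
#'
#' The constant-field current sum P_Na * i_Na(E) + P_Ca * i_Ca(E) with
#' P_Na = 1 and P_Ca = ratio, evaluated from single-ion activities.
#' Its zero is the reversal potential of the divalent-extended GHK
#' (Lewis) formulation. Cl-, buffers and chelators are treated as
#' impermeant (cation-selective channel).
#'
#' @param E membrane potential, mV (vectorized)
#' @param pair a \linkS4class{SolutionPair}
#' @param ratio P_Ca/P_Na, >= 0
#' @param model an \linkS4class{ActivityModel}
#' @return net current in normalized units (positive = outward)
#' @seealso \code{\link{ghkReversal}}
#' @export
ghkNetCurrent <- function(E, pair, ratio, model = activityModel()) {
  stopifnot(ratio >= 0)
  kT <- thermalVoltage(pair@temperature)
  aIn <- solutionActivities(pair@inner, model, pair@temperature)
  aOut <- solutionActivities(pair@outer, model, pair@temperature)
  get0 <- function(a, sp) if (sp %in% names(a)) unname(a[sp]) else 0
  if (get0(aIn, "Na") + get0(aOut, "Na") +
      get0(aIn, "Ca") + get0(aOut, "Ca") == 0)
    stop("no permeant species (Na, Ca) on either side")
  .ghkFlux(E, 1, get0(aIn, "Na"), get0(aOut, "Na"), kT) +
    ratio * .ghkFlux(E, 2, get0(aIn, "Ca"), get0(aOut, "Ca"), kT)
}

#' Reversal potential of the divalent-extended GHK equation
#'
#' Solves for the unique membrane potential at which the net Na+/Ca2+
#' constant-field current vanishes. The root satisfies the implicit
#' divalent-extended relation
#' E = (RT/F) ln[(aNa_o + 4 Po(E) r aCa_o) / (aNa_i + 4 Pi(E) r aCa_i)]
#' with side-specific divalent factors Po(E) = 1/(1 + exp(E F/RT)) and
#' Pi(E) = 1/(1 + exp(-E F/RT)). Note that the widely quoted variant
#' using a single factor P'(E) on both sides agrees with the exact
#' constant-field zero only to first order in the divalent term; this
#' implementation uses the exact zero, so the returned potential always
#' nulls \code{\link{ghkNetCurrent}} and matches the zero crossing of
#' the forward recording simulator.
#'
#' @param pair a \linkS4class{SolutionPair}
#' @param ratio P_Ca/P_Na
#' @param model an \linkS4class{ActivityModel}
#' @param bracket search interval, mV
#' @param tol absolute tolerance on E, mV
#' @return reversal potential, mV
#' @examples
#' ghkReversal(standardSolutions(0), ratio = 17.2)   # symmetric: 0 mV
#' ghkReversal(standardSolutions(1), ratio = 17.2)
#' @export
ghkReversal <- function(pair, ratio, model = activityModel(),
                        bracket = c(-150, 150), tol = 1e-9) {
  f <- function(E) ghkNetCurrent(E, pair, ratio, model)
  lo <- f(bracket[1]); hi <- f(bracket[2])
  if (lo == 0) return(bracket[1])
  if (hi == 0) return(bracket[2])
  if (sign(lo) == sign(hi))
    stop("no bracketing interval for the reversal potential in [",
         bracket[1], ", ", bracket[2], "] mV")
  stats::uniroot(f, bracket, tol = tol)$root
}

#' Invert a reversal-potential shift to P_Ca/P_Na
#'
#' Finds the permeability ratio r >= 0 at which the GHK reversal
#' potential of the test solutions minus that of the control solutions
#' equals the measured shift. The shift is strictly monotone in r for
#' single-sided Ca2+ addition, so the root is unique; it is found by
#' log-spaced bracket expansion and bisection. A shift of 0 returns
#' r = 0; a shift whose sign is inconsistent with the side of the Ca2+
#' addition is an error (no silent clamping to zero).
#'
#' @param deltaErev measured reversal-potential shift (test - control), mV
#' @param control Ca2+-free \linkS4class{SolutionPair}
#' @param test \linkS4class{SolutionPair} with Ca2+ added on one side
#' @param model an \linkS4class{ActivityModel}
#' @param rMax upper limit of the ratio search
#' @param tol relative tolerance on r
#' @return a \linkS4class{PermeabilityResult}
#' @examples
#' res <- permeabilityRatioFromShift(-4.02, standardSolutions(0),
#'                                   standardSolutions(1))
#' permeabilityRatio(res)
#' @export
permeabilityRatioFromShift <- function(deltaErev, control, test,
                                       model = activityModel(),
                                       rMax = 1e4, tol = 1e-9) {
  stopifnot(is.finite(deltaErev))
  if (abs(control@temperature - test@temperature) > 1e-9)
    stop("control and test solutions declare different temperatures")
  caCtrl <- c(control@inner@conc[control@inner@species == "Ca"],
              control@outer@conc[control@outer@species == "Ca"])
  if (any(caCtrl > 0))
    stop("control solutions must be Ca2+-free")
  shiftAt <- function(r)
    ghkReversal(test, r, model) - ghkReversal(control, r, model)
  ## shift at r = 0: zero for a symmetric activity table, but the Davies
  ## model gives the two sides slightly different gamma_Na (the Ca2+
  ## addition raises the inner ionic strength), so anchor there
  s0 <- shiftAt(0)
  if (deltaErev == s0) {
    eC <- ghkReversal(control, 0, model)
    return(new("PermeabilityResult",
               erevControl = eC, erevTest = eC + s0, shift = s0, ratio = 0,
               gamma = .gammaReport(control, test, model),
               diagnostics = list(iterations = 0L, bracket = c(0, 0))))
  }
  dir <- sign(shiftAt(1) - s0)   # direction of the shift as r grows
  if (sign(deltaErev - s0) != dir)
    stop("shift sign (", deltaErev, " mV) is inconsistent with the side ",
         "of the Ca2+ addition; refusing to clamp r to zero")
  ## expand r upward until the shift brackets the measurement
  upper <- 1
  while (abs(shiftAt(upper) - s0) < abs(deltaErev - s0) && upper < rMax)
    upper <- upper * 10
  if (abs(shiftAt(upper) - s0) < abs(deltaErev - s0))
    stop("measured shift exceeds the model shift at r = ", rMax)
  g <- function(r) shiftAt(r) - deltaErev
  sol <- stats::uniroot(g, c(0, upper), tol = tol * max(1, upper / 10))
  r <- sol$root
  eT <- ghkReversal(test, r, model)
  eC <- ghkReversal(control, r, model)
  new("PermeabilityResult",
      erevControl = eC, erevTest = eT, shift = eT - eC, ratio = r,
      gamma = .gammaReport(control, test, model),
      diagnostics = list(iterations = sol$iter, bracket = c(0, upper),
                         residual = g(r)))
}

.gammaReport <- function(control, test, model) {
  act <- function(sol, TK) {
    a <- solutionActivities(sol, model, TK)
    g <- a / (sol@conc / 1000)
    g[sol@conc == 0] <- NA_real_
    g
  }
  list(testInner = act(test@inner, test@temperature),
       testOuter = act(test@outer, test@temperature),
       controlInner = act(control@inner, control@temperature))
}

#' @describeIn permeabilityRatioFromShift extract the inferred P_Ca/P_Na
#' @param x a \linkS4class{PermeabilityResult}
#' @export
permeabilityRatio <- function(x) x@ratio

#' @describeIn permeabilityRatioFromShift extract the E_rev shift (mV)
#' @export
reversalShift <- function(x) x@shift

#' Calibrate a fixed activity table on measured shift/ratio pairs
#'
#' The single-ion activity coefficients actually entering a published
#' GHK inversion are rarely printed, and the inferred ratio is roughly
#' proportional to 1/gamma_Ca. This routine keeps gamma_Na and gamma_Cl
#' at their Davies values and solves, by least squares on log r, for the
#' single gamma_Ca under which the package's own inversion best
#' reproduces a set of reference (shift, ratio) pairs. The result is a
#' fixed-mode \linkS4class{ActivityModel} to be passed to
#' \code{\link{permeabilityRatioFromShift}}.
#'
#' @param shifts measured reversal-potential shifts, mV
#' @param ratios the P_Ca/P_Na values to reproduce
#' @param control,test the solution pairs the shifts were measured in
#' @param interval search interval for gamma_Ca
#' @return a fixed-mode \linkS4class{ActivityModel} with attribute
#'   \code{"objective"} (residual sum of squares in log r)
#' @examples
#' ctrl <- standardSolutions(0); test <- standardSolutions(1)
#' cal <- calibrateGammaCa(c(-0.47, -4.02), c(1.5, 17.2), ctrl, test)
#' @export
calibrateGammaCa <- function(shifts, ratios, control, test,
                             interval = c(0.02, 1)) {
  stopifnot(length(shifts) == length(ratios), all(ratios > 0))
  I <- ionicStrength(test@inner)
  gNa <- daviesGamma(1, I, test@temperature)
  makeModel <- function(gCa)
    activityModel("fixed", c(Na = gNa, Ca = gCa, Cl = gNa))
  obj <- function(logGCa) {
    m <- makeModel(exp(logGCa))
    pred <- vapply(shifts, function(dE)
      permeabilityRatio(permeabilityRatioFromShift(dE, control, test, m)),
      numeric(1))
    sum((log(pred) - log(ratios))^2)
  }
  opt <- stats::optimize(obj, log(interval), tol = 1e-10)
  out <- makeModel(exp(opt$minimum))
  attr(out, "objective") <- opt$objective
  out
}

setMethod("show", "PermeabilityResult", function(object) {
  cat(sprintf(
    "PermeabilityResult: PCa/PNa = %.4g (Erev %0.4g -> %0.4g mV, shift %0.4g mV)\n",
    object@ratio, object@erevControl, object@erevTest, object@shift))
})
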