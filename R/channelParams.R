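#' @include AllClasses.R
NULL

#' Construct a ChannelParams object
#'
#' @param nChannels number of channels in the patch
#' @param unitaryConductance single-channel conductance, pS
#' @param k05cGMP,nhcGMP Hill parameters for cGMP activation (uM, -)
#' @param k05cAMP,nhcAMP Hill parameters for cAMP activation (uM, -)
#' @param campEfficacy saturating-cAMP / saturating-cGMP current ratio
#' @param blockFractionDiltiazem fraction of open-channel current blocked
#'   by 25 uM L-cis-diltiazem
#' @param pCaOverPNa relative Ca2+/Na+ permeability
#' @param rectificationRatio |I(-60 mV)| / |I(+60 mV)|
#' @return a \linkS4class{ChannelParams} object
#' @examples
#' ChannelParams(k05cGMP = 10.3, nhcGMP = 2.4, campEfficacy = 0.19)
#' @export
ChannelParams <- function(nChannels = 300,
                          unitaryConductance = 25,
                          k05cGMP = 10.3, nhcGMP = 2.40,
                          k05cAMP = 1665, nhcAMP = 2.06,
                          campEfficacy = 0.19,
                          blockFractionDiltiazem = 0.21,
                          pCaOverPNa = 1.5,
                          rectificationRatio = 1.6) {
  new("ChannelParams",
      nChannels = nChannels, unitaryConductance = unitaryConductance,
      k05cGMP = k05cGMP, nhcGMP = nhcGMP,
      k05cAMP = k05cAMP, nhcAMP = nhcAMP,
      campEfficacy = campEfficacy,
      blockFractionDiltiazem = blockFractionDiltiazem,
      pCaOverPNa = pCaOverPNa,
      rectificationRatio = rectificationRatio)
}

#' Preset channel parameters for canine cone CNG channels
#'
#' Mean population parameters of homomeric (cA3) and heteromeric
#' (cA3 + hB3) channels: K_0.5 and N_h for both nucleotides, cAMP
#' efficacy, fractional diltiazem block, P_Ca/P_Na and the inward
#' rectification ratio at saturating cGMP. Channel count and unitary
#' conductance are generator conventions chosen so macroscopic currents
#' fall in the few-hundred-pA range typical of excised cone-channel
#' patches.
#'
#' @param which "cA3" (homomeric) or "cA3+hB3" (heteromeric)
#' @return a \linkS4class{ChannelParams} object
#' @examples
#' presetChannelParams("cA3+hB3")
#' @export
presetChannelParams <- function(which = c("cA3", "cA3+hB3")) {
  which <- match.arg(which)
  switch(which,
    "cA3" = ChannelParams(
      k05cGMP = 10.3, nhcGMP = 2.40,
      k05cAMP = 1665, nhcAMP = 2.06,
      campEfficacy = 0.19,
      blockFractionDiltiazem = 1 - 0.79,
      pCaOverPNa = 1.5,
      rectificationRatio = 1.6),
    "cA3+hB3" = ChannelParams(
      k05cGMP = 16.0, nhcGMP = 1.87,
      k05cAMP = 1569, nhcAMP = 2.36,
      campEfficacy = 0.33,
      blockFractionDiltiazem = 1 - 0.40,
      pCaOverPNa = 17.2,
      rectificationRatio = 1.25))
}

#' Hill open probability
#'
#' Fractional activation c^N / (c^N + K^N), scaled by the ligand
#' efficacy. Bounded in [0, 1] and monotone non-decreasing in c.
#'
#' @param conc ligand concentration, uM (>= 0)
#' @param k05 half-activating concentration, uM
#' @param nh Hill coefficient
#' @param efficacy maximal open probability at saturation (1 for the
#'   full agonist)
#' @return open probability vector
#' @examples
#' openProbability(10.3, 10.3, 2.4)   # half of maximum
#' @export
openProbability <- function(conc, k05, nh, efficacy = 1) {
  stopifnot(all(conc >= 0), k05 > 0, nh > 0,
            efficacy >= 0, efficacy <= 1)
  efficacy * conc^nh / (conc^nh + k05^nh)
}

setMethod("show", "ChannelParams", function(object) {
  cat("ChannelParams\n")
  cat(sprintf("  %d channels x %.3g pS\n",
              round(object@nChannels), object@unitaryConductance))
  cat(sprintf("  cGMP: K0.5 = %.4g uM, Nh = %.3g\n",
              object@k05cGMP, object@nhcGMP))
  cat(sprintf("  cAMP: K0.5 = %.4g uM, Nh = %.3g, efficacy = %.3g\n",
              object@k05cAMP, object@nhcAMP, object@campEfficacy))
  cat(sprintf("  diltiazem block = %.3g, PCa/PNa = %.3g, rectification = %.3g\n",
              object@blockFractionDiltiazem, object@pCaOverPNa,
              object@rectificationRatio))
})
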