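#' @include AllClasses.R constants.R
NULL

#' Construct an IonSolution
#'
#' @param species species names
#' @param conc molar concentrations, mM
#' @param valence signed valences
#' @return an \linkS4class{IonSolution}
#' @examples
#' IonSolution(c("Na", "Cl"), c(120, 120), c(1, -1))
#' @export
IonSolution <- function(species, conc, valence) {
  new("IonSolution", species = as.character(species),
      conc = as.numeric(conc), valence = as.numeric(valence))
}

#' Construct a SolutionPair
#'
#' @param inner intracellular (bath, in inside-out configuration)
#'   \linkS4class{IonSolution}
#' @param outer extracellular (electrode) \linkS4class{IonSolution}
#' @param temperature absolute temperature, K
#' @param pH bath pH
#' @return a \linkS4class{SolutionPair}
#' @export
SolutionPair <- function(inner, outer, temperature = 295, pH = 7.4) {
  new("SolutionPair", inner = inner, outer = outer,
      temperature = temperature, pH = pH)
}

#' Standard recording solutions
#'
#' Builds the symmetric 120 mM NaCl control pair and, optionally, the
#' test pair with CaCl2 added to the intracellular (bath) face, matching
#' the reversal-potential protocol for inside-out patches.
#'
#' @param caInner_mM CaCl2 added to the intracellular side, mM (0 for the
#'   control pair)
#' @param na_mM NaCl concentration on both sides, mM
#' @param temperature absolute temperature, K
#' @return a \linkS4class{SolutionPair}
#' @examples
#' control <- standardSolutions(0)
#' test <- standardSolutions(1)    # 1 mM [Ca2+]i added
#' @export
standardSolutions <- function(caInner_mM = 0, na_mM = 120,
                              temperature = 295) {
  outer <- IonSolution(c("Na", "Cl"), c(na_mM, na_mM), c(1, -1))
  inner <- if (caInner_mM > 0)
    IonSolution(c("Na", "Ca", "Cl"),
                c(na_mM, caInner_mM, na_mM + 2 * caInner_mM),
                c(1, 2, -1))
  else outer
  SolutionPair(inner = inner, outer = outer, temperature = temperature)
}

#' Construct an ActivityModel
#'
#' @param mode "davies" (compute gamma from ionic strength and valence)
#'   or "fixed" (use the supplied per-species table)
#' @param gamma named activity coefficients for fixed mode, e.g.
#'   \code{c(Na = 0.77, Ca = 0.49)}
#' @return an \linkS4class{ActivityModel}
#' @examples
#' activityModel()                          # Davies default
#' activityModel("fixed", c(Na = 0.77, Ca = 0.55))
#' @export
activityModel <- function(mode = c("davies", "fixed"), gamma = numeric()) {
  mode <- match.arg(mode)
  new("ActivityModel", mode = mode, gamma = gamma)
}

#' Ionic strength of a solution
#'
#' I = 1/2 sum c_i z_i^2, in mol/L.
#'
#' @param solution an \linkS4class{IonSolution}
#' @return ionic strength, M
#' @export
ionicStrength <- function(solution) {
  sum(solution@conc / 1000 * solution@valence^2) / 2
}

#' Davies single-ion activity coefficient
#'
#' log10(gamma) = -A z^2 (sqrt(I)/(1 + sqrt(I)) - 0.3 I), with the
#' Debye-Hueckel coefficient A evaluated at the given temperature.
#'
#' @param valence signed ionic valence
#' @param I ionic strength, M
#' @param temperature absolute temperature, K
#' @return activity coefficient in (0, 1]
#' @examples
#' daviesGamma(1, 0.12)   # Na+ in ~120 mM 1:1 salt
#' daviesGamma(2, 0.12)   # Ca2+
#' @export
daviesGamma <- function(valence, I, temperature = 295) {
  stopifnot(I >= 0)
  A <- .daviesA(temperature)
  s <- sqrt(I)
  10^(-A * valence^2 * (s / (1 + s) - 0.3 * I))
}

#' Single-ion activities of a solution
#'
#' activity = gamma * concentration. Davies mode derives gamma from the
#' solution's own ionic strength; fixed mode looks species up in the
#' model's table (gamma = 1 for species absent from the table with a
#' warning suppressed for those with zero concentration).
#'
#' @param solution an \linkS4class{IonSolution}
#' @param model an \linkS4class{ActivityModel}
#' @param temperature absolute temperature, K (Davies mode)
#' @return named numeric vector of activities, mol/L
#' @examples
#' s <- IonSolution(c("Na", "Ca", "Cl"), c(120, 1, 122), c(1, 2, -1))
#' solutionActivities(s, activityModel())
#' @export
solutionActivities <- function(solution, model = activityModel(),
                               temperature = 295) {
  concM <- solution@conc / 1000
  g <- if (model@mode == "davies") {
    I <- ionicStrength(solution)
    daviesGamma(solution@valence, I, temperature)
  } else {
    idx <- match(solution@species, names(model@gamma))
    missing <- is.na(idx) & concM > 0
    if (any(missing))
      stop("no activity coefficient for species: ",
           paste(solution@species[missing], collapse = ", "))
    out <- model@gamma[idx]
    out[is.na(out)] <- 1
    out
  }
  stats::setNames(g * concM, solution@species)
}

setMethod("show", "IonSolution", function(object) {
  cat("IonSolution:",
      paste(sprintf("%s %g mM (z=%+g)", object@species, object@conc,
                    object@valence), collapse = ", "), "\n")
})

setMethod("show", "SolutionPair", function(object) {
  cat(sprintf("SolutionPair (T = %g K, pH %g)\n", object@temperature,
              object@pH))
  cat("  inner: "); show(object@inner)
  cat("  outer: "); show(object@outer)
})

setMethod("show", "ActivityModel", function(object) {
  if (object@mode == "davies") cat("ActivityModel: Davies equation\n")
  else cat("ActivityModel: fixed table [",
           paste(sprintf("%s=%.4g", names(object@gamma), object@gamma),
                 collapse = ", "), "]\n")
})
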