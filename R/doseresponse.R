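#' @include sweep.R
NULL

#' @rdname netCurrent
#' @param tol tolerance for the protocol match (ms / mV)
#' @export
setMethod("netCurrent", signature("Sweep", "Sweep"),
  function(active, baseline, tol = 1e-6) {
    if (length(active@time) != length(baseline@time) ||
        max(abs(active@time - baseline@time)) > tol ||
        max(abs(active@voltage - baseline@voltage)) > tol)
      stop("protocol mismatch between active and baseline sweeps")
    meta <- active@meta
    meta$net <- TRUE
    Sweep(active@time, active@voltage,
          active@current - baseline@current, meta)
  })

#' @rdname steadyStateCurrent
#' @param windowFraction trailing fraction of the sweep to average
#'   (default 0.2: the mean over the final 20 percent of the step)
#' @export
setMethod("steadyStateCurrent", "Sweep",
  function(x, windowFraction = 0.2) {
    stopifnot(windowFraction > 0, windowFraction <= 1)
    n <- length(x@current)
    k <- max(1L, ceiling(windowFraction * n))
    if (k > n) stop("empty steady-state window")
    mean(x@current[seq(n - k + 1L, n)])
  })

#' Average repeated sweeps pointwise
#'
#' "Multiple traces" recorded under one condition are combined by
#' pointwise mean of their currents before steady-state extraction.
#'
#' @param sweeps list of \linkS4class{Sweep}s sharing a protocol
#' @return a single averaged \linkS4class{Sweep}
#' @export
averageSweeps <- function(sweeps) {
  stopifnot(length(sweeps) >= 1)
  ref <- sweeps[[1]]
  for (s in sweeps[-1])
    if (max(abs(s@time - ref@time)) > 1e-6 ||
        max(abs(s@voltage - ref@voltage)) > 1e-6)
      stop("protocol mismatch among repeated sweeps")
  cur <- rowMeans(vapply(sweeps, sweepCurrent,
                         numeric(length(ref@current))))
  Sweep(ref@time, ref@voltage, cur, ref@meta)
}

#' Net steady-state dose-response table from a recording set
#'
#' Pairs each ligand sweep at the requested voltage with the zero-ligand
#' baseline sweep at the same level, subtracts, and extracts the
#' trailing-window steady-state current.
#'
#' @param rs a \linkS4class{RecordingSet} (metadata fields
#'   concentration_uM, voltage_mV, blocker as written by the simulator
#'   and sweep reader)
#' @param voltage analysis voltage, mV (default -60)
#' @param windowFraction trailing window for the steady state
#' @return data.frame with columns conc (uM), current (pA), voltage (mV)
#' @export
doseResponseTable <- function(rs, voltage = -60, windowFraction = 0.2) {
  base <- filterSweeps(rs, concentration_uM = 0, voltage_mV = voltage)
  if (!length(base))
    stop("no zero-ligand baseline sweep at ", voltage, " mV")
  baseline <- averageSweeps(sweepList(base))
  act <- Filter(function(s) {
    m <- s@meta
    isTRUE(m$voltage_mV == voltage) && isTRUE(m$concentration_uM > 0)
  }, rs@sweeps)
  if (!length(act)) stop("no ligand sweeps at ", voltage, " mV")
  conc <- vapply(act, function(s) s@meta$concentration_uM, numeric(1))
  cur <- vapply(act, function(s)
    steadyStateCurrent(netCurrent(s, baseline),
                       windowFraction = windowFraction), numeric(1))
  out <- data.frame(conc = conc, current = cur, voltage = voltage)
  out[order(out$conc), , drop = FALSE]
}

#' cAMP efficacy
#'
#' Ratio of the maximal (saturating) cAMP-activated current to the
#' maximal cGMP-activated current at matched voltage; low values are a
#' homomeric-channel signature, higher values a heteromeric one.
#' Magnitudes are expected (the denominator must be positive).
#'
#' @param imaxCAMP saturating cAMP current magnitude, pA
#' @param imaxCGMP saturating cGMP current magnitude, pA (> 0)
#' @return the efficacy fraction
#' @examples
#' agonistEfficacy(28, 200)   # 0.14
#' @export
agonistEfficacy <- function(imaxCAMP, imaxCGMP) {
  if (!is.finite(imaxCGMP) || imaxCGMP <= 0)
    stop("imaxCGMP must be positive")
  if (!is.finite(imaxCAMP) || imaxCAMP < 0)
    stop("imaxCAMP must be non-negative")
  imaxCAMP / imaxCGMP
}

#' Fractional remaining current under diltiazem
#'
#' I_dil / I: the current remaining with the blocker, normalized to the
#' maximal cGMP-activated current of the same patch
#' (remaining-current convention: 1 = no block, 0 = full block).
#'
#' @param iWithBlocker current magnitude with blocker, pA
#' @param iCGMPMax maximal cGMP current magnitude, pA (> 0)
#' @return the remaining-current fraction
#' @examples
#' fractionalBlock(79, 100)   # 0.79
#' @export
fractionalBlock <- function(iWithBlocker, iCGMPMax) {
  if (!is.finite(iCGMPMax) || iCGMPMax <= 0)
    stop("iCGMPMax must be positive")
  if (!is.finite(iWithBlocker) || iWithBlocker < 0)
    stop("iWithBlocker must be non-negative")
  iWithBlocker / iCGMPMax
}

#' Classify a patch as homomeric or heteromeric
#'
#' Rapid-evaluation heuristic: homomeric channels show low cAMP
#' efficacy and very little diltiazem block (high remaining current);
#' heteromeric channels the opposite. A patch is called homomeric iff
#' efficacy < efficacy cut AND remaining-current ratio > block cut,
#' heteromeric iff both inequalities are reversed, and ambiguous
#' otherwise (values exactly at a cut are ambiguous). Default cuts are
#' the midpoints of the homomeric and heteromeric population means
#' (efficacy 0.19 vs 0.33 -> 0.26; remaining current 0.79 vs 0.40
#' -> 0.60).
#'
#' @param efficacy cAMP efficacy
#' @param diltiazemRatio remaining-current ratio I_dil/I
#' @param cuts named numeric: \code{efficacy} and \code{block} cuts
#' @return "homomeric", "heteromeric" or "ambiguous"
#' @examples
#' classifyPatch(0.19, 0.79)   # homomeric
#' classifyPatch(0.33, 0.40)   # heteromeric
#' @export
classifyPatch <- function(efficacy, diltiazemRatio,
                          cuts = c(efficacy = 0.26, block = 0.60)) {
  stopifnot(is.finite(efficacy), is.finite(diltiazemRatio),
            all(c("efficacy", "block") %in% names(cuts)))
  if (efficacy < cuts["efficacy"] && diltiazemRatio > cuts["block"])
    "homomeric"
  else if (efficacy > cuts["efficacy"] && diltiazemRatio < cuts["block"])
    "heteromeric"
  else "ambiguous"
}

#' Efficacy, block and classification of one patch
#'
#' Computes the cAMP efficacy and diltiazem remaining-current ratio from
#' a characterization \linkS4class{RecordingSet} (baseline, saturating
#' cGMP, saturating cAMP, cGMP + diltiazem sweeps at one voltage) and
#' classifies the patch.
#'
#' @param rs a \linkS4class{RecordingSet} as produced by
#'   \code{\link{simulatePatchSet}} or assembled from recordings
#' @param voltage analysis voltage, mV
#' @param cuts classification cuts, see \code{\link{classifyPatch}}
#' @param windowFraction steady-state window
#' @return one-row data.frame: efficacy, diltiazem_ratio, classification
#' @export
patchMetrics <- function(rs, voltage = -60,
                         cuts = c(efficacy = 0.26, block = 0.60),
                         windowFraction = 0.2) {
  base <- filterSweeps(rs, concentration_uM = 0, voltage_mV = voltage)
  if (!length(base)) stop("no baseline sweep at ", voltage, " mV")
  baseline <- averageSweeps(sweepList(base))
  pick <- function(ligand, blocker) {
    sel <- Filter(function(s) {
      m <- s@meta
      isTRUE(m$ligand == ligand) && isTRUE(m$blocker == blocker) &&
        isTRUE(m$voltage_mV == voltage) && isTRUE(m$concentration_uM > 0)
    }, rs@sweeps)
    if (!length(sel)) stop("missing ", ligand, "/", blocker, " sweep")
    conc <- vapply(sel, function(s) s@meta$concentration_uM, numeric(1))
    sel[[which.max(conc)]]
  }
  iss <- function(s) abs(steadyStateCurrent(netCurrent(s, baseline),
                                            windowFraction = windowFraction))
  iG <- iss(pick("cGMP", "none"))
  iA <- iss(pick("cAMP", "none"))
  iD <- iss(pick("cGMP", "diltiazem"))
  eff <- agonistEfficacy(iA, iG)
  blk <- fractionalBlock(iD, iG)
  data.frame(efficacy = eff, diltiazem_ratio = blk,
             classification = classifyPatch(eff, blk, cuts))
}
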