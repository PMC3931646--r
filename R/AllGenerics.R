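#' @import methods
NULL

#' Number of coordinate frames in an ensemble
#'
#' @param x a \linkS4class{StructureEnsemble}
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Net (baseline-subtracted) current
#'
#' Pointwise subtraction of a zero-ligand bath sweep from a
#' nucleotide-activated sweep recorded under the same voltage protocol.
#'
#' @param active \linkS4class{Sweep} recorded in the presence of ligand
#' @param baseline \linkS4class{Sweep} recorded without ligand
#' @param ... further arguments (tolerance for protocol matching)
#' @return a \linkS4class{Sweep} whose current is \code{active - baseline},
#'   with metadata flag \code{net = TRUE}
#' @export
setGeneric("netCurrent", function(active, baseline, ...)
  standardGeneric("netCurrent"))

#' Steady-state current of a voltage-step sweep
#'
#' @param x a \linkS4class{Sweep}
#' @param ... further arguments (\code{windowFraction})
#' @return mean current (pA) over the trailing window
#' @export
setGeneric("steadyStateCurrent", function(x, ...)
  standardGeneric("steadyStateCurrent"))

#' Scan protein sequences for the Tri-Asp motif
#'
#' @param x sequences: character vector or \code{Biostrings::AAStringSet}
#' @param ... further arguments (\code{strictness})
#' @return data.frame of motif hits (1-based positions)
#' @export
setGeneric("scanTriAsp", function(x, ...) standardGeneric("scanTriAsp"))

#' Write a multi-frame coordinate ensemble as a multi-MODEL PDB file
#'
#' @param x a \linkS4class{StructureEnsemble}
#' @param path output file path
#' @param ... unused
#' @return \code{path}, invisibly
#' @export
setGeneric("writeEnsemblePDB", function(x, path, ...)
  standardGeneric("writeEnsemblePDB"))
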