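#' @include sweep.R
NULL

#' Average ascending and descending ramp limbs onto a voltage grid
#'
#' Interpolates the current of each limb onto a common voltage grid and
#' averages pointwise. Averaging the two limbs cancels any
#' current offset that is antisymmetric between them (e.g. capacitive
#' charging of opposite sign on the up- and down-ramp).
#'
#' @param ascending,descending \linkS4class{Sweep}s covering the up and
#'   down limbs (order does not matter; each limb must span the grid)
#' @param grid voltage grid, mV; defaults to the overlap of the two limbs
#'   at 0.25-mV spacing
#' @return data.frame with columns \code{voltage_mV}, \code{current_pA}
#' @seealso \code{\link{estimateReversal}}, \code{\link{splitRampLimbs}}
#' @export
averageRamps <- function(ascending, descending, grid = NULL) {
  lim <- function(s) {
    o <- order(s@voltage)
    list(v = s@voltage[o], i = s@current[o])
  }
  a <- lim(ascending); d <- lim(descending)
  lo <- max(min(a$v), min(d$v))
  hi <- min(max(a$v), max(d$v))
  if (lo >= hi) stop("ramp limbs have non-overlapping voltage ranges")
  if (is.null(grid)) grid <- seq(lo, hi, by = 0.25)
  if (min(grid) < lo - 1e-9 || max(grid) > hi + 1e-9)
    stop("grid extends beyond the voltage range covered by both limbs")
  ia <- stats::approx(a$v, a$i, xout = grid, ties = mean)$y
  id <- stats::approx(d$v, d$i, xout = grid, ties = mean)$y
  data.frame(voltage_mV = grid, current_pA = (ia + id) / 2)
}

#' Split a single up-and-down ramp sweep into its two limbs
#'
#' @param sweep a ramp \linkS4class{Sweep} whose voltage rises then falls
#'   (or falls then rises)
#' @return list with elements \code{ascending} and \code{descending}
#' @export
splitRampLimbs <- function(sweep) {
  v <- sweep@voltage
  turn <- which.max(if (v[2] > v[1]) v else -v)
  idx1 <- seq_len(turn)
  idx2 <- seq(turn, length(v))
  s1 <- Sweep(sweep@time[idx1], v[idx1], sweep@current[idx1], sweep@meta)
  s2 <- Sweep(sweep@time[idx2], v[idx2], sweep@current[idx2], sweep@meta)
  if (v[2] > v[1]) list(ascending = s1, descending = s2)
  else list(ascending = s2, descending = s1)
}

#' Estimate the reversal potential from an averaged I-V table
#'
#' Locates the sign change of the current along increasing voltage and
#' fits a least-squares line to the points within \code{window} mV of
#' the crossing ("linearized to the zero-current value"); returns the
#' zero of that line.
#'
#' @param iv data.frame with columns \code{voltage_mV}, \code{current_pA}
#'   (as returned by \code{\link{averageRamps}})
#' @param window half-width of the linearization window, mV
#' @return reversal potential, mV
#' @examples
#' iv <- data.frame(voltage_mV = -10:10, current_pA = 2 * (-10:10 + 4.02))
#' estimateReversal(iv)   # -4.02
#' @export
estimateReversal <- function(iv, window = 5) {
  stopifnot(all(c("voltage_mV", "current_pA") %in% names(iv)),
            window > 0)
  v <- iv$voltage_mV; i <- iv$current_pA
  o <- order(v); v <- v[o]; i <- i[o]
  s <- sign(i)
  cross <- which(s[-1] * s[-length(s)] <= 0 & (s[-1] != 0 | s[-length(s)] != 0))
  if (!length(cross) && !any(s == 0))
    stop("no reversal in window: current does not change sign")
  v0 <- if (any(s == 0)) v[which(s == 0)[1]] else {
    k <- cross[1]
    v[k] + (v[k + 1] - v[k]) * (0 - i[k]) / (i[k + 1] - i[k])
  }
  sel <- abs(v - v0) <= window
  if (sum(sel) < 2) stop("fewer than two I-V points in the window")
  fit <- stats::lm(i[sel] ~ v[sel])
  b <- stats::coef(fit)
  unname(-b[1] / b[2])
}
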