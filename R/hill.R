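#' @include AllClasses.R
NULL

#' Hill activation current
#'
#' I(c) = Imax * c^nh / (c^nh + k05^nh). By construction
#' I(k05) = Imax / 2.
#'
#' @param conc ligand concentration, uM
#' @param imax maximal current, pA
#' @param k05 half-activating concentration, uM
#' @param nh Hill coefficient
#' @return predicted current
#' @export
hillCurrent <- function(conc, imax, k05, nh) {
  imax * conc^nh / (conc^nh + k05^nh)
}

## start heuristic: Imax from the largest observed magnitude, K from the
## concentration whose current is nearest half-max, N from the slope of
## log(I/(Imax - I)) against log(c) over the usable points
.hillStart <- function(conc, current) {
  imax0 <- max(abs(current)) * sign(current[which.max(abs(current))])
  k0 <- conc[which.min(abs(abs(current) - abs(imax0) / 2))]
  frac <- pmin(pmax(current / (1.05 * imax0), 1e-3), 1 - 1e-3)
  y <- log(frac / (1 - frac))
  sl <- tryCatch(unname(stats::coef(stats::lm(y ~ log(conc)))[2]),
                 error = function(e) NA_real_)
  n0 <- if (is.finite(sl) && sl > 0.2 && sl < 6) sl else 2
  list(imax = imax0, k05 = k0, nh = n0)
}

#' Fit the Hill equation to dose-response points
#'
#' Nonlinear least squares (Levenberg-Marquardt) on
#' I(c) = Imax c^N / (c^N + K^N). Starting values: Imax from the
#' largest observed current, K from the concentration nearest
#' half-maximal current, N from a logit-log slope. Imax may be fitted
#' freely (default) or constrained to a known saturating value.
#'
#' @param points data.frame with columns \code{conc} (uM) and
#'   \code{current} (pA), e.g. from \code{\link{doseResponseTable}};
#'   currents of either sign are accepted (fits are done on signed
#'   values)
#' @param fixImax \code{NULL} to fit Imax, or a numeric value to
#'   constrain it
#' @param start optional named list overriding the start heuristic
#' @return a \linkS4class{HillFit}
#' @examples
#' pts <- data.frame(conc = c(1, 3, 10, 30, 100, 300),
#'                   current = hillCurrent(c(1, 3, 10, 30, 100, 300),
#'                                         100, 10, 2))
#' fitHill(pts)
#' @export
fitHill <- function(points, fixImax = NULL, start = NULL) {
  stopifnot(all(c("conc", "current") %in% names(points)))
  conc <- points$conc
  current <- points$current
  if (any(conc <= 0)) stop("concentrations must be positive")
  nDistinct <- length(unique(conc))
  if (nDistinct < 2) stop("degenerate data: all concentrations equal")
  if (nDistinct < 3)
    warning("fewer than 3 distinct concentrations; Hill fit is ",
            "poorly constrained")
  st <- .hillStart(conc, current)
  if (!is.null(start)) st[names(start)] <- start
  if (min(conc) > st$k05 || max(conc) < st$k05)
    warning("concentrations do not span the apparent K0.5")
  dat <- data.frame(conc = conc, current = current)
  fit <- if (is.null(fixImax)) {
    minpack.lm::nlsLM(
      current ~ imax * conc^nh / (conc^nh + k05^nh), data = dat,
      start = list(imax = st$imax, k05 = st$k05, nh = st$nh),
      lower = c(imax = -Inf, k05 = 1e-9, nh = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12))
  } else {
    minpack.lm::nlsLM(
      current ~ fixImax * conc^nh / (conc^nh + k05^nh), data = dat,
      start = list(k05 = st$k05, nh = st$nh),
      lower = c(k05 = 1e-9, nh = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12))
  }
  cf <- stats::coef(fit)
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e)
                    stats::setNames(rep(NA_real_, length(cf)), names(cf)))
  se <- c(imax = if (is.null(fixImax)) unname(ses["imax"]) else NA_real_,
          k05 = unname(ses["k05"]), nh = unname(ses["nh"]))
  new("HillFit",
      imax = if (is.null(fixImax)) unname(cf["imax"]) else fixImax,
      k05 = unname(cf["k05"]), nh = unname(cf["nh"]),
      se = se,
      rss = sum(stats::residuals(fit)^2),
      converged = fit$convInfo$isConv,
      imaxFixed = !is.null(fixImax),
      data = dat)
}

#' @describeIn fitHill fitted coefficients as a named vector
#' @param object a \linkS4class{HillFit}
#' @export
setMethod("coef", "HillFit", function(object)
  c(imax = object@imax, k05 = object@k05, nh = object@nh))

setMethod("show", "HillFit", function(object) {
  cat(sprintf(
    "HillFit: Imax = %.4g pA%s, K0.5 = %.4g uM, Nh = %.3g  (RSS %.4g%s)\n",
    object@imax, if (object@imaxFixed) " [fixed]" else "",
    object@k05, object@nh, object@rss,
    if (object@converged) "" else "; NOT CONVERGED"))
})

#' Write a Hill fit report
#'
#' Structured JSON report with parameters, standard errors, residual sum
#' of squares and convergence flag.
#'
#' @param fit a \linkS4class{HillFit}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeHillReport <- function(fit, path) {
  rep <- list(model = "I(c) = Imax * c^Nh / (c^Nh + K05^Nh)",
              estimates = as.list(coef(fit)),
              standard_errors = as.list(fit@se),
              imax_fixed = fit@imaxFixed,
              rss = fit@rss, converged = fit@converged,
              n_points = nrow(fit@data))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
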