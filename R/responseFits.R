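#' @include AllClasses.R AllGenerics.R
NULL

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares fit of r(c) = bottom + (top - bottom) / (1 + (EC50/c)^h),
#' the standard 4PL reading of a concentration-response curve.  EC50 is
#' multi-start initialized across the dose range (log-spaced) and the best
#' converged fit kept, so the result is deterministic given the data.  A
#' dose of 0 is handled by the (EC50/c)^h parameterization limit (response
#' -> bottom); no logarithm of a dose is ever taken.  The hill slope can be
#' fixed (e.g. \code{fixHill = 1}).
#'
#' Flags: "no transition" when the responses are essentially constant;
#' "EC50 extrapolated" when the estimate falls outside
#' [min dose / 10, max dose * 10].
#'
#' @param doses concentrations (same units as the returned EC50, e.g. nM)
#' @param responses responses (e.g. percent editing), parallel to doses
#' @param fixHill optional fixed hill slope
#' @param nStarts number of EC50 starting values (default 8)
#' @return a [DoseResponseFit-class]
#' @export
fitDoseResponse <- function(doses, responses, fixHill = NULL, nStarts = 8L) {
  stopifnot(length(doses) == length(responses), length(doses) >= 4L)
  ord <- order(doses)
  c_ <- as.numeric(doses)[ord]; y <- as.numeric(responses)[ord]
  flags <- character()
  span <- diff(range(y))
  if (span < max(1e-8, 1e-6 * max(abs(y), 1))) {
    est <- c(EC50 = NA_real_, hill = NA_real_, top = max(y), bottom = min(y))
    return(new("DoseResponseFit", estimate = est,
               se = est * NA_real_, residualSD = 0,
               flags = "no transition"))
  }
  model <- function(par, cc) {
    ec50 <- exp(par[["logEC50"]])
    h <- if (is.null(fixHill)) par[["h"]] else fixHill
    bottom <- par[["bottom"]]; top <- par[["top"]]
    frac <- ifelse(cc > 0, 1 / (1 + (ec50 / cc)^h), 0)
    bottom + (top - bottom) * frac
  }
  residFun <- function(par) y - model(par, c_)
  posDoses <- c_[c_ > 0]
  starts <- exp(seq(log(min(posDoses)), log(max(posDoses)),
                    length.out = nStarts))
  best <- NULL
  for (e0 in starts) {
    par0 <- c(logEC50 = log(e0), bottom = min(y), top = max(y))
    if (is.null(fixHill)) par0 <- c(par0, h = 1)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = residFun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("dose-response fit failed to converge")
  p <- best$par
  ec50 <- exp(p[["logEC50"]])
  h <- if (is.null(fixHill)) p[["h"]] else fixHill
  if (ec50 < min(posDoses) / 10 || ec50 > max(c_) * 10)
    flags <- c(flags, "EC50 extrapolated")
  dof <- length(y) - length(p)
  sigma2 <- if (dof > 0) best$deviance / dof else 0
  covm <- tryCatch(sigma2 * solve(best$hessian), error = function(e)
    matrix(NA_real_, length(p), length(p), dimnames = list(names(p),
                                                           names(p))))
  seRaw <- sqrt(pmax(diag(covm), 0))
  est <- c(EC50 = ec50, hill = h, top = p[["top"]], bottom = p[["bottom"]])
  se <- c(EC50 = ec50 * seRaw[["logEC50"]],        # delta method on log scale
          hill = if (is.null(fixHill)) seRaw[["h"]] else 0,
          top = seRaw[["top"]], bottom = seRaw[["bottom"]])
  new("DoseResponseFit", estimate = est, se = se,
      residualSD = sqrt(sigma2), flags = flags)
}

#' Fit single-exponential cleavage kinetics
#'
#' Least-squares fit of F(t) = A (1 - e^{-k t}) to cleaved-fraction time
#' courses.  A t = 0 point (fraction 0) is implied when absent.
#'
#' @param times time points (minutes)
#' @param cleavedFraction cleaved fractions in [0, 1], parallel to times
#' @return a [KineticsFit-class]
#' @export
fitCleavageKinetics <- function(times, cleavedFraction) {
  stopifnot(length(times) == length(cleavedFraction))
  t_ <- as.numeric(times); y <- as.numeric(cleavedFraction)
  if (!any(t_ == 0)) { t_ <- c(0, t_); y <- c(0, y) }
  ord <- order(t_); t_ <- t_[ord]; y <- y[ord]
  if (max(y) <= 0) {
    est <- c(k = NA_real_, A = 0)
    return(new("KineticsFit", estimate = est, se = est * NA_real_,
               residualSD = 0, flags = "no cleavage"))
  }
  A0 <- min(max(y) * 1.05, 1)
  half <- t_[which(y >= 0.5 * max(y))[1L]]
  k0 <- if (half > 0) log(2) / half else 1
  residFun <- function(par)
    y - exp(par[["logA"]]) * (1 - exp(-exp(par[["logk"]]) * t_))
  fit <- minpack.lm::nls.lm(
    par = c(logk = log(k0), logA = log(A0)), fn = residFun,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  p <- fit$par
  k <- exp(p[["logk"]]); A <- exp(p[["logA"]])
  dof <- length(y) - 2L
  sigma2 <- if (dof > 0) fit$deviance / dof else 0
  covm <- tryCatch(sigma2 * solve(fit$hessian), error = function(e)
    matrix(NA_real_, 2L, 2L, dimnames = list(names(p), names(p))))
  seRaw <- sqrt(pmax(diag(covm), 0))
  new("KineticsFit",
      estimate = c(k = k, A = A),
      se = c(k = k * seRaw[["logk"]], A = A * seRaw[["logA"]]),
      residualSD = sqrt(sigma2),
      flags = if (A > 1.001) "plateau above 1" else character())
}

#' @describeIn fitDoseResponse named parameter estimates
#' @param x a fit object
#' @export
setMethod("fitEstimates", "DoseResponseFit", function(x) x@estimate)
#' @export
setMethod("fitEstimates", "KineticsFit", function(x) x@estimate)
#' @describeIn fitDoseResponse named standard errors
#' @export
setMethod("fitSE", "DoseResponseFit", function(x) x@se)
#' @export
setMethod("fitSE", "KineticsFit", function(x) x@se)
#' @describeIn fitDoseResponse fit warning flags
#' @export
setMethod("fitFlags", "DoseResponseFit", function(x) x@flags)
#' @export
setMethod("fitFlags", "KineticsFit", function(x) x@flags)

setMethod("show", "DoseResponseFit", function(object) {
  e <- object@estimate
  cat(sprintf("DoseResponseFit: EC50 = %.4g, hill = %.3g, range %.3g..%.3g\n",
              e[["EC50"]], e[["hill"]], e[["bottom"]], e[["top"]]))
  if (length(object@flags)) cat("  flags:", paste(object@flags,
                                                  collapse = "; "), "\n")
})

setMethod("show", "KineticsFit", function(object) {
  e <- object@estimate
  cat(sprintf("KineticsFit: k = %.4g /min, plateau A = %.3g\n",
              e[["k"]], e[["A"]]))
  if (length(object@flags)) cat("  flags:", paste(object@flags,
                                                  collapse = "; "), "\n")
})

#' Read a two-column (x, y) TSV for curve fitting
#' @param file path; first column dose or time, second response or fraction
#' @return data.frame with columns x, y
#' @export
readCurveTSV <- function(file) {
  df <- utils::read.delim(file)
  stopifnot(ncol(df) >= 2L)
  data.frame(x = as.numeric(df[[1L]]), y = as.numeric(df[[2L]]))
}
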