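#' @include AllClasses.R AllGenerics.R fractionCounts.R
NULL

# shared log-ratio-of-frequencies estimator with delta-method SE
.logRatioMeasure <- function(fc, numFraction, denFraction, reference, kind,
                             alpha = NULL) {
  stopifnot(is(fc, "FractionCounts"))
  if (is.null(alpha)) alpha <- metadata(fc)$alpha
  if (is.null(alpha)) alpha <- 0.5
  cts <- SummarizedExperiment::assay(fc, "counts")
  if (!reference %in% rownames(cts))
    stop("reference variant '", reference, "' not present in count table")
  cd <- colData(fc)
  reps <- intersect(cd$replicate[cd$fraction == numFraction],
                    cd$replicate[cd$fraction == denFraction])
  if (!length(reps))
    stop("no replicate has both '", numFraction, "' and '", denFraction,
         "' fractions")
  out <- lapply(reps, function(r) {
    cn <- cts[, fractionColumn(fc, numFraction, r)] + alpha
    cd_ <- cts[, fractionColumn(fc, denFraction, r)] + alpha
    fn <- cn / sum(cn)
    fd <- cd_ / sum(cd_)
    iref <- match(reference, rownames(cts))
    value <- log((fn / fn[iref]) / (fd / fd[iref]))
    se <- sqrt(1 / cn + 1 / cd_ + 1 / cn[iref] + 1 / cd_[iref])
    value[iref] <- 0
    se[iref] <- 0
    DataFrame(variant_id = rownames(cts), kind = kind,
              value = as.numeric(value), se = as.numeric(se),
              replicate = as.character(r))
  })
  do.call(rbind, out)
}

#' Relative binding affinity (lnKA) from bound/unbound fractions
#'
#' For each variant i, lnKA_i = ln[(f_bound,i / f_bound,ref) /
#' (f_unbound,i / f_unbound,ref)], the log ratio-of-ratios of
#' pseudocount-normalized frequencies between the protein-bound and unbound
#' sorted fractions.  The estimator is invariant to depth differences between
#' fractions.  Under a Boltzmann partition with variant energy E_i, its
#' expectation is -E_i, so mismatches carry negative lnKA.  The reference
#' (consensus) variant is 0 by construction.  Standard errors come from the
#' delta method: sqrt of the summed reciprocal pseudocounted counts of the
#' four cells involved.
#'
#' @param fc a [FractionCounts-class] containing bound and unbound columns
#' @param boundFraction,unboundFraction fraction labels (defaults "bound",
#'   "unbound")
#' @param reference reference variant ID (default "WT")
#' @param alpha pseudocount override (default: value stored in fc)
#' @return DataFrame of relative measures: variant_id, kind ("lnKA"),
#'   value, se, replicate (one block per replicate shared by both fractions)
#' @export
computeLnKA <- function(fc, boundFraction = "bound",
                        unboundFraction = "unbound", reference = "WT",
                        alpha = NULL) {
  .logRatioMeasure(fc, boundFraction, unboundFraction, reference,
                   kind = "lnKA", alpha = alpha)
}

#' Relative cleavage depletion (delta-d) from uncut/input fractions
#'
#' delta_d_i = ln[(f_uncut,i / f_uncut,ref) / (f_input,i / f_input,ref)].
#' Positive values mean the variant is enriched among uncut molecules, i.e.
#' cleaved more slowly than the reference.  Under first-order cleavage with
#' rate k_i = k_ref * exp(-E_i), the expectation is C * (1 - exp(-E_i))
#' with C = k_ref * t.
#'
#' @inheritParams computeLnKA
#' @param uncutFraction,inputFraction fraction labels (defaults "uncut",
#'   "input"; input is the mock-digest fraction)
#' @return DataFrame of relative measures with kind "delta_d"
#' @export
computeDeltaD <- function(fc, uncutFraction = "uncut",
                          inputFraction = "input", reference = "WT",
                          alpha = NULL) {
  .logRatioMeasure(fc, uncutFraction, inputFraction, reference,
                   kind = "delta_d", alpha = alpha)
}

# indicator design matrix of mismatches: one column per (position, alt base)
# actually observed; attributes carry the full coordinate frame
.mismatchDesign <- function(variantIds, library) {
  man <- variants(library)
  idx <- match(variantIds, man$variant_id)
  if (anyNA(idx))
    stop("measures contain variant IDs absent from the library manifest")
  labels <- positionLabels(library)
  refs <- strsplit(variableRegion(library), "")[[1]]
  names(refs) <- labels
  allParams <- unlist(lapply(labels, function(p)
    paste0(p, ":", setdiff(.DNA_BASES, refs[p]))), use.names = FALSE)
  mm <- parseMismatches(man$mismatches[idx])
  X <- matrix(0, nrow = length(variantIds), ncol = length(allParams),
              dimnames = list(variantIds, allParams))
  rows <- rep.int(seq_along(mm), vapply(mm, nrow, 0L))
  keys <- unlist(lapply(mm, function(d)
    if (nrow(d)) paste0(d$position, ":", d$alt) else character()),
    use.names = FALSE)
  if (length(keys)) X[cbind(rows, match(keys, allParams))] <- 1
  structure(X, labels = labels, refs = refs)
}

.emptyEnergySlots <- function(labels, refs) {
  eps <- matrix(NA_real_, 4L, length(labels),
                dimnames = list(.DNA_BASES, labels))
  flags <- matrix("unidentifiable", 4L, length(labels),
                  dimnames = list(.DNA_BASES, labels))
  refIdx <- cbind(match(refs, .DNA_BASES), seq_along(labels))
  eps[refIdx] <- 0
  flags[refIdx] <- "ref"
  se <- eps * 0
  list(eps = eps, se = se, flags = flags, refIdx = refIdx)
}

.fillEnergyMatrix <- function(coefs, ses, labels, refs, kind, C = NA_real_,
                              diagnostics = list(), satBound = Inf) {
  s <- .emptyEnergySlots(labels, refs)
  for (k in names(coefs)) {
    pb <- strsplit(k, ":", fixed = TRUE)[[1]]
    i <- match(pb[2L], .DNA_BASES); j <- match(pb[1L], labels)
    if (is.na(coefs[k])) next
    s$eps[i, j] <- coefs[k]
    s$se[i, j] <- ses[k]
    s$flags[i, j] <- if (is.finite(satBound) && coefs[k] >= satBound)
      "saturated" else "ok"
  }
  new("EnergyMatrix", positions = labels, refBases = refs, eps = s$eps,
      se = s$se, flags = s$flags, kind = kind, exposureC = C,
      diagnostics = diagnostics)
}

# inverse-variance averaging of per-replicate measures
.preAverageMeasures <- function(measures) {
  sp <- split(seq_len(nrow(measures)), measures$variant_id)
  rows <- lapply(sp, function(i) {
    w <- 1 / pmax(measures$se[i], 1e-12)^2
    DataFrame(variant_id = measures$variant_id[i][1L],
              kind = measures$kind[i][1L],
              value = sum(w * measures$value[i]) / sum(w),
              se = sqrt(1 / sum(w)), replicate = "pooled")
  })
  do.call(rbind, rows)
}

#' Fit the additive binding energy matrix
#'
#' Weighted least squares of -lnKA on per-(position, base) mismatch
#' indicators, with no intercept (the consensus anchors zero), weights
#' 1/SE^2.  Under the Boltzmann partition the log-odds identity makes this
#' linear model exact, which is why binding penalties need no nonlinear
#' machinery.  Multiple replicates are fit jointly with shared penalties by
#' default.  Mismatches never observed in the data are flagged
#' "unidentifiable" rather than silently reported as 0.
#'
#' @param measures DataFrame from [computeLnKA()]
#' @param library the [VariantLibrary-class] the measures refer to
#' @param preAverage inverse-variance-average replicate measures per variant
#'   before fitting instead of the joint fit (default FALSE)
#' @return an [EnergyMatrix-class] of kind "binding"
#' @export
fitBindingEnergyMatrix <- function(measures, library, preAverage = FALSE) {
  stopifnot(all(measures$kind == "lnKA"))
  if (preAverage) measures <- .preAverageMeasures(measures)
  X <- .mismatchDesign(measures$variant_id, library)
  labels <- attr(X, "labels"); refs <- attr(X, "refs")
  y <- -measures$value
  w <- 1 / pmax(measures$se, 1e-12)^2
  w[measures$se == 0] <- 0          # reference rows carry no information
  observed <- colSums(X[w > 0, , drop = FALSE]) > 0
  Xo <- X[, observed, drop = FALSE]
  fit <- stats::lm.wfit(Xo, y, w)
  dof <- sum(w > 0) - fit$rank
  sigma2 <- if (dof > 0) sum(w * fit$residuals^2) / dof else 0
  XtWX <- crossprod(Xo * sqrt(w))
  covm <- tryCatch(solve(XtWX) * sigma2,
                   error = function(e) matrix(NA_real_, ncol(Xo), ncol(Xo)))
  ses <- sqrt(pmax(diag(covm), 0))
  names(ses) <- colnames(Xo)
  coefs <- fit$coefficients
  names(coefs) <- colnames(Xo)
  .fillEnergyMatrix(coefs, ses, labels, refs, kind = "binding",
                    diagnostics = list(residualSD = sqrt(sigma2),
                                       n = sum(w > 0),
                                       nParams = sum(observed)))
}

#' Fit the saturating cleavage penalty model
#'
#' Nonlinear least squares of delta_d_i = C * (1 - exp(-sum_p eps(p, s_i[p])))
#' with the exposure scale C = k_ref * t shared across variants (one C per
#' replicate when replicates are fit jointly; penalties are always shared).
#' Initialization profiles C over a grid: for each candidate C the model is
#' linear in the penalties after the transform -log(1 - delta_d / C), and the
#' best profiled start seeds a Levenberg-Marquardt refinement.  Penalties at
#' the saturation ceiling are flagged "saturated" (the data only bound them
#' from below); when all measures are zero the penalties are zero and C is
#' unidentifiable, reported as NA.
#'
#' @inheritParams fitBindingEnergyMatrix
#' @param measures DataFrame from [computeDeltaD()]
#' @param satBound penalty value above which an estimate is flagged as a
#'   lower bound rather than a point estimate (default 8 natural-log units)
#' @param nStarts number of profiled C starting values (default 8)
#' @return an [EnergyMatrix-class] of kind "cleavage" with per-replicate C
#' @export
fitCleavagePenaltyModel <- function(measures, library, preAverage = FALSE,
                                    satBound = 8, nStarts = 8L) {
  stopifnot(all(measures$kind == "delta_d"))
  if (preAverage) measures <- .preAverageMeasures(measures)
  X <- .mismatchDesign(measures$variant_id, library)
  labels <- attr(X, "labels"); refs <- attr(X, "refs")
  y <- measures$value
  w <- 1 / pmax(measures$se, 1e-12)^2
  w[measures$se == 0] <- 0
  repId <- factor(measures$replicate)
  nrep <- nlevels(repId)

  if (max(abs(y[w > 0]), 0) < 1e-8) {
    em <- .fillEnergyMatrix(
      stats::setNames(rep(0, sum(colSums(X[w > 0, , drop = FALSE]) > 0)),
                      colnames(X)[colSums(X[w > 0, , drop = FALSE]) > 0]),
      stats::setNames(rep(0, ncol(X)), colnames(X)),
      labels, refs, kind = "cleavage",
      C = stats::setNames(rep(NA_real_, nrep), levels(repId)),
      diagnostics = list(residualSD = 0, note = "C unidentifiable: all delta_d are zero"))
    return(em)
  }

  observed <- colSums(X[w > 0, , drop = FALSE]) > 0
  Xo <- X[, observed, drop = FALSE]
  K <- ncol(Xo)
  sw <- sqrt(w)
  repMat <- outer(as.integer(repId), seq_len(nrep),
                  function(i, j) as.numeric(i == j))

  # profiled linear start for a fixed C (same C all replicates)
  profiledStart <- function(C) {
    z <- pmin(pmax(y / C, -20), 0.999)
    zz <- -log1p(-z)
    cf <- stats::lm.wfit(Xo, zz, w)$coefficients
    cf[is.na(cf)] <- 0
    cf
  }

  residFun <- function(par) {
    logC <- par[seq_len(nrep)]
    eps <- par[-seq_len(nrep)]
    Ci <- exp(logC)[as.integer(repId)]
    eta <- drop(Xo %*% eps)
    sw * (y - Ci * (1 - exp(-eta)))
  }
  jacFun <- function(par) {
    logC <- par[seq_len(nrep)]
    eps <- par[-seq_len(nrep)]
    Ci <- exp(logC)[as.integer(repId)]
    eta <- drop(Xo %*% eps)
    e <- exp(-eta)
    Jc <- -sw * (1 - e) * Ci * repMat
    Je <- -sw * Ci * e * Xo
    cbind(Jc, Je)
  }

  yPos <- max(y[w > 0], 1e-3)
  Cgrid <- yPos * exp(seq(log(1.05), log(20), length.out = nStarts))
  best <- NULL
  for (C0 in Cgrid) {
    par0 <- c(rep(log(C0), nrep), profiledStart(C0))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = residFun, jac = jacFun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("cleavage model failed to converge from any start")

  par <- best$par
  Cs <- exp(par[seq_len(nrep)])
  names(Cs) <- levels(repId)
  eps <- par[-seq_len(nrep)]
  names(eps) <- colnames(Xo)
  J <- jacFun(par)
  dof <- sum(w > 0) - length(par)
  sigma2 <- if (dof > 0) best$deviance / dof else 0
  covm <- tryCatch(solve(crossprod(J)) * sigma2,
                   error = function(e)
                     matrix(NA_real_, length(par), length(par)))
  seAll <- sqrt(pmax(diag(covm), 0))
  sesE <- stats::setNames(seAll[-seq_len(nrep)], colnames(Xo))
  .fillEnergyMatrix(eps, sesE, labels, refs, kind = "cleavage", C = Cs,
                    satBound = satBound,
                    diagnostics = list(residualSD = sqrt(sigma2),
                                       deviance = best$deviance,
                                       n = sum(w > 0),
                                       converged = best$info %in% 1:4))
}

#' @describeIn fitBindingEnergyMatrix penalty matrix (4 x positions)
#' @param x an EnergyMatrix
#' @export
setMethod("penalties", "EnergyMatrix", function(x) x@eps)
#' @describeIn fitBindingEnergyMatrix standard errors
#' @export
setMethod("penaltySE", "EnergyMatrix", function(x) x@se)
#' @describeIn fitBindingEnergyMatrix per-entry status flags
#' @export
setMethod("penaltyFlags", "EnergyMatrix", function(x) x@flags)
#' @describeIn fitBindingEnergyMatrix consensus base per position
#' @export
setMethod("refBases", "EnergyMatrix", function(x) x@refBases)
#' @describeIn fitBindingEnergyMatrix exposure scale C (cleavage only)
#' @export
setMethod("saturationScale", "EnergyMatrix", function(x) x@exposureC)
#' @describeIn fitBindingEnergyMatrix "binding" or "cleavage"
#' @export
setMethod("matrixKind", "EnergyMatrix", function(x) x@kind)
#' @describeIn fitBindingEnergyMatrix position labels
#' @export
setMethod("positionLabels", "EnergyMatrix", function(x) x@positions)

setMethod("show", "EnergyMatrix", function(object) {
  cat("EnergyMatrix (", object@kind, ") over ", length(object@positions),
      " positions\n", sep = "")
  if (object@kind == "cleavage")
    cat("  exposure C:",
        paste(sprintf("%s=%.3g", names(object@exposureC), object@exposureC),
              collapse = ", "), "\n")
  ok <- object@flags == "ok"
  if (any(ok))
    cat(sprintf("  mean mismatch penalty: %.3f (range %.3f..%.3f)\n",
                mean(object@eps[ok]), min(object@eps[ok]),
                max(object@eps[ok])))
  nbad <- sum(object@flags == "unidentifiable")
  if (nbad) cat("  unidentifiable entries:", nbad, "\n")
})

#' Convert an energy matrix to position base probabilities
#'
#' Boltzmann weights per position: p(p, b) = exp(-eps(p, b) / tau) /
#' sum_b' exp(-eps(p, b') / tau).  Entries flagged "saturated" are treated
#' as infinite penalties (probability 0); "unidentifiable" entries are
#' excluded from the normalization and returned as NA.
#'
#' @param matrix an [EnergyMatrix-class]
#' @param temperatureScale tau (default 1)
#' @return 4 x positions probability matrix, columns summing to 1
#' @export
matrixToPwm <- function(matrix, temperatureScale = 1) {
  eps <- penalties(matrix)
  eps[penaltyFlags(matrix) == "saturated"] <- Inf
  wts <- exp(-eps / temperatureScale)
  p <- sweep(wts, 2L, colSums(wts, na.rm = TRUE), "/")
  p
}

#' Compare two energy matrices
#'
#' Per-entry penalty differences A - B plus summary statistics: the mean
#' mismatch penalty per position for each matrix, the overall mean penalty
#' reduction of B relative to A (percent), and the positions where any
#' per-base difference exceeds twice the joint standard error.
#'
#' @param A,B [EnergyMatrix-class] objects on the same coordinate frame and
#'   of the same kind
#' @return list: delta (4 x positions matrix), meanPenaltyA, meanPenaltyB
#'   (per position), meanReductionPercent, flaggedPositions
#' @export
compareEnergyMatrices <- function(A, B) {
  if (!identical(positionLabels(A), positionLabels(B)) ||
      !identical(refBases(A), refBases(B)))
    stop("energy matrices are on different coordinate frames")
  if (matrixKind(A) != matrixKind(B))
    stop("energy matrices are of different kinds")
  ok <- penaltyFlags(A) %in% c("ok", "ref") &
        penaltyFlags(B) %in% c("ok", "ref")
  delta <- penalties(A) - penalties(B)
  delta[!ok] <- NA_real_
  mm <- penaltyFlags(A) == "ok" & penaltyFlags(B) == "ok"
  perPosA <- apply(ifelse(mm, penalties(A), NA), 2L, mean, na.rm = TRUE)
  perPosB <- apply(ifelse(mm, penalties(B), NA), 2L, mean, na.rm = TRUE)
  meanA <- mean(penalties(A)[mm])
  meanB <- mean(penalties(B)[mm])
  jointSE <- sqrt(penaltySE(A)^2 + penaltySE(B)^2)
  sig <- abs(delta) > 2 * jointSE & mm
  list(delta = delta,
       meanPenaltyA = perPosA,
       meanPenaltyB = perPosB,
       meanReductionPercent = 100 * (1 - meanB / meanA),
       flaggedPositions = positionLabels(A)[apply(sig, 2L, any, na.rm = TRUE)])
}

#' Write an energy matrix as TSV
#'
#' Long layout: position, base, epsilon, se, flag; cleavage matrices append
#' their C values as comment header lines.
#' @param matrix an [EnergyMatrix-class]
#' @param file path
#' @export
writeEnergyMatrixTSV <- function(matrix, file) {
  df <- data.frame(
    position = rep(positionLabels(matrix), each = 4L),
    base = rep(.DNA_BASES, length(positionLabels(matrix))),
    epsilon = as.vector(penalties(matrix)),
    se = as.vector(penaltySE(matrix)),
    flag = as.vector(penaltyFlags(matrix)))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# kind=", matrixKind(matrix)), con)
  if (matrixKind(matrix) == "cleavage")
    writeLines(paste0("# C ", names(saturationScale(matrix)), "=",
                      saturationScale(matrix)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
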